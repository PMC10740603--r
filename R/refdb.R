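# Taxonomically annotated reference databases: FASTA I/O in the Silva header
# dialect (">id rank1;rank2;...;rankN") and clade-based partitioning.

#' Construct a reference database
#'
#' @param id character vector of unique accessions.
#' @param sequence nucleotide strings; `U` is normalized to `T` and case to
#'   upper. Only IUPAC symbols are accepted after normalization.
#' @param lineage semicolon-separated taxonomy strings (may be empty).
#' @param source_label free-text provenance.
#' @return A `refdb`, a data frame with columns `id`, `lineage`, `sequence`.
#' @export
refdb <- function(id = character(), sequence = character(),
                  lineage = character(0), source_label = "") {
  if (length(lineage) == 0L) lineage <- rep("", length(id))
  stopifnot(length(id) == length(sequence), length(id) == length(lineage))
  if (anyDuplicated(id)) {
    stop("duplicate sequence id(s): ",
         paste(unique(id[duplicated(id)]), collapse = ", "))
  }
  sequence <- chartr("U", "T", toupper(sequence))
  if (length(sequence)) {
    ok <- grepl("^[ACGTMRWSYKVHDBN]+$", sequence)
    if (!all(ok)) {
      stop("record '", id[which(!ok)[1]],
           "' contains non-IUPAC symbols (or is empty) after normalization")
    }
  }
  db <- data.frame(id = as.character(id), lineage = as.character(lineage),
                   sequence = as.character(sequence), stringsAsFactors = FALSE)
  class(db) <- c("refdb", "data.frame")
  attr(db, "source_label") <- source_label
  db
}

#' @export
print.refdb <- function(x, ...) {
  src <- attr(x, "source_label")
  cat(sprintf("<refdb> %d record(s)%s\n", nrow(x),
              if (nzchar(src)) paste0(" [", src, "]") else ""))
  if (nrow(x)) {
    shown <- utils::head(x, 5)
    for (i in seq_len(nrow(shown))) {
      cat(sprintf("  %s  (%d nt)  %s\n", shown$id[i], nchar(shown$sequence[i]),
                  shown$lineage[i]))
    }
    if (nrow(x) > 5) cat("  ...\n")
  }
  invisible(x)
}

# Keep class/attributes when slicing internally.
refdb_slice <- function(db, idx) {
  out <- db[idx, , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("refdb", "data.frame")
  attr(out, "source_label") <- attr(db, "source_label")
  out
}

split_lineage <- function(lineage) {
  lapply(strsplit(lineage, ";", fixed = TRUE), trimws)
}

# Exact whole-rank, case-insensitive clade matching (no substring matches).
lineage_has_clade <- function(lineage, clade) {
  clade <- tolower(trimws(clade))
  vapply(split_lineage(lineage),
         function(r) any(tolower(r) %in% clade), logical(1))
}

#' Read a taxonomically annotated FASTA file
#'
#' In the `silva` dialect the header is `>id lineage` with a
#' semicolon-separated lineage after the first whitespace (tab or space);
#' the `plain` dialect carries no lineage. RNA alphabets are normalized
#' (`U` to `T`) and case is folded to upper.
#'
#' @param path FASTA file.
#' @param dialect `"silva"` or `"plain"`.
#' @param source_label provenance string stored on the result.
#' @return A [refdb].
#' @export
read_fasta_taxonomy <- function(path, dialect = c("silva", "plain"),
                                source_label = basename(path)) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("file not found: ", path)
  set <- tryCatch(
    Biostrings::readBStringSet(path),
    error = function(e) {
      lines <- readLines(path, warn = FALSE)
      bad <- which(nzchar(trimws(lines)))[1]
      if (!is.na(bad) && !startsWith(trimws(lines[bad]), ">")) {
        stop("malformed FASTA in '", path, "': line ", bad,
             " should start a '>' header", call. = FALSE)
      }
      stop("malformed FASTA in '", path, "': ", conditionMessage(e),
           call. = FALSE)
    }
  )
  nm <- names(set)
  id <- sub("[ \t].*$", "", nm)
  lineage <- if (dialect == "silva") {
    ifelse(grepl("[ \t]", nm), trimws(sub("^[^ \t]+[ \t]+", "", nm)), "")
  } else {
    rep("", length(nm))
  }
  refdb(id = id, sequence = as.character(set), lineage = lineage,
        source_label = source_label)
}

#' Write a reference database as Silva-dialect FASTA
#'
#' @param db a [refdb].
#' @param path output file.
#' @param width line width for the sequence block.
#' @return `path`, invisibly.
#' @export
write_fasta_taxonomy <- function(db, path, width = 70L) {
  set <- Biostrings::BStringSet(db$sequence)
  names(set) <- ifelse(nzchar(db$lineage), paste(db$id, db$lineage), db$id)
  Biostrings::writeXStringSet(set, path, width = width)
  invisible(path)
}

#' Partition a reference database into host, excluded and non-target sets
#'
#' A record whose lineage contains the host clade is host *even if* it also
#' contains an excluded clade: the host clade is typically nested inside an
#' excluded one (a snail is a metazoan), and both a host database and a
#' host-free, metazoan-free database must be constructible from one source.
#'
#' @param db a [refdb].
#' @param host_clade clade name defining the host set (exact whole-rank,
#'   case-insensitive match).
#' @param exclude_clades clade names removed from the non-target set.
#' @return A list with `refdb` elements `host`, `non_target`, `excluded`;
#'   the three partition `db` exactly.
#' @export
partition_by_taxonomy <- function(db, host_clade, exclude_clades = character()) {
  stopifnot(nzchar(host_clade))
  if (length(exclude_clades) && any(!nzchar(exclude_clades))) {
    stop("empty exclude clade name")
  }
  is_host <- lineage_has_clade(db$lineage, host_clade)
  is_excl <- rep(FALSE, nrow(db))
  for (cl in exclude_clades) {
    is_excl <- is_excl | lineage_has_clade(db$lineage, cl)
  }
  is_excl <- is_excl & !is_host
  if (nrow(db) > 0L && !any(is_host)) {
    warning("host clade '", host_clade, "' not found in any lineage")
  }
  list(
    host = refdb_slice(db, is_host),
    non_target = refdb_slice(db, !is_host & !is_excl),
    excluded = refdb_slice(db, is_excl)
  )
}

#' Subset a reference database to one clade
#'
#' @param db a [refdb].
#' @param clade clade name (exact whole-rank, case-insensitive).
#' @return A [refdb] with the matching records, input order preserved.
#' @export
subset_to_clade <- function(db, clade) {
  refdb_slice(db, lineage_has_clade(db$lineage, clade))
}

#' Export a partition as TSV
#'
#' Writes one row per record: `id`, `lineage`, `partition` (host /
#' non_target / excluded).
#'
#' @param parts result of [partition_by_taxonomy()].
#' @param path output TSV.
#' @return `path`, invisibly.
#' @export
export_partition_tsv <- function(parts, path) {
  rows <- do.call(rbind, lapply(names(parts), function(p) {
    d <- parts[[p]]
    if (!nrow(d)) return(NULL)
    data.frame(id = d$id, lineage = d$lineage, partition = p,
               stringsAsFactors = FALSE)
  }))
  if (is.null(rows)) {
    rows <- data.frame(id = character(), lineage = character(),
                       partition = character())
  }
  utils::write.table(rows, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
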