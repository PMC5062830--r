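# Readers and writers for the plain-text formats the pipeline consumes:
# FASTA alignments, two-column population maps, coordinate tables.

#' Read a FASTA alignment into a character matrix
#'
#' Sequences are uppercased and `U` is normalized to `T`. All sequences
#' must have equal length; duplicate labels are rejected.
#'
#' @param path FASTA file path.
#' @return Character matrix, one row per sequence, labelled rownames.
#' @export
read_fasta <- function(path) {
  ln <- readLines(path)
  ln <- ln[nzchar(trimws(ln))]
  if (!length(ln)) stop_invalid("empty alignment: %s", path)
  is_hdr <- startsWith(ln, ">")
  if (!is_hdr[1]) stop_invalid("not a FASTA file: %s", path)
  grp <- cumsum(is_hdr)
  labels <- sub("^>\\s*", "", ln[is_hdr])
  labels <- sub("\\s.*$", "", labels)
  if (anyDuplicated(labels)) {
    stop_invalid("duplicate FASTA labels: %s",
                 paste(unique(labels[duplicated(labels)]), collapse = ", "))
  }
  seqs <- vapply(split(ln[!is_hdr], grp[!is_hdr]),
                 function(x) paste(x, collapse = ""), "")
  if (length(seqs) != length(labels)) stop_invalid("malformed FASTA: %s", path)
  seqs <- chartr("u", "T", toupper(seqs))
  seqs <- chartr("U", "T", seqs)
  lens <- nchar(seqs)
  if (length(unique(lens)) != 1) {
    bad <- labels[which(lens != lens[1])[1]]
    stop_invalid("ragged alignment: sequence '%s' has length %d, expected %d",
                 bad, nchar(seqs[labels == bad][1]), lens[1])
  }
  m <- matrix(unlist(strsplit(seqs, "")), nrow = length(seqs), byrow = TRUE)
  rownames(m) <- labels
  m
}

#' Write a character-matrix alignment to FASTA
#'
#' @param aln character matrix with labelled rows.
#' @param path output path.
#' @param width line width for wrapping (default 70).
#' @return `path`, invisibly.
#' @export
write_fasta <- function(aln, path, width = 70) {
  if (is.null(rownames(aln))) stop_invalid("alignment rows must be labelled")
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_len(nrow(aln))) {
    s <- paste(aln[i, ], collapse = "")
    chunks <- substring(s, seq(1, nchar(s), width),
                        pmin(seq(1, nchar(s), width) + width - 1, nchar(s)))
    writeLines(c(paste0(">", rownames(aln)[i]), chunks), con)
  }
  invisible(path)
}

#' Read a two-column population map
#'
#' Tab-separated file with columns `label` and `population` (header
#' optional). Duplicate labels are rejected.
#'
#' @param path file path.
#' @return Data frame with columns `label`, `population`.
#' @export
read_popmap <- function(path) {
  first <- readLines(path, n = 1)
  has_header <- grepl("^label\\b", first)
  df <- read.table(path, sep = "\t", header = has_header,
                   stringsAsFactors = FALSE)
  if (ncol(df) < 2) stop_invalid("population map must have two columns")
  df <- df[, 1:2]
  names(df) <- c("label", "population")
  if (anyDuplicated(df$label)) {
    stop_invalid("duplicate labels in population map: %s",
                 paste(unique(df$label[duplicated(df$label)]), collapse = ", "))
  }
  if (!nrow(df)) stop_invalid("empty population map")
  df
}

#' Check that a population map covers an alignment
#'
#' @param aln labelled alignment matrix.
#' @param popmap data frame from [read_popmap()].
#' @return Invisibly `TRUE`; errors listing unmapped labels otherwise.
#' @export
validate_popmap <- function(aln, popmap) {
  missing <- setdiff(rownames(aln), popmap$label)
  if (length(missing)) {
    stop_invalid("alignment labels missing from population map: %s",
                 paste(head(missing, 10), collapse = ", "))
  }
  invisible(TRUE)
}

#' Read a coordinates table
#'
#' Tab-separated with columns `pop`, `lat`, `lon`.
#'
#' @param path file path.
#' @return Data frame.
#' @export
read_coordinates <- function(path) {
  df <- read.table(path, sep = "\t", header = TRUE,
                   stringsAsFactors = FALSE)
  need <- c("pop", "lat", "lon")
  if (!all(need %in% names(df))) {
    stop_invalid("coordinates table needs columns: %s",
                 paste(need, collapse = ", "))
  }
  df
}
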