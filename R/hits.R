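HIT_COLUMNS <- c(
  "query_id", "subject_id", "percent_identity", "alignment_length",
  "mismatches", "gap_opens", "q_start", "q_end", "s_start", "s_end",
  "evalue", "bitscore"
)

#' Read a 12-column BLAST tabular hit list
#'
#' The standard `-outfmt 6` layout: query, subject, percent identity,
#' alignment length, mismatches, gap opens, query start/end, subject
#' start/end, e-value, bit score. Row order is preserved.
#'
#' @param path Tab-separated file, 12 columns, no header.
#' @return A `data.frame` with columns [HIT_COLUMNS] (class `hit_table`).
#' @export
read_hits <- function(path) {
  if (!file.exists(path)) rc_format_error(paste0("no such file: ", path))
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  if (!length(lines)) {
    out <- as.data.frame(setNames(
      c(
        list(character(), character()), replicate(9, numeric(), simplify = FALSE),
        list(numeric())
      ), HIT_COLUMNS
    ))
    class(out) <- c("hit_table", "data.frame")
    return(out)
  }
  parts <- strsplit(lines, "\t", fixed = TRUE)
  nc <- lengths(parts)
  if (any(nc != 12L)) {
    rc_format_error(paste0(
      "line ", which(nc != 12L)[1], " of ", path, " has ", nc[nc != 12L][1],
      " columns (expected 12)"
    ))
  }
  m <- do.call(rbind, parts)
  num <- suppressWarnings(apply(m[, 3:12, drop = FALSE], 2, as.numeric))
  num <- matrix(num, ncol = 10)
  if (anyNA(num)) {
    bad <- which(rowSums(is.na(num)) > 0)[1]
    rc_format_error(paste0("non-numeric field on line ", bad, " of ", path))
  }
  out <- data.frame(
    query_id = m[, 1], subject_id = m[, 2],
    percent_identity = num[, 1], alignment_length = num[, 2],
    mismatches = num[, 3], gap_opens = num[, 4],
    q_start = num[, 5], q_end = num[, 6], s_start = num[, 7], s_end = num[, 8],
    evalue = num[, 9], bitscore = num[, 10],
    stringsAsFactors = FALSE
  )
  if (any(out$evalue < 0)) rc_format_error("negative e-value in hit list")
  if (any(out$q_start > out$q_end)) {
    rc_format_error("query start greater than query end in hit list")
  }
  class(out) <- c("hit_table", "data.frame")
  out
}

#' Write a hit table in BLAST tabular form
#'
#' @param hits A `hit_table` / data frame with [HIT_COLUMNS].
#' @param path Output path (12-column TSV, no header).
#' @return `path`, invisibly.
#' @export
write_hits <- function(hits, path) {
  con <- file(path, open = "wb")
  on.exit(close(con))
  write.table(hits[, HIT_COLUMNS, drop = FALSE], con,
    sep = "\t", quote = FALSE,
    row.names = FALSE, col.names = FALSE, fileEncoding = "UTF-8", eol = "\n"
  )
  invisible(path)
}

#' Read domain locations
#'
#' Tab-separated with header columns `protein_id`, `domain_id`, `start`,
#' `end`, `protein_length`; residue coordinates are 1-based inclusive
#' (BLAST/Pfam convention) and are validated against the protein length.
#'
#' @param path Domain TSV path.
#' @return A `data.frame` of domain hits.
#' @export
read_domains <- function(path) {
  if (!file.exists(path)) rc_format_error(paste0("no such file: ", path))
  d <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("protein_id", "domain_id", "start", "end", "protein_length")
  if (!all(need %in% names(d))) {
    rc_format_error(paste0(
      "domain file ", path, " must have columns: ", paste(need, collapse = ", ")
    ))
  }
  validate_domains(d)
}

validate_domains <- function(d) {
  bad <- d$start < 1 | d$start > d$end | d$end > d$protein_length
  if (any(bad)) {
    rc_validation_error(paste0(
      "invalid domain coordinates for: ",
      paste(unique(d$protein_id[bad]), collapse = ", ")
    ))
  }
  d
}
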