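#' Amino-acid alphabet accepted by the toolkit
#'
#' Twenty canonical residues plus ambiguity/rare codes X, B, Z, U
#' (selenocysteine) and O (pyrrolysine).
#'
#' @keywords internal
AA_ALPHABET <- strsplit("ACDEFGHIKLMNPQRSTVWYXBZUO", "")[[1]]

#' Default model-organism taxon labels
#'
#' The twelve taxa used to prefer model-organism members during
#' representative selection: nine Gene Ontology reference genomes plus cow,
#' dog and pig. Matching is by prefix, so "Gallus" covers "Gallus gallus".
#'
#' @return Character vector of taxon labels.
#' @export
#' @examples
#' model_organisms()
model_organisms <- function() {
  c(
    "Arabidopsis thaliana", "Caenorhabditis elegans", "Danio rerio",
    "Drosophila melanogaster", "Gallus", "Homo sapiens", "Mus musculus",
    "Rattus norvegicus", "Saccharomyces cerevisiae",
    "Bos taurus", "Canis familiaris", "Sus scrofa"
  )
}

#' Construct a validated set of protein records
#'
#' The central sequence container: one row per protein with the metadata that
#' drives representative selection (curation status, name, organism, length).
#'
#' @param id Character vector of unique, non-empty accessions.
#' @param sequence Uppercase amino-acid strings over [AA_ALPHABET].
#' @param reviewed Logical; curated (Swiss-Prot-like) entries are `TRUE`.
#' @param protein_name Free-text protein names.
#' @param organism Taxon labels ("" when unknown).
#' @param is_fragment Logical fragment flags.
#' @param model_taxa Taxon labels used to derive `is_model_organism`
#'   (prefix match on `organism`).
#'
#' @return A `data.frame` of class `protein_records` with columns `id`,
#'   `sequence`, `length`, `reviewed`, `protein_name`, `organism`,
#'   `is_fragment`, `is_model_organism`.
#' @export
#' @examples
#' protein_records(c("P1", "P2"), c("MKV", "MKVLA"), reviewed = c(TRUE, FALSE))
protein_records <- function(id, sequence, reviewed = FALSE,
                            protein_name = "", organism = "",
                            is_fragment = FALSE,
                            model_taxa = model_organisms()) {
  n <- length(id)
  rec <- data.frame(
    id = as.character(id),
    sequence = toupper(as.character(sequence)),
    length = nchar(sequence),
    reviewed = rep_len(as.logical(reviewed), n),
    protein_name = rep_len(as.character(protein_name), n),
    organism = rep_len(as.character(organism), n),
    is_fragment = rep_len(as.logical(is_fragment), n),
    stringsAsFactors = FALSE
  )
  rec$is_model_organism <- vapply(
    rec$organism,
    function(o) nzchar(o) && any(startsWith(o, model_taxa)),
    logical(1), USE.NAMES = FALSE
  )
  class(rec) <- c("protein_records", "data.frame")
  validate_protein_records(rec)
}

#' @rdname protein_records
#' @param x A `protein_records` object to validate.
#' @export
validate_protein_records <- function(x) {
  if (any(!nzchar(x$id))) rc_validation_error("protein ids must be non-empty")
  dup <- unique(x$id[duplicated(x$id)])
  if (length(dup)) {
    rc_validation_error(paste0(
      "duplicate protein id(s): ", paste(dup, collapse = ", ")
    ))
  }
  if (any(x$length < 1)) {
    bad <- x$id[x$length < 1]
    rc_validation_error(paste0(
      "empty sequence for record(s): ", paste(bad, collapse = ", ")
    ))
  }
  ok <- grepl(paste0("^[", paste(AA_ALPHABET, collapse = ""), "]+$"), x$sequence)
  if (any(!ok)) {
    rc_validation_error(paste0(
      "sequence with characters outside the amino-acid alphabet: ",
      paste(x$id[!ok], collapse = ", ")
    ))
  }
  stopifnot(identical(x$length, nchar(x$sequence)))
  x
}

# Parse one UniProt-style FASTA header ("sp|ACC|ENTRY Name ... OS=Taxon ...").
parse_uniprot_header <- function(header, entry_index) {
  m <- regmatches(header, regexec("^(sp|tr)\\|([^| ]+)\\|(\\S+)\\s*(.*)$", header))[[1]]
  if (!length(m)) {
    rc_format_error(paste0(
      "malformed uniprot header at entry ", entry_index, ": '>", header, "'"
    ))
  }
  rest <- m[5]
  # the description runs up to the first KEY= token (OS=, OX=, GN=, PE=, SV=...)
  desc <- sub("\\s*[A-Z]{2}=.*$", "", rest)
  organism <- ""
  os <- regmatches(rest, regexec("OS=(.*?)(\\s+[A-Z]{2}=|$)", rest))[[1]]
  if (length(os)) organism <- trimws(os[2])
  list(
    id = m[3],
    reviewed = identical(m[2], "sp"),
    protein_name = trimws(desc),
    organism = organism,
    is_fragment = grepl("(Fragment)", rest, fixed = TRUE)
  )
}

#' Read protein sequences from FASTA
#'
#' @param path Path to a FASTA file.
#' @param header_dialect `"uniprot"` parses `sp|ACC|ENTRY Name OS=Taxon`
#'   headers (sp/tr sets the reviewed flag, `OS=` the organism, a
#'   `(Fragment)` token the fragment flag); `"plain"` takes the first
#'   whitespace-delimited token as the id and applies defaults (unreviewed,
#'   no organism, not a fragment).
#' @param model_taxa Taxa used to flag model-organism records.
#'
#' @return A [protein_records] data frame, one row per FASTA entry.
#' @export
#' @examples
#' fa <- tempfile(fileext = ".fasta")
#' writeLines(c(">sp|P00001|A_HUMAN Kinase OS=Homo sapiens", "MKV"), fa)
#' read_fasta(fa, "uniprot")
read_fasta <- function(path, header_dialect = c("uniprot", "plain"),
                       model_taxa = model_organisms()) {
  header_dialect <- match.arg(header_dialect)
  if (!file.exists(path)) rc_format_error(paste0("no such file: ", path))
  seqs <- Biostrings::readAAStringSet(path)
  if (length(seqs) == 0L) {
    return(protein_records(character(), character(), model_taxa = model_taxa))
  }
  headers <- names(seqs)
  widths <- Biostrings::width(seqs)
  if (any(widths == 0L)) {
    rc_format_error(paste0(
      "empty sequence for entry: '>", headers[which(widths == 0L)[1]], "'"
    ))
  }
  if (header_dialect == "uniprot") {
    meta <- lapply(seq_along(headers), function(i) {
      parse_uniprot_header(headers[i], i)
    })
    rec <- protein_records(
      id = vapply(meta, `[[`, character(1), "id"),
      sequence = as.character(seqs),
      reviewed = vapply(meta, `[[`, logical(1), "reviewed"),
      protein_name = vapply(meta, `[[`, character(1), "protein_name"),
      organism = vapply(meta, `[[`, character(1), "organism"),
      is_fragment = vapply(meta, `[[`, logical(1), "is_fragment"),
      model_taxa = model_taxa
    )
  } else {
    ids <- sub("\\s.*$", "", headers)
    names_ <- trimws(sub("^\\S+\\s*", "", headers))
    rec <- protein_records(
      id = ids, sequence = as.character(seqs),
      protein_name = names_, model_taxa = model_taxa
    )
  }
  rec
}

#' Write protein records to FASTA
#'
#' Inverse of [read_fasta()]: the uniprot dialect reconstructs
#' `sp|ACC|ACC Name OS=Taxon` headers; the plain dialect writes `id name`.
#'
#' @param records A [protein_records] data frame.
#' @param path Output path.
#' @param header_dialect As in [read_fasta()].
#' @return `path`, invisibly.
#' @export
write_fasta <- function(records, path, header_dialect = c("uniprot", "plain")) {
  header_dialect <- match.arg(header_dialect)
  lines <- character(0)
  if (nrow(records)) {
    headers <- if (header_dialect == "uniprot") {
      paste0(
        ifelse(records$reviewed, "sp|", "tr|"), records$id, "|", records$id,
        ifelse(nzchar(records$protein_name), paste0(" ", records$protein_name), ""),
        ifelse(records$is_fragment, " (Fragment)", ""),
        ifelse(nzchar(records$organism), paste0(" OS=", records$organism), "")
      )
    } else {
      paste0(
        records$id,
        ifelse(nzchar(records$protein_name), paste0(" ", records$protein_name), "")
      )
    }
    lines <- as.vector(rbind(paste0(">", headers), records$sequence))
  }
  writeLines(lines, path, sep = "\n")
  invisible(path)
}
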