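#' Alignment scoring configuration
#'
#' Defaults follow common protein-clustering practice: BLOSUM62
#' substitution scores with affine gap penalties (open 10, extend 1).
#' `identity_denominator` selects the convention for the identity fraction:
#' `"shorter"` (identical residues over the shorter sequence's length, the
#' CD-HIT convention and the package default) or `"alignment"` (over the
#' aligned length).
#'
#' @param gap_opening,gap_extension Non-negative gap penalties.
#' @param substitution_matrix Name of a Biostrings matrix (e.g. "BLOSUM62").
#' @param identity_denominator `"shorter"` or `"alignment"`.
#' @return A `scoring_config` list.
#' @export
scoring_config <- function(gap_opening = 10, gap_extension = 1,
                           substitution_matrix = "BLOSUM62",
                           identity_denominator = c("shorter", "alignment")) {
  identity_denominator <- match.arg(identity_denominator)
  structure(
    list(
      gap_opening = gap_opening, gap_extension = gap_extension,
      substitution_matrix = substitution_matrix,
      identity_denominator = identity_denominator
    ),
    class = "scoring_config"
  )
}

# BLOSUM62 extended with U (selenocysteine) and O (pyrrolysine), which the
# shipped matrix lacks: self-match +1, anything else -4.
refclust_submat <- local({
  cache <- NULL
  function(name = "BLOSUM62") {
    if (!is.null(cache) && identical(attr(cache, "name"), name)) {
      return(cache)
    }
    env <- new.env()
    data(list = name, package = "Biostrings", envir = env)
    m <- env[[name]]
    extra <- setdiff(c("U", "O"), rownames(m))
    for (aa in extra) {
      m <- rbind(m, setNames(rep(-4L, ncol(m)), colnames(m)))
      rownames(m)[nrow(m)] <- aa
      m <- cbind(m, setNames(rep(-4L, nrow(m)), rownames(m)))
      colnames(m)[ncol(m)] <- aa
      m[aa, aa] <- 1L
    }
    attr(m, "name") <- name
    cache <<- m
    cache
  }
})

# Vectorized core: semi-global (end gaps free) alignment of each member
# sequence against one seed sequence. Returns identity fraction and the
# fraction of the seed covered by the aligned span.
align_stats_many <- function(member_seqs, seed_seq, config = scoring_config()) {
  canonical <- "[ACDEFGHIKLMNPQRSTVWY]"
  degenerate <- !grepl(canonical, c(member_seqs, seed_seq))
  if (any(degenerate)) {
    rc_abort(
      "sequence(s) consist only of ambiguity characters; alignment is degenerate",
      "refclust_alignment_degenerate"
    )
  }
  aln <- Biostrings::pairwiseAlignment(
    Biostrings::AAStringSet(member_seqs), Biostrings::AAString(seed_seq),
    type = "overlap",
    substitutionMatrix = refclust_submat(config$substitution_matrix),
    gapOpening = config$gap_opening, gapExtension = config$gap_extension
  )
  ident <- Biostrings::nmatch(aln)
  denom <- switch(config$identity_denominator,
    shorter = pmin(nchar(member_seqs), nchar(seed_seq)),
    alignment = Biostrings::nchar(aln)
  )
  span <- IRanges::end(Biostrings::subject(aln)) -
    IRanges::start(Biostrings::subject(aln)) + 1L
  data.frame(
    identity_fraction = ident / denom,
    seed_coverage = span / nchar(seed_seq),
    score = Biostrings::score(aln)
  )
}

#' Pairwise identity and seed coverage between a seed and a member
#'
#' Semi-global alignment (end gaps free) of `b` against the seed `a` under
#' the configured substitution scheme. The identity fraction is the number
#' of identical aligned residues divided by the shorter sequence's length
#' (see [scoring_config()]); the seed coverage is the fraction of the seed's
#' residues inside the aligned span. Both drive the 90/50-level clustering
#' rules: membership requires identity at or above the level threshold and
#' seed coverage of at least 80%.
#'
#' @param a Seed [protein_records] row (or any one-row records object);
#'   must be at least as long as `b`.
#' @param b Member record (one row).
#' @param config A [scoring_config()].
#' @return A one-row `data.frame` with `identity_fraction` and
#'   `seed_coverage`, both in `[0, 1]`.
#' @export
#' @examples
#' r <- protein_records(c("S", "M"), c("MKVLAWGHED", "MKVLA"))
#' align_identity(r[1, ], r[2, ])
align_identity <- function(a, b, config = scoring_config()) {
  a_seq <- if (is.data.frame(a)) a$sequence[1] else as.character(a)
  b_seq <- if (is.data.frame(b)) b$sequence[1] else as.character(b)
  if (!nzchar(a_seq) || !nzchar(b_seq)) {
    rc_validation_error("both sequences must be non-empty")
  }
  if (nchar(a_seq) < nchar(b_seq)) {
    rc_validation_error("the seed 'a' must be at least as long as 'b'")
  }
  st <- align_stats_many(b_seq, a_seq, config)
  data.frame(
    identity_fraction = st$identity_fraction,
    seed_coverage = st$seed_coverage
  )
}
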