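#' Expand seed-database hits with cluster members
#'
#' Replaces each hit on a cluster seed (or representative) by hits on every
#' member of that cluster; expanded hits inherit the seed hit's e-value and
#' bit score (expansion happens after the search, without re-scoring). A
#' subject reachable through several seeds keeps its best (lowest) e-value.
#' Hits are ordered per query by e-value ascending, then bit score
#' descending, then subject id.
#'
#' @param hits A `hit_table` (see [read_hits()]) whose subjects are cluster
#'   seeds or representatives.
#' @param clusters The [cluster_set()] used for expansion (typically the
#'   50% level, whose members cover the whole corpus).
#' @return A `data.frame` (class `expanded_hits`) with columns `query_id`,
#'   `subject_id`, `evalue`, `bitscore`, `origin_seed_id`, `cluster_id`.
#' @export
expand_hits <- function(hits, clusters) {
  lookup <- character(0)
  for (k in seq_along(clusters$clusters)) {
    cl <- clusters$clusters[[k]]
    lookup[cl$seed_id] <- cl$cluster_id
    lookup[cl$representative_id] <- cl$cluster_id
  }
  unknown <- setdiff(unique(hits$subject_id), names(lookup))
  if (length(unknown)) {
    rc_validation_error(paste0(
      "subject(s) are not seeds or representatives of any cluster: ",
      paste(head(unknown, 5), collapse = ", ")
    ))
  }
  by_id <- setNames(
    clusters$clusters,
    vapply(clusters$clusters, `[[`, character(1), "cluster_id")
  )
  pieces <- lapply(seq_len(nrow(hits)), function(i) {
    cl <- by_id[[lookup[[hits$subject_id[i]]]]]
    data.frame(
      query_id = hits$query_id[i], subject_id = cl$member_ids,
      evalue = hits$evalue[i], bitscore = hits$bitscore[i],
      origin_seed_id = hits$subject_id[i], cluster_id = cl$cluster_id,
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, c(pieces, list(data.frame(
    query_id = character(), subject_id = character(), evalue = numeric(),
    bitscore = numeric(), origin_seed_id = character(), cluster_id = character()
  ))))
  # best e-value per (query, subject); ties by bit score then subject id
  out <- out[order(out$query_id, out$evalue, -out$bitscore, out$subject_id), , drop = FALSE]
  out <- out[!duplicated(out[, c("query_id", "subject_id")]), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("expanded_hits", "data.frame")
  out
}

#' Precision and recall of an expanded search against a reference search
#'
#' True positives are the hits common to both searches; precision divides by
#' the expanded search's hit count and recall by the reference search's
#' (the reference is treated as all-true). Inputs may be character vectors
#' of subject ids (already thresholded) or data frames with `subject_id`
#' and `evalue` columns, in which case hits with
#' `evalue < evalue_threshold` are kept before comparison.
#'
#' @param expanded,reference Hit sets (see above).
#' @param evalue_threshold E-value cut applied to data-frame inputs
#'   (default 1e-4).
#' @return A list: `true_positive`, `precision`, `recall`, `n_expanded`,
#'   `n_reference`, plus `precision_defined` / `recall_defined` flags (a
#'   degenerate empty side yields `NA` with the flag unset, not an error).
#' @export
precision_recall <- function(expanded, reference, evalue_threshold = 1e-4) {
  as_set <- function(x) {
    if (is.data.frame(x)) {
      unique(x$subject_id[x$evalue < evalue_threshold])
    } else {
      unique(as.character(x))
    }
  }
  e <- as_set(expanded)
  r <- as_set(reference)
  tp <- length(intersect(e, r))
  list(
    true_positive = tp,
    precision = if (length(e)) tp / length(e) else NA_real_,
    recall = if (length(r)) tp / length(r) else NA_real_,
    n_expanded = length(e), n_reference = length(r),
    precision_defined = length(e) > 0L,
    recall_defined = length(r) > 0L
  )
}

#' Build truth query-target pairs from shared domains spanning the target
#'
#' A pair (query, target) is kept when the two proteins share at least one
#' domain id and the shared-domain hits on the target span more than
#' `coverage_threshold` of the target's length. In `"union"` mode (default)
#' the spans of all shared-domain hits are merged (overlaps counted once);
#' `"single"` mode requires one shared-domain hit alone to exceed the
#' threshold.
#'
#' @param query_ids Query protein ids.
#' @param domain_hits Domain table as from [read_domains()].
#' @param coverage_threshold Fraction of the target that must be covered
#'   (strictly exceeded; default 0.80).
#' @param mode `"union"` or `"single"`.
#' @return A `data.frame` (class `pair_set`): `query_id`, `target_id`,
#'   `domains` (semicolon-joined shared domain ids used), and
#'   `covered_fraction`.
#' @export
build_domain_pairs <- function(query_ids, domain_hits,
                               coverage_threshold = 0.80,
                               mode = c("union", "single")) {
  mode <- match.arg(mode)
  d <- validate_domains(domain_hits)
  doms_of <- lapply(split(d$domain_id, d$protein_id), unique)
  len_of <- tapply(d$protein_length, d$protein_id, `[`, 1)
  out <- list()
  for (q in intersect(unique(query_ids), names(doms_of))) {
    qd <- doms_of[[q]]
    for (t in names(doms_of)) {
      if (t == q) next
      shared <- intersect(qd, doms_of[[t]])
      if (!length(shared)) next
      ht <- d[d$protein_id == t & d$domain_id %in% shared, , drop = FALSE]
      covered <- if (mode == "union") {
        sum(IRanges::width(IRanges::reduce(IRanges::IRanges(ht$start, ht$end))))
      } else {
        max(ht$end - ht$start + 1L)
      }
      frac <- covered / len_of[[t]]
      if (frac > coverage_threshold) {
        out[[length(out) + 1L]] <- data.frame(
          query_id = q, target_id = t,
          domains = paste(sort(shared), collapse = ";"),
          covered_fraction = frac, stringsAsFactors = FALSE
        )
      }
    }
  }
  out <- do.call(rbind, c(out, list(data.frame(
    query_id = character(), target_id = character(), domains = character(),
    covered_fraction = numeric()
  ))))
  out <- out[order(out$query_id, out$target_id), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("pair_set", "data.frame")
  out
}

#' Percent difference in detected related sequences
#'
#' `100 * (n_uniref - n_reference) / n_reference`, the per-query comparison
#' of cluster-expanded versus reference-database detection counts. A zero
#' reference with a positive expanded count is flagged infinite and binned
#' as ">250%"; two zero counts are flagged undefined.
#'
#' @param n_uniref_detected,n_reference_detected Non-negative counts.
#' @return A list: `percent`, `bin` (one of "<0%", "0%", "(0,50]%",
#'   "(50,100]%", "(100,250]%", ">250%"), `infinite`, `defined`.
#' @export
detection_percent_difference <- function(n_uniref_detected, n_reference_detected) {
  stopifnot(n_uniref_detected >= 0, n_reference_detected >= 0)
  if (n_reference_detected == 0 && n_uniref_detected == 0) {
    return(list(percent = NA_real_, bin = NA_character_, infinite = FALSE, defined = FALSE))
  }
  if (n_reference_detected == 0) {
    return(list(percent = Inf, bin = ">250%", infinite = TRUE, defined = TRUE))
  }
  pct <- 100 * (n_uniref_detected - n_reference_detected) / n_reference_detected
  bin <- if (pct < 0) {
    "<0%"
  } else if (pct == 0) {
    "0%"
  } else if (pct <= 50) {
    "(0,50]%"
  } else if (pct <= 100) {
    "(50,100]%"
  } else if (pct <= 250) {
    "(100,250]%"
  } else {
    ">250%"
  }
  list(percent = pct, bin = bin, infinite = FALSE, defined = TRUE)
}

#' ROC50 score of a ranked hit list
#'
#' Area under the ROC curve truncated at the 50th false positive,
#' normalized to `[0, 1]`: walking the ranking, each of the first
#' `min(50, total FP)` false positives contributes the number of true
#' positives seen before it, and the sum is divided by
#' `n_false_used * n_true` where `n_true` is the number of truth positives
#' for the query. Perfect separation scores 1.0; fifty false positives
#' before any true positive scores 0.0. A ranking with no false positive at
#' all scores the retrieved fraction of truth positives.
#'
#' @param ranked_hits Character vector of subject ids in ranking order
#'   (best first), or an `expanded_hits` data frame for a single query
#'   (its invariant ordering is used).
#' @param truth_pairs Character vector of positive subject ids for the
#'   query (or a `pair_set` restricted to the query, whose `target_id`
#'   column is used).
#' @param max_fp Truncation point (default 50).
#' @return A list: `value` in `[0, 1]`, `n_false_used`, `n_true`,
#'   `defined` (`FALSE`, with `NA` value, when the truth set is empty).
#' @export
roc50 <- function(ranked_hits, truth_pairs, max_fp = 50L) {
  subjects <- if (is.data.frame(ranked_hits)) {
    ranked_hits[order(ranked_hits$evalue, -ranked_hits$bitscore, ranked_hits$subject_id), ]$subject_id
  } else {
    as.character(ranked_hits)
  }
  positives <- unique(if (is.data.frame(truth_pairs)) truth_pairs$target_id else as.character(truth_pairs))
  n_true <- length(positives)
  if (n_true == 0L) {
    return(list(value = NA_real_, n_false_used = 0L, n_true = 0L, defined = FALSE))
  }
  is_tp <- subjects %in% positives
  n_fp_total <- sum(!is_tp)
  n_false_used <- min(max_fp, n_fp_total)
  if (n_false_used == 0L) {
    return(list(
      value = sum(is_tp) / n_true,
      n_false_used = 0L, n_true = n_true, defined = TRUE
    ))
  }
  # cumsum at an FP position counts exactly the TPs ranked before it
  tp_seen <- cumsum(is_tp)
  fp_positions <- which(!is_tp)[seq_len(n_false_used)]
  total <- sum(tp_seen[fp_positions])
  list(
    value = total / (n_false_used * n_true),
    n_false_used = n_false_used, n_true = n_true, defined = TRUE
  )
}
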