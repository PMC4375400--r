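#' Transitive closure of a term over is_a edges
#'
#' Ancestors follow child-to-parent links up to the root; offspring follow
#' them downwards. The term itself is excluded, obsolete terms never appear,
#' and every distinct term counts once regardless of path multiplicity.
#'
#' @param dag A [go_dag].
#' @param term_id A non-obsolete term id.
#' @param direction `"ancestors"` or `"offspring"`.
#' @return Character vector of term ids (sorted).
#' @export
#' @examples
#' dag <- go_dag(
#'   data.frame(id = c("GO:R", "GO:A", "GO:B"), name = "", obsolete = FALSE),
#'   data.frame(child = c("GO:A", "GO:B"), parent = c("GO:R", "GO:A"))
#' )
#' go_closure(dag, "GO:B", "ancestors")
go_closure <- function(dag, term_id, direction = c("ancestors", "offspring")) {
  direction <- match.arg(direction)
  check_live_term(dag, term_id)
  mode <- if (direction == "ancestors") "out" else "in"
  reach <- igraph::subcomponent(dag$graph, term_id, mode = mode)
  sort(setdiff(names(reach), term_id))
}

check_live_term <- function(dag, term_id) {
  i <- match(term_id, dag$terms$id)
  if (is.na(i)) rc_validation_error(paste0("unknown term: ", term_id))
  if (dag$terms$obsolete[i]) {
    rc_validation_error(paste0("term is obsolete: ", term_id))
  }
  invisible(TRUE)
}

#' Term specificity from closure counts
#'
#' The specificity of a term is
#' `P = 1 - n_offspring / (n_offspring + n_ancestors)`, where both counts
#' are distinct-term transitive closures excluding the term itself. A term
#' is more specific when it has more ancestors than descendants: a leaf
#' (no descendants) scores exactly 1.0 and the root (no ancestors) exactly
#' 0.0.
#'
#' @param dag A [go_dag].
#' @param term_id A non-obsolete term id.
#' @return A one-row `data.frame` with `term_id`, `P`, `n_offspring`,
#'   `n_ancestors`.
#' @export
go_specificity <- function(dag, term_id) {
  n_off <- length(go_closure(dag, term_id, "offspring"))
  n_anc <- length(go_closure(dag, term_id, "ancestors"))
  if (n_off + n_anc == 0L) {
    rc_validation_error(paste0(
      "term ", term_id, " is isolated (no ancestors, no offspring); ",
      "specificity is undefined"
    ))
  }
  data.frame(
    term_id = term_id,
    P = 1 - n_off / (n_off + n_anc),
    n_offspring = n_off, n_ancestors = n_anc,
    stringsAsFactors = FALSE
  )
}

# is x a strict descendant of any term in set?
is_descendant_of_any <- function(dag, x, set) {
  anc <- go_closure(dag, x, "ancestors")
  any(set %in% anc)
}

#' Categorize a cluster's members by molecular-function consistency
#'
#' The five-way ladder over the members' direct annotation sets (no
#' ancestor propagation before comparison):
#' \describe{
#'   \item{I}{all members carry identical term sets;}
#'   \item{II-1}{all members share at least one term and the extra terms are
#'     not descendants of any shared term (typically parents or unrelated,
#'     no more specific);}
#'   \item{II-2}{all members share at least one term and some extra term is
#'     a strict descendant of a shared term (more specific);}
#'   \item{III}{no shared term, but some non-root term is an
#'     ancestor-or-self of at least one term of every member — the most
#'     specific such witness is reported;}
#'   \item{IV}{members' terms can only be traced back to the root.}
#' }
#' The result does not depend on member order.
#'
#' @param member_term_sets List (length >= 2) of non-empty character vectors
#'   of direct term ids.
#' @param dag A [go_dag].
#' @return A list with `category` (one of "I", "II-1", "II-2", "III", "IV"),
#'   `shared_terms`, `common_ancestor` (the Category III witness,
#'   `NA` otherwise) and `n_members`.
#' @export
categorize <- function(member_term_sets, dag) {
  sets <- lapply(member_term_sets, function(x) sort(unique(as.character(x))))
  if (length(sets) < 2L || any(lengths(sets) == 0L)) {
    rc_validation_error(
      "categorization needs at least two members with non-empty term sets"
    )
  }
  for (t in unique(unlist(sets))) check_live_term(dag, t)

  result <- function(category, shared, witness = NA_character_) {
    list(
      category = category, shared_terms = shared,
      common_ancestor = witness, n_members = length(sets)
    )
  }
  if (all(vapply(sets, identical, logical(1), sets[[1]]))) {
    return(result("I", sets[[1]]))
  }
  shared <- Reduce(intersect, sets)
  if (length(shared)) {
    extras <- setdiff(unique(unlist(sets)), shared)
    more_specific <- any(vapply(
      extras, is_descendant_of_any, logical(1), dag = dag, set = shared
    ))
    return(result(if (more_specific) "II-2" else "II-1", shared))
  }
  # no shared term: look for a non-root witness covering every member
  candidates <- setdiff(
    unique(unlist(lapply(unlist(sets), function(t) {
      c(t, go_closure(dag, t, "ancestors"))
    }))),
    dag$root_id
  )
  covers_all <- vapply(candidates, function(w) {
    below <- c(w, go_closure(dag, w, "offspring"))
    all(vapply(sets, function(s) any(s %in% below), logical(1)))
  }, logical(1))
  if (any(covers_all)) {
    wits <- candidates[covers_all]
    p <- vapply(wits, function(w) go_specificity(dag, w)$P, numeric(1))
    wits <- wits[order(-p, wits)]
    return(result("III", character(), wits[1]))
  }
  result("IV", character())
}

#' Maximum member-term specificity of a cluster
#'
#' The cluster-level specificity is the maximum [go_specificity()] `P` over
#' all distinct terms annotated on any member.
#'
#' @param member_term_sets List of character vectors of direct term ids.
#' @param dag A [go_dag].
#' @return A value in `[0, 1]`.
#' @export
cluster_specificity <- function(member_term_sets, dag) {
  terms <- unique(unlist(member_term_sets))
  if (!length(terms)) {
    rc_validation_error("no terms across members; specificity is undefined")
  }
  max(vapply(terms, function(t) go_specificity(dag, t)$P, numeric(1)))
}

CATEGORY_LEVELS <- c("I", "II-1", "II-2", "III", "IV")

#' Intra-cluster consistency report over a cluster set
#'
#' Applies [categorize()] to every cluster with at least `min_annotated`
#' members carrying molecular-function annotations (unannotated members are
#' ignored, not treated as inconsistent) and aggregates a category table
#' with counts and percentages.
#'
#' @param clusters A [cluster_set()].
#' @param annotations An `annotation_set` from [read_annotations()] (or a
#'   named list protein id -> term ids).
#' @param dag A [go_dag].
#' @param min_annotated Minimum annotated members for a cluster to enter the
#'   analysis (default 2).
#' @return A list with `reports` (per-cluster data frame: `cluster_id`,
#'   `category`, `shared_terms`, `common_ancestor`, `cluster_specificity`,
#'   `n_annotated_members`), `table` (per-category `count` and `percent`,
#'   percentages rounded to two decimals), `n_analyzed`, `n_skipped`, and
#'   `fraction_multi_member_analyzed`.
#' @export
consistency_table <- function(clusters, annotations, dag, min_annotated = 2) {
  reports <- list()
  n_skipped <- 0L
  n_multi <- 0L
  for (cl in clusters$clusters) {
    sets <- annotations[cl$member_ids]
    sets <- sets[!vapply(sets, is.null, logical(1))]
    sets <- sets[lengths(sets) > 0L]
    if (length(cl$member_ids) > 1L) n_multi <- n_multi + 1L
    if (length(sets) < min_annotated) {
      n_skipped <- n_skipped + 1L
      next
    }
    cat_ <- categorize(sets, dag)
    reports[[length(reports) + 1L]] <- data.frame(
      cluster_id = cl$cluster_id,
      category = cat_$category,
      shared_terms = paste(cat_$shared_terms, collapse = ";"),
      common_ancestor = cat_$common_ancestor,
      cluster_specificity = cluster_specificity(sets, dag),
      n_annotated_members = length(sets),
      stringsAsFactors = FALSE
    )
  }
  reports <- if (length(reports)) {
    do.call(rbind, reports)
  } else {
    data.frame(
      cluster_id = character(), category = character(),
      shared_terms = character(), common_ancestor = character(),
      cluster_specificity = numeric(), n_annotated_members = integer()
    )
  }
  counts <- table(factor(reports$category, levels = CATEGORY_LEVELS))
  n <- nrow(reports)
  tab <- data.frame(
    category = CATEGORY_LEVELS,
    count = as.integer(counts),
    percent = if (n > 0) round(100 * as.integer(counts) / n, 2) else rep(NA_real_, 5),
    stringsAsFactors = FALSE
  )
  list(
    reports = reports, table = tab, n_analyzed = n, n_skipped = n_skipped,
    fraction_multi_member_analyzed = if (n_multi > 0) n / n_multi else NA_real_
  )
}
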