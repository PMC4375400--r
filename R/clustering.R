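#' Clustering configuration
#'
#' Thresholds for the three-level hierarchy: the 100% level merges identical
#' sequences and exact subfragments (no overlap threshold, so fragment
#' redundancy is removed); the 90% and 50% levels require the stated
#' identity against the cluster seed plus a minimum 80% length overlap with
#' the seed, which keeps proteins sharing only partial sequences (domain
#' subsets, polyprotein components) in separate clusters.
#'
#' @param identity90,identity50 Identity thresholds in (0, 1].
#' @param overlap Seed-coverage threshold in `[0, 1]` applied at 90/50.
#' @param scoring A [scoring_config()].
#' @param model_taxa Taxa preferred during representative selection.
#' @return A `cluster_config` list.
#' @export
cluster_config <- function(identity90 = 0.90, identity50 = 0.50,
                           overlap = 0.80, scoring = scoring_config(),
                           model_taxa = model_organisms()) {
  stopifnot(
    identity90 > 0, identity90 <= 1, identity50 > 0, identity50 <= 1,
    overlap >= 0, overlap <= 1
  )
  structure(
    list(
      identity90 = identity90, identity50 = identity50, overlap = overlap,
      scoring = scoring, model_taxa = model_taxa
    ),
    class = "cluster_config"
  )
}

make_cluster_id <- function(level, representative_id) {
  paste0("UniRef", level, "_", representative_id)
}

new_cluster <- function(level, seed_id, representative_id, member_ids,
                        child_cluster_ids = character()) {
  list(
    cluster_id = make_cluster_id(level, representative_id),
    level = level,
    seed_id = seed_id,
    representative_id = representative_id,
    member_ids = sort(unname(member_ids)),
    child_cluster_ids = sort(unname(child_cluster_ids))
  )
}

#' Assemble and validate a cluster set (one identity level)
#'
#' @param level Identity level label (100, 90 or 50).
#' @param clusters List of cluster records (as produced by the clustering
#'   operations): each has `cluster_id`, `level`, `seed_id`,
#'   `representative_id`, `member_ids`, `child_cluster_ids`.
#' @return A `cluster_set`: list with `level`, `clusters` and a
#'   `member_index` (member id -> cluster id).
#' @export
cluster_set <- function(level, clusters) {
  members <- unlist(lapply(clusters, `[[`, "member_ids"), use.names = FALSE)
  dup <- unique(members[duplicated(members)])
  if (length(dup)) {
    rc_validation_error(paste0(
      "member(s) appear in more than one level-", level, " cluster: ",
      paste(head(dup, 5), collapse = ", ")
    ))
  }
  for (cl in clusters) {
    if (!(cl$representative_id %in% cl$member_ids) ||
      !(cl$seed_id %in% cl$member_ids)) {
      rc_validation_error(paste0(
        "cluster ", cl$cluster_id, ": seed and representative must be members"
      ))
    }
    if (!identical(cl$cluster_id, make_cluster_id(cl$level, cl$representative_id))) {
      rc_validation_error(paste0(
        "cluster id ", cl$cluster_id, " does not match its representative"
      ))
    }
  }
  idx <- setNames(
    rep(vapply(clusters, `[[`, character(1), "cluster_id"),
      vapply(clusters, function(cl) length(cl$member_ids), integer(1))
    ),
    members
  )
  structure(
    list(level = level, clusters = clusters, member_index = idx),
    class = "cluster_set"
  )
}

#' @export
print.cluster_set <- function(x, ...) {
  sizes <- vapply(x$clusters, function(cl) length(cl$member_ids), integer(1))
  cat(
    "cluster_set level", x$level, ":", length(x$clusters), "clusters,",
    sum(sizes), "members (", sum(sizes == 1L), "singletons )\n"
  )
  invisible(x)
}

#' Select a cluster's representative member
#'
#' Representatives are the best-annotated members, compared on the priority
#' tuple: curation status (reviewed first), then protein-name quality (names
#' containing hypothetical/putative/uncharacterized/probable rank last),
#' then model-organism membership, then sequence length (longest first),
#' with the accession id as the final deterministic tie-break.
#'
#' @param cluster A cluster record (see [cluster_set()]), or any list with a
#'   `member_ids` field, or a plain character vector of member ids.
#' @param records The [protein_records] covering every member.
#' @param model_taxa Preferred taxa (prefix-matched on organism).
#' @return The representative's accession id.
#' @export
select_representative <- function(cluster, records, model_taxa = model_organisms()) {
  ids <- if (is.list(cluster)) cluster$member_ids else cluster
  if (!length(ids)) rc_validation_error("cannot select from an empty cluster")
  pos <- match(ids, records$id)
  if (anyNA(pos)) {
    rc_validation_error(paste0(
      "no metadata for member(s): ", paste(ids[is.na(pos)], collapse = ", ")
    ))
  }
  m <- records[pos, , drop = FALSE]
  bad_name <- grepl("hypothetical|putative|uncharacterized|probable",
    m$protein_name,
    ignore.case = TRUE
  )
  model <- vapply(
    m$organism, function(o) nzchar(o) && any(startsWith(o, model_taxa)),
    logical(1), USE.NAMES = FALSE
  )
  ord <- order(-as.integer(m$reviewed), as.integer(bad_name),
    -as.integer(model), -m$length, m$id)
  m$id[ord[1]]
}

# Deterministic processing order shared by all greedy stages:
# length descending, accession ascending.
greedy_order <- function(records) order(-records$length, records$id)

#' Merge identical sequences and exact subfragments (the 100% level)
#'
#' Two records share a level-100 cluster iff one's sequence is an exact
#' substring of the other's (equality included); merging is transitive via
#' the containing sequence. No overlap threshold applies here — this level
#' exists precisely to absorb fragment redundancy. The seed is the longest
#' member.
#'
#' @param records A [protein_records] data frame.
#' @param model_taxa Passed to [select_representative()].
#' @return A level-100 [cluster_set()].
#' @export
dedupe100 <- function(records, model_taxa = model_organisms()) {
  records <- validate_protein_records(records)
  ord <- greedy_order(records)
  seeds_seq <- character(0)
  seeds_id <- character(0)
  membership <- integer(nrow(records))
  for (i in ord) {
    s <- records$sequence[i]
    hit <- 0L
    if (length(seeds_seq)) {
      cand <- which(vapply(seeds_seq, function(x) grepl(s, x, fixed = TRUE), logical(1)))
      if (length(cand)) hit <- cand[1]
    }
    if (hit == 0L) {
      seeds_seq <- c(seeds_seq, s)
      seeds_id <- c(seeds_id, records$id[i])
      hit <- length(seeds_seq)
    }
    membership[i] <- hit
  }
  clusters <- lapply(seq_along(seeds_id), function(k) {
    ids <- records$id[membership == k]
    new_cluster(
      level = 100, seed_id = seeds_id[k],
      representative_id = select_representative(ids, records, model_taxa),
      member_ids = ids
    )
  })
  cluster_set(100, clusters)
}

#' Greedy incremental identity clustering with a seed-overlap constraint
#'
#' Records are processed longest-first (ties by id); each record joins the
#' qualifying cluster whose seed it matches with the highest identity, or
#' founds a new cluster (becoming its seed). Joining requires
#' `identity_fraction >= identity_threshold` and
#' `seed_coverage >= overlap_threshold` against the cluster's seed; identity
#' ties go to the earliest-founded cluster.
#'
#' @param seed_records A [protein_records] data frame (at the 90/50 levels
#'   these are the finer level's seed sequences).
#' @param identity_threshold Identity threshold in (0, 1].
#' @param overlap_threshold Seed-coverage threshold in `[0, 1]`.
#' @param level Level label for cluster ids (defaults to
#'   `round(identity_threshold * 100)`).
#' @param config A [scoring_config()].
#' @param model_taxa Passed to [select_representative()].
#' @return A [cluster_set()] partitioning `seed_records`.
#' @export
greedy_cluster <- function(seed_records, identity_threshold, overlap_threshold,
                           level = round(identity_threshold * 100),
                           config = scoring_config(),
                           model_taxa = model_organisms()) {
  stopifnot(
    identity_threshold > 0, identity_threshold <= 1,
    overlap_threshold >= 0, overlap_threshold <= 1
  )
  if (nrow(seed_records) == 0L) {
    return(cluster_set(level, list()))
  }
  records <- validate_protein_records(seed_records)
  ord <- greedy_order(records)
  seed_idx <- integer(0) # row index of each cluster's seed, founding order
  membership <- integer(nrow(records))
  for (i in ord) {
    hit <- 0L
    if (length(seed_idx)) {
      st <- align_to_seeds(records$sequence[i], records$sequence[seed_idx], config)
      ok <- which(st$identity_fraction >= identity_threshold &
        st$seed_coverage >= overlap_threshold)
      if (length(ok)) {
        best <- ok[order(-st$identity_fraction[ok], ok)][1]
        hit <- best
      }
    }
    if (hit == 0L) {
      seed_idx <- c(seed_idx, i)
      hit <- length(seed_idx)
    }
    membership[i] <- hit
  }
  clusters <- lapply(seq_along(seed_idx), function(k) {
    ids <- records$id[membership == k]
    new_cluster(
      level = level, seed_id = records$id[seed_idx[k]],
      representative_id = select_representative(ids, records, model_taxa),
      member_ids = ids
    )
  })
  cluster_set(level, clusters)
}

# One record against many seeds in a single vectorized alignment call
# (patterns = seeds, subject = record); identity and per-seed coverage.
align_to_seeds <- function(record_seq, seed_seqs, config = scoring_config()) {
  canonical <- "[ACDEFGHIKLMNPQRSTVWY]"
  if (!any(grepl(canonical, record_seq)) || any(!grepl(canonical, seed_seqs))) {
    rc_abort(
      "sequence(s) consist only of ambiguity characters; alignment is degenerate",
      "refclust_alignment_degenerate"
    )
  }
  aln <- Biostrings::pairwiseAlignment(
    Biostrings::AAStringSet(seed_seqs), Biostrings::AAString(record_seq),
    type = "overlap",
    substitutionMatrix = refclust_submat(config$substitution_matrix),
    gapOpening = config$gap_opening, gapExtension = config$gap_extension
  )
  ident <- Biostrings::nmatch(aln)
  denom <- switch(config$identity_denominator,
    shorter = pmin(nchar(seed_seqs), nchar(record_seq)),
    alignment = Biostrings::nchar(aln)
  )
  span <- IRanges::end(Biostrings::pattern(aln)) -
    IRanges::start(Biostrings::pattern(aln)) + 1L
  data.frame(
    identity_fraction = ident / denom,
    seed_coverage = span / nchar(seed_seqs)
  )
}

# Regroup a coarse greedy clustering of seed records into full clusters:
# each coarse cluster's member set becomes the union of its constituent
# finer clusters' members, the representative is re-selected over that
# union, and child links point at the finer clusters.
expand_level <- function(coarse, finer, records, level, model_taxa) {
  finer_by_seed <- setNames(finer$clusters, vapply(finer$clusters, `[[`, character(1), "seed_id"))
  clusters <- lapply(coarse$clusters, function(cl) {
    children <- finer_by_seed[cl$member_ids]
    members <- unlist(lapply(children, `[[`, "member_ids"), use.names = FALSE)
    new_cluster(
      level = level, seed_id = cl$seed_id,
      representative_id = select_representative(members, records, model_taxa),
      member_ids = members,
      child_cluster_ids = vapply(children, `[[`, character(1), "cluster_id")
    )
  })
  cluster_set(level, clusters)
}

#' Build the full 100/90/50 cluster hierarchy
#'
#' Levels are computed hierarchically: subfragment/identical merging first
#' ([dedupe100()]); the level-100 seed sequences are then greedily clustered
#' at 90% identity with the 80% seed-overlap constraint, and the level-90
#' seeds at 50% identity. Each coarser cluster's member set is the union of
#' its constituent finer clusters' members, so nesting holds by
#' construction.
#'
#' @param records A [protein_records] data frame.
#' @param config A [cluster_config()].
#' @return A `uniref_hierarchy`: list with `level100`, `level90`, `level50`
#'   ([cluster_set()]s), plus the input `records` and `config` (kept so the
#'   hierarchy can be updated incrementally).
#' @export
#' @examples
#' rec <- protein_records(c("A", "B"), c("MKVLAWGHEDMKVLAWGHED", "MKVLAWGHED"))
#' h <- build_hierarchy(rec)
#' h$level100
build_hierarchy <- function(records, config = cluster_config()) {
  records <- validate_protein_records(records)
  l100 <- dedupe100(records, config$model_taxa)
  seeds100 <- records[match(
    vapply(l100$clusters, `[[`, character(1), "seed_id"), records$id
  ), , drop = FALSE]
  g90 <- greedy_cluster(seeds100, config$identity90, config$overlap,
    level = 90, config = config$scoring, model_taxa = config$model_taxa
  )
  l90 <- expand_level(g90, l100, records, 90, config$model_taxa)
  seeds90 <- records[match(
    vapply(l90$clusters, `[[`, character(1), "seed_id"), records$id
  ), , drop = FALSE]
  g50 <- greedy_cluster(seeds90, config$identity50, config$overlap,
    level = 50, config = config$scoring, model_taxa = config$model_taxa
  )
  # level-50 children are level-90 clusters; regroup over the 90 set
  l50 <- expand_level(g50, l90, records, 50, config$model_taxa)
  structure(
    list(
      level100 = l100, level90 = l90, level50 = l50,
      records = records, config = config
    ),
    class = "uniref_hierarchy"
  )
}

#' @export
print.uniref_hierarchy <- function(x, ...) {
  cat("uniref_hierarchy over", nrow(x$records), "records\n")
  print(x$level100)
  print(x$level90)
  print(x$level50)
  invisible(x)
}

#' Validate the nesting invariant of a hierarchy
#'
#' Every level-90 cluster must be a union of whole level-100 clusters and
#' every level-50 cluster a union of whole level-90 clusters; all three
#' levels must partition the same id set.
#'
#' @param hierarchy A `uniref_hierarchy`.
#' @return `TRUE` invisibly; otherwise a validation error.
#' @export
validate_hierarchy <- function(hierarchy) {
  ids <- sort(hierarchy$records$id)
  for (lv in c("level100", "level90", "level50")) {
    got <- sort(names(hierarchy[[lv]]$member_index))
    if (!identical(got, ids)) {
      rc_validation_error(paste0(lv, " does not partition the input ids"))
    }
  }
  check_union <- function(coarse, finer) {
    by_id <- setNames(finer$clusters, vapply(finer$clusters, `[[`, character(1), "cluster_id"))
    for (cl in coarse$clusters) {
      kids <- by_id[cl$child_cluster_ids]
      if (any(vapply(kids, is.null, logical(1)))) {
        rc_validation_error(paste0(cl$cluster_id, ": unknown child cluster id"))
      }
      u <- sort(unlist(lapply(kids, `[[`, "member_ids"), use.names = FALSE))
      if (!identical(u, cl$member_ids)) {
        rc_validation_error(paste0(
          cl$cluster_id, " is not the union of its child clusters"
        ))
      }
    }
  }
  check_union(hierarchy$level90, hierarchy$level100)
  check_union(hierarchy$level50, hierarchy$level90)
  invisible(TRUE)
}
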