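#' Incrementally fold new records into an existing hierarchy
#'
#' Mirrors the production update procedure that favors clustering new
#' sequences under existing clusters: each new record (processed
#' longest-first, ties by id) first tries to join an existing cluster at the
#' 100% level (exact substring relation with the cluster seed), then at the
#' 90% and 50% levels (identity and 80% overlap against existing seeds, the
#' highest identity wins). Records that qualify nowhere found new clusters
#' at every level. Cluster ids are preserved whenever the representative is
#' unchanged; representatives are re-selected only for clusters that gained
#' members. A new record longer than the seed of the cluster it joins
#' becomes that cluster's seed, preserving seed maximality.
#'
#' @param hierarchy A `uniref_hierarchy` from [build_hierarchy()].
#' @param new_records A [protein_records] data frame; ids must be disjoint
#'   from the hierarchy's.
#' @param config A [cluster_config()]; defaults to the hierarchy's own.
#' @return The updated `uniref_hierarchy`.
#' @export
incremental_update <- function(hierarchy, new_records, config = hierarchy$config) {
  new_records <- validate_protein_records(new_records)
  clash <- intersect(new_records$id, hierarchy$records$id)
  if (length(clash)) {
    rc_validation_error(paste0(
      "new record id(s) collide with existing ids: ", paste(clash, collapse = ", ")
    ))
  }
  if (nrow(new_records) == 0L) {
    return(hierarchy)
  }
  records <- rbind(hierarchy$records, new_records)
  class(records) <- c("protein_records", "data.frame")

  st <- new.env(parent = emptyenv())
  st$l100 <- hierarchy$level100$clusters
  st$l90 <- hierarchy$level90$clusters
  st$l50 <- hierarchy$level50$clusters
  st$dirty100 <- logical(length(st$l100))
  st$dirty90 <- logical(length(st$l90))
  st$dirty50 <- logical(length(st$l50))
  # member id -> cluster position per level
  pos_map <- function(cl_list) {
    setNames(
      rep(seq_along(cl_list), vapply(cl_list, function(cl) length(cl$member_ids), integer(1))),
      unlist(lapply(cl_list, `[[`, "member_ids"), use.names = FALSE)
    )
  }
  st$map100 <- pos_map(st$l100)
  st$map90 <- pos_map(st$l90)
  st$map50 <- pos_map(st$l50)

  seq_of <- function(id) records$sequence[match(id, records$id)]
  len_of <- function(id) records$length[match(id, records$id)]

  join <- function(level, k, id, founded = FALSE) {
    f <- paste0("l", level)
    st[[f]][[k]]$member_ids <- sort(c(st[[f]][[k]]$member_ids, id))
    if (len_of(id) > len_of(st[[f]][[k]]$seed_id)) {
      st[[f]][[k]]$seed_id <- id
    }
    if (!founded) st[[paste0("dirty", level)]][k] <- TRUE
    st[[paste0("map", level)]][id] <- k
  }

  # alignment of one record against existing seeds of mixed lengths: the
  # longer sequence of each pair plays the seed, so coverage is always
  # measured on the longer one
  stats_vs_seeds <- function(rec_seq, seed_seqs, scoring) {
    out <- data.frame(
      identity_fraction = numeric(length(seed_seqs)),
      seed_coverage = numeric(length(seed_seqs))
    )
    longer <- nchar(seed_seqs) >= nchar(rec_seq)
    if (any(longer)) {
      out[longer, ] <- align_to_seeds(rec_seq, seed_seqs[longer], scoring)
    }
    if (any(!longer)) {
      s <- align_stats_many(seed_seqs[!longer], rec_seq, scoring)
      out[!longer, ] <- s[, c("identity_fraction", "seed_coverage")]
    }
    out
  }

  try_greedy_join <- function(level, id, threshold) {
    cl_list <- st[[paste0("l", level)]]
    if (!length(cl_list)) {
      return(0L)
    }
    seed_seqs <- vapply(cl_list, function(cl) seq_of(cl$seed_id), character(1))
    s <- stats_vs_seeds(seq_of(id), seed_seqs, config$scoring)
    ok <- which(s$identity_fraction >= threshold & s$seed_coverage >= config$overlap)
    if (!length(ok)) {
      return(0L)
    }
    ok[order(-s$identity_fraction[ok], ok)][1]
  }

  found <- function(level, id, child_id = character()) {
    f <- paste0("l", level)
    st[[f]][[length(st[[f]]) + 1L]] <- new_cluster(
      level = level, seed_id = id, representative_id = id,
      member_ids = id, child_cluster_ids = child_id
    )
    st[[paste0("dirty", level)]] <- c(st[[paste0("dirty", level)]], FALSE)
    st[[paste0("map", level)]][id] <- length(st[[f]])
    length(st[[f]])
  }

  for (i in greedy_order(new_records)) {
    id <- new_records$id[i]
    s <- new_records$sequence[i]
    # level 100: exact substring relation with an existing seed
    k100 <- 0L
    if (length(st$l100)) {
      seed_seqs <- vapply(st$l100, function(cl) seq_of(cl$seed_id), character(1))
      cand <- which(
        vapply(seed_seqs, function(x) grepl(s, x, fixed = TRUE), logical(1)) |
          vapply(seed_seqs, function(x) grepl(x, s, fixed = TRUE), logical(1))
      )
      if (length(cand)) {
        k100 <- cand[order(-nchar(seed_seqs[cand]), cand)][1]
      }
    }
    if (k100 > 0L) {
      anchor <- st$l100[[k100]]$member_ids[1] # existing member locates parents
      join(100, k100, id)
      join(90, st$map90[[anchor]], id)
      join(50, st$map50[[anchor]], id)
      next
    }
    found(100, id)
    k90 <- try_greedy_join(90, id, config$identity90)
    if (k90 > 0L) {
      anchor <- st$l90[[k90]]$member_ids[1]
      join(90, k90, id)
      join(50, st$map50[[anchor]], id)
      next
    }
    found(90, id)
    k50 <- try_greedy_join(50, id, config$identity50)
    if (k50 > 0L) {
      join(50, k50, id)
    } else {
      found(50, id)
    }
  }

  # re-select representatives only where membership grew; refresh ids
  refresh <- function(level) {
    f <- paste0("l", level)
    dirty <- st[[paste0("dirty", level)]]
    for (k in which(dirty)) {
      rep_id <- select_representative(
        st[[f]][[k]]$member_ids, records, config$model_taxa
      )
      st[[f]][[k]]$representative_id <- rep_id
      st[[f]][[k]]$cluster_id <- make_cluster_id(level, rep_id)
    }
  }
  refresh(100)
  refresh(90)
  refresh(50)

  # child links re-derived from membership (cluster ids may have changed)
  relink <- function(coarse_level, finer_level) {
    fc <- paste0("l", coarse_level)
    ff <- paste0("l", finer_level)
    mapc <- st[[paste0("map", coarse_level)]]
    kids <- vector("list", length(st[[fc]]))
    for (j in seq_along(st[[ff]])) {
      parent <- mapc[[st[[ff]][[j]]$member_ids[1]]]
      kids[[parent]] <- c(kids[[parent]], st[[ff]][[j]]$cluster_id)
    }
    for (k in seq_along(st[[fc]])) {
      st[[fc]][[k]]$child_cluster_ids <- sort(kids[[k]] %||% character())
    }
  }
  relink(90, 100)
  relink(50, 90)

  out <- structure(
    list(
      level100 = cluster_set(100, st$l100),
      level90 = cluster_set(90, st$l90),
      level50 = cluster_set(50, st$l50),
      records = records, config = config
    ),
    class = "uniref_hierarchy"
  )
  validate_hierarchy(out)
  out
}
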