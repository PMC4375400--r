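AA20 <- setdiff(AA_ALPHABET, c("X", "B", "Z", "U", "O"))

# run `code` under a private RNG stream, restoring the caller's state
with_rng <- function(rng_seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(rng_seed)
  force(code)
}

#' Specification for a synthetic family corpus
#'
#' Defaults describe the corpus the evaluation suite runs on: 20 families of
#' 10 members (the family seed itself plus derived members) over 120-residue
#' family seeds, members derived by i.i.d. substitutions targeting 95%
#' identity, with 30% of derived members emitted as contiguous fragments
#' covering at least half of the full member. Substitution-only mutation
#' keeps the realized identity analytically predictable; fragments supply
#' the coverage axis that exercises the 80% seed-overlap rule. The family
#' seed is emitted as a corpus record whose accession sorts before all
#' derived members (mimicking reference sequences predating their homologs'
#' accessions), so greedy cluster seeds anchor at family seeds and
#' `target_identity` is directly the member-to-cluster-seed identity.
#'
#' @param n_families,members_per_family Corpus dimensions.
#' @param seed_length Family seed length in residues (>= 20).
#' @param target_identity Expected member identity to the family seed, in
#'   (0, 1].
#' @param fragment_rate Probability a member is emitted as a fragment, in
#'   `[0, 1)`.
#' @param fragment_min_cover Minimum fraction of the member a fragment
#'   covers, in (0, 1].
#' @param rng_seed Integer seed; the corpus is a pure function of the spec.
#' @return A `family_spec` list.
#' @export
family_spec <- function(n_families = 20, members_per_family = 10,
                        seed_length = 120, target_identity = 0.95,
                        fragment_rate = 0.30, fragment_min_cover = 0.50,
                        rng_seed = 1) {
  spec <- structure(
    list(
      n_families = n_families, members_per_family = members_per_family,
      seed_length = seed_length, target_identity = target_identity,
      fragment_rate = fragment_rate, fragment_min_cover = fragment_min_cover,
      rng_seed = rng_seed
    ),
    class = "family_spec"
  )
  if (n_families < 1 || members_per_family < 1 ||
    seed_length < 20 ||
    target_identity <= 0 || target_identity > 1 ||
    fragment_rate < 0 || fragment_rate >= 1 ||
    fragment_min_cover <= 0 || fragment_min_cover > 1) {
    rc_validation_error("infeasible family_spec (rates/lengths out of range)")
  }
  spec
}

mutate_sequence <- function(seed_chars, p) {
  mut <- runif(length(seed_chars)) < p
  if (any(mut)) {
    seed_chars[mut] <- vapply(
      seed_chars[mut],
      function(a) sample(setdiff(AA20, a), 1L),
      character(1), USE.NAMES = FALSE
    )
  }
  list(chars = seed_chars, mutated = mut)
}

#' Generate a synthetic protein-family corpus with known truth
#'
#' Per family, a random seed sequence is drawn and members are derived by
#' substituting each residue independently with probability
#' `1 - target_identity` (substitutions always change the residue, so the
#' expected identity equals the target). With probability `fragment_rate` a
#' member is emitted as a contiguous subfragment covering at least
#' `fragment_min_cover` of the member. Ids are assigned in shuffled order so
#' they encode nothing about family structure; the truth table records each
#' member's family, fragment status and realized identity to its family
#' seed.
#'
#' @param spec A [family_spec()].
#' @return A list: `records` ([protein_records]) and `truth`
#'   (`data.frame` with `member_id`, `family_id`, `is_fragment`,
#'   `realized_identity`).
#' @export
#' @examples
#' corpus <- make_family_corpus(family_spec(n_families = 2, members_per_family = 3))
#' head(corpus$truth)
make_family_corpus <- function(spec = family_spec()) {
  stopifnot(inherits(spec, "family_spec"))
  with_rng(spec$rng_seed, {
    p <- 1 - spec$target_identity
    rows <- list()
    for (f in seq_len(spec$n_families)) {
      seed_chars <- sample(AA20, spec$seed_length, replace = TRUE)
      for (j in seq_len(spec$members_per_family)) {
        if (j == 1L) { # the family seed itself enters the corpus untouched
          m <- list(chars = seed_chars, mutated = rep(FALSE, length(seed_chars)))
          is_frag <- FALSE
        } else {
          m <- mutate_sequence(seed_chars, p)
          is_frag <- runif(1) < spec$fragment_rate
        }
        keep <- seq_along(m$chars)
        if (is_frag) {
          cover <- runif(1, spec$fragment_min_cover, 1)
          flen <- max(20L, min(length(m$chars), as.integer(round(cover * length(m$chars)))))
          start <- sample.int(length(m$chars) - flen + 1L, 1L)
          keep <- start:(start + flen - 1L)
        }
        rows[[length(rows) + 1L]] <- list(
          family_id = paste0("FAM", sprintf("%03d", f)),
          is_family_seed = j == 1L,
          sequence = paste(m$chars[keep], collapse = ""),
          is_fragment = is_frag,
          realized_identity = mean(!m$mutated[keep]),
          reviewed = runif(1) < 0.2,
          bad_name = runif(1) < 0.15,
          organism = sample(
            c("Homo sapiens", "Escherichia coli", "Mus musculus", "Zea mays"), 1L
          )
        )
      }
    }
    # ids are assigned in shuffled order (they encode nothing about family);
    # family seeds draw from an "R" block that sorts before the member "S"
    # block, anchoring greedy seeds at family seeds
    is_ref <- vapply(rows, `[[`, logical(1), "is_family_seed")
    ids <- character(length(rows))
    ids[sample(which(is_ref))] <- paste0("R", sprintf("%05d", seq_len(sum(is_ref))))
    ids[sample(which(!is_ref))] <- paste0("S", sprintf("%05d", seq_len(sum(!is_ref))))
    records <- protein_records(
      id = ids,
      sequence = vapply(rows, `[[`, character(1), "sequence"),
      reviewed = vapply(rows, `[[`, logical(1), "reviewed"),
      protein_name = ifelse(
        vapply(rows, `[[`, logical(1), "bad_name"),
        paste("putative uncharacterized protein", ids),
        paste("synthetic family protein", ids)
      ),
      organism = vapply(rows, `[[`, character(1), "organism"),
      is_fragment = vapply(rows, `[[`, logical(1), "is_fragment")
    )
    truth <- data.frame(
      member_id = ids,
      family_id = vapply(rows, `[[`, character(1), "family_id"),
      is_family_seed = is_ref,
      is_fragment = vapply(rows, `[[`, logical(1), "is_fragment"),
      realized_identity = vapply(rows, `[[`, numeric(1), "realized_identity"),
      stringsAsFactors = FALSE
    )
    list(records = records, truth = truth)
  })
}

#' Build a toy rooted ontology
#'
#' A `branching`-ary tree of `depth` levels below the root (so depth 2 with
#' branching 1 is a three-term chain), optionally with extra cross-edges
#' that create diamond motifs: each cross-edge links a term to a second
#' parent drawn from a strictly shallower level, keeping the graph acyclic
#' and single-rooted.
#'
#' @param depth Levels below the root (>= 2 for the consistency ladders).
#' @param branching Children per internal term.
#' @param rng_seed Seed for cross-edge placement.
#' @param cross_edges Number of extra parent links to add.
#' @return A [go_dag].
#' @export
#' @examples
#' make_toy_dag(2, 1) # 3-term chain
make_toy_dag <- function(depth, branching = 2, rng_seed = 1, cross_edges = 0) {
  if (depth < 1) rc_validation_error("depth must be at least 1")
  ids <- function(k) paste0("GO:", sprintf("%07d", k))
  levels <- list(1L) # term numbers per level; root is term 1
  nxt <- 2L
  edges <- list()
  for (l in seq_len(depth)) {
    lvl <- integer(0)
    for (parent in levels[[l]]) {
      kids <- nxt + seq_len(branching) - 1L
      nxt <- nxt + branching
      edges[[length(edges) + 1L]] <- data.frame(
        child = ids(kids), parent = ids(parent), stringsAsFactors = FALSE
      )
      lvl <- c(lvl, kids)
    }
    levels[[l + 1L]] <- lvl
  }
  edges <- do.call(rbind, edges)
  n <- nxt - 1L
  terms <- data.frame(
    id = ids(seq_len(n)),
    name = c("molecular_function", paste0("toy term ", seq_len(n - 1L) + 1L)),
    obsolete = FALSE, stringsAsFactors = FALSE
  )
  if (cross_edges > 0) {
    resample <- function(x) x[sample.int(length(x), 1L)] # length-1 safe
    with_rng(rng_seed, {
      added <- 0L
      guard <- 0L
      while (added < cross_edges && guard < 1000L) {
        guard <- guard + 1L
        l <- resample(3:(depth + 1L)) # child at level >= 2 below root
        child <- ids(resample(levels[[l]]))
        parent <- ids(resample(levels[[resample(2:(l - 1L))]]))
        is_edge <- any(edges$child == child & edges$parent == parent)
        if (!is_edge) {
          edges <- rbind(edges, data.frame(child = child, parent = parent))
          added <- added + 1L
        }
      }
    })
  }
  go_dag(terms, edges)
}

dag_children <- function(dag) {
  split(dag$edges$child, dag$edges$parent)
}

#' Generate member term sets guaranteed to categorize as requested
#'
#' Constructs annotation scenarios for the five consistency categories:
#' identical sets (I); a shared term with a non-descendant extra (II-1); a
#' shared term with a strictly more specific extra (II-2); disjoint sets
#' whose terms sit under a common non-root ancestor (III); and sets that
#' share nothing but the root (IV).
#'
#' @param category One of "I", "II-1", "II-2", "III", "IV".
#' @param dag A [go_dag] deep enough for the requested pattern.
#' @param n_members Number of member sets (>= 2).
#' @param rng_seed Seed for the random choices among valid constructions.
#' @return List of `n_members` character vectors of term ids.
#' @export
make_category_scenario <- function(category, dag, n_members = 2, rng_seed = 1) {
  if (!category %in% CATEGORY_LEVELS) {
    rc_validation_error(paste0("unknown category: ", category))
  }
  if (n_members < 2) rc_validation_error("need at least two members")
  live <- setdiff(dag$terms$id[!dag$terms$obsolete], dag$root_id)
  kids <- dag_children(dag)
  with_rng(rng_seed, {
    pick <- function(x) if (length(x) == 1L) x else sample(x, 1L)
    sets <- switch(category,
      "I" = {
        t <- pick(live)
        rep(list(t), n_members)
      },
      "II-1" = {
        # shared child c, one member also carries its parent p (no more specific)
        c_ <- pick(intersect(live, dag$edges$child))
        p <- pick(dag$edges$parent[dag$edges$child == c_])
        c(rep(list(c_), n_members - 1L), list(sort(c(c_, p))))
      },
      "II-2" = {
        # shared term a, one member adds a strict descendant d
        a <- pick(intersect(live, names(kids)))
        d <- pick(kids[[a]])
        c(rep(list(a), n_members - 1L), list(sort(c(a, d))))
      },
      "III" = {
        # disjoint sets under a shared non-root parent
        w <- names(kids)[lengths(kids) >= 2 & names(kids) != dag$root_id]
        if (!length(w)) {
          rc_validation_error("dag too shallow for a Category III scenario")
        }
        w <- pick(w)
        xy <- sample(kids[[w]], 2L)
        lapply(seq_len(n_members), function(i) xy[[(i - 1L) %% 2L + 1L]])
      },
      "IV" = {
        # two terms whose only common ancestor is the root
        pairs <- NULL
        for (x in live) {
          ax <- setdiff(c(x, go_closure(dag, x, "ancestors")), dag$root_id)
          for (y in live) {
            if (y <= x) next
            ay <- setdiff(c(y, go_closure(dag, y, "ancestors")), dag$root_id)
            if (!length(intersect(ax, ay))) pairs <- rbind(pairs, c(x, y))
          }
        }
        if (is.null(pairs)) {
          rc_validation_error("dag too shallow for a Category IV scenario")
        }
        xy <- pairs[pick(seq_len(nrow(pairs))), ]
        lapply(seq_len(n_members), function(i) xy[[(i - 1L) %% 2L + 1L]])
      }
    )
    sets
  })
}

#' Engine settings for the miniature in-package search
#'
#' @param identity_cutoff Identity fraction at or above which a
#'   subject is reported as a hit (default 0.5, matching the coarsest
#'   clustering level).
#' @param scoring A [scoring_config()].
#' @return A list of engine settings.
#' @export
hit_engine_config <- function(identity_cutoff = 0.5, scoring = scoring_config()) {
  list(identity_cutoff = identity_cutoff, scoring = scoring)
}

search_against <- function(records, subjects, config) {
  out <- list()
  for (i in seq_len(nrow(records))) {
    st <- align_to_seeds(records$sequence[i], subjects$sequence, config$scoring)
    # self-hits stay in, as in a real database search
    hit <- which(st$identity_fraction >= config$identity_cutoff)
    if (!length(hit)) next
    minlen <- pmin(subjects$length[hit], records$length[i])
    out[[length(out) + 1L]] <- data.frame(
      query_id = records$id[i], subject_id = subjects$id[hit],
      percent_identity = round(100 * st$identity_fraction[hit], 2),
      alignment_length = minlen, mismatches = round((1 - st$identity_fraction[hit]) * minlen),
      gap_opens = 0, q_start = 1, q_end = records$length[i],
      s_start = 1, s_end = subjects$length[hit],
      evalue = round(1 - st$identity_fraction[hit], 6),
      bitscore = round(100 * st$identity_fraction[hit], 2),
      stringsAsFactors = FALSE
    )
  }
  out <- do.call(rbind, c(out, list(NULL)))
  if (is.null(out)) {
    out <- as.data.frame(setNames(
      c(
        list(character(), character()),
        replicate(9, numeric(), simplify = FALSE), list(numeric())
      ),
      HIT_COLUMNS
    ))
  }
  out <- out[order(out$query_id, out$evalue, -out$bitscore, out$subject_id), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("hit_table", "data.frame")
  out
}

#' Build hit-list and truth fixtures with the internal aligner
#'
#' A desk-scale analog of the two full-scale search protocols: `full_hits`
#' is the exhaustive all-vs-all search of the corpus (every subject at or
#' above the identity cutoff), `seed_hits` restricts the target database to
#' the given clusters' seed sequences (ready for [expand_hits()]), and
#' `truth_pairs` lists all ordered same-family pairs from the generation
#' truth table. E-values are a monotone transform of identity
#' (`1 - identity`), so rankings follow alignment quality.
#'
#' @param records Corpus [protein_records] from [make_family_corpus()].
#' @param truth The matching truth table.
#' @param clusters A [cluster_set()] whose seeds form the reduced target
#'   database (typically the 50% level of [build_hierarchy()]).
#' @param engine_config A [hit_engine_config()].
#' @return A list: `seed_hits`, `full_hits` (both `hit_table`s) and
#'   `truth_pairs` (`data.frame` with `query_id`, `target_id`).
#' @export
make_hit_fixture <- function(records, truth, clusters,
                             engine_config = hit_engine_config()) {
  seeds <- records[match(
    vapply(clusters$clusters, `[[`, character(1), "seed_id"), records$id
  ), , drop = FALSE]
  full_hits <- search_against(records, records, engine_config)
  seed_hits <- search_against(records, seeds, engine_config)
  fam <- split(truth$member_id, truth$family_id)
  truth_pairs <- do.call(rbind, c(lapply(fam, function(ids) {
    if (length(ids) < 2L) {
      return(NULL)
    }
    g <- expand.grid(query_id = ids, target_id = ids, stringsAsFactors = FALSE)
    g[g$query_id != g$target_id, , drop = FALSE]
  }), list(NULL)))
  truth_pairs <- truth_pairs[order(truth_pairs$query_id, truth_pairs$target_id), , drop = FALSE]
  rownames(truth_pairs) <- NULL
  list(seed_hits = seed_hits, full_hits = full_hits, truth_pairs = truth_pairs)
}
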