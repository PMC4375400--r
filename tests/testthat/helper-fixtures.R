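# Shared fixtures built in code. The evaluation corpus (the generator's
# default conditions) is memoised because several test files measure
# different properties of the same study corpus.

chain_obo_text <- function() {
  c(
    "format-version: 1.2", "",
    "[Term]", "id: GO:0000001", "name: molecular_function",
    "namespace: molecular_function", "",
    "[Term]", "id: GO:0000002", "name: binding",
    "namespace: molecular_function", "is_a: GO:0000001 ! molecular_function", "",
    "[Term]", "id: GO:0000003", "name: ATP binding",
    "namespace: molecular_function", "is_a: GO:0000002 ! binding", ""
  )
}

write_tmp <- function(lines, ext = ".txt") {
  path <- tempfile(fileext = ext)
  writeLines(lines, path)
  path
}

chain_dag <- function() {
  read_obo(write_tmp(chain_obo_text(), ".obo"))
}

acceptance_corpus <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      corpus <- make_family_corpus(family_spec())
      hierarchy <- build_hierarchy(corpus$records)
      cache <<- list(
        records = corpus$records, truth = corpus$truth, hierarchy = hierarchy
      )
    }
    cache
  }
})

# record constructor shorthand for alignment/clustering tests
rec1 <- function(id, seq, ...) protein_records(id, seq, ...)

# Post-hoc oracle audit of the greedy joining decisions: at level 90 the
# joining units are the level-100 seeds, at level 50 the level-90 seeds
# (exact subfragments absorbed at the 100% level ride along inside their
# cluster, as the hierarchy composes whole finer clusters).
audit_thresholds <- function(hierarchy) {
  seqs <- setNames(hierarchy$records$sequence, hierarchy$records$id)
  seed_of <- function(cs) {
    setNames(
      vapply(cs$clusters, `[[`, character(1), "seed_id"),
      vapply(cs$clusters, `[[`, character(1), "cluster_id")
    )
  }
  out <- list()
  for (step in list(
    list(coarse = hierarchy$level90, finer = hierarchy$level100, thr = 0.90),
    list(coarse = hierarchy$level50, finer = hierarchy$level90, thr = 0.50)
  )) {
    fine_seed <- seed_of(step$finer)
    for (cl in step$coarse$clusters) {
      units <- setdiff(unname(fine_seed[cl$child_cluster_ids]), cl$seed_id)
      for (u in units) {
        o <- oracle_align(seqs[[cl$seed_id]], seqs[[u]])
        out[[length(out) + 1L]] <- data.frame(
          level = step$coarse$level, threshold = step$thr,
          seed_id = cl$seed_id, unit_id = u,
          identity = o$identity_fraction, coverage = o$seed_coverage
        )
      }
    }
  }
  do.call(rbind, c(out, list(data.frame(
    level = integer(), threshold = numeric(), seed_id = character(),
    unit_id = character(), identity = numeric(), coverage = numeric()
  ))))
}
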