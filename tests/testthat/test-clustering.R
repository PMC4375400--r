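test_that("level-100 merging combines identical sequences and exact subfragments", {
  set.seed(31)
  s <- random_aa(100)
  rec <- protein_records(
    c("P1", "P2", "P3", "P4"),
    c(s, s, substr(s, 20, 49), substitute_k(s, 1))
  )
  cs <- dedupe100(rec)
  expect_equal(length(cs$clusters), 2L)
  expect_equal(cs$member_index[["P1"]], cs$member_index[["P2"]])
  expect_equal(cs$member_index[["P3"]], cs$member_index[["P1"]]) # subfragment merges
  expect_false(cs$member_index[["P4"]] == cs$member_index[["P1"]]) # 1 mismatch: separate
  big <- Filter(function(cl) length(cl$member_ids) == 3, cs$clusters)[[1]]
  expect_equal(big$seed_id, "P1") # longest member, id tie-break
})

test_that("subfragment merging is transitive via the containing sequence", {
  set.seed(32)
  s <- random_aa(120)
  rec <- protein_records(
    c("A", "B", "C"),
    c(s, substr(s, 1, 60), substr(s, 70, 110)) # B and C share nothing directly
  )
  cs <- dedupe100(rec)
  expect_equal(length(cs$clusters), 1L)
})

test_that("the 80% seed-overlap rule separates partial-sequence matches", {
  set.seed(33)
  s <- random_aa(100)
  # member identical to the seed over 79% of it: must stay separate even at 50%
  rec79 <- protein_records(c("SEED0", "FRAG1"), c(s, substr(s, 1, 79)))
  cs79 <- greedy_cluster(rec79, 0.50, 0.80, level = 50)
  expect_equal(length(cs79$clusters), 2L)
  cs79b <- greedy_cluster(rec79, 0.90, 0.80, level = 90)
  expect_equal(length(cs79b$clusters), 2L)
  # at 81% coverage the same member merges
  rec81 <- protein_records(c("SEED0", "FRAG1"), c(s, substr(s, 1, 81)))
  cs81 <- greedy_cluster(rec81, 0.50, 0.80, level = 50)
  expect_equal(length(cs81$clusters), 1L)
  # oracle confirms the boundary coverages
  expect_equal(oracle_align(s, substr(s, 1, 79))$seed_coverage, 0.79)
  expect_equal(oracle_align(s, substr(s, 1, 81))$seed_coverage, 0.81)
})

test_that("a full-coverage member at 92% identity joins a 90% cluster", {
  set.seed(34)
  s <- random_aa(100)
  m <- substitute_k(s, 8)
  expect_equal(oracle_align(s, m)$identity_fraction, 0.92)
  cs <- greedy_cluster(
    protein_records(c("AASEED", "ZMEMB1"), c(s, m)), 0.90, 0.80,
    level = 90
  )
  expect_equal(length(cs$clusters), 1L)
  expect_equal(cs$clusters[[1]]$seed_id, "AASEED") # equal length: id tie-break
})

test_that("joining prefers the highest-identity qualifying seed", {
  set.seed(35)
  s1 <- random_aa(100)
  s2 <- substitute_k(s1, 20) # second founder, 80% identical to first
  m <- substitute_k(s2, 2) # 98% to s2, ~78% to s1
  cs <- greedy_cluster(
    protein_records(c("A1", "B2", "C3"), c(s1, s2, m)), 0.70, 0.80,
    level = 90
  )
  expect_equal(cs$member_index[["C3"]], cs$member_index[["B2"]])
})

test_that("representative selection follows the curation/name/organism/length tuple", {
  base <- list(
    id = c("LONGU", "SHORTR"), sequence = c(paste(rep("MKVLAW", 20), collapse = ""), "MKVLAWGHED"),
    reviewed = c(FALSE, TRUE)
  )
  rec <- protein_records(base$id, base$sequence, reviewed = base$reviewed)
  expect_equal(select_representative(base$id, rec), "SHORTR") # curation outranks length

  rec2 <- protein_records(
    c("P1", "P2"), c("MKVLAWGHED", "MKVLAWGHED"),
    protein_name = c("putative kinase", "hexokinase")
  )
  expect_equal(select_representative(c("P1", "P2"), rec2), "P2")

  rec3 <- protein_records(
    c("P1", "P2"), c("MKVLAWGHED", "MKVLAWGHED"),
    organism = c("Zea mays", "Danio rerio")
  )
  expect_equal(select_representative(c("P1", "P2"), rec3), "P2") # model organism

  rec4 <- protein_records(
    c("P1", "P2"),
    c(paste(rep("MKVLAW", 20), collapse = ""), paste(rep("MKVLAW", 13), collapse = ""))
  )
  expect_equal(select_representative(c("P1", "P2"), rec4), "P1") # length last

  expect_error(
    select_representative(c("P1", "MISSING"), rec4),
    "MISSING",
    class = "refclust_validation_error"
  )
})

test_that("a one-family corpus collapses through the hierarchy as traced by hand", {
  set.seed(36)
  s <- random_aa(100)
  rec <- protein_records(
    c("FULL1", "COPY2", "FRAG3", "HOMO4"),
    c(s, s, substr(s, 11, 90), substitute_k(s, 8))
  )
  h <- build_hierarchy(rec)
  expect_equal(length(h$level100$clusters), 2L) # {FULL1,COPY2,FRAG3} + {HOMO4}
  expect_equal(length(h$level90$clusters), 1L)
  expect_equal(length(h$level50$clusters), 1L)
  expect_equal(sort(h$level90$clusters[[1]]$member_ids), sort(rec$id))
  validate_hierarchy(h)
})

test_that("unrelated families never merge at any level and empty input yields empty levels", {
  set.seed(37)
  a <- random_aa(80)
  b <- random_aa(80)
  rec <- protein_records(
    c("A1", "A2", "B1", "B2"),
    c(a, substitute_k(a, 4), b, substitute_k(b, 4))
  )
  h <- build_hierarchy(rec)
  expect_equal(length(h$level100$clusters), 4L)
  expect_equal(length(h$level90$clusters), 2L)
  expect_equal(length(h$level50$clusters), 2L)
  expect_false(h$level50$member_index[["A1"]] == h$level50$member_index[["B1"]])

  h0 <- build_hierarchy(protein_records(character(), character()))
  expect_equal(length(h0$level100$clusters), 0L)
  expect_equal(length(h0$level90$clusters), 0L)
  expect_equal(length(h0$level50$clusters), 0L)
})

test_that("every cluster admitted at 90/50 satisfies its thresholds by the DP oracle", {
  corpus <- make_family_corpus(family_spec(
    n_families = 4, members_per_family = 5, seed_length = 80, rng_seed = 8
  ))
  audit <- audit_thresholds(build_hierarchy(corpus$records))
  expect_gt(nrow(audit), 10L)
  expect_true(all(audit$identity >= audit$threshold))
  expect_true(all(audit$coverage >= 0.80))
})

test_that("hierarchies are byte-reproducible for fixed input", {
  corpus <- make_family_corpus(family_spec(
    n_families = 3, members_per_family = 4, seed_length = 50, rng_seed = 13
  ))
  d1 <- file.path(tempdir(), "hrun1")
  d2 <- file.path(tempdir(), "hrun2")
  write_hierarchy(build_hierarchy(corpus$records), d1)
  write_hierarchy(build_hierarchy(corpus$records), d2)
  for (f in list.files(d1)) {
    expect_identical(
      readBin(file.path(d1, f), "raw", file.size(file.path(d1, f))),
      readBin(file.path(d2, f), "raw", file.size(file.path(d2, f)))
    )
  }
})

test_that("families near 95% identity stay whole at 90% and near 55% split then merge", {
  # parameter recovery on 50 replicate families: high-identity families must
  # each form one level-90 cluster; low-identity families must split at 90
  # and re-unite at 50. Long sequences keep the binomial identity noise well
  # away from the thresholds.
  check_families <- function(spec, expect_one_at_90) {
    corpus <- make_family_corpus(spec)
    h <- build_hierarchy(corpus$records)
    fams <- split(corpus$truth$member_id, corpus$truth$family_id)
    ok <- vapply(fams, function(ids) {
      n90 <- length(unique(h$level90$member_index[ids]))
      n50 <- length(unique(h$level50$member_index[ids]))
      if (expect_one_at_90) n90 == 1L && n50 == 1L else n90 > 1L && n50 == 1L
    }, logical(1))
    ok
  }
  ok_high <- check_families(
    family_spec(
      n_families = 25, members_per_family = 3, seed_length = 300,
      target_identity = 0.95, fragment_rate = 0, rng_seed = 101
    ),
    expect_one_at_90 = TRUE
  )
  ok_low <- check_families(
    family_spec(
      n_families = 25, members_per_family = 3, seed_length = 900,
      target_identity = 0.55, fragment_rate = 0, rng_seed = 102
    ),
    expect_one_at_90 = FALSE
  )
  expect_gte(mean(c(ok_high, ok_low)), 0.95)
})
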