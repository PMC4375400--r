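test_that("uniprot FASTA headers map onto record metadata", {
  fa <- write_tmp(c(
    ">sp|P00001|A_HUMAN Alcohol dehydrogenase OS=Homo sapiens GN=ADH1", "MKV",
    ">tr|Q00002|B_ECOLI Uncharacterized protein (Fragment) OS=Escherichia coli", "MK"
  ), ".fasta")
  rec <- read_fasta(fa, "uniprot")
  expect_equal(rec$id, c("P00001", "Q00002"))
  expect_equal(rec$reviewed, c(TRUE, FALSE))
  expect_equal(rec$organism, c("Homo sapiens", "Escherichia coli"))
  expect_equal(rec$is_fragment, c(FALSE, TRUE))
  expect_equal(rec$length, c(3L, 2L))
  expect_equal(rec$is_model_organism, c(TRUE, FALSE))
  expect_equal(rec$protein_name[1], "Alcohol dehydrogenase")
})

test_that("plain FASTA dialect applies defaults and empty files yield empty sets", {
  fa <- write_tmp(c(">seq1 some description", "MKVA"), ".fasta")
  rec <- read_fasta(fa, "plain")
  expect_equal(rec$id, "seq1")
  expect_false(rec$reviewed)
  expect_equal(rec$organism, "")
  expect_false(rec$is_fragment)

  empty <- read_fasta(write_tmp(character(), ".fasta"), "uniprot")
  expect_s3_class(empty, "protein_records")
  expect_equal(nrow(empty), 0L)
})

test_that("FASTA parsing failures raise typed errors", {
  bad_header <- write_tmp(c(">not-a-uniprot-header", "MKV"), ".fasta")
  expect_error(read_fasta(bad_header, "uniprot"),
    class = "refclust_format_error"
  )
  dup <- write_tmp(c(">sp|P1|X a OS=Homo sapiens", "MK", ">sp|P1|X a OS=Homo sapiens", "MV"), ".fasta")
  expect_error(read_fasta(dup, "uniprot"), "P1", class = "refclust_validation_error")
  empty_seq <- write_tmp(c(">sp|P1|X a", "", ">sp|P2|Y b", "MK"), ".fasta")
  expect_error(read_fasta(empty_seq, "uniprot"), class = "refclust_format_error")
})

test_that("FASTA writer round-trips through the reader", {
  rec <- protein_records(
    id = c("P10", "Q20"), sequence = c("MKVLAW", "GHEDAK"),
    reviewed = c(TRUE, FALSE), protein_name = c("kinase alpha", "putative thing"),
    organism = c("Mus musculus", "Zea mays"), is_fragment = c(FALSE, TRUE)
  )
  path <- tempfile(fileext = ".fasta")
  write_fasta(rec, path)
  back <- read_fasta(path, "uniprot")
  expect_equal(back$sequence, rec$sequence)
  expect_equal(back$reviewed, rec$reviewed)
  expect_equal(back$organism, rec$organism)
  expect_equal(back$is_fragment, rec$is_fragment)
})

test_that("OBO chain parses into a rooted DAG with is_a edges", {
  dag <- chain_dag()
  expect_equal(nrow(dag$terms), 3L)
  expect_equal(nrow(dag$edges), 2L)
  expect_equal(dag$root_id, "GO:0000001")
})

test_that("obsolete terms are kept but excluded from closures", {
  obo <- write_tmp(c(
    chain_obo_text(),
    "[Term]", "id: GO:0000009", "name: dead term",
    "namespace: molecular_function", "is_obsolete: true", ""
  ), ".obo")
  dag <- read_obo(obo)
  expect_true(dag$terms$obsolete[dag$terms$id == "GO:0000009"])
  expect_error(go_closure(dag, "GO:0000009", "ancestors"),
    class = "refclust_validation_error"
  )
  expect_false("GO:0000009" %in% go_closure(dag, "GO:0000001", "offspring"))
})

test_that("namespace filtering drops off-namespace terms and their edges", {
  obo <- write_tmp(c(
    chain_obo_text(),
    "[Term]", "id: GO:0000010", "name: nucleus",
    "namespace: cellular_component", "is_a: GO:0000001", ""
  ), ".obo")
  dag <- read_obo(obo, "molecular_function")
  expect_equal(nrow(dag$terms), 3L) # the CC stanza is gone
  expect_false("GO:0000010" %in% dag$terms$id)
})

test_that("cyclic or multi-root ontologies are structural errors", {
  cyc <- write_tmp(c(
    "[Term]", "id: GO:1", "name: a", "namespace: molecular_function", "is_a: GO:2", "",
    "[Term]", "id: GO:2", "name: b", "namespace: molecular_function", "is_a: GO:1", ""
  ), ".obo")
  expect_error(read_obo(cyc), class = "refclust_validation_error")
  two_roots <- write_tmp(c(
    "[Term]", "id: GO:1", "name: a", "namespace: molecular_function", "",
    "[Term]", "id: GO:2", "name: b", "namespace: molecular_function", ""
  ), ".obo")
  expect_error(read_obo(two_roots), "root", class = "refclust_validation_error")
})

test_that("annotation reader keeps set semantics and drops unknown terms with a count", {
  dag <- chain_dag()
  tsv <- write_tmp(c(
    "P1\tGO:0000002", "P1\tGO:0000003", "P2\tGO:0000002",
    "P1\tGO:0000002", # duplicate row
    "P3\tGO:9999999" # unknown term
  ))
  expect_message(ann <- read_annotations(tsv, dag), "1 annotation row")
  expect_equal(ann$P1, c("GO:0000002", "GO:0000003"))
  expect_equal(ann$P2, "GO:0000002")
  expect_null(ann$P3)
  expect_equal(attr(ann, "dropped"), 1L)

  empty <- read_annotations(write_tmp(character()), dag)
  expect_length(empty, 0L)
})

test_that("extra annotation columns are ignored so GAF-like rows pass", {
  dag <- chain_dag()
  tsv <- write_tmp(c("P1\tGO:0000003\tIEA\textra junk"))
  ann <- read_annotations(tsv, dag)
  expect_equal(ann$P1, "GO:0000003")
})

test_that("BLAST tabular parsing preserves order and converts numerics", {
  tsv <- write_tmp(c(
    "q1\ts1\t97.5\t200\t5\t0\t1\t200\t1\t200\t1e-50\t380",
    "q1\ts2\t45.0\t150\t80\t3\t10\t160\t5\t150\t0.002\t88"
  ))
  hits <- read_hits(tsv)
  expect_equal(nrow(hits), 2L)
  expect_equal(hits$evalue, c(1e-50, 2e-3))
  expect_equal(hits$subject_id, c("s1", "s2"))
  expect_equal(nrow(read_hits(write_tmp(character()))), 0L)
})

test_that("malformed hit rows raise errors naming the line", {
  short_row <- write_tmp(c("q1\ts1\t97.5"))
  expect_error(read_hits(short_row), "line 1", class = "refclust_format_error")
  bad_num <- write_tmp(c("q1\ts1\t97.5\t200\t5\t0\t1\t200\t1\t200\tnot-a-number\t380"))
  expect_error(read_hits(bad_num), class = "refclust_format_error")
})

test_that("cluster TSV writer/reader round-trips randomized cluster sets", {
  set.seed(11)
  for (rep in 1:5) {
    corpus <- make_family_corpus(
      family_spec(
        n_families = 3, members_per_family = 4, seed_length = 40,
        target_identity = 0.9, rng_seed = rep
      )
    )
    h <- build_hierarchy(corpus$records)
    for (lv in c("level100", "level90", "level50")) {
      path <- tempfile(fileext = ".tsv")
      write_clusters(h[[lv]], path)
      back <- read_clusters(path)
      expect_equal(back$level, h[[lv]]$level)
      expect_equal(
        back$clusters[order(vapply(back$clusters, `[[`, character(1), "cluster_id"))],
        h[[lv]]$clusters[order(vapply(h[[lv]]$clusters, `[[`, character(1), "cluster_id"))]
      )
      expect_equal(back$member_index[sort(names(back$member_index))],
        h[[lv]]$member_index[sort(names(h[[lv]]$member_index))])
    }
  }
})

test_that("singleton clusters serialize as one self-referential row", {
  cs <- cluster_set(90, list(new_cluster(90, "P1", "P1", "P1")))
  path <- tempfile(fileext = ".tsv")
  write_clusters(cs, path)
  rows <- read.delim(path, colClasses = "character")
  expect_equal(nrow(rows), 1L)
  expect_equal(rows$seed_id, rows$member_id)
  expect_equal(rows$representative_id, rows$member_id)
})

test_that("a hand-edited file with a duplicated member is a partition error", {
  path <- write_tmp(c(
    "cluster_id\tlevel\tseed_id\trepresentative_id\tmember_id",
    "UniRef90_A\t90\tA\tA\tA",
    "UniRef90_A\t90\tA\tA\tB",
    "UniRef90_C\t90\tC\tC\tB"
  ), ".tsv")
  expect_error(read_clusters(path), "B", class = "refclust_validation_error")
})

test_that("cluster writer output is deterministic byte for byte", {
  corpus <- make_family_corpus(family_spec(
    n_families = 2, members_per_family = 3, seed_length = 30, rng_seed = 5
  ))
  h <- build_hierarchy(corpus$records)
  p1 <- tempfile(fileext = ".tsv")
  p2 <- tempfile(fileext = ".tsv")
  write_clusters(h$level90, p1)
  write_clusters(h$level90, p2)
  expect_identical(readBin(p1, "raw", file.size(p1)), readBin(p2, "raw", file.size(p2)))
})

test_that("domain tables validate their coordinates", {
  tsv <- write_tmp(c(
    "protein_id\tdomain_id\tstart\tend\tprotein_length",
    "P1\tPF00001\t10\t95\t100"
  ), ".tsv")
  d <- read_domains(tsv)
  expect_equal(d$end, 95)
  bad <- write_tmp(c(
    "protein_id\tdomain_id\tstart\tend\tprotein_length",
    "P1\tPF00001\t10\t120\t100"
  ), ".tsv")
  expect_error(read_domains(bad), class = "refclust_validation_error")
})
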