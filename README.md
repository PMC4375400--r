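# refclust

Reference-cluster databases (UniRef-style) replace a redundant protein
sequence database by clusters at fixed identity resolutions — 100%, 90% and
50% — each named after its best-annotated representative. Done well, this
buys three things at once: redundancy removal (identical sequences and
exact subfragments collapse at the 100% level), functional coherence
(members of a 90/50 cluster share molecular function often enough that
clusters can drive annotation), and cheaper similarity searches (search
the seed sequences, then expand hits back to cluster members). `refclust`
is an R toolkit for people who want to build and interrogate such
clusterings at laboratory scale: it implements the clustering procedure
itself, the Gene Ontology consistency analysis used to audit clusters, and
the evaluation machinery for cluster-expanded searches — plus a synthetic
corpus generator so that everything runs without downloading a database.

## The methods in brief

**Clustering.** Level 100 merges identical sequences and exact substrings
(transitively, no overlap threshold). Levels 90 and 50 run a greedy
incremental pass over the finer level's seed sequences, longest first: a
record joins a cluster only if its identity to the cluster seed — identical
aligned residues over the shorter sequence's length, from a semi-global
BLOSUM62 alignment (gap open 10, extend 1) — meets the level threshold
*and* the alignment covers at least 80% of the seed. The coverage rule
keeps partial-sequence matches (polyprotein components, shared single
domains) from fusing unrelated families. Representatives maximize
(reviewed, name quality, model organism, length), and cluster ids are
`UniRef<level>_<representative>`. `incremental_update()` folds new records
into an existing hierarchy, favoring existing clusters and preserving ids
whose representative is unchanged.

**Consistency.** On an is_a DAG of molecular-function terms, a term's
specificity is `P = 1 - offspring / (offspring + ancestors)` (closures
exclude the term itself): leaves score exactly 1, the root exactly 0.
Clusters with ≥ 2 annotated members are categorized from the members'
direct term sets: identical sets (I); a shared core with extras that are no
more specific (II-1) or strictly more specific (II-2); no shared term but a
common non-root ancestor (III); traceable only to the root (IV).

**Search evaluation.** `expand_hits()` turns seed-database hits into
member-level hits (inheriting e-value/bit score); `precision_recall()`
compares expanded against reference searches; `build_domain_pairs()`
builds truth pairs from domains spanning > 80% of a target (interval-union
semantics); `roc50()` scores rankings by the ROC area up to the 50th false
positive.

## A worked example

```r
library(refclust)

corpus <- make_family_corpus(family_spec(n_families = 4, members_per_family = 6, rng_seed = 42))
h <- build_hierarchy(corpus$records)
print(h)
#> uniref_hierarchy over 24 records
#> cluster_set level 100 : 23 clusters, 24 members ( 22 singletons )
#> cluster_set level 90 : 9 clusters, 24 members ( 5 singletons )
#> cluster_set level 50 : 8 clusters, 24 members ( 3 singletons )
```

Four families of six members (95% identity, 30% fragments) collapse to one
90% cluster per family plus fragment clusters that fail the 80% seed
overlap — one fragment was an exact substring of its family reference and
merged already at the 100% level (23 clusters, not 24).

Searching only the 8 level-50 seed sequences and expanding the hits back
through the clusters loses nothing relative to the exhaustive all-vs-all
search at the same identity cutoff:

```r
fx <- make_hit_fixture(corpus$records, corpus$truth, h$level50)
ex <- expand_hits(fx$seed_hits, h$level50)
full <- fx$full_hits[fx$full_hits$query_id != fx$full_hits$subject_id, ]
expd <- ex[ex$query_id != ex$subject_id, ]
precision_recall(paste(expd$query_id, expd$subject_id),
                 paste(full$query_id, full$subject_id))
#> precision 1.000 recall 1.000 (TP 120, expanded 120, reference 120)
```

On the ontology side, a middle term of a small two-level binary DAG has
six descendants and one ancestor, hence low specificity:

```r
dag <- make_toy_dag(depth = 3, branching = 2)
go_specificity(dag, "GO:0000002")
#>      term_id         P n_offspring n_ancestors
#> 1 GO:0000002 0.1428571           6           1

sets <- make_category_scenario("II-2", dag, n_members = 3, rng_seed = 1)
categorize(sets, dag)$category
#> [1] "II-2"
```

A command-line front end wraps the same functions
(`system.file("cli", "refclust", package = "refclust")`): subcommands
`cluster build/update`, `go-consistency`, `eval expand/pr/pairs/roc50` and
`simulate corpus/dag/scenario`, each writing its resolved configuration
next to its outputs.

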