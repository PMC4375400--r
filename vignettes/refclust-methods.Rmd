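---
title: "Methods: reference clustering, annotation consistency and cluster-expanded search"
author: "refclust"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: reference clustering, annotation consistency and cluster-expanded search}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(refclust)
```

## The problem

Reference cluster databases such as UniRef partition a protein sequence
space into clusters at fixed identity resolutions (100%, 90%, 50%), hide
redundancy behind a single best-annotated representative per cluster, and
in doing so make two practical promises: that a cluster groups proteins of
like molecular function, and that searching the reduced seed database and
expanding hits back to cluster members loses almost nothing relative to
searching the full database. `refclust` implements the clustering
procedure, the ontology-based consistency analysis and the search-expansion
evaluation as a self-contained toolkit, with a synthetic corpus generator
in place of database downloads.

## Hierarchical clustering

**The 100% level.** Two records share a level-100 cluster exactly when one
sequence is an identical copy or an exact substring of the other; merging
is transitive through the containing sequence. No overlap threshold applies
here — the level exists to absorb fragment redundancy. Records are
processed longest-first (ties broken by accession), so the seed of every
cluster is its longest member.

**The 90% and 50% levels.** The level-100 seed sequences are clustered by a
greedy incremental pass (CD-HIT style): records sorted longest-first either
found a new cluster, becoming its *seed*, or join an existing cluster. A
record may join only if, against that cluster's seed,

* the identity fraction — identical aligned residues divided by the
  *shorter* sequence's length (the CD-HIT convention; switchable to
  aligned-length in `scoring_config()`) — reaches the level threshold
  (0.90 / 0.50), and
* the aligned region covers at least 80% of the seed
  (`cluster_config(overlap = 0.80)`).

Among qualifying clusters the highest identity wins, with ties going to the
earliest-founded cluster. The coverage rule is what keeps polyproteins,
multi-domain chimeras and stray fragments from gluing unrelated families
together: a member identical to a seed over only 79% of it stays out, at
81% it joins. Each coarser cluster is then the union of whole finer
clusters, so nesting holds by construction — and, deliberately, exact
subfragments absorbed at the 100% level ride along into 90/50 clusters
even when they cover less than 80% of the coarser seed, matching how the
production databases are built (and why expanded hit lists recover
fragment sequences). The post-hoc threshold audit in the test suite
therefore checks the units the greedy stage actually admitted (level-100
seeds against their 90-seed, level-90 seeds against their 50-seed).

**Alignment.** Pairwise statistics come from a semi-global alignment
(`Biostrings::pairwiseAlignment`, `type = "overlap"`: end gaps free on
both sequences) under BLOSUM62 with affine gap penalties, open 10 / extend
1 per residue. The package extends the shipped BLOSUM62 with U
(selenocysteine) and O (pyrrolysine) rows (self-match +1, otherwise -4) so
the full input alphabet aligns. Identity counting is score-independent
once the alignment is fixed. A sequence consisting only of ambiguity
characters cannot be aligned meaningfully and raises a typed error. The
test suite re-derives every alignment statistic with an independent
ends-free affine dynamic program, which reproduces implementation scores
exactly.

**Representatives.** Within a cluster the representative maximizes the
priority tuple: reviewed status, then protein-name quality (names
containing *hypothetical*, *putative*, *uncharacterized* or *probable*
rank last), then model-organism membership (twelve configurable taxa:
the nine Gene Ontology reference genomes plus cow, dog and pig), then
length, with the accession as a final deterministic tie-break. Cluster
identifiers are `UniRef<level>_<representative accession>`, so an
identifier changes only when its representative does.

**Incremental updates.** `incremental_update()` mirrors the production
procedure that favors existing clusters: new records (longest-first) try
to join at 100 (substring relation), then 90, then 50, with the same
qualification rules against existing seeds; only records qualifying
nowhere found new clusters. Representatives are re-selected only for
clusters that gained members, so identifiers of untouched clusters are
stable by construction. A new record longer than the seed of the cluster
it joins becomes that cluster's seed — the alternative (refusing the
join) would contradict the intent of favoring existing clusters, while
keeping the old seed would break seed maximality. Updates are single-shot
operations; release scheduling is out of scope.

## Term specificity and consistency categories

Molecular-function consistency inside a cluster is judged on the members'
*direct* GO annotations over an is_a-only DAG. Only is_a edges build the
hierarchy (part_of and regulates are ignored): the specificity metric is
stated on a single hierarchy and molecular function is dominated by is_a;
this is a recorded choice, not a claim about what the original analysis
traversed. Obsolete terms are retained for diagnostics but never enter
closures. The specificity of a term is

$$P = 1 - \frac{\#\text{offspring}}{\#\text{offspring} + \#\text{ancestors}}$$

with both counts distinct-term transitive closures excluding the term
itself, so a leaf scores exactly 1.0 and the root exactly 0.0, and P
strictly increases along every parent-to-child edge (a child loses
offspring and gains ancestors). A cluster's specificity is the maximum P
over all terms on any member.

Clusters with at least two annotated members (`min_annotated = 2`;
unannotated members are ignored, not treated as inconsistent) are assigned
one of five categories by a decision ladder over the direct sets:

* **I** — all members carry identical sets;
* **II-1** — a non-empty shared core, and no extra term is a strict
  descendant of a shared term (extras are typically parents of shared
  terms, i.e. no more specific);
* **II-2** — a shared core and at least one extra term strictly below a
  shared term (more specific; mixed extras resolve here);
* **III** — no shared term, but some non-root term is an ancestor-or-self
  of at least one term of *every* member; the most specific such witness
  (ties by term id) is reported;
* **IV** — members trace together only at the root.

Two choices deserve emphasis. Annotations are *not* propagated to
ancestors before intersection: propagation would make II-1 unattainable,
because a member carrying a parent of a shared term as an extra would have
that parent swallowed into every member's closure. And "more specific" for
II-2 means strict descent in the DAG, not a numeric comparison of P values
— two terms can have similar P without any ancestry relation. The category
assignment is provably order-invariant (it only uses set intersections and
closures), and the suite fuzzes this along with the I ⇔ all-sets-equal
biconditional.

## Search evaluation

`expand_hits()` replaces each hit on a cluster seed (or representative) by
hits on all cluster members, inheriting the seed hit's e-value and bit
score — expansion happens after the search, without re-scoring, and the
provenance columns record the originating seed. A subject reachable
through several seeds keeps its best e-value. Precision divides the hits
common to both searches by the expanded search's total, recall by the
reference search's total (the reference is treated as all-true); both are
flagged rather than thrown on empty denominators, and the default
comparison threshold is e-value < 1e-4.

Truth query–target pairs for distant-similarity evaluation come from
domain annotations: a pair is kept when query and target share a domain
whose hits span more than 80% of the target. The default `"union"` mode
merges the intervals of all shared-domain hits (overlaps counted once, via
`IRanges::reduce`); `"single"` mode requires one hit alone to clear the
threshold, for the per-domain reading of the criterion. Per-query
detection differences are reported as `100 * (nA - nB) / nB` with an
infinite flag binned as ">250%" when the reference found nothing.

ROC50 truncates the ROC curve at the 50th false positive: each of the
first `min(50, total FP)` false positives contributes the count of true
positives ranked above it, normalized by `n_false_used * n_true` where
`n_true` counts the query's truth positives (so positives missing from the
ranking depress the score). With fewer than 50 false positives the
available count normalizes; with none at all the score is the retrieved
fraction of truth positives. Rankings order by e-value, then bit score
descending, then subject id. The implementation is checked against a
literal staircase enumeration on every true/false labeling of rankings up
to 8 hits.

## The synthetic generator

`make_family_corpus()` draws, per family, a random reference sequence
(uniform over the 20 canonical residues — compositional realism is
irrelevant to the invariants under test) and derives members by i.i.d.
substitutions with probability `1 - target_identity` per site,
substitutions always changing the residue. Expected member-to-reference
identity therefore equals the target exactly, and the realized per-site
identity is recorded in the truth table. A member is emitted as a
contiguous fragment with probability `fragment_rate`, covering at least
`fragment_min_cover` of the member. The reference itself enters the corpus
as a record whose accession block sorts before the derived members'
(references "R…", members "S…", each block shuffled): reference sequences
predate their homologs' accessions, and this anchors greedy seeds at
family references so that `target_identity` is directly the
member-to-cluster-seed identity. Ids encode nothing about family
membership.

Default conditions (`family_spec()`): 20 families × 10 members, 120
residue references, target identity 0.95, fragment rate 0.30, minimum
fragment cover 0.50. These sizes keep family identity well above the 90%
threshold, produce a realistic mix of full-coverage members and fragments
on both sides of the 80% overlap rule, and make the full corpus (200
records) cheap enough that the whole pipeline — clustering, oracle audit,
all-vs-all search — runs in the test suite. The parameter-recovery tests
use their own corpora: 25 families at target 0.95 with 300-residue
references, and 25 at 0.55 with 900-residue references, lengths chosen by
a binomial power analysis so that per-member identity noise
(sd ≈ √(t(1−t)/L)) sits more than three standard deviations from the
nearest clustering threshold — the properties then hold for ≥95% of
families by design rather than by luck.

What the generator does *not* emulate: insertions and deletions (kept out
so realized identity stays analytically predictable; the alignment layer
handles gaps, the generator just never produces them), domain shuffling,
phylogenetic correlation between members, biased composition, and
low-complexity regions. Passing tests therefore demonstrate the
correctness of the procedures under controlled identity/coverage
structure, not robustness to every pathology of real sequence databases —
notably the repeat- and composition-driven failure modes that full-scale
searches exhibit.

The miniature search engine behind `make_hit_fixture()` scores every
query–subject pair with the package's own aligner and reports subjects at
or above an identity cutoff (default 0.5, matching the coarsest clustering
level), with e-value defined as `1 - identity` — a monotone stand-in that
preserves ranking semantics. Self-hits stay in, as in a real database
search; evaluation code excludes the trivial self-pair. Exhaustive
all-vs-all hits serve as the reference search and seed-database hits (the
level-50 seeds as targets), expanded through the clusters, as the
evaluated search.

## Numerical and degenerate-input choices

* All residue coordinates are 1-based inclusive; nothing converts them.
* Thresholds compare with `>=` (identity, coverage) except the domain-span
  rule, which is strict (`> 0.80`), following its "more than 80%" phrasing.
* Writers emit UTF-8 with LF endings and globally sorted rows, so equal
  inputs give byte-identical outputs; every pipeline stage is deterministic
  given the configuration and RNG seeds.
* Toy ontologies: `depth` counts levels below the root (depth 2, branching
  1 is a three-term chain); cross-edges always point from a deeper term to
  a strictly shallower one, keeping the graph acyclic and single-rooted.
* Degenerate cases are flagged, not thrown, where a value can still be
  used (empty search sides in precision/recall, zero-truth ROC50,
  0/0 percent differences); structural violations (cycles, multiple roots,
  partition breaks, coordinate overflows) raise typed errors.
* Percentages in category tables round to two decimals.

## Known limitations

The greedy pass compares every record against existing seeds with no
k-mer prefilter, so complexity is quadratic in corpus size — fine at
toolkit scale, not at database scale. The 80% overlap is always tested
against the seed, including after an incremental update changes the
representative (the seed is re-anchored only when a longer member joins).
Isoform handling, UniParc ingestion and the dissemination XML format are
out of scope, as are biological-process and cellular-component namespaces
in the consistency analysis.
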