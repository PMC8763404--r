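---
title: "gutbridge: models, parameters and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{gutbridge: models, parameters and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`gutbridge` compares genome-resolved gut-microbiota catalogs of two host
species and identifies functionally equivalent bacterial species across
them. This vignette documents the underlying models, the parameters a user
might tune, the numerical conventions, and the limits of what the synthetic
data can demonstrate.

## Genome quality model

Assembly quality is summarized from CheckM-style estimates as

* quality score `QS = completeness − 5 × contamination`, and
* modified quality score `mQS = QS + ln(N50)`.

The natural logarithm is used in `mQS`; the base is a convention, and the
natural log is the default of the analysis environment, which makes
representative ranking reproducible. Since `ln(N50)` spans roughly 9–16 for
bacterial assemblies, the term acts as a contiguity tie-break on top of the
percent-scale `QS` rather than dominating it.

Tiers follow MIMAG-style practice. *High* quality requires completeness
≥ 90%, contamination < 5%, and structural criteria: at most 500 contigs,
genome size ≤ 8 Mb, N50 ≥ 10 kb, mean contig length ≥ 5 kb. *Medium-plus*
requires completeness ≥ 50%, contamination < 5% and `QS ≥ 50`. Two
conventions deserve note:

* The contamination cut is strict (`< 5`) by default; descriptions of the
  same rule sometimes use `≤ 5`. `classify_tier(contamination_inclusive =
  TRUE)` switches the convention.
* An N50 threshold is occasionally quoted as "10,000 kb"; a 10 Mb N50 would
  exclude essentially all metagenome-assembled genomes, so the intended
  10 kb (10,000 bp) is used.
* Structural criteria apply to isolates and MAGs alike by default;
  `classify_tier(structural_criteria = FALSE)` disables them.

Percentages are always on the 0–100 scale. Inputs that look like 0–1
fractions are rejected rather than silently rescaled, because a 0.95
"completeness" is more likely a unit error than a genuinely 1%-complete
genome.

## Sketching, dereplication and species clustering

A genome's sketch is the bottom-*s* MinHash of its canonical *k*-mers
(each *k*-mer is reduced to the lexicographic minimum of itself and its
reverse complement; *k*-mers containing non-ACGT symbols are skipped).
Defaults are *k* = 21 and *s* = 1000, the conventional desk-scale choices
for bacterial genomes; both are configurable per sketch. Hashing uses a
fixed 64-bit mixing function (a seeded splitmix64 finalizer) whose top 53
bits are kept, so hash values are exactly representable as R doubles and in
JSON, and sketches are bit-reproducible across platforms. The truncation
costs nothing statistically: 53-bit collisions are vanishingly rare at
sketch scale.

Two sketches estimate the Jaccard similarity *j* of the underlying k-mer
sets as the fraction of the *s* smallest hashes of the merged sketch
present in both. The Mash distance `d = −(1/k)·ln(2j/(1+j))` (clipped to
[0, 1], with `j = 0` mapped to `d = 1`) approximates per-base divergence,
and `ANI = 100(1 − d)`. Under the substitution-only model of the
generator the estimator is essentially unbiased: for per-site divergence
*m*, the expected k-mer Jaccard is `(1−m)^k / (2 − (1−m)^k)`, and plugging
it into the distance formula returns `−ln(1−m) ≈ m` exactly.

*Dereplication* removes near-identical genomes: visiting genomes by
descending `mQS` (ties by id), a genome is kept only if its Mash distance
to every kept genome exceeds 0.001 (99.9% ANI). *Species clustering*
applies the conventional 95% ANI species boundary with an alignment
fraction of 0.6. Alignment fraction is not estimable from bottom-*s*
sketches, so sketch *containment* (shared hashes over the smaller sketch's
size) stands in for it; this is an approximation of the coverage criterion
used by alignment-based dereplication tools and behaves like it when
genomes are of comparable size. Clustering is single-pass greedy centroid:
genomes in `mQS` order join the first cluster whose representative meets
both thresholds, else found a new cluster. A two-step
primary/secondary-threshold workflow could differ in rare edge cases near
the boundary; the single-pass rule is deterministic and applies the same
pairwise decision everywhere. All ties anywhere are broken by lexicographic
genome id so results are reproducible run to run.

An isolate is *previously uncultured* when its estimated ANI to every
genome of a cultured reference collection is below 95%.

## Pangenome feature matrices and pathway calls

Per-genome annotations are reduced to presence/absence — a genome either
carries a feature or it does not, regardless of copy number — and a species
profile is the fraction of member genomes carrying each feature, with
unannotated members still counted in the denominator. Feature identifiers
are namespaced by scheme (`INTERPRO:IPR023990`, `KEGG_KO:K00929`) so
schemes can be combined without collisions; combined profiles are the union
of namespaced features with no cross-scheme deduplication.

`feature_search()` returns species at or above a carrying-fraction
threshold, ranked by number of encoding genomes first and fraction second:
in a catalog where species differ greatly in genome counts, the number of
genomes encoding a gene is the better proxy for how confidently and
dominantly a species carries it. Threshold comparisons are inclusive
(`≥`), so a species at exactly the 70% producer threshold qualifies.

Butyrate terminal pathways illustrate multi-gene definitions: the direct
pathway needs butyryl-CoA:acetate CoA-transferase (IPR023990) alone, the
indirect pathway needs both phosphotransbutyrylase (IPR014079) and butyrate
kinase (IPR011245) — a species carrying only one of the pair is never
called a producer. A species qualifies when *every* required feature meets
the 70% genome-fraction threshold; the reported score is the minimum
fraction.

Between-species proportion comparisons use the two-proportion z-test with
Yates continuity correction under the pooled null; the statistic's square
equals the Yates-corrected chi-square of the 2×2 table (the tests agree
numerically with `prop.test`), and degenerate pooled proportions (0 or 1)
return `z = 0, p = 1`.

## Cross-host taxonomy/function mapping

Functional distance between two species is the Jaccard distance between
their profiles. The default `BINARY` mode thresholds fractions at zero
(presence) because the Jaccard index is defined on sets; a `WEIGHTED`
(Ruzicka) mode, `1 − Σ min / Σ max` over the real-valued fractions, is
available since profiles are genome fractions rather than sets, and the
mode is recorded on the resulting matrix. Two all-zero profiles have
distance 0. Binary Jaccard distance is a metric; the triangle inequality is
exercised in the tests.

Taxonomic distance is the cophenetic distance on a species phylogeny — the
sum of branch lengths on the unique path between two leaves — computed via
`ape` (the standard implementation, quadratic overall rather than per-pair
tree walking). Missing branch lengths are treated as zero with a warning;
sub-nanometre negative lengths from floating-point averaging are clamped.

For each host-A species the closest host-B species is found independently
under each distance (ties by smaller distance, then id; the taxonomic
neighbor is the cophenetic argmin, not a rank-walk over lineage strings).
The *shared rank* of query and taxonomic neighbor is the deepest rank at
which their GTDB lineage labels are identical and non-empty — unassigned
labels never match. Agreement (closest-functional = closest-taxonomic) is
tabulated per stratum with percentages rounded half away from zero at one
decimal, the rounding used for all reported percentages (base R `round()`
is banker's rounding and would map 0.25 to 0.2).

The Mantel test correlates the upper triangles of the two distance
matrices; significance comes from permuting the id order of one matrix,
with the one-sided p-value `(1 + #{r_perm ≥ r_obs}) / (1 + n_perm)`. The
identity permutation is excluded from the random draws because the observed
statistic already contributes through the `+1` terms — with it, a
self-comparison would not attain the minimal p-value of `1/(n_perm+1)`. An
`exact = TRUE` mode enumerates all `n!` permutations for small matrices.
Principal-coordinates analysis is classical metric MDS (`cmdscale`);
negative eigenvalues from non-Euclidean distances are dropped with a
warning and excluded from the explained-variance denominator.

Species are *shared* between catalogs when their species-rank lineage
labels match non-emptily, or their representatives meet the 95% ANI / 0.6
containment rule; each species pairs with at most one partner, label
matches first, then best ANI. Summary percentages
(`catalog_summary()`, `percent_of()`) are derived from integer counts and
rounded half away from zero at the precision conventionally printed (one
decimal, two for small shared fractions).

The overall agreement percentage depends on which query species are deemed
assignable; the package reports agreement over all assignable host-A
species and does not attempt to reproduce any particular subset choice.

## Protein catalog search

`local_align()` is Smith–Waterman with BLOSUM62 and affine gaps, gap open
11 and extend 1 (a gap of length L costs 11 + L) — the standard protein
BLAST parameterization. Percent identity is computed over all alignment
columns including internal gaps; end gaps do not arise in local alignment.
Traceback is deterministic: ties prefer diagonal over up over left, the
best cell is the first in row-major order, and gap runs close as early as
possible. All cell values are integer-valued, so the floating-point
equality tests in the traceback are exact.

`search_catalog()` prefilters candidates by at least one shared exact
5-mer. For a full-length homolog at ≥ 95% identity, mismatches can destroy
at most 5 × (#mismatches) of the overlapping 5-mer windows, so any
homolog of length ≥ 25 with ≤ 1 mismatch per 25 residues must retain a
shared word — the filter is lossless at the 95% cutoff for realistic
lengths, and the tests verify it against brute-force alignment. Hits must
reach the identity cutoff over an alignment covering at least 50% of the
query; the coverage floor suppresses spurious short-window perfect matches
and is configurable. Dominance ranking and cross-host sharing
classification mirror the pangenome conventions: distinct encoding genomes
first, then fraction; a gene is shared-conserved when the dominant species
of host B is the shared-species partner of host A's dominant species.
Genome-count dominance is used throughout; abundance-weighted dominance
would require metagenome profiles of both hosts and is deliberately out of
scope. E-value statistics are likewise not computed — identity cutoffs, not
significance, define functional equivalence here.

## Compositional community profiles

Prevalence is the percentage of samples in which a species reaches 0.01%
of classified reads (inclusive); count tables are converted to percent of
per-sample totals first, and mean abundance averages over all samples
including zeros. One table row per sample is assumed; merging of multi-run
samples is upstream of the package.

The Aitchison workflow replaces zeros with the simple
count-zero-multiplicative estimator — a zero part receives the posterior
expectation `0.5 / (N + 0.5 D)` of the sample under a uniform prior of
strength 0.5 per species, and non-zero parts are scaled multiplicatively to
preserve the total — rather than a fuller Bayesian-multiplicative family;
the simple estimator is deterministic, parameter-free and adequate at
typical sequencing depths. The centered log-ratio transform follows
(`log x − mean(log x)` per sample; rows sum to zero to machine precision),
and sample distances are Euclidean on clr rows. The Aitchison distance is
invariant to per-sample scaling of zero-free compositions; with zeros, the
replacement is depth-aware, so exact scale invariance holds only after
replacement.

## What the synthetic data does and does not show

The generators are seeded and byte-reproducible, and every emitted file
feeds the package's own readers (`audit_catalogs()` re-checks this).

* *Genome pairs* evolve by independent per-site substitutions only —
  no indels, no repeats, no rearrangements — so realized divergence is
  known exactly and the ANI/divergence correspondence is analytic. Real
  genomes violate all three assumptions; sketch-based ANI on real data is
  noisier than on these fixtures, which is why the species and
  dereplication thresholds sit far from the divergences simulated.
* *Catalogs* place each host-A species' twin, genus mates and genera on an
  exact ultrametric hierarchy, and the species tree is derived from that
  same hierarchy, so cophenetic distances and sketch ANI are mutually
  consistent by construction. Planted functional disagreements toggle a
  strict subset of the twin's feature toggles, guaranteeing — not merely
  making likely — that the planted species is functionally closer than the
  twin. Default conditions: 50 host-A species in genera of 5, twin
  divergence 2%, within-species divergence 0.5%, between-species 10%,
  300-feature universe at 30% presence, 10% feature turnover between
  twins, 10% planted disagreement.
* *Protein families* again substitute without indels, so alignment
  identity can only miss the realized identity by mismatch placement, not
  by gap ambiguity.
* *Abundance tables* draw multinomial counts at depth 10⁵ over log-normal
  expected abundances with a planted occupancy mask; at that depth every
  occupying species clears the 0.01% presence threshold, so prevalence
  equals planted occupancy.

Passing recovery tests on these fixtures demonstrates the correctness of
the decision rules and estimators under their stated models; it does not
demonstrate robustness to assembly error, chimerism, annotation noise or
uneven genome sampling in real catalogs.

Test and acceptance problem sizes — 80 kb genomes for sketch calibration,
5 species × 8 genomes for cluster recovery, 50 species for cross-host
mapping, 100-residue proteins for alignment oracles, 200 Mantel replicates
— were chosen as the smallest sizes at which the estimators' sampling error
is well separated from the decision thresholds.

## Known limitations

* Containment is a proxy for alignment fraction; genomes of very unequal
  size can pass containment while a true aligned-fraction criterion would
  fail them.
* Greedy quality-ordered clustering is order-dependent by design; a
  borderline genome joins the first qualifying cluster, not necessarily
  the nearest.
* Sketch ANI degrades above ~10–15% divergence (Jaccard approaches zero);
  the species boundary at 5% divergence is well within the reliable range.
* The alignment word prefilter is provably lossless only at high identity;
  at the 50% survey cutoff it can in principle drop a homolog with no
  shared 5-mer, although such cases are vanishingly rare for real protein
  families.
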