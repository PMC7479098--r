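---
title: "Species-level metataxonomic profiling: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Species-level metataxonomic profiling: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Short-read 16S surveys rarely resolve gut communities below the genus level.
With near full-length 16S rRNA amplicons (~1,400-1,500 nt) a species-level
("metataxonomic") profile becomes possible: reads are clustered at the
canonical species-discrimination identity threshold of 98.7%, the cluster
representatives are placed on a reference phylogeny of type strains, and each
placement is interpreted as a *species-level phylotype* (SLP) — either a
classified species, a potentially new species within a known genus, or a
potentially new higher taxon. The SLP-by-sample count table then feeds a
compositional statistics layer: prevalence strata, community typing,
permutational multivariate tests, differential abundance and proportionality
networks.

`metataxa` implements this whole chain, together with a synthetic-data
generator that produces reference databases, community profiles and
error-bearing read sets with known ground truth, so that every stage is
testable end to end without any external download.

## Pipeline model

### Reads to OTUs

`quality_filter()` drops reads containing any non-ACGT symbol, truncates
survivors to the positional window 10–1,490 (the standard near-full-length
window after primer excision) and removes reads whose trimmed length falls
outside [1,000, 1,600] nt. `chimera_filter()` is a reference-based bimera
screen: a read is removed when some two-parent model (left segment from
reference A, right from reference B, breakpoint scanned on a 50-nt grid)
explains it better than any single reference by an identity margin of at
least 0.02. This is a deliberate simplification of de-novo chimera detection;
the margin and grid are configurable and the screen can be disabled.

`greedy_cluster()` is abundance-sorted greedy centroid clustering. Unique
sequences are processed in decreasing multiplicity (ties broken by
lexicographic order); each sequence joins the first centroid, in founding
order, with identity at or above 98.7%, else founds a new centroid. Joining
is inclusive at the threshold (a flag switches to strict). The OTU
representative is the most abundant member sequence, ties again resolved
lexicographically, so the whole procedure is deterministic.

### Sequence identity

All identity values share a single definition: global alignment with match
+1, mismatch −1, gap open −2, gap extension −1; identity is matches divided
by alignment columns, with terminal gap runs excluded. The dynamic program
uses a fixed tie-break preference (substitution state over gap-in-second
over gap-in-first), so identities are reproducible to the last digit; an
independent pure-R implementation of the same recurrence is kept in the test
suite and must agree exactly. Two fast paths serve the full-scale pipeline:
equal-length pairs are scored gaplessly, with a DP confirmation when the
gapless value falls within 0.02 below the clustering threshold, and a banded
DP (band half-width 32–64 columns, exact whenever the optimal alignment stays
within the band) serves clustering and anchor scoring. On substitution-only
divergence, which is what both the generator and high-accuracy circular
consensus reads produce, these fast paths are exact.

### Alignment, masking and the reference tree

`align_profiles()` builds a center-star progressive alignment of the
references (pairwise global alignments to the most central reference, merged
under "once a gap, always a gap") and then maps each OTU representative onto
the *fixed* reference columns: the query is aligned to its highest-identity
reference and projected, dropping query insertions relative to the profile.
Reference columns are therefore never altered by queries, which mirrors the
workflow of inserting queries into a fixed curated alignment. When every
input shares one length the gapless alignment is returned directly.

`conservation_mask()` keeps a column iff its modal residue frequency among
non-gap entries is ≥ 30% — the standard conservational filter used to
suppress phylogenetic noise in 16S tree reconstruction — and its non-gap
fraction is ≥ 50%. The non-gap condition is our addition: conservation is
otherwise undefined for mostly-gap columns.

Pairwise mismatch fractions over masked columns are Jukes–Cantor corrected
(`d = −(3/4)·ln(1 − 4p/3)`; saturation at p ≥ 0.75 raises an error naming
the pair). The reference tree is canonical Saitou–Nei neighbor joining (via
`ape::nj`), negative branch lengths clamped to zero, rooted on a designated
outgroup that every generated database contains. Each query is then attached
by `parsimony_insert()`: over all edges, the attachment point and pendant
length minimizing the least-squares discrepancy between the query's
distances to all current leaves and the induced path lengths are found in
closed form; the argmin edge is subdivided. The reference topology is never
perturbed, and queries are inserted in decreasing OTU size. On additive
distances this recovers the true attachment exactly; the suite checks
agreement with full NJ reconstruction on random trees.

### OPUs and SLP categories

The *operational phylogenetic unit* (OPU) of a placed query is the smallest
clade on its root path containing at least one reference leaf. Queries merge
into one OPU when their minimal anchored clades coincide, or nest while
sharing the same reference leaves (the outer clade then adds only more
queries, leaving the nearest-reference anchor unchanged); nested clades that
recruit additional references remain separate OPUs. A brute-force
enumeration oracle in the test suite checks this delineation exactly on
hundreds of random trees.

Categorization combines clade homogeneity with rank identity floors. The
anchor is the clade reference closest to the OPU representative, type
strains preferred. If the anchor is a type strain and identity exceeds
98.7% (strictly), the OPU is a **classified species** carrying the anchor's
full lineage. Otherwise we find the finest rank at which (a) all clade
references share one lineage label and (b) the anchor identity reaches the
canonical rank floor — genus 94.5%, family 86.5%, order 82%, class 78.5%,
phylum 75%. Agreement at genus yields a **potential new species** in that
genus; agreement only at a coarser rank yields a **potential new taxon** at
the rank one below it. The identity floors are load-bearing, not cosmetic: a
genuinely novel genus often attaches *sister* to a single remaining
reference genus, so its minimal anchored clade is genus-homogeneous and
topology alone would mistake it for a new species; its 86–92% anchor
identity is what reveals the rank. Both signals must agree before a rank is
assigned. The floors are configurable (`rank_floors`).

Subtleties: rank homogeneity is evaluated on reference leaves only (queries
never vote), and when several type strains sit in one clade the
highest-identity one anchors. Raising the species threshold can only move
OPUs from classified to potential-new-species, never the reverse; the suite
asserts this monotonicity.

### Prevalence and roles

Presence is count > 0 (a `min_count` floor exists, default 1). Prevalence is
the percentage of samples with presence; strata are low (< 10%), medium
(10–60%, the 60% boundary inclusive, matching how the strata are phrased:
medium reaches *to* 60%, high is strictly *greater than* 60%) and high
(> 60%). The 5%-interval histogram, per-sample carriage summaries, and
physiological role annotation (probiotic / commensal / potential pathogen,
consumed as a `species → role` TSV and matched by exact name on classified
SLPs only) complete the layer. Because a group's share of the community can
be read two ways, `group_abundance()` reports both the pooled-read
percentage and the mean of per-sample percentages.

## Compositional statistics

Zeros are replaced multiplicatively on the proportion scale: a zero in
sample *s* becomes `0.65 / total_s` and the non-zero proportions shrink so
the row still sums to one — the standard count-zero-multiplicative choice;
0.65 is configurable. CLR is `x → ln x − mean(ln x)` per sample; Aitchison
distance is Euclidean distance between CLR rows. Community typing is
`hclust` ward.D2 (distances squared internally, heights on the distance
scale) cut at k = 2 by default, validated by silhouette widths computed from
the same distance matrix (a singleton cluster, or a k = n cut, scores 0 by
convention; the suite cross-checks our silhouettes against the `cluster`
package to 1e-12). Ordination is classical PCoA (`cmdscale`, warning when
negative eigenvalue mass exceeds 5%) and PCA of the CLR covariance; on
Aitchison distances the two agree up to sign.

`permanova()` is Anderson's one-way pseudo-F from between/within sums of
squared distances with seeded label permutations and the +1-corrected
p-value `(1 + #{F* ≥ F}) / (1 + n_perm)`; multiple factors are tested
marginally and BH-adjusted as one family. The implementation is ours and is
cross-checked against `vegan::adonis2` (identical F and R²) in the suite —
the permutation loop is kept in-package so type-I calibration can be
simulated cheaply.

`dirichlet_mc_da()` propagates count uncertainty through `n_mc = 256`
Dirichlet(counts + 0.5) Monte-Carlo instances per sample, CLR-transforming
each draw. Per SLP and instance, Welch's t and Wilcoxon rank-sum (normal
approximation with tie and continuity corrections) compare the two groups;
p-values are averaged over instances, then BH-adjusted per test family. The
effect size is the median over instances of (median between-group CLR
difference) / (max of the two within-group interquartile ranges) — a robust
standardized shift. An SLP is reported significant when the consensus FDR
(`max` of the two BH values, i.e. both tests must agree) is below 0.05 *or*
|effect| ≥ 1; the effect-size branch is deliberately sample-size-free.

Proportionality is `ρ(x, y) = 1 − var(x−y)/(var x + var y)` on CLR values
across samples; pairs involving zero-variance SLPs are reported missing. The
network connects pairs with ρ > 0.3 or ρ < −0.3 (strict), keeps the signed ρ
as edge weight, sizes nodes by overall relative abundance, and finds modules
by fast-greedy modularity maximization on absolute weights (via `igraph`),
reporting the modularity Q of that partition. Expectation-type ρ can be
obtained by passing expected CLR values from the differential-abundance step
instead of point CLR values; both routes are exposed.

## The synthetic-data generator

The generator defines the study conditions under which the pipeline's
recovery claims are tested; its defaults are fixed and are not tuned per
experiment.

**Reference databases.** Sequences of length 1,443 nt (the typical
near-full-length amplicon) evolve by random substitutions down a six-rank
taxonomy. Within each rank, descendants radiate on a random ultrametric-
within-rank topology: every descendant sits at a fixed divergence depth
below the rank ancestor, with split depths drawn uniformly from a per-rank
range, so realized pairwise identities fall in controlled bands — congeneric
species between 92% and 98.7% (straddling the species threshold from below),
confamilial genera between 86% and 92%. Band edges are configuration; the
generator measures realized identities with the package's own identity
function and *aborts, naming the band*, if a parameter set cannot realize
them (multiple substitutions at one site make realized divergence slightly
smaller than nominal, which the default depth ranges already budget for).
A divergent outgroup is always included for rooting.

**Communities.** A cohort splits into two planted types, P and B, each
dominated by its own always-present taxon (log-mean 5 versus 2/1/0 for
high/medium/low tiers, log-sd 1). Every non-dominant taxon is fixed into a
prevalence tier with per-sample Bernoulli occurrence 0.90 / 0.35 / 0.04
(high / medium / low), which lands expected prevalence in the > 60%, 10–60%
and < 10% strata. Two mechanisms differentiate the types as coordinated
guilds rather than by the dominant alone, because a single taxon cannot
carry a 70-dimensional CLR clustering signal: (i) a fixed per-taxon,
per-type log-abundance offset drawn uniformly from ±2.5 — bounded so that
no guild taxon overtakes the dominant in cluster-mean abundance — and (ii)
an antisymmetric per-taxon logit-occurrence shift of ±1.75 applied to
medium- and high-tier taxa (a taxon more prevalent in one type is
correspondingly less prevalent in the other, leaving cohort-level prevalence
and hence the planted tier approximately intact). Low-tier taxa carry no
occurrence shift: rare taxa are modeled as transient colonists rather than
type-associated residents. Planted novelty — species withheld from the
emitted references while congeners remain, and whole genera withheld with
one community member each — is assigned to the medium or high tier so that
withheld taxa actually surface in the reads.

**Reads.** Depth is multinomial per sample from the expected composition
(default 2,000 reads/sample, a desk-scale stand-in for the several-thousand
reads per specimen of a real full-length 16S run); each read copies its
source with i.i.d. per-base substitutions at 0.159% (the circular-consensus
error rate the pipeline is designed around); with probability `chimera_rate`
a read is replaced by a two-parent splice at a uniform breakpoint in
positions 300–1,200. No indel errors, quality scores or PCR bias are
modeled. Provenance (source taxon or chimera parents) is recorded per read,
which is what the recovery metrics consume.

Each operation takes its own seed; the same inputs and seed give
byte-identical output, including the FASTA emitted by the IO helpers.

**What passing tests do and do not show.** The generator produces
substitution-only divergence with well-separated identity bands, two cleanly
planted community types and modest chimera rates. Success under these
conditions demonstrates the pipeline's logic — clustering, placement,
delineation, categorization and the statistical layer — not robustness to
real-data pathologies: indel sequencing error, intragenomic 16S copy
variation, taxa whose true divergence contradicts the canonical thresholds,
or contamination. Those failure modes sit outside the generator by design.

## Study-scale checks and problem sizes

The packaged acceptance analysis (also run by `scripts/acceptance.R`)
simulates 40 samples (25 P-type, 15 B-type) at depth 2,000 over a database
of 108 species across 2 phyla / 4 families / 12 genera, with 60 classified
community members, 10 planted novel species, 4 planted novel genera, 0.159%
read error and 1% chimeras. On this scenario the pipeline recovers ≥ 95% of
OPU categories and classified species names and ≥ 90% of prevalence tiers;
Ward typing of the Aitchison distances recovers the planted types (adjusted
Rand ≥ 0.9, positive mean silhouette, perMANOVA p ≤ 0.01), each cluster's
top-abundance SLP is its planted dominant, the two dominants are flagged as
differentially abundant and covary negatively (ρ < 0). Statistical
calibration uses 1,000 null replicates for perMANOVA (n = 16, 99
permutations; the attainable level at α = 0.05 is exact) and
biological-variation nulls for the Dirichlet MC tests (40 samples, 12 SLPs,
depth 2,000 — between-sample log-normal variation with exchangeable labels;
under a *pure multinomial* null the test is intentionally conservative,
since the Dirichlet layer exists precisely to absorb count noise). Oracle
checks run brute-force clade enumeration on 200 random trees of up to 32
leaves and exact NJ reconstruction on random additive matrices of up to 8
taxa. The whole suite runs in a few minutes on one CPU.

## Numerical choices, degenerate inputs, known limitations

* Tie-breaks are deterministic everywhere: alignment traceback preference,
  lexicographic ordering in clustering and representative selection,
  first-minimal edge in placement.
* The Jukes–Cantor transform refuses mismatch fractions ≥ 0.75; with the
  30% conservation mask and the generator's divergence bands, saturation is
  unreachable in supported scenarios.
* Columns where either sequence is gapped are excluded from pairwise
  mismatch fractions; a pair with no shared unmasked columns is an error,
  not an NA.
* `replace_zeros` refuses all-zero rows or columns; `clr` refuses
  non-positive entries; `relative_abundance` names the offending sample on a
  zero column.
* Silhouette of a singleton cluster is 0; `ordinate` warns when > 5% of
  eigenvalue mass is negative.
* Reference databases here contain type strains plus an outgroup only; the
  placement step does not model a separate pool of uncultured "support"
  sequences, and no secondary-structure-aware alignment, maximum-likelihood
  inference or bootstrap support is provided.
* One OPU is treated as one species; 16S copy-number variation and
  subspecies structure are not modeled (subspecies collapse to species).
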