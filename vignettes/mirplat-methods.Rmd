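---
title: "Methods: cross-platform miRNA representation analysis"
author: "mirplat"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: cross-platform miRNA representation analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The problem

Small-RNA sequencing platforms differ in chemistry, library preparation
and throughput, and those differences can bias which mature miRNAs a
library captures. When two platforms sequence the same RNA, most miRNAs
agree well after depth normalization, but a small set shows
representation differences far beyond sampling noise — and those
discrepant sets tend to share sequence features. `mirplat` implements the
full analysis chain needed to find and characterize such platform bias:
counting reads against a mature-miRNA catalogue, normalizing across a
large throughput gap, calling differentially represented miRNAs, and
testing whether the discrepant sets are compositionally unusual —
in particular, whether uracil stretches are enriched in miRNAs favoured
by a semiconductor (flow-based) platform and adenines in miRNAs favoured
by a ligation-based one.

The package is organized as a workflow: every computation lives in
exported functions (tested in `tests/testthat/`), and the numbered
scripts under `analysis/` are thin drivers that run the stages in order
and write TSV/DOT artifacts under `results/`.

## Read assignment

Reads are assigned to catalogue entries under a seed-and-mismatch rule
(`mapping_policy()`): the first 18 nt of the read must equal the first
18 nt of the mature sequence exactly, and the positional comparison over
the full overlap may contain at most one mismatch. Alignment is anchored
at position 1 of both sequences — no gaps, no shifting. This is a
deliberate simplification: isomiR 5' offsets are real but their handling
is not part of the quantification rule this package encodes, and the
anchored form keeps the seed/mismatch semantics exactly testable against
a brute-force enumeration oracle.

Two boundary conventions are ours and documented here. Reads extending
past the mature 3' end (untrimmed adapter remnant) are tolerated up to 4
nt of overhang, beyond which the read is unassigned. Ties between
equal-mismatch matches resolve to the lexicographically smallest miRNA
id and flag the read as ambiguous, so tie-breaking is deterministic and
auditable. A consequence of seed exactness worth knowing: at a per-base
error rate of 1%, the expected fraction of reads that re-assign to their
source is bounded by $0.99^{18} \approx 0.835$, because any error inside
the seed is disqualifying. The test suite asserts this analytic
expectation rather than a more optimistic figure.

## Presence thresholds and the throughput coefficient

With one platform sequencing ~4 times deeper than the other, a fixed
minimum-read rule would count the platforms' detection sensitivity
unequally. The coefficient is the rounded ratio of total valid reads
(`throughput_coefficient()`; 7,883,393 / 1,924,046 = 4.1, rounded to 4),
and presence requires at least 2 reads on the low-throughput platform
and 2 × 4 = 8 on the high-throughput one. Presence is evaluated once, on
full libraries; rarefaction subsamples use a ≥ 1 read detection rule
instead, since thresholds tuned to full depth are meaningless at 1%
depth.

## Near-identical mature sequences

Mature miRNAs differing by a single nucleotide cannot be distinguished
by a one-mismatch mapper, so counting them separately splits one signal
across rows. `build_clusters()` collapses the catalogue by
single-linkage transitive closure over a "no or one mismatch" relation
computed from Smith–Waterman local alignment (match +5, mismatch −4,
gap open/extend 10/0.5). A pair is near-identical when its optimal local
alignment is gap-free, spans at least `min(len) − 1` positions, and its
mismatch columns plus any trimmed positions of the shorter sequence
total at most one. Counting trimmed positions matters: a local aligner
happily trims a terminal mismatch to raise its score, and without the
correction a pair differing at two positions (one terminal) would
masquerade as a one-mismatch pair. Single linkage is chosen over clique
clustering because it is the only rule that never separates a pair the
relation declares near-identical; the cost is that chained clusters can
contain members two mismatches apart, which we accept and record.

## Normalization, correlation, differential representation

Counts are depth-normalized as reads per million (`cpm()`), or
reads per kilobase per million (`rpkm()`) when transcript length matters.
Size factors (`size_factors()`) use the median-of-ratios procedure:
$s_j = \mathrm{median}_i \, k_{ij} / (\prod_j k_{ij})^{1/m}$ over rows
with positive geometric mean, rescaled to unit geometric mean. The
variance-stabilizing transform is the shifted log
$\log_2(k_{ij}/s_j + 1)$ — monotone, anchored at zero, and requiring no
mean-dispersion fit. A dispersion-fitted transform would change values
mostly at low counts; since the transform is used here for correlation
and visualisation, the monotone simplification is adequate and is
stated openly as a simplification.

With one library per platform per cell line there are no replicates, so
a count-model test with estimated dispersion is not identifiable.
`differential_table()` therefore tests each miRNA's share of the two
libraries with a two-proportion z-test with continuity correction
(signed z, two-tailed normal p, BH-adjusted across miRNAs), and flags
outliers by the quartile rule: a cross-platform difference of stabilized
values is an outlier when it exceeds $Q_3 + 1.5\,\mathrm{IQR}$, with
quartiles by linear interpolation (type 7) — the convention matters and
is fixed here because the rule's threshold depends on it. Fold changes
are reported to 4 significant figures with an `N.A.` sentinel when the
denominator platform has zero reads.

The binomial model behind the z-test treats library sampling as the only
noise source. Its calibration and recovery properties are therefore
evaluated with the generator in sampling-noise-only mode (dispersion 0);
under substantial extra-binomial noise at multi-million-read depth the
test rejects nearly everywhere, which is a property of the model, not a
bug, and is the reason the ranking (by p, then |z|) rather than the
absolute significance is what carries information on real, overdispersed
data. This limitation is inherited from the no-replicates design.

## Saturation curves

`saturation_curve()` subsamples each library without replacement
(multivariate hypergeometric, realized by chained `rhyper` draws) at
fractions 1%–100% and reports the mean number of miRNAs with at least
one read. In nested mode each repeat draws its largest subsample first
and derives smaller fractions from it, making every repeat's curve
monotone by construction; at fraction 1.0 the value is the exact
distinct count with no randomness. Defaults: 10 repeats, seed mandatory.

## Composition and homopolymer statistics

`base_fractions()` reports both pooled fractions (total base occurrences
over total length — the form quoted as set-level percentages) and
per-sequence fraction vectors (the form a two-sample t-test needs; the
two differ whenever sequence lengths differ). `homopolymer_runs()`
counts maximal runs of length ≥ 2, 3, 4 per base — a ten-uracil stretch
is one run at each threshold, not a sliding-window count.
`composition_compare()` runs a Welch t-test per base on per-sequence
fractions (a pooled-variance variant is available to probe sensitivity)
with BH adjustment across the four bases. Welch is the default because
nothing guarantees equal variances between a small enriched set and a
catalogue-scale reference.

## The nucleotide-adjacency graph statistic

Each sequence maps to a directed graph on nodes {A, C, G, U}: every
adjacent pair increments edge $s_i \to s_{i+1}$, so total edge weight is
length − 1. Degrees are weighted: `x_in` is the summed weight into x,
`x_out` out of x, and `x_both` their sum, giving 12 degree groups per
sequence. Two conventions are fixed and switchable: degrees are weighted
sums rather than distinct-edge counts (distinct-edge degree on a
4-node graph is ≤ 4 and nearly constant, carrying no signal), and a
self-loop contributes twice to the undirected degree (standard
convention; `self_loop_both = "once"` for the alternative). Raw degrees
scale with sequence length, so a length-normalized mode exists but is
off by default.

`degree_ztest()` compares each degree group between two sets with an
unpaired unequal-variance z-test and BH adjustment across the 12 groups.
At enriched-set sizes around n = 14 the normal reference makes the true
type-I error ≈ 0.067 rather than 0.05 (a t reference would be closer);
this is measured by the suite's null simulations and should be kept in
mind when reading borderline q-values from small sets.
`aggregate_graph()` sums member graphs for the "overplot" view whose
min/max edge weights drive a rendering scale; graphs export as DOT.

## The synthetic study generator

The generator exists so every stage is testable with known ground
truth, emulating the two-platform design: 500 mature miRNAs of 18–25 nt
(sub-populations of ~20% built to carry a U-run ≥ 4 nt and ~20% an
A-run); true abundances log-normal with $\log_{10}$ mean 1.5 and sd 1.0;
two cell lines as abundance vectors correlated at 0.95 in log space;
library sizes 2×10⁶ ("P") and 8×10⁶ ("S") reads, the 4× throughput gap;
negative-binomial counts with dispersion 0.1 by default, or exact
multinomial sampling at dispersion 0 for analytic checks.

Capture bias is compositional: planted miRNAs (drawn from the U-run
sub-population for platform P, A-run for platform S) get a multiplier
$e^\beta$ on their capture probability *before* renormalization, so
inflating one miRNA deflates the rest, as real library-prep bias does.
With $\beta = \log 4$ the expected cross-platform CPM ratio of a planted
miRNA is 4 × (ratio of the two platforms' normalizers); the correction
is visible when a planted miRNA is abundant, and the tests verify the
renormalized expectation, not the naive one. `emit_reads()` expands a
count column into reads with independent per-base substitution errors,
exercising the mapper end-to-end; flow-space homopolymer indels and
color-space miscalls are deliberately not simulated.

What passing tests on this generator do **not** show: real platform bias
is not a clean multiplicative indicator on a known sub-population; real
reads carry correlated, position-dependent errors; and real abundances
are more skewed than a lognormal with these parameters. The generator
validates the machinery, not the biology.

## Numerical and reproducibility choices

Problem sizes used by the suite and scripts, chosen to estimate each
quantity to the precision its check needs: oracle equivalence on
200-read × 50-entry mapping problems and ≤ 30-sequence clustering
problems; t-test calibration at 5,000–10,000 replicates; degree z-test
calibration at 8,000 replicates of 14-vs-100 sets (enough to resolve a
true rate of 0.067 against a 0.07 bound); differential null and recovery
over 20 and 10 generator seeds. Every stochastic function takes an
explicit seed (`withr::with_seed`), two runs of `run_compare()` with the
same config and seed are byte-identical, and the run manifest records
every parameter consumed. Degenerate inputs are pinned: zero-variance
t-tests return p = 1 on equal means, zero-variance degree groups return
p = 1, constant vectors produce no IQR outliers, empty read sets
collapse to an empty multiset rather than an error.

## Known limitations

Anchored, sense-only mapping (no isomiR offsets, no antisense reads);
shifted-log rather than dispersion-fitted stabilization; a
binomial-model differential test whose absolute p-values are
anti-conservative under overdispersion; single-linkage clusters can
chain; the degree z-test's normal reference is slightly anti-conservative
for sets smaller than ~30 sequences; published fold-change tables are
reproduced from printed reads/million, which round-trips exactly for all
but two rows whose printed folds were evidently computed upstream from
unrounded counts.
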