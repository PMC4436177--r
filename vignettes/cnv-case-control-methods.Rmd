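---
title: "Methods: CNV burden, association and familial overlap in cnvcc"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: CNV burden, association and familial overlap in cnvcc}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cnvcc)
```

## The analysis problem

`cnvcc` analyses lists of called copy-number variant (CNV) segments — one
row per segment per sample, with coordinates, a copy-number call and the
number of supporting array markers — in case-control cohorts and small
pedigrees. The motivating setting is a rare, male-biased congenital
malformation (coarctation of the aorta) where sex-chromosome dosage is a
plausible contributor, so the package treats the X chromosome with
particular care: analyses are stratified by sex, and the hemizygous male
X (expected one copy outside the pseudo-autosomal regions, PARs) uses a
different CNV definition than the diploid autosomes and female X.

Four questions are addressed:

1. **Burden** — do cases carry proportionally more *large* CNVs than
   controls?
2. **Association** — are there specific loci where case carriers are
   enriched?
3. **Familial sharing** — which regions are carried by (almost) all
   affected members of pedigrees and by no unaffected member?
4. **Annotation** — which genes of a candidate list do those regions
   contain?

A seeded simulator generates cohorts with the statistical structure the
analyses assume, so every method is exercisable end to end without any
array data.

## Coordinates and CNV definitions

Internally every interval is 0-based half-open, so `length = end -
start` with no off-by-one arithmetic. The canonical segment TSV on disk
uses 1-based inclusive coordinates (the convention in which published
tables print start positions and lengths); `read_segments()` and
`write_segments()` convert at the boundary, and a BED dialect is
available for interoperability.

A called segment counts as a CNV only relative to expected ploidy:

| location           | expected copies | CNV iff           |
|--------------------|-----------------|-------------------|
| autosome           | 2               | copy number ≠ 2   |
| female X           | 2               | copy number ≠ 2   |
| male X outside PAR | 1               | copy number ≠ 1   |

A male X segment intersecting a PAR by even 1 bp is excluded entirely
(`par_excluded`) rather than trimmed: segments are atomic calls, no
trimming rule is defensible without re-calling, and exclusion is the
conservative choice. The PAR coordinates default to the hg19 X PAR1/PAR2
intervals but are an explicit, overridable field of the genome model,
because different builds and calling pipelines disagree on them.
Y-chromosome segments are classified `not_cnv` and take no part in any
analysis. Loss/gain direction is judged against the same ploidy
baseline, so a male X segment at two copies is a *gain*.

## Sample QC

Arrays that call unusually many segments are quality suspects. The
cutoff is `2·median − min` of the per-sample segment counts, computed
*within* each cohort group (cases and controls separately — their
platforms and batches differ), and samples strictly above it are
excluded. The even-length median is the midpoint of the central pair, so
the cutoff may be non-integer. QC is a single pass: the cutoff is never
recomputed after exclusion, since iterating the rule would keep shaving
the tail of any heavy-tailed count distribution. By default all segments
count toward a sample's total regardless of size; a `min_size` argument
restricts counting to segments above a floor for pipelines that prefer
it. With very small groups (pedigrees) the rule is trigger-happy — with
four samples one noisy member is easily above `2·median − min` — which
is inherent to the rule, not a bug; users of tiny cohorts should inspect
the QC report before trusting exclusions.

## Size-stratified burden testing

For each stratum (autosomes, male X, female X) segments longer than
10 kb are cross-tabulated as group × size class, with *small* =
(10 kb, 100 kb] and *large* = > 100 kb. Both cuts are strict
"greater-than" boundaries: a segment of exactly 10 kb is below
threshold, one of exactly 100 kb is small. 100 kb is the conventional
threshold at which array-resolution CNV calls become individually
trustworthy and enrichment of large events is biologically
interpretable; both cuts are `size_bin_config()` parameters.

The test is Fisher's exact test on the 2×2 table, implemented as the
exact hypergeometric tail with all margins fixed. The default
alternative is one-sided (`greater`): the scientific hypothesis is an
*excess* of large CNVs in cases, i.e. an odds ratio above 1. The
reported odds ratio is the unconditional cross-product `(a/b)/(c/d)` —
not the conditional maximum-likelihood estimate `fisher.test()` reports
— because the cross-product is what size-stratified burden studies
print. Tables with a zero cell get a flagged, undefined OR by default;
the Haldane–Anscombe 0.5 correction is opt-in. The two-sided p, when
requested, sums all tables whose point probability does not exceed the
observed one (the "minlike" rule), with a 1e-7 relative tolerance
guarding ties against floating-point noise. Bonferroni correction
divides the family-wise level by the number of tests *actually
performed in the run* (three strata at α = 0.05 gives 0.0167), so
adding direction splits tightens the threshold automatically.

## Pseudo-marker permutation association

Case-control association does not test segments directly — segments
from different samples rarely coincide — but *breakpoints*: every start
and end of a qualifying segment (≥ 5 markers and ≥ 10 kb, both
inclusive) defines a pseudo-marker per direction. A sample carries a
marker when one of its same-direction segments contains the position,
with end-breakpoints evaluated one base inside so a segment carries
both of its own breakpoints; the union of the two rules is closed
containment `start ≤ position ≤ end`, which is how it is computed.

The test statistic at a marker is the case carrier count. Its null
distribution comes from permuting case/control labels with the case
count fixed; the empirical p uses the add-one correction
`(1 + #{T_perm ≥ T_obs}) / (1 + n_perm)`, whose floor at 100,000
permutations is 1/100,001 ≈ 1.0E-5. The statistic is the simplest
sufficient one under label permutation (equivalent to the one-sided
proportion difference), and its exhaustive-enumeration p equals the
one-sided Fisher p, which the test suite asserts. An exhaustive mode
enumerates all label assignments outright and is guarded at 10⁶
assignments.

Each marker's permutation stream is seeded deterministically from
(master seed, chromosome, position, direction), so results are
independent of traversal order and safe to parallelise. The X
chromosome is analysed separately per sex (carriers and labels
restricted to that sex), since male and female X CNV definitions
differ.

Markers passing the threshold (default 5e-5, compared as
`p ≤ threshold` so the 100,000-permutation floor passes) are merged
into loci only when consecutive on the same chromosome with the same
direction *and an identical carrier set* — overlap alone would chain
unrelated events through shared breakpoints of common polymorphisms.
Because per-marker seeds make Monte-Carlo p-values of identical carrier
sets differ slightly, a merged locus reports the smallest member p.

## Familial shared regions

Within pedigrees the question inverts: not "where are cases enriched"
but "which exact intervals do affected members share". A sweep-line
over the breakpoints of each (chromosome, direction) partitions the
axis into elementary intervals on which the set of covering samples is
constant; intervals where distinct affected carriers ≥ `min_affected`
and distinct unaffected carriers ≤ `max_unaffected` qualify, and
maximal runs of qualifying intervals are reported. Regions are maximal
in the count sense — extending any region by one base violates a count
condition — and when adjacent qualifying windows are covered by
different affected subsets, the region reports the *minimum* affected
count across its extent (the guaranteed sharing level) and the union of
contributing affected ids. Sharing means any base-pair overlap: no
reciprocal-overlap fraction is imposed, because jittered breakpoints
around a common event would defeat any fixed fraction. Only unaffected
relatives inside the families count against a region; external controls
do not.

`cross_cohort_overlap()` then intersects two region sets (for example,
sporadic association loci × familial shared regions) pairwise on the
same chromosome and direction.

## Gene annotation

Regions are matched against a user-supplied gene table (BED4 or TSV) in
two modes: `any_overlap` (≥ 1 bp intersection; the right default when a
partially-deleted gene is still of interest) and `containment` (gene
entirely inside the region; the convention for reporting genes "in" a
linkage region). Matching is interval overlap via `GenomicRanges`;
chromosome-naming mismatches ("chr1" vs "1") raise an error rather than
silently returning nothing. Gene lists are data, never hard-coded: the
package bundles no gene catalogue.

## The synthetic cohort model

`simulate_cohort()` draws, per sample: an autosomal segment count from
a negative binomial (over-dispersion is the norm in per-array call
counts); segment lengths from a log-normal truncated below at 1 kb,
giving the heavy right tail in which roughly 7% of segments exceed
100 kb under the defaults (`meanlog = log(20 kb)`, `sdlog = 1.1`);
uniform placement on length-weighted autosomes; and a fair loss/gain
coin (copy numbers 1/3). X segments use per-sex copy numbers (0/2 male,
placed outside the PARs so hemizygous logic always applies; 1/3
female). Marker counts are deterministic, `max(1, round(length /
2 kb))`, so the ≥ 5-marker association filter is exercisable.

The male-X enrichment mechanism acts on exactly the quantity the burden
test measures: for male *case* X segments the probability `p₀` of
drawing a length in the large class is tilted to odds `θ·p₀/(1−p₀)`,
so the population large-versus-small odds ratio between male cases and
male controls equals `θ` by construction. Planted association loci are
fixed intervals carried with Bernoulli(`f_case`/`f_control`)
membership; planted family duplications are copied into every affected
member with optional per-person breakpoint jitter, making the shared
core the intersection of the jittered copies. Everything is reproducible
from the config seed; the global RNG state is restored on exit.

Default group sizes mirror a 70-case (51 male) / 605-control cohort.
What the simulator does *not* model: probe-level intensities and
calling noise, locus-specific CNV rate variation (common CNP hotspots),
linkage disequilibrium, relatedness beyond the planted family segments,
and batch effects. Passing recovery tests on this generator therefore
demonstrates correctness of the statistical machinery under its stated
assumptions, not robustness to real-array artefacts.

## Numerical choices and problem sizes

* Exact tails are summed from `dhyper` densities; the suite checks them
  against an independent binomial-coefficient enumeration over every
  2×2 table with total ≤ 60 (one-sided) and ≤ 30 (two-sided).
* Monte-Carlo permutation p's are compared with exhaustive enumeration
  on 8-sample cohorts at 100,000 permutations (agreement within 0.01),
  and the test's null rejection rate at 0.05 is checked over 500
  simulated null markers against binomial 99% bounds.
* Parameter recovery runs 200 replicates per `θ ∈ {1.5, 2.5, 4}` on a
  scaled cohort of 100 + 100 male samples with 10 X segments each; the
  median sample OR must land within 15% of `θ`.
* The sweep-line is validated against a per-base brute force on random
  instances of up to 50 segments.
* Reported odds ratios use half-away-from-zero rounding
  (`round_half_away()`), the convention of published tables, rather
  than R's round-half-to-even.

These sizes are the package's chosen trade-off between statistical
resolution and a test suite that runs in minutes on one core.

## Known limitations

* No covariate adjustment or regression-based burden modelling; the
  burden test conditions on segment counts only.
* The carrier-set merge rule can split a biological locus into several
  reported loci when carrier sets differ at adjacent breakpoints
  (e.g. nested polymorphic events).
* QC assumes each cohort group is internally homogeneous; platform
  mixtures within a group will distort the median-based cutoff.
* Association p-values are not corrected beyond the fixed threshold —
  the threshold itself (default 5e-5) is the multiplicity control.
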