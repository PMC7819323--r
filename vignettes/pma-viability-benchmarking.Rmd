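---
title: "Benchmarking PMA viability sequencing: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Benchmarking PMA viability sequencing: models and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(viabench)
```

## The problem

Propidium monoazide (PMA) is a membrane-impermeant intercalating dye.
Photoactivated, it covalently binds DNA that is not protected by an intact
cell membrane and suppresses its amplification. Combining a PMA treatment
with 16S rRNA gene amplicon sequencing ("PMA-seq") is therefore a popular
attempt to profile only the *viable* fraction of a microbial community:
dead (membrane-compromised) cells and extracellular "relic" DNA should lose
their signal, live cells should keep it.

In practice PMA is neither perfectly effective nor perfectly selective. It
can leave relic DNA behind (sample matrices such as soil particles or host
DNA sequester it), and it can be toxic to viable cells. viabench provides
the machinery to quantify both failure modes: a generative simulator with
known ground truth, deterministic expectations for designed mixtures, a
spike-in efficacy statistic, per-taxon response ranking, and the standard
compositional statistics used to measure treatment effects.

## The generative model

A community is a `community_design`: components `(taxon, state, cell
fraction)` with per-taxon 16S copy numbers and a total cell count. Three
stochastic operations act on it.

**PMA action** (`apply_pma`). Each component's cell mass is binomially
thinned with retention `1 - p`, where `p` is `p_dead_removed` (times a
`matrix_attenuation` factor in `[0, 1]`) for dead components and
`p_live_removed` for live ones. `p_dead_removed = 1, p_live_removed = 0` is
the ideal treatment; attenuation below 1 models matrices that shield relic
DNA. Both probabilities may be taxon-specific (named vectors with a
`.default` entry), since susceptibility varies with cell-wall structure.

**Amplicon readout** (`sequence_community`). Reads are multinomial with
taxon weights proportional to cell mass times 16S copy number — the copy
number is what makes amplicon profiles semi-quantitative at best. Each read
is independently replaced by a draw from a contaminant pool with
probability `contamination_rate`, a per-read bleed-through model chosen
because one parameter reproduces the characteristic behaviour of near-empty
libraries: when the design has no surviving cells the library is filled
entirely by contaminant reads rather than being empty.

**qPCR readout** (`qpcr_total`). Total copies on the log10 scale plus
Gaussian noise (`qpcr_sigma_log10`); a zero-copy community reports a
below-detection flag, never `-Inf`.

All three take an explicit integer `seed`; the same seed reproduces the
same tables bit for bit. (The seed is an argument rather than a model
field, following the base-R `simulate()` convention.)

### Built-in scenarios

`make_fig1_designs()` returns the ten two-strain live/dead calibration
mixtures of *E. coli* (Gram-negative) and *S. sanguinis* (Gram-positive) at
1e5 cells, the standard first validation of a viability protocol. Default
copy numbers are 7 (*E. coli*) and 4 (*S. sanguinis*), literature operon
counts; the deterministic expectations below ignore copy weighting by
default, so these defaults only matter when the amplicon path is simulated.

`log_series_background()` draws complex all-live backgrounds with a Fisher
log-series rank-abundance shape. The intended operating points mirror a
spike-in calibration across biomass regimes: low-biomass surface swabs
(~50 taxa, ~1e3 cells, ~500-cell spike) and high-biomass soil/saliva
(~500 taxa, ~1e7 cells, 1e6-cell spike). The log-series shape and the
richness values are modelling choices for a realistic long-tailed
community; no claim is made about which real taxa they are.

`make_spiked_scenario()` builds the four-arm factorial — plain, PMA,
spike+, spike+PMA — and `simulate_spike_experiment()` runs replicates of
all four arms through sequencing and qPCR.

## Deterministic expectations

`expected_post_pma()` is the arithmetic the simulator must converge to
under ideal treatment: live cell fractions renormalized (all-dead designs
give an *empty* profile), plus the expected signal reduction, i.e. the dead
share of the community. With `copy_weighted = TRUE` both are computed on
copy-number-weighted mass, which is what a sequencer sees. The default is
cell-fraction based, because designed-mixture expectations (e.g. "67%/33%
after treatment" for a 50/25/25 mixture) are conventionally stated on cell
proportions. For mixed live/dead designs the unweighted reduction (25% for
the 50/25/25 mixture) and the copy-weighted one differ; both are available
and neither is privileged, since the physical basis of observed DNA-yield
reductions (cell counts, copy numbers, DNA mass) is ambiguous.

`compare_observed_expected()` scores an observed profile against an
expectation by total variation distance, `0.5 * sum(|obs - exp|)`; an empty
expectation is scored by the observed signal mass instead (any reads are
excess). A property test checks the oracle equivalence: simulating ideal
treatment at depth 1e5 and comparing to the copy-weighted expectation stays
within TV 0.01.

## The spike-in efficacy statistic

Spiking a 1:1 live:dead reference culture into every sample turns PMA
performance into a measurable number. With per-arm signals

* `A` — plain, `B` — PMA, `C` — spike+, `D` — spike+PMA,

each defined as mean(reference relative abundance over the arm's samples)
times mean(log10 16S copies by qPCR over the same samples),

```
efficacy = 1 - (D - B) / (C - A)
```

is the removed fraction of the spiked signal net of background: 0.5 is
ideal (exactly the dead half removed), below 0.5 means incomplete relic-DNA
depletion, above 0.5 toxicity to live cells. Values are deliberately not
clamped — an efficacy slightly above 1 (all spike signal plus some
background removed) is informative. The classification band around 0.5 is
`|value - 0.5| <= 0.05` by default.

Two definitional choices deserve note. First, the per-arm signal multiplies
the *mean* abundance by the *mean* log10 copies, not the mean of per-sample
products; `build_quadruplet()` implements exactly that and the tests pin it.
Second, multiplying relative abundance by *log10* copies (rather than
copies on the linear scale) is the field's normalization convention for
this statistic and is implemented as such; because the statistic is a ratio
of differences, any common monotone rescaling of the four signals largely
cancels, and the statistic is exactly invariant under common linear
rescaling.

**Analytic identity.** If the background signal is unchanged across arms
and the spike splits 1:1 live:dead with removal probabilities `p_d` (dead)
and `p_l` (live), the expected efficacy is `(p_d + p_l)/2`. The acceptance
suite verifies parameter recovery on simulation at depth 1e5 with 4
replicates per arm for `(p_d, p_l)` in {(1,0), (0.7,0), (1,1)} — targets
0.5, 0.35, 1.0 — within ±0.05. A small negative bias (~0.02-0.03) is
expected when the spike is a non-negligible fraction of the community
(1e6 cells against a 1e7-cell background): the relative-abundance
denominator shrinks as the spike is removed. The bias vanishes as the
spike-to-background ratio goes to zero.

Reference-taxon matching is a case-insensitive substring match against the
taxon ID and its lineage at any rank, so `"Enterobacteriaceae"` aggregates
the whole family — appropriate because short-read 16S profiling cannot
place *E. coli* more precisely than that.

## Fold-change response ranking

For each taxon and sample type, `fold_change()` compares arm means of
relative abundance and reports two numbers:

* `change = (mean_free - mean_PMA) / max(mean_free, floor)` — the
  normalized change, positive when treatment depletes the taxon; this
  drives the ranking.
* `ratio = max(mean_free, floor) / max(mean_PMA, floor)` (or its
  reciprocal, whichever is >= 1) — the fold ratio; ratios above 100 set the
  `large_change` flag used to highlight dramatic shifts.

Both are computed because "fold change" is genuinely ambiguous between the
difference-over-initial and ratio readings; keeping both preserves each
one's role. The floor (default 1e-6, one order below the smallest relative
abundance of practical interest, ~1e-5) makes zero means usable while
censoring flags (`undetectable_before` / `undetectable_after`) preserve the
information that a mean was genuinely zero.

`rank_responses()` scores each taxon by its mean |change| over the sample
types where it is detected in at least one arm (types where it is entirely
absent carry no information and are excluded from the average). Taxa scored
in at least `min_types` types (default 2) are eligible; the top 30 by
descending score are the PMA-responsive list and, among the remaining
eligible taxa, the 30 smallest form the PMA-resilient list. The eligibility
threshold is applied to both lists and responsive taxa are excluded from
the resilient list so the two are disjoint by construction; ties break
lexicographically, making the output order deterministic.

A caveat worth stating explicitly: relative abundances are compositional,
so a taxon's `change` measures the deviation of its survival from the
*community-mean* survival. In a community where most biomass dies, a fully
live rare taxon gains relative abundance sharply and ranks as responsive
"in the opposite direction" — a real phenomenon on high-touch surfaces, not
an artifact. A fully live taxon ranks resilient when it dominates the
community (so the community mean tracks it), which is exactly the situation
of abundant commensals on built-environment surfaces; the acceptance test
for the ranking constructs that situation.

## Compositional statistics

`bray_curtis()` implements `d(x,y) = 1 - 2*sum(min(x_i, y_i)) /
(sum(x) + sum(y))` on relative abundances and returns a base `dist`. The
0/0 case (two empty samples) is undefined in the formula and is defined
here as 0 with a warning, on the view that two "no signal" libraries are
indistinguishable.

`pcoa()` is classical metric scaling: double-center `-0.5 * D^2`,
eigendecompose, scale eigenvectors by the square roots of the positive
eigenvalues. Negative eigenvalues — which Bray-Curtis produces, as it is
not Euclidean — are reported but excluded from the variance-explained
denominator. On genuinely Euclidean distances the ordination round-trips
the input to 1e-9, which the tests use as the correctness oracle alongside
agreement with `stats::cmdscale`.

`permanova()` is the one-way permutation test on a distance matrix:
`SS_total = sum_{i<j} d_ij^2 / n`, within-group sums analogously, pseudo-F
with `(a - 1, n - a)` degrees of freedom, and
`p = (1 + #{F_perm >= F_obs}) / (1 + n_permutations)` under random
relabelling with a mandatory seed (identical seed, identical p, bit for
bit). For two groups, `exact = TRUE` enumerates all distinct label
assignments instead, with `p = #{F >= F_obs} / #assignments`; the tests
check this against an independent brute-force enumeration and the sampled
statistics against `vegan::adonis2`. Multiple metadata factors are tested
marginally (one one-way test per factor) with Benjamini-Hochberg adjustment
across factors via `permanova_factors()`; sequential (Type-I) partitioning
is deliberately not offered because it would impose an arbitrary model
order. Default 9999 permutations.

Distance summaries for paired designs (`group_distance_summary()`) use all
unordered pairs within an arm but only replicate-matched pairs between
arms, matching how paired PMA-free/PMA-treated samples are collected.

## Table preparation

`collapse_to_genus()` condenses OTUs to genus; OTUs without a genus
assignment are summed at their terminal (deepest assigned) rank and
labelled with Greengenes-style prefixes (`f__Enterobacteriaceae`), so
clades never silently merge across ranks. Per-sample totals are conserved
exactly (tested to 1e-12). `filter_taxa()` keeps a taxon when its relative
abundance strictly exceeds 0.01% in at least 10% of samples; "at least 10%"
is `ceiling(0.10 * n)` samples, reading the prevalence rule literally, and
the abundance bound is strict. Filtered tables are *not* renormalized by
default — the removed mass is real signal and downstream Bray-Curtis
distances are computed on what was observed — but a `renormalize` flag is
provided since conventions differ.

The TSV dialect (taxa as rows, `#OTU ID` header, optional trailing
`taxonomy` column) round-trips bit-exactly: counts as integers, relative
abundances at 17 significant digits. Relative tables are accepted when rows
sum to 1 within 1e-5, tolerating truncated published tables; tables the
package itself produces are exact. BIOM 1.0 JSON is read through
biomformat, read-only.

## Problem sizes and test design

The test suite runs entirely on synthetic data built in code. Monte-Carlo
checks use depth 1e5 and 4 replicates per arm for the efficacy recovery
grid (the designed operating point of the spike-in experiment), depth
1e4-2e4 elsewhere, and 1000 replicates for the qPCR noise check; binomial
and multinomial assertions use 3-sigma bands from the exact sampling
distributions. The whole suite completes in a few seconds on one CPU.

What passing these tests shows — and what it does not. The simulator
reproduces the *mechanisms* (copy-number weighting, binomial removal,
bleed-through, qPCR noise) with known ground truth, so the estimators'
correctness and their convergence behaviour are genuinely verified. It does
not emulate extraction or PCR amplification bias, chimeras, primer
mismatch, taxonomic misclassification, or the biochemical heterogeneity of
real matrices; good performance here therefore bounds estimator error under
the model's assumptions, not PMA-seq's accuracy on real communities — which
is precisely the question the spike-in efficacy statistic is designed to
answer per data set.

A reproduction pipeline for deposited studies
(`reproduce_study_estimates()`) chains the full analysis (genus collapse,
filter, per-type efficacies, marginal PERMANOVA) over user-supplied copies
of a study's taxonomy/metadata/qPCR tables; the tables themselves are
third-party supplementary data and are not shipped.

## Known limitations

* The PMA action model is per-cell independent (binomial); it has no
  dose-response curve, no photoactivation kinetics, and no explicit
  extracellular-DNA pool distinct from dead cells.
* Contamination is per-read and memoryless; real bleed-through is
  batch-structured.
* Efficacy assumes the background's reference-taxon signal is arm-invariant;
  communities with substantial native Enterobacteriaceae mortality violate
  this and bias the estimate.
* The compositional caveat above applies to all fold-change output; no
  absolute-abundance correction (e.g. qPCR-scaled counts) is applied in the
  ranking.
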