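---
title: "Causal discovery for ROI BOLD time series: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Causal discovery for ROI BOLD time series: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bgmci)
```

## The problem

Functional MRI records a blood-oxygenation (BOLD) proxy of regional neural
activity every repetition time (here 1.6 s). For deep-brain structures such
as the basal-ganglia motor circuit — M1, S1, putamen, external and internal
pallidum, subthalamic nucleus, substantia nigra, motor thalamus — the
activity can be observed but not manipulated, so cause/effect structure must
be inferred from the time series alone. Pairwise correlation cannot do this:
it is blind to direction, inflated by indirect paths, and fooled by common
drivers. `bgmci` implements a two-stage conditional-independence approach
(PCMCI-style) that addresses exactly those failure modes, together with the
signal conditioning that precedes it and a link taxonomy for reporting.

## The discovery procedure

Write $X^j_t$ for the series of region $j$. A candidate link
$X^i_{t-\tau} \to X^j_t$ ($\tau \le \tau_{\max}$) is kept only if the pair
remains dependent *given* a conditioning set $Z$ of other lagged series.

**Stage 1 (parent selection).** For each region $j$, all candidates
$(i, \tau)$, $\tau = 1..\tau_{\max}$ (including the autodependency) are
screened by iterative partial-correlation tests: at level $q$ each candidate
is tested conditional on the $q$ strongest other surviving candidates, and
candidates with $p >$ `pc_alpha` are removed, until the set stabilizes.
`pc_alpha` defaults to 0.2 — deliberately looser than the reporting level,
since the cost of missing a parent (an unconditioned confounder in stage 2)
exceeds the cost of an extra condition.

**Stage 2 (momentary conditional independence).** Every lagged ordered pair
and every contemporaneous unordered pair is tested conditional on the
parents of the target (minus the candidate itself) plus the time-shifted
parents of the source; each parent set contributes at most `max_conds = 3`
strongest entries, because unbounded conditioning makes the
nearest-neighbor CMI estimator unstable at realistic sample sizes. Links
with $p \le \alpha = 0.01$ (two-sided) are reported. Lag-0 links are
reported undirected: at a 1.6 s sampling interval the orientation of an
instantaneous dependence is not identifiable, so no orientation phase is
attempted. Autodependencies are used in conditioning but excluded from
reported graphs.

With $N = 8$ regions and $\tau_{\max} = 2$ the reported scan covers
$8 \times 7 \times 2 = 112$ directed lagged links plus
$\binom{8}{2} = 28$ undirected contemporaneous links. (Published counts of
candidate slots for this design — 42 instantaneous and 49 per delayed lag —
do not match any enumeration of an 8-node graph; this package enumerates
28 + 56 + 56 and documents the discrepancy rather than reverse-engineering
the printed numbers.)

## The three conditional-independence tests

* **PC (linear partial correlation).** Both series are residualized on
  $[1, Z]$ by least squares; the statistic is the Pearson correlation of
  the residuals. Most sensitive for linear dependence, blind to dependence
  with zero linear signal.
* **GPDC.** Both series are residualized on $Z$ by Gaussian-process
  regression (isotropic squared-exponential kernel plus a noise term,
  inputs standardized, hyperparameters by marginal-likelihood
  optimization); the statistic is the distance correlation of the
  residuals, which is zero iff the residuals are independent. For
  $n > 300$ the GP uses a deterministic subset-of-data approximation (fit
  and prediction basis thinned to 300 points) to keep the cost at
  $O(nm^2)$; the residual dependence being tested survives the
  approximation because only the conditional-mean estimate needs to be
  adequate. A failed GP fit falls back to linear residualization with a
  warning and a `fallback` flag.
* **CMIknn.** A KSG-style $k$-nearest-neighbor estimate (Chebyshev metric,
  per-column standardization, $k = 10$ by default; the underlying study
  does not state $k$) of the conditional mutual information
  $I(X; Y \mid Z)$ in nats, clipped at zero for reporting. Duplicate
  points are broken by seeded jitter at the $10^{-10}$ scale.

## Significance: block-shuffle permutations

BOLD series are autocorrelated, so i.i.d.-based analytic p-values are
invalid. All tests are calibrated by permutation: the tested series is cut
into contiguous blocks which are shuffled while the partner and the
conditioning set stay fixed, and
$p = (1 + \#\{|T_{perm}| \ge |T_{obs}|\}) / (n_{perm} + 1)$. The block
length defaults to the smallest lag at which the mean absolute
autocorrelation across channels falls below $2/\sqrt{n}$, clamped to
$[1, n/20]$; permuted blocks never cross concatenation boundaries when
boundary metadata is present, because the junctions between subjects are
artificial. For the GPDC test the GP residualization is computed once and
the permutations shuffle the residual series; re-fitting the GP per
permutation would test a different (and computationally prohibitive) null.
CMIknn also uses the block shuffle by default, consistent with the
significance procedure of the other two tests. A
nearest-neighbor-respecting local permutation scheme (each $x$ value
swapped among its $k_{perm} = 5$ nearest neighbors in $Z$-space, which
preserves the $x$–$Z$ relation under the null) is available, but it treats
samples as exchangeable in time: on AR(1) null series it rejected at
roughly twice the nominal rate in calibration runs, producing systematic
spurious "complex" links, so it is opt-in. The GPDC and CMIknn statistics
are nonnegative,
so the two-sided rule reduces to the upper tail. $n_{perm}$ defaults to
500; the validation benchmarks use 199 (and 99 for CMIknn), whose p-value
resolution (1/200, 1/100) still reaches the 0.01 reporting level. Parent
selection uses 49 permutations by default (`n_perm_pc`): its decisions are
taken at `pc_alpha` = 0.2, where a resolution of 1/50 is ample, and the
screening stage performs most of a run's tests.

Per-link permutation seeds are derived from the run seed and the *region
labels*, not column positions, so permuting the input columns permutes the
recovered graph exactly.

## Preprocessing chain

Per block: (1) optional nuisance regression of every region on a shared
regressor (the white-matter/ventricle mean in the original protocol),
removing residual motion and physiological components; (2) zero-phase
(forward–backward Butterworth, order 2 each way) high-pass filtering with a
0.009 Hz cutoff — zero-phase so that no phase shift biases lag estimates,
per block because the filter must not bleed across subjects (whether the
original analysis filtered per block or per recording is unstated; per
block is the conservative choice). Per subject: pooled demeaning across all
of the subject's samples ("normalized around the mean" is read as mean
removal only; unit-variance scaling exists but is off by default). Per
condition: concatenation in fixed order (subject ascending, block
ascending), smoothing only the first and last 5 samples of each block with
a Gaussian moving average (window 5, SD 1 sample, renormalized at edges) so
the artificial junctions do not create spurious dependence. Under the
default design this yields 100 × 2 × 20 = 4000 samples per condition.
Raw-image steps (slice timing, motion correction, the >0.5 mm exclusion
rule) are upstream of this package's contract, which starts at ROI series.

## Link taxonomy

* **Timing** follows the lag: instantaneous (lag 0), single-delayed
  (1 sample = 1.6 s), double-delayed (2 samples = 3.2 s).
* **Nature** follows detection precedence: *linear* if the PC test finds
  the link (regardless of the others), *non-linear* if GPDC finds it but
  PC does not, *complex* if only CMIknn finds it. The rules are applied
  strictly, with no reconciliation when methods disagree at the margin.
* **Persistence**: *permanent* if significant (any method) in both
  conditions, otherwise tagged with its single condition.

Display tables divide every statistic by the maximum absolute statistic of
its method × condition group — the only reading under which values are
"normalized between 0 and 1" while negative entries remain printable; signs
and orderings are preserved, and the strongest link maps to ±1. The
"detected more often than expected at random" screen for permanent links is
available as an optional binomial screen but is off by default: the
published description names no null model, and the significance-based rules
already reproduce the figure definitions.

## The synthetic generator

The generator exists because the original recordings are not deposited:
every downstream stage must be testable against known ground truth. Each
region follows an AR(1) innovation process (coefficient 0.3 by default,
Gaussian innovations; a uniform option tests robustness); planted couplings
add lagged terms of four kinds — linear, quadratic, threshold (centered
step), and multiplicative noise $Y_t \mathrel{+}= s\,X_{t-\ell}\,\epsilon_t$
(one concrete reading of variance-coupled dependence). Contemporaneous
couplings are realised as shared latent innovations injected into both
endpoints — not instantaneous structural equations — which avoids cyclic
ambiguity and matches the treatment of instantaneous links as undirected;
ground truth records them orientation-free. Linear coupling sets are
rejected unless the companion-matrix spectral radius is below 1. Per-block
seeds derive from the master seed by a counter over (subject, condition,
block), so extending the design never reshuffles existing subjects.

What the generator does **not** emulate: hemodynamic-response convolution,
voxel-level spatial structure, or realistic physiological-noise spectra
(the shared nuisance is a single additive AR(1) regressor). Passing tests
therefore demonstrate the statistical machinery under the assumed process
class, not fidelity to real BOLD physiology. Effect sizes in the shipped
presets are chosen for test power, since the real coupling strengths are
unknown.

## Validation benchmarks and problem sizes

The package validates itself at these sizes (chosen as the smallest designs
at which the tested properties are statistically meaningful):

* *Null calibration*: 10 replicates of 8 independent AR(1) channels at
  $n = 4000$, PC test, 199 permutations (1400 link tests in total); the
  significant-link fraction must sit inside the 99% binomial interval
  around 0.01.
* *Recovery*: a five-link linear graph (strengths 0.4–0.7, lags 1–2) at
  $n = 4000$, 10 replicates; mean recovery and false-discovery proportion
  are reported.
* *Method differentiation*: $y = x^2 + \epsilon$ at $n = 1000$ (50
  replicates) and pure $y = x\epsilon$ at $n = 2000$ (12 replicates).
* *Classification fixture*: a frozen two-condition study (5 regions,
  4 subjects × 1 block × 200 volumes) with one planted link per taxonomy
  cell, run end-to-end with all three tests sharing one parent-selection
  stage.

## Design choices where the design was open

* Parent selection always uses the partial-correlation test, whatever the
  MCI-stage method: GP- or CMI-based selection at stage-1 scale is
  computationally out of reach and the looser `pc_alpha` compensates for
  the linear screen's blind spots in practice. This is switchable.
* The quadratic source in the classification fixture is kept free of
  parents and lag-0 partners. This is not cosmetic: if the source $X$
  correlates with a conditioning variable, then
  $X^2 = (\hat{x} + r)^2$ contains a $2\hat{x}r$ cross term and the
  *partial* correlation of a purely quadratic link becomes genuinely
  nonzero — the linear test then "correctly" detects it, and the label
  moves to linear. Users interpreting nature labels on real data should
  keep this mechanism in mind.
* Threshold couplings use a centered step at 0 with configurable offset.
* The on-disk test cache is keyed by an MD5 of (data, method, options); it
  exists because CMI-based full-graph scans dominate runtime (the original
  analysis reports multi-day runs on 24 cores).

## Known limitations

* **Distance correlation sees multiplicative noise.** In this
  implementation's calibration runs, the block-shuffle-calibrated GPDC test
  detects pure multiplicative noise ($y = x\epsilon$, $n = 2000$) in
  essentially every replicate — equal to or above the CMIknn rate, with the
  linear test far below both. Distance covariance is zero only under
  independence and has real finite-$n$ power against variance coupling, so
  the *complex* class (CMIknn-only detection) materializes only for
  dependence outside dcor's practical power at the given $n$, and a planted
  multiplicative link is typically labeled *non-linear* rather than
  *complex*. The package reports what the rules yield; the fixture asserts
  the planted-kind expectations faithfully and documents this divergence.
* **A permutation-calibrated correlation is an independence test.** Under
  strong non-linear dependence with zero population correlation (e.g.
  $y = x^2 + \epsilon$), the *sample* correlation's standard deviation is
  inflated roughly three-fold relative to the shuffle null, so the PC test
  rejects on the order of 15–20% of such cases at the 1% level. Two
  consequences: a strongly non-linear link is sometimes labeled *linear*
  by the precedence rules, and "PC misses non-linear dependence" holds in
  tendency, not absolutely. An analytic $t$ calibration would not show
  this, but permutation significance is the method's stated design.
* **False-discovery arithmetic.** A full scan tests 140 candidate links at
  $\alpha = 0.01$; with five true links this implies an expected
  false-discovery proportion near 0.2 even for a perfectly calibrated
  pipeline. Judge reported graphs with the size of the scan in mind, or
  lower $\alpha$ when the scan is the object of interest.
* The method tests pairs of regions; simultaneous multi-region interactions
  are out of scope, as are effect-size estimation beyond the test
  statistic, time-varying graphs within a condition, and contemporaneous
  orientation.
* Permutation p-values have resolution $1/(n_{perm}+1)$; at the 0.01
  reporting level, 199 permutations leave only two attainable significant
  values. Raise `n_perm` for finer margins when runtime permits.
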