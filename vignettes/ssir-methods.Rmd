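---
title: "SSIR: model, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{SSIR: model, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ssir)
```

This vignette is the package's own account of the statistics it
implements: the model and its assumptions, the parameters that matter,
what the synthetic generator does and does not emulate, and the places
where the design was genuinely open and a choice had to be made.

## The model

SSIR treats an untargeted GC-MS experiment as a very wide, very sparse
binary design. A sample is not a peak list but a string of low/high
levels over grid nodes — (retention-time interval) × (fragment-mass
window) cells — and class-discriminating signal is sought directly in
that codification.

The selection statistic rests on a single probabilistic idea, the
**random-extractor null**: a rule (a conjunction of node levels) that
matches $n$ of the $N$ samples is treated, under the null, as if it had
drawn those $n$ samples uniformly at random. The number $X$ of
class-members among them is then hypergeometric, and the evidence that
the rule tracks the class is the upper tail

$$p = P(X \ge k) = \sum_{j = k}^{\min(n, K)}
  \frac{\binom{K}{j}\binom{N-K}{n-j}}{\binom{N}{n}},$$

with $K$ the class size and $k$ the observed class count. This is
exact for any $n$, symmetric under complementation (selecting a class
with one level is the same event as selecting the other class with the
complementary level — the engine exploits this and the test suite
asserts it to $10^{-9}$ relative), and free of distributional
assumptions on intensities: everything upstream (normalization, rank
binarization) exists to make the codification comparable across
samples, after which only 0/1 patterns matter.

Assumptions worth stating explicitly:

* **Exchangeability under the null.** Samples are treated as
  exchangeable; batch structure or run order would violate this and is
  not modelled.
* **No multiplicity correction.** Selection applies a raw threshold
  (default $5 \times 10^{-4}$) to every scored rule. The threshold is
  small enough that, at the scale of a few hundred representatives, the
  expected number of false selections stays well below one (the
  discreteness of the hypergeometric makes the raw test conservative in
  practice — see the calibration section). A user scanning much larger
  rule spaces (order 2–3) should tighten it.
* **Retention stability.** Nodes are fixed intervals; the method
  assumes retention drift across samples is small relative to the
  1/3-min bin width. No alignment or warping is performed.

## Parameters

| parameter | default | units | role |
|---|---|---|---|
| `time_start`, `time_end` | 6, 17 | min | analysis window; excludes early solvent region and late internal standard |
| `time_step` | 1/3 | min | node width in time (20 s) |
| `mass_center_min/max`, `mass_step` | 49–170, 0.5 | amu | 243 mass centers at integer and half-integer values |
| `mass_radius` | `mass_step`/2 | amu | half-open window [c − r, c + r); the default tiles the range |
| `target_mean` | 1000 | counts | per-sample mean of in-window intensities after rescaling |
| `top_fraction` | 0.01 | — | fraction of nodes codified high per sample |
| `max_order` | 1 | — | highest rule order enumerated (1–3) |
| `p_threshold` | 5e-4 | — | rule significance threshold |
| `scaling_mode` | autoscale | — | PCA on correlation (default) or covariance matrix |
| `n_components` | 1 | — | discriminant components (1–5) |

The default grid gives $33 \times 243 = 8019$ nodes and a per-sample
high count of $\lceil 0.01 \times 8019 \rceil = 81$.

## Numerical and convention choices

* **Half-open intervals everywhere.** Time bins are $[t_0, t_1)$ and
  mass windows $[c - r, c + r)$, so a register on a shared boundary
  belongs to exactly one node (the interval it opens) and the tiling
  has no double counting. `time_end` itself is excluded.
* **Mass centers: 243, not 244.** A 0.5-amu partition "from 49 to
  170.5" could be read as 244 centers; the package fixes the centers at
  49.0…170.0 (243), which is the count consistent with the 8019-node
  grid. Both endpoints are ordinary arguments, so the other convention
  is one keystroke away.
* **Rank rule, not quantile.** "Top 1%" is implemented as the
  $k = \lceil f \cdot n \rceil$ largest values per sample, with ties at
  the cutoff broken toward the lower node index. This is deterministic,
  exact for small $n$, and independent of interpolation conventions.
  The percentile scope is per sample (each sample is its own
  codification string); a pooled-cutoff variant is available via
  `percentile_scope = "pooled"` but is not the default.
* **Normalization scope.** The mean that sets the scale is computed
  over in-window registers only — the same registers that are
  accumulated — so signal outside the analysis window (e.g. an
  internal standard) cannot influence the codification.
* **Exact combinatorics.** `rule_pvalue()` sums
  $\binom{K}{j}\binom{N-K}{n-j}$ products in double-precision integer
  arithmetic while $\binom{N}{n} < 2^{53}$, which makes it
  bit-identical to exhaustive subset enumeration at small $N$; beyond
  that it switches to a log-sum-exp of `lchoose` terms (at $N = 56$,
  $\binom{56}{28} \approx 7.6 \times 10^{15}$ exceeds the exact double
  range). Both branches return values in $(0, 1]$.
* **Deterministic outputs.** PCA loading columns are sign-fixed
  (largest-magnitude entry positive); rule streams are enumerated in
  lexicographic node order with level maps in binary order; tied
  p-values rank by node index. Two runs on identical input are
  bit-identical, which the suite asserts.
* **Degenerate inputs.** All-zero in-window samples, all-constant
  codifications, empty selections, identical class means and singular
  pooled covariances all raise explicit errors (or a recorded
  "no-model" fold in cross-validation) rather than propagating NaNs.

## Rule orders

Order-1 rules — one node, either level — proved sufficient in the
motivating application, and they are the default. The engine still
enumerates orders 2 and 3 ($\binom{m}{r} 2^r$ conjunctions, scored for
both class directions, with rules containing an unmatched condition
skipped early), because interactions are the reason the rule formalism
exists. For order 1, the low and high readings of one node are
complementary descriptions of the same split; the engine emits both in
the stream (the enumeration is the documentation of the search space)
but collapses them before vote counting.

## The discriminant

PCA is computed on the *selected variables' intensity sums* — the
values from before binarization — so the classifier works on
quantitative signal while the selector works on codified signal.
Autoscaling is the default because selected variables span different
raw magnitudes yet should contribute comparably; near-uniform
first-component loadings across selected markers are the expected
signature. The discriminant is Fisher's: $w \propto S_p^{-1}(\bar
s_1 - \bar s_0)$ with the midpoint threshold, which for one component
reduces to a cut halfway between the class means on PC1.

## What the synthetic generator emulates

`simulate_chromatograms()` produces the only data the package's tests
can rely on, so its realism budget is spent on the features the
pipeline actually exercises:

* sparse centroided sticks at integer amu (unit-resolution ion-trap
  behaviour), which leaves half-integer mass windows empty — the
  "automatically discarded" half-integer intervals emerge rather than
  being coded in;
* Gaussian elution sampled at the scan interval (default 0.04 min,
  peak SD 0.05 min);
* a dataset-level library of class-independent background compounds
  (default 24, log-uniform apex heights over $10^4$–$10^7$);
* multiplicative lognormal abundance noise per compound per sample
  (default CV 0.2), a per-sample global scale factor (0.5–2×, which
  normalization must absorb — asserted in tests), per-register m/z
  jitter (SD 0.05 amu) and sparse exponential baseline peaks;
* three preset markers copying the motivating study's windows and ion
  sets, with class effects chosen as essentially absent on one side
  (100× generated, 0.01× removed). The base heights follow a sizing
  rule: every fragment of a marker must clear the top-1% codification
  cutoff in its enriched class and stay below it in the other class,
  across the cutoff variation induced by redrawing the background
  library. Effects of this magnitude are what all-or-nothing high/low
  reckonings in real treated/untreated comparisons look like; weaker
  effects are available by setting `class_effect` directly.

What it does **not** emulate: retention drift between samples, peak
tailing and co-elution structure, detector saturation, heteroscedastic
electronic noise, batch effects. Passing the recovery and
cross-validation tests therefore shows the pipeline is correct and
leak-free under its own assumptions — it does not show robustness to
misaligned or saturated real chromatograms.

One behaviour of the method that the generator *does* reproduce, and
users should know about: per-sample mean normalization is
compositional. A compound present only in one class shifts that class's
normalization factor, which moves *every other* node of those samples
slightly and can push a borderline background node across the
codification cutoff class-consistently. With strong markers this
occasionally yields a spurious perfect-split selection far from any
marker. It is a property of mean-based scaling, not a bug in the
selector; robust alternatives (median scaling) are deliberately out of
scope because the reference procedure normalizes by the mean.

## Calibration and validation design

Two properties anchor the package's trust in its own selector:

* **Permutation-null calibration.** Shuffling class labels cannot
  change any label-blind stage (normalization, accumulation,
  codification, constant-node removal, degeneracy grouping — none of
  them read labels), so the permutation studies re-run only rule
  scoring and selection on the fixed binary code. This is exactly
  equivalent to re-running the full pipeline per permutation and makes
  a 100-permutation study cost seconds. At the default threshold,
  permuted labellings select nothing in ≥ 95% of shuffles.
* **Leave-one-out without leakage.** Every fold refits everything from
  the raw scans of the retained samples; the held-out sample is
  normalized by its own mean (a self-contained, single-sample
  operation) and only then projected. The suite asserts the strongest
  observable consequence: multiplying any single held-out sample's
  intensities by $10^6$ leaves the entire cross-validation report
  bit-identical.

## Problem sizes

The shipped tests and the acceptance script run the preset at 10 + 10
samples per dataset (pipeline unit tests at 8 + 8), 10 seeded
replicates with full leave-one-out each, 100 label permutations, and
exhaustive subset enumeration of the p-value for all $N \le 12$. These
sizes give every stochastic check a comfortable margin while keeping a
full run of suite plus acceptance script in the low minutes on one
core; all of them are arguments, not constants, and scale up directly.

## Known limitations

* Binary (two-class, two-level) codification only; the rule formalism
  generalizes to multi-level categorical variables but this
  implementation does not.
* No retention-time alignment; gross drift across samples will split a
  compound's signal across adjacent time nodes.
* The variable ranking (ascending p, then node index) is one natural
  total order; other tie-breaking schemes are defensible.
* Order-3 enumeration at hundreds of representatives is combinatorially
  expensive in plain R; it is intended for small representative sets.
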