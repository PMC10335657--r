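---
title: "Methods: circadian temperature compensation and 3' UTR analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: circadian temperature compensation and 3' UTR analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(circatemp)
options(circatemp.log_level = "quiet")
```

# The scientific problem

Circadian clocks keep a near-24-hour free-running period that is remarkably
insensitive to ambient temperature, even though the underlying biochemistry
is not. This *temperature compensation* can be quantified by the temperature
coefficient

$$Q_{10} = \left(\frac{\tau_{low}}{\tau_{high}}\right)^{10/\Delta T},$$

where $\tau_{low}$ and $\tau_{high}$ are the free-running periods at two
temperatures $\Delta T$ degrees apart. A perfectly compensated clock has
$Q_{10} = 1$; values above 1 indicate that the clock speeds up with warmth
like an ordinary chemical reaction would.

`circatemp` implements the full analysis chain used to characterise a
genetic perturbation (a control/knockdown contrast) that *decompensates* the
clock, and to search for the posttranscriptional regulators responsible:
period estimation from bioluminescence reporters, the differential-slope
statistics with $Q_{10}$ conversion, alternative-polyadenylation (APA)
quantification from 3'-end sequencing, mRNA half-life estimation, and a
genome-scale three-layer (3' UTR length / transcript / protein) differential
temperature-response screen.

# Rhythm estimation

## Detrending

Raw plate recordings decay over days (reporter substrate consumption, cell
state). The baseline trend is removed with a centered moving average over a
24-hour window (`detrend()`, `detrend_window_h`). In `ratio` mode the
detrended series is `signal/trend - 1`, i.e. the oscillation relative to the
baseline magnitude; `subtract` mode returns `signal - trend`.

At the recording edges a full centered window does not exist. We shrink the
window symmetrically (half-width limited by the distance to the nearer
edge) rather than discarding 12 h at each end. The price is that the trend
estimate absorbs progressively more of the oscillation near the edges; for
this reason the damped-cosine fit excludes the trailing
`fit_trim_end_h = 12` h (half a window) by default, and the leading 24 h are
excluded anyway as a post-synchronization transient (`fit_skip_h`). With
these exclusions, noiseless simulated periods between 23 and 27.4 h are
recovered to better than 0.02 h; without the trailing trim the edge bias can
reach 0.09 h.

## Damped-cosine fitting

The detrended series is fitted by least squares to

$$y(t) = A\,e^{-\lambda t}\cos\!\big(2\pi (t - \varphi)/\tau\big).$$

The SSE surface is multimodal in $\tau$, so the fit multi-starts on a grid
of trial periods (18-36 h in 1 h steps, `tau_grid`) crossed with a small
damping grid; for fixed $(\tau, \lambda)$ the amplitude and phase enter
linearly through the basis $e^{-\lambda t}\{\cos,\sin\}(2\pi t/\tau)$ and
are profiled out. The best grid point seeds a Nelder-Mead refinement of
$(\tau, \lambda)$ with box constraints applied as a penalty; we avoid
gradient-based bounded optimizers here because their line searches abort on
the near-zero-residual floor reached with clean data.

**Fit error.** The QC statistic is the RMS residual divided by the fitted
amplitude $|A|$ (or by the signal RMS if $A = 0$). This definition is
scale-free, so the conventional QC threshold of 0.3 (`fit_error_max`) means
"residuals smaller than 30% of the oscillation amplitude" regardless of
units. A fit is `valid` when the optimizer converged, the fit error is at
most the threshold, and the period lies in the plausible circadian range
[16, 40] h. Invalid wells are excluded from condition summaries
(`summarize_wells()`), which report post-QC `n` and flag conditions with no
valid well rather than dropping them.

# Temperature-compensation statistics

Free-running period is modelled as linear in temperature within each
genotype (`fit_temperature_line()`, temperatures centered internally for
conditioning). Whether two genotypes respond differently is decided by the
classical pooled-variance test for equality of two regression slopes
(`compare_slopes()`):

$$s^2 = \frac{RSS_1 + RSS_2}{n_1 + n_2 - 4},\qquad
t = \frac{b_1 - b_2}{\sqrt{s^2/S_{xx,1} + s^2/S_{xx,2}}},$$

two-sided with $n_1 + n_2 - 4$ degrees of freedom. This statistic equals the
interaction-coefficient t test of a two-line model fitted jointly with a
common residual variance, which our tests use as an independent oracle. The
companion equality-of-elevations (intercept) test of the same classical
treatment is deliberately not implemented: only the slope contrast answers
the compensation question. If both groups fit exactly (zero pooled
variance) with different slopes, the result is flagged degenerate with
$p = 0$ rather than erroring.

$Q_{10}$ is evaluated from the fitted lines at 32 and 39 degrees C
(`q10_from_fit()`), with a first-order delta-method standard error that
propagates the full 2x2 covariance of the two predicted periods, including
the slope-intercept covariance. A 10,000-draw parametric bootstrap agrees
with the delta-method SE to within 10% in our tests. Note the period
convention $Q_{10} = (\tau_{low}/\tau_{high})^{10/\Delta T}$: a period
*shortening* with warmth gives $Q_{10} > 1$.

```{r q10}
# the headline desk numbers: control vs knockdown
q10_from_periods(24.4, 23.5, 7)
q10_from_periods(27.4, 24.2, 7)
```

# APA quantification

## NCOM

For a 3'-end read profile along an annotated 3' UTR of length $L$ (offsets
transcript-oriented, 0 at the stop codon for both strands; minus-strand
profiles must be reversed on ingest), the normalized center of mass is

$$\mathrm{NCOM} = \frac{1}{L}\cdot
  \frac{\sum_i c_i\,(p_i + 0.5)}{\sum_i c_i}.$$

NCOM near 0 means proximal polyadenylation-site (PAS) usage — a short
3' UTR — and near 1 distal usage. The half-base offset makes a uniform
profile map to exactly 0.5 and keeps single-base profiles strictly inside
(0, 1); the boundary values 0 and 1 are attained only in the continuous
limit. NCOM is a weighted mean, hence invariant to count rescaling, so it is
computed on raw counts; expression comparisons use size-factor-normalized
counts instead. Zero-coverage profiles yield NA (logged), never an error.

## PAS discovery and annotation extension

PAS discovery tiles the UTR and up to 5,000 nt beyond the annotated end into
consecutive 50-nt scanning windows (`pas_window_nt`,
`pas_max_extension_nt`). A window is called when its summed count reaches
`max(pas_min_abs_count, pas_min_frac * total)`; adjacent qualifying windows
merge. The thresholds (10 reads absolute, 1% of the profile) are this
package's own defaults, surfaced in the config and logged — published
window-scoring internals for this step are not specified anywhere we could
adopt them from. Calls entirely beyond the annotated end extend the
annotation (`extend_annotation()`): the UTR end moves to the distal edge of
the farthest extension call and the isoform id gains the suffix `_ext`.
The operation is idempotent — a second scan of the extended annotation finds
nothing new. Isoforms of a gene with identical UTR intervals are merged with
`|`-concatenated ids (`merge_identical_utrs()`).

## Normalization and distal usage

Between-sample depth normalization uses median-of-ratios size factors
(`size_factors()`): each sample's factor is the median over
all-positive features of the count divided by the feature's geometric mean
across samples (computed in log space, matching the reference
implementation in DESeq2, which our tests use as an oracle). The distal PAS
usage of a gene is the ratio of long-3'-UTR isoform expression to total
expression (`distal_usage()`); ratios above 1, possible with noisy
expression estimates, are kept raw and flagged.

# Genome-scale screens

All layer tables are `feature_table`s (features x samples with genotype /
temperature / replicate annotations). Layer scales: NCOM values in [0, 1],
transcript counts transformed to `log2(normalized + 1)` before testing,
protein LFQ intensities already log2. Missing values propagate: a feature
with fewer than the minimum finite observations yields an NA row that does
not count toward the BH family (`bh_adjust()` adjusts over non-NA entries
only).

* `shift_test()` — per feature, Welch t test knockdown vs control at one
  temperature. Effects: $\Delta$NCOM (knockdown minus control) or log2 fold
  change. The transcript-layer test is a Welch t test on log2 normalized
  counts with a pseudocount of 1 — a deliberate simplification of
  negative-binomial DE machinery, which is not this package's contribution;
  the slope statistics below are unaffected by this choice.
* `temperature_response()` — per feature and genotype, OLS of value on
  temperature; p from the slope t statistic (df $n - 2$); effect reported as
  the fitted change across the 32-39 degC span.
* `differential_response()` — per feature, the pooled-variance
  differential-slope test between genotypes (identical arithmetic to
  `compare_slopes()`), BH within the layer, plus per-genotype $Q_{10}$ from
  the fitted endpoint values. For abundance layers the fitted log2 values
  are exponentiated back to the natural scale first and the rate-like
  convention applies (abundance rising with warmth gives $Q_{10} > 1$);
  NCOM uses its own scale with the same convention. Periods keep the
  reciprocal convention of the tempcomp module. The per-feature $Q_{10}$ is
  computed from fitted endpoint values rather than a slope-only transform —
  with three temperatures both are available, and endpoint values keep the
  definition identical to the period analysis.
* `layer_overlap()` — Venn region counts over the intersection universe of
  features quantified in all compared layers, plus a 2x2 Fisher's exact
  test per pair of significant sets. The odds ratio reported is the sample
  odds ratio $(ad)/(bc)$, not the conditional MLE.

# The synthetic-data generators

Every analysis stage is exercised end to end on generated data with known
truth; all generators are pure functions of `(cfg, seed)`.

* **Bioluminescence** (`gen_bioluminescence()`):
  $y(t) = M(t)[1 + A e^{-\lambda t}\cos(2\pi(t-\varphi)/\tau(g,T))] + \varepsilon$,
  on a 0.5 h grid over 5.5 days, with baseline
  $M(t) = m_0 e^{-t/96\,\mathrm{h}}$ mimicking reporter signal decay and
  $\tau(g, T) = \tau_{0,g} + b_g (T - 35)$. The default lines pass through
  the study's printed endpoint periods (control 24.4 to 23.5 h, knockdown
  27.4 to 24.2 h across 32 to 39 degC), and the default plate design — four
  recording temperatures x four wells — gives the published 16 wells per
  genotype.
* **APA profiles** (`gen_apa_counts()`): two PASs per gene at relative
  positions $q = 0.2$ and $d = 0.8$; proximal usage
  $\pi(g,T) = \mathrm{logistic}(\beta_0 + \beta_g \mathbb{1}[KD] +
  \beta_T (T-37) + \beta_{gT}\mathbb{1}[KD](T-37))$ with the interaction
  active only in the first $\lceil 0.1 n \rceil$ genes; read positions
  Gaussian around each PAS (SD 30 nt) truncated to $[0, L)$; per-sample
  totals negative-binomial around lognormal gene depths (median 300 reads).
  Defaults: $\beta_0 = -1$ (control biased distal, NCOM $\approx 0.64$),
  $\beta_g = +2$ (knockdown shifts proximal, $\Delta$NCOM $\approx -0.28$,
  the direction and magnitude of the published global shortening),
  $\beta_T = -0.01$ (weak baseline temperature effect; NCOM rises slightly
  with warmth), $\beta_{gT} = 0.15$ logit/degC, about one logit unit across
  the 7-degree span — comparable to the strong knockdown shifts, i.e. a
  clearly decompensated APA response.
* **Abundances** (`gen_abundance()`): log-linear model in temperature with
  genotype main effects and interactions (random sign, 0.15 log2/degC,
  i.e. roughly a 2.8-fold $Q_{10}$ contrast — within the spread visible in
  genome-wide $Q_{10}$ scatter), replicate noise 0.15 log2 (tight technical
  replicates), 3 transcript and 4 protein replicates per condition at
  32/37/39 degC. Transcript values are exponentiated and rounded to counts.
* **Decay chases** (`gen_decay_series()`):
  $y(t) = y_0 2^{-t/t_{1/2}} e^{\varepsilon}$ over a 0-8 h chase.

Replicates are modelled as i.i.d. noise draws — the data the pipeline
emulates report technical replicates only, and no richer error structure is
stated. What the generators do **not** emulate: overdispersed biological
replication, batch effects, mappability artefacts and internal priming in
3'-end data, more than two PASs per gene, missing-not-at-random protein
intensities, and nonlinear (e.g. Arrhenius) temperature responses. Passing
recovery tests on these generators therefore demonstrates the estimators'
correctness under the stated model, not robustness to every pathology of
real data.

## An a-priori power sketch for the default effect sizes

With three temperatures (centered $S_{xx} = 26$ per replicate triple) and
3-4 replicates, the SE of a slope difference is
$\sigma\sqrt{2/S_{xx,tot}}$, i.e. $\approx 0.16\,\sigma$ per degC at 3
replicates. The default interaction sizes were chosen once, before any
acceptance run, so that realistic noise levels put the noncentrality near
5 — e.g. NCOM sampling noise $\approx 0.6\sqrt{\pi(1-\pi)/\mathrm{reads}}
\approx 0.02$ against an interaction slope difference of
$\approx 0.018$/degC. That yields sensitivity well above 0.8 at BH 5% with
10% true interactions, without being out of scale with the published
effects.

# mRNA half-lives

`fit_half_life()` regresses `ln(value)` on chase time; $t_{1/2} =
\ln 2 / k$ with $k = -$slope. The log base used for display is irrelevant —
it cancels in the half-life. Nonpositive values are dropped (logged);
non-decaying fits return `Inf` with a `stable` flag instead of erroring;
late near-zero points are *not* excluded automatically (no such rule is
stated for the procedure this emulates; callers can filter). Group
comparisons (`compare_half_lives()`) run on experiment-level values:
technical replicates are averaged per time point within an experiment
before fitting (`decay_table_fits()`), so `n` counts experiments.

# Numerical choices and degenerate inputs

* Temperatures are centered before every regression; slopes are unchanged,
  conditioning improves, and the prediction covariance simplifies.
* Ties/zero variance in t tests: identical groups return $p = 1$ (effect
  0); zero variance with unequal means returns $p = 0$ rather than an
  error.
* `call_pas` on an empty profile returns an empty call set; `compute_ncom`
  on zero coverage returns NA.
* All-zero traces produce an invalid `rhythm_fit`, not an exception; wells
  whose detrending fails (nonpositive signal in ratio mode) are logged and
  marked invalid by `fit_plate()`.
* Seeds: every generator consumes `cfg$seed` (plus a fixed per-generator
  offset so the four generators draw independent streams from one config).

# Problem sizes used by the test suite

The package's own test suite runs the full screen at the default scale
(2,000 genes, 10% interaction features) across five seeds, 1,000-replicate
null calibrations of the differential-slope test, a 10,000-draw bootstrap
check of the $Q_{10}$ standard error, and brute-force oracle comparisons
for NCOM (1,000 random profiles), size factors, BH, and Fisher's exact
test. These sizes were chosen as the smallest that make the stochastic
assertions stable across seeds.

# Known limitations

* The scanning-window PAS caller is a transparent stand-in for more
  elaborate published 3'-end quantifiers; window tiling (not overlapping
  windows) and the call thresholds are package choices.
* The transcript-layer two-group test is a t test on log2 normalized
  counts, not a count model; for three technical replicates of deeply
  sequenced libraries the practical difference is small, but counts near
  zero are better served by negative-binomial machinery.
* Temperature responses are modelled as linear throughout; $Q_{10}$ from
  two endpoints inherits this assumption and can mislead if the true
  response is strongly curved.
* The period-layer analysis assumes one oscillation per well; mixtures of
  rhythmic subpopulations are not modelled.
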