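---
title: "Co-toxicity analysis of binary pesticide mixtures"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Co-toxicity analysis of binary pesticide mixtures}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cotox)
```

## The problem

When a microbial insecticide (e.g. *Beauveria bassiana* conidia) is blended
with a botanical compound (e.g. azadirachtin), the blend can kill more,
equally, or less effectively than the dose-additive expectation from the
two components. The co-toxicity coefficient (CTC) quantifies this from
three dose-mortality bioassays — agent A alone, agent B alone, and the
mixture M — and is the standard screen for picking an optimal mixing
ratio. This package implements that full workflow: raw replicate-level
mortality tables, control correction, dose-response fitting, LC50
estimation with uncertainty, the CTC and its interaction classification,
and the companion compatibility metrics that check the chemical does not
harm the fungus itself.

## From counts to corrected mortality

A bioassay record is one replicate at one dose: `n_dead` of `n_exposed`
insects dead at the scoring endpoint (a fixed 7-day endpoint in the
motivating design; time-to-death is out of scope). Replicates are pooled
per dose and background mortality is removed with Abbott's correction,

$$p_{corr} = \frac{p_t - p_c}{1 - p_c},$$

with $p_t$ the pooled treatment mortality and $p_c$ the pooled control
(dose 0) mortality. Internally all mortalities are fractions in $[0,1]$;
percentages appear only at I/O boundaries, which removes a whole class of
$\times 100$ bookkeeping errors. When sampling noise puts $p_t$ below
$p_c$ the corrected value is clamped to 0 with a warning rather than
propagating a negative mortality. Assays with pooled control mortality
above 0.20 (the conventional rejection threshold, tunable in
`validate_assay()`) are flagged.

## Dose-response models and the LC50

Two models of mortality against $x = \log_{10}(\text{dose})$ are provided:

* **Linear** (`fit_linear_logdose()`): ordinary least squares of corrected
  mortality, as a percentage, on $x$. This is the "virulence equation"
  conventionally reported for mixture screens, and the model whose
  robustness the simulator is designed to probe.
* **Probit** (`fit_probit()`): maximum-likelihood binomial regression with
  a probit link, the field-standard quantal model, fitted to
  Abbott-corrected proportions via `stats::glm`.

The regression is always on $\log_{10}$ of the concentration in its
declared unit — never on a dilution-step index, which depends on an
arbitrary stock concentration and is irreproducible across labs. Every
fit records this convention in its serialized form.

LC50s come from inverse prediction: $10^{(50 - b_0)/b_1}$ for the linear
model (percent scale), $10^{(\Phi^{-1}(p) - b_0)/b_1}$ for probit. A zero
slope leaves the LC50 undefined and is an error, not a number.

Goodness of fit is a Pearson chi-square of observed versus expected dead
counts. Linear-model predictions are clamped to $[0,1]$ only at this
evaluation stage, never during fitting. Doses whose expected dead (or
expected surviving) count falls below 1 are merged with their neighbour
before the statistic is computed, the usual guard against sparse-cell
inflation; a merged cell whose fitted mortality is still pinned at 0 or 1
has its variance bounded by half a count.

## The co-toxicity coefficient

With agent A as the reference (toxicity index 100):

$$TI_B = \frac{LC50_A}{LC50_B} \times 100, \qquad
  TI_M^{act} = \frac{LC50_A}{LC50_M} \times 100,$$
$$TI_M^{theo} = TI_A \, w_A + TI_B \, w_B, \qquad
  CTC = \frac{TI_M^{act}}{TI_M^{theo}} \times 100,$$

where $w_A, w_B$ are the weight fractions of the two formulated agents in
the mixture (parts such as 9:1 are normalized on construction). The chain
is algebraically equivalent to

$$CTC = 100 \cdot \frac{LC50_{add}}{LC50_M}, \qquad
  LC50_{add} = \frac{1}{w_A/LC50_A + w_B/LC50_B},$$

i.e. the additive reference is the ratio-weighted harmonic mean
(`additive_lc50()`), and CTC = 100 means exact Loewe-type dose
additivity. The equivalence, its reference-swap symmetry and scale
invariance are enforced as property tests over random inputs at 1e-9
relative tolerance.

Classification: CTC > 120 synergism, CTC < 80 antagonism, and the closed
interval [80, 120] cumulative (additive). The boundaries are assigned to
the cumulative class because the defining wording is "higher than 120"
and "less than 80".

Two deliberate strictnesses: the three LC50s must share one declared
unit (a conidia/mL count cannot be averaged with mg/L without an explicit
potency conversion, which is the caller's responsibility), and CTC is kept
at full precision internally, rounded to 2 decimals only in reports.

## Uncertainty

No analytic variance is attempted for the CTC — it is a ratio of
nonlinear functionals of three separate fits. Instead a nonparametric
bootstrap, stratified by dose and deterministic per seed, refits
everything per resample and reports percentile intervals
(`bootstrap_lc_ci()`, `ctc_bootstrap()`).

The resampling unit matters. Resampling whole replicates within a dose
preserves between-replicate overdispersion, but with the standard design
of 3 replicates per dose a within-stratum bootstrap underestimates
variance by a factor of about $(k-1)/k = 2/3$, and its nominal-95%
intervals cover the truth in only about three quarters of simulated
experiments. The default therefore resamples the pooled *insects* within
each dose stratum (equivalently, redraws each pooled dead count
binomially at its observed mortality), which matches the binomial
sampling process of the assay and restores near-nominal coverage in the
package's own recovery simulations. `boot_unit = "replicate"` remains
available for assays with enough replicates for the classic scheme, or
where extra-binomial variation between replicates is the dominant noise
source. Replicates that yield no valid fit are dropped; if more than half
fail the interval is refused with a diagnostic rather than silently
reported.

## The simulator and what validation does (and does not) show

`simulate_bioassay()` draws dead counts from
$\mathrm{Binomial}(n,\; c + (1-c)\,\Phi(b\,(\log_{10} d - \log_{10} LC50)))$
per dose and replicate, with $c$ the background mortality. The truth model
is deliberately probit — not linear — so that the simpler linear fitter is
always exercised on realistically sigmoid data, mirroring how the
virulence equation approximates curved mortality in practice.

`simulate_mixture_experiment()` makes the true CTC a design parameter: the
mixture is simulated at
$LC50_M = LC50_{add} \times 100 / CTC_{true}$, so recovery of the entire
pipeline (simulate → pool → correct → fit → CTC) can be measured against
known truth. Per-assay and per-experiment seeds derive from one master
seed by a fixed affine counter scheme, making every study a pure function
of that seed.

Default design constants mirror the standard whitefly immersion assay: 5
dose levels spaced 10-fold, 3 replicates of 30 insects, zero control
mortality. Default true LC50s are 5.76 mg/L for agent A (a typical
azadirachtin potency) and 20 mg/L for agent B expressed in the same
mass-equivalent unit (the fungal agent's standalone potency must be
declared in a common unit; no spore-count conversion is assumed). Default
probit slopes are 1.5 per decade, a mid-range steepness for such assays.
Each treatment's gradient is anchored at a stock of 100 x its true LC50,
placing the LC50 at the middle dilution — the arrangement a
pilot-informed experiment aims for.

The validation suite runs recovery studies of 500 simulated experiments
per condition at true CTC 50, 100 and 200, with 499 bootstrap resamples
per experiment, checking median CTC recovery and empirical CI coverage;
`recovery_summary()` reproduces these tables. What this does **not**
show: robustness to between-replicate overdispersion (the generator is
exactly binomial), to dose-measurement error, to control mortality far
above the rejection threshold, or to gradients that badly miss the LC50 —
real assays can fail in all four ways, and the validation only covers the
designs it simulates.

## Compatibility metrics

For the chemical-fungus compatibility screen,
`inhibition_rate()` is $(\text{control} - \text{test})/\text{control}
\times 100$ on mean colony diameters (growth stimulation yields a
negative rate, flagged with a warning), and `germination_rate()` is
germinated/observed spores x 100. Plate replicates are averaged per
concentration before the formula; spore counts are pooled. Whether the
0.5-cm inoculation plug should be subtracted from measured diameters is
lab convention; it is off by default (`subtract_plug = FALSE`) since
published protocols frequently omit it, but a flag applies the
subtraction to control and treatment alike.

## Known limitations

* Only fixed-endpoint mortality: no time-dose-mortality surfaces.
* Only binary mixtures, and only the CTC interaction criterion — no
  isobolograms, Bliss independence or Chou-Talalay indices.
* The linear model can predict outside [0, 100]% within the fitted range;
  that is inherent to the conventional virulence equation, and the probit
  model is provided where this matters.
* Published mixture tables often omit the ingredients needed to
  back-compute their CTCs (the co-agent's standalone LC50, stock
  concentrations, the regression x-variable); such tables can be used as
  format and classification references only, which is exactly how the
  report writer treats them.
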