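---
title: "Methods: Franz-cell permeation analysis and TMWL barrier screening"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: Franz-cell permeation analysis and TMWL barrier screening}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(permeatr)
```

## The measurement model

A Franz static diffusion cell holds a membrane between a donor compartment
(carrying an applied dose of volume $V_{app}$ at concentration $C_0$) and a
stirred receptor compartment of volume $V_c$ with diffusion area $A$. At
each scheduled time an aliquot $V_s$ is withdrawn for assay and replaced
with fresh receptor fluid. The package's defaults are the protocol of its
reference analyses: $V_c = 3$ mL, $V_s = 0.2$ mL, $A = 1.86$ cm², samples
at 0, 0.5, 1, 2 and 4 h, and a pseudoinfinite dose of 300 µL at 1% w/v
($C_0 = 10^4$ µg/mL, 3000 µg applied). All of these are overridable through
`franz_cell()`, `dose_spec()` or a YAML configuration.

Units are fixed internally — µg, µg/mL, mL, cm², h — with TMWL kept
separately in g/(m²·h); converters belong at the I/O boundary only.

### Sampling correction

Because each withdrawn aliquot removes analyte mass $C_i V_s$ that later
samples can no longer see, the cumulative amount permeated per unit area is

$$Q_n = \frac{C_n V_c + \sum_{i=1}^{n-1} C_i V_s}{A}.$$

The correction sum runs over **all** strictly earlier samples; a time-0
sample (normally ≈ 0) participates like any other. This is exact mass
bookkeeping, not an approximation: for any withdraw-and-replace experiment
the reconstructed $Q_n$ equals the true transferred mass per area at every
sampling time. The simulator exploits this — its receptor mass ledger is
the package's strongest internal oracle, and the noise-free round trip is
tested to $10^{-10}$ relative.

Two conventions exist for percent-permeation profiles: normalising by the
applied dose or by the recovered (final cumulative) amount. A receptor peak
of 507 µg/mL in 3 mL against a 3000 µg dose is 50.7% under the applied-dose
convention, which matches how peak permeation fractions are usually quoted;
applied-dose is therefore the default and `reference = "recovered"` is
available where a self-normalised profile is wanted.

### Censoring

Assay limits of quantification are applied before the correction.
Readings strictly below the LoQ are set to zero by default (`half_loq` and
`keep` policies are provided); the boundary is inclusive — a reading
exactly at the LoQ is data. How sub-LoQ readings were handled is rarely
reported in practice, so the policy is explicit and recorded in the series
metadata. Negative instrument readings are rejected at import and clipped
(with a warning) if they reach the correction step.

## Kinetic analysis

Three candidate models are fitted to $Q(t)$:

| model | form | parameters | fit |
|---|---|---|---|
| zero order | $Q = J\,(t - T_l)$ | $J$, $T_l$ | OLS of $Q$ on $t$ |
| first order | $Q = Q_\infty(1 - e^{-kt})$ | $Q_\infty$, $k$ | Levenberg–Marquardt |
| Higuchi | $Q = K_H \sqrt t$ | $K_H$ | through-origin OLS in $\sqrt t$ |

The winner is the highest degrees-of-freedom-adjusted coefficient of
determination $R^2_{adj} = 1 - (1 - R^2)(N-1)/(N-p-1)$ — the conventional
penalty for parameter count at small $N$. Ties break toward fewer
parameters, then the fixed order zero, Higuchi, first. All-constant
profiles are flagged degenerate rather than fitted, and a selection with
only degenerate candidates is an error, not a silent answer.

First-order starting values are $Q_{\infty,0} = 1.2 \max Q$ and $k_0$ from
the log-linearisation $\log(1 - Q/Q_{\infty,0}) = -kt$ over the nonzero
samples, with up to 5 jittered restarts before the fit is declared
degenerate. On noise-free generator data each model recovers its own
parameters to $10^{-6}$ and is selected 3/3 — the model-attribution
consistency the tests pin down.

### Flux, lag time, permeability

The steady-state flux is the slope of the **linear portion** of $Q(t)$:
the longest contiguous terminal window (ending at the last sample) of at
least 3 points whose OLS $r^2 \ge 0.99$, falling back to the terminal 3
points when nothing qualifies. Both thresholds are arguments
(`r2_threshold`, `min_window`) because no universal rule exists. The lag
time is reported twice — as the window line's x-intercept (the classical
graphical definition) and as the zero-order model's own lag — since the
two do not coincide on curved profiles and practice varies.

$K_p = J / C_0$ (µg·cm⁻²·h⁻¹ over µg·cm⁻³ gives cm/h) holds exactly by
construction and is invariant to jointly rescaling $C_0$ and the measured
concentrations. $C_{max}$ is reported in µg/mL alongside $Q_{max}$ in
µg/cm², because both units are in routine use; $t_{max}$ is the earliest
time attaining the maximum. AUC uses the linear trapezoid, exact on
piecewise-linear profiles.

A validity note that matters for interpretation: the terminal-window
estimator measures $J$ only if steady state is reached inside the sampled
window. With a 4 h horizon this requires the membrane lag time to be well
under ~1 h; a strongly lagged barrier sampled for 4 h yields a terminal
slope that still underestimates the true steady flux, and no window rule
can repair that — it is an experimental-design constraint, not an
estimator defect.

## Barrier screening

Waterproofing formulations are screened by percent TMWL reduction against
the same membrane's untreated control,
$(TMWL_{ctrl} - TMWL_{treated})/TMWL_{ctrl} \times 100$, with replicates
averaged on both sides. Rankings are stable sorts so equal effects keep
panel order. The cross-membrane analysis regresses tissue TMWL on
surrogate TMWL over matched formulations — pooled across formulation
classes by default, since the screening question is whether the surrogate
predicts tissue response overall; $R^2$ is direction-invariant but slope
and intercept follow the tissue-on-surrogate convention. The packaged
reference panel (16 formulations on a polycarbonate surrogate and porcine
sublingual mucosa) gives $R^2 = 0.884$ on formulation means; means, not
replicates, are what panels of this kind publish, so means are the default
grain of the analysis.

Group comparisons use the Kruskal–Wallis rank test (`stats::kruskal.test`
behind the package's result type), with midrank ties and the standard tie
correction, and the chi-square approximation for $p$. At the panel's small
group sizes that approximation is coarse: exhaustive enumeration of the
70 assignments of two untied groups of 4 bounds the gap between the exact
permutation $p$ and the chi-square $p$ by 0.123 (0.187 for groups of 3).
A seeded permutation $p$-value (`exact_permutations`) is therefore
provided, and the tests assert chi-square/permutation agreement only
within the enumerated approximation bound, not within Monte-Carlo error.

## The synthetic study generator

The generator exists to make every stage falsifiable without laboratory
data. It emulates, layer by layer:

1. **Transport.** Transient Fickian diffusion through a homogeneous
   membrane (diffusivity $D$, thickness $h$, partition $K$) under sink
   conditions, via the exact eigenfunction series
   $$Q(t) = K h C_0\left[\frac{Dt}{h^2} - \frac16 - \frac{2}{\pi^2}
   \sum_{m\ge1}\frac{(-1)^m}{m^2}e^{-Dm^2\pi^2t/h^2}\right],$$
   whose asymptote has slope $KDC_0/h$ and time-intercept $h^2/6D$ — the
   quantities the analysis estimates. The series is truncated at
   `n_terms` (default 50) with an explicit tail bound; if the bound
   exceeds $10^{-9}$ of the steady-state slope at the earliest requested
   time the call fails asking for more terms rather than returning a
   silently wrong transient. An independent finite-difference solution of
   Fick's second law (200 spatial nodes) agrees within 0.5%.

2. **Sampling.** A receptor mass ledger: before sample $n$ the receptor
   holds the true transferred mass minus all previously withdrawn aliquot
   masses; withdrawal uses the *true* concentration, measurement noise is
   applied only to the reading. Mass conservation is exact at every step
   and the ledger is retained as ground truth.

3. **Noise.** Multiplicative Gaussian with coefficient of variation
   `noise_cv` (default 5%, a typical HPLC assay scale), truncated at
   $-3\sigma$ so concentrations stay non-negative at any CV ≤ 1/3.
   Analytical error at these concentration ranges is proportional, which
   is why the noise is multiplicative rather than additive.

4. **TMWL panels.** Each membrane has a baseline water loss (defaults
   80.8 and 72.4 g/m²·h for surrogate and mucosa, the observed magnitudes
   for high-permeability membranes); each formulation applies one
   multiplicative barrier effect shared across membranes, plus
   proportional noise. The default effect set is the surrogate's observed
   treated/control ratios, spanning strong hydrophobic barriers (~0.03)
   to weak hydrophilic gels (~0.93). Shared effects make the noise-free
   panel exactly proportional between membranes ($R^2 = 1$), and at 5%
   noise the recovered cross-membrane $R^2$ stays above 0.95 (median over
   20 seeds).

Membrane presets are illustrative placeholders spanning the observed
permeability range — surrogate $K_p \approx 50\times10^{-3}$ cm/h, mucosa
$\approx 35\times10^{-3}$, skin $\approx 2.5\times10^{-3}$ — with lag
times (0.002, 0.17, 0.42 h) deliberately inside the 4 h horizon so that
the steady-state linear portion the estimators read actually exists in
the sampled window (see the validity note above). No published effective
diffusivities or partitions exist for these membranes; the presets are
not fitted tissue properties and are documented as such.

Reproducibility: one root seed; the $i$-th consumer of randomness derives
child seed $(root \times 10007 + i) \bmod (2^{31}-1)$, so simulated cells
are independent, order-insensitive, and fixture files are byte-identical
across runs with the same seed.

```{r fixture, eval = FALSE}
dir <- tempfile()
generate_study_fixture(dir, seed = 1, noise_cv = 0.05)
cfg <- read_study_config(file.path(dir, "config.yaml"))
series <- read_timecourse_table(file.path(dir, "timecourse.csv"), cfg$cell)
params <- parameters_table(lapply(series, fit_permeation,
                                  cell = cfg$cell, dose = cfg$dose))
```

## What the synthetic tests do and do not show

Problem sizes mirror the reference design throughout: 5 sampling times,
triplicate cells, 7 analytes × 3 membranes (63 cells per fixture),
16-formulation two-membrane panels, 20-seed recovery experiments at 5%
noise. Under those conditions the suite establishes that the sampling
correction inverts the protocol exactly, that flux/permeability recovery
is unbiased to a few percent, and that model attribution is consistent.

What it cannot show: real membranes are not homogeneous Fickian slabs
(mucus binding, vascular clearance, follicular shunts and donor depletion
are all outside the generative model); formulation effects on real tissue
are not exactly multiplicative or exactly shared across membranes; and
real assay error has structure (carry-over, drift) beyond proportional
Gaussian noise. Passing recovery tests therefore validates the *analysis
pipeline*, not any claim about a particular biological membrane.

## Degenerate inputs and numerical choices

* All-zero profiles: flagged degenerate in every fitter; `J = 0` is an
  answer for the zero-order fit, an error only at model selection when
  nothing is fittable.
* $V_s = 0$ reduces the correction to $Q_n = C_n V_c / A$ exactly;
  $V_s \ge V_c$ is rejected as physically meaningless.
* Ties in ranking and in `tmax` resolve to the earliest/stable choice.
* Regression on a zero-variance predictor and panels missing a control
  row fail loudly with the reason named.
* Replicate counts are carried but never assumed (reference panels mix
  n = 3 and n = 4 designs); analyses operate on whatever replication the
  table provides.
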