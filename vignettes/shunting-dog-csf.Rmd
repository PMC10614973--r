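---
title: "A shunting Difference-of-Gaussians model of spatial contrast sensitivity"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A shunting Difference-of-Gaussians model of spatial contrast sensitivity}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dogcsf)
```

## The model

`dogcsf` simulates the contrast-sensitivity function (CSF) of a
one-dimensional array of rate-based visual neurons with
on-center/off-surround receptive fields. It is aimed at modeling work on
excitation/inhibition (E/I) balance in early vision — in particular the
contrasting spatial-frequency-sensitivity phenotypes reported for medicated
and unmedicated patients with schizophrenia — where the question is which
changes to the excitatory and inhibitory receptive-field subfields reproduce
a given perceptual signature.

Each neuron receives a luminance input through two concentric Gaussian
subfields,

$$G_{ex}(x) = A_{ex}\, e^{-x^2 / 2\sigma_{ex}^2}, \qquad
  G_{inh}(x) = A_{inh}\, e^{-x^2 / 2\sigma_{inh}^2},$$

each truncated at $\pm 5\sigma$. The input array $I$ is convolved with both
kernels, $I_{ex} = I * G_{ex}$ and $I_{inh} = I * G_{inh}$, and drives a
shunting (membrane-style) rate equation

$$\dot x = -Ax + (B - x) I_{ex} - (C + x) I_{inh},$$

whose multiplicative gating bounds activity in $(-C, B)$ for nonnegative
drive. All reported quantities use the closed-form equilibrium

$$x_{eq} = \frac{B I_{ex} - C I_{inh}}{A + I_{ex} + I_{inh}},$$

which substitutes into a normalized, input-weighted Difference of Gaussians
(DoG): the effective spatial filter is $B G_{ex} - C G_{inh}$. A separate
time-domain integrator (`integrate_dynamics()`, built on `deSolve`) exists
purely to validate the closed form; it is not on the CSF code path.

Stimuli are sinusoidal luminance gratings $y_i = a \sin(2\pi f i)$ at
amplitude $a = 0.1$, with $f$ swept over 200 frequencies from 0.1 to 100
cycles/degree (cpd). For each grating, the model's contrast representation
is the peak-minus-trough readout

$$S(f) = \max_i x_{eq,i} - \min_i x_{eq,i},$$

taken over interior neurons only (see *Edge handling*). Plotting $S$
against $f$ gives the model CSF.

## Parameters

| Parameter | Meaning | Unit | Default |
|---|---|---|---|
| $A$ | passive activity decay | 1/time | 1 |
| $B$ | activity upper bound | activity | 10.1 |
| $C$ | activity lower-bound magnitude | activity | 5 |
| $A_{ex}, A_{inh}$ | subfield peak heights | dimensionless | 1, 1 |
| $\sigma_{ex}, \sigma_{inh}$ | subfield widths | model units | 1, 1.6 |
| $a$ | grating amplitude | luminance modulation | 0.1 |
| `deg_per_unit` | degrees of visual angle per model unit | deg | 0.05 |
| grid | neurons / field width | — | 4000 over 10° |
| sweep | frequency range / count / spacing | cpd | 0.1–100, 200, log |

The base surround-to-center width ratio 1:1.6 is the classical
Marr–Hildreth optimum for contrast registration; with $B = 10.1$ and
$C = 5$ the effective filter $B\hat G_{ex}(f) - C\hat G_{inh}(f)$ is
band-pass, giving the characteristic CSF shape with, at the defaults, a
peak near 3 cpd and prominence ≈ 0.46.

**Spatial units.** The subfield widths are dimensionless "model units"; a
single scalar `deg_per_unit` places them (and nothing else) on the spatial
grid. The default of 0.05 °/unit was chosen once so that (a) the base
band-pass peak falls in the low spatial-frequency analysis band, (b) the
grid resolves at least 16 samples per cycle at 25 cpd, the top of the
analyzed range, and (c) the excitatory transfer function stays well above
the kernel-truncation noise floor through the low and medium bands. Larger
values push the truncation floor into the analyzed range; smaller values
move the CSF peak into the medium band.

**Frequency spacing.** Logarithmic spacing is the standard axis for CSFs
and is the default; `make_sweep(..., spacing_mode = "linear")` is available,
and the replication machinery runs under either.

## Numerical choices

* **Convolution.** "Same"-length discrete convolution with zero padding,
  scaled by the grid spacing so sums approximate the continuous integrals
  and results are resolution-independent. The inner products are
  accumulated in extended (long-double) precision in C++: near 25 cpd the
  excitatory transfer $e^{-2\pi^2\sigma^2 f^2}$ is $\sim 4\times10^{-14}$
  of the kernel mass, which double-precision accumulation would lose to
  cancellation.
* **Kernel truncation.** Kernels are evaluated on the grid lattice and
  truncated at the largest lattice multiple $\le 5\sigma$, per the model's
  subfield definition. Truncation has a measurable consequence: the sharp
  cutoff contributes spectral sidelobes of order
  $a A e^{-12.5}/(\pi f)$, which overtake the true Gaussian transform of
  the excitatory subfield above ≈ 14 cpd (inhibitory: ≈ 9 cpd) at the
  default units. Below those frequencies the simulated amplitudes match the
  analytic transform to better than 0.1%; above them, responses are
  sidelobe-dominated, roughly $10^{-7}$ of the CSF peak, and sign-unstable.
  Statements about the top of the high band should therefore be made at the
  band level (norms), not pointwise.
* **Edge handling.** Zero padding would distort peaks measured near the
  field boundary, so a `valid_mask` excludes $5\sigma$ (of the wider
  subfield) at each edge from every readout; interior samples have full
  kernel support and are truncation-free. Circular wrap-around was rejected
  because non-integer cycle counts would create seam discontinuities.
* **Degenerate dynamics.** The equilibrium denominator
  $A + I_{ex} + I_{inh}$ must exceed $10^{-9}$ at every valid sample;
  violations raise an error naming the sample. With $a = 0.1$ and the
  default kernels the perturbation to $A = 1$ is of order $10^{-2}$.
* **Peak descriptors.** The "distinct peak" language used to describe CSF
  shapes is quantified as: argmax over the sampled sweep (ties to the
  lowest frequency), prominence $1 - \max(S_{first}, S_{last})/S_{max}$,
  and a distinct peak iff the argmax is interior and prominence ≥ 0.05.
  The 0.05 threshold is this package's convention. Peak shifts smaller
  than one sweep step are reported as "unchanged".
* **Tolerances.** The ODE oracle integrates at `rtol = 1e-8` and must agree
  with the closed form to $10^{-6}$ (sup-norm) at $t = 20/A$; each neuron's
  equation is linear with relaxation rate $A + I_{ex} + I_{inh}$, so the
  residual transient is $\sim e^{-20}$.

## Comparison statistics

Curves are compared against the base (control) curve per spatial-frequency
band — low $[0.1, 4)$, medium $[4, 10)$, high $[10, 25]$ cpd — and over
their union ("overall"; frequencies above 25 cpd are numerically negligible
and excluded from norms). For a condition curve $\mathrm{MSV}$ and base
curve $\mathrm{MBCSV}$:

* cosine similarity $\cos\theta = \mathrm{MSV}\cdot\mathrm{MBCSV} /
  (|\mathrm{MSV}||\mathrm{MBCSV}|)$ and its angle $\theta$ (clamped before
  $\arccos$);
* the normalized difference index
  $\mathrm{NDI} = (|\mathrm{MSV}| - |\mathrm{MBCSV}|) /
  (|\mathrm{MSV}| + |\mathrm{MBCSV}|)$, with $|\cdot|$ the Euclidean norm —
  a band NDI beyond ±0.01 labels the band "increased"/"decreased";
* a two-sided paired t-test on the per-frequency differences within the
  band. A band NDI is a single scalar, so the test is constructed on the
  per-frequency differences; this construction is this package's
  convention, reported alongside the NDI at $\alpha = 0.05$.

## The condition catalog

`builtin_catalog()` encodes 25 named E/I manipulations: the isolated and
concurrent subfield changes studied in the E/I-imbalance modeling
literature (σ~ex~ ∈ {0.8, 1.2}, A~ex~ ∈ {0.8, 1.2}, σ~inh~ ∈ {1.2, 2.0},
A~inh~ ∈ {0.6, 1.4}, the four (σ~ex~, A~ex~) pairs at {0.6, 1.4}, four
(σ~inh~, A~inh~) pairs, ratio-preserving scalings of both widths (×0.9,
×1.1) and both amplitudes (×0.5, ×1.5)), plus five best-fit patient
signatures: medicated phenotypes (low-band loss: ↑σ~inh~∧↑A~inh~;
medium/high loss: ↑σ~ex~∧↑σ~inh~; overall loss: ↓A~ex~∧↓A~inh~) and
unmedicated phenotypes (low-band gain: ↓σ~inh~∧↓A~inh~; overall gain:
↓σ~ex~∧↑A~ex~). Where the literature gives directions without magnitudes,
the catalog reuses the corresponding single/concurrent-change values and
records the choice in each condition's `source` field.

Each condition carries the qualitative outcome reported for it (per-band
labels, expected peak-shift direction, distinct-peak flag);
`run_replication()` simulates every condition and scores observed behavior
against those expectations.

```{r replication, eval = FALSE}
rep <- run_replication()   # ~7 s: 26 curves x 200 frequencies x 4000 neurons
rep$results[, c("condition", "outcome_low", "outcome_medium", "outcome_high",
                "peak_shift_steps", "pass")]
rep$pass_fraction
```

## What the replication battery does and does not show

The simulated curves are exact consequences of the equations above, and the
package verifies them against independent oracles (closed-form Fourier
transforms, the time-domain integrator, small-signal linearity, grid
refinement). Agreement with the *qualitative literature expectations* is a
separate, empirical question, and at the default configuration it is
partial (`pass_fraction` ≈ 0.28). The failures are systematic, not
numerical, and a small-signal analysis explains them: with $a = 0.1$ the
equilibrium is effectively linear, so
$S(f) \propto |N(f)|$ with
$N(f) = B A_{ex}\sigma_{ex} e^{-c\sigma_{ex}^2 f^2} -
        C A_{inh}\sigma_{inh} e^{-c\sigma_{inh}^2 f^2}$,
$c = 2\pi^2 (\texttt{deg\_per\_unit})^2$. Three consequences:

1. **Low-frequency reversals.** Any change to a subfield *width* moves the
   DC gain $B A_{ex}\sigma_{ex} - C A_{inh}\sigma_{inh}$ in the opposite
   direction to its high-frequency effect; e.g. narrowing the excitatory
   subfield necessarily *lowers* sensitivity below ≈ 1.17× the base peak
   frequency in any unit system. "Greater at every frequency" claims for
   width manipulations therefore cannot co-hold with an interior base peak.
2. **Sign inversions under strong inhibition.** When the surround mass
   $C A_{inh}\sigma_{inh}$ exceeds the center mass $B A_{ex}\sigma_{ex}$
   (e.g. σ~inh~ = A~inh~ = 2), $N$ is negative at low frequency and the
   sign-blind peak-trough readout reports a *large* low-band response, the
   opposite of the expected low-band loss.
3. **Peak-shape thresholds.** Prominence is a fixed, unit-independent ratio
   of DC to peak response for a given parameter set, so some expected
   "lacks a distinct peak" flags disagree at the 0.05 threshold.

These are properties of the published model equations at these parameter
values, in the small-signal regime this implementation operates in; a model
whose convolution scaling placed the inputs far outside that regime (or
that rectified activities before readout) could behave differently. The
amplitude manipulations, amplitude-ratio scalings, several concurrent
conditions, and the NDI directions of three of the five patient signatures
do replicate; the per-condition scoring in `run_replication()` records
exactly which.

The synthetic stimuli are idealized: single-orientation, 1-D,
full-field, noise-free, zero-mean gratings at one fixed amplitude, with no
observer noise or psychometric threshold model. Passing tests therefore
validate the model's mechanics, not its calibration to human CSFs —
absolute sensitivities are in arbitrary units (the convolution scaling
convention is explicit but arbitrary), and only curve shapes and
between-condition comparisons are meaningful.

## Problem sizes

Default runs use 4000 neurons × 200 frequencies per curve; the replication
battery simulates 26 curves (~7 s on one core). Unit tests use reduced
grids (1000 neurons, 60 frequencies) where the property under test permits;
the acceptance suite exercises the full default configuration, including a
grid-doubling stability check at 8000 neurons.

## Limitations

* Single-layer, feedforward: no recurrent connectivity, thalamocortical
  loops or cortical feedback; the "receptive field" is a population-level
  abstraction collapsing LGN and early cortical stages.
* 1-D space: no orientation, 2-D isotropy, or eccentricity dependence.
* No temporal dynamics in the stimulus; the shunting equation is used only
  through its equilibrium.
* Luminance is a signed modulation, not calibrated cd/m²; a `dc_offset`
  option exists but defaults to 0, matching the generating equation as
  written.
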