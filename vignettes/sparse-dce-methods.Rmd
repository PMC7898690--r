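---
title: "Measuring subtle blood-brain-barrier leakage from sparsely sampled T1 maps"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring subtle blood-brain-barrier leakage from sparsely sampled T1 maps}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sparsedce)
```

## The measurement problem

A healthy blood-brain barrier (BBB) is nearly impermeable to
gadolinium-based contrast agents; its subtle disruption — seen in
small-vessel disease, dementia and normal ageing — lets contrast agent
extravasate at leakage rates on the order of $K_i \sim 10^{-4}$ to
$10^{-3}\ \mathrm{min^{-1}}$. Detecting exchange this slow with dynamic
contrast-enhanced (DCE) MRI requires long acquisitions (beyond 20 minutes),
but because the tissue signal changes so slowly, continuous dynamic
scanning wastes scanner time: a handful of high-SNR quantitative T1 maps at
well-chosen times can carry the same information, freeing the gap between
them for other sequences.

`sparsedce` implements that sparse protocol end to end:

1. a pharmacokinetic core (extended Tofts forward model, Patlak graphical
   estimator, T1-to-concentration conversions);
2. a vectorized Monte-Carlo simulator that answers the two protocol-design
   questions — how many postcontrast T1 maps, and when to place the last
   one;
3. a voxelwise quantification pipeline producing $K_i$ and $v_p$ maps from
   a precontrast T1 map, two or more postcontrast T1 maps, and a dynamic
   blood series from a venous region of interest;
4. a seeded digital phantom with known ground truth for validating the
   pipeline without scanner data.

## Models

### Forward model

Tissue concentration follows the extended Tofts model,

$$C_t(t) = v_p\,C_p(t) + K^{trans}\int_0^t C_p(\tau)\,
  e^{-K^{trans}(t-\tau)/v_e}\,d\tau ,$$

which, unlike the plain Patlak picture, allows backflux from the
extravascular-extracellular space (volume fraction $v_e$) into plasma —
relevant over long scan windows. Reference tissue values used throughout:
$K^{trans} = 5.0\times10^{-4}\ \mathrm{min^{-1}}$, $v_p = 0.036$ for white
matter (WM); $8.0\times10^{-4}\ \mathrm{min^{-1}}$, $v_p = 0.049$ for gray
matter (GM); $v_e = 0.05$ for both; "impaired" conditions scale
$K^{trans}$ up by 20%, matching reported small-vessel-disease effect
sizes. The convolution is evaluated by trapezoid quadrature on a dense
grid (default step 0.5 s, configurable) that always contains the readout
times; against the closed-form solution for an exponential input the
default grid is accurate to well below $10^{-6}$ mM.

### Estimator

The Patlak transform plots $y = C_t(t)/C_p(t)$ against the normalized
exposure $x = \int_0^t C_p\,d\tau / C_p(t)$; an unweighted ordinary
least-squares line gives $K_i$ (slope) and $v_p$ (intercept). With two
points the line interpolates them. The precontrast point ($C_t = C_p = 0$,
an indeterminate 0/0 coordinate) is excluded. Negative concentrations
produced by noise are retained so the linear estimator stays unbiased.

### Signal-to-concentration

Concentration is linear in the relaxation-rate change,
$C = (1/T_{1,post} - 1/T_{1,pre})/r_1$ with $r_1 = 4.2\
\mathrm{mM^{-1}s^{-1}}$ at 7 T; vessel (whole-blood) values are converted
to plasma via $C_p = C_b/(1 - Hct)$ with $Hct = 0.45$. Both constants are
config-exposed. Time is measured in minutes from injection start
everywhere; internally $r_1$ is used consistently with T1 in seconds.

### The plasma input

The in-vivo-style plasma curve is piecewise: the measured dynamic-series
segment (90 volumes at 1.86 s), then a mono-exponential tail fitted
log-linearly through the last dynamic point and the T1-map-derived vessel
points. The exposure integral uses trapezoid over the measured segment and
the analytic tail integral. Log-linear least squares is used for the tail
because it is deterministic and closed-form — entirely adequate for a
three-point fit; the rate is clamped at zero (and flagged) if the points
suggest a growing tail.

For simulations, where no measured curve exists, a parametric input stands
in: zero until injection, a linear (optionally gamma-variate) rise to the
bolus peak at $t_{peak} = 0.93$ min (the 30th dynamic volume), then
mono-exponential washout. Defaults $a_{peak} = 1.5$ mM and
$m = 0.03\ \mathrm{min^{-1}}$ are plausible for a slow 0.3 mL/s infusion
of 3 mL gadobutrol measured in the superior sagittal sinus. All four
parameters are exposed because *absolute* precision values depend on them;
the two quantities the protocol conclusions rest on — SD ratios between
schemes and the bias — are provably invariant to the curve's amplitude
(asserted numerically in the test suite to $10^{-8}$), though not to its
shape. This matters for interpretation: see "Known limitations".

## Protocol simulations

`run_monte_carlo()` adds i.i.d. Gaussian noise (default SD
$2.0\times10^{-3}$ mM, the concentration-domain noise level of 7 T T1-map
data) to the tissue concentrations only — the plasma input is treated as
noiseless — and refits the Patlak line per run. Because the slope is a
fixed linear functional of the noisy $y$ values, the 250,000 default runs
reduce to one matrix product and finish in under a second; results are
bit-identical to sequential per-run simulation under the same seed, which
the suite verifies. Sweeps derive an independent sub-seed per table row so
any row is reproducible in isolation. A `fast` config flag caps runs at
25,000 for exploratory work (summary standard errors scale as
$1/\sqrt{N}$).

Two sweeps mirror the protocol-design questions:

* `sweep_num_maps()`: 2–7 maps spanning 4 min 20 s to 30 min ("0–5
  additional maps", 5 approximating continuous acquisition; actual scan
  durations are not modelled as occupancy constraints).
* `sweep_last_time()`: two-point schemes with the last map at 9–39 min in
  2-min steps.

Accuracy (percentage difference $(K_{i,calc}/K_{i,true} - 1)\times 100$)
is reported from the noiseless run, which equals the Monte-Carlo mean by
linearity but is deterministic.

With the default input curve the two-map scheme loses a factor of about
1.23 in precision relative to seven maps, accuracy differs by under 0.2
percentage points between the two, SD($K_i$) falls steeply as the last map
moves later, and the backflux-driven underestimation of $K_i$ grows with
the last-map time and with $K^{trans}$ — late sampling buys precision at
the cost of a small, predictable negative bias.

One structural subtlety the simulations expose: SD($K_i$) is *not* strictly
monotone in the number of maps. The Patlak $y$ noise is heteroscedastic
($\sigma/C_p(t_j)$ grows as the plasma curve decays), and unweighted OLS
is not minimum-variance under heteroscedasticity; adding a single mid-time
point to the two-map scheme shifts leverage toward the noisier late point
and *raises* the closed-form slope SD by about 3% before further points
bring it down again. The end-to-end two-versus-seven comparison is
unaffected.

## The digital phantom

`make_phantom()` forward-simulates the acquisition on a block-geometry
volume (default $32^3$ at 1.2 mm): WM and GM slabs, a small
superior-sagittal-sinus block carrying whole-blood concentration
$C_b = C_p(1 - Hct)$, and background. Postcontrast T1 volumes are obtained
by inverting the linear relaxation relation
$1/T_{1,post} = 1/T_{1,pre} + r_1 C$ — so conversion back to concentration
is the exact inverse, which the suite asserts to $10^{-10}$ — and the
dynamic series samples the blood curve at 1.86 s for 90 volumes with the
bolus peak at the 30th.

Choices a user should know about:

* **Baseline T1** (WM 1.2 s, GM 2.0 s, blood 2.4 s) are plausible 7 T
  values; only $\Delta R_1$ carries information, so they affect realism,
  not correctness.
* **Noise** is additive Gaussian on the postcontrast T1 maps (T1 domain)
  and on the dynamic series (concentration domain). The default map noise
  of 0.012 s makes the WM concentration noise
  $\sigma_{T1}/(r_1 T_1^2) \approx 2.0\times10^{-3}$ mM, matching the
  simulator's noise level; because the conversion Jacobian depends on
  $T_1$, the implied concentration noise is smaller in longer-$T_1$ GM.
  The precontrast map is noiseless by default so per-voxel errors are
  independent across time points, mirroring the simulator's noise model
  (shared precontrast noise would correlate them).
* **Geometry** is deliberately non-anatomical: the voxelwise math is
  geometry-independent, and slabs give $>10^4$ voxels per class for tight
  Monte-Carlo comparisons.

What phantom-based validation does show: the pipeline's conversions,
plasma-model fitting, exposure integrals and voxelwise estimator are
mutually consistent and recover the programmed kinetics (exactly at zero
noise; class means within a few percent at default noise). What it cannot
show: robustness to motion, partial-volume mixing at tissue interfaces,
$B_1$ inhomogeneity, registration error, Rician signal statistics, or
water-exchange effects on the linear $\Delta R_1$–concentration relation —
real-data effects that are out of scope here (the pipeline expects
co-registered, segmented inputs).

## Quantification pipeline details

* Tissue concentrations come only from the T1 maps; the dynamic series
  contributes the blood curve alone (its field of view covers just a
  midsagittal slab in the emulated protocol).
* Hematocrit correction is applied to every blood-derived concentration
  before any fitting.
* ROI statistics trim to the central 95% of the ROI's own voxel
  distribution (percentile trimming, bounds inclusive) before averaging —
  robust outlier rejection for heavy-tailed parameter maps. A literal 95%
  confidence interval of the mean would exclude nearly every voxel, so the
  central-fraction reading is used deliberately.
* The WM-vs-GM comparison is a paired two-sided Wilcoxon signed-rank test.
  The default uses the normal approximation without continuity correction;
  an exact mode enumerates the signed-rank distribution. At $n = 5$ with
  uniformly positive differences the asymptotic p is 0.043 while the exact
  two-sided minimum is $2/32 = 0.0625$ — with five subjects only the
  asymptotic mode can reach $p < 0.05$, which is why both are provided and
  tested against brute-force enumeration.
* Voxels with non-positive T1 (air, failed fits) become `NA` sentinels,
  excluded from counts, never silently converted.

## Numerical and reproducibility choices

* Convolution/quadrature step 0.5 s (config-exposed); readout times are
  grid points, so no interpolation error at samples.
* Patlak fits with exactly two points return RSS 0 by construction;
  all-equal $x$ raises a singular-fit error rather than returning `NaN`.
* Every randomized computation takes an explicit integer seed; sweep rows
  use derived substreams below $2^{31}$; phantom generation is fully
  seeded, so `truth.json` plus the seed reproduces the dataset bit for bit.
* Problem sizes used by the validation suite — 250,000 runs for headline
  precision ratios, $10^5$ for oracle comparisons, $32^3$ phantoms with
  $\ge 10^3$ voxels per class — keep Monte-Carlo standard errors an order
  of magnitude below the tolerances they are checked against.

## Known limitations

* The true venous input function of any given study is unknown to the
  simulator; defaults are plausible, and ratio/bias conclusions are
  amplitude-invariant, but *absolute* SD values and the exact bias
  magnitudes do depend on the washout shape. The package therefore treats
  absolute precision numbers as configuration-dependent outputs, not
  claims.
* Unweighted OLS is used in the Patlak fit by design (matching standard
  practice for this protocol); a variance-weighted fit would change the
  map-count precision profile discussed above.
* No two-compartment exchange or tissue-homogeneity models, no VIF
  dispersion/delay correction, no Rician noise mode, no image
  registration or segmentation — inputs must be co-registered and masked.
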