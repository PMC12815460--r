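---
title: "Methods: models, parameters and design choices in endoquant"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: models, parameters and design choices in endoquant}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(endoquant)
```

`endoquant` quantifies the chain of weak equilibria that link an activated
arrestin to the clathrin/AP2 endocytic machinery: binding-constant fitting
from NMR titrations, binding-site mapping from peak lists, complex
quantification from size-exclusion chromatography (SEC), limited-proteolysis
time courses, and two-channel colocalization imaging. This vignette explains
the underlying models, the tunable parameters, what the synthetic-data
generators do and do not emulate, and the numerical decisions made where
more than one defensible choice existed.

## 1. The ligand-depletion binding isotherm

All equilibrium arithmetic rests on the exact 1:1 mass-action solution at
*total* concentrations. With total protein $[P]$, total ligand $[L]$ and
dissociation constant $K_D$ (all in µM), the bound fraction of the protein
is

$$ f = \frac{[L]+[P]+K_D-\sqrt{([L]+[P]+K_D)^2-4[P][L]}}{2[P]}. $$

The free-ligand approximation $f = [L]/([L]+K_D)$ is *not* used anywhere:
for the interactions this package targets, the observed protein
concentration (tens of µM, set by NMR sensitivity) is comparable to $K_D$,
so ligand depletion is substantial. The discriminant satisfies
$([L]+[P]+K_D)^2-4[P][L] \ge ([P]-[L])^2 + K_D^2 > 0$, so the root is
always real; a `pmax(, 0)` guards the square root against rounding only.

`fraction_bound()` is verified in the test suite against an independent
numeric root-finder of the raw mass-action system
$([P]-c)([L]-c) = K_D\,c$ (no quadratic formula) to $|\Delta| < 10^{-9}$
over 1,000 random parameter triples in $[0.1, 1000]$ µM.

## 2. Fitting $K_D$ from titrations

A fast-exchange NMR titration reports
$\Delta\delta = \Delta\delta_{max} \cdot f([L])$. `fit_kd()` minimizes the
unweighted residual sum of squares by Levenberg–Marquardt
(`minpack.lm::nlsLM`). Numerical choices:

* **Log-scale $K_D$.** The optimizer works on $\log K_D$. A hard positivity
  bound on the natural scale can trap Levenberg–Marquardt at the boundary,
  where the isotherm is flat in $K_D$ (stoichiometric limit) and the
  gradient matrix is singular; the log parameterization makes positivity
  structural and leaves the problem smooth. The reported standard error is
  mapped back by the delta method,
  $\mathrm{se}(K_D) = K_D \cdot \mathrm{se}(\log K_D)$.
* **Initialization.** $K_{D,0}$ = median ligand concentration (scale-aware:
  a sensible titration brackets its $K_D$) and
  $\Delta\delta_{max,0} = 1.2\times$ the largest observed response.
* **Weighting.** Unweighted, as no per-point error model is available for
  shift measurements; $\Delta\delta_{max}$ is unbounded in sign.
* **Responses** are absolute shift differences from the zero-ligand
  reference, avoiding direction ambiguity across residues.
* **Degenerate input** (all responses equal) raises an error rather than
  returning an unidentifiable fit; non-convergence is flagged in the
  result, never silently replaced.

On noiseless generator output the fit recovers the planted
$(K_D, \Delta\delta_{max})$ to $10^{-6}$ relative error; with Gaussian
response noise of 5% of $\Delta\delta_{max}$ on 8 points, the median of 100
fits is within 15% of truth and ±2 se covers the truth in ≈90% of runs.
A single 8-point titration at 2% response noise determines a ~100 µM
constant to roughly ±10 µM (1 se) — which is why single-fit checks in the
suite are judged against the fit's own reported uncertainty, and central
tendency across seeds against the planted value.

## 3. Binding-site mapping and significance rules

Two per-residue observables compare a complexed sample against the apo
reference, matched on the key (residue number, atom group):

* **Intensity attenuation** $I/I_0$: interface resonances broaden and lose
  intensity. Significant when the ratio is more than one standard deviation
  *below* the mean of all usable ratios.
* **Combined shift perturbation**
  $\Delta\delta_{comb} = \sqrt{\Delta\delta_H^2 + (\Delta\delta_X/w)^2}$
  with $w = 3.6$, the conventional weighting that equalizes the typical
  dispersions of the ¹H and heteronuclear dimensions ($w$ is exposed as
  `x_weight`). Significant when more than one standard deviation *above*
  the mean.

Choices within those rules:

* **Sample SD** ($n-1$) rather than population SD — the conservative
  small-sample default.
* **Strict inequalities** at the thresholds, so a zero-variance profile
  (e.g. identical lists) flags nothing.
* **Statistics over the intersection** of the two lists only; keys present
  in one list, with zero apo intensity, or with missing shifts are excluded
  from mean/SD and reported in the profile's `excluded` field — an
  exclusion warns but never fails the whole profile.
* Residue numbering is 1-based construct numbering throughout; no
  renumbering or assignment transfer is attempted, and peak integration is
  upstream of this package (intensities are consumed as given).

`segment_regions()` collapses the significant set into maximal runs; a
`max_gap` parameter (default 0) can bridge isolated missing assignments.

## 4. SEC complex quantification

`integrate_window()` is the trapezoidal integral with linear interpolation
at the window edges — exact for the piecewise-linear traces a chromatography
system exports, additive over adjacent windows, and invariant under
resampling. The complex concentration in the injected sample is

$$ c = \frac{I_{mix} - I_{apo}}{\varepsilon \cdot l \cdot V_{inj}} $$

with defaults $l = 1$ cm and $V_{inj} = 0.25$ ml (a 250 µl loop), a
default complex window of 2.4–2.8 ml around a 2.6 ml complex peak, and
$\varepsilon$ chosen as the extinction coefficient of the partner whose
co-elution creates the absorbance excess. The logic of the apo-profile
subtraction is that the other partner elutes in the window whether free or
complexed, so its absorbance cancels between mixture and apo reference and
the excess is attributable to the arriving partner alone. Phosphopeptides
without tryptophan contribute negligible A280 and are ignored. Further
choices: no baseline correction by default (an optional linear baseline is
off unless configured); a negative integral difference clamps to zero with
a warning (no complex, not an error); equilibrium is treated as frozen
during elution — no on-column dissociation correction; and all
concentrations refer to the injected sample, not to on-column dilution.
Apparent affinity then follows from the 1:1 mass balance,
$K_D = (A_0-c)(B_0-c)/c$, which the tests verify as the exact inverse of
the forward solver `complex_from_kd()`.

**Coupled activation model.** `apparent_adaptor_kd()` encodes the
assumption that only peptide-activated protein binds the adaptor, with no
further coupling: $K_{D,app} = K_{D,intr}/f_{act}$, where $f_{act}$ is the
ligand-depletion bound fraction of the activation equilibrium. This is a
deliberate minimal model: it reproduces the saturation limit
($K_{D,app} \to K_{D,intr}$) and the divergence at vanishing peptide, but
it ignores avidity, conformational selection and peptide rebinding, and
measured apparent affinities for weakly activating peptides can deviate
from its prediction by factors of ~2. It is exposed as a modelling tool,
not asserted as quantitative for partially activating peptides.

## 5. Proteolysis time courses

Relative abundance is the two-band normalization
$100\,F/(F+C)$ — invariant to loading and staining scale. The digestion
midpoint is the first 50% crossing, linearly interpolated between the
bracketing sampling times; the bracket itself is reported alongside the
interpolated value, because on coarse sampling grids the bracket is the
honest resolution of the experiment. Linear (not log-time) interpolation
was chosen to match that bracket-style reporting; on first-order decays
sampled on the conventional 0/5/10/20/30/60/90 min grid it recovers the
analytic half-life $\ln 2/k$ within 5%. A course that starts at or below
50% returns 0 with a "pre-digested" warning; one that never reaches 50% is
right-censored at the last time, and any protection factor built on it is
flagged as a lower bound.

## 6. Colocalization imaging

All pixel coordinates are 0-based row/col; physical units enter only
through the pixel size. Thresholded Mander's coefficients follow

$$ M_1 = \frac{\sum_{A > t_A} R_i}{\sum_{R > t_R} R_i}, \qquad
   M_2 = \frac{\sum_{R > t_R} A_i}{\sum_{A > t_A} A_i}, $$

i.e. the numerator conditions only on the *other* channel's mask. The
ratio is clamped at 1 for the rare case where off-mask background pushes it
marginally above; the exact identities $M = 1$ (identical channels) and
$M = 0$ (disjoint channels) hold by construction. Undefined coefficients
(no above-threshold signal in a channel) raise an error instead of
returning 0.

Puncta detection automates what is often done manually, with every
parameter explicit: a threshold (Otsu by default; mean + k·SD as the
background-statistics alternative), 8-connectivity (diagonal contact joins
a component — the labelling seeds come from `EBImage::bwlabel`, which is
4-connected, followed by a union-find merge of diagonally adjacent
labels), and a minimum physical area (default 0.05 µm² in the CLI) to
reject single-pixel noise. A receptor punctum is double-positive when at
least `overlap_fraction` (default 0.3) of its pixels exceed the arrestin
threshold; the partial-overlap tolerance absorbs PSF blur and slight
channel misregistration, and counts always partition the punctum set.
Densities are centroid counts scaled to the conventional 100 µm² reporting
unit. Line profiles are bilinear.

## 7. What the generators emulate — and what they do not

Every generator is a pure function of its arguments including the seed
(`withr::with_seed`; the global RNG stream is untouched), and returns
machine-readable ground truth so each stage can be scored without
re-deriving it.

* `gen_titration()`: responses exactly on the isotherm plus additive
  Gaussian noise. Defaults in examples use a 50 µM protein, 8 ligand points
  to 600 µM and a planted $K_D$ of ~100 µM — the regime of a weak
  clathrin-domain interaction.
* `gen_peaklist_pair()`: a two-level attenuation/CSP profile over a planted
  contiguous site (default depth 0.8, CSP 0.05 ppm). `noise_sd` is the SD
  of Gaussian noise on the intensity *ratio*; shift noise is scaled as
  `noise_sd * csp_peak` so the noiseless case is exact for both profiles
  and the significance thresholds have closed forms. Not emulated:
  exchange-regime line shapes, peak overlap, or assignment gaps.
* `gen_chromatogram_set()`: Gaussian peaks whose integrals obey
  Beer–Lambert, with species concentrations from the coupled activation
  equilibrium. By default the free-partner-A peak sits *inside* the complex
  window (2.65 ml) so the apo subtraction cancels it exactly as the
  quantification assumes, and the free-B peak sits outside (3.1 ml);
  configurations that push B into the window are flagged in the truth
  metadata. Not emulated: peak tailing, baseline drift, on-column
  dissociation, oligomers.
* `gen_proteolysis()`: first-order full-length decay with complementary
  cleaved band and multiplicative band noise, on the conventional
  0–90 min grid.
* `gen_coloc_images()`: Gaussian spots (amplitude 100 AU, PSF σ 0.2 µm,
  pixel 0.1 µm) with rejection-sampled non-overlapping placement, a planted
  colocalized subset, independent extra arrestin spots kept away from
  receptor spots, and background noise set by SNR. Not emulated: cell
  morphology, uneven illumination, out-of-focus light, 3-D stacks.

Because the generators idealize in these ways, green tests demonstrate the
*analysis* is correct and well-calibrated under its stated noise models —
not that real spectra, gels or micrographs meet those models. On real data
the exclusion paths (overlapped/missing peaks, baseline issues, censored
time courses) matter more than they do here.

## 8. Problem sizes and determinism in the test suite

The suite runs the oracle comparison on 1,000 random triples, estimator
consistency on 100 seeded titrations, site recovery on 100 seeded
peak-list pairs (requiring the planted interval within ±1 residue per
boundary in ≥95 of them), SEC round trips across two peak geometries, and
colocalization recovery at fractions {0, 0.5, 0.7, 1} over 50 seeds each
with 20 puncta per 128² image at SNR 10 — sizes chosen so the whole suite
completes in well under a minute per file while keeping Monte-Carlo
standard errors far below the asserted tolerances. All stochastic tests fix
their seeds; reruns are exactly reproducible.

## 9. Known limitations

* Single-site 1:1 binding only: no cooperative, multi-site or global
  (multi-residue) fitting, and no Bayesian uncertainty.
* SEC quantification assumes the apo reference profile of the co-eluting
  partner is unchanged by complex formation within the window; strongly
  shifted free-protein peaks would bias the subtraction.
* The proteolysis midpoint is a summary statistic, not a kinetic fit; no
  mechanism beyond first-order synthetic generation is modelled.
* Imaging works on single 2-D planes; no deconvolution, segmentation of
  cells, or spot sub-pixel localization.
* The TIFF container stores normalized 32-bit floats; intensity scale and
  pixel size travel out of band (function arguments or the sidecar JSON
  written by the simulators).
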