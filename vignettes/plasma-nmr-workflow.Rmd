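---
title: "Quantitative CPMG plasma NMR with a binding competitor: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantitative CPMG plasma NMR with a binding competitor}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

This vignette documents the models behind `plasmaNMR`, the parameters a
user may want to change, and the design decisions that were genuinely
open — in the spirit of a methods section, so that what the tests prove
(and do not prove) is explicit.

## 1. The physical model

### Competitive albumin binding

A single class of HSA sites at concentration $P_t$ (default 600 µM, the
order of plasma albumin) is shared by TSP, maleic acid (MA) and the
binder metabolites.  Each ligand $i$ at total concentration $L_i$ obeys
$\mathrm{bound}_i = L_i P_f/(K_{d,i}+P_f)$, and the free-site balance

$$P_f + \sum_i \frac{L_i P_f}{K_{d,i}+P_f} = P_t$$

is solved for $P_f$ with `uniroot` (monotone left side, bracketed on
$[0, P_t]$, relative tolerance $10^{-12}$).  Affinities are only known
ordinally — TSP binds far more strongly than the metabolites, MA far
more weakly — so representative dissociation constants were fixed once:
$K_d(\mathrm{TSP}) = 5$ µM, metabolite $K_d$ 700–1500 µM,
$K_d(\mathrm{MA}) = 2000$ µM.  Two constraints pinned these numbers:
with 4 mM TSP the residual bound fractions must be small enough that
(i) quantification of every binder is accurate to better than 2 % and
(ii) raising TSP from 4 to 8 mM changes no metabolite integral by more
than 0.5 % (the "saturating competitor" regime); and with 0 mM TSP the
binder $K_d$ must lie *below* MA's so that MA-normalized binder values
are biased low while non-binders are biased high — the qualitative
signature of an uncompeted plasma sample.

### Fast exchange and CPMG attenuation

All binding is assumed fast on the NMR timescale: each species shows one
line at the population-averaged shift
$\delta = \delta_\mathrm{free} + f\,\Delta\delta_\mathrm{bound}$
relaxing at the population-averaged rate
$1/T_2 = (1-f)/T_{2,\mathrm{free}} + f/T_{2,\mathrm{bound}}$
($T_{2,\mathrm{free}} = 2000$ ms, $T_{2,\mathrm{bound}} = 10$ ms).  The
CPMG echo train (64 ms total echo time: 160 loops of 0.4 ms) attenuates
each line by $\exp(-\mathrm{TE}/T_2)$.  A fully bound species is
therefore invisible ($e^{-6.4}$), a free one loses only 3 %.  The
fast-exchange picture is consistent with single averaged peaks that move
and grow upon TSP addition; slow- or intermediate-exchange lineshapes
are not modelled.

### Spectrum synthesis

Each proton group of the 62-metabolite spin library contributes its
first-order stick pattern (grammar: `d` consumes one J, `t` one J applied
twice, `q` three times, `p` four; composite codes like `dd`, `ddt` are
convolutions).  Sticks decay as Lorentzians of 1.0 Hz natural width;
unresolved multiplets (`m`) are modelled as a single envelope of 12 Hz.
Glucose and mannose carry both anomers at aqueous equilibrium fractions
(α:β = 36:64 and 67:33).  The FID further contains: the TSP singlet at
0.00 ppm, the MA singlet at 6.01 ppm (the text source says only "around
6 ppm"), a presaturation-suppressed residual water hump at 4.79 ppm
(20 Hz wide), broad lipid resonances (methyl/methylene/headgroup/
olefinic, $T_2$ 60–120 ms, so they partially survive the CPMG filter),
a heavily attenuated macromolecule background ($T_2 \approx 8$ ms),
optional hemolysis humps, polynomial baseline drift, and seeded complex
Gaussian noise.  The default time-domain noise standard deviation
(0.004) was calibrated once so that replicate MA-window integrals show a
relative standard deviation near 2 %, the robustness level a careful
instrument gives on pooled plasma.

## 2. Processing chain

The order is fixed and logged in each object's provenance: exponential
apodization (0.8 Hz) → zero filling (×4, 16k → 64k points) → FFT with
the half-first-point convention → phasing → baseline correction →
chemical-shift calibration.

* **Phasing.** Simulated FIDs are absorptive by construction, so the
  pipeline default applies no rotation; the automatic surrogate for
  interactive phasing (coarse grid over zero/first order, Nelder–Mead
  polish of the squared negative intensity) recovers injected phase
  errors to ~1°/5° and is exercised in the tests.
* **Baseline.** A peak-masked Whittaker smoother with a
  *fourth*-difference penalty on a 16-fold decimated grid.  The penalty
  nullspace contains all cubic polynomials, so global drift is followed
  essentially exactly, while the gain rolls off with the eighth power of
  frequency below the half-gain wavelength (default 2 ppm): metabolite
  lines and their Lorentzian pedestals are untouched.  Sharp features
  are excluded iteratively by masking points that protrude more than
  five robust standard deviations above the running median of the
  residual.  A classic asymmetric-least-squares smoother was tried
  first and rejected: its asymmetric weights multiply the effective
  stiffness by $1/p$, so it either flattens genuine drift or, made soft
  enough to follow it, eats several percent of the peak tails.
* **Calibration.** Local maxima above 5× the noise level (estimated
  from the signal-free 9.5–10.5 ppm stretch) are paired when separated
  by 7.2 ± 1.5 Hz; ties are broken by the largest summed height; the
  upfield line of the winning pair, refined by parabolic interpolation,
  is translated rigidly to 1.4938 ppm.  Absent a qualifying doublet the
  step fails loudly rather than guessing.

## 3. Regions, quantification and quality control

The literal ppm boundaries of the 237 regions are not recoverable from
the available source, so they are reconstructed from the spiking
library: every proton group claims its multiplet envelope
(centre ± half the expanded splitting, + 0.005 ppm padding), split
evenly when the group is assigned to several regions; line positions of
single-region groups are *protected* and overlap is resolved by
trimming padding at midpoints, never across a protected line; region
ids never referenced become filler windows (lipid / unidentified
territory) tiling the gaps; nothing intersects the water window
(4.7–4.9 ppm).  Where the printed assignments interleave irreducibly in
crowded segments, coverage is guaranteed against the span of a group's
assigned regions rather than per region.  The MA integration window
(5.98–6.04 ppm) is deliberately *outside* the 237 regions, matching the
normalization bookkeeping in which the standard is not itself a model
variable.

Quantification uses the internal-standard relation
$c = v \cdot c_\mathrm{MA} \cdot 2 / n_H$ on MA-normalized integrals.
Fixed windows clip Lorentzian tails, so closed-loop concentration
recovery additionally corrects both integrals by the closed-form
capture fraction of the known line set
(`lorentzian_capture()`); with that correction the simulator's spiked
concentrations are recovered to ≲1 % at 4 mM TSP.

Quality control removes variables with replicate (intrasample)
%RSD > 10 and variables with per-group (intersample) %RSD > 30 *in both
groups* — computed on MA-normalized values (whether the original
workflow normalized before or after this filter is not stated; the
normalized convention is adopted).  The packaged exclusion lists
(regions 1, 9, 21, 22, 24, 27, 29–31 replicate-unstable; 80, 209,
215–218, 237 cohort-unstable) reproduce the published 237 → 221 flow
exactly in `mode = "packaged"`.

One bookkeeping inconsistency in the source protocol is recorded rather
than resolved: 6.25 mg MA per 100 mL (62.50 µg/mL at molar mass
116.07 g/mol) is ≈ 538.5 µM, five times the stated 107.70 µM buffer
concentration.  The simulator uses the stated molar values (53.85 µM in
the final sample).

## 4. Chemometrics

`opls_da()` implements the Trygg–Wold scheme: weights from
$X^\top y$, orthogonalized candidate loadings split into a predictive
and a y-orthogonal part, orthogonal components deflated one at a time,
then a single predictive PLS component on the filtered matrix.  With
`n_ortho = 0` the model is numerically identical to one-component
NIPALS PLS1 (tested to $10^{-8}$ against an independent oracle).
Design choices the source leaves open:

* **Component count** — default one orthogonal component (binary
  response); `n_ortho = "auto"` adds components while seven-fold
  cross-validated Q² improves by > 0.01, emulating a Q²-guarded
  stopping rule.
* **Class coding** — control = 0, cancer = 1, decision threshold 0.5.
* **Cross-validation** — stratified seven-fold from an explicit seed;
  scaling is refit inside each training fold, so no information leaks
  from held-out samples (a dedicated test guards this).
* **Jack-knife selection** — per-fold predictive loadings are
  sign-aligned, a Tukey delete-d jack-knife standard error is computed
  over folds, and a variable is kept when its loading exceeds the
  two-sided Student-t 95 % interval half-width ($t_{0.975,\,6}\cdot$SE).
  A bare 1·SE rule was rejected because a zero-mean noise loading
  exceeds its own standard error about a third of the time, which would
  make the selection step useless as a noise filter.
* **VIP** — computed on the predictive component only (orthogonal
  variation is noise by construction), threshold 0.80; the S-plot
  reports covariance and correlation of each variable with the
  predictive score, and calls direction by the covariance sign.
* **Permutation testing** — labels shuffled, model and Q² refit; 200
  permutations by default.

## 5. What the synthetic study shows — and what it cannot

The generator plants the reported disease signature: glucose,
isoleucine, leucine, glycerol and isopropanol elevated (×1.3 by
default) and the lipid profile reduced (×0.75) in the cancer group,
with log-normal between-subject variation (CV 0.10 for metabolites,
0.25 for lipids), cohort sizes 80 + 80 (training) and 34 + 38
(validation), and 12 pool replicates for the robustness protocol.
Passing tests therefore demonstrate that the pipeline *recovers planted
effects of realistic size through the full physics* — binding,
T₂ editing, processing, integration, normalization, scaling,
selection — and that its negative controls (permutations, null labels)
behave.  They cannot demonstrate clinical performance: real plasma has
correlated metabolite physiology, lipoprotein fine structure,
instrument drifts and cohort confounders that the generator does not
emulate, which is why the near-perfect synthetic AUCs exceed published
cohort values, and why the headline cohort metrics are treated as
schema anchors, not reproduction targets.

Problem sizes used by the test-suite were chosen to keep the full run
in the order of a minute: statistically heavy properties (jack-knife
operating characteristics, 100 seeded runs; S-plot direction recovery,
five cohorts of 80 + 80) run on the analytic region-integral path of the
generator, which shares the binding and CPMG model with the spectral
path but skips lineshape synthesis; spectral end-to-end checks
(quantification recovery for all eight binders, calibration, doublet
measurements) use the full 16k-point acquisition at the protocol's
parameters.

## 6. Known limitations

* First-order multiplets only: no strong-coupling (second-order)
  patterns, no lipoprotein subclass modelling, no field-strength
  extrapolation.
* One HSA site class and fast exchange everywhere; real plasma shows
  site heterogeneity and intermediate-exchange broadening for some
  ligands.
* Region boundaries are a reconstruction; shared regions keep their
  multi-metabolite annotation, and a handful of crowded segments cannot
  reproduce the exact printed assignment interleaving.
* The hemolysis model is a minimal additive background used to exercise
  the exclusion filter, not a spectroscopic model of hemoglobin.
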