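---
title: "Quantifying condensate aging: models, estimators and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying condensate aging: models, estimators and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(condensage)
```

Biomolecular condensates formed by liquid-liquid phase separation are not at
equilibrium: over hours they *age*, hardening from viscous liquids into
Maxwell fluids and finally elastic, aggregate-laden solids. This vignette
explains the models behind each analysis stage in `condensage`, the
parameters that matter, what the synthetic-data generators do and do not
emulate, and the numerical choices we made where the underlying methods
literature leaves the design open.

## Passive particle-tracking microrheology

A probe bead of radius $a$ embedded in a condensate performs thermal motion
whose ensemble mean-squared displacement (MSD) encodes the local mechanics:

$$\langle \Delta r^2(\tau) \rangle = 4 D_{app} \tau^{\alpha(\tau)},
\qquad
\alpha(\tau) = \frac{d \ln \langle \Delta r^2(\tau) \rangle}{d \ln \tau}.$$

In a Newtonian fluid $\alpha = 1$ (Fickian diffusion); in a viscoelastic
medium probes are subdiffusive, $0 < \alpha < 1$; as a network arrests the
probes, $\alpha \to 0$.

`compute_msd()` uses the time-averaged, all-overlapping-pairs estimator per
trajectory, ensemble-averaged with pair-count weights. It is exactly the
brute-force all-pairs average (the test suite asserts equality), and lags
are retained only up to a fraction of the track length
(`max_lag_fraction`, default 0.25) because time averages at long lags rest
on very few displacement pairs.

`fit_powerlaw()` estimates $\alpha$ twice:

* a **local** exponent per lag, the derivative of a quadratic fitted to
  $\ln \langle \Delta r^2 \rangle$ versus $\ln \tau$ over a 7-point sliding
  window. This is the smoothed logarithmic derivative the GSER stage needs;
  the window width trades bias (wide) against noise amplification (narrow),
  and 7 points over a 50-lag curve is a conservative middle ground.
* a **long-time** exponent from a single linear log-log fit over a stated
  window (default: the first decade of lags, where every lag still has many
  pairs). $D_{app}$ is `exp(intercept)/4`.

### From MSD to moduli

The generalized Stokes-Einstein relation (GSER) converts the MSD into the
complex shear modulus, evaluated at $\omega = 1/\tau$:

$$|G^*(\omega)| = \frac{2 k_B T}
{C\, a\, \langle \Delta r^2(1/\omega) \rangle\, \Gamma[1 + \alpha(\omega)]},
\qquad
G' = |G^*| \cos\frac{\pi \alpha}{2}, \quad
G'' = |G^*| \sin\frac{\pi \alpha}{2}.$$

The prefactor $C$ deserves a note. With a **two-dimensional** MSD
($\langle \Delta r^2 \rangle = 4 D \tau$ for a Newtonian fluid) and
$D = k_B T / 6 \pi \eta a$, the formula with $C = 1$ returns
$G'' = 3\pi\,\eta\,\omega$ — three-pi times the true loss modulus of the
fluid. `condensage` therefore defaults to $C = 3\pi$
(`prefactor_mode = "stokes_einstein_consistent"`), which recovers
Stokes-Einstein exactly; the test suite verifies $\eta$ within 5% across
$\eta \in \{0.1, 1, 10\}$ Pa·s on simulated Newtonian fluids. The
`"literal"` mode keeps $C = 1$ for side-by-side comparison with analyses
that use the unmodified discrete GSER formula; the two differ by exactly
$3\pi$ at every frequency. Local $\alpha$ is clamped to $[0, 1]$ before the
phase is evaluated (the physically meaningful subdiffusive range; estimator
noise can otherwise push $\alpha$ slightly negative on plateaued MSDs, and
$\alpha > 1$ would produce negative storage moduli). Every clamp emits a
warning.

### Material-state classification

`find_crossover()` inspects the sign of $\log G' - \log G''$ after 3-point
median smoothing (which removes single-frequency sign flips from noise):

* negative everywhere → **viscous** (loss-dominated at all probed
  frequencies);
* positive everywhere → **elastic**;
* a single sign change, loss-dominated at low frequency → **Maxwell
  fluid**, with the critical frequency $\omega_c$ (where $G' = G''$)
  located by linear interpolation in log-log coordinates and the relaxation
  time $\tau_c = 1/\omega_c$.

Multiple crossings after smoothing are reported as Maxwell using the
lowest-frequency crossing, with a warning — a deliberate bias toward the
physically expected single-relaxation-time picture. The classification is
only meaningful over the probed frequency window
($\omega \in [1/\tau_{max}, 1/\tau_{min}]$); `classify_timecourse()` then
checks an age-ordered sequence of states against the monotone
viscous → Maxwell → elastic aging path.

## Synthetic probe trajectories

The generator supports three motion models, chosen to produce the three
material states:

* **newtonian** — independent Gaussian increments of variance $2 D \Delta t$
  per axis.
* **subdiffusive** — fractional Brownian motion with Hurst index
  $H = \alpha/2$ per axis, so the 2D MSD is $4 K \tau^{\alpha}$. We sample
  *exactly* from the fractional-Gaussian-noise covariance by Cholesky
  factorization of the $199 \times 199$ increment covariance (one
  factorization per ensemble, reused across particles). fBm is the minimal
  stationary-increment Gaussian process with a power-law MSD, which makes it
  the natural null model when nothing more is known about the medium.
* **jeffreys** — the sum of free diffusion and a confined component:
  $\langle \Delta r^2 \rangle = 4 D_{free} \tau +
  P\,(1 - e^{-\tau/\tau_{relax}})$. We realise it as Brownian motion plus a
  stationary Ornstein-Uhlenbeck process (exact discretization, per-axis
  stationary variance $P/4$), so the empirical MSD matches the formula
  pointwise, not just asymptotically. Over lag windows longer than
  $\tau_{relax}$ this produces a plateau-then-linear MSD — elastic at high
  frequency, viscous at low frequency — and hence exactly one modulus
  crossover, the Maxwell phenotype.

Localization error is additive Gaussian noise on positions (the standard
tracking-error model); it inflates the MSD by a constant $4\sigma^2$, which
`msd_theoretical()` exposes so tests can subtract it. Acquisition defaults
(50 frames/s, 200 frames, 100 nm bead radius, 298.15 K) are typical
spinning-disk microrheology settings for condensate work.

What the generator does **not** emulate: camera-specific noise (EMCCD
gain), anisotropic or 3D motion, probe-size polydispersity, static/dynamic
heterogeneity within a condensate, and drift. A pipeline that passes these
tests is validated as an estimator chain, not as a claim that real
condensate data are this clean.

## Spot detection and linking

Detection is Crocker-Grier style: a difference-of-Gaussians band-pass
(σ and 3σ), local maxima above `mean + threshold_sd * sd` of the filtered
frame, then intensity-weighted centroid refinement in a
$(2\lceil 3\sigma\rceil + 1)^2$ window with two re-centering iterations.
Spots whose window leaves the frame are discarded rather than truncated
(truncation biases the centroid toward the image interior). On noiseless
synthetic spots the localization error is below 0.01 px; at SNR 10 the RMSE
is ≈ 0.16 px.

Linking minimizes total squared displacement between consecutive frames
among candidate pairs within `max_displacement`. Conflicts are resolved
exactly: the bipartite candidate graph is split into connected components
and each component is matched by exhaustive enumeration (maximizing link
count first, then minimizing cost), with a greedy fallback only for
components larger than 64 track-detection pairs — far beyond anything a
well-chosen `max_displacement` produces. Gaps up to `memory` frames are
bridged and filled by linear interpolation so downstream MSD code sees
uniformly sampled tracks; interpolation slightly smooths displacements at
the gap, which is why the defaults keep `memory` at 0 or 1.

## FRAP

The analysis follows the standard reference-corrected normalization chain:
$C_f(t) = R_i / R(t)$, $I_{cor}(t) = C_f(t)\, I(t)$,
$I_n(t) = (I_{cor} - I_{min}) / (I_i - I_{min})$, then

$$I_n(t) = F_m \left(1 - e^{-\ln 2\, t / \tau_{1/2}}\right),
\qquad F_{im} = \frac{I_i - I_\infty}{I_i - I_{min}} = 1 - F_m,
\qquad D_{app} = \frac{0.22\, r^2}{\tau_{1/2}}.$$

Design choices where the convention is genuinely open:

* $I_i$ is the **mean of all pre-bleach corrected frames** (averaging
  reduces its noise, and nothing downstream depends on which pre-bleach
  frame is "the" initial one); $I_{min}$ is the first post-bleach frame.
* $I_\infty$ defaults to the **fitted asymptote**
  $I_{min} + F_m (I_i - I_{min})$ rather than the last noisy sample; the
  last-frame convention is available via `frap_analyze(..., i_inf =
  "last")`. The fitted value is unbiased under the model, the last frame is
  not.
* The recovery fit re-zeroes time at the bleach frame, uses uniform
  weights, and bounds $F_m \in [0, 1.2]$ (headroom for noise above full
  recovery). Flat traces (no detectable recovery) return $F_m \approx 0$
  with the half-time flagged unidentifiable instead of a meaningless fit.
* $I_\infty$ may exceed $I_i$ by up to 2% (noise headroom) before the
  record is rejected; within the band it is clipped to $I_i$ with a
  warning.

The synthetic generator applies a single-exponential acquisition bleach to
*both* ROI and reference. For that model the reference-based correction is
exact, so the correction stage's correctness is provable (residuals are
noise only) — a deliberately idealised choice. One caveat surfaced while
anchoring the module: published $D_{app}$ values are often not recoverable
from published $\tau_{1/2}$ and the nominal ROI radius via the $0.22 r^2$
formula, because the *effective* bleach radius (post-diffusion-during-bleach)
is rarely reported. `apparent_diffusion()` therefore takes the radius
explicitly and we treat literature $D_{app}$ values as order-of-magnitude
anchors only.

## Enzyme and aggregation kinetics

Initial rates are OLS slopes over the early window of a progress curve
(default: first 20% of points, minimum 3 — progress curves here are
synthetic and linear, but the windowed default keeps the estimator honest on
real, curving data). Michaelis-Menten fitting uses `minpack.lm::nlsLM` with
analytic starting values ($V_{max}$ = max rate, $K_M$ = substrate at
half-max) and positivity bounds; $k_{cat} = V_{max}/E_0$. A fitted $K_M$
more than 100× outside the substrate range is flagged unidentifiable rather
than reported as a number. The ThT stage fits
$I(t) = I_0 + (I_{max} - I_0) / (1 + e^{-k (t - t_{1/2})})$ the same way and
reports $R^2$; both fits are exact (residual < $10^{-6}$) on noiseless model
data. The generator's blank/standard-curve step mirrors plate-reader
practice: absorbance is `blank + slope * conc`, and `absorbance_to_conc()`
inverts it, flooring negative concentrations at zero with a warning.

## Condensate image metrics

The image generator places non-overlapping disks with interior/exterior
intensity ratio set per channel, which makes the expected enrichment index
equal to the generating ratio. Segmentation is Otsu thresholding of the
scaffold channel plus 8-connectivity component labelling, dropping
components under `min_area_px` (default 9 px — a 3×3 speck — to suppress
shot noise). The enrichment index divides the mean cargo intensity over
condensate pixels by the background mean, after excluding a 2-px dilated
halo around every condensate: edge pixels are blurred mixtures of inside
and outside and would bias the background upward. Because field-level
aggregation conventions differ, both the pooled-pixel index (default) and
the mean of per-condensate indices (`per_condensate = TRUE`) are available;
they coincide on uniform-ratio synthetic disks and differ on real images
with heterogeneous condensates. Line profiles are bilinear samples averaged
across `width_px` parallel lines, min-max normalized per channel, with the
Pearson correlation between channels as a colocalization summary; a
constant channel cannot be normalized and is returned as an all-zero
profile with a `degenerate` flag instead of NaNs.

## The pipeline and reproducibility

`run_pipeline()` executes generate → rheology ∥ FRAP ∥ kinetics ∥ imaging →
report for each age point of a validated configuration (unknown keys are
rejected before any stage runs). One root seed yields deterministic child
seeds per age point and stage, so a rerun with the same configuration is
bit-identical; the report carries the configuration hash and seed for
provenance, and an unchanged configuration re-uses the cached report unless
forced. `aging_timecourse_config()` parameterizes three age points as
viscous / Maxwell / elastic and is the package's end-to-end demonstration
that the full chain recovers a monotone aging path.

## Problem sizes and statistical expectations

The validation suite uses ensembles from 100 particles (enough for the
Fickian-exponent check, s.e. of $\hat\alpha \approx 0.02$) up to $10^4$
particles (generator-level MSD checks at the 2–5% level), 500-track fBm
ensembles for exponent recovery within ±0.05, and 9-cell FRAP parameter
grids at 1% noise with a 5% median-error budget. These sizes were chosen so
that each tolerance sits at ≥ 3 standard errors of the corresponding
estimator under the stated noise; larger ensembles would tighten the checks
without changing their meaning.

## Known limitations

* One-point microrheology assumes a continuum medium around the probe;
  near-probe-sized heterogeneity (aggregates) violates it, which is exactly
  the regime late-aging condensates enter. The estimators remain
  well-defined; their interpretation as bulk moduli weakens.
* The GSER power-law approximation is least accurate where $\alpha(\omega)$
  changes rapidly — i.e., near the Maxwell crossover it is used to locate.
  The 2% crossover tolerance on analytic moduli does not transfer to noisy
  experimental MSDs.
* The single-exponential FRAP model has no diffusion geometry; $D_{app}$ is
  an apparent, model-dependent quantity.
* Frequencies outside $[1/\tau_{max}, 1/\tau_{min}]$ are never
  extrapolated, and no drift correction is applied to trajectories.
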