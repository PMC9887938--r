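---
title: "Measuring effective membrane tension and cell contractility: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring effective membrane tension and cell contractility: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(memtension)
```

`memtension` implements the two measurement chains used to characterise how
cells regulate their mechanics on substrates of different stiffness: optical
tweezers (OT) membrane tether pulling, which probes effective membrane
tension, and traction force microscopy (TFM), which probes actomyosin
contractility. Both chains are exercised end to end on synthetic data with
known ground truth, so that every estimator in the package is tested against
the quantity it is supposed to recover. This vignette describes the models,
the tunable parameters, the numerical choices, and the limits of what the
synthetic tests demonstrate.

## Units and constants

OT quantities are carried in pN, nm and s; TFM quantities in Pa and µm.
`KB_PN_NM` pins the Boltzmann constant at 1.380649e-23 J/K (exact) in pN nm/K;
`stokes_drag_pN_s_nm()`, `pa_um2_to_nN()` (1 Pa µm² = 10⁻¹² N = 10⁻³ nN) and
`pa_um3_to_fJ()` are the only unit conversions, each unit-tested against its
defining identity. Defaults: temperature 298.15 K, water viscosity
1.0e-3 Pa s, bead diameter 2.16 µm. (Sources describing this bead type quote
both "2 µm" nominal and 2.16 µm measured; we default to 2.16 µm and expose
the radius as a parameter everywhere.)

## Trapped-bead simulation

A bead in an optical trap is an overdamped Hookean spring–mass system: an
Ornstein–Uhlenbeck (OU) process with relaxation time τ = γ/κ, drag
γ = 6πηr, and stationary variance k_BT/κ (equipartition). We use the *exact*
discretization

x_{n+1} = x_n e^{−Δt/τ} + ξ_n √((k_BT/κ)(1 − e^{−2Δt/τ})),

rather than an Euler scheme, so the stationary variance and autocorrelation
are correct at any sampling rate — a step-size-biased generator would
contaminate every calibration test downstream. Both lateral axes are
independent; everything is reproducible under the parameter seed. Defaults
(κ = 0.05 pN/nm, 20 kHz, 10 s) describe a soft trap with corner frequency
≈ 391 Hz, comfortably inside the sampled band.

## Power-spectrum trap calibration

`compute_psd()` averages one-sided periodograms over 64 non-overlapping
blocks (rectangular window, per-block mean removal), preserving Parseval's
identity to within numerical error. `fit_lorentzian()` estimates the corner
frequency f_c and diffusion coefficient D by an analytic linear-in-moments
least squares: the reciprocal spectrum is linear in its coefficients, so
minimising Σ(S_exp/S_fit − 1)² reduces to a 2×2 moment system — no
iteration, no starting values.

Two conventions matter here:

* **One-sided spectra.** The one-sided Lorentzian is
  S(f) = D/(π²(f_c² + f²)); with this form the fitted D is the physical
  Einstein coefficient k_BT/γ, which the detector-sensitivity conversion
  β² = (k_BT/γ)/D_measured relies on. (Fitting one-sided data with the
  two-sided form silently doubles D; κ is unaffected because it depends only
  on the spectral shape, which is why this class of bug survives in
  pipelines that never calibrate detector units.)
* **Aliasing.** A finitely sampled OU process is an AR(1) process whose
  spectrum is the *aliased* Lorentzian
  S(f) ∝ 1/(1 + a² − 2a cos 2πfΔt), a = e^{−2πf_cΔt}. Over the default fit
  band [50 Hz, f_s/4] the unaliased fit is biased several percent high in
  f_c *even on ideal data*. `calibrate()` therefore fits the aliased form by
  default (its reciprocal is linear in (1, cos 2πfΔt), so the same moment
  solution applies); the continuous form remains available via
  `fit_lorentzian()` for spectra already corrected upstream.

Stiffness follows as κ = 2πγf_c. The default band [50 Hz, f_s/4] excludes
drift-contaminated low frequencies and the near-Nyquist region; block count
and band are parameters. Fit failures (zero power, non-positive
coefficients, degenerate moments) raise errors rather than returning
numbers.

## Tether pulls: protocol, segmentation, PF/SSF

A pull follows the standard protocol: pre-contact Brownian baseline (5 s),
approach, 5 s stationary contact, a 0.25 µm attachment-test retraction, a
constant-speed retraction (presets: fibroblast 0.1 µm/s × 10 µm; neuron
0.5 µm/s × 20 µm), and a 30 s stationary hold at full extension. The mean
force of the pre-contact recording defines zero force for that pull
(`zero_baseline()`), making all metrics invariant to a rigid shift of the
raw trace.

The synthetic force curve is the simplest shape with the canonical
rise–peak–decay–plateau anatomy and independently tunable peak force (PF)
and steady-state force (SSF): a linear rise at attachment_stiffness × speed
to PF, an exponential decay (time constant `relax_time`, default 5 s) to
SSF over the remaining retraction, and a hold phase identically at SSF.
Noise-free PF and SSF therefore equal the requested parameters *exactly*,
which is what makes the extractor tests sharp. The decay must complete
during the retraction (`relax_time` ≪ remaining pull time); the constructor
enforces reachability of the peak. The recording is stored as bead position
(force/κ) so the analysis path exercises the same calibration step as real
data. Default sampling 200 Hz — typical of decimated force channels, and
6000 hold samples put the SSF standard error near 2/√6000 ≈ 0.03 pN at the
2 pN default noise.

Phase segmentation uses the stage channel only (the protocol defines the
phases; the force signature does not): samples are classified
moving/stationary by a forward-difference velocity threshold at 10% of the
protocol speed, gated by a smoothed velocity to reject blips, which keeps
episode edges sample-exact on clean channels — segmentation is invariant to
sampling rate (tested at 200 Hz–5 kHz). PF is the maximum force over
retraction ∪ hold (the peak occurs early in the pull; including the hold is
harmless and robust to slow ramps); SSF is the mean over the final 30 s of
the hold. No smoothing is applied before the PF search by default — the
maximum of a noisy trace is biased upward by roughly the noise SD times a
sampling-dependent factor (bounded by 4σ at our defaults), and any
pre-filtering changes that bias; an optional moving-median width is exposed
and documented rather than silently applied. A pull whose hold mean falls
below 1 pN (configurable) is flagged `tether_lost` but still reported:
flagging, not dropping, keeps selection effects visible.

## TFM: image simulation, PIV, FTTC

**Forward model.** Traction fields are sums of Gaussian-profile patches
(σ = radius/2), so each patch's integrated force has the closed form
peak·2πσ². The surface displacement of the elastic half-space follows the
Boussinesq solution per spatial frequency, ũ(k) = G̃(k)T̃(k), with the
standard Green's tensor and E = 2G′(1+ν). ν defaults to 0.5
(incompressible polyacrylamide); substrate presets cover the 0.1/0.3/1/10
kPa gel families. The k = 0 mode of the operator is unbounded: a net force
has no periodic solution, so unbalanced tractions are rejected (the
generator can instead project out the mean, with a warning, when asked to
render images for a deliberately unbalanced patch set — the stored ground
truth keeps the patches as specified).

**Periodicity.** Both `forward_displacement()` and `fttc_traction()` operate
on the periodic grid of the data — the standard FTTC convention — so
forward-then-inverse at λ = 0 is an identity to machine precision. We
measured the alternative (zero-padded isolated-source forward, periodic
inverse) at 40–135% relative L2 round-trip error even for compact patches:
the slowly decaying Boussinesq tail makes the cropped displacement window
non-periodic, and a λ = 0 inverse amplifies the mismatch. Padding (`pad > 1`)
therefore exists for isolated-source forward *modelling*, and is
deliberately not the operator the inverse assumes. The periodic convention's
own cost — spurious interaction with periodic images when the source fills
the field of view — is flagged by a support check (warning when the traction
support exceeds ¾ of the grid).

**Image rendering.** Beads are scattered uniformly (default 0.3/µm²,
FluoSpheres-like seeding; amplitudes 0.7–1.3), rendered as isotropic
Gaussian spots (σ = 1.5 px) at 0.1 µm/px, displaced by the bilinearly
interpolated field, with independent Gaussian image noise per frame (default
5% of unit amplitude). No photon shot noise, camera artifacts, defocus or
3-D deformation — the generator exercises the estimators, not the camera.

**PIV.** Displacement is estimated by normalized cross-correlation over
square interrogation windows (default 32 px, 75% overlap), FFT-based, with
a three-point Gaussian subpixel fit (parabolic fallback where logs are
undefined). One-pass correlation has a systematic bias toward zero (window
truncation weights the correlation peak asymmetrically); we remove it with
the standard two-pass discrete window offset — re-correlate with the
stressed window shifted by the integer displacement, putting the residual
peak at the origin where the subpixel fit is symmetric. At image borders the
offset is applied to whichever window stays in bounds. Weak correlation
peaks (< 0.3) are masked invalid; vectors failing the normalized-median
neighbourhood test are replaced by the neighbour median. Subpixel accuracy
presupposes adequate seeding — the PIV literature's rule of thumb of order
ten particles per window means ≥ ~0.8 beads/µm² at our window size and
pixel pitch; accuracy tests use 1.0 beads/µm². Rigid drift is estimated as
the median displacement over the cell-free mask complement and subtracted.

**Inversion and regularization.** Per mode, T̃ = (G̃ᴴG̃ + (λs)²I)⁻¹G̃ᴴũ,
where s is the largest singular value of the Green's operator over the
grid, making λ dimensionless; λ = 0 is exact on noise-free data, λ → ∞
drives the traction to zero, and the zero-frequency traction is always 0
(force balance; that mode is unobservable anyway). The default λ heuristic
is Morozov's discrepancy principle: pick λ whose forward-model residual
matches the noise floor √2·σ̂, with σ̂ estimated robustly from first
differences of the displacement field (MAD-based — valid because the true
field is smooth at grid scale while the noise is not). We also provide the
L-curve corner (triangle method) but do not default to it: on smooth
Gaussian-patch fields its corner locks onto the noise-floor elbow and
under-regularizes by an order of magnitude (measured relative L2 ≈ 2.6
versus ≈ 0.28 at the discrepancy choice, with the oracle optimum ≈ 0.26).
That measurement also locates the accuracy floor of single-parameter
Tikhonov FTTC at ~25–30% relative L2 for 5%-of-max white displacement
noise; integrated quantities are far more forgiving — ROI net force is
recovered to within ~5–10% in the same conditions, which is why per-cell
conclusions are drawn from net forces and ROI summaries, not pointwise
stresses.

**Time averaging.** Per-frame tractions are averaged componentwise (12
frames for neurons, 5 for fibroblasts in the default protocol). With the
same bead pattern in every frame, the pattern-specific PIV error is common
to all frames and does not average out; only the independent image noise
does, so the measured improvement from averaging is real but modest. The
generator reproduces exactly this structure, which is worth knowing before
reading too much into multi-frame averages of real single-position
recordings.

## Group statistics

The two tests behind the pipeline's scientific comparisons are implemented
from first principles so their small-sample behaviour is auditable:

* `mann_whitney()` — exact two-tailed p by the full permutation distribution
  of the rank sum, computed with a shift-algorithm dynamic programme over
  doubled mid-ranks (ties handled exactly); p = 2·min(P(U ≤ u), P(U ≥ u))
  capped at 1. Exact mode covers n + m ≤ 25; beyond that a tie-corrected
  normal approximation with continuity correction takes over (noted in the
  result). Tests verify the exact mode against brute-force enumeration of
  all C(n+m, n) labelings for n, m ≤ 8 and against the reference
  implementation where it is exact.
* `kruskal_wallis()` — H with the tie correction H/(1 − Σ(t³−t)/(N³−N)) and
  a χ²_{k−1} p-value; verified against hand-computed values and the
  reference implementation, and invariant under monotone transforms.
* `posthoc_pairwise()` — "Tukey post hoc" after a rank test is ambiguous, so
  both readings are provided: Dunn's z tests on pooled mid-ranks with Holm
  adjustment (default; the standard Kruskal–Wallis companion) and Tukey's
  HSD on rank-transformed data (the literal reading). Neither is claimed to
  reproduce any particular prior analysis.

Degenerate inputs (all observations identical) yield p = 1 with a note, not
an error. Type-I error of both tests is checked by null simulation at the
sizes used in the cohort comparisons.

## Orchestration and reproducibility

`run_pipeline()` chains simulate → calibrate → tether → TFM → statistics
from a single YAML-serialisable config; per-stage seeds derive from the
config seed by a documented counter scheme (`derive_seed()`), so identical
config + seed reproduces byte-identical metrics files. Traces are
tab-delimited text (lossless at 10 significant digits), images are TIFF,
ground truth and reports are JSON, and a manifest records stage timings and
surfaced warnings. A thin command-line wrapper
(`inst/cli/memtension.R`) exposes `simulate`, `calibrate`, `tether`, `tfm`,
`stats` and `run`.

## Problem sizes in the test suite

The suite exercises: 20 calibration traces (10 s at 20 kHz), 50 noisy
tether pulls at 200 Hz, 64×64 FTTC round trips, 256×256 rendered image
pairs (3 seeds for PIV accuracy, 10 seeds × 12 frames for net-force
recovery), 2000-replicate null simulations per rank test, and 200 synthetic
cohorts for the qualitative stiffness-comparison pattern. These sizes put
Monte-Carlo standard errors well inside the asserted tolerances while
keeping the suite fast.

## Known limitations

* Tether curves use an invented parametric shape; real pulls show
  force fluctuations from tether flow and sliding that the generator does
  not emulate, so PF/SSF recovery here validates the extractor, not the
  biology.
* The OU model omits detector filtering, aliasing from finite camera
  exposure, and low-frequency drift; calibration accuracy on real traces
  depends on those corrections (a hook for a correction callable exists).
* TFM assumes an infinite, linear-elastic, incompressible half-space with
  periodic boundary conditions; no finite-thickness correction, no 3-D
  displacement component, no cell segmentation (masks are inputs).
* Pointwise traction maps at realistic noise carry ~25%+ relative L2 error
  (the Tikhonov floor); quantitative claims should rest on integrated ROI
  quantities, as they do throughout the package.
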