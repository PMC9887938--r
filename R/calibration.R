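#' Block-averaged one-sided power spectral density
#'
#' Splits the position signal into `n_blocks` non-overlapping segments,
#' removes each segment's mean, and averages the one-sided periodograms
#' (rectangular window). Satisfies Parseval: sum(power) * df equals the
#' (block-demeaned) signal variance.
#'
#' @param trace a [trap_trace()] (uniform sampling enforced at construction)
#' @param n_blocks number of non-overlapping blocks to average (default 64)
#' @param channel which position channel to use, "x" or "y"
#' @return object of class `psd_estimate` with fields `frequencies` (Hz,
#'   excluding DC, up to Nyquist), `power` (nm^2/Hz), `n_blocks`, `df`
#' @export
compute_psd <- function(trace, n_blocks = 64, channel = c("x", "y")) {
  stopifnot(inherits(trace, "trap_trace"))
  channel <- match.arg(channel)
  x <- if (channel == "x") trace$position_x else trace$position_y
  if (is.null(x)) stop("requested channel not present in trace")
  n_blocks <- as.integer(n_blocks)
  if (n_blocks < 1) stop("n_blocks must be >= 1")
  if (length(x) < 2 * n_blocks)
    stop("trace shorter than 2 samples per block")
  fs <- trace$sampling_rate
  nb <- floor(length(x) / n_blocks)
  nb <- nb - nb %% 2L  # even block length keeps a clean Nyquist bin
  if (nb < 2) stop("blocks too short")
  half <- nb %/% 2L
  acc <- numeric(half)
  for (b in seq_len(n_blocks)) {
    seg <- x[((b - 1) * nb + 1):(b * nb)]
    seg <- seg - mean(seg)
    X <- stats::fft(seg)
    p2 <- (Mod(X)^2) / (nb * fs)            # two-sided
    one <- p2[2:(half + 1)]
    one[seq_len(half - 1)] <- 2 * one[seq_len(half - 1)]  # fold; Nyquist unpaired
    acc <- acc + one
  }
  structure(list(frequencies = (1:half) * fs / nb,
                 power = acc / n_blocks,
                 n_blocks = n_blocks,
                 df = fs / nb,
                 block_length = nb),
            class = "psd_estimate")
}

#' Theoretical Lorentzian power spectrum of a trapped bead
#'
#' One-sided spectrum of an overdamped bead in a harmonic trap,
#' S(f) = D / (pi^2 (f_c^2 + f^2)) for f >= 0, with D = k_B T / gamma the
#' free diffusion coefficient and f_c = kappa / (2 pi gamma) the corner
#' frequency. (The equivalent two-sided density is D / (2 pi^2 (f_c^2 +
#' f^2)); [compute_psd()] returns one-sided estimates, and keeping the
#' one-sided form here means D retains its physical Einstein value.)
#'
#' @param f frequencies in Hz
#' @param f_c corner frequency in Hz
#' @param D diffusion coefficient in nm^2/s
#' @return one-sided power density in nm^2/Hz
#' @export
lorentzian_psd <- function(f, f_c, D) {
  D / (pi^2 * (f_c^2 + f^2))
}

#' Fit a Lorentzian to a power spectrum
#'
#' Estimates the corner frequency and diffusion coefficient by the analytic
#' linear-in-moments least squares: since 1/S(f) = a + b f^2 is linear in
#' (a, b), minimizing sum over the fit band of (S_exp(f) (a + b f^2) - 1)^2 --
#' i.e. the relative residual sum((S_exp/S_fit - 1)^2) -- has a closed-form
#' solution in the moments of S_exp. Then f_c = sqrt(a/b) and, in the
#' one-sided convention of [lorentzian_psd()], D = pi^2 / b. No iteration,
#' no starting values.
#'
#' With `sampling_rate` given, the *aliased* Lorentzian is fitted instead:
#' a finitely sampled harmonic-trap recording folds all spectral images into
#' the Nyquist band, and the sampled process (an AR(1)) has the exact
#' spectrum S(f) = c / (1 + a^2 - 2 a cos(2 pi f dt)) with a = exp(-2 pi
#' f_c dt). Its reciprocal is linear in the basis (1, cos(2 pi f dt)), so
#' the same moment solution applies; ignoring aliasing biases f_c upward by
#' several percent even on ideal data when the band extends to f_s/4.
#'
#' @param psd a `psd_estimate` from [compute_psd()]
#' @param f_min,f_max fit band in Hz (default 50 Hz to half the Nyquist
#'   frequency, i.e. f_s/4)
#' @param sampling_rate if non-NULL, fit the aliased form for data sampled
#'   at this rate (Hz)
#' @return list with `f_c` (Hz), `D` (nm^2/s), `residual` (RMS relative
#'   residual over the band), `band`, `n_points`, `aliased`
#' @export
fit_lorentzian <- function(psd, f_min = 50, f_max = NULL,
                           sampling_rate = NULL) {
  stopifnot(inherits(psd, "psd_estimate"))
  f_nyq <- max(psd$frequencies)
  if (is.null(f_max)) f_max <- f_nyq / 2  # default band top: f_s/4
  sel <- psd$frequencies >= f_min & psd$frequencies <= f_max
  f <- psd$frequencies[sel]
  S <- psd$power[sel]
  if (length(f) < 10) stop("fit band contains fewer than 10 frequency bins")
  if (all(S <= 0)) stop("fit failure: all power in the band is zero")
  aliased <- !is.null(sampling_rate)
  # basis for the reciprocal spectrum: (1, f^2) for the continuous
  # Lorentzian, (1, cos(2 pi f dt)) for the aliased one
  g <- if (aliased) cos(2 * pi * f / sampling_rate) else f^2
  # least squares of S*(a + b g) ~ 1 in (a, b)
  s2 <- S^2
  M <- matrix(c(sum(s2), sum(s2 * g),
                sum(s2 * g), sum(s2 * g^2)), 2, 2)
  rhs <- c(sum(S), sum(S * g))
  ab <- tryCatch(solve(M, rhs), error = function(e)
    stop("fit failure: degenerate moment matrix"))
  if (any(!is.finite(ab))) stop("fit failure: non-finite coefficients")
  if (aliased) {
    A <- ab[1]; B <- ab[2]
    r <- B / A
    if (!(A > 0) || r >= 0 || r <= -1)
      stop("fit failure: coefficients outside the aliased-Lorentzian domain")
    ar1 <- (-1 + sqrt(1 - r^2)) / r       # AR(1) coefficient in (0, 1)
    dt <- 1 / sampling_rate
    f_c <- -log(ar1) / (2 * pi * dt)
    # one-sided AR(1) spectrum: S(f) = 2 sigma^2 (1 - a^2) dt / |1 - a z|^2
    cc <- (1 + ar1^2) / A                 # c = 2 dt sigma^2 (1 - ar1^2)
    sigma2 <- cc / (2 * dt * (1 - ar1^2)) # equipartition variance, nm^2
    D <- sigma2 * 2 * pi * f_c            # D = sigma^2 / tau
    fit <- cc / (1 + ar1^2 - 2 * ar1 * cos(2 * pi * f * dt))
  } else {
    a <- ab[1]; b <- ab[2]
    if (a <= 0 || b <= 0)
      stop("fit failure: non-positive Lorentzian coefficients")
    f_c <- sqrt(a / b)
    D <- pi^2 / b   # one-sided convention of lorentzian_psd()
    fit <- lorentzian_psd(f, f_c, D)
  }
  if (!(f_min < f_c && f_c < f_max))
    warning(sprintf("fit band [%g, %g] Hz does not straddle f_c = %.3g Hz",
                    f_min, f_max, f_c))
  list(f_c = f_c, D = D,
       residual = sqrt(mean((S / fit - 1)^2)),
       band = c(f_min, f_max), n_points = length(f), aliased = aliased)
}

#' Calibrate an optical trap from a Brownian-motion recording
#'
#' Power-spectrum calibration: block-average the position PSD, fit the
#' Lorentzian, then convert the corner frequency into trap stiffness through
#' the Stokes drag, kappa = 2 pi gamma f_c with gamma = 6 pi eta r. For a
#' trace recorded in raw detector units the detector sensitivity
#' beta (nm per detector unit) follows from requiring the fitted diffusion
#' coefficient to equal the Einstein value k_B T / gamma:
#' beta^2 = (k_B T / gamma) / D_measured. For physical-unit traces beta = 1.
#'
#' @param trace a [trap_trace()]
#' @param bead_radius bead radius in um
#' @param viscosity dynamic viscosity in Pa s
#' @param temperature temperature in K
#' @param band fit band c(f_min, f_max) in Hz; default c(50, f_s/4)
#' @param n_blocks PSD blocks (default 64)
#' @param alias_correct fit the aliased Lorentzian (default TRUE; see
#'   [fit_lorentzian()]). The continuous form is available for data already
#'   corrected upstream.
#' @return object of class `calibration_result` with corner frequency `f_c`
#'   (Hz), diffusion `D` (nm^2/s in physical units), stiffness `kappa`
#'   (pN/nm), sensitivity `beta` (nm per detector unit), drag `gamma`
#'   (pN s/nm), fit residual and band
#' @examples
#' tr <- simulate_trapped_bead(trap_sim_params(seed = 3, duration = 2))
#' cal <- calibrate(tr, bead_radius = 1.08, viscosity = 1e-3)
#' cal$kappa # ~0.05 pN/nm
#' @export
calibrate <- function(trace, bead_radius, viscosity,
                      temperature = 298.15, band = NULL, n_blocks = 64,
                      alias_correct = TRUE) {
  stopifnot(inherits(trace, "trap_trace"),
            bead_radius > 0, viscosity > 0, temperature > 0)
  psd <- compute_psd(trace, n_blocks = n_blocks)
  if (is.null(band)) band <- c(50, trace$sampling_rate / 4)
  fit <- fit_lorentzian(psd, band[1], band[2],
                        sampling_rate = if (alias_correct) trace$sampling_rate)
  gamma <- stokes_drag_pN_s_nm(bead_radius, viscosity)
  kappa <- 2 * pi * gamma * fit$f_c
  d_einstein <- kbt_pN_nm(temperature) / gamma   # nm^2/s
  if (trace$units_flag == "detector") {
    beta <- sqrt(d_einstein / fit$D)
    D_phys <- d_einstein
  } else {
    beta <- 1
    D_phys <- fit$D
  }
  structure(list(f_c = fit$f_c, D = D_phys, kappa = kappa,
                 beta = beta, gamma = gamma,
                 temperature = temperature,
                 bead_radius = bead_radius, viscosity = viscosity,
                 residual = fit$residual, band = fit$band,
                 n_blocks = n_blocks),
            class = "calibration_result")
}

#' @export
print.calibration_result <- function(x, ...) {
  cat(sprintf(paste0(
    "trap calibration (power-spectrum method)\n",
    "  corner frequency f_c : %.4g Hz\n",
    "  stiffness kappa      : %.4g pN/nm\n",
    "  diffusion D          : %.4g nm^2/s\n",
    "  sensitivity beta     : %.4g nm/du\n",
    "  drag gamma           : %.4g pN s/nm\n",
    "  fit residual (RMS)   : %.3g over [%g, %g] Hz\n"),
    x$f_c, x$kappa, x$D, x$beta, x$gamma,
    x$residual, x$band[1], x$band[2]))
  invisible(x)
}

#' Serialize a calibration result to JSON
#'
#' @param cal a `calibration_result`
#' @param path output file path
#' @return `path`, invisibly
#' @export
write_calibration <- function(cal, path) {
  stopifnot(inherits(cal, "calibration_result"))
  jsonlite::write_json(unclass(cal), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a calibration result from JSON
#' @param path file written by [write_calibration()]
#' @return a `calibration_result`
#' @export
read_calibration <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(obj, class = "calibration_result")
}
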