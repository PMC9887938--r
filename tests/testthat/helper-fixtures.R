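# shared fixtures, all generated in code

# a calibration with exactly known stiffness, bypassing the fit, for tests
# that exercise force conversion rather than calibration itself
exact_calibration <- function(kappa = 0.05, beta = 1) {
  structure(list(f_c = kappa / (2 * pi * 2.0358e-5), D = 2e5, kappa = kappa,
                 beta = beta, gamma = 2.0358e-5, temperature = 298.15,
                 bead_radius = 1.08, viscosity = 1e-3,
                 residual = 0, band = c(50, 5000), n_blocks = 64),
            class = "calibration_result")
}

# balanced contractile dipole of Gaussian patches on an n x n unit-spacing
# grid; sigma in grid nodes
dipole_field <- function(n = 64, sigma = 6, sep = 24, peak = 200) {
  x <- 0:(n - 1)
  patch_traction_field(list(
    list(center = c(n / 2 - sep / 2, n / 2), radius = 2 * sigma, peak = peak,
         direction = c(1, 0)),
    list(center = c(n / 2 + sep / 2, n / 2), radius = 2 * sigma, peak = peak,
         direction = c(-1, 0))), x, x)
}

# half-plane ROI containing the left pole of dipole_field
dipole_roi <- function(n = 64) {
  roi <- matrix(FALSE, n, n)
  roi[, 1:(n / 2)] <- TRUE
  roi
}

# rendered bead image pair deformed by a smooth sinusoidal field (max
# displacement 2 px), with additive Gaussian image noise; returns images,
# the displacement functions (um), and pixel size
smooth_piv_case <- function(seed, image_px = 256, pixel_size = 0.1,
                            density = 1.0, noise_sd = 0.05) {
  W <- image_px * pixel_size
  ufun <- function(x, y) 0.2 * sin(2 * pi * x / (2 * W)) * cos(2 * pi * y / (2 * W))
  vfun <- function(x, y) -0.15 * cos(2 * pi * x / (2 * W)) * sin(2 * pi * y / (2 * W))
  withr::with_seed(seed, {
    n <- round(density * W^2)
    beads <- cbind(stats::runif(n, 0, W), stats::runif(n, 0, W))
    ref <- render_beads(beads, c(image_px, image_px), pixel_size, 1.5) +
      matrix(stats::rnorm(image_px^2, sd = noise_sd), image_px)
    moved <- cbind(beads[, 1] + ufun(beads[, 1], beads[, 2]),
                   beads[, 2] + vfun(beads[, 1], beads[, 2]))
    str <- render_beads(moved, c(image_px, image_px), pixel_size, 1.5) +
      matrix(stats::rnorm(image_px^2, sd = noise_sd), image_px)
    list(reference = ref, stressed = str, ufun = ufun, vfun = vfun,
         pixel_size = pixel_size)
  })
}

# RMS error (px) of a PIV field against the analytic displacement functions
piv_rms_err_px <- function(d, ufun, vfun, pixel_size) {
  X <- matrix(d$x, length(d$y), length(d$x), byrow = TRUE)
  Y <- matrix(d$y, length(d$y), length(d$x))
  err <- sqrt((d$fx - ufun(X, Y))^2 + (d$fy - vfun(X, Y))^2) / pixel_size
  sqrt(mean(err[d$valid]^2))
}

# brute-force exact two-tailed Mann-Whitney p by full enumeration of
# C(n+m, n) labelings (independent oracle for the shift-algorithm DP)
mw_bruteforce_p <- function(a, b) {
  n <- length(a); N <- n + length(b)
  rk <- rank(c(a, b))
  u_obs <- sum(rk[seq_len(n)]) - n * (n + 1) / 2
  us <- apply(utils::combn(N, n), 2,
              function(ix) sum(rk[ix]) - n * (n + 1) / 2)
  min(1, 2 * min(mean(us <= u_obs), mean(us >= u_obs)))
}

rel_l2 <- function(est, truth) {
  tx <- truth$fx - mean(truth$fx); ty <- truth$fy - mean(truth$fy)
  sqrt(sum((est$fx - tx)^2 + (est$fy - ty)^2) / sum(tx^2 + ty^2))
}
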