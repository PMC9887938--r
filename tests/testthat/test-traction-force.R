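test_that("material parameters enforce the E = 2 G' (1 + nu) relation", {
  m <- material_params(1000, 0.5)
  expect_equal(m$young_modulus, 3000)
  expect_equal(material_preset("0.3kPa")$shear_modulus, 300)
  expect_error(material_preset("5kPa"), "unknown substrate")
  expect_error(material_params(-1), "shear_modulus")
  expect_error(material_params(1000, 0.7), "poisson_ratio")
})

test_that("identical images give a zero displacement field", {
  img <- withr::with_seed(1, {
    beads <- cbind(runif(300, 0, 12.8), runif(300, 0, 12.8))
    render_beads(beads, c(128, 128), 0.1, 1.5)
  })
  d <- piv_displacement(img, img, window = 32, overlap = 0.5, pixel_size = 0.1)
  expect_lt(max(abs(c(d$fx[d$valid], d$fy[d$valid]))), 1e-9)
})

test_that("an integer-pixel translation is recovered essentially exactly", {
  res <- withr::with_seed(9, {
    beads <- cbind(runif(160, 0, 12.8), runif(160, 0, 12.8))
    ref <- render_beads(beads, c(128, 128), 0.1, 1.5)
    str <- render_beads(cbind(beads[, 1] + 0.3, beads[, 2] - 0.2),
                        c(128, 128), 0.1, 1.5)
    piv_displacement(ref, str, window = 32, overlap = 0.5, pixel_size = 0.1)
  })
  err <- sqrt((res$meta$ux_px[res$valid] - 3)^2 +
                (res$meta$uy_px[res$valid] + 2)^2)
  expect_lt(sqrt(mean(err^2)), 0.05)
})

test_that("PIV resolves a smooth field with subpixel accuracy despite image noise", {
  cs <- smooth_piv_case(seed = 5)
  d <- piv_displacement(cs$reference, cs$stressed, window = 32,
                        overlap = 0.75, pixel_size = cs$pixel_size)
  expect_lt(piv_rms_err_px(d, cs$ufun, cs$vfun, cs$pixel_size), 0.2)
})

test_that("PIV rejects mismatched shapes and masks featureless windows", {
  expect_error(piv_displacement(matrix(0, 64, 64), matrix(0, 32, 32),
                                window = 16, pixel_size = 0.1), "shape")
  expect_error(piv_displacement(matrix(0, 64, 64), matrix(0, 64, 64),
                                window = 20, pixel_size = 0.1), "power of two")
  d <- piv_displacement(matrix(0, 64, 64), matrix(0, 64, 64),
                        window = 16, pixel_size = 0.1)
  expect_false(any(d$valid))
})

test_that("forward displacement is linear and scales inversely with stiffness", {
  truth <- dipole_field()
  m1 <- material_params(1000, 0.5)
  u <- suppressWarnings(forward_displacement(truth, m1))
  t2 <- truth; t2$fx <- 2 * truth$fx; t2$fy <- 2 * truth$fy
  u2 <- suppressWarnings(forward_displacement(t2, m1))
  expect_equal(u2$fx, 2 * u$fx, tolerance = 1e-12)
  # doubling E (via G') halves displacements
  uh <- suppressWarnings(forward_displacement(truth, material_params(2000, 0.5)))
  expect_equal(uh$fx, u$fx / 2, tolerance = 1e-12)
  # zero traction -> zero displacement
  z <- vector_field(truth$x, truth$y, 0 * truth$fx, 0 * truth$fy, unit = "Pa")
  expect_true(all(forward_displacement(z, m1)$fx == 0))
})

test_that("unbalanced traction is rejected by the forward solve", {
  n <- 32
  tx <- matrix(50, n, n)  # uniform traction: gross net force
  tr <- vector_field(0:(n - 1), 0:(n - 1), tx, 0 * tx, unit = "Pa")
  expect_error(forward_displacement(tr, material_params(1000, 0.5)),
               "unbalanced")
})

test_that("FTTC at lambda = 0 inverts the forward operator to machine precision", {
  truth <- dipole_field(n = 64, sigma = 6)
  mat <- material_params(1000, 0.5)
  u <- suppressWarnings(forward_displacement(truth, mat))
  rec <- fttc_traction(u, mat, lambda = 0)
  expect_lt(rel_l2(rec, truth), 1e-6)
  expect_equal(rec$meta$lambda, 0)
  # strong regularization kills the traction entirely
  rec_inf <- fttc_traction(u, mat, lambda = 1e5)
  expect_lt(max(abs(rec_inf$fx)), 1e-4 * max(abs(truth$fx)))
})

test_that("same displacement on a 10x stiffer substrate gives exactly 10x traction", {
  truth <- dipole_field()
  u <- suppressWarnings(forward_displacement(truth, material_params(1000, 0.5)))
  t1 <- fttc_traction(u, material_params(1000, 0.5), lambda = 0)
  t10 <- fttc_traction(u, material_params(10000, 0.5), lambda = 0)
  expect_equal(t10$fx, 10 * t1$fx, tolerance = 1e-10)
})

test_that("noisy round trip with the default lambda heuristic recovers the integrated force", {
  truth <- dipole_field(n = 64, sigma = 6)
  mat <- material_params(1000, 0.5)
  u <- suppressWarnings(forward_displacement(truth, mat))
  roi <- dipole_roi(64)
  nf_true <- net_force(truth, roi)[["Fmag_nN"]]
  mx <- max(sqrt(u$fx^2 + u$fy^2))
  res <- sapply(1:10, function(s) withr::with_seed(s, {
    un <- u
    un$fx <- u$fx + rnorm(length(u$fx), sd = 0.05 * mx)
    un$fy <- u$fy + rnorm(length(u$fy), sd = 0.05 * mx)
    lam <- choose_lambda(un, mat)$lambda
    rec <- fttc_traction(un, mat, lambda = lam)
    c(l2 = rel_l2(rec, truth),
      nf = abs(net_force(rec, roi)[["Fmag_nN"]] / nf_true - 1))
  }))
  expect_lt(median(res["nf", ]), 0.10)
  # reconstruction error at the discrepancy-principle lambda sits near the
  # single-parameter Tikhonov floor for this noise level (~0.26 measured at
  # the oracle-optimal lambda)
  expect_lt(median(res["l2", ]), 0.35)
})

test_that("time averaging is the componentwise mean and reduces noise", {
  truth <- dipole_field()
  neg <- truth; neg$fx <- -truth$fx; neg$fy <- -truth$fy
  avg0 <- time_average(list(truth, neg))
  expect_true(all(avg0$fx == 0))
  same <- time_average(rep(list(truth), 5))
  expect_equal(same$fx, truth$fx)
  expect_equal(same$meta$n_frames, 5)
  small <- vector_field(0:3, 0:3, matrix(0, 4, 4), matrix(0, 4, 4), unit = "Pa")
  expect_error(time_average(list(truth, small)), "mismatched")
  # 12 noisy copies: averaged error ~ single-frame error / sqrt(12)
  noisy <- lapply(1:12, function(s) withr::with_seed(s, {
    f <- truth
    f$fx <- truth$fx + rnorm(length(truth$fx), sd = 20)
    f$fy <- truth$fy + rnorm(length(truth$fy), sd = 20)
    f
  }))
  e1 <- sqrt(mean((noisy[[1]]$fx - truth$fx)^2))
  e12 <- sqrt(mean((time_average(noisy)$fx - truth$fx)^2))
  expect_lt(e12, e1 / 2.5)
})

test_that("net force integrates traction with the exact Pa um^2 -> nN conversion", {
  expect_equal(pa_um2_to_nN(1), 1e-3)   # 1 Pa um^2 = 1e-12 N = 1e-3 nN
  # uniform 100 Pa over 100 um^2 -> 10 nN
  g <- seq(0, 9)  # 10 x 10 grid, 1 um spacing -> 100 um^2
  uni <- vector_field(g, g, matrix(100, 10, 10), matrix(0, 10, 10), unit = "Pa")
  nf <- net_force(uni, matrix(TRUE, 10, 10))
  expect_equal(nf[["Fx_nN"]], 10)
  expect_equal(nf[["Fmag_nN"]], 10)
  z <- vector_field(g, g, matrix(0, 10, 10), matrix(0, 10, 10), unit = "Pa")
  expect_equal(unname(net_force(z, matrix(TRUE, 10, 10))), c(0, 0, 0))
  expect_error(net_force(uni, matrix(FALSE, 10, 10)), "empty ROI")
})

test_that("net force is additive over disjoint ROIs and splits a balanced dipole", {
  truth <- dipole_field(n = 64, sigma = 6)
  left <- dipole_roi(64); right <- !left
  whole <- matrix(TRUE, 64, 64)
  nf_l <- net_force(truth, left); nf_r <- net_force(truth, right)
  nf_w <- net_force(truth, whole)
  expect_equal(nf_w[["Fx_nN"]], nf_l[["Fx_nN"]] + nf_r[["Fx_nN"]],
               tolerance = 1e-12)
  # balanced: whole-field magnitude ~ 0, each pole ~ closed form
  expect_lt(nf_w[["Fmag_nN"]], 0.01 * nf_l[["Fmag_nN"]])
  expect_equal(nf_l[["Fmag_nN"]], 200 * 2 * pi * 36 * 1e-3, tolerance = 0.05)
})

test_that("traction summaries report mean, percentile and strain energy", {
  g <- seq(0, 9)
  uni <- vector_field(g, g, matrix(100, 10, 10), matrix(0, 10, 10), unit = "Pa")
  s <- traction_summary(uni, matrix(TRUE, 10, 10))
  expect_equal(s[["mean_stress_Pa"]], 100)
  expect_equal(s[["p90_stress_Pa"]], 100)
  u <- vector_field(g, g, matrix(0.5, 10, 10), matrix(0, 10, 10), unit = "um")
  s2 <- traction_summary(uni, matrix(TRUE, 10, 10), u)
  # U = 1/2 * 100 Pa * 0.5 um * 100 um^2 = 2500 Pa um^3 = 2.5 fJ
  expect_equal(s2[["strain_energy_fJ"]], 2.5)
})

test_that("drift correction removes a rigid offset estimated from cell-free regions", {
  truth <- dipole_field()
  mat <- material_params(1000, 0.5)
  u <- suppressWarnings(forward_displacement(truth, mat))
  u_drift <- u
  u_drift$fx <- u$fx + 0.07; u_drift$fy <- u$fy - 0.03
  mask <- sqrt(truth$fx^2 + truth$fy^2) > 1  # "cell" region
  fixed <- correct_drift(u_drift, mask)
  expect_equal(fixed$meta$drift_um, c(0.07, -0.03), tolerance = 0.01)
  expect_lt(median(abs(fixed$fx[!mask] - u$fx[!mask])), 0.01)
})
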