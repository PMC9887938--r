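test_that("trapped-bead simulation has the equipartition variance and OU autocorrelation", {
  p <- trap_sim_params(stiffness_kappa = 0.05, seed = 11, duration = 10)
  tr <- simulate_trapped_bead(p)
  sig2 <- kbt_pN_nm(298.15) / 0.05  # ~82.3 nm^2
  expect_equal(sd(tr$position_x), sqrt(sig2), tolerance = 0.03)
  expect_equal(sd(tr$position_y), sqrt(sig2), tolerance = 0.03)
  # lag-1 autocorrelation equals exp(-dt/tau)
  gamma <- stokes_drag_pN_s_nm(1.08, 1e-3)
  a_expect <- exp(-(1 / 20000) / (gamma / 0.05))
  a_hat <- cor(tr$position_x[-1], tr$position_x[-length(tr$position_x)])
  expect_equal(a_hat, a_expect, tolerance = 0.01)
})

test_that("stiff-trap limit collapses the position variance", {
  # a 1000x stiffer trap pushes f_c above Nyquist: undersampling warning is
  # expected and irrelevant to the variance check
  tr <- simulate_trapped_bead(suppressWarnings(
    trap_sim_params(stiffness_kappa = 50, duration = 1, seed = 2)))
  expect_lt(var(tr$position_x), kbt_pN_nm(298.15) / 50 * 1.5)
  expect_lt(var(tr$position_x), 0.2)  # nm^2, vs 82.3 at the soft default
})

test_that("generators are deterministic under a fixed seed", {
  p <- trap_sim_params(duration = 0.2, seed = 7)
  expect_identical(simulate_trapped_bead(p)$position_x,
                   simulate_trapped_bead(p)$position_x)
  tp <- tether_sim_params(seed = 7)
  expect_identical(simulate_tether_pull(tp)$trace$position_x,
                   simulate_tether_pull(tp)$trace$position_x)
  sp <- tfm_sim_params(image_shape = c(64, 64), seed = 7,
                       traction_patches = list(
                         list(center = c(2.2, 3.2), radius = 0.8, peak = 100,
                              direction = c(1, 0)),
                         list(center = c(4.2, 3.2), radius = 0.8, peak = 100,
                              direction = c(-1, 0))))
  b1 <- simulate_tfm_dataset(sp, n_frames = 2)
  b2 <- simulate_tfm_dataset(sp, n_frames = 2)
  expect_identical(b1$reference, b2$reference)
  expect_identical(b1$frames, b2$frames)
})

test_that("invalid physical parameters are rejected", {
  expect_error(trap_sim_params(stiffness_kappa = -1), "positive")
  expect_error(trap_sim_params(viscosity = 0), "positive")
  expect_error(tether_sim_params(peak_force = 20, steady_state_force = 30),
               "peak_force")
  expect_error(tether_sim_params(noise_sd = -1), "noise_sd")
  expect_warning(trap_sim_params(sampling_rate = 100), "corner frequency")
})

test_that("noise-free tether curve hits PF and SSF exactly and encodes the protocol", {
  sim <- simulate_tether_pull(tether_sim_params(
    peak_force = 60, steady_state_force = 30, noise_sd = 0))
  f <- sim$ground_truth$force_true
  expect_identical(max(f), 60)
  hold <- sim$ground_truth$phase == "hold"
  expect_true(all(f[hold] == 30))
  # fibroblast protocol: 10 um at 0.1 um/s -> 100 s retraction in the stage
  expect_equal(sum(sim$ground_truth$phase == "retract") /
                 sim$trace$sampling_rate, 100, tolerance = 1e-3)
  # stage travels the full pull distance
  expect_equal(max(sim$trace$stage_position), 10)
})

test_that("noisy tether hold window mean stays within standard error", {
  sim <- simulate_tether_pull(tether_sim_params(noise_sd = 2, seed = 3,
                                                sampling_rate = 200))
  hold <- sim$ground_truth$phase == "hold"
  # N = 6000 samples -> SE ~0.026 pN; 0.5 pN is a generous bound
  expect_lt(abs(mean(sim$trace$position_x[hold] * 0.05) - 30), 0.5)
})

test_that("TFM bundle bookkeeping: ground truth integrates to the closed form", {
  sigma <- 0.8  # um; patch radius 1.6
  patches <- list(
    list(center = c(4, 6.4), radius = 2 * sigma, peak = 150,
         direction = c(1, 0)),
    list(center = c(8.8, 6.4), radius = 2 * sigma, peak = 150,
         direction = c(-1, 0)))
  b <- suppressWarnings(simulate_tfm_dataset(
    tfm_sim_params(image_shape = c(128, 128), traction_patches = patches,
                   seed = 5), n_frames = 2))
  # balanced dipole: whole-field integral ~ 0
  all_roi <- matrix(TRUE, 128, 128)
  expect_lt(net_force(b$truth_traction, all_roi)[["Fmag_nN"]],
            0.01 * patch_net_force(patches)[1, "Fx_nN"])
  # one pole: closed form peak * 2 pi sigma^2
  expect_equal(net_force(b$truth_traction, b$roi)[["Fmag_nN"]],
               150 * 2 * pi * sigma^2 * 1e-3, tolerance = 0.02)
})

test_that("zero traction yields identical bead positions in stressed and reference frames", {
  b <- simulate_tfm_dataset(tfm_sim_params(
    image_shape = c(64, 64), image_noise_sd = 0, seed = 8,
    traction_patches = list(
      list(center = c(3.2, 3.2), radius = 1, peak = 0, direction = c(1, 0)),
      list(center = c(3.2, 3.2), radius = 1, peak = 0, direction = c(-1, 0)))),
    n_frames = 1)
  expect_equal(b$frames[[1]], b$reference, tolerance = 1e-12)
  expect_true(all(b$bead_disp == 0))
})

test_that("rendered bead displacement matches the analytic field at bead centres", {
  b <- suppressWarnings(simulate_tfm_dataset(
    tfm_sim_params(image_shape = c(128, 128), seed = 12,
                   traction_patches = list(
                     list(center = c(4.8, 6.4), radius = 2, peak = 200,
                          direction = c(1, 0)),
                     list(center = c(8, 6.4), radius = 2, peak = 200,
                          direction = c(-1, 0)))), n_frames = 1))
  xg <- (0:127) * 0.1
  ux <- pracma::interp2(xg, xg, b$displacement$fx, b$beads[, 1], b$beads[, 2])
  keep <- !is.na(ux)
  # interpolation agreement < 0.05 px for the smooth field
  expect_lt(max(abs(ux[keep] - b$bead_disp[keep, "ux"])) / 0.1, 0.05)
})

test_that("tether trace positions encode force through the trap stiffness", {
  sim <- simulate_tether_pull(tether_sim_params(noise_sd = 0,
                                                stiffness_kappa = 0.08))
  expect_equal(max(sim$trace$position_x) * 0.08, 60, tolerance = 1e-10)
})
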