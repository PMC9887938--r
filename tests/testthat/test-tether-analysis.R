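test_that("baseline offset equals stiffness times mean displacement", {
  cal <- exact_calibration(kappa = 0.05)
  t <- seq(0, 1, by = 0.005)
  # +10 nm shift at 0.05 pN/nm -> 0.5 pN
  tr <- trap_trace(time = t, position_x = rep(10, length(t)))
  expect_equal(zero_baseline(tr, cal), 0.5, tolerance = 1e-12)
  # zero-mean Brownian segment -> offset ~ 0 within SE
  x <- withr::with_seed(3, rnorm(5000, sd = 9))
  tr0 <- trap_trace(time = seq_along(x) / 1000, position_x = x)
  expect_lt(abs(zero_baseline(tr0, cal)), 0.05 * 3 * 9 / sqrt(5000) + 0.05)
  expect_error(zero_baseline(numeric(0), cal), "empty")
})

test_that("force curve labels protocol phases within two samples of ground truth", {
  cal <- exact_calibration()
  for (fs in c(200, 1000, 5000)) {
    sim <- simulate_tether_pull(tether_sim_params(noise_sd = 0,
                                                  sampling_rate = fs))
    curve <- to_force_curve(sim$trace, cal, pull_protocol(preset = "fibroblast"))
    gt <- sim$ground_truth$phase
    bd_gt <- which(gt[-1] != gt[-length(gt)])
    bd <- which(curve$phase[-1] != curve$phase[-length(curve$phase)])
    expect_length(bd, length(bd_gt))
    expect_true(all(abs(bd - bd_gt) <= 2),
                label = sprintf("boundaries at %d Hz", fs))
  }
})

test_that("neuron preset yields a 40 s retraction, fibroblast 100 s", {
  cal <- exact_calibration()
  simn <- simulate_tether_pull(tether_sim_params(
    protocol = pull_protocol(preset = "neuron"), noise_sd = 0,
    relax_time = 2))
  cn <- to_force_curve(simn$trace, cal, pull_protocol(preset = "neuron"))
  expect_equal(sum(cn$phase == "retract") / simn$trace$sampling_rate, 40,
               tolerance = 0.01)
  expect_equal(protocol_phase_durations(pull_protocol(preset = "fibroblast"))[["retract"]],
               100)
})

test_that("a stationary stage yields a single phase and constant force", {
  cal <- exact_calibration()
  t <- seq(0, 2, by = 0.005)
  tr <- trap_trace(time = t, position_x = rep(40, length(t)),
                   stage_position = rep(1.5, length(t)))
  curve <- to_force_curve(tr, cal, pull_protocol(preset = "fibroblast"),
                          baseline = 0)
  expect_length(unique(curve$phase), 1)
  expect_true(all(curve$force == curve$force[1]))
  trn <- trap_trace(time = t, position_x = rep(40, length(t)))
  expect_error(to_force_curve(trn, cal, pull_protocol(preset = "fibroblast")),
               "stage")
})

test_that("metrics recover generator ground truth exactly without noise", {
  cal <- exact_calibration()
  sim <- simulate_tether_pull(tether_sim_params(
    peak_force = 60, steady_state_force = 30, noise_sd = 0))
  m <- extract_metrics(to_force_curve(sim$trace, cal,
                                      pull_protocol(preset = "fibroblast")))
  expect_equal(m$peak_force, 60, tolerance = 1e-9)
  expect_equal(m$steady_state_force, 30, tolerance = 1e-9)
  expect_length(m$qc_flags, 0)
})

test_that("noisy pulls: SSF unbiased within SE, PF carries bounded max-statistic bias", {
  cal <- exact_calibration()
  res <- sapply(1:12, function(s) {
    sim <- simulate_tether_pull(tether_sim_params(noise_sd = 2, seed = s))
    m <- extract_metrics(to_force_curve(sim$trace, cal,
                                        pull_protocol(preset = "fibroblast")))
    c(m$peak_force, m$steady_state_force)
  })
  expect_lt(abs(mean(res[2, ]) - 30), 0.5)
  expect_true(all(res[1, ] >= 60))         # max statistic never below truth
  expect_true(all(res[1, ] <= 60 + 4 * 2)) # and bounded by PF + 4 sd
})

test_that("metric extraction is invariant to shifting the raw trace", {
  cal <- exact_calibration()
  sim <- simulate_tether_pull(tether_sim_params(noise_sd = 1, seed = 9))
  tr2 <- sim$trace
  tr2$position_x <- tr2$position_x + 25  # nm shift: absorbed by the baseline
  proto <- pull_protocol(preset = "fibroblast")
  m1 <- extract_metrics(to_force_curve(sim$trace, cal, proto))
  m2 <- extract_metrics(to_force_curve(tr2, cal, proto))
  expect_equal(m2$peak_force, m1$peak_force, tolerance = 1e-9)
  expect_equal(m2$steady_state_force, m1$steady_state_force, tolerance = 1e-9)
})

test_that("lost tethers are flagged, not dropped", {
  cal <- exact_calibration()
  sim <- simulate_tether_pull(tether_sim_params(
    peak_force = 1e-9, steady_state_force = 0, noise_sd = 0,
    attachment_stiffness = 1e-6))
  m <- extract_metrics(to_force_curve(sim$trace, cal,
                                      pull_protocol(preset = "fibroblast")))
  expect_true("tether_lost" %in% m$qc_flags)
  expect_equal(m$steady_state_force, 0, tolerance = 1e-9)
})

test_that("batch processing records per-pull errors and keeps going", {
  cal <- exact_calibration()
  proto <- pull_protocol(preset = "fibroblast")
  pulls <- lapply(1:3, function(s)
    simulate_tether_pull(tether_sim_params(noise_sd = 0, seed = s))$trace)
  names(pulls) <- paste0("p", 1:3)
  tab <- batch_pulls(pulls, cal, proto, group = "gel")
  expect_equal(nrow(tab), 3)
  expect_true(all(abs(tab$PF_pN - 60) < 1e-6))
  # one corrupt input: row-level error, batch continues
  bad <- c(pulls[1:2], list(p3 = "no/such/file.tsv"))
  tab2 <- batch_pulls(bad, cal, proto)
  expect_equal(sum(is.na(tab2$error)), 2)
  expect_match(tab2$error[3], "trace")
  # empty input: empty table, no error
  expect_equal(nrow(batch_pulls(list(), cal, proto)), 0)
})
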