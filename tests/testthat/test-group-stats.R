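test_that("exact Mann-Whitney matches the spec's enumerable example", {
  r <- mann_whitney(c(1.1, 2.3), c(3.7, 4.2))
  expect_equal(r$statistic, 0)
  expect_equal(r$p_value, 1 / 3, tolerance = 1e-12)
})

test_that("exact Mann-Whitney agrees with brute-force enumeration, ties included", {
  cases <- withr::with_seed(10, {
    lapply(1:25, function(i) {
      n <- sample(2:8, 1); m <- sample(2:8, 1)
      if (i %% 2 == 0) list(a = sample(1:5, n, TRUE), b = sample(1:5, m, TRUE))
      else list(a = rnorm(n), b = rnorm(m))
    })
  })
  for (cs in cases) {
    expect_equal(mann_whitney(cs$a, cs$b, mode = "exact")$p_value,
                 mw_bruteforce_p(cs$a, cs$b), tolerance = 1e-12)
  }
})

test_that("exact Mann-Whitney agrees with the reference implementation without ties", {
  withr::with_seed(2, {
    for (i in 1:10) {
      a <- rnorm(sample(3:9, 1)); b <- rnorm(sample(3:9, 1))
      expect_equal(mann_whitney(a, b, mode = "exact")$p_value,
                   stats::wilcox.test(a, b, exact = TRUE)$p.value,
                   tolerance = 1e-12)
    }
  })
})

test_that("Mann-Whitney handles degenerate and large-sample inputs", {
  r <- mann_whitney(rep(2, 5), rep(2, 7))
  expect_equal(r$p_value, 1)
  expect_match(r$method_detail, "degenerate")
  # identical multisets: maximal p
  expect_equal(mann_whitney(c(1, 2, 3), c(1, 2, 3))$p_value, 1)
  # auto mode switches to the normal approximation beyond n + m = 25
  big <- withr::with_seed(4, mann_whitney(rnorm(20), rnorm(20)))
  expect_match(big$method_detail, "normal approximation")
  expect_true(big$p_value >= 0 && big$p_value <= 1)
  expect_error(mann_whitney(numeric(0), 1:3), "non-empty")
})

test_that("Kruskal-Wallis reproduces the hand-computed rank statistic", {
  r <- kruskal_wallis(list(a = c(1, 2, 3), b = c(4, 5, 6), c = c(7, 8, 9)))
  expect_equal(r$statistic, 7.2, tolerance = 1e-12)
  expect_equal(r$df, 2)
  expect_equal(r$p_value, pchisq(7.2, 2, lower.tail = FALSE), tolerance = 1e-12)
  # identical groups: H = 0, p = 1
  r0 <- kruskal_wallis(list(a = rep(1, 4), b = rep(1, 4)))
  expect_equal(r0$statistic, 0)
  expect_equal(r0$p_value, 1)
})

test_that("Kruskal-Wallis matches the reference implementation under ties", {
  withr::with_seed(7, {
    for (i in 1:8) {
      g <- lapply(1:3, function(j) round(rnorm(10, j * 0.3), 1))
      names(g) <- letters[1:3]
      mine <- kruskal_wallis(g)
      ref <- stats::kruskal.test(unlist(g), factor(rep(1:3, each = 10)))
      expect_equal(mine$statistic, unname(ref$statistic), tolerance = 1e-12)
      expect_equal(mine$p_value, ref$p.value, tolerance = 1e-12)
    }
  })
})

test_that("H is invariant under strictly monotone transforms", {
  g <- withr::with_seed(8, list(a = rexp(9), b = rexp(9) * 2, c = rexp(9)))
  h1 <- kruskal_wallis(g)$statistic
  h2 <- kruskal_wallis(lapply(g, log))$statistic
  h3 <- kruskal_wallis(lapply(g, function(v) v^3))$statistic
  expect_equal(h2, h1, tolerance = 1e-12)
  expect_equal(h3, h1, tolerance = 1e-12)
})

test_that("both tests hold their nominal type-I error under the null", {
  reps <- 2000
  rej <- withr::with_seed(123, {
    mw <- mean(replicate(reps,
      mann_whitney(rnorm(8), rnorm(8), mode = "exact")$p_value <= 0.05))
    kw <- mean(replicate(reps, {
      kruskal_wallis(list(a = rnorm(10), b = rnorm(10), c = rnorm(10)))$p_value <= 0.05
    }))
    c(mw, kw)
  })
  expect_lt(abs(rej[1] - 0.05), 0.02)
  expect_lt(abs(rej[2] - 0.05), 0.02)
})

test_that("post hoc comparisons separate a shifted group and control multiplicity", {
  g <- withr::with_seed(11, list(soft = rnorm(20), mid = rnorm(20),
                                 far = rnorm(20) + 5))  # 5 pooled SDs away
  for (method in c("dunn_holm", "tukey_on_ranks")) {
    ph <- posthoc_pairwise(g, method = method)
    expect_equal(nrow(ph), 3)  # C(3,2)
    sig <- ph$p_adjusted < 0.05
    far_pairs <- ph$group1 == "far" | ph$group2 == "far"
    expect_true(all(sig[far_pairs]), label = method)
    expect_false(any(sig[!far_pairs]), label = method)
  }
  # adjusted never below unadjusted (Dunn/Holm)
  ph2 <- posthoc_pairwise(withr::with_seed(12, list(a = rnorm(10),
                                                    b = rnorm(10),
                                                    c = rnorm(10))))
  expect_true(all(ph2$p_adjusted >= ph2$p_unadjusted - 1e-12))
  # three identical groups: nothing significant
  same <- list(a = c(1, 2, 3, 4), b = c(1, 2, 3, 4), c = c(1, 2, 3, 4))
  expect_true(all(posthoc_pairwise(same)$p_adjusted >= 0.9))
  expect_error(posthoc_pairwise(list(a = 1:3, b = 4:6)), "k >= 3")
})

test_that("compare_conditions runs a design over a metrics table and survives bad rows", {
  tab <- withr::with_seed(13, data.frame(
    SSF_pN = c(rnorm(30, 30, 8), rnorm(30, 20, 8)),
    substrate = rep(c("1kPa", "glass"), each = 30)))
  rep1 <- compare_conditions(tab, list(
    list(metric = "SSF_pN", grouping = "substrate", test = "mann_whitney"),
    list(metric = "missing_col", grouping = "substrate", test = "mann_whitney")))
  expect_lt(rep1$results[[1]]$p_value, 0.05)
  expect_match(rep1$results[[2]]$error, "missing")
  # empty design -> empty report
  expect_length(compare_conditions(tab, list())$results, 0)
  # report serializes
  path <- withr::local_tempfile(fileext = ".json")
  write_report(rep1, path)
  expect_true(file.exists(path))
  parsed <- jsonlite::read_json(path)
  expect_length(parsed, 2)
})
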