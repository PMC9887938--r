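#' Grouped sample container
#'
#' @param values named list mapping group label to a numeric vector of
#'   measurements (tether forces in pN, net forces in nN, ...)
#' @param metric metric name (e.g. "SSF_pN")
#' @param units unit string
#' @return object of class `grouped_sample`
#' @export
grouped_sample <- function(values, metric = "value", units = "") {
  stopifnot(is.list(values), length(values) >= 2, !is.null(names(values)))
  for (g in names(values)) {
    v <- values[[g]]
    if (length(v) == 0 || !is.numeric(v) || any(!is.finite(v)))
      stop("group '", g, "' must be a non-empty finite numeric vector")
  }
  structure(list(values = values, metric = metric, units = units),
            class = "grouped_sample")
}

# mid-ranks of the pooled sample and the tie-group sizes
pooled_ranks <- function(pooled) {
  r <- rank(pooled, ties.method = "average")
  t_sizes <- as.numeric(table(pooled))
  list(ranks = r, ties = t_sizes[t_sizes > 1])
}

# exact null distribution of the rank sum of the first group, over all
# C(N, n) equally likely assignments, by the shift algorithm (dynamic
# programme over doubled mid-ranks, which are integers even with ties).
# Returns support (doubled rank sums) and counts.
ranksum_distribution <- function(ranks2, n) {
  N <- length(ranks2)
  maxsum <- sum(sort(ranks2, decreasing = TRUE)[seq_len(n)])
  # counts[m + 1, s + 1] = number of m-subsets with doubled rank sum s
  counts <- matrix(0, n + 1, maxsum + 1)
  counts[1, 1] <- 1
  for (r in ranks2) {
    upper <- min(n, N)  # process items one by one, update m descending
    for (m in upper:1) {
      nz <- which(counts[m, ] > 0)
      if (length(nz) == 0) next
      tgt <- nz + r
      keep <- tgt <= maxsum + 1
      counts[m + 1, tgt[keep]] <- counts[m + 1, tgt[keep]] + counts[m, nz[keep]]
    }
  }
  s <- which(counts[n + 1, ] > 0)
  list(support = s - 1, counts = counts[n + 1, s])
}

#' Mann-Whitney U test (exact or normal approximation)
#'
#' Two-tailed rank-sum test of two independent groups, implemented from
#' first principles. In exact mode the full permutation distribution of the
#' rank sum (hence of U) is computed by a shift-algorithm dynamic programme
#' over mid-ranks, so ties are handled exactly over all distinct
#' label arrangements; the two-tailed p is `2 min(P(U <= u), P(U >= u))`
#' capped at 1. In normal mode the tie-corrected variance and a continuity
#' correction are used. Exact mode requires n + m <= 25 and falls back to
#' the normal approximation beyond that (noted in the result).
#'
#' @param a,b numeric vectors (both non-empty)
#' @param mode "exact", "normal", or "auto" (exact when n + m <= 25)
#' @return object of class `stat_result` with fields `test`, `statistic`
#'   (U of group a), `p_value`, `method_detail`, `groups`
#' @examples
#' mann_whitney(c(1.1, 2.3), c(3.7, 4.2))$p_value # 1/3
#' @export
mann_whitney <- function(a, b, mode = c("auto", "exact", "normal")) {
  mode <- match.arg(mode)
  a <- as.numeric(a); b <- as.numeric(b)
  if (length(a) == 0 || length(b) == 0) stop("both groups must be non-empty")
  n <- length(a); m <- length(b); N <- n + m
  pooled <- c(a, b)
  note <- NULL
  if (length(unique(pooled)) == 1) {
    return(structure(list(test = "Mann-Whitney U", statistic = n * m / 2,
                          p_value = 1,
                          method_detail = "degenerate: all values identical",
                          groups = c(n = n, m = m)),
                     class = "stat_result"))
  }
  if (mode == "auto") mode <- if (N <= 25) "exact" else "normal"
  if (mode == "exact" && N > 25) {
    mode <- "normal"
    note <- "exact mode unavailable for n + m > 25; normal approximation used"
  }
  pr <- pooled_ranks(pooled)
  R1 <- sum(pr$ranks[seq_len(n)])
  U <- R1 - n * (n + 1) / 2
  if (mode == "exact") {
    dist <- ranksum_distribution(round(2 * pr$ranks), n)
    total <- sum(dist$counts)
    s_obs <- round(2 * R1)
    p_le <- sum(dist$counts[dist$support <= s_obs]) / total
    p_ge <- sum(dist$counts[dist$support >= s_obs]) / total
    p <- min(1, 2 * min(p_le, p_ge))
    detail <- "exact (shift-algorithm permutation distribution, mid-ranks)"
  } else {
    mu <- n * m / 2
    tie_term <- if (length(pr$ties)) sum(pr$ties^3 - pr$ties) else 0
    sigma2 <- n * m / 12 * ((N + 1) - tie_term / (N * (N - 1)))
    z <- (U - mu - sign(U - mu) * 0.5) / sqrt(sigma2)
    p <- min(1, 2 * stats::pnorm(-abs(z)))
    detail <- "normal approximation, tie-corrected variance, continuity correction"
  }
  if (!is.null(note)) detail <- paste0(detail, "; ", note)
  structure(list(test = "Mann-Whitney U", statistic = U, p_value = p,
                 method_detail = detail, groups = c(n = n, m = m)),
            class = "stat_result")
}

#' Kruskal-Wallis rank test
#'
#' H = 12 / (N (N + 1)) sum n_i Rbar_i^2 - 3 (N + 1), divided by the tie
#' correction 1 - sum(t^3 - t) / (N^3 - N); p from the chi-square
#' distribution with k - 1 degrees of freedom. Implemented from first
#' principles (the built-in test serves as an independent cross-check in the
#' package's tests, never as the implementation).
#'
#' @param groups a [grouped_sample()] or named list of numeric vectors
#' @return a `stat_result` with fields `test`, `statistic` (H, tie
#'   corrected), `p_value`, `df`, `method_detail`
#' @examples
#' kruskal_wallis(list(a = 1:3, b = 4:6, c = 7:9))$statistic # 7.2
#' @export
kruskal_wallis <- function(groups) {
  if (!inherits(groups, "grouped_sample")) groups <- grouped_sample(groups)
  vals <- groups$values
  k <- length(vals)
  pooled <- unlist(vals, use.names = FALSE)
  N <- length(pooled)
  if (length(unique(pooled)) == 1) {
    return(structure(list(test = "Kruskal-Wallis", statistic = 0,
                          p_value = 1, df = k - 1,
                          method_detail = "degenerate: all values identical",
                          groups = lengths(vals)),
                     class = "stat_result"))
  }
  pr <- pooled_ranks(pooled)
  gi <- rep(seq_len(k), lengths(vals))
  Rbar <- tapply(pr$ranks, gi, mean)
  n_i <- lengths(vals)
  H <- 12 / (N * (N + 1)) * sum(n_i * Rbar^2) - 3 * (N + 1)
  tie_corr <- 1 - (if (length(pr$ties)) sum(pr$ties^3 - pr$ties) else 0) /
    (N^3 - N)
  H <- H / tie_corr
  p <- stats::pchisq(H, df = k - 1, lower.tail = FALSE)
  structure(list(test = "Kruskal-Wallis", statistic = H, p_value = p,
                 df = k - 1,
                 method_detail = sprintf("chi-square approximation, %s",
                                         if (tie_corr < 1) "tie corrected" else "no ties"),
                 groups = n_i),
            class = "stat_result")
}

#' @export
print.stat_result <- function(x, ...) {
  cat(sprintf("%s: statistic = %.4g, p = %.4g (%s)\n",
              x$test, x$statistic, x$p_value, x$method_detail))
  if (!is.null(x$posthoc)) {
    cat("post hoc:\n")
    print(x$posthoc, row.names = FALSE)
  }
  invisible(x)
}

#' Pairwise post hoc comparisons after a Kruskal-Wallis test
#'
#' Two methods. `"dunn_holm"` (default): Dunn's z statistics on the pooled
#' mid-ranks with the tie-corrected variance, two-sided p-values adjusted by
#' Holm's step-down procedure. `"tukey_on_ranks"`: Tukey's HSD applied to
#' the rank-transformed data (an ANOVA on ranks followed by
#' `TukeyHSD`), the literal reading of a "Tukey post hoc" after a rank
#' test. Both control the family-wise error rate at the nominal level.
#'
#' @param groups a [grouped_sample()] or named list (k >= 3 groups)
#' @param method "dunn_holm" or "tukey_on_ranks"
#' @return data.frame with columns `group1`, `group2`, `statistic`,
#'   `p_unadjusted` (NA for tukey_on_ranks, which adjusts internally),
#'   `p_adjusted`
#' @export
posthoc_pairwise <- function(groups, method = c("dunn_holm", "tukey_on_ranks")) {
  method <- match.arg(method)
  if (!inherits(groups, "grouped_sample")) groups <- grouped_sample(groups)
  vals <- groups$values
  k <- length(vals)
  if (k < 3) stop("post hoc requires k >= 3 groups; use mann_whitney for two")
  pooled <- unlist(vals, use.names = FALSE)
  N <- length(pooled)
  gi <- factor(rep(names(vals), lengths(vals)), levels = names(vals))
  pairs <- utils::combn(names(vals), 2)
  if (method == "dunn_holm") {
    pr <- pooled_ranks(pooled)
    Rbar <- tapply(pr$ranks, gi, mean)
    n_i <- stats::setNames(lengths(vals), names(vals))
    tie_term <- if (length(pr$ties)) sum(pr$ties^3 - pr$ties) else 0
    base_var <- N * (N + 1) / 12 - tie_term / (12 * (N - 1))
    z <- p_raw <- numeric(ncol(pairs))
    for (j in seq_len(ncol(pairs))) {
      g1 <- pairs[1, j]; g2 <- pairs[2, j]
      se <- sqrt(base_var * (1 / n_i[[g1]] + 1 / n_i[[g2]]))
      z[j] <- (Rbar[[g1]] - Rbar[[g2]]) / se
      p_raw[j] <- 2 * stats::pnorm(-abs(z[j]))
    }
    out <- data.frame(group1 = pairs[1, ], group2 = pairs[2, ],
                      statistic = z, p_unadjusted = p_raw,
                      p_adjusted = stats::p.adjust(p_raw, method = "holm"),
                      stringsAsFactors = FALSE)
  } else {
    rk <- rank(pooled, ties.method = "average")
    fit <- stats::aov(rk ~ gi)
    tk <- stats::TukeyHSD(fit)$gi
    nm <- strsplit(rownames(tk), "-", fixed = TRUE)
    out <- data.frame(group1 = vapply(nm, `[`, "", 2),
                      group2 = vapply(nm, `[`, "", 1),
                      statistic = tk[, "diff"],
                      p_unadjusted = NA_real_,
                      p_adjusted = tk[, "p adj"],
                      stringsAsFactors = FALSE)
    rownames(out) <- NULL
  }
  attr(out, "method") <- method
  out
}

#' Run a set of planned group comparisons on a metrics table
#'
#' For each design row, splits `metrics[[metric]]` by `metrics[[grouping]]`
#' and runs the requested test: `"mann_whitney"` (2 groups),
#' `"kruskal_wallis"` or `"kruskal_wallis+posthoc"` (>= 2 groups, the latter
#' adding pairwise post hoc comparisons). Missing metrics/groups produce a
#' row-level error entry; the report continues.
#'
#' @param metrics data.frame of per-observation metrics (one row per pull or
#'   per cell)
#' @param design list of design rows, each a list with `metric`, `grouping`,
#'   `test`, and optionally `posthoc_method`, `subset` (logical vector)
#' @return object of class `comparison_report`: list of per-row results
#'   (each a `stat_result` or an error record)
#' @export
compare_conditions <- function(metrics, design) {
  stopifnot(is.data.frame(metrics), is.list(design))
  results <- lapply(design, function(row) {
    tryCatch({
      stopifnot(!is.null(row$metric), !is.null(row$grouping),
                !is.null(row$test))
      if (!row$metric %in% names(metrics))
        stop("metric column missing: ", row$metric)
      if (!row$grouping %in% names(metrics))
        stop("grouping column missing: ", row$grouping)
      df <- metrics
      if (!is.null(row$subset)) df <- df[row$subset, , drop = FALSE]
      df <- df[is.finite(df[[row$metric]]), , drop = FALSE]
      vals <- split(df[[row$metric]], df[[row$grouping]])
      vals <- vals[lengths(vals) > 0]
      gs <- grouped_sample(vals, metric = row$metric)
      res <- switch(row$test,
        mann_whitney = {
          if (length(vals) != 2) stop("mann_whitney needs exactly 2 groups")
          mann_whitney(vals[[1]], vals[[2]])
        },
        kruskal_wallis = kruskal_wallis(gs),
        `kruskal_wallis+posthoc` = {
          kw <- kruskal_wallis(gs)
          kw$posthoc <- posthoc_pairwise(
            gs, method = if (is.null(row$posthoc_method)) "dunn_holm"
                         else row$posthoc_method)
          kw
        },
        stop("unknown test: ", row$test))
      res$metric <- row$metric
      res$grouping <- row$grouping
      res
    }, error = function(e) {
      list(error = conditionMessage(e), metric = row$metric,
           grouping = row$grouping)
    })
  })
  structure(list(results = results, n_design = length(design)),
            class = "comparison_report")
}

#' Write a comparison report as JSON plus a text summary
#'
#' @param report a `comparison_report`
#' @param json_path output JSON path (or NULL to skip)
#' @return the report, invisibly
#' @export
write_report <- function(report, json_path = NULL) {
  stopifnot(inherits(report, "comparison_report"))
  ser <- lapply(report$results, function(r) {
    r <- unclass(r)
    if (!is.null(r$posthoc)) r$posthoc <- as.data.frame(r$posthoc)
    r
  })
  if (!is.null(json_path))
    jsonlite::write_json(ser, json_path, auto_unbox = TRUE, digits = NA,
                         force = TRUE)
  invisible(report)
}

#' @export
print.comparison_report <- function(x, ...) {
  cat(sprintf("comparison report: %d design row(s)\n", x$n_design))
  for (r in x$results) {
    if (!is.null(r$error)) {
      cat(sprintf("  [%s by %s] ERROR: %s\n", r$metric, r$grouping, r$error))
    } else {
      cat(sprintf("  [%s by %s] ", r$metric, r$grouping))
      print(r)
    }
  }
  invisible(x)
}
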