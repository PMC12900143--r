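#' Shapiro-Wilk normality screen
#'
#' Used to justify the non-parametric tests downstream: a sample is declared
#' `"non-normal"` when the Shapiro-Wilk p-value falls below `alpha`.
#'
#' @param x Numeric sample (n >= 3, non-constant).
#' @param alpha Significance level for the verdict.
#' @return A tibble `statistic` (W), `p_value`, `verdict`, `n`.
#' @export
normality_check <- function(x, alpha = 0.05) {
  x <- x[!is.na(x)]
  if (length(x) < 3)
    abort("Normality check needs at least 3 observations.",
          class = "neuroplay_sample_error")
  if (diff(range(x)) == 0)
    abort("Constant sample: normality test undefined.",
          class = "neuroplay_sample_error")
  if (length(x) > 5000) x <- x[seq(1, length(x), length.out = 5000)]
  s <- shapiro.test(x)
  tibble(test = "shapiro_wilk", statistic = unname(s$statistic),
         p_value = s$p.value,
         verdict = if (s$p.value < alpha) "non-normal" else "normal",
         n = length(x))
}

#' Mann-Whitney U (Wilcoxon rank-sum) group comparison
#'
#' Two-sided rank-sum comparison with midranks for ties. The exact null
#' distribution is enumerated when both samples are tie-free and
#' `n_x * n_y <= 64`; otherwise the normal approximation with tie and
#' continuity corrections is used. The reported `W` follows the common R
#' convention (rank sum of `x` minus its minimum), so tabulated study values
#' are directly comparable.
#'
#' @param x,y Numeric samples (missing values dropped and counted).
#' @param alternative Sidedness (default two-sided).
#' @return A `group_comparison` tibble: test, statistic, p-value, per-group n,
#'   missing counts, means and SDs.
#' @export
mann_whitney <- function(x, y, alternative = "two.sided") {
  miss <- c(sum(is.na(x)), sum(is.na(y)))
  x <- x[!is.na(x)]; y <- y[!is.na(y)]
  if (length(x) < 1 || length(y) < 1)
    abort("Both samples must contain at least one observation.",
          class = "neuroplay_sample_error")
  ties <- anyDuplicated(c(x, y)) > 0
  use_exact <- !ties && length(x) * length(y) <= 64
  if (diff(range(c(x, y))) == 0) {
    # complete degeneracy: every ranking equally likely, no evidence of shift
    wt <- list(statistic = c(W = length(x) * length(y) / 2), p.value = 1)
  } else {
    wt <- suppressWarnings(
      wilcox.test(x, y, alternative = alternative, exact = use_exact,
                  correct = TRUE))
  }
  res <- tibble(test = "mann_whitney_u",
                statistic = unname(wt$statistic),
                statistic_name = "W",
                p_value = wt$p.value,
                method = if (use_exact) "exact" else "normal_approximation",
                n_x = length(x), n_y = length(y),
                missing_x = miss[1], missing_y = miss[2],
                mean_x = mean(x), sd_x = if (length(x) > 1) sd(x) else 0,
                mean_y = mean(y), sd_y = if (length(y) > 1) sd(y) else 0)
  class(res) <- c("group_comparison", class(res))
  res
}

#' Seeded two-sample permutation test on the mean difference
#'
#' The observed statistic is the standardised difference of group means
#' (difference divided by its pooled-variance standard error). Group labels
#' are randomly reassigned `n_perm` times and the two-sided p-value uses the
#' add-one estimator `(1 + #{|Z*| >= |Z|}) / (n_perm + 1)`, so the smallest
#' attainable p is `1 / (n_perm + 1)`.
#'
#' @param x,y Numeric samples (missing values dropped and counted).
#' @param n_perm Number of permutations (>= 99).
#' @param seed Integer seed for the label shuffles.
#' @return A `group_comparison` tibble with statistic `Z`.
#' @export
permutation_test <- function(x, y, n_perm = 10000, seed = 1L) {
  miss <- c(sum(is.na(x)), sum(is.na(y)))
  x <- x[!is.na(x)]; y <- y[!is.na(y)]
  if (length(x) < 1 || length(y) < 1)
    abort("Both samples must contain at least one observation.",
          class = "neuroplay_sample_error")
  if (n_perm < 99)
    abort("Use at least 99 permutations.", class = "neuroplay_parameter_error")
  nx <- length(x); ny <- length(y); pooled <- c(x, y)
  zstat <- function(px, py) {
    vp <- (sum((px - mean(px))^2) + sum((py - mean(py))^2)) / (nx + ny - 2)
    if (vp == 0) return(NA_real_)
    (mean(px) - mean(py)) / sqrt(vp * (1 / nx + 1 / ny))
  }
  z_obs <- zstat(x, y)
  if (is.na(z_obs))
    abort("Pooled variance is zero: permutation statistic undefined.",
          class = "neuroplay_degenerate_error")
  z_perm <- withr::with_seed(seed, {
    vapply(seq_len(n_perm), function(i) {
      idx <- sample.int(nx + ny, nx)
      zstat(pooled[idx], pooled[-idx])
    }, numeric(1))
  })
  z_perm[is.na(z_perm)] <- Inf   # degenerate shuffles count as extreme
  p <- (1 + sum(abs(z_perm) >= abs(z_obs))) / (n_perm + 1)
  res <- tibble(test = "permutation", statistic = z_obs,
                statistic_name = "Z", p_value = p,
                method = sprintf("%d permutations, seed %d", n_perm, seed),
                n_x = nx, n_y = ny, missing_x = miss[1], missing_y = miss[2],
                mean_x = mean(x), sd_x = if (nx > 1) sd(x) else 0,
                mean_y = mean(y), sd_y = if (ny > 1) sd(y) else 0)
  class(res) <- c("group_comparison", class(res))
  res
}

#' Study-style summary of a performance metric
#'
#' Pools all metric windows of all participants per group (so n = number of
#' participants times windows per event, missing windows counted separately),
#' reports mean, SD and missing counts per group, and attaches the
#' Mann-Whitney comparison plus per-group normality screens.
#'
#' @param pm_cohort Stacked [performance_metrics()] outputs with
#'   `participant` and `group` columns.
#' @param metric Metric name.
#' @param event Event id.
#' @param groups Two group labels, experimental first.
#' @return A list with `summary` (one row per group) and `comparison`
#'   (a `group_comparison`).
#' @export
summarize_pm <- function(pm_cohort, metric, event,
                         groups = c("experimental", "control")) {
  if (!metric %in% pm_metric_names)
    abort(paste0("Unknown metric '", metric, "'."), class = "neuroplay_key_error")
  d <- pm_cohort |> filter(.data$metric == !!metric, .data$event == !!event)
  if (nrow(d) == 0)
    abort("No data for that metric/event.", class = "neuroplay_empty_group_error")
  pools <- lapply(groups, function(g) d$value[d$group == g])
  summary <- tibble(
    group = groups,
    metric = metric, event = event,
    n = vapply(pools, length, integer(1)),
    n_participants = vapply(groups, function(g)
      length(unique(d$participant[d$group == g])), integer(1)),
    missing = vapply(pools, function(v) sum(is.na(v)), integer(1)),
    mean = vapply(pools, function(v) mean(v, na.rm = TRUE), numeric(1)),
    sd = vapply(pools, function(v) sd(v, na.rm = TRUE), numeric(1)))
  comparison <- mann_whitney(pools[[1]], pools[[2]])
  normality <- lapply(pools, function(v) {
    tryCatch(normality_check(v[!is.na(v)]), error = function(e) NULL)
  })
  list(summary = summary, comparison = comparison,
       normality = setNames(normality, groups))
}

#' Aggregate 7-point Likert responses into sentiment percentages
#'
#' Default mapping: 1-3 negative, 4 neutral, 5-7 positive.
#'
#' @param responses A survey tibble from [generate_survey()] (long or wide),
#'   or a numeric vector of responses for a single question.
#' @param mapping Named list with integer vectors `negative`, `neutral`,
#'   `positive` partitioning 1:7.
#' @param by Extra grouping columns (e.g. `"group"`), for tibble input.
#' @return A tibble per question (and `by` groups) with `pct_negative`,
#'   `pct_neutral`, `pct_positive` summing to 100.
#' @export
likert_sentiment <- function(responses,
                             mapping = list(negative = 1:3, neutral = 4L,
                                            positive = 5:7),
                             by = character()) {
  if (!setequal(unlist(mapping), 1:7))
    abort("`mapping` must partition the 1-7 scale.",
          class = "neuroplay_parameter_error")
  pct <- function(v) {
    if (anyNA(v) || any(!v %in% 1:7))
      abort("Responses must lie in 1..7.", class = "neuroplay_validation_error")
    c(pct_negative = 100 * mean(v %in% mapping$negative),
      pct_neutral = 100 * mean(v %in% mapping$neutral),
      pct_positive = 100 * mean(v %in% mapping$positive))
  }
  if (is.numeric(responses)) {
    return(as_tibble(as.list(pct(responses))))
  }
  qcols <- setdiff(names(responses), c("participant", "group", by))
  long <- tidyr::pivot_longer(responses, all_of(qcols),
                              names_to = "question", values_to = "response")
  long |>
    group_by(across(all_of(c(by, "question")))) |>
    summarise(as_tibble(as.list(pct(.data$response))), .groups = "drop")
}

#' Optional multiplicity adjustment for a table of comparisons
#'
#' Raw p-values are reported by default throughout the package; when a
#' family-wise correction is wanted, this appends an adjusted column via
#' [stats::p.adjust()] (Holm by default).
#'
#' @param comparisons A tibble with a p-value column (e.g. stacked
#'   [tidy()][tidy.group_comparison] outputs or the pipeline's summary
#'   table).
#' @param method Adjustment method passed to [stats::p.adjust()].
#' @param column Name of the p-value column.
#' @return The input with an added `p_adjusted` column.
#' @export
adjust_pvalues <- function(comparisons, method = "holm",
                           column = "p_value") {
  if (!column %in% names(comparisons))
    abort(paste0("No column '", column, "' to adjust."),
          class = "neuroplay_key_error")
  comparisons$p_adjusted <- stats::p.adjust(comparisons[[column]], method)
  comparisons
}

#' @export
print.group_comparison <- function(x, ...) {
  cat(sprintf("%s: %s = %.4g, p = %.4g (%s)\n  n = %d vs %d (missing %d | %d), mean %0.3f +/- %0.3f vs %0.3f +/- %0.3f\n",
              x$test, x$statistic_name, x$statistic, x$p_value, x$method,
              x$n_x, x$n_y, x$missing_x, x$missing_y,
              x$mean_x, x$sd_x, x$mean_y, x$sd_y))
  invisible(x)
}

#' Tidy a group comparison
#'
#' @param x A `group_comparison`.
#' @param ... Unused.
#' @return A one-row tibble with `statistic`, `p.value`, `method` and group
#'   summaries.
#' @exportS3Method generics::tidy
tidy.group_comparison <- function(x, ...) {
  tibble(statistic = x$statistic, p.value = x$p_value,
         method = paste(x$test, x$method, sep = ": "),
         estimate = x$mean_x - x$mean_y,
         n1 = x$n_x, n2 = x$n_y)
}

#' @rdname tidy.group_comparison
#' @exportS3Method generics::glance
glance.group_comparison <- function(x, ...) tidy(x, ...)

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance
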