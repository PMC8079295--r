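test_result <- function(method, statistic, p_value, n, p_adjusted = NA_real_,
                        family = NA_character_, term = NA_character_) {
  tibble::tibble(method = method, term = term, statistic = statistic,
                 p_value = p_value, p_adjusted = p_adjusted, n = n,
                 family = family)
}

#' One-sample Wilcoxon signed-rank test
#'
#' Two-sided test of symmetry about `mu`, used for baseline side preference
#' against the 50 % null. Exact signed-rank distribution for n <= 25 without
#' ties or zeros; normal approximation with continuity correction otherwise.
#'
#' @param values Numeric observations (e.g. per-fish occupancy percentages).
#' @param mu Null location.
#' @return A one-row test-result tibble.
#' @export
one_sample_wilcoxon <- function(values, mu = 50) {
  d <- values - mu
  if (all(d == 0)) stop("degenerate test: all values equal mu", call. = FALSE)
  has_ties <- anyDuplicated(abs(d[d != 0])) > 0 || any(d == 0)
  ht <- suppressWarnings(stats::wilcox.test(
    values, mu = mu, alternative = "two.sided",
    exact = length(values) <= 25 && !has_ties, correct = TRUE))
  test_result("one-sample Wilcoxon signed-rank", unname(ht$statistic),
              ht$p.value, length(values))
}

#' Friedman rank-sum test
#'
#' Tests for any change across intervals of a repeatedly measured metric.
#' Rows are fish (blocks), columns are intervals (treatments); ranking within
#' fish uses average ranks for ties.
#'
#' @param mat Complete numeric matrix, fish x interval.
#' @return A one-row test-result tibble (chi-squared statistic).
#' @export
friedman_test <- function(mat) {
  mat <- as.matrix(mat)
  if (anyNA(mat)) stop("Friedman test requires a complete matrix", call. = FALSE)
  if (nrow(mat) < 2 || ncol(mat) < 2) {
    stop("need >= 2 fish and >= 2 intervals", call. = FALSE)
  }
  ht <- stats::friedman.test(mat)
  stat <- unname(ht$statistic)
  p <- ht$p.value
  if (!is.finite(stat)) {
    # every within-fish ranking fully tied: no evidence of any interval effect
    stat <- 0
    p <- 1
  }
  out <- test_result("Friedman rank-sum", stat, p, nrow(mat))
  out$df <- unname(ht$parameter)
  out
}

#' Paired Wilcoxon tests vs baseline with Holm correction
#'
#' For each post-baseline interval, a paired (by fish) Wilcoxon signed-rank
#' test of the interval's values against the baseline values, with Holm
#' step-down adjustment over the whole family of intervals for this metric.
#' Intervals with fewer than 5 informative (non-zero-difference) pairs get
#' `NA` with a warning.
#'
#' @param baseline Numeric vector, one value per fish.
#' @param interval_mat Numeric matrix fish x interval, fish order matching
#'   `baseline`.
#' @param family Label for the test family (e.g. the metric name).
#' @return A tibble with one row per interval: raw and Holm-adjusted p.
#' @export
pairwise_wilcoxon_holm <- function(baseline, interval_mat,
                                   family = "metric") {
  interval_mat <- as.matrix(interval_mat)
  stopifnot(length(baseline) == nrow(interval_mat))
  ids <- colnames(interval_mat)
  if (is.null(ids)) ids <- sprintf("I%02d", seq_len(ncol(interval_mat)))
  raw <- vapply(seq_len(ncol(interval_mat)), function(j) {
    d <- interval_mat[, j] - baseline
    if (sum(d != 0) < 5) {
      warning(sprintf("interval %s: fewer than 5 informative pairs; p = NA", ids[j]),
              call. = FALSE)
      return(c(NA_real_, NA_real_))
    }
    has_ties <- anyDuplicated(abs(d[d != 0])) > 0 || any(d == 0)
    ht <- suppressWarnings(stats::wilcox.test(
      interval_mat[, j], baseline, paired = TRUE,
      exact = length(baseline) <= 25 && !has_ties))
    c(unname(ht$statistic), ht$p.value)
  }, numeric(2))
  out <- test_result("paired Wilcoxon signed-rank vs baseline",
                     raw[1, ], raw[2, ], length(baseline), family = family,
                     term = ids)
  out$p_adjusted <- holm_adjust(out$p_value)
  out
}

#' Holm step-down adjustment
#'
#' @param p Raw p-values (NA allowed; NAs are excluded from the family size).
#' @return Adjusted p-values, same order as `p`.
#' @examples
#' holm_adjust(c(0.01, 0.04, 0.03))  # 0.03 0.06 0.06
#' @export
holm_adjust <- function(p) stats::p.adjust(p, method = "holm")

#' Mixed model for EOD frequency change
#'
#' Zero-intercept random-slope model of per-interval percent change of median
#' EOD frequency: fixed effects are experimental time (interval index) and
#' the interaction of inverted DO with the fraction of time spent in hypoxia;
#' fish ID enters as a random slope on time. Baseline rows (change identically
#' 0 by construction) must be excluded before fitting.
#'
#' Inverted DO is `(100 - do)/100` by default, so the interaction grows as DO
#' falls; `inverted = "reciprocal"` uses `1/do` instead.
#'
#' @param data Tibble with columns `fish_id`, `time` (interval index),
#'   `percent_change`, `do`, `residence_frac` (fraction of the interval in
#'   the hypoxic compartment, 0-1).
#' @param fixed Character subset of `c("time", "interaction")` to include.
#' @param inverted `"linear"` or `"reciprocal"` inverted-DO definition.
#' @return An `eod_lmm_fit`: coefficient table (Satterthwaite df), AIC,
#'   and the model formula used.
#' @export
fit_eod_lmm <- function(data, fixed = c("time", "interaction"),
                        inverted = c("linear", "reciprocal")) {
  inverted <- match.arg(inverted)
  fixed <- match.arg(fixed, c("time", "interaction"), several.ok = TRUE)
  data <- tibble::as_tibble(data)
  stopifnot(all(c("fish_id", "time", "percent_change", "do",
                  "residence_frac") %in% names(data)))
  data$inv_do <- if (inverted == "linear") (100 - data$do) / 100 else 1 / data$do
  data$interaction <- data$inv_do * data$residence_frac
  rhs <- paste(c(fixed, "(0 + time | fish_id)"), collapse = " + ")
  form <- stats::as.formula(paste("percent_change ~ 0 +", rhs))
  X <- stats::model.matrix(stats::as.formula(paste("~ 0 +", paste(fixed, collapse = "+"))),
                           data)
  if (qr(X)$rank < ncol(X)) {
    stop("rank-deficient design: collinear terms among ",
         paste(fixed, collapse = ", "), call. = FALSE)
  }
  fit <- tryCatch(suppressMessages(lmerTest::lmer(form, data = data, REML = FALSE)),
                  error = function(e) NULL)
  if (is.null(fit)) {
    # degenerate response (e.g. zero variance): plain zero-intercept OLS
    fit0 <- stats::lm(stats::as.formula(paste("percent_change ~ 0 +",
                                              paste(fixed, collapse = "+"))),
                      data = data)
    sm <- stats::coef(summary(fit0))
    return(structure(list(
      coefficients = tibble::tibble(
        term = rownames(sm), estimate = unname(sm[, "Estimate"]),
        std_error = unname(sm[, "Std. Error"]), df = fit0$df.residual,
        statistic = unname(sm[, "t value"]), p_value = unname(sm[, "Pr(>|t|)"])),
      aic = stats::AIC(fit0), formula = deparse(form),
      inverted = inverted, n = nrow(data), singular = TRUE
    ), class = "eod_lmm_fit"))
  }
  sm <- stats::coef(summary(fit))
  structure(list(
    coefficients = tibble::tibble(
      term = rownames(sm), estimate = unname(sm[, "Estimate"]),
      std_error = unname(sm[, "Std. Error"]), df = unname(sm[, "df"]),
      statistic = unname(sm[, "t value"]), p_value = unname(sm[, "Pr(>|t|)"])),
    aic = stats::AIC(fit), formula = deparse(form),
    inverted = inverted, n = nrow(data),
    singular = lme4::isSingular(fit, tol = 1e-5)
  ), class = "eod_lmm_fit")
}

#' @export
print.eod_lmm_fit <- function(x, ...) {
  cat(sprintf("<eod_lmm_fit> %s | AIC %.1f | n = %d\n", x$formula, x$aic, x$n))
  print(as.data.frame(x$coefficients), digits = 4)
  invisible(x)
}

#' AIC comparison of candidate EOD models
#'
#' Fits the three candidate fixed-effect sets (time; time + interaction;
#' interaction) and reports their AICs, lowest first.
#'
#' @inheritParams fit_eod_lmm
#' @return A tibble (`fixed_effects`, `aic`, `delta_aic`).
#' @export
compare_eod_models <- function(data, inverted = c("linear", "reciprocal")) {
  inverted <- match.arg(inverted)
  sets <- list("time" = "time",
               "time + interaction" = c("time", "interaction"),
               "interaction" = "interaction")
  aics <- purrr::map_dbl(sets, function(fx)
    fit_eod_lmm(data, fixed = fx, inverted = inverted)$aic)
  out <- tibble::tibble(fixed_effects = names(sets), aic = unname(aics))
  out <- out[order(out$aic), ]
  out$delta_aic <- out$aic - out$aic[1]
  out
}

#' Repeatability: two-way repeated-measures ANOVA
#'
#' Tests whether residence in hypoxia differs between the original and the
#' repeated trial day, with DO concentration as between-subject effect and
#' day as within-subject effect (subjects are fish-by-DO cells, each measured
#' on both days). Reports the F statistic and p for the day effect.
#'
#' @param data Tibble with columns `fish_id`, `do`, `day` (two levels) and
#'   `residence`.
#' @return A one-row test-result tibble with the day-effect F and p.
#' @export
rm_anova_repeatability <- function(data) {
  data <- tibble::as_tibble(data)
  stopifnot(all(c("fish_id", "do", "day", "residence") %in% names(data)))
  data$day <- factor(data$day)
  data$do_f <- factor(data$do)
  data$unit <- interaction(data$fish_id, data$do_f)
  counts <- table(data$unit, data$day)
  if (length(unique(data$day)) != 2 || any(counts != 1)) {
    stop("unbalanced design: each fish x DO cell needs exactly one value per day",
         call. = FALSE)
  }
  fit <- stats::aov(residence ~ do_f * day + Error(unit / day), data = data)
  tab <- summary(fit)[["Error: unit:day"]][[1]]
  i <- grep("^day", trimws(rownames(tab)))[1]
  f_day <- tab[i, "F value"]
  p_day <- tab[i, "Pr(>F)"]
  ss_total <- sum(stats::ave(data$residence, FUN = function(x) (x - mean(x))^2))
  if (tab[i, "Sum Sq"] <= 1e-12 * max(ss_total, 1)) {
    # day 2 numerically identical to day 1: no day effect by construction
    f_day <- 0
    p_day <- 1
  }
  test_result("two-way RM ANOVA (day effect)", f_day, p_day,
              length(unique(data$fish_id)))
}
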