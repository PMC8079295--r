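#' Random-intercept mixed model of residence vs DO
#'
#' Fits `residence ~ do + (1 | fish_id)` by maximum likelihood (ML rather
#' than REML, because the broken-stick loop compares fits across different
#' data splits). Reports fixed effects with Satterthwaite degrees of freedom,
#' the variance components, the residual sum of squares over conditional
#' residuals (observed minus fixed plus predicted random effects), and
#' Nakagawa marginal/conditional R2.
#'
#' A singular fit (zero random-effect variance) falls back to ordinary least
#' squares with `singular_fallback = TRUE`; `mode = "ols"` forces plain OLS,
#' the original broken-stick formulation.
#'
#' @param data A data frame with columns `fish_id`, `do`, `residence`.
#' @param mode `"lmm"` (default) or `"ols"`.
#' @param random `"intercept"` or `"slope"` (random intercept and slope).
#' @return An object of class `lmm_fit`.
#' @export
fit_random_intercept_lmm <- function(data, mode = c("lmm", "ols"),
                                     random = c("intercept", "slope")) {
  mode <- match.arg(mode)
  random <- match.arg(random)
  data <- tibble::as_tibble(data)
  stopifnot(all(c("fish_id", "do", "residence") %in% names(data)))
  if (length(unique(data$do)) < 2) {
    stop("need at least 2 distinct DO values", call. = FALSE)
  }
  if (mode == "lmm" && length(unique(data$fish_id)) < 2) {
    stop("need at least 2 fish for a mixed model", call. = FALSE)
  }
  if (mode == "ols") return(ols_fit(data))
  form <- if (random == "intercept") {
    residence ~ do + (1 | fish_id)
  } else {
    residence ~ do + (1 + do | fish_id)
  }
  fit <- tryCatch(
    suppressMessages(lmerTest::lmer(form, data = data, REML = FALSE,
                                    control = lme4::lmerControl(calc.derivs = FALSE))),
    error = function(e) NULL)
  if (is.null(fit) || lme4::isSingular(fit, tol = 1e-5)) {
    out <- ols_fit(data)
    out$singular_fallback <- TRUE
    return(out)
  }
  sm <- stats::coef(summary(fit))
  beta <- lme4::fixef(fit)
  X <- stats::model.matrix(fit)
  var_fixed <- stats::var(as.numeric(X %*% beta))
  # mean over observations of z' Sigma z; reduces to the intercept variance
  # for random-intercept models and handles random slopes too
  vc <- lme4::VarCorr(fit)$fish_id
  Z <- X[, seq_len(nrow(vc)), drop = FALSE]
  var_random <- mean(rowSums((Z %*% vc) * Z))
  sigma2 <- stats::sigma(fit)^2
  res <- stats::residuals(fit)
  new_lmm_fit(
    coefficients = tibble::tibble(
      term = rownames(sm), estimate = unname(sm[, "Estimate"]),
      std_error = unname(sm[, "Std. Error"]), df = unname(sm[, "df"]),
      statistic = unname(sm[, "t value"]), p_value = unname(sm[, "Pr(>|t|)"])),
    var_fixed = var_fixed, var_random = var_random, var_residual = sigma2,
    rss = sum(res^2), n = nrow(data),
    n_groups = length(unique(data$fish_id)),
    mode = "lmm", random = random, singular_fallback = FALSE,
    logLik = as.numeric(stats::logLik(fit)), aic = stats::AIC(fit))
}

ols_fit <- function(data) {
  fit <- stats::lm(residence ~ do, data = data)
  sm <- stats::coef(summary(fit))
  X <- stats::model.matrix(fit)
  var_fixed <- stats::var(as.numeric(X %*% stats::coef(fit)))
  res <- stats::residuals(fit)
  new_lmm_fit(
    coefficients = tibble::tibble(
      term = rownames(sm), estimate = unname(sm[, "Estimate"]),
      std_error = unname(sm[, "Std. Error"]), df = unname(fit$df.residual),
      statistic = unname(sm[, "t value"]), p_value = unname(sm[, "Pr(>|t|)"])),
    var_fixed = var_fixed, var_random = 0,
    var_residual = sum(res^2) / fit$df.residual,
    rss = sum(res^2), n = nrow(data),
    n_groups = length(unique(data$fish_id)),
    mode = "ols", random = "none", singular_fallback = FALSE,
    logLik = as.numeric(stats::logLik(fit)), aic = stats::AIC(fit))
}

new_lmm_fit <- function(...) {
  out <- list(...)
  r2 <- nakagawa_r2_components(out$var_fixed, out$var_random, out$var_residual)
  out$r2_marginal <- r2[1]
  out$r2_conditional <- r2[2]
  structure(out, class = "lmm_fit")
}

#' @export
print.lmm_fit <- function(x, ...) {
  cat(sprintf("<lmm_fit> %s%s | n = %d obs, %d fish | RSS = %.2f | R2m = %.3f, R2c = %.3f\n",
              x$mode, if (isTRUE(x$singular_fallback)) " (singular fallback to OLS)" else "",
              x$n, x$n_groups, x$rss, x$r2_marginal, x$r2_conditional))
  print(as.data.frame(x$coefficients), digits = 4)
  invisible(x)
}

nakagawa_r2_components <- function(var_fixed, var_random, var_residual) {
  total <- var_fixed + var_random + var_residual
  if (total <= 0) stop("undefined R2: all variance components are zero", call. = FALSE)
  c(var_fixed / total, (var_fixed + var_random) / total)
}

#' Nakagawa marginal and conditional R2
#'
#' Variance-decomposition R2 for mixed models: the marginal R2 is the share
#' of total variance (fixed + random + residual) explained by the fixed
#' effects, where the fixed-effect variance is the variance of the
#' fixed-effect linear predictor over the data; the conditional R2 adds the
#' random-effect variance to the numerator.
#'
#' @param fit An `lmm_fit`.
#' @return Named numeric vector `c(marginal, conditional)`.
#' @export
nakagawa_r2 <- function(fit) {
  stopifnot(inherits(fit, "lmm_fit"))
  stats::setNames(nakagawa_r2_components(fit$var_fixed, fit$var_random,
                                         fit$var_residual),
                  c("marginal", "conditional"))
}

#' Intersection of two regression lines
#'
#' The DO value where `b0_pre + b1_pre * x` meets `b0_post + b1_post * x`.
#'
#' @param b0_pre,b1_pre Intercept and slope of the pre-threshold line.
#' @param b0_post,b1_post Intercept and slope of the post-threshold line.
#' @return The x (DO) coordinate of the intersection.
#' @examples
#' intersect_lines(93.639, 0.049, -27.938, 5.6)  # ~21.9
#' @export
intersect_lines <- function(b0_pre, b1_pre, b0_post, b1_post) {
  if (abs(b1_post - b1_pre) < 1e-12) {
    stop("no intersection: lines are parallel", call. = FALSE)
  }
  (b0_pre - b0_post) / (b1_post - b1_pre)
}

#' Broken-stick threshold search
#'
#' Estimates the hypoxia-avoidance threshold by fitting two linear models to
#' the residence-vs-DO data, one above and one at/below a candidate split,
#' for every admissible split between consecutive distinct DO levels, and
#' keeping the split that minimises the combined residual sum of squares
#' (ties broken toward the higher-DO split). Each segment must retain at
#' least `min_levels` distinct DO levels; the boundary level belongs to the
#' post (low-DO) segment. The threshold is the DO at which the two
#' fixed-effect lines intersect.
#'
#' @param data A tibble (`fish_id`, `do`, `residence`), e.g. from
#'   [residence_dataset()].
#' @inheritParams fit_random_intercept_lmm
#' @param min_levels Minimum distinct DO levels per segment.
#' @return An object of class `broken_stick_fit`: `split_do` (the chosen
#'   split midpoint), `threshold`, `pre_fit`/`post_fit` (`lmm_fit`s),
#'   `rss_total`, and a `candidates` tibble of all evaluated splits.
#' @export
broken_stick_search <- function(data, mode = c("lmm", "ols"),
                                random = c("intercept", "slope"),
                                min_levels = 3) {
  mode <- match.arg(mode)
  random <- match.arg(random)
  data <- tibble::as_tibble(data)
  lv <- sort(unique(data$do))
  n_lv <- length(lv)
  if (n_lv < 2 * min_levels) {
    stop(sprintf("insufficient data: %d distinct DO levels, need >= %d",
                 n_lv, 2 * min_levels), call. = FALSE)
  }
  cand_idx <- seq(min_levels, n_lv - min_levels)
  cands <- purrr::map_dfr(cand_idx, function(i) {
    mid <- (lv[i] + lv[i + 1]) / 2
    post <- data[data$do <= mid, ]
    pre <- data[data$do > mid, ]
    pre_fit <- fit_random_intercept_lmm(pre, mode = mode, random = random)
    post_fit <- fit_random_intercept_lmm(post, mode = mode, random = random)
    tibble::tibble(split_do = mid, rss = pre_fit$rss + post_fit$rss,
                   pre_fit = list(pre_fit), post_fit = list(post_fit))
  })
  best_rss <- min(cands$rss)
  eligible <- which(cands$rss <= best_rss + 1e-9)
  pick <- eligible[which.max(cands$split_do[eligible])]
  pre_fit <- cands$pre_fit[[pick]]
  post_fit <- cands$post_fit[[pick]]
  threshold <- intersect_lines(pre_fit$coefficients$estimate[1],
                               pre_fit$coefficients$estimate[2],
                               post_fit$coefficients$estimate[1],
                               post_fit$coefficients$estimate[2])
  structure(list(split_do = cands$split_do[pick],
                 threshold = threshold,
                 pre_fit = pre_fit, post_fit = post_fit,
                 rss_total = cands$rss[pick],
                 candidates = cands[, c("split_do", "rss")],
                 mode = mode, random = random),
            class = "broken_stick_fit")
}

#' @export
print.broken_stick_fit <- function(x, ...) {
  cat(sprintf("<broken_stick_fit> split at %.2f %% air sat -> threshold %.2f %% air sat (total RSS %.2f)\n",
              x$split_do, x$threshold, x$rss_total))
  cat("pre-threshold segment:\n"); print(x$pre_fit)
  cat("post-threshold segment:\n"); print(x$post_fit)
  invisible(x)
}
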