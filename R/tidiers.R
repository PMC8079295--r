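#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a mixed-model segment fit
#'
#' @param x An `lmm_fit`.
#' @param ... Unused.
#' @return A tibble with one row per fixed effect: estimate, SE,
#'   Satterthwaite df, t statistic and p.
#' @export
tidy.lmm_fit <- function(x, ...) x$coefficients

#' @rdname tidy.lmm_fit
#' @export
glance.lmm_fit <- function(x, ...) {
  tibble::tibble(n = x$n, n_groups = x$n_groups, rss = x$rss,
                 var_fixed = x$var_fixed, var_random = x$var_random,
                 var_residual = x$var_residual,
                 r2_marginal = x$r2_marginal, r2_conditional = x$r2_conditional,
                 aic = x$aic, log_lik = x$logLik, mode = x$mode,
                 singular_fallback = isTRUE(x$singular_fallback))
}

#' Tidy a broken-stick threshold fit
#'
#' @param x A `broken_stick_fit`.
#' @param ... Unused.
#' @return One row per fixed effect of both segments, with a `segment`
#'   column (`pre`/`post`) and the segment's Nakagawa marginal R2, mirroring
#'   the usual reporting table for this analysis.
#' @export
tidy.broken_stick_fit <- function(x, ...) {
  dplyr::bind_rows(
    dplyr::mutate(tidy(x$pre_fit), segment = "pre",
                  r2_marginal = x$pre_fit$r2_marginal),
    dplyr::mutate(tidy(x$post_fit), segment = "post",
                  r2_marginal = x$post_fit$r2_marginal)
  ) |>
    dplyr::relocate("segment")
}

#' @rdname tidy.broken_stick_fit
#' @export
glance.broken_stick_fit <- function(x, ...) {
  tibble::tibble(split_do = x$split_do, threshold = x$threshold,
                 rss_total = x$rss_total,
                 pre_slope = x$pre_fit$coefficients$estimate[2],
                 post_slope = x$post_fit$coefficients$estimate[2],
                 pre_r2_marginal = x$pre_fit$r2_marginal,
                 post_r2_marginal = x$post_fit$r2_marginal,
                 mode = x$mode, n_candidates = nrow(x$candidates))
}

#' Tidy the EOD frequency mixed model
#'
#' @param x An `eod_lmm_fit`.
#' @param ... Unused.
#' @export
tidy.eod_lmm_fit <- function(x, ...) x$coefficients

#' @rdname tidy.eod_lmm_fit
#' @export
glance.eod_lmm_fit <- function(x, ...) {
  tibble::tibble(aic = x$aic, n = x$n, formula = x$formula,
                 inverted = x$inverted, singular = x$singular)
}
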