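#' Stepped dissolved-oxygen trial protocol
#'
#' Builds the DO schedule of a shuttle-box avoidance trial: a normoxic
#' baseline, then for each target saturation a linear ramp down followed by a
#' constant hold, and finally a reoxygenation phase in which the hypoxic side
#' is returned linearly to normoxia. The first ramp (normoxia to the first
#' step target) is part of the schedule, so the default protocol totals
#' 40 + 7*(10+10) + 20 = 200 min.
#'
#' @param baseline_min Normoxic baseline duration (min).
#' @param step_targets Ordered air-saturation targets (% air saturation),
#'   strictly decreasing, all in (0, 100].
#' @param ramp_min Duration of each downward ramp (min).
#' @param hold_min Duration of each constant hold (min).
#' @param reox_min Reoxygenation duration (min).
#' @param normoxia Air saturation treated as normoxic (%); the starting level
#'   of the hypoxic side and the endpoint of reoxygenation.
#' @param normoxic_target Target saturation maintained on the refuge
#'   (never-hypoxic) side (%).
#'
#' @return An object of class `trial_protocol`: the arguments plus a
#'   `segments` tibble (`kind`, `start_s`, `end_s`, `do_start`, `do_end`) and
#'   `total_min`/`total_s`.
#' @examples
#' p <- trial_protocol()
#' p$total_min   # 200
#' @export
trial_protocol <- function(baseline_min = 40,
                           step_targets = c(70, 50, 30, 25, 20, 15, 10),
                           ramp_min = 10,
                           hold_min = 10,
                           reox_min = 20,
                           normoxia = 100,
                           normoxic_target = 90) {
  if (baseline_min <= 0 || ramp_min <= 0 || hold_min <= 0 || reox_min <= 0) {
    stop("protocol durations must be positive", call. = FALSE)
  }
  if (length(step_targets)) {
    if (any(diff(step_targets) >= 0)) {
      stop("invalid protocol: step_targets must be strictly decreasing",
           call. = FALSE)
    }
    if (any(step_targets <= 0 | step_targets > 100)) {
      stop("invalid protocol: step_targets must lie in (0, 100]", call. = FALSE)
    }
  }
  segs <- list(tibble::tibble(kind = "baseline", duration_min = baseline_min,
                              do_start = normoxia, do_end = normoxia))
  prev <- normoxia
  for (tg in step_targets) {
    segs <- c(segs, list(
      tibble::tibble(kind = "ramp", duration_min = ramp_min,
                     do_start = prev, do_end = tg),
      tibble::tibble(kind = "hold", duration_min = hold_min,
                     do_start = tg, do_end = tg)
    ))
    prev <- tg
  }
  segs <- c(segs, list(tibble::tibble(kind = "reoxygenation",
                                      duration_min = reox_min,
                                      do_start = prev, do_end = normoxia)))
  segments <- dplyr::bind_rows(segs)
  segments$end_s <- cumsum(segments$duration_min) * 60
  segments$start_s <- segments$end_s - segments$duration_min * 60
  out <- structure(list(
    baseline_min = baseline_min, step_targets = step_targets,
    ramp_min = ramp_min, hold_min = hold_min, reox_min = reox_min,
    normoxia = normoxia, normoxic_target = normoxic_target,
    segments = segments[, c("kind", "start_s", "end_s", "do_start", "do_end")],
    total_min = sum(segments$duration_min)
  ), class = "trial_protocol")
  out$total_s <- out$total_min * 60
  stopifnot(out$total_min ==
              baseline_min + length(step_targets) * (ramp_min + hold_min) + reox_min)
  out
}

#' @export
print.trial_protocol <- function(x, ...) {
  cat("<trial_protocol>\n")
  cat(sprintf("  baseline %g min | %d steps (%s%% air sat), ramp %g + hold %g min | reox %g min\n",
              x$baseline_min, length(x$step_targets),
              paste(x$step_targets, collapse = ", "),
              x$ramp_min, x$hold_min, x$reox_min))
  cat(sprintf("  total duration: %g min\n", x$total_min))
  invisible(x)
}

#' Per-second DO targets of a protocol
#'
#' Maps every second of the trial to the target air saturation on the hypoxic
#' and the normoxic (refuge) side. Ramp and reoxygenation targets are linear
#' in time; holds are constant.
#'
#' @param protocol A [trial_protocol()].
#' @return A tibble with one row per second: `t_s` (0-based), `segment`
#'   (kind), `do_hypoxic`, `do_normoxic`.
#' @export
protocol_schedule <- function(protocol) {
  stopifnot(inherits(protocol, "trial_protocol"))
  segs <- protocol$segments
  purrr::pmap_dfr(segs, function(kind, start_s, end_s, do_start, do_end) {
    t <- seq.int(start_s, end_s - 1)
    frac <- (t - start_s) / (end_s - start_s)
    tibble::tibble(t_s = t, segment = kind,
                   do_hypoxic = do_start + frac * (do_end - do_start),
                   do_normoxic = protocol$normoxic_target)
  })
}

#' Analysis intervals of a protocol
#'
#' The analysis grid used throughout: the whole baseline as one interval,
#' then consecutive `bin_min`-minute bins to the end of the trial. With the
#' default protocol (10-min ramps and holds, 20-min reoxygenation) the bins
#' coincide with protocol segments, giving 16 post-baseline bins.
#'
#' `nominal_do` is the x-axis value the threshold model uses for the bin:
#' the step target for holds, the mean scheduled target for ramp and
#' reoxygenation bins, and the normoxic level for baseline.
#'
#' @param protocol A [trial_protocol()].
#' @param bin_min Post-baseline bin width (min).
#' @return A tibble: `interval_id`, `interval_kind`, `start_s`, `end_s`,
#'   `nominal_do`.
#' @export
protocol_intervals <- function(protocol, bin_min = 10) {
  stopifnot(inherits(protocol, "trial_protocol"))
  post_s <- protocol$total_s - protocol$baseline_min * 60
  n_bins <- ceiling(post_s / (bin_min * 60))
  starts <- protocol$baseline_min * 60 + (seq_len(n_bins) - 1) * bin_min * 60
  ends <- pmin(starts + bin_min * 60, protocol$total_s)
  segs <- protocol$segments
  kind_at <- function(t) segs$kind[findInterval(t, segs$start_s)]
  # continuous piecewise-linear target; exact time-average over a ramp bin is
  # the midpoint of its endpoint targets
  do_at <- function(t) {
    i <- findInterval(pmin(t, protocol$total_s - 1e-9), segs$start_s)
    frac <- (t - segs$start_s[i]) / (segs$end_s[i] - segs$start_s[i])
    segs$do_start[i] + frac * (segs$do_end[i] - segs$do_start[i])
  }
  bins <- tibble::tibble(
    interval_id = sprintf("I%02d", seq_len(n_bins)),
    interval_kind = kind_at(starts),
    start_s = starts, end_s = ends
  )
  bins$nominal_do <- purrr::map2_dbl(bins$start_s, bins$end_s, function(a, b) {
    kind <- kind_at(a)
    if (kind == "hold") do_at(a) else (do_at(a) + do_at(b)) / 2
  })
  dplyr::bind_rows(
    tibble::tibble(interval_id = "baseline", interval_kind = "baseline",
                   start_s = 0, end_s = protocol$baseline_min * 60,
                   nominal_do = protocol$normoxia),
    bins
  )
}
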