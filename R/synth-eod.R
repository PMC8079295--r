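#' Synthesise an EOD voltage trace for one fish
#'
#' Generates a quasi-sinusoidal electric organ discharge whose instantaneous
#' frequency follows the Q10 temperature law
#' \deqn{f(t) = f_0 \, Q_{10}^{(T(t) - T_0)/10}}
#' with \eqn{T_0} the temperature at trial start, plus configured harmonics
#' and Gaussian noise. Phase is accumulated sample by sample, so it is
#' continuous across the synthesised windows.
#'
#' Full-length synthesis of a 200-min trial at 20 kHz is rarely needed; by
#' default one 1-s window is synthesised every `eod_stride_s` trial seconds
#' (set `eod_stride_s = 1` in the config, or pass `seconds`, for denser
#' coverage).
#'
#' @param fish One row of [sample_cohort()].
#' @param log The fish's [position_log()] (supplies the temperature series).
#' @param config A [sim_config()].
#' @param seconds Integer trial seconds to synthesise; defaults to every
#'   `eod_stride_s`-th second of the log.
#' @return An [eod_recording()].
#' @export
simulate_eod <- function(fish, log, config, seconds = NULL) {
  stopifnot(inherits(config, "sim_config"), inherits(log, "position_log"))
  fish <- as.list(fish)
  if (is.null(seconds)) {
    seconds <- log$t_s[seq(1, nrow(log), by = config$eod_stride_s)]
  }
  stopifnot(all(seconds %in% log$t_s))
  i <- as.integer(sub("^F", "", fish$fish_id))
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed((fish_seed(config$seed, i) + 1555L) %% 2147483629L)

  fs <- config$eod_sample_rate
  t0_temp <- log$temp_c[1]
  temp <- log$temp_c[match(seconds, log$t_s)]
  freq <- fish$base_eod_freq_hz * config$q10^((temp - t0_temp) / 10)
  harm <- config$eod_harmonics
  phase <- 0
  samples <- vector("list", length(seconds))
  for (w in seq_along(seconds)) {
    phi <- phase + 2 * pi * freq[w] / fs * seq_len(fs)
    sig <- sin(phi)
    for (k in seq_along(harm)) sig <- sig + harm[k] * sin((k + 1) * phi)
    if (config$eod_noise_sd > 0) sig <- sig + stats::rnorm(fs, 0, config$eod_noise_sd)
    samples[[w]] <- sig
    phase <- phi[fs]
  }
  eod_recording(unlist(samples), sample_rate = fs, fish_id = fish$fish_id,
                second_index = seconds)
}
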