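#' Band-pass filter an EOD signal
#'
#' Zero-phase Butterworth band-pass (applied forward and backward with
#' `signal::filtfilt`), passing the EOD band and rejecting mains hum below
#' and digitisation noise above it.
#'
#' @param x Numeric signal.
#' @param sample_rate Sampling rate (Hz); must exceed `2 * high`.
#' @param low,high Pass-band edges (Hz).
#' @param order Butterworth prototype order per pass (the zero-phase
#'   application squares the magnitude response).
#' @return Filtered signal, same length as `x`.
#' @export
bandpass <- function(x, sample_rate, low = 300, high = 5000, order = 4) {
  if (sample_rate <= 2 * high) {
    stop("sample_rate must exceed twice the upper band edge", call. = FALSE)
  }
  bf <- signal::butter(order, c(low, high) / (sample_rate / 2), type = "pass")
  as.numeric(signal::filtfilt(bf, x))
}

#' Track EOD frequency second by second
#'
#' For every 1-s window of the recording the window is Hann-tapered,
#' zero-padded to `nfft` points and Fourier-transformed; the frequency of
#' the power-spectral-density maximum within the search band is the EOD
#' frequency for that second. At 20 kHz and the default `nfft = 2^18` the
#' frequency resolution is 20000/2^18 = 0.076 Hz.
#'
#' To avoid picking a strong harmonic, the lowest spectral peak within 6 dB
#' of the global maximum is preferred. All-zero windows yield `NA` with a
#' message.
#'
#' @param recording An [eod_recording()].
#' @param nfft Transform length after zero padding.
#' @param band Search band (Hz) for the PSD argmax.
#' @return A `frequency_track` tibble (`t_s`, `freq_hz`) with attributes
#'   `bin_width_hz` and `fish_id`.
#' @export
track_frequency <- function(recording, nfft = 2^18, band = c(300, 5000)) {
  stopifnot(inherits(recording, "eod_recording"))
  fs <- recording$sample_rate
  if (length(recording$samples) < fs) stop("recording shorter than 1 s", call. = FALSE)
  n_win <- length(recording$second_index)
  bin_width <- fs / nfft
  n_half <- nfft %/% 2
  freqs <- (seq_len(n_half) - 1) * bin_width
  in_band <- which(freqs >= band[1] & freqs <= band[2])
  taper <- 0.5 - 0.5 * cos(2 * pi * seq_len(fs) / (fs + 1))
  freq_hz <- vapply(seq_len(n_win), function(w) {
    win <- recording$samples[((w - 1) * fs + 1):(w * fs)]
    if (all(win == 0)) {
      message(sprintf("all-zero window at trial second %d; frequency set to NA",
                      recording$second_index[w]))
      return(NA_real_)
    }
    padded <- c((win - mean(win)) * taper, numeric(nfft - fs))
    psd <- Mod(stats::fft(padded)[in_band])^2
    peak_bin_preferring_fundamental(psd)
  }, numeric(1))
  structure(tibble::tibble(t_s = recording$second_index,
                           freq_hz = ifelse(is.na(freq_hz), NA_real_,
                                            freqs[in_band[1]] +
                                              (freq_hz - 1) * bin_width)),
            class = c("frequency_track", class(tibble::tibble())),
            bin_width_hz = bin_width, fish_id = recording$fish_id)
}

# index (within the band) of the chosen PSD peak: the lowest-frequency local
# peak within 6 dB of the global maximum, so a slightly stronger harmonic
# does not capture the estimate.
peak_bin_preferring_fundamental <- function(psd) {
  gmax <- max(psd)
  cand <- psd >= gmax * 10^(-6 / 10)
  runs <- rle(cand)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1
  first_run <- which(runs$values)[1]
  idx <- starts[first_run]:ends[first_run]
  idx[which.max(psd[idx])]
}

#' Interval medians and baseline normalisation of a frequency track
#'
#' Computes the median EOD frequency for the baseline and each analysis bin
#' and expresses every interval as percent change from the baseline median:
#' `100 * (median_i - median_baseline) / median_baseline`.
#'
#' @param track A `frequency_track` from [track_frequency()].
#' @param intervals The analysis grid from [protocol_intervals()].
#' @return A tibble per interval: `interval_id`, `interval_kind`,
#'   `nominal_do`, `median_freq_hz`, `percent_change`.
#' @export
normalize_track <- function(track, intervals) {
  idx <- findInterval(track$t_s, intervals$start_s)
  ok <- idx >= 1 & track$t_s < intervals$end_s[pmax(idx, 1)]
  med <- tibble::tibble(interval_id = intervals$interval_id[idx[ok]],
                        freq_hz = track$freq_hz[ok]) |>
    dplyr::group_by(.data$interval_id) |>
    dplyr::summarise(median_freq_hz = stats::median(.data$freq_hz, na.rm = TRUE),
                     .groups = "drop")
  out <- dplyr::left_join(intervals[, c("interval_id", "interval_kind", "nominal_do")],
                          med, by = "interval_id")
  base <- out$median_freq_hz[out$interval_id == "baseline"]
  if (!length(base) || is.na(base)) {
    stop("missing baseline median frequency", call. = FALSE)
  }
  out$percent_change <- 100 * (out$median_freq_hz - base) / base
  out
}

#' Q10-predicted relative frequency change
#'
#' The percent change of a rate with Q10 temperature sensitivity after a
#' temperature change `delta_t`: `100 * (q10^(delta_t/10) - 1)`. With
#' Q10 = 1.55 and the typical within-trial cooling of -0.15 degC this
#' predicts a frequency drop of about 0.7 %.
#'
#' @param q10 Q10 coefficient (> 0).
#' @param delta_t Temperature change (degC).
#' @return Percent change (negative for cooling when q10 > 1).
#' @examples
#' q10_predicted_change(1.55, -0.15)
#' @export
q10_predicted_change <- function(q10, delta_t) {
  if (!is.numeric(q10) || any(q10 <= 0)) stop("q10 must be > 0", call. = FALSE)
  100 * (q10^(delta_t / 10) - 1)
}
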