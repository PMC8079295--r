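#' Per-second position log of one fish
#'
#' Validates and classes a per-second tracking table. A position log is a
#' tibble with columns `t_s` (integer seconds from trial start, strictly
#' increasing at 1-s spacing), `x_cm`, `y_cm`, `dist_cm` (step distance),
#' `vel_cm_s`, `do_left`, `do_right` (% air saturation) and `temp_c`, and
#' carries the fish's identity, standard body length (SBL) and the side on
#' which hypoxia is induced as attributes.
#'
#' @param data A data frame with the columns above.
#' @param fish_id Fish identifier.
#' @param sbl_cm Standard body length (cm).
#' @param hypoxic_side `"left"` or `"right"`.
#' @return A `position_log` tibble.
#' @export
position_log <- function(data, fish_id, sbl_cm, hypoxic_side) {
  cols <- c("t_s", "x_cm", "y_cm", "dist_cm", "vel_cm_s",
            "do_left", "do_right", "temp_c")
  missing_cols <- setdiff(cols, names(data))
  if (length(missing_cols)) {
    stop("position log is missing columns: ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  hypoxic_side <- match.arg(hypoxic_side, c("left", "right"))
  # rebuild from plain columns so reader-specific attributes never leak in
  data <- tibble::as_tibble(lapply(stats::setNames(cols, cols),
                                   function(cn) as.vector(data[[cn]])))
  dt <- diff(data$t_s)
  if (any(dt != 1)) {
    bad <- which(dt != 1)[1] + 1
    stop(sprintf("time not strictly increasing at 1 s spacing near line %d (t_s = %s)",
                 bad, data$t_s[bad]), call. = FALSE)
  }
  if (any(data$dist_cm < 0)) stop("negative step distance", call. = FALSE)
  if (any(abs(data$vel_cm_s - data$dist_cm) > 0.02)) {
    stop("velocity inconsistent with per-second step distance", call. = FALSE)
  }
  if (any(data$do_left < 0 | data$do_left > 110 |
          data$do_right < 0 | data$do_right > 110)) {
    stop("DO values outside [0, 110] %% air saturation", call. = FALSE)
  }
  if (!is.numeric(sbl_cm) || sbl_cm <= 0) stop("sbl_cm must be > 0", call. = FALSE)
  structure(data, class = c("position_log", class(data)),
            fish_id = fish_id, sbl_cm = sbl_cm, hypoxic_side = hypoxic_side)
}

#' @rdname position_log
#' @param log A `position_log`.
#' @export
log_meta <- function(log) {
  list(fish_id = attr(log, "fish_id"),
       sbl_cm = attr(log, "sbl_cm"),
       hypoxic_side = attr(log, "hypoxic_side"))
}

#' Read and write position-log CSV files
#'
#' The on-disk format is UTF-8 comma-delimited text: three metadata comment
#' lines (`# fish_id:`, `# sbl_cm:`, `# hypoxic_side:`), one header line and
#' one data row per second. Coordinates and distances are written to 0.01 cm,
#' DO to 0.1 %, temperature to 0.001 degC, so write-then-read is lossless at
#' those precisions.
#'
#' @param path File path.
#' @param log A [position_log()].
#' @return `read_position_log()` returns a `position_log`;
#'   `write_position_log()` returns `path` invisibly.
#' @export
read_position_log <- function(path) {
  head_lines <- readLines(path, n = 10L)
  meta_lines <- grep("^#", head_lines, value = TRUE)
  get_meta <- function(key) {
    m <- grep(paste0("^#\\s*", key, ":"), meta_lines, value = TRUE)
    if (!length(m)) stop("position log file lacks '# ", key, ":' metadata line",
                         call. = FALSE)
    trimws(sub(paste0("^#\\s*", key, ":"), "", m[1]))
  }
  fish_id <- get_meta("fish_id")
  sbl_cm <- as.numeric(get_meta("sbl_cm"))
  hypoxic_side <- get_meta("hypoxic_side")
  body <- readr::read_csv(path, comment = "#", show_col_types = FALSE,
                          progress = FALSE)
  position_log(body, fish_id = fish_id, sbl_cm = sbl_cm,
               hypoxic_side = hypoxic_side)
}

#' @rdname read_position_log
#' @export
write_position_log <- function(log, path) {
  stopifnot(inherits(log, "position_log"))
  meta <- log_meta(log)
  con <- file(path, open = "w", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(c(sprintf("# fish_id: %s", meta$fish_id),
               sprintf("# sbl_cm: %s", format(meta$sbl_cm, digits = 15)),
               sprintf("# hypoxic_side: %s", meta$hypoxic_side),
               "t_s,x_cm,y_cm,dist_cm,vel_cm_s,do_left,do_right,temp_c"), con)
  rows <- sprintf("%d,%.2f,%.2f,%.2f,%.2f,%.1f,%.1f,%.3f",
                  log$t_s, log$x_cm, log$y_cm, log$dist_cm, log$vel_cm_s,
                  log$do_left, log$do_right, log$temp_c)
  writeLines(rows, con)
  invisible(path)
}

#' EOD recording container
#'
#' A single-channel voltage recording aligned to the position-log clock. To
#' keep long trials tractable the trace may be decimated: synthesised or
#' analysed only for a subset of trial seconds, recorded in `second_index`.
#'
#' @param samples Numeric voltage samples, concatenated 1-s windows.
#' @param sample_rate Samples per second (Hz).
#' @param fish_id Fish identifier.
#' @param second_index Integer trial seconds (0-based) covered by the
#'   successive 1-s windows; defaults to contiguous seconds from `start_time`.
#' @param start_time First trial second covered (s).
#' @return An object of class `eod_recording`.
#' @export
eod_recording <- function(samples, sample_rate = 20000, fish_id = "fish",
                          second_index = NULL, start_time = 0) {
  n_win <- length(samples) / sample_rate
  if (n_win != floor(n_win)) {
    stop("samples length must be a whole number of 1-s windows", call. = FALSE)
  }
  if (is.null(second_index)) second_index <- start_time + seq_len(n_win) - 1
  stopifnot(length(second_index) == n_win)
  structure(list(fish_id = fish_id, sample_rate = sample_rate,
                 samples = samples, second_index = as.integer(second_index),
                 start_time = min(second_index)),
            class = "eod_recording")
}

#' @export
print.eod_recording <- function(x, ...) {
  cat(sprintf("<eod_recording> fish %s: %d one-second windows at %g Hz\n",
              x$fish_id, length(x$second_index), x$sample_rate))
  invisible(x)
}

#' Read and write EOD recordings
#'
#' Raw little-endian float32 samples with a YAML sidecar (`<path>.yml`)
#' holding `fish_id`, `sample_rate` and the covered trial seconds.
#'
#' @param rec An [eod_recording()].
#' @param path Path for the raw sample file.
#' @return `read_eod_recording()` returns an `eod_recording`.
#' @export
write_eod_recording <- function(rec, path) {
  stopifnot(inherits(rec, "eod_recording"))
  writeBin(as.numeric(rec$samples), path, size = 4, endian = "little")
  yaml::write_yaml(list(fish_id = rec$fish_id, sample_rate = rec$sample_rate,
                        second_index = rec$second_index),
                   paste0(path, ".yml"))
  invisible(path)
}

#' @rdname write_eod_recording
#' @export
read_eod_recording <- function(path) {
  meta <- yaml::read_yaml(paste0(path, ".yml"))
  n <- file.info(path)$size / 4
  samples <- readBin(path, what = "numeric", n = n, size = 4, endian = "little")
  eod_recording(samples, sample_rate = meta$sample_rate, fish_id = meta$fish_id,
                second_index = meta$second_index)
}

#' Read and write trial configuration YAML
#'
#' Serialises the arena geometry and trial protocol to a single YAML file.
#'
#' @param geometry An [arena_geometry()].
#' @param protocol A [trial_protocol()].
#' @param path YAML file path.
#' @return `read_trial_config()` returns `list(geometry, protocol)`.
#' @export
write_trial_config <- function(geometry, protocol, path) {
  yaml::write_yaml(list(
    geometry = list(compartment_diameter = geometry$compartment_diameter,
                    passage_width = geometry$passage_width,
                    passage_length = geometry$passage_length),
    protocol = list(baseline_min = protocol$baseline_min,
                    step_targets = protocol$step_targets,
                    ramp_min = protocol$ramp_min,
                    hold_min = protocol$hold_min,
                    reox_min = protocol$reox_min,
                    normoxic_target = protocol$normoxic_target)
  ), path)
  invisible(path)
}

#' @rdname write_trial_config
#' @export
read_trial_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  list(geometry = do.call(arena_geometry, cfg$geometry),
       protocol = do.call(trial_protocol, cfg$protocol))
}
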