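#' Default signal-conditioning configuration
#'
#' All stages downstream of raw sensor data work at a common, reduced rate
#' (default 32 Hz) and on two filtered variants of every channel: a low-pass
#' series (<= 4 Hz) that preserves the gravity component and is suited to
#' orientation, and a band-pass series (0.1-4 Hz) that removes the DC
#' component and reflects movement dynamics. Filters are 4th-order
#' Chebyshev Type I designs (0.5 dB passband ripple) applied
#' forward-backward, so the overall response is zero-phase with doubled
#' effective ripple; segmentation timing is therefore not skewed by filter
#' delay.
#'
#' @param ... overrides for any of the config keys: `working_rate_hz`,
#'   `cheby.family` (`"cheby1"` or `"butter"`), `cheby.ripple_db`,
#'   `cheby.order`, `lp.cutoff_hz`, `band.low_hz`, `band.high_hz`,
#'   `band.cascade` (cascade a high-pass and a low-pass rather than one
#'   band-pass design; the cascade is the numerically robust default),
#'   `filter.zero_phase`.
#' @return a named list of configuration values.
#' @examples
#' preprocess_config(working_rate_hz = 32)
#' @export
preprocess_config <- function(...) {
  cfg <- list(
    working_rate_hz = 32,
    cheby.family = "cheby1",
    cheby.ripple_db = 0.5,
    cheby.order = 4,
    lp.cutoff_hz = 4,
    band.low_hz = 0.1,
    band.high_hz = 4,
    band.cascade = TRUE,
    filter.zero_phase = TRUE
  )
  dots <- list(...)
  unknown <- setdiff(names(dots), names(cfg))
  if (length(unknown) > 0) {
    stop_moveprof(paste0("unknown preprocess config key(s): ",
                         paste(unknown, collapse = ", ")),
                  "moveprof_config_error")
  }
  modifyList(cfg, dots)
}

#' Resample a series to a lower rate
#'
#' Anti-alias protected downsampling: a Kaiser-windowed-sinc FIR low-pass
#' (cutoff at 45% of the target rate, beta = 8) is applied at the original
#' rate, then the band-limited series is evaluated on the target time grid
#' with a cubic spline. The output covers the same duration as the input to
#' within one output sample.
#'
#' @param x numeric series sampled uniformly at `from_hz`.
#' @param from_hz,to_hz source and target sampling rates; only
#'   downsampling (`from_hz >= to_hz`) is supported.
#' @return numeric series at `to_hz`.
#' @examples
#' x <- sin(2 * pi * 1 * seq(0, 10, by = 1 / 100))
#' y <- resample_series(x, 100, 32)
#' length(y) / 32 # ~ 10 s
#' @export
resample_series <- function(x, from_hz, to_hz = 32) {
  if (!is_scalar_number(from_hz) || !is_scalar_number(to_hz) ||
      from_hz <= 0 || to_hz <= 0) {
    stop_moveprof("sampling rates must be positive scalars",
                  "moveprof_parameter_error")
  }
  if (to_hz > from_hz) {
    stop_moveprof("upsampling is not supported (from_hz < to_hz)",
                  "moveprof_parameter_error")
  }
  if (length(x) < 2) {
    stop_moveprof("series must have at least 2 samples",
                  "moveprof_parameter_error")
  }
  if (from_hz == to_hz) return(as.numeric(x))
  cutoff <- 0.45 * to_hz
  ntaps <- 4L * as.integer(ceiling(from_hz / (0.1 * to_hz))) + 1L
  half <- (ntaps - 1L) / 2
  k <- seq(-half, half)
  fc <- cutoff / from_hz
  kern <- ifelse(k == 0, 2 * fc, sin(2 * pi * fc * k) / (pi * k))
  kern <- kern * signal::kaiser(ntaps, 8)
  kern <- kern / sum(kern)
  np <- min(half, length(x) - 1L)
  xp <- pad_reflect(as.numeric(x), np)
  xf <- as.numeric(stats::filter(xp, kern, sides = 2))
  xf <- unpad(xf, np, length(x))
  # taps that ran off the ends (only when the series is shorter than the
  # kernel): fall back to the raw samples there
  miss <- is.na(xf)
  xf[miss] <- x[miss]
  tin <- (seq_along(x) - 1) / from_hz
  tout <- seq(0, tin[length(tin)], by = 1 / to_hz)
  stats::spline(tin, xf, xout = tout)$y
}

# design a Chebyshev-I (or Butterworth) section
design_filter <- function(order, edges_norm, type, family, ripple_db) {
  if (any(edges_norm <= 0) || any(edges_norm >= 1)) {
    stop_moveprof("filter cutoff must lie strictly inside (0, Nyquist)",
                  "moveprof_parameter_error")
  }
  switch(family,
    cheby1 = signal::cheby1(order, ripple_db, edges_norm, type = type),
    butter = signal::butter(order, edges_norm, type = type),
    stop_moveprof(paste0("unknown filter family: ", family),
                  "moveprof_config_error")
  )
}

# apply a designed filter with reflect padding; forward-backward if zero_phase
apply_filter <- function(x, flt, settle, zero_phase = TRUE) {
  np <- min(settle, length(x) - 1L)
  xp <- pad_reflect(as.numeric(x), np)
  y <- if (zero_phase) signal::filtfilt(flt, xp) else signal::filter(flt, xp)
  unpad(as.numeric(y), np, length(x))
}

#' Zero-phase Chebyshev low-pass and band-pass filters
#'
#' `lowpass_filter()` retains content below `cutoff_hz` (default 4 Hz, the
#' upper limit of voluntary-movement content for this protocol), including
#' DC/gravity. `bandpass_filter()` additionally removes the DC component
#' with a 0.1 Hz high-pass edge. Both use the design in
#' [preprocess_config()]; edge transients are controlled by reflect-padding
#' one settling length (three time constants of the lowest band edge).
#'
#' @param x numeric series.
#' @param rate_hz sampling rate of `x`.
#' @param cutoff_hz low-pass cutoff (Hz).
#' @param low_hz,high_hz band edges (Hz).
#' @param config see [preprocess_config()].
#' @return filtered numeric series, same length as `x`.
#' @examples
#' t <- seq(0, 20, by = 1 / 32)
#' x <- 5 + sin(2 * pi * 1 * t)
#' round(mean(bandpass_filter(x, 32)), 3) # DC removed
#' @export
lowpass_filter <- function(x, rate_hz, cutoff_hz = NULL,
                           config = preprocess_config()) {
  cutoff_hz <- cutoff_hz %||% config$lp.cutoff_hz
  if (cutoff_hz >= rate_hz / 2) {
    stop_moveprof("low-pass cutoff must be below the Nyquist rate",
                  "moveprof_parameter_error")
  }
  flt <- design_filter(config$cheby.order, cutoff_hz / (rate_hz / 2), "low",
                       config$cheby.family, config$cheby.ripple_db)
  settle <- as.integer(ceiling(3 * rate_hz / cutoff_hz))
  apply_filter(x, flt, settle, config$filter.zero_phase)
}

#' @rdname lowpass_filter
#' @export
bandpass_filter <- function(x, rate_hz, low_hz = NULL, high_hz = NULL,
                            config = preprocess_config()) {
  low_hz <- low_hz %||% config$band.low_hz
  high_hz <- high_hz %||% config$band.high_hz
  if (!(0 < low_hz && low_hz < high_hz && high_hz < rate_hz / 2)) {
    stop_moveprof("band edges must satisfy 0 < low < high < Nyquist",
                  "moveprof_parameter_error")
  }
  settle <- as.integer(ceiling(3 * rate_hz / low_hz))
  if (isTRUE(config$band.cascade)) {
    hp <- design_filter(config$cheby.order, low_hz / (rate_hz / 2), "high",
                        config$cheby.family, config$cheby.ripple_db)
    lp <- design_filter(config$cheby.order, high_hz / (rate_hz / 2), "low",
                        config$cheby.family, config$cheby.ripple_db)
    y <- apply_filter(x, hp, settle, config$filter.zero_phase)
    apply_filter(y, lp, as.integer(ceiling(3 * rate_hz / high_hz)),
                 config$filter.zero_phase)
  } else {
    bp <- design_filter(config$cheby.order,
                        c(low_hz, high_hz) / (rate_hz / 2), "pass",
                        config$cheby.family, config$cheby.ripple_db)
    apply_filter(x, bp, settle, config$filter.zero_phase)
  }
}

#' Resample and filter a full session
#'
#' Brings every channel of every sensor to the working rate and attaches
#' the low-pass and band-pass variants used by all downstream features, plus
#' the band-pass-filtered gyroscope magnitude used for segmentation and
#' inter-limb synchrony.
#'
#' @param session an `imu_session` (see [read_session()] or
#'   [generate_subject()]).
#' @param config see [preprocess_config()].
#' @return a `filtered_session`: list with `subject_id`, `rate_hz`,
#'   `markers`, `scores`, `truth`, and `channels`, a named list (one per
#'   placement) of tibbles with columns `t_s`, then `<axis>_lp` and
#'   `<axis>_bp` for the six accel/gyro axes, and `gmag_lp`, `gmag_bp`.
#' @export
preprocess_session <- function(session, config = preprocess_config()) {
  validate_session(session)
  rate <- config$working_rate_hz
  channels <- lapply(session$channels, function(ch) {
    axes <- c("ax_g", "ay_g", "az_g", "gx_dps", "gy_dps", "gz_dps")
    rs <- lapply(axes, function(a) resample_series(ch[[a]], ch_rate(ch), rate))
    names(rs) <- axes
    n <- length(rs[[1]])
    out <- list(t_s = (seq_len(n) - 1) / rate)
    for (a in axes) {
      out[[paste0(a, "_lp")]] <- lowpass_filter(rs[[a]], rate, config = config)
      out[[paste0(a, "_bp")]] <- bandpass_filter(rs[[a]], rate, config = config)
    }
    gmag <- sqrt(rs$gx_dps^2 + rs$gy_dps^2 + rs$gz_dps^2)
    out$gmag_lp <- lowpass_filter(gmag, rate, config = config)
    out$gmag_bp <- bandpass_filter(gmag, rate, config = config)
    tibble::as_tibble(out)
  })
  structure(
    list(
      subject_id = session$subject_id,
      rate_hz = rate,
      channels = channels,
      markers = session$markers,
      scores = session$scores,
      truth = session$truth
    ),
    class = "filtered_session"
  )
}

ch_rate <- function(ch) attr(ch, "rate_hz") %||% 100
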