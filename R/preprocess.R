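#' Zero-phase Butterworth band-pass filter
#'
#' Applies a 4th-order Butterworth band-pass forward and backward
#' (zero-phase, so burst onsets are not delayed) to every channel. The signal
#' is extended by odd reflection at both ends before filtering so edge
#' transients do not leak into the output; a constant (DC) input therefore
#' comes back as (numerical) zero over its whole length.
#'
#' @param rec an [emg_recording].
#' @param low,high band edges in Hz; defaults 100 and 999 Hz (the acquisition
#'   band at 2 kHz sampling). `high` is clamped to 98% of Nyquist.
#' @param order Butterworth order per pass (default 4).
#' @return a filtered [emg_recording]; the band is recorded in
#'   `attr(, "provenance")$filter`.
#' @export
emg_bandpass <- function(rec, low = 100, high = 999, order = 4) {
  validate_recording(rec)
  nyq <- rec$sampling_rate / 2
  high <- min(high, 0.98 * nyq)
  if (!(low > 0)) stop("filter parameter error: low must be > 0", call. = FALSE)
  if (!(low < high)) stop("filter parameter error: need low < high < Nyquist",
                          call. = FALSE)
  bf <- signal::butter(order, c(low, high) / nyq, type = "pass")
  n <- nrow(rec$signal)
  ## pad by ~30 cycles of the low cutoff: the slowest transient mode of the
  ## band-pass decays there to < 1e-6 of a unit step
  npad <- min(n - 1L, max(3L * (2L * order + 1L),
                          ceiling(30 * rec$sampling_rate / low)))
  out <- rec$signal
  for (j in seq_len(ncol(out))) {
    x <- out[, j]
    if (npad > 0L) {
      head_pad <- 2 * x[1] - x[(npad + 1L):2L]
      tail_pad <- 2 * x[n] - x[(n - 1L):(n - npad)]
      y <- signal::filtfilt(bf, c(head_pad, x, tail_pad))
      out[, j] <- y[(npad + 1L):(npad + n)]
    } else {
      out[, j] <- signal::filtfilt(bf, x)
    }
  }
  rec$signal <- out
  prov <- attr(rec, "provenance")
  prov$filter <- list(low_hz = low, high_hz = high, order = order,
                      zero_phase = TRUE)
  attr(rec, "provenance") <- prov
  rec
}

#' Full-wave rectification
#'
#' Replaces every sample by its absolute value.
#'
#' @param rec an [emg_recording].
#' @return rectified [emg_recording].
#' @export
emg_rectify <- function(rec) {
  validate_recording(rec)
  rec$signal <- abs(rec$signal)
  prov <- attr(rec, "provenance")
  prov$rectified <- TRUE
  attr(rec, "provenance") <- prov
  rec
}

#' Rectified-integrated envelope of one channel
#'
#' The envelope on which bursts are marked: the rectified signal averaged over
#' consecutive non-overlapping bins of `bin_s` seconds. Two presets matter in
#' practice: 5 ms bins for burst timing, and 50 ms (20 Hz) bins for amplitude
#' analysis. A trailing partial bin is dropped (`floor(duration / bin_s)`
#' bins).
#'
#' @param rec an [emg_recording] (raw or already rectified; rectification is
#'   idempotent and applied internally).
#' @param channel channel label.
#' @param bin_s integration bin width in seconds (default 0.005).
#' @return object of class `emg_envelope`: fields `channel`, `bin_s`,
#'   `values`, `t0`, `provenance`.
#' @export
emg_envelope <- function(rec, channel, bin_s = 0.005) {
  validate_recording(rec)
  channel <- channel_name(channel)
  j <- match(channel, rec$channels)
  if (is.na(j)) stop("envelope usage error: no channel '", channel, "'",
                     call. = FALSE)
  n_per <- round(bin_s * rec$sampling_rate)
  if (n_per < 1L)
    stop("envelope parameter error: bin shorter than one sample", call. = FALSE)
  x <- abs(rec$signal[, j])
  n_bins <- floor(length(x) / n_per)
  if (n_bins < 1L)
    stop("envelope parameter error: bin longer than the recording", call. = FALSE)
  vals <- colMeans(matrix(x[seq_len(n_bins * n_per)], nrow = n_per))
  prov <- attr(rec, "provenance")
  structure(
    list(channel = channel, bin_s = n_per / rec$sampling_rate, values = vals,
         t0 = rec$t0,
         provenance = list(filter = prov$filter, rectified = TRUE,
                           integration_s = n_per / rec$sampling_rate)),
    class = "emg_envelope")
}

#' @export
print.emg_envelope <- function(x, ...) {
  cat(sprintf("<emg_envelope> %s: %d bins of %g ms (%.3g s)\n", x$channel,
              length(x$values), 1000 * x$bin_s, length(x$values) * x$bin_s))
  invisible(x)
}

## Leading-edge time of envelope bin i (1-based).
env_bin_time <- function(env, i) env$t0 + (i - 1) * env$bin_s
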