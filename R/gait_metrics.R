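#' Step-cycle durations within an episode
#'
#' Cycle duration is the time between two consecutive burst onsets of the same
#' muscle.
#'
#' @param train a `burst_train`.
#' @param episode one row of [find_episodes] output.
#' @return numeric vector of cycle durations in seconds (empty when the
#'   episode holds fewer than 2 bursts).
#' @export
cycle_durations <- function(train, episode) {
  b <- bursts_in_episode(train, episode)
  if (nrow(b) < 2L) return(numeric(0))
  diff(b$onset)
}

#' Burst durations within an episode
#'
#' Onset-to-offset duration of each burst.
#'
#' @inheritParams cycle_durations
#' @return numeric vector of burst durations in seconds.
#' @export
burst_durations <- function(train, episode) {
  b <- bursts_in_episode(train, episode)
  b$offset - b$onset
}

#' Per-burst peak amplitudes within an episode
#'
#' Maximum of the envelope inside each burst's `[onset, offset]` window.
#' Amplitude analysis conventionally uses the 20 Hz (50 ms) envelope of at
#' least 10 consecutive steps; below 10 bursts a warning is raised and the
#' result carries `attr(, "short_episode") = TRUE`.
#'
#' @param env [emg_envelope] of the same channel as `train`.
#' @param train a `burst_train`.
#' @param episode one row of [find_episodes] output.
#' @return numeric vector of peak amplitudes (envelope units).
#' @export
peak_amplitudes <- function(env, train, episode) {
  stopifnot(inherits(env, "emg_envelope"), inherits(train, "burst_train"))
  if (env$channel != train$channel)
    stop("amplitude usage error: envelope channel '", env$channel,
         "' != train channel '", train$channel, "'", call. = FALSE)
  b <- bursts_in_episode(train, episode)
  tt <- env_bin_time(env, seq_along(env$values))  # bin leading edges
  out <- vapply(seq_len(nrow(b)), function(i) {
    ix <- which(tt + env$bin_s > b$onset[i] & tt < b$offset[i])
    if (!length(ix)) return(NA_real_)
    max(env$values[ix])
  }, numeric(1))
  out <- out[is.finite(out)]
  if (length(out) < 10L && length(out) > 0L) {
    warning("fewer than 10 bursts in episode: amplitude summary may be unstable",
            call. = FALSE)
    attr(out, "short_episode") <- TRUE
  }
  out
}

#' Summary statistics of a gait parameter
#'
#' Mean, sample SD (n-1 denominator), SEM = SD/sqrt(n) and coefficient of
#' variation CV = SD/mean of a series of per-step values. CV is undefined
#' (returned as `NA`) when the mean is not positive.
#'
#' @param values numeric vector, `length(values) >= 2`.
#' @param parameter which parameter the values measure: one of
#'   `"cycle_duration"`, `"burst_duration"`, `"peak_amplitude"`.
#' @return one-row data frame `parameter, mean, sd, sem, cv, n`.
#' @export
summarize_param <- function(values,
                            parameter = c("cycle_duration", "burst_duration",
                                          "peak_amplitude")) {
  parameter <- match.arg(parameter)
  values <- as.numeric(values)
  if (length(values) < 2L)
    stop("insufficient data: need at least 2 values to summarize", call. = FALSE)
  if (anyNA(values) || !all(is.finite(values)))
    stop("data error: non-finite values", call. = FALSE)
  m <- mean(values)
  s <- stats::sd(values)
  data.frame(parameter = parameter, mean = m, sd = s,
             sem = s / sqrt(length(values)),
             cv = if (m > 0) s / m else NA_real_,
             n = length(values))
}

#' Per-animal gait-metric table for one recording
#'
#' Convenience wrapper running the standard per-animal pipeline on every
#' muscle channel of a recording: band-pass (optional), 5 ms envelope for
#' burst timing, hysteresis detection, episode selection on the reference
#' channel, then per-muscle cycle/burst-duration summaries plus
#' peak-amplitude summaries from the `amp_bin_s` envelope.
#'
#' @param rec an [emg_recording].
#' @param reference_channel episode-defining channel (default `"Sol-L"`).
#' @param bin_s burst-timing envelope bin (default 0.005 s).
#' @param amp_bin_s amplitude envelope bin (default 0.05 s = 20 Hz).
#' @param bandpass apply the acquisition band-pass first (default TRUE).
#' @param episode_kind which episodes to use (default `"rhythmic"`).
#' @param ... further arguments to [detect_bursts].
#' @return list with `episodes`, `trains` (per channel), `envelopes`,
#'   and `metrics` — a tidy data frame `animal_id, group, condition, muscle,
#'   parameter, mean, sd, sem, cv, n`.
#' @export
animal_metrics <- function(rec, reference_channel = "Sol-L", bin_s = 0.005,
                           amp_bin_s = 0.05, bandpass = TRUE,
                           episode_kind = "rhythmic", ...) {
  validate_recording(rec)
  if (bandpass) rec <- emg_bandpass(rec)
  reference_channel <- channel_name(reference_channel)
  envs <- lapply(rec$channels, function(ch) emg_envelope(rec, ch, bin_s))
  names(envs) <- rec$channels
  trains <- lapply(envs, detect_bursts, ...)
  if (!reference_channel %in% rec$channels)
    stop("metrics usage error: reference channel '", reference_channel,
         "' absent", call. = FALSE)
  eps <- find_episodes(trains[[reference_channel]])
  eps <- eps[eps$kind %in% episode_kind, , drop = FALSE]
  rows <- list()
  if (nrow(eps) >= 1L) {
    ep <- eps[which.max(eps$n_bursts_reference), , drop = FALSE]
    for (ch in rec$channels) {
      tr <- trains[[ch]]
      add <- function(vals, param) {
        if (length(vals) >= 2L)
          rows[[length(rows) + 1L]] <<- cbind(
            data.frame(animal_id = rec$animal_id, group = rec$group,
                       condition = rec$condition, muscle = ch),
            summarize_param(vals, param))
      }
      add(cycle_durations(tr, ep), "cycle_duration")
      add(burst_durations(tr, ep), "burst_duration")
      amp_env <- emg_envelope(rec, ch, amp_bin_s)
      add(suppressWarnings(peak_amplitudes(amp_env, tr, ep)), "peak_amplitude")
    }
  }
  metrics <- if (length(rows)) do.call(rbind, rows) else
    data.frame(animal_id = character(0), group = character(0),
               condition = character(0), muscle = character(0),
               parameter = character(0), mean = numeric(0), sd = numeric(0),
               sem = numeric(0), cv = numeric(0), n = integer(0))
  rownames(metrics) <- NULL
  list(episodes = eps, trains = trains, envelopes = envs, metrics = metrics)
}
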