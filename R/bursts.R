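#' Detect EMG bursts on an envelope
#'
#' Dual-threshold hysteresis detector. Baseline `b` is the 20th percentile of
#' the envelope; spread `s` is the (scaled) median absolute deviation. The
#' envelope is segmented into maximal regions of bins at or above the off
#' threshold `b + k_off * s`; a region becomes a candidate burst iff it
#' sustains the on threshold `b + k_on * s` for at least half of `min_burst`
#' (consecutive bins), so single-bin baseline excursions neither seed bursts
#' nor contaminate onsets. Burst onset is the leading edge of that sustained
#' run's first bin; the offset is the trailing edge of the region (where the
#' envelope falls below the off threshold). Candidate bursts separated by
#' gaps shorter than `min_gap` merge, and bursts shorter than `min_burst`
#' are discarded.
#'
#' Both thresholds are additionally clamped into the envelope's dynamic range
#' `span = q95 - b`: the on threshold into `[b + 0.15 span, b + 0.5 span]`,
#' the off threshold into `[b + 0.07 span, b + 0.25 span]`. The lower clamp
#' keeps detection working on noise-free envelopes (where the MAD collapses
#' to zero although bursts are obvious) and keeps low-duty channels — where
#' the MAD reflects only baseline noise — from firing on baseline
#' fluctuations; the upper clamp keeps extreme MAD values from swallowing
#' real bursts. A genuinely flat envelope returns an empty train with
#' `flat = TRUE`.
#'
#' @param env an [emg_envelope].
#' @param k_on,k_off on/off thresholds in MAD units (defaults 3 and 1.5;
#'   require `k_on > k_off > 0`).
#' @param min_burst minimum burst duration in seconds (default 0.05).
#' @param min_gap gaps shorter than this merge adjacent runs (default 0.05).
#' @return object of class `burst_train`: `channel`, `bursts` (data frame
#'   `onset`, `offset`, `peak_time`, `peak_amplitude`), `detection_params`,
#'   `flat`.
#' @export
detect_bursts <- function(env, k_on = 3, k_off = 1.5, min_burst = 0.05,
                          min_gap = 0.05) {
  stopifnot(inherits(env, "emg_envelope"))
  if (!(k_on > k_off && k_off > 0))
    stop("burst parameter error: need k_on > k_off > 0", call. = FALSE)
  if (min_burst < env$bin_s || min_gap < env$bin_s)
    stop("burst parameter error: min_burst and min_gap must be >= bin width",
         call. = FALSE)
  v <- env$values
  params <- list(k_on = k_on, k_off = k_off, min_burst_s = min_burst,
                 min_gap_s = min_gap)
  empty <- data.frame(onset = numeric(0), offset = numeric(0),
                      peak_time = numeric(0), peak_amplitude = numeric(0))
  mk <- function(b, flat = FALSE) {
    structure(list(channel = env$channel, bursts = b,
                   detection_params = params, flat = flat),
              class = "burst_train")
  }
  b <- stats::quantile(v, 0.20, names = FALSE)
  s <- stats::mad(v)
  q95 <- stats::quantile(v, 0.95, names = FALSE)
  if (max(v) - min(v) <= 0) {
    w <- mk(empty, flat = TRUE)
    warning("flat envelope: no bursts detectable", call. = FALSE)
    return(w)
  }
  span <- max(q95 - b, max(v) - b)
  thr_on <- min(max(b + k_on * s, b + 0.15 * span), b + 0.5 * span)
  thr_off <- min(max(b + k_off * s, b + 0.07 * span), b + 0.25 * span)
  if (thr_off >= thr_on) thr_off <- b + 0.5 * (thr_on - b)
  above_off <- v >= thr_off
  if (!any(above_off)) return(mk(empty))
  r <- rle(above_off)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  reg <- cbind(start = starts[r$values], end = ends[r$values])
  ## classical hysteresis: a region is a candidate burst iff it sustains the
  ## on threshold for q consecutive bins (half of min_burst), which keeps
  ## single-bin baseline excursions from seeding or contaminating onsets;
  ## onset = start of the first such run, extent ends where the envelope
  ## falls below thr_off
  q_bins <- max(1L, ceiling(min_burst / env$bin_s / 2))
  qual <- apply(reg, 1L, function(rg) {
    hot <- v[rg[1L]:rg[2L]] >= thr_on
    rr <- rle(hot)
    ok <- which(rr$values & rr$lengths >= q_bins)
    if (!length(ok)) return(NA_integer_)
    rg[1L] + sum(rr$lengths[seq_len(ok[1L] - 1L)])
  })
  keep <- which(!is.na(qual))
  if (!length(keep)) return(mk(empty))
  cand <- data.frame(onset_bin = qual[keep], start_bin = reg[keep, "start"],
                     end_bin = reg[keep, "end"])
  ## merge candidate bursts whose off-threshold regions are separated by
  ## gaps < min_gap (edge to edge)
  gap_bins <- round(min_gap / env$bin_s)
  grp <- cumsum(c(1L, as.integer((cand$start_bin[-1L] -
                                  cand$end_bin[-nrow(cand)] - 1L) >= gap_bins)))
  out <- lapply(split(seq_len(nrow(cand)), grp), function(ix) {
    onset_bin <- cand$onset_bin[ix[1L]]
    i1 <- cand$end_bin[ix[length(ix)]]
    onset <- env_bin_time(env, onset_bin)
    offset <- env_bin_time(env, i1 + 1L)
    if (offset - onset < min_burst) return(NULL)
    seg <- onset_bin:i1
    pk <- seg[which.max(v[seg])]
    data.frame(onset = onset, offset = offset,
               peak_time = env_bin_time(env, pk) + env$bin_s / 2,
               peak_amplitude = v[pk])
  })
  bursts <- do.call(rbind, out[!vapply(out, is.null, logical(1))])
  if (is.null(bursts)) bursts <- empty
  rownames(bursts) <- NULL
  mk(bursts)
}

#' Number of bursts in a train
#' @param train a `burst_train`.
#' @return integer count.
#' @export
n_bursts <- function(train) nrow(train$bursts)

#' @export
print.burst_train <- function(x, ...) {
  cat(sprintf("<burst_train> %s: %d bursts%s\n", x$channel, n_bursts(x),
              if (isTRUE(x$flat)) " (flat envelope)" else ""))
  invisible(x)
}

#' Select analyzable episodes from a reference burst train
#'
#' Scans maximal runs of consecutive bursts (a run breaks where the
#' offset-to-onset gap exceeds `run_break_s`). A run of at least 10 bursts
#' whose cycle-duration coefficient of variation is at most `max_cycle_cv` is
#' a *rhythmic* episode; a failing run spanning at least `duration_floor`
#' seconds is an *irregular* episode; shorter failing runs yield nothing.
#' Episodes never overlap and rhythmic classification takes precedence.
#'
#' @param train reference-channel `burst_train` (conventionally the soleus,
#'   whose burst marks the stance phase).
#' @param max_cycle_cv rhythmicity criterion on the CV of onset-to-onset cycle
#'   durations (default 0.5).
#' @param duration_floor minimum span in seconds for an irregular episode
#'   (default 10).
#' @param run_break_s silent gap that splits runs of consecutive bursts
#'   (default 2 s).
#' @param min_bursts minimum burst count of a rhythmic episode (default 10).
#' @return data frame with columns `start`, `end`, `kind`
#'   (`"rhythmic"`/`"irregular"`), `n_bursts_reference`.
#' @export
find_episodes <- function(train, max_cycle_cv = 0.5, duration_floor = 10,
                          run_break_s = 2, min_bursts = 10) {
  stopifnot(inherits(train, "burst_train"))
  b <- train$bursts
  none <- data.frame(start = numeric(0), end = numeric(0),
                     kind = character(0), n_bursts_reference = integer(0))
  if (nrow(b) == 0L) return(none)
  gaps <- b$onset[-1L] - b$offset[-nrow(b)]
  run <- cumsum(c(1L, as.integer(gaps > run_break_s)))
  out <- lapply(split(seq_len(nrow(b)), run), function(ix) {
    nb <- length(ix)
    start <- b$onset[ix[1L]]; end <- b$offset[ix[nb]]
    if (nb >= min_bursts) {
      cyc <- diff(b$onset[ix])
      cv <- stats::sd(cyc) / mean(cyc)
      if (is.finite(cv) && cv <= max_cycle_cv)
        return(data.frame(start = start, end = end, kind = "rhythmic",
                          n_bursts_reference = nb))
    }
    if (end - start >= duration_floor)
      return(data.frame(start = start, end = end, kind = "irregular",
                        n_bursts_reference = nb))
    NULL
  })
  out <- do.call(rbind, out[!vapply(out, is.null, logical(1))])
  if (is.null(out)) return(none)
  rownames(out) <- NULL
  out
}

## Bursts of a train with onset inside [episode$start, episode$end].
bursts_in_episode <- function(train, episode) {
  b <- train$bursts
  b[b$onset >= episode$start & b$onset <= episode$end, , drop = FALSE]
}
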