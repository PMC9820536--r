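# Fixture builders shared across the suite. Everything is generated in code;
# no stored data files.

# Minimal recording from a signal matrix.
make_rec <- function(signal, fs = 2000, channels = NULL, group = "TTnoEB",
                     condition = "none", animal_id = "rat-1", t0 = 0) {
  signal <- as.matrix(signal)
  if (is.null(channels)) {
    channels <- colnames(signal)
    if (is.null(channels))
      channels <- c("Sol-L", "Sol-R", "TA-L", "TA-R")[seq_len(ncol(signal))]
  }
  emg_recording(signal, channels = channels, sampling_rate = fs,
                animal_id = animal_id, group = group, condition = condition,
                t0 = t0)
}

# Envelope object straight from a value vector (bypasses a recording).
make_env <- function(values, bin_s = 0.005, channel = "Sol-L", t0 = 0) {
  structure(list(channel = channel, bin_s = bin_s, values = as.numeric(values),
                 t0 = t0, provenance = list(integration_s = bin_s)),
            class = "emg_envelope")
}

# Square-wave envelope: bursts of `height` and duration `dur` every `period`
# seconds, on a baseline of `noise_sd` Gaussian bins (clipped at 0).
square_env <- function(n_bursts = 10, period = 1, dur = 0.3, height = 1,
                       bin_s = 0.005, noise_sd = 0, lead = 0.25) {
  total <- lead + n_bursts * period
  nb <- round(total / bin_s)
  v <- if (noise_sd > 0) pmax(stats::rnorm(nb, 0, noise_sd), 0) else numeric(nb)
  onsets <- lead + (seq_len(n_bursts) - 1) * period
  for (o in onsets) {
    i0 <- round(o / bin_s) + 1
    i1 <- round((o + dur) / bin_s)
    v[i0:i1] <- v[i0:i1] + height
  }
  list(env = make_env(v, bin_s), onsets = onsets, dur = dur)
}

# Burst train directly from onset/offset vectors.
make_train <- function(onsets, offsets = onsets + 0.3, channel = "Sol-L",
                       peak = 1) {
  structure(list(channel = channel,
                 bursts = data.frame(onset = onsets, offset = offsets,
                                     peak_time = (onsets + offsets) / 2,
                                     peak_amplitude = rep_len(peak, length(onsets))),
                 detection_params = list(), flat = FALSE),
            class = "burst_train")
}

episode_all <- function(train) {
  data.frame(start = min(train$bursts$onset) - 1e-9,
             end = max(train$bursts$offset) + 1e-9, kind = "rhythmic",
             n_bursts_reference = nrow(train$bursts))
}

# Exhaustive-enumeration oracle for the two-sided Mann-Whitney p-value:
# every assignment of pooled ranks to group A, doubling the smaller tail
# (the distribution of W is symmetric under H0).
mw_exact_enum <- function(a, b) {
  na <- length(a); nb <- length(b)
  pooled <- c(a, b)
  rk <- rank(pooled)
  w_obs <- sum(rk[seq_len(na)]) - na * (na + 1) / 2
  idx <- utils::combn(na + nb, na)
  ws <- apply(idx, 2, function(ix) sum(rk[ix]) - na * (na + 1) / 2)
  p <- 2 * min(mean(ws <= w_obs), mean(ws >= w_obs))
  min(1, p)
}
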