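## Synthetic locomotor-EMG generator: a central-pattern-generator style burst
## simulator whose statistical structure matches what the pipeline assumes --
## a stance-defining extensor (Sol) rhythm with Gaussian cycle jitter, the
## contralateral extensor and ipsilateral flexor coupled at configurable
## phases with von Mises noise, and band-limited-noise burst carriers.

#' Configuration of a synthetic EMG cohort
#'
#' All durations in seconds, frequencies in Hz, phases in degrees, amplitudes
#' in (volt-like) envelope units. The defaults describe a well-recovered
#' treadmill stepper: 1 s step cycle, long stance-related Sol bursts (duty
#' 0.35), brief swing-related TA bursts (duty 0.15), left-right and
#' flexor-extensor alternation (180 degrees) with concentration
#' `phase_kappa`.
#'
#' @param n_animals animals in the cohort.
#' @param group_label experimental group label.
#' @param condition recording condition tag.
#' @param duration recording length (default 25 s, ~ 24 step cycles).
#' @param sampling_rate sampling frequency (default 2000 Hz).
#' @param cycle_mean,cycle_jitter_sd step-cycle mean and Gaussian SD.
#' @param sol_duty,ta_duty burst duty cycles (fraction of the cycle).
#' @param interlimb_phase,intralimb_phase coupling phases in degrees.
#' @param phase_kappa von Mises concentration of the phase coupling
#'   (`Inf` disables phase jitter).
#' @param sol_amp,ta_amp within-burst signal amplitudes (carrier SD).
#' @param amp_jitter_cv per-burst lognormal amplitude jitter CV.
#' @param duty_jitter_cv per-burst lognormal duration jitter CV.
#' @param carrier_band band of the noise carrier (default 150-400 Hz).
#' @param carrier `"noise"` (band-limited Gaussian, realistic) or `"rect"`
#'   (alternating-sign rectangle whose rectified envelope is exactly the
#'   amplitude; used for exactness checks).
#' @param noise_sd baseline (non-burst) noise SD.
#' @param seed cohort master seed; each animal derives an independent
#'   substream from `(seed, animal_index)`.
#' @return object of class `cohort_config`.
#' @export
cohort_config <- function(n_animals = 5, group_label = "TTx2EB",
                          condition = "none", duration = 25,
                          sampling_rate = 2000, cycle_mean = 1.0,
                          cycle_jitter_sd = 0.05, sol_duty = 0.35,
                          ta_duty = 0.15, interlimb_phase = 180,
                          intralimb_phase = 180, phase_kappa = 8,
                          sol_amp = 1.0, ta_amp = 0.6, amp_jitter_cv = 0.1,
                          duty_jitter_cv = 0.08, carrier_band = c(150, 400),
                          carrier = c("noise", "rect"), noise_sd = 0.02,
                          seed = 1) {
  carrier <- match.arg(carrier)
  cfg <- list(n_animals = n_animals, group_label = group_label,
              condition = condition, duration = duration,
              sampling_rate = sampling_rate, cycle_mean = cycle_mean,
              cycle_jitter_sd = cycle_jitter_sd, sol_duty = sol_duty,
              ta_duty = ta_duty, interlimb_phase = interlimb_phase,
              intralimb_phase = intralimb_phase, phase_kappa = phase_kappa,
              sol_amp = sol_amp, ta_amp = ta_amp,
              amp_jitter_cv = amp_jitter_cv, duty_jitter_cv = duty_jitter_cv,
              carrier_band = carrier_band, carrier = carrier,
              noise_sd = noise_sd, seed = seed)
  if (!(cfg$sol_duty > 0 && cfg$sol_duty < 0.95) ||
      !(cfg$ta_duty > 0 && cfg$ta_duty < 0.95))
    stop("config error: duty cycles must lie in (0, 0.95) to avoid ",
         "overlapping same-muscle bursts", call. = FALSE)
  if (cfg$phase_kappa < 0) stop("config error: phase_kappa >= 0", call. = FALSE)
  if (cfg$sol_amp <= 0 || cfg$ta_amp <= 0)
    stop("config error: amplitudes must be > 0", call. = FALSE)
  structure(cfg, class = "cohort_config")
}

#' Treated-cohort preset (strong recovered stepping)
#'
#' Tight step rhythm (cycle jitter SD 0.05 s) and strong phase coupling
#' (kappa = 8, population r about 0.94): the generative picture of animals
#' whose polar-plot phases are concentrated.
#'
#' @param seed master seed.
#' @param ... overrides forwarded to [cohort_config].
#' @return a `cohort_config` with `group_label = "TTx2EB"`, `n_animals = 5`.
#' @export
preset_treated <- function(seed = 1, ...) {
  cohort_config(n_animals = 5, group_label = "TTx2EB", cycle_jitter_sd = 0.05,
                phase_kappa = 8, duty_jitter_cv = 0.08, seed = seed, ...)
}

#' Control-cohort preset (poorly coordinated stepping)
#'
#' Sloppy rhythm (cycle jitter SD 0.20 s), near-uniform phase coupling
#' (kappa = 0.3, population r about 0.15) and irregular burst durations
#' (duty jitter CV 0.25): the generative picture of dispersed polar plots.
#'
#' @inheritParams preset_treated
#' @return a `cohort_config` with `group_label = "TTnoEB"`, `n_animals = 7`.
#' @export
preset_control <- function(seed = 1, ...) {
  cohort_config(n_animals = 7, group_label = "TTnoEB", cycle_jitter_sd = 0.20,
                phase_kappa = 0.3, duty_jitter_cv = 0.25, seed = seed, ...)
}

#' Drug-perturbation configuration
#'
#' Generative transform emulating a 5-HT2 antagonist (cyproheptadine-like)
#' trial: reduced extensor amplitude and duration, lengthened but weaker
#' flexor bursts, and scrambled phase coupling. The default scale factors
#' mimic the direction and rough magnitude of the reference drug effects;
#' they are generative conveniences, not ground-truth claims.
#'
#' @param amp_scale_sol,amp_scale_ta post/pre amplitude scale factors.
#' @param sol_duration_scale,ta_duration_scale burst-duration scale factors.
#' @param phase_kappa_post post-drug von Mises concentration.
#' @param seed offset mixed into the post-drug substream.
#' @return object of class `drug_effect_config`.
#' @export
drug_effect_config <- function(amp_scale_sol = 0.45, amp_scale_ta = 0.5,
                               sol_duration_scale = 0.65,
                               ta_duration_scale = 2.2,
                               phase_kappa_post = 0.5, seed = 1) {
  stopifnot(amp_scale_sol > 0, amp_scale_ta > 0, sol_duration_scale > 0,
            ta_duration_scale > 0, phase_kappa_post >= 0)
  structure(list(amp_scale_sol = amp_scale_sol, amp_scale_ta = amp_scale_ta,
                 sol_duration_scale = sol_duration_scale,
                 ta_duration_scale = ta_duration_scale,
                 phase_kappa_post = phase_kappa_post, seed = seed),
            class = "drug_effect_config")
}

## Deterministic per-animal substream seed (kept below 2^31).
.animal_seed <- function(seed, animal_index, salt = 0) {
  as.integer((as.numeric(seed) * 1000003 + animal_index * 7919 +
                salt * 104729) %% 2147483647)
}

#' Generate one synthetic animal's recording
#'
#' Reference Sol-L onsets are drawn with Gaussian cycle jitter; Sol-R onsets
#' sit at `interlimb_phase` within each Sol-L cycle with von Mises noise; TA
#' onsets sit at `intralimb_phase` within the ipsilateral Sol cycles. Within
#' each burst window the signal is an amplitude-scaled unit-SD carrier
#' (band-limited noise, or an alternating-sign rectangle); outside bursts,
#' baseline noise. Fully deterministic for fixed `(seed, animal_index)`.
#' True burst windows are attached as `attr(, "truth")`.
#'
#' @param cfg a [cohort_config].
#' @param animal_index 1-based index of the animal within the cohort.
#' @return an [emg_recording] with channels `Sol-L`, `Sol-R`, `TA-L`, `TA-R`.
#' @export
generate_animal <- function(cfg, animal_index = 1) {
  stopifnot(inherits(cfg, "cohort_config"))
  old <- .save_rng(); on.exit(.restore_rng(old), add = TRUE)
  set.seed(.animal_seed(cfg$seed, animal_index))
  fs <- cfg$sampling_rate
  n <- round(cfg$duration * fs)
  ## reference rhythm: Sol-L onsets with truncated-Gaussian cycles
  k <- ceiling(cfg$duration / cfg$cycle_mean) + 4L
  cyc <- stats::rnorm(k, cfg$cycle_mean, cfg$cycle_jitter_sd)
  cyc <- pmax(cyc, 0.3 * cfg$cycle_mean)
  on_L <- 0.3 * cfg$cycle_mean + cumsum(c(0, cyc[-k]))
  keep <- on_L < cfg$duration - 0.05
  on_L <- on_L[keep]; cyc <- cyc[keep]
  nL <- length(on_L)
  vm_deg <- function(m, mu_deg) {
    rvonmises(m, mu_deg * pi / 180, cfg$phase_kappa) * 180 / pi
  }
  ## coupled onsets: one per reference cycle
  ph_R <- vm_deg(nL, cfg$interlimb_phase)
  on_R <- on_L + cyc * ph_R / 360
  ph_TL <- vm_deg(nL, cfg$intralimb_phase)
  on_TL <- on_L + cyc * ph_TL / 360
  cyc_R <- diff(on_R)
  ph_TR <- vm_deg(max(nL - 1L, 0L), cfg$intralimb_phase)
  on_TR <- on_R[-nL] + cyc_R * ph_TR / 360
  dur_jit <- function(m) {
    if (cfg$duty_jitter_cv <= 0) return(rep(1, m))
    sdl <- sqrt(log(1 + cfg$duty_jitter_cv^2))
    stats::rlnorm(m, -sdl^2 / 2, sdl)
  }
  amp_jit <- function(m, amp) {
    if (cfg$amp_jitter_cv <= 0) return(rep(amp, m))
    sdl <- sqrt(log(1 + cfg$amp_jitter_cv^2))
    amp * stats::rlnorm(m, -sdl^2 / 2, sdl)
  }
  mk_bursts <- function(onsets, local_cycle, duty, amp) {
    m <- length(onsets)
    dur <- duty * local_cycle * dur_jit(m)
    ## clip to the next same-muscle onset so bursts never overlap
    if (m > 1L) dur[-m] <- pmin(dur[-m], diff(onsets) - 2 / fs)
    dur <- pmax(dur, 2 / fs)
    list(onset = onsets, dur = dur, amp = amp_jit(m, amp))
  }
  bl <- list(
    "Sol-L" = mk_bursts(on_L, cyc, cfg$sol_duty, cfg$sol_amp),
    "Sol-R" = mk_bursts(on_R, c(cyc_R, cyc[nL]), cfg$sol_duty, cfg$sol_amp),
    "TA-L"  = mk_bursts(on_TL, cyc, cfg$ta_duty, cfg$ta_amp),
    "TA-R"  = mk_bursts(on_TR, cyc_R, cfg$ta_duty, cfg$ta_amp))
  carrier_unit <- function() {
    if (cfg$carrier == "rect") return(rep_len(c(1, -1), n))
    w <- stats::rnorm(n)
    bf <- signal::butter(4, cfg$carrier_band / (fs / 2), type = "pass")
    x <- signal::filtfilt(bf, w)
    x / stats::sd(x)
  }
  sig <- matrix(0, nrow = n, ncol = 4,
                dimnames = list(NULL, names(bl)))
  for (ch in names(bl)) {
    gate <- numeric(n)
    bb <- bl[[ch]]
    for (i in seq_along(bb$onset)) {
      i0 <- max(1L, round(bb$onset[i] * fs) + 1L)
      i1 <- min(n, round((bb$onset[i] + bb$dur[i]) * fs))
      if (i1 >= i0) gate[i0:i1] <- bb$amp[i]
    }
    x <- gate * carrier_unit()
    if (cfg$noise_sd > 0) x <- x + stats::rnorm(n, 0, cfg$noise_sd)
    sig[, ch] <- x
  }
  rec <- emg_recording(sig, sampling_rate = fs,
                       animal_id = sprintf("%s-%02d", cfg$group_label,
                                           animal_index),
                       group = cfg$group_label, condition = cfg$condition)
  attr(rec, "provenance") <- list(
    synthetic = list(seed = cfg$seed, animal_index = animal_index,
                     config = unclass(cfg)))
  attr(rec, "truth") <- bl
  rec
}

#' Generate a treated-vs-control cohort pair
#'
#' Two cohorts with known ground truth: by default a strongly coordinated,
#' low-jitter treated cohort (`n = 5`) and a weakly coordinated, high-jitter
#' control cohort (`n = 7`).
#'
#' @param cfg_treated,cfg_control [cohort_config]s (defaults
#'   [preset_treated] and [preset_control]).
#' @return named list of two lists of [emg_recording]s: `treated`, `control`.
#' @export
generate_cohort <- function(cfg_treated = preset_treated(),
                            cfg_control = preset_control()) {
  list(
    treated = lapply(seq_len(cfg_treated$n_animals), function(i)
      generate_animal(cfg_treated, i)),
    control = lapply(seq_len(cfg_control$n_animals), function(i)
      generate_animal(cfg_control, i)))
}

#' Generate a paired pre/post drug trial for one animal
#'
#' The pre-drug recording comes from `cfg` unchanged; the post-drug recording
#' is regenerated with the same animal identity under scaled amplitudes and
#' burst durations and the post-drug phase concentration, on an independent
#' random substream.
#'
#' @param cfg a [cohort_config] describing the pre-drug state.
#' @param drug a [drug_effect_config].
#' @param animal_index animal index within the cohort.
#' @return list with [emg_recording]s `pre` and `post`.
#' @export
apply_drug_effect <- function(cfg, drug = drug_effect_config(),
                              animal_index = 1) {
  stopifnot(inherits(cfg, "cohort_config"),
            inherits(drug, "drug_effect_config"))
  if (cfg$ta_duty * drug$ta_duration_scale >= 0.95)
    stop("config error: scaled TA duty >= cycle", call. = FALSE)
  if (cfg$sol_duty * drug$sol_duration_scale >= 0.95)
    stop("config error: scaled Sol duty >= cycle", call. = FALSE)
  pre_cfg <- cfg
  pre_cfg$condition <- "pre_drug"
  pre <- generate_animal(pre_cfg, animal_index)
  post_cfg <- cfg
  post_cfg$condition <- "post_drug"
  post_cfg$sol_amp <- cfg$sol_amp * drug$amp_scale_sol
  post_cfg$ta_amp <- cfg$ta_amp * drug$amp_scale_ta
  post_cfg$sol_duty <- cfg$sol_duty * drug$sol_duration_scale
  post_cfg$ta_duty <- cfg$ta_duty * drug$ta_duration_scale
  post_cfg$phase_kappa <- drug$phase_kappa_post
  post_cfg$seed <- .animal_seed(cfg$seed, animal_index, salt = drug$seed + 1)
  post <- generate_animal(post_cfg, animal_index)
  post$animal_id <- pre$animal_id
  list(pre = pre, post = post)
}
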