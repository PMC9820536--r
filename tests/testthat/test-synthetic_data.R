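test_that("generation is deterministic and leaves the caller's RNG alone", {
  cfg <- cohort_config(duration = 6, seed = 11)
  r1 <- generate_animal(cfg, 2)
  set.seed(999); before <- runif(1)
  r2 <- generate_animal(cfg, 2)
  expect_identical(r1$signal, r2$signal)
  # distinct animal indices give distinct streams
  r3 <- generate_animal(cfg, 3)
  expect_false(identical(r1$signal, r3$signal))
  # caller RNG restored
  set.seed(999)
  expect_identical(before, runif(1))
})

test_that("synthetic recordings satisfy the container invariants", {
  for (seed in 1:5) {
    rec <- generate_animal(cohort_config(duration = 5, seed = seed), 1)
    expect_silent(validate_recording(rec))
    expect_setequal(rec$channels, c("Sol-L", "Sol-R", "TA-L", "TA-R"))
  }
  expect_error(cohort_config(sol_duty = 0.99), "config error")
  expect_error(cohort_config(phase_kappa = -1), "config error")
})

test_that("noise-free rectangular bursts reproduce configured amplitudes exactly", {
  cfg <- cohort_config(duration = 12, cycle_jitter_sd = 0, phase_kappa = Inf,
                       amp_jitter_cv = 0, duty_jitter_cv = 0, noise_sd = 0,
                       carrier = "rect", sol_amp = 1.25, ta_amp = 0.5,
                       seed = 3)
  rec <- generate_animal(cfg, 1)
  env <- emg_envelope(rec, "Sol-L", 0.005)
  tr <- detect_bursts(env)
  ep <- episode_all(tr)
  pk <- suppressWarnings(peak_amplitudes(env, tr, ep))
  expect_equal(as.numeric(pk), rep(1.25, length(pk)), tolerance = 1e-12)
  env_ta <- emg_envelope(rec, "TA-L", 0.005)
  pk_ta <- suppressWarnings(
    peak_amplitudes(env_ta, detect_bursts(env_ta), ep))
  expect_equal(as.numeric(pk_ta), rep(0.5, length(pk_ta)), tolerance = 1e-12)
})

test_that("disabled phase jitter pins detected interlimb phases at 180 degrees", {
  cfg <- cohort_config(duration = 15, cycle_jitter_sd = 0, phase_kappa = Inf,
                       amp_jitter_cv = 0, duty_jitter_cv = 0, noise_sd = 0,
                       carrier = "rect", seed = 2)
  rec <- generate_animal(cfg, 1)
  trs <- lapply(c("Sol-L", "Sol-R"), function(ch)
    detect_bursts(emg_envelope(rec, ch, 0.005)))
  ep <- find_episodes(trs[[1]])
  ph <- onset_phases(trs[[1]], trs[[2]], ep[1, ], "interlimb")
  bin_phase <- 360 * 0.005 / 1.0
  expect_true(all(abs(ph$phases - 180) <= bin_phase + 1e-9))
})

test_that("cohort presets produce the designed group contrast", {
  coh <- generate_cohort(preset_treated(seed = 21), preset_control(seed = 22))
  expect_length(coh$treated, 5)
  expect_length(coh$control, 7)
  expect_equal(unique(vapply(coh$treated, function(r) r$group, "")), "TTx2EB")
  tre <- analyze_cohort(coh$treated, bandpass = FALSE)
  ctl <- analyze_cohort(coh$control, bandpass = FALSE)
  r_tre <- tre$coordination$r[tre$coordination$pairing == "interlimb"]
  r_ctl <- ctl$coordination$r[ctl$coordination$pairing == "interlimb"]
  expect_gt(median(r_tre), median(r_ctl))
  cv_tre <- tre$metrics$cv[tre$metrics$muscle == "Sol-L" &
                             tre$metrics$parameter == "cycle_duration"]
  cv_ctl <- ctl$metrics$cv[ctl$metrics$muscle == "Sol-L" &
                             ctl$metrics$parameter == "cycle_duration"]
  expect_lt(mean(cv_tre), mean(cv_ctl))
})

test_that("a unit drug transform leaves the generative configuration unchanged", {
  cfg <- cohort_config(duration = 8, seed = 13)
  null_drug <- drug_effect_config(amp_scale_sol = 1, amp_scale_ta = 1,
                                  sol_duration_scale = 1,
                                  ta_duration_scale = 1,
                                  phase_kappa_post = cfg$phase_kappa)
  pair <- apply_drug_effect(cfg, null_drug, 1)
  expect_identical(pair$pre$animal_id, pair$post$animal_id)
  pre_cfg <- attr(pair$pre, "provenance")$synthetic$config
  post_cfg <- attr(pair$post, "provenance")$synthetic$config
  same <- setdiff(names(pre_cfg), c("seed", "condition"))
  expect_identical(pre_cfg[same], post_cfg[same])
  expect_error(
    apply_drug_effect(cohort_config(ta_duty = 0.5),
                      drug_effect_config(ta_duration_scale = 2.2)),
    "config error")
})

test_that("the default drug transform shifts amplitude, duration and coupling", {
  cfg <- preset_treated(seed = 31)
  pair <- apply_drug_effect(cfg, drug_effect_config(), 1)
  bat <- drug_trial_battery(list(pair), bandpass = FALSE)
  rr <- bat$ratios
  expect_lt(rr$sol_peak_amplitude, 1)
  expect_lt(rr$sol_burst_duration, 1)
  expect_gt(rr$ta_burst_duration, 1)
  expect_lt(rr$interlimb_r, 1)
})
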