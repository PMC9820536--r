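test_that("onset phases map test onsets into reference cycles", {
  ref <- make_train(c(0, 1, 2), c(0.3, 1.3, 2.3))
  ep <- episode_all(ref)
  # half-cycle alternation
  tst <- make_train(c(0.5, 1.5), c(0.6, 1.6), channel = "Sol-R")
  ph <- onset_phases(ref, tst, ep, "interlimb")
  expect_equal(ph$phases, c(180, 180))
  # synchrony
  ph0 <- onset_phases(ref, make_train(c(0, 1), c(0.1, 1.1), channel = "Sol-R"),
                      ep, "interlimb")
  expect_equal(ph0$phases, c(0, 0))
  # quarter cycle
  ph90 <- onset_phases(make_train(c(0, 1), c(0.3, 1.3)),
                       make_train(0.25, 0.35, channel = "TA-L"),
                       episode_all(make_train(c(0, 1), c(0.3, 1.3))),
                       "intralimb")
  expect_equal(ph90$phases, 90)
  # multiple onsets in one cycle: first used, multiplicity flagged
  phm <- onset_phases(ref, make_train(c(0.25, 0.5), c(0.3, 0.6),
                                      channel = "Sol-R"), ep, "interlimb")
  expect_equal(phm$phases, 90)
  expect_equal(phm$n_multiple, 1)
  # empty-cycle skipping
  phs <- onset_phases(ref, make_train(1.5, 1.6, channel = "Sol-R"), ep,
                      "interlimb")
  expect_equal(phs$phases, 180)
})

test_that("mean vector obeys the resultant-length identities", {
  mv <- mean_vector(rep(90, 10))
  expect_equal(mv$r, 1)
  expect_equal(mv$mean_angle, 90)
  expect_true(mv$coordinated)
  # full symmetric cancellation
  expect_equal(mean_vector(c(0, 90, 180, 270))$r, 0, tolerance = 1e-12)
  expect_error(mean_vector(numeric(0)), "insufficient")
  # coordinated iff r > cR
  mv2 <- mean_vector(c(10, 100, 200, 300, 40))
  expect_equal(mv2$coordinated, mv2$r > mv2$cR)
  expect_equal(rayleigh_p(mv2$r, mv2$n) < 0.05, mv2$r > critical_r(mv2$n),
               tolerance = 0)
})

test_that("rotating all phases rotates the mean angle and preserves r and p", {
  set.seed(12)
  for (rep in 1:5) {
    ph <- runif(15, 0, 360)
    rot <- runif(1, 0, 360)
    m1 <- mean_vector(ph); m2 <- mean_vector((ph + rot) %% 360)
    expect_equal(m2$r, m1$r, tolerance = 1e-12)
    expect_equal(m2$rayleigh_p, m1$rayleigh_p, tolerance = 1e-12)
    expect_equal(m2$mean_angle, (m1$mean_angle + rot) %% 360,
                 tolerance = 1e-9)
    # Watson U2 invariant under common rotation of both samples
    ph2 <- runif(15, 0, 360)
    u1 <- watson_u2(ph, ph2)
    u2r <- watson_u2((ph + rot) %% 360, (ph2 + rot) %% 360)
    expect_equal(u1$statistic, u2r$statistic, tolerance = 1e-9)
  }
})

test_that("Watson U2 separates concentrated opposite samples, not identical ones", {
  set.seed(3)
  a <- rvonmises(20, 0, 20) * 180 / pi
  b <- rvonmises(20, pi, 20) * 180 / pi
  expect_lt(watson_u2(a, b, method = "permutation", seed = 2,
                      n_perm = 999)$p_value, 0.01)
  expect_lt(watson_u2(a, b)$p_value, 0.01)
  same <- runif(12, 0, 360)
  expect_gt(watson_u2(same, same, method = "permutation", seed = 2,
                      n_perm = 999)$p_value, 0.9)
  expect_error(watson_u2(runif(3, 0, 360), runif(10, 0, 360)), "n >= 4")
})

test_that("Moore's paired test finds consistent rotations of clustered phases", {
  set.seed(2)
  pre <- rvonmises(10, pi, 8) * 180 / pi
  shifted <- moore_paired(pre, pre + 90, n_perm = 1999, seed = 4)
  expect_lt(shifted$p_value, 0.05)
  # tabulated route agrees on significance
  expect_true(moore_paired(pre, pre + 90, method = "tabulated")$significant)
  # null case: no change
  expect_equal(moore_paired(pre, pre)$p_value, 1)
  expect_error(moore_paired(pre[1:4], pre[1:4] + 10), "5 pairs")
  expect_error(moore_paired(c(pre[-1], NA), pre), "non-finite")
})

test_that("von Mises sampler matches its closed-form resultant length", {
  set.seed(8)
  for (kappa in c(0.5, 2, 8)) {
    ang <- rvonmises(4000, pi / 3, kappa) * 180 / pi
    mv <- mean_vector(ang)
    expect_lt(abs(mv$r - vm_expected_r(kappa)), 0.03)
    expect_lt(abs(mv$mean_angle - 60), 5)
  }
  # kappa = 0 is uniform (r near 0); kappa = Inf is degenerate at mu
  expect_lt(mean_vector(rvonmises(4000, 0, 0) * 180 / pi)$r, 0.05)
  expect_equal(unique(rvonmises(5, 1, Inf)), 1)
})

test_that("coordination_report recovers generative coupling per animal", {
  rec <- generate_animal(cohort_config(seed = 5, phase_kappa = 8), 1)
  cr <- coordination_report(rec)
  df <- do.call(rbind, lapply(cr, as.data.frame))
  inter <- df[df$pairing == "interlimb", ]
  expect_lt(abs(inter$mean_angle_deg - 180), 10)
  expect_lt(abs(inter$r - vm_expected_r(8)), 0.07)
  expect_true(all(df$coordinated))
  # missing TA-R channel with side R requested -> usage error
  rec3 <- rec
  keep <- c("Sol-L", "Sol-R", "TA-L")
  rec3$signal <- rec3$signal[, keep]; rec3$channels <- keep
  expect_error(coordination_report(rec3, sides = "R"), "usage error")
  expect_s3_class(coordination_report(rec3)[[2]], "circ_stat")
})
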