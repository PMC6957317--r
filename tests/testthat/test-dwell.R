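test_that("immobile-track extraction requires slow-dwell recordings", {
  fastcell <- simulate_cell(catalog$MeCP2_GC_WT, nucleus_geometry(3),
                            fast_acq(100), n_molecules = 50, seed = 1)
  expect_error(extract_immobile_tracks(fastcell), "slow")
})

test_that("a persistently bound molecule yields one full-length track", {
  p <- kinetic_preset("stuck", 0.999999, 1.0, tau_short_s = 1e5,
                      tau_long_s = 1e6, f_long_event = 1)
  acq <- slow_acq(n_frames = 14, bleach_prob_per_frame = 0)
  cell <- simulate_cell(p, nucleus_geometry(3), acq, n_molecules = 1,
                        seed = 2, n_active = 1)
  tr <- extract_immobile_tracks(cell)
  expect_equal(length(unique(tr$track_id)), 1)
  expect_equal(nrow(tr), 14)
  expect_equal(track_durations(tr), 13 * 0.5)
})

test_that("free molecules cannot form multi-frame immobile tracks", {
  # analytic check: a free D = 1 step over 0.5 s is Rayleigh with
  # E[r^2] = 4 D dt = 2 um^2; the dwell gate is 0.316 um, so
  # P(step < gate) = 1 - exp(-0.1/2) ~ 4.9% per frame even before blur
  gate <- compute_r_max(0.05, 0.5)
  p_link <- 1 - exp(-gate^2 / (4 * 1 * 0.5))
  expect_lt(p_link, 0.05)
  # and in simulation free molecules are blurred away entirely
  pf <- kinetic_preset("free", 0, 1.0)
  cell <- simulate_cell(pf, nucleus_geometry(3), slow_acq(1000),
                        n_molecules = 50, seed = 3)
  expect_equal(nrow(cell$localizations), 0)
})

test_that("immobile track sets are almost purely bound molecules", {
  cell <- simulate_cell(catalog$MeCP2_GC_WT, nucleus_geometry(3),
                        slow_acq(2000), n_molecules = 60, seed = 4)
  tr <- extract_immobile_tracks(cell)
  gt <- cell$ground_truth
  st <- gt$state[match(paste(tr$molecule_id, tr$frame),
                       paste(gt$molecule_id, gt$frame))]
  expect_gte(mean(st != "FREE"), 0.95)
})

test_that("survival curves count and normalize correctly", {
  sc <- survival_curve(c(0.5, 1.0, 1.5), dt = 0.5)
  expect_equal(sc$t, c(0.5, 1.0, 1.5))
  expect_equal(sc$S, c(1, 2 / 3, 1 / 3))
  expect_true("low_n" %in% sc$flags)

  # all-equal durations: a step function
  sc2 <- survival_curve(rep(2, 100), dt = 0.5)
  expect_equal(sc2$S, 1)

  # exponential durations: slope of log S recovers the rate
  set.seed(6)
  d <- (1 + rgeom(10000, 1 - exp(-0.5 / 5))) * 0.5
  sc3 <- survival_curve(d, dt = 0.5)
  use <- sc3$S > 0.01
  slope <- coef(lm(log(sc3$S[use]) ~ sc3$t[use]))[2]
  expect_equal(unname(-slope), 1 / 5, tolerance = 0.05)
  expect_true(all(diff(sc3$S) <= 0))
})

test_that("double-exponential fits recover clean mixtures", {
  set.seed(7)
  # single-exponential truth: flagged, both time constants near 5 s
  d1 <- synthetic_durations(5000, 0, 5, 5)
  f1 <- fit_double_exponential(survival_curve(d1, 0.5),
                               detection_correction = FALSE)
  expect_true("effectively_single_exponential" %in% f1$flags)
  expect_equal(f1$tau_short_s, 5, tolerance = 0.15)

  # the studied mixture at 5e3 events, no bleaching
  d2 <- synthetic_durations(5000, 0.25, 2, 7)
  f2 <- fit_double_exponential(survival_curve(d2, 0.5),
                               detection_correction = FALSE)
  expect_gte(f2$f_long, 0.20); expect_lte(f2$f_long, 0.30)
  expect_gte(f2$tau_long_s, 5.6); expect_lte(f2$tau_long_s, 8.4)
  expect_equal(f2$tau_short_s, 2, tolerance = 0.25)

  # f_long = 1: a single exponential at tau_long; the two-component fit
  # is amplitude-degenerate there, so check the amplitude-weighted time
  # constant instead of the individual (unidentifiable) components
  d3 <- synthetic_durations(5000, 1, 2, 7)
  f3 <- fit_double_exponential(survival_curve(d3, 0.5),
                               detection_correction = FALSE)
  tau_eff <- f3$f_long_amplitude * f3$tau_long_s +
    (1 - f3$f_long_amplitude) * f3$tau_short_s
  expect_equal(tau_eff, 7, tolerance = 0.15)
})

test_that("non-monotone curves are rejected", {
  bad <- structure(list(t = c(0.5, 1, 1.5, 2, 2.5), S = c(1, 0.5, 0.6, 0.3, 0.1),
                        n_tracks = 100, durations = rep(1, 100), dt = 0.5,
                        flags = character(0)),
                   class = "survival_curve")
  expect_error(fit_double_exponential(bad), "monotone")
})

test_that("bleach correction divides out the control decay", {
  set.seed(8)
  # control identically 1: identity
  d <- synthetic_durations(2000, 0.25, 2, 7)
  sc <- survival_curve(d, 0.5)
  ctrl1 <- structure(list(t = c(0.5, max(sc$t)), S = c(1, 1), n_tracks = 1000,
                          durations = d, dt = 0.5, flags = character(0)),
                     class = "survival_curve")
  cc <- bleach_correct(sc, ctrl1)
  expect_equal(cc$S, sc$S, tolerance = 1e-12)

  # identical sample and control: flat S ~ 1
  cc2 <- bleach_correct(sc, sc)
  expect_true(all(abs(cc2$S - 1) < 1e-9))

  # known bleach rate: corrected tau recovers 1/(1/tau_obs - k_b)
  k_b <- 1 - exp(-0.5 * 0.04)   # per-frame survival for k_b = 0.04/s
  tau <- 5
  rate_obs <- 1 / tau + 0.04
  d_obs <- (1 + rgeom(20000, 1 - exp(-0.5 * rate_obs))) * 0.5
  d_ctl <- (1 + rgeom(20000, k_b)) * 0.5
  sco <- survival_curve(d_obs, 0.5)
  scc <- survival_curve(d_ctl, 0.5)
  corr <- bleach_correct(sco, scc)
  fitc <- fit_double_exponential(corr, detection_correction = FALSE)
  tau_hat <- max(fitc$tau_short_s, fitc$tau_long_s)
  expect_equal(tau_hat, tau, tolerance = 0.15)

  expect_error(bleach_correct(sco, survival_curve(c(0.5, 1), 0.5)), "support")
})

test_that("long residence times recover across reference factors", {
  # Sox2 / TBP / H1.0-style presets: tau_long within 20% at >= 3e3 events
  for (cond in list(c(10, 0.25), c(14, 0.25))) {
    set.seed(40 + cond[1])
    d <- synthetic_durations(5000, cond[2], 2, cond[1])
    f <- fit_double_exponential(survival_curve(d, 0.5),
                                detection_correction = FALSE)
    expect_lt(abs(f$tau_long_s - cond[1]) / cond[1], 0.2)
  }
})
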