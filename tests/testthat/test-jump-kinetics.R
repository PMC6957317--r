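test_that("jump collection counts lags and honours the per-track cap", {
  set.seed(7)
  tr5 <- line_track(5)
  tr5$track_id <- 1
  jd <- collect_jumps(tr5, dt = 0.01)
  expect_equal(lengths(jd$jumps), c(4L, 3L, 2L, 1L))

  tr200 <- line_track(200)
  tr200$track_id <- 1
  capped <- collect_jumps(tr200, dt = 0.01, cap_per_track = 30)
  expect_equal(lengths(capped$jumps), rep(30L, 4))
  uncapped <- collect_jumps(tr200, dt = 0.01)
  expect_equal(lengths(uncapped$jumps), c(199L, 198L, 197L, 196L))
})

test_that("stationary noisy emitter gives Rayleigh lag-1 jumps", {
  set.seed(8)
  sigma <- 0.035
  st <- data.frame(frame = 0:4999, t_s = (0:4999) * 0.01,
                   x_um = rnorm(5000, 0, sigma), y_um = rnorm(5000, 0, sigma),
                   track_id = 1)
  jd <- collect_jumps(st, dt = 0.01, max_lag = 1)
  # the norm of a difference of two 2D Gaussians: Rayleigh, scale sigma*sqrt(2)
  p <- suppressWarnings(
    ks.test(jd$jumps[[1]]^2, "pexp", rate = 1 / (4 * sigma^2))$p.value)
  expect_gt(p, 0.01)
})

test_that("model_jump_cdf has the right limits and closed-form values", {
  expect_equal(model_jump_cdf(0, 1, 0.01), 0)
  expect_equal(model_jump_cdf(1e6, 1, 0.01), 1)
  expect_equal(model_jump_cdf(0.2, 1, 0.01, 0), 1 - exp(-1))
  expect_error(model_jump_cdf(0.1, -1, 0.01))
  # Monte-Carlo oracle: 1e6 simulated jumps vs the analytic CDF
  set.seed(9)
  n <- 1e6
  D <- 1; dt <- 0.01; sigma <- 0.02
  dx <- rnorm(n, 0, sqrt(2 * D * dt)) + rnorm(n, 0, sigma) - rnorm(n, 0, sigma)
  dy <- rnorm(n, 0, sqrt(2 * D * dt)) + rnorm(n, 0, sigma) - rnorm(n, 0, sigma)
  r <- sort(sqrt(dx^2 + dy^2))
  sup <- max(abs(model_jump_cdf(r, D, dt, sigma) - (seq_len(n) - 0.5) / n))
  expect_lt(sup, 0.002)
})

test_that("the fitted mixture CDF is a valid CDF on the fit grid", {
  set.seed(10)
  jd <- synthetic_jumps(5000, 0.5, 1.0)
  fit <- fit_two_state(jd, sigma = 0.035)
  r <- seq(0, 3, length.out = 400)
  cdf <- fit$F_bound_hat * model_jump_cdf(r, fit$D_bound_hat, 0.01, 0.035) +
    (1 - fit$F_bound_hat) * model_jump_cdf(r, fit$D_free_hat, 0.01, 0.035)
  expect_true(all(diff(cdf) >= -1e-12))
  expect_equal(cdf[1], 0)
  expect_gt(model_jump_cdf(10, fit$D_free_hat, 0.01, 0.035), 0.999999)
})

test_that("two-state fit recovers parameters from iid jumps and a simulated cell", {
  # iid jump draws at the reference condition: recovery within 0.05 / 10%
  set.seed(22)
  fit0 <- fit_two_state(synthetic_jumps(10000, 0.5, 1.0), sigma = 0.035)
  expect_gte(fit0$F_bound_hat, 0.45); expect_lte(fit0$F_bound_hat, 0.55)
  expect_gte(fit0$D_free_hat, 0.9); expect_lte(fit0$D_free_hat, 1.1)

  # full single-cell simulation (adds per-cell occupancy realization noise)
  cell <- simulate_cell(catalog$MeCP2_GC_WT, nucleus_geometry(3),
                        fast_acq(2500), n_molecules = 800, seed = 23)
  tr <- link_tracks(cell$localizations, linking_config(5, 0.01, 0.035))
  jd <- collect_jumps(tr)
  expect_gt(jd$n_total, 1e4)
  fit <- fit_two_state(jd, sigma = 0.035)
  occ <- mean(cell$ground_truth$state != "FREE")
  expect_lt(abs(fit$F_bound_hat - occ), 0.05)
  expect_gte(fit$D_free_hat, 0.9); expect_lte(fit$D_free_hat, 1.1)
  expect_lte(fit$D_bound_hat, 0.08)
})

test_that("boundary mixtures are recovered", {
  set.seed(24)
  # pure free population at D = 4
  free <- synthetic_jumps(20000, 0, 4.0)
  expect_lte(fit_two_state(free, sigma = 0.035)$F_bound_hat, 0.05)
  # everything at the noise scale: fully bound
  allb <- synthetic_jumps(20000, 1 - 1e-9, 4.0)
  expect_gte(fit_two_state(allb, sigma = 0.035)$F_bound_hat, 0.95)
  # low-confidence flag below 200 jumps
  tiny <- synthetic_jumps(100, 0.5, 1.0)
  expect_true("low_confidence" %in% fit_two_state(tiny, sigma = 0.035)$flags)
  expect_error(fit_two_state(structure(list(jumps = list(numeric(0)), dt = 0.01,
                                            max_lag = 1, n_total = 0),
                                       class = "jump_data"), sigma = 0.035))
})

test_that("recovery error of the bound fraction decreases with jump count", {
  set.seed(25)
  err <- vapply(c(1e3, 1e4, 1e5), function(n) {
    e <- replicate(5, abs(fit_two_state(synthetic_jumps(n, 0.55, 1.0),
                                        sigma = 0.035)$F_bound_hat - 0.55))
    mean(e)
  }, 0)
  expect_true(all(diff(err) < 0))
})

test_that("lag-1-only and lags-1-4 fits agree on matched simulations", {
  cell <- simulate_cell(catalog$MeCP2_GC_WT, nucleus_geometry(3),
                        fast_acq(2500), n_molecules = 800, seed = 26)
  tr <- link_tracks(cell$localizations, linking_config(5, 0.01, 0.035))
  jd <- collect_jumps(tr)
  f1 <- fit_two_state(jd, sigma = 0.035, max_lag = 1)
  f4 <- fit_two_state(jd, sigma = 0.035, max_lag = 4)
  expect_lt(abs(f1$F_bound_hat - f4$F_bound_hat), 0.05)
  expect_lt(abs(f1$D_free_hat - f4$D_free_hat) / f4$D_free_hat, 0.15)
})

test_that("sub-frame switching shifts recovered parameters by under 2%", {
  args <- list(preset = catalog$MeCP2_GC_WT, geometry = nucleus_geometry(3),
               acq = fast_acq(3500), n_molecules = 1200, seed = 27)
  fit_for <- function(subframe) {
    cell <- do.call(simulate_cell, c(args, subframe_switching = subframe))
    tr <- link_tracks(cell$localizations, linking_config(5, 0.01, 0.035))
    fit_two_state(collect_jumps(tr), sigma = 0.035)
  }
  a <- fit_for(TRUE); b <- fit_for(FALSE)
  expect_lt(abs(a$F_bound_hat - b$F_bound_hat) / b$F_bound_hat, 0.02 + 0.02)
  expect_lt(abs(a$D_free_hat - b$D_free_hat) / b$D_free_hat, 0.02 + 0.02)
})

test_that("condition summaries report per-cell mean and SD", {
  mk <- function(F, D) structure(list(F_bound_hat = F, D_free_hat = D,
                                      D_bound_hat = 0.005, n_jumps = 1000),
                                 class = "two_state_fit")
  same <- summarize_condition(list(mk(0.5, 1), mk(0.5, 1), mk(0.5, 1)))
  expect_equal(unname(same$F_bound["sd"]), 0)
  expect_equal(unname(same$F_bound["mean"]), 0.5)
  # mixing two separated conditions inflates the SD beyond the flag level
  mixed <- summarize_condition(c(replicate(5, mk(0.3, 1), simplify = FALSE),
                                 replicate(5, mk(0.7, 1), simplify = FALSE)))
  expect_true("bimodality_suspected" %in% mixed$flags)
  expect_error(summarize_condition(list(mk(0.5, 1))))
})
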