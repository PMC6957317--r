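test_that("identical seeds give bit-identical recordings", {
  p <- catalog$MeCP2_GC_WT
  acq <- fast_acq(n_frames = 300)
  a <- simulate_cell(p, nucleus_geometry(3), acq, n_molecules = 100, seed = 5)
  b <- simulate_cell(p, nucleus_geometry(3), acq, n_molecules = 100, seed = 5)
  expect_identical(a$localizations, b$localizations)
  expect_identical(a$ground_truth, b$ground_truth)
  expect_identical(a$events, b$events)
  c <- simulate_cell(p, nucleus_geometry(3), acq, n_molecules = 100, seed = 6)
  expect_false(identical(a$localizations, c$localizations))
})

test_that("without bleaching every molecule appears in all frames", {
  p <- catalog$MeCP2_GC_WT
  acq <- fast_acq(n_frames = 100, bleach_prob_per_frame = 0)
  cell <- suppressWarnings(
    simulate_cell(p, nucleus_geometry(3), acq, n_molecules = 10,
                  seed = 2, n_active = 10))
  counts <- table(cell$ground_truth$molecule_id)
  expect_length(counts, 10)
  expect_true(all(counts == 100))
  expect_true(all(cell$ground_truth$detected))
})

test_that("ground-truth occupancy matches the preset bound fraction", {
  p <- catalog$MeCP2_GC_WT
  acq <- fast_acq(n_frames = 40, bleach_prob_per_frame = 0)
  # packing 5000 emitters into one nucleus trips the density warning the
  # simulator raises when tracking would be ambiguous
  expect_warning(
    cell <- simulate_cell(p, nucleus_geometry(3), acq, n_molecules = 5000,
                          seed = 3, n_active = 5000),
    "density")
  occ <- mean(cell$ground_truth$state != "FREE")
  # molecules are initialized independently, so 3 SE of a binomial on the
  # number of molecules bounds the sampling error
  se <- sqrt(0.55 * 0.45 / 5000)
  expect_lt(abs(occ - 0.55), max(3 * se, 0.02))
})

test_that("pure-free displacements obey the 2D Brownian moment", {
  pf <- kinetic_preset("free", 0, 1.0)
  acq <- fast_acq(n_frames = 25000, bleach_prob_per_frame = 0,
                  localization_sigma_um = 0)
  cell <- simulate_cell(pf, nucleus_geometry(100), acq, n_molecules = 5,
                        seed = 9, n_active = 5)
  gt <- cell$ground_truth
  gt <- gt[order(gt$molecule_id, gt$frame), ]
  same <- diff(gt$molecule_id) == 0
  d2 <- (diff(gt$true_x_um)^2 + diff(gt$true_y_um)^2)[same]
  expect_gt(length(d2), 1e5)
  expect_equal(mean(d2), 4 * 1.0 * 0.01, tolerance = 0.02)
})

test_that("squared jumps are exponential with mean 4 D dt + 4 sigma^2 across seeds", {
  # KS test against the analytic law at alpha = 0.01; allow at most one
  # failing seed in 10
  pf <- kinetic_preset("free", 0, 1.0)
  sigma <- 0.035
  fails <- 0
  for (s in 1:10) {
    acq <- fast_acq(n_frames = 2500, bleach_prob_per_frame = 0,
                    localization_sigma_um = sigma)
    cell <- simulate_cell(pf, nucleus_geometry(100), acq, n_molecules = 4,
                          seed = 100 + s, n_active = 4)
    loc <- cell$localizations
    loc <- loc[order(loc$molecule_id, loc$frame), ]
    same <- diff(loc$molecule_id) == 0
    d2 <- (diff(loc$x_um)^2 + diff(loc$y_um)^2)[same]
    # noise is truncated at 3 sigma, so compare against the simulated law
    # only in distributional shape via the analytic rate
    pval <- suppressWarnings(
      ks.test(d2, "pexp", rate = 1 / (4 * (1.0 * 0.01 + sigma^2)))$p.value)
    if (pval < 0.01) fails <- fails + 1
  }
  expect_lte(fails, 1)
})

test_that("bound-event durations match the two-exponential event mixture", {
  p <- catalog$MeCP2_GC_WT
  acq <- slow_acq(n_frames = 4000, bleach_prob_per_frame = 0)
  ev <- NULL
  for (s in 1:4) {
    cell <- simulate_cell(p, nucleus_geometry(3), acq, n_molecules = 6,
                          seed = 40 + s, n_active = 6)
    ev <- rbind(ev, cell$events)
  }
  ev <- ev[!ev$censored_start & !ev$censored_end, ]
  len <- ev$t_off - ev$t_on
  expect_gt(nrow(ev), 3000)
  expect_equal(mean(ev$state == "BOUND_LONG"), 0.25, tolerance = 0.05)
  expect_equal(mean(len[ev$state == "BOUND_SHORT"]), 2, tolerance = 0.05)
  expect_equal(mean(len[ev$state == "BOUND_LONG"]), 7, tolerance = 0.05)
})

test_that("no reported position lies beyond radius + 3 sigma", {
  p <- catalog$MeCP2_GC_WT
  acq <- fast_acq(n_frames = 2000)
  cell <- simulate_cell(p, nucleus_geometry(3), acq, n_molecules = 500,
                        seed = 8)
  r <- sqrt(cell$localizations$x_um^2 + cell$localizations$y_um^2)
  expect_true(all(r <= 3 + 3 * 0.035 + 1e-12))
})

test_that("slow-dwell mode records only immobile molecules", {
  p <- catalog$MeCP2_GC_WT
  cell <- simulate_cell(p, nucleus_geometry(3), slow_acq(n_frames = 1500),
                        n_molecules = 40, seed = 12)
  gt <- cell$ground_truth
  det <- gt[gt$detected, ]
  expect_gt(mean(det$state != "FREE"), 0.95)
  # free molecules are blurred away: detection among free frames is rare
  expect_lt(mean(gt$detected[gt$state == "FREE"]), 0.05)
})

test_that("simulate_condition replicates are seeded and independent", {
  p <- catalog$MeCP2_GC_WT
  acq <- fast_acq(n_frames = 200)
  a <- simulate_condition(p, 3, nucleus_geometry(3), acq, 50, base_seed = 77)
  b <- simulate_condition(p, 3, nucleus_geometry(3), acq, 50, base_seed = 77)
  expect_identical(lapply(a, `[[`, "localizations"),
                   lapply(b, `[[`, "localizations"))
  expect_false(identical(a[[1]]$localizations, a[[2]]$localizations))
})

test_that("per-cell ground-truth occupancies are tight and ordered across presets", {
  acq <- fast_acq(n_frames = 1000)
  occs <- function(preset, base) {
    cells <- simulate_condition(catalog[[preset]], 4, nucleus_geometry(3),
                                acq, 600, base_seed = base)
    vapply(cells, function(cl) mean(cl$ground_truth$state != "FREE"), 0)
  }
  lo <- occs("MeCP2_Dnmt3a_cKO", 300)
  hi <- occs("MeCP2_Tets_cKO", 400)
  expect_lt(sd(lo), 0.05)
  expect_lt(sd(hi), 0.05)
  # 0.45 vs 0.60 populations do not overlap at these molecule counts
  expect_lt(max(lo), min(hi))
})

test_that("chromatin maps hit the requested fraction and are reproducible", {
  geo <- nucleus_geometry(3)
  map <- simulate_chromatin_map(geo, het_fraction = 0.5, blob_scale_um = 0.5,
                                pixel_size_um = 0.05, seed = 21)
  n <- nrow(map$grid)
  cx <- -3 + (seq_len(n) - 0.5) * 0.05
  cy <- 3 - (seq_len(n) - 0.5) * 0.05
  inside <- outer(cy^2, cx^2, `+`) <= 9
  frac <- mean(map$grid[inside])
  expect_gte(frac, 0.48); expect_lte(frac, 0.52)
  map2 <- simulate_chromatin_map(geo, 0.5, 0.5, 0.05, seed = 21)
  expect_identical(map$grid, map2$grid)
  expect_error(simulate_chromatin_map(geo, 1.2), "het_fraction")
  expect_error(simulate_chromatin_map(geo, 0.5, pixel_size_um = 10))
})

test_that("mask autocorrelation length tracks the blob scale", {
  geo <- nucleus_geometry(3)
  # For a median-thresholded Gaussian field, the binary autocorrelation
  # is (2/pi) asin(rho) of the field autocorrelation exp(-k^2/(4 s^2)),
  # so the field rho crosses 1/e at lag 2 s. Estimate s as half that
  # crossing lag, on the central in-nucleus block, averaged over seeds.
  acl <- function(blob, seed) {
    map <- simulate_chromatin_map(geo, 0.5, blob, 0.05, seed = seed)
    ctr <- 30:90
    g <- map$grid[ctr, ctr]; g <- g - mean(g)
    v <- mean(g^2)
    for (k in 1:50) {
      acb <- mean(g[1:(nrow(g) - k), ] * g[(k + 1):nrow(g), ]) / v
      if (sin(pi / 2 * max(min(acb, 1), 0)) < exp(-1)) return(k * 0.05 / 2)
    }
    NA_real_
  }
  m3 <- mean(vapply(1:8, function(s) acl(0.3, 30 + s), 0))
  m5 <- mean(vapply(1:8, function(s) acl(0.5, 30 + s), 0))
  expect_equal(m3, 0.3, tolerance = 0.3)
  expect_equal(m5, 0.5, tolerance = 0.3)
  expect_gt(m5, m3)
})
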