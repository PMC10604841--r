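# SVD clutter filtering, power/dB images, intensity quartiles.

test_that("cutoff (0,0) is the identity filter and conserves energy exactly", {
  tr <- quick_truth(clutter_amplitude = 3, clutter_rank = 1,
                    noise_amplitude = 0.2)
  ens <- simulate_doppler_ensemble(tr, seed = 1)
  out <- svd_clutter_filter(ens, svd_cutoff(0, 0))
  expect_identical(out$frames, ens$frames)
})

test_that("a rank-1 ensemble of identical frames is annihilated by cutoff (1,0)", {
  frame <- matrix(complex(real = rnorm(36), imaginary = rnorm(36)), 6, 6)
  frames <- array(rep(frame, 10), c(6, 6, 10))
  ens <- doppler_ensemble(frames)
  out <- svd_clutter_filter(ens, svd_cutoff(1))
  expect_lt(sum(Mod(out$frames)^2) / sum(Mod(frames)^2), 1e-10)
})

test_that("removing singular components never increases ensemble energy", {
  tr <- quick_truth(clutter_rank = 3, clutter_amplitude = 10,
                    noise_amplitude = 0.3)
  ens <- simulate_doppler_ensemble(tr, seed = 2)
  e0 <- sum(Mod(ens$frames)^2)
  last <- e0
  for (k in 1:4) {
    ek <- sum(Mod(svd_clutter_filter(ens, svd_cutoff(k))$frames)^2)
    expect_lte(ek, last + 1e-8 * e0)
    last <- ek
  }
})

test_that("cutoffs that would remove every frame are rejected", {
  tr <- quick_truth(n_frames = 16)
  ens <- simulate_doppler_ensemble(tr, seed = 3)
  expect_error(svd_clutter_filter(ens, svd_cutoff(10, 6)), "below the number")
  expect_error(svd_cutoff(-1), "non-negative")
})

test_that("strong low-rank clutter is removed to within 10% of true flow power", {
  set.seed(14)
  cbv <- matrix(runif(20 * 20, 0.2, 0.8), 20)
  for (s in 1:3) {
    tr <- doppler_truth(cbv, clutter_rank = 2, clutter_amplitude = 100,
                        noise_amplitude = 0.05, n_frames = 350)
    ens <- simulate_doppler_ensemble(tr, seed = 700 + s)
    p <- power_doppler(svd_clutter_filter(ens, svd_cutoff(2)))$power
    expect_lt(median(abs(p - cbv) / cbv), 0.10)
  }
})

test_that("truth-aware cutoff selection finds the clutter rank; single candidate passes through", {
  set.seed(15)
  cbv <- matrix(runif(16 * 16, 0.2, 0.8), 16)
  for (s in 1:5) {
    tr <- doppler_truth(cbv, clutter_rank = 2, clutter_amplitude = 100,
                        noise_amplitude = 0.1, n_frames = 350)
    ens <- simulate_doppler_ensemble(tr, seed = 900 + s)
    sel <- select_cutoff(ens, lapply(0:3, svd_cutoff))
    expect_identical(sel$low, 2L)
  }
  one <- svd_cutoff(5)
  expect_identical(select_cutoff(ens, list(one)), one)
  expect_error(select_cutoff(ens, list()), "at least one")
})

test_that("cutoff selection does not fail on a pure-noise ensemble", {
  tr <- doppler_truth(matrix(0, 8, 8), clutter_rank = 0,
                      clutter_amplitude = 0, noise_amplitude = 1,
                      n_frames = 64)
  ens <- simulate_doppler_ensemble(tr, seed = 6)
  ens$truth <- NULL
  sel <- select_cutoff(ens, lapply(0:3, svd_cutoff))
  expect_s3_class(sel, "svd_cutoff")
})

test_that("power image is the temporal mean squared modulus", {
  frames <- array(2 + 0i, c(3, 4, 7))          # constant modulus 2
  expect_equal(power_doppler(doppler_ensemble(frames))$power,
               matrix(4, 3, 4))
  one <- array(complex(real = rnorm(12), imaginary = rnorm(12)), c(3, 4, 2))
  p <- power_doppler(doppler_ensemble(one))$power
  expect_equal(p, apply(Mod(one)^2, c(1, 2), mean))
  expect_true(all(p >= 0))
})

test_that("dB referencing maps the ROI maximum to 0 dB and is scale invariant", {
  pw <- matrix(c(10, 1, 5, 2), 2, 2)
  roi <- matrix(TRUE, 2, 2)
  img <- power_doppler(doppler_ensemble(array(0i, c(2, 2, 2))))
  img$power <- pw; img$roi_masks <- list(all = roi)
  db <- to_db(img, "all")
  expect_equal(db$reference_power, 10)
  expect_equal(max(db$db), 0)
  expect_equal(db$db[2, 1], -10)               # one tenth of the reference
  img2 <- img; img2$power <- 2 * pw            # doubling leaves dB unchanged
  expect_equal(to_db(img2, "all")$db, db$db)
})

test_that("dB referencing rejects empty or all-zero reference ROIs", {
  img <- power_doppler(doppler_ensemble(array(0i, c(2, 2, 2))),
                       roi_masks = list(none = matrix(FALSE, 2, 2),
                                        all = matrix(TRUE, 2, 2)))
  expect_error(to_db(img, "none"), "empty")
  expect_error(to_db(img, "all"), "degenerate")
  expect_error(to_db(img, "missing"), "unknown")
})

test_that("eight ROI pixels at -1..-8 dB split into the forced quartile means", {
  img <- power_doppler(doppler_ensemble(array(0i, c(2, 4, 2))))
  img$db <- matrix(-(1:8), 2, 4)               # column-major: -1, -2, ... -8
  img$power <- 10^(img$db / 10)
  img$roi_masks <- list(all = matrix(TRUE, 2, 4))
  img$reference_power <- 1
  q <- intensity_quartiles(img, "all")
  expect_equal(q$table$mean_db, c(-1.5, -3.5, -5.5, -7.5))
  expect_equal(q$table$n_pixels, rep(2L, 4))
  expect_identical(q$norm_constant, 8L)
})

test_that("quartile counts are balanced, exhaustive, and tie-broken by scan order", {
  img <- power_doppler(doppler_ensemble(array(0i, c(3, 3, 2))))
  img$db <- matrix(0, 3, 3)                    # fully tied ROI
  img$power <- matrix(1, 3, 3)
  img$roi_masks <- list(all = matrix(TRUE, 3, 3))
  img$reference_power <- 1
  q <- intensity_quartiles(img, "all")
  expect_equal(q$table$n_pixels, c(3L, 2L, 2L, 2L))  # 9 = 3+2+2+2
  expect_true(all(q$table$mean_db == 0))
  # ties assigned in raster-scan order: first three pixels are Q1
  expect_identical(q$assignment[1:3], rep(1L, 3))
  # partition property
  expect_identical(sum(q$table$n_pixels), q$norm_constant)
  expect_error(intensity_quartiles(img, "missing"), "unknown")
})

test_that("quartile means decrease strictly from Q1 to Q4 on graded CBV maps", {
  set.seed(16)
  for (s in 1:3) {
    cbv <- matrix(seq(0.05, 0.9, length.out = 144) +
                    runif(144, 0, 0.02), 12, 12)
    tr <- doppler_truth(pmin(cbv, 1), clutter_rank = 2,
                        clutter_amplitude = 30, noise_amplitude = 0.1,
                        n_frames = 350)
    ens <- simulate_doppler_ensemble(tr, seed = 40 + s)
    pd <- power_doppler(svd_clutter_filter(ens, svd_cutoff(2)),
                        roi_masks = list(all = matrix(TRUE, 12, 12)))
    q <- intensity_quartiles(to_db(pd, "all"), "all")
    expect_true(all(diff(q$table$mean_db) < 0))
  }
})

test_that("post-filter power is rank-correlated with the true CBV map", {
  set.seed(17)
  cbv <- matrix(runif(18 * 18, 0.1, 0.9), 18)
  tr <- doppler_truth(cbv, clutter_rank = 2, clutter_amplitude = 100,
                      noise_amplitude = 0.3, n_frames = 350)
  ens <- simulate_doppler_ensemble(tr, seed = 55)
  p <- power_doppler(svd_clutter_filter(ens, svd_cutoff(2)))$power
  expect_gt(cor(as.vector(p), as.vector(cbv), method = "spearman"), 0.9)
})

test_that("per-quartile group comparison flags identical groups as null", {
  set.seed(18)
  mk <- function(offset = 0, seed) {
    cbv <- matrix(runif(64, 0.3, 0.7), 8)
    tr <- doppler_truth(pmin(cbv + offset, 1), clutter_rank = 0,
                        clutter_amplitude = 0, noise_amplitude = 0.1,
                        n_frames = 96)
    ens <- simulate_doppler_ensemble(tr, seed = seed)
    pd <- power_doppler(ens, roi_masks = list(all = matrix(TRUE, 8, 8)))
    intensity_quartiles(to_db(pd, "all"), "all")
  }
  ga <- lapply(1:5, function(i) mk(seed = 100 + i))
  cmp_null <- mean_quartile_comparison(ga, ga)
  expect_true(all(cmp_null$p_value > 0.9))     # identical groups
  gb <- lapply(1:5, function(i) mk(seed = 200 + i))
  expect_error(mean_quartile_comparison(ga[1:2], gb), "at least 3")
})
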