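test_that("PANIC normalization closed forms and symmetry", {
  expect_equal(panic_normalize(3, 3, 3, 3), 1)
  expect_equal(panic_normalize(2, 2, 8, 8), 0.25)
  # swapping (A,B) -> (B,A) leaves I_norm unchanged
  expect_equal(panic_normalize(2.1, 1.9, 7, 9), panic_normalize(1.9, 2.1, 9, 7))
  # non-positive diagonal drops the point
  expect_true(is.na(panic_normalize(1, 1, 0, 2)))
  expect_true(is.na(panic_normalize(1, 1, 2, -3)))
  # sign carried from the cross-peak mean
  expect_lt(panic_normalize(-2, -2, 8, 8), 0)
})

test_that("PANIC cancels any factor common to a whole spectrum", {
  sys <- three_spin_chain()
  ser <- simulate_integrals(sys, noise_sd = 0.01, seed = 3)
  scale <- 7.3 # rescale every integral at mixing time 4
  a <- panic_normalize(ser$cross[4, "Hb", "Hc"], ser$cross[4, "Hc", "Hb"],
                       ser$diagonal[4, "Hb"], ser$diagonal[4, "Hc"])
  b <- panic_normalize(scale * ser$cross[4, "Hb", "Hc"],
                       scale * ser$cross[4, "Hc", "Hb"],
                       scale * ser$diagonal[4, "Hb"],
                       scale * ser$diagonal[4, "Hc"])
  expect_equal(a, b, tolerance = 1e-12)
})

test_that("build-up fit: exact line is recovered to machine precision", {
  t <- seq(0.1, 0.7, by = 0.1)
  cur <- fit_buildup(t, 0.04 * t)
  expect_equal(cur$slope, 0.04, tolerance = 1e-12)
  expect_equal(cur$r_squared, 1)
  expect_identical(cur$n_used, 7L)
  expect_length(cur$outliers_removed, 0L)
  expect_true(cur$valid)
})

test_that("build-up fit removes a gross outlier and matches the clean fit", {
  t <- seq(0.1, 0.7, by = 0.1)
  y <- 0.04 * t + 0.001
  y[4] <- y[4] + 0.05 # gross outlier at t = 0.4
  cur <- fit_buildup(t, y)
  expect_equal(cur$outliers_removed, 0.4)
  clean <- fit_buildup(t[-4], y[-4])
  expect_equal(cur$slope, clean$slope, tolerance = 1e-12)
  expect_true(cur$valid)
  expect_identical(cur$n_used, 6L)
})

test_that("outlier policy never discards points from already-good fits and stops at 2", {
  t <- seq(0.1, 0.7, by = 0.1)
  withr::with_seed(11, {
    good <- 0.04 * t + rnorm(7, 0, 1e-4)
  })
  expect_length(fit_buildup(t, good)$outliers_removed, 0L)
  withr::with_seed(1, {
    scatter <- rnorm(7, 0.01, 0.02)
  })
  cur <- fit_buildup(t, scatter)
  expect_lte(length(cur$outliers_removed), 2L)
  expect_gte(cur$n_used, 5L)
})

test_that("validity filter is a pure function of r_squared and n_used", {
  t <- seq(0.1, 0.7, by = 0.1)
  withr::with_seed(2, {
    noise <- rnorm(7, 0, 0.05)
  })
  cur <- fit_buildup(t, noise)
  expect_identical(cur$valid, cur$r_squared > 0.90 && cur$n_used > 4L)
  # fewer than 5 points: fit refused with a reason
  few <- fit_buildup(t[1:4], (0.04 * t)[1:4])
  expect_false(few$valid)
  expect_match(few$reason, "refused")
  expect_true(is.na(few$slope))
})

test_that("distance equation closed forms", {
  expect_identical(distance_from_slopes(0.05, 0.05), 1.78)
  expect_equal(distance_from_slopes(0.05 / 64, 0.05), 3.56, tolerance = 1e-12)
  expect_equal(distance_from_slopes(0.05 * (1.78 / 3.00)^6, 0.05), 3.00,
               tolerance = 1e-12)
  # monotone decreasing in sigma_AB; linear in r_ref
  s <- c(0.01, 0.02, 0.05, 0.2)
  r <- distance_from_slopes(s, 0.05)
  expect_false(is.unsorted(rev(r), strictly = TRUE))
  expect_equal(distance_from_slopes(s, 0.05, r_ref = 3.56), 2 * r)
  # non-positive slope -> undefined
  expect_true(is.na(distance_from_slopes(-0.01, 0.05)))
  expect_error(distance_from_slopes(0.05, 0), "sigma_ref")
})

test_that("noiseless integral-level chain recovers all 12-proton distances within 0.1%", {
  sys <- default_spin_system()
  tab <- build_distance_table(simulate_integrals(sys, noise_sd = 0))
  expect_identical(nrow(tab), 66L)
  expect_true(all(tab$valid))
  truth <- sys$distances[cbind(tab$pair_a, tab$pair_b)]
  expect_lt(max(abs(tab$r_ab - truth) / truth), 0.001)
  # reference pair fed back through the pipeline is exactly 1.78
  expect_identical(tab$r_ab[tab$pair_a == "H01" & tab$pair_b == "H02"], 1.78)
})

test_that("a corrupted weak pair is flagged invalid without affecting others", {
  sys <- default_spin_system()
  ser <- simulate_integrals(sys, noise_sd = 0)
  # break linearity for the longest-distance pair only
  far <- which(ser$cross[1, , ] == min(ser$cross[1, , ][ser$cross[1, , ] > 0]),
               arr.ind = TRUE)[1, ]
  a <- far[1]; b <- far[2]
  withr::with_seed(8, {
    ser$cross[, a, b] <- abs(rnorm(7, mean(ser$cross[, a, b]), 0.3))
    ser$cross[, b, a] <- abs(rnorm(7, mean(ser$cross[, b, a]), 0.3))
  })
  tab <- build_distance_table(ser)
  key_bad <- paste(sort(ser$labels[c(a, b)]), collapse = "|")
  keys <- paste(tab$pair_a, tab$pair_b, sep = "|")
  expect_false(tab$valid[keys == key_bad])
  expect_true(all(tab$valid[keys != key_bad]))
})

test_that("invalid reference curve is a hard error", {
  sys <- three_spin_chain()
  ser <- simulate_integrals(sys, noise_sd = 0)
  withr::with_seed(3, {
    ser$cross[, "Ha", "Hb"] <- abs(rnorm(7, 0.02, 0.05))
    ser$cross[, "Hb", "Ha"] <- abs(rnorm(7, 0.02, 0.05))
  })
  expect_error(build_distance_table(ser), "reference")
})

test_that("distance table CSV round trip", {
  sys <- three_spin_chain()
  tab <- build_distance_table(simulate_integrals(sys, noise_sd = 0))
  f <- withr::local_tempfile(fileext = ".csv")
  write_distance_table(tab, f)
  back <- read_distance_table(f)
  expect_equal(back$r_ab, tab$r_ab, tolerance = 1e-9)
  expect_identical(attr(back, "reference_pair"), c("Ha", "Hb"))
})
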