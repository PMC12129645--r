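test_that("cross-relaxation rates follow the inverse sixth-power law", {
  sys <- two_pair_system(d = 3.56)
  ser <- simulate_integrals(sys, noise_sd = 0)
  # 3.56 = 2 * 1.78, so the rate (and every cross integral) is 2^-6 = 1/64
  ratio <- ser$cross[, "Hc", "Hd"] / ser$cross[, "Ha", "Hb"]
  expect_equal(ratio, rep(1 / 64, length(ser$mixing_times)), tolerance = 1e-12)
})

test_that("integral simulation is deterministic under a seed and unbiased by it", {
  sys <- three_spin_chain()
  a <- simulate_integrals(sys, noise_sd = 0.02, seed = 5)
  b <- simulate_integrals(sys, noise_sd = 0.02, seed = 5)
  expect_identical(a$cross, b$cross)
  expect_identical(a$diagonal, b$diagonal)
  expect_false(identical(a$cross,
                         simulate_integrals(sys, noise_sd = 0.02, seed = 6)$cross))
})

test_that("relaxation-matrix model agrees with initial rate at short mixing time and diverges later", {
  sys <- three_spin_chain()
  times <- c(0.1, 0.7)
  ir <- simulate_integrals(sys, times, noise_sd = 0, model = "initial_rate")
  rm <- simulate_integrals(sys, times, noise_sd = 0, model = "relaxation_matrix")
  rel <- abs(rm$cross - ir$cross) / pmax(abs(ir$cross), 1e-300)
  off <- which(upper.tri(matrix(0, 3, 3)), arr.ind = TRUE)
  rel_short <- rel[1, , ][off]
  rel_long <- rel[2, , ][off]
  expect_lt(max(rel_short), 0.05)
  expect_true(all(rel_long > rel_short))
})

test_that("noise injection is unbiased: mean recovered distance equals ground truth", {
  sys <- three_spin_chain()
  r_bc <- vapply(1:200, function(s) {
    ser <- simulate_integrals(sys, noise_sd = 0.02, seed = s)
    tab <- build_distance_table(ser)
    tab$r_ab[tab$pair_a == "Hb" & tab$pair_b == "Hc"]
  }, numeric(1))
  se <- sd(r_bc) / sqrt(length(r_bc))
  expect_lt(abs(mean(r_bc) - 2.5), 4 * se + 0.004)
})

test_that("FID simulation: a single pair gives exactly 4 peaks and the expected integral ratios", {
  lab <- c("Ha", "Hb")
  d <- matrix(c(0, 1.78, 1.78, 0), 2, dimnames = list(lab, lab))
  sys <- spin_system(d, reference_pair = lab)
  fids <- simulate_fids(sys, mixing_times = c(0.2, 0.4), grid_size = 128L,
                        direct_size = 128L, noise_sd = 0)
  ser <- quantify_fids(fids, reconstructor = "none", f1_halfwidth = 6L)
  # 2 diagonal + 2 cross integrals well above everything else
  expect_true(all(ser$diagonal > 0))
  expect_true(all(ser$cross[, "Ha", "Hb"] > 0))
  # PANIC value is sigma * t by construction; common lineshape gain cancels
  inorm <- panic_normalize(ser$cross[, "Ha", "Hb"], ser$cross[, "Hb", "Ha"],
                           ser$diagonal[, "Ha"], ser$diagonal[, "Hb"])
  expect_equal(inorm, 0.05 * c(0.2, 0.4), tolerance = 0.02)
})

test_that("uniform FID round trip recovers integral ratios within 2%", {
  sys <- three_spin_chain()
  fids <- simulate_fids(sys, grid_size = 128L, direct_size = 128L,
                        noise_sd = 0)
  ser <- quantify_fids(fids, reconstructor = "none", f1_halfwidth = 6L)
  truth <- simulate_integrals(sys, noise_sd = 0)
  # apodization/integration gain is common to all peaks: compare ratios
  got <- ser$cross[, "Hb", "Hc"] / ser$cross[, "Ha", "Hb"]
  want <- truth$cross[, "Hb", "Hc"] / truth$cross[, "Ha", "Hb"]
  expect_equal(got, want, tolerance = 0.02)
  gotd <- ser$diagonal[, "Ha"] / ser$diagonal[, "Hc"]
  expect_equal(gotd, rep(1, 7), tolerance = 0.02)
})

test_that("FID-level uniform round trip recovers all 12-proton distances within 2%", {
  sys <- default_spin_system()
  fids <- simulate_fids(sys, noise_sd = 0) # default 512 x 512
  tab <- build_distance_table(quantify_fids(fids, reconstructor = "none"))
  expect_true(all(tab$valid))
  truth <- sys$distances[cbind(tab$pair_a, tab$pair_b)]
  expect_lt(max(abs(tab$r_ab - truth) / truth), 0.02)
})

test_that("FID simulation is seeded-deterministic", {
  sys <- three_spin_chain()
  a <- simulate_fids(sys, mixing_times = 0.3, grid_size = 64L,
                     direct_size = 64L, noise_sd = 0.01, seed = 4)
  b <- simulate_fids(sys, mixing_times = 0.3, grid_size = 64L,
                     direct_size = 64L, noise_sd = 0.01, seed = 4)
  expect_identical(a$fids, b$fids)
})

test_that("subsample zeroes exactly the unsampled rows and is idempotent", {
  sys <- three_spin_chain()
  fids <- simulate_fids(sys, mixing_times = 0.3, grid_size = 512L,
                        direct_size = 32L, noise_sd = 0)
  sch <- generate_poisson_gap(512, 0.5, 2)
  sub <- subsample(fids, sch)
  kept <- sch$indices + 1L
  expect_identical(sub$fids[[1]][kept, ], fids$fids[[1]][kept, ])
  expect_equal(sum(rowSums(Mod(sub$fids[[1]])) > 0), 256L)
  expect_identical(subsample(sub, sch)$fids, sub$fids)
  # uniform schedule is the identity
  expect_identical(subsample(fids, generate_uniform(512))$fids, fids$fids)
  expect_error(subsample(fids, generate_poisson_gap(256, 0.5, 1)), "grid_size")
})

test_that("noesy series survives a CSV round trip", {
  sys <- three_spin_chain()
  ser <- simulate_integrals(sys, noise_sd = 0.01, seed = 2)
  f <- withr::local_tempfile(fileext = ".csv")
  write_noesy_csv(ser, f)
  back <- read_noesy_csv(f)
  expect_equal(back$mixing_times, ser$mixing_times)
  expect_equal(back$cross[, "Ha", "Hb"], ser$cross[, "Ha", "Hb"],
               tolerance = 1e-12, ignore_attr = TRUE)
  # distances still computable with an explicit reference
  tab <- build_distance_table(back, reference_pair = c("Ha", "Hb"),
                              r_ref = 1.78)
  expect_true(tab$valid[tab$pair_a == "Ha" & tab$pair_b == "Hb"])
})

test_that("spin system validation", {
  lab <- c("Ha", "Hb")
  d <- matrix(c(0, 1.78, 1.78, 0), 2, dimnames = list(lab, lab))
  expect_s3_class(spin_system(d, lab), "spin_system")
  expect_error(spin_system(d, c("Ha", "Hx")), "reference_pair")
  expect_error(spin_system(d, lab, reference_distance = 2.0), "reference pair distance")
  d2 <- d; d2[1, 2] <- -1
  expect_error(spin_system(d2, lab), "positive|symmetric")
  sys <- default_spin_system()
  expect_length(sys$labels, 12L)
  off <- sys$distances[upper.tri(sys$distances)]
  expect_equal(range(off), c(1.78, 4.5))
  expect_gt(sum(off > 3.5), 10) # several long, fragile distances
})
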