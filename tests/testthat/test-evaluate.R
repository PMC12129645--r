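test_that("comparing a table against itself is the identity report", {
  tab <- build_distance_table(simulate_integrals(three_spin_chain(),
                                                 noise_sd = 0))
  rep <- compare_distance_tables(tab, tab)
  expect_equal(rep$retained_percent, 100)
  expect_equal(unname(rep$deviation_table), rep(0, 9))
  expect_equal(rep$mean_signed_deviation, 0)
  expect_equal(rep$mean_abs_deviation, 0)
  expect_equal(rep$l2_norm, 0)
  expect_length(rep$new_in_test, 0L)
})

test_that("retained percent counts common valid distances", {
  labs_a <- rep("Ha", 10)
  labs_b <- sprintf("Hb%02d", 1:10)
  ref <- make_table(labs_a, labs_b, seq(1.78, 4, length.out = 10))
  test <- make_table(labs_a, labs_b, seq(1.78, 4, length.out = 10),
                     valid = c(rep(TRUE, 8), FALSE, FALSE))
  # reference pair bookkeeping: reuse ref pair attr
  attr(test, "reference_pair") <- attr(ref, "reference_pair")
  rep <- compare_distance_tables(ref, test)
  expect_equal(rep$retained_percent, 80)
})

test_that("hand-built three-pair deviations match the arithmetic oracle", {
  r_ref <- c(2.0, 3.0, 4.0)
  dev <- c(2, -5, 8) # percent
  ref <- make_table(c("Ha", "Ha", "Hb"), c("Hb", "Hc", "Hc"), r_ref)
  test <- make_table(c("Ha", "Ha", "Hb"), c("Hb", "Hc", "Hc"),
                     r_ref * (1 + dev / 100))
  rep <- compare_distance_tables(ref, test, cutoffs = 4)
  expect_equal(unname(rep$deviation_table["4%"]), 200 / 3, tolerance = 1e-9)
  expect_equal(rep$mean_signed_deviation, 5 / 3, tolerance = 1e-9)
  expect_equal(rep$mean_abs_deviation, 5, tolerance = 1e-9)
  expect_equal(rep$l2_norm,
               sqrt(sum((r_ref * dev / 100)^2)), tolerance = 1e-9)
})

test_that("distances valid only in the test table are excluded from statistics", {
  ref <- make_table(c("Ha", "Ha"), c("Hb", "Hc"), c(2, 3),
                    valid = c(TRUE, FALSE))
  test <- make_table(c("Ha", "Ha"), c("Hb", "Hc"), c(2.1, 3.3))
  rep <- compare_distance_tables(ref, test)
  expect_identical(rep$new_in_test, "Ha|Hc")
  expect_equal(rep$n_common_valid, 1L)
  expect_equal(rep$mean_abs_deviation, 5, tolerance = 1e-9)
})

test_that("deviation table is non-increasing in the cutoff for random reports", {
  withr::with_seed(31, {
    for (k in 1:20) {
      npair <- 30
      r <- runif(npair, 1.8, 4.5)
      labs_b <- sprintf("Hx%02d", seq_len(npair))
      ref <- make_table(rep("Ha", npair), labs_b, r)
      test <- make_table(rep("Ha", npair), labs_b,
                         r * (1 + rnorm(npair, 0, 0.05)))
      rep <- compare_distance_tables(ref, test)
      expect_false(is.unsorted(rev(rep$deviation_table)))
    }
  })
})

test_that("artefact intensity: identity, box construction, overlap guard", {
  us <- matrix(0, 32, 32)
  expect_equal(artefact_intensity(us, us, list(list(rows = 1:5, cols = 1:5))), 0)
  nus <- us
  nus[3:4, 3:4] <- nus[3:4, 3:4] + 2.5 # box of total area 10 inside a region
  expect_equal(artefact_intensity(us, nus,
                                  list(list(rows = 1:8, cols = 1:8))), 10)
  expect_error(artefact_intensity(us, nus,
                                  list(list(rows = 1:4, cols = 1:4),
                                       list(rows = 4:6, cols = 4:6))),
               "overlap")
  v <- rnorm(16)
  expect_equal(artefact_intensity(v, v + 1, list(1:4, 9:10)), 6)
  expect_error(artefact_intensity(v, v[1:8], list(1:2)), "identical grids")
})

test_that("uniform-schedule difference spectrum is zero through the identical chain", {
  sys <- three_spin_chain()
  fids <- simulate_fids(sys, mixing_times = 0.3, grid_size = 128L,
                        direct_size = 64L, noise_sd = 0.001, seed = 5)
  u <- generate_uniform(128)
  a <- process_spectrum(fids$fids[[1]], zerofill_to = 256L)
  b <- process_spectrum(subsample(fids, u)$fids[[1]], zerofill_to = 256L)
  expect_equal(artefact_intensity(a, b, list(list(rows = 1:256, cols = 1:64))), 0)
})

test_that("pearson_r2 closed forms and degenerate cases", {
  expect_equal(pearson_r2(c(1, 2), c(5, 9)), 1)
  expect_true(is.na(pearson_r2(c(1, 1, 1), c(2, 3, 4))))
  expect_true(is.na(pearson_r2(c(1, NA), c(2, 3))))
  withr::with_seed(2, {
    x <- rnorm(50)
    y <- 2 * x + rnorm(50, 0, 0.1)
  })
  expect_equal(pearson_r2(x, y), cor(x, y)^2)
})

test_that("run_experiment with the uniform schedule is an end-to-end identity", {
  ex <- run_experiment(list(generate_uniform(128)),
                       system = three_spin_chain(),
                       mixing_times = seq(0.1, 0.7, by = 0.1),
                       grid_size = 128L, direct_size = 64L,
                       noise_sd = 0.001, seed = 3, f1_halfwidth = 6L)
  sm <- ex$summary
  expect_equal(sm$retained_percent, 100)
  expect_equal(sm$mean_abs_deviation, 0)
  expect_equal(sm$l2_norm, 0)
})

test_that("run_experiment is deterministic and records per-schedule failures", {
  sys <- three_spin_chain()
  scheds <- list(generate_uniform(128),
                 generate_hybrid(128, 0.5, 0.3, 1))
  args <- list(scheds, system = sys, mixing_times = seq(0.1, 0.7, by = 0.1),
               grid_size = 128L, direct_size = 64L, noise_sd = 0.001,
               seed = 9, f1_halfwidth = 6L, n_iterations = 50L)
  a <- do.call(run_experiment, args)
  b <- do.call(run_experiment, args)
  expect_identical(a$summary, b$summary)
  expect_s3_class(a$reports[[2]], "fidelity_report")
})
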