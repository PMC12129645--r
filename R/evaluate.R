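#' Compare NUS distances against a uniformly sampled reference
#'
#' Computes the fidelity observables of a US-versus-NUS comparison: the
#' fraction of reference-valid distances retained, the percentage of common
#' distances whose absolute deviation exceeds each cutoff, signed and absolute
#' mean deviations, and the Euclidean (L2) norm between the two distance sets.
#' Deviations are `100 * (r_test - r_reference) / r_reference` per pair, valid
#' in both tables. Pairs valid in the test table but not in the reference are
#' listed separately (`new_in_test`) and excluded from deviation statistics.
#'
#' @param reference the uniformly sampled `distance_table`.
#' @param test the NUS `distance_table`; must share the reference pair.
#' @param cutoffs deviation cutoffs in percent (default 1-9).
#' @return An object of class `fidelity_report`: `n_reference_valid`,
#'   `n_test_valid`, `n_common_valid`, `retained_percent`, `deviation_table`
#'   (named percent-exceeding per cutoff, non-increasing in the cutoff),
#'   `mean_signed_deviation`, `mean_abs_deviation`, `l2_norm` (A),
#'   `new_in_test`, and `detail` (per-pair rows).
#' @export
compare_distance_tables <- function(reference, test, cutoffs = 1:9) {
  stopifnot(inherits(reference, "distance_table"),
            inherits(test, "distance_table"))
  if (length(cutoffs) < 1L || any(cutoffs <= 0)) {
    stop_param("cutoffs must be positive percentages")
  }
  if (!identical(sort(attr(reference, "reference_pair")),
                 sort(attr(test, "reference_pair")))) {
    stop_param("tables do not share the same reference pair")
  }
  ref_valid <- reference[reference$valid, , drop = FALSE]
  if (nrow(ref_valid) == 0L) {
    stop_param("reference table has no valid distances")
  }
  test_valid <- test[test$valid, , drop = FALSE]
  rk <- pair_key(ref_valid$pair_a, ref_valid$pair_b)
  tk <- pair_key(test_valid$pair_a, test_valid$pair_b)
  common <- intersect(rk, tk)
  new_in_test <- setdiff(tk, rk)
  ri <- match(common, rk)
  ti <- match(common, tk)
  dev <- 100 * (test_valid$r_ab[ti] - ref_valid$r_ab[ri]) / ref_valid$r_ab[ri]
  has_common <- length(common) > 0L
  deviation_table <- vapply(cutoffs, function(cc) {
    if (has_common) 100 * mean(abs(dev) > cc) else NA_real_
  }, numeric(1))
  names(deviation_table) <- paste0(cutoffs, "%")
  detail <- data.frame(
    pair_a = ref_valid$pair_a[ri], pair_b = ref_valid$pair_b[ri],
    r_reference = ref_valid$r_ab[ri], r_test = test_valid$r_ab[ti],
    deviation_percent = dev, stringsAsFactors = FALSE
  )
  structure(
    list(n_reference_valid = nrow(ref_valid),
         n_test_valid = nrow(test_valid),
         n_common_valid = length(common),
         retained_percent = 100 * length(common) / nrow(ref_valid),
         deviation_table = deviation_table,
         mean_signed_deviation = if (has_common) mean(dev) else NA_real_,
         mean_abs_deviation = if (has_common) mean(abs(dev)) else NA_real_,
         l2_norm = if (has_common) {
           sqrt(sum((detail$r_test - detail$r_reference)^2))
         } else NA_real_,
         new_in_test = new_in_test,
         detail = detail),
    class = "fidelity_report"
  )
}

#' @export
print.fidelity_report <- function(x, ...) {
  cat(sprintf("<fidelity_report> retained %.1f%% (%d of %d reference-valid distances)\n",
              x$retained_percent, x$n_common_valid, x$n_reference_valid))
  cat(sprintf("  mean deviation: %+.3f%% signed, %.3f%% absolute; L2 norm %.4f A\n",
              x$mean_signed_deviation, x$mean_abs_deviation, x$l2_norm))
  cat("  %% of distances deviating by more than each cutoff:\n")
  print(round(x$deviation_table, 1))
  if (length(x$new_in_test)) {
    cat("  valid in test only (excluded from statistics):",
        paste(x$new_in_test, collapse = ", "), "\n")
  }
  invisible(x)
}

#' Integrated artefact intensity of a difference spectrum
#'
#' Integrates the magnitude-mode difference `|us - nus|` over named,
#' non-overlapping artefact regions. For spectra stored as vectors a region is
#' an integer vector of bins (1-based); for matrices, a list with elements
#' `rows` and `cols`.
#'
#' @param us,nus spectra on identical grids (numeric vector or matrix).
#' @param regions list of regions (see above).
#' @return Summed absolute difference over the union of regions.
#' @export
artefact_intensity <- function(us, nus, regions) {
  if (!identical(dim(us), dim(nus)) || length(us) != length(nus)) {
    stop_param("spectra must be on identical grids")
  }
  if (!is.list(regions) || length(regions) == 0L) {
    stop_param("regions must be a non-empty list")
  }
  d <- abs(us - nus)
  if (is.matrix(us)) {
    seen <- matrix(FALSE, nrow(us), ncol(us))
    total <- 0
    for (r in regions) {
      if (!all(c("rows", "cols") %in% names(r))) {
        stop_param("matrix regions need elements 'rows' and 'cols'")
      }
      if (any(seen[r$rows, r$cols])) stop_param("regions must not overlap")
      seen[r$rows, r$cols] <- TRUE
      total <- total + sum(d[r$rows, r$cols])
    }
    total
  } else {
    idx <- unlist(regions)
    if (anyDuplicated(idx)) stop_param("regions must not overlap")
    if (any(idx < 1L | idx > length(d))) stop_param("region index out of range")
    sum(d[idx])
  }
}

#' Pearson R squared between two observables
#'
#' Descriptive squared Pearson correlation over complete pairs. Returns `NA`
#' (not 0) when either column is constant or fewer than two complete pairs
#' exist.
#'
#' @param x,y numeric vectors of equal length.
#' @return R squared in [0, 1], or `NA`.
#' @export
pearson_r2 <- function(x, y) {
  ok <- is.finite(x) & is.finite(y)
  if (sum(ok) < 2L) return(NA_real_)
  if (stats::sd(x[ok]) == 0 || stats::sd(y[ok]) == 0) return(NA_real_)
  stats::cor(x[ok], y[ok])^2
}

#' Run a full schedule-evaluation experiment
#'
#' Orchestrates the whole pipeline on synthetic data: simulate a uniformly
#' sampled 2D NOESY mixing-time series, quantify it into the reference
#' distance table, then for each candidate schedule subsample the same data,
#' reconstruct, quantify, and compare against the reference. One summary row
#' per schedule combines the reference-free metrics (peak-to-sidelobe ratio,
#' relative sensitivity, forward fraction) with the fidelity observables
#' (retained percent, deviation-cutoff columns, mean deviations, L2 norm).
#' Deterministic given `seed`; a failure at any stage is recorded in the
#' schedule's row and the run continues.
#'
#' @param schedules list of [new_sampling_schedule()] objects with
#'   `grid_size == grid_size`.
#' @param system a [spin_system()] (default [default_spin_system()]).
#' @param mixing_times mixing times in seconds.
#' @param grid_size,direct_size synthetic data dimensions (t1 x t2).
#' @param noise_sd additive FID noise level, see [simulate_fids()].
#' @param seed seed for the synthetic data.
#' @param reconstructor passed to [quantify_fids()].
#' @param cutoffs deviation cutoffs in percent.
#' @param envelope envelope for [relative_sensitivity()].
#' @param ... further arguments to [quantify_fids()] (IST parameters,
#'   integration windows).
#' @return An object of class `nus_experiment`: `summary` (data frame, one row
#'   per schedule), `reports` (named list of `fidelity_report`s or error
#'   messages), `reference` (the US `distance_table`), `seed`.
#' @export
run_experiment <- function(schedules, system = default_spin_system(),
                           mixing_times = seq(0.1, 0.7, by = 0.1),
                           grid_size = 512L, direct_size = 512L,
                           noise_sd = 0.001, seed = 1L,
                           reconstructor = "ist", cutoffs = 1:9,
                           envelope = envelope_model(), ...) {
  if (inherits(schedules, "sampling_schedule")) schedules <- list(schedules)
  stopifnot(length(schedules) >= 1L,
            all(vapply(schedules, inherits, logical(1), "sampling_schedule")))
  us_fids <- simulate_fids(system, mixing_times, grid_size = grid_size,
                           direct_size = direct_size, noise_sd = noise_sd,
                           seed = seed)
  reference <- build_distance_table(quantify_fids(us_fids,
                                                  reconstructor = "none", ...))
  rows <- vector("list", length(schedules))
  reports <- vector("list", length(schedules))
  labels <- vapply(schedules, `[[`, character(1), "label")
  names(reports) <- labels
  for (k in seq_along(schedules)) {
    sch <- schedules[[k]]
    metrics <- data.frame(
      label = sch$label, kind = sch$kind,
      seed = if (is.na(sch$seed)) NA_integer_ else sch$seed,
      n_sampled = length(sch$indices),
      peak_to_sidelobe = peak_to_sidelobe(compute_psf(sch)),
      relative_sensitivity = relative_sensitivity(sch, envelope),
      forward_fraction = forward_fraction(sch),
      stringsAsFactors = FALSE
    )
    res <- tryCatch({
      ser <- quantify_fids(subsample(us_fids, sch),
                           reconstructor = reconstructor, ...)
      compare_distance_tables(reference, build_distance_table(ser), cutoffs)
    }, error = function(e) conditionMessage(e))
    reports[[k]] <- res
    if (inherits(res, "fidelity_report")) {
      fid <- data.frame(
        retained_percent = res$retained_percent,
        n_valid = res$n_test_valid,
        mean_signed_deviation = res$mean_signed_deviation,
        mean_abs_deviation = res$mean_abs_deviation,
        l2_norm = res$l2_norm, error = NA_character_,
        stringsAsFactors = FALSE
      )
      devs <- as.data.frame(as.list(res$deviation_table))
      names(devs) <- paste0("dev_gt_", sub("%", "pct", names(res$deviation_table)))
      rows[[k]] <- cbind(metrics, fid, devs)
    } else {
      warning("schedule ", sch$label, " failed: ", res, call. = FALSE)
      fid <- data.frame(retained_percent = NA_real_, n_valid = NA_integer_,
                        mean_signed_deviation = NA_real_,
                        mean_abs_deviation = NA_real_, l2_norm = NA_real_,
                        error = res, stringsAsFactors = FALSE)
      devs <- as.data.frame(as.list(rep(NA_real_, length(cutoffs))))
      names(devs) <- paste0("dev_gt_", cutoffs, "pct")
      rows[[k]] <- cbind(metrics, fid, devs)
    }
  }
  structure(list(summary = do.call(rbind, rows), reports = reports,
                 reference = reference, seed = as.integer(seed)),
            class = "nus_experiment")
}

#' @export
print.nus_experiment <- function(x, ...) {
  cat(sprintf("<nus_experiment> %d schedules, %d reference-valid distances\n",
              nrow(x$summary), sum(x$reference$valid)))
  cols <- c("label", "kind", "retained_percent", "mean_abs_deviation", "l2_norm")
  print(x$summary[, intersect(cols, names(x$summary))], digits = 4,
        row.names = FALSE)
  invisible(x)
}
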