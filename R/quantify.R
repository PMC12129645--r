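#' PANIC normalization of a cross peak
#'
#' Normalizes a cross-peak pair by the geometric mean of the two corresponding
#' diagonal peaks:
#' `I_norm = sqrt(cross_AB * cross_BA) / sqrt(diag_A * diag_B)`.
#' This cancels any factor common to a whole spectrum (overall scale, common
#' decay), which is the property that makes build-ups linear in mixing time.
#' The magnitude of the cross product is used under the square root, with the
#' sign carried from the mean of the two cross peaks. Vectorized over mixing
#' times; non-positive diagonals yield `NA` (point dropped by the fit).
#'
#' @param cross_ab,cross_ba cross-peak integrals for the two symmetric peaks.
#' @param diag_a,diag_b diagonal-peak integrals (must be positive).
#' @return Normalized intensity `I_norm`, `NA` where a diagonal is
#'   non-positive.
#' @examples
#' panic_normalize(2, 2, 8, 8)  # 0.25
#' @export
panic_normalize <- function(cross_ab, cross_ba, diag_a, diag_b) {
  ok <- diag_a > 0 & diag_b > 0
  out <- sign((cross_ab + cross_ba) / 2) *
    sqrt(abs(cross_ab * cross_ba)) / sqrt(ifelse(ok, diag_a * diag_b, NA_real_))
  out[!ok] <- NA_real_
  out
}

ols_r_squared <- function(fit) {
  # suppressWarnings: noiseless synthetic data trip lm's
  # "essentially perfect fit" warning, which is the expected case here
  r <- suppressWarnings(summary(fit)$r.squared)
  if (is.nan(r)) 0 else r
}

#' Fit a NOE build-up curve
#'
#' Ordinary least squares of normalized intensity against mixing time with a
#' free intercept, `I_norm = sigma * t + b`. Outlier policy: while the fit
#' fails the validity threshold (`r_squared <= r2_threshold`), more than
#' `min_keep` points remain and fewer than `max_outliers` points have been
#' removed, drop the single point with the largest absolute studentized
#' residual and refit. Points are never discarded from fits that already pass.
#' The curve is valid when `r_squared > r2_threshold` and more than 4 points
#' were used.
#'
#' @param times mixing times in seconds.
#' @param intensities PANIC-normalized intensities (`NA` points are ignored).
#' @param r2_threshold validity threshold on R squared (default 0.90).
#' @param min_points minimum number of points required to attempt a fit
#'   (default 5).
#' @param max_outliers maximum points removable by the outlier policy
#'   (default 2).
#' @param min_keep fit must keep more than this many points while trimming
#'   (default 5).
#' @return An object of class `buildup_curve`: `times`, `intensities`,
#'   `slope`, `intercept`, `r_squared`, `n_used`, `outliers_removed` (mixing
#'   times), `valid`, `reason`.
#' @export
fit_buildup <- function(times, intensities, r2_threshold = 0.90,
                        min_points = 5L, max_outliers = 2L, min_keep = 5L) {
  ok <- is.finite(times) & is.finite(intensities)
  t <- times[ok]
  y <- intensities[ok]
  out <- list(times = t, intensities = y, slope = NA_real_,
              intercept = NA_real_, r_squared = NA_real_,
              n_used = length(t), outliers_removed = numeric(0),
              valid = FALSE, reason = NA_character_)
  if (length(t) < min_points) {
    out$reason <- sprintf("fit refused: %d points supplied, %d required",
                          length(t), min_points)
    return(structure(out, class = "buildup_curve"))
  }
  removed <- numeric(0)
  repeat {
    fit <- stats::lm(y ~ t)
    r2 <- ols_r_squared(fit)
    if (r2 > r2_threshold || length(t) <= min_keep ||
        length(removed) >= max_outliers) {
      break
    }
    rs <- abs(stats::rstudent(fit))
    if (all(!is.finite(rs))) break
    worst <- which.max(rs)
    removed <- c(removed, t[worst])
    t <- t[-worst]
    y <- y[-worst]
  }
  out$slope <- unname(stats::coef(fit)[2L])
  out$intercept <- unname(stats::coef(fit)[1L])
  out$r_squared <- r2
  out$n_used <- length(t)
  out$outliers_removed <- removed
  out$valid <- r2 > r2_threshold && length(t) > 4L
  if (!out$valid) {
    out$reason <- sprintf("r_squared = %.3f (need > %.2f) with n = %d (need > 4)",
                          r2, r2_threshold, length(t))
  }
  structure(out, class = "buildup_curve")
}

#' @export
print.buildup_curve <- function(x, ...) {
  cat(sprintf("<buildup_curve> slope=%.4g 1/s, R2=%.4f, n=%d, outliers=%d, %s\n",
              x$slope, x$r_squared, x$n_used, length(x$outliers_removed),
              if (x$valid) "valid" else paste0("invalid (", x$reason, ")")))
  invisible(x)
}

#' Interproton distance from build-up gradients
#'
#' The inverse sixth-power law of dipolar cross-relaxation:
#' `r_AB = r_ref * (sigma_ref / sigma_AB)^(1/6)`. Distances are strictly
#' decreasing in `sigma_AB` and scale linearly with `r_ref`. Non-positive
#' slopes leave the distance undefined (`NA`).
#'
#' @param sigma_ab build-up gradient of the pair of interest, 1/s.
#' @param sigma_ref build-up gradient of the reference pair, 1/s (must be
#'   positive).
#' @param r_ref reference distance in A (default 1.78, geminal methylene
#'   protons).
#' @return Distance in A (vectorized over `sigma_ab`).
#' @examples
#' distance_from_slopes(0.05, 0.05)       # 1.78
#' distance_from_slopes(0.05 / 64, 0.05)  # 3.56
#' @export
distance_from_slopes <- function(sigma_ab, sigma_ref, r_ref = 1.78) {
  if (!is_scalar_number(sigma_ref) || sigma_ref <= 0) {
    stop_param("sigma_ref must be a single positive number")
  }
  if (!is_scalar_number(r_ref) || r_ref <= 0) {
    stop_param("r_ref must be a single positive number")
  }
  out <- r_ref * (sigma_ref / sigma_ab)^(1 / 6)
  out[!is.finite(sigma_ab) | sigma_ab <= 0] <- NA_real_
  out
}

pair_key <- function(a, b) {
  paste(pmin(a, b), pmax(a, b), sep = "|")
}

#' Build a distance table from a NOESY series
#'
#' The full quantitation chain for every proton pair with cross-peak data:
#' PANIC normalization per mixing time (points with a non-positive cross or
#' diagonal integral are excluded), outlier-trimmed linear build-up fit
#' ([fit_buildup()]), and distance extraction against the reference pair
#' ([distance_from_slopes()]). Pairs whose curves fail the validity criteria
#' (R squared > 0.90 and n > 4) are kept in the table flagged invalid - these
#' are the "missing" distances of a fidelity comparison.
#'
#' @param series a `noesy_series` from [simulate_integrals()],
#'   [quantify_fids()] or [read_noesy_csv()].
#' @param reference_pair two labels; defaults to the series' spin system
#'   reference pair. The reference curve must be valid, otherwise no distances
#'   can be referenced and an error is raised.
#' @param r_ref reference distance in A; defaults to the system's
#'   `reference_distance` (1.78 A).
#' @param ... fit parameters passed to [fit_buildup()].
#' @return A `distance_table`: a data frame with one row per unordered pair
#'   (`pair_a`, `pair_b` sorted lexicographically, `r_ab`, `valid`,
#'   `r_squared`, `n_used`, `n_outliers`, `slope`), with attributes
#'   `reference_pair`, `sigma_ref`, `r_ref` and `curves` (named list of
#'   [fit_buildup()] results).
#' @export
build_distance_table <- function(series, reference_pair = NULL, r_ref = NULL,
                                 ...) {
  stopifnot(inherits(series, "noesy_series"))
  if (is.null(reference_pair)) {
    if (is.null(series$system)) {
      stop_param("series has no spin system: supply reference_pair explicitly")
    }
    reference_pair <- series$system$reference_pair
  }
  if (is.null(r_ref)) {
    r_ref <- if (!is.null(series$system)) series$system$reference_distance else 1.78
  }
  labels <- series$labels
  if (!all(reference_pair %in% labels)) {
    stop_param("reference pair not present in the series")
  }
  n <- length(labels)
  pair_points <- function(a, b) {
    ca <- series$cross[, a, b]
    cb <- series$cross[, b, a]
    da <- series$diagonal[, a]
    db <- series$diagonal[, b]
    keep <- is.finite(ca) & is.finite(cb) & is.finite(da) & is.finite(db) &
      ca > 0 & cb > 0 & da > 0 & db > 0
    list(t = series$mixing_times[keep],
         i = panic_normalize(ca[keep], cb[keep], da[keep], db[keep]))
  }
  idx <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  idx <- idx[order(idx[, 1L], idx[, 2L]), , drop = FALSE]
  curves <- vector("list", nrow(idx))
  keys <- character(nrow(idx))
  for (k in seq_len(nrow(idx))) {
    a <- idx[k, 1L]
    b <- idx[k, 2L]
    pts <- pair_points(a, b)
    curves[[k]] <- fit_buildup(pts$t, pts$i, ...)
    keys[k] <- pair_key(labels[a], labels[b])
  }
  names(curves) <- keys
  ref_key <- pair_key(reference_pair[1L], reference_pair[2L])
  ref_curve <- curves[[ref_key]]
  if (is.null(ref_curve) || !ref_curve$valid || !is.finite(ref_curve$slope) ||
      ref_curve$slope <= 0) {
    stop_param("reference pair build-up curve is invalid; no distances can be referenced")
  }
  sigma_ref <- ref_curve$slope
  slopes <- vapply(curves, `[[`, numeric(1), "slope")
  pa <- pmin(labels[idx[, 1L]], labels[idx[, 2L]])
  pb <- pmax(labels[idx[, 1L]], labels[idx[, 2L]])
  tab <- data.frame(
    pair_a = pa, pair_b = pb,
    r_ab = distance_from_slopes(slopes, sigma_ref, r_ref),
    valid = vapply(curves, `[[`, logical(1), "valid") &
      is.finite(slopes) & slopes > 0,
    r_squared = vapply(curves, `[[`, numeric(1), "r_squared"),
    n_used = vapply(curves, `[[`, integer(1), "n_used"),
    n_outliers = vapply(curves, function(c) length(c$outliers_removed),
                        integer(1)),
    slope = slopes,
    stringsAsFactors = FALSE, row.names = NULL
  )
  distance_table(tab, reference_pair = sort(reference_pair),
                 sigma_ref = sigma_ref, r_ref = r_ref, curves = curves)
}

#' Construct a distance table from a data frame
#'
#' Low-level constructor used by [build_distance_table()], by
#' [read_distance_table()], and by tests that hand-build tables.
#'
#' @param df data frame with at least `pair_a`, `pair_b`, `r_ab`, `valid`.
#' @param reference_pair two labels housed in the table.
#' @param sigma_ref reference build-up gradient (1/s), may be `NA` for tables
#'   read from file.
#' @param r_ref reference distance (A).
#' @param curves optional named list of [fit_buildup()] objects.
#' @return A `distance_table` data frame.
#' @export
distance_table <- function(df, reference_pair, sigma_ref = NA_real_,
                           r_ref = 1.78, curves = NULL) {
  need <- c("pair_a", "pair_b", "r_ab", "valid")
  if (!all(need %in% names(df))) {
    stop_param("distance table needs columns ", paste(need, collapse = ", "))
  }
  if (any(df$valid & !(is.finite(df$r_ab) & df$r_ab > 0))) {
    stop_param("valid entries must have positive finite distances")
  }
  structure(as.data.frame(df),
            class = c("distance_table", "data.frame"),
            reference_pair = reference_pair, sigma_ref = sigma_ref,
            r_ref = r_ref, curves = curves)
}

#' Write / read a distance table as CSV
#'
#' @param table a `distance_table`.
#' @param path CSV file path.
#' @param reference_pair,r_ref reference metadata for tables read back from
#'   file; default: the lexicographically first pair flagged valid with
#'   `r_ab == r_ref`.
#' @return `write_distance_table()` returns `path` invisibly;
#'   `read_distance_table()` a `distance_table`.
#' @export
write_distance_table <- function(table, path) {
  stopifnot(inherits(table, "distance_table"))
  utils::write.csv(as.data.frame(table), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_distance_table
#' @export
read_distance_table <- function(path, reference_pair = NULL, r_ref = 1.78) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (is.null(reference_pair)) {
    hit <- which(df$valid & abs(df$r_ab - r_ref) < 1e-9)
    if (length(hit) == 0L) {
      stop_param("cannot infer reference pair; supply reference_pair")
    }
    reference_pair <- c(df$pair_a[hit[1L]], df$pair_b[hit[1L]])
  }
  distance_table(df, reference_pair = reference_pair, r_ref = r_ref)
}

#' @export
print.distance_table <- function(x, ...) {
  cat(sprintf("<distance_table> %d pairs (%d valid), reference %s-%s = %.2f A\n",
              nrow(x), sum(x$valid), attr(x, "reference_pair")[1L],
              attr(x, "reference_pair")[2L], attr(x, "r_ref")))
  print.data.frame(utils::head(as.data.frame(x), 10L), digits = 4)
  if (nrow(x) > 10L) cat("... (", nrow(x) - 10L, " more rows)\n", sep = "")
  invisible(x)
}
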