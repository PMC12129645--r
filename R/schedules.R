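#' Sampling schedules on a Nyquist grid
#'
#' A sampling schedule records which indirect-dimension (t1) complex increments
#' of an N-point Nyquist grid are acquired. Indices are 0-based, strictly
#' increasing and unique, and the number of sampled points always equals
#' `round(coverage * grid_size)` exactly (e.g. 256 of 512 at 50% coverage).
#' Schedules carry a label in the `"N-cov-us-seed"` convention, e.g.
#' `"512-50-30-0"` for a 512-point grid, 50% total sampling, a 30% uniformly
#' sampled prefix and seed 0.
#'
#' @param grid_size number of indirect-dimension complex increments (>= 2).
#' @param indices 0-based sampled increments, sorted, unique, in
#'   `[0, grid_size)`.
#' @param kind one of `"uniform"`, `"poisson_gap"`, `"random_shuffle"`,
#'   `"hybrid"`, or `"custom"` (schedules read from file).
#' @param us_fraction fraction of the grid covered by the uniformly sampled
#'   prefix (hybrid and uniform kinds; 0 otherwise).
#' @param seed integer seed the schedule was generated from, or `NA` for
#'   deterministic kinds.
#' @return An object of class `sampling_schedule`: a list with fields
#'   `grid_size`, `indices`, `coverage`, `kind`, `us_fraction`, `seed`,
#'   `label`.
#' @seealso [generate_poisson_gap()], [generate_random_shuffle()],
#'   [generate_hybrid()], [generate_uniform()], [read_nuslist()]
#' @export
new_sampling_schedule <- function(grid_size, indices, kind,
                                  us_fraction = 0, seed = NA_integer_) {
  grid_size <- check_count(grid_size, "grid_size", min = 2L)
  kinds <- c("uniform", "poisson_gap", "random_shuffle", "hybrid", "custom")
  if (!is.character(kind) || length(kind) != 1L || !kind %in% kinds) {
    stop_param("kind must be one of ", paste(kinds, collapse = ", "))
  }
  if (length(indices) < 1L) stop_param("a schedule must sample at least one point")
  if (any(!is.finite(indices)) || any(indices != round(indices))) {
    stop_param("indices must be finite integers")
  }
  indices <- as.integer(indices)
  if (is.unsorted(indices, strictly = TRUE)) {
    stop_param("indices must be strictly increasing (sorted, unique)")
  }
  if (indices[1L] < 0L || indices[length(indices)] >= grid_size) {
    stop_param("indices must lie in [0, grid_size)")
  }
  check_fraction(us_fraction, "us_fraction")
  coverage <- length(indices) / grid_size
  if (us_fraction > coverage + 1e-12) {
    stop_param("us_fraction cannot exceed coverage")
  }
  seed_txt <- if (is.na(seed)) "x" else format(as.integer(seed))
  label <- sprintf("%d-%g-%g-%s", grid_size, round(100 * coverage, 1),
                   round(100 * us_fraction, 1), seed_txt)
  structure(
    list(grid_size = grid_size, indices = indices, coverage = coverage,
         kind = kind, us_fraction = us_fraction,
         seed = if (is.na(seed)) NA_integer_ else as.integer(seed),
         label = label),
    class = "sampling_schedule"
  )
}

#' @export
print.sampling_schedule <- function(x, ...) {
  cat(sprintf("<sampling_schedule %s> kind=%s, %d/%d points (%.1f%%), forward fraction %.3f\n",
              x$label, x$kind, length(x$indices), x$grid_size,
              100 * x$coverage, forward_fraction(x)))
  invisible(x)
}

#' @export
format.sampling_schedule <- function(x, ...) x$label

n_points_for <- function(grid_size, coverage) {
  n <- as.integer(round(coverage * grid_size))
  if (n < 1L) stop_param("grid too small to place the requested number of points")
  n
}

# One Poisson-gap pass over a region of n_region points: walk from position 0,
# always sampling the current position, then jumping 1 + g where
# g ~ Poisson(lambda * sin(theta)) and theta sweeps 0 -> pi/2 across the region
# (small gaps early, large gaps late = forward weighting).
pg_draw <- function(n_region, lambda, sinusoidal = TRUE) {
  out <- integer(n_region)
  k <- 0L
  pos <- 0L
  while (pos < n_region) {
    k <- k + 1L
    out[k] <- pos
    w <- if (sinusoidal) sin((pos + 0.5) / n_region * (pi / 2)) else 1
    pos <- pos + 1L + stats::rpois(1L, lambda * w)
  }
  out[seq_len(k)]
}

# Redraw with a multiplicatively rescaled rate until the point count is exact.
# The rate adjustment (lambda * drawn/target) converges in a handful of
# iterations for sane parameters; a seeded add/drop repair of the closest draw
# guarantees termination for degenerate regions.
pg_adjust <- function(n_region, n_points, sinusoidal = TRUE, max_iter = 5000L) {
  if (n_points == 0L) return(integer(0))
  if (n_points >= n_region) return(seq_len(n_region) - 1L)
  mean_gap <- n_region / n_points - 1
  lambda <- if (sinusoidal) mean_gap * pi / 2 else mean_gap
  best <- NULL
  best_diff <- Inf
  for (it in seq_len(max_iter)) {
    s <- pg_draw(n_region, lambda, sinusoidal)
    d <- length(s) - n_points
    if (d == 0L) return(s)
    if (abs(d) < best_diff) {
      best <- s
      best_diff <- abs(d)
    }
    lambda <- lambda * (length(s) / n_points)
    if (!is.finite(lambda) || lambda <= 0) lambda <- mean_gap
  }
  s <- best
  if (length(s) > n_points) {
    drop <- 1L + sample.int(length(s) - 1L, length(s) - n_points) # keep index 0
    s <- s[-drop]
  } else {
    pool <- setdiff(seq_len(n_region) - 1L, s)
    s <- c(s, pool[sample.int(length(pool), n_points - length(s))])
  }
  sort(s)
}

#' Generate a Poisson-gap sampling schedule
#'
#' Gaps between consecutive sampled points are drawn from a Poisson law whose
#' rate is modulated sinusoidally along the grid, so that samples are biased
#' toward early increments (forward weighting, where the decaying signal is
#' strongest). The rate is rescaled and the schedule redrawn until the sampled
#' count equals `round(coverage * grid_size)` exactly. The first increment
#' (index 0) is always sampled.
#'
#' @inheritParams new_sampling_schedule
#' @param coverage fraction of the grid to sample, in (0, 1].
#' @param seed integer seed; the same `(grid_size, coverage, seed)` always
#'   yields bit-identical indices.
#' @param sinusoidal_weight if `FALSE`, use a constant Poisson rate (no forward
#'   weighting).
#' @return A [new_sampling_schedule()] object of kind `"poisson_gap"`.
#' @examples
#' s <- generate_poisson_gap(512, 0.5, seed = 7)
#' length(s$indices)  # exactly 256
#' @export
generate_poisson_gap <- function(grid_size, coverage, seed,
                                 sinusoidal_weight = TRUE) {
  grid_size <- check_count(grid_size, "grid_size", min = 2L)
  check_fraction(coverage, "coverage", lo = 0, hi = 1, lo_open = TRUE)
  n <- n_points_for(grid_size, coverage)
  idx <- if (n == grid_size) {
    seq_len(grid_size) - 1L
  } else {
    with_seed(seed, pg_adjust(grid_size, n, sinusoidal = sinusoidal_weight))
  }
  new_sampling_schedule(grid_size, idx, "poisson_gap", us_fraction = 0,
                        seed = seed)
}

#' Generate a random-shuffle sampling schedule
#'
#' A uniform random draw without replacement of `round(coverage * grid_size)`
#' increments from the grid, sorted. No forward weighting is applied; this is
#' the schedule family produced by spectrometer software in "random shuffle"
#' mode.
#'
#' @inheritParams generate_poisson_gap
#' @return A [new_sampling_schedule()] object of kind `"random_shuffle"`.
#' @export
generate_random_shuffle <- function(grid_size, coverage, seed) {
  grid_size <- check_count(grid_size, "grid_size", min = 2L)
  check_fraction(coverage, "coverage", lo = 0, hi = 1, lo_open = TRUE)
  n <- n_points_for(grid_size, coverage)
  idx <- if (n == grid_size) {
    seq_len(grid_size) - 1L
  } else {
    with_seed(seed, sort(sample.int(grid_size, n) - 1L))
  }
  new_sampling_schedule(grid_size, idx, "random_shuffle", us_fraction = 0,
                        seed = seed)
}

#' Generate a US-NUS hybrid sampling schedule
#'
#' A hybrid schedule samples an unbroken uniform prefix of
#' `k = round(us_fraction * grid_size)` increments (`0, ..., k-1`), followed by
#' a Poisson-gap draw with sinusoidal forward weighting over the remaining
#' `grid_size - k` increments, so that the total count is exactly
#' `round(coverage * grid_size)`. With `us_fraction = 0` the result is
#' identical to [generate_poisson_gap()] with the same seed; with
#' `us_fraction = coverage` it degenerates to the truncated-uniform schedule.
#'
#' @inheritParams generate_poisson_gap
#' @param us_fraction fraction of the grid sampled uniformly at the start,
#'   in `[0, coverage]`.
#' @return A [new_sampling_schedule()] object of kind `"hybrid"`, labelled in
#'   the `"N-cov-us-seed"` convention (e.g. `"512-50-30-0"`).
#' @examples
#' h <- generate_hybrid(512, 0.5, 0.30, seed = 0)
#' h$label                       # "512-50-30-0"
#' all(0:153 %in% h$indices)     # uniform prefix of round(0.30 * 512) points
#' @export
generate_hybrid <- function(grid_size, coverage, us_fraction, seed) {
  grid_size <- check_count(grid_size, "grid_size", min = 2L)
  check_fraction(coverage, "coverage", lo = 0, hi = 1, lo_open = TRUE)
  check_fraction(us_fraction, "us_fraction")
  if (us_fraction > coverage + 1e-12) {
    stop_param("us_fraction must not exceed coverage")
  }
  n <- n_points_for(grid_size, coverage)
  k <- as.integer(round(us_fraction * grid_size))
  if (k > n) stop_param("uniform prefix longer than the total point budget")
  n_tail <- n - k
  if (n_tail > grid_size - k) {
    stop_param("tail region too small for the remaining points")
  }
  tail_idx <- if (n_tail == 0L) {
    integer(0)
  } else {
    with_seed(seed, pg_adjust(grid_size - k, n_tail, sinusoidal = TRUE))
  }
  idx <- c(if (k > 0L) seq_len(k) - 1L, k + tail_idx)
  new_sampling_schedule(grid_size, idx, "hybrid", us_fraction = us_fraction,
                        seed = seed)
}

#' Generate a uniform (truncated-uniform) schedule
#'
#' Coverage 1 is conventional uniform sampling of the whole grid; coverage
#' below 1 samples the first `round(coverage * grid_size)` increments
#' (truncation).
#'
#' @inheritParams generate_poisson_gap
#' @param coverage fraction of the grid to sample, in (0, 1]; default 1.
#' @return A [new_sampling_schedule()] object of kind `"uniform"`.
#' @export
generate_uniform <- function(grid_size, coverage = 1) {
  grid_size <- check_count(grid_size, "grid_size", min = 2L)
  check_fraction(coverage, "coverage", lo = 0, hi = 1, lo_open = TRUE)
  n <- n_points_for(grid_size, coverage)
  new_sampling_schedule(grid_size, seq_len(n) - 1L, "uniform",
                        us_fraction = n / grid_size, seed = NA_integer_)
}

schedule_mask <- function(schedule) {
  m <- logical(schedule$grid_size)
  m[schedule$indices + 1L] <- TRUE
  m
}

is_full_schedule <- function(schedule) {
  length(schedule$indices) == schedule$grid_size
}
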