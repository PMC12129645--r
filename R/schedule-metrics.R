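#' Signal-envelope model for relative sensitivity
#'
#' Relative sensitivity weights each grid point by the decaying signal
#' envelope. The envelope is exponential,
#' `envelope(i) = exp(-decay_constant * i / grid_size)`, so `decay_constant`
#' is the grid length divided by the effective T2 in increment units:
#' `decay_constant = 0` is a flat envelope (constant-time limit), 1 means the
#' signal has decayed to 1/e at the end of the grid. The default 0.2 is a mild
#' decay consistent with 50%-coverage schedules capturing just above 50% of
#' the envelope.
#'
#' @param decay_constant dimensionless decay rate over the grid, >= 0.
#' @return An object of class `envelope_model`.
#' @export
envelope_model <- function(decay_constant = 0.2) {
  if (!is_scalar_number(decay_constant) || decay_constant < 0) {
    stop_param("decay_constant must be a single number >= 0")
  }
  structure(list(form = "exponential", decay_constant = decay_constant),
            class = "envelope_model")
}

envelope_values <- function(envelope, grid_size) {
  stopifnot(inherits(envelope, "envelope_model"))
  exp(-envelope$decay_constant * (seq_len(grid_size) - 1L) / grid_size)
}

#' Point-spread function of a sampling schedule
#'
#' The point-spread function (PSF) is the discrete Fourier transform of the
#' 0/1 sampling mask with unsampled points as zeros, zero-filled to
#' `zerofill_factor * grid_size` bins. Its sidelobes predict the aliasing
#' artefacts the schedule will smear a single resonance into. Amplitudes are
#' normalized so that the main (zero-frequency) lobe equals
#' `n_sampled / grid_size`.
#'
#' @param schedule a [new_sampling_schedule()] object.
#' @param zerofill_factor zero-filling multiple (>= 1; >= 2 needed to resolve
#'   sidelobes for [peak_to_sidelobe()]).
#' @return An object of class `nus_psf` with fields `amplitudes` (complex,
#'   length `zerofill_factor * grid_size`, zero frequency first),
#'   `main_lobe_index` (0), `main_lobe_width` (bins either side of zero
#'   frequency counted as main lobe), `grid_size`, `n_sampled`,
#'   `zerofill_factor`.
#' @export
compute_psf <- function(schedule, zerofill_factor = 4L) {
  stopifnot(inherits(schedule, "sampling_schedule"))
  zerofill_factor <- check_count(zerofill_factor, "zerofill_factor", min = 1L)
  n <- schedule$grid_size
  m <- zerofill_factor * n
  mask <- numeric(m)
  mask[schedule$indices + 1L] <- 1
  amps <- stats::fft(mask) / n
  structure(
    list(amplitudes = amps, main_lobe_index = 0L,
         main_lobe_width = zerofill_factor, grid_size = n,
         n_sampled = length(schedule$indices),
         zerofill_factor = zerofill_factor),
    class = "nus_psf"
  )
}

#' Peak-to-sidelobe ratio of a PSF
#'
#' The main-lobe amplitude divided by the tallest amplitude outside the main
#' lobe (bins within `main_lobe_width` of zero frequency, circularly).
#' Sidelobes are artefacts of *missing* samples: a complete schedule has none
#' and returns the `Inf` sentinel. (On the zero-filled grid the between-bin
#' values of a complete mask carry the finite acquisition-window response,
#' which is present identically in uniform acquisition and is not counted as a
#' sampling artefact.)
#'
#' @param psf a [compute_psf()] object computed with `zerofill_factor >= 2`.
#' @return A dimensionless ratio >= 1, or `Inf` when sidelobes are numerically
#'   zero.
#' @export
peak_to_sidelobe <- function(psf) {
  stopifnot(inherits(psf, "nus_psf"))
  if (psf$zerofill_factor < 2L) {
    stop_param("peak_to_sidelobe needs a PSF computed with zerofill_factor >= 2")
  }
  if (psf$n_sampled == psf$grid_size) return(Inf)
  m <- length(psf$amplitudes)
  bins <- seq_len(m) - 1L
  dist <- pmin(bins, m - bins) # circular distance to zero frequency
  mag <- Mod(psf$amplitudes)
  main <- mag[1L]
  side <- max(mag[dist > psf$main_lobe_width])
  if (side <= main * 1e-12) Inf else main / side
}

#' Relative sensitivity of a schedule
#'
#' The percentage of the decaying signal envelope captured by the sampled
#' points: `100 * sum(envelope[sampled]) / sum(envelope[all])`. Under a flat
#' envelope this is exactly `100 * coverage` for every schedule kind;
#' forward-weighted schedules score above `100 * coverage` under a decaying
#' envelope.
#'
#' @param schedule a [new_sampling_schedule()] object.
#' @param envelope an [envelope_model()]; default mild decay (0.2).
#' @return Percent in (0, 100].
#' @export
relative_sensitivity <- function(schedule, envelope = envelope_model()) {
  stopifnot(inherits(schedule, "sampling_schedule"))
  e <- envelope_values(envelope, schedule$grid_size)
  100 * sum(e[schedule$indices + 1L]) / sum(e)
}

#' Forward-weighting fraction
#'
#' Fraction of sampled points that fall in the first half of the grid. A
#' descriptive surrogate for forward weighting: 0.5 in expectation for
#' unbiased random draws, 1 for a truncated-uniform 50% schedule.
#'
#' @param schedule a [new_sampling_schedule()] object.
#' @return Fraction in [0, 1].
#' @export
forward_fraction <- function(schedule) {
  stopifnot(inherits(schedule, "sampling_schedule"))
  mean(schedule$indices < schedule$grid_size / 2)
}

#' Toy signal for SAAR scoring
#'
#' A noiseless sum of decaying complex cosinusoids with a high dynamic range
#' (default amplitudes 1, 0.1, 0.01 at incommensurate frequencies), used by
#' [saar()] to probe how a schedule's reconstruction artefacts compare with the
#' weakest real signals.
#'
#' @param frequencies fractions of the sampling frequency in [0, 1), one per
#'   component.
#' @param amplitudes positive amplitudes, one per component; the first is the
#'   apex peak.
#' @param decay total exponential decay over the grid (signal down by
#'   `exp(-decay)` at the last increment).
#' @return An object of class `toy_signal_spec`.
#' @export
toy_signal_spec <- function(frequencies = c(0.1133, 0.3217, 0.6841),
                            amplitudes = c(1, 0.1, 0.01),
                            decay = 3) {
  if (length(frequencies) != length(amplitudes) || length(frequencies) < 1L) {
    stop_param("frequencies and amplitudes must be non-empty and equal length")
  }
  if (any(frequencies < 0 | frequencies >= 1)) {
    stop_param("frequencies must be in [0, 1) (fractions of the sampling frequency)")
  }
  if (any(amplitudes <= 0)) stop_param("amplitudes must be positive")
  structure(list(frequencies = frequencies, amplitudes = amplitudes,
                 decay = decay),
            class = "toy_signal_spec")
}

toy_signal <- function(toy, grid_size) {
  t <- seq_len(grid_size) - 1L
  sig <- complex(length.out = grid_size)
  for (j in seq_along(toy$frequencies)) {
    sig <- sig + toy$amplitudes[j] *
      exp(2i * pi * toy$frequencies[j] * t - toy$decay * t / grid_size)
  }
  sig
}

#' Signal apex-to-artefact ratio (SAAR)
#'
#' Synthesizes the toy interferogram on the full grid, subsamples it with the
#' schedule, reconstructs (iterative soft thresholding, or plain zero filling),
#' Fourier transforms, and returns the apex magnitude of the strongest true
#' peak divided by the tallest magnitude outside all declared peak regions.
#' Higher is better; a fully sampled schedule has an artefact floor at
#' numerical noise and returns `Inf`.
#'
#' @param schedule a [new_sampling_schedule()] object.
#' @param toy a [toy_signal_spec()].
#' @param reconstructor `"ist"` (default) or `"zerofill"` (identity; the PSF
#'   limit).
#' @param zerofill_factor spectral zero filling applied before measuring.
#' @param peak_halfwidth half width, in bins of the zero-filled spectrum, of
#'   the region declared around each true peak.
#' @param apodization,first_point passed to [process_spectrum()];
#'   `apodization = "none"` with `first_point = 1` makes zero-fill SAAR on a
#'   single undamped on-bin cosinusoid coincide exactly with the PSF
#'   sidelobe structure.
#' @param ... further arguments passed to [ist_reconstruct()].
#' @return A dimensionless ratio > 0, or `Inf`. A complete schedule has no
#'   sampling artefacts and returns the `Inf` sentinel (the true signal's own
#'   lineshape tails, present identically under uniform sampling, are not
#'   counted).
#' @export
saar <- function(schedule, toy = toy_signal_spec(),
                 reconstructor = c("ist", "zerofill"),
                 zerofill_factor = 2L, peak_halfwidth = 16L,
                 apodization = c("sine2", "none"), first_point = 0.5, ...) {
  stopifnot(inherits(schedule, "sampling_schedule"),
            inherits(toy, "toy_signal_spec"))
  reconstructor <- match.arg(reconstructor)
  n <- schedule$grid_size
  m <- check_count(zerofill_factor, "zerofill_factor", min = 1L) * n
  bins_check <- as.integer(round(toy$frequencies * m)) %% m
  if ((2L * peak_halfwidth + 1L) * length(unique(bins_check)) >= m) {
    stop_param("peak regions cover the whole spectrum")
  }
  if (is_full_schedule(schedule)) return(Inf)
  sig <- toy_signal(toy, n)
  sub <- sig
  sub[!schedule_mask(schedule)] <- 0
  rec <- if (reconstructor == "ist") {
    ist_reconstruct(sub, schedule, ...)
  } else {
    sub
  }
  sp <- process_spectrum(rec, zerofill_to = m, mode = "magnitude",
                         apodization = match.arg(apodization),
                         first_point = first_point)
  bins <- as.integer(round(toy$frequencies * m)) %% m
  in_region <- logical(m)
  apex_region <- logical(m)
  for (j in seq_along(bins)) {
    idx <- ((bins[j] - peak_halfwidth):(bins[j] + peak_halfwidth)) %% m + 1L
    in_region[idx] <- TRUE
    if (j == which.max(toy$amplitudes)) apex_region[idx] <- TRUE
  }
  if (all(in_region)) stop_param("peak regions cover the whole spectrum")
  apex <- max(sp[apex_region])
  artefact <- max(sp[!in_region])
  if (artefact <= apex * 1e-12) Inf else apex / artefact
}

#' Score a schedule with all reference-free metrics
#'
#' Convenience wrapper returning peak-to-sidelobe ratio, relative sensitivity,
#' SAAR and forward-weighting fraction in one list.
#'
#' @inheritParams saar
#' @param envelope an [envelope_model()] for [relative_sensitivity()].
#' @param psf_zerofill zero-filling factor for the PSF.
#' @return A list with components `label`, `kind`, `n_sampled`, `grid_size`,
#'   `peak_to_sidelobe`, `relative_sensitivity`, `saar`, `forward_fraction`.
#' @export
schedule_metrics <- function(schedule, envelope = envelope_model(),
                             psf_zerofill = 4L, toy = toy_signal_spec(),
                             reconstructor = c("ist", "zerofill"), ...) {
  stopifnot(inherits(schedule, "sampling_schedule"))
  list(
    label = schedule$label,
    kind = schedule$kind,
    n_sampled = length(schedule$indices),
    grid_size = schedule$grid_size,
    peak_to_sidelobe = peak_to_sidelobe(compute_psf(schedule, psf_zerofill)),
    relative_sensitivity = relative_sensitivity(schedule, envelope),
    saar = saar(schedule, toy = toy, reconstructor = reconstructor, ...),
    forward_fraction = forward_fraction(schedule)
  )
}
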