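# Independent oracles used across the suite. These are deliberately naive
# implementations (direct summation, closed forms) kept separate from the
# package's code paths.

# O(N*M) term-by-term discrete transform of a sampling mask, normalized so the
# zero-frequency bin equals n_sampled / grid_size.
dft_psf_oracle <- function(indices, grid_size, m) {
  k <- 0:(m - 1)
  amps <- vapply(k, function(kk) {
    sum(exp(-2i * pi * kk * indices / m))
  }, complex(1))
  amps / grid_size
}

# |Dirichlet kernel| of a length-L boxcar starting at index 0, evaluated on an
# m-bin grid, normalized by grid_size.
dirichlet_mag_oracle <- function(l, grid_size, m) {
  k <- 0:(m - 1)
  num <- sin(pi * l * k / m)
  den <- sin(pi * k / m)
  out <- ifelse(abs(den) < 1e-14, l, abs(num / den))
  out / grid_size
}

# Direct-summation processing oracle: apodize, scale first point, zero fill,
# term-by-term DFT.
dft_process_oracle <- function(x, zerofill_to, first_point = 0.5) {
  n <- length(x)
  w <- cos((pi / 2) * (0:(n - 1)) / n)^2
  xa <- x * w
  xa[1] <- xa[1] * first_point
  xp <- c(xa, rep(0 + 0i, zerofill_to - n))
  k <- 0:(zerofill_to - 1)
  vapply(k, function(kk) {
    sum(xp * exp(-2i * pi * kk * (0:(zerofill_to - 1)) / zerofill_to))
  }, complex(1))
}

# small fixture systems -------------------------------------------------------

two_pair_system <- function(d = 3.56) {
  lab <- c("Ha", "Hb", "Hc", "Hd")
  m <- matrix(3.0, 4, 4, dimnames = list(lab, lab))
  diag(m) <- 0
  m["Ha", "Hb"] <- m["Hb", "Ha"] <- 1.78
  m["Hc", "Hd"] <- m["Hd", "Hc"] <- d
  spin_system(m, reference_pair = c("Ha", "Hb"))
}

three_spin_chain <- function() {
  lab <- c("Ha", "Hb", "Hc")
  m <- matrix(0, 3, 3, dimnames = list(lab, lab))
  m["Ha", "Hb"] <- m["Hb", "Ha"] <- 1.78
  m["Hb", "Hc"] <- m["Hc", "Hb"] <- 2.5
  m["Ha", "Hc"] <- m["Hc", "Ha"] <- 4.0
  spin_system(m, reference_pair = c("Ha", "Hb"))
}

# hand-built distance table for comparison tests
make_table <- function(pairs_a, pairs_b, r, valid = TRUE,
                       reference_pair = c("Ha", "Hb")) {
  distance_table(
    data.frame(pair_a = pairs_a, pair_b = pairs_b, r_ab = r,
               valid = rep_len(valid, length(r)),
               stringsAsFactors = FALSE),
    reference_pair = reference_pair, sigma_ref = 0.05, r_ref = 1.78
  )
}
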