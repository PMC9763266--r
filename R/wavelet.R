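# Periodised orthogonal discrete wavelet transform (1D, multilevel).
# Only what the stripe filter needs: analysis/synthesis with Daubechies
# filters and perfect reconstruction for even-length signals.

daubechies_filters <- function(name = "db5") {
  dec_lo <- switch(name,
    haar = c(1, 1) / sqrt(2),
    db2 = c(-0.12940952255092145, 0.22414386804185735,
            0.836516303737469, 0.48296291314469025),
    db5 = c(0.003335725285473771, -0.012580751999081999,
            -0.006241490212798274, 0.07757149384004572,
            -0.032244869584638375, -0.24229488706638203,
            0.13842814590132074, 0.7243085284377729,
            0.6038292697971896, 0.16010239797419293),
    stop("unknown wavelet: ", name)
  )
  n <- length(dec_lo)
  dec_hi <- rev(dec_lo) * (-1)^(seq_len(n) - 1)
  # orthogonal bank with correlation-style analysis: synthesis reuses the
  # decomposition filters directly
  list(dec_lo = dec_lo, dec_hi = dec_hi, rec_lo = dec_lo, rec_hi = dec_hi)
}

# periodised analysis step: correlation with the filter, dyadic downsample
# (0-based: y[k] = sum_j h[j] * x[(2k + j) mod n])
dwt_step <- function(x, h) {
  n <- length(x)
  k <- seq(0, n - 2, by = 2)
  y <- numeric(length(k))
  for (j in seq_along(h)) {
    y <- y + h[j] * x[((k + j - 1) %% n) + 1]
  }
  y
}

# periodised synthesis: x[i] = sum_k lo[(i-2k) mod n] a[k] + hi[...] d[k]
idwt_step <- function(approx, detail, lo, hi) {
  n <- 2L * length(approx)
  up <- function(v) { u <- numeric(n); u[seq(1, n, by = 2)] <- v; u }
  a <- up(approx); d <- up(detail)
  i <- seq_len(n) - 1
  y <- numeric(n)
  for (j in seq_along(lo)) {
    idx <- ((i - (j - 1)) %% n) + 1
    y <- y + lo[j] * a[idx] + hi[j] * d[idx]
  }
  y
}

# multilevel periodised DWT; returns list(approx, details = list(level1..))
dwt_multilevel <- function(x, levels, wavelet = "db5") {
  f <- daubechies_filters(wavelet)
  if (length(x) %% 2^levels != 0) {
    stop(sprintf("signal length %d not divisible by 2^%d", length(x), levels))
  }
  details <- vector("list", levels)
  a <- x
  for (lev in seq_len(levels)) {
    d <- dwt_step(a, f$dec_hi)
    a <- dwt_step(a, f$dec_lo)
    details[[lev]] <- d
  }
  list(approx = a, details = details, wavelet = wavelet, levels = levels)
}

idwt_multilevel <- function(w) {
  f <- daubechies_filters(w$wavelet)
  a <- w$approx
  for (lev in rev(seq_len(w$levels))) {
    a <- idwt_step(a, w$details[[lev]], f$rec_lo, f$rec_hi)
  }
  a
}
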