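## Independent brute-force oracles for the template entropies, written as
## literal double loops over explicitly materialized template matrices.

chebyshev <- function(a, b) max(abs(a - b))

templatesOf <- function(x, m) {
  n <- length(x) - m + 1
  t(vapply(seq_len(n), function(i) x[i:(i + m - 1)], numeric(m)))
}

apenOracle <- function(x, m, r) {
  phi <- function(mm) {
    tpl <- templatesOf(x, mm)
    n <- nrow(tpl)
    cs <- numeric(n)
    for (i in seq_len(n)) {
      cnt <- 0
      for (j in seq_len(n))
        if (chebyshev(tpl[i, ], tpl[j, ]) <= r) cnt <- cnt + 1
      cs[i] <- cnt / n
    }
    mean(log(cs))
  }
  phi(m) - phi(m + 1)
}

sampenOracle <- function(x, m, r) {
  n <- length(x) - m   # template count shared by both lengths
  tplm <- templatesOf(x, m)[seq_len(n), , drop = FALSE]
  tplm1 <- templatesOf(x, m + 1)
  A <- 0; B <- 0
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      if (chebyshev(tplm[i, ], tplm[j, ]) <= r) B <- B + 1
      if (chebyshev(tplm1[i, ], tplm1[j, ]) <= r) A <- A + 1
    }
  }
  if (A == 0 || B == 0) return(NA_real_)
  -log(A / B)
}

fuzzyenOracle <- function(x, m, r, nf) {
  phi <- function(mm) {
    n <- length(x) - m   # same offsets for both template lengths
    tpl <- templatesOf(x, mm)[seq_len(n), , drop = FALSE]
    tpl <- tpl - rowMeans(tpl)
    acc <- 0; cnt <- 0
    for (i in seq_len(n - 1)) {
      for (j in (i + 1):n) {
        d <- chebyshev(tpl[i, ], tpl[j, ])
        acc <- acc + exp(-(d / r)^nf)
        cnt <- cnt + 1
      }
    }
    acc / cnt
  }
  log(phi(m)) - log(phi(m + 1))
}

## Direct-formula amplitude oracle used for cross-checking the vectorized
## implementation on random vectors.
amplitudeOracle <- function(x) {
  locmax <- c(); locmin <- c()
  d <- diff(x)
  nz <- which(d != 0)
  if (length(nz) >= 2) {
    for (p in seq_len(length(nz) - 1)) {
      if (d[nz[p]] > 0 && d[nz[p + 1]] < 0) locmax <- c(locmax, nz[p] + 1)
      if (d[nz[p]] < 0 && d[nz[p + 1]] > 0) locmin <- c(locmin, nz[p] + 1)
    }
  }
  z <- (x - mean(x)) / sd(x)
  c(peak = max(x), p2p = max(x) - min(x), rms = sqrt(mean(x^2)),
    mlocmaxv = if (length(locmax)) mean(x[locmax]) else NA_real_,
    minlocminv = if (length(locmin)) mean(x[locmin]) else NA_real_,
    mav = mean(abs(x)), mavfd = mean(abs(diff(x))),
    mavfdn = mean(abs(diff(z))), mavsd = mean(abs(diff(diff(x)))),
    mavsdn = mean(abs(diff(diff(z)))))
}
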