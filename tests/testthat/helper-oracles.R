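# independent scalar transcription of the two-population variance components,
# written as a direct sum over populations (general-r form with r = 2)
wc_oracle <- function(n, p, h) {
  r <- length(n)
  nbar <- mean(n)
  nc <- (sum(n) - sum(n^2) / sum(n)) / (r - 1)
  pbar <- sum(n * p) / sum(n)
  s2 <- sum(n * (p - pbar)^2) / ((r - 1) * nbar)
  hbar <- sum(n * h) / sum(n)
  a <- (nbar / nc) * (s2 - (pbar * (1 - pbar) - (r - 1) / r * s2 - hbar / 4) / (nbar - 1))
  b <- (nbar / (nbar - 1)) * (pbar * (1 - pbar) - (r - 1) / r * s2 -
                                (2 * nbar - 1) / (4 * nbar) * hbar)
  cc <- hbar / 2
  if (a + b + cc == 0) NA_real_ else a / (a + b + cc)
}

# random genotype-count draw for one population: returns c(n, p, h)
random_pop_counts <- function(n_range = 2:300) {
  n <- sample(n_range, 1)
  g <- stats::rmultinom(1, n, stats::runif(3))   # (hom-ref, het, hom-alt)
  c(n = n, p = (2 * g[3] + g[2]) / (2 * n), h = g[2] / n)
}
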