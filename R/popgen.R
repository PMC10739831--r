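#' Per-site Weir-Cockerham Fst for two populations
#'
#' Computes the Weir-Cockerham variance components `a` (among populations),
#' `b` (among individuals within populations) and `c` (within individuals)
#' and the per-site estimator `theta = a / (a + b + c)` from sample sizes,
#' ALT-allele frequencies and observed heterozygote frequencies of two
#' population samples. With `r = 2` populations:
#' \deqn{\bar n = (n_1 + n_2)/2, \quad
#'       n_c = (r\bar n - (n_1^2 + n_2^2)/(r\bar n))/(r - 1)}
#' \deqn{\bar p = (n_1 p_1 + n_2 p_2)/(r\bar n), \quad
#'       s^2 = (n_1(p_1-\bar p)^2 + n_2(p_2-\bar p)^2)/((r-1)\bar n), \quad
#'       \bar h = (n_1 h_1 + n_2 h_2)/(r\bar n)}
#' \deqn{a = \frac{\bar n}{n_c}\left[s^2 - \frac{1}{\bar n - 1}
#'       \left(\bar p(1-\bar p) - \frac{r-1}{r}s^2 - \frac{\bar h}{4}\right)\right]}
#' \deqn{b = \frac{\bar n}{\bar n - 1}\left[\bar p(1-\bar p) -
#'       \frac{r-1}{r}s^2 - \frac{2\bar n - 1}{4\bar n}\bar h\right], \quad
#'       c = \bar h / 2}
#' Observed heterozygosity enters directly (no Hardy-Weinberg assumption).
#' Negative estimates are reported as-is, never clamped, so downstream
#' medians and tests see the estimator's true distribution. When
#' `a + b + c = 0` (e.g. a site monomorphic in both samples) `theta` is
#' `NA`, an explicit undefined sentinel.
#'
#' @param n1,n2 Diploid sample sizes (>= 2), vectorized.
#' @param p1,p2 ALT-allele frequencies in `[0, 1]`.
#' @param h1,h2 Observed heterozygote frequencies in `[0, 1]`, consistent
#'   with the allele frequencies (`h/2 <= min(p, 1 - p)`).
#' @return Data.frame with columns `n1`, `p1`, `h1`, `n2`, `p2`, `h2`,
#'   `a`, `b`, `c`, `theta`.
#' @examples
#' wc_fst(10, 0, 0, 10, 1, 0)$theta        # fixed difference: exactly 1
#' wc_fst(11, 0.5, 0.5, 11, 0.5, 0.5)$theta  # identical frequencies: -0.05
#' @export
wc_fst <- function(n1, p1, h1, n2, p2, h2) {
  k <- max(length(n1), length(p1), length(h1), length(n2), length(p2), length(h2))
  n1 <- rep_len(as.numeric(n1), k); n2 <- rep_len(as.numeric(n2), k)
  p1 <- rep_len(as.numeric(p1), k); p2 <- rep_len(as.numeric(p2), k)
  h1 <- rep_len(as.numeric(h1), k); h2 <- rep_len(as.numeric(h2), k)
  if (any(n1 < 2 | n2 < 2))
    validation_error("wc_fst needs at least 2 diploid individuals per population")
  if (any(p1 < 0 | p1 > 1 | p2 < 0 | p2 > 1))
    validation_error("allele frequencies must lie in [0, 1]")
  if (any(h1 < 0 | h1 > 1 | h2 < 0 | h2 > 1))
    validation_error("heterozygote frequencies must lie in [0, 1]")
  tol <- 1e-9
  if (any(h1 / 2 > pmin(p1, 1 - p1) + tol | h2 / 2 > pmin(p2, 1 - p2) + tol))
    validation_error("heterozygote frequency inconsistent with allele frequency (h/2 > min(p, 1-p))")

  r <- 2
  nbar <- (n1 + n2) / r
  nc <- (r * nbar - (n1^2 + n2^2) / (r * nbar)) / (r - 1)
  pbar <- (n1 * p1 + n2 * p2) / (r * nbar)
  s2 <- (n1 * (p1 - pbar)^2 + n2 * (p2 - pbar)^2) / ((r - 1) * nbar)
  hbar <- (n1 * h1 + n2 * h2) / (r * nbar)

  a <- (nbar / nc) * (s2 - (1 / (nbar - 1)) *
                        (pbar * (1 - pbar) - ((r - 1) / r) * s2 - hbar / 4))
  b <- (nbar / (nbar - 1)) * (pbar * (1 - pbar) - ((r - 1) / r) * s2 -
                                ((2 * nbar - 1) / (4 * nbar)) * hbar)
  cc <- hbar / 2
  denom <- a + b + cc
  theta <- ifelse(denom == 0, NA_real_, a / denom)
  data.frame(n1 = n1, p1 = p1, h1 = h1, n2 = n2, p2 = p2, h2 = h2,
             a = a, b = b, c = cc, theta = theta)
}

#' Per-SNP Weir-Cockerham Fst from a SNP count table
#'
#' Derives per-population allele and observed-heterozygote frequencies from
#' the genotype counts in a SNP table and evaluates [wc_fst()] for every
#' site.
#'
#' @param snps SNP table from [read_biallelic_snps()].
#' @param pop1,pop2 Population labels present in the table.
#' @return Data.frame: `snp_id`, `n1`, `n2`, `p1`, `p2`, `h1`, `h2`, `a`,
#'   `b`, `c`, `theta`.
#' @export
snp_fst <- function(snps, pop1, pop2) {
  for (p in c(pop1, pop2))
    if (is.null(snps[[paste0("n_called_", p)]]))
      validation_error(sprintf("no counts for population '%s' in SNP table", p))
  if (!nrow(snps))
    return(data.frame(snp_id = character(), n1 = numeric(), n2 = numeric(),
                      p1 = numeric(), p2 = numeric(), h1 = numeric(),
                      h2 = numeric(), a = numeric(), b = numeric(),
                      c = numeric(), theta = numeric()))
  n1 <- snps[[paste0("n_called_", pop1)]]
  n2 <- snps[[paste0("n_called_", pop2)]]
  if (any(n1 < 2 | n2 < 2))
    data_error(sprintf("fewer than 2 called diploids for SNP(s): %s",
                       paste(utils::head(snps$snp_id[n1 < 2 | n2 < 2], 10),
                             collapse = ", ")))
  p1 <- snps[[paste0("alt_count_", pop1)]] / (2 * n1)
  p2 <- snps[[paste0("alt_count_", pop2)]] / (2 * n2)
  h1 <- snps[[paste0("het_count_", pop1)]] / n1
  h2 <- snps[[paste0("het_count_", pop2)]] / n2
  comp <- wc_fst(n1, p1, h1, n2, p2, h2)
  cbind(data.frame(snp_id = snps$snp_id, stringsAsFactors = FALSE), comp)
}

#' Multi-locus Weir-Cockerham theta (ratio of summed components)
#'
#' Combines per-site variance components into the standard multi-locus
#' estimate `sum(a) / sum(a + b + c)`. Averaging per-site ratios is downward
#' biased (the expectation of a ratio is not the ratio of expectations, and
#' low-frequency sites contribute noisy ratios); the ratio of sums is the
#' canonical aggregate and is the quantity that recovers a simulation's
#' divergence parameter.
#'
#' @param fst Data.frame with columns `a`, `b`, `c` (from [snp_fst()] or
#'   [wc_fst()]).
#' @return A single theta estimate (`NA` if all components sum to zero).
#' @export
wc_fst_global <- function(fst) {
  denom <- sum(fst$a + fst$b + fst$c, na.rm = TRUE)
  if (denom == 0) return(NA_real_)
  sum(fst$a, na.rm = TRUE) / denom
}

#' Is a SNP strongly differentiated?
#'
#' A SNP counts as strongly differentiated between the two populations when
#' its Weir-Cockerham theta reaches the threshold (inclusive); 0.1 is the
#' conventional cutoff used throughout the bias diagnostics.
#'
#' @param theta Per-site theta value(s); must be defined (non-`NA`).
#' @param threshold Minimum theta, default 0.1.
#' @return Logical vector.
#' @export
strongly_differentiated <- function(theta, threshold = 0.1) {
  if (any(is.na(theta)))
    data_error("theta undefined (NA) for one or more sites")
  theta >= threshold
}

#' Write an Fst table as TSV
#' @param fst Data.frame from [snp_fst()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fst_tsv <- function(fst, path) {
  utils::write.table(fst, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read an Fst table written by [write_fst_tsv()]
#' @param path TSV path.
#' @return Fst data.frame.
#' @export
read_fst_tsv <- function(path) {
  if (!file.exists(path)) validation_error(sprintf("Fst table not found: %s", path))
  utils::read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE)
}
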