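toy_vcf <- function() {
  sites <- data.frame(
    chrom = "1", pos = c(100L, 200L, 300L, 400L),
    id = c("s1", "s2", "s3", "s4"),
    ref = c("A", "C", "A", "G"), alt = c("G", "T", "AT", "C"),
    stringsAsFactors = FALSE
  )
  gt <- rbind(
    c("0/0", "0/1", "1/1", "0/0", "0/1", "1/1"),   # s1
    c("./.", "0|1", "1/1", "0/.", "0/0", "0/0"),   # s2: missing + half-call
    c("0/0", "0/0", "0/0", "0/0", "0/0", "0/0"),   # s3: indel, skipped
    c("0/1", "0/1", "0/1", "0/0", "0/0", "0/0")    # s4
  )
  samples <- c(paste0("E", 1:3), paste0("A", 1:3))
  list(vcf = write_vcf_text(sites, gt, samples),
       panel = write_panel_text(samples, rep(c("EUR", "AFR"), each = 3)))
}

test_that("panel reading tolerates headers and rejects duplicates", {
  p <- read_panel(write_panel_text(c("a", "b", "c", "d"),
                                   c("EUR", "EUR", "AFR", "AFR")))
  expect_equal(nrow(p), 4L)
  expect_setequal(unique(p$population), c("EUR", "AFR"))

  no_hdr <- read_panel(write_panel_text(c("a", "b"), c("P1", "P2"),
                                        header = FALSE))
  expect_equal(no_hdr$sample, c("a", "b"))

  expect_error(read_panel(write_panel_text(c("a", "a"), c("EUR", "AFR"))),
               "duplicate", class = "psa_data_error")
  empty <- tempfile(); writeLines(character(), empty)
  expect_error(read_panel(empty), "empty", class = "psa_data_error")
})

test_that("biallelic SNV reading counts genotypes per population", {
  fx <- toy_vcf()
  panel <- read_panel(fx$panel)
  expect_message(snps <- read_biallelic_snps(fx$vcf, panel, c("EUR", "AFR")),
                 "skipped 1")
  expect_equal(snps$snp_id, c("s1", "s2", "s4"))   # indel s3 gone

  # s1 EUR: 0/0, 0/1, 1/1 -> n=3, alt=3, het=1
  expect_equal(snps$n_called_EUR[1], 3L)
  expect_equal(snps$alt_count_EUR[1], 3L)
  expect_equal(snps$het_count_EUR[1], 1L)
  # s2 EUR: ./. missing, 0|1 phased counts, 1/1 -> n=2, alt=3, het=1
  expect_equal(snps$n_called_EUR[2], 2L)
  expect_equal(snps$alt_count_EUR[2], 3L)
  expect_equal(snps$het_count_EUR[2], 1L)
  # s2 AFR: half-call 0/. missing -> n=2, alt=0
  expect_equal(snps$n_called_AFR[2], 2L)
  expect_equal(snps$alt_count_AFR[2], 0L)

  # ref + alt allele conservation at every site and population
  for (p in c("EUR", "AFR")) {
    alt <- snps[[paste0("alt_count_", p)]]
    expect_true(all(alt >= 0 & alt <= 2 * snps[[paste0("n_called_", p)]]))
  }

  expect_error(
    suppressMessages(read_biallelic_snps(fx$vcf, panel, c("EUR", "YRI"))),
    "YRI", class = "psa_validation_error")
})

test_that("VCF samples missing from the panel are excluded with a warning", {
  fx <- toy_vcf()
  panel <- read_panel(fx$panel)
  panel <- panel[panel$sample != "E3", ]
  expect_warning(
    snps <- suppressMessages(read_biallelic_snps(fx$vcf, panel, c("EUR", "AFR"))),
    "E3")
  expect_equal(snps$n_called_EUR[1], 2L)   # E3's 1/1 no longer counted
  expect_equal(snps$alt_count_EUR[1], 1L)
})

test_that("allele frequencies and MAF behave as defined", {
  fx <- toy_vcf()
  snps <- suppressMessages(
    read_biallelic_snps(fx$vcf, read_panel(fx$panel), c("EUR", "AFR")))
  expect_equal(allele_frequency(snps, "EUR")[1], 0.5)       # 3 / (2*3)
  expect_equal(allele_frequency(snps, "AFR")[2], 0)
  expect_equal(allele_frequency(snps, "AFR", minor = TRUE)[2], 0)
  expect_equal(allele_frequency(snps, "EUR")[3], 0.5)

  zero <- snps; zero$n_called_EUR[1] <- 0L
  expect_error(allele_frequency(zero, "EUR"), "undefined",
               class = "psa_data_error")
})

test_that("per-population counts match a naive per-sample recount", {
  set.seed(41)
  for (rep in 1:3) {
    n_sites <- 15; n_samp <- 8
    doses <- matrix(sample(c(0:2, NA), n_sites * n_samp, replace = TRUE,
                           prob = c(.4, .3, .2, .1)), n_sites)
    gt <- matrix(c("0/0", "0/1", "1/1")[doses + 1], n_sites)
    gt[is.na(gt)] <- "./."
    sites <- data.frame(chrom = "1", pos = seq_len(n_sites) * 10,
                        id = paste0("v", seq_len(n_sites)),
                        ref = "A", alt = "C")
    samples <- sprintf("S%02d", seq_len(n_samp))
    pops <- rep(c("P1", "P2"), each = n_samp / 2)
    snps <- read_biallelic_snps(write_vcf_text(sites, gt, samples),
                                read_panel(write_panel_text(samples, pops)),
                                c("P1", "P2"))
    for (p in c("P1", "P2")) {
      cols <- which(pops == p)
      expect_equal(snps[[paste0("n_called_", p)]],
                   rowSums(!is.na(doses[, cols])))
      expect_equal(snps[[paste0("alt_count_", p)]],
                   rowSums(doses[, cols], na.rm = TRUE))
      expect_equal(snps[[paste0("het_count_", p)]],
                   rowSums(doses[, cols] == 1, na.rm = TRUE))
    }
  }
})

test_that("frequency filter keeps either-population MAF >= threshold, inclusively", {
  # counts over 2*20 = 40 alleles per population: MAF granularity 0.025
  specs <- list(s1 = c(0, 0), s2 = c(1, 0), s3 = c(1, 1), s4 = c(2, 0),
                s5 = c(0, 2), s6 = c(2, 2), s7 = c(1, 2), s8 = c(39, 40),
                s9 = c(38, 1), s10 = c(20, 20))
  n <- 20L
  gt <- t(vapply(specs, function(cts)
    c(gt_for_count(cts[1], n), gt_for_count(cts[2], n)),
    character(2 * n)))
  sites <- data.frame(chrom = "1", pos = seq_along(specs) * 100,
                      id = names(specs), ref = "A", alt = "G")
  samples <- c(sprintf("E%02d", 1:n), sprintf("A%02d", 1:n))
  vcf <- write_vcf_text(sites, gt, samples)
  panel <- read_panel(write_panel_text(samples, rep(c("EUR", "AFR"), each = n)))
  snps <- read_biallelic_snps(vcf, panel, c("EUR", "AFR"))

  kept <- frequency_filter(snps, c("EUR", "AFR"), 0.05)
  # s4 and s5: boundary MAF exactly 0.05 in exactly one population
  expect_setequal(kept$snp_id, c("s4", "s5", "s6", "s7", "s9", "s10"))

  # monotone: raising the threshold never adds SNPs
  prev <- kept$snp_id
  for (thr in c(0.1, 0.25, 0.5)) {
    cur <- frequency_filter(snps, c("EUR", "AFR"), thr)$snp_id
    expect_true(all(cur %in% prev))
    prev <- cur
  }

  # segregation check in a single population at 1%
  seg <- frequency_filter(snps, "AFR", 0.01, mode = "freq_in_pop")
  expect_setequal(seg$snp_id, c("s3", "s5", "s6", "s7", "s9", "s10"))
  expect_error(frequency_filter(snps, character(), 0.05),
               class = "psa_validation_error")
  expect_error(frequency_filter(snps, c("EUR", "AFR"), 0.6),
               class = "psa_validation_error")
})

test_that("color-channel switching is every pair except A/T and C/G", {
  expect_false(is_color_switching("A", "T"))
  expect_false(is_color_switching("T", "A"))
  expect_false(is_color_switching("C", "G"))
  expect_true(all(is_color_switching(c("A", "A", "C", "G"),
                                     c("C", "G", "T", "T"))))
  expect_error(is_color_switching("A", "N"), "non-ACGT",
               class = "psa_data_error")
})

test_that("SNP tables round-trip through TSV", {
  fx <- toy_vcf()
  snps <- suppressMessages(
    read_biallelic_snps(fx$vcf, read_panel(fx$panel), c("EUR", "AFR")))
  f <- tempfile(fileext = ".tsv")
  write_snps_tsv(snps, f)
  back <- read_snps_tsv(f)
  expect_equal(back$snp_id, snps$snp_id)
  expect_equal(back$alt_count_AFR, snps$alt_count_AFR)
  expect_equal(attr(back, "populations"), c("EUR", "AFR"))
})
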