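# independent closed-form Welch transcription
welch_oracle <- function(a, b, conf = 0.95) {
  va <- var(a) / length(a); vb <- var(b) / length(b)
  se <- sqrt(va + vb)
  t <- (mean(a) - mean(b)) / se
  df <- (va + vb)^2 / (va^2 / (length(a) - 1) + vb^2 / (length(b) - 1))
  p <- 2 * pt(-abs(t), df)
  ci <- (mean(a) - mean(b)) + c(-1, 1) * qt(1 - (1 - conf) / 2, df) * se
  list(t = t, df = df, p = p, ci = ci)
}

test_that("Welch comparison matches the closed form and is translation invariant", {
  w <- welch_test(c(1, 2, 3), c(4, 5, 6))
  expect_equal(w$mean_diff, -3)
  expect_equal(w$t, -3.67423461417477, tolerance = 1e-10)
  expect_equal(w$p_value, 0.0213116411287567, tolerance = 1e-10)

  set.seed(81)
  for (rep in 1:30) {
    a <- rnorm(sample(3:40, 1), sd = runif(1, 0.5, 3))
    b <- rnorm(sample(3:40, 1), mean = runif(1, -2, 2))
    w <- welch_test(a, b)
    o <- welch_oracle(a, b)
    expect_equal(w$t, o$t, tolerance = 1e-10)
    expect_equal(w$df, o$df, tolerance = 1e-10)
    expect_equal(w$p_value, o$p, tolerance = 1e-10)
    expect_equal(w$conf_int, o$ci, tolerance = 1e-10)
    expect_true(w$conf_int[1] <= w$mean_diff && w$mean_diff <= w$conf_int[2])

    ws <- welch_test(a + 7.5, b + 7.5)
    expect_equal(ws$t, w$t)
    expect_equal(ws$p_value, w$p_value)
    expect_equal(diff(ws$conf_int), diff(w$conf_int))
  }

  ident <- welch_test(c(1, 2, 3), c(1, 2, 3))
  expect_equal(ident$mean_diff, 0)
  expect_equal(ident$p_value, 1)

  expect_error(welch_test(c(1), c(1, 2)), "'a'", class = "psa_validation_error")
  expect_error(welch_test(c(1, 2), c(3, 3)), "'b'", class = "psa_validation_error")
})

test_that("effect sizes are compared as magnitudes between probe-SNP groups", {
  audits <- data.frame(cpg_id = paste0("cg", 1:4),
                       has_probe_snp = c(TRUE, TRUE, FALSE, FALSE))
  meqtl <- data.frame(cpg_id = paste0("cg", c(1, 2, 3, 4, 4)),
                      snp_id = paste0("m", 1:5),
                      beta = c(-2, -2.5, 1, 0.8, -1.2))
  res <- compare_effect_sizes(meqtl, audits, use = "beta")
  expect_equal(unname(res$group_means["with_snp"]), 2.25)
  expect_equal(unname(res$group_means["without_snp"]), 1)
  expect_equal(res$n_with_snp, 2L)
  expect_equal(res$n_without_snp, 3L)

  # delta mode: records lacking ancestry-specific effects are dropped + counted
  meqtl$beta_eur <- c(1, 2, 0.5, 0.6, 1)
  meqtl$beta_afr <- c(0.2, 0.5, 0.1, 0.3, NA)
  meqtl$delta <- abs(meqtl$beta_eur - meqtl$beta_afr)
  resd <- compare_effect_sizes(meqtl, audits, use = "delta")
  expect_equal(resd$n_excluded, 1L)
  expect_equal(resd$n_with_snp, 2L)
  expect_equal(resd$n_without_snp, 2L)
  expect_equal(unname(resd$group_means["with_snp"]), mean(c(0.8, 1.5)))

  one_group <- audits; one_group$has_probe_snp <- TRUE
  expect_error(compare_effect_sizes(meqtl, one_group),
               class = "psa_validation_error")
})

test_that("polynomial fits recover exact relationships and order RSS by degree", {
  x <- 0:10
  fits <- fit_polynomials(x, x^3)
  expect_equal(fits[[3]]$r_squared, 1, tolerance = 1e-12)
  expect_lt(fits[[3]]$rss, 1e-12)
  expect_equal(fits[[3]]$coefficients, c(0, 0, 0, 1), tolerance = 1e-8)

  lin <- fit_polynomials(0:5, 2 + 3 * (0:5))
  expect_equal(lin[[1]]$coefficients, c(2, 3), tolerance = 1e-10)

  const <- fit_polynomials(0:10, rep(4, 11))
  expect_true(all(vapply(const, `[[`, 0, "r_squared") == 0))

  set.seed(82)
  for (rep in 1:10) {
    x <- sample(0:50, 60, replace = TRUE)
    y <- rnorm(60, 1 + 0.05 * x)
    f <- fit_polynomials(x, y)
    rss <- vapply(f, `[[`, 0, "rss")
    r2 <- vapply(f, `[[`, 0, "r_squared")
    expect_true(all(diff(rss) <= 1e-10))       # RSS non-increasing in degree
    expect_true(all(diff(r2) >= -1e-10))
    expect_true(all(r2 >= 0 & r2 <= 1))
  }

  expect_error(fit_polynomials(0:3, rnorm(4)), class = "psa_validation_error")
  expect_error(fit_polynomials(rep(c(1, 2), 10), rnorm(20)),
               class = "psa_data_error")
})

test_that("sequential F selection follows the stated statistic and stopping rule", {
  set.seed(83)
  x <- sample(0:50, 120, replace = TRUE)
  y <- 2 - 0.05 * x + 0.002 * x^2 + rnorm(120, 0, 0.3)
  fits <- fit_polynomials(x, y)
  sel <- select_degree(fits)
  # every step statistic must match R's own nested-model ANOVA
  for (k in 2:3) {
    m_prev <- lm(y ~ poly(x, k - 1, raw = TRUE))
    m_k <- lm(y ~ poly(x, k, raw = TRUE))
    an <- anova(m_prev, m_k)
    row <- sel$steps[sel$steps$degree == k, ]
    if (nrow(row) == 0) break   # selection stopped before this step
    expect_equal(row$f, an$F[2], tolerance = 1e-10)
    expect_equal(row$p_value, an$`Pr(>F)`[2], tolerance = 1e-10)
  }

  # equal RSS at consecutive degrees: F = 0, step rejected
  fits_eq <- list(list(degree = 1, rss = 5, r_squared = .5, n = 30,
                       coefficients = c(0, 1)),
                  list(degree = 2, rss = 5, r_squared = .5, n = 30,
                       coefficients = c(0, 1, 0)))
  sel_eq <- select_degree(fits_eq)
  expect_equal(sel_eq$chosen_degree, 1L)
  expect_equal(sel_eq$steps$f[1], 0)

  # a perfect higher-degree fit: infinite F, p = 0
  xx <- 0:9
  sel_perf <- select_degree(fit_polynomials(xx, xx^2))
  expect_equal(sel_perf$chosen_degree, 2L)
  expect_equal(sel_perf$steps$p_value[sel_perf$steps$degree == 2], 0)

  expect_error(select_degree(fits_eq[2]), class = "psa_validation_error")
})

test_that("CpG classification fractions count probe-SNP carriage", {
  audits <- data.frame(cpg_id = paste0("cg", 1:8),
                       has_probe_snp = c(TRUE, TRUE, FALSE, FALSE,
                                         TRUE, FALSE, FALSE, FALSE))
  res <- classify_cpgs(paste0("cg", 1:4), audits)
  expect_equal(res$meqtl_fraction, 0.5)
  expect_equal(res$non_meqtl_fraction, 0.25)
  expect_equal(res$n_meqtl, 4L)

  none <- audits; none$has_probe_snp <- FALSE
  res0 <- classify_cpgs(paste0("cg", 1:4), none)
  expect_equal(res0$meqtl_fraction, 0)
  expect_equal(res0$non_meqtl_fraction, 0)

  expect_error(classify_cpgs(paste0("cg", 1:8), audits),
               class = "psa_data_error")
  expect_error(classify_cpgs("cgX", audits), "cgX", class = "psa_data_error")
})

test_that("disruption accounting counts CpG-site SNPs above the Fst threshold", {
  audits <- data.frame(cpg_id = paste0("cg", 1:4),
                       has_probe_snp = c(TRUE, TRUE, TRUE, FALSE))
  hits <- data.frame(
    cpg_id = c("cg1", "cg2", "cg3"),
    snp_id = c("s1", "s2", "s3"),
    probe_index = c(0L, 1L, 2L),
    distance = c(0L, 1L, 2L),
    disrupts_cpg = c(TRUE, TRUE, FALSE)
  )
  fst <- data.frame(snp_id = c("s1", "s2", "s3"), theta = c(0.2, 0.09, 0.9))
  meqtl <- data.frame(cpg_id = paste0("cg", c(1, 1, 2, 3, 4)),
                      snp_id = paste0("m", 1:5), beta = 1)
  imp <- disruption_impact(meqtl, audits, hits, fst)
  # only cg1 counts: s2 is under-threshold, s3 not on the CpG dinucleotide
  expect_equal(imp$n_cpgs_disrupted_differentiated, 1L)
  expect_equal(imp$cpg_fraction, 0.25)
  expect_equal(imp$n_assoc_impacted, 2L)
  expect_equal(imp$assoc_fraction, 0.4)
  expect_equal(imp$median_fst_implicated, 0.2)

  # duplicate-free and order-invariant
  imp2 <- disruption_impact(meqtl[sample(5), ], audits,
                            hits[sample(3), ], fst[sample(3), ])
  expect_equal(imp2, imp)

  expect_error(disruption_impact(meqtl, audits, hits, fst[-1, ]), "s1",
               class = "psa_data_error")
})

test_that("regression points take one representative distance per CpG", {
  audits <- data.frame(cpg_id = c("cg1", "cg2", "cg3"),
                       has_probe_snp = c(TRUE, TRUE, FALSE),
                       rep_distance = c(5L, 0L, NA))
  meqtl <- data.frame(cpg_id = c("cg1", "cg1", "cg2", "cg3"),
                      snp_id = paste0("m", 1:4),
                      beta = c(2, -4, 1.5, 9))
  pts <- regression_points(meqtl, audits, use = "beta")
  pts <- pts[order(pts$cpg_id), ]
  expect_equal(pts$cpg_id, c("cg1", "cg2"))   # cg3 has no probe SNP
  expect_equal(pts$distance, c(5L, 0L))
  expect_equal(pts$value, c(3, 1.5))          # mean |beta| per CpG
})

test_that("report assembly flags incomplete runs and is deterministic", {
  set.seed(84)
  cfg <- sim_config(n_probes = 80, n_background_snps = 20,
                    n_per_pop = c(EUR = 25, AFR = 25))
  man <- simulate_manifest(cfg)
  regions <- compute_probe_regions(man$probes)
  sim <- simulate_population_snps(cfg, regions, man$truth_cpgs)
  vcf <- tempfile(fileext = ".vcf"); write_sim_vcf(sim$sites, sim$genotypes, vcf)
  panel <- sim$panel
  snps <- read_biallelic_snps(vcf, panel, c("EUR", "AFR"))
  snps <- frequency_filter(snps, c("EUR", "AFR"), 0.05)
  fst <- snp_fst(snps, "EUR", "AFR")
  hits <- apply_sbe_rule(find_probe_snps(regions, snps))
  audits <- audit_cpgs(regions, hits, fst = fst)
  meqtl <- simulate_meqtl_table(cfg, sim$truth_cpgs)

  rep1 <- build_report(audits, hits, fst, meqtl)
  rep2 <- build_report(audits, hits, fst, meqtl)
  rep1$timestamp <- rep2$timestamp <- NULL
  expect_equal(rep1, rep2)

  # no meQTL table: bias sections are explicit nulls, report incomplete
  rep0 <- build_report(audits, hits, fst, NULL)
  expect_false(rep0$complete)
  expect_null(rep0$enrichment)
  expect_null(rep0$regression_beta)
  f <- tempfile(fileext = ".json")
  write_report(rep0, f)
  js <- jsonlite::read_json(f)
  expect_true("enrichment" %in% names(js))
  expect_null(js$enrichment)
})
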