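#' Read a meQTL association table
#'
#' Tab-separated with header; required columns `cpg_id`, `snp_id`, `beta`
#' (the association's effect size in methylation units per allele), optional
#' `beta_eur` and `beta_afr` for ancestry-specific fits. When both
#' ancestry-specific effects are present the table gains
#' `delta = |beta_eur - beta_afr|`, the effect-size heterogeneity between
#' European and African local-ancestry backgrounds.
#'
#' @param path TSV path.
#' @return Data.frame of meQTL records.
#' @export
read_meqtl <- function(path) {
  if (!file.exists(path)) validation_error(sprintf("meQTL table not found: %s", path))
  m <- utils::read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE)
  need <- c("cpg_id", "snp_id", "beta")
  if (!all(need %in% names(m)))
    data_error(paste("meQTL table lacks column(s):",
                     paste(setdiff(need, names(m)), collapse = ", ")))
  if (all(c("beta_eur", "beta_afr") %in% names(m)))
    m$delta <- abs(m$beta_eur - m$beta_afr)
  m
}

#' Probe-SNP enrichment among meQTL CpGs
#'
#' Fraction of CpGs carrying at least one retained probe SNP, separately for
#' the meQTL-associated CpGs and for all remaining audited CpGs.
#'
#' @param meqtl_cpg_ids Character vector of CpG ids with a meQTL association.
#' @param audits Audit table from [audit_cpgs()].
#' @return List with `meqtl_fraction`, `non_meqtl_fraction` and the four
#'   underlying counts.
#' @export
classify_cpgs <- function(meqtl_cpg_ids, audits) {
  meqtl_cpg_ids <- unique(meqtl_cpg_ids)
  unknown <- setdiff(meqtl_cpg_ids, audits$cpg_id)
  if (length(unknown))
    data_error(paste("meQTL CpG id(s) not audited:",
                     paste(utils::head(unknown, 10), collapse = ", ")))
  is_meqtl <- audits$cpg_id %in% meqtl_cpg_ids
  if (all(is_meqtl))
    data_error("every audited CpG is meQTL-associated; non-meQTL fraction undefined")
  list(
    meqtl_fraction = mean(audits$has_probe_snp[is_meqtl]),
    non_meqtl_fraction = mean(audits$has_probe_snp[!is_meqtl]),
    n_meqtl = sum(is_meqtl),
    n_meqtl_with_snp = sum(audits$has_probe_snp[is_meqtl]),
    n_non_meqtl = sum(!is_meqtl),
    n_non_meqtl_with_snp = sum(audits$has_probe_snp[!is_meqtl])
  )
}

#' Welch two-sample comparison
#'
#' Two-sided unequal-variance t-test with a Welch-Satterthwaite confidence
#' interval for the difference in means (group a minus group b).
#'
#' @param a,b Numeric vectors, each with at least two values and nonzero
#'   variance.
#' @param conf_level Confidence level for the interval, default 0.95.
#' @return List: `mean_diff`, `t`, `df`, `p_value`, `conf_int` (length-2),
#'   `n_a`, `n_b`.
#' @export
welch_test <- function(a, b, conf_level = 0.95) {
  check <- function(x, nm) {
    x <- x[!is.na(x)]
    if (length(x) < 2) validation_error(sprintf("group '%s' has fewer than 2 values", nm))
    if (stats::var(x) == 0) validation_error(sprintf("group '%s' has zero variance", nm))
    x
  }
  a <- check(a, "a"); b <- check(b, "b")
  tt <- stats::t.test(a, b, var.equal = FALSE, conf.level = conf_level)
  list(mean_diff = unname(tt$estimate[1] - tt$estimate[2]),
       t = unname(tt$statistic), df = unname(tt$parameter),
       p_value = tt$p.value, conf_int = as.numeric(tt$conf.int),
       n_a = length(a), n_b = length(b))
}

#' Compare meQTL effect sizes between CpGs with and without probe SNPs
#'
#' Partitions meQTL records by whether their CpG carries a retained probe
#' SNP and Welch-compares effect-size magnitudes `|beta|` (or the
#' ancestry-specific heterogeneity `delta`) between the two groups. In
#' `delta` mode, records without both ancestry-specific effects are dropped
#' and their number reported.
#'
#' @param meqtl meQTL records from [read_meqtl()].
#' @param audits Audit table from [audit_cpgs()].
#' @param use `"beta"` (magnitudes) or `"delta"`.
#' @return List: the [welch_test()] result plus `group_means`
#'   (with / without probe SNP), group sizes and `n_excluded`.
#' @export
compare_effect_sizes <- function(meqtl, audits, use = c("beta", "delta")) {
  use <- match.arg(use)
  has_snp <- audits$has_probe_snp[match(meqtl$cpg_id, audits$cpg_id)]
  if (any(is.na(has_snp)))
    data_error(paste("meQTL CpG id(s) not audited:",
                     paste(utils::head(unique(meqtl$cpg_id[is.na(has_snp)]), 10),
                           collapse = ", ")))
  n_excluded <- 0L
  if (use == "beta") {
    val <- abs(meqtl$beta)
  } else {
    if (is.null(meqtl$delta)) meqtl$delta <- rep(NA_real_, nrow(meqtl))
    keep <- !is.na(meqtl$delta)
    n_excluded <- sum(!keep)
    val <- meqtl$delta[keep]
    has_snp <- has_snp[keep]
  }
  if (!any(has_snp) || all(has_snp))
    validation_error("effect-size comparison needs records in both groups (with and without probe SNPs)")
  wt <- welch_test(val[has_snp], val[!has_snp])
  c(wt, list(group_means = c(with_snp = mean(val[has_snp]),
                             without_snp = mean(val[!has_snp])),
             n_with_snp = sum(has_snp), n_without_snp = sum(!has_snp),
             n_excluded = n_excluded, measure = use))
}

#' Polynomial regressions of effect magnitude on probe-SNP distance
#'
#' Ordinary least squares with intercept for every degree 1..`max_degree`
#' (raw polynomial basis). `R^2 = 1 - RSS/TSS`.
#'
#' @param x Distances (base pairs between probe SNP and targeted cytosine).
#' @param y Effect-size magnitudes.
#' @param max_degree Highest polynomial degree, default 3.
#' @return List of fits; each has `degree`, `coefficients` (intercept
#'   first), `rss`, `r_squared`, `n`.
#' @export
fit_polynomials <- function(x, y, max_degree = 3) {
  ok <- !is.na(x) & !is.na(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n <= max_degree + 1)
    validation_error(sprintf("need more than %d observations for degree %d",
                             max_degree + 1, max_degree))
  if (length(unique(x)) < max_degree + 1)
    data_error("x too degenerate for the requested polynomial degrees")
  tss <- sum((y - mean(y))^2)
  lapply(seq_len(max_degree), function(k) {
    fit <- stats::lm(y ~ stats::poly(x, k, raw = TRUE))
    if (anyNA(stats::coef(fit)))
      data_error(sprintf("rank-deficient design at degree %d", k))
    rss <- sum(stats::residuals(fit)^2)
    list(degree = k, coefficients = unname(stats::coef(fit)),
         rss = rss, r_squared = if (tss > 0) 1 - rss / tss else 0, n = n)
  })
}

#' Sequential F-test polynomial degree selection
#'
#' Starting from the linear model, each higher degree `k` is tested against
#' degree `k - 1` with the nested-model F statistic
#' `F = ((RSS_{k-1} - RSS_k)/1) / (RSS_k/(n - k - 1))`; the chosen degree is
#' the last one accepted before the first non-significant step. A perfect
#' higher-degree fit (`RSS_k = 0`) gives an infinite F and p = 0.
#'
#' @param fits Fits for consecutive degrees 1..K from [fit_polynomials()]
#'   on the same data.
#' @param alpha Per-step significance level, default 0.05.
#' @return List: `chosen_degree`, `alpha`, and `steps` — a data.frame with
#'   one row per tested step (`degree`, `f`, `df1`, `df2`, `p_value`).
#' @export
select_degree <- function(fits, alpha = 0.05) {
  degs <- vapply(fits, `[[`, 0, "degree")
  if (!identical(degs, as.numeric(seq_along(fits))))
    validation_error("fits must cover consecutive degrees starting at 1")
  ns <- unique(vapply(fits, `[[`, 0, "n"))
  if (length(ns) != 1) validation_error("fits come from different data (n differs)")
  n <- ns
  K <- length(fits)
  steps <- data.frame(degree = integer(), f = numeric(), df1 = integer(),
                      df2 = integer(), p_value = numeric())
  chosen <- 1L
  if (K >= 2) {
    for (k in 2:K) {
      rss_prev <- fits[[k - 1]]$rss
      rss_k <- fits[[k]]$rss
      df2 <- n - k - 1
      if (rss_k == 0) {
        f <- Inf; p <- 0
      } else {
        f <- ((rss_prev - rss_k) / 1) / (rss_k / df2)
        p <- stats::pf(f, 1, df2, lower.tail = FALSE)
      }
      steps <- rbind(steps, data.frame(degree = k, f = f, df1 = 1L,
                                       df2 = as.integer(df2), p_value = p))
      if (p < alpha) chosen <- k else break
    }
  }
  list(chosen_degree = chosen, alpha = alpha, steps = steps)
}

#' CpG-disruption impact accounting
#'
#' A meQTL-associated CpG is counted as disrupted when one of its retained
#' probe SNPs falls on the CpG dinucleotide itself (probe index 0 or 1) and
#' is strongly differentiated (theta >= `fst_min`): for such CpGs an
#' unmethylated readout can be a genotype artifact. The summary reports the
#' disrupted fraction of meQTL CpGs, the fraction of meQTL associations
#' whose CpG is disrupted, and the median theta of the implicated probe
#' SNPs.
#'
#' @param meqtl meQTL records from [read_meqtl()].
#' @param audits Audit table from [audit_cpgs()] (defines the audited set).
#' @param hits Retained hits from [apply_sbe_rule()].
#' @param fst Fst table from [snp_fst()].
#' @param fst_min Minimum theta for "strongly differentiated", default 0.1.
#' @return List: `n_cpgs_total`, `n_cpgs_disrupted_differentiated`,
#'   `cpg_fraction`, `n_assoc_total`, `n_assoc_impacted`, `assoc_fraction`,
#'   `median_fst_implicated`.
#' @export
disruption_impact <- function(meqtl, audits, hits, fst, fst_min = 0.1) {
  cpgs <- unique(meqtl$cpg_id)
  unknown <- setdiff(cpgs, audits$cpg_id)
  if (length(unknown))
    data_error(paste("meQTL CpG id(s) not audited:",
                     paste(utils::head(unknown, 10), collapse = ", ")))
  rel <- hits[hits$cpg_id %in% cpgs & hits$disrupts_cpg, , drop = FALSE]
  theta <- fst$theta[match(rel$snp_id, fst$snp_id)]
  missing_fst <- unique(rel$snp_id[!rel$snp_id %in% fst$snp_id])
  if (length(missing_fst))
    data_error(paste("no Fst for probe SNP(s):", paste(missing_fst, collapse = ", ")))
  strong <- !is.na(theta) & theta >= fst_min
  disrupted_cpgs <- unique(rel$cpg_id[strong])
  impl_theta <- theta[strong]
  n_assoc <- nrow(meqtl)
  list(
    n_cpgs_total = length(cpgs),
    n_cpgs_disrupted_differentiated = length(disrupted_cpgs),
    cpg_fraction = length(disrupted_cpgs) / length(cpgs),
    n_assoc_total = n_assoc,
    n_assoc_impacted = sum(meqtl$cpg_id %in% disrupted_cpgs),
    assoc_fraction = sum(meqtl$cpg_id %in% disrupted_cpgs) / n_assoc,
    median_fst_implicated = if (length(impl_theta)) stats::median(impl_theta) else NA_real_
  )
}

#' One distance / one effect magnitude per CpG for the regressions
#'
#' Each CpG with a retained probe SNP contributes one point: x is the
#' representative (nearest retained) hit distance, y the mean effect
#' magnitude (`|beta|`, or mean `delta`) over that CpG's associations.
#'
#' @param meqtl meQTL records.
#' @param audits Audit table.
#' @param use `"beta"` or `"delta"`.
#' @return Data.frame `cpg_id`, `distance`, `value`.
#' @export
regression_points <- function(meqtl, audits, use = c("beta", "delta")) {
  use <- match.arg(use)
  if (use == "delta") {
    if (is.null(meqtl$delta)) return(data.frame(cpg_id = character(),
                                                distance = integer(),
                                                value = numeric()))
    meqtl <- meqtl[!is.na(meqtl$delta), , drop = FALSE]
    val <- meqtl$delta
  } else {
    val <- abs(meqtl$beta)
  }
  aud <- audits[audits$has_probe_snp, , drop = FALSE]
  keep <- meqtl$cpg_id %in% aud$cpg_id
  meqtl <- meqtl[keep, , drop = FALSE]; val <- val[keep]
  if (!nrow(meqtl)) return(data.frame(cpg_id = character(),
                                      distance = integer(), value = numeric()))
  agg <- stats::aggregate(val, by = list(cpg_id = meqtl$cpg_id), FUN = mean)
  data.frame(cpg_id = agg$cpg_id,
             distance = aud$rep_distance[match(agg$cpg_id, aud$cpg_id)],
             value = agg$x, stringsAsFactors = FALSE)
}

#' Assemble the bias-diagnostic report
#'
#' Collects the enrichment, Fst comparison, effect-size comparisons,
#' distance regressions and disruption accounting into one JSON-ready
#' report. Sections whose inputs are unavailable are explicit `NULL`s and
#' the report is flagged incomplete.
#'
#' @param audits Audit table from [audit_cpgs()].
#' @param hits Retained hits from [apply_sbe_rule()].
#' @param fst Fst table from [snp_fst()].
#' @param meqtl meQTL records from [read_meqtl()], or `NULL`.
#' @param alpha Significance level for degree selection.
#' @param fst_min Differentiation threshold for disruption accounting.
#' @param max_degree Highest regression degree.
#' @param provenance Named list recorded verbatim (inputs, seed, thresholds).
#' @return A `bias_report` list; `$complete` says whether every section was
#'   computable.
#' @export
build_report <- function(audits, hits, fst, meqtl = NULL, alpha = 0.05,
                         fst_min = 0.1, max_degree = 3, provenance = list()) {
  report <- list(
    tool = "probesnpaudit",
    version = as.character(utils::packageVersion("probesnpaudit")),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    provenance = c(provenance, list(alpha = alpha, fst_min = fst_min,
                                    max_degree = max_degree)),
    n_cpgs_audited = nrow(audits),
    n_probe_snp_hits = nrow(hits),
    enrichment = NULL, fst_comparison = NULL,
    effect_size_beta = NULL, effect_size_delta = NULL,
    regression_beta = NULL, regression_delta = NULL,
    impact_naive = NULL, impact_aware = NULL,
    complete = FALSE
  )
  if (is.null(meqtl) || !nrow(meqtl)) return(report)

  meqtl_cpgs <- unique(meqtl$cpg_id)
  report$enrichment <- classify_cpgs(meqtl_cpgs, audits)

  # Fst contrast: probe SNPs of meQTL CpGs vs probe SNPs of other CpGs,
  # one value per distinct SNP within each group
  th <- fst$theta[match(hits$snp_id, fst$snp_id)]
  grp <- hits$cpg_id %in% meqtl_cpgs
  t_me <- th[grp][!duplicated(hits$snp_id[grp])]
  t_non <- th[!grp][!duplicated(hits$snp_id[!grp])]
  t_me <- t_me[!is.na(t_me)]; t_non <- t_non[!is.na(t_non)]
  if (length(t_me) >= 2 && length(t_non) >= 2) {
    report$fst_comparison <- c(
      welch_test(t_me, t_non),
      list(median_meqtl = stats::median(t_me),
           median_non_meqtl = stats::median(t_non))
    )
  }

  report$effect_size_beta <- tryCatch(
    compare_effect_sizes(meqtl, audits, use = "beta"),
    psa_error = function(e) NULL)
  report$impact_naive <- disruption_impact(meqtl, audits, hits, fst, fst_min)

  pts <- regression_points(meqtl, audits, use = "beta")
  if (nrow(pts) > max_degree + 1) {
    fits <- fit_polynomials(pts$distance, pts$value, max_degree)
    report$regression_beta <- list(
      n = nrow(pts),
      fits = lapply(fits, function(f) f[c("degree", "coefficients", "rss", "r_squared")]),
      selection = select_degree(fits, alpha)
    )
  }

  la_aware <- !is.null(meqtl$delta) && any(!is.na(meqtl$delta))
  if (la_aware) {
    report$effect_size_delta <- tryCatch(
      compare_effect_sizes(meqtl, audits, use = "delta"),
      psa_error = function(e) NULL)
    aware <- meqtl[!is.na(meqtl$delta), , drop = FALSE]
    report$impact_aware <- disruption_impact(aware, audits, hits, fst, fst_min)
    ptsd <- regression_points(meqtl, audits, use = "delta")
    if (nrow(ptsd) > max_degree + 1) {
      fitsd <- fit_polynomials(ptsd$distance, ptsd$value, max_degree)
      report$regression_delta <- list(
        n = nrow(ptsd),
        fits = lapply(fitsd, function(f) f[c("degree", "coefficients", "rss", "r_squared")]),
        selection = select_degree(fitsd, alpha)
      )
    }
  }
  core <- c("enrichment", "fst_comparison", "effect_size_beta",
            "regression_beta", "impact_naive")
  report$complete <- !any(vapply(report[core], is.null, TRUE))
  class(report) <- c("bias_report", "list")
  report
}

#' Write a bias report as JSON
#' @param report A `bias_report` from [build_report()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_report <- function(report, path) {
  jsonlite::write_json(unclass(report), path, auto_unbox = TRUE, digits = NA,
                       null = "null", pretty = TRUE, force = TRUE)
  invisible(path)
}
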