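#' Build and validate an audit run configuration
#'
#' Collects every input path and threshold for [run_audit()]. Paths are
#' checked up front so a misconfigured run fails before any work starts.
#' A YAML config file can supply any of these fields; arguments given here
#' override the file.
#'
#' @param manifest Probe manifest CSV.
#' @param vcf Variant VCF (plain or gzipped).
#' @param panel Sample-to-population panel file.
#' @param meqtl meQTL association TSV, or `NULL` to stop after the Fst
#'   stage (the report then carries explicit null bias sections).
#' @param out_dir Directory for intermediate files and the report.
#' @param populations Two population labels, differentiation is computed
#'   between the first and second.
#' @param maf MAF retention threshold (either-population semantics).
#' @param fst_min Differentiation threshold for disruption accounting.
#' @param alpha Significance level for regression degree selection.
#' @param max_degree Highest regression degree.
#' @param strip_chr Normalize `chr` prefixes on both manifest and VCF.
#' @param type1_window Type I window convention, see
#'   [compute_probe_regions()].
#' @param seed Optional seed recorded in provenance (the audit itself is
#'   deterministic).
#' @param config_file Optional YAML file with any of the above fields.
#' @return A validated `audit_config` list.
#' @export
audit_config <- function(manifest = NULL, vcf = NULL, panel = NULL,
                         meqtl = NULL, out_dir = NULL,
                         populations = c("EUR", "AFR"), maf = 0.05,
                         fst_min = 0.1, alpha = 0.05, max_degree = 3,
                         strip_chr = FALSE, type1_window = "sbe_minus1",
                         seed = NULL, config_file = NULL) {
  cfg <- list(manifest = manifest, vcf = vcf, panel = panel, meqtl = meqtl,
              out_dir = out_dir, populations = populations, maf = maf,
              fst_min = fst_min, alpha = alpha, max_degree = max_degree,
              strip_chr = strip_chr, type1_window = type1_window, seed = seed)
  if (!is.null(config_file)) {
    if (!file.exists(config_file))
      validation_error(sprintf("config file not found: %s", config_file))
    file_cfg <- yaml::read_yaml(config_file)
    for (k in names(file_cfg)) if (is.null(cfg[[k]])) cfg[[k]] <- file_cfg[[k]]
  }
  for (k in c("manifest", "vcf", "panel", "out_dir"))
    if (is.null(cfg[[k]]))
      validation_error(sprintf("audit config lacks required field '%s'", k))
  for (k in c("manifest", "vcf", "panel"))
    if (!file.exists(cfg[[k]]))
      validation_error(sprintf("%s file not found: %s", k, cfg[[k]]))
  if (!is.null(cfg$meqtl) && !file.exists(cfg$meqtl))
    validation_error(sprintf("meqtl file not found: %s", cfg$meqtl))
  if (length(cfg$populations) != 2)
    validation_error("exactly two populations are required")
  if (cfg$maf <= 0 || cfg$maf > 0.5)
    validation_error("maf threshold must lie in (0, 0.5]")
  if (cfg$fst_min < 0 || cfg$fst_min > 1)
    validation_error("fst_min must lie in [0, 1]")
  if (cfg$alpha <= 0 || cfg$alpha >= 1)
    validation_error("alpha must lie in (0, 1)")
  class(cfg) <- c("audit_config", "list")
  cfg
}

stage_msg <- function(verbose, stage, fmt, ...) {
  if (verbose) message(sprintf("[%s] %s", stage, sprintf(fmt, ...)))
}

#' Run the full probe-SNP audit
#'
#' Chains every stage: probe-region designation, SNP reading and frequency
#' filtering, region-SNP cross-referencing with the extension-position rule,
#' per-site Weir-Cockerham Fst, and the meQTL bias diagnostics. Writes
#' `regions.bed`, `snps.tsv`, `hits.tsv`, `fst.tsv`, `audits.tsv` and
#' `report.json` into the configured output directory. Stage failures carry
#' the stage name; reruns on identical inputs produce identical outputs
#' (the report differs only in its timestamp).
#'
#' @param config An [audit_config()].
#' @param verbose Log per-stage record counts and timings to stderr.
#' @return The `bias_report`, invisibly.
#' @export
run_audit <- function(config, verbose = TRUE) {
  stopifnot(inherits(config, "audit_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  stage <- function(name, expr) {
    t0 <- proc.time()[["elapsed"]]
    res <- withCallingHandlers(
      tryCatch(expr, psa_error = function(e) {
        stop(errorCondition(sprintf("stage '%s': %s", name, conditionMessage(e)),
                            class = class(e)))
      }),
      warning = function(w) {
        stage_msg(verbose, name, "warning: %s", conditionMessage(w))
        invokeRestart("muffleWarning")
      })
    stage_msg(verbose, name, "done in %.2fs", proc.time()[["elapsed"]] - t0)
    res
  }

  regions <- stage("regions", {
    probes <- read_manifest(config$manifest, strip_chr = config$strip_chr)
    r <- compute_probe_regions(probes, type1_window = config$type1_window)
    write_regions_bed(r, file.path(config$out_dir, "regions.bed"))
    stage_msg(verbose, "regions", "%d probe regions", nrow(r))
    r
  })

  snps <- stage("snps", {
    panel <- read_panel(config$panel)
    s <- read_biallelic_snps(config$vcf, panel, config$populations,
                             strip_chr = config$strip_chr)
    s <- frequency_filter(s, config$populations, config$maf, mode = "maf_any_pop")
    write_snps_tsv(s, file.path(config$out_dir, "snps.tsv"))
    stage_msg(verbose, "snps", "%d SNPs retained at MAF >= %g", nrow(s), config$maf)
    s
  })

  fst <- stage("fst", {
    f <- snp_fst(snps, config$populations[1], config$populations[2])
    write_fst_tsv(f, file.path(config$out_dir, "fst.tsv"))
    f
  })

  audit_objs <- stage("crossref", {
    hits <- apply_sbe_rule(find_probe_snps(regions, snps))
    audits <- audit_cpgs(regions, hits, fst = fst)
    write_hits_tsv(hits, file.path(config$out_dir, "hits.tsv"))
    utils::write.table(audits, file.path(config$out_dir, "audits.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    stage_msg(verbose, "crossref", "%d retained hits on %d CpGs",
              nrow(hits), sum(audits$has_probe_snp))
    list(hits = hits, audits = audits)
  })

  report <- stage("bias-report", {
    meqtl <- if (!is.null(config$meqtl)) read_meqtl(config$meqtl) else NULL
    rep <- build_report(
      audit_objs$audits, audit_objs$hits, fst, meqtl,
      alpha = config$alpha, fst_min = config$fst_min,
      max_degree = config$max_degree,
      provenance = list(manifest = config$manifest, vcf = config$vcf,
                        panel = config$panel,
                        meqtl = config$meqtl %||% NA,
                        populations = config$populations, maf = config$maf,
                        seed = config$seed %||% NA)
    )
    write_report(rep, file.path(config$out_dir, "report.json"))
    rep
  })
  if (!is.null(config$meqtl) && !isTRUE(report$complete))
    data_error("bias report incomplete: one or more sections could not be computed")
  invisible(report)
}
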