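#' Simulation configuration
#'
#' Builds the configuration for the synthetic fixture generator. The
#' defaults emulate, at desk scale, the data structure the audit expects to
#' see: a manifest mixing both targeted strands and both Infinium types;
#' two population samples whose planted probe SNPs are drawn from a
#' Balding-Nichols model with strong divergence for meQTL-CpG probes
#' (`F_differentiated = 0.35`) and weak divergence elsewhere
#' (`F_background = 0.07`), mirroring the differentiation contrast the audit
#' is designed to detect; probe-SNP carriage rates of 37.5% among meQTL
#' CpGs versus 16.1% among the rest; and meQTL effect magnitudes that decay
#' with probe-SNP distance following a cubic curve whose noise leaves the
#' distance explaining about 42% of the variance (about 25% for the
#' quadratic ancestry-heterogeneity curve). With `n_probes = 3000` and
#' `frac_meqtl = 0.31` the defaults yield roughly 350 meQTL CpGs carrying a
#' probe SNP, the sample size at which the distance regression is meant to
#' operate.
#'
#' @param n_probes Number of CpG probes in the manifest.
#' @param chrom Chromosome name used throughout.
#' @param spacing,jitter Base spacing between consecutive probe target
#'   positions and the uniform jitter added to each; the defaults guarantee
#'   non-overlapping 51-bp regions.
#' @param chrom_length Optional chromosome length; an error is raised when
#'   the requested probes cannot be spaced within it.
#' @param type_props Named proportions for Infinium types `I` and `II`.
#' @param strand_props Named proportions for targeted strands `F` and `R`.
#' @param frac_meqtl Fraction of CpGs designated meQTL-associated.
#' @param p_probe_snp_meqtl,p_probe_snp_nonmeqtl Probability that a meQTL /
#'   non-meQTL CpG's probe region receives a planted SNP.
#' @param n_background_snps SNPs planted outside any probe region.
#' @param F_differentiated,F_background Balding-Nichols divergence for
#'   planted SNPs of meQTL CpGs and for everything else; both in (0, 1).
#' @param n_per_pop Named vector of diploid sample sizes per population.
#' @param p_anc_planted,p_anc_background Ranges of the uniform ancestral
#'   allele frequency for planted and background SNPs; planted SNPs use a
#'   narrower range so they stay common after divergence, as real probe
#'   SNPs surviving a 5% MAF screen are.
#' @param maf MAF threshold the generator assumes downstream (used to mark
#'   which planted SNPs are expected to survive filtering).
#' @param beta_coefs,beta_sigma Cubic coefficients (intercept first) and
#'   noise SD of the |effect size| vs distance model.
#' @param beta_baseline_mean,beta_baseline_sd Effect-magnitude model for
#'   CpGs without probe SNPs: `|N(mean, sd)|`.
#' @param delta_coefs,delta_sigma Quadratic model for the ancestry
#'   effect-size difference vs distance.
#' @param delta_baseline_mean,delta_baseline_sd Baseline delta model.
#' @param assoc_lambda Extra associations per meQTL CpG follow
#'   `Poisson(assoc_lambda)` (every CpG gets at least one).
#' @param la_aware Emit ancestry-specific effect columns.
#' @return A validated `sim_config` list.
#' @export
sim_config <- function(n_probes = 3000,
                       chrom = "1",
                       spacing = 160, jitter = 40,
                       chrom_length = NULL,
                       type_props = c(I = 0.3, II = 0.7),
                       strand_props = c(F = 0.5, R = 0.5),
                       frac_meqtl = 0.31,
                       p_probe_snp_meqtl = 0.375,
                       p_probe_snp_nonmeqtl = 0.161,
                       n_background_snps = 300,
                       F_differentiated = 0.35,
                       F_background = 0.07,
                       n_per_pop = c(EUR = 100, AFR = 100),
                       p_anc_planted = c(0.2, 0.8),
                       p_anc_background = c(0.05, 0.95),
                       maf = 0.05,
                       beta_coefs = c(2.290833404, -0.183080367,
                                      0.005729845, -5.7328380e-05),
                       beta_sigma = 0.585891482,
                       beta_baseline_mean = 0.5, beta_baseline_sd = 0.25,
                       delta_coefs = c(1.393592564, -0.059005636,
                                       7.67293415e-04),
                       delta_sigma = 0.585821557,
                       delta_baseline_mean = 0.4, delta_baseline_sd = 0.2,
                       assoc_lambda = 0.34,
                       la_aware = TRUE) {
  cfg <- as.list(environment())
  if (n_probes < 1) validation_error("n_probes must be at least 1")
  if (abs(sum(type_props) - 1) > 1e-8 || abs(sum(strand_props) - 1) > 1e-8)
    validation_error("type_props and strand_props must each sum to 1")
  for (f in c(F_differentiated, F_background))
    if (f <= 0 || f >= 1) validation_error("divergence parameters must lie in (0, 1)")
  if (beta_sigma <= 0 || delta_sigma <= 0) validation_error("noise SDs must be positive")
  if (any(n_per_pop < 2)) validation_error("need at least 2 diploids per population")
  if (length(n_per_pop) != 2 || is.null(names(n_per_pop)))
    validation_error("n_per_pop must name exactly two populations")
  needed <- 100 + n_probes * (spacing + jitter) + 100
  if (!is.null(chrom_length) && chrom_length < needed)
    validation_error(sprintf("chromosome length %d cannot hold %d probes at spacing %d",
                             chrom_length, n_probes, spacing))
  class(cfg) <- c("sim_config", "list")
  cfg
}

#' Simulate a probe manifest
#'
#' Draws probe positions spaced so that 51-bp regions never overlap, with
#' strand and Infinium-type mixtures from the configuration; all four
#' strand-by-type combinations are guaranteed present when `n_probes >= 4`.
#' A random subset of CpGs is designated meQTL-associated (these later
#' receive differentiated probe SNPs at the higher carriage rate). Uses the
#' current RNG state; seed once per run for reproducibility.
#'
#' @param config A [sim_config()].
#' @return List: `probes` (manifest data.frame) and `truth_cpgs`
#'   (`cpg_id`, `is_meqtl`).
#' @export
simulate_manifest <- function(config) {
  n <- config$n_probes
  pos <- as.integer(100 + (seq_len(n) - 1L) * config$spacing +
                      sample.int(config$jitter + 1L, n, replace = TRUE) - 1L)
  strand <- sample(names(config$strand_props), n, replace = TRUE,
                   prob = config$strand_props)
  itype <- sample(names(config$type_props), n, replace = TRUE,
                  prob = config$type_props)
  if (n >= 4) {
    # guarantee all four strand x type combinations among the first probes
    combos <- expand.grid(s = c("F", "R"), t = c("I", "II"),
                          stringsAsFactors = FALSE)
    perm <- sample.int(4L)
    strand[1:4] <- combos$s[perm]
    itype[1:4] <- combos$t[perm]
  }
  probes <- data.frame(
    cpg_id = sprintf("cg%06d", seq_len(n)),
    chrom = config$chrom, pos = pos, strand = strand, infinium_type = itype,
    stringsAsFactors = FALSE
  )
  truth_cpgs <- data.frame(
    cpg_id = probes$cpg_id,
    is_meqtl = seq_len(n) %in% sample.int(n, round(config$frac_meqtl * n)),
    stringsAsFactors = FALSE
  )
  list(probes = probes, truth_cpgs = truth_cpgs)
}

#' Simulate two-population SNPs around a manifest
#'
#' Plants at most one SNP per probe region (carriage probability depending
#' on the CpG's meQTL designation, position uniform over the region's
#' probe-index window, so indices 0, 1 and the Type I extension position all
#' occur) and scatters background SNPs outside all regions. Allele
#' frequencies follow the Balding-Nichols model: ancestral frequency
#' `p ~ Uniform(range)`, then per population
#' `p_pop ~ Beta(p(1-F)/F, (1-p)(1-F)/F)` with the class's divergence `F`;
#' diploid genotypes are `Binomial(2, p_pop)` (Hardy-Weinberg within
#' populations). Planted SNPs of meQTL CpGs use `F_differentiated`, all
#' others `F_background`.
#'
#' @param config A [sim_config()].
#' @param regions Regions from [compute_probe_regions()] for the simulated
#'   manifest.
#' @param truth_cpgs Truth table from [simulate_manifest()].
#' @return List: `sites` (chrom, pos, snp_id, ref, alt), `genotypes`
#'   (sites x samples matrix of ALT doses), `panel`, `truth_snps` (per-SNP
#'   class, planted index, model and realized frequencies) and `truth_cpgs`
#'   augmented with planting outcome (`planted`, `distance`,
#'   `probe_snp_retained` — whether the planted SNP is expected to survive
#'   the extension rule and the configured MAF screen).
#' @export
simulate_population_snps <- function(config, regions, truth_cpgs) {
  pops <- names(config$n_per_pop)
  is_meqtl <- truth_cpgs$is_meqtl[match(regions$cpg_id, truth_cpgs$cpg_id)]
  p_plant <- ifelse(is_meqtl, config$p_probe_snp_meqtl, config$p_probe_snp_nonmeqtl)
  planted <- stats::runif(nrow(regions)) < p_plant

  idx <- rep(NA_integer_, nrow(regions))
  k <- sum(planted)
  idx[planted] <- regions$index_min[planted] +
    (sample.int(51L, k, replace = TRUE) - 1L)
  plus_pos <- ifelse(regions$strand == "F",
                     regions$target_c_pos + idx, regions$target_c_pos - idx)

  planted_sites <- data.frame(
    chrom = config$chrom, pos = as.integer(plus_pos[planted]),
    cpg_id = regions$cpg_id[planted],
    planted_index = idx[planted],
    class = ifelse(is_meqtl[planted], "differentiated", "background"),
    stringsAsFactors = FALSE
  )

  # background SNPs anywhere outside the probe regions
  lo <- min(regions$start); hi <- max(regions$end) + 1000L
  cand <- sample.int(hi, min(hi, config$n_background_snps * 4L))
  reg_ir <- IRanges::IRanges(start = regions$start + 1L, end = regions$end)
  in_region <- IRanges::overlapsAny(IRanges::IRanges(start = cand, width = 1L), reg_ir)
  cand <- setdiff(cand[!in_region], planted_sites$pos)
  bg_pos <- sort(utils::head(cand, config$n_background_snps))
  bg_sites <- data.frame(
    chrom = config$chrom, pos = bg_pos, cpg_id = NA_character_,
    planted_index = NA_integer_, class = "background",
    stringsAsFactors = FALSE
  )

  sites <- rbind(planted_sites, bg_sites)
  sites <- sites[!duplicated(sites$pos), , drop = FALSE]
  sites <- sites[order(sites$pos), , drop = FALSE]
  n_sites <- nrow(sites)
  sites$snp_id <- sprintf("snp%06d", seq_len(n_sites))

  bases <- c("A", "C", "G", "T")
  ref <- sample(bases, n_sites, replace = TRUE)
  alt <- vapply(ref, function(r) sample(setdiff(bases, r), 1L), "")
  sites$ref <- ref; sites$alt <- unname(alt)

  divergence <- ifelse(sites$class == "differentiated",
                       config$F_differentiated, config$F_background)
  is_bg <- is.na(sites$cpg_id)
  rb <- config$p_anc_background; rp <- config$p_anc_planted
  p_anc <- ifelse(is_bg,
                  stats::runif(n_sites, rb[1], rb[2]),
                  stats::runif(n_sites, rp[1], rp[2]))
  bn_draw <- function(p, F) stats::rbeta(length(p), p * (1 - F) / F,
                                         (1 - p) * (1 - F) / F)
  pop_freq <- vapply(pops, function(pp) bn_draw(p_anc, divergence),
                     numeric(n_sites))

  samples <- unlist(lapply(pops, function(pp)
    sprintf("%s_%03d", pp, seq_len(config$n_per_pop[[pp]]))))
  panel <- data.frame(sample = samples,
                      population = rep(pops, times = config$n_per_pop),
                      stringsAsFactors = FALSE)
  genotypes <- matrix(0L, nrow = n_sites, ncol = length(samples),
                      dimnames = list(sites$snp_id, samples))
  for (j in seq_along(pops)) {
    cols <- which(panel$population == pops[j])
    genotypes[, cols] <- stats::rbinom(n_sites * length(cols), 2L,
                                       rep(pop_freq[, j], times = length(cols)))
  }

  truth_snps <- data.frame(
    sites[, c("chrom", "pos", "snp_id", "ref", "alt", "class", "cpg_id",
              "planted_index")],
    p_anc = p_anc, stringsAsFactors = FALSE
  )
  for (j in seq_along(pops)) {
    truth_snps[[paste0("p_model_", pops[j])]] <- pop_freq[, j]
    cols <- which(panel$population == pops[j])
    f <- rowSums(genotypes[, cols, drop = FALSE]) / (2 * length(cols))
    truth_snps[[paste0("maf_", pops[j])]] <- pmin(f, 1 - f)
  }

  # which planted SNPs should survive the extension rule + MAF screen
  tc <- truth_cpgs
  m <- match(tc$cpg_id, truth_snps$cpg_id)
  tc$planted <- !is.na(m)
  tc$planted_index <- truth_snps$planted_index[m]
  tc$distance <- abs(tc$planted_index)
  sbe_idx <- regions$sbe_index[match(tc$cpg_id, regions$cpg_id)]
  at_sbe <- !is.na(m) &
    regions$infinium_type[match(tc$cpg_id, regions$cpg_id)] == "I" &
    tc$planted_index == sbe_idx
  switches <- rep(FALSE, nrow(tc))
  switches[!is.na(m)] <- is_color_switching(truth_snps$ref[m[!is.na(m)]],
                                            truth_snps$alt[m[!is.na(m)]])
  maf_ok <- rep(FALSE, nrow(tc))
  maf_cols <- paste0("maf_", pops)
  maf_ok[!is.na(m)] <- apply(
    truth_snps[m[!is.na(m)], maf_cols, drop = FALSE] >= config$maf, 1L, any)
  tc$probe_snp_retained <- tc$planted & (!at_sbe | switches) & maf_ok

  list(sites = sites[, c("chrom", "pos", "snp_id", "ref", "alt")],
       genotypes = genotypes, panel = panel,
       truth_snps = truth_snps, truth_cpgs = tc)
}

#' Write simulated genotypes as a plain-text VCF
#'
#' Minimal valid VCF 4.2 with GT-only genotype columns (unphased), suitable
#' for any standard VCF reader.
#'
#' @param sites Site table from [simulate_population_snps()].
#' @param genotypes ALT-dose matrix from the same.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_sim_vcf <- function(sites, genotypes, path) {
  gt_str <- c("0/0", "0/1", "1/1")[genotypes + 1L]
  dim(gt_str) <- dim(genotypes)
  header <- c(
    "##fileformat=VCFv4.2",
    sprintf("##contig=<ID=%s>", unique(sites$chrom)),
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", colnames(genotypes)), collapse = "\t")
  )
  body <- paste(sites$chrom, sites$pos, sites$snp_id, sites$ref, sites$alt,
                ".", "PASS", ".", "GT",
                apply(gt_str, 1L, paste, collapse = "\t"), sep = "\t")
  writeLines(c(header, body), path)
  invisible(path)
}

#' Write a two-column sample panel
#' @param panel Data.frame with `sample` and `population`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_panel <- function(panel, path) {
  writeLines(c("sample\tpop",
               paste(panel$sample, panel$population, sep = "\t")), path)
  invisible(path)
}

#' Simulate Balding-Nichols genotype counts for two populations
#'
#' Stand-alone frequency/genotype simulator used for estimator calibration:
#' ancestral frequencies `Uniform(p_anc_range)`, population frequencies from
#' the Balding-Nichols beta with divergence `F`, diploid genotypes
#' `Binomial(2, p_pop)`. Returns a count table in the same shape as
#' [read_biallelic_snps()], ready for [snp_fst()].
#'
#' @param n_snps Number of independent sites.
#' @param F Divergence parameter in (0, 1), directly comparable to the
#'   expected per-site Weir-Cockerham theta.
#' @param n_per_pop Named vector of diploid sample sizes for two populations.
#' @param p_anc_range Range of the uniform ancestral frequency.
#' @return SNP count table with `attr(, "populations")`.
#' @export
simulate_bn_counts <- function(n_snps, F, n_per_pop = c(EUR = 100, AFR = 100),
                               p_anc_range = c(0.05, 0.95)) {
  if (F <= 0 || F >= 1) validation_error("F must lie in (0, 1)")
  pops <- names(n_per_pop)
  p_anc <- stats::runif(n_snps, p_anc_range[1], p_anc_range[2])
  out <- data.frame(
    chrom = "1", pos = seq_len(n_snps),
    snp_id = sprintf("bn%06d", seq_len(n_snps)),
    ref = "A", alt = "G", stringsAsFactors = FALSE
  )
  for (pp in pops) {
    n <- n_per_pop[[pp]]
    pf <- stats::rbeta(n_snps, p_anc * (1 - F) / F, (1 - p_anc) * (1 - F) / F)
    g <- matrix(stats::rbinom(n_snps * n, 2L, rep(pf, times = n)), nrow = n_snps)
    out[[paste0("n_called_", pp)]] <- n
    out[[paste0("alt_count_", pp)]] <- as.integer(rowSums(g))
    out[[paste0("het_count_", pp)]] <- as.integer(rowSums(g == 1L))
  }
  attr(out, "populations") <- pops
  out
}

poly_eval <- function(coefs, x) {
  drop(outer(x, seq_along(coefs) - 1, `^`) %*% coefs)
}

#' Simulate a meQTL association table
#'
#' Every meQTL-designated CpG receives `1 + Poisson(assoc_lambda)`
#' associations. For CpGs whose planted probe SNP is expected to be retained,
#' the effect-size magnitude follows the configured cubic in the probe
#' SNP-to-cytosine distance plus Gaussian noise (floored at zero); CpGs
#' without a retained probe SNP draw from the baseline magnitude model. With
#' `la_aware = TRUE`, an ancestry effect-size difference is generated the
#' same way from the quadratic model and split symmetrically into
#' `beta_eur`/`beta_afr`.
#'
#' @param config A [sim_config()].
#' @param truth_cpgs Truth table with columns `cpg_id`, `is_meqtl`,
#'   `probe_snp_retained`, `distance` (from [simulate_population_snps()], or
#'   constructed directly for regression-only studies).
#' @return Data.frame: `cpg_id`, `snp_id`, `beta` and, when requested,
#'   `beta_eur`, `beta_afr`.
#' @export
simulate_meqtl_table <- function(config, truth_cpgs) {
  tc <- truth_cpgs[truth_cpgs$is_meqtl, , drop = FALSE]
  if (!nrow(tc)) validation_error("no meQTL CpGs in the truth table")
  n_assoc <- 1L + stats::rpois(nrow(tc), config$assoc_lambda)
  cpg <- rep(tc$cpg_id, n_assoc)
  with_snp <- rep(tc$probe_snp_retained %in% TRUE, n_assoc)
  dist <- rep(tc$distance, n_assoc)

  mu <- numeric(length(cpg))
  mu[with_snp] <- poly_eval(config$beta_coefs, dist[with_snp])
  if (any(mu[with_snp] < -1e-6))
    warning("effect model predicts negative magnitudes; flooring at 0", call. = FALSE)
  beta <- numeric(length(cpg))
  beta[with_snp] <- pmax(0, mu[with_snp] +
                           stats::rnorm(sum(with_snp), 0, config$beta_sigma))
  beta[!with_snp] <- abs(stats::rnorm(sum(!with_snp), config$beta_baseline_mean,
                                      config$beta_baseline_sd))
  out <- data.frame(
    cpg_id = cpg, snp_id = sprintf("mq%06d", seq_along(cpg)),
    beta = beta, stringsAsFactors = FALSE
  )
  if (isTRUE(config$la_aware)) {
    delta <- numeric(length(cpg))
    mud <- poly_eval(config$delta_coefs, dist[with_snp])
    delta[with_snp] <- pmax(0, mud + stats::rnorm(sum(with_snp), 0, config$delta_sigma))
    delta[!with_snp] <- abs(stats::rnorm(sum(!with_snp), config$delta_baseline_mean,
                                         config$delta_baseline_sd))
    out$beta_eur <- out$beta + delta / 2
    out$beta_afr <- out$beta - delta / 2
  }
  out
}

#' Write a meQTL table as TSV
#' @param meqtl meQTL table.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_meqtl_tsv <- function(meqtl, path) {
  utils::write.table(meqtl, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Generate a complete fixture set on disk
#'
#' Runs the whole generator under a single seed and writes
#' `manifest.csv`, `genotypes.vcf`, `panel.txt`, `meqtl.tsv`,
#' `truth_snps.tsv` and `truth_cpgs.tsv` into `out_dir`. Re-running with
#' the same config and seed reproduces every file byte for byte.
#'
#' @param config A [sim_config()].
#' @param seed Integer seed for the single RNG stream.
#' @param out_dir Output directory (created if needed).
#' @return Named list of file paths plus the in-memory `truth` tables,
#'   invisibly.
#' @export
simulate_fixtures <- function(config, seed, out_dir) {
  set.seed(seed)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  man <- simulate_manifest(config)
  regions <- compute_probe_regions(man$probes)
  sim <- simulate_population_snps(config, regions, man$truth_cpgs)
  meqtl <- simulate_meqtl_table(config, sim$truth_cpgs)

  paths <- list(
    manifest = file.path(out_dir, "manifest.csv"),
    vcf = file.path(out_dir, "genotypes.vcf"),
    panel = file.path(out_dir, "panel.txt"),
    meqtl = file.path(out_dir, "meqtl.tsv"),
    truth_snps = file.path(out_dir, "truth_snps.tsv"),
    truth_cpgs = file.path(out_dir, "truth_cpgs.tsv")
  )
  man_out <- data.frame(IlmnID = man$probes$cpg_id, CHR = man$probes$chrom,
                        MAPINFO = man$probes$pos, Strand = man$probes$strand,
                        Infinium_Design_Type = man$probes$infinium_type)
  utils::write.csv(man_out, paths$manifest, row.names = FALSE, quote = FALSE)
  write_sim_vcf(sim$sites, sim$genotypes, paths$vcf)
  write_panel(sim$panel, paths$panel)
  write_meqtl_tsv(meqtl, paths$meqtl)
  utils::write.table(sim$truth_snps, paths$truth_snps, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(sim$truth_cpgs, paths$truth_cpgs, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(c(paths, list(truth = list(snps = sim$truth_snps,
                                       cpgs = sim$truth_cpgs))))
}
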