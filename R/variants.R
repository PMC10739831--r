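#' Read a sample-to-population panel
#'
#' Reads a whitespace- or tab-delimited panel file in the style of the 1000
#' Genomes Phase 3 panel: first column sample id, second column population
#' label; any further columns are ignored. A header line (first field equal to
#' `sample`, case-insensitive) is tolerated and dropped.
#'
#' @param path Panel file path.
#' @return A data.frame with columns `sample` and `population`.
#' @export
read_panel <- function(path) {
  if (!file.exists(path)) validation_error(sprintf("panel file not found: %s", path))
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) data_error("panel file is empty")
  fields <- strsplit(trimws(lines), "[ \t]+")
  if (tolower(fields[[1]][1]) %in% c("sample", "sample_id", "id"))
    fields <- fields[-1]
  if (!length(fields)) data_error("panel file has a header but no samples")
  short <- vapply(fields, length, 1L) < 2L
  if (any(short))
    data_error(sprintf("panel line(s) %s lack a population column",
                       paste(which(short), collapse = ", ")))
  panel <- data.frame(sample = vapply(fields, `[`, "", 1L),
                      population = vapply(fields, `[`, "", 2L),
                      stringsAsFactors = FALSE)
  dup <- unique(panel$sample[duplicated(panel$sample)])
  if (length(dup))
    data_error(paste("duplicate sample id(s) in panel:", paste(dup, collapse = ", ")))
  panel
}

#' Read biallelic SNVs with per-population genotype counts
#'
#' Reads a VCF (plain or gzipped), keeps only biallelic single-nucleotide
#' variants (indels, multiallelic and symbolic records are skipped, with a
#' message giving the counts) and tallies, for every requested population,
#' the number of diploid individuals with called genotypes, the ALT allele
#' count and the heterozygote count. Phased (`|`) and unphased (`/`)
#' separators are treated identically; any genotype containing a missing
#' allele (`.`, including half-calls) is excluded from that site's counts.
#' VCF samples absent from the panel are dropped with a warning.
#'
#' @param vcf_path Path to the VCF.
#' @param panel Data.frame from [read_panel()].
#' @param populations Character vector of population labels to count.
#' @param strip_chr Drop a leading `"chr"` from chromosome names.
#' @return A data.frame with one row per retained SNV: `chrom`, `pos`,
#'   `snp_id`, `ref`, `alt`, and for every population `P` the columns
#'   `n_called_P`, `alt_count_P`, `het_count_P`. The population labels are
#'   kept in `attr(, "populations")`.
#' @export
read_biallelic_snps <- function(vcf_path, panel, populations, strip_chr = FALSE) {
  if (!file.exists(vcf_path)) validation_error(sprintf("VCF not found: %s", vcf_path))
  if (!length(populations)) validation_error("no populations requested")
  unknown_pop <- setdiff(populations, unique(panel$population))
  if (length(unknown_pop))
    validation_error(paste("population(s) not in panel:", paste(unknown_pop, collapse = ", ")))

  vcf <- vcfR::read.vcfR(vcf_path, verbose = FALSE)
  fix <- as.data.frame(vcf@fix, stringsAsFactors = FALSE)
  if (!nrow(fix))
    return(empty_snp_table(populations))

  ref <- fix$REF
  alt <- fix$ALT
  snv <- !is.na(alt) & nchar(ref) == 1L & nchar(alt) == 1L &
    ref %in% c("A", "C", "G", "T") & alt %in% c("A", "C", "G", "T")
  multi <- !is.na(alt) & grepl(",", alt, fixed = TRUE)
  n_skip <- sum(!snv)
  if (n_skip)
    message(sprintf("skipped %d non-biallelic-SNV record(s) (%d multiallelic)",
                    n_skip, sum(multi)))

  gt <- vcfR::extract.gt(vcf, element = "GT")
  gt <- gt[snv, , drop = FALSE]
  fix <- fix[snv, , drop = FALSE]
  if (!nrow(fix))
    return(empty_snp_table(populations))

  vcf_samples <- colnames(gt)
  off_panel <- setdiff(vcf_samples, panel$sample)
  if (length(off_panel))
    warning(sprintf("%d VCF sample(s) absent from panel excluded from all counts: %s",
                    length(off_panel),
                    paste(utils::head(off_panel, 5), collapse = ", ")), call. = FALSE)

  # genotype string -> alt dose (0/1/2), NA for anything containing "."
  dose_of <- function(g) {
    g <- sub(":.*$", "", g)
    g[g %in% c(".", "./.", ".|.")] <- NA_character_
    miss <- is.na(g) | grepl(".", g, fixed = TRUE)
    d <- integer(length(g))
    d[!miss] <- vapply(strsplit(g[!miss], "[/|]"),
                       function(a) sum(a == "1"), 0L)
    d[miss] <- NA_integer_
    # anything that is not a diploid 0/1 genotype is treated as missing
    ploidy_ok <- !miss & vapply(strsplit(g, "[/|]"), function(a)
      length(a) == 2L && all(a %in% c("0", "1")), TRUE)
    d[!miss & !ploidy_ok] <- NA_integer_
    d
  }
  dose <- apply(gt, 2L, dose_of)
  if (is.null(dim(dose))) dose <- matrix(dose, nrow = nrow(fix),
                                         dimnames = list(NULL, vcf_samples))

  out <- data.frame(
    chrom = if (strip_chr) normalize_chrom(fix$CHROM) else fix$CHROM,
    pos = as.integer(fix$POS),
    snp_id = ifelse(is.na(fix$ID) | fix$ID == ".",
                    paste(fix$CHROM, fix$POS, fix$REF, fix$ALT, sep = ":"), fix$ID),
    ref = fix$REF, alt = fix$ALT, stringsAsFactors = FALSE
  )
  for (p in populations) {
    samp <- intersect(panel$sample[panel$population == p], vcf_samples)
    if (!length(samp))
      data_error(sprintf("no samples from population '%s' found in the VCF", p))
    d <- dose[, samp, drop = FALSE]
    out[[paste0("n_called_", p)]] <- as.integer(rowSums(!is.na(d)))
    out[[paste0("alt_count_", p)]] <- as.integer(rowSums(d, na.rm = TRUE))
    out[[paste0("het_count_", p)]] <- as.integer(rowSums(d == 1L, na.rm = TRUE))
  }
  attr(out, "populations") <- populations
  out
}

empty_snp_table <- function(populations) {
  out <- data.frame(chrom = character(), pos = integer(), snp_id = character(),
                    ref = character(), alt = character(), stringsAsFactors = FALSE)
  for (p in populations) {
    out[[paste0("n_called_", p)]] <- integer()
    out[[paste0("alt_count_", p)]] <- integer()
    out[[paste0("het_count_", p)]] <- integer()
  }
  attr(out, "populations") <- populations
  out
}

#' Alternate and minor allele frequency in one population
#'
#' @param snps SNP table from [read_biallelic_snps()].
#' @param pop Population label.
#' @param minor Return the minor-allele frequency `min(f, 1 - f)` instead of
#'   the ALT-allele frequency.
#' @return Numeric vector of frequencies in `[0, 1]`.
#' @export
allele_frequency <- function(snps, pop, minor = FALSE) {
  nc <- snps[[paste0("n_called_", pop)]]
  ac <- snps[[paste0("alt_count_", pop)]]
  if (is.null(nc) || is.null(ac))
    validation_error(sprintf("no counts for population '%s' in SNP table", pop))
  if (any(nc == 0L))
    data_error(sprintf("allele frequency undefined (no called genotypes) for SNP(s): %s",
                       paste(utils::head(snps$snp_id[nc == 0L], 10), collapse = ", ")))
  f <- ac / (2 * nc)
  if (minor) pmin(f, 1 - f) else f
}

#' Frequency-based SNP retention
#'
#' Two retention modes: `maf_any_pop` keeps a SNP when its minor-allele
#' frequency reaches `threshold` in at least one of the listed populations
#' (the "at least 5% in either EUR or AFR" rule); `freq_in_pop` keeps a SNP
#' whose minor-allele frequency reaches `threshold` in the single named
#' population (segregation checks, e.g. "at least 1%" in a target cohort —
#' segregation is symmetric in allele labels, hence minor frequency).
#' Both comparisons are inclusive (`>=`).
#'
#' @param snps SNP table from [read_biallelic_snps()].
#' @param populations Population label(s); exactly one for `freq_in_pop`.
#' @param threshold Frequency threshold; in `(0, 0.5]` for `maf_any_pop`,
#'   `(0, 1]` for `freq_in_pop`.
#' @param mode Retention mode.
#' @return The retained subset of `snps` (attributes preserved).
#' @export
frequency_filter <- function(snps, populations, threshold,
                             mode = c("maf_any_pop", "freq_in_pop")) {
  mode <- match.arg(mode)
  if (!length(populations)) validation_error("empty population list")
  if (mode == "maf_any_pop" && (threshold <= 0 || threshold > 0.5))
    validation_error("threshold must be in (0, 0.5] for maf_any_pop")
  if (mode == "freq_in_pop") {
    if (length(populations) != 1L)
      validation_error("freq_in_pop mode takes exactly one population")
    if (threshold <= 0 || threshold > 1)
      validation_error("threshold must be in (0, 1] for freq_in_pop")
  }
  if (!nrow(snps)) return(snps)
  mafs <- vapply(populations, function(p) allele_frequency(snps, p, minor = TRUE),
                 numeric(nrow(snps)))
  if (is.null(dim(mafs))) mafs <- matrix(mafs, nrow = nrow(snps))
  keep <- apply(mafs >= threshold, 1L, any)
  out <- snps[keep, , drop = FALSE]
  attr(out, "populations") <- attr(snps, "populations")
  rownames(out) <- NULL
  out
}

#' Does a SNP switch fluorescence color channel?
#'
#' On the array, alleles of an A/T or a C/G SNP are read in the same color
#' channel; every other allele pair switches channels. Only color-switching
#' SNPs matter at the single-base-extension position of a Type I probe.
#'
#' @param ref,alt Single-base alleles (vectorized).
#' @return Logical: `TRUE` iff the unordered pair is neither \{A,T\} nor \{C,G\}.
#' @export
is_color_switching <- function(ref, alt) {
  ref <- toupper(ref); alt <- toupper(alt)
  ok <- ref %in% c("A", "C", "G", "T") & alt %in% c("A", "C", "G", "T")
  if (any(!ok))
    data_error(sprintf("non-ACGT allele(s): %s",
                       paste(unique(c(ref[!ok], alt[!ok])), collapse = ", ")))
  pair <- paste(pmin(ref, alt), pmax(ref, alt))
  !(pair %in% c("A T", "C G"))
}

#' Write a SNP table as TSV
#' @param snps SNP table from [read_biallelic_snps()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_snps_tsv <- function(snps, path) {
  utils::write.table(snps, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a SNP table written by [write_snps_tsv()]
#' @param path TSV path.
#' @return SNP table with `attr(, "populations")` restored from the headers.
#' @export
read_snps_tsv <- function(path) {
  if (!file.exists(path)) validation_error(sprintf("SNP table not found: %s", path))
  snps <- utils::read.table(path, sep = "\t", header = TRUE,
                            stringsAsFactors = FALSE,
                            colClasses = c(chrom = "character"))
  attr(snps, "populations") <- sub("^n_called_", "",
                                   grep("^n_called_", names(snps), value = TRUE))
  snps
}
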