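#' Intersect probe regions with SNPs
#'
#' Finds every (probe region, SNP) pair whose variant position falls inside
#' the 51-bp region, and annotates each hit with the signed probe index, the
#' distance `|index|` to the targeted cytosine, whether the variant disrupts
#' the CpG dinucleotide itself (index 0 or 1) and whether it sits at a Type I
#' probe's single-base-extension position. Output order is deterministic
#' (cpg_id, distance, probe_index, snp_id) regardless of input order.
#'
#' @param regions Data.frame from [compute_probe_regions()].
#' @param snps SNP table from [read_biallelic_snps()].
#' @return Data.frame of hits: `cpg_id`, `snp_id`, `chrom`, `pos`, `ref`,
#'   `alt`, `infinium_type`, `probe_index`, `distance`, `disrupts_cpg`,
#'   `at_sbe_position`.
#' @export
find_probe_snps <- function(regions, snps) {
  if (!nrow(regions) || !nrow(snps)) return(empty_hits())
  reg_gr <- GenomicRanges::GRanges(
    seqnames = regions$chrom,
    ranges = IRanges::IRanges(start = regions$start + 1L, end = regions$end)
  )
  snp_gr <- GenomicRanges::GRanges(
    seqnames = snps$chrom,
    ranges = IRanges::IRanges(start = snps$pos, width = 1L)
  )
  ov <- suppressWarnings(GenomicRanges::findOverlaps(snp_gr, reg_gr))
  if (!length(ov)) return(empty_hits())
  si <- S4Vectors::queryHits(ov)
  ri <- S4Vectors::subjectHits(ov)

  target <- regions$target_c_pos[ri]
  idx <- ifelse(regions$strand[ri] == "F", snps$pos[si] - target, target - snps$pos[si])
  hits <- data.frame(
    cpg_id = regions$cpg_id[ri], snp_id = snps$snp_id[si],
    chrom = as.character(snps$chrom[si]), pos = snps$pos[si],
    ref = snps$ref[si], alt = snps$alt[si],
    infinium_type = regions$infinium_type[ri],
    probe_index = as.integer(idx), distance = as.integer(abs(idx)),
    disrupts_cpg = idx %in% c(0L, 1L),
    at_sbe_position = regions$infinium_type[ri] == "I" & idx == regions$sbe_index[ri],
    stringsAsFactors = FALSE
  )
  hits[order(hits$cpg_id, hits$distance, hits$probe_index, hits$snp_id), , drop = FALSE] |>
    `rownames<-`(NULL)
}

empty_hits <- function() {
  data.frame(cpg_id = character(), snp_id = character(), chrom = character(),
             pos = integer(), ref = character(), alt = character(),
             infinium_type = character(), probe_index = integer(),
             distance = integer(), disrupts_cpg = logical(),
             at_sbe_position = logical(), stringsAsFactors = FALSE)
}

#' Apply the Type I single-base-extension retention rule
#'
#' At the single-base-extension position of a Type I probe only fluorescent
#' color-channel switching SNPs (pairs other than A/T and C/G) are
#' informative; same-channel SNPs there are dropped. Hits anywhere else, and
#' all hits on Type II probes, are retained unchanged. The returned table
#' carries a `passes_sbe_rule` column (all `TRUE` after filtering), so
#' re-applying the rule is a no-op.
#'
#' @param hits Data.frame from [find_probe_snps()].
#' @return The retained hits.
#' @export
apply_sbe_rule <- function(hits) {
  if (!nrow(hits)) {
    hits$passes_sbe_rule <- logical(0)
    return(hits)
  }
  passes <- !hits$at_sbe_position | is_color_switching(hits$ref, hits$alt)
  out <- hits[passes, , drop = FALSE]
  out$passes_sbe_rule <- rep(TRUE, nrow(out))
  rownames(out) <- NULL
  out
}

#' Per-CpG rollup of retained probe-SNP hits
#'
#' Produces one audit row per probe region, including regions with no hits.
#' The representative hit is the retained hit nearest the targeted cytosine;
#' ties are broken by higher Fst (when an Fst table is supplied) and then by
#' lexicographic snp_id, so the result does not depend on input order.
#'
#' @param regions Data.frame from [compute_probe_regions()].
#' @param hits Retained hits from [apply_sbe_rule()].
#' @param fst Optional Fst table from [snp_fst()] (columns `snp_id`,
#'   `theta`), used for tie-breaking and the `max_fst` annotation.
#' @return Data.frame with one row per CpG: `cpg_id`, `has_probe_snp`,
#'   `n_hits`, representative-hit columns (`rep_snp_id`, `rep_distance`,
#'   `rep_probe_index`, `rep_disrupts_cpg`, `rep_at_sbe_position`) and, when
#'   `fst` is given, `max_fst_snp_id` and `max_fst`.
#' @export
audit_cpgs <- function(regions, hits, fst = NULL) {
  unknown <- setdiff(hits$cpg_id, regions$cpg_id)
  if (length(unknown))
    data_error(paste("hit(s) reference unknown cpg_id:", paste(unknown, collapse = ", ")))

  theta <- rep(NA_real_, nrow(hits))
  if (!is.null(fst) && nrow(hits)) {
    theta <- fst$theta[match(hits$snp_id, fst$snp_id)]
  }
  audits <- data.frame(
    cpg_id = regions$cpg_id, has_probe_snp = FALSE, n_hits = 0L,
    rep_snp_id = NA_character_, rep_distance = NA_integer_,
    rep_probe_index = NA_integer_, rep_disrupts_cpg = NA,
    rep_at_sbe_position = NA, stringsAsFactors = FALSE
  )
  if (!is.null(fst)) {
    audits$max_fst_snp_id <- NA_character_
    audits$max_fst <- NA_real_
  }
  if (nrow(hits)) {
    # representative: min distance, then max theta (NA last), then snp_id
    ord <- order(hits$cpg_id, hits$distance, -ifelse(is.na(theta), -Inf, theta),
                 hits$snp_id)
    h <- hits[ord, , drop = FALSE]
    first <- !duplicated(h$cpg_id)
    i <- match(h$cpg_id[first], audits$cpg_id)
    audits$rep_snp_id[i] <- h$snp_id[first]
    audits$rep_distance[i] <- h$distance[first]
    audits$rep_probe_index[i] <- h$probe_index[first]
    audits$rep_disrupts_cpg[i] <- h$disrupts_cpg[first]
    audits$rep_at_sbe_position[i] <- h$at_sbe_position[first]
    tab <- table(hits$cpg_id)
    j <- match(names(tab), audits$cpg_id)
    audits$n_hits[j] <- as.integer(tab)
    audits$has_probe_snp <- audits$n_hits > 0L
    if (!is.null(fst)) {
      ht <- theta[ord]
      ordf <- order(h$cpg_id, -ifelse(is.na(ht), -Inf, ht), h$snp_id)
      hf <- h[ordf, , drop = FALSE]
      firstf <- !duplicated(hf$cpg_id)
      k <- match(hf$cpg_id[firstf], audits$cpg_id)
      audits$max_fst_snp_id[k] <- hf$snp_id[firstf]
      audits$max_fst[k] <- ht[ordf][firstf]
    }
  }
  audits
}

#' Write probe-SNP hits as TSV
#' @param hits Hits table.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_hits_tsv <- function(hits, path) {
  utils::write.table(hits, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a hits TSV written by [write_hits_tsv()]
#' @param path TSV path.
#' @return Hits data.frame.
#' @export
read_hits_tsv <- function(path) {
  if (!file.exists(path)) validation_error(sprintf("hits table not found: %s", path))
  utils::read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE,
                    colClasses = c(chrom = "character"))
}
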