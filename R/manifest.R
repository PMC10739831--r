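#' Read a CpG probe manifest
#'
#' Parses a manifest CSV describing CpG assay probes. The expected columns
#' (remappable through `col_map`) follow common Illumina manifest practice:
#' a probe identifier, chromosome, the 1-based plus-strand coordinate of the
#' CpG's plus-strand cytosine (MAPINFO-style, for both targeted strands), the
#' targeted strand (`F`/`R`) and the Infinium chemistry type (`I`/`II`).
#'
#' @param path Path to the manifest CSV.
#' @param col_map Named character vector mapping the internal field names
#'   `cpg_id`, `chrom`, `pos`, `strand`, `infinium_type` to column names in the
#'   file. If the `cpg_id` column is absent, a column named `Name` is tried as
#'   a fallback.
#' @param strip_chr Drop a leading `"chr"` from chromosome names so manifests
#'   and VCFs on different conventions can be intersected.
#' @return A data.frame of probes with columns `cpg_id`, `chrom`, `pos`,
#'   `strand`, `infinium_type`.
#' @examples
#' man <- data.frame(IlmnID = c("cg01", "cg02"), CHR = "1",
#'                   MAPINFO = c(1000L, 2000L), Strand = c("F", "R"),
#'                   Infinium_Design_Type = c("II", "I"))
#' f <- tempfile(fileext = ".csv")
#' write.csv(man, f, row.names = FALSE)
#' read_manifest(f)
#' @export
read_manifest <- function(path,
                          col_map = c(cpg_id = "IlmnID", chrom = "CHR",
                                      pos = "MAPINFO", strand = "Strand",
                                      infinium_type = "Infinium_Design_Type"),
                          strip_chr = FALSE) {
  if (!file.exists(path)) validation_error(sprintf("manifest file not found: %s", path))
  # colClasses: an all-"F" strand column must not become logical
  raw <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE,
                         colClasses = "character")
  needed <- c("cpg_id", "chrom", "pos", "strand", "infinium_type")
  missing_map <- setdiff(needed, names(col_map))
  if (length(missing_map))
    validation_error(paste("col_map lacks entries for:", paste(missing_map, collapse = ", ")))
  if (!col_map[["cpg_id"]] %in% names(raw) && "Name" %in% names(raw))
    col_map[["cpg_id"]] <- "Name"
  absent <- col_map[!col_map %in% names(raw)]
  if (length(absent))
    data_error(paste("manifest lacks column(s):", paste(absent, collapse = ", ")))

  probes <- data.frame(
    cpg_id = as.character(raw[[col_map[["cpg_id"]]]]),
    chrom = as.character(raw[[col_map[["chrom"]]]]),
    pos = suppressWarnings(as.integer(raw[[col_map[["pos"]]]])),
    strand = as.character(raw[[col_map[["strand"]]]]),
    infinium_type = as.character(raw[[col_map[["infinium_type"]]]]),
    stringsAsFactors = FALSE
  )
  if (strip_chr) probes$chrom <- normalize_chrom(probes$chrom)

  # row-numbered diagnostics (data rows, excluding the header)
  bad <- function(cond, what) {
    if (any(cond)) {
      rows <- which(cond)
      data_error(sprintf("manifest row(s) %s: %s",
                         paste(utils::head(rows, 10), collapse = ", "), what))
    }
  }
  bad(is.na(probes$pos) | probes$pos < 1L, "missing or non-positive coordinate")
  bad(!probes$strand %in% c("F", "R"), "strand must be 'F' or 'R'")
  bad(!probes$infinium_type %in% c("I", "II"), "Infinium type must be 'I' or 'II'")
  dup <- unique(probes$cpg_id[duplicated(probes$cpg_id)])
  if (length(dup))
    data_error(paste("duplicated cpg_id in manifest:", paste(dup, collapse = ", ")))
  probes
}

#' Compute 51-bp probe regions for a manifest
#'
#' Each CpG assay probe covers 50 bases downstream (forward-targeted) or
#' upstream (reverse-targeted) of the targeted cytosine, plus the extension
#' position, for a 51-position footprint. Positions within a region are
#' addressed by a signed probe index: index 0 is always the targeted cytosine
#' and index 1 the guanine of the CpG dinucleotide, whichever strand is
#' targeted. Under the default convention a Type II probe body spans indices
#' 1..50 with the extension interrogating index 0, and a Type I body spans
#' 0..49 with its single-base extension at index -1.
#'
#' For a reverse-targeted probe the targeted cytosine is the C of the minus
#' strand, i.e. plus-strand coordinate `pos + 1`; on the plus strand the
#' region runs leftwards from there. Getting this one base right matters:
#' a variant at plus-strand `p + 1` sits exactly on the targeted cytosine of
#' every minus-strand probe.
#'
#' @param probes Data.frame from [read_manifest()] (or a single-row
#'   data.frame with the same columns).
#' @param type1_window Placement of the Type I window on the probe-index
#'   axis: `"sbe_minus1"` (default; indices -1..49, extension before the C)
#'   or `"target_at_0"` (indices 0..50, like Type II). A convention switch,
#'   since array documentation differs in how the extension base is drawn.
#' @return A data.frame with one row per probe: `cpg_id`, `chrom`, `start`,
#'   `end` (0-based half-open plus-strand interval of width 51), `strand`,
#'   `infinium_type`, `target_c_pos` (1-based plus-strand coordinate of the
#'   targeted cytosine), `index_min`, `index_max`, `sbe_index`.
#' @export
compute_probe_regions <- function(probes, type1_window = c("sbe_minus1", "target_at_0")) {
  type1_window <- match.arg(type1_window)
  stopifnot(all(c("cpg_id", "chrom", "pos", "strand", "infinium_type") %in% names(probes)))

  type1 <- probes$infinium_type == "I"
  index_min <- ifelse(type1 & type1_window == "sbe_minus1", -1L, 0L)
  index_max <- index_min + 50L
  sbe_index <- ifelse(type1, ifelse(type1_window == "sbe_minus1", -1L, 0L), 0L)

  # targeted cytosine on the plus strand: the C itself for F, p+1 (the C of
  # the minus strand) for R
  target_c_pos <- ifelse(probes$strand == "F", probes$pos, probes$pos + 1L)

  # plus-strand coordinate of probe index i: F -> target + i, R -> target - i
  lo1 <- ifelse(probes$strand == "F", target_c_pos + index_min, target_c_pos - index_max)
  hi1 <- ifelse(probes$strand == "F", target_c_pos + index_max, target_c_pos - index_min)
  if (any(lo1 < 1L))
    data_error(sprintf("probe region extends below coordinate 1 for: %s",
                       paste(probes$cpg_id[lo1 < 1L], collapse = ", ")))

  data.frame(
    cpg_id = probes$cpg_id, chrom = probes$chrom,
    start = as.integer(lo1 - 1L), end = as.integer(hi1),
    strand = probes$strand, infinium_type = probes$infinium_type,
    target_c_pos = as.integer(target_c_pos),
    index_min = as.integer(index_min), index_max = as.integer(index_max),
    sbe_index = as.integer(sbe_index),
    stringsAsFactors = FALSE
  )
}

#' @rdname compute_probe_regions
#' @param probe A single-row data.frame describing one probe.
#' @export
compute_probe_region <- function(probe, type1_window = c("sbe_minus1", "target_at_0")) {
  if (nrow(probe) != 1L) validation_error("compute_probe_region expects exactly one probe")
  compute_probe_regions(probe, type1_window)
}

#' Signed probe index of a genomic position
#'
#' Maps a 1-based plus-strand coordinate inside a probe region to the signed
#' probe-index coordinate system: `x - target_c_pos` for forward-targeted
#' probes and `target_c_pos - x` for reverse-targeted ones, so that index 0 is
#' the targeted cytosine on either strand.
#'
#' @param region One-row data.frame from [compute_probe_regions()].
#' @param x Vector of 1-based plus-strand coordinates within the region.
#' @return Integer vector of signed probe indices.
#' @export
probe_index_of <- function(region, x) {
  if (nrow(region) != 1L) validation_error("probe_index_of expects a single region row")
  x <- as.integer(x)
  inside <- x >= region$start + 1L & x <= region$end
  if (any(!inside))
    data_error(sprintf("position(s) %s outside probe region %s [%d, %d]",
                       paste(x[!inside], collapse = ", "), region$cpg_id,
                       region$start + 1L, region$end))
  if (region$strand == "F") x - region$target_c_pos else region$target_c_pos - x
}

#' Write probe regions as BED6
#'
#' Standard BED: 0-based start, half-open end, name = cpg_id, score = 0,
#' strand `+` for forward-targeted and `-` for reverse-targeted probes. Rows
#' are ordered by (chrom, start, cpg_id) so output is deterministic.
#'
#' @param regions Data.frame from [compute_probe_regions()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_regions_bed <- function(regions, path) {
  ord <- order(regions$chrom, regions$start, regions$cpg_id)
  bed <- data.frame(
    chrom = regions$chrom[ord], start = regions$start[ord], end = regions$end[ord],
    name = regions$cpg_id[ord], score = rep(0L, length(ord)),
    strand = ifelse(regions$strand[ord] == "F", "+", "-")
  )
  con <- file(path, "w")
  on.exit(close(con))
  if (nrow(bed))
    utils::write.table(bed, con, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a BED6 file of probe regions
#'
#' @param path BED file written by [write_regions_bed()].
#' @return Data.frame with columns `chrom`, `start`, `end`, `cpg_id`, `strand`.
#' @export
read_regions_bed <- function(path) {
  if (!file.exists(path)) validation_error(sprintf("BED file not found: %s", path))
  if (file.size(path) == 0)
    return(data.frame(chrom = character(), start = integer(), end = integer(),
                      cpg_id = character(), strand = character()))
  bed <- utils::read.table(path, sep = "\t", stringsAsFactors = FALSE)
  data.frame(chrom = as.character(bed[[1]]), start = as.integer(bed[[2]]),
             end = as.integer(bed[[3]]), cpg_id = as.character(bed[[4]]),
             strand = as.character(bed[[6]]), stringsAsFactors = FALSE)
}

normalize_chrom <- function(x) sub("^chr", "", as.character(x))
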