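# Builders for small in-code fixtures shared across test files.

make_manifest <- function(cpg_id, chrom = "1", pos, strand, infinium_type) {
  data.frame(cpg_id = cpg_id, chrom = chrom, pos = as.integer(pos),
             strand = strand, infinium_type = infinium_type,
             stringsAsFactors = FALSE)
}

random_manifest <- function(n, spacing = 200) {
  make_manifest(
    cpg_id = sprintf("cg%05d", seq_len(n)),
    pos = 100 + (seq_len(n) - 1) * spacing + sample(0:50, n, replace = TRUE),
    strand = sample(c("F", "R"), n, replace = TRUE),
    infinium_type = sample(c("I", "II"), n, replace = TRUE)
  )
}

# a manifest holding all four strand x type combinations at fixed spots
combo_manifest <- function(pos = c(1000, 2000, 3000, 4000)) {
  make_manifest(
    cpg_id = paste0("cg", 1:4), pos = pos,
    strand = c("F", "F", "R", "R"), infinium_type = c("II", "I", "II", "I")
  )
}

write_manifest_csv <- function(probes, path = tempfile(fileext = ".csv")) {
  out <- data.frame(IlmnID = probes$cpg_id, CHR = probes$chrom,
                    MAPINFO = probes$pos, Strand = probes$strand,
                    Infinium_Design_Type = probes$infinium_type)
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  path
}

# write a VCF from a site table and a genotype-string matrix (sites x samples)
write_vcf_text <- function(sites, gt, samples, path = tempfile(fileext = ".vcf")) {
  header <- c(
    "##fileformat=VCFv4.2",
    sprintf("##contig=<ID=%s>", unique(sites$chrom)),
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", samples), collapse = "\t")
  )
  body <- paste(sites$chrom, sites$pos, sites$id, sites$ref, sites$alt,
                ".", "PASS", ".", "GT",
                apply(gt, 1, paste, collapse = "\t"), sep = "\t")
  writeLines(c(header, body), path)
  path
}

write_panel_text <- function(samples, pops, path = tempfile(fileext = ".txt"),
                             header = TRUE) {
  lines <- paste(samples, pops, sep = "\t")
  if (header) lines <- c("sample\tpop", lines)
  writeLines(lines, path)
  path
}

# genotype strings realizing a given ALT allele count out of 2n alleles:
# as many heterozygotes as possible, remainder homozygous ALT
gt_for_count <- function(alt_count, n) {
  hom <- max(0L, alt_count - n)
  het <- alt_count - 2L * hom
  c(rep("1/1", hom), rep("0/1", het), rep("0/0", n - hom - het))
}
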