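# Hand-rolled VCF text fixtures so tests control every field, including
# malformed genotypes. `records` is a data frame with columns chrom, pos,
# ref, alt, f, m, p (sample strings, already "GT:GQ:DP" or just "GT" when
# format = "GT").
write_vcf_fixture <- function(records, path = tempfile(fileext = ".vcf"),
                              format = "GT:GQ:DP",
                              samples = c("FATHER", "MOTHER", "PROBAND")) {
  header <- c(
    "##fileformat=VCFv4.2",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "##FORMAT=<ID=GQ,Number=1,Type=Integer,Description=\"Genotype Quality\">",
    "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Read Depth\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", samples), collapse = "\t")
  )
  body <- paste(records$chrom, records$pos, ".", records$ref, records$alt,
                ".", "PASS", ".", format, records$f, records$m, records$p,
                sep = "\t")
  writeLines(c(header, body), path)
  path
}

# A clean fully genotyped biallelic fixture: n sites on one chromosome,
# everything passes the default QC.
simple_trio_records <- function(n = 5, chrom = "chr1", gq = 99, dp = 60) {
  s <- function(gt) paste(gt, gq, dp, sep = ":")
  data.frame(chrom = chrom, pos = seq(100, by = 100, length.out = n),
             ref = "A", alt = "G",
             f = s("0/1"), m = s("0/0"), p = s("0/1"))
}

# Small trio tibble built directly (bypassing VCF I/O) for caller-level
# tests.
make_trio <- function(chrom, pos, gf, gm, gp, gq = 99L, dp = 60L) {
  n <- length(pos)
  tibble::tibble(
    chrom = chrom, pos = as.integer(pos),
    gt_father = as.integer(gf), gt_mother = as.integer(gm),
    gt_proband = as.integer(gp),
    gq_father = rep_len(as.integer(gq), n),
    gq_mother = rep_len(as.integer(gq), n),
    gq_proband = rep_len(as.integer(gq), n),
    dp_father = rep_len(as.integer(dp), n),
    dp_mother = rep_len(as.integer(dp), n),
    dp_proband = rep_len(as.integer(dp), n)
  )
}
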