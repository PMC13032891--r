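#' Read a parent-offspring trio from a multi-sample VCF
#'
#' Loads genotypes (GT), genotype qualities (GQ) and read depths (DP) for the
#' proband and both parents, keeping only biallelic single-nucleotide
#' substitutions at which all three samples carry a called diploid genotype.
#' Phased (`|`) and unphased (`/`) separators are treated identically; only
#' the alternate-allele count matters. Missing GQ/DP values are recorded as 0
#' (so such sites fail quality control when it is applied, and are retained
#' when it is not).
#'
#' Sex chromosomes are excluded by default: hemizygous male genotypes violate
#' the diploid observation model and there is no haploid emission model.
#'
#' @param path Path to a VCF 4.x file (plain or gzipped) containing the three
#'   samples.
#' @param proband,father,mother Sample names as they appear in the VCF header.
#' @param exclude Optional exclusion regions: a BED3 file path or a data frame
#'   with columns `chrom`, `start`, `end` in BED convention (0-based
#'   half-open). Sites falling in these regions are dropped. Typically a list
#'   of known conflicting regions (segmental duplications, low-complexity
#'   sequence).
#' @param drop_sex_chroms Drop chromosomes named X/Y (with or without a "chr"
#'   prefix)? Default `TRUE`.
#' @return A tibble with one row per retained site, columns `chrom`, `pos`
#'   (1-based VCF position), `gt_father`, `gt_mother`, `gt_proband`
#'   (alternate-allele dosage in `{0, 1, 2}`), `gq_*` and `dp_*` for the three
#'   samples. Positions are strictly increasing within each chromosome. The
#'   sample names are kept in the `"samples"` attribute. A chromosome with no
#'   retained sites simply contributes no rows.
#' @seealso [apply_qc()], [encode_observations()], [call_upd()]
#' @export
read_trio_vcf <- function(path, proband, father, mother,
                          exclude = NULL, drop_sex_chroms = TRUE) {
  if (!file.exists(path))
    abort(paste0("VCF file not found: ", path))
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  have <- colnames(vcf@gt)[-1]
  wanted <- c(proband = proband, father = father, mother = mother)
  absent <- wanted[!wanted %in% have]
  if (length(absent))
    abort(paste0("Sample(s) not present in VCF: ",
                 paste(absent, collapse = ", "),
                 ". Available: ", paste(have, collapse = ", ")))

  fix <- vcf@fix
  chrom <- fix[, "CHROM"]
  pos <- as.integer(fix[, "POS"])

  # biallelic SNVs only: single-base REF and single-base ALT, no comma
  bases <- c("A", "C", "G", "T", "a", "c", "g", "t")
  keep <- fix[, "REF"] %in% bases & fix[, "ALT"] %in% bases

  gt <- vcfR::extract.gt(vcf, element = "GT")
  gq <- suppressWarnings(vcfR::extract.gt(vcf, element = "GQ",
                                          as.numeric = TRUE))
  dp <- suppressWarnings(vcfR::extract.gt(vcf, element = "DP",
                                          as.numeric = TRUE))

  dosage <- function(x) {
    u <- unique(x)
    parts <- strsplit(u, "[/|]")
    d <- vapply(parts, function(p) {
      if (length(p) == 2L && all(p %in% c("0", "1"))) sum(p == "1") else NA_real_
    }, numeric(1))
    as.integer(d[match(x, u)])
  }
  gt_f <- dosage(gt[, father])
  gt_m <- dosage(gt[, mother])
  gt_p <- dosage(gt[, proband])
  keep <- keep & !is.na(gt_f) & !is.na(gt_m) & !is.na(gt_p)

  if (drop_sex_chroms)
    keep <- keep & !grepl("^(chr)?[XY]$", chrom, ignore.case = TRUE)

  trio <- tibble(
    chrom = chrom,
    pos = pos,
    gt_father = gt_f, gt_mother = gt_m, gt_proband = gt_p,
    gq_father = as.integer(round(ifelse(is.na(gq[, father]), 0, gq[, father]))),
    gq_mother = as.integer(round(ifelse(is.na(gq[, mother]), 0, gq[, mother]))),
    gq_proband = as.integer(round(ifelse(is.na(gq[, proband]), 0, gq[, proband]))),
    dp_father = as.integer(round(ifelse(is.na(dp[, father]), 0, dp[, father]))),
    dp_mother = as.integer(round(ifelse(is.na(dp[, mother]), 0, dp[, mother]))),
    dp_proband = as.integer(round(ifelse(is.na(dp[, proband]), 0, dp[, proband])))
  )[keep, ]

  # VCFs must be coordinate-sorted within chromosome; refuse to guess order
  unsorted <- trio |>
    dplyr::group_by(.data$chrom) |>
    dplyr::summarise(bad = is.unsorted(.data$pos), .groups = "drop")
  if (any(unsorted$bad))
    abort(paste0("VCF is not coordinate-sorted on: ",
                 paste(unsorted$chrom[unsorted$bad], collapse = ", ")))
  dup <- duplicated(trio[, c("chrom", "pos")])
  if (any(dup)) {
    warn(sprintf("Dropping %d duplicated positions.", sum(dup)))
    trio <- trio[!dup, ]
  }

  if (!is.null(exclude))
    trio <- exclude_regions(trio, exclude)

  attr(trio, "samples") <- wanted
  trio
}

#' Drop sites overlapping BED exclusion regions
#'
#' @param trio A trio tibble from [read_trio_vcf()] or [simulate_trio()].
#' @param regions BED3 path or data frame (`chrom`, `start`, `end`, 0-based
#'   half-open).
#' @return The trio tibble without sites inside any region.
#' @export
exclude_regions <- function(trio, regions) {
  if (is.character(regions)) regions <- read_bed3(regions)
  stopifnot(all(c("chrom", "start", "end") %in% names(regions)))
  drop <- rep(FALSE, nrow(trio))
  for (ch in unique(regions$chrom)) {
    r <- regions[regions$chrom == ch, ]
    on_ch <- which(trio$chrom == ch)
    if (!length(on_ch)) next
    hit <- IRanges::overlapsAny(
      IRanges::IRanges(start = trio$pos[on_ch], width = 1L),
      IRanges::IRanges(start = r$start + 1L, end = r$end) # BED -> 1-based
    )
    drop[on_ch][hit] <- TRUE
  }
  out <- trio[!drop, ]
  attr(out, "samples") <- attr(trio, "samples")
  out
}

read_bed3 <- function(path) {
  bed <- read.table(path, sep = "\t", header = FALSE,
                    col.names = c("chrom", "start", "end"),
                    colClasses = c("character", "integer", "integer"))
  as_tibble(bed)
}

#' Quality-control filter for trio sites
#'
#' Retains exactly the sites where *all six* per-sample quality values pass
#' strict thresholds: genotype quality `GQ > min_gq` and read depth
#' `DP > min_dp` in the proband and in both parents. The defaults are the
#' conventional short-read trio thresholds (GQ > 20, DP > 30). Idempotent;
#' site order is preserved.
#'
#' @param trio A trio tibble ([read_trio_vcf()]).
#' @param min_gq,min_dp Non-negative strict lower thresholds.
#' @return The filtered trio tibble (possibly empty).
#' @export
apply_qc <- function(trio, min_gq = 20, min_dp = 30) {
  stopifnot(min_gq >= 0, min_dp >= 0)
  keep <- trio$gq_father > min_gq & trio$gq_mother > min_gq &
    trio$gq_proband > min_gq &
    trio$dp_father > min_dp & trio$dp_mother > min_dp &
    trio$dp_proband > min_dp
  out <- trio[keep, ]
  attr(out, "samples") <- attr(trio, "samples")
  out
}

#' Encode trio genotypes as HMM observation codes
#'
#' @param trio A trio tibble.
#' @return Integer vector of observation codes in `[0, 26]`, one per site
#'   (`gf * 9 + gm * 3 + gp`).
#' @export
encode_observations <- function(trio) {
  encode_trio_code(trio$gt_father, trio$gt_mother, trio$gt_proband)
}
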