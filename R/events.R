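upd_call_cols <- c(
  "sample_id", "chrom", "start", "end", "state", "n_snps",
  "n_mendelian_errors", "log_likelihood_ratio", "p_value",
  "depth_ratio_proband", "depth_ratio_father", "depth_ratio_mother"
)

empty_upd_calls <- function() {
  out <- tibble(
    sample_id = character(), chrom = character(),
    start = integer(), end = integer(), state = character(),
    n_snps = integer(), n_mendelian_errors = integer(),
    log_likelihood_ratio = numeric(), p_value = numeric(),
    depth_ratio_proband = numeric(), depth_ratio_father = numeric(),
    depth_ratio_mother = numeric()
  )
  class(out) <- c("upd_calls", class(out))
  out
}

as_upd_calls <- function(x) {
  x <- as_tibble(x)
  x <- x[, c(upd_call_cols, setdiff(names(x), upd_call_cols))]
  class(x) <- c("upd_calls", setdiff(class(x), "upd_calls"))
  x
}

#' Aggregate a decoded state path into candidate event blocks
#'
#' Run-length encodes the decoded path into maximal runs of identical state
#' and keeps the non-normal runs. Block coordinates are the genomic positions
#' of the first and last variant in the run (1-based inclusive); blocks of
#' different states are never merged.
#'
#' @param path An `upd_path` from [viterbi_decode()], or a character vector of
#'   state labels.
#' @param positions Integer vector of 1-based variant positions aligned to the
#'   path.
#' @return A tibble with columns `state`, `first_index`, `last_index` (1-based
#'   indices into the path), `start`, `end` (positions) and `n_snps`.
#' @export
aggregate_blocks <- function(path, positions) {
  labels <- if (inherits(path, "upd_path")) path$labels else as.character(path)
  stopifnot(length(labels) == length(positions))
  if (!length(labels))
    return(tibble(state = character(), first_index = integer(),
                  last_index = integer(), start = integer(),
                  end = integer(), n_snps = integer()))
  r <- rle(labels)
  last <- cumsum(r$lengths)
  first <- last - r$lengths + 1L
  keep <- r$values != "normal"
  tibble(
    state = r$values[keep],
    first_index = first[keep],
    last_index = last[keep],
    start = as.integer(positions[first[keep]]),
    end = as.integer(positions[last[keep]]),
    n_snps = r$lengths[keep]
  )
}

# Probability of the observed proband dosage under Mendelian transmission;
# exact zeros identify trio-incompatible (Mendelian-error) sites.
mendelian_site_prob <- function(gt_father, gt_mother, gt_proband) {
  pf <- gt_father / 2
  pm <- gt_mother / 2
  p0 <- (1 - pf) * (1 - pm)
  p2 <- pf * pm
  p1 <- pf * (1 - pm) + (1 - pf) * pm
  ifelse(gt_proband == 0L, p0, ifelse(gt_proband == 1L, p1, p2))
}

#' Count Mendelian errors in a block of trio sites
#'
#' A Mendelian error is a site whose proband genotype has probability zero
#' under biparental transmission given the parental genotypes (before any
#' error smoothing), e.g. hom-ref parents with an alternate allele in the
#' child, or opposite-homozygous parents with a homozygous child.
#'
#' @param trio A trio tibble.
#' @param first_index,last_index 1-based inclusive row range (defaults: whole
#'   table).
#' @return Integer count of incompatible sites in the range.
#' @export
count_mendelian_errors <- function(trio, first_index = 1L,
                                   last_index = nrow(trio)) {
  if (first_index > last_index) return(0L)
  stopifnot(first_index >= 1L, last_index <= nrow(trio))
  i <- first_index:last_index
  sum(mendelian_site_prob(trio$gt_father[i], trio$gt_mother[i],
                          trio$gt_proband[i]) == 0)
}

#' Likelihood-ratio statistic of a block under a UPD state
#'
#' Natural-log likelihood ratio of the block's observations under the given
#' UPD state versus the normal (Mendelian) state, using emission terms only:
#' the transition contributions are identical under both hypotheses up to
#' boundary terms of order `log(tau)` and cancel. The p-value is the
#' upper-tail chi-square probability (1 degree of freedom) at `2 * LLR`
#' (Wilks), clamped to 1 when the LLR is non-positive. Emitted uncorrected;
#' with many events, adjust downstream (e.g. `p.adjust`).
#'
#' @param model An `upd_hmm`.
#' @param obs Integer observation codes.
#' @param state A non-normal state label.
#' @param from,to 1-based inclusive index range of the block (>= 1 site).
#' @return A list with elements `llr` and `p_value`.
#' @export
event_llr <- function(model, obs, state, from = 1L, to = length(obs)) {
  stopifnot(from <= to)
  llr <- path_emission_loglik(model, obs, state, from, to) -
    path_emission_loglik(model, obs, "normal", from, to)
  p <- if (llr <= 0) 1 else pchisq(2 * llr, df = 1, lower.tail = FALSE)
  list(llr = llr, p_value = p)
}

#' Depth ratios of a candidate event
#'
#' For each trio member, the median read depth over the sites inside the
#' block divided by the median depth over all retained sites outside the
#' block, genome-wide. Copy-neutral events sit near 1 in all three samples;
#' deviations flag possible copy-number variants. A zero out-of-block median
#' yields `NA` (undefined), never an error.
#'
#' @param trio The full retained trio tibble (all chromosomes).
#' @param in_block Logical vector over rows of `trio`, `TRUE` inside the
#'   block.
#' @return Named numeric vector `c(proband, father, mother)`.
#' @export
depth_ratio <- function(trio, in_block) {
  stopifnot(length(in_block) == nrow(trio))
  one <- function(dp) {
    m_out <- median(dp[!in_block])
    if (!length(dp[!in_block]) || is.na(m_out) || m_out == 0) return(NA_real_)
    median(dp[in_block]) / m_out
  }
  c(proband = one(trio$dp_proband),
    father = one(trio$dp_father),
    mother = one(trio$dp_mother))
}

#' Call uniparental-disomy events in a trio
#'
#' The full caller: per chromosome, sites are encoded as genotype-combination
#' observations, the inheritance path is Viterbi-decoded under the five-state
#' HMM, contiguous non-Mendelian states are aggregated into blocks, and each
#' block is annotated with its SNP count, Mendelian-error count,
#' log-likelihood ratio with p-value, and the three per-sample depth ratios
#' (in-block vs rest of genome). Chromosomes are processed independently, so
#' results do not depend on how the input is split.
#'
#' @param trio A trio tibble from [read_trio_vcf()] or [simulate_trio()].
#' @param model An [build_hmm()] model.
#' @param sample_id Proband identifier for the output table; defaults to the
#'   proband name recorded by [read_trio_vcf()], else `"proband"`.
#' @param qc Apply [apply_qc()] first? Default `TRUE` (the recommended
#'   workflow); set `FALSE` if the input is already filtered or carries no
#'   GQ/DP.
#' @param min_gq,min_dp QC thresholds when `qc = TRUE`.
#' @param verbose Emit a per-chromosome message with site and event counts?
#' @return A `upd_calls` tibble, one row per event (possibly zero rows), with
#'   columns `sample_id`, `chrom`, `start`, `end`, `state`, `n_snps`,
#'   `n_mendelian_errors`, `log_likelihood_ratio`, `p_value`,
#'   `depth_ratio_proband`, `depth_ratio_father`, `depth_ratio_mother`.
#'   Events on a chromosome never overlap. All blocks >= 1 SNP are reported;
#'   size/recurrence/depth filtering is downstream (see [filter_events()],
#'   [collapse_events()], [mark_recurrent_regions()]).
#' @seealso [autoplot.upd_calls()], [write_events()]
#' @export
#' @examples
#' sim <- simulate_trio(sim_spec(
#'   chrom_lengths = c(chr1 = 2e6),
#'   implants = data.frame(chrom = "chr1", start = 5e5, end = 15e5,
#'                         state = "father_isodisomy"),
#'   seed = 7))
#' call_upd(sim$trio, verbose = FALSE)
call_upd <- function(trio, model = build_hmm(), sample_id = NULL,
                     qc = TRUE, min_gq = 20, min_dp = 30, verbose = TRUE) {
  stopifnot(inherits(model, "upd_hmm"))
  sample_id <- sample_id %||%
    unname(attr(trio, "samples")["proband"]) %||% "proband"
  if (is.na(sample_id)) sample_id <- "proband"
  if (qc) trio <- apply_qc(trio, min_gq = min_gq, min_dp = min_dp)
  if (!nrow(trio)) return(empty_upd_calls())

  chroms <- unique(trio$chrom)
  rows <- vector("list", length(chroms))
  for (k in seq_along(chroms)) {
    ch <- chroms[k]
    idx <- which(trio$chrom == ch)
    obs <- encode_observations(trio[idx, ])
    path <- viterbi_decode(model, obs)
    blocks <- aggregate_blocks(path, trio$pos[idx])
    if (verbose)
      inform(sprintf("%s: %d sites, %d event(s)", ch, length(idx),
                     nrow(blocks)))
    if (!nrow(blocks)) next
    ann <- purrr::pmap(blocks, function(state, first_index, last_index,
                                        start, end, n_snps) {
      lr <- event_llr(model, obs, state, first_index, last_index)
      in_block <- rep(FALSE, nrow(trio))
      in_block[idx[first_index:last_index]] <- TRUE
      dr <- depth_ratio(trio, in_block)
      tibble(
        sample_id = sample_id, chrom = ch,
        start = start, end = end, state = state, n_snps = n_snps,
        n_mendelian_errors = count_mendelian_errors(
          trio[idx, ], first_index, last_index),
        log_likelihood_ratio = lr$llr, p_value = lr$p_value,
        depth_ratio_proband = dr[["proband"]],
        depth_ratio_father = dr[["father"]],
        depth_ratio_mother = dr[["mother"]]
      )
    })
    rows[[k]] <- dplyr::bind_rows(ann)
  }
  out <- dplyr::bind_rows(rows)
  if (!nrow(out)) return(empty_upd_calls())
  as_upd_calls(out)
}

#' Read / write an events table as TSV
#'
#' One row per event with exactly the caller's annotation columns.
#'
#' @param events A `upd_calls` tibble.
#' @param path File path.
#' @return `write_events()` returns `path` invisibly; `read_events()` a
#'   `upd_calls` tibble.
#' @export
write_events <- function(events, path) {
  readr::write_tsv(as_tibble(events), path)
  invisible(path)
}

#' @rdname write_events
#' @export
read_events <- function(path) {
  out <- readr::read_tsv(
    path,
    col_types = readr::cols(
      sample_id = "c", chrom = "c", start = "i", end = "i", state = "c",
      n_snps = "i", n_mendelian_errors = "i",
      log_likelihood_ratio = "d", p_value = "d",
      depth_ratio_proband = "d", depth_ratio_father = "d",
      depth_ratio_mother = "d", .default = "?"
    )
  )
  as_upd_calls(out)
}
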