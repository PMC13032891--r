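#' Merge same-type calls on a chromosome into a single event
#'
#' For each (sample, chromosome, state) group with two or more events, emits
#' one event spanning `min(start)` to `max(end)`. SNP counts, Mendelian-error
#' counts and log-likelihood ratios are summed; the p-value is recomputed
#' from the summed LLR; events of different states or chromosomes never
#' merge. Useful for fragmented whole-chromosome events, e.g. before size
#' estimation. Idempotent.
#'
#' Depth ratios over the merged span can only be recomputed from per-site
#' depths: pass the retained `trio` table to get them, otherwise merged
#' events carry `NA` ratios (single events keep theirs).
#'
#' @param events A `upd_calls` tibble (one sample, or carrying `sample_id`).
#' @param trio Optional trio tibble used to recompute merged-span depth
#'   ratios.
#' @return A `upd_calls` tibble with at most one event per (sample,
#'   chromosome, state).
#' @export
collapse_events <- function(events, trio = NULL) {
  if (!nrow(events)) return(as_upd_calls(events))
  groups <- dplyr::group_split(
    dplyr::group_by(as_tibble(events),
                    .data$sample_id, .data$chrom, .data$state))
  merged <- purrr::map(groups, function(g) {
    if (nrow(g) == 1L) return(g)
    llr <- sum(g$log_likelihood_ratio)
    dr <- c(proband = NA_real_, father = NA_real_, mother = NA_real_)
    span <- c(min(g$start), max(g$end))
    if (!is.null(trio)) {
      in_block <- trio$chrom == g$chrom[1] &
        trio$pos >= span[1] & trio$pos <= span[2]
      dr <- depth_ratio(trio, in_block)
    }
    tibble(
      sample_id = g$sample_id[1], chrom = g$chrom[1],
      start = span[1], end = span[2], state = g$state[1],
      n_snps = sum(g$n_snps),
      n_mendelian_errors = sum(g$n_mendelian_errors),
      log_likelihood_ratio = llr,
      p_value = if (llr <= 0) 1 else pchisq(2 * llr, 1, lower.tail = FALSE),
      depth_ratio_proband = dr[["proband"]],
      depth_ratio_father = dr[["father"]],
      depth_ratio_mother = dr[["mother"]]
    )
  })
  out <- dplyr::arrange(dplyr::bind_rows(merged),
                        .data$sample_id, .data$chrom, .data$start)
  as_upd_calls(out[, names(events)[names(events) %in% names(out)]])
}

#' Find regions recurrently called across samples
#'
#' Sweep-line over event endpoints, per chromosome: returns the maximal
#' sub-intervals where the number of *distinct* samples with an overlapping
#' event reaches `min_samples`. A sample with several overlapping events
#' counts once — recurrence across unrelated samples signals systematic
#' artifacts (poorly mapped or conflicting regions), not within-sample
#' fragmentation.
#'
#' @param events A multi-sample `upd_calls` tibble (any state).
#' @param min_samples Distinct-sample threshold; default
#'   `max(2, ceiling(0.01 * n_samples))`.
#' @return A tibble of regions: `chrom`, `start`, `end` (1-based inclusive),
#'   `n_samples` (distinct samples overlapping the region; always >=
#'   `min_samples`).
#' @seealso [mark_recurrent_regions()], [write_regions_bed()]
#' @export
identify_recurrent_regions <- function(events, min_samples = NULL) {
  min_samples <- min_samples %||%
    max(2L, ceiling(0.01 * dplyr::n_distinct(events$sample_id)))
  out <- list()
  for (ch in unique(events$chrom)) {
    e <- events[events$chrom == ch, ]
    bp <- sort(unique(c(e$start, e$end + 1L)))
    if (length(bp) < 2L) next
    seg_start <- bp[-length(bp)]
    seg_end <- bp[-1L] - 1L
    # events contain no internal breakpoints, so covering the segment start
    # means covering the whole segment
    n_seg <- vapply(seg_start, function(s) {
      dplyr::n_distinct(e$sample_id[e$start <= s & e$end >= s])
    }, integer(1))
    ok <- n_seg >= min_samples
    if (!any(ok)) next
    r <- rle(ok)
    last <- cumsum(r$lengths)
    first <- last - r$lengths + 1L
    for (j in which(r$values)) {
      rs <- seg_start[first[j]]
      re <- seg_end[last[j]]
      n <- dplyr::n_distinct(e$sample_id[e$start <= re & e$end >= rs])
      out[[length(out) + 1L]] <- tibble(chrom = ch, start = rs, end = re,
                                        n_samples = n)
    }
  }
  if (!length(out))
    return(tibble(chrom = character(), start = integer(),
                  end = integer(), n_samples = integer()))
  dplyr::arrange(dplyr::bind_rows(out), .data$chrom, .data$start)
}

#' Flag events overlapping recurrent regions
#'
#' Adds a logical `recurrent` column: `TRUE` when the event shares at least
#' one base with any region on the same chromosome (inclusive coordinates).
#' The table is otherwise unchanged.
#'
#' @param events A `upd_calls` tibble.
#' @param regions Regions from [identify_recurrent_regions()] (or
#'   [read_regions_bed()]).
#' @return `events` with the `recurrent` flag.
#' @export
mark_recurrent_regions <- function(events, regions) {
  flag <- rep(FALSE, nrow(events))
  for (ch in unique(regions$chrom)) {
    on_ch <- which(events$chrom == ch)
    if (!length(on_ch)) next
    r <- regions[regions$chrom == ch, ]
    flag[on_ch] <- IRanges::overlapsAny(
      IRanges::IRanges(start = events$start[on_ch], end = events$end[on_ch]),
      IRanges::IRanges(start = r$start, end = r$end)
    )
  }
  events$recurrent <- flag
  events
}

#' Filter called events
#'
#' The downstream exclusion step of the calling workflow: drops events
#' flagged as recurrent, events whose depth ratios deviate from copy
#' neutrality in any trio member (likely copy-number variants rather than
#' copy-neutral UPD), and events below size/SNP-count floors. Undefined
#' (`NA`) depth ratios are not treated as deviations. The default depth
#' bounds `[0.75, 1.25]` are a conventional copy-neutral band; tune them to
#' the cohort's coverage dispersion.
#'
#' @param events A `upd_calls` tibble, optionally carrying the `recurrent`
#'   flag.
#' @param min_snps Minimum `n_snps` (default 1: keep all).
#' @param min_size Minimum event span in bp (`end - start + 1`; default 0).
#' @param depth_ratio_bounds Length-2 copy-neutral interval applied to all
#'   three depth ratios, or `NULL` to disable.
#' @param drop_recurrent Drop events with `recurrent == TRUE` (if the column
#'   is present)?
#' @return The filtered `upd_calls` tibble.
#' @export
filter_events <- function(events, min_snps = 1L, min_size = 0L,
                          depth_ratio_bounds = c(0.75, 1.25),
                          drop_recurrent = TRUE) {
  keep <- events$n_snps >= min_snps &
    (events$end - events$start + 1L) >= min_size
  if (!is.null(depth_ratio_bounds)) {
    stopifnot(length(depth_ratio_bounds) == 2L)
    ok_dr <- function(x) is.na(x) |
      (x >= depth_ratio_bounds[1] & x <= depth_ratio_bounds[2])
    keep <- keep & ok_dr(events$depth_ratio_proband) &
      ok_dr(events$depth_ratio_father) & ok_dr(events$depth_ratio_mother)
  }
  if (drop_recurrent && "recurrent" %in% names(events))
    keep <- keep & !events$recurrent
  events[keep, ]
}

#' Read / write recurrent regions as BED3+1
#'
#' Column 4 carries the distinct-sample count; coordinates convert to/from
#' BED's 0-based half-open convention at the file boundary.
#'
#' @param regions Regions tibble ([identify_recurrent_regions()]).
#' @param path File path.
#' @return `write_regions_bed()` returns `path` invisibly; `read_regions_bed()`
#'   a regions tibble (1-based inclusive).
#' @export
write_regions_bed <- function(regions, path) {
  bed <- data.frame(chrom = regions$chrom,
                    start = regions$start - 1L,
                    end = regions$end,
                    n_samples = regions$n_samples)
  write.table(bed, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname write_regions_bed
#' @export
read_regions_bed <- function(path) {
  bed <- read.table(path, sep = "\t", header = FALSE,
                    col.names = c("chrom", "start", "end", "n_samples"),
                    colClasses = c("character", "integer", "integer",
                                   "integer"))
  tibble(chrom = bed$chrom, start = bed$start + 1L, end = bed$end,
         n_samples = bed$n_samples)
}
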