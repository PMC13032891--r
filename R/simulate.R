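#' Specify a synthetic trio simulation
#'
#' The generative backbone: per site an allele frequency is drawn from
#' `Beta(af_shape[1], af_shape[2])` (default Beta(0.5, 0.5), a U-shaped
#' spectrum rich in both rare and common variants), each parent's two alleles
#' are drawn independently at that frequency (Hardy-Weinberg), and the
#' proband receives one allele from each parent by Mendelian transmission.
#' Inside each implanted event the proband is overridden: isodisomy
#' duplicates one uniformly chosen allele of the named parent per site (an
#' unphased approximation of a single duplicated haplotype); heterodisomy
#' copies the named parent's genotype. Symmetric genotyping error then
#' replaces each sample's genotype by a uniformly chosen different genotype
#' with rate `error_rate`, independently across sites and samples. Depth and
#' quality are Poisson draws.
#'
#' `"genome"` mode places variants uniformly (default density 1 per kb);
#' `"exome"` mode restricts variants to gene-like blocks covering
#' `target_fraction` of each chromosome, emulating the clustered footprint of
#' capture data.
#'
#' @param chrom_lengths Named integer vector of chromosome lengths in bp.
#' @param variant_density Variants per bp of simulated territory (default
#'   1e-3 = 1/kb).
#' @param mode `"genome"` (uniform) or `"exome"` (clustered).
#' @param target_fraction,block_size Exome mode: fraction of the chromosome
#'   covered by gene blocks, and the block size in bp.
#' @param af_shape Length-2 Beta shape parameters of the allele-frequency law.
#' @param error_rate Per-genotype symmetric error rate (default 0.002).
#' @param dp_mean,gq_mean Poisson means of read depth and genotype quality
#'   (GQ capped at 99). Defaults 60 and 80 emulate a well-covered short-read
#'   trio in which the conventional GQ > 20 / DP > 30 QC retains most sites.
#' @param implants Data frame of events to implant: columns `chrom`, `start`,
#'   `end` (1-based inclusive), `state` (a non-normal [upd_states()] label).
#'   Must lie within chromosome bounds and not overlap each other.
#' @param seed Integer seed; the simulation is fully reproducible from it.
#' @return A `sim_spec` list.
#' @seealso [simulate_trio()]
#' @export
sim_spec <- function(chrom_lengths = c(chr1 = 5e7),
                     variant_density = 1e-3,
                     mode = c("genome", "exome"),
                     target_fraction = 0.02, block_size = 2e4,
                     af_shape = c(0.5, 0.5),
                     error_rate = 0.002,
                     dp_mean = 60, gq_mean = 80,
                     implants = NULL, seed = 1L) {
  mode <- match.arg(mode)
  stopifnot(length(chrom_lengths) >= 1L, !is.null(names(chrom_lengths)),
            all(chrom_lengths > 0), variant_density > 0,
            error_rate >= 0, error_rate < 1,
            dp_mean > 0, gq_mean > 0, length(af_shape) == 2L,
            all(af_shape > 0))
  if (!is.null(implants)) {
    implants <- as_tibble(implants)
    stopifnot(all(c("chrom", "start", "end", "state") %in% names(implants)),
              all(implants$state %in% upd_states()[-1]),
              all(implants$chrom %in% names(chrom_lengths)),
              all(implants$start >= 1),
              all(implants$end <= chrom_lengths[implants$chrom]),
              all(implants$start <= implants$end))
    for (ch in unique(implants$chrom)) {
      im <- implants[implants$chrom == ch, ]
      im <- im[order(im$start), ]
      if (nrow(im) > 1L && any(im$start[-1] <= im$end[-nrow(im)]))
        abort("Implanted events on the same chromosome must not overlap.")
    }
    implants$start <- as.integer(implants$start)
    implants$end <- as.integer(implants$end)
  }
  structure(
    list(chrom_lengths = chrom_lengths, variant_density = variant_density,
         mode = mode, target_fraction = target_fraction,
         block_size = block_size, af_shape = af_shape,
         error_rate = error_rate, dp_mean = dp_mean, gq_mean = gq_mean,
         implants = implants, seed = as.integer(seed)),
    class = "sim_spec"
  )
}

apply_genotype_error <- function(gt, rate) {
  if (rate <= 0) return(gt)
  err <- which(runif(length(gt)) < rate)
  if (length(err))
    gt[err] <- (gt[err] + sample(1:2, length(err), replace = TRUE)) %% 3L
  as.integer(gt)
}

#' Simulate a genotyped trio with implanted UPD events
#'
#' Draws a full trio according to a [sim_spec()] and returns the trio site
#' table together with the implanted ground truth. Byte-identical output is
#' guaranteed for identical specs (the seed drives every draw); the caller's
#' RNG state is left untouched.
#'
#' @param spec A [sim_spec()].
#' @return A list of class `trio_sim`: `trio` (tibble as from
#'   [read_trio_vcf()], samples PROBAND/FATHER/MOTHER), `truth` (tibble
#'   `chrom`, `start`, `end`, `state`; zero rows when nothing was implanted)
#'   and `spec`.
#' @export
#' @examples
#' sim <- simulate_trio(sim_spec(chrom_lengths = c(chr1 = 1e6), seed = 1))
#' dplyr::count(sim$trio, chrom)
simulate_trio <- function(spec) {
  stopifnot(inherits(spec, "sim_spec"))
  bases <- c("A", "C", "G", "T")
  trio <- withr::with_seed(spec$seed, {
    per_chrom <- purrr::imap(spec$chrom_lengths, function(L, ch) {
      L <- as.integer(L)
      if (spec$mode == "genome") {
        n <- max(1L, as.integer(round(L * spec$variant_density)))
        pos <- sort(sample.int(L, min(n, L)))
      } else {
        bs <- as.integer(spec$block_size)
        nb <- max(1L, ceiling(L * spec$target_fraction / bs))
        starts <- sort(sample.int(max(1L, L - bs), nb))
        n <- max(1L, as.integer(round(nb * bs * spec$variant_density)))
        pos <- sort(unique(starts[sample.int(nb, n, replace = TRUE)] +
                             sample.int(bs, n, replace = TRUE) - 1L))
        pos <- pos[pos <= L]
      }
      n <- length(pos)
      p <- rbeta(n, spec$af_shape[1], spec$af_shape[2])
      gf <- rbinom(n, 2L, p)
      gm <- rbinom(n, 2L, p)
      gp <- rbinom(n, 1L, gf / 2) + rbinom(n, 1L, gm / 2)

      implants <- spec$implants
      if (!is.null(implants)) {
        for (i in which(implants$chrom == ch)) {
          inside <- which(pos >= implants$start[i] & pos <= implants$end[i])
          if (!length(inside)) next
          st <- implants$state[i]
          g_par <- if (startsWith(st, "father")) gf[inside] else gm[inside]
          gp[inside] <- if (endsWith(st, "isodisomy")) {
            2L * rbinom(length(inside), 1L, g_par / 2)
          } else {
            g_par
          }
        }
      }

      gf <- apply_genotype_error(gf, spec$error_rate)
      gm <- apply_genotype_error(gm, spec$error_rate)
      gp <- apply_genotype_error(gp, spec$error_rate)

      ref <- sample(bases, n, replace = TRUE)
      alt <- bases[(match(ref, bases) - 1L +
                      sample.int(3L, n, replace = TRUE)) %% 4L + 1L]

      tibble(
        chrom = ch, pos = as.integer(pos), ref = ref, alt = alt,
        gt_father = gf, gt_mother = gm, gt_proband = as.integer(gp),
        gq_father = pmin(99L, rpois(n, spec$gq_mean)),
        gq_mother = pmin(99L, rpois(n, spec$gq_mean)),
        gq_proband = pmin(99L, rpois(n, spec$gq_mean)),
        dp_father = rpois(n, spec$dp_mean),
        dp_mother = rpois(n, spec$dp_mean),
        dp_proband = rpois(n, spec$dp_mean)
      )
    })
    dplyr::bind_rows(per_chrom)
  })
  attr(trio, "samples") <- c(proband = "PROBAND", father = "FATHER",
                             mother = "MOTHER")
  truth <- if (is.null(spec$implants)) {
    tibble(chrom = character(), start = integer(), end = integer(),
           state = character())
  } else {
    spec$implants[, c("chrom", "start", "end", "state")]
  }
  structure(list(trio = trio, truth = truth, spec = spec),
            class = "trio_sim")
}

#' @export
print.trio_sim <- function(x, ...) {
  cat(sprintf("<trio_sim> %d sites on %d chromosome(s), %d implanted event(s)\n",
              nrow(x$trio), length(unique(x$trio$chrom)), nrow(x$truth)))
  invisible(x)
}

#' Write a trio table as a sorted multi-sample VCF
#'
#' Emits a minimal valid VCF 4.2 with FORMAT `GT:GQ:DP` and sample columns
#' FATHER, MOTHER, PROBAND (names configurable). REF/ALT columns of the trio
#' table are used when present (the simulator provides them), else A/C.
#'
#' @param trio A trio tibble.
#' @param path Output path (plain text).
#' @param proband,father,mother Sample column names to write.
#' @return `path`, invisibly.
#' @export
write_trio_vcf <- function(trio, path, proband = "PROBAND",
                           father = "FATHER", mother = "MOTHER") {
  gt_str <- function(g) c("0/0", "0/1", "1/1")[g + 1L]
  fmt <- function(g, gq, dp) paste(gt_str(g), gq, dp, sep = ":")
  ref <- if ("ref" %in% names(trio)) trio$ref else rep("A", nrow(trio))
  alt <- if ("alt" %in% names(trio)) trio$alt else rep("C", nrow(trio))
  contigs <- vapply(split(trio$pos, trio$chrom), max, numeric(1))
  contigs <- contigs[unique(trio$chrom)]
  header <- c(
    "##fileformat=VCFv4.2",
    "##source=triodisomy-simulator",
    sprintf("##contig=<ID=%s,length=%d>", names(contigs),
            as.integer(contigs)),
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "##FORMAT=<ID=GQ,Number=1,Type=Integer,Description=\"Genotype Quality\">",
    "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Read Depth\">",
    paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
          "FORMAT", father, mother, proband, sep = "\t")
  )
  body <- paste(trio$chrom, trio$pos, ".", ref, alt, ".", "PASS", ".",
                "GT:GQ:DP",
                fmt(trio$gt_father, trio$gq_father, trio$dp_father),
                fmt(trio$gt_mother, trio$gq_mother, trio$dp_mother),
                fmt(trio$gt_proband, trio$gq_proband, trio$dp_proband),
                sep = "\t")
  writeLines(c(header, body), path)
  invisible(path)
}

state_origin <- function(state) sub("_(iso|hetero)disomy$", "", state)
state_type <- function(state) sub("^(father|mother)_", "", state)

# total inclusive-coordinate length of the union of [s, e] intervals
interval_union_length <- function(s, e) {
  if (!length(s)) return(0)
  o <- order(s)
  s <- s[o]; e <- e[o]
  tot <- 0; cs <- s[1]; ce <- e[1]
  for (i in seq_along(s)[-1]) {
    if (s[i] <= ce + 1) ce <- max(ce, e[i])
    else { tot <- tot + (ce - cs + 1); cs <- s[i]; ce <- e[i] }
  }
  tot + (ce - cs + 1)
}

#' Score called events against simulated ground truth
#'
#' For every truth event, collects the calls overlapping it on the same
#' chromosome (inclusive-coordinate intersection) and reports:
#' * `matched` — at least one overlapping call agrees in both UPD type
#'   (iso/hetero) and parental origin; this is the detection notion used for
#'   sensitivity.
#' * `detected` — at least one overlapping call agrees in type *or* origin
#'   (a looser notion, kept for diagnostic use).
#' * `classification` — `right` when every overlapping call matches both,
#'   `wrong` when none does, `uncertain` when matching and non-matching
#'   types co-occur; `NA` with no overlapping call.
#' * `overlap_fraction` — truth bases covered by the union of fully matching
#'   calls, divided by truth length; `NA` when not matched.
#'
#' Calls overlapping no truth event are false positives.
#'
#' @param truth Tibble `chrom`, `start`, `end`, `state`.
#' @param calls A `upd_calls` tibble.
#' @return A list of class `upd_eval`: `events` (per-truth tibble),
#'   `false_positive_count`, `n_calls`.
#' @export
score_run <- function(truth, calls) {
  rows <- purrr::pmap(truth, function(chrom, start, end, state, ...) {
    ov <- which(calls$chrom == chrom & calls$start <= end &
                  calls$end >= start)
    if (!length(ov)) {
      return(tibble(chrom = chrom, start = start, end = end, state = state,
                    detected = FALSE, matched = FALSE,
                    classification = NA_character_,
                    overlap_fraction = NA_real_))
    }
    st <- calls$state[ov]
    full <- st == state
    loose <- state_origin(st) == state_origin(state) |
      state_type(st) == state_type(state)
    classification <- if (all(full)) "right" else if (!any(full)) "wrong"
    else "uncertain"
    ovf <- NA_real_
    if (any(full)) {
      s <- pmax(calls$start[ov][full], start)
      e <- pmin(calls$end[ov][full], end)
      ovf <- interval_union_length(s, e) / (end - start + 1)
    }
    tibble(chrom = chrom, start = start, end = end, state = state,
           detected = any(loose), matched = any(full),
           classification = classification, overlap_fraction = ovf)
  })
  events <- if (length(rows)) dplyr::bind_rows(rows) else
    tibble(chrom = character(), start = integer(), end = integer(),
           state = character(), detected = logical(), matched = logical(),
           classification = character(), overlap_fraction = numeric())
  # a call is a false positive when it overlaps no truth event at all
  fp <- 0L
  if (nrow(calls)) {
    fp <- sum(!purrr::map_lgl(seq_len(nrow(calls)), function(i) {
      any(truth$chrom == calls$chrom[i] & truth$start <= calls$end[i] &
            truth$end >= calls$start[i])
    }))
  }
  structure(list(events = events, false_positive_count = fp,
                 n_calls = nrow(calls)),
            class = "upd_eval")
}

#' @export
print.upd_eval <- function(x, ...) {
  cat(sprintf(
    "<upd_eval> %d truth event(s): %d matched, %d false positive call(s)\n",
    nrow(x$events), sum(x$events$matched), x$false_positive_count))
  invisible(x)
}

#' Benchmark caller sensitivity and coordinate accuracy by event size
#'
#' For each implant size and UPD type, simulates `replicates` independent
#' trios carrying a single implanted event at a seeded random location, runs
#' the full caller (QC, decoding, aggregation, annotation) and scores the
#' calls against the truth. The simulated chromosome is twice the implant
#' size (at least `min_chrom_length`) so every event has flanking normal
#' territory. Fully reproducible: replicate seeds are derived from `seed`.
#'
#' @param sizes Implant sizes in bp. Default `c(0.5, 1, 2, 5, 10, 25) * 1e6`,
#'   straddling the megabase range where sensitivity transitions.
#' @param states UPD states to implant (default all four).
#' @param replicates Trios per size x state cell (default 20).
#' @param variant_density,error_rate,dp_mean,gq_mean Passed to [sim_spec()].
#' @param model Caller model (default [build_hmm()] defaults).
#' @param qc Apply GQ/DP quality control in the caller (default `TRUE`).
#' @param min_chrom_length Minimum simulated chromosome length in bp.
#' @param seed Base seed.
#' @return A list of class `upd_benchmark`: `summary` (tibble `size`,
#'   `state`, `n`, `sensitivity`, `mean_overlap`, `false_positives`) and
#'   `events` (per-truth-event detail with `size`, `state`, `replicate`,
#'   `matched`, `classification`, `overlap_fraction`,
#'   `false_positive_count`).
#' @seealso [autoplot.upd_benchmark()], [glance.upd_benchmark()]
#' @export
benchmark_sensitivity <- function(sizes = c(0.5, 1, 2, 5, 10, 25) * 1e6,
                                  states = upd_states()[-1],
                                  replicates = 20,
                                  variant_density = 1e-3,
                                  error_rate = 0.002,
                                  dp_mean = 60, gq_mean = 80,
                                  model = build_hmm(),
                                  qc = TRUE,
                                  min_chrom_length = 1e7,
                                  seed = 1L) {
  grid <- expand.grid(size = sizes, state = states, replicate =
                        seq_len(replicates), stringsAsFactors = FALSE)
  detail <- vector("list", nrow(grid))
  for (i in seq_len(nrow(grid))) {
    size <- as.integer(grid$size[i])
    st <- grid$state[i]
    L <- as.integer(max(min_chrom_length, 2 * size))
    run_seed <- (as.integer(seed) + 104729L * i) %% 2147483647L
    start <- withr::with_seed(run_seed + 1L,
                              sample.int(L - size + 1L, 1L))
    spec <- sim_spec(
      chrom_lengths = c(chr1 = L), variant_density = variant_density,
      error_rate = error_rate, dp_mean = dp_mean, gq_mean = gq_mean,
      implants = tibble(chrom = "chr1", start = start,
                        end = start + size - 1L, state = st),
      seed = run_seed
    )
    sim <- simulate_trio(spec)
    calls <- call_upd(sim$trio, model = model, qc = qc, verbose = FALSE)
    ev <- score_run(sim$truth, calls)
    detail[[i]] <- dplyr::mutate(
      ev$events, size = size, replicate = grid$replicate[i],
      false_positive_count = ev$false_positive_count, .before = 1
    )
  }
  events <- dplyr::bind_rows(detail)
  if (!nrow(events)) {
    events <- tibble(size = integer(), replicate = integer(),
                     false_positive_count = integer(), chrom = character(),
                     start = integer(), end = integer(), state = character(),
                     detected = logical(), matched = logical(),
                     classification = character(),
                     overlap_fraction = numeric())
  }
  summary <- events |>
    dplyr::group_by(.data$size, .data$state) |>
    dplyr::summarise(
      n = dplyr::n(),
      sensitivity = mean(.data$matched),
      mean_overlap = ifelse(any(.data$matched),
                            mean(.data$overlap_fraction[.data$matched]),
                            NA_real_),
      false_positives = sum(.data$false_positive_count),
      .groups = "drop"
    )
  structure(list(summary = summary, events = events),
            class = "upd_benchmark")
}

#' @export
print.upd_benchmark <- function(x, ...) {
  cat("<upd_benchmark>\n")
  print(x$summary, n = Inf)
  invisible(x)
}
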