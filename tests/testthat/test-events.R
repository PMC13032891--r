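test_that("blocks are maximal same-state runs excluding normal", {
  pos <- c(100, 200, 300, 400)
  expect_equal(nrow(aggregate_blocks(rep("normal", 3), c(1, 2, 3))), 0)

  b <- aggregate_blocks(c("normal", "father_isodisomy", "father_isodisomy",
                          "normal"), pos)
  expect_equal(nrow(b), 1)
  expect_equal(b$state, "father_isodisomy")
  expect_equal(c(b$start, b$end, b$n_snps), c(200, 300, 2))
  expect_equal(c(b$first_index, b$last_index), c(2, 3))

  b2 <- aggregate_blocks(c("father_isodisomy", "father_isodisomy",
                           "mother_heterodisomy", "mother_heterodisomy"),
                         pos)
  expect_equal(b2$state, c("father_isodisomy", "mother_heterodisomy"))
  expect_equal(b2$start, c(100, 300))
  expect_equal(b2$end, c(200, 400))

  expect_equal(nrow(aggregate_blocks(character(0), integer(0))), 0)
})

test_that("Mendelian errors are the zero-probability trio combinations", {
  trio <- make_trio("chr1", 1:6 * 10,
                    gf = c(0, 1, 2, 0, 2, 2),
                    gm = c(0, 1, 2, 2, 0, 2),
                    gp = c(1, 2, 1, 0, 1, 2))
  # site 1: hom-ref x hom-ref with alt allele -> error
  # site 2: het x het compatible with anything -> ok
  # site 3: hom-alt x hom-alt het child -> error
  # site 4: opposite homozygotes, child not het -> error
  # site 5: opposite homozygotes, het child -> ok
  # site 6: hom-alt x hom-alt hom-alt child -> ok
  expect_equal(count_mendelian_errors(trio), 3L)
  expect_equal(count_mendelian_errors(trio, 2, 2), 0L)
  expect_equal(count_mendelian_errors(trio, 5, 4), 0L)
  # het x het can never be an error whatever the child
  het <- make_trio("chr1", 1:3, gf = 1, gm = 1, gp = 0:2)
  expect_equal(count_mendelian_errors(het), 0L)
  # block of 10 with 3 planted (2,2) -> gp 1 errors
  ten <- make_trio("chr1", 1:10 * 10, gf = c(rep(1, 7), 2, 2, 2),
                   gm = c(rep(1, 7), 2, 2, 2),
                   gp = c(rep(0, 7), 1, 1, 1))
  expect_equal(count_mendelian_errors(ten), 3L)
})

test_that("the block LLR is the emission log-ratio with a Wilks p-value", {
  m <- build_hmm(epsilon = 0.05)
  # (0,0,0): father_isodisomy and normal agree exactly -> llr 0, p 1
  r <- event_llr(m, rep(0L, 10), "father_isodisomy")
  expect_equal(r$llr, 0)
  expect_equal(r$p_value, 1)
  # single informative site, closed form
  obs <- encode_trio_code(1, 0, 1)
  r1 <- event_llr(m, obs, "father_heterodisomy")
  expect_equal(r1$llr, log(0.95 + 0.05 / 3) - log(0.475 + 0.05 / 3))
  expect_equal(r1$p_value, pchisq(2 * r1$llr, 1, lower.tail = FALSE))
  # additivity over concatenated sub-blocks
  withr::with_seed(8, {
    obs <- sample(0:26, 40, replace = TRUE)
    whole <- event_llr(m, obs, "mother_isodisomy", 1, 40)
    expect_equal(whole$llr,
                 event_llr(m, obs, "mother_isodisomy", 1, 15)$llr +
                   event_llr(m, obs, "mother_isodisomy", 16, 40)$llr)
  })
})

test_that("depth ratios compare in-block to genome-wide out-of-block medians", {
  trio <- make_trio("chr1", 1:10 * 100, gf = 1, gm = 1, gp = 1, dp = 30L)
  in_block <- seq_len(10) %in% 3:5
  expect_equal(depth_ratio(trio, in_block),
               c(proband = 1, father = 1, mother = 1))
  trio$dp_proband[3:5] <- 45L
  expect_equal(depth_ratio(trio, in_block)[["proband"]], 1.5)
  trio$dp_mother <- 0L
  expect_true(is.na(depth_ratio(trio, in_block)[["mother"]]))
})

test_that("an all-Mendelian trio yields no events", {
  sim <- simulate_trio(sim_spec(chrom_lengths = c(chr1 = 2e6, chr2 = 1e6),
                                error_rate = 0, seed = 5))
  calls <- call_upd(sim$trio, verbose = FALSE)
  expect_s3_class(calls, "upd_calls")
  expect_equal(nrow(calls), 0)
})

test_that("an implanted isodisomy is recovered as one matching event", {
  spec <- sim_spec(chrom_lengths = c(chr1 = 5e6, chr2 = 2e6),
                   implants = data.frame(chrom = "chr1", start = 1e6,
                                         end = 3e6,
                                         state = "father_isodisomy"),
                   seed = 31)
  sim <- simulate_trio(spec)
  calls <- call_upd(sim$trio, verbose = FALSE)
  fi <- calls[calls$state == "father_isodisomy", ]
  expect_equal(nrow(fi), 1)
  expect_equal(fi$chrom, "chr1")
  # span overlaps the implant and the statistics behave
  expect_lt(fi$start, 3e6)
  expect_gt(fi$end, 1e6)
  expect_gt(fi$log_likelihood_ratio, 0)
  expect_lt(fi$p_value, 0.05)
  expect_lte(fi$n_mendelian_errors, fi$n_snps)
  expect_gt(fi$n_mendelian_errors, 0) # mother opposite-hom sites exist
  expect_equal(fi$depth_ratio_proband, 1, tolerance = 0.1)
  # per-chromosome messages appear when verbose
  expect_message(call_upd(sim$trio, verbose = TRUE), "chr1")
})

test_that("chromosomes are processed independently", {
  spec <- sim_spec(chrom_lengths = c(chr1 = 3e6, chr2 = 3e6),
                   implants = data.frame(chrom = c("chr1", "chr2"),
                                         start = c(5e5, 1e6),
                                         end = c(25e5, 28e5),
                                         state = c("mother_isodisomy",
                                                   "father_heterodisomy")),
                   seed = 13)
  sim <- simulate_trio(spec)
  together <- call_upd(sim$trio, verbose = FALSE)
  apart <- dplyr::bind_rows(
    call_upd(sim$trio[sim$trio$chrom == "chr1", ], verbose = FALSE),
    call_upd(sim$trio[sim$trio$chrom == "chr2", ], verbose = FALSE)
  )
  coord_cols <- c("chrom", "start", "end", "state", "n_snps",
                  "n_mendelian_errors", "log_likelihood_ratio", "p_value")
  expect_equal(as.data.frame(together[, coord_cols]),
               as.data.frame(apart[, coord_cols]))
})

test_that("events never overlap and SNP counts partition the non-normal path", {
  spec <- sim_spec(chrom_lengths = c(chr1 = 4e6),
                   implants = data.frame(chrom = "chr1",
                                         start = c(2e5, 2e6),
                                         end = c(1e6, 3e6),
                                         state = c("father_isodisomy",
                                                   "mother_heterodisomy")),
                   seed = 77)
  sim <- simulate_trio(spec)
  trio <- apply_qc(sim$trio)
  model <- build_hmm()
  calls <- call_upd(trio, model = model, qc = FALSE, verbose = FALSE)
  calls <- calls[order(calls$start), ]
  if (nrow(calls) > 1)
    expect_true(all(calls$start[-1] > calls$end[-nrow(calls)]))
  path <- viterbi_decode(model, encode_observations(trio))
  expect_equal(sum(calls$n_snps), sum(path$labels != "normal"))
})

test_that("events tables round-trip through TSV", {
  spec <- sim_spec(chrom_lengths = c(chr1 = 3e6),
                   implants = data.frame(chrom = "chr1", start = 5e5,
                                         end = 2e6,
                                         state = "mother_heterodisomy"),
                   seed = 2)
  calls <- call_upd(simulate_trio(spec)$trio, verbose = FALSE)
  path <- tempfile(fileext = ".tsv")
  write_events(calls, path)
  back <- read_events(path)
  expect_equal(as.data.frame(back), as.data.frame(calls))
})
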