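test_that("Mendelian transmission distribution enumerates correctly", {
  expect_equal(mendelian_proband_distribution(1, 1), c(0.25, 0.5, 0.25))
  expect_equal(mendelian_proband_distribution(0, 0), c(1, 0, 0))
  expect_equal(mendelian_proband_distribution(2, 0), c(0, 1, 0))
  expect_equal(mendelian_proband_distribution(2, 1), c(0, 0.5, 0.5))
  for (gf in 0:2) for (gm in 0:2)
    expect_equal(sum(mendelian_proband_distribution(gf, gm)), 1)
})

test_that("UPD distributions follow iso/hetero transmission rules", {
  expect_equal(upd_proband_distribution("father_isodisomy", 1, 0),
               c(0.5, 0, 0.5))
  expect_equal(upd_proband_distribution("father_heterodisomy", 1, 2),
               c(0, 1, 0))
  expect_equal(upd_proband_distribution("mother_isodisomy", 2, 0),
               c(1, 0, 0))
  expect_equal(upd_proband_distribution("mother_heterodisomy", 0, 2),
               c(0, 0, 1))
  # the non-contributing parent never alters the distribution
  for (st in upd_states()[-1]) for (g in 0:2) for (other in 0:2) {
    if (startsWith(st, "father")) {
      expect_equal(upd_proband_distribution(st, g, other),
                   upd_proband_distribution(st, g, 0))
    } else {
      expect_equal(upd_proband_distribution(st, other, g),
                   upd_proband_distribution(st, 0, g))
    }
  }
})

test_that("model construction smooths, normalizes and logs correctly", {
  m <- build_hmm(epsilon = 0.05, tau = 1e-6)
  # impossible-under-Mendelian observation gets exactly epsilon/3
  expect_equal(exp(m$log_emission["normal", encode_trio_code(0, 0, 1) + 1]),
               0.05 / 3)
  # all entries finite
  expect_true(all(is.finite(m$log_emission)))
  expect_true(all(is.finite(m$log_transition)))
  # conditional emission normalization over the proband genotype,
  # for every state x parental combination
  for (s in m$states) for (gf in 0:2) for (gm in 0:2) {
    cols <- encode_trio_code(gf, gm, 0:2) + 1
    expect_equal(sum(exp(m$log_emission[s, cols])), 1, tolerance = 1e-12)
  }
  # transition rows and initial distribution are probability vectors
  expect_equal(unname(rowSums(exp(m$log_transition))), rep(1, 5),
               tolerance = 1e-12)
  expect_equal(sum(exp(m$log_initial)), 1, tolerance = 1e-12)
  expect_equal(exp(m$log_transition[2, 2]), 1 - 4e-6)
  expect_equal(exp(m$log_initial[["father_isodisomy"]]), 1e-6)
})

test_that("out-of-range model parameters are rejected", {
  expect_error(build_hmm(epsilon = 0), "epsilon")
  expect_error(build_hmm(epsilon = 0.5), "epsilon")
  expect_error(build_hmm(tau = 0.2), "tau")
  expect_error(build_hmm(tau = 0), "tau")
})

test_that("Viterbi matches exhaustive path enumeration on short sequences", {
  withr::with_seed(42, {
    for (i in 1:40) {
      model <- if (i %% 2) random_hmm() else
        build_hmm(epsilon = runif(1, 0.01, 0.3), tau = runif(1, 1e-8, 0.05))
      n <- sample(0:8, 1)
      obs <- sample(0:26, n, replace = TRUE)
      got <- viterbi_decode(model, obs)
      want <- brute_force_viterbi(model, obs)
      expect_equal(got$log_joint, want$log_joint, tolerance = 1e-9)
      expect_equal(got$path, want$path)
    }
  })
})

test_that("Viterbi agrees with an independent R decoder on long sequences", {
  withr::with_seed(7, {
    model <- build_hmm()
    obs <- sample(0:26, 3000, replace = TRUE)
    got <- viterbi_decode(model, obs)
    want <- r_viterbi(model, obs)
    expect_equal(got$log_joint, want$log_joint, tolerance = 1e-8)
    expect_equal(got$path, want$path)
  })
})

test_that("empty observation sequences decode to an empty path", {
  p <- viterbi_decode(build_hmm(), integer(0))
  expect_length(p$path, 0)
  expect_equal(p$log_joint, 0)
})

test_that("a sustained heterodisomy-favoured signal is decoded as UPD", {
  # (gf=1, gm=1, gp=1): emission 0.95 + eps/3 under father_heterodisomy vs
  # 0.475 + eps/3 under normal; over 100 sites the per-site ratio dwarfs the
  # 1e-6 initial penalty. mother_heterodisomy ties exactly, so the
  # tie-break toward the lower state index decides the label.
  m <- build_hmm()
  p100 <- viterbi_decode(m, rep(encode_trio_code(1, 1, 1), 100))
  expect_equal(unique(p100$labels), "father_heterodisomy")
  expect_equal(p100$log_joint, r_viterbi(m, rep(13L, 100))$log_joint,
               tolerance = 1e-9)
  # a handful of sites cannot pay the switch penalty: stays normal
  p3 <- viterbi_decode(m, rep(encode_trio_code(1, 1, 1), 3))
  expect_equal(unique(p3$labels), "normal")
})

test_that("decoding is deterministic and symmetric in the parents", {
  withr::with_seed(99, {
    model <- build_hmm()
    dec <- decode_trio_code(sample(0:26, 500, replace = TRUE))
    obs <- encode_trio_code(dec$gt_father, dec$gt_mother, dec$gt_proband)
    swapped <- encode_trio_code(dec$gt_mother, dec$gt_father, dec$gt_proband)
    a <- viterbi_decode(model, obs)
    b <- viterbi_decode(model, obs)
    expect_identical(a$path, b$path)
    # father<->mother swap exchanges paternal and maternal state labels
    swap_map <- c(normal = "normal",
                  father_isodisomy = "mother_isodisomy",
                  father_heterodisomy = "mother_heterodisomy",
                  mother_isodisomy = "father_isodisomy",
                  mother_heterodisomy = "father_heterodisomy")
    s <- viterbi_decode(model, swapped)
    expect_equal(unname(swap_map[a$labels]), s$labels)
    expect_equal(a$log_joint, s$log_joint, tolerance = 1e-9)
  })
})

test_that("single-state emission log-likelihood sums and decomposes", {
  m <- build_hmm(epsilon = 0.05)
  expect_equal(path_emission_loglik(m, integer(0), "normal"), 0)
  expect_equal(path_emission_loglik(m, c(5L, 7L), "normal", from = 2, to = 1),
               0)
  expect_equal(path_emission_loglik(m, 0L, "normal"),
               log(0.95 + 0.05 / 3))
  withr::with_seed(3, {
    obs <- sample(0:26, 30, replace = TRUE)
    for (st in c("normal", "mother_isodisomy")) {
      expect_equal(
        path_emission_loglik(m, obs, st, 1, 30),
        path_emission_loglik(m, obs, st, 1, 12) +
          path_emission_loglik(m, obs, st, 13, 30))
    }
  })
})

test_that("a model round-trips through its plain-text dump", {
  m <- build_hmm(epsilon = 0.07, tau = 3e-6)
  path <- tempfile(fileext = ".hmm")
  write_hmm(m, path)
  m2 <- read_hmm(path)
  expect_equal(m2$epsilon, m$epsilon)
  expect_equal(m2$tau, m$tau)
  expect_equal(m2$log_emission, m$log_emission)
  expect_equal(m2$log_transition, m$log_transition)
  withr::with_seed(5, {
    obs <- sample(0:26, 200, replace = TRUE)
    expect_identical(viterbi_decode(m, obs)$path,
                     viterbi_decode(m2, obs)$path)
  })
})
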