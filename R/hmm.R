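#' Inheritance states of the trio HMM
#'
#' The hidden alphabet of the model: Mendelian (biparental) inheritance plus
#' the four uniparental-disomy states. Isodisomy means both proband homologs
#' derive from the *same* parental chromosome (the proband is homozygous
#' wherever that parent is informative); heterodisomy means the proband
#' carries *both* homologs of one parent (the proband mirrors that parent's
#' genotype). State order is fixed, with `"normal"` first; ties during
#' decoding resolve toward the earlier state.
#'
#' @return Character vector of the five state labels.
#' @export
#' @examples
#' upd_states()
upd_states <- function() {
  c("normal",
    "father_isodisomy", "father_heterodisomy",
    "mother_isodisomy", "mother_heterodisomy")
}

#' Encode / decode a trio genotype combination
#'
#' A site's observation is the ordered triple (father, mother, proband) of
#' alternate-allele dosages in `{0, 1, 2}`, packed into a single code
#' `gf * 9 + gm * 3 + gp` in `[0, 26]`. The packing is bijective over the 27
#' triples.
#'
#' @param gt_father,gt_mother,gt_proband Integer genotype codes in `{0, 1, 2}`
#'   (number of alternate alleles). Vectorised.
#' @param code Integer observation code(s) in `[0, 26]`.
#' @return `encode_trio_code()`: integer codes. `decode_trio_code()`: a tibble
#'   with columns `gt_father`, `gt_mother`, `gt_proband`.
#' @export
#' @examples
#' encode_trio_code(1, 0, 1) # 10
#' decode_trio_code(0:26)
encode_trio_code <- function(gt_father, gt_mother, gt_proband) {
  stopifnot(all(gt_father %in% 0:2), all(gt_mother %in% 0:2),
            all(gt_proband %in% 0:2))
  as.integer(gt_father * 9L + gt_mother * 3L + gt_proband)
}

#' @rdname encode_trio_code
#' @export
decode_trio_code <- function(code) {
  stopifnot(all(code %in% 0:26))
  code <- as.integer(code)
  tibble(gt_father = code %/% 9L,
         gt_mother = (code %/% 3L) %% 3L,
         gt_proband = code %% 3L)
}

#' Proband genotype distribution under Mendelian inheritance
#'
#' Probability of each proband alternate-allele dosage when one allele is
#' transmitted uniformly at random from each parent (biparental inheritance).
#'
#' @param gt_father,gt_mother Parental genotype codes in `{0, 1, 2}` (scalars).
#' @return Numeric length-3 vector `P(gp = 0), P(gp = 1), P(gp = 2)`,
#'   summing to 1.
#' @export
#' @examples
#' mendelian_proband_distribution(1, 1) # 0.25 0.50 0.25
mendelian_proband_distribution <- function(gt_father, gt_mother) {
  stopifnot(length(gt_father) == 1L, length(gt_mother) == 1L,
            gt_father %in% 0:2, gt_mother %in% 0:2)
  pf <- gt_father / 2   # P(father transmits alt)
  pm <- gt_mother / 2
  c((1 - pf) * (1 - pm),
    pf * (1 - pm) + (1 - pf) * pm,
    pf * pm)
}

#' Proband genotype distribution under a UPD state
#'
#' Under isodisomy one allele of the contributing parent is duplicated: the
#' proband is homozygous ref or hom-alt, each with probability 1/2 when that
#' parent is heterozygous. Under heterodisomy both homologs of the
#' contributing parent are transmitted, so the proband's genotype equals that
#' parent's genotype. The non-contributing parent never alters the
#' distribution.
#'
#' @param state One of the four non-normal labels from [upd_states()].
#' @param gt_father,gt_mother Parental genotype codes in `{0, 1, 2}` (scalars).
#' @return Numeric length-3 probability vector over the proband dosage.
#' @export
#' @examples
#' upd_proband_distribution("father_isodisomy", 1, 0)    # 0.5 0.0 0.5
#' upd_proband_distribution("father_heterodisomy", 1, 2) # 0 1 0
upd_proband_distribution <- function(state, gt_father, gt_mother) {
  state <- match.arg(state, upd_states()[-1])
  g <- if (startsWith(state, "father")) gt_father else gt_mother
  stopifnot(length(g) == 1L, g %in% 0:2)
  if (endsWith(state, "isodisomy")) {
    switch(g + 1L, c(1, 0, 0), c(0.5, 0, 0.5), c(0, 0, 1))
  } else {
    switch(g + 1L, c(1, 0, 0), c(0, 1, 0), c(0, 0, 1))
  }
}

#' Build the five-state inheritance HMM
#'
#' Emissions are conditional on the parental genotypes:
#' `P(gp | gf, gm, state) = (1 - epsilon) * d_state(gp | gf, gm) + epsilon / 3`,
#' where `d_state` is the Mendelian transmission distribution for the normal
#' state and the iso-/heterodisomy distribution otherwise. The uniform
#' `epsilon` mixture absorbs genotyping errors so no observation has zero
#' probability under any state. The state-independent parental prior
#' `P(gf, gm)` would multiply every state identically and cancels in path
#' comparisons and likelihood ratios, so it is omitted (no population allele
#' frequencies required).
#'
#' Transitions are per *variant site*: stay with probability `1 - 4 * tau`,
#' switch to each of the other four states with probability `tau`. The
#' initial distribution puts `init_upd` on each UPD state. Everything is
#' stored in natural-log space.
#'
#' @param epsilon Genotyping-error smoothing rate, in (0, 0.5). Default 0.05.
#' @param tau Per-site state-switch probability, in (0, 0.1). Default 1e-6;
#'   together with the per-site emission ratios it sets the effective minimum
#'   event length.
#' @param init_upd Initial probability of each UPD state. Default 1e-6.
#' @return An object of class `upd_hmm`: list with `states`, `log_initial`
#'   (length 5), `log_transition` (5 x 5), `log_emission` (5 x 27, columns
#'   indexed by observation code + 1), `epsilon`, `tau`.
#' @seealso [viterbi_decode()], [tidy.upd_hmm()]
#' @export
#' @examples
#' m <- build_hmm()
#' exp(m$log_emission["normal", encode_trio_code(0, 0, 1) + 1]) # 0.05/3
build_hmm <- function(epsilon = 0.05, tau = 1e-6, init_upd = 1e-6) {
  if (!is.numeric(epsilon) || length(epsilon) != 1L ||
      epsilon <= 0 || epsilon >= 0.5)
    abort("`epsilon` must be a single number in (0, 0.5).")
  if (!is.numeric(tau) || length(tau) != 1L || tau <= 0 || tau >= 0.1)
    abort("`tau` must be a single number in (0, 0.1).")
  if (!is.numeric(init_upd) || length(init_upd) != 1L ||
      init_upd <= 0 || init_upd >= 0.25)
    abort("`init_upd` must be a single number in (0, 0.25).")

  states <- upd_states()
  S <- length(states)

  emission <- matrix(NA_real_, nrow = S, ncol = 27,
                     dimnames = list(states, as.character(0:26)))
  for (gf in 0:2) {
    for (gm in 0:2) {
      cols <- encode_trio_code(gf, gm, 0:2) + 1L
      for (s in seq_along(states)) {
        d <- if (states[s] == "normal") {
          mendelian_proband_distribution(gf, gm)
        } else {
          upd_proband_distribution(states[s], gf, gm)
        }
        emission[s, cols] <- (1 - epsilon) * d + epsilon / 3
      }
    }
  }

  transition <- matrix(tau, S, S, dimnames = list(states, states))
  diag(transition) <- 1 - (S - 1) * tau

  initial <- setNames(rep(init_upd, S), states)
  initial["normal"] <- 1 - (S - 1) * init_upd

  structure(
    list(states = states,
         log_initial = log(initial),
         log_transition = log(transition),
         log_emission = log(emission),
         epsilon = epsilon,
         tau = tau),
    class = "upd_hmm"
  )
}

#' @export
print.upd_hmm <- function(x, ...) {
  cat("<upd_hmm> 5-state trio inheritance model\n")
  cat("  states: ", paste(x$states, collapse = ", "), "\n", sep = "")
  cat(sprintf("  epsilon = %g, tau = %g\n", x$epsilon, x$tau))
  invisible(x)
}

#' Decode the most likely inheritance path
#'
#' Viterbi decoding of the maximum-a-posteriori joint state path, computed in
#' log space. Ties are broken toward the lower state index, so the normal
#' state is preferred when paths are equally likely. Decoding is
#' deterministic.
#'
#' @param model An [build_hmm()] model.
#' @param obs Integer observation codes in `[0, 26]` (one chromosome's sites,
#'   in positional order). May be empty.
#' @return An object of class `upd_path`: list with `path` (integer state
#'   indices, 1 = normal, aligned to `obs`), `labels` (the state names), and
#'   `log_joint`, the log probability of (path, observations). An empty input
#'   gives an empty path with `log_joint = 0`.
#' @export
#' @examples
#' m <- build_hmm()
#' viterbi_decode(m, encode_trio_code(c(1, 1), c(1, 1), c(1, 1)))$labels
viterbi_decode <- function(model, obs) {
  stopifnot(inherits(model, "upd_hmm"))
  obs <- as.integer(obs)
  if (anyNA(obs) || (length(obs) && (min(obs) < 0L || max(obs) > 26L)))
    abort("Observation codes must be integers in [0, 26].")
  res <- viterbi_cpp(model$log_initial, model$log_transition,
                     model$log_emission, obs)
  structure(
    list(path = res$path + 1L,
         labels = model$states[res$path + 1L],
         log_joint = res$log_joint),
    class = "upd_path"
  )
}

#' @export
print.upd_path <- function(x, ...) {
  cat(sprintf("<upd_path> %d sites, log joint = %.4f\n",
              length(x$path), x$log_joint))
  if (length(x$path)) {
    r <- rle(x$labels)
    cat("  blocks: ",
        paste(sprintf("%s x%d", r$values, r$lengths), collapse = " | "),
        "\n", sep = "")
  }
  invisible(x)
}

#' Emission log-likelihood of a range under a single state
#'
#' Sum of log emission probabilities of `obs[from:to]` under one fixed state;
#' the additive building block of the event likelihood-ratio statistic. An
#' empty range (`from > to`) contributes 0.
#'
#' @param model An [build_hmm()] model.
#' @param obs Integer observation codes in `[0, 26]`.
#' @param state A state label from [upd_states()].
#' @param from,to 1-based index range into `obs` (inclusive).
#' @return A single log probability.
#' @export
path_emission_loglik <- function(model, obs, state,
                                 from = 1L, to = length(obs)) {
  stopifnot(inherits(model, "upd_hmm"))
  state <- match.arg(state, model$states)
  if (from > to) return(0)
  stopifnot(from >= 1L, to <= length(obs))
  idx <- as.integer(obs[from:to])
  stopifnot(all(idx >= 0L & idx <= 26L))
  sum(model$log_emission[state, idx + 1L])
}

#' Dump / load an HMM as a plain-text key-value file
#'
#' Serialises the model parameters (and the derived log matrices, at full
#' precision) so a run's exact model travels with its results.
#'
#' @param model An `upd_hmm` object.
#' @param path File path.
#' @return `write_hmm()` returns `path` invisibly; `read_hmm()` returns an
#'   `upd_hmm`.
#' @export
write_hmm <- function(model, path) {
  stopifnot(inherits(model, "upd_hmm"))
  num <- function(x) paste(format(x, digits = 17L, scientific = TRUE),
                           collapse = " ")
  lines <- c(
    paste0("states=", paste(model$states, collapse = " ")),
    paste0("epsilon=", num(model$epsilon)),
    paste0("tau=", num(model$tau)),
    paste0("log_initial=", num(model$log_initial)),
    paste0("log_transition=", num(as.vector(model$log_transition))),
    paste0("log_emission=", num(as.vector(model$log_emission)))
  )
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_hmm
#' @export
read_hmm <- function(path) {
  lines <- readLines(path)
  kv <- strsplit(lines, "=", fixed = TRUE)
  vals <- setNames(lapply(kv, function(x) strsplit(x[2], " ")[[1]]),
                   vapply(kv, `[`, "", 1L))
  states <- vals$states
  S <- length(states)
  model <- list(
    states = states,
    log_initial = setNames(as.numeric(vals$log_initial), states),
    log_transition = matrix(as.numeric(vals$log_transition), S, S,
                            dimnames = list(states, states)),
    log_emission = matrix(as.numeric(vals$log_emission), S, 27,
                          dimnames = list(states, as.character(0:26))),
    epsilon = as.numeric(vals$epsilon),
    tau = as.numeric(vals$tau)
  )
  structure(model, class = "upd_hmm")
}
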