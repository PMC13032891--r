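#' Tidy the emission distributions of a trio inheritance HMM
#'
#' @param x An `upd_hmm` from [build_hmm()].
#' @param ... Unused.
#' @return A tibble with one row per (state, trio genotype combination):
#'   `state`, `gt_father`, `gt_mother`, `gt_proband`, `probability`
#'   (`P(gp | gf, gm, state)`, epsilon-smoothed).
#' @export
tidy.upd_hmm <- function(x, ...) {
  combos <- decode_trio_code(0:26)
  purrr::map_dfr(x$states, function(s) {
    dplyr::mutate(combos, state = s,
                  probability = unname(exp(x$log_emission[s, ])),
                  .before = 1)
  })
}

#' @rdname tidy.upd_hmm
#' @export
glance.upd_hmm <- function(x, ...) {
  tibble(n_states = length(x$states),
         epsilon = x$epsilon,
         tau = x$tau,
         log_stay = x$log_transition[1, 1],
         log_switch = x$log_transition[1, 2])
}

#' Tidy benchmark results
#'
#' @param x An `upd_benchmark` from [benchmark_sensitivity()].
#' @param ... Unused.
#' @return `tidy()`: the per-cell summary tibble. `glance()`: one row with
#'   `n_events`, overall `sensitivity` (fraction of truth events matched in
#'   type + origin + chromosome), `frac_overlap_90` (fraction of *matched*
#'   events whose coordinates overlap truth by >= 0.9) and total
#'   `false_positives`.
#' @export
tidy.upd_benchmark <- function(x, ...) x$summary

#' @rdname tidy.upd_benchmark
#' @export
glance.upd_benchmark <- function(x, ...) {
  ev <- x$events
  matched <- ev[ev$matched, ]
  tibble(
    n_events = nrow(ev),
    sensitivity = if (nrow(ev)) mean(ev$matched) else NA_real_,
    frac_overlap_90 = if (nrow(matched))
      mean(matched$overlap_fraction >= 0.9) else NA_real_,
    false_positives = sum(ev$false_positive_count[!duplicated(
      paste(ev$size, ev$state, ev$replicate))])
  )
}

#' @rdname score_run
#' @param x An `upd_eval`.
#' @param ... Unused.
#' @export
tidy.upd_eval <- function(x, ...) x$events
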