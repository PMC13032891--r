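upd_state_palette <- c(
  father_isodisomy = "#1b6ca8",
  father_heterodisomy = "#73b7e8",
  mother_isodisomy = "#b6174b",
  mother_heterodisomy = "#f08bab"
)

#' Plot called UPD events along chromosomes
#'
#' One horizontal track per chromosome with events drawn as coloured segments
#' (paternal states in blues, maternal in reds).
#'
#' @param object A `upd_calls` tibble from [call_upd()].
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.upd_calls <- function(object, ...) {
  df <- as_tibble(object)
  ggplot2::ggplot(df) +
    ggplot2::geom_segment(
      ggplot2::aes(x = .data$start / 1e6, xend = .data$end / 1e6,
                   y = .data$chrom, yend = .data$chrom,
                   colour = .data$state),
      linewidth = 4, lineend = "butt"
    ) +
    ggplot2::scale_colour_manual(values = upd_state_palette, name = NULL) +
    ggplot2::labs(x = "position (Mb)", y = NULL,
                  title = "Called UPD events") +
    ggplot2::theme_minimal()
}

#' Plot benchmark sensitivity by implant size
#'
#' @param object An `upd_benchmark` from [benchmark_sensitivity()].
#' @param ... Unused.
#' @return A ggplot of sensitivity against implant size, one line per UPD
#'   state.
#' @export
autoplot.upd_benchmark <- function(object, ...) {
  ggplot2::ggplot(object$summary,
                  ggplot2::aes(x = .data$size / 1e6, y = .data$sensitivity,
                               colour = .data$state)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::scale_x_log10() +
    ggplot2::scale_colour_manual(values = upd_state_palette, name = NULL) +
    ggplot2::labs(x = "implant size (Mb)", y = "sensitivity",
                  title = "Detection sensitivity by event size") +
    ggplot2::theme_minimal()
}

#' Plot the emission model as a heat map
#'
#' Proband-genotype emission probabilities for each inheritance state and
#' parental genotype combination.
#'
#' @param object An `upd_hmm`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.upd_hmm <- function(object, ...) {
  df <- tidy(object)
  df$parents <- paste0(df$gt_father, "x", df$gt_mother)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$parents,
                                   y = factor(.data$gt_proband),
                                   fill = .data$probability)) +
    ggplot2::geom_tile() +
    ggplot2::facet_wrap(~state, ncol = 1) +
    ggplot2::scale_fill_viridis_c(limits = c(0, 1)) +
    ggplot2::labs(x = "father x mother genotype", y = "proband genotype",
                  fill = "P(gp | gf, gm, state)") +
    ggplot2::theme_minimal()
}
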