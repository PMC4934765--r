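#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' Tidy an interaction-energy profile into a long bin table
#'
#' @param x an `energy_profile`.
#' @param ... unused.
#' @return Tibble with bin midpoints and the distribution / lowest-cluster
#'   counts.
#' @export
tidy.energy_profile <- function(x, ...) {
  mids <- (utils::head(x$edges, -1) + utils::tail(x$edges, -1)) / 2
  tibble(bin_mid = mids,
         bin_lo = utils::head(x$edges, -1),
         bin_hi = utils::tail(x$edges, -1),
         distribution = x$dist_counts,
         lowest_cluster = x$cluster_counts)
}

#' Overlaid histogram plot of an interaction-energy profile
#'
#' Mirrors the standard presentation: the full distribution behind, the
#' most stabilising cluster in front on the same bin boundaries.
#'
#' @param object an `energy_profile`.
#' @param ... unused.
#' @return A ggplot object.
#' @export
autoplot.energy_profile <- function(object, ...) {
  tb <- tidy.energy_profile(object)
  long <- tidyr::pivot_longer(tb, c("distribution", "lowest_cluster"),
                              names_to = "set", values_to = "count")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$bin_mid, y = .data$count,
                                     fill = .data$set)) +
    ggplot2::geom_col(position = "identity", alpha = 0.65,
                      width = diff(object$edges)[1]) +
    ggplot2::scale_fill_manual(values = c(distribution = "#D55E88",
                                          lowest_cluster = "#3355BB")) +
    ggplot2::labs(x = "interaction energy (kJ/mol)", y = "dimer count",
                  fill = NULL,
                  title = if (!is.na(object$eps_r))
                    paste0("energy profile, eps_r = ", object$eps_r)
                  else "energy profile") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy the verdicts of a readout study
#' @param x a `readout_study`.
#' @param ... unused.
#' @return The verdict tibble.
#' @export
tidy.readout_study <- function(x, ...) x$verdicts

#' One-line summary of a readout study
#' @param x a `readout_study`.
#' @param ... unused.
#' @return Tibble with entry, dimer and verdict counts.
#' @export
glance.readout_study <- function(x, ...) {
  tibble(n_entries = nrow(x$entries),
         n_dimers = length(unique(paste(x$dimer_table$structure_id,
                                        x$dimer_table$chain,
                                        x$dimer_table$aa_resno,
                                        x$dimer_table$base))),
         n_clustered = sum(!is.na(x$dimer_table$cluster) &
                             x$dimer_table$eps_r ==
                             x$params$media[1]),
         n_strong = sum(x$verdicts$grade == "strong"),
         n_ambiguous = sum(x$verdicts$grade == "ambiguous"))
}
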