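# ggplot2 displays for the main result types.

#' @export
autoplot.sfs <- function(object, cumulative = FALSE, ...) {
  d <- tidy(object)
  d$prop <- d$n_sites / sum(d$n_sites)
  if (cumulative) {
    d$cum <- cumsum(d$prop)
    ggplot2::ggplot(d, ggplot2::aes(.data$allele_count, .data$cum)) +
      ggplot2::geom_step() +
      ggplot2::labs(x = if (object$folded) "minor-allele count" else "derived-allele count",
                    y = "cumulative proportion of sites")
  } else {
    ggplot2::ggplot(d, ggplot2::aes(.data$allele_count, .data$prop)) +
      ggplot2::geom_col(width = 0.9) +
      ggplot2::labs(x = if (object$folded) "minor-allele count" else "derived-allele count",
                    y = "proportion of segregating sites")
  }
}

#' @export
autoplot.rate_grid <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(.data$rate, .data$e_rare)) +
    ggplot2::geom_pointrange(ggplot2::aes(ymin = .data$e_rare - 2 * .data$e_rare_se,
                                          ymax = .data$e_rare + 2 * .data$e_rare_se)) +
    ggplot2::geom_line() +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "mutation rate (per bp per generation per haploid)",
                  y = "fraction of rare variants among biallelic sites")
}

#' Plot per-stratum rare fractions with bootstrap intervals
#'
#' @param strata Output of [stratified_rare_fraction()].
#' @return A ggplot.
#' @export
plot_stratified_rare <- function(strata) {
  ggplot2::ggplot(strata, ggplot2::aes(.data$stratum, .data$rare_fraction)) +
    ggplot2::geom_pointrange(ggplot2::aes(ymin = .data$ci_lo, ymax = .data$ci_hi)) +
    ggplot2::labs(x = "stratum", y = "fraction of rare variants") +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' Plot substituted-species coefficients against split times
#'
#' @param fit A `rare_logit`.
#' @param branches Lineage table with `species` and `split_years`.
#' @param block `"ns"` or `"syn"`.
#' @return A ggplot.
#' @export
plot_species_trend <- function(fit, branches = primate_branches(),
                               block = c("ns", "syn")) {
  block <- match.arg(block)
  co <- dplyr::filter(tidy(fit), .data$block == paste0("species_", block))
  d <- dplyr::inner_join(co, branches, by = "species")
  ggplot2::ggplot(d, ggplot2::aes(.data$split_years, .data$estimate)) +
    ggplot2::geom_pointrange(ggplot2::aes(ymin = .data$estimate - 2 * .data$std_error,
                                          ymax = .data$estimate + 2 * .data$std_error)) +
    ggplot2::geom_smooth(method = "lm", formula = y ~ x, se = FALSE) +
    ggplot2::geom_text(ggplot2::aes(label = .data$species), vjust = -1, size = 3) +
    ggplot2::labs(x = "split time from human (years)",
                  y = sprintf("%s log-odds of being rare vs human-private", block))
}
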