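# Stratified rare-variant summaries with bootstrap confidence intervals.

#' Rare-variant fraction per stratum of a covariate, with bootstrap CI
#'
#' Sites are grouped by a covariate (mutation type, strand class, chromatin
#' state, recombination rate, ...). Categorical covariates define strata
#' directly; continuous covariates are first standardized by their mean over
#' all input sites and then binned on a log scale. Per stratum the function
#' reports the fraction of rare sites (minor-allele count at most
#' `rare_max_count`) and a seeded percentile bootstrap 95% confidence
#' interval obtained by resampling sites with replacement within the stratum.
#'
#' @param sites Data frame with a `minor_count` column (or a logical `rare`
#'   column) and the covariate column.
#' @param covariate Covariate column (tidy evaluation).
#' @param n_bins Number of log-spaced bins for a continuous covariate.
#' @param rare_max_count Largest minor-allele count counted as rare.
#' @param n_bootstrap Number of bootstrap replicates.
#' @param seed Integer seed for the bootstrap.
#' @param conf_level Confidence level of the percentile interval.
#' @return A tibble with per-stratum `n_sites`, `rare_fraction`, `ci_lo`,
#'   `ci_hi` and a `ci_undefined` flag for strata with fewer than 2 sites.
#' @export
stratified_rare_fraction <- function(sites, covariate, n_bins = 10,
                                     rare_max_count = 2, n_bootstrap = 1000,
                                     seed = 1L, conf_level = 0.95) {
  stopifnot(n_bootstrap >= 1)
  cov <- dplyr::pull(sites, {{ covariate }})
  rare <- if ("rare" %in% names(sites)) as.logical(sites$rare) else
    sites$minor_count <= rare_max_count
  if (anyNA(rare)) stop("rare status could not be determined for all sites")

  if (is.numeric(cov)) {
    std <- cov / mean(cov)
    stratum <- cut(std, breaks = log_bins(std, n_bins), include.lowest = TRUE)
  } else {
    stratum <- as.factor(cov)
  }

  tab <- tibble::tibble(stratum = stratum, rare = rare) |>
    dplyr::filter(!is.na(.data$stratum)) |>
    dplyr::group_by(.data$stratum) |>
    dplyr::summarise(n_sites = dplyr::n(), n_rare = sum(.data$rare)) |>
    dplyr::mutate(rare_fraction = .data$n_rare / .data$n_sites)

  # Percentile bootstrap. Resampling sites with replacement within a stratum
  # and recomputing the rare fraction is a draw from Binomial(n, p_hat)/n,
  # which is sampled directly.
  set.seed(seed)
  alpha <- (1 - conf_level) / 2
  ci <- purrr::map2(tab$n_sites, tab$rare_fraction, function(n, p) {
    if (n < 2) return(c(NA_real_, NA_real_))
    reps <- rbinom(n_bootstrap, n, p) / n
    quantile(reps, c(alpha, 1 - alpha), names = FALSE, type = 1)
  })
  tab |>
    dplyr::mutate(
      ci_lo = purrr::map_dbl(ci, 1),
      ci_hi = purrr::map_dbl(ci, 2),
      ci_undefined = .data$n_sites < 2
    ) |>
    dplyr::select(-"n_rare")
}
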