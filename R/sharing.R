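# Cross-population sharing of polymorphisms.

#' Log-spaced bin edges covering a positive range
#'
#' @param x Positive numeric values to cover.
#' @param n_bins Number of bins.
#' @return Numeric vector of `n_bins + 1` strictly increasing edges.
#' @export
log_bins <- function(x, n_bins = 10) {
  x <- x[is.finite(x) & x > 0]
  stopifnot(length(x) > 0, n_bins >= 1)
  r <- range(x)
  if (r[1] == r[2]) r <- r * c(0.999, 1.001)
  edges <- 10^seq(log10(r[1]), log10(r[2]), length.out = n_bins + 1)
  edges[1] <- edges[1] * (1 - 1e-9)
  edges[n_bins + 1] <- edges[n_bins + 1] * (1 + 1e-9)
  edges
}

#' Sharing of polymorphisms between two subpopulations, by allele count
#'
#' For each bin of the combined minor-allele count, computes the fraction of
#' sites whose minor allele is observed (count > 0) in both subpopulations.
#' Bins with no sites are reported with `NA` sharing rather than zero.
#'
#' @param sites Data frame with per-site minor-allele counts in the two
#'   subpopulations, columns `count_a` and `count_b`.
#' @param bins Numeric vector of bin edges for the combined count
#'   `count_a + count_b`; defaults to [log_bins()] over the observed counts.
#' @param n_bins Number of log-spaced bins used when `bins` is `NULL`.
#' @return A tibble with one row per bin: `bin`, `count_lo`, `count_hi`,
#'   `n_sites`, `sharing`.
#' @export
sharing_by_count <- function(sites, bins = NULL, n_bins = 10) {
  stopifnot(all(c("count_a", "count_b") %in% names(sites)))
  total <- sites$count_a + sites$count_b
  if (any(total <= 0)) stop("each site must carry at least one minor-allele copy")
  if (is.null(bins)) bins <- log_bins(total, n_bins)
  idx <- cut(total, breaks = bins, labels = FALSE, include.lowest = TRUE)
  shared <- sites$count_a > 0 & sites$count_b > 0
  out <- tibble::tibble(
    bin = seq_len(length(bins) - 1L),
    count_lo = bins[-length(bins)],
    count_hi = bins[-1]
  )
  agg <- tibble::tibble(idx = idx, shared = shared) |>
    dplyr::filter(!is.na(.data$idx)) |>
    dplyr::group_by(.data$idx) |>
    dplyr::summarise(n_sites = dplyr::n(), sharing = mean(.data$shared))
  out |>
    dplyr::left_join(agg, by = c(bin = "idx")) |>
    dplyr::mutate(n_sites = dplyr::coalesce(.data$n_sites, 0L))
}
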