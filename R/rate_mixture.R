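# Lognormal within-mutation-type mutation-rate mixture and the
# total-expectation integral for the rare-variant fraction.
#
# log10 M ~ Normal(log10(mu) - sigma^2 * ln(10) / 2, sigma^2), the
# mean-preserving parameterization: E[M] = mu for every sigma.

#' Named reference values for the within-type rate spread
#'
#' `sigma_default` (0.57) is the working value used throughout;
#' `sigma_noncpg_hodgkinson` (0.83) and `sigma_cpg_hodgkinson` (0.8) are the
#' estimates of Hodgkinson et al. for non-CpG mutations and CpG transitions.
#' @export
sigma_reference <- c(sigma_default = 0.57,
                     sigma_noncpg_hodgkinson = 0.83,
                     sigma_cpg_hodgkinson = 0.8)

#' Construct a lognormal within-type rate mixture
#'
#' @param mu Mean mutation rate of the type (per bp per generation per
#'   haploid); `E[M] = mu` under the mixture.
#' @param sigma Standard deviation of `log10 M` (log10-rate units).
#' @return An object of class `rate_mixture`.
#' @examples
#' mix <- rate_mixture(1.2e-8, 0.57)
#' tail_prob(5, 0.57) # share of sites with > 5x the type mean rate
#' @export
rate_mixture <- function(mu, sigma = 0.57) {
  stopifnot(mu > 0, sigma >= 0)
  structure(list(mu = mu, sigma = sigma), class = "rate_mixture")
}

#' @export
print.rate_mixture <- function(x, ...) {
  cat(sprintf("<lognormal rate mixture> mu = %.4g, sigma = %.3g (log10 units)\n",
              x$mu, x$sigma))
  invisible(x)
}

#' Density g(M; mu) of the rate mixture
#'
#' @param M Vector of rates (> 0).
#' @param mixture A `rate_mixture`.
#' @return Density values.
#' @export
density_g <- function(M, mixture) {
  stopifnot(inherits(mixture, "rate_mixture"), all(M > 0))
  if (mixture$sigma == 0) {
    stop("sigma = 0 is a point mass at mu; density queries are not defined")
  }
  loc <- log10(mixture$mu) - mixture$sigma^2 * log(10) / 2
  dnorm(log10(M), loc, mixture$sigma) / (M * log(10))
}

#' Probability that a site's rate exceeds a multiple of the type mean
#'
#' `P(M > k * mu)` under the mean-preserving lognormal mixture; independent
#' of `mu`.
#'
#' @param k Fold threshold (> 0).
#' @param sigma Spread of `log10 M`.
#' @return Probability.
#' @export
tail_prob <- function(k, sigma = 0.57) {
  stopifnot(all(k > 0), sigma >= 0)
  if (sigma == 0) return(ifelse(k >= 1, 0, 1))
  1 - pnorm((log10(k) + sigma^2 * log(10) / 2) / sigma)
}

# integration grid in log10 M over +/- `span` sigmas around the
# mean-preserving location (falls back to a narrow window for tiny sigma)
mixture_grid <- function(mixture, span = 4, n_points = 512) {
  s <- max(mixture$sigma, 1e-3)
  lmu <- log10(mixture$mu)
  seq(lmu - span * s, lmu + span * s, length.out = n_points)
}

# log-linear interpolation of a positive grid quantity at log10-rate x
interp_log <- function(log10_rates, values, x) {
  lv <- log(pmax(values, 1e-300))
  exp(approx(log10_rates, lv, xout = x, rule = 1)$y)
}

check_grid_coverage <- function(grid, lx) {
  lr <- log10(grid$rate)
  lo <- min(lx); hi <- max(lx)
  if (lo < min(lr) - 1e-9 || hi > max(lr) + 1e-9) {
    stop(sprintf(paste0("rate grid covers [%.3g, %.3g] but the mixture ",
                        "integral needs [%.3g, %.3g]; extend the grid"),
                 min(grid$rate), max(grid$rate), 10^lo, 10^hi))
  }
}

#' Conditional rate density at biallelic polymorphic sites
#'
#' `f(M | S = 1; mu) = P(S = 1 | M) g(M; mu) / integral(P(S = 1 | M') g(M'; mu) dM')`:
#' Bayes conditioning of the rate mixture on the site being a biallelic
#' polymorphism, with `P(S = 1 | M)` log-linearly interpolated on the rate
#' grid.
#'
#' @param M Vector of rates at which to evaluate the density.
#' @param mixture A `rate_mixture`.
#' @param grid A `rate_grid` covering the integration range
#'   `[mu * 10^(-4 sigma), mu * 10^(4 sigma)]`.
#' @param span Truncation of the integral, in sigmas of `log10 M`.
#' @return Density values of `f(M | S = 1)`.
#' @export
conditional_density_f <- function(M, mixture, grid, span = 4) {
  stopifnot(inherits(mixture, "rate_mixture"), inherits(grid, "rate_grid"))
  lx <- mixture_grid(mixture, span)
  check_grid_coverage(grid, range(c(lx, log10(M))))
  lr <- log10(grid$rate)
  p_of <- function(x) interp_log(lr, grid$p_biallelic, x)
  # normalizer by trapezoid quadrature in log10 M (dM = M ln(10) dlog10M)
  xg <- 10^lx
  integrand <- p_of(lx) * density_g(xg, mixture) * xg * log(10)
  Z <- trapz(lx, integrand)
  p_of(log10(M)) * density_g(M, mixture) / Z
}

trapz <- function(x, y) sum(diff(x) * (head(y, -1) + tail(y, -1)) / 2)

#' Expected rare fraction under the rate mixture
#'
#' The law-of-total-expectation integral
#' `E[Y | S = 1; mu] = integral(E[Y | M, S = 1] f(M | S = 1; mu) dM)`,
#' evaluated by trapezoid quadrature in `log10 M` over
#' `[mu * 10^(-span * sigma), mu * 10^(span * sigma)]`, with both grid
#' factors log-linearly interpolated. For `sigma = 0` this degenerates to
#' the grid rare fraction interpolated at `mu`.
#'
#' @inheritParams conditional_density_f
#' @param n_points Number of quadrature nodes.
#' @return Expected fraction of rare variants among biallelic sites.
#' @export
mixture_rare_fraction <- function(mixture, grid, span = 4, n_points = 512) {
  stopifnot(inherits(mixture, "rate_mixture"), inherits(grid, "rate_grid"))
  lr <- log10(grid$rate)
  if (mixture$sigma == 0) {
    check_grid_coverage(grid, log10(mixture$mu))
    return(interp_log(lr, grid$e_rare, log10(mixture$mu)))
  }
  lx <- mixture_grid(mixture, span, n_points)
  check_grid_coverage(grid, range(lx))
  xg <- 10^lx
  g <- density_g(xg, mixture) * xg * log(10) # density in log10-M units
  p <- interp_log(lr, grid$p_biallelic, lx)
  e <- interp_log(lr, grid$e_rare, lx)
  trapz(lx, e * p * g) / trapz(lx, p * g)
}

#' Mixture rare-fraction curve over a set of type mean rates
#'
#' @param mus Vector of type mean rates.
#' @param grid A `rate_grid`.
#' @param sigma Within-type spread.
#' @param span,n_points Quadrature controls, see [mixture_rare_fraction()].
#' @return A tibble with columns `mu`, `sigma`, `e_rare_mixture`.
#' @export
mixture_curve <- function(mus, grid, sigma = 0.57, span = 4, n_points = 512) {
  vals <- purrr::map_dbl(mus, function(m) {
    mixture_rare_fraction(rate_mixture(m, sigma), grid, span, n_points)
  })
  tibble::tibble(mu = mus, sigma = sigma, e_rare_mixture = vals)
}

#' Least-squares recovery of the within-type spread sigma
#'
#' Fits `sigma` by grid search + golden-section refinement so that the
#' mixture rare-fraction curve matches observed per-type rare fractions.
#' This is an extension beyond the fixed working value of `sigma`.
#'
#' @param mus Type mean rates.
#' @param rare_fractions Observed rare fractions, parallel to `mus`.
#' @param grid A `rate_grid`.
#' @param sigma_range Search interval.
#' @param span,n_points Quadrature controls.
#' @return The fitted `sigma`.
#' @export
fit_sigma <- function(mus, rare_fractions, grid, sigma_range = c(0, 1.2),
                      span = 4, n_points = 256) {
  stopifnot(length(mus) == length(rare_fractions))
  loss <- function(s) {
    pred <- purrr::map_dbl(mus, function(m) {
      mixture_rare_fraction(rate_mixture(m, s), grid, span, n_points)
    })
    sum((pred - rare_fractions)^2)
  }
  optimize(loss, sigma_range)$minimum
}
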