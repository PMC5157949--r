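# Two-category molecular-clock model for the distribution of mutation
# rates at parallel-substitution sites.
#
# Mutation types split into a "uniform clock" category U, whose yearly
# substitution rate is constant across lineages (CpG-transition-like), and a
# generation-scaled category G, whose per-generation rate is constant so the
# yearly rate varies inversely with the lineage's generation time. A site
# carries a rate multiplier M drawn from a lognormal spread (mean 1), and
# substitutions on a lineage are a Poisson thinning of branch length:
#   U: P(substituted) = 1 - exp(-r_u * M * t_years)
#   G: P(substituted) = 1 - exp(-r_g * M * t_years / g_years).

#' Default primate lineage branches
#'
#' Editable table of the five conditioning species with the length of their
#' own lineage since the split from human (years), an approximate
#' generation time (years), and the matching human-side branch length.
#' Values are round numbers in the range of current literature estimates
#' (e.g. Langergraber et al. 2012 for great-ape generation times) and are
#' meant to be replaced by the user's preferred calibration.
#'
#' @return A tibble with columns `species`, `split_years`,
#'   `gen_time_years`, `human_branch_years`.
#' @export
primate_branches <- function() {
  tibble::tibble(
    species = primate_species,
    split_years = c(6.5e6, 9e6, 16e6, 19e6, 28e6),
    gen_time_years = c(25, 19, 27, 10, 11),
    human_branch_years = c(6.5e6, 9e6, 16e6, 19e6, 28e6)
  )
}

#' Two-category mutation mix
#'
#' @param w_u Fraction of sites in the uniform-clock category U (the
#'   generation-scaled category G gets `1 - w_u`).
#' @param r_u Mean yearly substitution rate of category U on any lineage,
#'   per unit multiplier.
#' @param r_g Mean per-generation rate of category G, per unit multiplier
#'   (converted to a yearly rate by dividing by the lineage generation
#'   time).
#' @param sigma Spread of the per-site rate multiplier `M` (lognormal,
#'   mean 1, log10 units).
#' @param human_gen_years Human generation time, used to convert yearly
#'   category-U rates into the per-generation rates that drive human
#'   polymorphism.
#' @return An object of class `clock_mix`.
#' @export
clock_mix <- function(w_u = 0.2, r_u = 5e-10, r_g = 1e-8, sigma = 0.57,
                      human_gen_years = 29) {
  stopifnot(w_u >= 0, w_u <= 1, r_u > 0, r_g > 0, sigma >= 0)
  structure(list(w_u = w_u, r_u = r_u, r_g = r_g, sigma = sigma,
                 human_gen_years = human_gen_years), class = "clock_mix")
}

#' @export
print.clock_mix <- function(x, ...) {
  cat(sprintf(paste0("<two-category clock mix> w_U = %.2f, r_U = %.3g/yr, ",
                     "r_G = %.3g/gen, sigma = %.2f\n"),
              x$w_u, x$r_u, x$r_g, x$sigma))
  invisible(x)
}

#' Probability of a substitution on a lineage branch
#'
#' @param M Rate multiplier (vectorized).
#' @param branch One row of [primate_branches()] (or a list with
#'   `split_years` and `gen_time_years`).
#' @param category `"U"` (uniform yearly clock) or `"G"`
#'   (generation-scaled).
#' @param mix A `clock_mix`.
#' @return Substitution probabilities.
#' @export
branch_substitution_prob <- function(M, branch, category = c("U", "G"), mix) {
  category <- match.arg(category)
  stopifnot(all(M >= 0), inherits(mix, "clock_mix"))
  t <- branch$split_years
  if (category == "U") {
    -expm1(-mix$r_u * M * t)
  } else {
    -expm1(-mix$r_g * M * t / branch$gen_time_years)
  }
}

# human per-generation rate per category (drives P(polymorphic) ~ rate)
human_pergen_rate <- function(mix, category) {
  if (category == "U") mix$r_u * mix$human_gen_years else mix$r_g
}

# multiplier quadrature grid (log10 space) and the lognormal mean-1 density
multiplier_grid <- function(sigma, span = 5, n_points = 1024) {
  s <- max(sigma, 1e-3)
  lx <- seq(-span * s - s^2 * log(10) / 2, span * s, length.out = n_points)
  dens <- dnorm(lx, -s^2 * log(10) / 2, s) # density in log10 units
  list(lx = lx, M = 10^lx, dens = dens)
}

#' Distribution of rate multipliers at substituted-species sites
#'
#' Posterior density of the per-site rate multiplier `M` given that the
#' site is polymorphic in humans and substituted in the given species:
#' proportional to `P(polymorphic | M, c) * P(substituted_s | M, c) *
#' g(M) * w_c`, summed over the two clock categories, with the human
#' polymorphism probability taken linear in the per-generation human rate
#' (or from a [estimate_grid()] rate grid when supplied). Normalized by
#' trapezoid quadrature in `log10 M`.
#'
#' @param species One of [primate_species].
#' @param mix A `clock_mix`.
#' @param branches Lineage table, defaults to [primate_branches()].
#' @param grid Optional `rate_grid` providing `P(S=1 | rate)` for the human
#'   polymorphism factor; the multiplier is converted to a human
#'   per-generation rate per category before lookup.
#' @param conditioning `"substituted"` (polymorphic and substituted) or
#'   `"polymorphic"` (polymorphic only) or `"random"` (no conditioning).
#' @param n_points Quadrature nodes.
#' @return A tibble with `M`, `density` (marginal over categories), and the
#'   per-category components `density_u`, `density_g`.
#' @export
rate_distribution_at_substituted_sites <- function(species, mix,
                                                   branches = primate_branches(),
                                                   grid = NULL,
                                                   conditioning = c("substituted",
                                                                    "polymorphic",
                                                                    "random"),
                                                   n_points = 1024) {
  conditioning <- match.arg(conditioning)
  stopifnot(inherits(mix, "clock_mix"))
  br <- branches[branches$species == species, ]
  if (nrow(br) != 1) stop("unknown species: ", species)
  q <- multiplier_grid(mix$sigma, n_points = n_points)
  w <- c(U = mix$w_u, G = 1 - mix$w_u)
  comp <- purrr::map(c("U", "G"), function(cat) {
    poly <- switch(conditioning,
      random = rep(1, length(q$M)),
      {
        r_h <- human_pergen_rate(mix, cat) * q$M
        if (is.null(grid)) r_h else interp_log(log10(grid$rate), grid$p_biallelic, log10(r_h))
      })
    sub <- if (conditioning == "substituted") {
      branch_substitution_prob(q$M, br, cat, mix)
    } else rep(1, length(q$M))
    w[[cat]] * q$dens * poly * sub
  })
  total <- comp[[1]] + comp[[2]]
  Z <- trapz(q$lx, total)
  if (!is.finite(Z) || Z <= 0) stop("posterior is not normalizable for ", species)
  tibble::tibble(M = q$M, density = total / Z,
                 density_u = comp[[1]] / Z, density_g = comp[[2]] / Z)
}

#' Uniform-clock enrichment at substituted-species sites
#'
#' Expected fraction of substituted-`s` sites belonging to the
#' uniform-clock category U, by Bayes weighting of the category fractions
#' with the per-category probabilities of being polymorphic in human and
#' substituted in `s`.
#'
#' @inheritParams rate_distribution_at_substituted_sites
#' @param species Character vector of species; defaults to all of
#'   `branches`.
#' @return A tibble with `species`, `gen_time_years`, `split_years`,
#'   `enrichment_u` (posterior U fraction) and the prior `w_u`.
#' @export
uniform_clock_enrichment <- function(mix, branches = primate_branches(),
                                     species = branches$species, grid = NULL,
                                     n_points = 1024) {
  rows <- purrr::map(species, function(sp) {
    d <- rate_distribution_at_substituted_sites(sp, mix, branches, grid,
                                                n_points = n_points)
    lx <- log10(d$M)
    u_mass <- trapz(lx, d$density_u)
    br <- branches[branches$species == sp, ]
    tibble::tibble(species = sp, gen_time_years = br$gen_time_years,
                   split_years = br$split_years, enrichment_u = u_mass,
                   w_u = mix$w_u)
  })
  dplyr::bind_rows(rows)
}
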