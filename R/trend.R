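# Logistic model for the probability that a variant is rare, with
# substituted-species terms, and the exact permutation trend test on the
# species coefficients.
#
# The model is
#   logit P(Y = 1 | mu, s, Z) = b0 + b_mu . mu + (1 - Z) b_s_syn . s + Z b_s_ns . s
# with Y the rare indicator, mu mutually exclusive mutation-type dummies,
# s substituted-species dummies (human_private is the baseline) and Z the
# nonsynonymous indicator. Note there is no Z main effect: human-private
# synonymous and nonsynonymous sites share the baseline.

#' Fit the rare-variant logistic regression
#'
#' Coding sites only (synonymous and nonsynonymous). Sites are aggregated
#' by covariate pattern and fitted by maximum likelihood (IRLS via
#' [stats::glm()]), which is deterministic given the data.
#'
#' @param sites Site table with `func_class`, `minor_count` (or `rare`),
#'   a `category` column (else computed via [classify_category()]), and
#'   flanks/alleles for mutation typing.
#' @param type_resolution `"none"` (no mutation-type terms), `"mono"`
#'   (six strand-collapsed mononucleotide types) or `"trimer"` (3-mer
#'   context types).
#' @param include_cpg Keep CpG transitions (excluded by default; when kept
#'   at resolution `"mono"` they form their own `CpG>TpG` type).
#' @param rare_max_count Rare threshold on the minor-allele count.
#' @return An object of class `rare_logit` with [tidy()] and [glance()]
#'   methods.
#' @export
fit_rare_logit <- function(sites, type_resolution = c("mono", "none", "trimer"),
                           include_cpg = FALSE, rare_max_count = 2) {
  type_resolution <- match.arg(type_resolution)
  if (!"category" %in% names(sites)) sites <- classify_category(sites)
  sites <- dplyr::filter(sites, .data$func_class %in% c("synonymous", "nonsynonymous"),
                         .data$category != "other")
  lvl <- if (type_resolution == "trimer") "trimer" else "cpg_ti"
  sites <- mutation_type(sites, lvl)
  if (!include_cpg) sites <- dplyr::filter(sites, !.data$is_cpg)
  sites <- dplyr::filter(sites, !is.na(.data$mutation_type))
  if (nrow(sites) == 0) stop("no usable coding sites")
  rare <- if ("rare" %in% names(sites)) as.logical(sites$rare) else
    sites$minor_count <= rare_max_count

  species_lvls <- paste0("substituted_", primate_species)
  present <- species_lvls[species_lvls %in% as.character(sites$category)]
  absent <- setdiff(species_lvls, present)
  if (length(absent) > 0) {
    warning("empty substituted categories dropped: ", paste(absent, collapse = ", "))
  }
  if (length(present) < 2) stop("need at least 2 substituted-species categories")

  agg <- tibble::tibble(
    type = as.character(sites$mutation_type),
    cat = as.character(sites$category),
    z = as.integer(sites$func_class == "nonsynonymous"),
    rare = rare
  ) |>
    dplyr::group_by(.data$type, .data$cat, .data$z) |>
    dplyr::summarise(n_rare = sum(.data$rare), n_tot = dplyr::n(), .groups = "drop")

  # explicit design matrix: intercept + type dummies + (1-Z) and Z species
  # dummies against the human_private baseline
  X <- matrix(numeric(0), nrow = nrow(agg), ncol = 0)
  terms <- character(0)
  if (type_resolution != "none") {
    types <- sort(unique(agg$type))
    for (ty in types[-1]) {
      X <- cbind(X, as.numeric(agg$type == ty))
      terms <- c(terms, paste0("mu_", ty))
    }
  }
  for (sp in present) {
    X <- cbind(X, (1 - agg$z) * as.numeric(agg$cat == sp))
    terms <- c(terms, paste0("syn_", sp))
  }
  for (sp in present) {
    X <- cbind(X, agg$z * as.numeric(agg$cat == sp))
    terms <- c(terms, paste0("ns_", sp))
  }
  colnames(X) <- terms
  fit <- glm(cbind(agg$n_rare, agg$n_tot - agg$n_rare) ~ X,
             family = binomial(), control = list(epsilon = 1e-10, maxit = 100))
  est <- coef(fit)
  names(est) <- sub("^X", "", names(est))
  if (!fit$converged || any(!is.finite(est)) || any(abs(est) > 15)) {
    culprit <- names(est)[which(!is.finite(est) | abs(est) > 15)]
    stop("complete or quasi-complete separation for covariate(s): ",
         paste(culprit, collapse = ", "))
  }
  se <- sqrt(diag(summary(fit)$cov.scaled))
  names(se) <- names(est)
  block <- c("intercept",
             ifelse(grepl("^mu_", names(est)[-1]), "type",
                    ifelse(grepl("^syn_", names(est)[-1]), "species_syn", "species_ns")))
  coefs <- tibble::tibble(
    term = names(est), estimate = unname(est), std_error = unname(se),
    block = block,
    species = sub("^(syn|ns)_substituted_", "", names(est)) |>
      (\(x) ifelse(block %in% c("species_syn", "species_ns"), x, NA_character_))()
  )
  # Bernoulli log-likelihood of the fit (free of the aggregation-dependent
  # binomial coefficients, so nested type resolutions are comparable)
  p_hat <- fit$fitted.values
  log_lik <- sum(agg$n_rare * log(p_hat) +
                   (agg$n_tot - agg$n_rare) * log1p(-p_hat))
  structure(list(coefficients = coefs, fit = fit,
                 type_resolution = type_resolution, include_cpg = include_cpg,
                 n_sites = sum(agg$n_tot), species = sub("substituted_", "", present),
                 log_lik = log_lik),
            class = "rare_logit")
}

#' @export
print.rare_logit <- function(x, ...) {
  cat(sprintf("<rare-variant logit> type resolution '%s', %d sites, logLik %.2f\n",
              x$type_resolution, x$n_sites, x$log_lik))
  print(x$coefficients, n = Inf)
  invisible(x)
}

#' @export
tidy.rare_logit <- function(x, ...) x$coefficients

#' @export
glance.rare_logit <- function(x, ...) {
  tibble::tibble(log_lik = x$log_lik, n_sites = x$n_sites,
                 n_terms = nrow(x$coefficients),
                 type_resolution = x$type_resolution,
                 include_cpg = x$include_cpg,
                 aic = x$fit$aic, converged = x$fit$converged)
}

#' Substituted-species coefficients of a fitted rare-variant logit
#'
#' @param x A `rare_logit`.
#' @param block `"ns"` (nonsynonymous) or `"syn"` (synonymous) species
#'   block.
#' @return Named numeric vector ordered by relatedness to human.
#' @export
species_coefficients <- function(x, block = c("ns", "syn")) {
  block <- match.arg(block)
  b <- paste0("species_", block)
  co <- dplyr::filter(x$coefficients, .data$block == b)
  ord <- match(primate_species, co$species)
  ord <- ord[!is.na(ord)]
  setNames(co$estimate[ord], co$species[ord])
}

# all permutations of 1..k as a k! x k matrix
permutation_matrix <- function(k) {
  if (k == 1) return(matrix(1L, 1, 1))
  sub <- permutation_matrix(k - 1L)
  out <- matrix(0L, nrow = factorial(k), ncol = k)
  row <- 1L
  for (i in seq_len(k)) {
    vals <- c(i, setdiff(seq_len(k), i))
    block <- cbind(i, matrix(vals[-1][as.vector(sub)], nrow(sub), k - 1L))
    out[row:(row + nrow(sub) - 1L), ] <- block
    row <- row + nrow(sub)
  }
  out
}

#' Exact permutation trend test on species coefficients
#'
#' Spearman rank correlation between the substituted-species coefficients
#' and the species' split times from human, with a two-sided p-value from
#' full enumeration of all `n!` orderings: the fraction of permutations
#' with `|rho|` at least the observed `|rho|`. Ties are handled by
#' midranks (and noted in the output).
#'
#' @param coefs Numeric vector of species coefficients (or a `rare_logit`,
#'   whose nonsynonymous block is used).
#' @param split_times Species split times (any monotone relatedness score),
#'   parallel to `coefs`.
#' @return A list with `rho`, `p_value`, `n`, `ties`.
#' @export
coefficient_trend <- function(coefs, split_times) {
  if (inherits(coefs, "rare_logit")) coefs <- species_coefficients(coefs, "ns")
  k <- length(coefs)
  stopifnot(length(split_times) == k, k >= 2)
  if (k > 8) stop("exact enumeration supports at most 8 species")
  ties <- anyDuplicated(coefs) > 0 || anyDuplicated(split_times) > 0
  rx <- rank(coefs)
  ry <- rank(split_times)
  ryc <- ry - mean(ry)
  rho_of <- function(x) {
    xc <- x - mean(x)
    den <- sqrt(sum(xc^2) * sum(ryc^2))
    if (den == 0) return(0)
    sum(xc * ryc) / den
  }
  rho_obs <- rho_of(rx)
  P <- permutation_matrix(k)
  RX <- matrix(rx[P], nrow(P), k)
  RXc <- RX - rowMeans(RX)
  dens <- sqrt(rowSums(RXc^2) * sum(ryc^2))
  rhos <- as.numeric(RXc %*% ryc) / ifelse(dens == 0, Inf, dens)
  p <- mean(abs(rhos) >= abs(rho_obs) - 1e-12)
  list(rho = rho_obs, p_value = p, n = k, ties = ties)
}
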