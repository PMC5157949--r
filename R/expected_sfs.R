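# Expected infinite-sites SFS under piecewise demography.
#
# The expected spectrum follows from expected coalescent level times:
#   E[xi_b]  =  sum_k  k * p(n, b, k) * E[T_k],
# where T_k is the time during which the sample's genealogy has k lineages
# and p(n, b, k) = C(n-b-1, k-2) / C(n-1, k-1) is the classical probability
# that a branch present while there are k lineages subtends b of the n
# sampled leaves. p() is evaluated in log space, so the mixture is stable at
# large n.
#
# E[T_k] is computed either by Monte Carlo ("simulation") or by a hybrid
# deterministic/exact scheme ("analytic"): for large lineage counts the
# decay of the number of ancestral lineages is treated deterministically
# (the pair-intensity ODE dK/dLambda = -K(K-1)/2 has the closed-form
# solution K = 1 / (1 - (1 - 1/n) exp(-Lambda/2))), and once the count
# reaches `K_exact` the remaining death chain is integrated exactly as a
# small ODE system, with the unbounded constant terminal epoch handled in
# closed form.

level_probs <- function(n, b, k) {
  exp(lchoose(n - b - 1, k - 2) - lchoose(n - 1, k - 1))
}

# E[T_k] for k = 2..n (returned as vector indexed by k - 1)
expected_level_times <- function(model, n, method = c("analytic", "simulation"),
                                 K_exact = 200, reps = 200, seed = NULL) {
  method <- match.arg(method)
  stopifnot(inherits(model, "demog_model"), n >= 2)
  if (method == "simulation") {
    if (!is.null(seed)) set.seed(seed)
    res <- cpp_coal_times(as.integer(n), epoch_matrix(model), as.integer(reps))
    return(res$sum_t / reps)
  }
  ep <- model$epochs
  if (nrow(ep) == 1L) { # constant size: exact closed form
    k <- 2:n
    return(4 * ep$size[1] / (k * (k - 1)))
  }
  K0 <- min(n, as.integer(K_exact))
  Tk <- numeric(n - 1) # index k - 1
  t_star <- 0
  if (n > K0) {
    ks <- K0:n
    lam <- 2 * log((n - 1) * ks / (n * (ks - 1)))
    s_at <- vapply(lam, function(l) pair_intensity_inverse(model, l), numeric(1))
    # s_at[i]: time at which the deterministic count reaches ks[i]
    for (k in (K0 + 1):n) {
      Tk[k - 1] <- s_at[k - 1 - K0 + 1] - s_at[k - K0 + 1]
    }
    t_star <- s_at[1]
  }
  Tk[is.na(Tk)] <- 0
  t_term <- terminal_start(model)
  P <- c(numeric(K0 - 1), 1) # P_j for j = 1..K0, mass at K0
  if (t_star < t_term) {
    sol <- integrate_death_chain(model, K0, P, t_star, t_term)
    P <- sol$P
    Tk[(2:K0) - 1] <- Tk[(2:K0) - 1] + sol$occupancy[2:K0]
  }
  # constant terminal epoch: a level k <= current count is eventually
  # occupied for an Exp(k(k-1)/(4N)) stretch
  N_term <- ep$size[nrow(ep)]
  surv <- rev(cumsum(rev(P))) # surv[j] = P(count >= j) at terminal entry
  for (k in 2:K0) Tk[k - 1] <- Tk[k - 1] + surv[k] * 4 * N_term / (k * (k - 1))
  Tk
}

# Integrate the lineage-count death chain (states 1..K0) together with
# per-level occupancy-time accumulators from t0 to t1.
integrate_death_chain <- function(model, K0, P0, t0, t1) {
  ep <- model$epochs
  state <- c(P0, numeric(K0)) # P_1..P_K0, A_1..A_K0
  j <- seq_len(K0)
  rate_coef <- j * (j - 1) / 4
  deriv <- function(t, y, parms) {
    N <- parms$size * exp(-parms$rho * (t - parms$t_start))
    P <- y[seq_len(K0)]
    c_j <- rate_coef / N
    flux <- c_j * P
    dP <- -flux
    dP[j < K0] <- dP[j < K0] + flux[-1]
    list(c(dP, P))
  }
  for (e in seq_len(nrow(ep))) {
    a <- max(t0, ep$t_start[e])
    b <- min(t1, ep$t_start[e] + ep$duration[e])
    if (b <= a) next
    parms <- list(size = ep$size[e], rho = ep$rho[e], t_start = ep$t_start[e])
    sol <- deSolve::lsoda(state, c(a, b), deriv, parms,
                          rtol = 1e-10, atol = 1e-12)
    state <- as.numeric(sol[nrow(sol), -1])
    state[seq_len(K0)] <- pmax(state[seq_len(K0)], 0)
  }
  list(P = state[seq_len(K0)], occupancy = state[K0 + seq_len(K0)])
}

#' Expected infinite-sites SFS under a demographic model
#'
#' Returns the normalized expected proportions of derived-allele counts for
#' a sample of `n` chromosomes, assuming every mutation hits a new site.
#'
#' @param model A `demog_model`.
#' @param n Number of chromosomes (>= 2).
#' @param method `"analytic"` (deterministic-lineage hybrid, exact for a
#'   constant-size model) or `"simulation"` (Monte Carlo over genealogies).
#' @param reps Number of simulated genealogies for `method = "simulation"`.
#' @param seed Optional seed for the simulation method.
#' @param K_exact Lineage count below which the analytic method switches
#'   from the deterministic approximation to exact integration.
#' @param max_n Guard on the full-spectrum computation (O(n^2)); for larger
#'   samples use [expected_rare_fraction()], which only needs the extreme
#'   frequency classes.
#' @return An unfolded `sfs` of expected class proportions.
#' @export
expected_sfs_infinite <- function(model, n, method = c("analytic", "simulation"),
                                  reps = 200, seed = NULL, K_exact = 200,
                                  max_n = 5000) {
  method <- match.arg(method)
  n <- as.integer(n)
  if (n > max_n) {
    stop("full expected spectrum at n = ", n, " exceeds max_n = ", max_n,
         "; use expected_rare_fraction() for large samples")
  }
  Tk <- expected_level_times(model, n, method, K_exact = K_exact,
                             reps = reps, seed = seed)
  k <- 2:n
  kT <- k * Tk
  xi <- vapply(seq_len(n - 1L), function(b) sum(level_probs(n, b, k) * kT),
               numeric(1))
  sfs_unfolded(xi / sum(xi), n)
}

#' Expected fraction of rare variants at large sample sizes
#'
#' Computes the rare-variant fraction (minor-allele count at most
#' `rare_max_count` after folding) of the expected infinite-sites SFS
#' without forming the full spectrum: only the extreme frequency classes
#' and the total expected branch length are evaluated, so the computation
#' is O(n) and stable for samples of tens of thousands of chromosomes.
#'
#' @inheritParams expected_sfs_infinite
#' @param rare_max_count Largest minor-allele count counted as rare.
#' @return Proportion in `[0, 1]`; for `method = "simulation"` the Monte
#'   Carlo standard error is attached as attribute `"se"` (batch means).
#' @export
expected_rare_fraction <- function(model, n, rare_max_count = 2,
                                   method = c("analytic", "simulation"),
                                   reps = 200, seed = NULL, K_exact = 200,
                                   n_batches = 10) {
  method <- match.arg(method)
  n <- as.integer(n)
  r <- as.integer(rare_max_count)
  stopifnot(n > 2 * r)
  classes <- c(seq_len(r), n - seq_len(r))
  rare_frac_from_Tk <- function(Tk) {
    k <- 2:n
    kT <- k * Tk
    rare <- sum(vapply(classes, function(b) sum(level_probs(n, b, k) * kT),
                       numeric(1)))
    rare / sum(kT)
  }
  if (method == "analytic") {
    return(rare_frac_from_Tk(expected_level_times(model, n, "analytic",
                                                  K_exact = K_exact)))
  }
  if (!is.null(seed)) set.seed(seed)
  B <- max(2L, as.integer(n_batches))
  per <- max(1L, reps %/% B)
  batch <- vapply(seq_len(B), function(b) {
    res <- cpp_coal_times(n, epoch_matrix(model), per)
    rare_frac_from_Tk(res$sum_t / per)
  }, numeric(1))
  est <- mean(batch)
  attr(est, "se") <- sd(batch) / sqrt(B)
  est
}

#' Probability that at least two sample lineages survive to a past time
#'
#' `P(TMRCA > t)` for a sample of `n` chromosomes: the probability that at
#' least two lineages ancestral to the sample exist `t` generations before
#' present.
#'
#' @inheritParams expected_sfs_infinite
#' @param t Time in generations before present.
#' @return Probability; for the simulation method the MC standard error is
#'   attached as attribute `"se"`.
#' @export
prob_two_or_more_lineages <- function(model, n, t, reps = 10000, seed = NULL) {
  stopifnot(t >= 0, n >= 2)
  if (t == 0) return(1)
  ep <- model$epochs
  if (n == 2 && nrow(ep) == 1L) {
    return(exp(-t / (2 * ep$size[1])))
  }
  if (!is.null(seed)) set.seed(seed)
  res <- cpp_coal_times(as.integer(n), epoch_matrix(model), as.integer(reps))
  p <- mean(res$tmrca > t)
  attr(p, "se") <- sqrt(p * (1 - p) / reps)
  p
}

#' Upper bound on the probability of an ancestrally shared polymorphism
#'
#' Estimates the probability that a neutral site polymorphic in a sample of
#' `n` chromosomes still had at least two ancestral lineages at a species
#' split time. Genealogies are simulated under the demographic model and
#' weighted by their total branch length (the mutation opportunity, which is
#' the conditioning on the site being polymorphic); the estimate is the
#' weighted fraction of genealogies with two or more lineages at `t_split`.
#' With `worst_case = TRUE` the epochs after the out-of-Africa event (all
#' non-terminal epochs) are replaced by a no-coalescence assumption: all `n`
#' lineages reach the terminal epoch, which maximizes lineage survival.
#'
#' @inheritParams expected_sfs_infinite
#' @param t_split Split time in generations before present.
#' @param worst_case Replace the recent epochs by "no coalescence".
#' @param reps Number of simulated genealogies.
#' @return Probability with MC standard error attached as attribute `"se"`.
#' @export
ancestral_polymorphism_bound <- function(model, n, t_split, worst_case = FALSE,
                                         reps = 20000, seed = NULL) {
  stopifnot(inherits(model, "demog_model"), t_split >= 0, n >= 2)
  if (t_split == 0) return(structure(1, se = 0))
  if (worst_case && t_split < terminal_start(model)) {
    stop("worst_case requires t_split inside the terminal (pre-OOA) epoch; ",
         "t_split = ", t_split, " < ", terminal_start(model))
  }
  if (!is.null(seed)) set.seed(seed)
  res <- cpp_ancestral_bound(as.integer(n), epoch_matrix(model),
                             t_split, isTRUE(worst_case), as.integer(reps))
  w <- res$weight
  est <- sum(w * res$shared) / sum(w)
  # delta-method SE for the ratio estimator
  se <- sqrt(var(w * (res$shared - est)) / reps) / mean(w)
  structure(est, se = se)
}

#' Expected number of ancestrally shared sites
#'
#' @param p Per-site probability of ancestral sharing.
#' @param n_sites Number of sites.
#' @return `round(p * n_sites)` as an integer.
#' @examples
#' expected_shared_sites(1.4e-5, 3531936)
#' @export
expected_shared_sites <- function(p, n_sites) {
  stopifnot(p >= 0, p <= 1, n_sites >= 0)
  as.integer(round(p * n_sites))
}
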