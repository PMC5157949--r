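# Finite-sites simulation: Kingman genealogies + Jukes-Cantor mutation
# dropping, and the mutation-rate grid consumed by the mixture integral.

phylo_from_parent <- function(parent, age) {
  tot <- length(parent)
  n <- (tot + 1L) %/% 2L
  # C++ ids: leaves 0..n-1, internal n..2n-2 in coalescence order (root last).
  # phylo ids: tips 1..n, root n+1, later internal nodes decreasing in age.
  new_id <- integer(tot)
  new_id[seq_len(n)] <- seq_len(n)
  new_id[(n + 1):tot] <- 3L * n - 1L - (n:(tot - 1L))
  edge <- matrix(0L, tot - 1L, 2L)
  edge_length <- numeric(tot - 1L)
  row <- 0L
  for (v in seq_len(tot)) {
    p <- parent[v] # 0-based, -1 for root
    if (p < 0) next
    row <- row + 1L
    edge[row, ] <- c(new_id[p + 1L], new_id[v])
    edge_length[row] <- age[p + 1L] - age[v]
  }
  structure(list(edge = edge, edge.length = edge_length,
                 tip.label = paste0("t", seq_len(n)), Nnode = n - 1L),
            class = "phylo", order = NULL)
}

#' Simulate Kingman coalescent genealogies under a demographic model
#'
#' @param model A `demog_model`.
#' @param n Number of sampled chromosomes.
#' @param num_trees Number of independent genealogies.
#' @param seed Optional integer seed.
#' @return A list of `phylo` trees with branch lengths in generations.
#' @export
simulate_genealogies <- function(model, n, num_trees = 1, seed = NULL) {
  stopifnot(inherits(model, "demog_model"), n >= 2, num_trees >= 1)
  if (!is.null(seed)) set.seed(seed)
  em <- epoch_matrix(model)
  purrr::map(seq_len(num_trees), function(i) {
    g <- cpp_sim_genealogy(as.integer(n), em)
    phylo_from_parent(g$parent, g$age)
  })
}

# parent/age arrays (C++ layout) from an ultrametric phylo
parent_age_from_phylo <- function(tree) {
  n <- length(tree$tip.label)
  tot <- 2L * n - 1L
  parent0 <- integer(tot) - 1L
  depth <- numeric(tot)
  # depths by traversing edges from the root; phylo edges are parent -> child
  ord <- order(tree$edge[, 1]) # root-first is not guaranteed; iterate to fix
  depth[] <- NA_real_
  depth[n + 1L] <- 0
  remaining <- seq_len(nrow(tree$edge))
  while (length(remaining) > 0) {
    done <- logical(length(remaining))
    for (i in seq_along(remaining)) {
      e <- remaining[i]
      p <- tree$edge[e, 1]; v <- tree$edge[e, 2]
      if (!is.na(depth[p])) {
        depth[v] <- depth[p] + tree$edge.length[e]
        done[i] <- TRUE
      }
    }
    if (!any(done)) stop("tree edges are not connected to the root")
    remaining <- remaining[!done]
  }
  h <- max(depth[seq_len(n)])
  age_phylo <- h - depth
  # map phylo ids back to the C++ layout: order internal nodes by age
  internal <- (n + 1L):tot
  internal <- internal[order(age_phylo[internal])] # youngest first
  cpp_of_phylo <- integer(tot)
  cpp_of_phylo[seq_len(n)] <- seq_len(n) - 1L
  cpp_of_phylo[internal] <- n:(tot - 1L)
  parent <- integer(tot)
  age <- numeric(tot)
  for (v in seq_len(tot)) age[cpp_of_phylo[v] + 1L] <- age_phylo[v]
  parent[] <- -1L
  for (e in seq_len(nrow(tree$edge))) {
    p <- tree$edge[e, 1]; v <- tree$edge[e, 2]
    parent[cpp_of_phylo[v] + 1L] <- cpp_of_phylo[p]
  }
  list(parent = parent, age = age, n = n)
}

#' Drop finite-sites Jukes-Cantor mutations on a genealogy
#'
#' Simulates `L` independent sites along the tree: the root base is uniform
#' on \{A, C, G, T\}, mutation events arise as a Poisson process with
#' intensity `M` per site per generation on every branch, and each event
#' replaces the current base by one of the other three uniformly. Multiple
#' and back mutations are allowed. Sites are classified as monomorphic,
#' biallelic, triallelic or quadallelic; for biallelic sites the derived
#' count is the number of leaves carrying a non-root allele (when recurrent
#' mutation removes the root allele entirely, the minor allele is reported
#' as derived).
#'
#' @param tree An ultrametric `phylo` genealogy with branch lengths in
#'   generations (e.g. from [simulate_genealogies()]).
#' @param M Mutation rate per basepair per generation per haploid.
#' @param L Number of sites.
#' @param seed Optional integer seed.
#' @return A tibble with one row per site: `n_mutations`, `n_alleles`,
#'   `class`, `minor_count`, `derived_count`.
#' @export
mutate_jc <- function(tree, M, L, seed = NULL) {
  stopifnot(inherits(tree, "phylo"), M >= 0, L >= 1)
  if (!is.null(seed)) set.seed(seed)
  pa <- parent_age_from_phylo(tree)
  out <- cpp_mutate_sites(pa$parent, pa$age, pa$n, M, as.integer(L))
  cls <- c("monomorphic", "monomorphic", "biallelic", "triallelic", "quadallelic")
  tibble::tibble(
    site = seq_len(nrow(out)),
    n_mutations = out[, 1],
    n_alleles = out[, 2],
    class = cls[out[, 2] + 1L],
    minor_count = out[, 3],
    derived_count = out[, 4]
  )
}

#' Log-spaced mutation-rate grid
#'
#' @param n_points Number of grid points.
#' @param min_rate,max_rate Grid end points (per bp per generation per
#'   haploid). Defaults span the range relevant for human point mutations.
#' @return Numeric vector of strictly increasing rates.
#' @export
rate_grid_points <- function(n_points = 40, min_rate = 1e-9, max_rate = 5.3e-5) {
  10^seq(log10(min_rate), log10(max_rate), length.out = n_points)
}

# Two-stage simulation towards a biallelic-site target: a fixed pilot
# estimates the per-tree biallelic yield, then a tree count chosen from the
# pilot alone is simulated. No stopping decision depends on the outcomes it
# reports, which avoids the sequential-stopping bias that arises when few
# genealogies suffice (stopping on the target would overweight high-yield
# trees).
grid_point_two_stage <- function(em, n, M, sigma, L, target_biallelic,
                                 max_trees, rare_max_count, n_pilot = 32L,
                                 max_stages = 6L) {
  acc <- cpp_grid_point(as.integer(n), em, M, sigma, as.integer(L),
                        .Machine$integer.max, n_pilot,
                        as.integer(rare_max_count))
  for (stage in seq_len(max_stages)) {
    need <- target_biallelic - acc$n_biallelic
    if (need <= 0) break
    yield <- max(acc$n_biallelic, 1) / acc$n_trees
    n2 <- min(ceiling(1.05 * need / yield), max(0, max_trees - acc$n_trees))
    if (n2 <= 0) break
    more <- cpp_grid_point(as.integer(n), em, M, sigma, as.integer(L),
                           .Machine$integer.max, as.integer(n2),
                           as.integer(rare_max_count))
    acc <- list(n_sites = acc$n_sites + more$n_sites,
                n_biallelic = acc$n_biallelic + more$n_biallelic,
                n_tri = acc$n_tri + more$n_tri,
                n_quad = acc$n_quad + more$n_quad,
                n_rare = acc$n_rare + more$n_rare,
                n_trees = acc$n_trees + more$n_trees,
                sfs_derived = acc$sfs_derived + more$sfs_derived)
  }
  acc
}

#' Estimate polymorphism probabilities and rare fractions on a rate grid
#'
#' For each mutation rate, simulates non-recombining blocks of `L` sites on
#' independent genealogies until at least `min_biallelic` biallelic sites
#' have accumulated, and records the probability that a site is a biallelic
#' polymorphism, `P(S = 1 | M)`, and the expected fraction of rare variants
#' among biallelic sites, `E[Y | S = 1, M]` (Y: minor-allele count at most
#' `rare_max_count`). Tri- and quadallelic sites are excluded from the
#' spectra but counted. Monte Carlo standard errors are estimated across
#' `n_batches` independent batches of genealogies, which respects the
#' correlation of sites sharing a tree.
#'
#' @param model A `demog_model`.
#' @param n Number of chromosomes per genealogy.
#' @param rates Increasing vector of mutation rates (see
#'   [rate_grid_points()]).
#' @param min_biallelic Biallelic-site floor per rate.
#' @param L Sites per non-recombining block.
#' @param rare_max_count Rare threshold on the minor-allele count.
#' @param sigma Within-type rate spread in log10 units; 0 simulates a fixed
#'   rate, positive values draw each site's rate from the mean-preserving
#'   lognormal mixture around the grid rate.
#' @param max_trees Cap on genealogies per rate (per batch); rates whose
#'   biallelic floor is not reached within the cap are flagged.
#' @param n_batches Number of batches for SE estimation.
#' @param seed Optional integer seed.
#' @return A `rate_grid`: a tibble with columns `rate`, `p_biallelic`,
#'   `p_biallelic_se`, `e_rare`, `e_rare_se`, `n_sites`, `n_biallelic`,
#'   `n_tri`, `n_quad`, `flagged`, and a list-column `sfs_derived` of pooled
#'   unfolded spectra of biallelic sites; attributes record `n`, the model
#'   name, `L`, `rare_max_count`, `sigma` and the seed.
#' @export
estimate_grid <- function(model, n, rates, min_biallelic = 10000, L = 1000,
                          rare_max_count = 2, sigma = 0, max_trees = 2e5,
                          n_batches = 8, seed = NULL) {
  stopifnot(inherits(model, "demog_model"), n >= 2,
            all(diff(rates) > 0), all(rates > 0))
  if (!is.null(seed)) set.seed(seed)
  em <- epoch_matrix(model)
  per_batch <- ceiling(min_biallelic / n_batches)
  rows <- purrr::map(rates, function(M) {
    bat <- purrr::map(seq_len(n_batches), function(b) {
      grid_point_two_stage(em, n, M, sigma, L, per_batch, max_trees,
                           rare_max_count)
    })
    n_sites <- sum(purrr::map_dbl(bat, "n_sites"))
    n_bi <- sum(purrr::map_dbl(bat, "n_biallelic"))
    p_hat <- purrr::map_dbl(bat, ~ .x$n_biallelic / .x$n_sites)
    e_hat <- purrr::map_dbl(bat, ~ if (.x$n_biallelic > 0) .x$n_rare / .x$n_biallelic else NA_real_)
    sfs <- Reduce(`+`, purrr::map(bat, "sfs_derived"))
    flagged <- n_bi < 0.8 * min_biallelic
    if (flagged) {
      warning("rate ", signif(M, 3), ": only ", n_bi, " biallelic sites in ",
              sum(purrr::map_dbl(bat, "n_trees")), " genealogies; estimates flagged")
    }
    tibble::tibble(
      rate = M,
      p_biallelic = n_bi / n_sites,
      p_biallelic_se = sd(p_hat) / sqrt(n_batches),
      e_rare = sum(purrr::map_dbl(bat, "n_rare")) / n_bi,
      e_rare_se = sd(e_hat, na.rm = TRUE) / sqrt(sum(!is.na(e_hat))),
      n_sites = n_sites, n_biallelic = n_bi,
      n_tri = sum(purrr::map_dbl(bat, "n_tri")),
      n_quad = sum(purrr::map_dbl(bat, "n_quad")),
      flagged = flagged,
      sfs_derived = list(as.numeric(sfs))
    )
  })
  grid <- dplyr::bind_rows(rows)
  structure(grid,
            class = c("rate_grid", class(grid)),
            n = as.integer(n), model = model$name, L = as.integer(L),
            rare_max_count = as.integer(rare_max_count), sigma = sigma,
            seed = seed)
}

#' Build a rate grid from precomputed columns
#'
#' Wraps a data frame with at least `rate`, `p_biallelic` and `e_rare`
#' columns as a `rate_grid`, e.g. for analytically known toy grids or
#' externally computed tables.
#'
#' @param df Data frame with `rate`, `p_biallelic`, `e_rare` (rates
#'   strictly increasing).
#' @param n Chromosome sample size the grid refers to.
#' @param model Model name for provenance.
#' @return A `rate_grid`.
#' @export
as_rate_grid <- function(df, n = NA_integer_, model = "external") {
  stopifnot(all(c("rate", "p_biallelic", "e_rare") %in% names(df)),
            all(diff(df$rate) > 0))
  df <- tibble::as_tibble(df)
  structure(df, class = c("rate_grid", class(df)),
            n = as.integer(n), model = model, L = NA_integer_,
            rare_max_count = 2L, sigma = 0, seed = NULL)
}

#' @export
print.rate_grid <- function(x, ...) {
  cat(sprintf("<rate grid> n = %d chromosomes, model '%s', %d rates\n",
              attr(x, "n"), attr(x, "model"), nrow(x)))
  NextMethod()
}

#' Serialize a rate grid to TSV plus a JSON provenance sidecar
#'
#' @param grid A `rate_grid`.
#' @param path Output TSV path; the sidecar is written to `paste0(path,
#'   ".json")`.
#' @return `path`, invisibly.
#' @export
write_rate_grid <- function(grid, path) {
  stopifnot(inherits(grid, "rate_grid"))
  tab <- as.data.frame(grid[setdiff(names(grid), "sfs_derived")])
  write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  meta <- list(n = attr(grid, "n"), model = attr(grid, "model"),
               L = attr(grid, "L"), rare_max_count = attr(grid, "rare_max_count"),
               sigma = attr(grid, "sigma"), seed = attr(grid, "seed"))
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE)
  invisible(path)
}

#' Read a rate grid written by [write_rate_grid()]
#'
#' @param path TSV path.
#' @return A `rate_grid` (without the pooled spectra list-column).
#' @export
read_rate_grid <- function(path) {
  tab <- tibble::as_tibble(read.table(path, header = TRUE, sep = "\t"))
  meta_path <- paste0(path, ".json")
  meta <- if (file.exists(meta_path)) jsonlite::read_json(meta_path) else list()
  structure(tab, class = c("rate_grid", class(tab)),
            n = meta$n %||% NA_integer_, model = meta$model %||% "unknown",
            L = meta$L %||% NA_integer_,
            rare_max_count = meta$rare_max_count %||% 2L,
            sigma = meta$sigma %||% 0, seed = meta$seed)
}

#' Paired derived spectra at several rates on shared genealogies
#'
#' Simulates one stream of genealogies and drops mutations at every rate on
#' each of them, so that spectrum comparisons across rates are paired and
#' genealogy-level noise cancels in differences (e.g. when locating the
#' sample size at which the rare fractions of a fast and a slow mutation
#' type cross under subsampling).
#'
#' @inheritParams estimate_grid
#' @param n_trees Number of shared genealogies.
#' @return A list with `spectra` (list of unfolded `sfs` per rate),
#'   `n_biallelic`, `n_sites` and `n_trees`.
#' @export
paired_rate_spectra <- function(model, n, rates, sigma = 0, L = 1000,
                                n_trees = 1000, seed = NULL) {
  stopifnot(inherits(model, "demog_model"), length(rates) >= 1)
  if (!is.null(seed)) set.seed(seed)
  res <- cpp_paired_spectra(as.integer(n), epoch_matrix(model),
                            as.numeric(rates), sigma, as.integer(L),
                            as.integer(n_trees))
  spectra <- purrr::map(seq_along(rates), function(r) {
    sfs_unfolded(res$sfs[, r], n)
  })
  list(spectra = spectra, n_biallelic = res$n_biallelic,
       n_sites = res$n_sites, n_trees = res$n_trees)
}

#' Closed-form biallelic probability for a sample of two chromosomes
#'
#' Independent analytic oracle for the finite-sites simulator: for `n = 2`
#' under a constant population of `N` diploids, integrating the
#' Jukes-Cantor mismatch probability over the exponential coalescence time
#' gives `P(biallelic) = (3/4) * theta' / (1 + theta')` with
#' `theta' = (16/3) N M`.
#'
#' @param N Diploid population size.
#' @param M Mutation rate per bp per generation per haploid.
#' @return Probability that the two sampled chromosomes differ.
#' @export
jc_pairwise_biallelic_prob <- function(N, M) {
  theta_p <- 16 / 3 * N * M
  3 / 4 * theta_p / (1 + theta_p)
}
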