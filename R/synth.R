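# Synthetic site-table generator.
#
# Emulates the statistical structure of a large exome call set joined to
# primate orthologs: substitution-category composition, a CpG-transition
# fraction gradient across categories, within-type lognormal rate spread,
# minor-allele counts drawn from demography- and rate-dependent spectra,
# and nuisance covariates. Every latent variable is recorded in a manifest
# so downstream classifiers and models can be checked against ground truth.

MONO_TYPES <- c("A>C", "A>G", "A>T", "C>A", "C>G", "C>T")

default_type_rates <- c(
  "A>C" = 3.3e-9, "A>G" = 1.2e-8, "A>T" = 3.0e-9,
  "C>A" = 3.7e-9, "C>G" = 3.9e-9, "C>T" = 1.3e-8,
  "CpG>TpG" = 1.1e-7
)

default_noncpg_weights <- c(
  "A>C" = 0.09, "A>G" = 0.36, "A>T" = 0.08,
  "C>A" = 0.10, "C>G" = 0.10, "C>T" = 0.27
)

#' Configuration for the synthetic site-table generator
#'
#' Defaults describe the desk-scale study conditions: 50,000 sites over
#' 2,000 chromosomes, a human-private majority with the substituted
#' categories in the relative proportions of a large exome data set but
#' upweighted to give desk-scale category counts, a CpG-transition fraction
#' that decreases with phylogenetic distance of the substituted species,
#' literature-range per-type mean rates with a lognormal within-type spread
#' of 0.57, and a recent-growth demography.
#'
#' @param n_sites Number of sites to generate.
#' @param n_chrom Chromosome sample size (2x diploids).
#' @param model Demographic model for allele-count draws.
#' @param category_props Named proportions over `human_private` and the
#'   `substituted_*` categories (must sum to 1).
#' @param cpg_fraction Named per-category fraction of CpG transitions.
#' @param type_rates Named per-type mean mutation rates (per bp per
#'   generation per haploid); must include `CpG>TpG`.
#' @param noncpg_weights Relative weights of the six mononucleotide types
#'   within the non-CpG fraction.
#' @param sigma Within-type lognormal spread (log10 units).
#' @param func_props Named proportions over functional classes.
#' @param ns_singleton_boost Probability that a nonsynonymous site's count
#'   is forced to a singleton (selection skew; 0 disables, the default, so
#'   that rarity depends on mutation type only).
#' @param opportunity_scale Multiplier on the mutation opportunity (rate
#'   times tree length) used when simulating type spectra. Demographies
#'   fitted to SFS shape underestimate the absolute recurrence level of
#'   large exome data; the default of 16 places CpG transitions in the
#'   multiple-hit regime (about 6-7 expected origins per site at 67,500
#'   chromosomes) where their spectra show the rare-variant depletion seen
#'   in such data. Set to 1 for the raw demographic-model opportunity.
#' @param recurrence_threshold Expected-recurrence level (scaled type mean
#'   rate times mean tree length) above which a type's allele counts are
#'   drawn from a finite-sites simulated spectrum instead of the analytic
#'   infinite-sites spectrum.
#' @param spectrum_min_biallelic Biallelic floor for simulated type
#'   spectra.
#' @param flank_len Flank length emitted on each side.
#' @param seed Integer seed (mandatory).
#' @return A list of class `synth_config`.
#' @export
synth_config <- function(n_sites = 50000,
                         n_chrom = 2000,
                         model = demog_modified_nelson(),
                         category_props = c(
                           human_private = 0.70,
                           substituted_chimpanzee = 0.0297,
                           substituted_gorilla = 0.0414,
                           substituted_orangutan = 0.0601,
                           substituted_gibbon = 0.0885,
                           substituted_macaque = 0.0803),
                         cpg_fraction = c(
                           human_private = 0.17,
                           substituted_chimpanzee = 0.30,
                           substituted_gorilla = 0.25,
                           substituted_orangutan = 0.20,
                           substituted_gibbon = 0.15,
                           substituted_macaque = 0.10),
                         type_rates = default_type_rates,
                         noncpg_weights = default_noncpg_weights,
                         sigma = 0.57,
                         func_props = c(synonymous = 0.3, nonsynonymous = 0.5,
                                        intronic = 0.15, UTR = 0.05),
                         ns_singleton_boost = 0,
                         opportunity_scale = 16,
                         recurrence_threshold = 0.05,
                         spectrum_min_biallelic = 20000,
                         flank_len = 5,
                         seed = 1L) {
  stopifnot(!is.null(seed), n_sites >= 1, n_chrom >= 4)
  if (abs(sum(category_props) - 1) > 1e-8) stop("category_props must sum to 1")
  if (abs(sum(func_props) - 1) > 1e-8) stop("func_props must sum to 1")
  stopifnot(all(names(cpg_fraction) == names(category_props)),
            "CpG>TpG" %in% names(type_rates),
            all(MONO_TYPES %in% names(type_rates)))
  structure(as.list(environment()), class = "synth_config")
}

# expected total tree length (generations) under the model
expected_tree_length <- function(model, n) {
  Tk <- expected_level_times(model, n, "analytic")
  sum((2:n) * Tk)
}

#' Per-type allele-count spectra used by the generator
#'
#' Computes, for each mutation type of a [synth_config()], the folded
#' spectrum from which minor-allele counts are drawn: the analytic
#' infinite-sites expected spectrum for low-rate types, and a finite-sites
#' simulated spectrum (with the within-type sigma mixture) for types whose
#' expected number of mutation origins per genealogy site exceeds the
#' recurrence threshold.
#'
#' @param config A `synth_config`.
#' @param verbose Report which types are simulated.
#' @return Named list over types: each entry has `probs` (folded spectrum
#'   probabilities), `source` (`"analytic"` or `"simulated"`),
#'   `e_rare` (ground-truth rare fraction), `lambda` (expected origins).
#' @export
synth_type_spectra <- function(config, verbose = FALSE) {
  stopifnot(inherits(config, "synth_config"))
  n <- config$n_chrom
  tl <- expected_tree_length(config$model, n)
  inf_probs <- NULL
  types <- names(config$type_rates)
  out <- purrr::map(types, function(ty) {
    mu <- config$type_rates[[ty]]
    lambda <- mu * config$opportunity_scale * tl
    if (lambda <= config$recurrence_threshold && n <= 5000) {
      if (is.null(inf_probs)) {
        inf_folded <- fold(expected_sfs_infinite(config$model, n, "analytic"))
        inf_probs <<- inf_folded$counts / sum(inf_folded$counts)
      }
      probs <- inf_probs
      src <- "analytic"
    } else {
      if (verbose) message("simulating conditional spectrum for ", ty)
      res <- grid_point_two_stage(epoch_matrix(config$model), n,
                                  mu * config$opportunity_scale,
                                  config$sigma, 1000L,
                                  config$spectrum_min_biallelic, 2e5L, 2L)
      folded <- fold(sfs_unfolded(res$sfs_derived, n))
      probs <- folded$counts / sum(folded$counts)
      src <- "simulated"
    }
    rare <- sum(probs[seq_len(min(2, length(probs)))])
    list(probs = probs, source = src, e_rare = rare, lambda = lambda)
  })
  names(out) <- types
  out
}

flank_matrix <- function(n, len) {
  matrix(sample(BASES, n * len, replace = TRUE), n, len)
}

collapse_rows <- function(mat) do.call(paste0, asplit(mat, 2))

# reverse complement of every row, as strings
revcomp_rows <- function(mat) {
  collapse_rows(matrix(chartr("ACGT", "TGCA", mat[, rev(seq_len(ncol(mat))),
                                                  drop = FALSE]),
                       nrow(mat)))
}

#' Generate a synthetic site table with a ground-truth manifest
#'
#' @param config A `synth_config`.
#' @param type_spectra Optional precomputed [synth_type_spectra()] (reused
#'   across calls to avoid recomputation).
#' @return A list with `sites` (tibble in the native dialect), `manifest`
#'   (per-site latent variables) and `type_truth` (per-type ground truth:
#'   mean rate, spectrum source, expected rare fraction, expected origins).
#' @export
generate_sites <- function(config, type_spectra = NULL) {
  stopifnot(inherits(config, "synth_config"))
  set.seed(config$seed)
  if (is.null(type_spectra)) type_spectra <- synth_type_spectra(config)
  n <- config$n_sites
  cats <- names(config$category_props)
  category <- sample(cats, n, replace = TRUE, prob = config$category_props)

  # mutation type given category: CpG fraction gradient, shared non-CpG mix
  ncw <- config$noncpg_weights / sum(config$noncpg_weights)
  mtype <- character(n)
  for (ca in cats) {
    idx <- which(category == ca)
    pc <- config$cpg_fraction[[ca]]
    probs <- c(ncw * (1 - pc), "CpG>TpG" = pc)
    mtype[idx] <- sample(names(probs), length(idx), replace = TRUE, prob = probs)
  }

  # per-site latent rate (mean-preserving lognormal around the type mean)
  mu_site <- unname(unlist(config$type_rates)[mtype])
  site_rate <- mu_site *
    10^(rnorm(n, 0, config$sigma) - config$sigma^2 * log(10) / 2)

  # minor-allele counts from the type-level conditional spectra (the sigma
  # mixture marginal); nonsynonymous selection skew optionally forces
  # singletons
  func_class <- sample(names(config$func_props), n, replace = TRUE,
                       prob = config$func_props)
  minor_count <- integer(n)
  for (ty in unique(mtype)) {
    idx <- which(mtype == ty)
    sp <- type_spectra[[ty]]
    minor_count[idx] <- sample.int(length(sp$probs), length(idx),
                                   replace = TRUE, prob = sp$probs)
  }
  if (config$ns_singleton_boost > 0) {
    hit <- func_class == "nonsynonymous" &
      runif(n) < config$ns_singleton_boost
    minor_count[hit] <- 1L
  }

  # expected number of mutation origins per site (stylized: 1 + Poisson)
  lambda <- purrr::map_dbl(type_spectra, "lambda")[mtype]
  n_origins <- 1L + stats::rpois(n, lambda)

  # alleles in pyrimidine-major form, then random strand presentation
  is_cpg <- mtype == "CpG>TpG"
  maj <- ifelse(is_cpg, "C", substr(mtype, 1, 1))
  min_ <- ifelse(is_cpg, "T", substr(mtype, 3, 3))
  umat <- flank_matrix(n, config$flank_len)
  dmat <- flank_matrix(n, config$flank_len)
  # enforce CpG context for CpG sites and break it for plain C>T sites
  breaks_g <- !is_cpg & maj == "C" & min_ == "T" & dmat[, 1] == "G"
  dmat[is_cpg, 1] <- "G"
  dmat[breaks_g, 1] <- sample(c("A", "C", "T"), sum(breaks_g), replace = TRUE)
  up <- collapse_rows(umat)
  down <- collapse_rows(dmat)

  flip <- runif(n) < 0.5
  major <- ifelse(flip, unname(COMP[maj]), maj)
  minor <- ifelse(flip, unname(COMP[min_]), min_)
  flank_up <- ifelse(flip, revcomp_rows(dmat), up)
  flank_down <- ifelse(flip, revcomp_rows(umat), down)

  # primate alleles consistent with the category (complete data)
  pm <- matrix(major, n, length(ascertainment_species),
               dimnames = list(NULL, ascertainment_species))
  for (sp in primate_species) {
    hit <- category == paste0("substituted_", sp)
    pm[hit, sp] <- minor[hit]
  }

  sites <- tibble::tibble(
    chrom = "chr1",
    pos = seq_len(n),
    major = major, minor = minor,
    minor_count = minor_count,
    total_chroms = as.integer(config$n_chrom),
    flank_up = flank_up, flank_down = flank_down,
    strand = sample(c("+", "-"), n, replace = TRUE),
    func_class = func_class,
    recomb_rate = stats::rlnorm(n, meanlog = 0, sdlog = 1),
    chromatin = sample(paste0("state", 1:5), n, replace = TRUE)
  )
  sites <- dplyr::bind_cols(sites, tibble::as_tibble(pm))

  manifest <- tibble::tibble(
    pos = sites$pos,
    category = category,
    mutation_type = mtype,
    site_rate = site_rate,
    n_origins = n_origins,
    func_class = func_class,
    strand_presented = ifelse(flip, "revcomp", "as_typed")
  )
  type_truth <- tibble::tibble(
    mutation_type = names(type_spectra),
    mu = unname(unlist(config$type_rates)[names(type_spectra)]),
    source = unname(purrr::map_chr(type_spectra, "source")),
    e_rare = unname(purrr::map_dbl(type_spectra, "e_rare")),
    lambda = unname(purrr::map_dbl(type_spectra, "lambda"))
  )
  list(sites = sites, manifest = manifest, type_truth = type_truth)
}

#' Split each site's minor copies between two subpopulations
#'
#' By default the allocation is hypergeometric: the `minor_count` copies of
#' each site are distributed between two subsamples of `round(p * total)`
#' and the remaining chromosomes, as if the carriers were exchangeable.
#' Optionally, a stylized population-structure mechanism is layered on
#' top: single-origin sites are made private to one subpopulation with
#' probability `private_prob` (young variants have not spread), while
#' sites with two or more independent mutation origins (`origins >= 2`)
#' place each origin's copies wholly into one subpopulation drawn
#' independently - so recurrent sites show excess sharing at low counts.
#'
#' @param sites Tibble with `minor_count` and `total_chroms`.
#' @param proportion Fraction of chromosomes in subpopulation A, in (0,1).
#' @param seed Integer seed.
#' @param origins Optional integer vector of mutation-origin counts per
#'   site (e.g. the generator manifest's `n_origins`).
#' @param private_prob Probability that a single-origin site is private to
#'   one subpopulation (0 = pure hypergeometric).
#' @return Tibble with `count_a`, `count_b`, `n_a`, `n_b` appended.
#' @export
split_two_populations <- function(sites, proportion = 0.5, seed = 1L,
                                  origins = NULL, private_prob = 0) {
  if (proportion <= 0 || proportion >= 1) stop("proportion must be in (0, 1)")
  stopifnot(all(sites$minor_count >= 1))
  set.seed(seed)
  n <- nrow(sites)
  n_a <- as.integer(round(proportion * sites$total_chroms))
  n_b <- as.integer(sites$total_chroms) - n_a
  count_a <- rhyper(n, m = sites$minor_count,
                    n = sites$total_chroms - sites$minor_count, k = n_a)
  # integer-vector hypergeometric: rhyper recycles over sites
  if (!is.null(origins) || private_prob > 0) {
    if (is.null(origins)) origins <- rep(1L, n)
    single <- origins < 2
    priv <- single & runif(n) < private_prob
    side_a <- runif(n) < proportion
    count_a[priv] <- ifelse(side_a[priv], sites$minor_count[priv], 0L)
    multi <- which(!single)
    for (i in multi) {
      k <- origins[i]
      parts <- as.integer(tabulate(sample.int(k, sites$minor_count[i],
                                              replace = TRUE), nbins = k))
      in_a <- runif(k) < proportion
      count_a[i] <- sum(parts[in_a])
    }
  }
  dplyr::mutate(sites,
                count_a = as.integer(count_a),
                count_b = .data$minor_count - as.integer(count_a),
                n_a = n_a, n_b = n_b)
}
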