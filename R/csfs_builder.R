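# Phylogenetically-conditioned SFS: classify human SNPs by the pattern of
# orthologous primate alleles, annotate mutation types, and summarize the
# conditioned spectra.

#' Primate species used for conditioning
#'
#' Five species can define a substituted-species category, ordered by
#' relatedness to human; baboon is used solely for ascertainment (all-other-
#' species-match checks) and never yields a category of its own.
#' @export
primate_species <- c("chimpanzee", "gorilla", "orangutan", "gibbon", "macaque")

#' @rdname primate_species
#' @export
ascertainment_species <- c(primate_species, "baboon")

#' All substitution categories
#' @export
substitution_categories <- c("human_private",
                             paste0("substituted_", primate_species),
                             "other")

BASES <- c("A", "C", "G", "T")
COMP <- c(A = "T", C = "G", G = "C", T = "A")

primate_allele_matrix <- function(sites) {
  missing_cols <- setdiff(ascertainment_species, names(sites))
  if (length(missing_cols) > 0) {
    stop("site table lacks primate allele columns: ",
         paste(missing_cols, collapse = ", "))
  }
  m <- as.matrix(sites[ascertainment_species])
  m[m == "." | m == ""] <- NA_character_
  bad <- !is.na(m) & !(m %in% BASES)
  if (any(bad)) stop("primate alleles must be A/C/G/T or '.' (missing)")
  m
}

#' Classify sites by primate substitution pattern
#'
#' A site is `human_private` when every non-missing primate allele equals
#' the human major allele; it is `substituted_<species>` when exactly that
#' one species carries the human minor allele and all other primates
#' (baboon included) carry the human major allele. Everything else is
#' `other`. In the default strict mode a substituted call additionally
#' requires all six primate alleles to be non-missing (the ascertainment
#' uses baboon); `strict = FALSE` ignores missing species.
#'
#' @param sites Site table with human `major`/`minor` allele columns and one
#'   allele column per species in `ascertainment_species` (`"."` = missing).
#' @param strict Require all six primates non-missing for substituted calls.
#' @return `sites` with a `category` column added (factor over
#'   [substitution_categories]).
#' @export
classify_category <- function(sites, strict = TRUE) {
  m <- primate_allele_matrix(sites)
  if (any(rowSums(!is.na(m)) == 0)) {
    stop("sites with all primate alleles missing cannot be classified")
  }
  eq_major <- m == sites$major
  eq_minor <- m == sites$minor
  n_obs <- rowSums(!is.na(m))
  n_major <- rowSums(eq_major, na.rm = TRUE)
  n_minor <- rowSums(eq_minor, na.rm = TRUE)
  private <- n_major == n_obs
  category <- rep("other", nrow(sites))
  category[private] <- "human_private"
  complete <- n_obs == length(ascertainment_species)
  for (sp in primate_species) {
    is_sub <- !is.na(eq_minor[, sp]) & eq_minor[, sp] &
      n_minor == 1 & (n_major == n_obs - 1)
    if (strict) is_sub <- is_sub & complete
    category[is_sub] <- paste0("substituted_", sp)
  }
  dplyr::mutate(sites,
                category = factor(category, levels = substitution_categories))
}

#' Most closely related primate carrying the human minor allele
#'
#' Alternative conditioning: instead of requiring exactly one substituted
#' species, label each site by the nearest species (chimpanzee < gorilla <
#' orangutan < gibbon < macaque) whose allele equals the human minor allele.
#'
#' @inheritParams classify_category
#' @return `sites` with a `closest_carrier` column (`NA` when no species
#'   carries the minor allele).
#' @export
closest_minor_carrier <- function(sites) {
  m <- primate_allele_matrix(sites)[, primate_species, drop = FALSE]
  eq_minor <- !is.na(m) & m == sites$minor
  idx <- apply(eq_minor, 1, function(z) if (any(z)) which(z)[1] else NA_integer_)
  dplyr::mutate(sites, closest_carrier = primate_species[idx])
}

flank_context <- function(sites) {
  up <- toupper(substring(sites$flank_up, nchar(sites$flank_up)))
  down <- toupper(substr(sites$flank_down, 1, 1))
  up[up == ""] <- NA_character_
  down[down == ""] <- NA_character_
  list(up = up, down = down)
}

is_cpg_transition <- function(sites) {
  ctx <- flank_context(sites)
  (sites$major == "C" & sites$minor == "T" & !is.na(ctx$down) & ctx$down == "G") |
  (sites$major == "G" & sites$minor == "A" & !is.na(ctx$up) & ctx$up == "C")
}

#' Annotate mutation types
#'
#' Types are computed on the major-to-minor change and collapsed with the
#' reverse complement so that each type refers to a change on either strand
#' (six mononucleotide types with major allele written as A or C). At level
#' `"cpg_ti"` a C-to-T change in CpG context (or G-to-A with a preceding C)
#' overrides the `C>T` label with `CpG>TpG`. Level `"trimer"` appends the
#' two flanking reference bases, also strand-collapsed. Sites whose needed
#' context base is ambiguous (N or absent) get an `NA` type and are flagged.
#'
#' @inheritParams classify_category
#' @param level `"mono"`, `"cpg_ti"` or `"trimer"`.
#' @return `sites` with columns `mutation_type`, `is_cpg` and
#'   `type_flagged` added.
#' @export
mutation_type <- function(sites, level = c("cpg_ti", "mono", "trimer")) {
  level <- match.arg(level)
  stopifnot(all(sites$major %in% BASES), all(sites$minor %in% BASES))
  flip <- sites$major %in% c("G", "T")
  maj <- ifelse(flip, COMP[sites$major], sites$major)
  min_ <- ifelse(flip, COMP[sites$minor], sites$minor)
  cpg <- is_cpg_transition(sites)
  type <- paste0(maj, ">", min_)
  flagged <- rep(FALSE, nrow(sites))
  if (level == "cpg_ti") {
    ctx <- flank_context(sites)
    # C>T sites need the CpG-defining context base to be unambiguous
    need <- type == "C>T"
    ctx_base <- ifelse(sites$major == "C", ctx$down, ctx$up)
    flagged <- need & (is.na(ctx_base) | !(ctx_base %in% BASES))
    type[cpg] <- "CpG>TpG"
    type[flagged] <- NA_character_
  } else if (level == "trimer") {
    ctx <- flank_context(sites)
    up <- ifelse(flip, COMP[ctx$down], ctx$up)
    down <- ifelse(flip, COMP[ctx$up], ctx$down)
    flagged <- is.na(up) | is.na(down) | !(up %in% BASES) | !(down %in% BASES)
    type <- ifelse(flagged, NA_character_,
                   paste0(up, "[", maj, ">", min_, "]", down))
  }
  dplyr::mutate(sites, mutation_type = type, is_cpg = cpg,
                type_flagged = flagged)
}

#' Build the phylogenetically-conditioned SFS
#'
#' Groups classified sites by substitution category (or by closest minor
#' carrier) and functional class, and summarizes each conditioned spectrum:
#' number of sites, rare fraction with an exact binomial 95% CI, the folded
#' spectrum (when all sites share one chromosome sample size) and its CDF.
#' Categories with no sites are reported with zero counts.
#'
#' @param sites Site table with `minor_count`, `total_chroms`, `func_class`
#'   and either a `category` column (from [classify_category()]) or the
#'   columns needed to compute one.
#' @param conditioning `"substituted"` (default) or `"closest"`.
#' @param functional Optional character vector restricting `func_class`.
#' @param rare_max_count Rare threshold on the minor-allele count.
#' @param strict Passed to [classify_category()] when classification is
#'   needed.
#' @return A tibble with one row per category (x functional class when
#'   present): `category`, `func_class`, `n_sites`, `rare_fraction`,
#'   `ci_lo`, `ci_hi`, and list-columns `spectrum` (folded `sfs` or `NULL`)
#'   and `cdf` (tibble of minor count vs cumulative proportion).
#' @export
build_csfs <- function(sites, conditioning = c("substituted", "closest"),
                       functional = NULL, rare_max_count = 2, strict = TRUE) {
  conditioning <- match.arg(conditioning)
  if (conditioning == "substituted") {
    if (!"category" %in% names(sites)) sites <- classify_category(sites, strict)
    sites$._cat <- as.character(sites$category)
    levels_cat <- substitution_categories
  } else {
    if (!"closest_carrier" %in% names(sites)) sites <- closest_minor_carrier(sites)
    sites$._cat <- ifelse(is.na(sites$closest_carrier), "human_private",
                          paste0("closest_", sites$closest_carrier))
    levels_cat <- c("human_private", paste0("closest_", primate_species))
  }
  if (!is.null(functional)) sites <- dplyr::filter(sites, .data$func_class %in% functional)
  has_func <- "func_class" %in% names(sites)
  keys <- if (has_func) {
    tidyr::expand_grid(._cat = levels_cat,
                       func_class = sort(unique(sites$func_class)))
  } else tibble::tibble(._cat = levels_cat)

  summarise_group <- function(df) {
    n <- nrow(df)
    if (n == 0) {
      return(tibble::tibble(n_sites = 0L, rare_fraction = NA_real_,
                            ci_lo = NA_real_, ci_hi = NA_real_,
                            spectrum = list(NULL), cdf = list(NULL)))
    }
    n_rare <- sum(df$minor_count <= rare_max_count)
    ci <- stats::binom.test(n_rare, n)$conf.int
    spec <- NULL
    if (length(unique(df$total_chroms)) == 1) {
      nn <- df$total_chroms[1]
      counts <- tabulate(df$minor_count, nbins = nn %/% 2)
      spec <- sfs_folded(counts, nn)
    }
    cdf <- df |>
      dplyr::count(.data$minor_count, name = "n_sites") |>
      dplyr::arrange(.data$minor_count) |>
      dplyr::mutate(cum_prop = cumsum(.data$n_sites) / n)
    tibble::tibble(n_sites = n, rare_fraction = n_rare / n,
                   ci_lo = ci[1], ci_hi = ci[2],
                   spectrum = list(spec), cdf = list(cdf))
  }

  by_cols <- intersect(c("._cat", "func_class"), names(keys))
  out <- keys |>
    dplyr::mutate(.row = dplyr::row_number()) |>
    dplyr::group_by(.data$.row) |>
    dplyr::reframe({
      key <- dplyr::pick(dplyr::all_of(by_cols))
      df <- dplyr::inner_join(sites, key, by = by_cols)
      dplyr::bind_cols(key, summarise_group(df))
    }) |>
    dplyr::select(-".row") |>
    dplyr::rename(category = "._cat")
  out
}

#' Fraction of CpG transitions per substitution category
#'
#' @inheritParams build_csfs
#' @return A tibble with `category`, `n_sites`, `n_cpg`, `cpg_fraction` and
#'   exact binomial 95% CI columns.
#' @export
cpg_fraction_by_category <- function(sites, strict = TRUE) {
  if (!"category" %in% names(sites)) sites <- classify_category(sites, strict)
  if (!"is_cpg" %in% names(sites)) sites <- mutation_type(sites, "cpg_ti")
  sites |>
    dplyr::group_by(.data$category, .drop = FALSE) |>
    dplyr::summarise(n_sites = dplyr::n(), n_cpg = sum(.data$is_cpg)) |>
    dplyr::mutate(
      cpg_fraction = ifelse(.data$n_sites > 0, .data$n_cpg / .data$n_sites, 0),
      ci = purrr::map2(.data$n_cpg, .data$n_sites, function(x, n) {
        if (n == 0) c(NA_real_, NA_real_) else stats::binom.test(x, n)$conf.int
      }),
      ci_lo = purrr::map_dbl(.data$ci, 1),
      ci_hi = purrr::map_dbl(.data$ci, 2)
    ) |>
    dplyr::select(-"ci")
}

#' Partition transcribed sites by coding vs template strand
#'
#' Re-expresses each site's mutation change relative to the coding strand of
#' its gene (no reverse-complement collapse): a site whose coding-strand
#' change has major allele A or C is labelled `coding` for the collapsed
#' type, otherwise `template`. CpG transitions are excluded, as are
#' strandless sites (their count is reported via a message).
#'
#' @inheritParams classify_category
#' @return Annotated tibble with columns `mutation_type` (collapsed),
#'   `change_coding` (uncollapsed coding-strand change) and `strand_class`.
#' @export
strand_partition <- function(sites) {
  stopifnot("strand" %in% names(sites))
  if (!"is_cpg" %in% names(sites)) sites <- mutation_type(sites, "cpg_ti")
  strandless <- is.na(sites$strand) | !(sites$strand %in% c("+", "-"))
  if (any(strandless)) {
    message(sum(strandless), " strandless sites excluded from strand partition")
  }
  df <- sites[!strandless & !sites$is_cpg, , drop = FALSE]
  on_minus <- df$strand == "-"
  maj_c <- ifelse(on_minus, COMP[df$major], df$major)
  min_c <- ifelse(on_minus, COMP[df$minor], df$minor)
  flip <- maj_c %in% c("G", "T")
  dplyr::mutate(df,
    change_coding = paste0(maj_c, ">", min_c),
    mutation_type = paste0(ifelse(flip, COMP[maj_c], maj_c), ">",
                           ifelse(flip, COMP[min_c], min_c)),
    strand_class = ifelse(flip, "template", "coding")
  )
}

#' Weighted regression of per-type rare fractions on mutation rates
#'
#' Weighted least squares of the rare-variant fraction on the de novo
#' mutation rate across mutation types, weighted by per-type site counts.
#'
#' @param types Data frame with columns `rare_fraction`, `rate` and
#'   `n_sites` (weights), one row per mutation type.
#' @return A list with `slope`, `intercept`, `se`, `p_value` and the fitted
#'   `lm` object.
#' @export
rate_vs_rare_regression <- function(types) {
  stopifnot(all(c("rare_fraction", "rate", "n_sites") %in% names(types)))
  if (nrow(types) < 3) stop("need at least 3 mutation types")
  if (length(unique(types$rate)) == 1) stop("all mutation rates are equal; slope undefined")
  fit <- lm(rare_fraction ~ rate, data = types, weights = types$n_sites)
  s <- summary(fit)$coefficients
  list(slope = s["rate", "Estimate"], intercept = s["(Intercept)", "Estimate"],
       se = s["rate", "Std. Error"], p_value = s["rate", "Pr(>|t|)"], fit = fit)
}
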