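# build coding site tables with controlled rare probabilities
make_logit_sites <- function(n, rare_prob_fn, seed = 1,
                             cats = c("human_private", paste0("substituted_",
                                                             primate_species)),
                             cat_probs = c(0.5, rep(0.1, 5))) {
  set.seed(seed)
  cat <- sample(cats, n, TRUE, prob = cat_probs)
  type <- sample(c("A>C", "A>G", "C>T"), n, TRUE, prob = c(0.3, 0.4, 0.3))
  z <- sample(c(0L, 1L), n, TRUE)
  p <- rare_prob_fn(cat, type, z)
  maj <- ifelse(substr(type, 1, 1) == "A", "A", "C")
  min_ <- substr(type, 3, 3)
  tbl <- tibble::tibble(
    chrom = "chr1", pos = seq_len(n), major = maj, minor = min_,
    minor_count = ifelse(runif(n) < p, 1L, 20L), total_chroms = 2000L,
    flank_up = "AAACA", flank_down = "ATACA",
    strand = "+",
    func_class = ifelse(z == 1, "nonsynonymous", "synonymous"),
    category = factor(cat, levels = substitution_categories)
  )
  for (sp in ascertainment_species) tbl[[sp]] <- tbl$major
  for (sp in primate_species) {
    hit <- cat == paste0("substituted_", sp)
    tbl[[sp]][hit] <- tbl$minor[hit]
  }
  tbl
}

test_that("the saturated model reproduces raw per-category log-odds", {
  probs <- c(human_private = 0.6, substituted_chimpanzee = 0.5,
             substituted_gorilla = 0.45, substituted_orangutan = 0.4,
             substituted_gibbon = 0.35, substituted_macaque = 0.3)
  sites <- make_logit_sites(60000, function(cat, type, z) probs[cat], seed = 2)
  fit <- fit_rare_logit(sites, type_resolution = "none")
  co <- tidy(fit)
  b0 <- co$estimate[co$term == "(Intercept)"]
  emp <- sites |>
    dplyr::group_by(.data$category, syn = .data$func_class == "synonymous") |>
    dplyr::summarise(logit = qlogis(mean(.data$minor_count <= 2)), .groups = "drop")
  for (sp in primate_species) {
    cat <- paste0("substituted_", sp)
    for (block in c("syn", "ns")) {
      est <- co$estimate[co$term == paste0(block, "_", cat)]
      raw <- emp$logit[emp$category == cat & emp$syn == (block == "syn")]
      # saturated cells: fitted log-odds equal observed log-odds exactly,
      # up to the shared human-private baseline
      expect_equal(b0 + est, raw, tolerance = 1e-6)
    }
  }
})

test_that("null species coefficients are z-calibrated across replicates", {
  # rarity depends on mutation type only; species z-scores ~ N(0,1)
  zs <- numeric(0)
  for (r in 1:60) {
    sites <- make_logit_sites(4000, function(cat, type, z)
      c("A>C" = 0.65, "A>G" = 0.5, "C>T" = 0.35)[type], seed = 100 + r)
    fit <- fit_rare_logit(sites, type_resolution = "mono")
    co <- tidy(fit)
    sel <- co$block %in% c("species_syn", "species_ns")
    zs <- c(zs, co$estimate[sel] / co$std_error[sel])
  }
  expect_gt(suppressWarnings(stats::ks.test(zs, "pnorm")$p.value), 0.01)
})

test_that("an injected nonsynonymous-only species gradient is recovered", {
  grad <- c(substituted_chimpanzee = -0.5, substituted_gorilla = -0.35,
            substituted_orangutan = -0.2, substituted_gibbon = -0.1,
            substituted_macaque = 0)
  sites <- make_logit_sites(150000, function(cat, type, z) {
    base <- c("A>C" = 0.6, "A>G" = 0.5, "C>T" = 0.4)[type]
    eff <- ifelse(z == 1 & cat != "human_private", grad[cat], 0)
    plogis(qlogis(base) + ifelse(is.na(eff), 0, eff))
  }, seed = 3)
  fit <- fit_rare_logit(sites, type_resolution = "mono")
  ns <- species_coefficients(fit, "ns")
  syn <- species_coefficients(fit, "syn")
  expect_lt(max(abs(ns - grad[paste0("substituted_", names(ns))])), 0.12)
  expect_lt(max(abs(syn)), 0.1)
  # and the recovered nonsynonymous gradient is monotone in relatedness
  expect_true(all(diff(ns) > -0.05))
})

test_that("log-likelihood is non-decreasing across nested type resolutions", {
  cfg <- synth_config(n_sites = 15000, seed = 12)
  res <- generate_sites(cfg)
  sites <- classify_category(res$sites)
  fits <- purrr::map(c("none", "mono", "trimer"), function(r)
    fit_rare_logit(sites, type_resolution = r))
  ll <- purrr::map_dbl(fits, "log_lik")
  expect_true(all(diff(ll) >= -1e-6))
})

test_that("fitting is invariant to row order and flags separation", {
  sites <- make_logit_sites(20000, function(cat, type, z) 0.5, seed = 5)
  f1 <- fit_rare_logit(sites, "mono")
  set.seed(6)
  f2 <- fit_rare_logit(sites[sample(nrow(sites)), ], "mono")
  expect_equal(tidy(f1)$estimate, tidy(f2)$estimate, tolerance = 1e-10)
  # complete separation: one category entirely rare
  sep <- make_logit_sites(5000, function(cat, type, z)
    ifelse(cat == "substituted_macaque", 1, 0.5), seed = 7)
  expect_error(fit_rare_logit(sep, "none"), "separation")
  # missing categories produce a warning and are dropped
  few <- make_logit_sites(5000, function(cat, type, z) 0.5, seed = 8,
                          cats = c("human_private", "substituted_chimpanzee",
                                   "substituted_gorilla"),
                          cat_probs = c(0.6, 0.2, 0.2))
  expect_warning(fit_rare_logit(few, "none"), "dropped")
})

test_that("exact permutation p-values match full enumeration", {
  tr <- coefficient_trend(c(5, 4, 3, 2, 1), 1:5)
  expect_equal(tr$rho, -1)
  expect_equal(tr$p_value, 2 / 120)
  tr2 <- coefficient_trend(1:5, 1:5)
  expect_equal(tr2$rho, 1)
  expect_equal(tr2$p_value, 2 / 120)
  # one adjacent transposition: |rho| = 0.9, p = 10/120
  tr3 <- coefficient_trend(c(1, 2, 3, 5, 4), 1:5)
  expect_equal(tr3$rho, 0.9)
  expect_equal(tr3$p_value, 10 / 120)
  expect_false(tr3$ties)
  # ties fall back to midranks and are noted
  tr4 <- coefficient_trend(c(1, 1, 2, 3), 1:4)
  expect_true(tr4$ties)
  expect_error(coefficient_trend(1:9, 1:9), "at most 8")
})

test_that("glance reports the fit summary", {
  sites <- make_logit_sites(10000, function(cat, type, z) 0.5, seed = 9)
  g <- glance(fit_rare_logit(sites, "mono"))
  expect_true(g$converged)
  expect_equal(g$n_sites, 10000)
})
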