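test_that("the hand-written fixture is classified exactly", {
  s <- classify_category(fixture_categories())
  expect_equal(as.character(s$category),
               c("human_private", "human_private",
                 "substituted_chimpanzee", "substituted_gorilla",
                 "substituted_orangutan", "substituted_gibbon",
                 "substituted_macaque",
                 "other", "other", "other",
                 "human_private", "other"))
  # lenient mode admits the missing-baboon substituted-orangutan site
  lenient <- classify_category(fixture_categories(), strict = FALSE)
  expect_equal(as.character(lenient$category)[12], "substituted_orangutan")
  # all primate alleles missing is an error
  allmiss <- site_row()
  allmiss[ascertainment_species] <- "."
  expect_error(classify_category(allmiss), "missing")
})

test_that("every random site lands in exactly one category", {
  set.seed(14)
  n <- 400
  tbl <- dplyr::bind_rows(purrr::map(seq_len(n), function(i) {
    maj <- sample(c("A", "C", "G", "T"), 1)
    min_ <- sample(setdiff(c("A", "C", "G", "T"), maj), 1)
    args <- setNames(as.list(sample(c(maj, min_, "G", "."), 6, replace = TRUE)),
                     ascertainment_species)
    args$major <- maj; args$minor <- min_; args$pos <- i
    do.call(site_row, args)
  }))
  keep <- rowSums(as.matrix(tbl[ascertainment_species]) != ".") > 0
  s <- classify_category(tbl[keep, ])
  expect_false(anyNA(s$category))
  expect_true(all(as.character(s$category) %in% substitution_categories))
})

test_that("closest minor carrier respects the relatedness order", {
  s <- closest_minor_carrier(dplyr::bind_rows(
    site_row(gorilla = "C", macaque = "C"),
    site_row(),
    site_row(chimpanzee = "C")
  ))
  expect_equal(s$closest_carrier, c("gorilla", NA, "chimpanzee"))
  # agreement with classify_category on substituted sites
  fix <- classify_category(closest_minor_carrier(fixture_categories()))
  sub <- !is.na(fix$closest_carrier) &
    as.character(fix$category) %in% paste0("substituted_", primate_species)
  expect_equal(paste0("substituted_", fix$closest_carrier[sub]),
               as.character(fix$category)[sub])
})

test_that("mutation types collapse strands and recognize CpG context", {
  s <- mutation_type(dplyr::bind_rows(
    site_row(major = "C", minor = "T", flank_down = "GTTAA"), # CpG>TpG
    site_row(major = "G", minor = "A", flank_up = "AAAAC"),   # CpG>TpG (strand)
    site_row(major = "A", minor = "C"),                       # A>C
    site_row(major = "T", minor = "G"),                       # A>C after collapse
    site_row(major = "C", minor = "T", flank_down = "ATTAA")  # plain C>T
  ), "cpg_ti")
  expect_equal(s$mutation_type, c("CpG>TpG", "CpG>TpG", "A>C", "A>C", "C>T"))
  expect_equal(s$is_cpg, c(TRUE, TRUE, FALSE, FALSE, FALSE))
  # ambiguous context flags the site
  amb <- mutation_type(site_row(major = "C", minor = "T", flank_down = "NTTAA"),
                       "cpg_ti")
  expect_true(amb$type_flagged)
  expect_true(is.na(amb$mutation_type))
})

test_that("type assignment is invariant under reverse complementation", {
  set.seed(15)
  for (i in 1:40) {
    maj <- sample(c("A", "C", "G", "T"), 1)
    min_ <- sample(setdiff(c("A", "C", "G", "T"), maj), 1)
    up <- paste(sample(c("A", "C", "G", "T"), 4, TRUE), collapse = "")
    dn <- paste(sample(c("A", "C", "G", "T"), 4, TRUE), collapse = "")
    a <- site_row(major = maj, minor = min_, flank_up = up, flank_down = dn)
    b <- site_row(major = rc_base(maj), minor = rc_base(min_),
                  flank_up = rc_str(dn), flank_down = rc_str(up))
    for (lvl in c("mono", "cpg_ti", "trimer")) {
      expect_identical(mutation_type(a, lvl)$mutation_type,
                       mutation_type(b, lvl)$mutation_type)
    }
  }
})

test_that("the cSFS summary reports every category and conserves sites", {
  s <- classify_category(fixture_categories())
  res <- build_csfs(s)
  expect_true(all(substitution_categories %in% res$category))
  expect_equal(sum(res$n_sites), nrow(s) * length(unique(s$func_class)) /
                 length(unique(s$func_class)))
  # empty categories are reported with zero sites, not dropped
  empty <- res[res$n_sites == 0, ]
  expect_true(all(is.na(empty$rare_fraction)))
  # closest-carrier conditioning on the same fixture
  res2 <- build_csfs(closest_minor_carrier(s), conditioning = "closest")
  expect_true("closest_gorilla" %in% res2$category |
                sum(res2$n_sites) == nrow(s))
})

test_that("generator rare probabilities are recovered per category", {
  set.seed(16)
  n <- 8000
  rare_p <- c(human_private = 0.6, substituted_chimpanzee = 0.35)
  rows <- purrr::map(seq_len(n), function(i) {
    cat <- sample(names(rare_p), 1, prob = c(0.7, 0.3))
    rare <- runif(1) < rare_p[[cat]]
    site_row(pos = i, minor_count = if (rare) 1 else 25,
             chimpanzee = if (cat == "substituted_chimpanzee") "C" else "A")
  })
  s <- classify_category(dplyr::bind_rows(rows))
  res <- build_csfs(s)
  for (cat in names(rare_p)) {
    row <- res[res$category == cat, ]
    expect_true(row$ci_lo <= rare_p[[cat]] && rare_p[[cat]] <= row$ci_hi)
  }
  # spectra conservation: per-category spectra sum to the overall spectrum
  specs <- res$spectrum[res$n_sites > 0]
  pooled <- Reduce(`+`, lapply(specs, function(x) x$counts))
  expect_equal(sum(pooled), n)
})

test_that("CpG fractions per category come with binomial intervals", {
  s <- mutation_type(classify_category(fixture_categories()), "cpg_ti")
  res <- cpg_fraction_by_category(s)
  expect_true(all(res$cpg_fraction >= 0 & res$cpg_fraction <= 1))
  hp <- res[res$category == "human_private", ]
  expect_equal(hp$n_cpg / hp$n_sites, hp$cpg_fraction)
  none <- res[res$n_sites == 0, ]
  expect_true(all(none$cpg_fraction == 0))
})

test_that("strand partition re-expresses changes on the coding strand", {
  s <- dplyr::bind_rows(
    site_row(major = "A", minor = "G", strand = "+"),
    site_row(major = "A", minor = "G", strand = "-"),
    site_row(major = "T", minor = "C", strand = "+"),
    site_row(major = "C", minor = "T", strand = "N", flank_down = "ATTAA"),
    site_row(major = "C", minor = "T", flank_down = "GTTAA", strand = "+")
  )
  expect_message(part <- strand_partition(s), "strandless")
  # CpG and strandless sites are excluded
  expect_equal(nrow(part), 3)
  expect_equal(part$mutation_type, rep("A>G", 3))
  expect_equal(part$strand_class, c("coding", "template", "template"))
  expect_equal(part$change_coding, c("A>G", "T>C", "T>C"))
})

test_that("an injected strand gap in rare fraction is recovered", {
  set.seed(17)
  n <- 6000
  strand <- sample(c("+", "-"), 2 * n, TRUE)
  coding <- rep(c(TRUE, FALSE), each = n) # coding-strand A>G vs template
  p <- ifelse(coding, 0.45, 0.46) # 1-percentage-point gap
  rows <- purrr::map(seq_len(2 * n), function(i) {
    maj <- if (coding[i] == (strand[i] == "+")) "A" else "T"
    min_ <- if (maj == "A") "G" else "C"
    site_row(pos = i, major = maj, minor = min_, strand = strand[i],
             minor_count = if (runif(1) < p[i]) 1 else 30)
  })
  part <- strand_partition(dplyr::bind_rows(rows))
  res <- part |>
    dplyr::group_by(.data$strand_class) |>
    dplyr::summarise(rare = mean(minor_count <= 2), n = dplyr::n())
  gap <- res$rare[res$strand_class == "template"] -
    res$rare[res$strand_class == "coding"]
  se <- sqrt(sum(0.455 * 0.545 / res$n))
  expect_within_3se(gap, 0.01, se)
})

test_that("weighted regression of rare fraction on rate behaves", {
  types <- tibble::tibble(rate = c(1e-9, 2e-9, 3e-9, 4e-9),
                          rare_fraction = 0.8 - 1e7 * c(1e-9, 2e-9, 3e-9, 4e-9),
                          n_sites = c(10, 20, 30, 40))
  fit <- rate_vs_rare_regression(types)
  expect_equal(fit$slope, -1e7, tolerance = 1e-6)
  expect_lt(sum(stats::residuals(fit$fit)^2), 1e-20)
  # equal weights reduce to ordinary least squares
  types$n_sites <- 5
  types$rare_fraction <- types$rare_fraction + c(0.01, -0.02, 0.015, -0.005)
  w <- rate_vs_rare_regression(types)
  o <- lm(rare_fraction ~ rate, data = types)
  expect_equal(w$slope, unname(coef(o)[2]), tolerance = 1e-10)
  expect_error(rate_vs_rare_regression(types[1:2, ]), "3 mutation types")
  types$rate <- 1e-9
  expect_error(rate_vs_rare_regression(types), "equal")
})
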