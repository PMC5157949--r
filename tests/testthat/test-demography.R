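test_that("model construction enforces a single constant terminal epoch", {
  expect_error(demographic_model(epoch(100, 1e4)), "infinite")
  expect_error(demographic_model(dplyr::bind_rows(epoch(Inf, 1e4), epoch(100, 1e3))),
               "infinite")
  expect_error(demographic_model(
    dplyr::bind_rows(epoch(100, 1e4, 0.02), epoch(Inf, 1e4, 0.01))), "constant")
  expect_error(epoch(0, 1e4), "duration")
  expect_error(epoch(10, -5))
})

test_that("population size follows the piecewise-exponential trajectory", {
  m <- demographic_model(dplyr::bind_rows(epoch(100, 1e6, 0.05), epoch(Inf, 1e4)),
                         growth_mode = "compound")
  expect_equal(population_size(m, 0), 1e6)
  expect_equal(population_size(m, 50), 1e6 * 1.05^-50)
  expect_equal(population_size(m, 150), 1e4)
  me <- demographic_model(dplyr::bind_rows(epoch(100, 1e6, 0.05), epoch(Inf, 1e4)),
                          growth_mode = "exponential")
  expect_equal(population_size(me, 50), 1e6 * exp(-0.05 * 50))
})

test_that("demographic models round-trip through YAML", {
  path <- tempfile(fileext = ".yaml")
  m <- demog_tennessen_eur()
  write_demog_yaml(m, path)
  r <- read_demog_yaml(path)
  expect_equal(r$epochs$size, m$epochs$size, tolerance = 1e-12)
  expect_equal(r$epochs$duration, m$epochs$duration)
  expect_equal(r$growth_mode, m$growth_mode)
  unlink(path)
})

test_that("constant-size expected SFS matches the 1/i law exactly", {
  e <- expected_sfs_infinite(demog_constant(1e4), 4)
  expect_equal(e$counts, c(6, 3, 2) / 11, tolerance = 1e-10)
  # harmonic-sum rare fraction at n = 100
  H99 <- sum(1 / (1:99))
  expect_equal(expected_rare_fraction(demog_constant(5e3), 100),
               (1 + 1 / 2 + 1 / 98 + 1 / 99) / H99, tolerance = 1e-8)
  # rare fraction is independent of the constant size
  expect_equal(expected_rare_fraction(demog_constant(1e3), 50),
               expected_rare_fraction(demog_constant(1e6), 50), tolerance = 1e-8)
})

test_that("growth skews the expected SFS towards rare variants", {
  n <- 500
  expect_gt(expected_rare_fraction(demog_modified_nelson(), n),
            expected_rare_fraction(demog_constant(1e4), n))
  expect_gt(expected_rare_fraction(demog_tennessen_eur(), n),
            expected_rare_fraction(demog_constant(1e4), n))
})

test_that("analytic and simulated expected spectra agree under growth", {
  m <- demog_modified_nelson()
  a <- expected_rare_fraction(m, 60)
  s <- expected_rare_fraction(m, 60, method = "simulation", reps = 3000, seed = 2)
  expect_within_3se(s, a, attr(s, "se"))
  # full spectra, small n: sup-norm agreement within MC noise
  sa <- expected_sfs_infinite(m, 12)
  ss <- expected_sfs_infinite(m, 12, method = "simulation", reps = 20000, seed = 3)
  expect_lt(max(abs(sa$counts - ss$counts)), 0.01)
})

test_that("piecewise model with equal sizes is indistinguishable from constant", {
  m_pieces <- demographic_model(
    dplyr::bind_rows(epoch(300, 2e3), epoch(700, 2e3), epoch(Inf, 2e3)))
  set.seed(7)
  t1 <- cpp_coal_times(20L, csfs:::epoch_matrix(m_pieces), 800L)$tmrca
  t2 <- cpp_coal_times(20L, csfs:::epoch_matrix(demog_constant(2e3)), 800L)$tmrca
  expect_gt(suppressWarnings(stats::ks.test(t1, t2)$p.value), 0.01)
})

test_that("lineage-survival probability behaves like the textbook case", {
  m <- demog_constant(1e4)
  expect_equal(prob_two_or_more_lineages(m, 10, 0), 1)
  expect_equal(prob_two_or_more_lineages(m, 2, 5000), exp(-5000 / 2e4))
  # monotone non-increasing in t (simulated)
  ps <- vapply(c(1e3, 1e4, 5e4, 2e5),
               function(t) as.numeric(prob_two_or_more_lineages(m, 8, t,
                                                                reps = 4000,
                                                                seed = 11)),
               numeric(1))
  expect_true(all(diff(ps) <= 0.02))
})

test_that("the ancestral-polymorphism bound matches a brute-force oracle", {
  m <- demog_constant(1000)
  expect_equal(as.numeric(ancestral_polymorphism_bound(m, 4, 0)), 1)
  b <- ancestral_polymorphism_bound(m, 4, 1000, reps = 40000, seed = 9)
  # independent oracle from plain exponential level times
  set.seed(99)
  T4 <- rexp(2e5, 6 / 2000); T3 <- rexp(2e5, 3 / 2000); T2 <- rexp(2e5, 1 / 2000)
  L <- 4 * T4 + 3 * T3 + 2 * T2
  oracle <- sum(L * ((T4 + T3 + T2) > 1000)) / sum(L)
  expect_within_3se(as.numeric(b), oracle, attr(b, "se"))
})

test_that("worst-case bound dominates and grows with the terminal size", {
  m <- demographic_model(dplyr::bind_rows(epoch(150, 200), epoch(Inf, 1500)),
                         "bottleneck")
  t_split <- 600
  bw <- ancestral_polymorphism_bound(m, 10, t_split, worst_case = TRUE,
                                     reps = 20000, seed = 3)
  bn <- ancestral_polymorphism_bound(m, 10, t_split, worst_case = FALSE,
                                     reps = 20000, seed = 3)
  expect_gte(as.numeric(bw) + 2 * attr(bw, "se"), as.numeric(bn))
  # monotone non-decreasing in the pre-OOA size
  sizes <- c(500, 1500, 5000)
  bs <- vapply(sizes, function(N) {
    mm <- demographic_model(dplyr::bind_rows(epoch(150, 200), epoch(Inf, N)), "b")
    as.numeric(ancestral_polymorphism_bound(mm, 10, t_split, worst_case = TRUE,
                                            reps = 20000, seed = 5))
  }, numeric(1))
  expect_true(all(diff(bs) > -0.01))
  expect_error(ancestral_polymorphism_bound(m, 10, 100, worst_case = TRUE),
               "terminal")
})

test_that("expected shared-site arithmetic rounds to the nearest site", {
  expect_identical(expected_shared_sites(1.4e-5, 3531936), 49L)
  expect_identical(expected_shared_sites(1.0e-5, 3531936), 35L)
  expect_identical(expected_shared_sites(0, 1e7), 0L)
})
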