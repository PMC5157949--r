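test_that("branch substitution probabilities honor the clock categories", {
  mix <- clock_mix(w_u = 0.3, r_u = 5e-10, r_g = 1e-8, sigma = 0.5)
  br <- primate_branches()[3, ] # orangutan
  expect_equal(branch_substitution_prob(0, br, "U", mix), 0)
  expect_equal(branch_substitution_prob(0, br, "G", mix), 0)
  # U is invariant to generation time
  br2 <- br; br2$gen_time_years <- br$gen_time_years * 3
  M <- c(0.2, 1, 4)
  expect_equal(branch_substitution_prob(M, br, "U", mix),
               branch_substitution_prob(M, br2, "U", mix))
  # doubling generation time halves the small-rate G probability
  small <- clock_mix(w_u = 0.3, r_u = 5e-13, r_g = 1e-12, sigma = 0.5)
  p1 <- branch_substitution_prob(1, br, "G", small)
  br_twice <- br; br_twice$gen_time_years <- 2 * br$gen_time_years
  p2 <- branch_substitution_prob(1, br_twice, "G", small)
  expect_lt(p1, 0.01)
  expect_equal(p1 / p2, 2, tolerance = 0.01)
})

test_that("posterior rate densities are normalized and size-biased", {
  mix <- clock_mix()
  d <- rate_distribution_at_substituted_sites("gibbon", mix)
  lx <- log10(d$M)
  trap <- function(y) sum(diff(lx) * (head(y, -1) + tail(y, -1)) / 2)
  expect_equal(trap(d$density), 1, tolerance = 1e-6)
  # conditioning on polymorphism alone already enriches high multipliers
  dp <- rate_distribution_at_substituted_sites("gibbon", mix,
                                               conditioning = "polymorphic")
  dr <- rate_distribution_at_substituted_sites("gibbon", mix,
                                               conditioning = "random")
  mean_of <- function(d_) trap(d_$M * d_$density)
  expect_gt(mean_of(dp), mean_of(dr))
  expect_equal(mean_of(dr), 1, tolerance = 1e-3) # multiplier has mean 1
  expect_gt(mean_of(d), mean_of(dp)) # substitution conditioning adds more
})

test_that("a pure uniform-clock model is identical across substituted species", {
  # densities coincide exactly in the linear (small-rate) regime, where the
  # per-branch substitution probability is proportional to branch length
  # and the branch scale cancels on normalization
  mix_small <- clock_mix(w_u = 1, r_u = 1e-16, sigma = 0.5)
  ds <- purrr::map(c("chimpanzee", "gibbon", "macaque"), function(sp) {
    rate_distribution_at_substituted_sites(sp, mix_small)$density
  })
  expect_lt(max(abs(ds[[1]] - ds[[2]])), 1e-6)
  expect_lt(max(abs(ds[[1]] - ds[[3]])), 1e-6)
})

test_that("two-category posterior mean rises with generation time", {
  mix <- clock_mix(w_u = 0.25, r_u = 5e-10, r_g = 1.2e-8, sigma = 0.57)
  br <- primate_branches()
  br$split_years <- rep(1e7, 5) # isolate the generation-time effect
  br$gen_time_years <- c(8, 12, 18, 24, 30)
  means <- purrr::map_dbl(br$species, function(sp) {
    d <- rate_distribution_at_substituted_sites(sp, mix, branches = br)
    lx <- log10(d$M)
    sum(diff(lx) * (head(d$M * d$density, -1) + tail(d$M * d$density, -1)) / 2)
  })
  expect_true(all(diff(means) > 0))
  # rejection-sampling oracle for one species
  set.seed(23)
  M <- 10^(rnorm(3e5, 0, 0.57) - 0.57^2 * log(10) / 2)
  cat_u <- runif(3e5) < 0.25
  t <- 1e7; g <- 30
  p_poly <- ifelse(cat_u, mix$r_u * 29, mix$r_g) * M
  p_sub <- ifelse(cat_u, -expm1(-mix$r_u * M * t), -expm1(-mix$r_g * M * t / g))
  w <- p_poly * p_sub
  keep <- runif(3e5) < w / max(w)
  oracle <- mean(M[keep])
  se <- sd(M[keep]) / sqrt(sum(keep))
  expect_within_3se(means[5], oracle, se + 1e-3)
})

test_that("uniform-clock enrichment tracks generation time, not relatedness", {
  mix <- clock_mix(w_u = 0.2, r_u = 5e-10, r_g = 1.2e-8, sigma = 0.57)
  br <- primate_branches()
  # equal generation times: enrichment identical across species only when
  # branch lengths are also equal (the yearly clocks integrate branch length)
  br_eq <- br
  br_eq$gen_time_years <- rep(20, 5)
  br_eq$split_years <- rep(1e7, 5)
  enr_eq <- uniform_clock_enrichment(mix, branches = br_eq)
  expect_lt(diff(range(enr_eq$enrichment_u)), 1e-10)
  # enrichment strictly increasing in generation time, all else fixed
  br_g <- br_eq
  br_g$gen_time_years <- c(8, 12, 18, 24, 30)
  enr_g <- uniform_clock_enrichment(mix, branches = br_g)
  expect_true(all(diff(enr_g$enrichment_u) > 0))
})

test_that("a two-species toy matches the closed-form category posterior", {
  # in the linear (small-rate, sigma -> 0) regime with P(poly) ~ rate:
  # posterior odds U:G = w_u (r_u g_h)(r_u t) : w_g r_g (r_g t / g)
  mix <- clock_mix(w_u = 0.4, r_u = 1e-13, r_g = 2e-12, sigma = 0.01)
  br <- primate_branches()[1, ]
  enr <- uniform_clock_enrichment(mix, branches = br)$enrichment_u
  odds <- (0.4 * (1e-13 * 29) * 1e-13) /
    (0.6 * 2e-12 * (2e-12 / br$gen_time_years))
  expect_equal(enr / (1 - enr), odds, tolerance = 0.01)
})

test_that("enrichment depends only on rate ratios in the small-rate limit", {
  br <- primate_branches()
  e1 <- uniform_clock_enrichment(clock_mix(w_u = 0.2, r_u = 1e-12,
                                           r_g = 4e-12, sigma = 0.4),
                                 branches = br)
  e2 <- uniform_clock_enrichment(clock_mix(w_u = 0.2, r_u = 1e-13,
                                           r_g = 4e-13, sigma = 0.4),
                                 branches = br)
  expect_equal(e1$enrichment_u, e2$enrichment_u, tolerance = 1e-3)
})
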