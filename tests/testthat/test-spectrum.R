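test_that("folding pools complementary classes and conserves sites", {
  expect_equal(fold(sfs_unfolded(c(4, 3, 2, 1, 0), 6))$counts, c(4, 4, 2))
  expect_equal(fold(sfs_unfolded(c(5, 2, 1), 4))$counts, c(6, 2))
  s <- sfs_unfolded(rpois(19, 10), 20)
  expect_equal(sum(fold(s)$counts), sum(s$counts))
  # odd sample size: no self-complementary class
  s2 <- sfs_unfolded(rpois(8, 5), 9)
  expect_equal(sum(fold(s2)$counts), sum(s2$counts))
  expect_identical(fold(fold(s2)), fold(s2))
})

test_that("constructors validate lengths and signs", {
  expect_error(sfs_unfolded(c(1, 2), 4), "n - 1")
  expect_error(sfs_folded(c(1, 2, 3), 4), "floor")
  expect_error(sfs_unfolded(c(-1, 0, 1), 4), "nonnegative")
})

test_that("fraction_rare matches hand-computed examples", {
  expect_equal(fraction_rare(sfs_folded(c(12, 8, 5, 5), 8)), 20 / 30)
  expect_equal(fraction_rare(sfs_folded(c(0, 0, 7), 6)), 0)
  expect_equal(fraction_rare(sfs_unfolded(c(4, 3, 2, 1, 0), 6)), 0.8)
  expect_error(fraction_rare(sfs_folded(c(0, 0, 0), 6)), "no segregating")
  # invariant to rescaling all counts
  s <- sfs_folded(c(3, 1, 4, 1, 5), 10)
  expect_equal(fraction_rare(s), fraction_rare(sfs_folded(s$counts * 7.5, 10)))
})

test_that("fraction_maf_le thresholds on minor count over n", {
  counts <- rep(1, 100)
  s <- sfs_folded(counts, 200)
  expect_equal(fraction_maf_le(s, 0.01), 2 / 100) # classes 1 and 2
  expect_equal(fraction_maf_le(s, 0.5), 1)
  # equivalence with fraction_rare when threshold * n = rare_max_count
  expect_equal(fraction_maf_le(s, 2 / 200), fraction_rare(s, 2))
  expect_error(fraction_maf_le(s, 0), "0.5")
  expect_error(fraction_maf_le(s, 0.6), "0.5")
})

test_that("projection matches the exhaustively enumerated subsample", {
  # one site with 2 derived copies among n=4, projected to m=2:
  # C(4,2)=6 subsamples; 4 give one derived copy, 1 gives two, 1 gives none
  p <- project_sfs(sfs_unfolded(c(0, 1, 0), 4), 2)
  expect_equal(p$counts, 4 / 6)
  expect_equal(attr(p, "lost"), 1 / 6)
  expect_equal(attr(p, "fixed"), 1 / 6)
})

test_that("projection is the identity at m = n and errors out of range", {
  s <- sfs_unfolded(c(4, 3, 2, 1, 0), 6)
  expect_identical(project_sfs(s, 6), s)
  expect_error(project_sfs(s, 7), "2 <= m <= n")
  expect_error(project_sfs(s, 1), "2 <= m <= n")
  expect_error(project_sfs(fold(s), 4), "unfolded")
})

test_that("projection equals exhaustive subsample enumeration for n <= 8", {
  # independent oracle: enumerate all C(n, m) chromosome subsets directly
  enumerate_projection <- function(counts, n, m) {
    out <- numeric(m + 1)
    subsets <- utils::combn(n, m)
    for (i in seq_len(n - 1)) {
      if (counts[i] == 0) next
      derived <- seq_len(i) # which chromosomes carry the derived allele
      hits <- colSums(matrix(subsets %in% derived, nrow = m))
      tab <- tabulate(hits + 1, nbins = m + 1)
      out <- out + counts[i] * tab / ncol(subsets)
    }
    out
  }
  set.seed(11)
  for (n in 4:8) {
    counts <- rpois(n - 1, 3)
    counts[1] <- counts[1] + 1
    s <- sfs_unfolded(counts, n)
    for (m in 2:(n - 1)) {
      oracle <- enumerate_projection(counts, n, m)
      p <- project_sfs(s, m)
      expect_equal(p$counts, oracle[2:m], tolerance = 1e-12)
      expect_equal(attr(p, "lost"), oracle[1], tolerance = 1e-12)
      expect_equal(attr(p, "fixed"), oracle[m + 1], tolerance = 1e-12)
    }
  }
})

test_that("projection is linear and composes", {
  set.seed(2)
  a <- sfs_unfolded(rpois(11, 6), 12)
  b <- sfs_unfolded(rpois(11, 2), 12)
  both <- sfs_unfolded(a$counts + 2 * b$counts, 12)
  expect_equal(project_sfs(both, 6)$counts,
               project_sfs(a, 6)$counts + 2 * project_sfs(b, 6)$counts,
               tolerance = 1e-12)
  # project(project(S, m1), m2) = project(S, m2)
  once <- project_sfs(a, 5)
  twice <- project_sfs(project_sfs(a, 9), 5)
  expect_equal(once$counts, twice$counts, tolerance = 1e-10)
})

test_that("projected rare fraction agrees with Monte-Carlo subsampling", {
  set.seed(33)
  n <- 40
  counts <- c(rpois(20, 50), rpois(19, 5))
  s <- sfs_unfolded(counts, n)
  m <- 10
  expected <- fraction_rare(project_sfs(s, m))
  # simulate subsampling of individual sites
  reps <- 10000
  i <- sample(rep(seq_len(n - 1), counts), reps, replace = TRUE)
  j <- rhyper(reps, i, n - i, m)
  seg <- j > 0 & j < m
  rare <- seg & pmin(j, m - j) <= 2
  est <- sum(rare) / sum(seg)
  se <- sqrt(est * (1 - est) / sum(seg))
  expect_within_3se(est, expected, se)
  # O(n) shortcut matches the full projection
  expect_equal(projected_rare_fraction(s, m), expected, tolerance = 1e-12)
})

test_that("spectra round-trip through the TSV format", {
  path <- withr::local_tempfile(fileext = ".tsv")
  s <- sfs_unfolded(c(4.5, 3, 0, 1, 2), 6)
  write_sfs_tsv(s, path)
  r <- read_sfs_tsv(path)
  expect_equal(r$counts, s$counts)
  expect_equal(r$sample_size, s$sample_size)
  expect_false(r$folded)
  f <- fold(s)
  write_sfs_tsv(f, path)
  expect_true(read_sfs_tsv(path)$folded)
  expect_error(read_sfs_tsv(system.file("DESCRIPTION", package = "csfs")),
               "header")
})

test_that("tidy() exposes the spectrum as a tibble", {
  d <- tidy(sfs_folded(c(5, 3), 4))
  expect_s3_class(d, "tbl_df")
  expect_equal(d$n_sites, c(5, 3))
  expect_equal(d$allele_count, 1:2)
})
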