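# Site frequency spectrum containers and summaries.
#
# A spectrum is stored as a numeric vector of site counts plus the chromosome
# sample size. Unfolded spectra are indexed by derived-allele count 1..n-1,
# folded spectra by minor-allele count 1..floor(n/2). Counts may be real
# valued (expected spectra).

new_sfs <- function(counts, sample_size, folded) {
  structure(
    list(counts = as.numeric(counts), sample_size = as.integer(sample_size),
         folded = isTRUE(folded)),
    class = "sfs"
  )
}

#' Construct an unfolded site frequency spectrum
#'
#' @param counts Numeric vector of site counts indexed by derived-allele count
#'   `1..n-1`. Real values are allowed (expected spectra).
#' @param sample_size Integer number of chromosomes `n` (>= 2).
#' @return An object of class `sfs`.
#' @examples
#' s <- sfs_unfolded(c(4, 3, 2, 1, 0), sample_size = 6)
#' fraction_rare(s)
#' @export
sfs_unfolded <- function(counts, sample_size) {
  sample_size <- as.integer(sample_size)
  stopifnot(sample_size >= 2)
  if (length(counts) != sample_size - 1L) {
    stop("unfolded spectrum must have n - 1 = ", sample_size - 1L, " classes")
  }
  if (any(counts < 0) || anyNA(counts)) stop("spectrum counts must be nonnegative")
  new_sfs(counts, sample_size, folded = FALSE)
}

#' Construct a folded site frequency spectrum
#'
#' @param counts Numeric vector of site counts indexed by minor-allele count
#'   `1..floor(n/2)`.
#' @inheritParams sfs_unfolded
#' @return An object of class `sfs`.
#' @export
sfs_folded <- function(counts, sample_size) {
  sample_size <- as.integer(sample_size)
  stopifnot(sample_size >= 2)
  if (length(counts) != sample_size %/% 2L) {
    stop("folded spectrum must have floor(n/2) = ", sample_size %/% 2L, " classes")
  }
  if (any(counts < 0) || anyNA(counts)) stop("spectrum counts must be nonnegative")
  new_sfs(counts, sample_size, folded = TRUE)
}

is_folded <- function(x) {
  stopifnot(inherits(x, "sfs"))
  x$folded
}

#' @export
print.sfs <- function(x, ...) {
  cat(sprintf("<%s SFS> n = %d chromosomes, %d classes, %.6g segregating sites\n",
              if (x$folded) "folded" else "unfolded",
              x$sample_size, length(x$counts), sum(x$counts)))
  invisible(x)
}

#' @export
tidy.sfs <- function(x, ...) {
  tibble::tibble(
    allele_count = seq_along(x$counts),
    n_sites = x$counts,
    sample_size = x$sample_size,
    folded = x$folded
  )
}

#' Fold an unfolded spectrum onto minor-allele counts
#'
#' Class `i` of the folded spectrum pools derived-allele counts `i` and
#' `n - i`; for even `n` the central class `n/2` is copied once. The total
#' number of segregating sites is conserved.
#'
#' @param spectrum An unfolded `sfs`. A folded spectrum is returned unchanged.
#' @return A folded `sfs`.
#' @export
fold <- function(spectrum) {
  stopifnot(inherits(spectrum, "sfs"))
  if (spectrum$folded) return(spectrum)
  n <- spectrum$sample_size
  half <- n %/% 2L
  counts <- vapply(seq_len(half), function(i) {
    if (i == n - i) spectrum$counts[i] else spectrum$counts[i] + spectrum$counts[n - i]
  }, numeric(1))
  sfs_folded(counts, n)
}

# minor-allele count for each class of a spectrum (vector parallel to counts)
minor_counts_of <- function(spectrum) {
  n <- spectrum$sample_size
  i <- seq_along(spectrum$counts)
  if (spectrum$folded) i else pmin(i, n - i)
}

#' Fraction of rare variants in a spectrum
#'
#' Rare variants are sites whose minor-allele count is at most
#' `rare_max_count` (singletons and doubletons by default).
#'
#' @param spectrum A folded or unfolded `sfs`.
#' @param rare_max_count Largest minor-allele count still counted as rare.
#' @return Proportion in `[0, 1]`.
#' @export
fraction_rare <- function(spectrum, rare_max_count = 2) {
  stopifnot(inherits(spectrum, "sfs"), rare_max_count >= 1)
  total <- sum(spectrum$counts)
  if (total <= 0) stop("spectrum has no segregating sites")
  rare <- sum(spectrum$counts[minor_counts_of(spectrum) <= rare_max_count])
  rare / total
}

#' Fraction of variants at or below a minor allele frequency threshold
#'
#' @inheritParams fraction_rare
#' @param maf_threshold Minor allele frequency threshold in `(0, 0.5]`.
#' @return Proportion in `[0, 1]`.
#' @export
fraction_maf_le <- function(spectrum, maf_threshold = 0.01) {
  stopifnot(inherits(spectrum, "sfs"))
  if (!is.numeric(maf_threshold) || maf_threshold <= 0 || maf_threshold > 0.5) {
    stop("maf_threshold must lie in (0, 0.5]")
  }
  total <- sum(spectrum$counts)
  if (total <= 0) stop("spectrum has no segregating sites")
  keep <- minor_counts_of(spectrum) / spectrum$sample_size <= maf_threshold
  sum(spectrum$counts[keep]) / total
}

#' Hypergeometric projection of a spectrum to a smaller sample size
#'
#' Computes the expected unfolded spectrum of a subsample of `m` chromosomes
#' drawn without replacement from the `n` sampled chromosomes: the expected
#' count in class `j` is `sum_i counts[i] * P(Hypergeom(n, i, m) = j)`.
#' Classes `j = 0` and `j = m` (sites lost or fixed in the subsample) are
#' dropped from the spectrum and reported via attributes `lost` and `fixed`.
#' Summaries of the projected spectrum (e.g. [fraction_rare()]) are therefore
#' renormalized to sites still segregating in the subsample; the raw retained
#' mass is `sum(projected$counts)`.
#'
#' @param spectrum An unfolded `sfs` at sample size `n`.
#' @param m Target number of chromosomes, `2 <= m <= n`.
#' @return An unfolded `sfs` at sample size `m` with attributes `lost` and
#'   `fixed` (expected numbers of sites monomorphic in the subsample).
#' @export
project_sfs <- function(spectrum, m) {
  stopifnot(inherits(spectrum, "sfs"))
  if (spectrum$folded) stop("projection is defined for unfolded spectra")
  n <- spectrum$sample_size
  m <- as.integer(m)
  if (m < 2 || m > n) stop("projection size m must satisfy 2 <= m <= n")
  if (m == n) return(spectrum)
  i <- seq_len(n - 1L)
  # H[j+1, i] = P(j derived in subsample | i derived among n)
  proj <- vapply(i, function(ii) dhyper(0:m, ii, n - ii, m), numeric(m + 1L))
  expected <- as.numeric(proj %*% spectrum$counts)
  out <- sfs_unfolded(expected[2:m], m)
  attr(out, "lost") <- expected[1L]
  attr(out, "fixed") <- expected[m + 1L]
  out
}

#' Rare fraction of a subsampled spectrum without forming the projection
#'
#' Equivalent to `fraction_rare(project_sfs(spectrum, m), rare_max_count)`
#' but only evaluates the extreme hypergeometric classes, so it is O(n) per
#' subsample size and practical for spectra over tens of thousands of
#' chromosomes (e.g. rare-fraction-versus-sample-size curves).
#'
#' @inheritParams project_sfs
#' @param rare_max_count Largest minor-allele count counted as rare.
#' @return Proportion among sites still segregating in the subsample.
#' @export
projected_rare_fraction <- function(spectrum, m, rare_max_count = 2) {
  stopifnot(inherits(spectrum, "sfs"), !spectrum$folded)
  n <- spectrum$sample_size
  m <- as.integer(m)
  if (m < 2 || m > n) stop("projection size m must satisfy 2 <= m <= n")
  i <- seq_len(n - 1L)
  cls <- function(j) sum(spectrum$counts * dhyper(j, i, n - i, m))
  r <- min(rare_max_count, m %/% 2)
  lowhigh <- unique(c(seq_len(r), m - seq_len(r)))
  rare <- sum(vapply(lowhigh, cls, numeric(1)))
  total <- sum(spectrum$counts) - cls(0L) - cls(m)
  rare / total
}

#' Serialize a spectrum to a two-column TSV
#'
#' The file carries a single header comment line with the sample size and the
#' folded/unfolded flag, then columns `allele_count` and `n_sites`.
#'
#' @param spectrum An `sfs`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_sfs_tsv <- function(spectrum, path) {
  stopifnot(inherits(spectrum, "sfs"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# sample_size=%d folded=%s", spectrum$sample_size,
                     if (spectrum$folded) "true" else "false"), con)
  writeLines("allele_count\tn_sites", con)
  writeLines(sprintf("%d\t%.17g", seq_along(spectrum$counts), spectrum$counts), con)
  invisible(path)
}

#' Read a spectrum written by [write_sfs_tsv()]
#'
#' @param path File path.
#' @return An `sfs`.
#' @export
read_sfs_tsv <- function(path) {
  header <- readLines(path, n = 1L)
  m <- regmatches(header, regexec("sample_size=(\\d+) folded=(true|false)", header))[[1]]
  if (length(m) != 3) stop("not a spectrum TSV: missing header line in ", path)
  tab <- read.table(path, header = TRUE, sep = "\t", comment.char = "#")
  counts <- tab$n_sites[order(tab$allele_count)]
  if (m[3] == "true") sfs_folded(counts, as.integer(m[2])) else
    sfs_unfolded(counts, as.integer(m[2]))
}
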