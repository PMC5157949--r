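# Site-table input/output.
#
# The native dialect is a TSV with one column per field; primate alleles
# occupy six columns with '.' marking missing data. Coordinates are 1-based
# (VCF convention).

site_table_columns <- c("chrom", "pos", "major", "minor", "minor_count",
                        "total_chroms", "flank_up", "flank_down", "strand",
                        "func_class", ascertainment_species)

#' Read a site table from TSV
#'
#' @param path TSV file with a header; required columns are `chrom`, `pos`,
#'   human `major`/`minor` alleles, `minor_count`, `total_chroms`,
#'   `flank_up`, `flank_down`, `strand`, `func_class`, and one allele column
#'   per primate (`"."` = missing). Extra covariate columns are kept.
#' @param min_chroms Sites genotyped in fewer chromosomes are dropped
#'   (set to 0 to keep everything). The default mirrors the 100,000
#'   chromosome filter used for large exome call sets.
#' @return A tibble of site records.
#' @export
read_site_table <- function(path, min_chroms = 0) {
  tab <- tibble::as_tibble(
    read.table(path, header = TRUE, sep = "\t", colClasses = NA,
               na.strings = character(), stringsAsFactors = FALSE,
               comment.char = "")
  )
  missing_cols <- setdiff(site_table_columns, names(tab))
  if (length(missing_cols) > 0) {
    bad <- utils::head(missing_cols, 3)
    stop("malformed site table ", path, ": missing column(s) ",
         paste(bad, collapse = ", "))
  }
  check_site_table(tab)
  if (min_chroms > 0) tab <- dplyr::filter(tab, .data$total_chroms >= min_chroms)
  tab
}

check_site_table <- function(tab) {
  bad <- which(!(tab$major %in% BASES) | !(tab$minor %in% BASES))
  if (length(bad) > 0) {
    stop("malformed site table: non-ACGT human allele first at line ", bad[1] + 1)
  }
  bad <- which(tab$minor_count <= 0 | tab$minor_count > tab$total_chroms / 2)
  if (length(bad) > 0) {
    stop("malformed site table: minor count outside (0, total/2] first at line ",
         bad[1] + 1)
  }
  invisible(tab)
}

#' Write a site table to TSV
#'
#' @param sites Site tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_site_table <- function(sites, path) {
  out <- as.data.frame(sites)
  for (sp in intersect(ascertainment_species, names(out))) {
    out[[sp]][is.na(out[[sp]])] <- "."
  }
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read sites from a VCF plus a primate-allele sidecar TSV
#'
#' Reads biallelic SNP records and their allele counts (INFO `AC` and `AN`)
#' from a VCF and joins a sidecar TSV (keyed by `chrom` and `pos`) carrying
#' the flanks, strand, functional class and primate alleles. The major
#' allele is whichever of REF/ALT has count above AN/2; ties take REF as
#' major.
#'
#' @param vcf_path VCF file (uncompressed or bgzipped, via vcfR).
#' @param sidecar_path TSV with `chrom`, `pos` and the annotation columns of
#'   the native dialect.
#' @param min_chroms Minimum AN filter.
#' @return A site tibble in the native dialect.
#' @export
read_sites_vcf <- function(vcf_path, sidecar_path, min_chroms = 0) {
  if (!requireNamespace("vcfR", quietly = TRUE)) {
    stop("the VCF adapter needs the vcfR package")
  }
  v <- vcfR::read.vcfR(vcf_path, verbose = FALSE)
  fix <- tibble::as_tibble(as.data.frame(vcfR::getFIX(v), stringsAsFactors = FALSE))
  ac <- as.numeric(vcfR::extract.info(v, "AC"))
  an <- as.numeric(vcfR::extract.info(v, "AN"))
  keep <- fix$REF %in% BASES & fix$ALT %in% BASES & !is.na(ac) & !is.na(an)
  tab <- tibble::tibble(
    chrom = fix$CHROM[keep], pos = as.integer(fix$POS[keep]),
    ref = fix$REF[keep], alt = fix$ALT[keep],
    ac = ac[keep], an = an[keep]
  ) |>
    dplyr::mutate(
      alt_major = .data$ac > .data$an / 2,
      major = ifelse(.data$alt_major, .data$alt, .data$ref),
      minor = ifelse(.data$alt_major, .data$ref, .data$alt),
      minor_count = as.integer(ifelse(.data$alt_major, .data$an - .data$ac, .data$ac)),
      total_chroms = as.integer(.data$an)
    ) |>
    dplyr::filter(.data$minor_count > 0, .data$total_chroms >= min_chroms) |>
    dplyr::select("chrom", "pos", "major", "minor", "minor_count", "total_chroms")
  side <- tibble::as_tibble(
    read.table(sidecar_path, header = TRUE, sep = "\t",
               na.strings = character(), stringsAsFactors = FALSE)
  )
  dplyr::inner_join(tab, side, by = c("chrom", "pos"))
}
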