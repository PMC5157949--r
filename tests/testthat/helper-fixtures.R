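# shared fixtures built in code

# one site record in the native dialect; primate alleles default to the
# human major (human-private pattern) and are overridden by name
site_row <- function(major = "A", minor = "C", minor_count = 1, total = 200,
                     flank_up = "AACCA", flank_down = "ATTCA", strand = "+",
                     func_class = "synonymous", pos = 1, ...) {
  primates <- setNames(rep(major, length(ascertainment_species)),
                       ascertainment_species)
  over <- list(...)
  for (nm in names(over)) primates[[nm]] <- over[[nm]]
  tibble::tibble(
    chrom = "chr1", pos = pos, major = major, minor = minor,
    minor_count = minor_count, total_chroms = total,
    flank_up = flank_up, flank_down = flank_down,
    strand = strand, func_class = func_class,
    !!!as.list(primates)
  )
}

# hand-written table covering every substitution category
fixture_categories <- function() {
  dplyr::bind_rows(
    site_row(pos = 1),                                     # human_private
    site_row(pos = 2, minor_count = 5),                    # human_private
    site_row(pos = 3, chimpanzee = "C"),                   # substituted_chimpanzee
    site_row(pos = 4, gorilla = "C"),                      # substituted_gorilla
    site_row(pos = 5, orangutan = "C"),                    # substituted_orangutan
    site_row(pos = 6, gibbon = "C"),                       # substituted_gibbon
    site_row(pos = 7, macaque = "C"),                      # substituted_macaque
    site_row(pos = 8, chimpanzee = "C", gorilla = "C"),    # other: two carriers
    site_row(pos = 9, baboon = "C"),                       # other: baboon carrier
    site_row(pos = 10, chimpanzee = "G"),                  # other: third allele
    site_row(pos = 11, macaque = "."),                     # human_private (missing ok)
    site_row(pos = 12, orangutan = "C", baboon = ".")      # strict: other
  )
}

# deterministic two-leaf ultrametric tree with branch length t_branch
pair_tree <- function(t_branch) {
  structure(list(edge = matrix(c(3L, 1L, 3L, 2L), 2, 2, byrow = TRUE),
                 edge.length = c(t_branch, t_branch),
                 tip.label = c("t1", "t2"), Nnode = 1L),
            class = "phylo")
}

# reverse complement of allele characters / flank strings
rc_base <- function(x) chartr("ACGT", "TGCA", x)
rc_str <- function(x) vapply(strsplit(chartr("ACGT", "TGCA", x), NULL),
                             function(ch) paste(rev(ch), collapse = ""),
                             character(1))

expect_within_3se <- function(est, truth, se, label = NULL) {
  expect_lt(abs(est - truth), 3 * se + 1e-12, label = label)
}
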