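toy_loci <- function(pos, ref = "G", alt = "A") {
  snp_loci(paste0("rs", seq_along(pos)), "chr1", pos, ref, alt)
}

test_that("variant bases are applied to the CDS and translated by the standard code", {
  refseq <- "ATGGAAAAA"                       # M E K
  exons <- data.frame(start = 1L, end = 9L)
  loci <- toy_loci(4L)
  expect_equal(translate_allele("0", loci, exons, refseq), "MEK")
  # pos 4 G->A: GAA (E) -> AAA (K), the E2K substitution
  expect_equal(translate_allele("1", loci, exons, refseq), "MKK")

  # synonymous change: GAA -> GAG, both glutamate
  syn <- toy_loci(6L, ref = "A", alt = "G")
  expect_equal(translate_allele("1", syn, exons, refseq),
               translate_allele("0", syn, exons, refseq))

  # stop codons are retained as '*'
  stopv <- toy_loci(4L, ref = "G", alt = "T")  # GAA -> TAA
  expect_equal(translate_allele("1", stopv, exons, refseq), "M*K")
})

test_that("splicing, strandedness and frame are honoured", {
  # two exons with an intron; minus strand reverse-complements before translating
  refseq <- "ATGGAATTTTTAAA"                  # exons 1-6 and 12-14
  exons <- data.frame(start = c(1L, 12L), end = c(6L, 14L))
  expect_equal(translate_allele("0", toy_loci(4L), exons, refseq), "MEK")
  # minus strand: revcomp(ATGGAAAAA) = TTTTTCCAT -> FFH... compute directly
  minus <- as.character(Biostrings::translate(Biostrings::reverseComplement(
    Biostrings::DNAString("ATGGAAAAA")), no.init.codon = TRUE))
  expect_equal(translate_allele("0", toy_loci(4L), exons, refseq,
                                strand = "-"), minus)

  # intronic variant is ignored with a warning
  expect_warning(
    p <- translate_allele("1", toy_loci(8L, ref = "T", alt = "C"),
                          exons, refseq),
    "outside the coding exons")
  expect_equal(p, "MEK")

  # CDS length not divisible by 3
  bad <- data.frame(start = 1L, end = 7L)
  expect_error(translate_allele("0", toy_loci(4L), bad, "ATGGAAAAA"),
               "frame violation")

  # reference-base mismatches are reported
  expect_warning(translate_allele("0", toy_loci(4L, ref = "C", alt = "A"),
                                  exons, refseq), "mismatch")
})

test_that("FASTA input and whole-model translation work", {
  fa <- tempfile(fileext = ".fa")
  writeLines(c(">chr1 toy", "ATGGAAAAA"), fa)
  exons <- data.frame(start = 1L, end = 9L)
  loci <- toy_loci(4L)
  expect_equal(translate_allele("1", loci, exons, fa), "MKK")

  m <- perfect_model()
  m$alleles <- c("A*1" = "0", "A*2" = "1")
  prot <- translate_model_alleles(m, loci, exons, fa)
  expect_equal(unname(prot), c("MEK", "MKK"))
})

test_that("synonymous collapse merges proteins, sums frequencies and relabels by control rank", {
  tab <- data.frame(allele = c("G*1", "G*2", "G*3"),
                    freq_control = c(0.5, 0.3, 0.2),
                    freq_case = c(0.45, 0.35, 0.2))
  prot <- c("G*1" = "MEK", "G*2" = "MKK", "G*3" = "MKK")
  aa <- collapse_synonymous(tab, prot)
  expect_equal(nrow(aa), 2L)
  expect_equal(aa$aa_allele, c("G*aa*1", "G*aa*2"))
  expect_equal(aa$freq_control[aa$protein == "MKK"], 0.5)
  expect_equal(aa$freq_case[aa$protein == "MKK"], 0.55)
  # total mass preserved per phenotype group
  expect_equal(sum(aa$freq_control), 1)
  expect_equal(sum(aa$freq_case), 1)
  # mapping assigns each DNA allele to exactly one aa allele
  map <- attr(aa, "mapping")
  expect_equal(unname(map[c("G*2", "G*3")]), rep(aa$aa_allele[aa$protein == "MKK"], 2))

  # all-distinct proteins: identity grouping
  aa2 <- collapse_synonymous(tab, c("G*1" = "A", "G*2" = "B", "G*3" = "C"))
  expect_equal(nrow(aa2), 3L)
  expect_error(collapse_synonymous(tab, prot[1:2]), "no translation")
})
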