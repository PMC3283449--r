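#' Enumerate haplotype pairs compatible with an unphased genotype
#'
#' Expands an unphased genotype vector into every ordered pair of haplotypes
#' whose per-locus allele counts reproduce it. Heterozygous loci contribute a
#' factor of 2 (the two phase assignments); missing loci are free, so both
#' haplotypes vary independently there (a factor of 4 in ordered pairs).
#'
#' @param codes Integer vector of genotype codes (0, 1, 2 or `NA`), one per
#'   locus.
#'
#' @return A two-column character matrix (`hap1`, `hap2`) of ordered
#'   haplotype pairs; haplotypes are "0"/"1" code strings.
#' @export
#'
#' @examples
#' enumerate_compatible_pairs(c(1L, 1L))  # 4 ordered pairs
enumerate_compatible_pairs <- function(codes) {
  codes <- as.integer(codes)
  if (length(codes) == 0) stop("degenerate genotype vector")
  per_locus <- lapply(codes, function(cj) {
    if (is.na(cj)) list(c(0L, 0L), c(0L, 1L), c(1L, 0L), c(1L, 1L))
    else if (cj == 0L) list(c(0L, 0L))
    else if (cj == 2L) list(c(1L, 1L))
    else if (cj == 1L) list(c(0L, 1L), c(1L, 0L))
    else stop("genotype codes must be 0, 1, 2 or NA")
  })
  combos <- expand.grid(per_locus, KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  h1 <- apply(combos, 1L, function(r) paste0(vapply(r, `[`, integer(1), 1L), collapse = ""))
  h2 <- apply(combos, 1L, function(r) paste0(vapply(r, `[`, integer(1), 2L), collapse = ""))
  cbind(hap1 = h1, hap2 = h2)
}

check_span <- function(freqs, codes) {
  loci <- ft_loci(freqs)
  L <- if (!is.null(loci)) nrow(loci) else unique(nchar(freqs$hap))
  if (length(L) != 1 || L != length(codes))
    stop("frequency table and genotype vector span different locus lists")
}

#' Likelihood of an unphased genotype under HWE
#'
#' Probability of observing genotype `codes` when the two haplotypes of a
#' subject are independent draws from `freqs` (Hardy-Weinberg equilibrium):
#' the sum of `f(H1) * f(H2)` over every compatible ordered haplotype pair.
#' Haplotypes absent from the table have frequency zero; entries below
#' `1e-10` are treated as zero.
#'
#' @param freqs A [freq_table()] over the same loci as `codes`.
#' @param codes Genotype code vector (0/1/2/`NA`).
#'
#' @return A probability in \[0, 1\].
#' @export
pair_likelihood <- function(freqs, codes) {
  check_span(freqs, codes)
  keep <- freqs$freq > .FREQ_ZERO
  hm <- hap_to_mat(freqs$hap[keep])
  prs <- pairs_for_obs(hm, NULL, as.integer(codes))
  if (!nrow(prs)) return(0)
  f <- freqs$freq[keep]
  sum(f[prs[, 1]] * f[prs[, 2]])
}

#' Posterior distribution over unordered haplotype pairs
#'
#' Bayesian posterior of the phased pair given an unphased genotype: each
#' unordered pair's mass is proportional to `f(H1) * f(H2)`, doubled for
#' heterozygous (distinct) pairs, normalized over all compatible pairs.
#'
#' @inheritParams pair_likelihood
#'
#' @return Named numeric vector of posterior probabilities (summing to 1);
#'   names are `"hap1/hap2"` with the lexicographically smaller haplotype
#'   first.
#' @export
posterior_pairs <- function(freqs, codes) {
  check_span(freqs, codes)
  keep <- freqs$freq > .FREQ_ZERO
  hap <- freqs$hap[keep]
  f <- freqs$freq[keep]
  prs <- pairs_for_obs(hap_to_mat(hap), NULL, as.integer(codes))
  if (!nrow(prs)) stop("genotype inconsistent with model")
  w <- f[prs[, 1]] * f[prs[, 2]]
  tot <- sum(w)
  if (tot <= 0) stop("genotype inconsistent with model")
  key <- pair_key(hap[prs[, 1]], hap[prs[, 2]])
  post <- vapply(split(w, key), sum, numeric(1)) / tot
  post[order(names(post))]
}
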