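#' EM configuration
#'
#' Tuning constants for the haplotype-frequency EM.
#'
#' @param prune Haplotypes with estimated frequency below this are dropped
#'   between progressive locus insertions (and from the final table).
#' @param tol_freq Stop when the largest absolute frequency change falls
#'   below this.
#' @param tol_ll Stop when the log-likelihood improves by less than this.
#' @param max_iter Iteration cap per EM stage.
#'
#' @return List of class `em_config`.
#' @export
em_config <- function(prune = 1e-5, tol_freq = 1e-7, tol_ll = 1e-9,
                      max_iter = 1000L) {
  structure(list(prune = prune, tol_freq = tol_freq, tol_ll = tol_ll,
                 max_iter = as.integer(max_iter)), class = "em_config")
}

# observed alternate-allele frequency of one genotype column (for
# initializing the two extensions of each retained haplotype)
alt_freq <- function(col) {
  m <- mean(col, na.rm = TRUE) / 2
  if (!is.finite(m)) m <- 0.5
  min(max(m, 0.01), 0.99)
}

#' Estimate haplotype frequencies from unphased genotypes by EM
#'
#' Maximizes the HWE multinomial likelihood
#' `l = sum_i log sum_{pairs compatible with g_i} f(H1) f(H2)`
#' over the haplotype frequency simplex. Loci are introduced progressively:
#' EM is run over the first two loci, each retained haplotype is then
#' extended with both alleles of the next locus (mass split by that locus's
#' observed allele frequency), haplotypes below the pruning threshold are
#' dropped, and EM is re-run — so genes with many SNPs never require the
#' full `2^L` enumeration. Initialization is uniform and the procedure is
#' deterministic.
#'
#' @param G A [geno_matrix()] (subjects x loci, codes 0/1/2/`NA`).
#' @param cfg An [em_config()].
#'
#' @return A [freq_table()] over `G`'s loci with attributes `loglik` (final
#'   observed-data log-likelihood), `ll_trace` (per-iteration log-likelihood
#'   of the final EM stage) and `n_subjects`.
#' @export
em_frequencies <- function(G, cfg = em_config()) {
  loci <- geno_loci(G)
  if (nrow(G) < 1 || ncol(G) < 1) stop("need at least one subject and one locus")
  if (all(is.na(G))) stop("all genotypes missing")

  L <- ncol(G)
  l0 <- min(2L, L)
  hm <- as.matrix(expand.grid(rep(list(0:1), l0), KEEP.OUT.ATTRS = FALSE))
  storage.mode(hm) <- "integer"
  freq <- rep(1 / nrow(hm), nrow(hm))

  fit <- NULL
  for (l in seq(l0, L)) {
    px <- pair_index(hm, NULL, G[, seq_len(l), drop = FALSE])
    fit <- em_run(freq, px, cfg$max_iter, cfg$tol_freq, cfg$tol_ll)
    freq <- fit$freq
    if (l < L) {
      keep <- freq >= cfg$prune
      if (!any(keep)) keep <- freq == max(freq)
      hm <- hm[keep, , drop = FALSE]
      freq <- freq[keep] / sum(freq[keep])
      p <- alt_freq(G[, l + 1L])
      hm <- rbind(cbind(hm, 0L), cbind(hm, 1L))
      freq <- c(freq * (1 - p), freq * p)
    }
  }
  keep <- freq > 1e-12
  ft <- freq_table(mat_to_hap(hm[keep, , drop = FALSE]),
                   freq[keep] / sum(freq[keep]), loci = loci)
  attr(ft, "loglik") <- fit$loglik
  attr(ft, "ll_trace") <- fit$ll_trace
  attr(ft, "n_subjects") <- nrow(G)
  ft
}

#' Call per-subject diplotypes at a posterior threshold
#'
#' For each subject, computes the posterior over compatible unordered
#' haplotype pairs under `freqs` and calls the maximum-posterior pair when
#' its probability strictly exceeds `threshold`; otherwise the subject is
#' left uncalled (missing). Ties at the maximum are broken by the
#' lexicographic order of the pair key, for reproducibility.
#'
#' @param freqs A [freq_table()] spanning `G`'s loci.
#' @param G A [geno_matrix()].
#' @param threshold Posterior probability a call must exceed (default 0.95,
#'   the stringent phasing threshold).
#'
#' @return A data.frame with one row per subject: `sample`, `hap1`, `hap2`
#'   (`NA` when uncalled), `posterior` of the best pair, and logical
#'   `called`.
#' @export
call_diplotypes <- function(freqs, G, threshold = 0.95) {
  check_span(freqs, rep(0L, ncol(G)))
  n <- nrow(G)
  out <- data.frame(sample = rownames(G), hap1 = NA_character_,
                    hap2 = NA_character_, posterior = NA_real_,
                    called = FALSE, stringsAsFactors = FALSE)
  for (i in seq_len(n)) {
    post <- tryCatch(posterior_pairs(freqs, G[i, ]), error = function(e) NULL)
    if (is.null(post)) {
      warning("subject ", rownames(G)[i],
              " has genotypes inconsistent with the frequency model; left missing")
      next
    }
    best <- which(post == max(post))[1L]  # names sorted: lexicographic tie-break
    out$posterior[i] <- post[best]
    if (post[best] > threshold) {
      hp <- strsplit(names(post)[best], "/", fixed = TRUE)[[1L]]
      out$hap1[i] <- hp[1L]; out$hap2[i] <- hp[2L]
      out$called[i] <- TRUE
    }
  }
  out
}

#' Label gene alleles by frequency rank
#'
#' Assigns each distinct gene allele (haplotype over the intragenic SNPs) a
#' label `GeneName*k`, with `k = 1, 2, ...` in order of decreasing
#' population frequency. Equal frequencies are ordered by the lexicographic
#' order of the allele code strings.
#'
#' @param freqs A [freq_table()] of gene haplotype frequencies.
#' @param gene_name Gene symbol used as the label prefix.
#'
#' @return A data.frame `label`, `hap`, `freq` sorted by rank.
#' @export
label_alleles <- function(freqs, gene_name) {
  if (!nrow(freqs)) stop("empty frequency table")
  ord <- order(-freqs$freq, freqs$hap)
  data.frame(label = paste0(gene_name, "*", seq_len(nrow(freqs))),
             hap = freqs$hap[ord], freq = freqs$freq[ord],
             stringsAsFactors = FALSE)
}

#' Phase one gene end to end
#'
#' Convenience wrapper for the per-gene phasing stage: estimates intragenic
#' haplotype frequencies on the full sample, labels the alleles by frequency
#' rank, and calls diplotypes — by design frequency estimation may use all
#' samples while diplotype calling can then be repeated per subset (pass
#' subsets of `G` to [call_diplotypes()] for the training and validation
#' sets separately).
#'
#' @inheritParams em_frequencies
#' @param gene_name Gene symbol for allele labels.
#' @param threshold Posterior calling threshold (default 0.95).
#'
#' @return List of class `phased_gene`: `freqs`, `alleles` (label table),
#'   `calls` (as [call_diplotypes()] plus `allele1`/`allele2` label
#'   columns).
#' @export
phase_gene <- function(G, gene_name = "GENE", threshold = 0.95,
                       cfg = em_config()) {
  freqs <- em_frequencies(G, cfg)
  alleles <- label_alleles(freqs, gene_name)
  calls <- call_diplotypes(freqs, G, threshold)
  calls <- label_calls(calls, alleles)
  structure(list(freqs = freqs, alleles = alleles, calls = calls),
            class = "phased_gene")
}

#' Attach allele labels to haplotype-level diplotype calls
#'
#' @param calls Output of [call_diplotypes()].
#' @param alleles Label table from [label_alleles()].
#'
#' @return `calls` with `allele1`/`allele2` columns (rank-1 label first
#'   within each pair).
#' @export
label_calls <- function(calls, alleles) {
  lut <- stats::setNames(alleles$label, alleles$hap)
  a1 <- unname(lut[calls$hap1])
  a2 <- unname(lut[calls$hap2])
  swap <- !is.na(a1) & !is.na(a2) & a2 < a1
  calls$allele1 <- ifelse(swap, a2, a1)
  calls$allele2 <- ifelse(swap, a1, a2)
  calls
}
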