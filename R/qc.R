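#' Per-gene missingness filter
#'
#' Flags every sample with at least one missing genotype inside the gene.
#' The gene itself is excluded when more than 50% of samples are flagged
#' (`status = "filtered"`) or when it has at most one SNP
#' (`status = "too_few_snps"`); otherwise `status = "kept"` and the flagged
#' samples are dropped from this gene's analysis.
#'
#' @param G A [geno_matrix()] of the gene's intragenic SNPs.
#' @param gene Gene name for the report.
#'
#' @return List of class `gene_qc_report`: `gene`, `status`,
#'   `n_samples_kept`, `n_samples_filtered`, `n_snps`, and the named logical
#'   vector `sample_filtered`.
#' @export
filter_gene <- function(G, gene = "GENE") {
  flagged <- apply(G, 1L, anyNA)
  n <- nrow(G)
  status <- if (ncol(G) <= 1L) "too_few_snps"
            else if (mean(flagged) > 0.5) "filtered"
            else "kept"
  structure(list(gene = gene, status = status,
                 n_samples_kept = sum(!flagged),
                 n_samples_filtered = sum(flagged),
                 n_snps = ncol(G),
                 sample_filtered = stats::setNames(flagged, rownames(G))),
            class = "gene_qc_report")
}

#' @export
print.gene_qc_report <- function(x, ...) {
  cat(sprintf("gene %s: %s (%d SNPs, %d kept / %d filtered samples)\n",
              x$gene, x$status, x$n_snps, x$n_samples_kept,
              x$n_samples_filtered))
  invisible(x)
}

#' Cohort-level sample exclusion across genes
#'
#' A sample is excluded from the whole analysis when it was flagged by the
#' per-gene missingness filter in more than 60% of the kept genes. Genes
#' whose status is not `"kept"` do not enter the denominator.
#'
#' @param reports List of `gene_qc_report`s from [filter_gene()], one per
#'   gene, over a common sample set.
#'
#' @return Character vector of excluded sample names (possibly empty).
#' @export
filter_samples_across_genes <- function(reports) {
  kept <- Filter(function(r) r$status == "kept", reports)
  if (!length(kept)) stop("no kept genes")
  flags <- vapply(kept, function(r) r$sample_filtered,
                  logical(length(kept[[1]]$sample_filtered)))
  flags <- matrix(flags, ncol = length(kept),
                  dimnames = list(names(kept[[1]]$sample_filtered), NULL))
  names(which(rowMeans(flags) > 0.6))
}

#' Phasing quality gate
#'
#' A gene's phased diplotypes are usable for model building only when fewer
#' than 10% of subjects are uncalled (posterior below the phasing
#' threshold) in the training set and in the validation set.
#'
#' @param train_calls,val_calls Call tables from [call_diplotypes()] (any
#'   data.frame with a logical `called` column).
#'
#' @return List: `pass` (logical), `frac_missing_train`,
#'   `frac_missing_val`.
#' @export
phasing_qc <- function(train_calls, val_calls) {
  stopifnot(nrow(train_calls) > 0, nrow(val_calls) > 0)
  ft <- mean(!train_calls$called)
  fv <- mean(!val_calls$called)
  list(pass = ft < 0.10 && fv < 0.10,
       frac_missing_train = ft, frac_missing_val = fv)
}

#' Shannon entropy of an allele frequency distribution
#'
#' `E(G) = -sum_i f_i log(f_i)` (natural log), the polymorphism measure for
#' a multi-allelic gene: 0 for a monomorphic gene, `log(n)` for `n` equally
#' frequent alleles.
#'
#' @param freqs Numeric vector of allele frequencies (or a [freq_table()]),
#'   non-negative and summing to 1 within `1e-9`; zero frequencies
#'   contribute nothing.
#'
#' @return Non-negative entropy in nats.
#' @export
allele_entropy <- function(freqs) {
  if (inherits(freqs, "freq_table")) freqs <- freqs$freq
  freqs <- as.numeric(freqs)
  if (any(freqs < 0)) stop("frequencies must be non-negative")
  if (abs(sum(freqs) - 1) > 1e-9)
    stop("frequencies must sum to 1 (got ", format(sum(freqs)), ")")
  f <- freqs[freqs > 0]
  -sum(f * log(f))
}
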