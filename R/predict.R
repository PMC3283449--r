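#' Predict a subject's gene diplotype from tag-SNP genotypes
#'
#' Bayesian prediction of the unordered pair of gene alleles: the posterior
#' of each pair is the joint-frequency mass of all ordered gene-SNP
#' haplotype pairs carrying those gene alleles and compatible with the
#' observed SNP genotypes, normalized over all compatible pairs. Missing
#' genotypes are marginalized (an all-missing subject receives the HWE
#' prior over allele pairs). A call is emitted only when the maximum
#' posterior strictly exceeds the call threshold `ct`; ties at the maximum
#' are broken by the lexicographic order of the allele-label pair.
#'
#' @param model A [prediction_model()].
#' @param codes Genotype codes (0/1/2/`NA`) over `model$snps`, in order.
#' @param ct Call threshold in \[0, 1); default 0, so any subject with
#'   positive posterior support is called.
#'
#' @return List of class `diplotype_call`: `allele1`, `allele2`,
#'   `posterior` (of the best pair), `called`, `reason` (`"ok"`,
#'   `"below_ct"` or `"outside_support"`), and `posterior_table` (the full
#'   named posterior over pairs).
#' @export
predict_diplotype <- function(model, codes, ct = 0) {
  tab <- model$joint
  if (length(codes) != nrow(model$snps))
    stop("genotype vector does not span the model's selected SNPs")
  keep <- tab$freq > .FREQ_ZERO
  hm <- hap_to_mat(tab$hap[keep])
  if (ncol(hm) == 0 && sum(keep)) hm <- matrix(integer(0), sum(keep), 0)
  allele <- tab$allele[keep]
  f <- tab$freq[keep]

  prs <- pairs_for_obs(hm, allele, as.integer(codes))
  no_call <- list(allele1 = NA_character_, allele2 = NA_character_,
                  posterior = NA_real_, called = FALSE,
                  reason = "outside_support", posterior_table = numeric(0))
  class(no_call) <- "diplotype_call"
  if (!nrow(prs)) return(no_call)
  w <- f[prs[, 1]] * f[prs[, 2]]
  tot <- sum(w)
  if (tot <= 0) return(no_call)
  key <- pair_key(allele[prs[, 1]], allele[prs[, 2]])
  post <- vapply(split(w, key), sum, numeric(1)) / tot
  post <- post[order(names(post))]
  best <- which(post == max(post))[1L]
  ab <- strsplit(names(post)[best], "/", fixed = TRUE)[[1L]]
  out <- list(allele1 = ab[1L], allele2 = ab[2L],
              posterior = unname(post[best]),
              called = post[best] > ct,
              reason = if (post[best] > ct) "ok" else "below_ct",
              posterior_table = post)
  if (!out$called) { out$allele1 <- NA_character_; out$allele2 <- NA_character_ }
  class(out) <- "diplotype_call"
  out
}

#' @export
print.diplotype_call <- function(x, ...) {
  if (x$called)
    cat(sprintf("call: %s / %s  (posterior %.4f)\n", x$allele1, x$allele2,
                x$posterior))
  else cat("NO_CALL (", x$reason, ")\n", sep = "")
  invisible(x)
}

#' Predict diplotypes for a cohort
#'
#' Applies [predict_diplotype()] to every row of a genotype matrix.
#'
#' @param model A [prediction_model()].
#' @param G [geno_matrix()] containing the model's selected loci (matched
#'   by id; extra loci are ignored).
#' @param ct Call threshold.
#'
#' @return Data.frame `sample`, `allele1`, `allele2`, `posterior`,
#'   `called`; the per-subject posterior tables are attached as attribute
#'   `"posteriors"` (a named list).
#' @export
predict_cohort <- function(model, G, ct = 0) {
  idx <- match(model$snps$id, geno_loci(G)$id)
  if (anyNA(idx)) stop("genotype matrix lacks some of the model's selected loci")
  Gm <- unclass(G)[, idx, drop = FALSE]
  n <- nrow(Gm)
  out <- data.frame(sample = rownames(G), allele1 = NA_character_,
                    allele2 = NA_character_, posterior = NA_real_,
                    called = FALSE, stringsAsFactors = FALSE)
  posts <- vector("list", n)
  names(posts) <- rownames(G)
  for (i in seq_len(n)) {
    p <- predict_diplotype(model, Gm[i, ], ct)
    out$allele1[i] <- p$allele1; out$allele2[i] <- p$allele2
    out$posterior[i] <- p$posterior; out$called[i] <- p$called
    posts[[i]] <- p$posterior_table
  }
  attr(out, "posteriors") <- posts
  out
}

#' Diplotype prediction accuracy
#'
#' The fraction of correctly predicted gene alleles over called subjects:
#' per subject, the number of matching alleles `n_i` (0, 1 or 2) is the
#' maximum over the two possible phase matchings of the predicted pair
#' against the observed pair, and accuracy is `sum(n_i) / (2N)`. Subjects
#' without a call (in either argument) are excluded from both the sum and
#' `N`, so accuracy and call rate are reported separately.
#'
#' @param predicted,observed Data.frames with `allele1`/`allele2` columns
#'   (and optionally `called`), equal row counts, aligned by row.
#'
#' @return Fraction in \[0, 1\] (`NaN` when no subject is called).
#' @export
prediction_accuracy <- function(predicted, observed) {
  if (nrow(predicted) != nrow(observed))
    stop("predicted and observed call tables differ in length")
  ok <- !is.na(predicted$allele1) & !is.na(predicted$allele2) &
        !is.na(observed$allele1) & !is.na(observed$allele2)
  if (!is.null(predicted$called)) ok <- ok & predicted$called
  if (!is.null(observed$called)) ok <- ok & observed$called
  if (!any(ok)) return(NaN)
  ni <- pmax(
    (predicted$allele1[ok] == observed$allele1[ok]) +
    (predicted$allele2[ok] == observed$allele2[ok]),
    (predicted$allele1[ok] == observed$allele2[ok]) +
    (predicted$allele2[ok] == observed$allele1[ok]))
  sum(ni) / (2 * sum(ok))
}

#' Call rate
#'
#' Fraction of subjects with an emitted prediction.
#'
#' @param calls Data.frame with a logical `called` column (or a logical
#'   vector).
#'
#' @return Fraction in \[0, 1\].
#' @export
call_rate <- function(calls) {
  v <- if (is.data.frame(calls)) calls$called else calls
  if (!length(v)) stop("no calls")
  mean(v)
}

#' Evaluate a model at several call thresholds
#'
#' @param model A [prediction_model()].
#' @param G Validation [geno_matrix()].
#' @param truth Observed diplotypes (`allele1`/`allele2`).
#' @param cts Call thresholds to evaluate (default 0, 0.5, 0.9).
#'
#' @return Data.frame `ct`, `accuracy`, `call_rate`, `n_called`.
#' @export
evaluate_model <- function(model, G, truth, cts = c(0, 0.5, 0.9)) {
  res <- lapply(cts, function(ct) {
    pred <- predict_cohort(model, G, ct)
    data.frame(ct = ct,
               accuracy = prediction_accuracy(pred, truth),
               call_rate = call_rate(pred),
               n_called = sum(pred$called))
  })
  do.call(rbind, res)
}
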