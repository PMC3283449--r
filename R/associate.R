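#' Posterior-expected allele dosages
#'
#' Converts per-subject posterior distributions over gene-allele pairs into
#' expected allele counts (dosages): `dosage(a) = sum_pairs P(pair) *
#' (copies of a in pair)`. Each subject's dosages sum to 2, so prediction
#' uncertainty is carried into downstream association testing instead of
#' being collapsed to a hard call.
#'
#' @param posteriors Either the output of [predict_cohort()] (its
#'   `"posteriors"` attribute is used) or a list of named numeric vectors
#'   over `"a/b"` pair keys, one per subject.
#' @param alleles Optional character vector fixing the column set/order;
#'   defaults to every allele seen.
#'
#' @return Numeric matrix, subjects x alleles; rows of subjects with no
#'   posterior support are `NA`.
#' @export
expected_dosages <- function(posteriors, alleles = NULL) {
  if (is.data.frame(posteriors)) posteriors <- attr(posteriors, "posteriors")
  stopifnot(is.list(posteriors))
  split_pairs <- lapply(posteriors, function(p) {
    if (!length(p)) return(NULL)
    do.call(rbind, strsplit(names(p), "/", fixed = TRUE))
  })
  if (is.null(alleles)) {
    alleles <- sort(unique(unlist(lapply(split_pairs, as.vector))))
  }
  D <- matrix(NA_real_, length(posteriors), length(alleles),
              dimnames = list(names(posteriors), alleles))
  for (i in seq_along(posteriors)) {
    p <- posteriors[[i]]
    if (!length(p)) next
    d <- stats::setNames(numeric(length(alleles)), alleles)
    ab <- split_pairs[[i]]
    for (j in seq_along(p)) {
      d[ab[j, 1L]] <- d[ab[j, 1L]] + p[j]
      d[ab[j, 2L]] <- d[ab[j, 2L]] + p[j]
    }
    D[i, ] <- d
  }
  D
}

#' Hard-call allele dosages
#'
#' Integer dosages (0/1/2) from called diplotypes; uncalled subjects get
#' `NA` rows.
#'
#' @param calls Data.frame with `allele1`/`allele2` (and optionally
#'   `called`).
#' @param alleles Optional fixed allele set.
#'
#' @return Numeric matrix, subjects x alleles.
#' @export
hard_call_dosages <- function(calls, alleles = NULL) {
  ok <- !is.na(calls$allele1) & !is.na(calls$allele2)
  if (!is.null(calls$called)) ok <- ok & calls$called
  if (is.null(alleles))
    alleles <- sort(unique(c(calls$allele1[ok], calls$allele2[ok])))
  D <- matrix(NA_real_, nrow(calls), length(alleles),
              dimnames = list(calls$sample, alleles))
  for (i in which(ok)) {
    d <- stats::setNames(numeric(length(alleles)), alleles)
    d[calls$allele1[i]] <- d[calls$allele1[i]] + 1
    d[calls$allele2[i]] <- d[calls$allele2[i]] + 1
    D[i, ] <- d
  }
  D
}

#' Multi-allelic case-control association test
#'
#' Jointly regresses case/control status on the dosages of every common
#' non-reference gene allele (logistic regression, Wald inference), mirroring
#' a multi-allelic haplotype test: each tested allele's coefficient is its
#' log-odds ratio versus the reference allele. Alleles whose frequency is
#' not strictly above `floor` in both cases and controls are reported with
#' frequencies only (`tested = FALSE`).
#'
#' @param dosages Subjects x alleles dosage matrix ([expected_dosages()] or
#'   [hard_call_dosages()]); subjects with `NA` dosages are dropped.
#' @param phenotype Integer/logical vector, 1 = case, 0 = control, aligned
#'   with `dosages` rows.
#' @param reference Reference allele label; default the most frequent
#'   allele overall. Must be common (frequency > `floor`) in both groups.
#' @param floor Per-group frequency floor for testing (default 0.01,
#'   strict).
#'
#' @return Data.frame of class `association_result`, one row per allele:
#'   `allele`, `freq_control`, `freq_case`, `tested`, `is_reference`,
#'   `coef`, `se`, `or_`, `ci_lo`, `ci_hi`, `z`, `p`, `converged`.
#' @export
multiallelic_test <- function(dosages, phenotype, reference = NULL,
                              floor = 0.01) {
  phenotype <- as.integer(phenotype)
  stopifnot(length(phenotype) == nrow(dosages), all(phenotype %in% 0:1))
  ok <- stats::complete.cases(dosages)
  D <- dosages[ok, , drop = FALSE]
  y <- phenotype[ok]
  if (!any(y == 1) || !any(y == 0)) stop("need both cases and controls")

  f_ctrl <- colSums(D[y == 0, , drop = FALSE]) / (2 * sum(y == 0))
  f_case <- colSums(D[y == 1, , drop = FALSE]) / (2 * sum(y == 1))
  f_all <- (colSums(D)) / (2 * nrow(D))
  if (is.null(reference)) reference <- colnames(D)[which.max(f_all)]
  if (!reference %in% colnames(D)) stop("unknown reference allele: ", reference)
  if (f_ctrl[reference] <= floor || f_case[reference] <= floor)
    stop("reference allele must be common (> ", floor, ") in both groups")

  common <- f_ctrl > floor & f_case > floor
  tested <- common & colnames(D) != reference

  res <- data.frame(allele = colnames(D),
                    freq_control = unname(f_ctrl),
                    freq_case = unname(f_case),
                    tested = unname(tested),
                    is_reference = colnames(D) == reference,
                    coef = NA_real_, se = NA_real_, or_ = NA_real_,
                    ci_lo = NA_real_, ci_hi = NA_real_,
                    z = NA_real_, p = NA_real_, converged = NA,
                    stringsAsFactors = FALSE)

  if (any(tested)) {
    X <- D[, tested, drop = FALSE]
    dat <- data.frame(y = y, X, check.names = FALSE)
    fit <- suppressWarnings(
      stats::glm(y ~ ., data = dat, family = stats::binomial()))
    cf <- summary(fit)$coefficients
    cf_names <- gsub("^`|`$", "", rownames(cf))  # glm backticks non-syntactic names
    rows <- match(colnames(X), cf_names)
    if (anyNA(rows)) rows <- match(make.names(colnames(X)), cf_names)
    if (anyNA(rows)) stop("could not match fitted coefficients to allele dosages")
    conv <- fit$converged && all(abs(cf[rows, 1]) < 15)
    i <- which(tested)
    res$coef[i] <- cf[rows, 1]
    res$se[i] <- cf[rows, 2]
    res$or_[i] <- exp(res$coef[i])
    res$ci_lo[i] <- exp(res$coef[i] - 1.96 * res$se[i])
    res$ci_hi[i] <- exp(res$coef[i] + 1.96 * res$se[i])
    res$z[i] <- res$coef[i] / res$se[i]
    res$p[i] <- 2 * stats::pnorm(-abs(res$z[i]))
    res$converged[i] <- conv
    if (!conv)
      warning("logistic fit did not converge cleanly (possible separation); ",
              "results flagged")
  }
  res <- res[order(!res$is_reference, -pmin(res$freq_control, res$freq_case)), ]
  rownames(res) <- NULL
  class(res) <- c("association_result", "data.frame")
  res
}

#' Allele-ratio odds ratio from group frequencies
#'
#' The odds ratio of carrying one allele versus the reference allele in
#' cases relative to controls, computed directly from the four printed
#' frequencies: `(f_case_allele / f_case_ref) / (f_ctrl_allele /
#' f_ctrl_ref)`.
#'
#' @param freq_case_allele,freq_case_ref Allele and reference frequencies
#'   in cases.
#' @param freq_ctrl_allele,freq_ctrl_ref Same in controls.
#'
#' @return Odds ratio (numeric scalar).
#' @export
allele_ratio_or <- function(freq_case_allele, freq_case_ref,
                            freq_ctrl_allele, freq_ctrl_ref) {
  if (freq_case_ref <= 0 || freq_ctrl_ref <= 0)
    stop("reference allele frequency must be positive")
  stopifnot(freq_case_allele > 0, freq_ctrl_allele > 0)
  (freq_case_allele / freq_case_ref) / (freq_ctrl_allele / freq_ctrl_ref)
}
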