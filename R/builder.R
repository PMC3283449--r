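# Joint gene-SNP haplotype model fitting and AIC-penalized tag-SNP selection.

#' Model-building configuration
#'
#' @param eps Minimum objective improvement for accepting a forward or
#'   backward move (guards against cycling on float noise).
#' @param max_snps Cap on the number of selected SNPs.
#' @param em [em_config()] used for every joint EM refit.
#'
#' @return List of class `build_config`.
#' @export
build_config <- function(eps = 1e-6, max_snps = 40L, em = em_config()) {
  structure(list(eps = eps, max_snps = as.integer(max_snps), em = em),
            class = "build_config")
}

# evaluate `code` under a temporary RNG seed, restoring the caller's stream
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# subset a geno_matrix by column index, keeping the locus table in step
g_sub <- function(G, idx) {
  geno_matrix(unclass(G)[, idx, drop = FALSE], geno_loci(G)[idx, , drop = FALSE])
}

as_gene_pairs <- function(diplos) {
  stopifnot(all(c("allele1", "allele2") %in% names(diplos)))
  if (anyNA(diplos$allele1) || anyNA(diplos$allele2))
    stop("all training subjects must have a called gene diplotype")
  cbind(diplos$allele1, diplos$allele2)
}

# Fit the joint gene-SNP haplotype frequency table by EM. The gene diplotype
# of each training subject is observed (from phasing); the SNP phase and the
# pairing of gene alleles with SNP haplotypes are latent. With `init` (a
# list hap/allele/freq over Gsel's loci) a single warm-started EM stage is
# run; otherwise SNPs are introduced progressively from the allele-counting
# estimate.
fit_joint <- function(diplos, Gsel, allele_dict, cfg = em_config(), init = NULL) {
  gene_pairs <- as_gene_pairs(diplos)
  loci <- geno_loci(Gsel)
  L <- ncol(Gsel)

  if (is.null(init)) {
    cnt <- table(factor(c(gene_pairs), levels = names(allele_dict)))
    freq <- as.numeric(cnt) / sum(cnt)
    allele <- names(allele_dict)
    keep <- freq > 0
    allele <- allele[keep]; freq <- freq[keep]
    hm <- matrix(integer(0), length(allele), 0)
    l_from <- 1L
  } else {
    allele <- init$allele
    hm <- hap_to_mat(init$hap)
    if (ncol(hm) == 0 && length(init$hap)) hm <- matrix(integer(0), length(init$hap), 0)
    freq <- init$freq / sum(init$freq)
    stopifnot(ncol(hm) == L)
    l_from <- L  # single stage
  }

  fit <- NULL
  stages <- if (L == 0) 0L else seq(l_from, L)
  if (L == 0 || is.null(init)) {
    # stage over 0 SNPs is exact (gene pairs observed): counting estimate
    fit <- list(freq = freq, loglik = NA_real_, ll_trace = numeric(0))
  }
  for (l in stages) {
    if (l == 0L) break
    if (ncol(hm) < l) {
      p <- alt_freq(unclass(Gsel)[, l])
      allele <- c(allele, allele)
      hm <- rbind(cbind(hm, 0L), cbind(hm, 1L))
      freq <- c(freq * (1 - p), freq * p)
    }
    px <- pair_index(hm, allele, unclass(Gsel)[, seq_len(l), drop = FALSE],
                     gene_pairs)
    fit <- em_run(freq, px, cfg$max_iter, cfg$tol_freq, cfg$tol_ll)
    freq <- fit$freq
    if (l < L) {
      keep <- freq >= cfg$prune
      if (!any(keep)) keep <- freq == max(freq)
      hm <- hm[keep, , drop = FALSE]
      allele <- allele[keep]
      freq <- freq[keep] / sum(freq[keep])
    }
  }
  keep <- freq > 1e-12
  tab <- freq_table(mat_to_hap(hm[keep, , drop = FALSE]),
                    freq[keep] / sum(freq[keep]), loci = loci,
                    allele = allele[keep])
  list(table = tab, loglik = fit$loglik)
}

# -sum_i log f(h_i | g_i) + (m - k) for a fitted joint table
q_from_table <- function(tab, diplos, Gsel, k, prune = 1e-5) {
  gene_pairs <- as_gene_pairs(diplos)
  keep <- tab$freq > .FREQ_ZERO
  hm <- hap_to_mat(tab$hap[keep])
  if (ncol(hm) == 0 && sum(keep)) hm <- matrix(integer(0), sum(keep), 0)
  allele <- tab$allele[keep]
  f <- tab$freq[keep]
  Gm <- unclass(Gsel)

  px_num <- pair_index(hm, allele, Gm, gene_pairs)
  px_den <- pair_index(hm, allele, Gm, NULL)
  num <- obs_likelihood(f, px_num)[px_num$subj_obs]
  den <- obs_likelihood(f, px_den)[px_den$subj_obs]
  fh <- num / den
  if (any(!is.finite(fh) | fh <= 0))
    stop("model inconsistent with training subject")
  m <- sum(tab$freq > prune)
  -sum(log(fh)) + (m - k)
}

#' AIC-penalized prediction objective Q
#'
#' `Q = -sum_i log f(h_i | g_i) + (m - k)`: the negative log posterior of
#' each training subject's known gene diplotype given their tag-SNP
#' genotypes, penalized by the number of additional free parameters the
#' tag SNPs introduce — the count of fitted gene-SNP haplotypes (`m`,
#' frequencies above the pruning threshold) minus the count of gene alleles
#' (`k`). Lower is better; natural log throughout.
#'
#' @param model A [prediction_model()].
#' @param diplos Data.frame of called training diplotypes (`allele1`,
#'   `allele2` labels), rows aligned with `G`.
#' @param G A [geno_matrix()] containing at least the model's selected loci
#'   (matched by locus id).
#'
#' @return The objective value (numeric scalar).
#' @export
objective_q <- function(model, diplos, G) {
  idx <- match(model$snps$id, geno_loci(G)$id)
  if (anyNA(idx)) stop("genotype matrix lacks some of the model's selected loci")
  prune <- if (!is.null(model$meta$cfg$em$prune)) model$meta$cfg$em$prune else 1e-5
  q_from_table(model$joint, diplos, g_sub(G, idx),
               k = length(model$alleles), prune = prune)
}

#' Candidate tag SNPs within a flanking window
#'
#' Restricts a SNP catalog to the window `[start - flank_size, end +
#' flank_size]` around a gene and orders it for stepwise search: intragenic
#' SNPs first (distance 0), then by increasing distance from the nearer gene
#' boundary, ties by position.
#'
#' @param gene List with `chrom`, `start`, `end` (1-based inclusive).
#' @param flank_size Window half-width in bp.
#' @param catalog Locus table ([snp_loci()]) sorted by position.
#'
#' @return The ordered subset of `catalog` (possibly empty).
#' @export
candidate_window <- function(gene, flank_size, catalog) {
  cand <- catalog[catalog$chrom == gene$chrom &
                  catalog$pos >= gene$start - flank_size &
                  catalog$pos <= gene$end + flank_size, , drop = FALSE]
  dist <- pmax(gene$start - cand$pos, cand$pos - gene$end, 0L)
  cand[order(dist, cand$pos), , drop = FALSE]
}

#' Fit a joint gene-SNP model for a fixed SNP set
#'
#' Estimates the joint gene-SNP haplotype frequencies by EM for a given set
#' of SNPs (no selection) and assembles a [prediction_model()] with its
#' objective value. Useful for evaluating a chosen SNP panel or for
#' exhaustive-subset comparisons against [forward_backward_select()].
#'
#' @inheritParams forward_backward_select
#'
#' @return A [prediction_model()] over all of `G`'s loci.
#' @export
fit_gene_snp_model <- function(diplos, G, allele_dict, gene,
                               flank_size = NA_real_, cfg = build_config()) {
  stopifnot(nrow(diplos) == nrow(G))
  fit <- fit_joint(diplos, G, allele_dict, cfg$em)
  q <- q_from_table(fit$table, diplos, G, k = length(allele_dict),
                    prune = cfg$em$prune)
  prediction_model(
    gene = gene, snps = geno_loci(G), joint = fit$table,
    alleles = allele_dict, flank_size = flank_size,
    meta = list(n_train = nrow(diplos), q = q, q_trace = q,
                k = length(allele_dict),
                m = sum(fit$table$freq > cfg$em$prune), cfg = cfg))
}

#' Forward-backward selection of informative tag SNPs
#'
#' Greedy stepwise minimization of [objective_q()]: starting from the
#' prior-only model (no SNPs), each forward pass refits the joint gene-SNP
#' EM with every remaining candidate added and accepts the candidate with
#' the lowest Q when it improves the current Q by more than `cfg$eps`; each
#' backward pass likewise removes a selected SNP when doing so improves Q.
#' The loop stops when neither pass improves or `cfg$max_snps` is reached.
#' The accepted-step Q trace is strictly decreasing by construction.
#'
#' @param diplos Called training diplotypes (`allele1`, `allele2` label
#'   columns), one row per subject, aligned with `G`'s rows.
#' @param G [geno_matrix()] of the candidate SNPs, columns in candidate
#'   order (see [candidate_window()]).
#' @param allele_dict Named character vector label -> intragenic haplotype
#'   (from [label_alleles()]).
#' @param gene List with `name`, `chrom`, `start`, `end`.
#' @param flank_size Flanking window size recorded on the model (bp;
#'   default 250000, the operating point that minimizes the rescaled
#'   objective for most genes).
#' @param cfg A [build_config()].
#'
#' @return A [prediction_model()]; `meta$q_trace` holds Q after each
#'   accepted step (starting at the empty model).
#' @export
forward_backward_select <- function(diplos, G, allele_dict, gene,
                                    flank_size = 250000, cfg = build_config()) {
  stopifnot(nrow(diplos) == nrow(G))
  k <- length(allele_dict)
  prune <- cfg$em$prune
  qval <- function(fit, idx) q_from_table(fit$table, diplos, g_sub(G, idx),
                                          k = k, prune = prune)

  sel <- integer(0)
  cur_fit <- fit_joint(diplos, g_sub(G, sel), allele_dict, cfg$em)
  q_cur <- qval(cur_fit, sel)
  q_trace <- q_cur

  extend_init <- function(fit, col) {
    p <- alt_freq(unclass(G)[, col])
    list(allele = c(fit$table$allele, fit$table$allele),
         hap = c(paste0(fit$table$hap, "0"), paste0(fit$table$hap, "1")),
         freq = c(fit$table$freq * (1 - p), fit$table$freq * p))
  }
  drop_init <- function(fit, pos_in_sel) {
    hap <- paste0(substr(fit$table$hap, 1L, pos_in_sel - 1L),
                  substring(fit$table$hap, pos_in_sel + 1L))
    key <- paste(fit$table$allele, hap, sep = "|")
    agg <- rowsum(fit$table$freq, key)
    parts <- strsplit(rownames(agg), "|", fixed = TRUE)
    list(allele = vapply(parts, `[`, character(1), 1L),
         hap = vapply(parts, function(p) if (length(p) > 1) p[2L] else "",
                      character(1)),
         freq = agg[, 1])
  }

  repeat {
    changed <- FALSE

    if (length(sel) < cfg$max_snps) {
      remaining <- setdiff(seq_len(ncol(G)), sel)
      best <- NULL
      for (cand in remaining) {
        idx <- c(sel, cand)
        fit <- tryCatch(
          fit_joint(diplos, g_sub(G, idx), allele_dict, cfg$em,
                    init = extend_init(cur_fit, cand)),
          error = function(e) NULL)
        if (is.null(fit)) next
        q <- tryCatch(qval(fit, idx), error = function(e) Inf)
        if (is.null(best) || q < best$q) best <- list(q = q, fit = fit, cand = cand)
      }
      if (!is.null(best) && best$q < q_cur - cfg$eps) {
        sel <- c(sel, best$cand)
        cur_fit <- best$fit
        q_cur <- best$q
        q_trace <- c(q_trace, q_cur)
        changed <- TRUE
      }
    }

    if (length(sel) >= 1L) {
      best <- NULL
      for (j in seq_along(sel)) {
        idx <- sel[-j]
        fit <- tryCatch(
          fit_joint(diplos, g_sub(G, idx), allele_dict, cfg$em,
                    init = drop_init(cur_fit, j)),
          error = function(e) NULL)
        if (is.null(fit)) next
        q <- tryCatch(qval(fit, idx), error = function(e) Inf)
        if (is.null(best) || q < best$q) best <- list(q = q, fit = fit, j = j)
      }
      if (!is.null(best) && best$q < q_cur - cfg$eps) {
        sel <- sel[-best$j]
        cur_fit <- best$fit
        q_cur <- best$q
        q_trace <- c(q_trace, q_cur)
        changed <- TRUE
      }
    }

    if (!changed) break
  }

  prediction_model(
    gene = gene,
    snps = geno_loci(G)[sel, , drop = FALSE],
    joint = cur_fit$table,
    alleles = allele_dict,
    flank_size = flank_size,
    meta = list(n_train = nrow(diplos), q = q_cur, q_trace = q_trace,
                k = k, m = sum(cur_fit$table$freq > prune), cfg = cfg))
}

#' Scan flanking-window sizes
#'
#' Runs one full tag-SNP selection per flanking size and records the final
#' objective `O_g`, plus the rescaled value
#' `(O_g - min(O_g)) / (max(O_g) - min(O_g))` used to compare window sizes
#' across genes (all zeros when the series is constant).
#'
#' @inheritParams forward_backward_select
#' @param catalog Locus table of all available SNPs (matched against `G`'s
#'   loci by id).
#' @param sizes Increasing vector of window sizes in bp (default 0 to
#'   500 kb in 50 kb steps).
#'
#' @return Data.frame of class `flank_scan`: `size`, `objective`,
#'   `rescaled`, `n_snps`.
#' @export
flank_scan <- function(diplos, G, allele_dict, gene, catalog = geno_loci(G),
                       sizes = seq(0, 500000, by = 50000),
                       cfg = build_config()) {
  stopifnot(length(sizes) > 0, !is.unsorted(sizes))
  obj <- numeric(length(sizes))
  nsnp <- integer(length(sizes))
  for (i in seq_along(sizes)) {
    cand <- candidate_window(gene, sizes[i], catalog)
    idx <- match(cand$id, geno_loci(G)$id)
    idx <- idx[!is.na(idx)]
    m <- forward_backward_select(diplos, g_sub(G, idx), allele_dict, gene,
                                 flank_size = sizes[i], cfg = cfg)
    obj[i] <- m$meta$q
    nsnp[i] <- nrow(m$snps)
  }
  rng <- max(obj) - min(obj)
  rescaled <- if (rng > 0) (obj - min(obj)) / rng else rep(0, length(obj))
  structure(data.frame(size = sizes, objective = obj, rescaled = rescaled,
                       n_snps = nsnp),
            class = c("flank_scan", "data.frame"))
}

#' Split samples into training and validation halves by population
#'
#' Within each population label, assigns `ceiling(n/2)` samples to the
#' training set uniformly at random (the extra sample of an odd-sized
#' population goes to training) and the rest to validation.
#'
#' @param samples Data.frame with columns `sample` and `population`.
#' @param seed Integer seed; the same seed reproduces the same split.
#'
#' @return List with character vectors `train` and `validation` (disjoint,
#'   exhaustive).
#' @export
split_train_validation <- function(samples, seed = 1L) {
  stopifnot(all(c("sample", "population") %in% names(samples)))
  with_seed(seed, {
    train <- character(0)
    for (pop in unique(samples$population)) {
      s <- samples$sample[samples$population == pop]
      train <- c(train, sample(s, ceiling(length(s) / 2)))
    }
    list(train = train, validation = setdiff(samples$sample, train))
  })
}
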