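# Internal EM engine shared by single-gene phasing and joint gene-SNP model
# fitting. A "support" is a candidate set of haplotypes: an integer matrix of
# allele codes (K x L, possibly L = 0) plus an optional parallel vector of
# gene-allele labels for joint gene-SNP haplotypes.

hap_to_mat <- function(hap) {
  if (!length(hap)) return(matrix(integer(0), 0, 0))
  L <- nchar(hap[1])
  if (L == 0) return(matrix(integer(0), length(hap), 0))
  m <- matrix(0L, length(hap), L)
  sp <- strsplit(hap, "", fixed = TRUE)
  for (i in seq_along(sp)) m[i, ] <- as.integer(sp[[i]])
  m
}

mat_to_hap <- function(m) {
  if (ncol(m) == 0) return(rep("", nrow(m)))
  apply(m, 1L, paste0, collapse = "")
}

support_keys <- function(hap, allele = NULL) {
  if (is.null(allele)) hap else paste(allele, hap, sep = "|")
}

# All ordered pairs (i1, i2) of support rows consistent with one observation:
# genotype codes (0/1/2/NA) over the support's loci, and optionally a known
# unordered gene-allele pair c(a, b). Missing codes are free: both alleles
# of the pair vary independently at those loci.
pairs_for_obs <- function(hap_mat, allele, codes, gene_pair = NULL) {
  K <- nrow(hap_mat)
  L <- ncol(hap_mat)
  if (K == 0) return(cbind(i1 = integer(0), i2 = integer(0)))
  stopifnot(length(codes) == L)
  hap_chr <- mat_to_hap(hap_mat)
  key <- support_keys(hap_chr, allele)
  # second-element lookup: by full key when the gene pair is constrained (or
  # absent), by SNP haplotype alone when the gene allele is latent
  hap_groups <- if (!is.null(allele) && is.null(gene_pair))
    split(seq_len(K), paste0("h", hap_chr)) else NULL  # "h" prefix: "" is not addressable

  ok <- rep(TRUE, K)
  for (j in seq_len(L)) {
    cj <- codes[j]
    if (is.na(cj) || cj == 1L) next
    ok <- ok & (hap_mat[, j] == cj %/% 2L)
  }
  if (!is.null(gene_pair)) ok <- ok & allele %in% gene_pair
  idx1 <- which(ok)
  if (!length(idx1)) return(cbind(i1 = integer(0), i2 = integer(0)))

  miss <- which(is.na(codes))
  fills <- if (length(miss)) {
    as.matrix(expand.grid(rep(list(0:1), length(miss)), KEEP.OUT.ATTRS = FALSE))
  } else matrix(integer(0), 1, 0)

  I1 <- integer(0); I2 <- integer(0)
  for (i1 in idx1) {
    patt <- codes - hap_mat[i1, ]
    a2 <- NULL
    if (!is.null(gene_pair)) {
      a2 <- if (allele[i1] == gene_pair[1]) gene_pair[2] else gene_pair[1]
    }
    # enumerate second-haplotype patterns over missing loci
    for (f in seq_len(nrow(fills))) {
      p <- patt
      if (length(miss)) p[miss] <- fills[f, ]
      hap2 <- paste0(p, collapse = "")
      if (!is.null(hap_groups)) {
        j2 <- hap_groups[[paste0("h", hap2)]]
        if (!is.null(j2)) { I1 <- c(I1, rep.int(i1, length(j2))); I2 <- c(I2, j2) }
      } else {
        k2 <- if (is.null(a2)) hap2 else paste(a2, hap2, sep = "|")
        j2 <- match(k2, key)
        if (!is.na(j2)) { I1 <- c(I1, i1); I2 <- c(I2, j2) }
      }
    }
  }
  cbind(i1 = I1, i2 = I2)
}

# Group subjects by identical observation and enumerate compatible pairs once
# per unique observation. Returns a flattened index ready for vectorized EM:
#   I1, I2  support row indices of each ordered pair
#   P       observation id of each pair
#   n_obs   subject multiplicity per observation
#   subj_obs observation id per subject
#   n_pat   number of distinct observations
pair_index <- function(hap_mat, allele, G, gene_pairs = NULL) {
  n <- nrow(G)
  obs_key <- apply(G, 1L, function(r) paste(ifelse(is.na(r), ".", r), collapse = ""))
  if (!is.null(gene_pairs))
    obs_key <- paste(obs_key, pair_key(gene_pairs[, 1], gene_pairs[, 2]), sep = "#")
  u <- !duplicated(obs_key)
  uniq <- which(u)
  subj_obs <- match(obs_key, obs_key[uniq])
  n_obs <- tabulate(subj_obs, nbins = length(uniq))

  I1 <- integer(0); I2 <- integer(0); P <- integer(0)
  for (p in seq_along(uniq)) {
    i <- uniq[p]
    gp <- if (is.null(gene_pairs)) NULL else as.character(gene_pairs[i, ])
    prs <- pairs_for_obs(hap_mat, allele, as.integer(G[i, ]), gp)
    if (nrow(prs)) {
      I1 <- c(I1, prs[, 1]); I2 <- c(I2, prs[, 2])
      P <- c(P, rep.int(p, nrow(prs)))
    }
  }
  list(I1 = I1, I2 = I2, P = P, n_obs = n_obs, subj_obs = subj_obs,
       n_pat = length(uniq))
}

# Per-observation total probability sum_{(i1,i2)} f[i1] f[i2]
obs_likelihood <- function(freq, px) {
  tot <- numeric(px$n_pat)
  if (length(px$I1)) {
    w <- freq[px$I1] * freq[px$I2]
    rs <- rowsum(w, px$P)
    tot[as.integer(rownames(rs))] <- rs[, 1]
  }
  tot
}

# EM over a fixed support. Observations with no compatible pair (or zero
# total mass) are dropped from the likelihood with a warning.
em_run <- function(freq, px, max_iter = 1000L, tol_freq = 1e-7, tol_ll = 1e-9) {
  K <- length(freq)
  live <- which(obs_likelihood(rep(1, K), px) > 0)  # structural zeros
  if (length(live) < px$n_pat)
    warning(px$n_pat - length(live),
            " observation pattern(s) incompatible with the haplotype support; dropped")
  keep <- px$P %in% live
  I1 <- px$I1[keep]; I2 <- px$I2[keep]; P <- px$P[keep]
  n_obs <- px$n_obs
  N2 <- 2 * sum(n_obs[live])
  if (N2 == 0) stop("no observations compatible with the haplotype support")

  ll_trace <- numeric(0)
  ll_old <- -Inf
  for (it in seq_len(max_iter)) {
    w <- freq[I1] * freq[I2]
    tot <- numeric(px$n_pat)
    rs <- rowsum(w, P)
    tot[as.integer(rownames(rs))] <- rs[, 1]
    pos <- live[tot[live] > 0]
    if (length(pos) < length(live)) {
      # estimated-zero path for some observation: restart those from uniform
      # mass cannot recover under EM; drop them from the likelihood
      warning(length(live) - length(pos),
              " observation pattern(s) lost all posterior mass; dropped")
      live <- pos
      keep <- P %in% live
      I1 <- I1[keep]; I2 <- I2[keep]; P <- P[keep]
      N2 <- 2 * sum(n_obs[live])
      if (N2 == 0) stop("no observations compatible with the haplotype support")
      w <- freq[I1] * freq[I2]
      tot <- numeric(px$n_pat)
      rs <- rowsum(w, P)
      tot[as.integer(rownames(rs))] <- rs[, 1]
    }
    ll <- sum(n_obs[live] * log(tot[live]))
    ll_trace <- c(ll_trace, ll)

    resp <- w / tot[P] * n_obs[P]
    cnt <- numeric(K)
    rs2 <- rowsum(c(resp, resp), c(I1, I2))
    cnt[as.integer(rownames(rs2))] <- rs2[, 1]
    freq_new <- cnt / N2

    delta <- max(abs(freq_new - freq))
    converged <- delta < tol_freq || (is.finite(ll_old) && ll - ll_old < tol_ll)
    freq <- freq_new
    if (converged) break
    ll_old <- ll
  }
  list(freq = freq, loglik = ll_trace[length(ll_trace)], ll_trace = ll_trace,
       live = live)
}
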