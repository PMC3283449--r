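# Independent brute-force oracles used to pin down expected values.
# These deliberately share no code with the package internals: plain loops
# over the fully enumerated haplotype space.

all_haps <- function(L) {
  apply(as.matrix(expand.grid(rep(list(0:1), L), KEEP.OUT.ATTRS = FALSE)),
        1L, paste0, collapse = "")
}

hap_ints <- function(h) as.integer(strsplit(h, "", fixed = TRUE)[[1L]])

# HWE genotype likelihood by summation over all 2^L x 2^L ordered pairs
oracle_pair_likelihood <- function(freq, codes) {
  L <- length(codes)
  haps <- all_haps(L)
  f <- function(h) if (h %in% names(freq)) unname(freq[h]) else 0
  tot <- 0
  for (h1 in haps) for (h2 in haps) {
    g <- hap_ints(h1) + hap_ints(h2)
    if (all(is.na(codes) | g == codes)) tot <- tot + f(h1) * f(h2)
  }
  tot
}

# Posterior over unordered pairs by the same enumeration
oracle_posterior <- function(freq, codes) {
  L <- length(codes)
  haps <- all_haps(L)
  f <- function(h) if (h %in% names(freq)) unname(freq[h]) else 0
  acc <- list()
  for (h1 in haps) for (h2 in haps) {
    g <- hap_ints(h1) + hap_ints(h2)
    if (all(is.na(codes) | g == codes)) {
      key <- paste(sort(c(h1, h2)), collapse = "/")
      acc[[key]] <- (if (is.null(acc[[key]])) 0 else acc[[key]]) + f(h1) * f(h2)
    }
  }
  v <- unlist(acc)
  v <- v[v > 0]
  v / sum(v)
}

# EM over the fully enumerated haplotype space, direct per-subject loops
oracle_em <- function(G, max_iter = 5000L, tol = 1e-12) {
  L <- ncol(G); n <- nrow(G)
  haps <- all_haps(L)
  K <- length(haps)
  hm <- do.call(rbind, lapply(haps, hap_ints))
  comp <- lapply(seq_len(n), function(i) {
    ci <- as.integer(G[i, ])
    out <- NULL
    for (a in seq_len(K)) for (b in seq_len(K)) {
      g <- hm[a, ] + hm[b, ]
      if (all(is.na(ci) | g == ci)) out <- rbind(out, c(a, b))
    }
    out
  })
  freq <- rep(1 / K, K)
  ll <- NA_real_; ll_old <- -Inf
  for (it in seq_len(max_iter)) {
    cnt <- numeric(K); ll <- 0
    for (i in seq_len(n)) {
      prs <- comp[[i]]
      w <- freq[prs[, 1]] * freq[prs[, 2]]
      tot <- sum(w)
      ll <- ll + log(tot)
      w <- w / tot
      for (r in seq_len(nrow(prs))) {
        cnt[prs[r, 1]] <- cnt[prs[r, 1]] + w[r]
        cnt[prs[r, 2]] <- cnt[prs[r, 2]] + w[r]
      }
    }
    freq <- cnt / (2 * n)
    if (abs(ll - ll_old) < tol) break
    ll_old <- ll
  }
  list(freq = stats::setNames(freq, haps), loglik = ll)
}

# random unphased-genotype instance drawn from a random haplotype pool
random_em_instance <- function(seed, max_loci = 5L, max_subjects = 30L) {
  set.seed(seed)
  L <- sample(2:max_loci, 1L)
  n <- sample(5:max_subjects, 1L)
  haps <- all_haps(L)
  k <- sample(2:min(6L, length(haps)), 1L)
  pool <- sample(haps, k)
  f <- rgamma(k, 0.8); f <- f / sum(f)
  h1 <- sample(pool, n, replace = TRUE, prob = f)
  h2 <- sample(pool, n, replace = TRUE, prob = f)
  codes <- t(vapply(seq_len(n), function(i) hap_ints(h1[i]) + hap_ints(h2[i]),
                    integer(L)))
  loci <- snp_loci(paste0("s", seq_len(L)), "chr1", seq_len(L) * 100, "A", "G")
  geno_matrix(codes, loci)
}

# random normalized frequency table + compatible genotype, for posterior
# normalization properties
random_table_and_genotype <- function(seed, max_loci = 4L) {
  set.seed(seed)
  L <- sample(1:max_loci, 1L)
  haps <- all_haps(L)
  k <- sample(2:length(haps), 1L)
  pool <- sample(haps, k)
  f <- rgamma(k, 0.6); f <- f / sum(f)
  h1 <- sample(pool, 1L, prob = f); h2 <- sample(pool, 1L, prob = f)
  codes <- hap_ints(h1) + hap_ints(h2)
  list(ft = freq_table(pool, f), codes = codes)
}
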