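# Synthetic cohorts with known truth: a pool of gene-SNP haplotypes with
# skewed allele frequencies, HWE random mating, tag SNPs in tunable LD with
# the gene alleles, and case/control sampling under per-allele logistic
# effects.

#' Simulation configuration
#'
#' Defaults mirror the scale of a typical deeply sequenced coding gene and
#' a GWAS-sized case/control cohort: 9 intragenic SNPs and 9 gene alleles
#' (a KCNJ11-like gene), 6 flanking tag SNPs, skewed Dirichlet(0.5) allele
#' frequencies that produce a few common and several rare alleles, and
#' 2000 cases / 3000 controls.
#'
#' @param n_gene_snps Number of intragenic SNPs.
#' @param n_flank_snps Number of flanking tag SNPs.
#' @param n_alleles Number of distinct gene alleles (<= `2^n_gene_snps`).
#' @param dirichlet_alpha Dirichlet concentration for allele frequencies;
#'   smaller = more skewed.
#' @param tag_fidelity Probability that a haplotype's flanking tag SNPs
#'   deterministically encode its gene allele; with probability
#'   `1 - tag_fidelity` the tag haplotype is drawn from the pool's marginal
#'   tag distribution instead (imperfect LD).
#' @param n_subjects Cohort size for [simulate_cohort()].
#' @param n_cases,n_controls Group sizes for [simulate_case_control()].
#' @param allele_freqs Optional explicit allele frequency vector (length
#'   `n_alleles`, summing to 1); overrides the Dirichlet draw. Useful for
#'   fixtures where every allele must be common enough to appear in a
#'   cohort.
#' @param effect_map Named numeric vector of per-allele log-odds ratios
#'   (alleles absent from the map have effect 0).
#' @param gene_name Gene symbol used in allele labels.
#' @param seed Integer seed; every generator is a pure function of
#'   (config, seed).
#'
#' @return List of class `sim_config`.
#' @export
sim_config <- function(n_gene_snps = 9L, n_flank_snps = 6L, n_alleles = 9L,
                       dirichlet_alpha = 0.5, tag_fidelity = 1,
                       allele_freqs = NULL,
                       n_subjects = 500L, n_cases = 2000L, n_controls = 3000L,
                       effect_map = NULL, gene_name = "GENE1", seed = 1L) {
  stopifnot(n_gene_snps >= 1, n_flank_snps >= 1, n_alleles >= 1,
            n_subjects >= 1, n_cases >= 1, n_controls >= 1,
            tag_fidelity >= 0, tag_fidelity <= 1, dirichlet_alpha > 0)
  if (!is.null(allele_freqs)) {
    stopifnot(length(allele_freqs) == n_alleles, all(allele_freqs > 0),
              abs(sum(allele_freqs) - 1) < 1e-9)
    allele_freqs <- sort(allele_freqs, decreasing = TRUE)
  }
  structure(list(n_gene_snps = as.integer(n_gene_snps),
                 n_flank_snps = as.integer(n_flank_snps),
                 n_alleles = as.integer(n_alleles),
                 dirichlet_alpha = dirichlet_alpha,
                 tag_fidelity = tag_fidelity,
                 allele_freqs = allele_freqs,
                 n_subjects = as.integer(n_subjects),
                 n_cases = as.integer(n_cases),
                 n_controls = as.integer(n_controls),
                 effect_map = effect_map, gene_name = gene_name,
                 seed = as.integer(seed)),
            class = "sim_config")
}

# n distinct binary strings of length L, most-frequent-first assignment
distinct_haps <- function(n, L) {
  if (n > 2^L) stop("n_alleles exceeds 2^n_snps distinct haplotypes")
  if (2^L <= 4096) {
    all_h <- mat_to_hap(as.matrix(expand.grid(rep(list(0:1), L),
                                              KEEP.OUT.ATTRS = FALSE)))
    sample(all_h, n)
  } else {
    h <- character(0)
    while (length(h) < n)
      h <- unique(c(h, paste0(sample(0:1, L, replace = TRUE), collapse = "")))
    h[seq_len(n)]
  }
}

#' Simulate a gene-SNP haplotype pool
#'
#' Draws `n_alleles` distinct intragenic haplotypes with
#' Dirichlet(`dirichlet_alpha`) frequencies (sorted decreasing, so labels
#' follow frequency rank), assigns each gene allele a distinct flanking tag
#' haplotype, and mixes in imperfect LD: the joint frequency of gene allele
#' `a` with tag haplotype `t_b` is
#' `f_a * (fidelity * I(b == a) + (1 - fidelity) * f_b)`.
#'
#' @param cfg A [sim_config()].
#'
#' @return List of class `sim_pool`: `joint` (a joint [freq_table()] over
#'   the flanking loci), `alleles` (label table with intragenic sequences),
#'   `gene` (name/interval), `gene_loci`, `flank_loci`, `tag_of` (named
#'   vector allele -> tag haplotype), `config`.
#' @export
simulate_pool <- function(cfg = sim_config()) {
  with_seed(cfg$seed, {
    k <- cfg$n_alleles
    gene_hap <- distinct_haps(k, cfg$n_gene_snps)
    f <- if (!is.null(cfg$allele_freqs)) cfg$allele_freqs
         else {
           r <- stats::rgamma(k, shape = cfg$dirichlet_alpha)
           sort(r / sum(r), decreasing = TRUE)
         }
    labels <- paste0(cfg$gene_name, "*", seq_len(k))
    # tag codes are drawn so that every unordered pair of codes has a
    # distinct per-locus sum: at full fidelity the unphased tag genotype
    # then identifies the diplotype, not just each haplotype, making
    # perfect recovery information-theoretically possible
    tag_hap <- distinct_haps(k, cfg$n_flank_snps)
    pair_ij <- which(upper.tri(diag(k), diag = TRUE), arr.ind = TRUE)
    for (try in seq_len(500L)) {
      hm <- hap_to_mat(tag_hap)
      sums <- apply(pair_ij, 1L, function(ij)
        paste0(hm[ij[1L], ] + hm[ij[2L], ], collapse = ""))
      if (!anyDuplicated(sums)) break
      tag_hap <- distinct_haps(k, cfg$n_flank_snps)
    }

    # joint over (allele, tag haplotype)
    fid <- cfg$tag_fidelity
    joint <- expand.grid(a = seq_len(k), b = seq_len(k))
    jf <- f[joint$a] * (fid * (joint$a == joint$b) + (1 - fid) * f[joint$b])
    keep <- jf > 0
    joint <- joint[keep, ]; jf <- jf[keep]

    start <- 100001L
    end <- start + 100L * cfg$n_gene_snps + 400L
    gene_loci <- snp_loci(
      id = paste0("g", seq_len(cfg$n_gene_snps)), chrom = "chr1",
      pos = start + 100L * (seq_len(cfg$n_gene_snps) - 1L) + 50L,
      ref = rep("A", cfg$n_gene_snps), alt = rep("G", cfg$n_gene_snps))
    side <- rep_len(c(-1L, 1L), cfg$n_flank_snps)
    off <- 5000L * ((seq_len(cfg$n_flank_snps) + 1L) %/% 2L)
    fpos <- ifelse(side < 0, start - off, end + off)
    ord <- order(fpos)
    flank_loci <- snp_loci(
      id = paste0("f", seq_len(cfg$n_flank_snps))[ord], chrom = "chr1",
      pos = fpos[ord], ref = rep("C", cfg$n_flank_snps),
      alt = rep("T", cfg$n_flank_snps))
    # tag haplotype strings follow flank_loci (position) order
    reorder_hap <- function(h) {
      ch <- strsplit(h, "", fixed = TRUE)[[1L]]
      paste0(ch[ord], collapse = "")
    }
    tag_hap <- vapply(tag_hap, reorder_hap, character(1), USE.NAMES = FALSE)

    jt <- freq_table(hap = tag_hap[joint$b], freq = jf / sum(jf),
                     loci = flank_loci, allele = labels[joint$a])
    structure(list(
      joint = jt,
      alleles = data.frame(label = labels, hap = gene_hap, freq = f,
                           stringsAsFactors = FALSE),
      gene = list(name = cfg$gene_name, chrom = "chr1", start = start,
                  end = end),
      gene_loci = gene_loci, flank_loci = flank_loci,
      tag_of = stats::setNames(tag_hap, labels),
      config = cfg), class = "sim_pool")
  })
}

# sample 2n joint haplotypes (allele index + tag hap) from the pool
draw_haps <- function(pool, n2) {
  idx <- sample.int(nrow(pool$joint), n2, replace = TRUE,
                    prob = pool$joint$freq)
  list(allele = pool$joint$allele[idx], tag = pool$joint$hap[idx])
}

codes_from_haps <- function(h1, h2) {
  hap_to_mat(h1) + hap_to_mat(h2)
}

subject_tables <- function(pool, d, ids) {
  odd <- seq(1, length(d$allele), by = 2)
  a1 <- d$allele[odd]; a2 <- d$allele[odd + 1L]
  swap <- a2 < a1
  truth <- data.frame(sample = ids,
                      allele1 = ifelse(swap, a2, a1),
                      allele2 = ifelse(swap, a1, a2),
                      called = TRUE, stringsAsFactors = FALSE)
  lut <- stats::setNames(pool$alleles$hap, pool$alleles$label)
  Gg <- geno_matrix(codes_from_haps(unname(lut[d$allele[odd]]),
                                    unname(lut[d$allele[odd + 1L]])),
                    pool$gene_loci)
  Gf <- geno_matrix(codes_from_haps(d$tag[odd], d$tag[odd + 1L]),
                    pool$flank_loci)
  rownames(Gg) <- ids; rownames(Gf) <- ids
  list(truth = truth, gene_genotypes = Gg, flank_genotypes = Gf)
}

#' Simulate an HWE cohort from a pool
#'
#' Each subject's two gene-SNP haplotypes are independent draws from the
#' pool (random mating); genotypes are the unphased per-locus sums, and the
#' true diplotypes are retained.
#'
#' @param pool A `sim_pool` from [simulate_pool()].
#' @param n_subjects Number of subjects (default from the pool's config).
#' @param seed Integer seed.
#'
#' @return List of class `sim_cohort`: `truth` (sample, allele1, allele2),
#'   `gene_genotypes` and `flank_genotypes` ([geno_matrix()]s).
#' @export
simulate_cohort <- function(pool, n_subjects = pool$config$n_subjects,
                            seed = pool$config$seed + 1L) {
  with_seed(seed, {
    d <- draw_haps(pool, 2L * n_subjects)
    out <- subject_tables(pool, d, paste0("S", seq_len(n_subjects)))
    structure(out, class = "sim_cohort")
  })
}

#' Simulate a case-control cohort under per-allele logistic effects
#'
#' Subjects are drawn from the pool under HWE; the probability of being a
#' case is `plogis(b0 + sum_a dosage(a) * effect_map[a])`, with the
#' intercept `b0` solved so the expected case fraction matches
#' `n_cases / (n_cases + n_controls)`. Subjects are then rejection-sampled
#' until both groups reach their exact target sizes.
#'
#' @param pool A `sim_pool`.
#' @param effect_map Named numeric vector allele label -> log-odds ratio
#'   (missing alleles have effect 0).
#' @param n_cases,n_controls Exact group sizes.
#' @param seed Integer seed.
#'
#' @return List of class `sim_case_control`: `phenotypes` (sample, status),
#'   `truth`, `gene_genotypes`, `flank_genotypes`, `b0`.
#' @export
simulate_case_control <- function(pool,
                                  effect_map = pool$config$effect_map,
                                  n_cases = pool$config$n_cases,
                                  n_controls = pool$config$n_controls,
                                  seed = pool$config$seed + 2L) {
  if (is.null(effect_map)) effect_map <- stats::setNames(numeric(0), character(0))
  bad <- setdiff(names(effect_map), pool$alleles$label)
  if (length(bad)) stop("effect_map names unknown to the pool: ",
                        paste(bad, collapse = ", "))
  beta <- stats::setNames(rep(0, nrow(pool$alleles)), pool$alleles$label)
  beta[names(effect_map)] <- effect_map
  f <- stats::setNames(pool$alleles$freq, pool$alleles$label)
  target <- n_cases / (n_cases + n_controls)

  # expected case fraction under HWE, as a function of the intercept
  pair <- expand.grid(a = pool$alleles$label, b = pool$alleles$label,
                      stringsAsFactors = FALSE)
  p_ab <- f[pair$a] * f[pair$b]
  eta_ab <- beta[pair$a] + beta[pair$b]
  efrac <- function(b0) sum(p_ab * stats::plogis(b0 + eta_ab)) - target
  sol <- tryCatch(stats::uniroot(efrac, c(-25, 25), tol = 1e-10),
                  error = function(e)
    stop("unreachable case fraction ", target, " under the given effects"))
  b0 <- sol$root

  with_seed(seed, {
    lut_beta <- beta
    need_case <- n_cases; need_ctrl <- n_controls
    acc <- list()
    guard <- 0L
    while ((need_case > 0 || need_ctrl > 0) && guard < 10000L) {
      guard <- guard + 1L
      batch <- max(256L, 2L * (need_case + need_ctrl))
      d <- draw_haps(pool, 2L * batch)
      odd <- seq(1, length(d$allele), by = 2)
      eta <- b0 + lut_beta[d$allele[odd]] + lut_beta[d$allele[odd + 1L]]
      is_case <- stats::runif(batch) < stats::plogis(eta)
      take <- ifelse(is_case, need_case > cumsum(is_case) - 1L,
                     need_ctrl > cumsum(!is_case) - 1L)
      sel <- which(take)
      if (length(sel)) {
        keep2 <- sort(c(2L * sel - 1L, 2L * sel))
        acc[[length(acc) + 1L]] <- list(
          allele = d$allele[keep2], tag = d$tag[keep2],
          status = as.integer(is_case[sel]))
        need_case <- need_case - sum(is_case[sel])
        need_ctrl <- need_ctrl - sum(!is_case[sel])
      }
    }
    if (need_case > 0 || need_ctrl > 0)
      stop("unreachable case fraction: rejection sampling did not fill groups")
    d <- list(allele = unlist(lapply(acc, `[[`, "allele")),
              tag = unlist(lapply(acc, `[[`, "tag")))
    status <- unlist(lapply(acc, `[[`, "status"))
    ids <- paste0("S", seq_along(status))
    out <- subject_tables(pool, d, ids)
    structure(c(list(phenotypes = data.frame(sample = ids, status = status,
                                             stringsAsFactors = FALSE),
                     b0 = b0), out),
              class = "sim_case_control")
  })
}
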