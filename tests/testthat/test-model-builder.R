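two_allele_loci <- function(n = 2L) {
  snp_loci(paste0("t", seq_len(n)), "chr1", 500L + seq_len(n), "C", "T")
}

test_that("objective Q combines prediction log-loss with the m - k penalty", {
  # perfect tagging, m = k: Q = 0
  m <- perfect_model()
  diplos <- data.frame(allele1 = c("A*1", "A*1"), allele2 = c("A*2", "A*2"))
  G <- geno_matrix(matrix(c(1L, 1L), 2, 1), m$snps)
  expect_equal(objective_q(m, diplos, G), 0)

  # f(h|g) = 0.5 per subject and m - k = 2: Q = 2 ln 2 + 2
  loci <- two_allele_loci(1L)
  joint <- freq_table(c("0", "1", "0", "1"), rep(0.25, 4), loci,
                      allele = c("A*1", "A*1", "A*2", "A*2"))
  m2 <- prediction_model(gene = list(name = "A", chrom = "chr1", start = 1L,
                                     end = 10L),
                         snps = loci, joint = joint,
                         alleles = c("A*1" = "0", "A*2" = "1"))
  G2 <- geno_matrix(matrix(c(1L, 1L), 2, 1), loci)
  expect_equal(objective_q(m2, diplos, G2), 2 * log(2) + 2, tolerance = 1e-12)

  # a subject the model cannot explain is an error
  bad <- data.frame(allele1 = "A*1", allele2 = "A*1")
  Gbad <- geno_matrix(matrix(2L, 1, 1), m$snps)  # hom-alt needs A*2|1 twice
  expect_error(objective_q(m, bad, Gbad), "inconsistent with training")
})

test_that("candidate windows order SNPs by distance from the gene", {
  catalog <- snp_loci(paste0("s", 1:4), "chr1", c(60L, 150L, 240L, 260L),
                      "A", "G")
  gene <- list(chrom = "chr1", start = 100L, end = 200L)
  w <- candidate_window(gene, 50L, catalog)
  expect_equal(w$pos, c(150L, 60L, 240L))  # intragenic first, tie by position

  expect_equal(candidate_window(gene, 0L, catalog)$pos, 150L)
  expect_equal(nrow(candidate_window(gene, 10000L, catalog)), 4L)
  expect_equal(nrow(candidate_window(list(chrom = "chr9", start = 1L,
                                          end = 2L), 50L, catalog)), 0L)
})

test_that("stepwise selection keeps informative SNPs and drops noise", {
  set.seed(21)
  n <- 60L
  a1 <- sample(c("A*1", "A*2"), n, TRUE, prob = c(0.6, 0.4))
  a2 <- sample(c("A*1", "A*2"), n, TRUE, prob = c(0.6, 0.4))
  sw <- a2 < a1
  diplos <- data.frame(allele1 = ifelse(sw, a2, a1),
                       allele2 = ifelse(sw, a1, a2),
                       stringsAsFactors = FALSE)
  tag <- (a1 == "A*2") + (a2 == "A*2")          # perfectly tagging SNP
  noise <- sample(0:2, n, TRUE, prob = c(.49, .42, .09))
  loci <- two_allele_loci(2L)
  G <- geno_matrix(cbind(tag, noise), loci)
  dict <- c("A*1" = "0", "A*2" = "1")
  gene <- list(name = "A", chrom = "chr1", start = 1L, end = 10L)

  model <- forward_backward_select(diplos, G, dict, gene)
  expect_equal(model$snps$id, "t1")              # tagging SNP only
  expect_true(all(diff(model$meta$q_trace) < -1e-6))

  # exhaustive subset search agrees on the best subset
  subsets <- list(integer(0), 1L, 2L, 1:2)
  qs <- vapply(subsets, function(idx) {
    fit_gene_snp_model(diplos, G[, idx, drop = FALSE], dict, gene)$meta$q
  }, numeric(1))
  expect_equal(model$meta$q, min(qs), tolerance = 1e-6)
  expect_equal(subsets[[which.min(qs)]], 1L)

  # pure-noise candidates: nothing is selected, prior-only model survives
  G0 <- geno_matrix(cbind(noise, sample(0:2, n, TRUE, prob = c(.49, .42, .09))),
                    loci)
  m0 <- forward_backward_select(diplos, G0, dict, gene)
  expect_equal(nrow(m0$snps), 0L)
  q_subsets <- vapply(list(integer(0), 1L, 2L, 1:2), function(idx) {
    fit_gene_snp_model(diplos, G0[, idx, drop = FALSE], dict, gene)$meta$q
  }, numeric(1))
  expect_lte(q_subsets[1], min(q_subsets[-1]) + 1e-6)
})

test_that("flank scan records objectives and rescales them to [0, 1]", {
  pool <- simulate_pool(sim_config(n_gene_snps = 2L, n_flank_snps = 4L,
                                   n_alleles = 4L, dirichlet_alpha = 2,
                                   tag_fidelity = 1, seed = 5L))
  coh <- simulate_cohort(pool, 120L, seed = 6L)
  dict <- stats::setNames(pool$alleles$hap, pool$alleles$label)
  sizes <- c(0, 6000, 12000, 200000)
  fs <- flank_scan(coh$truth, coh$flank_genotypes, dict, pool$gene,
                   catalog = pool$flank_loci, sizes = sizes)
  expect_equal(fs$size, sizes)
  expect_true(all(fs$rescaled >= 0 & fs$rescaled <= 1))
  rng <- max(fs$objective) - min(fs$objective)
  expect_equal(fs$rescaled,
               if (rng > 0) (fs$objective - min(fs$objective)) / rng
               else rep(0, length(sizes)))
  # larger windows can only match or improve the best objective
  expect_equal(which.min(fs$objective), which(fs$rescaled == 0)[1])

  # identical candidate sets across sizes: constant series rescales to 0
  fs2 <- flank_scan(coh$truth, coh$flank_genotypes, dict, pool$gene,
                    catalog = pool$flank_loci, sizes = c(150000, 250000))
  expect_equal(fs2$objective[1], fs2$objective[2])
  expect_equal(fs2$rescaled, c(0, 0))
})

test_that("population-stratified splits are half-half, disjoint and reproducible", {
  samples <- data.frame(sample = paste0("S", 1:21),
                        population = rep(c("CEU", "YRI", "CHB"), c(10, 6, 5)))
  sp <- split_train_validation(samples, seed = 42L)
  expect_equal(length(sp$train), 5 + 3 + 3)     # ceiling(n/2) per population
  expect_equal(length(sp$validation), 21 - 11)
  expect_length(intersect(sp$train, sp$validation), 0)
  expect_setequal(c(sp$train, sp$validation), samples$sample)

  sp2 <- split_train_validation(samples, seed = 42L)
  expect_identical(sp, sp2)
  sp3 <- split_train_validation(samples, seed = 43L)
  expect_false(identical(sp$train, sp3$train))
})
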