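test_that("pools are normalized, deterministic and respect tag fidelity", {
  cfg <- sim_config(n_gene_snps = 3L, n_flank_snps = 4L, n_alleles = 5L,
                    seed = 2L)
  pool <- simulate_pool(cfg)
  expect_equal(sum(pool$joint$freq), 1, tolerance = 1e-12)
  expect_equal(nrow(pool$alleles), 5L)
  expect_false(is.unsorted(rev(pool$alleles$freq)))    # rank order
  expect_equal(anyDuplicated(pool$alleles$hap), 0L)

  # tag_fidelity = 1: flank haplotype -> gene allele is a function
  expect_equal(anyDuplicated(pool$joint$hap), 0L)
  # same seed, same pool; different seed differs
  expect_identical(simulate_pool(cfg), pool)
  expect_false(identical(simulate_pool(sim_config(n_gene_snps = 3L,
                                                  n_flank_snps = 4L,
                                                  n_alleles = 5L,
                                                  seed = 3L)), pool))

  # leaky tagging spreads each allele over several tag haplotypes
  leaky <- simulate_pool(sim_config(n_gene_snps = 3L, n_flank_snps = 4L,
                                    n_alleles = 5L, tag_fidelity = 0.8,
                                    seed = 2L))
  expect_gt(nrow(leaky$joint), nrow(pool$joint))

  expect_error(simulate_pool(sim_config(n_gene_snps = 2L, n_alleles = 5L)),
               "exceeds")
})

test_that("HWE cohorts reproduce pool frequencies within binomial error", {
  pool <- simulate_pool(sim_config(n_gene_snps = 4L, n_flank_snps = 5L,
                                   n_alleles = 6L, dirichlet_alpha = 1,
                                   seed = 8L))
  n <- 5000L
  coh <- simulate_cohort(pool, n, seed = 9L)
  cnt <- table(factor(c(coh$truth$allele1, coh$truth$allele2),
                      levels = pool$alleles$label))
  emp <- as.numeric(cnt) / (2 * n)
  for (i in seq_along(emp)) {
    f <- pool$alleles$freq[i]
    expect_lt(abs(emp[i] - f), 3 * sqrt(f * (1 - f) / (2 * n)) + 1e-9)
  }
  # genotypes are the unphased sums of the drawn haplotypes
  expect_true(all(unclass(coh$gene_genotypes) %in% 0:2))
  expect_identical(simulate_cohort(pool, 50L, seed = 10L),
                   simulate_cohort(pool, 50L, seed = 10L))

  # point-mass pool: every subject homozygous for the single haplotype
  pm <- simulate_pool(sim_config(n_gene_snps = 2L, n_flank_snps = 2L,
                                 n_alleles = 1L, seed = 1L))
  coh1 <- simulate_cohort(pm, 20L, seed = 2L)
  expect_true(all(coh1$truth$allele1 == coh1$truth$allele2))
  expect_true(all(unclass(coh1$gene_genotypes) %in% c(0L, 2L)))
})

test_that("case-control sampling hits exact group sizes and the null keeps groups exchangeable", {
  pool <- simulate_pool(sim_config(n_gene_snps = 3L, n_flank_snps = 4L,
                                   n_alleles = 4L, dirichlet_alpha = 2,
                                   seed = 12L))
  cc <- simulate_case_control(pool, NULL, n_cases = 300L, n_controls = 450L,
                              seed = 13L)
  expect_equal(sum(cc$phenotypes$status == 1), 300L)
  expect_equal(sum(cc$phenotypes$status == 0), 450L)
  expect_equal(cc$b0, stats::qlogis(300 / 750), tolerance = 1e-8)

  # null effects: allele frequencies agree between groups within sampling error
  D <- hard_call_dosages(cc$truth, alleles = pool$alleles$label)
  fc <- colSums(D[cc$phenotypes$status == 1, ]) / 600
  f0 <- colSums(D[cc$phenotypes$status == 0, ]) / 900
  for (i in seq_along(fc)) {
    se <- sqrt(fc[i] * (1 - fc[i]) / 600 + f0[i] * (1 - f0[i]) / 900)
    expect_lt(abs(fc[i] - f0[i]), 4 * se + 0.02)
  }

  expect_identical(simulate_case_control(pool, NULL, 100L, 100L, seed = 5L),
                   simulate_case_control(pool, NULL, 100L, 100L, seed = 5L))
  expect_error(simulate_case_control(pool, c("NOPE*1" = 1), 10L, 10L),
               "unknown to the pool")
})

test_that("a nonzero allele effect shifts case frequencies in the right direction", {
  pool <- simulate_pool(sim_config(n_gene_snps = 3L, n_flank_snps = 4L,
                                   n_alleles = 4L,
                                   allele_freqs = c(0.4, 0.3, 0.2, 0.1),
                                   seed = 21L))
  target <- pool$alleles$label[2]
  cc <- simulate_case_control(pool, stats::setNames(0.5, target),
                              n_cases = 1500L, n_controls = 1500L, seed = 22L)
  D <- hard_call_dosages(cc$truth, alleles = pool$alleles$label)
  fc <- colSums(D[cc$phenotypes$status == 1, ]) / 3000
  f0 <- colSums(D[cc$phenotypes$status == 0, ]) / 3000
  expect_gt(fc[[target]], f0[[target]])
})
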