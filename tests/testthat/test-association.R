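test_that("expected dosages spread posterior mass and conserve ploidy", {
  posts <- list(S1 = c("A*1/A*2" = 1.0),
                S2 = c("A*1/A*1" = 0.5, "A*1/A*2" = 0.5),
                S3 = numeric(0))
  D <- expected_dosages(posts)
  expect_equal(D["S1", ], c("A*1" = 1, "A*2" = 1))
  expect_equal(D["S2", ], c("A*1" = 1.5, "A*2" = 0.5))
  expect_true(all(is.na(D["S3", ])))
  expect_equal(unname(rowSums(D[1:2, ])), c(2, 2))

  hc <- hard_call_dosages(data.frame(sample = c("a", "b"),
                                     allele1 = c("A*1", NA),
                                     allele2 = c("A*1", NA)))
  expect_equal(hc["a", "A*1"], 2)
  expect_true(all(is.na(hc["b", ])))
})

test_that("the multi-allelic test is calibrated under the null and applies the frequency floor", {
  set.seed(31)
  n <- 2000L
  alleles <- c("G*1", "G*2", "G*3", "G*4")
  f <- c(0.5, 0.3, 0.15, 0.05)
  a1 <- sample(alleles, n, TRUE, f); a2 <- sample(alleles, n, TRUE, f)
  D <- matrix(0, n, 4, dimnames = list(NULL, alleles))
  for (i in seq_len(n)) { D[i, a1[i]] <- D[i, a1[i]] + 1
                          D[i, a2[i]] <- D[i, a2[i]] + 1 }
  y <- rep(0:1, n / 2)  # phenotype independent of dosage
  res <- multiallelic_test(D, y)
  expect_s3_class(res, "association_result")
  expect_true(res$is_reference[res$allele == "G*1"])
  tested <- res[res$tested, ]
  expect_true(all(abs(tested$coef) < 3 * tested$se))
  # internal consistency of every emitted row
  expect_equal(tested$or_, exp(tested$coef))
  expect_equal(tested$ci_lo, exp(tested$coef - 1.96 * tested$se))
  expect_true(all(tested$ci_lo <= tested$or_ & tested$or_ <= tested$ci_hi))
  expect_equal(tested$p, 2 * pnorm(-abs(tested$z)))

  # an allele rare in one group is reported but not tested
  D2 <- cbind(D, "G*5" = 0)
  rare <- sample(which(y == 1), 30)
  D2[rare, "G*5"] <- 1; D2[rare, "G*1"] <- D2[rare, "G*1"] - 1
  res2 <- multiallelic_test(D2, y)
  row5 <- res2[res2$allele == "G*5", ]
  expect_false(row5$tested)
  expect_true(is.na(row5$coef))
  expect_equal(row5$freq_control, 0)

  expect_error(multiallelic_test(D, y, reference = "G*9"), "unknown reference")
  expect_error(multiallelic_test(D, y, reference = "G*4", floor = 0.2),
               "must be common")
})

test_that("allele-ratio odds ratios reproduce the worked T2D examples", {
  # amino-acid allele aa*8 vs reference aa*5
  expect_equal(round(allele_ratio_or(0.365, 0.616, 0.336, 0.647), 2), 1.14)
  # genomic allele *5 vs reference *3
  expect_equal(round(allele_ratio_or(0.018, 0.364, 0.015, 0.336), 1), 1.1)
  expect_equal(allele_ratio_or(0.2, 0.5, 0.2, 0.5), 1.0)
  expect_error(allele_ratio_or(0.1, 0, 0.1, 0.3), "must be positive")
})

test_that("collapsing synonymous alleles boosts the association signal of a shared protein effect", {
  # two rare DNA alleles translate to one causal protein; pooling their
  # copies should usually beat the best single-allele test
  pool <- simulate_pool(sim_config(n_gene_snps = 3L, n_alleles = 4L,
                                   allele_freqs = c(0.5, 0.26, 0.12, 0.12),
                                   seed = 55L))
  labs <- pool$alleles$label
  proteins <- stats::setNames(c("MEK", "MGK", "MKK", "MKK"), labs)
  eff <- stats::setNames(c(0.35, 0.35), labs[3:4])  # shared protein effect
  wins <- 0L
  reps <- 40L
  for (r in seq_len(reps)) {
    cc <- simulate_case_control(pool, eff, 1000L, 1500L,
                                seed = 900L + r)
    D <- hard_call_dosages(cc$truth, alleles = labs)
    res_dna <- multiallelic_test(D, cc$phenotypes$status, reference = labs[1])
    z_dna <- max(abs(res_dna$z[res_dna$tested]), na.rm = TRUE)
    freqs <- data.frame(allele = labs,
                        freq_control = colMeans(D[cc$phenotypes$status == 0, ]) / 2,
                        freq_case = colMeans(D[cc$phenotypes$status == 1, ]) / 2)
    aa <- collapse_synonymous(freqs, proteins)
    Daa <- collapse_dosages(D, attr(aa, "mapping"))
    expect_equal(unname(rowSums(Daa)), rep(2, nrow(Daa)))
    # reference the aa allele of the effect-free DNA reference, mirroring
    # the most-frequent-null-allele convention
    aa_ref <- unname(attr(aa, "mapping")[labs[1]])
    res_aa <- multiallelic_test(Daa, cc$phenotypes$status,
                                reference = aa_ref)
    z_aa <- max(abs(res_aa$z[res_aa$tested]), na.rm = TRUE)
    if (z_aa >= z_dna) wins <- wins + 1L
  }
  expect_gte(wins / reps, 0.8)
})
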