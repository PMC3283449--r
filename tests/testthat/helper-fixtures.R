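# Shared fixtures, built in code at test time.

# one perfectly tagging SNP: allele A*1 <-> SNP 0, A*2 <-> SNP 1
perfect_model <- function(f1 = 0.5) {
  loci <- snp_loci("t1", "chr1", 500L, "C", "T")
  joint <- freq_table(hap = c("0", "1"), freq = c(f1, 1 - f1),
                      loci = loci, allele = c("A*1", "A*2"))
  prediction_model(gene = list(name = "A", chrom = "chr1", start = 100L,
                               end = 200L),
                   snps = loci, joint = joint,
                   alleles = c("A*1" = "0", "A*2" = "1"))
}

# joint table {A*1|0: 0.4, A*2|1: 0.4, A*2|0: 0.2} over one SNP
leaky_model <- function() {
  loci <- snp_loci("t1", "chr1", 500L, "C", "T")
  joint <- freq_table(hap = c("0", "1", "0"), freq = c(0.4, 0.4, 0.2),
                      loci = loci, allele = c("A*1", "A*2", "A*2"))
  prediction_model(gene = list(name = "A", chrom = "chr1", start = 100L,
                               end = 200L),
                   snps = loci, joint = joint,
                   alleles = c("A*1" = "0", "A*2" = "1"))
}

# deterministic-recovery study conditions: 8 common alleles over 4
# intragenic SNPs, each encoded by a distinct haplotype of 6 flanking tag
# SNPs; every allele frequent enough to appear in a 200-subject training set
recovery_config <- function(tag_fidelity = 1, seed = 11L) {
  sim_config(n_gene_snps = 4L, n_flank_snps = 6L, n_alleles = 8L,
             tag_fidelity = tag_fidelity,
             allele_freqs = c(0.25, 0.20, 0.15, 0.12, 0.10, 0.08, 0.06, 0.04),
             n_subjects = 400L, seed = seed)
}

# build on true training diplotypes, predict the validation half
run_recovery <- function(tag_fidelity = 1, seed = 11L, ct = 0) {
  pool <- simulate_pool(recovery_config(tag_fidelity, seed))
  coh <- simulate_cohort(pool, 400L, seed = seed + 1L)
  tr <- 1:200; va <- 201:400
  dict <- stats::setNames(pool$alleles$hap, pool$alleles$label)
  model <- forward_backward_select(coh$truth[tr, ], coh$flank_genotypes[tr, ],
                                   dict, pool$gene)
  pred <- predict_cohort(model, coh$flank_genotypes[va, ], ct = ct)
  list(pool = pool, model = model, pred = pred, truth_val = coh$truth[va, ],
       accuracy = prediction_accuracy(pred, coh$truth[va, ]),
       call_rate = call_rate(pred))
}

# map labels assigned by phasing back to the generator's labels via the
# intragenic sequences, reordering pairs canonically
relabel_to_pool <- function(calls, dict, pool) {
  lut <- stats::setNames(pool$alleles$label, pool$alleles$hap)
  to_pool <- stats::setNames(unname(lut[dict]), names(dict))
  calls$allele1 <- unname(to_pool[calls$allele1])
  calls$allele2 <- unname(to_pool[calls$allele2])
  sw <- !is.na(calls$allele1) & !is.na(calls$allele2) &
        calls$allele2 < calls$allele1
  tmp <- calls$allele1[sw]
  calls$allele1[sw] <- calls$allele2[sw]
  calls$allele2[sw] <- tmp
  calls
}
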