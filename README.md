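# diplotyper

Predicting phased multi-allelic gene alleles from flanking SNP genotypes.

## What it does, and for whom

Read as a phased sequence, the intragenic SNPs of a gene define a
multi-allelic polymorphism: each distinct phased sequence is a **gene
allele**, and a diploid subject carries an unordered pair of them (a
**diplotype**). Deep-sequencing reference panels resolve these alleles
directly, but GWAS cohorts usually have only unphased SNP-array genotypes.
`diplotyper` is for statistical geneticists who want to bridge that gap:
it learns, from a phased training cohort, the joint distribution of gene
alleles and flanking **tag SNPs**, and then predicts a pair of phased gene
alleles for new subjects from tag-SNP genotypes alone — effectively
sequencing the gene *in silico*. Predicted coding alleles translate to
amino-acid sequences, so downstream case-control associations can be read
at the protein level.

## The model in brief

* **Phasing.** Haplotype frequencies are estimated from unphased genotypes
  by EM on the Hardy-Weinberg likelihood
  `l = Σ_i log Σ_{(H1,H2)∈Ω(g_i)} f(H1) f(H2)`, with progressive locus
  insertion and pruning so genes with many SNPs never require full `2^L`
  enumeration. Diplotypes are called when the Bayesian posterior of the
  best pair exceeds 0.95; alleles are labeled `GeneName*k` by frequency
  rank.
* **Tag-SNP selection.** A joint gene-SNP haplotype table `Pr(hG)` is
  fitted by the same EM; SNPs are chosen forward-and-backward to minimize
  the AIC-penalized objective `Q = −Σ_i log f(h_i|g_i) + (m − k)`, where
  `m` counts fitted gene-SNP haplotypes and `k` gene alleles. Candidates
  come from a flanking window (default ±250 kb), intragenic SNPs first.
* **Prediction.** For a new subject, the posterior over unordered allele
  pairs is `f(h|g) = f(h,g) / Σ_H f(H,g)`; a call is made when it exceeds
  the call threshold CT (default 0; 0.5/0.9 trade call rate for
  confidence). Accuracy is `(1/2N) Σ_i n_i` with `n_i` the matched alleles
  under the better phase matching, reported alongside the call rate.
* **Association & translation.** Case/control status is regressed on
  per-allele dosages (all common non-reference alleles jointly; Wald
  OR/CI/Z/p against the most frequent allele, frequency floor 0.01).
  Coding alleles are translated with the standard code and synonymous
  alleles collapsed into amino-acid alleles, pooling copies of a shared
  protein for more powerful tests.
* **Simulation.** A generator produces gene-SNP haplotype pools with
  skewed allele frequencies and tunable tag fidelity, HWE cohorts, and
  case/control data under per-allele logistic effects — with known truth,
  so the whole pipeline is testable end to end.

## Worked example

Simulate a deterministically tagged 8-allele gene, build a model on 200
training subjects, and validate on 200 held-out subjects:

```r
library(diplotyper)

cfg <- sim_config(n_gene_snps = 4, n_flank_snps = 6, n_alleles = 8,
                  tag_fidelity = 1,
                  allele_freqs = c(0.25, 0.20, 0.15, 0.12, 0.10, 0.08, 0.06, 0.04),
                  n_subjects = 400, seed = 11)
pool <- simulate_pool(cfg)
coh  <- simulate_cohort(pool, 400, seed = 12)
train <- 1:200; val <- 201:400

dict  <- setNames(pool$alleles$hap, pool$alleles$label)
model <- forward_backward_select(coh$truth[train, ], coh$flank_genotypes[train, ],
                                 dict, pool$gene)
model
#> prediction_model for gene GENE1
#>   interval: chr1:100001-100801 (flank 250000 bp)
#>   gene alleles: 8  selected SNPs: 5  joint haplotypes: 8
#>   objective Q: 0

evaluate_model(model, coh$flank_genotypes[val, ], coh$truth[val, ])
#>    ct accuracy call_rate n_called
#> 1 0.0        1         1      200
#> 2 0.5        1         1      200
#> 3 0.9        1         1      200
```

The selection kept 5 of the 6 tag SNPs (enough to separate all 8 tag
codes), reached `Q = 0` — every training diplotype has posterior 1 and the
SNPs add no free parameters beyond the 8 alleles (`m = k`) — and every
validation subject is predicted correctly at every call threshold.

Gene-level polymorphism of the simulated pool, and an allele-ratio odds
ratio computed directly from published case/control allele frequencies
(amino-acid allele `KCNJ11*aa*8` vs reference `aa*5` in a Type 2 diabetes
cohort):

```r
allele_entropy(pool$alleles$freq)
#> [1] 1.937337

or <- allele_ratio_or(0.365, 0.616, 0.336, 0.647)
round(c(or = or, coef = log(or)), 2)
#>   or coef
#> 1.14 0.13
```

A thin command-line interface over the same functions ships in
`inst/cli/diplotyper.R` (subcommands `simulate`, `phase`, `build`,
`predict`, `evaluate`, `associate`, `translate`).

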