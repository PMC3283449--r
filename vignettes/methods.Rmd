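---
title: "Predicting phased gene alleles from tag SNPs: models and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting phased gene alleles from tag SNPs: models and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(diplotyper)
```

## The problem

A gene's intragenic SNPs, read as a phased sequence, define a multi-allelic
polymorphism: each distinct phased sequence is one *gene allele*, and a
diploid subject carries an unordered pair of them (a *diplotype*). Direct
sequencing resolves these alleles, but most cohorts only have unphased SNP
array genotypes. Because nearby SNPs are in linkage disequilibrium with the
gene alleles, a model trained on a deeply sequenced reference cohort can
predict a new subject's pair of gene alleles from flanking *tag SNPs*
alone. Predicted coding alleles translate directly to amino-acid sequences,
which makes downstream association results interpretable at the protein
level.

`diplotyper` implements this whole workflow: phasing the training cohort,
labeling alleles, selecting informative tag SNPs, predicting diplotypes
with calibrated posteriors, testing multi-allelic case-control association
on allele dosages, and translating alleles to proteins. A simulation module
generates cohorts with known truth so every stage is testable without any
external download.

## Model

### Haplotype frequencies from unphased genotypes

Let $g_i = (g_{i1}, \dots, g_{iq})$ be subject $i$'s unphased genotype
codes (0/1/2 alternate-allele counts) and let $\Omega(g_i)$ be the set of
ordered haplotype pairs consistent with them. Under Hardy-Weinberg
equilibrium the two haplotypes are independent draws from the population
frequencies $f(\cdot)$, so the observed-data log-likelihood is

$$\ell = \sum_{i=1}^N \log \sum_{(H_1,H_2) \in \Omega(g_i)} f(H_1)\,f(H_2).$$

`em_frequencies()` maximizes $\ell$ by EM. Because a gene may have dozens
of SNPs, the haplotype space is never enumerated fully: EM starts on the
first two loci, then repeatedly extends every retained haplotype with both
alleles of the next locus (mass split by that locus's observed allele
frequency), prunes haplotypes with estimated frequency below `prune`
(default $10^{-5}$), and re-runs EM. Initialization is uniform and there is
no randomness, so results are reproducible by construction.

Per-subject diplotypes are then called by the Bayesian posterior over
compatible pairs; `call_diplotypes()` emits a call only when the best
pair's posterior strictly exceeds a threshold (default 0.95, a stringent
setting appropriate for building training data — miscalled training
diplotypes are worse than missing ones). Alleles are labeled
`GeneName*1, GeneName*2, ...` in decreasing frequency order
(`label_alleles()`), with exact ties broken lexicographically on the
allele code string so labels are stable across runs.

### The joint gene-SNP model and the selection objective

For prediction, the model couples each gene allele $h$ with a haplotype
$G$ of the selected flanking SNPs: the *gene-SNP haplotype* $hG$, with
multinomial frequencies $\Pr(hG)$ estimated by the same EM machinery (the
gene diplotype is observed in training; the SNP phase and the pairing of
alleles to SNP haplotypes are latent). Prediction for a new subject uses
the Bayesian rule

$$f(h \mid g) = \frac{f(h, g)}{\sum_{H} f(H, g)},$$

summing joint frequencies over ordered pairs compatible with the observed
SNP genotypes; missing genotypes are marginalized, so a subject typed on a
subset of the model's SNPs still gets a (less confident) posterior.

Tag SNPs are chosen by minimizing

$$Q = -\sum_{i=1}^N \log f(h_i \mid g_i) + (m - k),$$

the negative log posterior of the known training diplotypes plus an
AIC-style penalty: $m$ is the number of fitted gene-SNP haplotypes (above
the pruning threshold) and $k$ the number of gene alleles, so $m - k$
counts the extra parameters the SNPs introduce. `forward_backward_select()`
greedily adds the candidate SNP that most lowers $Q$ and removes any
selected SNP whose absence lowers $Q$, stopping when no move improves $Q$
by more than `eps` ($10^{-6}$, which prevents cycling on float noise); the
accepted-step trace of $Q$ is therefore strictly decreasing, and the code
asserts it. Candidates are tried intragenic-first, then by distance from
the gene boundary (`candidate_window()`); previously removed SNPs may
re-enter, and intragenic SNPs are tried first but not forced. Each
candidate evaluation refits the joint EM warm-started from the current
table (the new SNP's column initialized by its allele frequency; removal
marginalizes the table), a standard acceleration that leaves the fixed
point unchanged.

`flank_scan()` repeats the whole selection at window sizes 0–500 kb (50 kb
steps) and rescales the objectives to $[0,1]$ via
$(O_g - \min O_g)/(\max O_g - \min O_g)$ (all zeros for a constant
series), which is how a common operating window is chosen across genes;
250 kb is the default `flank_size`.

### Prediction, accuracy and call rate

`predict_diplotype()` emits the maximum-posterior unordered allele pair
when its posterior strictly exceeds the call threshold `ct` (default 0 —
always call when the genotype has support; 0.5 and 0.9 trade call rate for
confidence). Ties at the maximum are broken lexicographically by label
pair. Accuracy over a validation set is
$\tfrac{1}{2N}\sum_i n_i$ where $n_i \in \{0,1,2\}$ is the number of
matching alleles under the better of the two phase matchings; subjects
without a call are excluded from both numerator and denominator, so
accuracy and call rate are reported side by side (`evaluate_model()`).
Polymorphism is summarized by the Shannon entropy
$E = -\sum_i f_i \log f_i$ (natural log throughout the package), 0 for a
monomorphic gene and $\log n$ at the uniform maximum.

### Association and translation

`multiallelic_test()` regresses case/control status jointly on the dosages
of all common non-reference alleles (logistic regression, Wald
coefficients, SEs, ORs, 95% CIs as $\exp(\hat\beta \pm 1.96\,SE)$ and
two-sided p-values), with the most frequent allele as the default
reference and a strict per-group frequency floor of 0.01 — rarer alleles
are reported with frequencies only, untested. Dosages can be posterior
expectations (`expected_dosages()`, the default route, which carries
prediction uncertainty into the test and conserves a total of 2 per
subject) or hard calls (`hard_call_dosages()`). `allele_ratio_or()`
computes the frequency-ratio odds ratio
$(f^{case}_a/f^{case}_{ref})/(f^{ctrl}_a/f^{ctrl}_{ref})$ directly from
printed group frequencies, which is how the package reproduces published
table values without subject-level data.

`translate_allele()` applies an allele's variant bases to a reference
sequence, splices the coding exons, reverse-complements on the minus
strand and translates with the standard code (stops kept as `*`);
`collapse_synonymous()` merges DNA alleles with identical proteins,
summing frequencies and relabeling `GeneName*aa*k` by control-frequency
rank. Collapsing pools the copies of a shared causal protein, which is
where the power gain of amino-acid-level testing comes from; the test
suite verifies this as a simulation property (the collapsed test's best
$|Z|$ beats the best single-allele $|Z|$ in 87.5% of 40 seeded replicates
with two rare DNA alleles sharing one causal protein).

## What the simulator emulates — and what it does not

`simulate_pool()` builds a pool of gene alleles (distinct intragenic
haplotypes) with Dirichlet-distributed frequencies (default concentration
0.5, giving a few common and several rare alleles, the regime where
rare-allele prediction failures live), links each allele to a distinct
flanking tag haplotype, and mixes in imperfect LD through `tag_fidelity`:
with probability $1-\text{fidelity}$ a haplotype's tag code is drawn from
the marginal tag distribution instead of its own. Cohorts are sampled
under HWE (`simulate_cohort()`), and case/control datasets under a
per-allele logistic model whose intercept is solved so the expected case
fraction matches the target (`simulate_case_control()`, rejection-sampled
to exact group sizes; defaults 2000/3000, GWAS-like). All generators are
pure functions of (config, seed).

Two deliberate design points:

* **Identifiable tag codes.** At `tag_fidelity = 1` the tag codes are
  drawn so that every unordered pair of codes has a distinct per-locus
  sum. Without this, two diplotypes can share one unphased tag genotype
  (e.g. codes 111000+110010 and 111010+110000 both sum to 221010), making
  perfect recovery impossible for any method — an ambiguity of the
  encoding, not of the model. With it, the deterministic-tagging fixture
  is genuinely recoverable and the recovery tests demand accuracy 1.0.
* **Explicit fixture frequencies.** The recovery fixtures fix allele
  frequencies at (0.25, 0.20, 0.15, 0.12, 0.10, 0.08, 0.06, 0.04) so that
  every allele is essentially certain to appear in a 200-subject training
  set; with skewed Dirichlet draws, an allele absent from training is
  unlearnable and the fixture would measure sampling luck instead of the
  method.

The simulator does **not** model recombination maps, coalescent genealogy,
population structure, genotyping error or structural variants. Passing
recovery tests therefore show correctness of the estimation and selection
machinery under the model's own assumptions (HWE, stable LD), not
performance on real cohorts, where accuracy is bounded by LD strength,
training-panel size and rare alleles — the same factors that limit the
method in practice.

## Numerical choices

* Natural log everywhere (likelihood, $Q$, entropy).
* EM stops when the largest frequency change is below `1e-7` or the
  log-likelihood gain is below `1e-9` (cap 1000 iterations). These
  defaults target stable *calls*; tests that compare the progressive EM's
  final log-likelihood against a full-enumeration EM tighten both
  tolerances so that each EM is much closer to its optimum than the
  `1e-6` comparison slack.
* Frequencies below `1e-10` are treated as exactly zero when enumerating
  compatible pairs, bounding the pair search.
* Subjects whose genotypes are incompatible with the current haplotype
  support are dropped from the likelihood with a warning during phasing;
  in model fitting an unexplainable training subject is an error, since Q
  is undefined there.
* All ties (allele labeling, argmax calls, predicted pairs) break
  lexicographically on the code or label strings — reproducibility over
  aesthetics.
* Train/validation splitting is stratified by population with
  `ceiling(n/2)` to training (the odd sample goes to training),
  seed-reproducible.

## Problem sizes used in the test suite

Phasing oracle comparisons use up to 5 loci and 30 subjects against full
enumeration; recovery fixtures use 8 alleles, 4 intragenic SNPs, 6 tag
SNPs and 200/200 train/validation subjects; association calibration and
coverage use 100 replicates of 2000 cases / 3000 controls with hard-call
dosages from the generator's truth. These sizes exercise every code path
while keeping a full run in tens of seconds; the machinery itself has no
hard limits beyond the progressive EM's pruning threshold.

## Known limitations

* Alleles absent from (or miscalled in) the training cohort cannot be
  predicted; rare-allele accuracy is limited by training-panel size.
* A tag panel that cannot distinguish two alleles (no informative SNP in
  LD) leaves their posterior split by prior frequency; the honest remedy
  is combining such alleles or genotyping the missing SNP, not a more
  confident model.
* The association test conditions on predicted dosages; severe prediction
  uncertainty inflates dosage shrinkage toward the prior and attenuates
  effect estimates.
* Ploidy 2 and biallelic SNPs only; structural variants would enter as
  additional allele levels but are not modeled here.
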