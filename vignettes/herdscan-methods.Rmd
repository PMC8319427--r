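---
title: "Quantifying host genetic effects on the gut microbiota with herdscan"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying host genetic effects on the gut microbiota with herdscan}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(herdscan)
```

## The scientific problem

Gut microbial communities are shaped by diet, age, environment — and, less
visibly, by the host's own genome. Disentangling the genetic signal requires
a cohort with graded genetic variation raised under shared conditions, such
as a multibreed Angus–Brahman herd in which every animal carries a known
Brahman fraction between 0 and 1, binned into six breed groups (BG1, mostly
Angus, through BG6, mostly Brahman). herdscan implements the statistical
machinery for this design end to end: genotype quality control, community
diversity and ordination, per-taxon heritability from a genomic animal
model, two-step mixed-model genome scans, microbiability of growth and
immune phenotypes, regression association scans with a
significance/tendency classification, and Spearman co-occurrence networks.

Because the original herd's chip genotypes and 16S profiles are not
redistributable, the package ships a synthetic multibreed herd generator
that plants known parameters (heritabilities, microbiabilities, breed
slopes), so every stage can be validated by parameter recovery rather than
by re-analysis of restricted data.

## The core model

The central estimator is a single-random-effect animal model,

$$\mathbf{y} = \mathbf{X\beta} + \mathbf{u} + \mathbf{e}, \qquad
  \mathbf{u} \sim N(\mathbf{0}, \mathbf{K}\sigma^2_u), \qquad
  \mathbf{e} \sim N(\mathbf{0}, \mathbf{I}\sigma^2_e),$$

fitted by restricted maximum likelihood with one record per animal.

* With $\mathbf{K} = \mathbf{G}$, the VanRaden (method 1) genomic
  relationship matrix $\mathbf{G} = \mathbf{WW}'/2\sum_j p_j(1-p_j)$
  (genotypes centred by twice the cohort allele frequency), the variance
  ratio $h^2 = \sigma^2_u/(\sigma^2_u+\sigma^2_e)$ is the heritability of a
  taxon's log$_{10}$ relative abundance.
* With $\mathbf{K} = \mathbf{M} = \mathbf{OO}'/n$, the microbial
  relationship matrix built from the column-standardized (mean 0, SD 1)
  log$_{10}$ abundances of the $n$ core taxa, the same ratio is the
  *microbiability* $m^2$ of a phenotype such as weight gain or plasma IgG1.

The restricted likelihood is profiled on the ratio
$h = \sigma^2_u/(\sigma^2_u+\sigma^2_e)$ through a single symmetric
eigendecomposition of $\mathbf{K}$ (the rotated model is diagonal, so each
likelihood evaluation is $O(np)$), and maximized by bounded scalar
optimization on $[10^{-6}, 1-10^{-6}]$ with explicit endpoint checks. A
likelihood whose range over a 101-point grid is below $10^{-6}$ — e.g. when
$\mathbf{K} = \mathbf{I}$ and only the total variance is identifiable — is
flagged flat and the ratio reported as `NA` rather than as an arbitrary
interior point.

```{r animal-model}
cfg <- sim_config(n_individuals = 120, n_snps = 600, n_taxa = 40,
                  taxon_h2 = 0.4, seed = 7)
herd <- simulate_herd(cfg)
dat <- herd$meta
dat$y <- herd$taxa$latent[, 1]
fit <- animal_model(y ~ age + sex, data = dat, K = herd$taxa$G)
summary(fit)
```

## The two-step genome scan

Re-estimating variance components for every SNP is wasteful and, in this
two-step scheme, deliberately avoided: step 1 fits the animal model once
without markers; step 2 tests each SNP by generalized least squares under
the *fixed* covariance $\mathbf{V} = \mathbf{G}\hat\sigma^2_u +
\mathbf{I}\hat\sigma^2_e$, reusing the step-1 eigendecomposition to whiten
the data once. The Wald statistic $\hat\beta^2_{SNP}/\mathrm{se}^2$ is
referred to $\chi^2_1$; the genomic-control factor
$\lambda = \mathrm{median}(\chi^2)/0.4549$ (clipped below at 1, so
deflation is never applied) rescales the statistics, and
Benjamini–Hochberg adjustment flags associations at FDR < 0.05. Missing
genotypes are mean-imputed to $2p$ at this stage only — never during QC —
and monomorphic SNPs are flagged untested rather than silently dropped.

## Preprocessing and diversity conventions

* **Core taxa**: nonzero abundance in at least 50% of samples, threshold
  inclusive (present in exactly half the samples counts as core).
* **Log transform**: taxa that are absent somewhere get half the detection
  limit (0.00004613) added to *all* of their values before log$_{10}$;
  taxa present everywhere are transformed unchanged. The implied detection
  limit, 0.00009226, is the generator's default flooring constant.
* **Rarefaction**: subsampling without replacement to a fixed depth
  (default 10,840 reads); shallower samples are dropped with a warning.
* **Shannon index**: base-2 logarithm by default (the QIIME 2 convention);
  the base is an argument.
* **Bray–Curtis, PCoA**: `vegan::vegdist` and classical scaling; negative
  eigenvalues are reported but never embedded.
* **PERMANOVA**: one fixed factor, raw label permutations,
  $p = (\#\{F_\pi \ge F\} + 1)/(n_\pi + 1)$ with ties counted toward the
  numerator (conservative). When the number of distinct label assignments
  is at most `n_perm` the test switches to exhaustive enumeration, where
  the identity assignment is included and the toy two-groups-of-three case
  with saturated separation gives exactly $p = 2/20$.

## Association scans and their classification

Breed-composition scans regress each core taxon's log abundance on the
continuous Brahman fraction, centred age, and a single male indicator.
Phenotype scans add the taxon's log abundance to the phenotype model (plus
initial body weight for weight gain), optionally controlling for the
polygenic animal effect via generalized least squares with the step-1
variance components and a t-test on $n - \mathrm{rank}(X) - 1$ degrees of
freedom. Associations are classified as significant ($p < 0.05$), tendency
($0.05 \le p < 0.10$), or ns. The printed cutoffs leave both boundaries
ambiguous ("$p<0.05$", "$0.05<p<0.10$"); the package assigns $p = 0.05$ to
tendency and $p = 0.10$ to ns, and unit-tests both boundaries. No
multiple-testing correction is applied in these regression scans — BH
belongs to the genomic scans, where thousands of markers are tested.

Co-occurrence networks keep taxon pairs with $|\rho_s| > 0.25$ *and*
BH-adjusted $p < 0.001$, both strict, with BH applied over the upper
triangle (each unordered pair tested once). All maximal-degree nodes are
reported as hubs; the singular "hub" is preserved only when unique.

## The synthetic herd generator

The generator emulates the features of the multibreed design that the
statistics consume, with one seed driving every draw (sub-stages derive
child seeds deterministically, so regenerating phenotypes never perturbs
the genotype stream):

* **Breed structure**: animals spread evenly over six breed groups;
  Brahman fraction uniform within each group's range (BG3 is the fixed
  62.5/37.5 cross, a degenerate range). The diallel pedigree itself is not
  simulated — no pipeline stage consumes a pedigree, only the marginal
  breed-fraction spectrum.
* **Genotypes**: per SNP, Angus and Brahman allele frequencies are drawn
  independently from U(0.05, 0.95); an animal with Brahman fraction $b$
  has allele frequency $p(b) = p_A + b(p_B - p_A)$ and genotype
  $\mathrm{Bin}(2, p(b))$. SNPs are independent: the generator plants no
  linkage disequilibrium, which keeps the GRM well conditioned and the
  recovery targets analyzable.
* **Taxa**: latent natural-log abundances
  $\alpha_t + s_t b + \gamma\,\mathrm{male} + g + \varepsilon$ with
  $g \sim N(0, \mathbf{G}\sigma^2_u)$ drawn through a Cholesky factor of
  $\mathbf{G} + 10^{-8}\mathbf{I}$ and the ratio set to the taxon's target
  heritability (unit total latent variance). Latent values are
  exponentiated, renormalized to compositions, and floored to exact zeros
  below the detection limit. Baseline log abundances $\alpha_t$ are
  N(0, 1.5) by default, giving realistically uneven compositions.
* **Phenotypes**: microbiome effects drawn with covariance
  $\mathbf{M}\sigma^2_m$ at the target microbiability; weight gain is
  anchored so that `WG_stage = BW_stage - BW_initial` holds exactly, with
  stage-typical weight and age scales (e.g. newborn weight N(30, 6) kg,
  preweaning age N(90, 10) days).

Effect sizes for sex and age on taxa are not reported for the original
herd; the defaults (0.2 latent-log units for sex, breed slope 0.5) are
documented choices of plausible magnitude, not calibrations, and are set
once in `sim_config()`.

**What passing recovery tests do and do not show.** The generator draws
independent SNPs, lognormal-compositional taxa, and Gaussian phenotypes.
Real 16S data add sequencing noise, zero inflation beyond a hard floor,
linkage disequilibrium, and repeated measures across stages; recovery of
planted parameters here validates the estimators' correctness under their
own model, not robustness to those violations.

## Numerical and design choices

* A shared slope planted on *every* taxon cancels under compositional
  renormalization — relative abundances are invariant to common scaling —
  so breed-effect recovery is exercised with heterogeneous slopes.
* QC filters run in the published order (call rate on individuals, then
  SNPs; heterozygosity/IBS outliers; MAF; HWE; Y chromosome), with per-SNP
  statistics recomputed after individual removal and strict `<` at every
  threshold (call rate exactly 0.95 passes). Each removal records its
  first-triggering reason, and kept + removed reconciles with the input.
* "Very high heterozygosity/IBS (FDR < 1%)" is operationalized as
  one-sided z-scores, normal p-values, and BH at 0.01 — the procedure
  inside the original QC tool is not documented, so the choice is recorded
  in the QC report metadata.
* The HWE test is the 1-df chi-square goodness of fit (no test is named in
  the source methods); monomorphic markers return $p = 1$.
* Genomic control is median-based; the original analysis used a
  regression-based variant whose internals are undocumented, so the
  deviation is deliberate and recorded in the scan metadata.
* Whether heritability models should include breed composition among the
  fixed effects is left open in the source description; both
  configurations are expressible through the `animal_model()` formula, and
  the pipeline default uses age and sex only.
* REML rather than ML throughout: it removes the fixed-effect bias in the
  variance components and matches standard animal-model practice.

## Problem sizes used in validation

Parameter recovery runs 100 replicates of $n = 200$ animals with 2,000
SNPs (heritability; planted ratios 0.46 and 0.21) or 100 taxa
(microbiability; planted fractions 0.106 and 0.100), reflecting the
approximate per-stage cohort sizes of the motivating design at a
desk-scale marker count. Unit tests use smaller cohorts (40–300 animals,
50–600 SNPs) chosen for tight Monte-Carlo behaviour of each property under
test. At $n = 200$ with an unstructured GRM the per-replicate sampling
spread of the REML ratio is large (SD ≈ 0.25), and because the ratio is
truncated at zero the replicate mean overestimates small planted values by
up to ~0.05 — visible for the 0.21 target, and an inherent property of
bounded REML at this design, not an implementation artifact (the optimum
matches a brute-force restricted-likelihood grid to 0.001).

## Known limitations

* Single variance component only: no joint genomic-plus-microbial model,
  no dominance or epistasis, no exact per-SNP REML.
* Stages are analyzed as independent cohorts; no longitudinal joint model.
* Phylogeny-aware diversity metrics (UniFrac, Faith PD) are out of scope —
  only tree-free metrics are reported by the pipeline.
* SNP-to-gene annotation is consumed as an input table, never computed.
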