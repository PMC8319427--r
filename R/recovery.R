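# Parameter-recovery simulation studies.
#
# These validate the REML estimator end-to-end: plant a known variance ratio
# in the generative model, re-estimate it from the simulated data, and repeat
# over independent replicates. Used by the test suite and the reproduction
# script; also handy for power/bias exploration at other design points.

#' Heritability recovery study
#'
#' For each replicate, simulates a cohort of unrelated animals (allele
#' frequencies uniform on `freq_range`, binomial genotypes, no linkage
#' disequilibrium), builds the VanRaden genomic relationship matrix, draws a
#' log-abundance trait from the animal model
#' `y = b0 + b_sex male + b_age age_c + u + e` with
#' `u ~ N(0, G sigma2_u)`, `e ~ N(0, I sigma2_e)` and
#' `sigma2_u / (sigma2_u + sigma2_e) = true_h2`, then re-estimates the ratio
#' by [reml_varcomp()] with age and sex as fixed effects.
#'
#' @param true_h2 generative variance ratio in `[0, 1)`.
#' @param n animals per replicate.
#' @param n_snps SNPs per replicate.
#' @param n_reps number of replicates.
#' @param seed master seed; replicate `i` uses `derive_seed(seed, i)`.
#' @param freq_range allele-frequency range.
#' @return Data frame with one row per replicate: `rep`, `estimate`.
#' @export
h2_recovery_study <- function(true_h2, n = 200, n_snps = 2000, n_reps = 100,
                              seed = 1, freq_range = c(0.05, 0.95)) {
  check_prob(true_h2, "true_h2", open_hi = TRUE)
  est <- vapply(seq_len(n_reps), function(i) {
    cfg <- sim_config(n_individuals = n, n_snps = n_snps, n_taxa = 1,
                      graded_freq = FALSE, allele_freq_range = freq_range,
                      seed = derive_seed(seed, i))
    pop <- simulate_population(cfg)
    G <- grm_vanraden(pop$genotypes)
    set.seed(derive_seed(cfg$seed, 2L))
    u <- drop(simulate_polygenic_values(G, true_h2))
    male <- as.numeric(pop$meta$sex == "M")
    age_c <- pop$meta$age - mean(pop$meta$age)
    y <- 1 + 0.3 * male + 0.01 * age_c + u + rnorm(n, sd = sqrt(1 - true_h2))
    reml_varcomp(y, cbind(1, age = age_c, sexM = male), G)$ratio
  }, numeric(1))
  data.frame(rep = seq_len(n_reps), estimate = est)
}

#' Microbiability recovery study
#'
#' For each replicate, simulates a cohort with compositional taxon
#' abundances, builds the microbial relationship matrix `M = OO'/n` from the
#' core-filtered, floor-adjusted, standardized log10 abundances, draws a
#' phenotype with microbiome-effect covariance `M sigma2_m` and residual
#' `I sigma2_e` such that `sigma2_m / (sigma2_m + sigma2_e) = true_m2`, and
#' re-estimates the ratio by [reml_varcomp()] with `K = M`.
#'
#' @param true_m2 generative microbiome-variance fraction in `[0, 1)`.
#' @param n samples per replicate.
#' @param n_taxa taxa per replicate.
#' @param n_reps number of replicates.
#' @param seed master seed; replicate `i` uses `derive_seed(seed, i)`.
#' @return Data frame with one row per replicate: `rep`, `estimate`.
#' @export
m2_recovery_study <- function(true_m2, n = 200, n_taxa = 100, n_reps = 100,
                              seed = 1) {
  check_prob(true_m2, "true_m2", open_hi = TRUE)
  est <- vapply(seq_len(n_reps), function(i) {
    cfg <- sim_config(n_individuals = n, n_snps = 200, n_taxa = n_taxa,
                      phenotype_m2 = true_m2, seed = derive_seed(seed, i))
    pop <- simulate_population(cfg)
    taxa <- simulate_taxa(pop, cfg)
    O <- log10_floor_transform(core_taxa_filter(taxa$abundance))
    M <- microbial_relationship(O)
    set.seed(derive_seed(cfg$seed, 3L))
    m <- drop(simulate_polygenic_values(M, true_m2))
    male <- as.numeric(pop$meta$sex == "M")
    age_c <- pop$meta$age - mean(pop$meta$age)
    y <- 10 + 2 * male + 0.05 * age_c + m + rnorm(n, sd = sqrt(1 - true_m2))
    reml_varcomp(y, cbind(1, age = age_c, sexM = male), M)$ratio
  }, numeric(1))
  data.frame(rep = seq_len(n_reps), estimate = est)
}
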