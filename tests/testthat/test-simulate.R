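test_that("simulation is deterministic given the same config and seed", {
  cfg <- sim_config(n_individuals = 40, n_snps = 50, n_taxa = 10, seed = 5)
  a <- simulate_herd(cfg)
  b <- simulate_herd(cfg)
  expect_identical(a$population$genotypes$calls, b$population$genotypes$calls)
  expect_identical(a$taxa$abundance, b$taxa$abundance)
  expect_identical(a$meta, b$meta)
  # and a different seed changes the draws
  c2 <- simulate_herd(sim_config(n_individuals = 40, n_snps = 50,
                                 n_taxa = 10, seed = 6))
  expect_false(identical(a$population$genotypes$calls,
                         c2$population$genotypes$calls))
})

test_that("brahman fractions respect the breed-group ranges", {
  pop <- simulate_population(sim_config(n_individuals = 300, n_snps = 10,
                                        n_taxa = 5, seed = 11))
  ranges <- rbind(c(0, 0.20), c(0.21, 0.40), c(0.375, 0.375),
                  c(0.41, 0.60), c(0.61, 0.80), c(0.81, 1.00))
  for (bg in 1:6) {
    bf <- pop$meta$brahman_fraction[pop$meta$breed_group == bg]
    expect_true(all(bf >= ranges[bg, 1] & bf <= ranges[bg, 2]),
                label = sprintf("BG%d fractions inside printed range", bg))
  }
  # BG6 specifically: 81-100% Brahman
  bf6 <- pop$meta$brahman_fraction[pop$meta$breed_group == 6]
  expect_true(length(bf6) > 0 && all(bf6 >= 0.81 & bf6 <= 1.00))
})

test_that("breed-graded SNP frequency increases across BG1..BG6", {
  # oracle: direct binomial sampling at the six BG-midpoint fractions
  set.seed(1)
  p_A <- 0.1; p_B <- 0.9
  mids <- c(0.10, 0.305, 0.375, 0.505, 0.705, 0.905)
  oracle <- vapply(mids, function(b)
    mean(rbinom(2000, 2, p_A + b * (p_B - p_A))) / 2, numeric(1))
  expect_true(all(diff(oracle) > 0))

  # generator: average the per-BG alt frequency over all SNPs with a strong
  # positive breed gradient; the group means must increase strictly
  pop <- simulate_population(sim_config(n_individuals = 600, n_snps = 300,
                                        n_taxa = 5, seed = 17))
  grad <- pop$truth$p_B - pop$truth$p_A
  snps <- which(grad > 0.5)
  expect_gt(length(snps), 10)
  freq_by_bg <- vapply(1:6, function(bg) {
    rows <- pop$meta$breed_group == bg
    mean(pop$genotypes$calls[rows, snps]) / 2
  }, numeric(1))
  expect_true(all(diff(freq_by_bg) > 0))
})

test_that("taxon abundances are compositional with a detection floor", {
  hs <- small_herd(seed = 23, n = 60, n_snps = 100, n_taxa = 25)
  ab <- hs$herd$taxa$abundance
  # pre-floor compositions sum to one exactly
  rel <- exp(hs$herd$taxa$latent)
  rel <- rel / rowSums(rel)
  expect_true(all(abs(rowSums(rel) - 1) < 1e-12))
  # post-floor sums live in (1 - n_taxa * floor, 1]
  floor <- hs$cfg$detection_floor
  expect_true(all(rowSums(ab) > 1 - ncol(ab) * floor))
  expect_true(all(rowSums(ab) <= 1 + 1e-12))
  # flooring is exact zeroing, never truncation to small positives
  expect_true(all(ab == 0 | ab >= floor))
})

test_that("realized genetic variance matches the planted heritability", {
  # oracle: the generator's genetic values are drawn from a Cholesky factor
  # of G, so their realized variance ratio should average the target
  hs <- small_herd(seed = 31, n = 150, n_snps = 400, n_taxa = 60,
                   taxon_h2 = 0.5)
  g <- hs$herd$taxa$genetic
  ratios <- apply(g, 2, var)  # total latent variance is 1 by construction
  expect_lt(abs(mean(ratios) - 0.5), 0.06)
})

test_that("null heritability and microbiability simulate as null", {
  hs <- small_herd(seed = 37, n = 100, n_snps = 200, n_taxa = 20,
                   taxon_h2 = 0, breed_slope = 0, phenotype_m2 = 0)
  herd <- hs$herd
  expect_true(all(herd$taxa$genetic == 0))
  # downstream REML on a few latent taxa averages near zero
  G <- herd$taxa$G
  X <- cbind(1, as.numeric(herd$meta$sex == "M"))
  est <- vapply(1:8, function(j)
    reml_varcomp(herd$taxa$latent[, j], X, G)$ratio, numeric(1))
  expect_lt(mean(est, na.rm = TRUE), 0.12)
  # microbiome effects for the phenotypes are identically zero
  expect_true(all(herd$phenotypes$truth$m_WG == 0))
})

test_that("weight gain equals final minus initial body weight", {
  hs <- small_herd(seed = 41, n = 40, n_snps = 60, n_taxa = 10)
  meta <- hs$herd$meta
  expect_equal(meta$WG_preweaning, meta$BW_preweaning - meta$BW_newborn,
               tolerance = 1e-12)
  # postweaning cohorts use the stage-matched weights
  hs2 <- small_herd(seed = 41, n = 40, n_snps = 60, n_taxa = 10,
                    stage = "postweaning")
  meta2 <- hs2$herd$meta
  expect_equal(meta2$WG_postweaning,
               meta2$BW_postweaning - meta2$BW_preweaning, tolerance = 1e-12)
})

test_that("invalid generator configurations error", {
  expect_error(sim_config(n_individuals = 0, seed = 1), "n_individuals")
  expect_error(sim_config(n_snps = 1, seed = 1), "n_snps")
  expect_error(sim_config(taxon_h2 = 1, seed = 1), "taxon_h2")
  expect_error(sim_config(phenotype_m2 = -0.1, seed = 1), "phenotype_m2")
  expect_error(sim_config(), "seed")
})
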