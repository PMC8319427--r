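test_that("association classes follow the printed cutoffs, boundaries included", {
  p <- c(0.04, 0.05, 0.07, 0.0999, 0.10, 0.5, NA)
  expect_equal(classify_association(p),
               c("significant", "tendency", "tendency", "tendency",
                 "ns", "ns", NA))
})

test_that("fit_ols matches the normal equations and flags collinearity", {
  # (x, y) = (0,1), (1,3), (2,5): slope 2, intercept 1
  fit <- suppressWarnings(fit_ols(c(1, 3, 5), cbind(x = 0:2)))
  expect_equal(unname(fit$coefficients[, "Estimate"]), c(1, 2),
               tolerance = 1e-12)
  # exactly linear response: R^2 = 1, vanishing residual sum of squares
  expect_equal(fit$r_squared, 1)
  expect_lt(sum(fit$residuals^2), 1e-16)
  # duplicated covariate -> error naming it
  X <- cbind(a = rnorm(10), b = rnorm(10))
  X <- cbind(X, a2 = X[, "a"])
  expect_error(fit_ols(rnorm(10), X), "a2")
  # under-determined fit
  expect_error(fit_ols(c(1, 2), cbind(x = c(1, 2), z = c(2, 1))),
               "observations")
  # closed-form oracle on random designs
  set.seed(7)
  for (i in 1:5) {
    Xr <- cbind(x1 = rnorm(25), x2 = rnorm(25))
    yr <- rnorm(25)
    fr <- fit_ols(yr, Xr)
    Xi <- cbind(1, Xr)
    bhat <- solve(crossprod(Xi), crossprod(Xi, yr))
    expect_equal(unname(fr$coefficients[, "Estimate"]), unname(drop(bhat)),
                 tolerance = 1e-8)
  }
})

test_that("breed association scan classifies every core taxon and recovers planted slopes", {
  # plant a strong slope on a minority of taxa: a slope shared by every
  # taxon would cancel under compositional renormalization, and if the
  # affected taxa dominate the composition the renormalization offset eats
  # most of their own signal too, so keep them sparse and the baseline even
  hs <- small_herd(seed = 101, n = 200, n_snps = 100, n_taxa = 40,
                   breed_slope = c(2.5, rep(0, 9)), taxon_h2 = 0.2,
                   intercept_sd = 0.5)
  logab <- log10_floor_transform(core_taxa_filter(hs$herd$taxa$abundance))
  scan <- breed_association_scan(logab, hs$herd$meta)
  expect_equal(nrow(scan), ncol(logab))
  expect_true(all(scan$class %in% c("significant", "tendency", "ns")))
  # classes partition the records
  expect_equal(sum(table(scan$class)), nrow(scan))
  # taxa carrying the positive slope get positive breed coefficients
  truth <- hs$herd$taxa$truth
  planted <- truth$taxon[truth$slope > 0]
  hit <- scan$beta[scan$taxon %in% planted]
  expect_gte(mean(hit > 0), 0.95)
})

test_that("planted negative breed slopes flip the coefficient sign", {
  hs <- small_herd(seed = 103, n = 200, n_snps = 100, n_taxa = 40,
                   breed_slope = c(-2.5, rep(0, 9)), taxon_h2 = 0.2,
                   intercept_sd = 0.5)
  logab <- log10_floor_transform(core_taxa_filter(hs$herd$taxa$abundance))
  scan <- breed_association_scan(logab, hs$herd$meta)
  truth <- hs$herd$taxa$truth
  planted <- truth$taxon[truth$slope < 0]
  hit <- scan$beta[scan$taxon %in% planted]
  expect_gte(mean(hit < 0), 0.95)
})

test_that("phenotype scan uses stage covariates and both model variants agree when sigma2_u = 0", {
  hs <- small_herd(seed = 107, n = 80, n_snps = 120, n_taxa = 20)
  herd <- hs$herd
  logab <- log10_floor_transform(core_taxa_filter(herd$taxa$abundance))
  # weight gain uses the newborn weight as initial body weight
  scan_wg <- phenotype_association_scan(herd$meta, logab, response = "WG")
  expect_equal(nrow(scan_wg), ncol(logab))
  scan_ig <- phenotype_association_scan(herd$meta, logab, response = "IgG1")
  expect_equal(nrow(scan_ig), ncol(logab))
  # with K = I the likelihood is flat, the animal effect pins to zero and
  # the mixed-model variant reproduces the plain regression
  n <- nrow(herd$meta)
  with_k <- phenotype_association_scan(herd$meta, logab, response = "IgG1",
                                       animal_effect = TRUE, K = diag(n))
  expect_equal(with_k$p, scan_ig$p, tolerance = 1e-10)
  # missing response errors
  meta2 <- herd$meta
  meta2$IgG1 <- NULL
  expect_error(phenotype_association_scan(meta2, logab, response = "IgG1"),
               "not available")
})

test_that("scan summary reproduces printed-fraction arithmetic", {
  scan <- data.frame(class = c(rep("significant", 3), rep("tendency", 2),
                               rep("ns", 5)))
  s <- scan_summary(scan)
  expect_equal(s$n_assoc, 5)
  expect_equal(s$percent, 50)
  expect_equal(scan_summary(n_assoc = 36, n_total = 69)$percent, 52.2)
})

test_that("genotype-breed Spearman correlation matches rank arithmetic", {
  calls <- cbind(s1 = c(0L, 1L, 2L), s2 = c(0L, 1L, 2L), s3 = c(1L, 1L, 1L))
  rownames(calls) <- c("a1", "a2", "a3")
  g <- genotype_matrix(calls, NULL)
  meta <- data.frame(animal = rownames(calls),
                     brahman_fraction = c(0, 0.5, 1),
                     breed_group = c(1, 3, 6))
  out <- genotype_breed_correlation(g, meta)
  cors <- out$correlations
  expect_equal(cors$rho[cors$snp == "s1"], 1)       # perfect monotone
  # d = (-2, 1, 1): rho = 1 - 6*6/(3*8) = -0.5
  meta2 <- meta
  meta2$brahman_fraction <- c(1.0, 0.2, 0.6)
  out2 <- genotype_breed_correlation(g, meta2, snps = "s2")
  expect_equal(out2$correlations$rho, -0.5)
  # monomorphic SNP flagged, not tested
  expect_true(cors$monomorphic[cors$snp == "s3"])
  expect_true(is.na(cors$rho[cors$snp == "s3"]))
  # per-breed-group MAF table has one column per group
  expect_equal(colnames(out$maf_by_group), c("BG1", "BG3", "BG6"))
  expect_error(genotype_breed_correlation(g, meta, snps = "nope"), "unknown")
})
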