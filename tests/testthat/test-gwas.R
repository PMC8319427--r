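test_that("with no polygenic variance the scan reduces to per-SNP OLS", {
  set.seed(21)
  n <- 40
  calls <- matrix(rbinom(n * 5, 2, 0.4), n, 5,
                  dimnames = list(NULL, paste0("s", 1:5)))
  x_age <- rnorm(n)
  X <- cbind(1, age = x_age)
  y <- 1 + 0.2 * x_age + rnorm(n)
  vc <- reml_varcomp(y, X, diag(n))  # flat -> lambda pinned to zero
  expect_true(vc$flat_likelihood)
  rec <- gwas_scan(vc, calls)
  for (j in 1:5) {
    ols <- summary(lm(y ~ x_age + calls[, j]))$coefficients
    expect_equal(rec$beta[j], ols[3, 1], tolerance = 1e-10)
    expect_equal(rec$se[j], ols[3, 2], tolerance = 1e-10)
    # identical Wald chi-square p-value computed from the same statistic
    expect_equal(rec$p_raw[j],
                 pchisq(ols[3, 3]^2, 1, lower.tail = FALSE),
                 tolerance = 1e-10)
  }
})

test_that("scan betas equal the closed-form GLS solution on a tiny instance", {
  hs <- small_herd(seed = 71, n = 30, n_snps = 40, n_taxa = 3)
  G <- hs$herd$taxa$G
  meta <- hs$herd$meta
  X <- cbind(1, sexM = as.numeric(meta$sex == "M"))
  y <- hs$herd$taxa$latent[, 1]
  vc <- reml_varcomp(y, X, G)
  rec <- gwas_scan(vc, hs$herd$population$genotypes)
  # oracle: explicit (Xf' V^-1 Xf)^-1 Xf' V^-1 y with the step-1 V
  lambda <- vc$ratio / (1 - vc$ratio)
  Vi <- solve(lambda * G + diag(30))
  for (j in c(1, 7, 23)) {
    snp <- hs$herd$population$genotypes$calls[, j]
    Xf <- cbind(X, snp)
    bhat <- solve(t(Xf) %*% Vi %*% Xf, t(Xf) %*% Vi %*% y)
    expect_equal(rec$beta[j], bhat[3], tolerance = 1e-8)
  }
})

test_that("the scan is calibrated on null SNPs and invariant to allele flips", {
  set.seed(31)
  n <- 150
  pop <- simulate_population(sim_config(n_individuals = n, n_snps = 500,
                                        n_taxa = 2, graded_freq = FALSE,
                                        seed = 41))
  G <- grm_vanraden(pop$genotypes)
  X <- cbind(1, sexM = as.numeric(pop$meta$sex == "M"))
  y <- rnorm(n)  # independent of every SNP
  vc <- reml_varcomp(y, X, G)
  rec <- gwas_scan(vc, pop$genotypes)
  frac <- mean(rec$p_raw[rec$tested] < 0.05)
  expect_gt(frac, 0.02)
  expect_lt(frac, 0.09)
  # allele-label flip: g -> 2 - g flips the sign, keeps the p-value
  flipped <- pop$genotypes
  flipped$calls <- 2L - flipped$calls
  rec2 <- gwas_scan(vc, flipped)
  expect_equal(rec2$beta, -rec$beta, tolerance = 1e-10)
  expect_equal(rec2$p_raw, rec$p_raw, tolerance = 1e-10)
})

test_that("monomorphic SNPs are flagged and not tested", {
  set.seed(51)
  n <- 30
  calls <- cbind(poly = rbinom(n, 2, 0.5), mono = rep(1L, n))
  y <- rnorm(n)
  vc <- reml_varcomp(y, matrix(1, n, 1), diag(n))
  rec <- gwas_scan(vc, calls)
  expect_false(rec$tested[2])
  expect_true(is.na(rec$p_raw[2]))
  expect_true(rec$tested[1])
})

test_that("genomic control rescales statistics by the median-based lambda", {
  # lambda exactly 1 leaves p-values untouched
  rec <- data.frame(chi2 = c(0.1, qchisq(0.5, 1), 2.3))
  rec$p_raw <- pchisq(rec$chi2, 1, lower.tail = FALSE)
  out <- suppressWarnings(genomic_control(rec))
  expect_equal(attr(out, "lambda_gc"), 1)
  expect_equal(out$p_gc, out$p_raw)
  # median 0.9098 -> lambda ~= 2, every statistic halved
  rec2 <- data.frame(chi2 = c(0.2, 0.9098, 3.1))
  out2 <- suppressWarnings(genomic_control(rec2))
  expect_equal(attr(out2, "lambda_gc"), 0.9098 / qchisq(0.5, 1))
  expect_equal(attr(out2, "lambda_gc"), 2, tolerance = 1e-3)
  expect_equal(out2$p_gc,
               pchisq(rec2$chi2 / attr(out2, "lambda_gc"), 1,
                      lower.tail = FALSE))
  # lambda is clipped below at one (no deflation)
  rec3 <- data.frame(chi2 = rep(0.1, 200))
  expect_equal(attr(genomic_control(rec3), "lambda_gc"), 1)
  expect_error(genomic_control(data.frame(chi2 = NA_real_)), "finite")
})

test_that("BH adjustment matches the hand-stepped oracle and is monotone", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_adjust(rep(0.2, 5)), rep(0.2, 5))
  expect_equal(bh_adjust(0.123), 0.123)
  expect_identical(bh_adjust(numeric(0)), numeric(0))
  expect_error(bh_adjust(c(0.5, 1.2)), "0, 1")
  set.seed(61)
  p <- runif(50)
  q <- bh_adjust(p)
  expect_true(all(q >= p))
  # sorting by p sorts by q (monotone transform)
  expect_true(all(diff(q[order(p)]) >= -1e-15))
})

test_that("covariate test reduces to ordinary regression without the animal effect", {
  set.seed(71)
  n <- 50
  X <- cbind(1, age = rnorm(n))
  x_cov <- rnorm(n)
  y <- 1 + 0.5 * X[, 2] + 0.3 * x_cov + rnorm(n)
  # plain multiple-regression path
  rec <- covariate_effect_test(y, X, x_cov, animal_effect = FALSE)
  ols <- summary(lm(y ~ X[, 2] + x_cov))$coefficients
  expect_equal(rec$statistic, ols[3, 3], tolerance = 1e-10)
  expect_equal(rec$p, ols[3, 4], tolerance = 1e-10)
  # animal-effect path with K = I (flat -> lambda 0) gives the same t
  rec2 <- covariate_effect_test(y, X, x_cov, K = diag(n),
                                animal_effect = TRUE)
  expect_equal(rec2$statistic, rec$statistic, tolerance = 1e-10)
  expect_error(covariate_effect_test(y, X, rep(1, n)), "constant")
})

test_that("covariate test has the right size and power direction", {
  hs <- small_herd(seed = 81, n = 60, n_snps = 150, n_taxa = 4)
  G <- hs$herd$taxa$G
  meta <- hs$herd$meta
  X <- cbind(1, sexM = as.numeric(meta$sex == "M"))
  set.seed(91)
  # size under the null over replicates
  rej <- replicate(400, {
    y <- rnorm(60)
    x <- rnorm(60)
    covariate_effect_test(y, X, x, K = G)$p < 0.05
  })
  expect_gt(mean(rej), 0.02)
  expect_lt(mean(rej), 0.09)
  # planted positive effect (signal-to-noise 1) has a positive sign
  signs <- replicate(40, {
    x <- rnorm(60)
    y <- x + rnorm(60)
    sign(covariate_effect_test(y, X, x, K = G)$beta)
  })
  expect_gte(mean(signs > 0), 0.95)
})
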