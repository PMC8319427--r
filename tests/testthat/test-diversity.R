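test_that("core-taxon filter is inclusive at the prevalence threshold", {
  tab <- cbind(half = c(1, 2, 0, 0),     # 2 of 4 samples -> kept
               rare = c(1, 0, 0, 0),     # 1 of 4 -> dropped
               always = c(1, 1, 1, 1))   # kept
  out <- core_taxa_filter(tab, 0.5)
  expect_equal(colnames(out), c("half", "always"))
  expect_error(core_taxa_filter(tab, 0), "min_prevalence")
  expect_error(core_taxa_filter(tab, 1.2), "min_prevalence")
})

test_that("floor-adjusted log10 transform follows the half-detection-limit rule", {
  tab <- cbind(with_zero = c(0, 0.01, 0.3),
               no_zero = c(0.01, 0.5, 1))
  out <- log10_floor_transform(tab)
  # zero in a zero-containing taxon -> log10 of the constant
  expect_equal(unname(out[1, 1]), log10(0.00004613))
  # the constant is added to ALL values of that taxon
  expect_equal(unname(out[2, 1]), log10(0.01 + 0.00004613))
  # taxa with no zeros are transformed unchanged
  expect_equal(unname(out[1, 2]), -2)
  expect_equal(unname(out[3, 2]), 0)
  expect_error(log10_floor_transform(cbind(c(-0.1, 1))), "non-negative")
})

test_that("floor-adjusted transform is strictly monotone within taxa", {
  set.seed(8)
  tab <- matrix(runif(200), 20, 10)
  tab[sample(length(tab), 30)] <- 0
  out <- log10_floor_transform(tab)
  for (j in seq_len(ncol(tab))) {
    ord <- order(tab[, j])
    expect_true(all(diff(out[ord, j]) >= 0))
    strict <- diff(tab[ord, j]) > 0
    expect_true(all(diff(out[ord, j])[strict] > 0))
  }
})

test_that("rarefaction subsamples to exact depth, deterministically", {
  set.seed(3)
  counts <- matrix(rpois(60, 40), 6, 10,
                   dimnames = list(paste0("s", 1:6), paste0("t", 1:10)))
  counts[1, ] <- c(100, rep(0, 9))  # total exactly 100
  depth <- 100
  w <- capture_warnings(
    r1 <- rarefy_counts(rbind(counts, low = rep(1, 10)), depth = depth,
                        seed = 4))
  expect_true(any(grepl("below depth", w)))
  expect_false("low" %in% rownames(r1))
  # (capture/suppress also absorbs vegan's small-count advisory on toy data)
  r2 <- suppressWarnings(rarefy_counts(counts, depth = depth, seed = 4))
  expect_true(all(rowSums(r2) == depth))
  # a sample whose total equals the depth is returned unchanged
  expect_equal(r2[1, ], counts[1, ])
  # determinism vs a differently seeded draw
  r3 <- suppressWarnings(rarefy_counts(counts, depth = depth, seed = 4))
  r4 <- suppressWarnings(rarefy_counts(counts, depth = depth, seed = 5))
  expect_identical(r2, r3)
  expect_false(identical(r2, r4))
})

test_that("Shannon index matches closed forms and the vegan oracle", {
  expect_equal(shannon_index(rep(1, 4)), 2)          # uniform on 4 = log2 4
  expect_equal(shannon_index(c(5, 0, 0)), 0)         # single taxon
  expect_equal(shannon_index(c(0.5, 0.25, 0.25)), 1.5)
  expect_error(shannon_index(c(0, 0)), "all zero")
  # cross-check against vegan (natural-log convention)
  set.seed(2)
  x <- runif(12)
  expect_equal(shannon_index(x, base = exp(1)),
               unname(vegan::diversity(rbind(x), index = "shannon")),
               tolerance = 1e-12)
  # maximal at the uniform composition
  h_unif <- shannon_index(rep(1, 8))
  for (i in 1:20) {
    p <- rep(1, 8) + runif(8, 0, 0.5)
    expect_lt(shannon_index(p), h_unif + 1e-12)
  }
})

test_that("Bray-Curtis matches hand values and metric properties", {
  expect_equal(bray_curtis(rbind(a = c(1, 2), b = c(1, 2)))["a", "b"], 0)
  expect_equal(bray_curtis(rbind(a = c(1, 0), b = c(0, 3)))["a", "b"], 1)
  expect_equal(bray_curtis(rbind(a = c(0.6, 0.4), b = c(0.2, 0.8)))["a", "b"],
               0.4)
  # hand-formula oracle + symmetry/range/identity on random tables
  set.seed(12)
  tab <- matrix(runif(80), 8, 10)
  D <- bray_curtis(tab)
  hand <- function(x, y) sum(abs(x - y)) / sum(x + y)
  for (i in 1:7) for (j in (i + 1):8) {
    expect_equal(D[i, j], hand(tab[i, ], tab[j, ]), tolerance = 1e-12)
  }
  expect_equal(D, t(D))
  expect_true(all(diag(D) == 0))
  expect_true(all(D >= 0 & D <= 1))
  expect_error(bray_curtis(rbind(c(0, 0), c(1, 1))), "all-zero")
})

test_that("PCoA embeds Euclidean distances exactly and reports eigenvalues", {
  # a 3-4-5 right triangle is exactly embeddable in two axes
  D <- matrix(0, 3, 3)
  D[1, 2] <- D[2, 1] <- 3
  D[1, 3] <- D[3, 1] <- 4
  D[2, 3] <- D[3, 2] <- 5
  res <- pcoa(D, k = 2)
  got <- as.matrix(dist(res$points))
  expect_lt(max(abs(got - D)), 1e-8)
  # eigenvalue sum equals the trace of the Gower-centered matrix
  n <- 3
  J <- diag(n) - matrix(1 / n, n, n)
  B <- -0.5 * J %*% D^2 %*% J
  expect_equal(sum(res$eig), sum(diag(B)), tolerance = 1e-8)
  # all-zero distances -> all-zero coordinates
  z <- pcoa(matrix(0, 4, 4), k = 2)
  expect_true(all(z$points == 0))
  # k beyond the positive spectrum is truncated with a warning
  expect_warning(tr <- pcoa(D, k = 3), "positive eigenvalues")
  expect_equal(tr$k, 2)
})

test_that("PERMANOVA reproduces the exhaustive toy case 2/20", {
  D <- matrix(1, 6, 6)
  D[1:3, 1:3] <- 0
  D[4:6, 4:6] <- 0
  diag(D) <- 0
  res <- permanova(D, rep(c("x", "y"), each = 3), n_perm = 999, seed = 1)
  expect_true(res$exhaustive)
  expect_equal(res$n_perm, 20)
  expect_equal(res$p, 2 / 20)
})

test_that("PERMANOVA pseudo-F matches vegan::adonis2", {
  set.seed(19)
  tab <- matrix(runif(24 * 12), 24, 12)
  grp <- rep(c("a", "b", "c"), each = 8)
  D <- bray_curtis(tab)
  mine <- permanova(D, grp, n_perm = 99, seed = 2)
  ref <- vegan::adonis2(as.dist(D) ~ grp, permutations = 99)
  expect_equal(mine$f, ref$F[1], tolerance = 1e-8)
  expect_equal(unname(mine$ss["between"]), ref$SumOfSqs[1], tolerance = 1e-8)
})

test_that("PERMANOVA p-values are calibrated under the null", {
  set.seed(77)
  n <- 16
  ps <- replicate(300, {
    tab <- matrix(runif(n * 6), n, 6)
    D <- bray_curtis(tab)
    permanova(D, rep(c("a", "b"), each = n / 2), n_perm = 199,
              seed = sample.int(1e6, 1))$p
  })
  ks <- suppressWarnings(ks.test(ps, "punif"))$statistic
  # 1% critical value for n = 300 plus slack for the 1/200 discreteness
  expect_lt(unname(ks), 1.63 / sqrt(300) + 0.01)
  # minimum attainable p with n_perm permutations is 1/(n_perm + 1)
  expect_true(all(ps >= 1 / 200))
})

test_that("PERMANOVA input validation", {
  D <- matrix(0.5, 4, 4); diag(D) <- 0
  expect_error(permanova(D, rep("a", 4)), "two groups")
  expect_error(permanova(D, c("a", "a", "a", "b")), "at least two samples")
})
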