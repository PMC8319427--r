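# Fixtures built in code.

# A deterministic 200 x 40 genotype matrix that passes every QC filter:
# each SNP has exact Hardy-Weinberg counts 50/100/50 at MAF 0.5 and full
# call rate. Individual rows are permutations so columns stay balanced.
clean_calls <- function(n = 200, p = 40) {
  base <- rep(c(0L, 1L, 1L, 2L), n / 4)
  calls <- vapply(seq_len(p), function(j) {
    # deterministic rotation keeps per-SNP counts exact
    base[(seq_len(n) + 3L * j) %% n + 1L]
  }, integer(n))
  dimnames(calls) <- list(sprintf("I%03d", seq_len(n)),
                          sprintf("S%03d", seq_len(p)))
  calls
}

# QC fixture with planted violations on top of a clean matrix:
# 3 low-call-rate SNPs, 2 SNPs with MAF 0.01, 1 SNP with MAF 0.04,
# 1 HWE-violating SNP, 4 Y-chromosome SNPs.
planted_qc_fixture <- function() {
  calls <- clean_calls()
  n <- nrow(calls)
  # low call rate: 20 missing calls (rate 0.90), spread over distinct rows
  for (k in 1:3) calls[((k - 1) * 20 + 1):(k * 20), k] <- NA_integer_
  # MAF 0.01: 4 het carriers among 200
  for (k in 4:5) calls[, k] <- c(rep(1L, 4), rep(0L, n - 4))
  # MAF 0.04: 16 het carriers
  calls[, 6] <- c(rep(1L, 16), rep(0L, n - 16))
  # HWE violation at MAF 0.5: no heterozygotes at all
  calls[, 7] <- rep(c(0L, 2L), n / 2)
  map <- data.frame(snp = colnames(calls),
                    chrom = as.character(rep_len(1:29, ncol(calls))),
                    pos = seq_len(ncol(calls)), stringsAsFactors = FALSE)
  map$chrom[8:11] <- "Y"
  list(g = genotype_matrix(calls, map),
       expect_removed = list(call_rate = colnames(calls)[1:3],
                             maf = colnames(calls)[4:6],
                             hwe = colnames(calls)[7],
                             y_chromosome = colnames(calls)[8:11]))
}

# Block relationship matrix K = ZZ' for a grouping factor: the animal model
# with this K is exactly a random-intercept model, giving lme4 as an oracle.
block_K <- function(groups) {
  Z <- outer(groups, unique(groups), `==`) + 0
  tcrossprod(Z)
}

# Direct-formula REML criterion on a grid of ratio values (independent of
# the package's eigendecomposition path).
grid_reml_ratio <- function(y, X, K, step = 0.001) {
  n <- length(y)
  p <- ncol(X)
  hs <- seq(step, 1 - step, by = step)
  ll <- vapply(hs, function(h) {
    V <- h * K + (1 - h) * diag(n)
    Vi <- solve(V)
    A <- crossprod(X, Vi) %*% X
    beta <- solve(A, crossprod(X, Vi) %*% y)
    r <- y - X %*% beta
    s2 <- drop(crossprod(r, Vi %*% r)) / (n - p)
    -0.5 * ((n - p) * log(s2) +
              as.numeric(determinant(V)$modulus) +
              as.numeric(determinant(A)$modulus))
  }, numeric(1))
  hs[which.max(ll)]
}

# Small simulated herd reused by several tests.
small_herd <- function(seed = 421, n = 80, n_snps = 300, n_taxa = 30,
                       taxon_h2 = 0.4, ...) {
  cfg <- sim_config(n_individuals = n, n_snps = n_snps, n_taxa = n_taxa,
                    taxon_h2 = taxon_h2, seed = seed, ...)
  list(cfg = cfg, herd = simulate_herd(cfg))
}
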