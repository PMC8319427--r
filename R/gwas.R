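# Two-step mixed-model genome scan.
#
# Step 1 estimates variance components once, without markers
# (reml_varcomp / animal_model). Step 2 tests every SNP by generalized least
# squares under the fixed covariance V = K sigma2_u + I sigma2_e; variance
# components are NOT re-estimated per SNP (the point of the two-step scheme).
# Observed test statistics are then deflated by the genomic-control factor
# lambda and adjusted for multiple testing by Benjamini-Hochberg.

#' Per-SNP generalized least squares under the step-1 covariance
#'
#' Rotates the data by the eigenvectors of `K` and whitens with the fitted
#' ratio, reducing each SNP test to an ordinary regression on the whitened
#' data (Frisch-Waugh residualization against the fixed effects). The Wald
#' statistic `beta^2 / se^2` is referred to chi-square with 1 df. Missing
#' genotypes are mean-imputed; monomorphic SNPs are flagged and not tested.
#'
#' @param fit a step-1 [animal_model()] fit (or `"varcomp"`) on the same
#'   animals, in the same order.
#' @param g a [genotype_matrix()] or plain dosage matrix (individuals x SNPs).
#' @return A data frame of class `"gwas_scan"`, one row per SNP: `snp`,
#'   `chrom`, `pos`, `beta`, `se`, `chi2`, `p_raw`, `tested`.
#' @export
gwas_scan <- function(fit, g) {
  vc <- if (inherits(fit, "animal_model")) fit$varcomp else fit
  stopifnot(inherits(vc, "varcomp"))
  calls <- if (inherits(g, "genotype_matrix")) g$calls else as.matrix(g)
  map <- if (inherits(g, "genotype_matrix")) g$map else
    data.frame(snp = colnames(calls) %||% sprintf("snp%d", seq_len(ncol(calls))),
               chrom = NA_character_, pos = NA_integer_)
  n <- vc$n
  stopifnot(nrow(calls) == n)

  # mean-impute missing dosages and flag monomorphic SNPs
  cm <- colMeans(calls, na.rm = TRUE)
  idx <- which(is.na(calls))
  if (length(idx)) calls[idx] <- cm[(idx - 1) %/% n + 1]
  mono <- apply(calls, 2L, function(x) var(x) == 0 || !is.finite(var(x)))

  lambda <- if (is.na(vc$ratio)) 0 else vc$ratio / (1 - vc$ratio)
  e <- vc$eig
  sw <- sqrt(1 / (lambda * e$values + 1))
  yw <- sw * e$yt
  Xw <- sw * e$Xt
  Gw <- sw * (e$Ut %*% calls)

  qx <- qr(Xw)
  yr <- qr.resid(qx, yw)
  Gr <- qr.resid(qx, Gw)
  den <- colSums(Gr^2)
  beta <- colSums(Gr * yr) / den
  df <- n - ncol(Xw) - 1L
  rss <- sum(yr^2) - beta^2 * den
  se <- sqrt(rss / df / den)
  chi2 <- (beta / se)^2
  beta[mono] <- se[mono] <- chi2[mono] <- NA_real_

  out <- data.frame(snp = map$snp, chrom = map$chrom, pos = map$pos,
                    beta = beta, se = se, chi2 = chi2,
                    p_raw = pchisq(chi2, df = 1, lower.tail = FALSE),
                    tested = !mono, row.names = NULL,
                    stringsAsFactors = FALSE)
  class(out) <- c("gwas_scan", "data.frame")
  out
}

#' Genomic control correction
#'
#' Estimates the inflation factor `lambda = median(chi2) / 0.4549` (the
#' median of a 1-df chi-square), clips it below at 1 (no deflation), and
#' rescales every statistic: `p_gc = P(chi2_1 >= chi2 / lambda)`.
#'
#' @param records a [gwas_scan()] result (or any data frame with a `chi2`
#'   column).
#' @return The records with `p_gc` added; the estimated factor is in
#'   `attr(., "lambda_gc")`. Warns when fewer than 100 SNPs were tested.
#' @export
genomic_control <- function(records) {
  chi2 <- records$chi2
  ok <- is.finite(chi2)
  if (!any(ok)) stop("no finite test statistics", call. = FALSE)
  if (sum(ok) < 100) warning("fewer than 100 tested SNPs; lambda is unstable")
  lambda <- max(1, median(chi2[ok]) / qchisq(0.5, df = 1))
  records$p_gc <- pchisq(chi2 / lambda, df = 1, lower.tail = FALSE)
  attr(records, "lambda_gc") <- lambda
  records
}

#' Benjamini-Hochberg adjustment
#'
#' Standard step-up BH with monotonicity enforcement (via
#' [stats::p.adjust()]); associations with `q < 0.05` are flagged
#' significant.
#'
#' @param p vector of p-values in `[0, 1]` (`NA` allowed for untested SNPs).
#' @return The q-values, same length/order as `p`.
#' @export
bh_adjust <- function(p) {
  if (!length(p)) return(numeric(0))
  if (any(p < 0 | p > 1, na.rm = TRUE))
    stop("p-values must lie in [0, 1]", call. = FALSE)
  p.adjust(p, method = "BH")
}

#' Run the full two-step scan for one response
#'
#' Convenience wrapper: step-1 REML, step-2 GLS per SNP, genomic control,
#' BH FDR.
#'
#' @param y response vector (e.g. log10 abundance of one core taxon).
#' @param X fixed-effect design matrix (intercept included).
#' @param K genomic relationship matrix.
#' @param g a [genotype_matrix()].
#' @param fdr significance threshold on the BH q-value.
#' @return A `"gwas_scan"` data frame with `p_gc`, `q_bh` and `significant`
#'   columns; `attr(., "lambda_gc")` and `attr(., "varcomp")` carry the
#'   correction factor and the step-1 fit.
#' @export
gwas_two_step <- function(y, X, K, g, fdr = 0.05) {
  vc <- reml_varcomp(y, X, K)
  rec <- gwas_scan(vc, g)
  rec <- genomic_control(rec)
  rec$q_bh <- bh_adjust(rec$p_gc)
  rec$significant <- !is.na(rec$q_bh) & rec$q_bh < fdr
  attr(rec, "varcomp") <- vc
  rec
}

#' Test one continuous covariate under the animal model
#'
#' Generalized least squares estimate of the covariate effect (e.g. a
#' taxon's log abundance on a phenotype) holding the step-1 variance
#' components fixed, i.e. controlling for the polygenic animal effect. The
#' significance of the coefficient is evaluated with a t-test on
#' `n - rank(X) - 1` degrees of freedom. With `animal_effect = FALSE` (or a
#' flat step-1 likelihood, where the ratio pins to zero) the test reduces to
#' the plain multiple-regression t-test.
#'
#' @param y response vector (phenotype).
#' @param X fixed-effect design matrix (intercept included).
#' @param x_cov the covariate of interest (per-animal numeric).
#' @param K relationship matrix (required when `animal_effect = TRUE`).
#' @param animal_effect include the random animal effect?
#' @return A one-row data frame: `beta`, `se`, `statistic`, `df`, `p`.
#' @export
covariate_effect_test <- function(y, X, x_cov, K = NULL,
                                  animal_effect = TRUE) {
  x_cov <- as.numeric(x_cov)
  if (var(x_cov) == 0) stop("covariate is constant", call. = FALSE)
  X <- as.matrix(X)
  n <- length(y)
  if (animal_effect) {
    stopifnot(!is.null(K))
    vc <- reml_varcomp(y, X, K)
    lambda <- if (is.na(vc$ratio)) 0 else vc$ratio / (1 - vc$ratio)
    e <- vc$eig
    sw <- sqrt(1 / (lambda * e$values + 1))
    yw <- sw * e$yt
    Xw <- sw * cbind(e$Xt, drop(e$Ut %*% x_cov))
  } else {
    yw <- as.numeric(y)
    Xw <- cbind(X, x_cov)
  }
  qx <- qr(Xw)
  if (qx$rank < ncol(Xw))
    stop("covariate is collinear with the fixed effects", call. = FALSE)
  cf <- qr.coef(qx, yw)
  res <- qr.resid(qx, yw)
  df <- n - ncol(Xw)
  sigma2 <- sum(res^2) / df
  XtXinv <- solve(crossprod(Xw))
  se <- sqrt(sigma2 * XtXinv[ncol(Xw), ncol(Xw)])
  beta <- cf[ncol(Xw)]
  tval <- beta / se
  data.frame(beta = beta, se = se, statistic = tval, df = df,
             p = 2 * pt(abs(tval), df = df, lower.tail = FALSE),
             row.names = NULL)
}
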