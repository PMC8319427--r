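# Single-component REML animal model.
#
# y = X beta + u + e with u ~ N(0, K sigma2_u), e ~ N(0, I sigma2_e) and one
# record per animal. The restricted likelihood is profiled on the variance
# ratio h = sigma2_u / (sigma2_u + sigma2_e) via a one-time eigendecomposition
# of K, then maximized by bounded scalar optimization with endpoint checks.
# With K the genomic relationship matrix the ratio is a heritability; with
# the microbial relationship matrix it is a microbiability.

# Restricted log-likelihood profiled on the ratio, in the rotated basis.
# yt = U'y, Xt = U'X, d = eigenvalues of K. Additive constants dropped.
reml_profile_ll <- function(h, yt, Xt, d, n, p) {
  lambda <- h / (1 - h)
  w <- 1 / (lambda * d + 1)
  A <- crossprod(Xt, w * Xt)
  b <- crossprod(Xt, w * yt)
  beta <- solve(A, b)
  r <- yt - Xt %*% beta
  rss <- sum(w * r^2)
  sigma2e <- rss / (n - p)
  -0.5 * ((n - p) * log(sigma2e) + sum(log(lambda * d + 1)) +
            as.numeric(determinant(A, logarithm = TRUE)$modulus))
}

check_full_rank <- function(X) {
  qx <- qr(X)
  if (qx$rank < ncol(X)) {
    aliased <- colnames(X)[qx$pivot[(qx$rank + 1):ncol(X)]]
    stop(sprintf("fixed-effect design is rank deficient; collinear column(s): %s",
                 paste(aliased, collapse = ", ")), call. = FALSE)
  }
  invisible(TRUE)
}

#' REML variance components for one random effect
#'
#' Estimates `sigma2_u`, `sigma2_e` and the ratio
#' `sigma2_u / (sigma2_u + sigma2_e)` by restricted maximum likelihood,
#' profiling the restricted likelihood on the ratio through a single
#' eigendecomposition of `K` and maximizing it on `[1e-6, 1 - 1e-6]` with
#' endpoint checks. A likelihood whose range over the evaluation grid is
#' below `1e-6` (e.g. `K = I`, where only the total variance is identifiable)
#' is flagged flat and the ratio reported as `NA`.
#'
#' @param y numeric response (one record per animal).
#' @param X fixed-effect design matrix (full column rank; include the
#'   intercept column).
#' @param K relationship matrix (genomic `G` or microbial `M`), aligned with
#'   `y`.
#' @param grid_n number of ratio grid points used for the flatness check and
#'   bracketing.
#' @return A list of class `"varcomp"`: `ratio`, `sigma2_u`, `sigma2_e`,
#'   `loglik` (restricted, up to an additive constant), `beta`, `se_beta`,
#'   `flat_likelihood`, `convergence`, plus the cached eigendecomposition
#'   (`eig`) reused by [gwas_scan()].
#' @export
reml_varcomp <- function(y, X, K, grid_n = 101L) {
  y <- as.numeric(y)
  X <- as.matrix(X)
  K <- as.matrix(K)
  n <- length(y)
  stopifnot(nrow(X) == n, nrow(K) == n, ncol(K) == n)
  if (anyNA(y) || anyNA(X)) stop("missing values in y or X", call. = FALSE)
  check_full_rank(X)
  p <- ncol(X)
  if (n <= p + 1L) stop("too few records for REML", call. = FALSE)

  eg <- eigen(K, symmetric = TRUE)
  d <- pmax(eg$values, 0)
  Ut <- t(eg$vectors)
  yt <- drop(Ut %*% y)
  Xt <- Ut %*% X

  lo <- 1e-6
  hi <- 1 - 1e-6
  grid <- seq(lo, hi, length.out = grid_n)
  ll_grid <- vapply(grid, reml_profile_ll, numeric(1),
                    yt = yt, Xt = Xt, d = d, n = n, p = p)
  flat <- (max(ll_grid) - min(ll_grid)) < 1e-6

  finish <- function(h, ll, flat) {
    if (flat || is.na(h)) {
      lambda <- 0
      w <- rep(1, n)
    } else {
      lambda <- h / (1 - h)
      w <- 1 / (lambda * d + 1)
    }
    A <- crossprod(Xt, w * Xt)
    beta <- drop(solve(A, crossprod(Xt, w * yt)))
    r <- yt - drop(Xt %*% beta)
    sigma2e <- sum(w * r^2) / (n - p)
    names(beta) <- colnames(X)
    se <- sqrt(diag(solve(A)) * sigma2e)
    structure(list(ratio = if (flat) NA_real_ else h,
                   sigma2_u = if (flat) NA_real_ else lambda * sigma2e,
                   sigma2_e = sigma2e,
                   loglik = ll,
                   beta = beta, se_beta = se,
                   flat_likelihood = flat, convergence = TRUE,
                   n = n, rank_x = p,
                   eig = list(values = d, Ut = Ut, yt = yt, Xt = Xt),
                   kind = attr(K, "kind") %||% "K"),
              class = "varcomp")
  }

  if (flat) return(finish(NA_real_, ll_grid[(grid_n + 1L) %/% 2L], TRUE))

  i_best <- which.max(ll_grid)
  bracket <- c(grid[max(1L, i_best - 1L)], grid[min(grid_n, i_best + 1L)])
  opt <- optimize(reml_profile_ll, interval = bracket, maximum = TRUE,
                  tol = 1e-9, yt = yt, Xt = Xt, d = d, n = n, p = p)
  # endpoint checks: the optimum may sit at the boundary of the ratio range
  cand_h <- c(opt$maximum, lo, hi, grid[i_best])
  cand_ll <- c(opt$objective, ll_grid[1], ll_grid[grid_n], ll_grid[i_best])
  j <- which.max(cand_ll)
  finish(cand_h[j], cand_ll[j], FALSE)
}

#' @export
print.varcomp <- function(x, ...) {
  cat(sprintf("REML variance components (%s): sigma2_u = %.4g, sigma2_e = %.4g, ratio = %s%s\n",
              x$kind, x$sigma2_u, x$sigma2_e,
              if (is.na(x$ratio)) "NA" else sprintf("%.4f", x$ratio),
              if (x$flat_likelihood) " [flat likelihood]" else ""))
  invisible(x)
}

#' Fit a single-random-effect animal model
#'
#' Formula interface over [reml_varcomp()]. The random animal effect has
#' covariance `K * sigma2_u`; the residual is iid. The estimated variance
#' ratio is a heritability when `K` is a genomic relationship matrix
#' ([grm_vanraden()]) and a microbiability when `K` is a microbial
#' relationship matrix ([microbial_relationship()]).
#'
#' @param formula model formula for the response and fixed effects, e.g.
#'   `log_abundance ~ age + sex`.
#' @param data data frame with one row per animal, aligned with `K` (or
#'   carrying an `animal` column matching `rownames(K)`).
#' @param K relationship matrix.
#' @param ... passed to [reml_varcomp()].
#' @return An object of class `"animal_model"` with `print()`, `summary()`,
#'   `coef()`, `fitted()`, `residuals()` and `logLik()` methods. The variance
#'   ratio is available as `heritability(fit)` / `microbiability(fit)`.
#' @examples
#' cfg <- sim_config(n_individuals = 60, n_snps = 300, n_taxa = 20,
#'                   taxon_h2 = 0.4, seed = 42)
#' herd <- simulate_herd(cfg)
#' dat <- herd$meta
#' dat$y <- herd$taxa$latent[, 1]
#' fit <- animal_model(y ~ age + sex, data = dat, K = herd$taxa$G)
#' heritability(fit)
#' @export
animal_model <- function(formula, data, K, ...) {
  kind <- attr(K, "kind")
  K <- as.matrix(K)
  if (!is.null(rownames(K)) && "animal" %in% names(data) &&
      all(data$animal %in% rownames(K))) {
    K <- K[data$animal, data$animal, drop = FALSE]
  }
  attr(K, "kind") <- kind
  mf <- model.frame(formula, data)
  y <- model.response(mf)
  X <- model.matrix(attr(mf, "terms"), mf)
  vc <- reml_varcomp(y, X, K, ...)
  structure(list(call = match.call(), formula = formula, varcomp = vc,
                 y = y, X = X, kind = attr(K, "kind") %||% "K"),
            class = "animal_model")
}

#' Extract the estimated variance ratio
#'
#' @param fit an [animal_model()] fit or a `"varcomp"` object.
#' @return The REML estimate of `sigma2_u / (sigma2_u + sigma2_e)` (`NA` if
#'   the restricted likelihood was flat).
#' @export
heritability <- function(fit) {
  if (inherits(fit, "animal_model")) fit$varcomp$ratio else fit$ratio
}

#' @rdname heritability
#' @export
microbiability <- heritability

#' @export
print.animal_model <- function(x, ...) {
  label <- switch(x$kind, G = "heritability (h2)", M = "microbiability (m2)",
                  "variance ratio")
  cat("Animal model:", deparse(x$formula), "\n")
  vc <- x$varcomp
  cat(sprintf("  sigma2_u = %.4g, sigma2_e = %.4g\n  %s = %s%s\n",
              vc$sigma2_u, vc$sigma2_e, label,
              if (is.na(vc$ratio)) "NA" else sprintf("%.4f", vc$ratio),
              if (vc$flat_likelihood) " [flat likelihood]" else ""))
  invisible(x)
}

#' @export
summary.animal_model <- function(object, ...) {
  vc <- object$varcomp
  z <- vc$beta / vc$se_beta
  coefs <- cbind(Estimate = vc$beta, `Std. Error` = vc$se_beta,
                 `z value` = z,
                 `Pr(>|z|)` = 2 * pnorm(abs(z), lower.tail = FALSE))
  out <- list(call = object$call, coefficients = coefs,
              sigma2_u = vc$sigma2_u, sigma2_e = vc$sigma2_e,
              ratio = vc$ratio, kind = object$kind,
              flat_likelihood = vc$flat_likelihood, n = vc$n)
  class(out) <- "summary.animal_model"
  out
}

#' @export
print.summary.animal_model <- function(x, ...) {
  cat("Call: "); print(x$call)
  cat("\nFixed effects (generalized least squares at the REML optimum):\n")
  stats::printCoefmat(x$coefficients, P.values = TRUE, has.Pvalue = TRUE)
  cat(sprintf("\nVariance components: sigma2_u = %.4g, sigma2_e = %.4g\n",
              x$sigma2_u, x$sigma2_e))
  label <- switch(x$kind, G = "Heritability", M = "Microbiability",
                  "Variance ratio")
  cat(sprintf("%s: %s  (n = %d)%s\n", label,
              if (is.na(x$ratio)) "NA" else sprintf("%.4f", x$ratio), x$n,
              if (x$flat_likelihood) "  [flat likelihood]" else ""))
  invisible(x)
}

#' @export
coef.animal_model <- function(object, ...) object$varcomp$beta

#' @export
logLik.animal_model <- function(object, ...) {
  structure(object$varcomp$loglik, df = length(object$varcomp$beta) + 2L,
            class = "logLik")
}

#' @export
fitted.animal_model <- function(object, ...) {
  # fixed part + BLUP of the animal effect
  vc <- object$varcomp
  xb <- drop(object$X %*% vc$beta)
  if (is.na(vc$ratio)) return(xb)
  lambda <- vc$ratio / (1 - vc$ratio)
  e <- vc$eig
  w <- 1 / (lambda * e$values + 1)
  rt <- e$yt - drop(e$Xt %*% vc$beta)
  # u_hat = sigma2_u K V^{-1} r = U diag(lambda d w) U' r in the rotated basis
  u <- drop(t(e$Ut) %*% (lambda * e$values * w * rt))
  xb + u
}

#' @export
residuals.animal_model <- function(object, ...) {
  object$y - fitted(object)
}
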