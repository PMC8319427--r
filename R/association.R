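# Regression association scans: breed composition vs taxa/phenotypes,
# taxa vs weight gain / IgG1, and genotype-vs-breed-composition Spearman
# correlation. Associations are classified as significant (p < 0.05),
# tendency (0.05 <= p < 0.10) or ns; no multiple-testing correction is
# applied in these scans (BH belongs to the genomic scans).

#' Classify an association p-value
#'
#' `p < 0.05` is significant and `0.05 < p < 0.10` a tendency. The printed
#' intervals leave both boundaries ambiguous; here `p = 0.05` falls in
#' `tendency` and `p = 0.10` in `ns`.
#'
#' @param p vector of p-values.
#' @return Character vector in `{"significant", "tendency", "ns"}`.
#' @export
classify_association <- function(p) {
  ifelse(is.na(p), NA_character_,
         ifelse(p < 0.05, "significant",
                ifelse(p < 0.10, "tendency", "ns")))
}

#' Ordinary least-squares fit with per-coefficient t-tests
#'
#' Thin wrapper around [stats::lm()] that fails loudly on collinear or
#' under-determined designs, naming the offending columns.
#'
#' @param y numeric response.
#' @param X design matrix **without** an intercept column (one is added).
#' @return A list: `coefficients` (matrix with estimate/se/t/p),
#'   `r_squared`, `sigma2`, `df_residual`, `fitted`, `residuals`.
#' @export
fit_ols <- function(y, X) {
  X <- as.matrix(X)
  n <- length(y)
  stopifnot(nrow(X) == n)
  if (n <= ncol(X) + 1L)
    stop("more coefficients than observations", call. = FALSE)
  Xi <- cbind(`(Intercept)` = 1, X)
  check_full_rank(Xi)
  fit <- lm(y ~ X)
  sm <- summary(fit)
  coefs <- sm$coefficients
  rownames(coefs) <- colnames(Xi)
  list(coefficients = coefs, r_squared = sm$r.squared,
       sigma2 = sm$sigma^2, df_residual = fit$df.residual,
       fitted = fitted(fit), residuals = residuals(fit))
}

# Standard covariate block: centered age + male indicator (+ extras).
assoc_design <- function(meta, extra = NULL) {
  X <- cbind(age = meta$age - mean(meta$age),
             sexM = as.numeric(meta$sex == "M"))
  if (!is.null(extra)) X <- cbind(X, extra)
  X
}

#' Breed-composition association scan over core taxa
#'
#' Per taxon, fits `log10 abundance ~ brahman_fraction + age + sex` by
#' ordinary least squares and classifies the breed-composition coefficient's
#' p-value. Input taxa should already be core-filtered and log-transformed.
#'
#' @param logabund samples x taxa matrix of log10 abundances.
#' @param meta metadata with `brahman_fraction`, `age`, `sex`, aligned rows.
#' @return Data frame, one row per taxon: `taxon`, `beta`, `se`, `p`,
#'   `class`.
#' @export
breed_association_scan <- function(logabund, meta) {
  logabund <- as.matrix(logabund)
  stopifnot(nrow(logabund) == nrow(meta))
  X <- assoc_design(meta, cbind(brahman = meta$brahman_fraction))
  out <- lapply(colnames(logabund), function(tx) {
    fit <- fit_ols(logabund[, tx], X)
    cf <- fit$coefficients["brahman", ]
    data.frame(taxon = tx, beta = cf[1], se = cf[2], p = cf[4],
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  out$class <- classify_association(out$p)
  rownames(out) <- NULL
  out
}

#' Phenotype association scan over core taxa
#'
#' Per taxon, regresses a phenotype (weight gain or IgG1) on age, sex, breed
#' composition and the taxon's log abundance; weight-gain models additionally
#' include the initial body weight. With `animal_effect = TRUE` the taxon
#' coefficient is tested under the animal model
#' ([covariate_effect_test()] with the genomic relationship matrix),
#' controlling for population structure; otherwise a plain multiple
#' regression is used.
#'
#' @param meta metadata with the response column, `brahman_fraction`, `age`,
#'   `sex` and (for WG) the initial body-weight column.
#' @param logabund samples x taxa matrix of log10 abundances (aligned rows).
#' @param response `"WG"` or `"IgG1"` (a column of `meta`).
#' @param animal_effect control for the polygenic animal effect?
#' @param K genomic relationship matrix (required if `animal_effect`).
#' @param initial_bw name of the initial body-weight column used for WG
#'   models; by default the first `BW_*` column present.
#' @return Data frame, one row per taxon: `taxon`, `beta`, `se`,
#'   `statistic`, `p`, `class`.
#' @export
phenotype_association_scan <- function(meta, logabund,
                                       response = c("WG", "IgG1"),
                                       animal_effect = FALSE, K = NULL,
                                       initial_bw = NULL) {
  response <- match.arg(response)
  if (!response %in% names(meta) || all(is.na(meta[[response]])))
    stop(sprintf("response '%s' is not available for this stage", response),
         call. = FALSE)
  logabund <- as.matrix(logabund)
  stopifnot(nrow(logabund) == nrow(meta))
  y <- meta[[response]]

  extra <- cbind(brahman = meta$brahman_fraction)
  if (response == "WG") {
    if (is.null(initial_bw)) {
      bw_cols <- grep("^BW_", names(meta), value = TRUE)
      if (!length(bw_cols))
        stop("weight-gain models need an initial body-weight column",
             call. = FALSE)
      initial_bw <- bw_cols[1]
    }
    extra <- cbind(extra, initial_bw = meta[[initial_bw]])
  }
  X <- assoc_design(meta, extra)

  out <- lapply(colnames(logabund), function(tx) {
    x <- logabund[, tx]
    rec <- covariate_effect_test(y, cbind(1, X), x, K = K,
                                 animal_effect = animal_effect)
    data.frame(taxon = tx, beta = rec$beta, se = rec$se,
               statistic = rec$statistic, p = rec$p,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  out$class <- classify_association(out$p)
  rownames(out) <- NULL
  out
}

#' Summarize an association scan
#'
#' Counts taxa whose association is significant or a tendency and reports
#' the percentage (one decimal, the convention used for scan summaries such
#' as "36 (52.2%) out of 69").
#'
#' @param scan a scan data frame with a `class` column, or the counts
#'   directly via `n_assoc` and `n_total`.
#' @param n_assoc,n_total optional explicit counts overriding `scan`.
#' @return A one-row data frame: `n_total`, `n_assoc`, `percent`.
#' @export
scan_summary <- function(scan = NULL, n_assoc = NULL, n_total = NULL) {
  if (is.null(n_assoc) || is.null(n_total)) {
    stopifnot(!is.null(scan), "class" %in% names(scan))
    n_total <- nrow(scan)
    n_assoc <- sum(scan$class %in% c("significant", "tendency"))
  }
  data.frame(n_total = n_total, n_assoc = n_assoc,
             percent = round(100 * n_assoc / n_total, 1))
}

# Spearman rank correlation (average ranks for ties) with two-sided p from
# the t approximation; returns c(rho, p). NA on degenerate input.
spearman_cor <- function(x, y) {
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3L || var(x) == 0 || var(y) == 0)
    return(c(rho = NA_real_, p = NA_real_))
  rho <- cor(rank(x), rank(y))
  if (abs(rho) >= 1) return(c(rho = rho, p = 0))
  tval <- rho * sqrt((n - 2) / (1 - rho^2))
  c(rho = rho, p = 2 * pt(abs(tval), df = n - 2, lower.tail = FALSE))
}

#' Genotype vs breed-composition Spearman correlation and per-group MAF
#'
#' For each selected SNP (e.g. markers in short-chain fatty-acid receptor
#' genes), computes the Spearman rank correlation between the 0/1/2 genotype
#' and the Brahman fraction (average ranks for ties, two-sided p,
#' significance at p < 0.05), and tabulates the minor allele frequency
#' within each breed group.
#'
#' @param g a [genotype_matrix()].
#' @param meta metadata with `brahman_fraction` and `breed_group`, aligned
#'   with the genotype rows.
#' @param snps SNP ids to test (default: all).
#' @return A list: `correlations` (data frame `snp`, `rho`, `p`,
#'   `significant`, `monomorphic`) and `maf_by_group` (SNP x breed-group
#'   matrix of MAFs).
#' @export
genotype_breed_correlation <- function(g, meta, snps = NULL) {
  stopifnot(inherits(g, "genotype_matrix"),
            nrow(g$calls) == nrow(meta))
  snps <- snps %||% colnames(g$calls)
  missing_snps <- setdiff(snps, colnames(g$calls))
  if (length(missing_snps))
    stop("unknown SNP id(s): ", paste(missing_snps, collapse = ", "),
         call. = FALSE)
  calls <- g$calls[, snps, drop = FALSE]
  bf <- meta$brahman_fraction

  cors <- t(apply(calls, 2L, spearman_cor, y = bf))
  mono <- apply(calls, 2L, function(x) {
    v <- var(x, na.rm = TRUE); !is.finite(v) || v == 0
  })
  correlations <- data.frame(snp = snps, rho = cors[, "rho"], p = cors[, "p"],
                             significant = !is.na(cors[, "p"]) &
                               cors[, "p"] < 0.05,
                             monomorphic = mono, row.names = NULL,
                             stringsAsFactors = FALSE)

  groups <- sort(unique(meta$breed_group))
  maf <- sapply(groups, function(bg) {
    sub <- calls[meta$breed_group == bg, , drop = FALSE]
    nm <- colSums(!is.na(sub))
    f <- ifelse(nm > 0, colSums(sub, na.rm = TRUE) / (2 * nm), NA_real_)
    pmin(f, 1 - f)
  })
  maf <- matrix(maf, nrow = length(snps),
                dimnames = list(snps, paste0("BG", groups)))
  list(correlations = correlations, maf_by_group = maf)
}
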