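# Genotype quality control.
#
# Replicates the marker/individual filter chain used on the herd's chip data:
# (1) call rate < 0.95 (individuals, then SNPs); (2) individuals with very
# high autosomal heterozygosity or very high identity-by-state (both at
# FDR < 1%); (3) SNPs with MAF < 0.05; (4) SNPs deviating from Hardy-Weinberg
# equilibrium (p < 0.05); (5) Y-chromosome SNPs. All comparisons are strict
# (`<`), statistics are recomputed after individual removal, and every
# removal carries its first-triggering reason.

#' Hardy-Weinberg equilibrium chi-square test
#'
#' One-degree-of-freedom goodness-of-fit test of observed genotype counts
#' against expectations at the observed allele frequency. Monomorphic input
#' returns p = 1 (nothing segregates, nothing to test). Vectorized.
#'
#' @param n_AA,n_Aa,n_aa genotype counts (non-negative; recycled).
#' @return A list with `chi2` and `p`.
#' @export
hwe_test <- function(n_AA, n_Aa, n_aa) {
  if (any(c(n_AA, n_Aa, n_aa) < 0, na.rm = TRUE))
    stop("genotype counts must be non-negative", call. = FALSE)
  n <- n_AA + n_Aa + n_aa
  if (any(n <= 0, na.rm = TRUE))
    stop("total genotype count must be positive", call. = FALSE)
  p <- (2 * n_AA + n_Aa) / (2 * n)
  q <- 1 - p
  e_AA <- n * p^2
  e_Aa <- 2 * n * p * q
  e_aa <- n * q^2
  chi2 <- ifelse(p == 0 | p == 1, 0,
                 (n_AA - e_AA)^2 / e_AA + (n_Aa - e_Aa)^2 / e_Aa +
                   (n_aa - e_aa)^2 / e_aa)
  list(chi2 = chi2, p = pchisq(chi2, df = 1, lower.tail = FALSE))
}

#' Per-SNP summary: call rate, allele frequency, MAF, HWE p-value
#'
#' Missing genotypes are excluded from all frequency computations (never
#' imputed at the QC stage). An all-missing SNP has call rate 0 and `NA`
#' frequencies.
#'
#' @param g a [genotype_matrix()] or plain 0/1/2/NA matrix.
#' @return Data frame with one row per SNP: `snp`, `chrom`, `pos`,
#'   `call_rate`, `alt_freq`, `maf`, `hwe_p`.
#' @export
snp_summary <- function(g) {
  calls <- if (inherits(g, "genotype_matrix")) g$calls else as.matrix(g)
  map <- if (inherits(g, "genotype_matrix")) g$map else
    data.frame(snp = colnames(calls) %||% sprintf("snp%d", seq_len(ncol(calls))),
               chrom = NA_character_, pos = NA_integer_)
  if (nrow(calls) < 1L) stop("need at least one individual", call. = FALSE)
  nm <- colSums(!is.na(calls))
  call_rate <- nm / nrow(calls)
  alt_freq <- ifelse(nm > 0, colSums(calls, na.rm = TRUE) / (2 * nm), NA_real_)
  maf <- pmin(alt_freq, 1 - alt_freq)
  n2 <- colSums(calls == 2, na.rm = TRUE)
  n1 <- colSums(calls == 1, na.rm = TRUE)
  n0 <- colSums(calls == 0, na.rm = TRUE)
  hwe_p <- rep(NA_real_, ncol(calls))
  ok <- nm > 0
  if (any(ok)) hwe_p[ok] <- hwe_test(n2[ok], n1[ok], n0[ok])$p
  data.frame(snp = map$snp, chrom = map$chrom, pos = map$pos,
             call_rate = call_rate, alt_freq = alt_freq, maf = maf,
             hwe_p = hwe_p, row.names = NULL, stringsAsFactors = FALSE)
}

# Pairwise identity-by-state: mean over shared non-missing SNPs of
# 1 - |g_i - g_j| / 2, computed with indicator cross-products.
ibs_matrix <- function(calls) {
  if (nrow(calls) < 2L) stop("IBS needs at least two individuals", call. = FALSE)
  A0 <- (!is.na(calls) & calls == 0) + 0
  A1 <- (!is.na(calls) & calls == 1) + 0
  A2 <- (!is.na(calls) & calls == 2) + 0
  NN <- tcrossprod(A0 + A1 + A2)               # shared non-missing count
  absdiff <- tcrossprod(A0, A1) + tcrossprod(A1, A0) +
    tcrossprod(A1, A2) + tcrossprod(A2, A1) +
    2 * (tcrossprod(A0, A2) + tcrossprod(A2, A0))
  if (any(NN[upper.tri(NN)] == 0))
    warning("some pairs share no non-missing SNPs; their IBS is NA")
  ibs <- 1 - absdiff / (2 * NN)
  ibs[NN == 0] <- NA_real_
  dimnames(ibs) <- list(rownames(calls), rownames(calls))
  ibs
}

#' Per-individual summary: call rate, autosomal heterozygosity, max IBS
#'
#' Heterozygosity is the fraction of non-missing autosomal calls equal to 1;
#' max IBS is the largest pairwise identity-by-state against any other
#' individual.
#'
#' @param g a [genotype_matrix()].
#' @return Data frame with `animal`, `call_rate`, `heterozygosity`, `max_ibs`.
#' @export
sample_summary <- function(g) {
  stopifnot(inherits(g, "genotype_matrix"))
  calls <- g$calls
  autosomal <- g$map$chrom %in% as.character(1:29)
  call_rate <- rowMeans(!is.na(calls))
  ac <- calls[, autosomal, drop = FALSE]
  het <- rowSums(ac == 1, na.rm = TRUE) / pmax(1L, rowSums(!is.na(ac)))
  max_ibs <- if (nrow(calls) >= 2L) {
    ibs <- ibs_matrix(calls)
    diag(ibs) <- NA
    apply(ibs, 1L, max, na.rm = TRUE)
  } else rep(NA_real_, nrow(calls))
  data.frame(animal = rownames(calls), call_rate = call_rate,
             heterozygosity = het, max_ibs = max_ibs,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Default QC thresholds
#'
#' The defaults are the filter chain's published values: call rate < 0.95
#' (both axes), MAF < 0.05, HWE p < 0.05, heterozygosity/IBS outliers at
#' FDR < 1%, Y-chromosome SNPs removed. All comparisons are strict.
#'
#' @param call_rate,maf,hwe_p,outlier_fdr filter thresholds.
#' @param drop_y remove Y-chromosome SNPs?
#' @return A named list of thresholds.
#' @export
qc_thresholds <- function(call_rate = 0.95, maf = 0.05, hwe_p = 0.05,
                          outlier_fdr = 0.01, drop_y = TRUE) {
  list(call_rate = call_rate, maf = maf, hwe_p = hwe_p,
       outlier_fdr = outlier_fdr, drop_y = isTRUE(drop_y))
}

# Upper-tail z-score outliers at BH FDR < threshold. Returns logical vector.
upper_outliers <- function(x, fdr) {
  s <- sd(x, na.rm = TRUE)
  if (!is.finite(s) || s == 0) return(rep(FALSE, length(x)))
  z <- (x - mean(x, na.rm = TRUE)) / s
  q <- p.adjust(pnorm(z, lower.tail = FALSE), method = "BH")
  !is.na(q) & q < fdr
}

#' Apply the genotype QC filter chain
#'
#' Filters run in the published order: individual call rate, SNP call rate,
#' heterozygosity outliers, IBS outliers, then (with per-SNP statistics
#' recomputed on the kept individuals) MAF, HWE and Y chromosome. Each
#' removal records its first-triggering reason; kept + removed reconciles
#' with the input on both axes. "Very high" heterozygosity/IBS is
#' operationalized as one-sided z-scores converted to normal p-values and
#' BH-adjusted, removing individuals at FDR < 1%.
#'
#' @param g a [genotype_matrix()].
#' @param thresholds a [qc_thresholds()] list.
#' @param outlier_filters set `FALSE` to skip the heterozygosity/IBS outlier
#'   steps (useful on clean simulated data and required for idempotence).
#' @return A list of class `"qc_result"`: `genotypes` (filtered matrix) and
#'   `report` (class `"qc_report"`: removals with reasons, per-SNP and
#'   per-individual statistics, thresholds, counts).
#' @export
apply_qc <- function(g, thresholds = qc_thresholds(), outlier_filters = TRUE) {
  stopifnot(inherits(g, "genotype_matrix"))
  th <- thresholds
  calls <- g$calls
  removed_ind <- data.frame(animal = character(), reason = character(),
                            stringsAsFactors = FALSE)
  removed_snp <- data.frame(snp = character(), reason = character(),
                            stringsAsFactors = FALSE)
  drop_ind <- function(ids, reason) {
    ids <- setdiff(ids, removed_ind$animal)
    if (length(ids))
      removed_ind <<- rbind(removed_ind,
                            data.frame(animal = ids, reason = reason,
                                       stringsAsFactors = FALSE))
  }
  drop_snp <- function(ids, reason) {
    ids <- setdiff(ids, removed_snp$snp)
    if (length(ids))
      removed_snp <<- rbind(removed_snp,
                            data.frame(snp = ids, reason = reason,
                                       stringsAsFactors = FALSE))
  }

  # (1) call rate, individuals then SNPs
  ind_cr <- rowMeans(!is.na(calls))
  drop_ind(rownames(calls)[ind_cr < th$call_rate], "call_rate")
  keep_i <- setdiff(rownames(calls), removed_ind$animal)
  snp_cr <- colMeans(!is.na(calls[keep_i, , drop = FALSE]))
  drop_snp(colnames(calls)[snp_cr < th$call_rate], "call_rate")
  keep_s <- setdiff(colnames(calls), removed_snp$snp)

  # (2) heterozygosity then IBS outliers, on surviving calls
  sub <- genotype_matrix(calls[keep_i, keep_s, drop = FALSE],
                         g$map[match(keep_s, g$map$snp), , drop = FALSE])
  samp <- if (length(keep_i) >= 2L) sample_summary(sub) else NULL
  if (outlier_filters && !is.null(samp)) {
    drop_ind(samp$animal[upper_outliers(samp$heterozygosity, th$outlier_fdr)],
             "heterozygosity")
    still <- setdiff(samp$animal, removed_ind$animal)
    drop_ind(still[upper_outliers(samp$max_ibs[match(still, samp$animal)],
                                  th$outlier_fdr)], "ibs")
    keep_i <- setdiff(keep_i, removed_ind$animal)
  }

  # (3)-(5) SNP filters on statistics recomputed after individual removal
  sub_calls <- calls[keep_i, keep_s, drop = FALSE]
  map_s <- g$map[match(keep_s, g$map$snp), , drop = FALSE]
  stats_s <- snp_summary(genotype_matrix(sub_calls, map_s))
  drop_snp(stats_s$snp[!is.na(stats_s$maf) & stats_s$maf < th$maf], "maf")
  still <- setdiff(stats_s$snp, removed_snp$snp)
  hw <- stats_s[match(still, stats_s$snp), ]
  drop_snp(hw$snp[!is.na(hw$hwe_p) & hw$hwe_p < th$hwe_p], "hwe")
  if (th$drop_y) {
    still <- setdiff(keep_s, removed_snp$snp)
    ych <- map_s$snp[map_s$chrom %in% c("Y", "y") & map_s$snp %in% still]
    drop_snp(ych, "y_chromosome")
  }
  keep_s <- setdiff(keep_s, removed_snp$snp)

  if (length(keep_i) == 0L || length(keep_s) == 0L) {
    err <- simpleError("QC removed all individuals or all SNPs")
    err$report <- list(removed_individuals = removed_ind,
                       removed_snps = removed_snp)
    stop(err)
  }

  filtered <- genotype_matrix(calls[keep_i, keep_s, drop = FALSE],
                              g$map[match(keep_s, g$map$snp), , drop = FALSE])
  report <- structure(list(
    removed_individuals = removed_ind,
    removed_snps = removed_snp,
    snp_stats = stats_s,
    sample_stats = samp,
    thresholds = th,
    outlier_filters = outlier_filters,
    outlier_method = "one-sided z-score -> normal p -> BH, FDR < outlier_fdr",
    n_in = dim(g$calls), n_out = dim(filtered$calls)),
    class = "qc_report")
  structure(list(genotypes = filtered, report = report), class = "qc_result")
}

#' @export
print.qc_report <- function(x, ...) {
  cat(sprintf("QC: %d/%d individuals and %d/%d SNPs kept\n",
              x$n_out[1], x$n_in[1], x$n_out[2], x$n_in[2]))
  if (nrow(x$removed_individuals))
    print(table(reason = x$removed_individuals$reason))
  if (nrow(x$removed_snps))
    print(table(reason = x$removed_snps$reason))
  invisible(x)
}

#' Write a QC report's removal tables as TSV
#'
#' @param report a `"qc_report"`.
#' @param dir output directory.
#' @return The directory, invisibly.
#' @export
write_qc_report <- function(report, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write.table(report$removed_individuals,
              file.path(dir, "removed_individuals.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(report$removed_snps, file.path(dir, "removed_snps.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(report$snp_stats, file.path(dir, "snp_stats.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(dir)
}
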