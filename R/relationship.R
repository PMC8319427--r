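# Relationship matrices: genomic (VanRaden method 1) and microbial
# (Gram matrix of standardized log abundances, M = OO'/n).

#' Genomic relationship matrix (VanRaden method 1)
#'
#' `G = WW' / (2 * sum p (1 - p))` where `W` holds genotypes centered by
#' twice the allele frequency (`g - 2p`) and frequencies are estimated from
#' the analyzed cohort. Missing genotypes are mean-imputed to `2p` at this
#' stage only (never during QC). Monomorphic SNPs contribute nothing and are
#' ignored.
#'
#' @param g a [genotype_matrix()] or plain 0/1/2/NA matrix (individuals x
#'   SNPs), normally post-QC.
#' @return An N x N symmetric matrix with `attr(., "kind") == "G"`.
#' @export
grm_vanraden <- function(g) {
  calls <- if (inherits(g, "genotype_matrix")) g$calls else as.matrix(g)
  nm <- colSums(!is.na(calls))
  p <- ifelse(nm > 0, colSums(calls, na.rm = TRUE) / (2 * nm), NA_real_)
  poly <- !is.na(p) & p > 0 & p < 1
  if (!any(poly)) stop("no polymorphic SNPs", call. = FALSE)
  calls <- calls[, poly, drop = FALSE]
  p <- p[poly]
  W <- sweep(calls, 2L, 2 * p)
  W[is.na(W)] <- 0  # missing -> 2p, i.e. zero after centering
  denom <- 2 * sum(p * (1 - p))
  G <- tcrossprod(W) / denom
  G <- (G + t(G)) / 2
  dimnames(G) <- list(rownames(calls), rownames(calls))
  attr(G, "kind") <- "G"
  G
}

#' Microbial relationship matrix M = OO'/n
#'
#' Columns of the log-abundance matrix are standardized to mean 0 and SD 1,
#' then `M = OO' / n` with `n` the number of taxa. Input should already be
#' core-filtered (>= 50% prevalence) and floor-adjusted log-transformed.
#' Zero-variance taxa are dropped with a warning. With the sample-variance
#' (S - 1) denominator in the standardization, `trace(M) = S - 1`.
#'
#' @param o samples x taxa log-abundance matrix.
#' @return An S x S symmetric PSD matrix with `attr(., "kind") == "M"`.
#' @export
microbial_relationship <- function(o) {
  o <- as.matrix(o)
  sds <- apply(o, 2L, sd)
  keep <- is.finite(sds) & sds > 0
  if (!all(keep)) {
    warning(sprintf("dropping %d zero-variance taxon column(s)", sum(!keep)))
    o <- o[, keep, drop = FALSE]
  }
  if (!ncol(o)) stop("no taxa with positive variance", call. = FALSE)
  Os <- scale(o)
  M <- tcrossprod(Os) / ncol(Os)
  M <- (M + t(M)) / 2
  dimnames(M) <- list(rownames(o), rownames(o))
  attr(M, "kind") <- "M"
  M
}
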