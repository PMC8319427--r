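# Abundance-table preprocessing and community-level analysis: core-taxon
# prevalence filter, floor-adjusted log10 transform, rarefaction, Shannon
# diversity, Bray-Curtis dissimilarity, principal coordinates, PERMANOVA.

#' Core-taxon prevalence filter
#'
#' Keeps taxa with nonzero abundance in at least `min_prevalence` of the
#' samples (inclusive; a taxon present in exactly half of the samples is
#' core at the default 0.5).
#'
#' @param tab samples x taxa abundance matrix.
#' @param min_prevalence minimum fraction of samples with nonzero abundance,
#'   in `(0, 1]`.
#' @return The filtered matrix.
#' @export
core_taxa_filter <- function(tab, min_prevalence = 0.5) {
  tab <- as.matrix(tab)
  if (!nrow(tab) || !ncol(tab)) stop("abundance table is empty", call. = FALSE)
  if (!is.numeric(min_prevalence) || length(min_prevalence) != 1L ||
      min_prevalence <= 0 || min_prevalence > 1)
    stop("'min_prevalence' must lie in (0, 1]", call. = FALSE)
  prev <- colMeans(tab > 0)
  tab[, prev >= min_prevalence, drop = FALSE]
}

#' Floor-adjusted log10 transform of relative abundances
#'
#' For each taxon that is absent from at least one sample, a small constant
#' (half of the detection limit, 0.00004613) is added to all of that taxon's
#' values before taking log10; taxa present in every sample are log10'd
#' unchanged.
#'
#' @param tab samples x taxa relative-abundance matrix (non-negative).
#' @param half_floor the additive constant.
#' @return The transformed matrix (same shape).
#' @export
log10_floor_transform <- function(tab, half_floor = 0.00004613) {
  tab <- as.matrix(tab)
  if (any(tab < 0)) stop("abundances must be non-negative", call. = FALSE)
  has_zero <- apply(tab == 0, 2L, any)
  tab[, has_zero] <- tab[, has_zero, drop = FALSE] + half_floor
  log10(tab)
}

#' Rarefy a count table to fixed depth
#'
#' Subsamples each sample's reads without replacement to exactly `depth`
#' (via [vegan::rrarefy()]); samples with fewer total reads are dropped with
#' a warning. Deterministic given `seed`.
#'
#' @param counts samples x taxa integer count matrix.
#' @param depth target sequencing depth per sample.
#' @param seed integer seed.
#' @return The rarefied count matrix (possibly fewer rows).
#' @export
rarefy_counts <- function(counts, depth = 10840, seed) {
  counts <- as.matrix(counts)
  if (depth <= 0) stop("'depth' must be positive", call. = FALSE)
  if (any(counts != round(counts)) || any(counts < 0))
    stop("'counts' must be non-negative integers", call. = FALSE)
  if (missing(seed)) stop("'seed' is required", call. = FALSE)
  totals <- rowSums(counts)
  low <- totals < depth
  if (any(low)) {
    warning(sprintf("dropping %d sample(s) below depth %d: %s",
                    sum(low), depth,
                    paste(rownames(counts)[low], collapse = ", ")))
    counts <- counts[!low, , drop = FALSE]
  }
  if (!nrow(counts)) stop("no samples reach the rarefaction depth",
                          call. = FALSE)
  set.seed(derive_seed(seed, 11L))
  vegan::rrarefy(counts, sample = depth)
}

#' Shannon diversity index
#'
#' `H = -sum(p_i * log(p_i, base))` over nonzero proportions after
#' renormalization. Base 2 (bits) by default, following the QIIME 2
#' convention.
#'
#' @param x non-negative abundance vector for one sample.
#' @param base logarithm base.
#' @return The Shannon index (scalar).
#' @export
shannon_index <- function(x, base = 2) {
  if (any(x < 0)) stop("abundances must be non-negative", call. = FALSE)
  s <- sum(x)
  if (s <= 0) stop("sample is all zero", call. = FALSE)
  p <- x[x > 0] / s
  -sum(p * log(p, base = base))
}

#' Bray-Curtis dissimilarity matrix
#'
#' `D[i, j] = sum |x_i - x_j| / sum (x_i + x_j)` over taxa, computed with
#' [vegan::vegdist()].
#'
#' @param tab samples x taxa abundance matrix (>= 2 samples).
#' @return A square symmetric matrix with zero diagonal, entries in `[0, 1]`.
#' @export
bray_curtis <- function(tab) {
  tab <- as.matrix(tab)
  if (nrow(tab) < 2L) stop("need at least two samples", call. = FALSE)
  if (any(rowSums(tab) == 0))
    stop("all-zero samples make Bray-Curtis undefined", call. = FALSE)
  D <- as.matrix(vegan::vegdist(tab, method = "bray"))
  dimnames(D) <- list(rownames(tab), rownames(tab))
  D
}

#' Principal coordinates analysis (classical scaling)
#'
#' Gower double-centering of `-D^2/2`, eigendecomposition, coordinates from
#' the top positive eigenvalues. Negative eigenvalues are reported but their
#' axes are omitted; if `k` exceeds the number of positive eigenvalues the
#' embedding is truncated with a warning.
#'
#' @param D square symmetric distance matrix (or `dist`).
#' @param k number of axes requested.
#' @return A list with `points` (n x k' coordinate matrix), `eig` (all
#'   eigenvalues, descending) and `k` (axes returned).
#' @export
pcoa <- function(D, k = 2) {
  D <- as.matrix(D)
  stopifnot(nrow(D) == ncol(D))
  if (max(abs(D - t(D))) > 1e-8) stop("'D' must be symmetric", call. = FALSE)
  n <- nrow(D)
  # cmdscale warns on its own when k exceeds the positive spectrum; the
  # truncation warning is raised below with an explicit count instead
  cs <- suppressWarnings(cmdscale(as.dist(D), k = min(k, n - 1L), eig = TRUE))
  eig <- cs$eig
  npos <- sum(eig > max(eig, 0) * 1e-10)
  if (npos == 0L) {
    return(list(points = matrix(0, n, k, dimnames = list(rownames(D), NULL)),
                eig = eig, k = 0L))
  }
  if (k > npos) {
    warning(sprintf("only %d positive eigenvalues; returning %d axes",
                    npos, npos))
    k <- npos
  }
  pts <- cs$points[, seq_len(min(k, ncol(cs$points))), drop = FALSE]
  rownames(pts) <- rownames(D)
  list(points = pts, eig = eig, k = ncol(pts))
}

# Pseudo-F for one grouping factor from squared distances:
# SS_total = sum_{i<j} d_ij^2 / n ; SS_within = sum_g sum_{i<j in g} d^2 / n_g.
# This is the Gower-centered inner-product partition in distance form.
permanova_f <- function(D2, grouping) {
  n <- nrow(D2)
  g <- length(unique(grouping))
  ss_total <- sum(D2) / (2 * n)
  ss_within <- 0
  for (lev in unique(grouping)) {
    idx <- which(grouping == lev)
    ss_within <- ss_within + sum(D2[idx, idx]) / (2 * length(idx))
  }
  ss_between <- ss_total - ss_within
  (ss_between / (g - 1)) / (ss_within / (n - g))
}

# All distinct assignments of ids to groups of the given sizes (one matrix
# column per assignment, entries = group index per position).
enumerate_assignments <- function(n, sizes) {
  recur <- function(free, sizes_left) {
    if (length(sizes_left) == 1L)
      return(matrix(free, ncol = 1L))
    first <- combn(free, sizes_left[1])
    out <- NULL
    for (j in seq_len(ncol(first))) {
      rest <- recur(setdiff(free, first[, j]), sizes_left[-1])
      out <- cbind(out, rbind(matrix(first[, j], nrow = sizes_left[1],
                                     ncol = ncol(rest)), rest))
    }
    out
  }
  recur(seq_len(n), sizes)
}

#' PERMANOVA: permutation test of group effects on a distance matrix
#'
#' One fixed factor. The pseudo-F is the between/within partition of squared
#' distances; significance comes from raw label permutations with
#' `p = (#{F_perm >= F_obs} + 1) / (n_perm + 1)` (ties count toward the
#' numerator). When the number of distinct label assignments is at most
#' `n_perm`, the test switches to exhaustive enumeration and
#' `p = #{F >= F_obs} / #assignments` (the identity assignment included).
#'
#' @param D distance matrix (square symmetric or `dist`).
#' @param grouping factor/vector of group labels, one per sample.
#' @param n_perm number of label permutations.
#' @param seed integer seed for the permutation stream.
#' @return A list of class `"permanova"`: `f`, `p`, `n_perm`, `exhaustive`,
#'   `ss` (between/within/total).
#' @export
permanova <- function(D, grouping, n_perm = 999, seed = 1) {
  D <- as.matrix(D)
  grouping <- as.character(grouping)
  stopifnot(nrow(D) == ncol(D), length(grouping) == nrow(D))
  tab <- table(grouping)
  if (length(tab) < 2L) stop("need at least two groups", call. = FALSE)
  if (any(tab < 2L)) stop("each group needs at least two samples",
                          call. = FALSE)
  n <- nrow(D)
  D2 <- D^2
  f_obs <- permanova_f(D2, grouping)

  sizes <- as.integer(tab)
  n_distinct <- exp(lgamma(n + 1) - sum(lgamma(sizes + 1)))
  if (is.finite(n_distinct) && n_distinct <= n_perm) {
    assign_mat <- enumerate_assignments(n, sizes)
    levs <- rep(names(tab), sizes)
    f_perm <- apply(assign_mat, 2L, function(ord) {
      gr <- character(n); gr[ord] <- levs
      permanova_f(D2, gr)
    })
    p <- sum(f_perm >= f_obs) / length(f_perm)
    exhaustive <- TRUE
    n_used <- length(f_perm)
  } else {
    set.seed(derive_seed(seed, 13L))
    f_perm <- vapply(seq_len(n_perm), function(i)
      permanova_f(D2, grouping[sample.int(n)]), numeric(1))
    p <- (sum(f_perm >= f_obs) + 1) / (n_perm + 1)
    exhaustive <- FALSE
    n_used <- n_perm
  }

  ss_total <- sum(D2) / (2 * n)
  ss_w <- 0
  for (lev in unique(grouping)) {
    idx <- which(grouping == lev)
    ss_w <- ss_w + sum(D2[idx, idx]) / (2 * length(idx))
  }
  structure(list(f = f_obs, p = p, n_perm = n_used, exhaustive = exhaustive,
                 ss = c(between = ss_total - ss_w, within = ss_w,
                        total = ss_total)),
            class = "permanova")
}

#' @export
print.permanova <- function(x, ...) {
  cat(sprintf("PERMANOVA: pseudo-F = %.4g, p = %.4g (%s, %d permutations)\n",
              x$f, x$p, if (x$exhaustive) "exhaustive" else "sampled",
              x$n_perm))
  invisible(x)
}
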