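# Co-occurrence network over core genera: pairwise Spearman correlations,
# BH adjustment over the upper triangle, edges at |rho| > 0.25 and
# q < 0.001 (both strict), hub = maximal-degree node(s).

#' Pairwise Spearman correlation matrix with raw p-values
#'
#' Average ranks for ties; two-sided p-values from the t approximation.
#' Constant taxon columns yield `NA` rows/columns and are reported in
#' `attr(., "undefined")`.
#'
#' @param tab samples x taxa abundance matrix (>= 3 samples).
#' @return A list with `rho` (taxa x taxa, unit diagonal) and `p`
#'   (diagonal `NA`, untested).
#' @export
spearman_matrix <- function(tab) {
  tab <- as.matrix(tab)
  n <- nrow(tab)
  if (n < 3L) stop("need at least three samples", call. = FALSE)
  constant <- apply(tab, 2L, function(x) var(x) == 0)
  ranks <- apply(tab, 2L, rank)
  rho <- suppressWarnings(cor(ranks))
  rho[constant, ] <- NA_real_
  rho[, constant] <- NA_real_
  diag(rho) <- ifelse(constant, NA_real_, 1)
  tstat <- rho * sqrt((n - 2) / pmax(1 - rho^2, 0))
  p <- 2 * pt(abs(tstat), df = n - 2, lower.tail = FALSE)
  p[abs(rho) >= 1] <- 0
  diag(p) <- NA_real_
  out <- list(rho = rho, p = p)
  attr(out, "undefined") <- colnames(tab)[constant]
  out
}

#' Build the thresholded co-occurrence network
#'
#' BH-adjusts the upper-triangle p-values (each unordered pair tested once),
#' keeps edges with `|rho| > min_rho` AND `q < max_q` (both strict), and
#' reports node degrees and the hub(s) — all nodes of maximal degree.
#'
#' @param sm a [spearman_matrix()] result (or a list with `rho` and `p`).
#' @param min_rho correlation magnitude threshold (exclusive).
#' @param max_q BH-adjusted p-value threshold (exclusive).
#' @return A list of class `"cooccurrence_network"`: `edges` (data frame
#'   `from`, `to`, `rho`, `q`, `sign`, with `from < to`), `degree` (named
#'   vector over all taxa), `hub` (character vector, empty when there are no
#'   edges), `graph` (an igraph object), `fdr_family` (how BH was applied).
#' @export
build_network <- function(sm, min_rho = 0.25, max_q = 0.001) {
  rho <- sm$rho
  p <- sm$p
  if (is.null(rho) || !nrow(rho)) stop("empty correlation input", call. = FALSE)
  taxa <- colnames(rho)
  ut <- which(upper.tri(rho), arr.ind = TRUE)
  p_ut <- p[ut]
  q_ut <- rep(NA_real_, length(p_ut))
  ok <- !is.na(p_ut)
  q_ut[ok] <- bh_adjust(p_ut[ok])
  rho_ut <- rho[ut]
  keep <- !is.na(rho_ut) & !is.na(q_ut) &
    abs(rho_ut) > min_rho & q_ut < max_q

  edges <- data.frame(from = taxa[ut[keep, 1]], to = taxa[ut[keep, 2]],
                      rho = rho_ut[keep], q = q_ut[keep],
                      sign = ifelse(rho_ut[keep] > 0, "positive", "negative"),
                      stringsAsFactors = FALSE)
  degree <- setNames(integer(length(taxa)), taxa)
  if (nrow(edges)) {
    tab <- table(c(edges$from, edges$to))
    degree[names(tab)] <- as.integer(tab)
  }
  hub <- if (nrow(edges)) names(degree)[degree == max(degree)] else character(0)

  graph <- igraph::graph_from_data_frame(
    edges, directed = FALSE,
    vertices = data.frame(name = taxa, degree = as.integer(degree),
                          stringsAsFactors = FALSE))
  structure(list(edges = edges, degree = degree, hub = hub, graph = graph,
                 thresholds = c(min_rho = min_rho, max_q = max_q),
                 fdr_family = "BH over the upper triangle (each pair once)"),
            class = "cooccurrence_network")
}

#' @export
print.cooccurrence_network <- function(x, ...) {
  cat(sprintf("co-occurrence network: %d nodes, %d edges (|rho| > %g, q < %g)\n",
              length(x$degree), nrow(x$edges),
              x$thresholds["min_rho"], x$thresholds["max_q"]))
  if (length(x$hub))
    cat("hub:", paste(x$hub, collapse = ", "),
        sprintf("(degree %d)\n", max(x$degree)))
  invisible(x)
}

#' Co-occurrence network straight from an abundance table
#'
#' @param tab samples x taxa abundance matrix (core genera).
#' @param ... passed to [build_network()].
#' @return A `"cooccurrence_network"`.
#' @export
cooccurrence_network <- function(tab, ...) {
  build_network(spearman_matrix(tab), ...)
}

#' Export a network
#'
#' `write_network_edges()` writes the edge list as TSV
#' (source, target, rho, q, sign); `write_network_graphml()` writes GraphML
#' with degree as a node attribute and rho/q as edge attributes.
#'
#' @param net a `"cooccurrence_network"`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_network_edges <- function(net, path) {
  edges <- net$edges
  names(edges)[1:2] <- c("source", "target")
  write.table(edges, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_network_edges
#' @export
write_network_graphml <- function(net, path) {
  g <- net$graph
  if (nrow(net$edges)) {
    igraph::E(g)$rho <- net$edges$rho
    igraph::E(g)$q <- net$edges$q
  }
  igraph::write_graph(g, path, format = "graphml")
  invisible(path)
}
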