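#' Canberra distance between two vectors
#'
#' `d(u, v) = sum_i |u_i - v_i| / (|u_i| + |v_i|)`, where coordinates with
#' both entries zero contribute 0. On binary vectors this reduces to the
#' Hamming distance restricted to coordinates that are not both zero.
#'
#' @param u,v Numeric vectors of equal length.
#' @return Non-negative scalar distance.
#' @export
canberra_distance <- function(u, v) {
  if (length(u) != length(v))
    stopf("`u` (length %d) and `v` (length %d) differ in length",
          length(u), length(v))
  denom <- abs(u) + abs(v)
  keep <- denom > 0
  sum(abs(u[keep] - v[keep]) / denom[keep])
}

# all-pairs Canberra distances between the rows of a matrix, as a dist
canberra_dist_rows <- function(M) {
  n <- nrow(M)
  d <- matrix(0, n, n)
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n)
    d[i, j] <- d[j, i] <- canberra_distance(M[i, ], M[j, ])
  stats::as.dist(d)
}

#' Hierarchical-clustering order of matrix rows or columns
#'
#' Average-linkage agglomerative clustering on pairwise Canberra distances;
#' the returned order is the dendrogram leaf order. `hclust` merges are
#' deterministic (ties resolved by original index), so repeated runs give
#' identical orders.
#'
#' @param M Numeric matrix.
#' @param axis `"rows"` or `"cols"`.
#' @return List with `order` (integer permutation of the axis) and
#'   `linkage` (the `hclust` object, or `NULL` for a single item).
#' @export
cluster_order <- function(M, axis = c("rows", "cols")) {
  axis <- match.arg(axis)
  if (axis == "cols") M <- t(M)
  n <- nrow(M)
  if (n < 1L) stopf("nothing to cluster")
  if (n == 1L) return(list(order = 1L, linkage = NULL))
  hc <- stats::hclust(canberra_dist_rows(M), method = "average")
  list(order = hc$order, linkage = hc)
}

#' Build and cluster the design structure matrix
#'
#' Constructs the binary sets x genes membership matrix for a selection
#' (entry 1 when the gene belongs to the set) and orders both axes by
#' unsupervised average-linkage clustering on Canberra distances of the
#' membership vectors.
#'
#' @param selection A `"dsm_selection"` from [select_for_dsm()], or a list
#'   with `sets` and `genes` character vectors.
#' @param catalog The `"gene_set_catalog"` the selection refers to.
#' @return A `"dsm"`: list with `membership` (binary matrix), `row_order`,
#'   `col_order` (permutations), `row_linkage`, `col_linkage`.
#' @export
design_structure_matrix <- function(selection, catalog) {
  sets <- selection$sets
  genes <- selection$genes
  if (length(sets) == 0L || length(genes) == 0L)
    stopf("empty selection: relax `set_q_max` or `gene_quantile_max` to select sets/genes")
  missing_sets <- setdiff(sets, names(catalog$sets))
  if (length(missing_sets))
    stopf("selected set(s) not in catalog: %s",
          paste(missing_sets, collapse = ", "))
  membership <- vapply(genes, function(g)
    as.integer(vapply(catalog$sets[sets], function(s) g %in% s, logical(1))),
    integer(length(sets)))
  membership <- matrix(membership, nrow = length(sets),
                       dimnames = list(sets, genes))
  orphan <- colSums(membership) == 0L
  if (any(orphan))
    stopf("selected gene(s) belong to no selected set: %s",
          paste(genes[orphan], collapse = ", "))
  ro <- cluster_order(membership, "rows")
  co <- cluster_order(membership, "cols")
  structure(list(membership = membership, row_order = ro$order,
                 col_order = co$order, row_linkage = ro$linkage,
                 col_linkage = co$linkage),
            class = "dsm")
}

#' @export
print.dsm <- function(x, ...) {
  cat(sprintf("Design structure matrix: %d sets x %d genes (%d memberships)\n",
              nrow(x$membership), ncol(x$membership), sum(x$membership)))
  invisible(x)
}

#' Plot a clustered design structure matrix
#'
#' Displays the membership matrix with rows and columns in clustered order;
#' optionally adds the companion row-standardized expression heat map of the
#' selected genes below it.
#'
#' @param x A `"dsm"` object.
#' @param expression Optional log2 expression matrix containing the selected
#'   genes, for the companion Z-score heat map.
#' @param ... Unused.
#' @export
plot.dsm <- function(x, expression = NULL, ...) {
  M <- x$membership[x$row_order, x$col_order, drop = FALSE]
  if (!is.null(expression)) {
    old <- graphics::par(mfrow = c(2, 1), mar = c(6, 8, 2, 1))
    on.exit(graphics::par(old))
  } else {
    old <- graphics::par(mar = c(6, 8, 2, 1))
    on.exit(graphics::par(old))
  }
  graphics::image(t(M[rev(seq_len(nrow(M))), , drop = FALSE]),
                  col = c("white", "black"), axes = FALSE,
                  main = "design structure matrix")
  graphics::axis(1, at = seq(0, 1, length.out = ncol(M)),
                 labels = colnames(M), las = 2, cex.axis = 0.6)
  graphics::axis(2, at = seq(0, 1, length.out = nrow(M)),
                 labels = rev(rownames(M)), las = 2, cex.axis = 0.6)
  if (!is.null(expression)) {
    Z <- zscore_matrix(expression, colnames(M))
    pal <- grDevices::colorRampPalette(c("blue", "black", "yellow"))(64)
    graphics::image(t(Z[rev(seq_len(nrow(Z))), , drop = FALSE]),
                    col = pal, axes = FALSE, main = "rescaled Z-values")
    graphics::axis(2, at = seq(0, 1, length.out = nrow(Z)),
                   labels = rev(rownames(Z)), las = 2, cex.axis = 0.6)
  }
  invisible(x)
}
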