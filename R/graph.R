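#' Recommended histology weight beta
#'
#' Balances the histology intensity term against the spatial term in the fused
#' spot distance: the squared coordinate ranges divided by the squared
#' intensity range,
#' \deqn{\beta = \frac{\max_{i,j}(x_i-x_j)^2 + \max_{i,j}(y_i-y_j)^2}{\max_{i,j}(z_i-z_j)^2}.}
#' A vague or absent histology signal should contribute little; when `z` is
#' missing or constant the limit `beta = 0` is returned, which removes the
#' histology term altogether.
#'
#' @param geometry a [spot_geometry()] object with at least 2 spots.
#' @return non-negative scalar.
#' @examples
#' g <- spot_geometry(c("a", "b"), x = c(0, 10), y = c(0, 10), z = c(0, 2))
#' compute_beta(g)  # (100 + 100) / 4 = 50
#' @export
compute_beta <- function(geometry) {
  stopifnot(inherits(geometry, "spot_geometry"))
  if (geometry$n_spots < 2L) stop("need at least 2 spots to compute beta")
  z <- geometry$z
  if (is.null(z)) return(0)
  dz2 <- diff(range(z))^2
  if (dz2 == 0) return(0)
  (diff(range(geometry$x))^2 + diff(range(geometry$y))^2) / dz2
}

#' Fused squared distance matrix between spots
#'
#' Entry (i, j) is \eqn{(x_i-x_j)^2 + (y_i-y_j)^2 + \beta (z_i-z_j)^2}: the
#' squared planar distance plus the squared histology-intensity difference
#' scaled by `beta`. With `beta = 0` (or `z` absent) this is the plain squared
#' Euclidean distance on the array.
#'
#' @param geometry a [spot_geometry()] object.
#' @param beta non-negative histology weight; see [compute_beta()].
#' @return symmetric M x M numeric matrix with zero diagonal.
#' @export
squared_distance_matrix <- function(geometry, beta = 0) {
  stopifnot(inherits(geometry, "spot_geometry"))
  if (!is.finite(beta) || beta < 0) stop("beta must be a non-negative finite scalar")
  d2 <- outer(geometry$x, geometry$x, "-")^2 + outer(geometry$y, geometry$y, "-")^2
  if (beta > 0 && !is.null(geometry$z)) {
    d2 <- d2 + beta * outer(geometry$z, geometry$z, "-")^2
  }
  dimnames(d2) <- list(geometry$spot_ids, geometry$spot_ids)
  d2
}

#' Build the sparse spot adjacency graph and its Laplacian
#'
#' Converts fused squared distances into a sparse non-negative similarity
#' matrix G keeping only each spot's `k` nearest neighbors, then forms the
#' degree matrix D (`D_jj = sum_l G_jl`) and graph Laplacian `L = D - G` used
#' by the solver's smoothing penalty. Keeping the top entries per row after
#' the distance-to-similarity conversion means the *nearest* spots are kept,
#' so `Tr(H' L H)` penalizes proportion differences between neighbors.
#'
#' Modes:
#' * `"binary"` (default): weight 1 on each row's `k` smallest off-diagonal
#'   squared distances.
#' * `"heat"`: weight `exp(-d2/sigma2)` on those entries, with `sigma2` the
#'   median of all kept squared distances.
#'
#' Row-wise selection is symmetrized by the elementwise maximum (an edge is
#' kept if either endpoint selects it), or by the elementwise minimum when
#' `mutual = TRUE` (both must select it). Distance ties are broken by lower
#' spot index.
#'
#' @param sq_dist symmetric M x M matrix of squared distances with zero
#'   diagonal, from [squared_distance_matrix()].
#' @param k integer, neighbors kept per row (default 5), `1 <= k <= M - 1`.
#' @param mode `"binary"` or `"heat"`.
#' @param mutual logical; use mutual-kNN (elementwise minimum) symmetrization.
#' @return An object of class `spatial_graph`: list with sparse `G`, `D`, `L`
#'   (`Matrix` classes), `k`, `mode` and `beta` (carried for provenance via
#'   the `beta` argument attribute; stored as `NA` if unknown).
#' @export
spatial_graph <- function(sq_dist, k = 5L, mode = c("binary", "heat"),
                          mutual = FALSE) {
  mode <- match.arg(mode)
  m <- nrow(sq_dist)
  if (m != ncol(sq_dist)) stop("sq_dist must be square")
  if (max(abs(sq_dist - t(sq_dist))) > 1e-8 * (1 + max(abs(sq_dist)))) {
    stop("sq_dist must be symmetric")
  }
  k <- as.integer(k)
  if (k < 1L || k > m - 1L) stop("k must satisfy 1 <= k <= M - 1, got ", k)

  # k nearest off-diagonal entries per row; ties broken by lower index
  neigh <- matrix(0L, m, k)
  for (i in seq_len(m)) {
    d <- sq_dist[i, ]
    d[i] <- Inf
    neigh[i, ] <- order(d, seq_len(m))[seq_len(k)]
  }
  ii <- rep(seq_len(m), each = k)
  jj <- as.integer(t(neigh))
  kept_d2 <- sq_dist[cbind(ii, jj)]
  w <- if (mode == "binary") {
    rep(1, length(ii))
  } else {
    sigma2 <- stats::median(kept_d2)
    if (sigma2 <= 0) sigma2 <- 1  # degenerate all-coincident spots
    exp(-kept_d2 / sigma2)
  }
  A <- Matrix::sparseMatrix(i = ii, j = jj, x = w, dims = c(m, m))
  G <- if (mutual) {
    # keep edge only if selected in both directions
    sel <- Matrix::sparseMatrix(i = ii, j = jj, x = 1, dims = c(m, m))
    both <- sel * Matrix::t(sel)          # 1 where mutual
    (A * both + Matrix::t(A) * both) / 2
  } else {
    pmax_sparse(A, Matrix::t(A))
  }
  G <- methods::as(Matrix::drop0(G), "generalMatrix")
  deg <- Matrix::rowSums(G)
  D <- Matrix::Diagonal(m, deg)
  L <- D - G
  ids <- rownames(sq_dist)
  structure(list(G = G, D = D, L = L, k = k, mode = mode,
                 spot_ids = ids, n_spots = m),
            class = "spatial_graph")
}

# elementwise maximum of two non-negative sparse matrices
pmax_sparse <- function(A, B) {
  # max(a, b) = a + b - min(a, b); for non-negative sparse inputs use
  # the identity max = (a + b + |a - b|) / 2
  (A + B + abs(A - B)) / 2
}

#' @export
print.spatial_graph <- function(x, ...) {
  cat("spatial_graph:", x$n_spots, "spots, k =", x$k, ", mode =", x$mode,
      ",", Matrix::nnzero(x$G), "edges (directed count)\n")
  invisible(x)
}

#' Graph-Laplacian quadratic form
#'
#' Computes `Tr(H' L H)`, the smoothness of the columns of H over the spot
#' graph. For a symmetric similarity G this equals
#' \eqn{\frac12 \sum_{j,l} G_{jl} \lVert h_j - h_l \rVert^2}, so it is zero
#' when all rows of H coincide and grows as neighboring spots disagree.
#'
#' @param H numeric M x R matrix (rows = spots).
#' @param graph a [spatial_graph()] object with `n_spots == nrow(H)`.
#' @return non-negative scalar.
#' @export
laplacian_quadratic <- function(H, graph) {
  stopifnot(inherits(graph, "spatial_graph"))
  H <- as.matrix(H)
  if (nrow(H) != graph$n_spots) {
    stop("H has ", nrow(H), " rows but the graph has ", graph$n_spots, " spots")
  }
  sum(H * as.matrix(graph$L %*% H))
}

#' Build a spot graph from geometry in one call
#'
#' Convenience wrapper: computes `beta` (recommended value unless supplied),
#' the fused squared distance matrix, and the sparsified graph.
#'
#' @inheritParams spatial_graph
#' @param geometry a [spot_geometry()] object.
#' @param beta `"auto"` for the recommended value from [compute_beta()], or a
#'   non-negative scalar.
#' @return a `spatial_graph`.
#' @export
build_spot_graph <- function(geometry, k = 5L, mode = c("binary", "heat"),
                             beta = "auto", mutual = FALSE) {
  mode <- match.arg(mode)
  b <- if (identical(beta, "auto")) compute_beta(geometry) else as.numeric(beta)
  g <- spatial_graph(squared_distance_matrix(geometry, b), k = k, mode = mode,
                     mutual = mutual)
  g$beta <- b
  g
}

#' Write / read a spot graph as an edge list
#'
#' Three-column tab-separated edge list (`spot_i`, `spot_j`, `weight`), one
#' row per undirected edge (i < j).
#'
#' @param graph a `spatial_graph`.
#' @param path output TSV path.
#' @export
write_graph_edges <- function(graph, path) {
  stopifnot(inherits(graph, "spatial_graph"))
  T3 <- Matrix::summary(methods::as(Matrix::triu(graph$G, 1), "TsparseMatrix"))
  ids <- graph$spot_ids %||% as.character(seq_len(graph$n_spots))
  df <- data.frame(spot_i = ids[T3$i], spot_j = ids[T3$j], weight = T3$x)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_graph_edges
#' @param spot_ids spot identifier order defining the matrix indices.
#' @export
read_graph_edges <- function(path, spot_ids) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  i <- match(df$spot_i, spot_ids); j <- match(df$spot_j, spot_ids)
  if (anyNA(i) || anyNA(j)) stop("edge list refers to spot ids absent from spot_ids")
  m <- length(spot_ids)
  G <- Matrix::sparseMatrix(i = c(i, j), j = c(j, i), x = rep(df$weight, 2),
                            dims = c(m, m))
  D <- Matrix::Diagonal(m, Matrix::rowSums(G))
  structure(list(G = G, D = D, L = D - G, k = NA_integer_, mode = "file",
                 spot_ids = spot_ids, n_spots = m),
            class = "spatial_graph")
}

`%||%` <- function(a, b) if (is.null(a)) b else a
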