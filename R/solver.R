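#' Regularized NMF objective
#'
#' The quantity minimized by [fast_fit()]:
#' \deqn{\lVert X - W H^\top \rVert_F^2
#'   + \lambda_1 \,\mathrm{Tr}(H^\top L H)
#'   + \lambda_2 \lVert H J - J_M \rVert_F^2,}
#' where L is the spot-graph Laplacian, J the R x M all-ones matrix and J_M
#' the M x M all-ones matrix. The sum-to-one term is evaluated by the closed
#' form \eqn{M \sum_j (\sum_r H_{jr} - 1)^2} — the all-ones matrices are never
#' materialized.
#'
#' @param X numeric N x M matrix (genes x spots), non-negative.
#' @param W numeric N x R non-negative signature matrix.
#' @param H numeric M x R non-negative abundance matrix.
#' @param graph a [spatial_graph()] with M spots, or `NULL` when
#'   `lambda1 = 0`.
#' @param lambda1 non-negative weight of the graph smoothing term.
#' @param lambda2 non-negative weight of the sum-to-one term.
#' @return scalar objective value.
#' @export
fast_objective <- function(X, W, H, graph = NULL, lambda1 = 0, lambda2 = 0) {
  check_factor_shapes(X, W, H)
  obj <- sum((X - tcrossprod(W, H))^2)
  if (lambda1 > 0) {
    if (is.null(graph)) stop("lambda1 > 0 requires a graph")
    obj <- obj + lambda1 * laplacian_quadratic(H, graph)
  }
  if (lambda2 > 0) {
    obj <- obj + lambda2 * nrow(H) * sum((rowSums(H) - 1)^2)
  }
  obj
}

check_factor_shapes <- function(X, W, H) {
  if (nrow(W) != nrow(X)) stop("W has ", nrow(W), " rows but X has ", nrow(X))
  if (nrow(H) != ncol(X)) stop("H has ", nrow(H), " rows but X has ", ncol(X), " columns")
  if (ncol(W) != ncol(H)) stop("W and H must have the same number of columns (rank)")
  invisible(TRUE)
}

#' Multiplicative update for the signature matrix W
#'
#' One step of the multiplicative rule
#' `W <- W * (X H) / (W (H'H) + eps)`, elementwise. Derived from the KKT
#' stationarity condition of the objective with H fixed (the penalties do not
#' involve W, so this is the classical Frobenius-NMF rule). Preserves
#' non-negativity and does not increase the objective.
#'
#' @inheritParams fast_objective
#' @param eps small denominator floor preventing division by zero.
#' @return updated W.
#' @export
fast_update_w <- function(X, W, H, eps = 1e-12) {
  W * (X %*% H) / (W %*% crossprod(H) + eps)
}

#' Multiplicative update for the abundance matrix H
#'
#' One step of
#' `H <- H * (X'W + lambda1 G H + lambda2 M 1) / (H (W'W) + lambda1 D H + lambda2 M H 1_RR + eps)`.
#' Splitting `L = D - G` puts the attractive part (G, neighbor averaging) in
#' the numerator and the degree part in the denominator, so every term stays
#' non-negative; the sum-to-one penalty gradient
#' `2 lambda2 M (H 1_RR - 1_MR)` splits the same way. With W fixed the
#' objective does not increase.
#'
#' @inheritParams fast_update_w
#' @param graph a [spatial_graph()]; ignored (may be `NULL`) when `lambda1 = 0`.
#' @param lambda1,lambda2 non-negative penalty weights.
#' @return updated H.
#' @export
fast_update_h <- function(X, W, H, graph = NULL, lambda1 = 0, lambda2 = 0,
                          eps = 1e-12) {
  num <- crossprod(X, W)
  den <- H %*% crossprod(W)
  if (lambda1 > 0) {
    if (is.null(graph)) stop("lambda1 > 0 requires a graph")
    num <- num + lambda1 * as.matrix(graph$G %*% H)
    den <- den + lambda1 * as.matrix(graph$D %*% H)
  }
  if (lambda2 > 0) {
    m <- nrow(H)
    num <- num + lambda2 * m
    den <- den + lambda2 * m * rowSums(H)  # H %*% ones(R, R) recycled by column
  }
  H * num / (den + eps)
}

#' Initialize W and H
#'
#' `"random"` draws all entries uniformly on (0, 1). `"nndsvd"` is a
#' non-negative double SVD: the leading singular triplets are split into
#' their positive and negative parts and the larger-energy part of each is
#' kept, after which zero entries are replaced by `mean(X) / 100` so
#' multiplicative updates can move them.
#'
#' @param X data matrix.
#' @param R rank.
#' @param method `"random"` or `"nndsvd"`.
#' @return list with `W` (N x R) and `H` (M x R).
#' @export
init_factors <- function(X, R, method = c("random", "nndsvd")) {
  method <- match.arg(method)
  n <- nrow(X); m <- ncol(X)
  if (method == "random") {
    return(list(W = matrix(stats::runif(n * R), n, R),
                H = matrix(stats::runif(m * R), m, R)))
  }
  s <- svd(X, nu = R, nv = R)
  W <- matrix(0, n, R); Ht <- matrix(0, R, m)
  W[, 1] <- sqrt(s$d[1]) * abs(s$u[, 1])
  Ht[1, ] <- sqrt(s$d[1]) * abs(s$v[, 1])
  if (R >= 2) for (r in 2:R) {
    u <- s$u[, r]; v <- s$v[, r]
    up <- pmax(u, 0); un <- pmax(-u, 0)
    vp <- pmax(v, 0); vn <- pmax(-v, 0)
    npn <- sqrt(sum(up^2)) * sqrt(sum(vp^2))
    nnn <- sqrt(sum(un^2)) * sqrt(sum(vn^2))
    if (npn >= nnn && npn > 0) {
      W[, r] <- sqrt(s$d[r] * npn) * up / sqrt(sum(up^2))
      Ht[r, ] <- sqrt(s$d[r] * npn) * vp / sqrt(sum(vp^2))
    } else if (nnn > 0) {
      W[, r] <- sqrt(s$d[r] * nnn) * un / sqrt(sum(un^2))
      Ht[r, ] <- sqrt(s$d[r] * nnn) * vn / sqrt(sum(vn^2))
    }
  }
  floor_val <- mean(X) / 100
  W[W == 0] <- floor_val
  Ht[Ht == 0] <- floor_val
  list(W = W, H = t(Ht))
}

#' Fit the regularized NMF deconvolution model
#'
#' Minimizes [fast_objective()] by alternating the multiplicative updates
#' [fast_update_w()] and [fast_update_h()] from a seeded initialization,
#' stopping when the relative objective change falls below `tol` or after
#' `max_iter` iterations. Identical inputs, config and seed give a
#' bit-identical result.
#'
#' @param X numeric N x M non-negative matrix (genes x spots); may carry
#'   dimnames, which are propagated to W and H.
#' @param graph a [spatial_graph()] over the M spots; may be `NULL` if
#'   `lambda1 = 0`.
#' @param R rank: number of cell types to deconvolve (`R <= min(N, M)`).
#' @param lambda1 graph-smoothing weight (default 1).
#' @param lambda2 sum-to-one weight (default 1).
#' @param max_iter maximum number of update sweeps (default 1000).
#' @param tol relative objective-change convergence tolerance (default 1e-5).
#' @param seed RNG seed for the initialization.
#' @param init `"random"` (uniform(0,1), the default) or `"nndsvd"`.
#' @param eps denominator floor in the updates.
#' @return An object of class `fast_fit`: list with `W` (N x R), `H` (M x R,
#'   raw, not normalized), `objective_trace`, `n_iter`, `converged`, and the
#'   resolved configuration in `config`.
#' @examples
#' set.seed(1)
#' X <- matrix(rpois(60, 5), 10, 6)
#' fit <- fast_fit(X, graph = NULL, R = 2, lambda1 = 0, lambda2 = 1, seed = 1)
#' head(spot_proportions(fit))
#' @export
fast_fit <- function(X, graph = NULL, R, lambda1 = 1, lambda2 = 1,
                     max_iter = 1000L, tol = 1e-5, seed = 1L,
                     init = c("random", "nndsvd"), eps = 1e-12) {
  init <- match.arg(init)
  X <- as.matrix(X)
  if (any(X < 0) || !all(is.finite(X))) stop("X must be non-negative and finite")
  n <- nrow(X); m <- ncol(X)
  if (R < 1 || R > min(n, m)) {
    stop("R must satisfy 1 <= R <= min(N, M) = ", min(n, m), ", got ", R)
  }
  if (lambda1 < 0 || lambda2 < 0 || tol < 0 || eps < 0) {
    stop("lambda1, lambda2, tol and eps must be non-negative")
  }
  if (lambda1 > 0) {
    if (is.null(graph)) stop("lambda1 > 0 requires a spot graph")
    if (graph$n_spots != m) {
      stop("graph has ", graph$n_spots, " spots but X has ", m, " columns")
    }
  }
  set.seed(seed)
  fac <- init_factors(X, R, init)
  W <- fac$W; H <- fac$H

  trace <- numeric(max_iter + 1L)
  trace[1L] <- fast_objective(X, W, H, graph, lambda1, lambda2)
  converged <- FALSE
  it <- 0L
  while (it < max_iter) {
    it <- it + 1L
    W <- fast_update_w(X, W, H, eps)
    H <- fast_update_h(X, W, H, graph, lambda1, lambda2, eps)
    obj <- fast_objective(X, W, H, graph, lambda1, lambda2)
    if (!is.finite(obj)) stop("objective became non-finite at iteration ", it)
    trace[it + 1L] <- obj
    prev <- trace[it]
    if (prev > 0 && abs(prev - obj) / prev < tol) {
      converged <- TRUE
      break
    }
  }
  dimnames(W) <- list(rownames(X), paste0("CT", seq_len(R)))
  dimnames(H) <- list(colnames(X), paste0("CT", seq_len(R)))
  structure(list(
    W = W, H = H,
    objective_trace = trace[seq_len(it + 1L)],
    n_iter = it, converged = converged,
    config = list(R = R, lambda1 = lambda1, lambda2 = lambda2,
                  max_iter = max_iter, tol = tol, seed = seed, init = init,
                  eps = eps)),
    class = "fast_fit")
}

#' @export
print.fast_fit <- function(x, ...) {
  cat("fast_fit: rank", x$config$R, "on", nrow(x$W), "genes x", nrow(x$H),
      "spots\n", " lambda1 =", x$config$lambda1, ", lambda2 =",
      x$config$lambda2, "\n ", x$n_iter, "iterations,",
      if (x$converged) "converged" else "max_iter reached",
      "; final objective", format(tail_value(x$objective_trace)), "\n")
  invisible(x)
}

tail_value <- function(v) v[length(v)]

#' Per-spot cell-type proportions
#'
#' Rows of H normalized to sum to one. The sum-to-one penalty encourages but
#' does not enforce unit row sums, so the reported proportions are the
#' row-normalized abundances; the raw H stays available in the fit object.
#' An all-zero row (no abundance mass at all) becomes the uniform vector
#' `1/R` with a warning.
#'
#' @param model a [fast_fit()] result, or a raw non-negative M x R matrix.
#' @return M x R row-stochastic matrix.
#' @export
spot_proportions <- function(model) {
  H <- if (inherits(model, "fast_fit")) model$H else as.matrix(model)
  if (any(H < 0)) stop("H must be non-negative")
  rs <- rowSums(H)
  zero <- rs == 0
  if (any(zero)) {
    warning(sum(zero), " all-zero row(s) in H set to the uniform proportion")
    H[zero, ] <- 1
    rs[zero] <- ncol(H)
  }
  H / rs
}
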