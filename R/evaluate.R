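#' Annotate inferred factors against reference signatures
#'
#' Each inferred factor (column of `W_est`) is assigned the reference cell
#' type whose signature column has the highest Pearson correlation with it.
#' The assignment is data-driven and may be many-to-one: several factors can
#' map to the same type. Correlation ties are broken by the lower reference
#' index; a zero-variance column makes its correlations `-Inf` with a
#' warning, so it never wins a tie.
#'
#' @param W_est N x R inferred signature matrix.
#' @param W_ref N x K reference signature matrix, same gene order.
#' @return integer vector of length R: reference type index per factor, with
#'   reference column names as names when available.
#' @export
annotate_factors <- function(W_est, W_ref) {
  W_est <- as.matrix(W_est); W_ref <- as.matrix(W_ref)
  if (nrow(W_est) != nrow(W_ref)) {
    stop("W_est and W_ref must share the same genes (rows)")
  }
  sd_e <- apply(W_est, 2, stats::sd)
  sd_r <- apply(W_ref, 2, stats::sd)
  if (any(sd_e == 0) || any(sd_r == 0)) {
    warning("zero-variance column(s); their correlations treated as -Inf")
  }
  C <- suppressWarnings(stats::cor(W_est, W_ref))
  C[!is.finite(C)] <- -Inf
  assign <- apply(C, 1L, which.max)  # which.max: first (lowest index) on ties
  stats::setNames(as.integer(assign),
                  colnames(W_est) %||% paste0("factor", seq_along(assign)))
}

# sum estimated proportion columns mapping to the same reference type;
# returns an M x K matrix aligned with the reference types (zero columns for
# types that received no factor)
collapse_by_assignment <- function(H_est, assignment, K) {
  m <- nrow(H_est)
  out <- matrix(0, m, K)
  for (r in seq_along(assignment)) {
    out[, assignment[r]] <- out[, assignment[r]] + H_est[, r]
  }
  out
}

#' Mean Pearson correlation of matched proportions
#'
#' The unweighted mean, over reference cell types, of the Pearson correlation
#' across spots between the estimated and true proportion columns. Estimated
#' factors assigned to the same type are summed first; a reference type with
#' no assigned factor (or a constant column, whose correlation is undefined)
#' contributes 0 to the mean, with a warning.
#'
#' @param H_est M x R estimated proportion matrix.
#' @param H_true M x K true proportion matrix.
#' @param assignment factor-to-type map from [annotate_factors()].
#' @return scalar in `[-1, 1]`.
#' @export
mean_pearson <- function(H_est, H_true, assignment) {
  H_est <- as.matrix(H_est); H_true <- as.matrix(H_true)
  check_assignment(assignment, ncol(H_est), ncol(H_true))
  M <- collapse_by_assignment(H_est, assignment, ncol(H_true))
  mean(per_type_pearson(M, H_true))
}

per_type_pearson <- function(M, H_true) {
  vapply(seq_len(ncol(H_true)), function(k) {
    if (stats::sd(M[, k]) == 0 || stats::sd(H_true[, k]) == 0) {
      warning("constant proportion column for type ", k,
              "; correlation recorded as 0")
      return(0)
    }
    stats::cor(M[, k], H_true[, k])
  }, numeric(1))
}

check_assignment <- function(assignment, R, K) {
  if (length(assignment) != R) {
    stop("assignment must map every one of the ", R, " factors")
  }
  if (any(assignment < 1L | assignment > K)) {
    stop("assignment refers to reference types outside 1..", K)
  }
  invisible(TRUE)
}

#' RMSE between matched proportion matrices
#'
#' Root-mean-square difference over all (spot, type) entries after mapping
#' estimated factors onto the reference types and row-normalizing both
#' matrices to proportions (rows that sum to zero are left at zero).
#'
#' @inheritParams mean_pearson
#' @param normalize row-normalize both matrices before comparing
#'   (default TRUE).
#' @return non-negative scalar.
#' @export
prop_rmse <- function(H_est, H_true, assignment, normalize = TRUE) {
  H_est <- as.matrix(H_est); H_true <- as.matrix(H_true)
  check_assignment(assignment, ncol(H_est), ncol(H_true))
  M <- collapse_by_assignment(H_est, assignment, ncol(H_true))
  if (normalize) {
    M <- row_normalize(M)
    H_true <- row_normalize(H_true)
  }
  if (!all(dim(M) == dim(H_true))) stop("matched matrices differ in shape")
  sqrt(mean((M - H_true)^2))
}

row_normalize <- function(A) {
  rs <- rowSums(A)
  rs[rs == 0] <- 1
  A / rs
}

#' Adjusted Rand index between two partitions
#'
#' Chance-corrected agreement; invariant to label naming on either side.
#'
#' @param a,b label vectors of equal length.
#' @return scalar, 1 for identical partitions, ~0 at chance.
#' @export
adjusted_rand_index <- function(a, b) {
  if (length(a) != length(b)) stop("partitions must have equal length")
  mclust::adjustedRandIndex(a, b)
}

#' ARI of K-means clusters of the proportion matrix
#'
#' Clusters the rows of H with K-means (10 restarts, seeded) and scores the
#' clustering against the true spot labels with the adjusted Rand index —
#' the downstream-clustering benchmark for deconvolution output.
#'
#' @param H M x R proportion (or abundance) matrix.
#' @param true_labels length-M vector of reference labels (e.g. regions).
#' @param k number of clusters (>= 2).
#' @param seed RNG seed for K-means.
#' @return scalar ARI.
#' @export
cluster_ari <- function(H, true_labels, k, seed = 1L) {
  H <- as.matrix(H)
  if (length(true_labels) != nrow(H)) stop("true_labels must have length nrow(H)")
  if (k < 2L) stop("k must be >= 2")
  if (k > nrow(H)) stop("k exceeds the number of spots")
  set.seed(seed)
  cl <- stats::kmeans(H, centers = k, nstart = 10L)$cluster
  adjusted_rand_index(cl, true_labels)
}

#' Score a fit against simulation ground truth
#'
#' Full evaluation: annotates factors by maximum correlation with the true
#' signatures, then computes the mean Pearson correlation and RMSE of the
#' matched proportions, and optionally the ARI of K-means clusters of H
#' against region labels.
#'
#' @param fit a [fast_fit()] result.
#' @param truth a `sim_dataset` (or list with `W_true`, `H_true`, optionally
#'   `region_labels`).
#' @param cluster_k if non-NULL, also compute [cluster_ari()] with this k.
#' @param seed seed for clustering.
#' @return list of class `fast_eval`: `assignment`, `per_type_pearson`,
#'   `mean_pearson`, `rmse`, `ari` (NA unless requested).
#' @export
evaluate_fit <- function(fit, truth, cluster_k = NULL, seed = 1L) {
  W_est <- if (inherits(fit, "fast_fit")) fit$W else fit$W
  H_est <- spot_proportions(fit)
  assign <- annotate_factors(W_est, truth$W_true)
  M <- collapse_by_assignment(H_est, assign, ncol(truth$H_true))
  ptp <- per_type_pearson(M, truth$H_true)
  ari <- NA_real_
  if (!is.null(cluster_k)) {
    if (is.null(truth$region_labels)) stop("truth has no region_labels for ARI")
    ari <- cluster_ari(H_est, truth$region_labels, cluster_k, seed)
  }
  structure(list(assignment = assign, per_type_pearson = ptp,
                 mean_pearson = mean(ptp),
                 rmse = prop_rmse(H_est, truth$H_true, assign),
                 ari = ari),
            class = "fast_eval")
}

#' @export
print.fast_eval <- function(x, ...) {
  cat("fast_eval: mean Pearson =", round(x$mean_pearson, 4),
      ", RMSE =", round(x$rmse, 4),
      if (!is.na(x$ari)) paste(", ARI =", round(x$ari, 4)) else "", "\n")
  invisible(x)
}
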