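#' Scan candidate ranks
#'
#' Fits the model at each candidate rank with several seeded random restarts
#' and records, per rank: the best (smallest) final reconstruction error
#' `||X - WH'||_F`, the explained variance `1 - err^2 / ||X||_F^2`, and a
#' restart-stability score — the mean over restart pairs of the mean absolute
#' Pearson correlation between greedily matched W columns. High stability
#' plus an elbow in the error curve indicates a well-supported rank.
#'
#' @inheritParams fast_fit
#' @param ranks integer vector of candidate ranks.
#' @param restarts number of seeded restarts per rank (>= 1).
#' @param ... further arguments passed to [fast_fit()] (`lambda1`,
#'   `lambda2`, `max_iter`, `tol`, ...).
#' @return An object of class `rank_scan`: data frame with columns `rank`,
#'   `recon_error`, `explained_var`, `stability`.
#' @export
scan_ranks <- function(X, graph = NULL, ranks, restarts = 3L, seed = 1L, ...) {
  if (length(ranks) == 0L) stop("ranks must be a non-empty integer vector")
  X <- as.matrix(X)
  xnorm2 <- sum(X^2)
  rows <- lapply(ranks, function(R) {
    fits <- lapply(seq_len(restarts), function(s) {
      fast_fit(X, graph, R = R, seed = seed + (s - 1L) * 1000L + R, ...)
    })
    errs <- vapply(fits, function(f) sqrt(sum((X - tcrossprod(f$W, f$H))^2)),
                   numeric(1))
    best <- min(errs)
    stab <- if (restarts == 1L) 1 else {
      pairs <- utils::combn(restarts, 2)
      mean(apply(pairs, 2, function(p) {
        matched_column_agreement(fits[[p[1]]]$W, fits[[p[2]]]$W)
      }))
    }
    data.frame(rank = R, recon_error = best,
               explained_var = 1 - best^2 / xnorm2, stability = stab)
  })
  structure(do.call(rbind, rows), class = c("rank_scan", "data.frame"))
}

# greedy one-to-one matching of columns by |Pearson|, mean matched |cor|
matched_column_agreement <- function(A, B) {
  R <- ncol(A)
  if (R == 1L) return(abs(safe_cor(A[, 1], B[, 1])))
  C <- abs(stats::cor(A, B))
  C[!is.finite(C)] <- 0
  out <- numeric(R)
  for (r in seq_len(R)) {
    idx <- arrayInd(which.max(C), dim(C))
    out[r] <- C[idx[1], idx[2]]
    C[idx[1], ] <- -Inf
    C[, idx[2]] <- -Inf
  }
  mean(out)
}

safe_cor <- function(a, b) {
  if (stats::sd(a) == 0 || stats::sd(b) == 0) return(0)
  stats::cor(a, b)
}

#' Suggest a rank from a scan
#'
#' Elbow criterion on the reconstruction-error curve: the candidate rank whose
#' point has the maximum perpendicular distance to the chord joining the first
#' and last points of the curve. Invariant to affine rescaling of either axis
#' relative ordering; ties are broken by the smaller rank.
#'
#' @param result a `rank_scan` from [scan_ranks()], or any data frame with
#'   columns `rank` and `recon_error` (>= 3 rows).
#' @return integer, the suggested rank.
#' @export
suggest_rank <- function(result) {
  if (nrow(result) < 3L) stop("need at least 3 scanned ranks to locate an elbow")
  r <- as.numeric(result$rank)
  e <- as.numeric(result$recon_error)
  # normalize both axes so the chord geometry is scale-free
  rn <- (r - r[1]) / (r[length(r)] - r[1])
  en <- (e - e[1]) / if (e[length(e)] != e[1]) (e[length(e)] - e[1]) else 1
  # distance from (rn, en) to the line through (0,0) and (1,1): |rn - en| / sqrt(2);
  # endpoints lie on the chord, so only interior ranks are elbow candidates
  d <- abs(rn - en)
  interior <- seq(2L, length(d) - 1L)
  result$rank[interior[which.max(d[interior])]]  # first maximum: smaller rank
}
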