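#' Read a gene x spot count matrix
#'
#' Supported formats: Matrix Market (`.mtx`, with plain-text sidecar files
#' `<path>.rownames` and `<path>.colnames`, one identifier per line) and
#' dense CSV/TSV with gene identifiers in the first column and spot
#' identifiers in the header. Genes are rows, spots columns. Negative
#' entries are rejected with their coordinates; all-zero rows and columns
#' are dropped with a message.
#'
#' @param path input file.
#' @param format `"auto"` (by extension), `"mtx"`, `"csv"` or `"tsv"`.
#' @return numeric matrix with gene rownames and spot colnames.
#' @export
read_counts <- function(path, format = c("auto", "mtx", "csv", "tsv")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("counts file not found: ", path)
  if (format == "auto") {
    format <- switch(tolower(tools::file_ext(path)),
                     mtx = "mtx", csv = "csv", tsv = "tsv", txt = "tsv",
                     stop("cannot infer format from extension of ", path))
  }
  if (format == "mtx") {
    X <- as.matrix(Matrix::readMM(path))
    rn <- paste0(path, ".rownames"); cn <- paste0(path, ".colnames")
    if (!file.exists(rn) || !file.exists(cn)) {
      stop("missing sidecar name files ", rn, " / ", cn)
    }
    rownames(X) <- readLines(rn)
    colnames(X) <- readLines(cn)
    if (nrow(X) != length(rownames(X)) || ncol(X) != length(colnames(X))) {
      stop("sidecar name files do not match the matrix dimensions")
    }
  } else {
    sep <- if (format == "csv") "," else "\t"
    df <- utils::read.table(path, header = TRUE, sep = sep, row.names = 1,
                            check.names = FALSE)
    X <- as.matrix(df)
  }
  storage.mode(X) <- "double"
  validate_counts(X)
}

validate_counts <- function(X) {
  if (!all(is.finite(X))) stop("counts contain non-finite values")
  neg <- which(X < 0, arr.ind = TRUE)
  if (nrow(neg) > 0) {
    stop("negative entry at gene '", rownames(X)[neg[1, 1]] %||% neg[1, 1],
         "', spot '", colnames(X)[neg[1, 2]] %||% neg[1, 2], "'")
  }
  zr <- rowSums(X) == 0; zc <- colSums(X) == 0
  if (any(zr)) {
    message("dropping ", sum(zr), " all-zero gene row(s)")
    X <- X[!zr, , drop = FALSE]
  }
  if (any(zc)) {
    message("dropping ", sum(zc), " all-zero spot column(s)")
    X <- X[, !zc, drop = FALSE]
  }
  X
}

#' Write a count matrix
#'
#' Inverse of [read_counts()]: Matrix Market plus `.rownames`/`.colnames`
#' sidecars, or dense CSV/TSV with gene ids in the first column.
#'
#' @param X gene x spot matrix with dimnames.
#' @param path output file; format chosen as in [read_counts()].
#' @param format see [read_counts()].
#' @export
write_counts <- function(X, path, format = c("auto", "mtx", "csv", "tsv")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- switch(tolower(tools::file_ext(path)),
                     mtx = "mtx", csv = "csv", tsv = "tsv", txt = "tsv",
                     stop("cannot infer format from extension of ", path))
  }
  if (format == "mtx") {
    Matrix::writeMM(methods::as(Matrix::Matrix(X, sparse = TRUE), "CsparseMatrix"),
                    path)
    writeLines(rownames(X), paste0(path, ".rownames"))
    writeLines(colnames(X), paste0(path, ".colnames"))
  } else {
    sep <- if (format == "csv") "," else "\t"
    df <- data.frame(gene = rownames(X), X, check.names = FALSE)
    utils::write.table(df, path, sep = sep, quote = FALSE, row.names = FALSE)
  }
  invisible(path)
}

#' Select highly variable genes
#'
#' Ranks genes by standardized log dispersion: per-gene dispersion
#' `var/mean` on the raw scale, log-transformed, then z-scored within 20
#' equal-frequency bins of log mean expression so the score is comparable
#' across expression strata. Deterministic; ties broken by gene order.
#'
#' @param X gene x spot matrix.
#' @param n number of genes to keep (`n <= nrow(X)`).
#' @return integer vector of the selected gene row indices, in rank order.
#' @export
select_variable_genes <- function(X, n) {
  N <- nrow(X)
  if (n > N) stop("n = ", n, " exceeds the number of genes ", N)
  mu <- rowMeans(X)
  v <- apply(X, 1L, stats::var)
  disp <- ifelse(mu > 0, v / mu, 0)
  ldisp <- log1p(disp)
  lmu <- log1p(mu)
  n_bins <- max(1L, min(20L, N %/% 5L))  # keep several genes per bin
  bins <- cut(rank(lmu, ties.method = "first"), breaks = n_bins, labels = FALSE)
  score <- ldisp
  for (b in unique(bins)) {
    idx <- bins == b
    s <- stats::sd(ldisp[idx])
    score[idx] <- if (is.na(s) || s == 0) 0 else (ldisp[idx] - mean(ldisp[idx])) / s
  }
  order(-score, seq_len(N))[seq_len(n)]
}

#' Write fit results to a directory
#'
#' W and H as CSV with identifiers, the objective trace as CSV, proportions
#' as CSV, and run metadata (config, iterations, final objective, package
#' version) as JSON.
#'
#' @param fit a [fast_fit()].
#' @param dir output directory (created if absent).
#' @export
write_fit <- function(fit, dir) {
  stopifnot(inherits(fit, "fast_fit"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(data.frame(gene = rownames(fit$W) %||%
                                paste0("g", seq_len(nrow(fit$W))), fit$W,
                              check.names = FALSE),
                   file.path(dir, "W.csv"), row.names = FALSE, quote = FALSE)
  utils::write.csv(data.frame(spot = rownames(fit$H) %||%
                                paste0("spot", seq_len(nrow(fit$H))), fit$H,
                              check.names = FALSE),
                   file.path(dir, "H.csv"), row.names = FALSE, quote = FALSE)
  utils::write.csv(data.frame(iteration = seq_along(fit$objective_trace) - 1L,
                              objective = fit$objective_trace),
                   file.path(dir, "objective_trace.csv"), row.names = FALSE,
                   quote = FALSE)
  P <- spot_proportions(fit)
  utils::write.csv(data.frame(spot = rownames(fit$H) %||%
                                paste0("spot", seq_len(nrow(P))), P,
                              check.names = FALSE),
                   file.path(dir, "proportions.csv"), row.names = FALSE,
                   quote = FALSE)
  meta <- c(fit$config,
            list(n_iter = fit$n_iter, converged = fit$converged,
                 final_objective = fit$objective_trace[length(fit$objective_trace)],
                 package_version = as.character(utils::packageVersion("fastdeconv"))))
  jsonlite::write_json(meta, file.path(dir, "run.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(dir)
}

#' Run the full deconvolution pipeline
#'
#' Graph construction, model fitting and (when ground truth is supplied)
#' evaluation, with all outputs, the resolved configuration and the seed
#' written to `out_dir`.
#'
#' @param X gene x spot matrix (or path readable by [read_counts()]).
#' @param coords data frame with `spot_id`, `x`, `y` (or a path for
#'   [read_spot_coords()]); order must match the columns of X.
#' @param out_dir output directory.
#' @param R rank.
#' @param intensity optional per-spot grey intensity vector.
#' @param k,graph_mode,beta graph options, see [build_spot_graph()].
#' @param truth optional `sim_dataset` ground truth; triggers evaluation.
#' @param cluster_k optional K for the clustering ARI.
#' @param ... solver options passed to [fast_fit()].
#' @param seed seed passed to the solver (and clustering).
#' @return invisible list with `graph`, `fit` and (optionally) `eval`.
#' @export
run_pipeline <- function(X, coords, out_dir, R, intensity = NULL, k = 5L,
                         graph_mode = "binary", beta = "auto", truth = NULL,
                         cluster_k = NULL, seed = 1L, ...) {
  if (is.character(X)) X <- read_counts(X)
  if (is.character(coords)) coords <- read_spot_coords(coords)
  if (!identical(as.character(coords$spot_id), colnames(X))) {
    stop("spot order in the coordinate table does not match the count matrix columns")
  }
  geom <- spot_geometry(coords$spot_id, coords$x, coords$y, z = intensity)
  graph <- build_spot_graph(geom, k = k, mode = graph_mode, beta = beta)
  fit <- fast_fit(X, graph, R = R, seed = seed, ...)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  write_fit(fit, out_dir)
  write_graph_edges(graph, file.path(out_dir, "graph_edges.tsv"))
  res <- list(graph = graph, fit = fit)
  if (!is.null(truth)) {
    ev <- evaluate_fit(fit, truth, cluster_k = cluster_k, seed = seed)
    jsonlite::write_json(
      list(mean_pearson = ev$mean_pearson, rmse = ev$rmse, ari = ev$ari,
           assignment = as.list(ev$assignment),
           per_type_pearson = ev$per_type_pearson),
      file.path(out_dir, "report.json"), auto_unbox = TRUE, digits = NA,
      pretty = TRUE)
    res$eval <- ev
  }
  invisible(res)
}
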