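#' Simulation design: regions, spot counts and Dirichlet parameters
#'
#' Describes a layered tissue whose spots draw their cell-type composition
#' from a region-specific Dirichlet distribution. The default construction
#' mirrors a mouse-olfactory-bulb-like slide with concentric layers.
#'
#' @param regions list of regions, each a list with `name`, `n_spots`
#'   (integer >= 1) and `alpha` (positive Dirichlet parameter vector over the
#'   cell types, all the same length).
#' @param n_genes number of genes simulated.
#' @param n_cell_types number of cell types; must match the alpha lengths.
#' @param cells_per_spot number of single cells pooled into each spot.
#' @param marker_fraction fraction of genes reserved for type-specific marker
#'   blocks, in (0, 1).
#' @param effect_size fold elevation of a marker gene's mean in its own type.
#' @param dispersion negative-binomial dispersion of per-cell counts
#'   (`size = 1/dispersion`).
#' @return An object of class `sim_design` (a list of the above).
#' @seealso [mob_table1_design()] for the built-in three-layer preset.
#' @export
sim_design <- function(regions, n_genes = 500L, n_cell_types = 2L,
                       cells_per_spot = 10L, marker_fraction = 0.2,
                       effect_size = 4, dispersion = 0.5) {
  for (rg in regions) {
    if (is.null(rg$name) || is.null(rg$n_spots) || is.null(rg$alpha)) {
      stop("each region needs name, n_spots and alpha")
    }
    if (rg$n_spots < 1L) stop("region ", rg$name, " has n_spots < 1")
    if (length(rg$alpha) != n_cell_types || any(rg$alpha <= 0)) {
      stop("region ", rg$name, " alpha must be length ", n_cell_types,
           " with positive entries")
    }
  }
  if (marker_fraction <= 0 || marker_fraction >= 1) {
    stop("marker_fraction must lie in (0, 1)")
  }
  structure(list(regions = regions, n_genes = as.integer(n_genes),
                 n_cell_types = as.integer(n_cell_types),
                 cells_per_spot = as.integer(cells_per_spot),
                 marker_fraction = marker_fraction,
                 effect_size = effect_size, dispersion = dispersion),
            class = "sim_design")
}

#' Three-layer olfactory-bulb-style design
#'
#' The layered two-cell-type benchmark design: 75 granule-layer spots with
#' Dirichlet alpha = (1, 3) (second type, "astrocytes", dominant), 140
#' mitral-layer spots with alpha = (3, 1) ("neurons" dominant), and 45
#' nerve-layer spots with alpha = (1, 1) (balanced); 260 spots in total,
#' laid out as concentric annuli (granule innermost, nerve outermost).
#'
#' @inheritParams sim_design
#' @param ... further arguments passed to [sim_design()].
#' @return a `sim_design`.
#' @export
mob_table1_design <- function(n_genes = 500L, cells_per_spot = 10L,
                              marker_fraction = 0.2, effect_size = 4, ...) {
  sim_design(
    regions = list(
      list(name = "granule", n_spots = 75L, alpha = c(1, 3)),
      list(name = "mitral",  n_spots = 140L, alpha = c(3, 1)),
      list(name = "nerve",   n_spots = 45L, alpha = c(1, 1))),
    n_genes = n_genes, n_cell_types = 2L, cells_per_spot = cells_per_spot,
    marker_fraction = marker_fraction, effect_size = effect_size, ...)
}

#' Synthetic cell-type mean signatures
#'
#' Baseline per-cell gene means are drawn from a log-normal; each cell type
#' then receives a disjoint block of `floor(marker_fraction * n_genes /
#' n_cell_types)` marker genes whose means are multiplied by `effect_size`.
#' With `effect_size = 1` all types share an identical profile.
#'
#' @inheritParams sim_design
#' @param seed RNG seed.
#' @param meanlog,sdlog log-normal parameters of the baseline means.
#' @return list with `W_true` (n_genes x n_cell_types mean matrix, genes
#'   named `g1..`, types `type1..`), `marker_blocks` (list of marker index
#'   vectors per type) and `dispersion`.
#' @export
make_signatures <- function(n_genes, n_cell_types, marker_fraction = 0.2,
                            effect_size = 4, seed = 1L, dispersion = 0.5,
                            meanlog = 0, sdlog = 1) {
  block <- floor(marker_fraction * n_genes / n_cell_types)
  if (block * n_cell_types > n_genes) stop("marker blocks exceed n_genes")
  set.seed(seed)
  base <- stats::rlnorm(n_genes, meanlog = meanlog, sdlog = sdlog)
  W <- matrix(base, n_genes, n_cell_types)
  blocks <- vector("list", n_cell_types)
  for (k in seq_len(n_cell_types)) {
    idx <- if (block > 0) ((k - 1L) * block + 1L):(k * block) else integer(0)
    blocks[[k]] <- idx
    W[idx, k] <- W[idx, k] * effect_size
  }
  dimnames(W) <- list(paste0("g", seq_len(n_genes)),
                      paste0("type", seq_len(n_cell_types)))
  list(W_true = W, marker_blocks = blocks, dispersion = dispersion)
}

# draw one Dirichlet vector
rdirichlet1 <- function(alpha) {
  g <- stats::rgamma(length(alpha), shape = alpha, rate = 1)
  if (sum(g) == 0) g <- alpha  # vanishing gamma draws at tiny alpha
  g / sum(g)
}

#' Simulate a spatial transcriptomics dataset with known ground truth
#'
#' For every spot: draw cell-type proportions from its region's Dirichlet,
#' assign `cells_per_spot` cells to types multinomially, draw each cell's
#' counts from a negative binomial around its type's mean profile, and sum
#' the cells into the spot's expression vector (a sum of `n` i.i.d.
#' NB(mu, size) cells is drawn in one step as NB(n mu, n size)). The true
#' proportion matrix records the realized cell-count fractions. Spots are
#' placed uniformly in concentric annuli (one per region, in region order,
#' innermost first) and given a region-specific synthetic grey intensity so
#' the histology term of the graph is exercisable.
#'
#' @param design a [sim_design()].
#' @param signatures from [make_signatures()]; must match `design$n_genes`
#'   and `design$n_cell_types`.
#' @param seed RNG seed; the same seed reproduces the dataset bit-identically.
#' @param intensity_levels per-region mean grey intensity (recycled).
#' @param intensity_sd spot-level Gaussian noise on the intensity.
#' @return list of class `sim_dataset` with `X` (genes x spots integer
#'   counts), `H_true` (spots x types, rows sum to 1), `W_true`, `geometry`
#'   (a [spot_geometry()] with synthetic `z`), `region_labels`, `design`.
#' @export
simulate_dataset <- function(design, signatures, seed = 1L,
                             intensity_levels = c(0.35, 0.60, 0.85),
                             intensity_sd = 0.03) {
  stopifnot(inherits(design, "sim_design"))
  W <- signatures$W_true
  if (nrow(W) != design$n_genes || ncol(W) != design$n_cell_types) {
    stop("signatures do not match the design dimensions")
  }
  size0 <- 1 / signatures$dispersion
  set.seed(seed)
  n_reg <- length(design$regions)
  m <- sum(vapply(design$regions, `[[`, integer(1), "n_spots"))
  K <- design$n_cell_types
  X <- matrix(0L, design$n_genes, m)
  H <- matrix(0, m, K)
  xs <- ys <- zs <- numeric(m)
  labels <- character(m)
  levels <- rep_len(intensity_levels, n_reg)
  # concentric annuli of equal width on a disc of radius 10
  bounds <- seq(0, 10, length.out = n_reg + 1L)
  j <- 0L
  for (ri in seq_len(n_reg)) {
    rg <- design$regions[[ri]]
    for (s in seq_len(rg$n_spots)) {
      j <- j + 1L
      p <- rdirichlet1(rg$alpha)
      ncells <- as.integer(stats::rmultinom(1, design$cells_per_spot, p))
      H[j, ] <- ncells / design$cells_per_spot
      xv <- numeric(design$n_genes)
      for (k in seq_len(K)) {
        if (ncells[k] > 0) {
          xv <- xv + stats::rnbinom(design$n_genes,
                                    mu = ncells[k] * W[, k],
                                    size = ncells[k] * size0)
        }
      }
      X[, j] <- as.integer(xv)
      rr <- sqrt(stats::runif(1, bounds[ri]^2, bounds[ri + 1L]^2))
      th <- stats::runif(1, 0, 2 * pi)
      xs[j] <- rr * cos(th); ys[j] <- rr * sin(th)
      zs[j] <- min(1, max(0, stats::rnorm(1, levels[ri], intensity_sd)))
      labels[j] <- rg$name
    }
  }
  ids <- paste0("spot", seq_len(m))
  dimnames(X) <- list(rownames(W), ids)
  dimnames(H) <- list(ids, colnames(W))
  structure(list(X = X, H_true = H, W_true = W,
                 geometry = spot_geometry(ids, xs, ys, zs),
                 region_labels = labels, design = design, seed = seed),
            class = "sim_dataset")
}

#' Wilcoxon rank-sum DE gene filter
#'
#' Mimics the marker-gene preselection applied to a single-cell pool before
#' building spots: per gene, a two-sample Wilcoxon rank-sum test between cell
#' types (one-vs-rest when more than two types are present, keeping the
#' smallest p), Benjamini-Hochberg adjustment, and retention of genes with
#' adjusted p below `alpha_cutoff`. The test uses the normal approximation
#' with tie correction and continuity correction (the large-sample form of
#' `stats::wilcox.test`), vectorized across genes.
#'
#' @param cell_matrix genes x cells count matrix.
#' @param cell_labels cell-type label per cell (length = ncol).
#' @param alpha_cutoff adjusted-p threshold (default 1e-5).
#' @return integer vector of retained gene row indices.
#' @export
de_gene_filter <- function(cell_matrix, cell_labels, alpha_cutoff = 1e-5) {
  cell_labels <- as.character(cell_labels)
  types <- unique(cell_labels)
  if (length(types) < 2L) stop("need at least 2 cell types")
  tab <- table(cell_labels)
  if (any(tab < 2L)) {
    stop("cell type(s) with fewer than 2 cells: ",
         paste(names(tab)[tab < 2L], collapse = ", "))
  }
  groups <- if (length(types) == 2L) list(cell_labels == types[1L]) else {
    lapply(types, function(tp) cell_labels == tp)  # one vs rest
  }
  pmin_mat <- vapply(groups, function(in1) {
    wilcox_rank_sum_rows(cell_matrix, in1)
  }, numeric(nrow(cell_matrix)))
  p <- if (is.matrix(pmin_mat)) apply(pmin_mat, 1L, min) else pmin_mat
  padj <- stats::p.adjust(p, method = "BH")
  which(padj < alpha_cutoff)
}

# row-wise two-sample Wilcoxon rank-sum p-values, normal approximation with
# tie correction and continuity correction (wilcox.test exact = FALSE)
wilcox_rank_sum_rows <- function(mat, in_group1) {
  n1 <- sum(in_group1); n2 <- sum(!in_group1); n <- n1 + n2
  apply(mat, 1L, function(v) {
    r <- rank(v)
    U <- sum(r[in_group1]) - n1 * (n1 + 1) / 2
    ties <- table(v)
    tiecor <- sum(ties^3 - ties) / (n * (n - 1))
    sigma2 <- (n1 * n2 / 12) * (n + 1 - tiecor)
    if (sigma2 <= 0) return(1)
    z <- U - n1 * n2 / 2
    z <- sign(z) * max(0, abs(z) - 0.5)  # continuity correction
    2 * stats::pnorm(-abs(z) / sqrt(sigma2))
  })
}

#' Simulate a single-cell pool from signatures
#'
#' Draws `cells_per_type` cells per type with NB counts around the type mean
#' profile — the pool on which [de_gene_filter()] operates before spots are
#' assembled.
#'
#' @inheritParams simulate_dataset
#' @param cells_per_type number of cells per type.
#' @return list with `counts` (genes x cells) and `labels`.
#' @export
simulate_cell_pool <- function(signatures, cells_per_type = 100L, seed = 1L) {
  W <- signatures$W_true
  size0 <- 1 / signatures$dispersion
  K <- ncol(W); G <- nrow(W)
  set.seed(seed)
  counts <- matrix(0L, G, K * cells_per_type)
  labels <- rep(colnames(W), each = cells_per_type)
  for (k in seq_len(K)) {
    cols <- ((k - 1L) * cells_per_type + 1L):(k * cells_per_type)
    counts[, cols] <- stats::rnbinom(G * cells_per_type,
                                     mu = W[, k], size = size0)
  }
  rownames(counts) <- rownames(W)
  list(counts = counts, labels = labels)
}

#' One-call simulation study dataset
#'
#' The full generative pipeline: synthetic signatures, a single-cell pool,
#' the Wilcoxon DE-gene filter on the pool, and spot assembly restricted to
#' the retained genes — i.e. the layered-tissue benchmark with marker
#' preselection applied, ready for [fast_fit()].
#'
#' @param design a [sim_design()]; default [mob_table1_design()].
#' @param seed RNG seed governing every stage.
#' @param de_filter apply the DE-gene filter (default TRUE).
#' @param cells_per_type pool size per type for the filter.
#' @param alpha_cutoff adjusted-p cutoff for the filter.
#' @return a `sim_dataset` (see [simulate_dataset()]); genes are the
#'   retained subset when `de_filter` is on.
#' @export
simulate_study <- function(design = mob_table1_design(), seed = 1L,
                           de_filter = TRUE, cells_per_type = 100L,
                           alpha_cutoff = 1e-5) {
  sig <- make_signatures(design$n_genes, design$n_cell_types,
                         design$marker_fraction, design$effect_size,
                         seed = seed, dispersion = design$dispersion)
  if (de_filter) {
    pool <- simulate_cell_pool(sig, cells_per_type, seed = seed + 1L)
    keep <- de_gene_filter(pool$counts, pool$labels, alpha_cutoff)
    if (length(keep) < 2L) {
      warning("DE filter retained ", length(keep), " gene(s); keeping all genes")
    } else {
      sig$W_true <- sig$W_true[keep, , drop = FALSE]
      design$n_genes <- length(keep)
    }
  }
  simulate_dataset(design, sig, seed = seed + 2L)
}
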