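# Independent brute-force oracles, deliberately written with loops and
# explicit matrices so they share no code path with the package.

# plain Frobenius multiplicative-update NMF (Lee-Seung), one sweep
plain_nmf_step <- function(X, W, H, eps = 1e-12) {
  Ht <- t(H)
  W <- W * (X %*% t(Ht)) / (W %*% Ht %*% t(Ht) + eps)
  Ht <- Ht * (t(W) %*% X) / (t(W) %*% W %*% Ht + eps)
  list(W = W, H = t(Ht))
}

plain_nmf <- function(X, R, seed, n_iter, eps = 1e-12) {
  set.seed(seed)
  W <- matrix(runif(nrow(X) * R), nrow(X), R)
  H <- matrix(runif(ncol(X) * R), ncol(X), R)
  Ws <- vector("list", n_iter); Hs <- vector("list", n_iter)
  for (it in seq_len(n_iter)) {
    st <- plain_nmf_step(X, W, H, eps)
    W <- st$W; H <- st$H
    Ws[[it]] <- W; Hs[[it]] <- H
  }
  list(W = W, H = H, W_trace = Ws, H_trace = Hs)
}

# objective with the all-ones matrices J (R x M) and J_M (M x M) materialized
objective_explicit <- function(X, W, H, G = NULL, lambda1 = 0, lambda2 = 0) {
  R <- ncol(H); M <- nrow(H)
  val <- sum((X - W %*% t(H))^2)
  if (lambda1 > 0) {
    D <- diag(rowSums(as.matrix(G)))
    L <- D - as.matrix(G)
    val <- val + lambda1 * sum(diag(t(H) %*% L %*% H))
  }
  if (lambda2 > 0) {
    J <- matrix(1, R, M)
    JM <- matrix(1, M, M)
    val <- val + lambda2 * sum((H %*% J - JM)^2)
  }
  val
}

# 1/2 sum_jl G_jl ||h_j - h_l||^2 by double loop
laplacian_quadratic_loop <- function(H, G) {
  G <- as.matrix(G)
  s <- 0
  for (j in seq_len(nrow(H))) for (l in seq_len(nrow(H))) {
    s <- s + G[j, l] * sum((H[j, ] - H[l, ])^2)
  }
  s / 2
}

# median over the clipped window by explicit index enumeration
median_window_brute <- function(image, r, c, window) {
  half <- (window - 1) / 2
  vals <- c()
  for (i in (r - half):(r + half)) for (j in (c - half):(c + half)) {
    if (i >= 1 && i <= nrow(image) && j >= 1 && j <= ncol(image)) {
      vals <- c(vals, image[i, j])
    }
  }
  median(vals)
}

# random small spot geometry
random_geometry <- function(m, with_z = TRUE, seed = 1) {
  set.seed(seed)
  spot_geometry(paste0("s", seq_len(m)),
                x = runif(m, 0, 10), y = runif(m, 0, 10),
                z = if (with_z) runif(m) else NULL)
}

random_graph <- function(m, k = 3, seed = 1, mode = "binary") {
  g <- random_geometry(m, seed = seed)
  build_spot_graph(g, k = min(k, m - 1), mode = mode)
}
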