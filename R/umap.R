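# In-package UMAP (uniform manifold approximation and projection).
#
# Standard construction: per-point smooth kNN kernel (local connectivity 1,
# bandwidth found by bisection so the kernel mass equals log2(k)), fuzzy
# union symmetrization, spectral initialisation from the normalized graph
# Laplacian, then stochastic gradient descent on the fuzzy cross-entropy with
# negative sampling. All randomness is confined to the SGD phase and driven
# by the explicit seed, so a fixed seed on a fixed input reproduces the
# embedding bit-for-bit.

#' UMAP embedding of samples
#'
#' Embeds the sample columns of a beta matrix into two dimensions. The
#' default seed of 15 is the package's reference setting for episignature
#' visualisation; `n_neighbors` defaults to `min(15, n_samples - 1)`.
#'
#' @param x a [beta_matrix], or a samples-by-features numeric matrix.
#' @param seed integer RNG seed; the embedding is deterministic given the
#'   seed and the input.
#' @param n_neighbors local neighborhood size (2 <= n_neighbors < n_samples).
#' @param min_dist minimum spacing of embedded points (default 0.1).
#' @param n_epochs SGD epochs (default 200).
#' @param negative_sample_rate repulsive samples per attractive update.
#' @return A `beta_embedding` with `method = "umap"`, the seed, and the
#'   effective parameters (including the fitted output-kernel coefficients
#'   `a`, `b`).
#' @export
umap_embed <- function(x, seed = 15, n_neighbors = NULL, min_dist = 0.1,
                       n_epochs = 200, negative_sample_rate = 5) {
  pts <- embedding_input(x)
  n <- nrow(pts)
  if (n < 4) {
    stop("UMAP needs at least 4 samples; use beta_mds() for smaller sets")
  }
  if (is.null(n_neighbors)) n_neighbors <- min(15, n - 1)
  if (n_neighbors >= n) stop("n_neighbors must be smaller than the number of samples")
  n_neighbors <- max(2L, as.integer(n_neighbors))

  D <- as.matrix(stats::dist(pts))
  W <- fuzzy_graph(D, n_neighbors)
  ab <- find_ab(min_dist)
  init <- spectral_init(W)

  coords <- with_seed(seed, optimize_layout(
    init, W, a = ab[1], b = ab[2], n_epochs = n_epochs,
    negative_sample_rate = negative_sample_rate))
  rownames(coords) <- rownames(pts)
  new_embedding("umap", coords, seed,
                list(n_neighbors = n_neighbors, min_dist = min_dist,
                     n_epochs = n_epochs, a = ab[1], b = ab[2],
                     negative_sample_rate = negative_sample_rate))
}

# Smooth-kNN membership strengths, symmetrized by fuzzy union.
fuzzy_graph <- function(D, k) {
  n <- nrow(D)
  P <- matrix(0, n, n)
  target <- log2(k)
  for (i in seq_len(n)) {
    d <- D[i, -i]
    nn <- order(d)[seq_len(k)]
    dn <- d[nn]
    rho <- if (any(dn > 0)) min(dn[dn > 0]) else 0
    sigma <- smooth_knn_sigma(dn, rho, target)
    w <- exp(-pmax(0, dn - rho) / sigma)
    idx <- seq_len(n)[-i][nn]
    P[i, idx] <- w
  }
  P + t(P) - P * t(P)
}

smooth_knn_sigma <- function(dn, rho, target) {
  lo <- 0; hi <- Inf; mid <- 1
  for (iter in 1:64) {
    val <- sum(exp(-pmax(0, dn - rho) / mid))
    if (abs(val - target) < 1e-5) break
    if (val > target) {
      hi <- mid; mid <- (lo + hi) / 2
    } else {
      lo <- mid
      mid <- if (is.finite(hi)) (lo + hi) / 2 else mid * 2
    }
  }
  max(mid, 1e-10)
}

# Least-squares fit of the output kernel 1 / (1 + a d^(2b)) to the target
# piecewise curve defined by min_dist (spread fixed at 1).
find_ab <- function(min_dist, spread = 1) {
  xs <- seq(1e-3, 3 * spread, length.out = 300)
  ys <- ifelse(xs < min_dist, 1, exp(-(xs - min_dist) / spread))
  obj <- function(p) {
    a <- exp(p[1]); b <- exp(p[2])
    sum((1 / (1 + a * xs^(2 * b)) - ys)^2)
  }
  fit <- stats::optim(c(0, 0), obj, method = "Nelder-Mead",
                      control = list(maxit = 500, reltol = 1e-10))
  exp(fit$par)
}

# Eigenvectors of the symmetric normalized Laplacian for the two smallest
# non-trivial eigenvalues, rescaled to a [-10, 10] box. Deterministic; axis
# signs fixed as in classical MDS.
spectral_init <- function(W) {
  n <- nrow(W)
  deg <- pmax(rowSums(W), 1e-8)
  Dh <- 1 / sqrt(deg)
  L <- diag(n) - (Dh %o% Dh) * W
  ev <- eigen((L + t(L)) / 2, symmetric = TRUE)
  take <- c(n - 1L, n - 2L)  # columns sorted by decreasing eigenvalue
  init <- ev$vectors[, take, drop = FALSE]
  init <- fix_axis_signs(init)
  scale_f <- max(abs(init))
  if (scale_f > 0) init <- init / scale_f * 10
  init
}

optimize_layout <- function(coords, W, a, b, n_epochs, negative_sample_rate) {
  n <- nrow(coords)
  eps <- which(upper.tri(W) & W > 0, arr.ind = TRUE)
  w <- W[eps]
  if (length(w) == 0) return(coords)
  eps_per_sample <- max(w) / w
  next_sample <- eps_per_sample
  clip4 <- function(v) pmax(pmin(v, 4), -4)

  for (epoch in seq_len(n_epochs)) {
    alpha <- 1 - (epoch - 1) / n_epochs
    due <- which(next_sample <= epoch)
    for (e in due) {
      h <- eps[e, 1]; t_ <- eps[e, 2]
      diff <- coords[h, ] - coords[t_, ]
      d2 <- sum(diff^2)
      if (d2 > 0) {
        gc <- (-2 * a * b * d2^(b - 1)) / (1 + a * d2^b)
        g <- clip4(gc * diff) * alpha
        coords[h, ] <- coords[h, ] + g
        coords[t_, ] <- coords[t_, ] - g
      }
      for (s in seq_len(negative_sample_rate)) {
        j <- sample.int(n, 1)
        if (j == h) next
        diff <- coords[h, ] - coords[j, ]
        d2 <- sum(diff^2)
        gc <- (2 * b) / ((0.001 + d2) * (1 + a * d2^b))
        coords[h, ] <- coords[h, ] + clip4(gc * diff) * alpha
      }
      next_sample[e] <- next_sample[e] + eps_per_sample[e]
    }
  }
  coords
}
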