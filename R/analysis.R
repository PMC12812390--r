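# Concordance, clustering and embedding over beta matrices.

#' Pearson correlation between two beta vectors
#'
#' Thin validity-checked wrapper around the product-moment coefficient:
#' requires equal length >= 3 and non-constant inputs (the coefficient is
#' undefined for constant vectors).
#'
#' @param x,y numeric vectors of equal length >= 3.
#' @return The Pearson correlation coefficient.
#' @export
pearson_r <- function(x, y) {
  if (length(x) != length(y)) stop("vectors differ in length")
  if (length(x) < 3) stop("need at least 3 paired values")
  if (anyNA(x) || anyNA(y)) stop("missing values in input")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("undefined correlation: constant input")
  }
  stats::cor(x, y, method = "pearson")
}

#' Pairwise cross-platform correlations
#'
#' Computes, for each requested sample pair, the Pearson correlation of beta
#' values across the matrix's probe rows — the cross-platform concordance
#' statistic used to compare sequencing-derived and array-derived profiles of
#' the same individuals.
#'
#' @param x a [beta_matrix].
#' @param pairs data frame (or 2-column matrix) with columns `sample_a`,
#'   `sample_b`; every name must be a column of `x`.
#' @return Data frame with columns `sample_a`, `sample_b`, `r`, `n_probes`,
#'   one row per input pair, order preserved.
#' @export
platform_correlations <- function(x, pairs) {
  stopifnot(inherits(x, "beta_matrix"))
  pairs <- as.data.frame(pairs, stringsAsFactors = FALSE)
  if (ncol(pairs) < 2) stop("pairs must have two columns")
  names(pairs)[1:2] <- c("sample_a", "sample_b")
  unknown <- setdiff(unique(c(pairs$sample_a, pairs$sample_b)),
                     colnames(x$values))
  if (length(unknown) > 0) {
    stop("unknown sample(s): ", paste(unknown, collapse = ", "))
  }
  r <- mapply(function(a, b) pearson_r(x$values[, a], x$values[, b]),
              pairs$sample_a, pairs$sample_b)
  data.frame(sample_a = pairs$sample_a, sample_b = pairs$sample_b,
             r = unname(r), n_probes = nrow(x$values),
             stringsAsFactors = FALSE)
}

#' Hierarchical clustering of samples
#'
#' Agglomerative clustering of the sample columns using Euclidean distance
#' and complete linkage. Deterministic for a fixed input; complete linkage
#' guarantees non-decreasing merge heights.
#'
#' @param x a [beta_matrix] with no undefined entries.
#' @return An object of class `hclust` (see [stats::hclust()]); labels are
#'   sample IDs.
#' @export
beta_hclust <- function(x) {
  stopifnot(inherits(x, "beta_matrix"))
  if (anyNA(x$values)) stop("beta matrix contains undefined entries")
  if (ncol(x$values) < 2) stop("clustering needs at least 2 samples")
  d <- stats::dist(t(x$values), method = "euclidean")
  stats::hclust(d, method = "complete")
}

#' Export a dendrogram as Newick text
#'
#' @param hc an `hclust` object.
#' @return A single Newick string with branch lengths derived from merge
#'   heights.
#' @export
dendrogram_newick <- function(hc) {
  stopifnot(inherits(hc, "hclust"))
  ape::write.tree(ape::as.phylo(hc))
}

#' Classical (metric) multidimensional scaling of samples
#'
#' Embeds the sample columns by eigendecomposition of the double-centered
#' squared Euclidean distance matrix (Torgerson scaling, via
#' [stats::cmdscale()]). The sign of each axis is fixed so that its
#' largest-magnitude coordinate is positive, making the output reproducible
#' across platforms. For point sets that genuinely lie in `k` dimensions the
#' embedding reproduces all pairwise distances exactly.
#'
#' @param x a [beta_matrix], or a samples-by-features numeric matrix.
#' @param k embedding dimension (default 2).
#' @return An object of class `beta_embedding`: list with `method = "mds"`,
#'   `coordinates` (samples x k, rownames are sample IDs), `seed` (`NA`;
#'   deterministic), `params`, `eig` (the eigenvalues).
#' @export
beta_mds <- function(x, k = 2) {
  pts <- embedding_input(x)
  n <- nrow(pts)
  if (n < 2) stop("MDS needs at least 2 samples")
  d <- stats::dist(pts)
  if (all(d == 0)) {
    coords <- matrix(0, n, k, dimnames = list(rownames(pts), NULL))
    return(new_embedding("mds", coords, NA_integer_, list(k = k),
                         eig = rep(0, n)))
  }
  fit <- stats::cmdscale(d, k = min(k, n - 1), eig = TRUE)
  npos <- sum(fit$eig > max(fit$eig) * 1e-12)
  if (k > npos) {
    stop("requested k = ", k, " exceeds the ", npos,
         " positive eigenvalue(s) of the centered distance matrix")
  }
  coords <- fit$points[, seq_len(k), drop = FALSE]
  coords <- fix_axis_signs(coords)
  rownames(coords) <- rownames(pts)
  new_embedding("mds", coords, NA_integer_, list(k = k), eig = fit$eig)
}

embedding_input <- function(x) {
  if (inherits(x, "beta_matrix")) {
    if (anyNA(x$values)) stop("beta matrix contains undefined entries")
    t(x$values)
  } else {
    as.matrix(x)
  }
}

fix_axis_signs <- function(coords) {
  for (j in seq_len(ncol(coords))) {
    i <- which.max(abs(coords[, j]))
    if (length(i) == 1 && coords[i, j] < 0) coords[, j] <- -coords[, j]
  }
  coords
}

new_embedding <- function(method, coordinates, seed, params, eig = NULL) {
  structure(list(method = method, coordinates = coordinates, seed = seed,
                 params = params, eig = eig),
            class = "beta_embedding")
}

#' @export
print.beta_embedding <- function(x, ...) {
  cat("2-D embedding (", x$method, "): ", nrow(x$coordinates), " samples",
      if (!is.na(x$seed)) paste0(", seed ", x$seed), "\n", sep = "")
  invisible(x)
}

#' Mean silhouette width of a 2-group labeling
#'
#' Cohesion/separation statistic in \[-1, 1\] for case/control labels on
#' embedding coordinates (Euclidean distance); positive means samples sit
#' closer to their own group than to the other.
#'
#' @param coords numeric matrix of embedding coordinates (samples x dims), or
#'   a `beta_embedding`.
#' @param labels vector of group labels, one per sample, exactly two distinct
#'   values.
#' @return Mean silhouette width (single number).
#' @export
group_silhouette <- function(coords, labels) {
  if (inherits(coords, "beta_embedding")) coords <- coords$coordinates
  labels <- as.character(labels)
  if (length(unique(labels)) < 2) stop("silhouette needs two groups")
  sil <- cluster::silhouette(as.integer(factor(labels)),
                             stats::dist(coords))
  mean(sil[, "sil_width"])
}
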