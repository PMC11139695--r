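#' @useDynLib dietclust, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

# Calibrate the low-dimensional similarity curve 1/(1 + a*d^(2b)) so that it
# approximates an offset exponential with plateau `min_dist`; this is the
# standard least-squares fit over [0, 3*spread].
find_ab_params <- function(min_dist, spread = 1) {
  xv <- seq(0, spread * 3, length.out = 300)
  yv <- ifelse(xv < min_dist, 1, exp(-(xv - min_dist) / spread))
  fit <- stats::nls(yv ~ 1 / (1 + a * xv^(2 * b)),
                    start = list(a = 1, b = 1))
  as.list(stats::coef(fit))
}

pairwise_dist <- function(X, metric) {
  method <- switch(metric,
                   chebyshev = "maximum",
                   euclidean = "euclidean",
                   manhattan = "manhattan",
                   stop("unsupported metric '", metric, "'"))
  as.matrix(stats::dist(X, method = method))
}

# Per-point bandwidth calibration: binary-search sigma_i so that
# sum_j exp(-max(0, d_ij - rho_i)/sigma_i) = log2(k), with rho_i the distance
# to the nearest neighbor (smallest positive neighbor distance).
smooth_knn <- function(knn_dist, n_iter = 64, tol = 1e-5) {
  k <- ncol(knn_dist)
  target <- log2(k)
  n <- nrow(knn_dist)
  rho <- numeric(n)
  sigma <- numeric(n)
  for (i in seq_len(n)) {
    di <- knn_dist[i, ]
    pos <- di[di > 0]
    rho[i] <- if (length(pos)) min(pos) else 0
    lo <- 0; hi <- Inf; mid <- 1
    for (iter in seq_len(n_iter)) {
      psum <- sum(exp(-pmax(di - rho[i], 0) / mid))
      if (abs(psum - target) < tol) break
      if (psum > target) {
        hi <- mid; mid <- (lo + hi) / 2
      } else {
        lo <- mid
        mid <- if (is.finite(hi)) (lo + hi) / 2 else mid * 2
      }
    }
    sigma[i] <- mid
  }
  list(rho = rho, sigma = sigma)
}

#' Embed a numeric matrix in two dimensions with UMAP
#'
#' Uniform manifold approximation and projection: an exact k-nearest-neighbor
#' graph under the chosen metric is converted to a fuzzy topological
#' representation (per-point adaptive bandwidths calibrated to log2(k),
#' probabilistic-union symmetrization) and laid out in `n_components`
#' dimensions by stochastic gradient descent with negative sampling. The
#' layout is initialized from the first two principal components (scaled to
#' max-abs 10 with a small seeded jitter), so the whole embedding is
#' deterministic given `(X, seed)`.
#'
#' @param X numeric matrix, one row per observation
#' @param n_neighbors neighborhood size (default 10)
#' @param min_dist minimum spacing of points in the layout (default 0.1)
#' @param n_components output dimension (default 2)
#' @param metric one of "chebyshev" (default), "euclidean", "manhattan"
#' @param seed integer seed controlling jitter and negative sampling
#' @param n_epochs SGD epochs (default 500, suited to small cohorts)
#' @param learning_rate initial SGD step size
#' @param negative_sample_rate negatives drawn per positive edge sample
#' @return numeric matrix (n x n_components) of embedding coordinates
#' @export
umap_embed <- function(X, n_neighbors = 10, min_dist = 0.1, n_components = 2,
                       metric = "chebyshev", seed = 42L, n_epochs = 500L,
                       learning_rate = 1, negative_sample_rate = 5) {
  X <- as.matrix(X)
  n <- nrow(X)
  if (n < n_neighbors + 1)
    stop("need at least n_neighbors + 1 = ", n_neighbors + 1, " rows, got ", n)
  D <- pairwise_dist(X, metric)
  knn_idx <- t(apply(D, 1, function(r) order(r)[2:(n_neighbors + 1)]))
  knn_dist <- t(vapply(seq_len(n), function(i) D[i, knn_idx[i, ]],
                       numeric(n_neighbors)))
  sk <- smooth_knn(knn_dist)

  ii <- rep(seq_len(n), each = n_neighbors)
  jj <- as.vector(t(knn_idx))
  w <- exp(-pmax(as.vector(t(knn_dist)) - sk$rho[ii], 0) / sk$sigma[ii])

  # probabilistic union A + t(A) - A*t(A) on the sparse triplets
  key <- (ii - 1) * n + jj
  tkey <- (jj - 1) * n + ii
  wt <- w[match(key, tkey)]
  wt[is.na(wt)] <- 0
  # combine each unordered pair once
  sym_w <- w + wt - w * wt
  ord_pair <- paste(pmin(ii, jj), pmax(ii, jj))
  first <- !duplicated(ord_pair)
  head_i <- ii[first]; tail_j <- jj[first]; ew <- sym_w[first]

  # sampling schedule: strong edges sampled every epoch, weak ones rarely
  ew[ew < max(ew) / n_epochs] <- 0
  pos <- ew > 0
  head_i <- head_i[pos]; tail_j <- tail_j[pos]; ew <- ew[pos]
  eps <- max(ew) / ew

  ab <- find_ab_params(min_dist)

  pc <- stats::prcomp(X, rank. = n_components)$x
  init <- pc / max(abs(pc)) * 10
  set.seed(seed)
  init <- init + matrix(stats::rnorm(length(init), sd = 1e-4), nrow = n)

  emb <- umap_layout_cpp(init, head_i - 1L, tail_j - 1L, eps,
                         ab$a, ab$b, 1.0, learning_rate,
                         as.integer(n_epochs), negative_sample_rate,
                         as.integer(seed))
  dimnames(emb) <- list(rownames(X), paste0("D", seq_len(n_components)))
  emb
}
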