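#' Clustering-stage configuration
#'
#' Bundles the embedding and partitioning parameters used to derive dietary
#' patterns: UMAP neighborhood size 10, minimum distance 0.1, two output
#' dimensions and the Chebyshev metric; K-means with 10 random restarts; a
#' Gaussian kernel density estimate on a 200x200 grid with Scott's-rule
#' bandwidth and a 5%-of-maximum peak threshold for the contour diagnostic.
#'
#' @param n_neighbors UMAP neighborhood size
#' @param min_dist UMAP minimum layout distance
#' @param n_components embedding dimension (the pipeline uses 2)
#' @param metric distance metric for the neighbor graph
#' @param seed integer seed for the whole stage
#' @param n_epochs UMAP optimization epochs
#' @param kmeans_nstart K-means random restarts
#' @param kde_grid KDE evaluation grid resolution per axis
#' @param kde_threshold density peaks below this fraction of the maximum are
#'   ignored
#' @param kde_bandwidth optional fixed bandwidth (per-axis kernel SD);
#'   default NULL means Scott's rule
#' @return a `dc_config` list
#' @export
clustering_config <- function(n_neighbors = 10, min_dist = 0.1,
                              n_components = 2, metric = "chebyshev",
                              seed = 42L, n_epochs = 500L,
                              kmeans_nstart = 10, kde_grid = 200,
                              kde_threshold = 0.05, kde_bandwidth = NULL) {
  stopifnot(n_neighbors >= 2)
  structure(list(n_neighbors = n_neighbors, min_dist = min_dist,
                 n_components = n_components, metric = metric,
                 seed = as.integer(seed), n_epochs = as.integer(n_epochs),
                 kmeans_nstart = kmeans_nstart, kde_grid = kde_grid,
                 kde_threshold = kde_threshold, kde_bandwidth = kde_bandwidth),
            class = "dc_config")
}

#' Encode questionnaire responses as a numeric matrix
#'
#' Columns are the selected variables' 1-based integer scale positions (the
#' raw ordinal codes, not the scoring weights — for the packaged schema the
#' two coincide). An optional grouping map averages member columns into
#' composite columns, emulating item-aggregation ablations.
#'
#' @param cohort a `dc_cohort` with schema
#' @param categories subset of `c("food_item","dietary_behavior","cooking_method")`
#' @param grouping optional named list: group name -> character vector of
#'   member variable ids
#' @return numeric matrix, one row per participant
#' @export
encode_matrix <- function(cohort,
                          categories = c("food_item", "dietary_behavior",
                                         "cooking_method"),
                          grouping = NULL) {
  if (length(categories) == 0) stop("category subset must be non-empty")
  bad <- setdiff(categories,
                 c("food_item", "dietary_behavior", "cooking_method"))
  if (length(bad)) stop("unknown categories: ", paste(bad, collapse = ", "))
  vars <- Filter(function(v) v$category %in% categories,
                 cohort$schema$variables)
  if (!length(vars)) stop("no variables in the selected categories")
  cols <- vapply(vars, function(v) {
    match(cohort$data[[v$id]], v$scale_labels)
  }, numeric(nrow(cohort$data)))
  if (nrow(cohort$data) == 1) cols <- matrix(cols, nrow = 1)
  colnames(cols) <- names(vars)
  if (is.null(grouping)) return(cols)
  grouped <- vapply(grouping, function(members) {
    miss <- setdiff(members, colnames(cols))
    if (length(miss)) stop("grouping refers to unselected variables: ",
                           paste(miss, collapse = ", "))
    rowMeans(cols[, members, drop = FALSE])
  }, numeric(nrow(cols)))
  if (nrow(cols) == 1) grouped <- matrix(grouped, nrow = 1,
                                         dimnames = list(NULL, names(grouping)))
  rest <- setdiff(colnames(cols), unlist(grouping))
  cbind(grouped, cols[, rest, drop = FALSE])
}

#' Embed an encoded matrix in 2D under a clustering configuration
#'
#' @param X numeric matrix (participants x variables)
#' @param config a `dc_config`
#' @return a `dc_embedding`: the n x 2 coordinate matrix with the config
#'   attached as an attribute
#' @export
embed_matrix <- function(X, config = clustering_config()) {
  emb <- umap_embed(X, n_neighbors = config$n_neighbors,
                    min_dist = config$min_dist,
                    n_components = config$n_components,
                    metric = config$metric, seed = config$seed,
                    n_epochs = config$n_epochs)
  if (any(!is.finite(emb))) stop("embedding produced non-finite coordinates")
  structure(emb, config = config, class = c("dc_embedding", class(emb)))
}

wcss_curve <- function(emb, k_range, nstart, seed) {
  vapply(k_range, function(k) {
    set.seed(seed + k)
    stats::kmeans(emb, centers = k, nstart = nstart,
                  iter.max = 50)$tot.withinss
  }, numeric(1))
}

silhouette_curve <- function(emb, k_range, nstart, seed) {
  dd <- stats::dist(emb)
  vapply(k_range, function(k) {
    set.seed(seed + k)
    km <- stats::kmeans(emb, centers = k, nstart = nstart, iter.max = 50)
    mean(cluster::silhouette(km$cluster, dd)[, "sil_width"])
  }, numeric(1))
}

#' Count density peaks of a 2D embedding
#'
#' Evaluates a Gaussian kernel density estimate on a regular grid and counts
#' the strict local maxima (8-neighborhood) whose density exceeds
#' `threshold` times the maximal density — the "contour map" diagnostic for
#' the number of clusters.
#'
#' @param emb n x 2 coordinate matrix (>= 10 points recommended)
#' @param bandwidth per-axis kernel SD; default NULL = Scott's rule
#'   (`sd * n^(-1/6)` per axis)
#' @param grid grid resolution per axis
#' @param threshold fraction of the maximum density below which maxima are
#'   ignored
#' @return integer peak count
#' @export
kde_peak_count <- function(emb, bandwidth = NULL, grid = 200,
                           threshold = 0.05) {
  emb <- as.matrix(emb)
  n <- nrow(emb)
  if (stats::sd(emb[, 1]) == 0 && stats::sd(emb[, 2]) == 0) return(1L)
  if (is.null(bandwidth)) {
    bandwidth <- pmax(c(stats::sd(emb[, 1]), stats::sd(emb[, 2])),
                      1e-8) * n^(-1 / 6)
  } else if (length(bandwidth) == 1) bandwidth <- rep(bandwidth, 2)
  if (any(bandwidth <= 0)) stop("bandwidth must be positive")
  pad <- 3 * bandwidth
  # kde2d's h is 4x the kernel SD
  dens <- MASS::kde2d(emb[, 1], emb[, 2], h = 4 * bandwidth, n = grid,
                      lims = c(range(emb[, 1]) + c(-1, 1) * pad[1],
                               range(emb[, 2]) + c(-1, 1) * pad[2]))
  z <- dens$z
  cutoff <- threshold * max(z)
  nr <- nrow(z); nc <- ncol(z)
  # candidate cells: at least as high as every 8-neighbor and above cutoff;
  # a mode that falls exactly between grid cells yields a tied plateau, so
  # adjacent candidates are merged and counted once
  cand <- matrix(FALSE, nr, nc)
  for (i in seq_len(nr)) {
    for (j in seq_len(nc)) {
      v <- z[i, j]
      if (v < cutoff) next
      nb <- z[max(1, i - 1):min(nr, i + 1), max(1, j - 1):min(nc, j + 1)]
      if (v >= max(nb)) cand[i, j] <- TRUE
    }
  }
  idx <- which(cand, arr.ind = TRUE)
  if (nrow(idx) == 0) return(1L)
  comp <- seq_len(nrow(idx))
  repeat {
    changed <- FALSE
    for (p in seq_len(nrow(idx))) {
      near <- which(abs(idx[, 1] - idx[p, 1]) <= 1 &
                      abs(idx[, 2] - idx[p, 2]) <= 1)
      m <- min(comp[near])
      if (any(comp[near] != m)) { comp[near] <- m; changed <- TRUE }
    }
    if (!changed) break
  }
  length(unique(comp))
}

#' Select the number of clusters for a 2D embedding
#'
#' Scans `k_range` with K-means, reporting the within-cluster sum of squares
#' curve (elbow diagnostic: maximal second difference), the mean silhouette
#' per k, and the KDE peak count. The selected k is the KDE peak count when
#' it agrees with either the elbow or the silhouette optimum (mirroring
#' confirmation of the cluster number on the contour map); otherwise the
#' silhouette optimum is returned with `agreed = FALSE` so the user can
#' override.
#'
#' @param emb n x 2 embedding
#' @param k_range candidate cluster numbers (default 2:10)
#' @param config a `dc_config`
#' @return list with `k`, `agreed`, and `diagnostics` (per-k WCSS and
#'   silhouette, elbow k, silhouette k, KDE peak count)
#' @export
select_k <- function(emb, k_range = 2:10, config = clustering_config()) {
  emb <- as.matrix(emb)
  if (nrow(unique(emb)) == 1) stop("degenerate embedding: all points identical")
  k_range <- k_range[k_range >= 2 & k_range <= nrow(emb) - 1]
  wcss <- wcss_curve(emb, k_range, config$kmeans_nstart, config$seed)
  sil <- silhouette_curve(emb, k_range, config$kmeans_nstart, config$seed)
  elbow_k <- if (length(k_range) >= 3) {
    k_range[which.max(diff(diff(wcss))) + 1]
  } else k_range[1]
  sil_k <- k_range[which.max(sil)]
  peaks <- kde_peak_count(emb, bandwidth = config$kde_bandwidth,
                          grid = config$kde_grid,
                          threshold = config$kde_threshold)
  agreed <- peaks %in% c(elbow_k, sil_k)
  k <- if (agreed) peaks else sil_k
  list(k = k, agreed = agreed,
       diagnostics = list(k_range = k_range, wcss = wcss, silhouette = sil,
                          elbow_k = elbow_k, silhouette_k = sil_k,
                          kde_peak_count = peaks))
}

#' Partition an embedding with K-means
#'
#' @param emb n x 2 embedding
#' @param k number of clusters
#' @param config a `dc_config` (restarts + seed)
#' @param diagnostics optional diagnostics list from [select_k()] to attach
#' @return a `dc_assignment`: list with 0-based `labels`, `k`, `centers`,
#'   `embedding`, `diagnostics`
#' @export
kmeans_assign <- function(emb, k, config = clustering_config(),
                          diagnostics = NULL) {
  set.seed(config$seed + k)
  km <- stats::kmeans(as.matrix(emb), centers = k,
                      nstart = config$kmeans_nstart, iter.max = 50)
  # relabel clusters in a canonical order (by center D1 then D2) so labels do
  # not depend on kmeans' internal initialization order
  ord <- order(km$centers[, 1], km$centers[, 2])
  relab <- match(km$cluster, ord) - 1L
  structure(list(labels = relab, k = k,
                 centers = km$centers[ord, , drop = FALSE],
                 embedding = as.matrix(emb), diagnostics = diagnostics),
            class = "dc_assignment")
}

#' @export
print.dc_assignment <- function(x, ...) {
  cat("Cluster assignment: k =", x$k, "\n")
  print(table(cluster = cluster_names(sort(unique(x$labels)))[x$labels + 1]))
  invisible(x)
}

all_permutations <- function(v) {
  if (length(v) <= 1) return(list(v))
  out <- list()
  for (i in seq_along(v))
    for (p in all_permutations(v[-i]))
      out[[length(out) + 1]] <- c(v[i], p)
  out
}

#' Per-cluster overlap between two assignments
#'
#' Matches the labels of `b` to those of `a` one-to-one so that total
#' agreement is maximal (exhaustive search over label permutations, k <= 8;
#' ties broken toward the identity-ordered permutation, which is generated
#' first), then reports, per cluster of `a`, the percentage of its members
#' that carry the matched label in `b`.
#'
#' @param a,b `dc_assignment`s (or integer label vectors) over the same
#'   participants
#' @return named numeric vector of per-cluster overlap percentages (names are
#'   `a`'s cluster letters)
#' @export
cluster_overlap <- function(a, b) {
  la <- if (inherits(a, "dc_assignment")) a$labels else a
  lb <- if (inherits(b, "dc_assignment")) b$labels else b
  if (length(la) != length(lb))
    stop("assignments cover different participant sets")
  ua <- sort(unique(la)); ub <- sort(unique(lb))
  if (length(ub) > 8) stop("exhaustive matching supports at most 8 clusters")
  conf <- table(factor(la, levels = ua), factor(lb, levels = ub))
  # pad to square so unmatched labels are allowed
  k <- max(length(ua), length(ub))
  m <- matrix(0, k, k)
  m[seq_along(ua), seq_along(ub)] <- conf
  perms <- all_permutations(seq_len(k))
  scores <- vapply(perms, function(p) sum(m[cbind(seq_len(k), p)]), numeric(1))
  best <- perms[[which.max(scores)]]
  overlap <- vapply(seq_along(ua), function(i) {
    100 * m[i, best[i]] / sum(la == ua[i])
  }, numeric(1))
  stats::setNames(overlap, cluster_names(ua))
}

#' Adjusted Rand index between two partitions
#'
#' Chance-corrected agreement between two labelings of the same items; 1 for
#' identical partitions (up to relabeling), ~0 for independent ones.
#'
#' @param a,b integer/factor label vectors of equal length
#' @return numeric scalar
#' @export
adjusted_rand <- function(a, b) {
  if (length(a) != length(b)) stop("label vectors differ in length")
  tab <- table(a, b)
  choose2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(choose2(tab))
  sum_a <- sum(choose2(rowSums(tab)))
  sum_b <- sum(choose2(colSums(tab)))
  n2 <- choose2(length(a))
  expected <- sum_a * sum_b / n2
  maxi <- (sum_a + sum_b) / 2
  if (maxi == expected) return(1)
  (sum_ij - expected) / (maxi - expected)
}

#' Scatter-plus-contour plot of an embedding
#'
#' @param emb n x 2 embedding
#' @param labels optional cluster labels for coloring
#' @param main plot title
#' @return invisibly, the KDE used for the contour
#' @export
plot_embedding <- function(emb, labels = NULL, main = "Dietary-pattern embedding") {
  emb <- as.matrix(emb)
  cols <- if (is.null(labels)) "grey30" else labels + 2L
  graphics::plot(emb, col = cols, pch = 19, cex = 0.6,
                 xlab = "D1", ylab = "D2", main = main)
  bw <- pmax(apply(emb, 2, stats::sd), 1e-8) * nrow(emb)^(-1 / 6)
  dens <- MASS::kde2d(emb[, 1], emb[, 2], h = 4 * bw, n = 100)
  graphics::contour(dens, add = TRUE, drawlabels = FALSE, col = "grey60")
  invisible(dens)
}
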