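#' Map a response label to its scoring weight
#'
#' @param schema_var a variable definition from a `dc_schema`
#'   (`schema$variables[[id]]`)
#' @param label a response label on that variable's scale
#' @return the integer point value for that category
#' @export
#' @examples
#' sch <- bdhq_schema()
#' map_weight(sch$variables$chicken, "2-3 times per week")  # 4
map_weight <- function(schema_var, label) {
  w <- schema_var$weight_map[label]
  if (anyNA(w))
    stop("unknown label '", paste(label[is.na(w)], collapse = "', '"),
         "' for variable ", schema_var$id)
  unname(w)
}

#' Trend score of a category-proportion vector
#'
#' The trend score of a variable within a cluster is the weighted sum
#' `sum_i w_i * p_i`, where `w` are the per-category point values and `p` the
#' within-cluster category proportions. It equals the mean mapped weight of
#' the cluster's participants and is bounded by `[min(w), max(w)]`.
#'
#' @param w numeric vector of category weights (strictly increasing)
#' @param p numeric vector of category proportions (non-negative, sums to 1)
#' @param n number of participants behind `p` (0 is an error: an empty
#'   cluster has no trend)
#' @return the trend score
#' @export
trend_score <- function(w, p, n = NULL) {
  if (!is.null(n) && n == 0) stop("empty cluster: trend score undefined")
  if (length(w) != length(p))
    stop("weight and proportion vectors differ in length")
  if (any(p < 0) || abs(sum(p) - 1) > 1e-12)
    stop("proportions must be non-negative and sum to 1")
  sum(w * p)
}

#' Per-cluster trend-score table with cross-cluster tests
#'
#' Computes one trend score per (cluster, variable), a cross-cluster one-way
#' ANOVA p-value per variable on the participant-level mapped weights, and
#' flags the cluster(s) attaining the maximal score for each variable.
#'
#' @param cohort a `dc_cohort` with a schema
#' @param labels integer cluster labels (one per participant, values
#'   `0..k-1`) or a `dc_assignment`
#' @return a `dc_trend_table`: list with `scores` (clusters x variables
#'   matrix), `p_value` (per variable), `max_cluster` (per variable, ties
#'   comma-separated), `n` (per-cluster sizes), `categories`
#' @export
trend_table <- function(cohort, labels) {
  if (inherits(labels, "dc_assignment")) labels <- labels$labels
  d <- cohort$data
  if (length(labels) != nrow(d))
    stop("labels must cover every participant")
  if (anyNA(labels)) stop("every participant must be assigned")
  cl <- sort(unique(labels))
  if (length(cl) < 1) stop("no clusters")
  ids <- schema_ids(cohort$schema)
  scores <- matrix(NA_real_, nrow = length(cl), ncol = length(ids),
                   dimnames = list(cluster_names(cl), ids))
  pval <- stats::setNames(rep(NA_real_, length(ids)), ids)
  for (v in cohort$schema$variables) {
    wts <- map_weight(v, d[[v$id]])
    for (j in seq_along(cl)) {
      sel <- labels == cl[j]
      if (!any(sel)) stop("empty cluster ", cl[j])
      scores[j, v$id] <- mean(wts[sel])
    }
    pval[v$id] <- if (length(cl) > 1 && stats::var(wts) > 0) {
      # zero-residual fixtures make the F-test warn about perfect fits;
      # those cases resolve to p ~ 0 or 1 which is the right answer here
      suppressWarnings(
        stats::anova(stats::lm(wts ~ factor(labels)))[["Pr(>F)"]][1])
    } else NA_real_
  }
  maxc <- apply(scores, 2, function(s) {
    paste(rownames(scores)[abs(s - max(s)) < 1e-9], collapse = ",")
  })
  structure(list(scores = scores, p_value = pval, max_cluster = maxc,
                 n = table(factor(labels, levels = cl)),
                 categories = schema_categories(cohort$schema)),
            class = "dc_trend_table")
}

cluster_names <- function(cl) LETTERS[seq_along(cl)]

#' @export
print.dc_trend_table <- function(x, digits = 3, ...) {
  cat("Trend table:", nrow(x$scores), "clusters x", ncol(x$scores),
      "variables\n")
  print(utils::head(t(round(x$scores, digits)), 10))
  invisible(x)
}

#' Export a trend table as CSV (clusters as columns)
#' @param x a `dc_trend_table`
#' @param path output path
#' @param digits decimals for the reported scores (default 3)
#' @return `path`, invisibly
#' @export
write_trend_table <- function(x, path, digits = 3) {
  out <- data.frame(variable = colnames(x$scores),
                    category = unname(x$categories),
                    round(t(x$scores), digits),
                    p_value = signif(unname(x$p_value), 4),
                    max_cluster = unname(x$max_cluster),
                    check.names = FALSE)
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}

#' Summarize which variables each cluster dominates
#'
#' For each cluster, counts the variables (by category) on which it attains
#' the maximal trend score, e.g. "29/58 food items". Ties count for every
#' tied cluster.
#'
#' @param x a `dc_trend_table`
#' @return data.frame with one row per (cluster, category): `cluster`,
#'   `category`, `n_max`, `n_total`, `summary`
#' @export
rank_clusters <- function(x) {
  cls <- rownames(x$scores)
  cats <- unique(x$categories)
  rows <- list()
  for (cc in cls) {
    holds <- vapply(seq_len(ncol(x$scores)), function(j)
      cc %in% strsplit(x$max_cluster[j], ",")[[1]], logical(1))
    for (ct in cats) {
      in_cat <- x$categories == ct
      rows[[length(rows) + 1]] <- data.frame(
        cluster = cc, category = ct,
        n_max = sum(holds & in_cat), n_total = sum(in_cat),
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  out$summary <- sprintf("%d/%d %s", out$n_max, out$n_total,
                         c(food_item = "items", dietary_behavior = "behaviors",
                           cooking_method = "methods")[out$category])
  out
}
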