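#' Components of the DASH-style diet score
#'
#' The eight components and their directions: higher consumption of fruits,
#' vegetables, nuts/legumes, low-fat dairy and whole grains is favorable;
#' higher sodium, sweetened beverages and red/processed meats is restricted
#' (reverse-scored).
#'
#' @return data.frame with `component` and `direction`
#'   ("favorable"/"restricted")
#' @export
dash_components <- function() {
  data.frame(
    component = c("fruits", "vegetables", "nuts_legumes", "low_fat_dairy",
                  "whole_grains", "sodium", "sweetened_beverages",
                  "red_processed_meats"),
    direction = c(rep("favorable", 5), rep("restricted", 3)),
    stringsAsFactors = FALSE)
}

#' Quintile sub-score for one DASH component
#'
#' Ranks the cohort's intake values (average ranks for ties) and assigns
#' quintile sub-scores 1-5: the highest quintile scores 5 for a favorable
#' component and 1 for a restricted one. A boundary tie resolves toward the
#' lower quintile via the average-rank ceiling rule. If all values are
#' identical every participant receives the midpoint 3, with a warning.
#'
#' @param values numeric intake values across the cohort
#' @param direction "favorable" or "restricted"
#' @return integer sub-scores in 1..5, one per participant
#' @export
dash_subscore <- function(values, direction = c("favorable", "restricted")) {
  direction <- match.arg(direction)
  if (anyNA(values)) stop("component intakes must be complete")
  if (length(unique(values)) == 1) {
    warning("component is constant across the cohort; assigning midpoint 3")
    return(rep(3L, length(values)))
  }
  r <- rank(values, ties.method = "average")
  q <- as.integer(pmin(5, pmax(1, ceiling(5 * r / length(values)))))
  if (direction == "restricted") q <- 6L - q
  q
}

#' Total DASH score and cohort-relative quartile
#'
#' @param sub_scores n x 8 matrix (or data.frame) of component sub-scores in
#'   1..5, one column per component
#' @return data.frame with `total` (8..40) and `quartile` ("Q1".."Q4",
#'   cohort-relative by average ranks)
#' @export
dash_total <- function(sub_scores) {
  m <- as.matrix(sub_scores)
  if (ncol(m) != 8) stop("exactly 8 component sub-scores are required")
  if (any(m < 1 | m > 5)) stop("sub-scores must lie in 1..5")
  total <- rowSums(m)
  r <- rank(total, ties.method = "average")
  quart <- paste0("Q", pmin(4, pmax(1, ceiling(4 * r / length(total)))))
  data.frame(total = total, quartile = quart, stringsAsFactors = FALSE)
}

#' Compute DASH scores for a cohort from component intakes
#'
#' @param intakes data.frame with one numeric column per DASH component
#'   (names as in [dash_components()])
#' @return data.frame with the 8 sub-scores, `total` and `quartile`
#' @export
dash_score <- function(intakes) {
  comp <- dash_components()
  miss <- setdiff(comp$component, names(intakes))
  if (length(miss)) stop("missing DASH component(s): ",
                         paste(miss, collapse = ", "))
  subs <- vapply(seq_len(nrow(comp)), function(i)
    dash_subscore(intakes[[comp$component[i]]], comp$direction[i]),
    integer(nrow(intakes)))
  colnames(subs) <- comp$component
  cbind(as.data.frame(subs), dash_total(subs))
}

#' DASH quartile composition and mean score by cluster
#'
#' Builds the K x 4 quartile composition table and, against a designated
#' reference cluster, compares each other cluster's composition (Pearson
#' chi-square on the 2 x 4 table) and mean total score (Welch t-test). A
#' cluster with fewer than 2 participants is skipped with a warning.
#'
#' @param dash data.frame from [dash_score()]
#' @param labels cluster labels (0-based) or `dc_assignment`
#' @param reference reference cluster letter (default: last cluster)
#' @return list with `composition` (percent), `counts`, `mean_total`, and
#'   `comparisons` (per non-reference cluster: chi-square and t-test p)
#' @export
dash_by_cluster <- function(dash, labels, reference = NULL) {
  if (inherits(labels, "dc_assignment")) labels <- labels$labels
  cl <- sort(unique(labels))
  nm <- cluster_names(cl)
  if (is.null(reference)) reference <- nm[length(nm)]
  qlev <- paste0("Q", 1:4)
  counts <- t(vapply(cl, function(c0)
    table(factor(dash$quartile[labels == c0], levels = qlev)),
    numeric(4)))
  rownames(counts) <- nm
  mean_total <- vapply(cl, function(c0) mean(dash$total[labels == c0]),
                       numeric(1))
  names(mean_total) <- nm
  comps <- list()
  for (cc in setdiff(nm, reference)) {
    c0 <- cl[match(cc, nm)]; r0 <- cl[match(reference, nm)]
    if (sum(labels == c0) < 2 || sum(labels == r0) < 2) {
      warning("cluster ", cc, " or reference too small; comparison skipped")
      next
    }
    chi_p <- suppressWarnings(
      stats::chisq.test(counts[c(cc, reference), , drop = FALSE])$p.value)
    t_p <- stats::t.test(dash$total[labels == c0],
                         dash$total[labels == r0])$p.value
    comps[[cc]] <- data.frame(cluster = cc, reference = reference,
                              chisq_p = chi_p, mean_p = t_p,
                              stringsAsFactors = FALSE)
  }
  list(composition = 100 * counts / rowSums(counts), counts = counts,
       mean_total = mean_total,
       comparisons = if (length(comps)) do.call(rbind, comps) else NULL)
}
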