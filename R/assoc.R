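#' Case/non-case contingency table by cluster
#'
#' @param cohort a `dc_cohort` (or data.frame) with a binary outcome column
#' @param labels cluster labels (0-based) or a `dc_assignment`
#' @param outcome outcome column name (default "incident_hypertension")
#' @param reference reference cluster letter, or NULL for the default rule:
#'   among clusters, prefer highest prevalence breaking ties by size; the
#'   packaged rule targets the largest, highest-prevalence pattern
#' @return a `dc_contingency`: list with `counts` (2 x K matrix, rows
#'   cases/non-cases), `n`, `prevalence` (percent), `reference`
#' @export
contingency_by_cluster <- function(cohort, labels,
                                   outcome = "incident_hypertension",
                                   reference = NULL) {
  d <- if (inherits(cohort, "dc_cohort")) cohort$data else cohort
  if (inherits(labels, "dc_assignment")) labels <- labels$labels
  if (length(labels) != nrow(d) || anyNA(labels))
    stop("every participant must be assigned to a cluster")
  y <- d[[outcome]]
  if (anyNA(y) || !all(y %in% c(0, 1, TRUE, FALSE)))
    stop("outcome must be binary with no missing values")
  y <- as.integer(y)
  cl <- sort(unique(labels))
  nm <- cluster_names(cl)
  counts <- vapply(cl, function(c0) {
    sel <- labels == c0
    c(cases = sum(y[sel]), noncases = sum(sel) - sum(y[sel]))
  }, numeric(2))
  colnames(counts) <- nm
  n <- colSums(counts)
  prev <- 100 * counts["cases", ] / n
  if (is.null(reference)) {
    # aversive-pattern rule: the cluster with the highest prevalence,
    # ties broken by size
    reference <- nm[order(-prev, -n)][1]
  }
  structure(list(counts = counts, n = n, prevalence = prev,
                 reference = reference), class = "dc_contingency")
}

#' @export
print.dc_contingency <- function(x, ...) {
  cat("Outcome by cluster (reference:", x$reference, ")\n")
  out <- rbind(x$counts, n = x$n, `prevalence %` = round(x$prevalence, 2))
  print(out)
  invisible(x)
}

#' Crude odds ratios from a contingency table
#'
#' For each non-reference cluster, the cross-product odds ratio
#' `(a*d)/(b*c)` against the reference, with a 95% Wald interval on the log
#' scale: `exp(log(OR) +/- 1.96 * sqrt(1/a + 1/b + 1/c + 1/d))`.
#'
#' @param tab a `dc_contingency`
#' @param reference reference cluster letter (default: the table's)
#' @param continuity if TRUE, add 0.5 to all four cells of a 2x2 sub-table;
#'   by default a zero cell is an error
#' @return a `dc_or` data.frame: `cluster`, `or`, `ci_low`, `ci_high`,
#'   `model`
#' @export
crude_or <- function(tab, reference = tab$reference, continuity = FALSE) {
  nm <- colnames(tab$counts)
  if (!reference %in% nm) stop("unknown reference cluster ", reference)
  rows <- lapply(setdiff(nm, reference), function(cc) {
    a <- tab$counts["cases", cc];    b <- tab$counts["noncases", cc]
    c0 <- tab$counts["cases", reference]
    d0 <- tab$counts["noncases", reference]
    cells <- c(a, b, c0, d0)
    if (any(cells == 0)) {
      if (!continuity)
        stop("zero cell in 2x2 table for cluster ", cc,
             "; set continuity = TRUE to add 0.5 to all cells")
      cells <- cells + 0.5
    }
    or <- (cells[1] * cells[4]) / (cells[2] * cells[3])
    se <- sqrt(sum(1 / cells))
    data.frame(cluster = cc, or = or,
               ci_low = exp(log(or) - 1.96 * se),
               ci_high = exp(log(or) + 1.96 * se),
               model = "crude", stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("dc_or", class(out))
  out
}

#' Covariate sets for the nested logistic models
#'
#' Model 1: cluster only. Model 2 adds age and BMI. Model 3 adds smoking,
#' education and physical activity. Model 4 adds dyslipidemia and diabetes.
#' Model 5 adds salt intake (a potential mediator). `drop` removes a
#' covariate from every model, as in age-matched sensitivity runs where age
#' is matched away.
#'
#' @param models integer subset of 1:5
#' @param drop character vector of covariates to drop from all models
#' @return named list: model name -> character vector of covariates
#' @export
model_specs <- function(models = 1:5, drop = NULL) {
  base <- list(
    `Model 1` = character(0),
    `Model 2` = c("age", "bmi"),
    `Model 3` = c("age", "bmi", "smoking", "education", "pa_category"),
    `Model 4` = c("age", "bmi", "smoking", "education", "pa_category",
                  "dyslipidemia", "diabetes"),
    `Model 5` = c("age", "bmi", "smoking", "education", "pa_category",
                  "dyslipidemia", "diabetes", "salt_intake")
  )
  specs <- base[models]
  if (!is.null(drop)) specs <- lapply(specs, setdiff, y = drop)
  specs
}

#' Fit nested logistic odds-ratio models for cluster membership
#'
#' For each covariate set, fits `outcome ~ cluster + covariates` by logistic
#' regression; reports per-cluster ORs with 95% Wald intervals and a
#' model-level p-value from the likelihood-ratio test of the model against
#' the same model without the cluster indicators. Smoking and physical
#' activity enter as indicator sets (factors), education and disease flags as
#' binaries, age/BMI/salt as continuous.
#'
#' @param cohort `dc_cohort` or data.frame with outcome and covariates
#' @param labels cluster labels (0-based) or `dc_assignment`
#' @param specs list from [model_specs()]
#' @param reference reference cluster letter; default from
#'   [contingency_by_cluster()]'s rule
#' @param outcome outcome column name
#' @return a `dc_or` data.frame with one row per (model, non-reference
#'   cluster): `model`, `cluster`, `or`, `ci_low`, `ci_high`, `lr_p`
#' @export
fit_models <- function(cohort, labels, specs = model_specs(),
                       reference = NULL,
                       outcome = "incident_hypertension") {
  d <- if (inherits(cohort, "dc_cohort")) cohort$data else cohort
  if (inherits(labels, "dc_assignment")) labels <- labels$labels
  tab <- contingency_by_cluster(d, labels, outcome, reference)
  reference <- tab$reference
  nm <- colnames(tab$counts)
  cl_letter <- nm[match(labels, sort(unique(labels)))]
  dd <- d
  dd$.cluster <- stats::relevel(factor(cl_letter), ref = reference)
  dd$.y <- as.integer(d[[outcome]])
  for (v in c("smoking", "pa_category", "education"))
    if (v %in% names(dd)) dd[[v]] <- factor(dd[[v]])
  out <- list()
  for (mn in names(specs)) {
    covars <- specs[[mn]]
    miss <- setdiff(covars, names(dd))
    if (length(miss)) stop("missing covariate column(s): ",
                           paste(miss, collapse = ", "))
    rhs <- paste(c(".cluster", covars), collapse = " + ")
    rhs0 <- if (length(covars)) paste(covars, collapse = " + ") else "1"
    fit <- stats::glm(stats::as.formula(paste(".y ~", rhs)),
                      family = stats::binomial(), data = dd)
    if (!fit$converged || any(abs(stats::coef(fit)) > 15, na.rm = TRUE)) {
      big <- names(which(abs(stats::coef(fit)) > 15))
      stop("separation or non-convergence in ", mn,
           if (length(big)) paste0(" (coefficient(s): ",
                                   paste(big, collapse = ", "), ")"))
    }
    fit0 <- stats::glm(stats::as.formula(paste(".y ~", rhs0)),
                       family = stats::binomial(), data = dd)
    lr <- stats::anova(fit0, fit, test = "LRT")
    lr_p <- lr[["Pr(>Chi)"]][2]
    est <- summary(fit)$coefficients
    idx <- grep("^\\.cluster", rownames(est))
    res <- data.frame(
      model = mn,
      cluster = sub("^\\.cluster", "", rownames(est)[idx]),
      or = exp(est[idx, "Estimate"]),
      ci_low = exp(est[idx, "Estimate"] - 1.96 * est[idx, "Std. Error"]),
      ci_high = exp(est[idx, "Estimate"] + 1.96 * est[idx, "Std. Error"]),
      lr_p = lr_p, stringsAsFactors = FALSE, row.names = NULL)
    out[[mn]] <- res
  }
  res <- do.call(rbind, c(out, make.row.names = FALSE))
  class(res) <- c("dc_or", class(res))
  res
}

#' @export
print.dc_or <- function(x, digits = 2, ...) {
  y <- x
  for (v in c("or", "ci_low", "ci_high"))
    y[[v]] <- sprintf(paste0("%.", digits, "f"), x[[v]])
  if ("lr_p" %in% names(y)) y$lr_p <- signif(x$lr_p, 3)
  print.data.frame(y)
  invisible(x)
}

#' Cross-cluster descriptive comparison of one variable
#'
#' One-way ANOVA for a continuous variable, Pearson chi-square for a
#' categorical one, with a Kolmogorov-Smirnov normality screen reported as a
#' side diagnostic for continuous variables.
#'
#' @param cohort `dc_cohort` or data.frame
#' @param labels cluster labels or `dc_assignment`
#' @param variable column name
#' @param type "continuous", "categorical", or "auto" (numeric -> continuous)
#' @return list with `p` (NA with `note` when the variable is constant),
#'   `test`, and `ks_p` for continuous variables
#' @export
descriptive_compare <- function(cohort, labels, variable, type = "auto") {
  d <- if (inherits(cohort, "dc_cohort")) cohort$data else cohort
  if (inherits(labels, "dc_assignment")) labels <- labels$labels
  x <- d[[variable]]
  if (is.null(x)) stop("no column '", variable, "'")
  if (type == "auto")
    type <- if (is.numeric(x)) "continuous" else "categorical"
  g <- factor(labels)
  if (length(unique(x)) < 2)
    return(list(p = NA_real_, test = "none",
                note = "constant variable: p undefined"))
  if (type == "continuous") {
    ks <- suppressWarnings(
      stats::ks.test(scale(x), "pnorm"))$p.value
    p <- stats::anova(stats::lm(x ~ g))[["Pr(>F)"]][1]
    list(p = p, test = "anova", ks_p = ks)
  } else {
    p <- suppressWarnings(stats::chisq.test(table(x, g))$p.value)
    list(p = p, test = "chisq")
  }
}
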