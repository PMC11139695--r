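# The published 2x4 outcome table: cases 6/17/9/32 of cluster sizes
# 75/130/100/142, reference = the largest, highest-prevalence cluster D.
printed_cases <- c(6, 17, 9, 32)
printed_sizes <- c(75, 130, 100, 142)

test_that("contingency table reproduces the printed prevalence row", {
  d <- counts_to_cohort(printed_cases, printed_sizes)
  tab <- contingency_by_cluster(d, d$labels)
  expect_equal(unname(tab$n), printed_sizes, ignore_attr = TRUE)
  expect_true(all(abs(unname(tab$prevalence) -
                        c(8.00, 13.08, 9.00, 22.53)) <= 0.01))
  expect_equal(tab$reference, "D")
  expect_error(contingency_by_cluster(d, c(NA, d$labels[-1])), "assigned")
})

test_that("crude odds ratios and Wald intervals match the printed results", {
  d <- counts_to_cohort(printed_cases, printed_sizes)
  tab <- contingency_by_cluster(d, d$labels)
  or <- crude_or(tab)
  expect_equal(or$cluster, c("A", "B", "C"))
  expect_equal(or$or, c(0.2989, 0.5171, 0.3400), tolerance = 1e-4)
  expect_equal(round(or$ci_low[1], 2), 0.12)
  expect_equal(round(or$ci_high[1], 2), 0.75)
  expect_equal(round(or$ci_low[2], 3), 0.272)
  expect_equal(round(or$ci_high[2], 3), 0.985)
  expect_equal(round(or$ci_low[3], 3), 0.154)
  expect_equal(round(or$ci_high[3], 3), 0.749)
})

test_that("zero cells error by default and obey the continuity flag", {
  d <- counts_to_cohort(c(0, 5), c(20, 20))
  tab <- contingency_by_cluster(d, d$labels, reference = "B")
  expect_error(crude_or(tab), "zero cell")
  or <- crude_or(tab, continuity = TRUE)
  expect_equal(or$or, (0.5 * 15.5) / (20.5 * 5.5), tolerance = 1e-12)
  # equal case proportions give OR exactly 1
  d1 <- counts_to_cohort(c(5, 10), c(20, 40))
  expect_equal(crude_or(contingency_by_cluster(d1, d1$labels,
                                               reference = "B"))$or, 1)
})

test_that("single-predictor logistic ORs equal the closed-form cross-products", {
  d <- counts_to_cohort(printed_cases, printed_sizes)
  tab <- contingency_by_cluster(d, d$labels)
  closed <- crude_or(tab)
  fit <- fit_models(d, d$labels, model_specs(1))
  expect_equal(fit$or[match(closed$cluster, fit$cluster)], closed$or,
               tolerance = 1e-6)
  expect_equal(fit$ci_low[match(closed$cluster, fit$cluster)], closed$ci_low,
               tolerance = 1e-6)
})

test_that("the crude-model likelihood-ratio p reproduces the printed 0.006", {
  d <- counts_to_cohort(printed_cases, printed_sizes)
  fit <- fit_models(d, d$labels, model_specs(1))
  # independent oracle: G2 = 2 * sum(O * log(O/E)) on the 2x4 table, df 3
  O <- rbind(printed_cases, printed_sizes - printed_cases)
  E <- outer(rowSums(O), colSums(O)) / sum(O)
  g2 <- 2 * sum(O * log(O / E))
  p_oracle <- pchisq(g2, df = 3, lower.tail = FALSE)
  expect_equal(fit$lr_p[1], p_oracle, tolerance = 1e-9)
  expect_equal(round(fit$lr_p[1], 3), 0.006)
})

test_that("swapping the reference inverts odds ratios and swaps CI bounds", {
  d <- counts_to_cohort(printed_cases, printed_sizes)
  tab <- contingency_by_cluster(d, d$labels)
  fwd <- crude_or(tab, reference = "D")
  rev <- crude_or(tab, reference = "A")
  expect_equal(rev$or[rev$cluster == "D"], 1 / fwd$or[fwd$cluster == "A"],
               tolerance = 1e-12)
  expect_equal(rev$ci_low[rev$cluster == "D"],
               1 / fwd$ci_high[fwd$cluster == "A"], tolerance = 1e-12)
})

test_that("adding covariates never increases model deviance", {
  g <- generate_cohort(paper_like_preset(n = 400), seed = 21L)
  d <- g$cohort$data
  devs <- vapply(1:5, function(m) {
    spec <- model_specs(m)[[1]]
    rhs <- paste(c("factor(lab)", spec), collapse = " + ")
    dd <- d; dd$lab <- g$labels
    fit <- glm(as.formula(paste("incident_hypertension ~", rhs)),
               binomial(), dd)
    deviance(fit)
  }, numeric(1))
  expect_true(all(diff(devs) <= 1e-8))
  # and the packaged nested models run end-to-end on the same data
  res <- fit_models(g$cohort, g$labels, model_specs())
  expect_equal(nrow(res), 15)  # 5 models x 3 non-reference clusters
  expect_true(all(res$ci_low <= res$or & res$or <= res$ci_high))
  expect_true(all(res$or > 0))
})

test_that("descriptive comparisons use ANOVA / chi-square as typed", {
  # printed diabetes counts: (0, 2, 1, 14) of (75, 130, 100, 142)
  lab <- rep(0:3, printed_sizes)
  diab <- unlist(mapply(function(k, n) c(rep("yes", k), rep("no", n - k)),
                        c(0, 2, 1, 14), printed_sizes))
  d <- data.frame(id = seq_along(lab), diabetes = diab)
  res <- descriptive_compare(d, lab, "diabetes")
  expect_equal(res$test, "chisq")
  expect_lt(res$p, 0.001)

  # two groups: ANOVA p equals the equal-variance t-test p (F = t^2)
  set.seed(2)
  d2 <- data.frame(id = 1:60, age = rnorm(60, 45, 9))
  lab2 <- rep(0:1, 30)
  res2 <- descriptive_compare(d2, lab2, "age")
  t_p <- t.test(d2$age[lab2 == 0], d2$age[lab2 == 1], var.equal = TRUE)$p.value
  expect_equal(res2$p, t_p, tolerance = 1e-12)
  expect_true(res2$ks_p >= 0 && res2$ks_p <= 1)

  # constant variable: p undefined, reported as such
  d3 <- data.frame(id = 1:10, x = rep(1, 10))
  res3 <- descriptive_compare(d3, rep(0:1, 5), "x")
  expect_true(is.na(res3$p))
  expect_match(res3$note, "constant")
})

test_that("the cluster LR p is uniform under the null", {
  set.seed(17)
  n <- 400
  reps <- 200
  pvals <- vapply(seq_len(reps), function(r) {
    lab <- sample(0:3, n, TRUE)
    y <- rbinom(n, 1, 0.15)  # outcome independent of cluster
    d <- data.frame(id = seq_len(n), incident_hypertension = y)
    fit_models(d, lab, model_specs(1))$lr_p[1]
  }, numeric(1))
  ks <- suppressWarnings(ks.test(pvals, "punif"))
  expect_gt(ks$p.value, 0.01)
})
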