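test_that("map_weight returns the published point values", {
  sch <- bdhq_schema()
  expect_equal(map_weight(sch$variables$chicken, "2-3 times per week"), 4)
  expect_equal(map_weight(sch$variables$coffee, "4 or more cups per day"), 8)
  expect_equal(map_weight(sch$variables$breakfast, "daily"), 9)
  # lowest category is always 1 point, on every scale
  for (v in sch$variables)
    expect_equal(map_weight(v, v$scale_labels[1]), 1)
  expect_error(map_weight(sch$variables$chicken, "ten times/day"),
               "unknown label")
})

test_that("trend_score is the weighted proportion sum with its contract", {
  expect_equal(trend_score(7:1, c(0.5, 0.25, 0, 0.25, 0, 0, 0)), 6.0)
  expect_equal(trend_score(1:7, rep(1 / 7, 7)), 4.0)
  # degenerate distribution at any category returns that weight
  for (i in 1:7) {
    p <- rep(0, 7); p[i] <- 1
    expect_equal(trend_score(1:7, p), i)
  }
  expect_error(trend_score(1:7, rep(1 / 7, 7), n = 0), "empty cluster")
  expect_error(trend_score(1:5, rep(1 / 7, 7)), "length")
  expect_error(trend_score(1:7, rep(0.2, 7)), "sum to 1")
})

test_that("trend scores are bounded by the weight range and linear in pooling", {
  set.seed(42)
  for (rep in 1:20) {
    len <- sample(c(5, 7, 9), 1)
    w <- cumsum(c(1, runif(len - 1, 0.2, 2)))
    p <- as.vector(stats::rmultinom(1, 50, runif(len))) / 50
    s <- trend_score(w, p)
    expect_gte(s, min(w)); expect_lte(s, max(w))
    # pooling two equal-size clusters averages their scores
    p2 <- as.vector(stats::rmultinom(1, 50, runif(len))) / 50
    expect_equal(trend_score(w, (p + p2) / 2),
                 (trend_score(w, p) + trend_score(w, p2)) / 2,
                 tolerance = 1e-12)
  }
})

test_that("trend_table matches the independent proportion-sum oracle", {
  sch <- toy_schema()
  set.seed(7)
  n <- 60
  d <- toy_responses(sch, sample(7, n, TRUE), sample(9, n, TRUE),
                     sample(5, n, TRUE), sample(7, n, TRUE))
  co <- cohort(d, sch)
  labels <- rep(0:1, each = n / 2)
  tt <- trend_table(co, labels)
  # oracle: explicit sum of weight * within-cluster category proportion
  for (v in sch$variables) {
    for (cl in 0:1) {
      resp <- d[[v$id]][labels == cl]
      prop <- table(factor(resp, levels = v$scale_labels)) / length(resp)
      oracle <- sum(v$weight_map[v$scale_labels] * as.numeric(prop))
      expect_equal(tt$scores[cl + 1, v$id], oracle, tolerance = 1e-12)
    }
  }
})

test_that("planted cluster differences appear only in the differing variable", {
  sch <- toy_schema()
  n <- 40
  # identical multisets everywhere except coffee (cluster 1 drinks more)
  base <- rep(1:5, 8)
  d <- toy_responses(sch,
                     coffee = c(rep(2, n), rep(6, n)),
                     alcohol = rep(base, 2),
                     noodle = rep(rep(1:5, 8), 2),
                     grill = rep(base, 2))
  co <- cohort(d, sch)
  labels <- rep(0:1, each = n)
  tt <- trend_table(co, labels)
  expect_gt(abs(diff(tt$scores[, "coffee"])), 3.9)
  expect_lt(tt$p_value["coffee"], 1e-10)
  # identical distributions: equal scores, F = 0, p = 1
  for (v in c("alcohol_frequency", "noodle_soup", "grilled_fish")) {
    expect_equal(diff(tt$scores[, v]), 0, ignore_attr = TRUE)
    expect_equal(unname(tt$p_value[v]), 1)
  }
})

test_that("degenerate and single-cluster trend tables behave", {
  sch <- toy_schema()
  n <- 20
  d <- toy_responses(sch, rep(1, n), rep(1, n), rep(1, n), rep(1, n))
  co <- cohort(d, sch)
  tt <- trend_table(co, rep(0L, n))
  expect_true(all(tt$scores == 1))   # everyone in the lowest category
  expect_true(all(is.na(tt$p_value)))  # constant: no cross-cluster test
  rk <- rank_clusters(tt)
  expect_true(all(rk$n_max == rk$n_total))  # single cluster holds every max
  expect_error(trend_table(co, rep(c(0L, NA), n / 2)), "assigned")
})

test_that("rank_clusters counts category-wise maxima with shared ties", {
  sch <- toy_schema()
  n <- 30
  d <- toy_responses(sch,
                     coffee = c(rep(6, n), rep(2, n)),
                     alcohol = c(rep(2, n), rep(8, n)),
                     noodle = rep(3, 2 * n),
                     grill = c(rep(5, n), rep(1, n)))
  co <- cohort(d, sch)
  tt <- trend_table(co, rep(0:1, each = n))
  rk <- rank_clusters(tt)
  get <- function(cl, cat) rk$n_max[rk$cluster == cl & rk$category == cat]
  expect_equal(get("A", "food_item"), 1)        # coffee
  expect_equal(get("B", "food_item"), 1)        # alcohol
  expect_equal(get("A", "cooking_method"), 1)   # grill
  expect_equal(get("B", "cooking_method"), 0)
  # noodle is tied: both clusters share the maximum
  expect_equal(get("A", "dietary_behavior"), 1)
  expect_equal(get("B", "dietary_behavior"), 1)
  expect_equal(rk$summary[rk$cluster == "A" & rk$category == "food_item"],
               "1/2 items")
})
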