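# Small in-code fixtures shared across test files.

# A 4-variable schema (one per scale family) written through the YAML
# interface so tests exercise the same constructor users do.
toy_schema <- function() {
  path <- tempfile(fileext = ".yaml")
  yaml::write_yaml(list(
    scales = list(
      freq7 = list(labels = as.list(c("never", "rare", "weekly", "often",
                                      "most days", "daily", "2+ daily")),
                   weights = as.list(1:7)),
      freq9 = list(labels = as.list(paste0("f", 1:9)), weights = as.list(1:9)),
      beh5 = list(labels = as.list(c("very low", "low", "medium", "high",
                                     "very high")),
                  weights = as.list(1:5))
    ),
    variables = list(
      list(id = "coffee", category = "food_item", scale = "freq7"),
      list(id = "alcohol_frequency", category = "food_item", scale = "freq9"),
      list(id = "noodle_soup", category = "dietary_behavior", scale = "beh5"),
      list(id = "grilled_fish", category = "cooking_method", scale = "freq7")
    )), path)
  read_schema(path)
}

# data.frame of toy responses; each argument is a vector of scale positions
toy_responses <- function(schema, coffee, alcohol, noodle, grill,
                          id = NULL) {
  v <- schema$variables
  n <- length(coffee)
  data.frame(
    id = if (is.null(id)) sprintf("T%03d", seq_len(n)) else id,
    coffee = v$coffee$scale_labels[coffee],
    alcohol_frequency = v$alcohol_frequency$scale_labels[alcohol],
    noodle_soup = v$noodle_soup$scale_labels[noodle],
    grilled_fish = v$grilled_fish$scale_labels[grill],
    stringsAsFactors = FALSE)
}

# Expand printed per-cluster (cases, size) counts into participant rows.
counts_to_cohort <- function(cases, n) {
  labels <- rep(seq_along(n) - 1L, n)
  y <- unlist(lapply(seq_along(n), function(i)
    c(rep(1L, cases[i]), rep(0L, n[i] - cases[i]))))
  data.frame(id = sprintf("C%04d", seq_along(labels)),
             incident_hypertension = y, labels = labels)
}

# 2D Gaussian blobs for k-selection tests
gaussian_blobs <- function(centers, n_per, sd = 0.5, seed = 1) {
  set.seed(seed)
  do.call(rbind, lapply(seq_len(nrow(centers)), function(i)
    cbind(rnorm(n_per, centers[i, 1], sd), rnorm(n_per, centers[i, 2], sd))))
}
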