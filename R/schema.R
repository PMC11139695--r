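#' Response scales used by the packaged questionnaire schema
#'
#' Each scale is an ordered set of response labels together with the point
#' value ("weight") assigned to each label for trend scoring. Weights are
#' strictly increasing and start at 1 for the lowest-consumption category.
#'
#' @return Named list of scales; each scale has `labels` and `weights`.
#' @keywords internal
bdhq_scales <- function() {
  list(
    freq7 = list(
      labels = c("never", "less than once per week", "once per week",
                 "2-3 times per week", "4-6 times per week", "once per day",
                 "2 or more times per day"),
      weights = 1:7
    ),
    bev8 = list(
      labels = c("never", "less than 1 cup per week", "1 cup per week",
                 "2-3 cups per week", "4-6 cups per week", "1 cup per day",
                 "2-3 cups per day", "4 or more cups per day"),
      weights = 1:8
    ),
    freq9 = list(
      labels = c("never", "less than once per week", "once per week",
                 "twice per week", "3 times per week", "4 times per week",
                 "5 times per week", "6 times per week", "daily"),
      weights = 1:9
    ),
    alc7 = list(
      labels = c("never", "less than 0.5 cup per week", "0.5 cup per week",
                 "1 cup per week", "2 cups per day", "3 cups per day",
                 "4 or more cups per day"),
      weights = 1:7
    ),
    beh5 = list(
      labels = c("very low", "low", "medium", "high", "very high"),
      weights = 1:5
    ),
    yn2 = list(
      labels = c("no", "yes"),
      weights = 1:2
    )
  )
}

# variable id -> (category, scale) table for the packaged 79-item instrument:
# 58 food/beverage items, 12 dietary behaviors, 9 cooking methods.
bdhq_variable_table <- function() {
  food7 <- c(
    "reduced_fat_milk_yogurt", "milk_yogurt", "chicken", "pork_beef",
    "ham_sausage_bacon", "liver", "squid_octopus_shrimp_shellfish",
    "small_fish_with_bones", "canned_tuna", "dried_salted_fish", "oily_fish",
    "lean_fish", "egg", "tofu", "natto", "potatoes",
    "pickled_green_leafy_vegetables", "other_pickled_vegetables",
    "lettuce_cabbage_raw", "green_leafy_vegetables", "cabbage_chinese_cabbage",
    "carrots_pumpkin", "japanese_radish_turnip", "other_root_vegetables",
    "tomatoes", "mushrooms", "seaweeds", "western_confectioneries",
    "japanese_confectioneries", "rice_crackers", "ice_cream", "citrus_fruit",
    "persimmon_strawberry_kiwifruit", "other_fruits", "mayonnaise", "bread",
    "buckwheat_noodles", "japanese_wheat_noodles", "chinese_noodles", "pasta",
    "other_grains", "sugar", "citrus_fruit_seasonal", "persimmon_seasonal",
    "strawberry_seasonal"
  )
  beverages <- c("green_tea", "black_tea_oolong_tea", "coffee",
                 "cola_soft_drink", "juice")
  food9 <- c("rice", "miso_soup", "alcohol_frequency")
  alcohol <- c("sake", "beer", "shochu", "whisky", "wine")
  behaviors5 <- c("noodle_soup", "seasoning_taste", "meat_fat_preference",
                  "soy_sauce_amount", "soy_sauce_frequency", "side_dishes",
                  "rice_amount", "eating_speed")
  cooking <- c("raw_fish", "grilled_fish", "boiled_fish", "fried_fish",
               "grilled_meat", "hamburg_curry", "deep_fried_meat",
               "stir_fried_meat", "stewed_meat")
  rbind(
    data.frame(id = food7, category = "food_item", scale = "freq7"),
    data.frame(id = beverages, category = "food_item", scale = "bev8"),
    data.frame(id = food9, category = "food_item", scale = "freq9"),
    data.frame(id = alcohol, category = "food_item", scale = "alc7"),
    data.frame(id = behaviors5, category = "dietary_behavior", scale = "beh5"),
    data.frame(id = "breakfast", category = "dietary_behavior", scale = "freq9"),
    data.frame(id = "supplements", category = "dietary_behavior", scale = "freq7"),
    data.frame(id = c("eating_habit_change", "dietary_guidance"),
               category = "dietary_behavior", scale = "yn2"),
    data.frame(id = cooking, category = "cooking_method", scale = "freq7")
  )
}

#' Build the packaged 79-variable diet-history questionnaire schema
#'
#' The schema describes 58 food/beverage items, 12 dietary behaviors and 9
#' cooking methods, each with an ordered response scale (2, 5, 7, 8 or 9
#' categories) and an integer weight per category used for trend scoring.
#' Most food items sit on a 7-point frequency scale; non-alcoholic beverages
#' on an 8-point cups-per-day scale; rice, miso soup, overall alcohol
#' frequency and breakfast on a 9-point weekly-frequency scale; the five
#' specified alcoholic drinks on a 7-point cups scale; most behaviors on a
#' generic 5-point scale, with two yes/no items and supplements on the
#' 7-point frequency scale.
#'
#' @return An object of class `dc_schema`: a list of variable definitions,
#'   each with `id`, `category`, `scale_labels` and `weight_map`.
#' @export
#' @examples
#' sch <- bdhq_schema()
#' length(sch$variables)          # 79
#' table(schema_categories(sch))  # 58 food, 12 behavior, 9 cooking
bdhq_schema <- function() {
  scales <- bdhq_scales()
  tab <- bdhq_variable_table()
  vars <- lapply(seq_len(nrow(tab)), function(i) {
    sc <- scales[[tab$scale[i]]]
    list(id = tab$id[i], category = tab$category[i],
         scale_labels = sc$labels,
         weight_map = stats::setNames(sc$weights, sc$labels))
  })
  names(vars) <- tab$id
  new_schema(vars)
}

new_schema <- function(variables) {
  obj <- structure(list(variables = variables), class = "dc_schema")
  validate_schema(obj)
  obj
}

#' @export
print.dc_schema <- function(x, ...) {
  cat("Questionnaire schema:", length(x$variables), "variables\n")
  print(table(schema_categories(x)))
  invisible(x)
}

#' Variable categories of a schema
#' @param schema a `dc_schema`
#' @return character vector, one category per variable
#' @export
schema_categories <- function(schema) {
  vapply(schema$variables, function(v) v$category, character(1))
}

#' Variable ids of a schema
#' @param schema a `dc_schema`
#' @return character vector of variable ids
#' @export
schema_ids <- function(schema) {
  vapply(schema$variables, function(v) v$id, character(1))
}

validate_schema <- function(schema) {
  for (v in schema$variables) {
    stopifnot(is.character(v$id), length(v$id) == 1)
    if (!v$category %in% c("food_item", "dietary_behavior", "cooking_method"))
      stop("unknown category '", v$category, "' for variable ", v$id)
    nl <- length(v$scale_labels)
    if (!nl %in% c(2, 5, 7, 8, 9))
      stop("variable ", v$id, ": scale length ", nl, " not in {2,5,7,8,9}")
    w <- v$weight_map[v$scale_labels]
    if (anyNA(w))
      stop("variable ", v$id, ": weight_map does not cover all scale labels")
    if (any(diff(w) <= 0))
      stop("variable ", v$id, ": weights must be strictly increasing over the scale")
    if (min(w) < 1)
      stop("variable ", v$id, ": minimum weight must be >= 1")
  }
  if (anyDuplicated(schema_ids(schema)))
    stop("duplicate variable ids in schema")
  invisible(schema)
}

#' Read a questionnaire schema from YAML
#'
#' The YAML file lists shared `scales` (labels + weights) and `variables`
#' (id, category, scale reference). The packaged schema is available via
#' `system.file("extdata", "bdhq_schema.yaml", package = "dietclust")`.
#'
#' @param path path to a schema YAML file
#' @return a `dc_schema`
#' @export
read_schema <- function(path) {
  y <- yaml::read_yaml(path)
  if (is.null(y$scales) || is.null(y$variables))
    stop("schema file must contain 'scales' and 'variables' sections")
  vars <- lapply(y$variables, function(v) {
    sc <- y$scales[[v$scale]]
    if (is.null(sc)) stop("variable ", v$id, " references unknown scale '", v$scale, "'")
    list(id = v$id, category = v$category,
         scale_labels = as.character(sc$labels),
         weight_map = stats::setNames(as.numeric(sc$weights),
                                      as.character(sc$labels)))
  })
  names(vars) <- vapply(vars, function(v) v$id, character(1))
  new_schema(vars)
}

#' Write a questionnaire schema to YAML
#'
#' Identical scales are pooled into a shared `scales` section so the file
#' round-trips through [read_schema()].
#'
#' @param schema a `dc_schema`
#' @param path output path
#' @return `path`, invisibly
#' @export
write_schema <- function(schema, path) {
  sigs <- vapply(schema$variables, function(v)
    paste(c(v$scale_labels, unname(v$weight_map[v$scale_labels])), collapse = "\x01"),
    character(1))
  u <- unique(sigs)
  scale_names <- paste0("scale", match(sigs, u))
  scales <- list()
  for (i in match(u, sigs)) {
    v <- schema$variables[[i]]
    scales[[scale_names[i]]] <- list(
      labels = as.list(v$scale_labels),
      weights = as.list(unname(v$weight_map[v$scale_labels])))
  }
  variables <- lapply(seq_along(schema$variables), function(i) {
    v <- schema$variables[[i]]
    list(id = v$id, category = v$category, scale = scale_names[i])
  })
  yaml::write_yaml(list(scales = scales, variables = variables), path)
  invisible(path)
}
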