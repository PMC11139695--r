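#' Derive a per-stage seed from a global seed
#'
#' Fans one global seed out to named stages (simple string-hash mixing kept
#' below 2^31) so stages stay individually reproducible under reordering.
#'
#' @param seed global integer seed
#' @param stage stage name
#' @return integer seed
#' @export
stage_seed <- function(seed, stage) {
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer((as.numeric(seed) * 7919 + h * 104729) %% 2147483647)
}

#' Run the full dietary-pattern analysis pipeline
#'
#' Orchestrates: cohort acquisition (a scenario to simulate, or a CSV +
#' schema to load) -> optional exclusion cascade -> ordinal encoding ->
#' 2D embedding -> cluster-number selection -> K-means assignment -> trend
#' table -> crude and adjusted odds-ratio models -> age-matched sensitivity
#' reruns -> DASH comparison, writing every artifact plus a manifest into
#' `out_dir`.
#'
#' @param scenario a `dc_scenario` (mutually exclusive with `cohort_path`)
#' @param cohort_path,schema_path delimited cohort + schema YAML to load
#' @param out_dir output directory (created if needed); NULL skips writing
#' @param config a `dc_config` for the clustering stage
#' @param k fixed number of clusters; NULL selects automatically
#' @param models integer subset of 1:5
#' @param calipers age-matching tolerances for the sensitivity rerun
#' @param seed global seed fanned out to the stochastic stages
#' @return a `dc_run` list: `cohort`, `cascade`, `embedding`, `selection`,
#'   `assignment`, `trend`, `contingency`, `crude`, `models`, `matched`,
#'   `dash`, `manifest`
#' @export
run_pipeline <- function(scenario = NULL, cohort_path = NULL,
                         schema_path = NULL, out_dir = NULL,
                         config = NULL, k = NULL, models = 1:5,
                         calipers = c(0, 2), seed = 1L) {
  if (is.null(scenario) == is.null(cohort_path))
    stop("provide exactly one of 'scenario' or 'cohort_path'")
  if (is.null(config))
    config <- clustering_config(seed = stage_seed(seed, "embed"))

  latent <- NULL
  if (!is.null(scenario)) {
    sim <- generate_cohort(scenario, seed = stage_seed(seed, "simulate"))
    coh <- sim$cohort
    latent <- sim$labels
  } else {
    coh <- load_cohort(cohort_path, schema_path)
  }

  casc <- NULL
  if (all(c("consented", "female", "followed_up") %in% names(coh$data))) {
    ids_before <- coh$data$id
    ex <- apply_exclusion_cascade(coh, paper_exclusion_steps())
    coh <- ex$cohort; casc <- ex$cascade
    if (!is.null(latent)) latent <- latent[match(coh$data$id, ids_before)]
  }

  X <- encode_matrix(coh)
  emb <- embed_matrix(X, config)
  sel <- select_k(emb, config = config)
  k_used <- if (is.null(k)) sel$k else k
  asg <- kmeans_assign(emb, k_used, config, diagnostics = sel$diagnostics)

  trend <- trend_table(coh, asg)
  tab <- contingency_by_cluster(coh, asg)
  crude <- crude_or(tab)
  mods <- fit_models(coh, asg, model_specs(models), reference = tab$reference)
  matched <- matched_sensitivity(coh, asg, calipers = calipers,
                                 models = models, reference = tab$reference)
  comp <- dash_components()$component
  dash <- NULL
  if (all(comp %in% names(coh$data))) {
    ds <- dash_score(coh$data[comp])
    dash <- dash_by_cluster(ds, asg, reference = tab$reference)
  }

  run <- list(cohort = coh, cascade = casc, embedding = emb, selection = sel,
              assignment = asg, trend = trend, contingency = tab,
              crude = crude, models = mods, matched = matched, dash = dash,
              latent = latent, seed = seed, config = config)
  if (!is.null(out_dir)) run$manifest <- write_run(run, out_dir)
  class(run) <- "dc_run"
  run
}

#' @export
print.dc_run <- function(x, ...) {
  cat("Pipeline run (seed", x$seed, ")\n")
  if (!is.null(x$cascade)) print(x$cascade)
  cat("Selected k =", x$assignment$k,
      if (isTRUE(x$selection$agreed)) "(diagnostics agree)" else
        "(diagnostics disagree; silhouette optimum used)", "\n")
  print(x$contingency)
  print(x$crude)
  invisible(x)
}

write_run <- function(run, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  p <- function(f) file.path(out_dir, f)
  write_cohort(run$cohort, p("cohort.csv"))
  if (!is.null(run$cascade)) cascade_to_json(run$cascade, p("cascade.json"))
  utils::write.csv(data.frame(id = run$cohort$data$id, run$embedding,
                              cluster = run$assignment$labels),
                   p("embedding.csv"), row.names = FALSE)
  write_trend_table(run$trend, p("trend_table.csv"))
  utils::write.csv(as.data.frame(run$models), p("or_models.csv"),
                   row.names = FALSE)
  utils::write.csv(as.data.frame(run$crude), p("or_crude.csv"),
                   row.names = FALSE)
  for (nm in names(run$matched))
    utils::write.csv(as.data.frame(run$matched[[nm]]),
                     p(paste0("or_", nm, ".csv")), row.names = FALSE)
  diag <- run$selection$diagnostics
  utils::write.csv(data.frame(k = diag$k_range, wcss = diag$wcss,
                              silhouette = diag$silhouette),
                   p("k_diagnostics.csv"), row.names = FALSE)
  cfg_path <- p("config.yaml")
  yaml::write_yaml(list(seed = run$seed,
                        config = unclass(run$config)[!vapply(run$config,
                                                             is.null,
                                                             logical(1))]),
                   cfg_path)
  manifest <- list(
    seed = run$seed,
    config_md5 = unname(tools::md5sum(cfg_path)),
    n_participants = n_participants(run$cohort),
    k = run$assignment$k,
    kde_peak_count = diag$kde_peak_count,
    files = list.files(out_dir))
  jsonlite::write_json(manifest, p("manifest.json"), auto_unbox = TRUE,
                       pretty = TRUE)
  manifest
}
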