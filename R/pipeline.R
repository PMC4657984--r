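# End-to-end orchestration: simulate -> extract -> search, driven by a
# YAML run configuration. The thin command-line wrapper in
# inst/scripts/crownpheno.R calls these functions.

#' Default run configuration
#'
#' Defaults mirror the protocol's stated parameters: 0.50 m inward crown
#' buffer, 20% relative-intensity shadow cut, 500-tree forests repeated 20
#' times on 50 crowns per species.
#'
#' @param ... Named overrides of any field.
#' @return A list of class `run_config`.
#' @export
default_run_config <- function(...) {
  cfg <- list(
    out_dir = "crownpheno_run",
    manifest = NULL,            # set after simulate, or point at real data
    crowns = NULL,
    preset = "paper_like",
    n_crowns_per_species = 12,
    dates = NULL,
    buffer_m = 0.50,
    shadow_threshold = 20,
    min_sunlit = 10,
    glcm = list(levels = 32, offsets = GLCM_OFFSETS_DEFAULT),
    rf = list(n_trees = 500, n_repetitions = 20, n_per_class = 50),
    families = c("k1", "k2", "k3"),
    top_m = 5,
    seed = 1L
  )
  overrides <- list(...)
  for (nm in names(overrides)) cfg[[nm]] <- overrides[[nm]]
  structure(cfg, class = "run_config")
}

#' Read a run configuration from YAML
#'
#' Unstated fields fall back to [default_run_config()] values.
#'
#' @param path YAML file.
#' @return A `run_config`.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop("config not found: ", path, call. = FALSE)
  user <- yaml::read_yaml(path)
  cfg <- default_run_config()
  for (nm in names(user)) {
    if (is.list(cfg[[nm]]) && is.list(user[[nm]])) {
      for (sub in names(user[[nm]])) cfg[[nm]][[sub]] <- user[[nm]][[sub]]
    } else {
      cfg[[nm]] <- user[[nm]]
    }
  }
  cfg$seed <- as.integer(cfg$seed)
  cfg
}

#' Simulate a synthetic world to disk
#'
#' @param config A `run_config`.
#' @return The manifest path, invisibly.
#' @export
pipeline_simulate <- function(config) {
  phen <- make_phenology(config$preset, seed = config$seed)
  sc <- scene_config(n_crowns_per_species = config$n_crowns_per_species,
                     seed = config$seed, dates = config$dates)
  world <- generate_world(phen, sc)
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  manifest <- write_world(world, file.path(config$out_dir, "world"))
  message("world written: ", dirname(manifest))
  invisible(manifest)
}

#' Extract the feature table for a study
#'
#' @param config A `run_config` whose `manifest` and `crowns` point at a
#'   study on disk (after [pipeline_simulate()] the default locations
#'   under `out_dir/world/` are used).
#' @return The feature table, invisibly; written to
#'   `out_dir/features.csv` (+ JSON sidecar).
#' @export
pipeline_extract <- function(config) {
  manifest <- config$manifest %||% file.path(config$out_dir, "world", "manifest.csv")
  crowns_path <- config$crowns %||% file.path(config$out_dir, "world", "crowns.geojson")
  layers <- load_study(manifest)
  crowns <- read_crowns(crowns_path)
  offs <- lapply(config$glcm$offsets, as.integer)
  ft <- withCallingHandlers(
    build_feature_table(layers, crowns, buffer_m = config$buffer_m,
                        shadow_threshold = config$shadow_threshold,
                        min_sunlit = config$min_sunlit,
                        glcm_levels = config$glcm$levels,
                        glcm_offsets = offs),
    warning = function(w) {
      message("drop log: ", conditionMessage(w))
      invokeRestart("muffleWarning")
    })
  write_feature_table(ft, file.path(config$out_dir, "features.csv"))
  invisible(ft)
}

#' Rank date combinations for a study
#'
#' Runs the requested scenario families (`k1` also produces the per-camera
#' comparison for every survey) and writes ranked CSV/JSON plus a
#' plain-text summary per family.
#'
#' @param config A `run_config`.
#' @param table Optional in-memory feature table; read from
#'   `out_dir/features.csv` when absent.
#' @return Named list of `scenario_ranking` objects, invisibly.
#' @export
pipeline_search <- function(config, table = NULL) {
  if (is.null(table)) {
    table <- read_feature_table(file.path(config$out_dir, "features.csv"))
  }
  survey_ids <- sort(unique(attr(table, "surveys")$survey_id))
  rf <- config$rf
  out <- list()
  for (family in config$families) {
    k <- as.integer(sub("^k", "", family))
    scenarios <- enumerate_scenarios(survey_ids, k)
    ranking <- rank_scenarios(table, scenarios,
                              n_repetitions = rf$n_repetitions,
                              n_trees = rf$n_trees,
                              n_per_class = rf$n_per_class,
                              seed = config$seed)
    stem <- file.path(config$out_dir, paste0("ranking_", family))
    df <- as.data.frame(ranking)
    df$earliest_date <- format(df$earliest_date)
    utils::write.csv(df, paste0(stem, ".csv"), row.names = FALSE)
    jsonlite::write_json(df, paste0(stem, ".json"), auto_unbox = TRUE,
                         digits = NA)
    txt <- utils::capture.output(format_ranking(ranking, config$top_m))
    writeLines(txt, paste0(stem, ".txt"))
    out[[family]] <- ranking
  }
  invisible(out)
}

#' Read back a persisted feature table
#'
#' @param path CSV written by [write_feature_table()].
#' @return A `feature_table` data frame (survey metadata reconstructed
#'   from the column namespace; dates unavailable are `NA`).
#' @export
read_feature_table <- function(path) {
  if (!file.exists(path)) stop("feature table not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  cols <- setdiff(names(df), c("crown_id", "species"))
  parts <- strsplit(cols, ".", fixed = TRUE)
  meta <- unique(data.frame(
    survey_id = vapply(parts, `[[`, "", 1),
    camera = vapply(parts, `[[`, "", 2),
    stringsAsFactors = FALSE))
  meta$date <- as.Date(NA)
  cal <- survey_calendar()
  known <- match(meta$survey_id, cal$survey_id)
  meta$date[!is.na(known)] <- cal$date[known[!is.na(known)]]
  attr(df, "surveys") <- meta
  class(df) <- c("feature_table", "data.frame")
  df
}
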