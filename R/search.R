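# Exhaustive ranking of acquisition-date combinations and camera
# configurations by averaged out-of-bag error.

#' Enumerate date-combination scenarios
#'
#' All size-`k` subsets of the survey ids, each bound to the requested
#' camera set. Multi-date scenarios conventionally combine both cameras
#' (a "survey" is the RGB + CIR flight pair).
#'
#' @param survey_ids Character vector of survey ids.
#' @param k Combination size, 1–3.
#' @param cameras Cameras whose metric columns the scenarios use (default
#'   both).
#' @return List of scenario descriptors (`id`, `surveys`, `cameras`).
#' @export
enumerate_scenarios <- function(survey_ids, k, cameras = c("RGB", "CIR")) {
  stopifnot(k >= 1, k <= 3)
  survey_ids <- sort(unique(survey_ids))
  if (k > length(survey_ids)) {
    stop("k = ", k, " exceeds the ", length(survey_ids),
         " available surveys", call. = FALSE)
  }
  cameras <- match.arg(cameras, c("RGB", "CIR"), several.ok = TRUE)
  combos <- utils::combn(survey_ids, k, simplify = FALSE)
  lapply(combos, function(sv) {
    list(id = paste0(paste(sv, collapse = "+"), ":",
                     paste(cameras, collapse = "+")),
         surveys = sv, cameras = cameras)
  })
}

# deterministic per-scenario seed: stable hash of master seed + identity,
# so adding scenarios never perturbs existing results
scenario_seed <- function(master_seed, surveys, cameras) {
  key <- paste(c(sort(surveys), sort(cameras)), collapse = "|")
  h <- as.double(master_seed %% 2147483647L)
  for (code in utf8ToInt(key)) {
    h <- (h * 131 + code) %% 2147483647
  }
  as.integer(h)
}

#' Rank scenarios by averaged out-of-bag error
#'
#' Evaluates every scenario with [run_scenario()] under a deterministic
#' per-scenario seed and sorts ascending by overall OOB error. Ties break
#' by earliest survey date in the combination, then lexicographic scenario
#' id, so the ranking is a well-defined permutation.
#'
#' @param table A feature table carrying the scenarios' columns.
#' @param scenarios [enumerate_scenarios()] output.
#' @param n_repetitions,n_trees,n_per_class Forwarded to [run_scenario()].
#' @param seed Master seed.
#' @return Data frame of class `scenario_ranking`: `rank`, `scenario_id`,
#'   `surveys`, `cameras`, `overall_oob`, one `oob_<species>` column per
#'   class; full reports in the `"reports"` attribute (by scenario id).
#' @export
rank_scenarios <- function(table, scenarios, n_repetitions = 20,
                           n_trees = 500, n_per_class = 50, seed = 1L) {
  stopifnot(length(scenarios) >= 1)
  meta <- attr(table, "surveys")
  reports <- list()
  rows <- list()
  for (sc in scenarios) {
    cols <- feature_columns(table, surveys = sc$surveys, cameras = sc$cameras)
    if (length(cols) == 0) {
      stop("scenario ", sc$id, ": no matching feature columns", call. = FALSE)
    }
    rep_seed <- scenario_seed(seed, sc$surveys, sc$cameras)
    report <- tryCatch(
      run_scenario(table, cols, n_repetitions, n_trees, n_per_class, rep_seed),
      error = function(e) {
        stop("scenario ", sc$id, ": ", conditionMessage(e), call. = FALSE)
      })
    reports[[sc$id]] <- report
    earliest <- if (!is.null(meta)) {
      min(meta$date[meta$survey_id %in% sc$surveys])
    } else as.Date(NA)
    row <- data.frame(scenario_id = sc$id,
                      surveys = paste(sc$surveys, collapse = "+"),
                      cameras = paste(sc$cameras, collapse = "+"),
                      overall_oob = report$overall_oob,
                      earliest_date = earliest,
                      stringsAsFactors = FALSE)
    for (cl in names(report$per_class_oob)) {
      row[[paste0("oob_", cl)]] <- report$per_class_oob[[cl]]
    }
    rows[[sc$id]] <- row
  }
  out <- do.call(rbind, rows)
  ord <- order(out$overall_oob, out$earliest_date, out$scenario_id)
  out <- out[ord, , drop = FALSE]
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  out <- out[, c("rank", setdiff(names(out), "rank"))]
  attr(out, "reports") <- reports
  class(out) <- c("scenario_ranking", "data.frame")
  out
}

#' Top scenarios of a ranking
#' @param ranking A [rank_scenarios()] result.
#' @param m How many to keep (default 5).
#' @return The first `m` rows.
#' @export
top_scenarios <- function(ranking, m = 5) {
  utils::head(as.data.frame(ranking), m)
}

#' Compare cameras on a single survey date
#'
#' Classifies one survey three ways — RGB metrics only, CIR metrics only,
#' and both combined — under the same seed and therefore the same balanced
#' samples, isolating the camera effect.
#'
#' @param table A feature table holding both cameras for `survey_id`.
#' @param survey_id The survey to compare.
#' @param n_repetitions,n_trees,n_per_class,seed As in [run_scenario()].
#' @return Data frame with rows `RGB`, `CIR`, `RGB+CIR` (overall and
#'   per-class OOB, feature counts); reports in the `"reports"` attribute.
#' @export
camera_comparison <- function(table, survey_id, n_repetitions = 20,
                              n_trees = 500, n_per_class = 50, seed = 1L) {
  modes <- list(RGB = "RGB", CIR = "CIR", `RGB+CIR` = c("RGB", "CIR"))
  for (cam in c("RGB", "CIR")) {
    if (length(feature_columns(table, survey_id, cam)) == 0) {
      stop("camera ", cam, " has no columns for survey ", survey_id,
           call. = FALSE)
    }
  }
  shared_seed <- scenario_seed(seed, survey_id, c("RGB", "CIR"))
  reports <- list()
  rows <- list()
  for (nm in names(modes)) {
    cols <- feature_columns(table, surveys = survey_id, cameras = modes[[nm]])
    report <- run_scenario(table, cols, n_repetitions, n_trees, n_per_class,
                           shared_seed)
    reports[[nm]] <- report
    row <- data.frame(mode = nm, n_features = length(cols),
                      overall_oob = report$overall_oob,
                      stringsAsFactors = FALSE)
    for (cl in names(report$per_class_oob)) {
      row[[paste0("oob_", cl)]] <- report$per_class_oob[[cl]]
    }
    rows[[nm]] <- row
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "reports") <- reports
  out
}

#' Plain-text summary of a ranking, one line per scenario
#'
#' @param ranking A [rank_scenarios()] result.
#' @param m Lines to show (default all).
#' @return Character vector of formatted lines, invisibly; printed as a
#'   side effect.
#' @export
format_ranking <- function(ranking, m = nrow(ranking)) {
  df <- utils::head(as.data.frame(ranking), m)
  class_cols <- grep("^oob_", names(df), value = TRUE)
  lines <- c(
    sprintf("%-4s %-22s %-8s %-9s %s", "rank", "surveys", "cameras",
            "OOB [%]", paste(sub("^oob_", "", class_cols), collapse = " ")),
    vapply(seq_len(nrow(df)), function(i) {
      sprintf("%-4d %-22s %-8s %-9.1f %s", df$rank[i], df$surveys[i],
              df$cameras[i], 100 * df$overall_oob[i],
              paste(sprintf("%.0f", 100 * unlist(df[i, class_cols])),
                    collapse = " "))
    }, "")
  )
  cat(lines, sep = "\n")
  invisible(lines)
}
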