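# Balanced repeated random-forest classification scored by averaged
# out-of-bag error.

#' Draw a balanced per-species sample of crowns
#'
#' Sampling an equal number of crowns per species before every forest fit
#' removes the class-imbalance bias a raw inventory (e.g. 72 birches vs
#' 196 ashes) would otherwise inject into the error estimate.
#'
#' @param table A feature table ([build_feature_table()]) or any data frame
#'   with a `species` column.
#' @param n_per_class Crowns to draw per species, without replacement
#'   (default 50).
#' @param seed Integer seed; the same seed reproduces the same subset.
#' @return The sampled subset of `table`.
#' @export
balanced_sample <- function(table, n_per_class = 50, seed = 1L) {
  counts <- table(table$species)
  short <- counts[counts < n_per_class]
  if (length(short) > 0) {
    stop("species with fewer than n_per_class = ", n_per_class, " crowns: ",
         paste(sprintf("%s (%d)", names(short), short), collapse = ", "),
         call. = FALSE)
  }
  with_seed(seed, {
    idx <- unlist(lapply(sort(unique(table$species)), function(sp) {
      sample(which(table$species == sp), n_per_class)
    }))
    table[sort(idx), , drop = FALSE]
  })
}

#' Repeated balanced random-forest classification of one scenario
#'
#' Runs `n_repetitions` independent random forests, each on a fresh
#' balanced sample of `n_per_class` crowns per species, and averages their
#' out-of-bag misclassification errors. Out-of-bag votes are tallied with
#' a deterministic tie-break (first label in sorted species order). Rows
#' carrying any missing metric among the selected columns are excluded
#' before sampling.
#'
#' @param table A feature table with a `species` column.
#' @param feature_columns Character vector of metric columns to use;
#'   `NULL` means all metric columns.
#' @param n_repetitions Number of forests (default 20).
#' @param n_trees Trees per forest (default 500).
#' @param n_per_class Balanced sample size per species (default 50).
#' @param seed Master seed; repetition `r` uses `seed + r`.
#' @return An object of class `classification_report`: `overall_oob`
#'   (mean misclassified fraction), `per_class_oob` (named, averaged over
#'   repetitions), `confusion` (pooled counts, rows = truth, sorted
#'   species order), `per_repetition_oob`, `settings`.
#' @export
run_scenario <- function(table, feature_columns = NULL, n_repetitions = 20,
                         n_trees = 500, n_per_class = 50, seed = 1L) {
  cols <- feature_columns %||%
    setdiff(names(table), c("crown_id", "species"))
  if (length(cols) == 0) {
    stop("empty feature column selection", call. = FALSE)
  }
  missing_cols <- setdiff(cols, names(table))
  if (length(missing_cols) > 0) {
    stop("feature columns not in table: ",
         paste(utils::head(missing_cols, 5), collapse = ", "), call. = FALSE)
  }
  complete <- stats::complete.cases(table[, cols, drop = FALSE])
  tab <- table[complete, , drop = FALSE]
  classes <- sort(unique(tab$species))
  if (length(classes) < 2) {
    stop("need at least 2 species classes, got ", length(classes),
         call. = FALSE)
  }
  counts <- table(tab$species)
  if (any(counts < n_per_class)) {
    short <- counts[counts < n_per_class]
    stop("after excluding rows with missing metrics, species below ",
         "n_per_class = ", n_per_class, ": ",
         paste(sprintf("%s (%d)", names(short), short), collapse = ", "),
         call. = FALSE)
  }
  k <- length(classes)
  confusion <- matrix(0L, k, k, dimnames = list(truth = classes,
                                                predicted = classes))
  per_rep <- numeric(n_repetitions)
  per_class <- matrix(0, n_repetitions, k, dimnames = list(NULL, classes))
  mtry <- max(1L, floor(sqrt(length(cols))))
  for (r in seq_len(n_repetitions)) {
    samp <- balanced_sample(tab, n_per_class, seed = seed + r)
    y <- factor(samp$species, levels = classes)
    x <- as.matrix(samp[, cols, drop = FALSE])
    rf <- with_seed(seed + r,
      randomForest::randomForest(x = x, y = y, ntree = n_trees, mtry = mtry))
    votes <- rf$votes[, classes, drop = FALSE]
    pred <- classes[max.col(votes, ties.method = "first")]
    per_rep[r] <- mean(pred != samp$species)
    for (ci in seq_len(k)) {
      in_class <- samp$species == classes[ci]
      per_class[r, ci] <- mean(pred[in_class] != classes[ci])
    }
    confusion <- confusion + table(factor(samp$species, levels = classes),
                                   factor(pred, levels = classes))
  }
  structure(
    list(overall_oob = mean(per_rep),
         per_class_oob = colMeans(per_class),
         confusion = confusion,
         per_repetition_oob = per_rep,
         settings = list(n_trees = n_trees, n_repetitions = n_repetitions,
                         n_per_class = n_per_class,
                         feature_columns = cols, mtry = mtry,
                         seed = as.integer(seed))),
    class = "classification_report"
  )
}

#' @export
print.classification_report <- function(x, ...) {
  s <- x$settings
  cat(sprintf("<classification_report> %d x RF(%d trees), %d crowns/class\n",
              s$n_repetitions, s$n_trees, s$n_per_class))
  cat(sprintf("  overall OOB error: %.1f%%\n", 100 * x$overall_oob))
  pc <- sprintf("%s %.0f%%", names(x$per_class_oob), 100 * x$per_class_oob)
  cat("  per class:", paste(pc, collapse = ", "), "\n")
  invisible(x)
}

#' Persist a classification report (JSON + per-repetition CSV)
#'
#' @param report A [run_scenario()] result.
#' @param path Output JSON path; per-repetition errors are written next to
#'   it with `_repetitions.csv` appended to the stem.
#' @return `path`, invisibly.
#' @export
write_report <- function(report, path) {
  out <- list(
    overall_oob = report$overall_oob,
    per_class_oob = as.list(report$per_class_oob),
    confusion = list(species = rownames(report$confusion),
                     counts = unclass(report$confusion)),
    settings = report$settings[c("n_trees", "n_repetitions", "n_per_class",
                                 "mtry", "seed")]
  )
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA)
  csv <- paste0(sub("\\.json$", "", path), "_repetitions.csv")
  utils::write.csv(
    data.frame(repetition = seq_along(report$per_repetition_oob),
               oob_error = report$per_repetition_oob),
    csv, row.names = FALSE)
  invisible(path)
}
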