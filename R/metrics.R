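# Object-based crown metrics: shadow-filtered spectral statistics, band
# ratios, normalized bands, vegetation indices and GLCM texture, one vector
# per (crown, survey, camera).

GLCM_OFFSETS_DEFAULT <- list(c(0L, 1L), c(1L, 0L), c(1L, 1L), c(1L, -1L))
GLCM_NAMES <- c("variance", "homogeneity", "contrast", "dissimilarity",
                "entropy", "second_moment", "correlation")

#' Relative intensity of a mosaic
#'
#' Pixel intensity is the sum of the three band values; relative intensity
#' rescales it to 0–100 by the min–max over all valid pixels of the mosaic.
#' The darkest pixels of a crown — its cast-shadow parts — end up near 0
#' and are discarded by [sunlit_mask()]. A constant-intensity mosaic maps
#' to 100 everywhere (nothing is classed as shadow).
#'
#' @param layer A [survey_layer].
#' @return Matrix (rows x cols) of relative intensities in `[0, 100]`;
#'   `NA` where any band is nodata.
#' @export
relative_intensity <- function(layer) {
  stopifnot(inherits(layer, "survey_layer"))
  intensity <- layer$bands[, , 1] + layer$bands[, , 2] + layer$bands[, , 3]
  if (all(is.na(intensity))) {
    stop("all pixels are nodata; cannot compute relative intensity",
         call. = FALSE)
  }
  rng <- range(intensity, na.rm = TRUE)
  if (rng[1] == rng[2]) {
    ri <- intensity
    ri[!is.na(ri)] <- 100
    return(ri)
  }
  100 * (intensity - rng[1]) / (rng[2] - rng[1])
}

#' Keep the sunlit pixels of a crown mask
#'
#' Discards mask pixels whose relative intensity is strictly below the
#' threshold (a pixel exactly at the threshold is kept).
#'
#' @param mask Integer matrix of 0-based `row`, `col` pixel coordinates.
#' @param ri Relative-intensity grid from [relative_intensity()].
#' @param threshold Percent in `[0, 100]`, default 20.
#' @return The surviving subset of `mask`.
#' @export
sunlit_mask <- function(mask, ri, threshold = 20) {
  stopifnot(is.numeric(threshold), length(threshold) == 1,
            threshold >= 0, threshold <= 100)
  if (nrow(mask) == 0) return(mask)
  v <- ri[cbind(mask[, "row"] + 1L, mask[, "col"] + 1L)]
  mask[!is.na(v) & v >= threshold, , drop = FALSE]
}

#' Spectral metrics of one crown on one layer
#'
#' Means and population standard deviations per band, the three unordered
#' band-mean ratios, the normalized bands (one band mean over the sum of
#' the three), and three camera-specific normalized-difference indices
#' computed on the crown-mean band values: for RGB (bands blue, green,
#' red) NGRVI = (G-R)/(G+R), NGBI = (G-B)/(G+B), NRBI = (R-B)/(R+B); for
#' CIR (bands NIR, red, green) NDVI = (NIR-R)/(NIR+R), GNDVI =
#' (NIR-G)/(NIR+G), NGRVI = (G-R)/(G+R). A zero denominator yields 0 by
#' convention (reported via a message).
#'
#' @param pixels Numeric n x 3 matrix of the crown's sunlit pixel values.
#' @param camera `"RGB"` or `"CIR"` (selects the index set).
#' @param min_sunlit Minimum pixel count for the crown to be retained
#'   (default 10).
#' @return Named numeric vector (`mean_1..3`, `sd_1..3`, `ratio_12`,
#'   `ratio_13`, `ratio_23`, `norm_1..3`, three indices, `n_sunlit`), or
#'   `NULL` when fewer than `min_sunlit` pixels remain.
#' @export
spectral_metrics <- function(pixels, camera, min_sunlit = 10) {
  camera <- match.arg(camera, c("RGB", "CIR"))
  if (is.null(dim(pixels)) || ncol(pixels) != 3) {
    stop("`pixels` must be an n x 3 matrix of band values", call. = FALSE)
  }
  n <- nrow(pixels)
  if (n < min_sunlit) return(NULL)
  mu <- colMeans(pixels)
  sd_pop <- sqrt(colMeans(sweep(pixels, 2, mu)^2))
  safe_ratio <- function(a, b, what) {
    if (b == 0) { message("zero denominator in ", what, "; 0 by convention"); 0 }
    else a / b
  }
  nd <- function(x, y, what) {
    if (x + y == 0) { message("zero denominator in ", what, "; 0 by convention"); 0 }
    else (x - y) / (x + y)
  }
  tot <- sum(mu)
  norms <- if (tot == 0) {
    message("zero total intensity; normalized bands set to 0")
    c(0, 0, 0)
  } else mu / tot
  out <- c(mean_1 = mu[[1]], mean_2 = mu[[2]], mean_3 = mu[[3]],
           sd_1 = sd_pop[[1]], sd_2 = sd_pop[[2]], sd_3 = sd_pop[[3]],
           ratio_12 = safe_ratio(mu[[1]], mu[[2]], "ratio_12"),
           ratio_13 = safe_ratio(mu[[1]], mu[[3]], "ratio_13"),
           ratio_23 = safe_ratio(mu[[2]], mu[[3]], "ratio_23"),
           norm_1 = norms[[1]], norm_2 = norms[[2]], norm_3 = norms[[3]])
  idx <- if (camera == "RGB") {
    # bands: 1 = blue, 2 = green, 3 = red
    c(ngrvi = nd(mu[[2]], mu[[3]], "ngrvi"),
      ngbi = nd(mu[[2]], mu[[1]], "ngbi"),
      nrbi = nd(mu[[3]], mu[[1]], "nrbi"))
  } else {
    # bands: 1 = NIR, 2 = red, 3 = green
    c(ndvi = nd(mu[[1]], mu[[2]], "ndvi"),
      gndvi = nd(mu[[1]], mu[[3]], "gndvi"),
      ngrvi = nd(mu[[3]], mu[[2]], "ngrvi"))
  }
  c(out, idx, n_sunlit = n)
}

#' Gray-level co-occurrence texture metrics of one crown object
#'
#' Quantizes the masked pixel values into `levels` equal-width bins over
#' the fixed 8-bit scale `[0, 255]`, counts co-occurrences of pixel pairs
#' where both pixels belong to the mask (symmetrized, pooled over all
#' offsets), normalizes to a joint distribution p(i, j), and returns the
#' seven Haralick-style metrics: variance, homogeneity, contrast,
#' dissimilarity, entropy, second moment and correlation. Correlation is 0
#' by convention when the marginal variance is 0 (e.g. a constant crown).
#'
#' @param band Numeric matrix, the full raster band (DN 0–255).
#' @param mask Integer matrix of 0-based `row`, `col` coordinates (usually
#'   the sunlit crown pixels).
#' @param levels Number of gray levels (>= 2, default 32).
#' @param offsets List of integer `c(drow, dcol)` displacements; default
#'   `(0,1), (1,0), (1,1), (1,-1)`.
#' @return Named numeric vector `glcm_variance`, `glcm_homogeneity`,
#'   `glcm_contrast`, `glcm_dissimilarity`, `glcm_entropy`,
#'   `glcm_second_moment`, `glcm_correlation`; `NULL` when no valid pixel
#'   pair exists (reported via a message).
#' @export
glcm_metrics <- function(band, mask, levels = 32,
                         offsets = GLCM_OFFSETS_DEFAULT) {
  if (!is.numeric(levels) || length(levels) != 1 || levels < 2) {
    stop("`levels` must be a single integer >= 2", call. = FALSE)
  }
  levels <- as.integer(levels)
  if (nrow(mask) == 0) {
    message("empty mask; GLCM metrics absent")
    return(NULL)
  }
  nr <- nrow(band); nc <- ncol(band)
  # quantize the full scale [0,255] into equal-width bins
  q <- matrix(NA_integer_, nr, nc)
  sel <- cbind(mask[, "row"] + 1L, mask[, "col"] + 1L)
  q[sel] <- pmin(as.integer(band[sel] %/% (256 / levels)), levels - 1L)
  inmask <- matrix(FALSE, nr, nc)
  inmask[sel] <- TRUE
  counts <- numeric(levels * levels)
  for (off in offsets) {
    dr <- off[1]; dc <- off[2]
    r1 <- mask[, "row"] + 1L; c1 <- mask[, "col"] + 1L
    r2 <- r1 + dr; c2 <- c1 + dc
    ok <- r2 >= 1L & r2 <= nr & c2 >= 1L & c2 <= nc
    if (!any(ok)) next
    ok[ok] <- inmask[cbind(r2[ok], c2[ok])]
    if (!any(ok)) next
    i <- q[cbind(r1[ok], c1[ok])]
    j <- q[cbind(r2[ok], c2[ok])]
    # symmetric: count both (i, j) and (j, i)
    counts <- counts + tabulate(i * levels + j + 1L, nbins = levels^2) +
      tabulate(j * levels + i + 1L, nbins = levels^2)
  }
  total <- sum(counts)
  if (total == 0) {
    message("no co-occurring pixel pair in mask; GLCM metrics absent")
    return(NULL)
  }
  p <- counts / total
  lev <- 0:(levels - 1L)
  i_idx <- rep(lev, each = levels)   # row level of p(i, j)
  j_idx <- rep(lev, times = levels)
  contrast <- sum(p * (i_idx - j_idx)^2)
  dissimilarity <- sum(p * abs(i_idx - j_idx))
  homogeneity <- sum(p / (1 + (i_idx - j_idx)^2))
  entropy <- -sum(p[p > 0] * log(p[p > 0]))
  second_moment <- sum(p^2)
  mu <- sum(i_idx * p)               # symmetric: row marginal = col marginal
  variance <- sum(p * (i_idx - mu)^2)
  correlation <- if (variance == 0) 0 else {
    sum(p * (i_idx - mu) * (j_idx - mu)) / variance
  }
  c(glcm_variance = variance, glcm_homogeneity = homogeneity,
    glcm_contrast = contrast, glcm_dissimilarity = dissimilarity,
    glcm_entropy = entropy, glcm_second_moment = second_moment,
    glcm_correlation = correlation)
}

# all metrics of one crown on one layer; NULL when the crown is unusable
crown_layer_metrics <- function(layer, mask, ri, shadow_threshold, min_sunlit,
                                glcm_levels, glcm_offsets) {
  sunlit <- sunlit_mask(mask, ri, shadow_threshold)
  if (nrow(sunlit) < min_sunlit) return(NULL)
  sel <- cbind(sunlit[, "row"] + 1L, sunlit[, "col"] + 1L)
  pixels <- cbind(layer$bands[, , 1][sel], layer$bands[, , 2][sel],
                  layer$bands[, , 3][sel])
  spec <- spectral_metrics(pixels, layer$camera, min_sunlit)
  if (is.null(spec)) return(NULL)
  glcm <- numeric(0)
  for (b in 1:3) {
    g <- glcm_metrics(layer$bands[, , b], sunlit, glcm_levels, glcm_offsets)
    if (is.null(g)) return(NULL)
    names(g) <- paste0(names(g), "_", b)
    glcm <- c(glcm, g)
  }
  c(spec, glcm)
}

#' Build the crowns-by-metrics feature table
#'
#' Narrows every crown inward by `buffer_m`, rasterizes it, strips shadowed
#' pixels per layer by the relative-intensity rule, and computes the full
#' metric vector per (crown, survey, camera). A crown enters the table only
#' if it is usable on every requested layer; dropped crowns and reasons are
#' attached as the `"dropped"` attribute and reported as warnings.
#'
#' @param layers Named list of co-registered [survey_layer] objects.
#' @param crowns Crown data frame (see [read_crowns()]).
#' @param buffer_m Inward crown buffer in meters (default 0.5).
#' @param shadow_threshold Relative-intensity cut in percent (default 20).
#' @param min_sunlit Minimum sunlit pixels per crown per layer (default 10).
#' @param glcm_levels,glcm_offsets GLCM quantization levels (default 32)
#'   and displacement set.
#' @return Data frame of class `feature_table`: `crown_id`, `species`,
#'   then one numeric column per `<survey_id>.<camera>.<metric>`; rows
#'   sorted by `crown_id`. Attributes: `surveys` (survey metadata),
#'   `dropped` (crown_id, reason).
#' @export
build_feature_table <- function(layers, crowns, buffer_m = 0.5,
                                shadow_threshold = 20, min_sunlit = 10,
                                glcm_levels = 32,
                                glcm_offsets = GLCM_OFFSETS_DEFAULT) {
  stopifnot(length(layers) >= 1, nrow(crowns) >= 1)
  ref <- layers[[1]]
  for (l in layers) {
    if (!same_grid(ref, l)) {
      stop("crownpheno_grid_error: layers are not co-registered", call. = FALSE)
    }
  }
  ri_list <- lapply(layers, relative_intensity)
  ord <- order(crowns$crown_id)
  crowns <- crowns[ord, , drop = FALSE]
  rows <- list()
  dropped <- list()
  for (i in seq_len(nrow(crowns))) {
    id <- crowns$crown_id[i]
    narrowed <- narrow_crown(crowns$geometry[[i]], buffer_m)
    if (is.null(narrowed)) {
      dropped[[id]] <- "crown vanishes under the inward buffer"
      next
    }
    mask <- suppressMessages(crown_pixel_mask(narrowed, ref))
    if (nrow(mask) == 0) {
      dropped[[id]] <- "no pixel center inside the narrowed crown"
      next
    }
    vec <- numeric(0)
    reason <- NULL
    for (nm in names(layers)) {
      m <- suppressMessages(
        crown_layer_metrics(layers[[nm]], mask, ri_list[[nm]],
                            shadow_threshold, min_sunlit,
                            glcm_levels, glcm_offsets))
      if (is.null(m)) {
        reason <- paste0("fewer than ", min_sunlit,
                         " sunlit pixels on layer ", nm)
        break
      }
      names(m) <- paste0(layers[[nm]]$survey_id, ".", layers[[nm]]$camera,
                         ".", names(m))
      vec <- c(vec, m)
    }
    if (!is.null(reason)) { dropped[[id]] <- reason; next }
    rows[[id]] <- vec
  }
  if (length(dropped) > 0) {
    for (id in names(dropped)) {
      warning("crown ", id, " dropped: ", dropped[[id]], call. = FALSE)
    }
  }
  if (length(rows) == 0) {
    stop("no crown survives metric extraction on all layers", call. = FALSE)
  }
  mat <- do.call(rbind, rows)
  keep <- crowns$crown_id %in% names(rows)
  out <- data.frame(crown_id = crowns$crown_id[keep],
                    species = crowns$species[keep],
                    mat, stringsAsFactors = FALSE, check.names = FALSE)
  rownames(out) <- NULL
  attr(out, "surveys") <- unique(data.frame(
    survey_id = vapply(layers, `[[`, "", "survey_id"),
    date = as.Date(vapply(layers, function(l) format(l$date), "")),
    camera = vapply(layers, `[[`, "", "camera"),
    stringsAsFactors = FALSE, row.names = NULL))
  attr(out, "dropped") <- if (length(dropped) > 0) {
    data.frame(crown_id = names(dropped),
               reason = unlist(dropped, use.names = FALSE),
               stringsAsFactors = FALSE)
  } else data.frame(crown_id = character(0), reason = character(0))
  class(out) <- c("feature_table", "data.frame")
  out
}

#' Metric column names of a feature table
#'
#' @param table A [build_feature_table()] result.
#' @param surveys Optional survey ids to keep (e.g. `c("s03", "s04")`).
#' @param cameras Optional cameras to keep (`"RGB"`, `"CIR"` or both).
#' @return Character vector of matching column names.
#' @export
feature_columns <- function(table, surveys = NULL, cameras = NULL) {
  cols <- setdiff(names(table), c("crown_id", "species"))
  parts <- strsplit(cols, ".", fixed = TRUE)
  sv <- vapply(parts, `[[`, "", 1)
  cam <- vapply(parts, `[[`, "", 2)
  keep <- rep(TRUE, length(cols))
  if (!is.null(surveys)) keep <- keep & sv %in% surveys
  if (!is.null(cameras)) keep <- keep & cam %in% cameras
  cols[keep]
}

#' Persist a feature table as CSV plus a JSON sidecar
#'
#' @param table A [build_feature_table()] result.
#' @param path Output CSV path; the sidecar gets the same name with
#'   `.json` appended.
#' @return `path`, invisibly.
#' @export
write_feature_table <- function(table, path) {
  utils::write.csv(table, path, row.names = FALSE)
  sidecar <- list(
    columns = setdiff(names(table), c("crown_id", "species")),
    namespace = "survey_id.camera.metric",
    dropped = attr(table, "dropped")
  )
  jsonlite::write_json(sidecar, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}
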