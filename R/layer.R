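#' One co-registered camera flight for one survey date
#'
#' A `survey_layer` couples a 3-band 8-bit raster with the survey metadata
#' the downstream analysis needs: acquisition date, season, accumulated
#' growing degree days (metadata only), camera kind and pixel size. All
#' layers of a study must share one grid — co-registration is an input
#' contract, not something this package performs.
#'
#' @param survey_id Short survey label, e.g. `"s03"`.
#' @param date Acquisition date (`Date` or coercible).
#' @param season One of `"spring"`, `"summer"`, `"autumn"`.
#' @param gdd Growing degree days at acquisition (base 10 degC); carried as
#'   metadata, never used in computation.
#' @param camera `"RGB"` (bands blue, green, red) or `"CIR"` (bands NIR,
#'   red, green).
#' @param bands Numeric array `rows x cols x 3` of digital numbers in
#'   0..255; `NA` marks nodata.
#' @param gsd Ground sample distance, meters per pixel (> 0).
#' @param origin Map coordinates `c(x, y)` of the raster's top-left corner.
#' @return An object of class `survey_layer`.
#' @export
survey_layer <- function(survey_id, date, season, gdd, camera, bands,
                         gsd = 0.20, origin = NULL) {
  if (length(dim(bands)) != 3 || dim(bands)[3] != 3) {
    stop("`bands` must be a rows x cols x 3 array; got ",
         paste(dim(bands), collapse = " x "), call. = FALSE)
  }
  if (!is.numeric(gsd) || length(gsd) != 1 || gsd <= 0) {
    stop("`gsd` must be a single positive number (meters/pixel)", call. = FALSE)
  }
  camera <- match.arg(camera, c("RGB", "CIR"))
  season <- match.arg(season, c("spring", "summer", "autumn"))
  if (is.null(origin)) origin <- c(0, dim(bands)[1] * gsd)
  rng <- range(bands, na.rm = TRUE)
  if (rng[1] < 0 || rng[2] > 255) {
    stop("band values must be 8-bit digital numbers in [0, 255]", call. = FALSE)
  }
  structure(
    list(survey_id = survey_id, date = as.Date(date), season = season,
         gdd = gdd, camera = camera, bands = bands, gsd = gsd,
         origin = as.numeric(origin), nodata = NA_real_),
    class = "survey_layer"
  )
}

#' @export
print.survey_layer <- function(x, ...) {
  d <- dim(x$bands)
  cat(sprintf("<survey_layer> %s %s (%s, GDD %s)\n", x$survey_id, x$camera,
              format(x$date), format(x$gdd)))
  cat(sprintf("  %d x %d px, 3 bands, %.2f m/px, origin (%.1f, %.1f)\n",
              d[1], d[2], x$gsd, x$origin[1], x$origin[2]))
  invisible(x)
}

#' @export
dim.survey_layer <- function(x) dim(x$bands)

# grid identity contract between co-registered layers
same_grid <- function(a, b) {
  identical(dim(a$bands), dim(b$bands)) &&
    isTRUE(all.equal(a$gsd, b$gsd)) &&
    isTRUE(all.equal(a$origin, b$origin))
}

# seed-scoped RNG: run expr under a seed, restore global RNG state after
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

clamp_dn <- function(x) pmin(pmax(x, 0), 255)
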