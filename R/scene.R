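# Synthetic multitemporal scene generator.

#' Configuration of a synthetic scene
#'
#' @param n_crowns_per_species Crowns generated per species (default 10).
#' @param grid_size `c(rows, cols)` in pixels, or `NULL` to size the grid
#'   automatically so the requested crowns pack comfortably.
#' @param gsd Ground sample distance, meters/pixel (default 0.20).
#' @param crown_radius_range `c(min, max)` crown radius in meters.
#' @param seed Integer; same seed and configuration reproduce the world
#'   byte for byte.
#' @param dates Optional integer indices selecting a subset of the
#'   phenology's survey dates to render (default: all).
#' @return An object of class `scene_config`.
#' @export
scene_config <- function(n_crowns_per_species = 10, grid_size = NULL,
                         gsd = 0.20, crown_radius_range = c(1.2, 2.4),
                         seed = 1L, dates = NULL) {
  stopifnot(n_crowns_per_species >= 1, gsd > 0,
            length(crown_radius_range) == 2,
            crown_radius_range[1] > 0,
            crown_radius_range[2] >= crown_radius_range[1])
  n_total <- n_crowns_per_species * length(SPECIES_DEFAULT)
  if (is.null(grid_size)) {
    # one jittered-grid cell per crown plus clearance
    cell_m <- 2 * crown_radius_range[2] * 1.25 + 0.8
    side_m <- ceiling(sqrt(n_total)) * cell_m + 2 * crown_radius_range[2]
    side_px <- ceiling(side_m / gsd)
    grid_size <- c(side_px, side_px)
  }
  structure(
    list(n_crowns_per_species = as.integer(n_crowns_per_species),
         grid_size = as.integer(grid_size), gsd = gsd,
         crown_radius_range = crown_radius_range,
         seed = as.integer(seed), dates = dates),
    class = "scene_config"
  )
}

#' Generate a synthetic multitemporal crown world
#'
#' Renders, for every requested survey date, an RGB layer (bands blue,
#' green, red) and a CIR layer (bands NIR, red, green) over a shared grid,
#' plus the crown delineations with their true species labels. Crown
#' interiors receive a crown-level spectral offset (between-tree variance)
#' and per-pixel noise (within-crown variance); a contiguous fraction of
#' each crown is attenuated tenfold to emulate cast shadow; the background
#' is a distinct low-intensity texture; an optional luminosity ramp
#' multiplies values along the column axis.
#'
#' @param phenology A [make_phenology()] parameter set.
#' @param config A [scene_config()].
#' @return A list of class `crown_world`: `crowns` (data frame `crown_id`,
#'   `species`, list-column `geometry`), `layers` (list of [survey_layer],
#'   RGB and CIR per date), `masks` (per-crown pixel sets), `shadows`
#'   (per date, the true per-crown shadow pixel sets — ground truth for
#'   validating the shadow filter), `phenology`, `config`.
#' @export
generate_world <- function(phenology, config = scene_config()) {
  stopifnot(inherits(phenology, "phenology_params"),
            inherits(config, "scene_config"))
  dates <- config$dates %||% seq_len(nrow(phenology$surveys))
  if (any(dates < 1 | dates > nrow(phenology$surveys))) {
    stop("`dates` indices out of range", call. = FALSE)
  }
  with_seed(config$seed, {
    crowns <- place_crowns(phenology$species, config)
    masks <- lapply(crowns$geometry, crown_pixel_mask,
                    layer = blank_layer(config))
    layers <- list()
    shadows <- list()
    for (d in dates) {
      rendered <- render_date(phenology, config, crowns, masks, d)
      field <- rendered$field
      meta <- phenology$surveys[d, ]
      shadows[[meta$survey_id]] <- rendered$shadows
      rgb <- field[, , 1:3]                       # B, G, R
      cir <- field[, , c(4, 3, 2)]                # NIR, R, G
      if (phenology$cir_mixing) {
        # near-collinear CIR bands: heavy cross-talk between channels
        a <- 0.85
        mix <- (cir[, , 1] + cir[, , 2] + cir[, , 3]) / 3
        for (b in 1:3) cir[, , b] <- (1 - a) * cir[, , b] + a * mix
      }
      layers[[paste0(meta$survey_id, ".RGB")]] <-
        survey_layer(meta$survey_id, meta$date, meta$season, meta$gdd,
                     "RGB", round(clamp_dn(rgb)), gsd = config$gsd)
      layers[[paste0(meta$survey_id, ".CIR")]] <-
        survey_layer(meta$survey_id, meta$date, meta$season, meta$gdd,
                     "CIR", round(clamp_dn(cir)), gsd = config$gsd)
    }
    structure(list(crowns = crowns, layers = layers, masks = masks,
                   shadows = shadows, phenology = phenology, config = config),
              class = "crown_world")
  })
}

`%||%` <- function(a, b) if (is.null(a)) b else a

blank_layer <- function(config) {
  survey_layer("blank", Sys.Date(), "spring", 0, "RGB",
               array(0, c(config$grid_size, 3)), gsd = config$gsd)
}

# non-overlapping convex crowns by bounded rejection sampling
place_crowns <- function(species, config) {
  n_total <- config$n_crowns_per_species * length(species)
  side_x <- config$grid_size[2] * config$gsd
  side_y <- config$grid_size[1] * config$gsd
  rmax <- config$crown_radius_range[2]
  centers <- matrix(NA_real_, n_total, 2)
  radii <- numeric(n_total)
  max_attempts <- 500L * n_total
  attempts <- 0L
  for (i in seq_len(n_total)) {
    repeat {
      attempts <- attempts + 1L
      if (attempts > max_attempts) {
        stop("could not place ", n_total, " non-overlapping crowns in a ",
             config$grid_size[1], " x ", config$grid_size[2], " px grid; ",
             "reduce n_crowns_per_species or enlarge grid_size", call. = FALSE)
      }
      r <- stats::runif(1, config$crown_radius_range[1], rmax)
      # jitter allows vertices up to 1.25 * r from the center
      reach <- 1.25 * r
      cx <- stats::runif(1, reach + config$gsd, side_x - reach - config$gsd)
      cy <- stats::runif(1, reach + config$gsd, side_y - reach - config$gsd)
      if (i == 1) ok <- TRUE else {
        prev <- seq_len(i - 1)
        dd <- sqrt((centers[prev, 1] - cx)^2 + (centers[prev, 2] - cy)^2)
        ok <- all(dd >= 1.25 * (radii[prev] + r) + 0.4)
      }
      if (ok) break
    }
    centers[i, ] <- c(cx, cy)
    radii[i] <- r
  }
  geometry <- lapply(seq_len(n_total), function(i) {
    convex_crown_polygon(centers[i, ], radii[i],
                         n_vertices = sample(8:12, 1), jitter = 0.2)
  })
  data.frame(
    crown_id = sprintf("c%03d", seq_len(n_total)),
    species = rep(species, each = config$n_crowns_per_species),
    geometry = I(geometry),
    stringsAsFactors = FALSE
  )
}

# render the 4-band DN field (rows x cols x B,G,R,NIR) for one date;
# returns the field plus the per-crown true shadow pixel sets
render_date <- function(phenology, config, crowns, masks, d) {
  nr <- config$grid_size[1]; nc <- config$grid_size[2]
  field <- array(0, c(nr, nc, 4))
  bg_base <- c(14, 16, 12, 10)
  for (b in 1:4) {
    field[, , b] <- bg_base[b] + matrix(stats::runif(nr * nc, 0, 8), nr, nc)
  }
  sp_idx <- match(crowns$species, phenology$species)
  shadows <- vector("list", nrow(crowns))
  for (i in seq_len(nrow(crowns))) {
    m <- masks[[i]]
    npix <- nrow(m)
    if (npix == 0) next
    mu <- phenology$mean_spectrum[sp_idx[i], d, ]
    offset <- stats::rnorm(4, 0, phenology$between_tree_sd[sp_idx[i], d])
    crown_mean <- clamp_dn(mu + offset)
    # contiguous shadow: the crown pixels most extreme along a random axis
    n_shadow <- round(phenology$shadow_fraction * npix)
    theta <- stats::runif(1, 0, 2 * pi)
    proj <- m[, "col"] * cos(theta) + m[, "row"] * sin(theta)
    shadow <- order(proj)[seq_len(n_shadow)]
    shadows[[i]] <- m[shadow, , drop = FALSE]
    idx <- m[, "row"] + 1L + nr * m[, "col"]      # linear index into a band
    for (b in 1:4) {
      vals <- crown_mean[b] + stats::rnorm(npix, 0, phenology$within_crown_sd)
      if (n_shadow > 0) vals[shadow] <- vals[shadow] * 0.1
      band <- field[, , b]
      band[idx] <- vals
      field[, , b] <- band
    }
  }
  if (phenology$luminosity_gradient != 0) {
    ramp <- 1 + phenology$luminosity_gradient *
      (seq_len(nc) - 1) / max(1, nc - 1) - phenology$luminosity_gradient / 2
    for (b in 1:4) field[, , b] <- sweep(field[, , b], 2, ramp, `*`)
  }
  list(field = clamp_dn(field), shadows = shadows)
}

#' @export
print.crown_world <- function(x, ...) {
  cat(sprintf("<crown_world> preset '%s': %d crowns, %d layers (%d x %d px)\n",
              x$phenology$preset, nrow(x$crowns), length(x$layers),
              x$config$grid_size[1], x$config$grid_size[2]))
  invisible(x)
}
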