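# Raster, vector and manifest I/O.
#
# Rasters travel as 3-band 8-bit TIFFs with an ESRI world file (.tfw)
# sidecar carrying the geotransform (plain-text, six lines: x pixel size,
# two rotation terms, negative y pixel size, and the map coordinates of the
# center of the top-left pixel). Crowns travel as GeoJSON. A CSV manifest
# plus a YAML sidecar describe a study.

world_file_path <- function(path) sub("\\.tiff?$", ".tfw", path)

#' Write a survey layer as TIFF + world file
#'
#' @param layer A [survey_layer].
#' @param path Output path ending in `.tif`; a `.tfw` world file is written
#'   alongside.
#' @return `path`, invisibly.
#' @export
write_survey <- function(layer, path) {
  stopifnot(inherits(layer, "survey_layer"))
  bands <- layer$bands
  bands[is.na(bands)] <- 0
  tiff::writeTIFF(bands / 255, path, bits.per.sample = 8L,
                  compression = "none")
  tfw <- c(layer$gsd, 0, 0, -layer$gsd,
           layer$origin[1] + layer$gsd / 2,
           layer$origin[2] - layer$gsd / 2)
  writeLines(formatC(tfw, format = "f", digits = 10), world_file_path(path))
  invisible(path)
}

#' Read a survey layer from TIFF + world file
#'
#' @param path Path to a 3-band 8-bit TIFF written by [write_survey()] (or
#'   any co-registered equivalent with a `.tfw` sidecar).
#' @param metadata List or one-row data frame with `survey_id`, `date`,
#'   `season`, `gdd`, `camera`.
#' @param reference Optional [survey_layer] whose grid this layer must
#'   match; a mismatch raises a co-registration error.
#' @return A [survey_layer].
#' @export
read_survey <- function(path, metadata, reference = NULL) {
  if (!file.exists(path)) {
    stop("survey raster not found: ", path, call. = FALSE)
  }
  img <- tiff::readTIFF(path)
  if (length(dim(img)) != 3 || dim(img)[3] != 3) {
    stop("crownpheno_band_error: expected a 3-band raster, got ",
         if (length(dim(img)) == 2) 1 else dim(img)[3], " band(s) in ", path,
         call. = FALSE)
  }
  tfwp <- world_file_path(path)
  if (!file.exists(tfwp)) {
    stop("world file missing for ", path, call. = FALSE)
  }
  tfw <- as.numeric(readLines(tfwp))
  gsd <- tfw[1]
  origin <- c(tfw[5] - gsd / 2, tfw[6] + gsd / 2)
  layer <- survey_layer(metadata$survey_id, metadata$date, metadata$season,
                        metadata$gdd, metadata$camera,
                        round(img * 255), gsd = gsd, origin = origin)
  if (!is.null(reference) && !same_grid(layer, reference)) {
    stop("crownpheno_grid_error: raster grid of ", path,
         " does not match the study's reference grid (co-registration ",
         "is an input contract)", call. = FALSE)
  }
  layer
}

#' Write crown records as GeoJSON
#'
#' @param crowns Data frame with `crown_id`, `species` and a `geometry`
#'   list-column of n x 2 vertex matrices.
#' @param path Output `.geojson` path.
#' @return `path`, invisibly.
#' @export
write_crowns <- function(crowns, path) {
  features <- lapply(seq_len(nrow(crowns)), function(i) {
    ring <- crowns$geometry[[i]]
    ring <- rbind(ring, ring[1, ])  # GeoJSON rings are closed
    list(
      type = "Feature",
      properties = list(crown_id = crowns$crown_id[i],
                        species = crowns$species[i]),
      geometry = list(type = "Polygon",
                      coordinates = list(lapply(seq_len(nrow(ring)),
                                                function(k) ring[k, ])))
    )
  })
  fc <- list(type = "FeatureCollection", features = features)
  jsonlite::write_json(fc, path, auto_unbox = TRUE, digits = 10)
  invisible(path)
}

#' Read and validate crown records from GeoJSON
#'
#' @param path `.geojson` file whose features carry `crown_id` and
#'   `species` properties and polygon geometry.
#' @param species_set Allowed species labels (default: the generator's
#'   five).
#' @return Data frame `crown_id`, `species`, list-column `geometry`.
#' @export
read_crowns <- function(path, species_set = SPECIES_DEFAULT) {
  if (!file.exists(path)) stop("crown file not found: ", path, call. = FALSE)
  fc <- jsonlite::read_json(path)
  feats <- fc$features
  crown_id <- vapply(feats, function(f) as.character(f$properties$crown_id), "")
  species <- vapply(feats, function(f) as.character(f$properties$species), "")
  geometry <- lapply(feats, function(f) {
    ring <- do.call(rbind, lapply(f$geometry$coordinates[[1]], unlist))
    check_poly(ring)
  })
  bad_sp <- unique(species[!species %in% species_set])
  if (length(bad_sp) > 0) {
    stop("unknown species label(s): ", paste(bad_sp, collapse = ", "),
         "; expected one of ", paste(species_set, collapse = ", "),
         call. = FALSE)
  }
  dup <- unique(crown_id[duplicated(crown_id)])
  if (length(dup) > 0) {
    stop("duplicated crown_id(s): ", paste(dup, collapse = ", "), call. = FALSE)
  }
  ok <- vapply(geometry, poly_is_valid, logical(1))
  if (!all(ok)) {
    stop("invalid crown geometry for crown_id(s): ",
         paste(crown_id[!ok], collapse = ", "), call. = FALSE)
  }
  data.frame(crown_id = crown_id, species = species,
             geometry = I(geometry), stringsAsFactors = FALSE)
}

#' Write a generated world to disk
#'
#' Emits one TIFF (+ world file) per date per camera, a GeoJSON of crown
#' polygons, a CSV manifest (`survey_id`, `date`, `season`, `gdd`,
#' `camera`, `path`) and a YAML sidecar recording preset, seed and — when
#' the preset plants one — the optimal date `t_star`.
#'
#' @param world A [generate_world()] result.
#' @param dir Output directory (created if needed).
#' @return The manifest path, invisibly.
#' @export
write_world <- function(world, dir) {
  stopifnot(inherits(world, "crown_world"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  rows <- list()
  for (nm in names(world$layers)) {
    layer <- world$layers[[nm]]
    fn <- file.path(dir, paste0(nm, ".tif"))
    write_survey(layer, fn)
    rows[[nm]] <- data.frame(survey_id = layer$survey_id,
                             date = format(layer$date), season = layer$season,
                             gdd = layer$gdd, camera = layer$camera,
                             path = basename(fn), stringsAsFactors = FALSE)
  }
  manifest <- do.call(rbind, rows)
  manifest_path <- file.path(dir, "manifest.csv")
  utils::write.csv(manifest, manifest_path, row.names = FALSE)
  write_crowns(world$crowns, file.path(dir, "crowns.geojson"))
  sidecar <- list(preset = world$phenology$preset,
                  seed = world$config$seed,
                  gsd = world$config$gsd,
                  grid_size = world$config$grid_size,
                  species = world$phenology$species)
  if (!is.na(world$phenology$t_star)) {
    sidecar$t_star <- world$phenology$t_star
    sidecar$t_star_survey <- world$phenology$surveys$survey_id[world$phenology$t_star]
  }
  yaml::write_yaml(sidecar, file.path(dir, "world.yaml"))
  invisible(manifest_path)
}

#' Load a study (all survey layers) from a manifest
#'
#' @param manifest_path CSV manifest as written by [write_world()]; raster
#'   paths are resolved relative to the manifest's directory.
#' @return Named list of [survey_layer] (`<survey_id>.<camera>`), all
#'   verified to share one grid.
#' @export
load_study <- function(manifest_path) {
  if (!file.exists(manifest_path)) {
    stop("manifest not found: ", manifest_path, call. = FALSE)
  }
  manifest <- utils::read.csv(manifest_path, stringsAsFactors = FALSE)
  base <- dirname(manifest_path)
  layers <- list()
  reference <- NULL
  for (i in seq_len(nrow(manifest))) {
    meta <- manifest[i, ]
    layer <- read_survey(file.path(base, meta$path), meta, reference)
    if (is.null(reference)) reference <- layer
    layers[[paste0(meta$survey_id, ".", meta$camera)]] <- layer
  }
  layers
}
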