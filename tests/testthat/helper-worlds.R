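# Shared fixtures: worlds are expensive to render, so build each once per
# test run and cache by key.

.world_cache <- new.env(parent = emptyenv())

cached <- function(key, builder) {
  if (!exists(key, envir = .world_cache)) {
    assign(key, builder(), envir = .world_cache)
  }
  get(key, envir = .world_cache)
}

# small two-date world for structural tests
tiny_world <- function(preset = "separable_world", seed = 1L) {
  cached(paste("tiny", preset, seed), function() {
    generate_world(
      make_phenology(preset, seed = seed),
      scene_config(n_crowns_per_species = 4, seed = seed, dates = c(1L, 3L),
                   crown_radius_range = c(1.5, 2.2)))
  })
}

tiny_table <- function(preset = "separable_world", seed = 1L) {
  cached(paste("tinytab", preset, seed), function() {
    w <- tiny_world(preset, seed)
    suppressWarnings(build_feature_table(w$layers, w$crowns))
  })
}

# brute-force GLCM oracle: explicit pair enumeration, independent of the
# implementation's vectorised counting
glcm_oracle <- function(band, mask, levels, offsets) {
  width <- 256 / levels
  inmask <- matrix(FALSE, nrow(band), ncol(band))
  inmask[cbind(mask[, 1] + 1L, mask[, 2] + 1L)] <- TRUE
  p <- matrix(0, levels, levels)
  for (k in seq_len(nrow(mask))) {
    r <- mask[k, 1] + 1L; c <- mask[k, 2] + 1L
    for (off in offsets) {
      r2 <- r + off[1]; c2 <- c + off[2]
      if (r2 < 1 || r2 > nrow(band) || c2 < 1 || c2 > ncol(band)) next
      if (!inmask[r2, c2]) next
      i <- min(floor(band[r, c] / width), levels - 1) + 1
      j <- min(floor(band[r2, c2] / width), levels - 1) + 1
      p[i, j] <- p[i, j] + 1
      p[j, i] <- p[j, i] + 1
    }
  }
  tot <- sum(p)
  if (tot == 0) return(NULL)
  p <- p / tot
  lev <- 0:(levels - 1)
  contrast <- 0; dissim <- 0; homog <- 0; entropy <- 0; sm <- 0
  mu <- 0
  for (i in seq_len(levels)) for (j in seq_len(levels)) {
    pij <- p[i, j]
    contrast <- contrast + pij * (lev[i] - lev[j])^2
    dissim <- dissim + pij * abs(lev[i] - lev[j])
    homog <- homog + pij / (1 + (lev[i] - lev[j])^2)
    if (pij > 0) entropy <- entropy - pij * log(pij)
    sm <- sm + pij^2
    mu <- mu + lev[i] * pij
  }
  variance <- 0; cov <- 0
  for (i in seq_len(levels)) for (j in seq_len(levels)) {
    variance <- variance + p[i, j] * (lev[i] - mu)^2
    cov <- cov + p[i, j] * (lev[i] - mu) * (lev[j] - mu)
  }
  correlation <- if (variance == 0) 0 else cov / variance
  c(glcm_variance = variance, glcm_homogeneity = homog,
    glcm_contrast = contrast, glcm_dissimilarity = dissim,
    glcm_entropy = entropy, glcm_second_moment = sm,
    glcm_correlation = correlation)
}

# single-layer wrapper around a plain band matrix
band_layer <- function(bands, gsd = 0.2, camera = "RGB") {
  if (length(dim(bands)) == 2) {
    bands <- array(rep(bands, 3), c(dim(bands), 3))
  }
  survey_layer("s00", "2013-05-28", "spring", 0, camera, bands, gsd = gsd)
}

full_mask <- function(nr, nc) {
  as.matrix(expand.grid(row = 0:(nr - 1), col = 0:(nc - 1)))
}
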