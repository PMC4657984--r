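test_that("same seed and config reproduce the world exactly", {
  cfg <- scene_config(n_crowns_per_species = 3, seed = 5, dates = c(1L, 9L))
  phen <- make_phenology("paper_like", seed = 5)
  w1 <- generate_world(phen, cfg)
  w2 <- generate_world(phen, cfg)
  expect_identical(w1$crowns$crown_id, w2$crowns$crown_id)
  expect_identical(w1$crowns$geometry, w2$crowns$geometry)
  for (nm in names(w1$layers)) {
    expect_identical(w1$layers[[nm]]$bands, w2$layers[[nm]]$bands)
  }
})

test_that("crowns are non-overlapping and fully inside the grid", {
  w <- tiny_world("paper_like")
  polys <- w$crowns$geometry
  side_x <- w$config$grid_size[2] * w$config$gsd
  side_y <- w$config$grid_size[1] * w$config$gsd
  for (p in polys) {
    expect_true(all(p[, 1] >= 0 & p[, 1] <= side_x))
    expect_true(all(p[, 2] >= 0 & p[, 2] <= side_y))
  }
  # pairwise disjoint: no vertex of one crown inside another
  n <- length(polys)
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      expect_false(any(points_in_polygon(polys[[j]][, 1], polys[[j]][, 2],
                                         polys[[i]])))
    }
  }
})

test_that("impossible packing raises an informative error", {
  phen <- make_phenology("null_world")
  cfg <- scene_config(n_crowns_per_species = 30, seed = 1, dates = 1L,
                      grid_size = c(60L, 60L))
  expect_error(generate_world(phen, cfg), "non-overlapping crowns")
})

test_that("true shadow pixels are darker than sunlit pixels in >= 99% of crowns", {
  w <- tiny_world("paper_like")
  checks <- 0; ok <- 0
  for (sid in names(w$shadows)) {
    layer <- w$layers[[paste0(sid, ".RGB")]]
    ri <- relative_intensity(layer)
    for (i in seq_len(nrow(w$crowns))) {
      m <- w$masks[[i]]
      sh <- w$shadows[[sid]][[i]]
      if (nrow(sh) == 0 || nrow(sh) == nrow(m)) next
      key <- function(x) paste(x[, "row"], x[, "col"])
      sun <- m[!key(m) %in% key(sh), , drop = FALSE]
      ri_at <- function(px) ri[cbind(px[, "row"] + 1L, px[, "col"] + 1L)]
      checks <- checks + 1
      if (max(ri_at(sh)) < min(ri_at(sun))) ok <- ok + 1
    }
  }
  expect_gt(checks, 20)
  expect_gte(ok / checks, 0.99)
})

test_that("with no between-tree variance, pooled species means converge", {
  # law-of-large-numbers check on sunlit pixel values: with the crown-level
  # variance component silenced, per-species pooled means at >= 1e4 pixels
  # differ by less than 0.5 DN
  phen <- make_phenology("null_world", seed = 4)
  phen$between_tree_sd[] <- 0
  phen$shadow_fraction <- 0
  w <- generate_world(phen, scene_config(n_crowns_per_species = 22, seed = 4,
                                         dates = 3L,
                                         crown_radius_range = c(2.8, 3.4)))
  layer <- w$layers[[1]]
  pooled <- list()
  for (sp in unique(w$crowns$species)) {
    idx <- which(w$crowns$species == sp)
    px <- do.call(rbind, w$masks[idx])
    sel <- cbind(px[, "row"] + 1L, px[, "col"] + 1L)
    expect_gte(nrow(sel), 1e4)
    pooled[[sp]] <- c(mean(layer$bands[, , 1][sel]),
                      mean(layer$bands[, , 2][sel]),
                      mean(layer$bands[, , 3][sel]))
  }
  mat <- do.call(rbind, pooled)
  expect_lt(max(dist(mat)), 0.5)
})

test_that("separable world crown means classify perfectly by nearest centroid", {
  w <- tiny_world("separable_world")
  layer <- w$layers[["s01.RGB"]]
  ri <- relative_intensity(layer)
  feats <- t(vapply(seq_len(nrow(w$crowns)), function(i) {
    sun <- sunlit_mask(w$masks[[i]], ri, 20)
    sel <- cbind(sun[, "row"] + 1L, sun[, "col"] + 1L)
    c(mean(layer$bands[, , 1][sel]), mean(layer$bands[, , 2][sel]),
      mean(layer$bands[, , 3][sel]))
  }, numeric(3)))
  species <- w$crowns$species
  centroids <- apply(feats, 2, tapply, species, mean)
  d2 <- as.matrix(dist(rbind(feats, centroids)))
  d2 <- d2[seq_len(nrow(feats)), nrow(feats) + seq_len(nrow(centroids))]
  pred <- rownames(centroids)[max.col(-d2)]
  expect_equal(pred, species)
})
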