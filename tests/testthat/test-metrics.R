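test_that("relative intensity hits its endpoints and degenerate convention", {
  # 2-pixel mosaic: intensities 30 and 90 map to 0 and 100
  b <- array(0, c(1, 2, 3)); b[1, 1, ] <- 10; b[1, 2, ] <- 30
  ri <- relative_intensity(band_layer(b))
  expect_equal(as.numeric(ri), c(0, 100))
  # inserting intensity 60 between them gives 50
  b3 <- array(0, c(1, 3, 3)); b3[1, 1, ] <- 10; b3[1, 2, ] <- 20; b3[1, 3, ] <- 30
  expect_equal(as.numeric(relative_intensity(band_layer(b3))), c(0, 50, 100))
  # constant mosaic: everything is 100, nothing classed as shadow
  expect_true(all(relative_intensity(band_layer(array(7, c(3, 3, 3)))) == 100))
})

test_that("shadow filter keeps the threshold boundary and is monotone", {
  ri <- matrix(c(5, 19.9, 20, 80), 1, 4)
  mask <- cbind(row = rep(0L, 4), col = 0:3)
  kept <- sunlit_mask(mask, ri, 20)
  expect_equal(kept[, "col"], c(2L, 3L))  # RI = 20 is kept, 19.9 dropped
  expect_equal(sunlit_mask(mask, ri, 0), mask)  # threshold 0 is identity
  prev <- nrow(mask)
  for (thr in c(0, 10, 20, 50, 90, 100)) {
    n <- nrow(sunlit_mask(mask, ri, thr))
    expect_lte(n, prev)
    prev <- n
  }
})

test_that("generated shadow survives the 20% rule at the planted rate", {
  phen <- make_phenology("null_world", seed = 9)
  phen$shadow_fraction <- 0.3
  w <- generate_world(phen, scene_config(n_crowns_per_species = 6, seed = 9,
                                         dates = 1L,
                                         crown_radius_range = c(1.8, 2.4)))
  layer <- w$layers[[1]]
  ri <- relative_intensity(layer)
  surviving <- vapply(w$masks, function(m) {
    nrow(sunlit_mask(m, ri, 20)) / nrow(m)
  }, numeric(1))
  expect_true(all(abs(surviving - 0.7) <= 0.05))
})

test_that("spectral metrics obey their defining identities", {
  set.seed(1)
  px <- cbind(runif(50, 40, 60), runif(50, 90, 110), runif(50, 50, 70))
  m <- spectral_metrics(px, "RGB")
  expect_equal(unname(m["norm_1"] + m["norm_2"] + m["norm_3"]), 1)
  expect_equal(unname(m["ratio_12"]), unname(m["mean_1"] / m["mean_2"]))
  # population standard deviation: n divisor
  expect_equal(unname(m["sd_1"]),
               sqrt(mean((px[, 1] - mean(px[, 1]))^2)))
  expect_equal(unname(m["n_sunlit"]), 50)
  # G = R -> NGRVI = 0
  eq <- cbind(rep(30, 20), rep(80, 20), rep(80, 20))
  expect_equal(unname(spectral_metrics(eq, "RGB")["ngrvi"]), 0)
  # NIR = 3 R -> NDVI = 0.5 (CIR band order NIR, R, G)
  cir <- cbind(rep(150, 20), rep(50, 20), rep(90, 20))
  expect_equal(unname(spectral_metrics(cir, "CIR")["ndvi"]), 0.5)
  # all normalized-difference indices stay within [-1, 1]
  for (cam in c("RGB", "CIR")) {
    v <- spectral_metrics(px, cam)
    idx <- setdiff(names(v), c(paste0("mean_", 1:3), paste0("sd_", 1:3),
                               paste0("ratio_", c(12, 13, 23)),
                               paste0("norm_", 1:3), "n_sunlit"))
    expect_true(all(v[idx] >= -1 & v[idx] <= 1))
  }
  # under-populated crowns yield no vector
  expect_null(spectral_metrics(px[1:5, ], "RGB", min_sunlit = 10))
})

test_that("GLCM of a constant crown is the single-cell matrix", {
  band <- matrix(100, 6, 6)
  g <- glcm_metrics(band, full_mask(6, 6))
  expect_equal(unname(g["glcm_contrast"]), 0)
  expect_equal(unname(g["glcm_dissimilarity"]), 0)
  expect_equal(unname(g["glcm_homogeneity"]), 1)
  expect_equal(unname(g["glcm_entropy"]), 0)
  expect_equal(unname(g["glcm_second_moment"]), 1)
  expect_equal(unname(g["glcm_variance"]), 0)
  expect_equal(unname(g["glcm_correlation"]), 0)
})

test_that("GLCM matches the hand-derived checkerboard case", {
  # two adjacent quantization levels (bin width 8 at 32 levels), offset (0,1)
  band <- matrix(c(8, 16, 16, 8), 2, 2)   # levels 1 and 2 as a checkerboard
  g <- glcm_metrics(band, full_mask(2, 2), levels = 32,
                    offsets = list(c(0L, 1L)))
  expect_equal(unname(g["glcm_contrast"]), 1)
  expect_equal(unname(g["glcm_dissimilarity"]), 1)
  expect_equal(unname(g["glcm_homogeneity"]), 0.5)
  expect_equal(unname(g["glcm_correlation"]), -1)
  expect_equal(unname(g["glcm_entropy"]), log(2))
  expect_equal(unname(g["glcm_second_moment"]), 0.5)
  expect_equal(unname(g["glcm_variance"]), 0.25)
})

test_that("GLCM equals the brute-force pair-enumeration oracle exactly", {
  set.seed(11)
  offsets <- list(c(0L, 1L), c(1L, 0L), c(1L, 1L), c(1L, -1L))
  for (rep in 1:40) {
    nr <- sample(2:8, 1); nc <- sample(2:8, 1)
    band <- matrix(sample(0:255, nr * nc, replace = TRUE), nr, nc)
    m <- full_mask(nr, nc)
    m <- m[runif(nrow(m)) < 0.7, , drop = FALSE]
    if (nrow(m) == 0) next
    levels <- sample(c(4, 8, 32), 1)
    for (off in offsets) {
      got <- suppressMessages(glcm_metrics(band, m, levels, list(off)))
      want <- glcm_oracle(band, m, levels, list(off))
      expect_equal(got, want)
    }
    got <- suppressMessages(glcm_metrics(band, m, levels, offsets))
    want <- glcm_oracle(band, m, levels, offsets)
    expect_equal(got, want)
  }
})

test_that("GLCM parameter and degenerate-input handling", {
  band <- matrix(1, 4, 4)
  expect_error(glcm_metrics(band, full_mask(4, 4), levels = 1), "levels")
  # single isolated pixel: no co-occurring pair
  expect_message(g <- glcm_metrics(band, cbind(row = 0L, col = 0L)),
                 "no co-occurring")
  expect_null(g)
})

test_that("shifting all bands by one quantization bin leaves GLCM unchanged", {
  set.seed(3)
  band <- matrix(sample(40:180, 49, replace = TRUE), 7, 7)
  m <- full_mask(7, 7)
  g1 <- glcm_metrics(band, m, levels = 32)
  g2 <- glcm_metrics(band + 8, m, levels = 32)  # bin width 256/32 = 8
  expect_equal(g1[names(g1) != "glcm_variance"],
               g2[names(g2) != "glcm_variance"])
  # variance is invariant too: the whole distribution shifts by one level
  expect_equal(g1["glcm_variance"], g2["glcm_variance"])
  # while a constant offset moves ratios and indices as the formulas say
  px <- cbind(runif(30, 50, 80), runif(30, 90, 120), runif(30, 40, 60))
  s1 <- spectral_metrics(px, "RGB")
  s2 <- spectral_metrics(px + 8, "RGB")
  mu <- colMeans(px) + 8
  expect_equal(unname(s2["ratio_12"]), mu[1] / mu[2])
  expect_equal(unname(s2["ngrvi"]), (mu[2] - mu[3]) / (mu[2] + mu[3]))
  expect_lt(abs(s2["ngrvi"]), abs(s1["ngrvi"]))  # offsets damp ND indices
})

test_that("feature table has the documented shape and drop behaviour", {
  w <- tiny_world("separable_world")
  ft <- tiny_table("separable_world")
  # one row per retained crown; 37 metrics per (survey, camera) block
  n_layers <- length(w$layers)
  expect_equal(ncol(ft), 2 + n_layers * 37)
  expect_lte(nrow(ft), nrow(w$crowns))
  expect_true(all(c("crown_id", "species") %in% names(ft)))
  expect_true(all(grepl("^s\\d\\d\\.(RGB|CIR)\\.", setdiff(names(ft),
                                                           c("crown_id", "species")))))
  expect_false(anyNA(ft))
  # retained + dropped = all crowns
  dropped <- attr(ft, "dropped")
  expect_setequal(c(ft$crown_id, dropped$crown_id), w$crowns$crown_id)
  # permuting crown input order leaves the table identical (sorted rows)
  perm <- sample(nrow(w$crowns))
  ft2 <- suppressWarnings(build_feature_table(w$layers, w$crowns[perm, ]))
  expect_equal(as.data.frame(ft2), as.data.frame(ft))
})

test_that("a fully shadowed crown is dropped with a logged reason", {
  w <- tiny_world("separable_world")
  layers <- w$layers["s01.RGB"]
  # darken one crown below the shadow threshold on a copy of the layer
  victim <- 3L
  m <- w$masks[[victim]]
  l <- layers[[1]]
  for (b in 1:3) {
    band <- l$bands[, , b]
    band[cbind(m[, "row"] + 1L, m[, "col"] + 1L)] <- 0
    l$bands[, , b] <- band
  }
  layers[[1]] <- l
  expect_warning(
    ft <- build_feature_table(layers, w$crowns),
    paste0(w$crowns$crown_id[victim], ".*sunlit"))
  expect_false(w$crowns$crown_id[victim] %in% ft$crown_id)
})
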