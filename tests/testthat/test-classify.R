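# small synthetic feature frames are enough for the protocol mechanics;
# world-backed classification behaviour is covered in test-acceptance.R

fake_table <- function(counts, p = 4, seed = 1) {
  set.seed(seed)
  species <- rep(names(counts), counts)
  n <- length(species)
  df <- data.frame(crown_id = sprintf("c%04d", seq_len(n)),
                   species = species, stringsAsFactors = FALSE)
  for (k in seq_len(p)) df[[paste0("s01.RGB.m", k)]] <- rnorm(n)
  df
}

test_that("balanced sampling reproduces the inventory arithmetic", {
  # the study inventory: 72 birches, 186 oaks, 142 maples, 196 ashes, 81 poplars
  counts <- c(birch = 72, oak = 186, maple = 142, ash = 196, poplar = 81)
  tab <- fake_table(counts)
  samp <- balanced_sample(tab, n_per_class = 50, seed = 42)
  expect_equal(nrow(samp), 250L)
  expect_true(all(table(samp$species) == 50))
  expect_false(any(duplicated(samp$crown_id)))
  # deterministic under a fixed seed
  expect_identical(samp, balanced_sample(tab, 50, seed = 42))
  expect_false(identical(samp, balanced_sample(tab, 50, seed = 43)))
})

test_that("a class below the quota fails with its name and count", {
  tab <- fake_table(c(oak = 40, ash = 60))
  expect_error(balanced_sample(tab, 50), "oak \\(40\\)")
})

test_that("report accounting: repetitions, confusion totals, error identities", {
  tab <- fake_table(c(a = 30, b = 30, c = 30), p = 3)
  rep <- run_scenario(tab, n_repetitions = 4, n_trees = 50,
                      n_per_class = 20, seed = 7)
  expect_length(rep$per_repetition_oob, 4)
  expect_equal(rep$overall_oob, mean(rep$per_repetition_oob))
  expect_equal(sum(rep$confusion), 4 * 3 * 20)
  # balanced design: identical row sums, one per class
  expect_true(all(rowSums(rep$confusion) == 4 * 20))
  # pooled confusion agrees with the averaged error
  expect_equal(1 - sum(diag(rep$confusion)) / sum(rep$confusion),
               rep$overall_oob, tolerance = 1e-12)
  # the class-mean error equals the overall error under balance
  expect_equal(mean(rep$per_class_oob), rep$overall_oob, tolerance = 1e-12)
  expect_true(rep$overall_oob >= 0 && rep$overall_oob <= 1)
})

test_that("identical inputs and seed reproduce the full report", {
  tab <- fake_table(c(a = 25, b = 25), p = 3)
  r1 <- run_scenario(tab, n_repetitions = 3, n_trees = 50, n_per_class = 15,
                     seed = 9)
  r2 <- run_scenario(tab, n_repetitions = 3, n_trees = 50, n_per_class = 15,
                     seed = 9)
  expect_identical(r1$per_repetition_oob, r2$per_repetition_oob)
  expect_identical(r1$confusion, r2$confusion)
})

test_that("degenerate scenarios raise explicit errors", {
  tab <- fake_table(c(a = 30, b = 30))
  expect_error(run_scenario(tab, character(0)), "empty feature column")
  expect_error(run_scenario(tab, "nope"), "not in table")
  one <- fake_table(c(a = 30))
  expect_error(run_scenario(one, n_per_class = 10), "2 species")
  # rows with missing metrics are excluded before balancing
  tab$s01.RGB.m1[tab$species == "a"][1:15] <- NA
  expect_error(run_scenario(tab, n_per_class = 25, n_repetitions = 2,
                            n_trees = 20),
               "missing metrics.*a \\(15\\)")
})

test_that("missing-metric rows are dropped, not imputed", {
  tab <- fake_table(c(a = 40, b = 40), p = 3)
  tab$s01.RGB.m2[1:5] <- NA
  rep <- run_scenario(tab, n_repetitions = 2, n_trees = 30, n_per_class = 30,
                      seed = 3)
  expect_equal(sum(rep$confusion), 2 * 2 * 30)
})
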