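# Phenology parameterisations driving the synthetic scene generator.
#
# The generator's statistical target is the mechanism that makes a
# late-spring survey the best acquisition window for deciduous species
# mapping: within-species spectral variance is smallest at the end of leaf
# flush (every crown of a species is uniformly green) and largest in early
# spring and late autumn (crowns of one species leaf out and senesce
# asynchronously), while between-species spectral differences persist.

SPECIES_DEFAULT <- c("ash", "birch", "maple", "oak", "poplar")
BAND_NAMES <- c("B", "G", "R", "NIR")

# ten-survey calendar: three spring, three summer, four autumn flights
survey_calendar <- function() {
  data.frame(
    survey_id = sprintf("s%02d", 1:10),
    date = as.Date(c("2012-04-27", "2011-04-27", "2013-05-28", "2012-06-05",
                     "2013-07-08", "2014-08-21", "2014-09-18", "2013-10-01",
                     "2012-10-22", "2013-11-15")),
    season = c("spring", "spring", "spring", "summer", "summer", "summer",
               "autumn", "autumn", "autumn", "autumn"),
    gdd = c(64, 178, 183, 305, 491, 732, 897, 1085, 1409, 1169),
    stringsAsFactors = FALSE
  )
}

# reference spectra (8-bit DN, bands B,G,R,NIR)
SPEC_LEAF_OFF <- c(55, 62, 72, 82)    # bark/ground dominated crown
SPEC_LEAF_ON  <- c(35, 105, 55, 185)  # fully flushed green canopy
SPEC_AUTUMN   <- c(45, 92, 115, 125)  # coloured senescing foliage

#' Build the phenology parameters for a synthetic world
#'
#' Returns the per-species, per-date mean 4-band spectrum (blue, green, red,
#' near-infrared digital numbers) plus the variance components that drive
#' [generate_world()]. Four presets cover the regimes the pipeline must
#' distinguish:
#'
#' * `"null_world"` — every species shares one spectrum and one variance at
#'   every date: a chance-level control for the classifier.
#' * `"separable_world"` — species means separated by at least ten
#'   between-tree standard deviations at every date: classification should
#'   be near perfect.
#' * `"planted_optimum"` — one date `t_star` (drawn from `seed`) combines
#'   small within-species variance with wide between-species spacing; all
#'   other dates are noisy and crowded. The date-ranking search must
#'   recover `t_star`.
#' * `"paper_like"` — five species, ten dates spanning spring to autumn,
#'   species-specific leaf flush and senescence timing, and a U-shaped
#'   within-species variance profile over the season that bottoms out at
#'   the third survey (end of leaf flush).
#'
#' @param preset One of `"paper_like"`, `"null_world"`, `"separable_world"`,
#'   `"planted_optimum"`.
#' @param seed Integer seed controlling the preset's random choices (only
#'   `planted_optimum` uses it, to place `t_star`).
#' @param cir_mixing Logical; when `TRUE` the generator renders the CIR
#'   camera with heavily cross-talking, near-collinear bands, emulating the
#'   redundant band sensitivity of a hot-mirror-removed consumer camera.
#' @return An object of class `phenology_params`: species labels, survey
#'   table (id, date, season, GDD), `mean_spectrum` (species x date x 4
#'   array, DN), `between_tree_sd` (species x date, DN), `within_crown_sd`
#'   (DN), `shadow_fraction`, `luminosity_gradient`, `t_star` (date index
#'   or `NA`).
#' @seealso [separation_ratio()] for the between/within separability of a
#'   parameter set.
#' @export
make_phenology <- function(preset, seed = 1L, cir_mixing = FALSE) {
  presets <- c("paper_like", "null_world", "separable_world", "planted_optimum")
  if (length(preset) != 1 || !preset %in% presets) {
    stop("unknown preset ", deparse(preset), "; valid presets: ",
         paste(presets, collapse = ", "), call. = FALSE)
  }
  surveys <- survey_calendar()
  nd <- nrow(surveys)
  sp <- SPECIES_DEFAULT
  ns <- length(sp)
  mean_spectrum <- array(0, dim = c(ns, nd, 4),
                         dimnames = list(sp, surveys$survey_id, BAND_NAMES))
  t_star <- NA_integer_

  # distinct species direction patterns (rows pairwise >= 1 apart, unit scale)
  dir5 <- rbind(c(0, 0, 0, 0),
                c(1, 1, 1, 1),
                c(1, -1, 1, -1),
                c(-1, 1, 1, -1),
                c(-1, -1, 1, 1)) / 2

  if (preset == "null_world") {
    for (s in seq_len(ns)) for (d in seq_len(nd))
      mean_spectrum[s, d, ] <- SPEC_LEAF_ON
    between_sd <- matrix(8, ns, nd)
    within_sd <- 5
  } else if (preset == "separable_world") {
    for (s in seq_len(ns)) for (d in seq_len(nd))
      mean_spectrum[s, d, ] <- clamp_dn(SPEC_LEAF_ON + 28 * dir5[s, ])
    between_sd <- matrix(2, ns, nd)
    within_sd <- 2
  } else if (preset == "planted_optimum") {
    t_star <- with_seed(seed, sample.int(nd, 1))
    spacing <- rep(6, nd); spacing[t_star] <- 40
    sds <- rep(15, nd); sds[t_star] <- 3
    for (s in seq_len(ns)) for (d in seq_len(nd))
      mean_spectrum[s, d, ] <- clamp_dn(SPEC_LEAF_ON + spacing[d] * dir5[s, ])
    between_sd <- matrix(rep(sds, each = ns), ns, nd)
    within_sd <- 4
  } else { # paper_like
    # species-specific leaf flush onset / senescence onset (day of year)
    onset <- c(ash = 145, birch = 90, maple = 130, oak = 130, poplar = 115)
    senesce <- c(ash = 270, birch = 315, maple = 285, oak = 310, poplar = 290)
    flush_days <- 25; fall_days <- 35
    doy <- as.integer(strftime(surveys$date, "%j"))
    for (s in seq_len(ns)) {
      for (d in seq_len(nd)) {
        f <- min(1, max(0, (doy[d] - onset[sp[s]]) / flush_days))   # flush progress
        a <- min(1, max(0, (doy[d] - senesce[sp[s]]) / fall_days))  # senescence progress
        leaf <- (1 - a) * SPEC_LEAF_ON + a * ((1 - a) * SPEC_AUTUMN + a * SPEC_LEAF_OFF)
        spec <- (1 - f) * SPEC_LEAF_OFF + f * leaf
        mean_spectrum[s, d, ] <- clamp_dn(spec + 9 * dir5[s, ])
      }
    }
    # within-species sd: high at season edges, minimal at survey 3
    sd_profile <- c(16, 12, 4, 6, 7, 8, 9, 11, 14, 15)
    between_sd <- matrix(rep(sd_profile, each = ns), ns, nd)
    within_sd <- 5
  }
  dimnames(between_sd) <- list(sp, surveys$survey_id)

  structure(
    list(species = sp, surveys = surveys, mean_spectrum = mean_spectrum,
         between_tree_sd = between_sd, within_crown_sd = within_sd,
         shadow_fraction = 0.15, luminosity_gradient = 0,
         cir_mixing = isTRUE(cir_mixing), preset = preset,
         seed = as.integer(seed), t_star = t_star),
    class = "phenology_params"
  )
}

#' @export
print.phenology_params <- function(x, ...) {
  cat(sprintf("<phenology_params> preset '%s': %d species x %d dates\n",
              x$preset, length(x$species), nrow(x$surveys)))
  if (!is.na(x$t_star))
    cat(sprintf("  planted optimal date: %s (index %d)\n",
                x$surveys$survey_id[x$t_star], x$t_star))
  cat(sprintf("  within-crown sd %.1f DN, shadow fraction %.2f\n",
              x$within_crown_sd, x$shadow_fraction))
  invisible(x)
}

#' Between/within spectral separation ratio per survey date
#'
#' For each date, the minimum pairwise Euclidean distance between species
#' mean spectra divided by the maximum between-tree standard deviation —
#' the generative analogue of class separability. For a `planted_optimum`
#' parameter set the ratio is strictly maximal at `t_star`.
#'
#' @param phenology A [make_phenology()] result.
#' @return Named numeric vector, one ratio per survey date.
#' @export
separation_ratio <- function(phenology) {
  stopifnot(inherits(phenology, "phenology_params"))
  nd <- nrow(phenology$surveys)
  out <- numeric(nd)
  for (d in seq_len(nd)) {
    m <- phenology$mean_spectrum[, d, ]
    dmin <- min(stats::dist(m))
    smax <- max(phenology$between_tree_sd[, d])
    out[d] <- if (smax > 0) dmin / smax else Inf
  }
  names(out) <- phenology$surveys$survey_id
  out
}
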