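# crownpheno

Object-based discrimination of deciduous tree species from a multitemporal
series of very-high-resolution (20 cm/pixel) orthomosaics, and an exhaustive
search for the acquisition dates that separate species best.

## The problem and the method

Mapping individual deciduous species in a mixed broadleaved forest from
aerial imagery is hard on any single date: crowns of different species are
all green in summer, and all brown-ish in early spring. What does separate
species is *phenology* — the species-specific timing of leaf flush,
senescence and leaf fall. A time series of cheap UAS surveys (one RGB and
one color-infrared flight per date) can exploit that, provided one can
answer: **which date, or small set of dates, discriminates species best?**

`crownpheno` implements the full analysis chain:

1. **Crown metrics** (`build_feature_table()`). Each manually delineated
   crown polygon is narrowed by a 0.50 m inward buffer to strip the mixed
   border, rasterized by the pixel-center rule, and cleared of cast shadow:
   with pixel intensity `I = B + G + R` (or `NIR + R + G`) and relative
   intensity `RI = 100 (I − I_min)/(I_max − I_min)` over the mosaic, pixels
   with `RI < 20` are discarded. On the surviving sunlit pixels the package
   computes, per crown × survey × camera: band means and SDs, the three
   band-mean ratios, normalized bands `mean_b / Σ mean`, the
   normalized-difference indices `ND(x, y) = (x − y)/(x + y)` (RGB: NGRVI,
   NGBI, NRBI; CIR: NDVI, GNDVI, NGRVI), and seven gray-level co-occurrence
   (GLCM) texture metrics per band (variance, homogeneity, contrast,
   dissimilarity, entropy, second moment, correlation) from a 32-level,
   symmetric, offset-pooled co-occurrence matrix over the crown object.
2. **Balanced repeated random forests** (`run_scenario()`). For each
   classification scenario, 20 forests of 500 trees are fitted, each on a
   fresh balanced draw of 50 crowns per species; the forests'
   out-of-bag (OOB) misclassification errors are averaged. The OOB error —
   each crown predicted only by trees whose bootstrap excluded it — is the
   cross-validation currency of the whole analysis.
3. **Date-combination search** (`rank_scenarios()`). All single dates,
   pairs and trios of surveys (each survey = RGB + CIR metrics) are scored
   and ranked by averaged OOB error; `camera_comparison()` isolates the
   RGB vs CIR vs combined effect on any one date.
4. **Synthetic phenology worlds** (`make_phenology()`, `generate_world()`).
   Because real orthomosaics cannot ship with a package, a scene generator
   renders crown worlds with known statistical structure — including a
   `planted_optimum` preset in which exactly one date combines small
   within-species variance with wide between-species spacing, so the whole
   pipeline can be validated as a parameter-recovery problem.

## Worked example

```r
library(crownpheno)

phen  <- make_phenology("planted_optimum", seed = 11)
phen$t_star                      # index of the planted optimal date
#> [1] 10
world <- generate_world(phen, scene_config(n_crowns_per_species = 15,
                                           seed = 11))
ft    <- build_feature_table(world$layers, world$crowns)
ids   <- sort(unique(attr(ft, "surveys")$survey_id))
rk    <- rank_scenarios(ft, enumerate_scenarios(ids, k = 1),
                        n_repetitions = 5, n_trees = 200, n_per_class = 12,
                        seed = 1)
rk$surveys[1]                    # best single date found by the search
#> [1] "s10"
round(rk$overall_oob[1:3], 3)    # its OOB error, then the runners-up
#> [1] 0.000 0.740 0.753
```

The search recovers the planted date `s10` with a 0% OOB error, while every
other date sits near the 80% chance level of a 5-class balanced problem —
the signature of a world where only one acquisition window separates the
species. On `paper_like` worlds the same machinery ranks the
end-of-leaf-flush date first, for the same reason real late-spring surveys
win: within-species spectral variance is minimal exactly when all crowns of
a species are uniformly green.

A thin CLI over the same functions lives in `inst/scripts/crownpheno.R`
(subcommands `simulate`, `extract`, `search`, `all`, configured by YAML).

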