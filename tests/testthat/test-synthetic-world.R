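test_that("world generation is deterministic and satisfies type invariants", {
  cfg <- world_config(n_rows = 25, n_cols = 25)
  w1 <- make_world(cfg, seed = 3)
  w2 <- make_world(cfg, seed = 3)
  expect_identical(w1, w2)

  ep <- w1$epochs$t0
  expect_length(ep$vi_series, 23)
  for (m in 1:12) {
    expect_true(all(ep$monthly_tmax[[m]]$values >= ep$monthly_tmin[[m]]$values))
    expect_true(all(ep$monthly_prec[[m]]$values >= 0))
  }
  vi_rng <- range(sapply(ep$vi_series, function(g) range(g$values)))
  expect_true(vi_rng[1] >= -1 && vi_rng[2] <= 1)
  # coarse regional extent strictly contains the fine local extent
  fine <- grid_extent(ep$landcover)
  coarse <- grid_extent(ep$coarse_tmax[[1]])
  expect_true(coarse["xmin"] < fine["xmin"] && coarse["xmax"] > fine["xmax"])
  expect_true(coarse["ymin"] < fine["ymin"] && coarse["ymax"] > fine["ymax"])
})

test_that("zero noise and flat gradients give spatially constant climate", {
  cfg <- world_config(n_rows = 10, n_cols = 10, temp_noise_sd = 0,
                      prec_noise_sd = 0, temp_gradient = 0, prec_gradient = 0)
  w <- make_world(cfg, seed = 1)
  for (m in c(1, 7)) {
    expect_equal(diff(range(w$epochs$t0$monthly_tmax[[m]]$values)), 0)
    expect_equal(diff(range(w$epochs$t0$monthly_prec[[m]]$values)), 0)
  }
})

test_that("realized land-cover fractions track the configured proportions", {
  cfg <- world_config(n_rows = 200, n_cols = 200)
  w <- make_world(cfg, seed = 9)
  lc <- w$epochs$t0$landcover$values
  forest_frac <- mean(lc == lc_levels[["forest"]])
  expect_lt(abs(forest_frac - 0.21), 0.03)
  scrub_frac <- mean(lc == lc_levels[["scrubland"]])
  expect_lt(abs(scrub_frac - 0.62), 0.03)
})

test_that("an all-zero change scenario reproduces t0 exactly", {
  w <- make_world(world_config(n_rows = 15, n_cols = 15), seed = 4)
  w <- apply_change(w, no_change(), seed = 4)
  expect_identical(w$epochs$t1$monthly_tmax, w$epochs$t0$monthly_tmax)
  expect_identical(w$epochs$t1$landcover, w$epochs$t0$landcover)
  expect_identical(w$epochs$t1$vi_series, w$epochs$t0$vi_series)
})

test_that("total encroachment removes every cropland cell", {
  w <- make_world(world_config(n_rows = 20, n_cols = 20), seed = 4)
  ch <- change_scenario(encroachment_rate = 1, n_fires = 0)
  w <- apply_change(w, ch, seed = 4)
  expect_equal(sum(w$epochs$t1$landcover$values == lc_levels[["cropland"]]), 0)
})

test_that("land-cover change conserves the cell count across classes", {
  w <- make_world(world_config(n_rows = 30, n_cols = 30), seed = 6)
  w <- apply_change(w, change_scenario(), seed = 6)
  lc1 <- w$epochs$t1$landcover$values
  expect_true(all(lc1 %in% lc_levels))
  expect_equal(length(lc1), 900)
})

test_that("fire patches convert the rasterized disc area", {
  # all-burnable world: every converted cell lies in a disc, so the converted
  # count equals the brute-force rasterized area of the discs minus overlaps
  cfg <- world_config(n_rows = 40, n_cols = 40,
                      class_props = c(scrubland = 0.5, forest = 0.5,
                                      cropland = 0, other = 0))
  w <- make_world(cfg, seed = 8)
  lc0 <- w$epochs$t0$landcover$values
  ch <- change_scenario(tmax_delta = 0, tmin_delta = 0, prec_delta = 0,
                        encroachment_rate = 0, n_fires = 3,
                        fire_patch_radius = 5, niche_shift_sd = 0)
  w <- apply_change(w, ch, seed = 8)
  lc1 <- w$epochs$t1$landcover$values
  changed <- which(lc1 != lc0)
  # recover the disc centres: burnable everywhere, so the sampled centres are
  # reproducible from the same child-seed stream used by apply_change
  expect_gt(length(changed), 0)
  # forest inside a disc becomes scrubland; scrubland becomes other
  expect_true(all(lc1[changed] %in% lc_levels[c("scrubland", "other")]))
  # every changed cell lies within radius of some changed region; disc area
  # bound: 3 discs of radius 5 cover at most 3 * |disc(5)| cells
  single_disc <- disc_cells_oracle(40, 40, matrix(c(20, 20), 1), 5)
  expect_lte(length(changed), 3 * single_disc)
  expect_error(change_scenario(n_fires = -1), "n_fires")
  expect_error(change_scenario(encroachment_rate = 1.2), "encroachment")
})

test_that("virtual species honour the trait design and coefficient constraints", {
  sp <- make_virtual_species(8, trait_design = "balanced", seed = 2)
  for (tr in c("origin", "phenology", "specialization", "preference")) {
    expect_equal(as.vector(table(sp[[tr]])), c(4L, 4L), info = tr)
  }
  for (i in seq_len(nrow(sp))) {
    b <- sp$beta[[i]]
    if (sp$preference[i] == "forest") expect_gt(b[["frac_forest"]], 0)
    if (sp$preference[i] == "open") expect_lt(b[["frac_forest"]], 0)
  }
  expect_error(make_virtual_species(0), "n_species")
  expect_error(make_virtual_species(2, beta_ranges = c(2, 1)), "beta_ranges")
})

test_that("true suitability is the logistic of the linear predictor", {
  stack <- toy_stack()
  null_sp <- list(species_id = "null", beta0 = 0,
                  beta = c(z1 = 0, z2 = 0))
  s <- true_suitability(null_sp, stack)
  expect_true(all(abs(s$values - 0.5) < 1e-12))

  sat <- list(beta0 = 20, beta = c(z1 = 0, z2 = 0))
  expect_true(all(true_suitability(sat, stack)$values > 0.999))

  one <- list(beta0 = 0, beta = c(z1 = 1))
  s1 <- true_suitability(one, stack)
  cell <- which(abs(stack$z1$values - 1) < 1e-9)[1]
  expect_equal(s1$values[cell], 1 / (1 + exp(-1)), tolerance = 1e-6)

  expect_error(true_suitability(list(beta0 = 0, beta = c(zmissing = 1)), stack),
               "missing")
})

test_that("surveys respect the design geometry and detection law", {
  s_const <- const_grid(1, n = 30)
  suit0 <- list(spA = s_const)
  occ_all <- sample_surveys(suit0, suit0, survey_design(100, 60, 100), seed = 1)
  expect_true(all(occ_all$detected == 1))

  s_half <- const_grid(0.5, n = 30)
  occ <- sample_surveys(list(spA = s_half), list(spA = s_half),
                        survey_design(344, 204, 384), seed = 1)
  cal <- occ[occ$protocol == "calibration", ]
  int <- occ[occ$protocol == "internal_tt", ]
  ext <- occ[occ$protocol == "external_tt", ]
  # binomial(344, 0.5) band
  expect_true(sum(cal$detected) >= 140 && sum(cal$detected) <= 204)
  # geometry invariants
  key <- function(d) paste(d$x, d$y)
  expect_true(all(key(int) %in% key(cal)))
  expect_length(intersect(key(ext), key(cal)), 0)
  expect_equal(c(nrow(cal), nrow(int), nrow(ext)), c(344, 204, 384))

  expect_error(sample_surveys(list(spA = const_grid(1, n = 5)),
                              list(spA = const_grid(1, n = 5)),
                              survey_design(20, 10, 20), seed = 1),
               "exceed")
  expect_error(survey_design(n_calibration = 100, n_internal = 150), "exceed")
})

test_that("Bernoulli sampling frequencies match the suitability law", {
  # 1000 draws at p = 0.3: frequency within 4 * sqrt(p(1-p)/1000)
  for (p in c(0.2, 0.5, 0.8)) {
    g <- const_grid(p, n = 40)
    occ <- sample_surveys(list(sp = g), list(sp = g),
                          survey_design(1000, 500, 500), seed = round(p * 100))
    f <- mean(occ$detected[occ$protocol == "calibration"])
    expect_lt(abs(f - p), 4 * sqrt(p * (1 - p) / 1000))
  }
})

test_that("survey generation is deterministic per seed", {
  g <- const_grid(0.4, n = 25)
  o1 <- sample_surveys(list(a = g), list(a = g), survey_design(80, 40, 80), seed = 12)
  o2 <- sample_surveys(list(a = g), list(a = g), survey_design(80, 40, 80), seed = 12)
  expect_identical(o1, o2)
})

test_that("the prevalence filter applies a strict more-than rule", {
  mk <- function(id, n_pres, n_total = 50) {
    tibble::tibble(species_id = id, x = seq_len(n_total), y = 1,
                   detected = rep(c(1L, 0L), c(n_pres, n_total - n_pres)),
                   epoch = "t0", protocol = "calibration")
  }
  occ <- dplyr::bind_rows(mk("at15", 15), mk("at16", 16), mk("none", 0))
  pf <- prevalence_filter(occ)
  expect_false(pf$retained[pf$species_id == "at15"])
  expect_true(pf$retained[pf$species_id == "at16"])
  expect_false(pf$retained[pf$species_id == "none"])
})
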