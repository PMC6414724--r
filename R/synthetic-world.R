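#' Land-cover class codes
#'
#' Integer coding of the four land-cover classes used throughout:
#' 1 = scrubland, 2 = forest, 3 = cropland, 4 = other.
#' @export
lc_levels <- c(scrubland = 1L, forest = 2L, cropland = 3L, other = 4L)

#' Configuration for a synthetic two-epoch world
#'
#' Defaults emulate the kind of Atlantic–Mediterranean transition mountain
#' landscape the framework is designed around: a shrubland-dominated mosaic
#' (62% scrubland, 21% forest, 10% cropland) on a fine "local" grid of 230-m
#' cells, nested inside a coarse "regional" grid whose extent is 10x larger
#' with ~10-km cells (a 43x cell-size ratio). Climate fields are smooth
#' (Gaussian-filtered noise plus a north–south gradient), precipitation is
#' winter-peaked, and the vegetation-index year is a 23-composite seasonal
#' curve whose level, amplitude and peak timing depend on land cover.
#'
#' @param n_rows,n_cols Fine-grid dimensions (cells).
#' @param cell_size Fine cell size in metres.
#' @param coarse_extent_factor Regional extent as a multiple of the local extent.
#' @param coarse_cell_factor Regional cell size as a multiple of the local one.
#' @param smoothing_sigma Gaussian length scale of spatial noise, in cells.
#' @param tmean_annual Annual mean of monthly maximum temperature (deg C).
#' @param seasonal_amp Seasonal half-amplitude of temperature (deg C).
#' @param diurnal_range Mean excess of tmax over tmin (deg C, > 0).
#' @param temp_gradient North-to-south increase of temperature across the fine
#'   extent (deg C); scaled by extent on the coarse grid.
#' @param temp_noise_sd SD of the smooth spatial temperature anomaly (deg C).
#' @param prec_base Mean monthly precipitation (mm).
#' @param prec_seasonal_amp Fractional seasonal amplitude of precipitation.
#' @param prec_gradient North-to-south precipitation change across the extent (mm).
#' @param prec_noise_sd SD of the smooth spatial precipitation anomaly (mm).
#' @param class_props Named proportions over the four land-cover classes
#'   (must sum to 1).
#' @param vi_noise_sd SD of the smooth spatial vegetation-index anomaly.
#'
#' @return A list of class `world_config`.
#' @export
world_config <- function(n_rows = 60, n_cols = 60, cell_size = 230,
                         coarse_extent_factor = 10, coarse_cell_factor = 43,
                         smoothing_sigma = 6,
                         tmean_annual = 14, seasonal_amp = 8,
                         diurnal_range = 9, temp_gradient = 3,
                         temp_noise_sd = 1.5,
                         prec_base = 80, prec_seasonal_amp = 0.6,
                         prec_gradient = 40, prec_noise_sd = 18,
                         class_props = c(scrubland = 0.62, forest = 0.21,
                                         cropland = 0.10, other = 0.07),
                         vi_noise_sd = 0.05) {
  if (n_rows < 1 || n_cols < 1 || cell_size <= 0) {
    stop("world_config: grid dimensions and cell size must be positive",
         call. = FALSE)
  }
  if (abs(sum(class_props) - 1) > 1e-8 ||
      !setequal(names(class_props), names(lc_levels))) {
    stop("world_config: class_props must be named over the four classes and sum to 1",
         call. = FALSE)
  }
  structure(as.list(environment()), class = "world_config")
}

# smooth unit-variance anomaly field (zero if sd == 0)
anomaly_field <- function(n_rows, n_cols, sigma, sd) {
  if (sd <= 0) return(matrix(0, n_rows, n_cols))
  f <- gaussian_smooth(matrix(rnorm(n_rows * n_cols), n_rows, n_cols), sigma)
  s <- stats::sd(as.numeric(f))
  if (s < 1e-12) return(matrix(0, n_rows, n_cols))
  f / s * sd
}

make_climate_epoch <- function(n_rows, n_cols, cell_size, origin, cfg,
                               gradient_scale = 1) {
  month_jit <- rnorm(12, 0, 0.2)
  t_anom <- anomaly_field(n_rows, n_cols, cfg$smoothing_sigma, cfg$temp_noise_sd)
  p_anom <- anomaly_field(n_rows, n_cols, cfg$smoothing_sigma, cfg$prec_noise_sd)
  seas_mod <- 1 + anomaly_field(n_rows, n_cols, cfg$smoothing_sigma,
                                0.15 * (cfg$prec_noise_sd > 0))
  range_f <- pmax(cfg$diurnal_range +
                    anomaly_field(n_rows, n_cols, cfg$smoothing_sigma,
                                  0.8 * (cfg$temp_noise_sd > 0)), 0.5)
  row_frac <- matrix((seq_len(n_rows) - 0.5) / n_rows, n_rows, n_cols)
  t_grad <- cfg$temp_gradient * gradient_scale * row_frac
  p_grad <- cfg$prec_gradient * gradient_scale * (1 - row_frac)

  g <- function(v) raster_grid(v, cell_size, origin)
  tmax <- tmin <- prec <- vector("list", 12L)
  for (m in 1:12) {
    season_t <- cfg$seasonal_amp * cos(2 * pi * (m - 7) / 12)
    season_p <- cos(2 * pi * (m - 1) / 12)
    tx <- cfg$tmean_annual + season_t + month_jit[m] + t_grad + t_anom
    pr <- pmax((cfg$prec_base + p_grad + p_anom) *
                 (1 + cfg$prec_seasonal_amp * seas_mod * season_p), 0)
    tmax[[m]] <- g(tx)
    tmin[[m]] <- g(tx - range_f)
    prec[[m]] <- g(pr)
  }
  list(monthly_tmax = tmax, monthly_tmin = tmin, monthly_prec = prec)
}

make_landcover <- function(n_rows, n_cols, cell_size, origin, cfg) {
  u <- gaussian_smooth(matrix(rnorm(n_rows * n_cols), n_rows, n_cols),
                       cfg$smoothing_sigma)
  props <- cfg$class_props[names(lc_levels)]
  cuts <- stats::quantile(as.numeric(u), probs = cumsum(props)[-4])
  codes <- matrix(1L + findInterval(as.numeric(u), cuts, left.open = TRUE),
                  n_rows, n_cols)
  raster_grid(codes, cell_size, origin)
}

# per-class vegetation-index annual curve parameters (level, half-amplitude,
# peak composite of 23)
vi_class_params <- function() {
  tibble::tibble(
    class = names(lc_levels),
    level = c(0.30, 0.45, 0.35, 0.12),
    amp = c(0.18, 0.10, 0.28, 0.04),
    peak = c(11, 13, 9, 11)
  )
}

make_vi_series <- function(landcover, cfg) {
  pars <- vi_class_params()
  code <- landcover$values
  lvl <- matrix(pars$level[code], nrow(code), ncol(code))
  amp <- matrix(pars$amp[code], nrow(code), ncol(code))
  pk <- matrix(pars$peak[code], nrow(code), ncol(code))
  anom <- anomaly_field(nrow(code), ncol(code), cfg$smoothing_sigma, cfg$vi_noise_sd)
  lapply(1:23, function(d) {
    v <- lvl + anom + amp * cos(2 * pi * (d - pk) / 23) +
      rnorm(length(code), 0, 0.01)
    grid_like(landcover, pmin(pmax(v, -1), 1))
  })
}

#' Generate a synthetic two-epoch world (epoch t0)
#'
#' Builds the calibration-epoch landscape: monthly climate on the fine local
#' grid and the enclosing coarse regional grid, patch-structured land cover,
#' and a 23-composite vegetation-index year. [apply_change()] then derives
#' epoch t1. Deterministic for a fixed seed.
#'
#' @param config A [world_config()].
#' @param seed Integer master seed.
#' @return A list of class `synthetic_world` with elements `config`, `seed`
#'   and `epochs$t0` (fields `monthly_tmax`, `monthly_tmin`, `monthly_prec`,
#'   `coarse_tmax`, `coarse_tmin`, `coarse_prec`, `landcover`, `vi_series`).
#' @export
make_world <- function(config = world_config(), seed = 1L) {
  stopifnot(inherits(config, "world_config"))
  cfg <- config
  # fine extent centred inside the coarse extent
  fine_w <- cfg$n_cols * cfg$cell_size
  fine_h <- cfg$n_rows * cfg$cell_size
  coarse_cell <- cfg$cell_size * cfg$coarse_cell_factor
  coarse_n_cols <- max(4L, as.integer(ceiling(cfg$n_cols * cfg$coarse_extent_factor /
                                                cfg$coarse_cell_factor)))
  coarse_n_rows <- max(4L, as.integer(ceiling(cfg$n_rows * cfg$coarse_extent_factor /
                                                cfg$coarse_cell_factor)))
  coarse_origin <- c(0, coarse_n_rows * coarse_cell)
  fine_origin <- c((coarse_n_cols * coarse_cell - fine_w) / 2,
                   coarse_origin[2] - (coarse_n_rows * coarse_cell - fine_h) / 2)

  climate <- with_seed(child_seed(seed, 1L), {
    make_climate_epoch(cfg$n_rows, cfg$n_cols, cfg$cell_size, fine_origin, cfg)
  })
  coarse <- with_seed(child_seed(seed, 2L), {
    make_climate_epoch(coarse_n_rows, coarse_n_cols, coarse_cell, coarse_origin,
                       cfg, gradient_scale = cfg$coarse_extent_factor)
  })
  landcover <- with_seed(child_seed(seed, 3L), {
    make_landcover(cfg$n_rows, cfg$n_cols, cfg$cell_size, fine_origin, cfg)
  })
  vi <- with_seed(child_seed(seed, 4L), make_vi_series(landcover, cfg))

  t0 <- list(monthly_tmax = climate$monthly_tmax,
             monthly_tmin = climate$monthly_tmin,
             monthly_prec = climate$monthly_prec,
             coarse_tmax = coarse$monthly_tmax,
             coarse_tmin = coarse$monthly_tmin,
             coarse_prec = coarse$monthly_prec,
             landcover = landcover,
             vi_series = vi)
  structure(list(config = cfg, seed = seed, epochs = list(t0 = t0)),
            class = "synthetic_world")
}

#' @export
print.synthetic_world <- function(x, ...) {
  cat(sprintf("<synthetic_world> fine %dx%d @ %gm; epochs: %s\n",
              x$config$n_rows, x$config$n_cols, x$config$cell_size,
              paste(names(x$epochs), collapse = ", ")))
  invisible(x)
}

#' Environmental-change scenario between epochs
#'
#' @param tmax_delta,tmin_delta Additive temperature change (deg C).
#' @param prec_delta Additive monthly precipitation change (mm).
#' @param encroachment_rate Fraction in `[0, 1]` of cropland cells converting
#'   to scrubland and of scrubland cells converting to forest (land
#'   abandonment / vegetation encroachment).
#' @param n_fires Number of disc-shaped burn patches (>= 0).
#' @param fire_patch_radius Burn-patch radius in fine cells.
#' @param niche_shift_sd Logit-scale SD of the smooth unobserved-driver
#'   perturbation entering the t1 truth (see [disturbance_field()]): the
#'   disturbance and disequilibrium dynamics that reshape occupancy at the
#'   later epoch without being visible to any predictor. Zero means species
#'   track the mapped environment perfectly between epochs.
#' @return A list of class `change_scenario`.
#' @export
change_scenario <- function(tmax_delta = 0.8, tmin_delta = 0.8,
                            prec_delta = -8, encroachment_rate = 0.15,
                            n_fires = 5, fire_patch_radius = 4,
                            niche_shift_sd = 3) {
  if (encroachment_rate < 0 || encroachment_rate > 1) {
    stop("change_scenario: encroachment_rate must lie in [0, 1]", call. = FALSE)
  }
  if (n_fires < 0) stop("change_scenario: n_fires must be >= 0", call. = FALSE)
  stopifnot(is.finite(tmax_delta), is.finite(tmin_delta), is.finite(prec_delta),
            niche_shift_sd >= 0)
  structure(as.list(environment()), class = "change_scenario")
}

#' Zero-change scenario (epoch t1 identical in expectation to t0)
#' @return A [change_scenario()] with all change terms zero.
#' @export
no_change <- function() {
  change_scenario(tmax_delta = 0, tmin_delta = 0, prec_delta = 0,
                  encroachment_rate = 0, n_fires = 0, niche_shift_sd = 0)
}

#' Unobserved-driver disturbance field for the later epoch
#'
#' A smooth zero-mean logit-scale perturbation, one independent field per
#' species, added to the species' linear predictor when its t1 truth is
#' built. It represents the component of occupancy change that no mapped
#' predictor carries — disturbance history, resource pulses after fire,
#' distributional disequilibrium — and is what makes temporal transferability
#' genuinely fall short of within-epoch accuracy. Its SD is the change
#' scenario's `niche_shift_sd`; with [no_change()] the field is identically
#' zero.
#'
#' @param world A `synthetic_world` with a change scenario applied.
#' @param species_index Integer identifying the species (its own field).
#' @param seed Integer seed.
#' @return A fine-grid [raster_grid()] of logit offsets.
#' @export
disturbance_field <- function(world, species_index = 1L, seed = 1L) {
  template <- world$epochs$t0$landcover
  sd <- if (is.null(world$change)) 0 else world$change$niche_shift_sd
  f <- with_seed(child_seed(seed, 70L + species_index), {
    anomaly_field(template$n_rows, template$n_cols,
                  world$config$smoothing_sigma, sd)
  })
  grid_like(template, f, matrix(FALSE, template$n_rows, template$n_cols))
}

rasterize_discs <- function(n_rows, n_cols, centres, radius) {
  burned <- matrix(FALSE, n_rows, n_cols)
  for (k in seq_len(nrow(centres))) {
    r0 <- centres[k, 1]; c0 <- centres[k, 2]
    rr <- max(1, r0 - radius):min(n_rows, r0 + radius)
    cc <- max(1, c0 - radius):min(n_cols, c0 + radius)
    for (i in rr) for (j in cc) {
      if ((i - r0)^2 + (j - c0)^2 <= radius^2) burned[i, j] <- TRUE
    }
  }
  burned
}

#' Derive epoch t1 by applying a change scenario
#'
#' Climate shifts additively; a fraction `encroachment_rate` of cropland
#' converts to scrubland and of scrubland to forest (encroachment acts first);
#' each fire patch then converts forest to scrubland and scrubland to "other"
#' within a disc. The vegetation-index year is regenerated from the t1 land
#' cover. Cells only move between the four classes; the cell count is
#' conserved.
#'
#' @param world A `synthetic_world` holding epoch t0.
#' @param change A [change_scenario()].
#' @param seed Integer seed for the stochastic conversions.
#' @return The world with `epochs$t1` filled in.
#' @export
apply_change <- function(world, change = change_scenario(), seed = 1L) {
  stopifnot(inherits(world, "synthetic_world"), inherits(change, "change_scenario"))
  t0 <- world$epochs$t0
  shift <- function(gs, d) lapply(gs, function(g) grid_like(g, g$values + d))
  shift_p <- function(gs, d) lapply(gs, function(g) grid_like(g, pmax(g$values + d, 0)))

  lc <- t0$landcover$values
  with_seed(child_seed(seed, 11L), {
    if (change$encroachment_rate > 0) {
      crop <- which(lc == lc_levels[["cropland"]])
      scrub <- which(lc == lc_levels[["scrubland"]])
      take <- function(idx) {
        n <- round(length(idx) * change$encroachment_rate)
        if (n > 0) sample(idx, n) else integer(0)
      }
      crop_conv <- take(crop)
      scrub_conv <- take(scrub)
      lc[crop_conv] <- lc_levels[["scrubland"]]
      lc[scrub_conv] <- lc_levels[["forest"]]
    }
    if (change$n_fires > 0) {
      burnable <- which(lc %in% lc_levels[c("forest", "scrubland")])
      if (length(burnable)) {
        centres_idx <- sample(burnable, min(change$n_fires, length(burnable)))
        centres <- cbind((centres_idx - 1L) %% nrow(lc) + 1L,
                         (centres_idx - 1L) %/% nrow(lc) + 1L)
        burned <- rasterize_discs(nrow(lc), ncol(lc), centres,
                                  change$fire_patch_radius)
        was_forest <- burned & lc == lc_levels[["forest"]]
        was_scrub <- burned & lc == lc_levels[["scrubland"]]
        lc[was_forest] <- lc_levels[["scrubland"]]
        lc[was_scrub] <- lc_levels[["other"]]
      }
    }
  })
  landcover1 <- grid_like(t0$landcover, lc)
  # the vegetation-index year follows the land cover: regenerated when any
  # cell changed class, untouched otherwise (so an all-zero scenario leaves
  # every t1 layer identical to t0)
  vi1 <- if (identical(lc, t0$landcover$values)) t0$vi_series else {
    with_seed(child_seed(seed, 12L), make_vi_series(landcover1, world$config))
  }

  world$epochs$t1 <- list(
    monthly_tmax = shift(t0$monthly_tmax, change$tmax_delta),
    monthly_tmin = shift(t0$monthly_tmin, change$tmin_delta),
    monthly_prec = shift_p(t0$monthly_prec, change$prec_delta),
    coarse_tmax = shift(t0$coarse_tmax, change$tmax_delta),
    coarse_tmin = shift(t0$coarse_tmin, change$tmin_delta),
    coarse_prec = shift_p(t0$coarse_prec, change$prec_delta),
    landcover = landcover1,
    vi_series = vi1
  )
  world$change <- change
  world
}

#' Local predictor names by family
#'
#' The nine local predictors: the three selected bioclimatic variables
#' (maximum temperature of the warmest month, annual precipitation,
#' precipitation seasonality), the three land-cover fractions, and the three
#' ecosystem functional attributes.
#' @return Named list of character vectors (`CLI`, `LULC`, `EFA`).
#' @export
predictor_families <- function() {
  list(CLI = c("bio5", "bio12", "bio15"),
       LULC = c("frac_scrubland", "frac_forest", "frac_cropland"),
       EFA = c("efa_mean", "efa_sd", "efa_peak"))
}

#' Generate virtual species with known suitability and trait labels
#'
#' Each species' true suitability is a logistic function of standardized
#' local predictors; its coefficients are tied to its traits so that the trait
#' labels are ecologically meaningful in the synthetic truth: forest-preferring
#' species load positively on forest fraction (open-habitat ones on scrubland),
#' Mediterranean species load positively on warm-month temperature
#' (Eurosiberian negatively), migrants load on vegetation-index seasonality,
#' and specialists carry larger coefficient magnitudes than generalists.
#'
#' @param n_species Number of species (>= 1).
#' @param trait_design `"balanced"` (each level of each binary trait appears
#'   equally often, up to rounding) or `"random"`.
#' @param beta_ranges Length-2 numeric: magnitude range for nonzero
#'   coefficients on the standardized scale.
#' @param families `"all"` (every species responds to all three driver
#'   families — the design used for combined-model recovery checks) or
#'   `"trait_linked"` (each species responds to a random non-empty subset).
#' @param seed Integer seed.
#' @return Tibble with columns `species_id`, the four trait columns,
#'   `uses_cli`, `uses_lulc`, `uses_efa`, `beta0`, and list-column `beta`
#'   (named numeric coefficient vectors).
#' @export
make_virtual_species <- function(n_species, trait_design = c("balanced", "random"),
                                 beta_ranges = c(0.6, 1.4),
                                 families = c("all", "trait_linked"),
                                 seed = 1L) {
  trait_design <- match.arg(trait_design)
  families <- match.arg(families)
  if (n_species < 1) stop("make_virtual_species: n_species must be >= 1", call. = FALSE)
  if (length(beta_ranges) != 2 || any(!is.finite(beta_ranges)) ||
      beta_ranges[2] < beta_ranges[1]) {
    stop("make_virtual_species: beta_ranges must be a finite length-2 range",
         call. = FALSE)
  }

  levels_of <- list(origin = c("Eurosiberian", "Mediterranean"),
                    phenology = c("sedentary", "migrant"),
                    specialization = c("generalist", "specialist"),
                    preference = c("forest", "open"))
  with_seed(child_seed(seed, 21L), {
    traits <- purrr::map(levels_of, function(lv) {
      if (trait_design == "balanced") {
        sample(rep(lv, length.out = n_species))
      } else {
        sample(lv, n_species, replace = TRUE)
      }
    })
    fam <- predictor_families()
    rows <- purrr::map(seq_len(n_species), function(i) {
      mag <- function() runif(1, beta_ranges[1], beta_ranges[2])
      scale_spec <- if (traits$specialization[i] == "specialist") 1.4 else 0.7
      beta <- c(
        bio5 = (if (traits$origin[i] == "Mediterranean") 1 else -1) * mag(),
        bio12 = sample(c(-1, 1), 1) * mag() * 0.6,
        bio15 = sample(c(-1, 1), 1) * mag() * 0.4,
        frac_forest = (if (traits$preference[i] == "forest") 1 else -1) * mag(),
        frac_scrubland = (if (traits$preference[i] == "open") 1 else 0) * mag() * 0.8,
        frac_cropland = sample(c(-1, 1), 1) * mag() * 0.3,
        efa_mean = (if (traits$preference[i] == "forest") 1 else -1) * mag() * 0.6,
        efa_sd = (if (traits$phenology[i] == "migrant") 1 else -1) * mag() * 0.8,
        efa_peak = sample(c(-1, 1), 1) * mag() * 0.3
      ) * scale_spec
      uses <- c(cli = TRUE, lulc = TRUE, efa = TRUE)
      if (families == "trait_linked") {
        uses[] <- FALSE
        uses[sample(3, sample(1:3, 1))] <- TRUE
        for (f in names(fam)) {
          if (!uses[[tolower(f)]]) beta[fam[[f]]] <- 0
        }
      }
      tibble::tibble(
        species_id = sprintf("sp%02d", i),
        origin = traits$origin[i], phenology = traits$phenology[i],
        specialization = traits$specialization[i], preference = traits$preference[i],
        uses_cli = uses[["cli"]], uses_lulc = uses[["lulc"]], uses_efa = uses[["efa"]],
        beta0 = runif(1, -0.4, 0.4),
        beta = list(beta)
      )
    })
    dplyr::bind_rows(rows)
  })
}

#' True suitability surface of a virtual species
#'
#' `S*(x) = logistic(beta0 + sum_j beta_j z_j(x))` over a standardized
#' predictor stack.
#'
#' @param species One row of the tibble from [make_virtual_species()] (or a
#'   list with `beta0` and named `beta`).
#' @param predictor_stack Named list of standardized, co-registered
#'   [raster_grid()]s containing every predictor named in `beta` with a
#'   nonzero coefficient.
#' @param logit_offset Optional co-registered [raster_grid()] added to the
#'   linear predictor (the t1 [disturbance_field()]).
#' @return A [raster_grid()] with values in `[0, 1]`.
#' @export
true_suitability <- function(species, predictor_stack, logit_offset = NULL) {
  beta <- if (is.data.frame(species)) species$beta[[1]] else species$beta
  beta0 <- if (is.data.frame(species)) species$beta0[1] else species$beta0
  beta <- beta[beta != 0]
  missing <- setdiff(names(beta), names(predictor_stack))
  if (length(missing)) {
    stop("true_suitability: predictor(s) missing from stack: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  template <- predictor_stack[[1]] %||% stop("true_suitability: empty stack")
  eta <- matrix(beta0, template$n_rows, template$n_cols)
  mask <- template$nodata_mask
  for (nm in names(beta)) {
    g <- predictor_stack[[nm]]
    eta <- eta + beta[[nm]] * g$values
    mask <- mask | g$nodata_mask
  }
  if (!is.null(logit_offset)) {
    eta <- eta + logit_offset$values
    mask <- mask | logit_offset$nodata_mask
  }
  s <- logistic(eta)
  s[mask] <- NA_real_
  grid_like(template, s, mask)
}

#' Survey design sizes
#'
#' Defaults mirror the field design the framework emulates: 344 calibration
#' point counts at t0, 204 of them revisited at t1 (internal transferability
#' test) and 384 fresh, spatially distinct points at t1 (external test).
#'
#' @param n_calibration,n_internal,n_external Point counts per protocol.
#' @param internal_subset `"random"` (default) or `"stratified"` (balanced on
#'   the calibration detections of the first species).
#' @return A list of class `survey_design`.
#' @export
survey_design <- function(n_calibration = 344, n_internal = 204,
                          n_external = 384,
                          internal_subset = c("random", "stratified")) {
  internal_subset <- match.arg(internal_subset)
  if (n_internal > n_calibration) {
    stop("survey_design: n_internal cannot exceed n_calibration", call. = FALSE)
  }
  structure(list(n_calibration = n_calibration, n_internal = n_internal,
                 n_external = n_external, internal_subset = internal_subset),
            class = "survey_design")
}

#' Sample the three survey datasets for a set of species
#'
#' Calibration locations are distinct fine-grid cell centres drawn uniformly;
#' detections are Bernoulli draws from the species' true t0 suitability.
#' Internal-transferability points revisit a subset of calibration locations
#' with detections from the t1 suitability; external points are fresh
#' locations disjoint from the calibration set, also scored at t1. Locations
#' are shared across species (one survey, many species), detections are
#' independent per species. Detection equals occurrence: no imperfect
#' detection is simulated.
#'
#' @param suit_t0,suit_t1 Named lists (by `species_id`) of true-suitability
#'   [raster_grid()]s at each epoch.
#' @param design A [survey_design()].
#' @param seed Integer seed.
#' @return Occurrence tibble with columns `species_id`, `x`, `y`, `detected`,
#'   `epoch`, `protocol`.
#' @export
sample_surveys <- function(suit_t0, suit_t1, design = survey_design(), seed = 1L) {
  stopifnot(inherits(design, "survey_design"))
  template <- suit_t0[[1]]
  cells <- cell_centres(template)
  cells <- cells[!template$nodata_mask[cbind(cells$row, cells$col)], ]
  n_avail <- nrow(cells)
  if (design$n_calibration + design$n_external > n_avail) {
    stop("sample_surveys: design counts exceed available cells (",
         n_avail, ")", call. = FALSE)
  }
  species_ids <- names(suit_t0)
  stopifnot(setequal(species_ids, names(suit_t1)))

  with_seed(child_seed(seed, 31L), {
    cal_idx <- sample(n_avail, design$n_calibration)
    ext_idx <- sample(setdiff(seq_len(n_avail), cal_idx), design$n_external)
    int_idx <- if (design$internal_subset == "random") {
      sample(cal_idx, design$n_internal)
    } else {
      # balance the revisited subset on the first species' t0 detections
      p1 <- extract_at(suit_t0[[1]], cells$x[cal_idx], cells$y[cal_idx])
      ord <- order(p1)
      sort(cal_idx[ord][round(seq(1, design$n_calibration,
                                  length.out = design$n_internal))])
    }
    draw <- function(idx, suit, epoch, protocol, sid) {
      p <- extract_at(suit, cells$x[idx], cells$y[idx])
      tibble::tibble(species_id = sid, x = cells$x[idx], y = cells$y[idx],
                     detected = rbinom(length(idx), 1L, p),
                     epoch = epoch, protocol = protocol)
    }
    purrr::map_dfr(species_ids, function(sid) {
      dplyr::bind_rows(
        draw(cal_idx, suit_t0[[sid]], "t0", "calibration", sid),
        draw(int_idx, suit_t1[[sid]], "t1", "internal_tt", sid),
        draw(ext_idx, suit_t1[[sid]], "t1", "external_tt", sid)
      )
    })
  })
}

#' Minimum-prevalence filter
#'
#' A species is retained only if its calibration survey holds strictly more
#' than `min_presences` presences (the "more than 15 presences" rule that
#' guarantees at least 5 occurrences per predictor in a trivariate model).
#'
#' @param occ Occurrence tibble from [sample_surveys()].
#' @param min_presences Strict lower bound on calibration presences.
#' @return Tibble with `species_id`, `n_presences`, `retained`.
#' @export
prevalence_filter <- function(occ, min_presences = 15) {
  occ |>
    dplyr::filter(.data$protocol == "calibration") |>
    dplyr::group_by(.data$species_id) |>
    dplyr::summarise(n_presences = sum(.data$detected), .groups = "drop") |>
    dplyr::mutate(retained = .data$n_presences > min_presences)
}
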