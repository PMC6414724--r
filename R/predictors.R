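#' Compute the 19 bioclimatic variables from monthly climate
#'
#' Standard bioclim definitions from 12 monthly layers each of maximum
#' temperature, minimum temperature and precipitation. Quarters are running
#' 3-month windows with December–January wraparound; ties (warmest quarter
#' etc.) break to the earliest starting month; the sample (n-1) standard
#' deviation is used throughout; precipitation seasonality (bio15) is
#' `100 * SD(monthly prec) / (1 + bio12/12)`, the convention that keeps the
#' coefficient of variation finite in fully arid cells.
#'
#' @param monthly_tmax,monthly_tmin,monthly_prec Lists of 12 co-registered
#'   [raster_grid()]s (deg C, deg C, mm).
#' @return Named list `bio1` ... `bio19` of [raster_grid()]s.
#' @export
compute_bioclim <- function(monthly_tmax, monthly_tmin, monthly_prec) {
  for (nm in c("monthly_tmax", "monthly_tmin", "monthly_prec")) {
    x <- get(nm)
    if (length(x) != 12L) {
      stop("compute_bioclim: ", nm, " must hold exactly 12 monthly layers",
           call. = FALSE)
    }
  }
  template <- monthly_tmax[[1]]
  all_layers <- c(monthly_tmax, monthly_tmin, monthly_prec)
  if (!all(vapply(all_layers, same_geometry, logical(1), b = template))) {
    stop("compute_bioclim: monthly layers are not co-registered", call. = FALSE)
  }

  as_cube <- function(gs) {
    a <- array(NA_real_, c(template$n_rows, template$n_cols, 12L))
    for (m in 1:12) a[, , m] <- gs[[m]]$values
    a
  }
  tmx <- as_cube(monthly_tmax)
  tmn <- as_cube(monthly_tmin)
  prc <- as_cube(monthly_prec)
  tav <- (tmx + tmn) / 2

  mask <- Reduce(`|`, lapply(all_layers, function(g) g$nodata_mask))

  # quarter = 3-month running window starting at month q, wrapping at year end
  qmonths <- lapply(1:12, function(q) ((q - 1):(q + 1)) %% 12 + 1)
  qsum <- function(cube) {
    out <- array(NA_real_, dim(cube))
    for (q in 1:12) {
      out[, , q] <- cube[, , qmonths[[q]][1]] + cube[, , qmonths[[q]][2]] +
        cube[, , qmonths[[q]][3]]
    }
    out
  }
  prc_q <- qsum(prc)        # quarter precipitation totals
  tav_q <- qsum(tav) / 3    # quarter mean temperatures

  # per-cell earliest arg-max/min over the 3rd dimension
  pick <- function(cube, which_fn) {
    apply(cube, c(1, 2), which_fn)
  }
  sel <- function(cube, idx) {
    out <- matrix(NA_real_, nrow(idx), ncol(idx))
    for (q in 1:12) {
      hit <- idx == q
      if (any(hit)) out[hit] <- cube[, , q][hit]
    }
    out
  }
  row_sd <- function(cube) apply(cube, c(1, 2), stats::sd)

  warm_q <- pick(tav_q, which.max)
  cold_q <- pick(tav_q, which.min)
  wet_q <- pick(prc_q, which.max)
  dry_q <- pick(prc_q, which.min)

  bio <- list()
  bio$bio1 <- apply(tav, c(1, 2), mean)
  bio$bio2 <- apply(tmx - tmn, c(1, 2), mean)
  bio$bio4 <- row_sd(tav) * 100
  bio$bio5 <- apply(tmx, c(1, 2), max)
  bio$bio6 <- apply(tmn, c(1, 2), min)
  bio$bio7 <- bio$bio5 - bio$bio6
  bio$bio3 <- ifelse(bio$bio7 > 0, bio$bio2 / bio$bio7 * 100, 0)
  bio$bio8 <- sel(tav_q, wet_q)
  bio$bio9 <- sel(tav_q, dry_q)
  bio$bio10 <- sel(tav_q, warm_q)
  bio$bio11 <- sel(tav_q, cold_q)
  bio$bio12 <- apply(prc, c(1, 2), sum)
  bio$bio13 <- apply(prc, c(1, 2), max)
  bio$bio14 <- apply(prc, c(1, 2), min)
  bio$bio15 <- 100 * row_sd(prc) / (1 + bio$bio12 / 12)
  bio$bio16 <- sel(prc_q, wet_q)
  bio$bio17 <- sel(prc_q, dry_q)
  bio$bio18 <- sel(prc_q, warm_q)
  bio$bio19 <- sel(prc_q, cold_q)

  bio <- bio[paste0("bio", 1:19)]
  lapply(bio, function(v) grid_like(template, v, mask))
}

#' Compute ecosystem functional attributes from a vegetation-index year
#'
#' Three per-cell summaries of the 23-composite annual curve: the annual mean
#' (productivity), the sample standard deviation across composites
#' (seasonality), and the 1-based index of the maximum composite (phenology;
#' earliest composite on ties).
#'
#' @param vi_series List of exactly 23 co-registered [raster_grid()]s with
#'   values in `[-1, 1]`.
#' @return Named list with `efa_mean`, `efa_sd`, `efa_peak` [raster_grid()]s.
#' @export
compute_efas <- function(vi_series) {
  if (length(vi_series) != 23L) {
    stop("compute_efas: vi_series must hold exactly 23 composites", call. = FALSE)
  }
  template <- vi_series[[1]]
  if (!all(vapply(vi_series, same_geometry, logical(1), b = template))) {
    stop("compute_efas: composites are not co-registered", call. = FALSE)
  }
  cube <- array(NA_real_, c(template$n_rows, template$n_cols, 23L))
  for (d in 1:23) cube[, , d] <- vi_series[[d]]$values
  mask <- Reduce(`|`, lapply(vi_series, function(g) g$nodata_mask))
  list(
    efa_mean = grid_like(template, apply(cube, c(1, 2), mean), mask),
    efa_sd = grid_like(template, apply(cube, c(1, 2), stats::sd), mask),
    efa_peak = grid_like(template, apply(cube, c(1, 2), which.max), mask)
  )
}

#' Aggregate categorical land cover to fractional cover
#'
#' Block aggregation of a fine categorical land-cover grid to the coarser
#' analysis resolution: each coarse cell's value for a class is the fraction
#' of its fine cells in that class. Partial edge blocks use only the covered
#' fine cells. The target cell size must be an integer multiple of the fine
#' cell size.
#'
#' @param landcover Categorical fine [raster_grid()] coded per [lc_levels].
#' @param target_cell_size Coarse cell size (metres).
#' @return Named list `frac_scrubland`, `frac_forest`, `frac_cropland` of
#'   [raster_grid()]s in `[0, 1]` (the remainder is "other").
#' @export
aggregate_lulc_fractions <- function(landcover, target_cell_size) {
  ratio <- target_cell_size / landcover$cell_size
  if (abs(ratio - round(ratio)) > 1e-9) {
    stop("aggregate_lulc_fractions: target cell size must be an integer ",
         "multiple of the fine cell size", call. = FALSE)
  }
  factor <- as.integer(round(ratio))
  frac_of <- function(code) {
    block_aggregate(landcover, factor,
                    function(v) mean(v[!is.na(v)] == code))
  }
  list(frac_scrubland = frac_of(lc_levels[["scrubland"]]),
       frac_forest = frac_of(lc_levels[["forest"]]),
       frac_cropland = frac_of(lc_levels[["cropland"]]))
}

#' Derive the nine local predictors for one epoch
#'
#' The three selected bioclimatic variables (bio5, bio12, bio15), the three
#' land-cover fractions (aggregated to `lulc_factor` fine cells per block,
#' then resampled back to the fine grid by nearest neighbour so all layers are
#' co-registered), and the three ecosystem functional attributes.
#'
#' @param world A `synthetic_world`.
#' @param epoch `"t0"` or `"t1"`.
#' @param lulc_factor Block size (fine cells) of the fractional-cover
#'   aggregation before co-registration.
#' @return Named list of nine co-registered fine-resolution [raster_grid()]s.
#' @export
derive_local_predictors <- function(world, epoch = c("t0", "t1"),
                                    lulc_factor = 2) {
  epoch <- match.arg(epoch)
  ep <- world$epochs[[epoch]]
  if (is.null(ep)) stop("derive_local_predictors: epoch ", epoch,
                        " not present; run apply_change() first", call. = FALSE)
  bio <- compute_bioclim(ep$monthly_tmax, ep$monthly_tmin, ep$monthly_prec)
  efa <- compute_efas(ep$vi_series)
  frac <- aggregate_lulc_fractions(ep$landcover,
                                   ep$landcover$cell_size * lulc_factor)
  # co-register the coarse fractions back onto the fine grid
  fine_cell <- ep$landcover$cell_size
  frac_fine <- lapply(frac, function(g) {
    r <- resample_grid(g, fine_cell, method = "nearest")
    # clip to the fine grid's dimensions (ceiling blocks can overhang)
    raster_grid(r$values[seq_len(ep$landcover$n_rows),
                         seq_len(ep$landcover$n_cols), drop = FALSE],
                fine_cell, ep$landcover$origin_xy)
  })
  c(list(bio5 = bio$bio5, bio12 = bio$bio12, bio15 = bio$bio15),
    frac_fine, efa)
}

#' Derive the regional (coarse) climate predictors for one epoch
#'
#' @param world A `synthetic_world`.
#' @param epoch `"t0"` or `"t1"`.
#' @return Named list with coarse-resolution `bio5`, `bio12`, `bio15`.
#' @export
derive_regional_bioclim <- function(world, epoch = c("t0", "t1")) {
  epoch <- match.arg(epoch)
  ep <- world$epochs[[epoch]]
  if (is.null(ep)) stop("derive_regional_bioclim: epoch ", epoch,
                        " not present", call. = FALSE)
  bio <- compute_bioclim(ep$coarse_tmax, ep$coarse_tmin, ep$coarse_prec)
  bio[c("bio5", "bio12", "bio15")]
}
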