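# shared small fixtures, built in code

grid_of <- function(mat, cell_size = 1, origin = c(0, nrow(as.matrix(mat)) * cell_size)) {
  raster_grid(as.matrix(mat), cell_size, origin)
}

const_grid <- function(value, n = 4, cell_size = 1) {
  grid_of(matrix(value, n, n), cell_size)
}

# 12 constant monthly layers at the given per-month values
monthly_grids <- function(values_by_month, n = 3) {
  lapply(values_by_month, function(v) const_grid(v, n))
}

# a small standardized 2-predictor stack with known values
toy_stack <- function(n = 5) {
  z1 <- matrix(seq(-2, 2, length.out = n * n), n, n)
  z2 <- matrix(rep(seq(-1.5, 1.5, length.out = n), n), n, n)
  list(z1 = grid_of(z1), z2 = grid_of(z2))
}

# memoised tiny world shared across test files
tiny_world_env <- new.env(parent = emptyenv())
tiny_world <- function() {
  if (is.null(tiny_world_env$w)) {
    w <- make_world(world_config(n_rows = 30, n_cols = 30), seed = 11)
    tiny_world_env$w <- apply_change(w, change_scenario(), seed = 11)
  }
  tiny_world_env$w
}

tiny_experiment_config <- function(...) {
  experiment_config(
    world = world_config(n_rows = 30, n_cols = 30),
    n_species = 3,
    design = survey_design(n_calibration = 120, n_internal = 60,
                           n_external = 120),
    algorithms = "glm",
    n_replicates = 4,
    n_regional = 150,
    ...
  )
}

tiny_experiment_env <- new.env(parent = emptyenv())
tiny_experiment <- function() {
  if (is.null(tiny_experiment_env$ex)) {
    tiny_experiment_env$ex <- suppressWarnings(
      run_experiment(tiny_experiment_config(), seed = 5, verbose = FALSE))
  }
  tiny_experiment_env$ex
}
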