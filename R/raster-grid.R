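#' Georeferenced raster layer
#'
#' The atom every mapped quantity in the package lives in: a 2D numeric matrix
#' with planar georeference (cell size in metres, origin at the outer corner of
#' the top-left cell) and a nodata mask. Row 1 is the northern (top) row; a
#' point (x, y) falls in the cell whose half-open interval
#' `[left, right) x (bottom, top]` contains it.
#'
#' @param values Numeric matrix (rows = north to south).
#' @param cell_size Cell edge length in metres (> 0).
#' @param origin_xy Numeric length-2: x of the left edge, y of the top edge.
#' @param nodata_mask Logical matrix, `TRUE` where the cell carries no data.
#'
#' @return An object of class `raster_grid`.
#' @export
raster_grid <- function(values, cell_size = 1, origin_xy = c(0, 0),
                        nodata_mask = NULL) {
  values <- as.matrix(values)
  if (nrow(values) < 1L || ncol(values) < 1L) {
    stop("raster_grid: grid must have at least one row and one column",
         call. = FALSE)
  }
  if (!is.numeric(cell_size) || length(cell_size) != 1L || cell_size <= 0) {
    stop("raster_grid: cell_size must be a single positive number",
         call. = FALSE)
  }
  if (is.null(nodata_mask)) {
    nodata_mask <- matrix(FALSE, nrow(values), ncol(values))
  }
  nodata_mask <- nodata_mask | !is.finite(values)
  stopifnot(identical(dim(nodata_mask), dim(values)))
  structure(
    list(values = values,
         n_rows = nrow(values), n_cols = ncol(values),
         cell_size = as.numeric(cell_size),
         origin_xy = as.numeric(origin_xy),
         nodata_mask = nodata_mask),
    class = "raster_grid"
  )
}

#' @export
print.raster_grid <- function(x, ...) {
  v <- x$values[!x$nodata_mask]
  cat(sprintf("<raster_grid> %d x %d cells of %g m, origin (%g, %g)\n",
              x$n_rows, x$n_cols, x$cell_size, x$origin_xy[1], x$origin_xy[2]))
  if (length(v)) {
    cat(sprintf("  values: [%.4g, %.4g], %d nodata cells\n",
                min(v), max(v), sum(x$nodata_mask)))
  } else {
    cat("  all cells nodata\n")
  }
  invisible(x)
}

#' @export
dim.raster_grid <- function(x) c(x$n_rows, x$n_cols)

is_raster_grid <- function(x) inherits(x, "raster_grid")

#' Extent of a raster grid
#'
#' @param grid A [raster_grid()].
#' @return Named numeric `c(xmin, xmax, ymin, ymax)`.
#' @export
grid_extent <- function(grid) {
  c(xmin = grid$origin_xy[1],
    xmax = grid$origin_xy[1] + grid$n_cols * grid$cell_size,
    ymin = grid$origin_xy[2] - grid$n_rows * grid$cell_size,
    ymax = grid$origin_xy[2])
}

same_geometry <- function(a, b) {
  a$n_rows == b$n_rows && a$n_cols == b$n_cols &&
    isTRUE(all.equal(a$cell_size, b$cell_size)) &&
    isTRUE(all.equal(a$origin_xy, b$origin_xy))
}

# derive a sibling grid sharing geometry
grid_like <- function(template, values, nodata_mask = NULL) {
  raster_grid(values, template$cell_size, template$origin_xy,
              nodata_mask %||% template$nodata_mask)
}

#' Cell centre coordinates
#'
#' @param grid A [raster_grid()].
#' @return Tibble with `row`, `col`, `x`, `y` for every cell (row-major).
#' @export
cell_centres <- function(grid) {
  rows <- rep(seq_len(grid$n_rows), times = grid$n_cols)
  cols <- rep(seq_len(grid$n_cols), each = grid$n_rows)
  tibble::tibble(
    row = rows, col = cols,
    x = grid$origin_xy[1] + (cols - 0.5) * grid$cell_size,
    y = grid$origin_xy[2] - (rows - 0.5) * grid$cell_size
  )
}

#' Map point coordinates to cell indices
#'
#' Half-open convention: a point on a cell's left/top edge belongs to that
#' cell; points outside the extent get `NA` indices.
#'
#' @param grid A [raster_grid()].
#' @param x,y Point coordinates (metres).
#' @return Tibble with `row`, `col` (1-based).
#' @export
locate_cells <- function(grid, x, y) {
  col <- floor((x - grid$origin_xy[1]) / grid$cell_size) + 1
  row <- floor((grid$origin_xy[2] - y) / grid$cell_size) + 1
  bad <- col < 1 | col > grid$n_cols | row < 1 | row > grid$n_rows
  col[bad] <- NA_integer_
  row[bad] <- NA_integer_
  tibble::tibble(row = as.integer(row), col = as.integer(col))
}

#' Extract raster values at point locations
#'
#' @param grid A [raster_grid()].
#' @param x,y Point coordinates.
#' @return Numeric vector; `NA` outside the extent or on nodata cells.
#' @export
extract_at <- function(grid, x, y) {
  idx <- locate_cells(grid, x, y)
  out <- rep(NA_real_, length(x))
  ok <- !is.na(idx$row)
  lin <- cbind(idx$row[ok], idx$col[ok])
  v <- grid$values[lin]
  v[grid$nodata_mask[lin]] <- NA_real_
  out[ok] <- v
  out
}

#' Resample a raster grid to a new cell size
#'
#' Continuous layers are usually resampled bilinearly, categorical layers by
#' nearest neighbour; `block_mean` averages complete blocks and requires the
#' target cell size to be an integer multiple of the source's. Nodata
#' propagates: any nodata contributor makes the output cell nodata for
#' `bilinear` and `block_mean`.
#'
#' @param grid A [raster_grid()].
#' @param target_cell_size New cell size (metres).
#' @param method `"nearest"`, `"bilinear"` or `"block_mean"`.
#' @return A [raster_grid()] covering the same extent.
#' @export
resample_grid <- function(grid, target_cell_size,
                          method = c("bilinear", "nearest", "block_mean")) {
  if (length(method) == 1L && !method %in% c("bilinear", "nearest", "block_mean")) {
    stop("resample_grid: unknown method '", method, "'", call. = FALSE)
  }
  method <- match.arg(method)
  if (target_cell_size <= 0) stop("resample_grid: target_cell_size must be > 0",
                                  call. = FALSE)

  if (method == "block_mean") {
    ratio <- target_cell_size / grid$cell_size
    if (abs(ratio - round(ratio)) > 1e-9) {
      stop("resample_grid: block_mean needs an integer cell-size ratio",
           call. = FALSE)
    }
    return(block_aggregate(grid, as.integer(round(ratio)), mean_block))
  }

  n_rows <- max(1L, as.integer(ceiling(grid$n_rows * grid$cell_size / target_cell_size)))
  n_cols <- max(1L, as.integer(ceiling(grid$n_cols * grid$cell_size / target_cell_size)))
  cx <- grid$origin_xy[1] + (seq_len(n_cols) - 0.5) * target_cell_size
  cy <- grid$origin_xy[2] - (seq_len(n_rows) - 0.5) * target_cell_size

  if (method == "nearest") {
    col <- pmin(pmax(floor((cx - grid$origin_xy[1]) / grid$cell_size) + 1, 1), grid$n_cols)
    row <- pmin(pmax(floor((grid$origin_xy[2] - cy) / grid$cell_size) + 1, 1), grid$n_rows)
    vals <- grid$values[row, col, drop = FALSE]
    mask <- grid$nodata_mask[row, col, drop = FALSE]
    return(raster_grid(vals, target_cell_size, grid$origin_xy, mask))
  }

  # bilinear between the four surrounding cell centres, clamped at edges
  fx <- (cx - (grid$origin_xy[1] + 0.5 * grid$cell_size)) / grid$cell_size
  fy <- ((grid$origin_xy[2] - 0.5 * grid$cell_size) - cy) / grid$cell_size
  c0 <- pmin(pmax(floor(fx), 0), grid$n_cols - 1L)
  r0 <- pmin(pmax(floor(fy), 0), grid$n_rows - 1L)
  c1 <- pmin(c0 + 1, grid$n_cols - 1L)
  r1 <- pmin(r0 + 1, grid$n_rows - 1L)
  wx <- pmin(pmax(fx - c0, 0), 1)
  wy <- pmin(pmax(fy - r0, 0), 1)

  vals <- matrix(NA_real_, n_rows, n_cols)
  mask <- matrix(FALSE, n_rows, n_cols)
  V <- grid$values
  M <- grid$nodata_mask
  for (i in seq_len(n_rows)) {
    ra <- r0[i] + 1L; rb <- r1[i] + 1L; w_y <- wy[i]
    va <- V[ra, c0 + 1L] * (1 - wx) + V[ra, c1 + 1L] * wx
    vb <- V[rb, c0 + 1L] * (1 - wx) + V[rb, c1 + 1L] * wx
    vals[i, ] <- va * (1 - w_y) + vb * w_y
    mask[i, ] <- M[ra, c0 + 1L] | M[ra, c1 + 1L] | M[rb, c0 + 1L] | M[rb, c1 + 1L]
  }
  vals[mask] <- NA_real_
  raster_grid(vals, target_cell_size, grid$origin_xy, mask)
}

mean_block <- function(v) if (all(is.na(v))) NA_real_ else mean(v)

# block aggregation with partial edge blocks using only covered cells;
# f receives the block's values with nodata cells as NA
block_aggregate <- function(grid, factor, f) {
  n_rows <- as.integer(ceiling(grid$n_rows / factor))
  n_cols <- as.integer(ceiling(grid$n_cols / factor))
  V <- grid$values
  V[grid$nodata_mask] <- NA_real_
  out <- matrix(NA_real_, n_rows, n_cols)
  msk <- matrix(FALSE, n_rows, n_cols)
  for (i in seq_len(n_rows)) {
    ri <- (((i - 1L) * factor + 1L):min(i * factor, grid$n_rows))
    for (j in seq_len(n_cols)) {
      cj <- (((j - 1L) * factor + 1L):min(j * factor, grid$n_cols))
      block <- V[ri, cj]
      out[i, j] <- f(block)
      msk[i, j] <- anyNA(block)
    }
  }
  raster_grid(out, grid$cell_size * factor, grid$origin_xy, msk)
}

#' Standardize a predictor stack
#'
#' Centres and scales each layer to zero mean and unit standard deviation over
#' its unmasked cells. When `reference_stats` is supplied (projection of a
#' later epoch with calibration-epoch statistics), those statistics are reused
#' and never recomputed, so both epochs live on the same scale.
#'
#' @param layers Named list of co-registered [raster_grid()]s.
#' @param reference_stats Optional tibble from a previous call (`layer`,
#'   `mean`, `sd`).
#' @return List with `layers` (standardized grids) and `stats` (tibble).
#' @export
standardize_stack <- function(layers, reference_stats = NULL) {
  stopifnot(is.list(layers), !is.null(names(layers)))
  if (is.null(reference_stats)) {
    reference_stats <- purrr::imap_dfr(layers, function(g, nm) {
      v <- g$values[!g$nodata_mask]
      s <- stats::sd(v)
      if (!is.finite(s) || s < 1e-12) {
        stop("standardize_stack: layer '", nm, "' has (near-)zero variance",
             call. = FALSE)
      }
      tibble::tibble(layer = nm, mean = mean(v), sd = s)
    })
  } else {
    missing <- setdiff(names(layers), reference_stats$layer)
    if (length(missing)) {
      stop("standardize_stack: no reference statistics for layer(s): ",
           paste(missing, collapse = ", "), call. = FALSE)
    }
  }
  std <- purrr::imap(layers, function(g, nm) {
    st <- reference_stats[reference_stats$layer == nm, ]
    grid_like(g, (g$values - st$mean) / st$sd, g$nodata_mask)
  })
  list(layers = std, stats = reference_stats)
}

#' Write a raster grid as an ESRI ASCII grid
#'
#' Plain-text single-band raster (`.asc`) with `nodata_value -9999`, readable
#' by any GIS. [write_layer_manifest()] records the layer catalogue alongside.
#'
#' @param grid A [raster_grid()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_raster_asc <- function(grid, path) {
  hdr <- c(
    sprintf("ncols %d", grid$n_cols),
    sprintf("nrows %d", grid$n_rows),
    sprintf("xllcorner %.10g", grid$origin_xy[1]),
    sprintf("yllcorner %.10g", grid$origin_xy[2] - grid$n_rows * grid$cell_size),
    sprintf("cellsize %.10g", grid$cell_size),
    "nodata_value -9999"
  )
  V <- grid$values
  V[grid$nodata_mask] <- -9999
  body <- apply(V, 1L, function(r) paste(format(r, digits = 10, trim = TRUE),
                                         collapse = " "))
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Read an ESRI ASCII grid raster
#'
#' @param path File written by [write_raster_asc()].
#' @return A [raster_grid()].
#' @export
read_raster_asc <- function(path) {
  lines <- readLines(path)
  hdr <- lines[1:6]
  val <- function(key) {
    ln <- hdr[startsWith(tolower(hdr), key)]
    as.numeric(strsplit(trimws(ln), "\\s+")[[1]][2])
  }
  n_cols <- val("ncols"); n_rows <- val("nrows")
  cell <- val("cellsize")
  x0 <- val("xllcorner"); y0 <- val("yllcorner") + n_rows * cell
  nodata <- val("nodata")
  V <- do.call(rbind, lapply(lines[-(1:6)], function(ln) {
    as.numeric(strsplit(trimws(ln), "\\s+")[[1]])
  }))
  mask <- V == nodata
  V[mask] <- NA_real_
  raster_grid(V, cell, c(x0, y0), mask)
}

#' Write a JSON manifest cataloguing raster layers
#'
#' @param entries Tibble/data frame with at least `name`, `family`, `epoch`,
#'   `resolution`, `file`.
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_layer_manifest <- function(entries, path) {
  jsonlite::write_json(entries, path, dataframe = "rows", auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(path)
}
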