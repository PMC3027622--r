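#' Raster grid specification
#'
#' A regular grid with lower-left corner (`xmin`, `ymin`), square cells of
#' side `cellsize` (m), `ncol` columns and `nrow` rows. Cell centres are at
#' `xmin + (col - 0.5) * cellsize`, `ymin + (row - 0.5) * cellsize`, with row
#' 1 at the bottom (values matrices in this package are stored bottom-up;
#' ESRI ASCII export reorders to the top-down file convention).
#'
#' @param xmin,ymin lower-left corner (m).
#' @param cellsize cell side (m), > 0.
#' @param ncol,nrow grid dimensions (>= 1).
#' @return An object of class `brb_grid`.
#' @export
grid_spec <- function(xmin, ymin, cellsize, ncol, nrow) {
  stopifnot(cellsize > 0, ncol >= 1L, nrow >= 1L)
  structure(list(xmin = xmin, ymin = ymin, cellsize = cellsize,
                 ncol = as.integer(ncol), nrow = as.integer(nrow)),
            class = "brb_grid")
}

#' @export
print.brb_grid <- function(x, ...) {
  cat(sprintf("brb_grid: %d cols x %d rows, cell %g m, lower-left (%g, %g)\n",
              x$ncol, x$nrow, x$cellsize, x$xmin, x$ymin))
  invisible(x)
}

grid_x <- function(grid) grid$xmin + (seq_len(grid$ncol) - 0.5) * grid$cellsize
grid_y <- function(grid) grid$ymin + (seq_len(grid$nrow) - 0.5) * grid$cellsize

same_grid <- function(a, b, tol = 1e-9) {
  abs(a$xmin - b$xmin) < tol && abs(a$ymin - b$ymin) < tol &&
    abs(a$cellsize - b$cellsize) < tol && a$ncol == b$ncol && a$nrow == b$nrow
}

#' Grid covering a set of locations with a margin
#'
#' Builds a [grid_spec()] whose extent covers the bounding box of the given
#' coordinates extended by `margin` on every side (default `4 * h_max`, so
#' that truncated Gaussian kernels lose negligible mass at the border). The
#' origin is snapped down to a multiple of the cell size for reproducible
#' alignment.
#'
#' @param x,y location coordinates (m).
#' @param cellsize cell side (m).
#' @param margin margin beyond the bounding box (m).
#' @return A `brb_grid`.
#' @export
auto_grid <- function(x, y, cellsize, margin) {
  stopifnot(length(x) > 0, length(x) == length(y), cellsize > 0, margin >= 0)
  xmin <- floor((min(x) - margin) / cellsize) * cellsize
  ymin <- floor((min(y) - margin) / cellsize) * cellsize
  ncol <- ceiling((max(x) + margin - xmin) / cellsize)
  nrow <- ceiling((max(y) + margin - ymin) / cellsize)
  grid_spec(xmin, ymin, cellsize, max(ncol, 1L), max(nrow, 1L))
}
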