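round_half_up <- function(x) floor(x + 0.5)  # round-half-away-from-zero, x >= 0

#' Interpolate kernel locations along included segments
#'
#' Implements the location-interpolation step of the MKDE method. Each
#' included segment of activity time `T_i` is divided into
#' `n_i = round(T_i / tau)` equal intervals (at least 1), placing
#' interpolated locations at `z0 + (z1 - z0) * m / n_i`; the location at
#' index `m` stands for the expected position at activity time
#' `t = m * T_i / n_i` and receives the bandwidth of [smoothing_parameter()].
#' Segments marked `null_D` (active but immobile, or resting segments of a
#' global UD) get the fixed bandwidth `h_min` along their whole length.
#'
#' Every recorded relocation contributes exactly once with `h = h_min`,
#' whatever the status of its adjoining segments. This de-duplicates the
#' junctions of contiguous included segments (the flat re-indexing of the
#' kernel sum would otherwise double-count shared endpoints, breaking the
#' time weighting), and it makes the method degenerate gracefully: when every
#' segment is excluded, the plan reduces to the recorded fixes with constant
#' bandwidth `h_min`, i.e. a classical fixed-bandwidth LKDE.
#'
#' The interpolation constant must satisfy `h_min > 0.5 * tau * L_i / T_i`
#' for every included moving segment (interpolated points less than two
#' bandwidths apart), otherwise an error asks for a smaller `tau`. When
#' `tau = NULL` the largest admissible value is used, capped so that no
#' segment gets more than `max_n` intervals.
#'
#' @param segments a filtered `brb_segments` data frame (no included segment
#'   may have `T_R > params$T_max`).
#' @param params a [brb_params()] object.
#' @param tau interpolation time constant (min), or `NULL` for the default.
#' @param max_n cap on intervals per segment when deriving the default `tau`.
#' @return An object of class `brb_plan`: a data.frame with columns `x, y, h,
#'   recorded` and attributes `tau`, `N_L`, `params`.
#' @export
plan_interpolation <- function(segments, params, tau = NULL, max_n = 1000L) {
  stopifnot(inherits(segments, "brb_segments"), inherits(params, "brb_params"))
  inc <- segments[segments$included, , drop = FALSE]
  if (any(inc$T_R > params$T_max)) {
    stop("segments with T_R > T_max must be excluded before interpolation; ",
         "run filter_segments() first")
  }
  moving <- inc[inc$T > 0 & inc$L > 0, , drop = FALSE]
  if (is.null(tau)) {
    if (nrow(moving)) {
      tau <- 0.99 * min(2 * params$h_min * moving$T / moving$L)
      tau <- max(tau, max(inc$T) / max_n)
    } else {
      tau <- max(inc$T, 1)
    }
  }
  if (tau <= 0) stop("`tau` must be > 0")
  if (nrow(moving)) {
    bad <- params$h_min <= 0.5 * tau * moving$L / moving$T
    if (any(bad)) {
      stop(sprintf(paste0(
        "interpolated locations too far apart for %d segment(s): ",
        "h_min = %g must exceed 0.5 * tau * L/T = %g; ",
        "use a smaller tau (< %g) or a larger sigma_min"),
        sum(bad), params$h_min, max(0.5 * tau * moving$L / moving$T),
        min(2 * params$h_min * moving$T / moving$L)))
    }
  }
  # recorded fixes: every segment start, plus the final end fix per animal
  last <- !duplicated(segments$id, fromLast = TRUE)
  rec_x <- c(segments$x0, segments$x1[last])
  rec_y <- c(segments$y0, segments$y1[last])
  ord <- order(c(segments$t0, segments$t1[last]))
  rec <- data.frame(x = rec_x[ord], y = rec_y[ord], h = params$h_min,
                    recorded = TRUE)
  interp <- NULL
  if (nrow(inc)) {
    n_i <- pmax(round_half_up(inc$T / tau), 1)
    pieces <- lapply(which(n_i > 1), function(j) {
      n <- n_i[j]
      m <- seq_len(n - 1L)
      h <- if (inc$null_D[j]) rep(params$h_min, n - 1L)
           else smoothing_parameter(m, n, inc$T[j], params)
      data.frame(x = inc$x0[j] + (inc$x1[j] - inc$x0[j]) * m / n,
                 y = inc$y0[j] + (inc$y1[j] - inc$y0[j]) * m / n,
                 h = h, recorded = FALSE)
    })
    interp <- do.call(rbind, pieces)
  }
  plan <- rbind(rec, interp)
  rownames(plan) <- NULL
  structure(plan, tau = tau, N_L = nrow(plan), params = params,
            class = c("brb_plan", "data.frame"))
}

#' Compute the UD raster from an interpolation plan
#'
#' The movement-based kernel density estimate: each of the `N_L` planned
#' locations contributes a circular bivariate Gaussian kernel of standard
#' deviation `h_k`, with equal weight `1 / N_L` (time weighting is carried by
#' the constant interpolation interval, which places more locations where the
#' animal spent more time per unit length). Kernels are truncated at radius
#' `trunc * h` (default 4, < 1e-4 relative mass loss), and the raster is
#' renormalized so its cell masses sum to exactly 1.
#'
#' @param plan a [plan_interpolation()] result.
#' @param grid a [grid_spec()], or `NULL` to build one automatically with
#'   cell size `cellsize` and margin `4 * h_max`.
#' @param cellsize cell size (m) for the automatic grid; default
#'   `sigma_min / 2`.
#' @param trunc truncation radius in bandwidth units.
#' @return An object of class `brb_ud`: list with `grid`, `values` (matrix
#'   `nrow x ncol`, bottom-up rows, 1/m^2), `N_L` and `normalized = TRUE`.
#' @export
compute_ud <- function(plan, grid = NULL, cellsize = NULL, trunc = 4) {
  stopifnot(inherits(plan, "brb_plan"))
  if (nrow(plan) == 0L) stop("empty interpolation plan")
  params <- attr(plan, "params")
  if (is.null(grid)) {
    if (is.null(cellsize)) cellsize <- params$sigma_min / 2
    grid <- auto_grid(plan$x, plan$y, cellsize, margin = trunc * params$h_max)
  }
  stopifnot(inherits(grid, "brb_grid"))
  gx <- grid_x(grid)
  gy <- grid_y(grid)
  vals <- matrix(0, nrow = grid$nrow, ncol = grid$ncol)
  r <- grid$cellsize
  for (k in seq_len(nrow(plan))) {
    h <- plan$h[k]
    xk <- plan$x[k]; yk <- plan$y[k]
    ci <- which(gx >= xk - trunc * h & gx <= xk + trunc * h)
    ri <- which(gy >= yk - trunc * h & gy <= yk + trunc * h)
    if (!length(ci) || !length(ri)) next
    dx2 <- (gx[ci] - xk)^2
    dy2 <- (gy[ri] - yk)^2
    kern <- outer(dy2, dx2, "+")
    inside <- kern <= (trunc * h)^2
    kern <- exp(-kern / (2 * h^2)) / (2 * pi * h^2)
    kern[!inside] <- 0
    vals[ri, ci] <- vals[ri, ci] + kern
  }
  vals <- vals / nrow(plan)
  raw_mass <- sum(vals) * r^2
  if (raw_mass <= 0) stop("UD has zero mass on the given grid")
  vals <- vals / raw_mass
  structure(list(grid = grid, values = vals, N_L = nrow(plan),
                 raw_mass = raw_mass, normalized = TRUE),
            class = "brb_ud")
}

#' @export
print.brb_ud <- function(x, ...) {
  cat(sprintf("brb_ud: %d x %d cells (%g m), %d kernel locations, mass %.6f\n",
              x$grid$ncol, x$grid$nrow, x$grid$cellsize, x$N_L,
              sum(x$values) * x$grid$cellsize^2))
  invisible(x)
}

#' Cumulative-frequency isopleths of a UD
#'
#' Cells are ranked by density (descending; ties broken by cell index in
#' column-major order, deterministically) and a cell belongs to the `p`%
#' isopleth region when the cumulative mass up to and including it does not
#' exceed `p/100`. Areas are cell counts times the cell area; regions are
#' nested by construction.
#'
#' @param ud a normalized [compute_ud()] raster.
#' @param levels cumulative-frequency percentages in (0, 100].
#' @return An object of class `brb_isopleths`: list with `levels`, `areas`
#'   (m^2, named by level) and `masks` (list of logical matrices on the UD
#'   grid).
#' @export
isopleths <- function(ud, levels = c(50, 95)) {
  stopifnot(inherits(ud, "brb_ud"))
  if (any(levels <= 0 | levels > 100)) stop("isopleth levels must lie in (0, 100]")
  v <- as.vector(ud$values)
  ord <- order(-v, seq_along(v))
  cum <- cumsum(v[ord]) * ud$grid$cellsize^2
  masks <- list()
  areas <- numeric(length(levels))
  for (i in seq_along(levels)) {
    keep_ord <- ord[cum <= levels[i] / 100 + 1e-12]
    mask <- matrix(FALSE, nrow = ud$grid$nrow, ncol = ud$grid$ncol)
    mask[keep_ord] <- TRUE
    masks[[as.character(levels[i])]] <- mask
    areas[i] <- length(keep_ord) * ud$grid$cellsize^2
  }
  names(areas) <- as.character(levels)
  structure(list(levels = levels, areas = areas, masks = masks,
                 grid = ud$grid),
            class = "brb_isopleths")
}

#' @export
print.brb_isopleths <- function(x, ...) {
  cat("UD isopleths (cell-counted areas):\n")
  for (i in seq_along(x$levels)) {
    cat(sprintf("  %5.1f%% : %.4g m^2 (%.4g km^2)\n", x$levels[i],
                x$areas[i], x$areas[i] / 1e6))
  }
  invisible(x)
}

#' Export a UD raster
#'
#' `"esri_ascii"` writes an ESRI ASCII grid (ncols/nrows/xllcorner/yllcorner/
#' cellsize/NODATA_value header, rows top-down) at full double precision so a
#' round trip reproduces the values exactly; `"csv"` writes one row per cell
#' (`x, y, u` at cell centres). GeoTIFF output is not supported.
#'
#' @param ud a [compute_ud()] raster.
#' @param path output file path.
#' @param format `"esri_ascii"` or `"csv"`.
#' @return `path`, invisibly.
#' @export
export_ud <- function(ud, path, format = c("esri_ascii", "csv", "geotiff")) {
  stopifnot(inherits(ud, "brb_ud"))
  format <- match.arg(format)
  if (format == "geotiff")
    stop("GeoTIFF output is not supported; use \"esri_ascii\" or \"csv\"")
  if (format == "esri_ascii") {
    write_ascii_grid(ud$values, ud$grid, path)
  } else {
    df <- data.frame(x = rep(grid_x(ud$grid), each = ud$grid$nrow),
                     y = rep(grid_y(ud$grid), times = ud$grid$ncol),
                     u = as.vector(ud$values))
    utils::write.csv(df, path, row.names = FALSE)
  }
  invisible(path)
}

write_ascii_grid <- function(values, grid, path, nodata = -9999) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(sprintf("ncols %d", grid$ncol),
               sprintf("nrows %d", grid$nrow),
               sprintf("xllcorner %.10g", grid$xmin),
               sprintf("yllcorner %.10g", grid$ymin),
               sprintf("cellsize %.10g", grid$cellsize),
               sprintf("NODATA_value %g", nodata)), con)
  vals <- values
  vals[is.na(vals)] <- nodata
  for (i in rev(seq_len(grid$nrow))) {   # file rows run top-down
    writeLines(paste(formatC(vals[i, ], format = "g", digits = 17),
                     collapse = " "), con)
  }
  invisible(path)
}

#' Read an ESRI ASCII grid
#'
#' Reads an ESRI ASCII raster (via [sp::read.asciigrid()]) into a values
#' matrix with bottom-up rows and a [grid_spec()]. NODATA cells become `NA`.
#'
#' @param path path to the `.asc` file.
#' @return A list with `values` (matrix `nrow x ncol`) and `grid`.
#' @export
read_ascii_grid <- function(path) {
  if (!file.exists(path)) stop(sprintf("raster file not found: %s", path))
  sgdf <- sp::read.asciigrid(path)
  gt <- sgdf@grid
  nc <- gt@cells.dim[1L]; nr <- gt@cells.dim[2L]
  r <- gt@cellsize[1L]
  if (abs(gt@cellsize[2L] - r) > 1e-9 * r)
    stop("only square-celled ESRI ASCII grids are supported")
  m <- matrix(sgdf@data[[1L]], nrow = nr, ncol = nc, byrow = TRUE)  # top-down
  m <- m[rev(seq_len(nr)), , drop = FALSE]                          # bottom-up
  list(values = m,
       grid = grid_spec(gt@cellcentre.offset[1L] - r / 2,
                        gt@cellcentre.offset[2L] - r / 2, r, nc, nr))
}

#' Read a UD raster written by [export_ud()]
#' @param path path to the ESRI ASCII file.
#' @return A `brb_ud` object (assumed normalized).
#' @export
read_ud <- function(path) {
  g <- read_ascii_grid(path)
  g$values[is.na(g$values)] <- 0
  structure(list(grid = g$grid, values = g$values, N_L = NA_integer_,
                 raw_mass = NA_real_, normalized = TRUE),
            class = "brb_ud")
}
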