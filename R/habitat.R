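#' Categorical habitat raster
#'
#' Integer habitat categories on a [grid_spec()], with an optional legend
#' mapping codes to names and a NODATA code. Values matrices are stored
#' bottom-up like UD rasters.
#'
#' @param grid a [grid_spec()].
#' @param codes integer matrix (`grid$nrow x grid$ncol`, bottom-up rows).
#' @param legend optional named character vector or data frame (`code`,
#'   `name`) mapping codes to habitat names.
#' @param nodata NODATA code (default -9999).
#' @return An object of class `brb_habitat`.
#' @export
habitat_map <- function(grid, codes, legend = NULL, nodata = -9999L) {
  stopifnot(inherits(grid, "brb_grid"), is.matrix(codes),
            nrow(codes) == grid$nrow, ncol(codes) == grid$ncol)
  storage.mode(codes) <- "integer"
  if (is.data.frame(legend)) {
    stopifnot(all(c("code", "name") %in% names(legend)))
    legend <- stats::setNames(as.character(legend$name), legend$code)
  }
  present <- unique(codes[!is.na(codes) & codes != nodata])
  if (!is.null(legend)) {
    uncovered <- setdiff(present, as.integer(names(legend)))
    if (length(uncovered))
      stop("legend does not cover habitat code(s): ",
           paste(uncovered, collapse = ", "))
  }
  structure(list(grid = grid, codes = codes, legend = legend,
                 nodata = as.integer(nodata)),
            class = "brb_habitat")
}

#' Read a habitat raster from an ESRI ASCII grid
#'
#' @param path path to the `.asc` file.
#' @param legend optional legend (see [habitat_map()]); a path to a CSV with
#'   columns `code,name` is also accepted.
#' @return A `brb_habitat`.
#' @export
read_habitat <- function(path, legend = NULL) {
  g <- read_ascii_grid(path)
  if (is.character(legend) && length(legend) == 1L && file.exists(legend))
    legend <- utils::read.csv(legend, stringsAsFactors = FALSE)
  codes <- g$values
  codes[is.na(codes)] <- -9999
  habitat_map(g$grid, matrix(as.integer(round(codes)), nrow = g$grid$nrow),
              legend = legend, nodata = -9999L)
}

#' Habitat code at point locations
#'
#' Nearest-cell (containing-cell) lookup. Points outside the raster or on
#' NODATA cells return `NA`.
#'
#' @param hab a [habitat_map()].
#' @param x,y coordinates (m), vectorized.
#' @return Integer habitat codes (or `NA`).
#' @export
habitat_at <- function(hab, x, y) {
  stopifnot(inherits(hab, "brb_habitat"))
  g <- hab$grid
  ci <- floor((x - g$xmin) / g$cellsize) + 1
  ri <- floor((y - g$ymin) / g$cellsize) + 1
  ok <- ci >= 1 & ci <= g$ncol & ri >= 1 & ri <= g$nrow
  out <- rep(NA_integer_, length(x))
  idx <- cbind(ri[ok], ci[ok])
  v <- hab$codes[idx]
  v[!is.na(v) & v == hab$nodata] <- NA_integer_
  out[ok] <- v
  out
}

#' Habitat fully encompassing each segment
#'
#' A segment is fully encompassed in a habitat when both endpoints and all
#' points sampled every `step` metres along its chord fall in that habitat.
#' Segments crossing habitat boundaries (or NODATA / off-raster cells) get
#' `NA`.
#'
#' @param segments a `brb_segments` data frame.
#' @param hab a [habitat_map()].
#' @param step chord sampling spacing (m), > 0.
#' @return Integer vector, one code (or `NA`) per segment.
#' @export
segment_habitat <- function(segments, hab, step) {
  stopifnot(inherits(segments, "brb_segments"), inherits(hab, "brb_habitat"),
            step > 0)
  vapply(seq_len(nrow(segments)), function(j) {
    L <- segments$L[j]
    n <- ceiling(L / step)
    f <- seq(0, 1, length.out = n + 1L)
    codes <- habitat_at(hab,
                        segments$x0[j] + (segments$x1[j] - segments$x0[j]) * f,
                        segments$y0[j] + (segments$y1[j] - segments$y0[j]) * f)
    if (anyNA(codes) || length(unique(codes)) != 1L) NA_integer_ else codes[1L]
  }, integer(1L))
}

#' Resample a habitat map onto a UD grid
#'
#' Nearest-neighbour (containing-cell) resampling of the habitat raster onto
#' the target grid. If the grids already coincide the map is returned
#' unchanged; otherwise a warning reports that cells were reassigned.
#'
#' @param hab a [habitat_map()].
#' @param grid the target [grid_spec()].
#' @return A `brb_habitat` on `grid`.
#' @export
align_habitat <- function(hab, grid) {
  stopifnot(inherits(hab, "brb_habitat"), inherits(grid, "brb_grid"))
  if (same_grid(hab$grid, grid)) return(hab)
  xs <- grid_x(grid); ys <- grid_y(grid)
  codes <- matrix(habitat_at(hab,
                             rep(xs, each = grid$nrow),
                             rep(ys, times = grid$ncol)),
                  nrow = grid$nrow, ncol = grid$ncol)
  codes[is.na(codes)] <- hab$nodata
  warning(sprintf("habitat raster resampled (nearest neighbour) onto the UD grid (%d cells)",
                  grid$nrow * grid$ncol))
  habitat_map(grid, codes, legend = hab$legend, nodata = hab$nodata)
}

habitat_codes <- function(hab) {
  sort(unique(hab$codes[!is.na(hab$codes) & hab$codes != hab$nodata]))
}

habitat_name <- function(hab, code) {
  if (is.null(hab$legend)) as.character(code)
  else unname(hab$legend[as.character(code)])
}

#' Habitat availability within a mask
#'
#' Non-weighted proportion of each habitat type among the non-NODATA cells of
#' the mask (typically the 95% UD isopleth region), in percent.
#'
#' @param hab a [habitat_map()].
#' @param mask logical matrix on the same grid (e.g. from [isopleths()]
#'   `$masks`).
#' @return A data frame `habitat, name, availability_pct` (percentages sum to
#'   100 over the mask).
#' @export
availability <- function(hab, mask) {
  stopifnot(inherits(hab, "brb_habitat"), is.logical(mask),
            all(dim(mask) == dim(hab$codes)))
  codes <- hab$codes[mask]
  codes <- codes[!is.na(codes) & codes != hab$nodata]
  if (length(codes) == 0L) stop("empty mask (no non-NODATA cells selected)")
  all_codes <- habitat_codes(hab)
  counts <- vapply(all_codes, function(cd) sum(codes == cd), numeric(1L))
  data.frame(habitat = all_codes,
             name = vapply(all_codes, function(cd) habitat_name(hab, cd), ""),
             availability_pct = 100 * counts / length(codes))
}

#' UD-weighted habitat use within a mask
#'
#' Proportion of the masked UD mass falling in each habitat type, in percent.
#' NODATA cells are excluded from both numerator and denominator.
#'
#' @param ud a normalized [compute_ud()] raster.
#' @param hab a [habitat_map()] on the same grid (use [align_habitat()]
#'   first if needed).
#' @param mask logical matrix on the same grid.
#' @return A data frame `habitat, name, use_pct` (percentages sum to 100).
#' @export
ud_weighted_use <- function(ud, hab, mask) {
  stopifnot(inherits(ud, "brb_ud"), inherits(hab, "brb_habitat"),
            is.logical(mask), all(dim(mask) == dim(ud$values)))
  if (!same_grid(ud$grid, hab$grid))
    stop("UD and habitat grids differ; align_habitat() first")
  valid <- mask & !is.na(hab$codes) & hab$codes != hab$nodata
  total <- sum(ud$values[valid])
  if (total <= 0) stop("zero UD mass within the mask")
  all_codes <- habitat_codes(hab)
  use <- vapply(all_codes, function(cd)
    sum(ud$values[valid & hab$codes == cd]) / total, numeric(1L))
  data.frame(habitat = all_codes,
             name = vapply(all_codes, function(cd) habitat_name(hab, cd), ""),
             use_pct = 100 * use)
}

#' Habitat preference table
#'
#' Combines availability and UD-weighted use into use/availability ratios
#' normalized to sum to one (unit-sum constraint), optionally joined with
#' habitat-specific diffusion and drift estimates and their sample sizes.
#' Habitats with zero availability are excluded with a warning. The
#' preferences are invariant to any uniform rescaling of the UD.
#'
#' @param avail data frame from [availability()].
#' @param use data frame from [ud_weighted_use()].
#' @param D_by_habitat optional data frame from [estimate_D_by_habitat()].
#' @param drift optional data frame from [estimate_drift_speeds()].
#' @return A data frame `habitat, name, availability_pct, use_pct, ratio,
#'   preference` (+ `D_hat, N_C, v, N_H` when supplied); `preference` sums
#'   to 1.
#' @export
preference_table <- function(avail, use, D_by_habitat = NULL, drift = NULL) {
  tab <- merge(avail, use[, c("habitat", "use_pct")], by = "habitat")
  zero <- tab$availability_pct == 0
  if (any(zero)) {
    warning("habitat(s) with zero availability excluded: ",
            paste(tab$habitat[zero], collapse = ", "))
    tab <- tab[!zero, , drop = FALSE]
  }
  tab$ratio <- tab$use_pct / tab$availability_pct
  if (sum(tab$ratio) == 0) stop("all use/availability ratios are zero")
  tab$preference <- tab$ratio / sum(tab$ratio)
  if (!is.null(D_by_habitat))
    tab <- merge(tab, D_by_habitat[, c("habitat", "D_hat", "N_C")],
                 by = "habitat", all.x = TRUE)
  if (!is.null(drift))
    tab <- merge(tab, drift[, c("habitat", "v_sq", "v", "N_H")],
                 by = "habitat", all.x = TRUE)
  tab <- tab[order(tab$habitat), , drop = FALSE]
  rownames(tab) <- NULL
  class(tab) <- c("brb_preferences", "data.frame")
  tab
}
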