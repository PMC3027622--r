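#' Construct a relocation track
#'
#' A track is a data frame of fixes with columns `id` (animal identifier),
#' `t` (time in minutes, numeric), `x`, `y` (projected planar coordinates in
#' metres) and `p` (proportion of activity time in `[0, 1]` for the recording
#' interval ENDING at the fix). Fixes are sorted by time within each animal.
#'
#' @param id animal identifier(s), recycled.
#' @param t time in minutes (numeric, strictly increasing within an animal).
#' @param x,y planar coordinates (m).
#' @param p activity proportion in `[0, 1]` (default 1, i.e. always active).
#' @return A `brb_track` data frame.
#' @export
brb_track <- function(id = "animal1", t, x, y, p = 1) {
  n <- length(t)
  df <- data.frame(id = rep_len(as.character(id), n),
                   t = as.numeric(t),
                   x = rep_len(as.numeric(x), n),
                   y = rep_len(as.numeric(y), n),
                   p = rep_len(as.numeric(p), n))
  validate_track(df)
}

validate_track <- function(df) {
  stopifnot(all(c("id", "t", "x", "y", "p") %in% names(df)))
  if (!all(is.finite(df$x)) || !all(is.finite(df$y)))
    stop("track coordinates must be finite")
  if (any(df$p < 0 | df$p > 1, na.rm = TRUE))
    stop("activity proportion `p` must lie within [0, 1]")
  df <- df[order(df$id, df$t), , drop = FALSE]
  dup <- unlist(tapply(df$t, df$id, function(tt) duplicated(tt)), use.names = FALSE)
  if (any(dup)) {
    stop(sprintf("duplicate timestamps within an animal's track (first at t = %g)",
                 df$t[which(dup)[1L]]))
  }
  rownames(df) <- NULL
  class(df) <- c("brb_track", "data.frame")
  df
}

#' Read a relocation track from delimited text
#'
#' Reads a CSV (or other delimited) file of GPS fixes, maps columns by name,
#' converts timestamps to minutes, sorts fixes by time within each animal and
#' validates the result. Coordinates must already be in a projected planar
#' reference system in metres; no geographic transform is applied.
#'
#' Timestamps may be numeric (interpreted as minutes) or ISO-8601 date-times,
#' which are parsed as UTC and converted to minutes elapsed since the earliest
#' timestamp in the file (the origin is kept as attribute `t_origin`). If the
#' activity column is absent, all fixes are assumed fully active (`p = 1`)
#' and a warning is emitted.
#'
#' @param path path to the delimited text file (with header).
#' @param id,time,x,y,activity column names in the file; `id` and `activity`
#'   may be absent (single-animal file / no activity sensor).
#' @param sep field separator (default comma).
#' @return A `brb_track` data frame (see [brb_track()]).
#' @export
read_track <- function(path, id = "id", time = "t", x = "x", y = "y",
                       activity = "p", sep = ",") {
  if (!file.exists(path)) stop(sprintf("track file not found: %s", path))
  raw <- utils::read.csv(path, sep = sep, stringsAsFactors = FALSE)
  if (nrow(raw) == 0L) stop(sprintf("empty track file: %s", path))
  for (col in c(time, x, y)) {
    if (!col %in% names(raw))
      stop(sprintf("column \"%s\" not found in %s", col, path))
  }
  tcol <- raw[[time]]
  t_origin <- NA_character_
  if (is.character(tcol) || inherits(tcol, "factor")) {
    tt <- as.POSIXct(as.character(tcol), tz = "UTC",
                     tryFormats = c("%Y-%m-%dT%H:%M:%OS", "%Y-%m-%d %H:%M:%OS",
                                    "%Y-%m-%dT%H:%M", "%Y-%m-%d %H:%M"))
    if (anyNA(tt)) {
      bad <- which(is.na(tt))[1L]
      stop(sprintf("unparseable timestamp \"%s\" at data row %d of %s",
                   as.character(tcol)[bad], bad, path))
    }
    t_origin <- format(min(tt), "%Y-%m-%dT%H:%M:%SZ")
    tnum <- as.numeric(difftime(tt, min(tt), units = "mins"))
  } else {
    tnum <- as.numeric(tcol)
    if (anyNA(tnum)) {
      stop(sprintf("unparseable numeric time at data row %d of %s",
                   which(is.na(tnum))[1L], path))
    }
  }
  xy <- cbind(suppressWarnings(as.numeric(raw[[x]])),
              suppressWarnings(as.numeric(raw[[y]])))
  if (anyNA(xy)) {
    stop(sprintf("unparseable coordinate at data row %d of %s",
                 which(rowSums(is.na(xy)) > 0)[1L], path))
  }
  ids <- if (id %in% names(raw)) as.character(raw[[id]]) else "animal1"
  if (activity %in% names(raw)) {
    p <- suppressWarnings(as.numeric(raw[[activity]]))
    if (anyNA(p)) {
      stop(sprintf("unparseable activity value at data row %d of %s",
                   which(is.na(p))[1L], path))
    }
  } else {
    warning("no activity column found; assuming fully active fixes (p = 1)")
    p <- 1
  }
  out <- brb_track(id = ids, t = tnum, x = xy[, 1L], y = xy[, 2L], p = p)
  attr(out, "t_origin") <- t_origin
  out
}

#' Build track segments from consecutive fixes
#'
#' One segment per pair of successive fixes of the same animal, carrying the
#' recording interval `T_R = t1 - t0` (min), the activity time
#' `T = p1 * T_R` (min; the activity proportion attached to the interval's
#' end fix), the Euclidean length `L` (m), and inclusion flags (all segments
#' start included; see [filter_segments()]).
#'
#' @param track a `brb_track` (>= 2 fixes per animal).
#' @return A `brb_segments` data frame with columns `id, t0, t1, x0, y0, x1,
#'   y1, T_R, T, L, included, reason, null_D`.
#' @export
build_segments <- function(track) {
  stopifnot(inherits(track, "brb_track"))
  if (nrow(track) < 2L) stop("at least 2 fixes are required to build segments")
  pieces <- lapply(split(seq_len(nrow(track)), track$id), function(idx) {
    if (length(idx) < 2L) return(NULL)
    a <- idx[-length(idx)]
    b <- idx[-1L]
    data.frame(
      id = track$id[a],
      t0 = track$t[a], t1 = track$t[b],
      x0 = track$x[a], y0 = track$y[a],
      x1 = track$x[b], y1 = track$y[b],
      T_R = track$t[b] - track$t[a],
      T = track$p[b] * (track$t[b] - track$t[a]),
      L = sqrt((track$x[b] - track$x[a])^2 + (track$y[b] - track$y[a])^2),
      included = TRUE, reason = "none", null_D = FALSE,
      stringsAsFactors = FALSE)
  })
  seg <- do.call(rbind, pieces)
  if (is.null(seg) || nrow(seg) == 0L)
    stop("at least 2 fixes are required to build segments")
  rownames(seg) <- NULL
  class(seg) <- c("brb_segments", "data.frame")
  seg
}

#' Flag segments excluded from UD computation
#'
#' Applies the two exclusion rules of the BRB method:
#' \itemize{
#'   \item segments whose recording interval exceeds `T_max` are excluded
#'     (`reason = "exceeds_Tmax"`): their activity time is removed from all
#'     downstream sums, because the drift cannot be assumed constant over so
#'     long an interval;
#'   \item segments shorter than `L_min` (e.g. 50 m for a grazer whose "short
#'     but active" bouts reflect disturbance rather than feeding) are either
#'     excluded (`immobile = "drop"`, `reason = "below_Lmin"`) or -- for
#'     species that feed while nearly immobile -- retained but marked for a
#'     null diffusion coefficient (`immobile = "keep_null_D"`), so they
#'     contribute with the fixed bandwidth `h_min`.
#' }
#' The function is idempotent; previously excluded segments are untouched.
#'
#' @param segments a `brb_segments` data frame.
#' @param T_max upper recording-interval threshold (min), > 0.
#' @param L_min minimum segment length (m), >= 0.
#' @param immobile how to treat active-but-immobile segments (`L < L_min`).
#' @return The segments with updated `included`, `reason`, `null_D` columns.
#' @export
filter_segments <- function(segments, T_max, L_min = 0,
                            immobile = c("drop", "keep_null_D")) {
  stopifnot(inherits(segments, "brb_segments"))
  immobile <- match.arg(immobile)
  if (!is.numeric(T_max) || length(T_max) != 1L || T_max <= 0)
    stop("`T_max` must be a single positive number")
  if (L_min < 0) stop("`L_min` must be >= 0")
  over <- segments$included & segments$T_R > T_max
  segments$included[over] <- FALSE
  segments$reason[over] <- "exceeds_Tmax"
  short <- segments$included & segments$L < L_min
  if (immobile == "drop") {
    segments$included[short] <- FALSE
    segments$reason[short] <- "below_Lmin"
  } else {
    segments$null_D[short] <- TRUE
  }
  segments
}

#' Convert segments for a global (rather than active-only) UD
#'
#' By default only activity time enters bridge computations: resting time is
#' ignored, yielding an "active" UD. To compute a global UD instead, every
#' segment's full recording interval is treated as activity time, and segments
#' during which the animal was essentially resting (activity proportion at or
#' below `resting_p`) are marked for a null diffusion coefficient, so resting
#' relocations spread only by the relocation variance `h_min`.
#'
#' @param segments a `brb_segments` data frame.
#' @param resting_p activity-proportion threshold at or below which a segment
#'   counts as resting (default 0).
#' @return Segments with `T = T_R` everywhere and `null_D` set on resting
#'   segments.
#' @export
as_global_segments <- function(segments, resting_p = 0) {
  stopifnot(inherits(segments, "brb_segments"))
  p <- ifelse(segments$T_R > 0, segments$T / segments$T_R, 1)
  segments$null_D <- segments$null_D | (p <= resting_p)
  segments$T <- segments$T_R
  segments
}

#' Sliding-window stationarity diagnostic
#'
#' Mean and variance of each coordinate computed in a sliding time window, the
#' diagnostic used to delineate stationary home-range periods by eye: marked
#' and durable changes in the mean or variance of either coordinate indicate a
#' shift to a new period. Detection is deliberately not automated; this only
#' emits the series.
#'
#' Windows are half-open, `[centre - window/2, centre + window/2)`, and
#' variances are population variances (equal weights), so results are exactly
#' reproducible. Windows holding fewer than two fixes are omitted (with a
#' message).
#'
#' @param track a `brb_track` (single or multiple animals; windows are
#'   computed per animal).
#' @param window window width (min), at least twice the recording interval.
#' @param step spacing between successive window centres (min).
#' @return A data frame with columns `id, centre, n, mean_x, mean_y, var_x,
#'   var_y`, ordered by centre time within animal.
#' @export
sliding_window_stats <- function(track, window, step) {
  stopifnot(inherits(track, "brb_track"), window > 0, step > 0)
  pieces <- lapply(split(track, track$id), function(tr) {
    if (nrow(tr) < 2L) return(NULL)
    lo <- min(tr$t) + window / 2
    hi <- max(lo, max(tr$t) - window / 2)
    centres <- seq(lo, hi + step / 2, by = step)
    rows <- lapply(centres, function(ct) {
      inw <- tr$t >= ct - window / 2 & tr$t < ct + window / 2
      if (sum(inw) < 2L) return(NULL)
      xs <- tr$x[inw]; ys <- tr$y[inw]
      data.frame(id = tr$id[1L], centre = ct, n = sum(inw),
                 mean_x = mean(xs), mean_y = mean(ys),
                 var_x = mean((xs - mean(xs))^2),
                 var_y = mean((ys - mean(ys))^2))
    })
    omitted <- sum(vapply(rows, is.null, logical(1L)))
    if (omitted > 0L)
      message(sprintf("%d window(s) with < 2 fixes omitted for animal %s",
                      omitted, tr$id[1L]))
    do.call(rbind, rows)
  })
  out <- do.call(rbind, pieces)
  if (is.null(out)) out <- data.frame(id = character(), centre = numeric(),
                                      n = integer(), mean_x = numeric(),
                                      mean_y = numeric(), var_x = numeric(),
                                      var_y = numeric())
  rownames(out) <- NULL
  out
}

#' Write segments to CSV
#'
#' @param segments a `brb_segments` data frame.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_segments <- function(segments, path) {
  stopifnot(inherits(segments, "brb_segments"))
  utils::write.csv(as.data.frame(segments), path, row.names = FALSE)
  invisible(path)
}

#' Read segments from a CSV written by [write_segments()]
#' @param path input file path.
#' @return A `brb_segments` data frame.
#' @export
read_segments <- function(path) {
  seg <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("id", "t0", "t1", "x0", "y0", "x1", "y1", "T_R", "T", "L",
            "included", "reason", "null_D")
  miss <- setdiff(need, names(seg))
  if (length(miss)) stop("missing segment columns: ", paste(miss, collapse = ", "))
  seg$id <- as.character(seg$id)
  class(seg) <- c("brb_segments", "data.frame")
  seg
}
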