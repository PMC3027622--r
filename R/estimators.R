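#' Couples of consecutive segments usable for diffusion estimation
#'
#' The diffusion coefficient is estimated from relocation triplets
#' `(z[i-1], z[i], z[i+1])`: if the middle fix were missing but the drift
#' stayed constant over both segments, the expected position at activity time
#' `T1` would be the time-weighted chord point
#' `mu_B = z[i-1] + (z[i+1] - z[i-1]) * T1 / (T1 + T2)`, with movement
#' variance `2 D T1 T2 / (T1 + T2)` per axis, hence
#' `E(delta^2) = 4 D T1 T2 / (T1 + T2)` for the squared deviation
#' `delta^2 = ||z[i] - mu_B||^2`.
#'
#' A couple is retained only when the movement is plausibly homogeneous over
#' the triplet: the two segments must be contiguous (same animal, shared
#' middle fix), both active (`T > 0`), jointly short enough
#' (`T_R1 + T_R2 <= T_max`), and balanced (neither activity time nor length
#' may differ by more than a factor 2 between the two segments).
#'
#' @param segments a `brb_segments` data frame (ordered, as produced by
#'   [build_segments()]).
#' @param T_max upper threshold (min) on the summed recording intervals.
#' @return A data frame with one row per retained couple: `id, t_mid, x_mid,
#'   y_mid, delta_sq, T1, T2, L1, L2, D_couple`, where
#'   `D_couple = delta_sq * (T1 + T2) / (4 * T1 * T2)` is the per-couple
#'   unbiased estimate. May have zero rows.
#' @export
diffusion_couples <- function(segments, T_max) {
  stopifnot(inherits(segments, "brb_segments"), T_max > 0)
  n <- nrow(segments)
  if (n < 2L) return(empty_couples())
  a <- seq_len(n - 1L)
  b <- a + 1L
  contiguous <- segments$id[a] == segments$id[b] &
    segments$t1[a] == segments$t0[b] &
    segments$x1[a] == segments$x0[b] & segments$y1[a] == segments$y0[b]
  T1 <- segments$T[a]; T2 <- segments$T[b]
  L1 <- segments$L[a]; L2 <- segments$L[b]
  keep <- contiguous &
    segments$T_R[a] + segments$T_R[b] <= T_max &
    T1 > 0 & T2 > 0 &
    T1 <= 2 * T2 & T1 >= T2 / 2 &
    L1 <= 2 * L2 & L1 >= L2 / 2
  keep[is.na(keep)] <- FALSE
  if (!any(keep)) return(empty_couples())
  a <- a[keep]; b <- b[keep]
  T1 <- segments$T[a]; T2 <- segments$T[b]
  w <- T1 / (T1 + T2)
  mux <- segments$x0[a] + (segments$x1[b] - segments$x0[a]) * w
  muy <- segments$y0[a] + (segments$y1[b] - segments$y0[a]) * w
  delta_sq <- (segments$x1[a] - mux)^2 + (segments$y1[a] - muy)^2
  data.frame(
    id = segments$id[a],
    t_mid = segments$t1[a], x_mid = segments$x1[a], y_mid = segments$y1[a],
    delta_sq = delta_sq, T1 = T1, T2 = T2,
    L1 = segments$L[a], L2 = segments$L[b],
    D_couple = delta_sq * (T1 + T2) / (4 * T1 * T2),
    stringsAsFactors = FALSE)
}

empty_couples <- function() {
  data.frame(id = character(), t_mid = numeric(), x_mid = numeric(),
             y_mid = numeric(), delta_sq = numeric(), T1 = numeric(),
             T2 = numeric(), L1 = numeric(), L2 = numeric(),
             D_couple = numeric(), stringsAsFactors = FALSE)
}

#' Estimate the diffusion coefficient from segment couples
#'
#' Default estimator: the mean of the per-couple unbiased estimates
#' `delta^2 * (T1 + T2) / (4 * T1 * T2)` over the `N_C` retained couples.
#' The pooled variant (`method = "pooled"`) is the ratio of sums
#' `sum(delta^2) / (4 * sum(T1 * T2 / (T1 + T2)))`, provided for sensitivity
#' checks; both are unbiased for a homogeneous diffusive movement.
#'
#' Each per-couple estimate has a coefficient of variation close to 1 (the
#' squared deviation is asymptotically exponential), so habitat-specific
#' estimates from small `N_C` must be treated with caution; `N_C` is always
#' reported. `D_hat = 0` (immobile-but-active, or purely advective straight
#' movement) is a legitimate estimate.
#'
#' @param couples a data frame from [diffusion_couples()].
#' @param method `"mean"` (mean of per-couple ratios, default) or `"pooled"`.
#' @return An object of class `diffusion_estimate`: list with `D_hat`
#'   (m^2/min; `NA` with a warning when `N_C = 0`), `N_C`, `method`,
#'   `cv` (sample coefficient of variation of the per-couple estimates) and
#'   the `couples` themselves.
#' @export
estimate_D <- function(couples, method = c("mean", "pooled")) {
  method <- match.arg(method)
  n <- nrow(couples)
  if (n == 0L) {
    warning("no usable couples of consecutive segments; D is undefined")
    D_hat <- NA_real_
    cv <- NA_real_
  } else {
    D_hat <- if (method == "mean") {
      mean(couples$D_couple)
    } else {
      sum(couples$delta_sq) / (4 * sum(couples$T1 * couples$T2 /
                                         (couples$T1 + couples$T2)))
    }
    cv <- if (n > 1L && D_hat > 0) {
      stats::sd(couples$D_couple) / mean(couples$D_couple)
    } else NA_real_
  }
  structure(list(D_hat = D_hat, N_C = n, method = method, cv = cv,
                 couples = couples),
            class = "diffusion_estimate")
}

#' @export
print.diffusion_estimate <- function(x, ...) {
  if (is.na(x$D_hat)) {
    cat(sprintf("Diffusion estimate: undefined (N_C = %d)\n", x$N_C))
  } else {
    cat(sprintf("Diffusion estimate: D = %.4g m^2/min (N_C = %d, %s%s)\n",
                x$D_hat, x$N_C, x$method,
                if (is.na(x$cv)) "" else sprintf(", per-couple CV = %.2f", x$cv)))
  }
  invisible(x)
}

#' Habitat-specific diffusion coefficients
#'
#' Applies [estimate_D()] separately to the couples of consecutive segments
#' whose two segments are both fully encompassed in the same habitat type. A
#' segment is "fully encompassed" in a habitat when both endpoints and all
#' points sampled every `step` metres along its chord fall in that habitat.
#' Habitats in which no full couple occurs get an undefined estimate with
#' `N_C = 0`; small samples are common for scarce or fragmented habitats and
#' the reported `N_C` should drive how much the estimate is trusted.
#'
#' @param segments a `brb_segments` data frame.
#' @param hab a [habitat_map()].
#' @param T_max upper threshold (min) on summed recording intervals.
#' @param step chord sampling spacing (m); defaults to half the habitat-map
#'   cell size.
#' @param method passed to [estimate_D()].
#' @return A data frame with one row per habitat code: `habitat, D_hat, N_C,
#'   cv`.
#' @export
estimate_D_by_habitat <- function(segments, hab, T_max,
                                  step = NULL, method = "mean") {
  stopifnot(inherits(hab, "brb_habitat"))
  if (is.null(step)) step <- hab$grid$cellsize / 2
  seg_h <- segment_habitat(segments, hab, step)
  couples <- diffusion_couples(segments, T_max)
  codes <- sort(unique(as.vector(hab$codes[hab$codes != hab$nodata &
                                             !is.na(hab$codes)])))
  # map couples back to their segment pair to test habitat encompassment
  n <- nrow(segments)
  a <- seq_len(max(n - 1L, 0L))
  pair_key <- paste(segments$id[a], segments$t1[a])
  couple_first <- match(paste(couples$id, couples$t_mid), pair_key)
  h1 <- seg_h[couple_first]
  h2 <- seg_h[couple_first + 1L]
  same <- !is.na(h1) & !is.na(h2) & h1 == h2
  out <- lapply(codes, function(code) {
    sub <- couples[same & h1 == code, , drop = FALSE]
    est <- suppressWarnings(estimate_D(sub, method = method))
    data.frame(habitat = code, D_hat = est$D_hat, N_C = est$N_C, cv = est$cv)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Upper movement standard deviation from D and T_max
#'
#' `beta_Tmax = sqrt(D * T_max / 2)`, the standard deviation reached at the
#' centre of a fully active segment lasting `T_max`; monotone in both
#' arguments.
#'
#' @param D diffusion coefficient (m^2/min), >= 0 (vectorized).
#' @param T_max upper recording-interval threshold (min).
#' @return beta (m).
#' @examples
#' beta_from_D(440, 180)  # 198.997... m, displayed as 200 m
#' @export
beta_from_D <- function(D, T_max) {
  stopifnot(all(D >= 0), T_max > 0)
  sqrt(D * T_max / 2)
}

#' Display-rounded beta (nearest 10 m)
#'
#' Reporting helper: beta values are conventionally quoted to the nearest
#' 10 m (e.g. D = 440 m^2/min with T_max = 180 min gives beta = 199 m,
#' quoted as 200 m).
#'
#' @inheritParams beta_from_D
#' @return beta rounded to the nearest 10 m.
#' @export
beta_display <- function(D, T_max) {
  10 * round(beta_from_D(D, T_max) / 10)
}

#' Habitat-specific squared drift speeds
#'
#' For a simplified biased random walk the expected squared segment length is
#' `E(L^2) = v^2 T^2 + 4 D T`, so the squared drift speed in habitat `H` is
#' estimated as the mean of `(L^2 - 4 D T) / T^2` over the `N_H` active
#' segments fully encompassed in `H`. Large values indicate fast oriented
#' transit (less preferred habitat); low values indicate mainly diffusive
#' movement within preferred patches. Negative estimates can legitimately
#' occur when the habitat-specific diffusion is lower than the `D` used; they
#' are reported as-is with `v` flagged undefined, never clipped.
#'
#' @param segments a `brb_segments` data frame.
#' @param hab a [habitat_map()], or `NULL` to pool all segments into one
#'   stratum (habitat code `NA`).
#' @param D global diffusion coefficient (m^2/min), used for every habitat
#'   unless a habitat-specific value is available in `D_by_habitat`.
#' @param D_by_habitat optional data frame from [estimate_D_by_habitat()];
#'   habitats with a defined `D_hat` use it instead of the global `D`.
#' @param step chord sampling spacing (m) for habitat encompassment; defaults
#'   to half the habitat-map cell size.
#' @param method `"mean"` (mean of per-segment values, default) or
#'   `"pooled"` (`(sum L^2 - 4 D sum T) / sum T^2`).
#' @return A data frame with one row per habitat: `habitat, v_sq
#'   (m^2/min^2), v (m/min; NA when v_sq < 0 or N_H = 0), N_H, D_used`.
#' @export
estimate_drift_speeds <- function(segments, hab = NULL, D, D_by_habitat = NULL,
                                  step = NULL, method = c("mean", "pooled")) {
  method <- match.arg(method)
  stopifnot(inherits(segments, "brb_segments"), is.numeric(D), D >= 0)
  active <- segments$T > 0
  if (is.null(hab)) {
    strata <- list(list(code = NA_integer_, rows = which(active)))
  } else {
    stopifnot(inherits(hab, "brb_habitat"))
    if (is.null(step)) step <- hab$grid$cellsize / 2
    seg_h <- segment_habitat(segments, hab, step)
    codes <- sort(unique(as.vector(hab$codes[hab$codes != hab$nodata &
                                               !is.na(hab$codes)])))
    strata <- lapply(codes, function(code)
      list(code = code, rows = which(active & !is.na(seg_h) & seg_h == code)))
  }
  rows <- lapply(strata, function(st) {
    D_used <- D
    if (!is.null(D_by_habitat) && !is.na(st$code)) {
      hit <- which(D_by_habitat$habitat == st$code & !is.na(D_by_habitat$D_hat))
      if (length(hit)) D_used <- D_by_habitat$D_hat[hit[1L]]
    }
    n <- length(st$rows)
    if (n == 0L) {
      return(data.frame(habitat = st$code, v_sq = NA_real_, v = NA_real_,
                        N_H = 0L, D_used = D_used))
    }
    L <- segments$L[st$rows]
    Tt <- segments$T[st$rows]
    v_sq <- if (method == "mean") {
      mean((L^2 - 4 * D_used * Tt) / Tt^2)
    } else {
      (sum(L^2) - 4 * D_used * sum(Tt)) / sum(Tt^2)
    }
    data.frame(habitat = st$code, v_sq = v_sq,
               v = if (v_sq >= 0) sqrt(v_sq) else NA_real_,
               N_H = n, D_used = D_used)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
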