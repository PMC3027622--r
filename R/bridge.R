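#' Movement variance of a simplified biased random bridge
#'
#' Per-axis positional variance of an advective-diffusive bridge at activity
#' time `t` within a segment of total activity time `T`:
#' `2 D t (1 - t/T)`. It is zero at both endpoints, symmetric about `t = T/2`,
#' and reaches its maximum `D T / 2` at the centre, irrespective of the
#' segment length.
#'
#' @param t activity time(s) since the segment start (min), in `[0, T]`.
#' @param T segment activity time (min), > 0 (T = 0 allowed when t = 0).
#' @param D diffusion coefficient (m^2/min).
#' @return Variance (m^2), vectorized over `t`.
#' @examples
#' movement_variance(90, T = 180, D = 440)  # maximum D*T/2 = 39600
#' @export
movement_variance <- function(t, T, D) {
  stopifnot(is.numeric(t), is.numeric(T), length(T) == 1L, T >= 0,
            is.numeric(D), length(D) == 1L, D >= 0)
  if (any(t < 0 | t > T)) stop("`t` must lie within [0, T]")
  if (T == 0) return(rep(0, length(t)))
  2 * D * t * (1 - t / T)
}

#' Total (relocation + movement) variance of a simplified BRB
#'
#' Adds the relocation variance `sigma_min^2` to the movement variance, using
#' either the constant-weight model or the merging model (see [brb_params()]).
#' Both models return exactly `sigma_min^2` at `t = 0` and `t = T`, so kernel
#' bandwidths never fall below `h_min = sigma_min`.
#'
#' @param t activity time(s) (min), in `[0, T]`.
#' @param T segment activity time (min), `0 <= T <= params$T_max`.
#' @param params a [brb_params()] object.
#' @return Variance (m^2), vectorized over `t`.
#' @export
total_variance <- function(t, T, params) {
  stopifnot(inherits(params, "brb_params"), is.numeric(t),
            is.numeric(T), length(T) == 1L)
  if (T < 0 || T > params$T_max) stop("`T` must lie within [0, T_max]")
  if (any(t < 0 | t > T)) stop("`t` must lie within [0, T]")
  s2 <- params$sigma_min^2
  u <- if (T > 0) t * (1 - t / T) else rep(0, length(t))
  if (params$mode == "constant") {
    s2 + 2 * params$D * u
  } else {
    w <- 4 * u / params$T_max
    s2 * (1 - w) + params$beta_Tmax^2 * w
  }
}

#' Conditioned (bridge) density at a fixed time
#'
#' Density of the animal's position at activity time `t`, conditioned on the
#' segment's start and end relocations. For a simplified (isotropically
#' diffusive) biased random bridge this is a circular bivariate Gaussian,
#' independent of the drift, centred on the point sliding at constant speed
#' along the chord: `mu_B(t) = z0 + (zT - z0) * t / T`.
#'
#' @param z evaluation point(s): numeric length-2 vector or a two-column
#'   matrix of (x, y) coordinates (m).
#' @param t activity time (min), `0 <= t <= T`.
#' @param z0,zT segment start / end coordinates, numeric length 2 (m).
#' @param T segment activity time (min), > 0.
#' @param variance per-axis variance at time `t` (m^2), > 0 (typically from
#'   [total_variance()]).
#' @return Density values (1/m^2), one per row of `z`.
#' @export
bridge_density <- function(z, t, z0, zT, T, variance) {
  if (is.null(dim(z))) z <- matrix(z, ncol = 2L)
  stopifnot(ncol(z) == 2L, length(z0) == 2L, length(zT) == 2L,
            length(t) == 1L, length(T) == 1L, T > 0)
  if (t < 0 || t > T) stop("`t` must lie within [0, T]")
  if (!is.numeric(variance) || length(variance) != 1L || variance <= 0)
    stop("`variance` must be a single positive number")
  mu <- z0 + (zT - z0) * t / T
  d2 <- (z[, 1L] - mu[1L])^2 + (z[, 2L] - mu[2L])^2
  exp(-d2 / (2 * variance)) / (2 * pi * variance)
}

#' Time-integrated bridge density (quadrature oracle)
#'
#' Space-use density contributed by one segment: the time average
#' `(1/T) * integral_0^T f_B(z, t) dt` of the bridge density, evaluated by
#' composite midpoint quadrature in `t` with the total variance of
#' [total_variance()] (finite everywhere, since the variance floor is
#' `sigma_min^2`). This is the brute-force reference against which the MKDE
#' kernel-sum estimator is validated; the kernel sum is the practical way to
#' compute the same quantity over a whole track.
#'
#' @inheritParams bridge_density
#' @param params a [brb_params()] object; `T` must not exceed `params$T_max`.
#' @param n_quad number of midpoint quadrature nodes (>= 16).
#' @return Density values (1/m^2), one per row of `z`.
#' @export
integrated_bridge_density <- function(z, z0, zT, T, params, n_quad = 64L) {
  if (is.null(dim(z))) z <- matrix(z, ncol = 2L)
  stopifnot(inherits(params, "brb_params"), T > 0, n_quad >= 16L)
  if (T > params$T_max) stop("`T` must not exceed params$T_max")
  tj <- (seq_len(n_quad) - 0.5) * T / n_quad
  acc <- numeric(nrow(z))
  for (t in tj) {
    acc <- acc + bridge_density(z, t, z0, zT, T, total_variance(t, T, params))
  }
  acc / n_quad
}

#' Variable smoothing parameter along a track segment
#'
#' Discrete-time bandwidth schedule of the MKDE method: the kernel standard
#' deviation attributed to the `m`-th of the `n_i + 1` locations (recorded
#' endpoints plus interpolated interior points) of a segment with activity
#' time `T_i` is the total standard deviation of the bridge at time
#' `t = m * T_i / n_i`:
#' `h_i(m) = sqrt(total_variance(m * T_i / n_i, T_i, params))`.
#' Recorded locations (`m = 0` or `m = n_i`) get `h_min`; the centre of a
#' fully active segment lasting `T_max` gets `h_max`.
#'
#' @param m location index (0 .. `n_i`), vectorized.
#' @param n_i number of interpolation intervals (>= 1).
#' @param T_i segment activity time (min), `<= params$T_max`.
#' @param params a [brb_params()] object.
#' @return Bandwidth(s) h (m).
#' @export
smoothing_parameter <- function(m, n_i, T_i, params) {
  stopifnot(inherits(params, "brb_params"), length(n_i) == 1L, n_i >= 1L,
            length(T_i) == 1L)
  if (any(m < 0 | m > n_i)) stop("`m` must lie within [0, n_i]")
  sqrt(total_variance(m * T_i / n_i, T_i, params))
}
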