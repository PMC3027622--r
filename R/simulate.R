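#' Von Mises concentration from a mean resultant length
#'
#' Solves `c = I1(kappa) / I0(kappa)` for `kappa`, so that headings drawn
#' from a von Mises distribution have the requested angular concentration
#' `c = E[cos(theta - phi)]`.
#'
#' @param c mean resultant length in `[0, 1)`.
#' @return Concentration parameter kappa (>= 0).
#' @export
kappa_from_c <- function(c) {
  if (!is.numeric(c) || length(c) != 1L || c < 0 || c >= 1)
    stop("`c` must lie within [0, 1)")
  if (c == 0) return(0)
  f <- function(k) besselI(k, 1, expon.scaled = TRUE) /
    besselI(k, 0, expon.scaled = TRUE) - c
  stats::uniroot(f, c(1e-8, 2 / (1 - c) + 10), tol = 1e-10,
                 extendInt = "upX")$root
}

# Best & Fisher (1979) rejection sampler for von Mises deviates, vectorized
# in batches; kappa ~ 0 falls back to the uniform circular distribution.
rvonmises <- function(n, mu = 0, kappa = 0) {
  if (n == 0L) return(numeric(0))
  if (kappa < 1e-8) return(runif(n, -pi, pi) + mu)
  a <- 1 + sqrt(1 + 4 * kappa^2)
  b <- (a - sqrt(2 * a)) / (2 * kappa)
  r <- (1 + b^2) / (2 * b)
  out <- numeric(0)
  while (length(out) < n) {
    m <- max(n - length(out), 16L)
    m <- ceiling(m * 1.5)
    u1 <- runif(m); u2 <- runif(m); u3 <- runif(m)
    z <- cos(pi * u1)
    f <- (1 + r * z) / (r + z)
    cc <- kappa * (r - f)
    ok <- (cc * (2 - cc) - u2 > 0) | (log(cc / u2) + 1 - cc >= 0)
    theta <- sign(u3[ok] - 0.5) * acos(f[ok])
    out <- c(out, theta)
  }
  (out[seq_len(n)] + mu + pi) %% (2 * pi) - pi
}

#' Effective diffusion coefficient of a simulated walk
#'
#' Ground-truth diffusion coefficients implied by the walk parameters, used
#' to validate the estimators. For an uncorrelated (Brownian) or biased
#' random walk with constant step length `s * dt`, the per-step displacement
#' covariance trace is `s^2 dt^2 (1 - c^2)`, giving an isotropic-equivalent
#' `D = s^2 dt (1 - c^2) / 4` (for `c = 0`: `s^2 dt / 4`). For a correlated
#' random walk the long-time (asymptotic) value is
#' `D = s^2 dt (1 + c) / (4 (1 - c))`.
#'
#' @param s speed (m/min).
#' @param c angular concentration in `[0, 1)`.
#' @param dt step duration (min).
#' @param type walk type (`"brownian"`, `"brw"`, `"crw"`).
#' @return D (m^2/min).
#' @export
walk_diffusion <- function(s, c = 0, dt = 1, type = c("brownian", "brw", "crw")) {
  type <- match.arg(type)
  if (type == "crw") s^2 * dt * (1 + c) / (4 * (1 - c))
  else s^2 * dt * (1 - c^2) / 4
}

#' Simulate a discrete-step random walk
#'
#' Constant-step-length walks whose successive movement directions are drawn
#' from a von Mises distribution:
#' \describe{
#'   \item{`"brownian"`}{uniform directions (no correlation, no bias).}
#'   \item{`"brw"`}{biased random walk: absolute headings concentrated
#'     around the preferred direction `phi` with concentration `c`; generates
#'     a drift of speed `v = s * c` in direction `phi`.}
#'   \item{`"crw"`}{correlated random walk: turning angles (relative to the
#'     previous heading) concentrated around 0; the initial heading is
#'     uniform.}
#'   \item{`"bcrw"`}{biased correlated random walk: each step heads towards a
#'     compromise direction between `phi` (weight `bias_weight`) and the
#'     previous heading, with concentration `c`.}
#' }
#' Runs are deterministic given `seed` (or the current RNG state when
#' `seed = NULL`).
#'
#' @param n_steps number of steps (>= 1).
#' @param dt step duration (min).
#' @param s speed (m/min); step length is `s * dt`.
#' @param type walk type.
#' @param phi preferred direction (rad) for `"brw"`/`"bcrw"`.
#' @param c angular concentration in `[0, 1)`; `c = 0` downgrades a BRW to
#'   Brownian motion.
#' @param bias_weight weight of the preferred direction in `"bcrw"`.
#' @param start starting coordinates (m).
#' @param id animal identifier for the output track.
#' @param seed optional integer seed.
#' @return A `brb_track` with `n_steps + 1` fully active fixes (`p = 1`).
#' @export
simulate_walk <- function(n_steps, dt = 1, s = 10,
                          type = c("brownian", "brw", "crw", "bcrw"),
                          phi = 0, c = 0, bias_weight = 0.5,
                          start = c(0, 0), id = "sim", seed = NULL) {
  type <- match.arg(type)
  stopifnot(n_steps >= 1L, dt > 0, s >= 0)
  if (c < 0 || c >= 1) stop("`c` must lie within [0, 1)")
  if (!is.null(seed)) set.seed(seed)
  kappa <- kappa_from_c(c)
  theta <- switch(type,
    brownian = runif(n_steps, -pi, pi),
    brw = rvonmises(n_steps, phi, kappa),
    crw = {
      turns <- rvonmises(n_steps - 1L, 0, kappa)
      cumsum(c(runif(1L, -pi, pi), turns))
    },
    bcrw = {
      eps <- rvonmises(n_steps, 0, kappa)
      th <- numeric(n_steps)
      prev <- runif(1L, -pi, pi)
      w <- bias_weight
      for (k in seq_len(n_steps)) {
        target <- atan2(w * sin(phi) + (1 - w) * sin(prev),
                        w * cos(phi) + (1 - w) * cos(prev))
        th[k] <- target + eps[k]
        prev <- th[k]
      }
      th
    })
  step <- s * dt
  brb_track(id = id,
            t = (0:n_steps) * dt,
            x = start[1L] + c(0, cumsum(step * cos(theta))),
            y = start[2L] + c(0, cumsum(step * sin(theta))),
            p = 1)
}

# cumulative active time at time t for periodic active/rest blocks
.active_time <- function(t, active, rest, offset = 0) {
  period <- active + rest
  tt <- t + offset
  floor(tt / period) * active + pmin(tt %% period, active) -
    (floor(offset / period) * active + pmin(offset %% period, active))
}

#' Subsample a simulated walk like a GPS collar
#'
#' Keeps one fix every `T_R` minutes (the collar's programmed interval),
#' attaches a per-interval activity proportion `p`, and optionally drops
#' retained fixes at random to create doubled recording intervals (emulating
#' occasional GPS failures, which exercise the `T_max` filter).
#'
#' The activity model is either constant (`activity = list(p = 0.8)`) or
#' periodic active/rest blocks (`activity = list(active = 240, rest = 120)`,
#' minutes): the interval's `p` is then the exact fraction of the interval
#' overlapping active blocks.
#'
#' @param track a `brb_track` with equally spaced fixes (e.g. from
#'   [simulate_walk()]).
#' @param T_R recording interval (min); must be a multiple of the track's
#'   step duration.
#' @param activity activity model (see Details); `NULL` keeps `p = 1`.
#' @param dropout probability that an interior retained fix is dropped.
#' @param seed optional integer seed (for the dropout draws).
#' @return A `brb_track` of retained fixes with activity proportions.
#' @export
gps_subsample <- function(track, T_R, activity = NULL, dropout = 0,
                          seed = NULL) {
  stopifnot(inherits(track, "brb_track"), T_R > 0, dropout >= 0, dropout < 1)
  if (!is.null(seed)) set.seed(seed)
  dts <- diff(track$t)
  dt <- dts[1L]
  if (any(abs(dts - dt) > 1e-9))
    stop("gps_subsample() requires equally spaced fixes")
  k <- T_R / dt
  if (abs(k - round(k)) > 1e-9)
    stop("`T_R` must be a multiple of the track's step duration")
  keep <- seq(1L, nrow(track), by = as.integer(round(k)))
  if (dropout > 0 && length(keep) > 2L) {
    interior <- keep[-c(1L, length(keep))]
    drop <- runif(length(interior)) < dropout
    keep <- sort(c(keep[1L], interior[!drop], keep[length(keep)]))
  }
  sub <- track[keep, , drop = FALSE]
  p <- rep(1, nrow(sub))
  if (!is.null(activity)) {
    if (!is.null(activity$p)) {
      p <- rep(activity$p, nrow(sub))
    } else if (!is.null(activity$active)) {
      rest <- if (is.null(activity$rest)) 0 else activity$rest
      at <- .active_time(sub$t - sub$t[1L], activity$active, rest)
      p <- c(1, diff(at) / diff(sub$t))
    } else {
      stop("unrecognized activity model; use list(p = ...) or list(active = , rest = )")
    }
  }
  brb_track(id = sub$id, t = sub$t, x = sub$x, y = sub$y, p = p)
}

#' Endpoint-conditioned walk ensembles
#'
#' Validates the bridge variance model by brute force: walks of duration `T`
#' are simulated from `z0` and kept only when they end within a tolerance
#' radius of `zT` (rejection sampling). For the accepted paths the mean
#' squared deviation `delta^2(t) = ||z(t) - mu_B(t)||^2` from the chord point
#' `mu_B(t) = z0 + (zT - z0) t / T` is accumulated in time bins. For a
#' diffusive walk the profile should be maximal at `t = T/2`, proportional
#' to `T` at its maximum, and follow `4 t/T (1 - t/T)` once normalized by its
#' central value; correlated walks give a more bell-shaped profile.
#'
#' The tolerance is `tol_factor * sqrt(2 D T)` with `D` from
#' [walk_diffusion()]; small factors cost acceptance rate but keep the
#' endpoint pinning tight (the residual `delta^2(T)` is of order `tol^2/2`).
#'
#' @param z0,zT start and target end coordinates (m).
#' @param T walk duration (min); `T / dt` must be an integer.
#' @param dt step duration (min).
#' @param s speed (m/min).
#' @param type walk type (`"brownian"`, `"brw"`, `"crw"`).
#' @param phi preferred direction for `"brw"`.
#' @param c angular concentration in `[0, 1)`.
#' @param tol_factor endpoint tolerance in multiples of `sqrt(2 D T)`.
#' @param n_accept number of accepted paths required.
#' @param n_bins number of time bins over `(0, T)`.
#' @param chunk number of walks simulated per vectorized batch.
#' @param max_walks abort threshold: if this many walks yield an acceptance
#'   rate below 1e-5, stop and suggest a larger tolerance.
#' @param seed optional integer seed.
#' @return An object of class `brb_ensemble`: list with `profile` (data
#'   frame `t, mean_delta_sq, n`), `accepted`, `tried`, `tol`, `D`, `T`.
#' @export
bridge_ensemble <- function(z0, zT, T, dt = 1, s = 10,
                            type = c("brownian", "brw", "crw"),
                            phi = 0, c = 0, tol_factor = 0.2,
                            n_accept = 2000L, n_bins = 12L, chunk = 20000L,
                            max_walks = 5e6, seed = NULL) {
  type <- match.arg(type)
  stopifnot(length(z0) == 2L, length(zT) == 2L, T > 0, dt > 0,
            tol_factor > 0, n_accept >= 1L, n_bins >= 3L)
  if (!is.null(seed)) set.seed(seed)
  n <- round(T / dt)
  if (abs(n * dt - T) > 1e-9) stop("`T` must be a multiple of `dt`")
  D <- walk_diffusion(s, c, dt, type)
  tol <- tol_factor * sqrt(2 * D * T)
  kappa <- kappa_from_c(c)
  step <- s * dt
  tj <- seq_len(n) * dt
  bins <- pmin(n_bins, floor(tj / T * n_bins) + 1L)
  mux <- z0[1L] + (zT[1L] - z0[1L]) * tj / T
  muy <- z0[2L] + (zT[2L] - z0[2L]) * tj / T
  sum_d2 <- numeric(n_bins)
  cnt <- numeric(n_bins)
  accepted <- 0L
  tried <- 0
  while (accepted < n_accept) {
    m <- as.integer(chunk)
    theta <- switch(type,
      brownian = matrix(runif(m * n, -pi, pi), m, n),
      brw = matrix(rvonmises(m * n, phi, kappa), m, n),
      crw = {
        tm <- matrix(rvonmises(m * n, 0, kappa), m, n)
        tm[, 1L] <- runif(m, -pi, pi)
        for (j in 2:n) tm[, j] <- tm[, j - 1L] + tm[, j]
        tm
      })
    dx <- step * cos(theta)
    dy <- step * sin(theta)
    for (j in 2:n) {
      dx[, j] <- dx[, j - 1L] + dx[, j]
      dy[, j] <- dy[, j - 1L] + dy[, j]
    }
    # dx, dy now hold cumulative displacements from z0
    endx <- z0[1L] + dx[, n]
    endy <- z0[2L] + dy[, n]
    ok <- (endx - zT[1L])^2 + (endy - zT[2L])^2 <= tol^2
    tried <- tried + m
    if (any(ok)) {
      take <- which(ok)
      if (accepted + length(take) > n_accept)
        take <- take[seq_len(n_accept - accepted)]
      ex <- dx[take, , drop = FALSE] + z0[1L]
      ey <- dy[take, , drop = FALSE] + z0[2L]
      d2_by_step <- colSums((ex - matrix(mux, length(take), n, byrow = TRUE))^2 +
                            (ey - matrix(muy, length(take), n, byrow = TRUE))^2)
      step_sums <- rowsum(d2_by_step, bins)
      sum_d2[as.integer(rownames(step_sums))] <-
        sum_d2[as.integer(rownames(step_sums))] + step_sums[, 1L]
      step_counts <- rowsum(rep(length(take), n), bins)
      cnt[as.integer(rownames(step_counts))] <-
        cnt[as.integer(rownames(step_counts))] + step_counts[, 1L]
      accepted <- accepted + length(take)
    }
    if (tried >= max_walks && accepted / tried < 1e-5) {
      stop(sprintf(paste0(
        "acceptance rate %.2g after %g walks; enlarge tol_factor (current %g)"),
        accepted / tried, tried, tol_factor))
    }
  }
  centres <- (seq_len(n_bins) - 0.5) * T / n_bins
  structure(list(profile = data.frame(t = centres,
                                      mean_delta_sq = sum_d2 / cnt,
                                      n = cnt),
                 accepted = accepted, tried = tried, tol = tol, D = D, T = T),
            class = "brb_ensemble")
}

#' @export
print.brb_ensemble <- function(x, ...) {
  cat(sprintf(
    "brb_ensemble: %d accepted / %g tried walks (tol %.3g m), T = %g min\n",
    x$accepted, x$tried, x$tol, x$T))
  invisible(x)
}
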