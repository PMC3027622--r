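# Shared fixtures, generated in code.

# straight eastward track: n fixes every T_R minutes, speed v m/min
line_track <- function(n = 4L, T_R = 30, v = 10, p = 1, id = "a1") {
  brb_track(id = id, t = (0:(n - 1L)) * T_R, x = (0:(n - 1L)) * v * T_R,
            y = 0, p = p)
}

# a two-habitat map: code 1 for x < split, code 2 for x >= split
two_habitat_map <- function(xmin = -1e5, ymin = -1e5, cellsize = 1000,
                            ncol = 200L, nrow = 200L, split = 0) {
  g <- grid_spec(xmin, ymin, cellsize, ncol, nrow)
  xs <- xmin + (seq_len(ncol) - 0.5) * cellsize
  codes <- matrix(rep(ifelse(xs < split, 1L, 2L), each = nrow),
                  nrow = nrow, ncol = ncol)
  habitat_map(g, codes)
}

# subsampled Brownian GPS track shared by estimator tests (built once)
brownian_gps <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      tr <- simulate_walk(105000L, dt = 1, s = 10, type = "brownian", seed = 42)
      cache <<- gps_subsample(tr, T_R = 30)
    }
    cache
  }
})

# independent fixed-bandwidth KDE oracle on a grid (plain dnorm sum, with the
# same 4h kernel truncation the estimator documents)
lkde_oracle <- function(x, y, h, grid, trunc = 4) {
  gx <- grid$xmin + (seq_len(grid$ncol) - 0.5) * grid$cellsize
  gy <- grid$ymin + (seq_len(grid$nrow) - 0.5) * grid$cellsize
  vals <- matrix(0, grid$nrow, grid$ncol)
  for (k in seq_along(x)) {
    kern <- outer(dnorm(gy, y[k], h), dnorm(gx, x[k], h))
    d2 <- outer((gy - y[k])^2, (gx - x[k])^2, "+")
    kern[d2 > (trunc * h)^2] <- 0
    vals <- vals + kern
  }
  vals / length(x)
}

grid_xs <- function(grid) grid$xmin + (seq_len(grid$ncol) - 0.5) * grid$cellsize

grid_points <- function(grid) {
  gx <- grid$xmin + (seq_len(grid$ncol) - 0.5) * grid$cellsize
  gy <- grid$ymin + (seq_len(grid$nrow) - 0.5) * grid$cellsize
  cbind(rep(gx, each = grid$nrow), rep(gy, times = grid$ncol))
}
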