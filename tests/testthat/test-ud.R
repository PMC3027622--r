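# Interpolation plan, kernel UD raster, isopleths, raster I/O.

test_that("interpolation divides segments by activity time and keeps h_min at fixes", {
  p <- brb_params(100, 440, 180)
  tr <- brb_track(t = c(0, 30), x = c(0, 30), y = 0)
  seg <- filter_segments(build_segments(tr), T_max = 180)
  plan <- plan_interpolation(seg, p, tau = 10)   # n = 3
  interp <- plan[!plan$recorded, ]
  expect_equal(sort(interp$x), c(10, 20))
  expect_equal(attr(plan, "N_L"), 4L)
  # recorded endpoints get h_min
  expect_equal(plan$h[plan$recorded], c(p$h_min, p$h_min))
  # interior bandwidths follow the smoothing schedule
  expect_equal(sort(interp$h), sort(smoothing_parameter(1:2, 3, 30, p)))
  # 1-min interpolation: n = T_i / tau = 30 intervals
  plan1 <- plan_interpolation(seg, p, tau = 1)
  expect_equal(attr(plan1, "N_L"), 2L + 29L)
})

test_that("contiguous segments share junction fixes exactly once", {
  p <- brb_params(100, 440, 180)
  tr <- line_track(4, T_R = 30, v = 10)
  seg <- filter_segments(build_segments(tr), T_max = 180)
  plan <- plan_interpolation(seg, p, tau = 10)
  # 4 recorded fixes + 2 interior points per segment
  expect_equal(attr(plan, "N_L"), 4L + 3L * 2L)
  expect_equal(sum(plan$recorded), 4L)
})

test_that("interpolation refuses spacings coarser than the bandwidth floor", {
  p <- brb_params(10, 440, 180)   # small h_min
  tr <- brb_track(t = c(0, 30), x = c(0, 3000), y = 0)  # fast segment
  seg <- filter_segments(build_segments(tr), T_max = 180)
  expect_error(plan_interpolation(seg, p, tau = 10), "smaller tau")
  expect_silent(plan_interpolation(seg, p, tau = 0.1))
  # the default tau satisfies the constraint
  plan <- plan_interpolation(seg, p)
  tau <- attr(plan, "tau")
  expect_true(p$h_min > 0.5 * tau * 3000 / 30)
})

test_that("null-diffusion segments are interpolated at the fixed bandwidth", {
  p <- brb_params(100, 440, 180)
  tr <- brb_track(t = c(0, 30), x = c(0, 40), y = 0)
  seg <- filter_segments(build_segments(tr), T_max = 180, L_min = 50,
                         immobile = "keep_null_D")
  plan <- plan_interpolation(seg, p, tau = 10)
  expect_equal(plan$h, rep(p$h_min, nrow(plan)))
})

test_that("the UD raster is a normalized density with little truncation loss", {
  p <- brb_params(50, 100, 120)
  tr <- line_track(6, T_R = 30, v = 15)
  seg <- filter_segments(build_segments(tr), T_max = 120)
  plan <- plan_interpolation(seg, p, tau = 2)
  for (r in c(p$sigma_min / 2, p$sigma_min / 4)) {
    ud <- compute_ud(plan, cellsize = r)
    expect_equal(sum(ud$values) * r^2, 1, tolerance = 1e-9)
    expect_equal(ud$raw_mass, 1, tolerance = 2e-3)
    expect_true(all(ud$values >= 0))
  }
})

test_that("a single kernel reproduces the Gaussian peak on a fine grid", {
  p <- brb_params(100, 440, 180)
  tr <- brb_track(t = c(0, 1), x = c(0, 0), y = c(0, 1e-9))
  seg <- filter_segments(build_segments(tr), 180)
  plan <- plan_interpolation(seg, p, tau = 10)
  grid <- grid_spec(-450, -450, 10, 90, 90)
  ud <- compute_ud(plan, grid)
  centre <- ud$values[45, 45]
  expect_equal(centre, 1 / (2 * pi * 100^2), tolerance = 0.01)
})

test_that("UD mass splits evenly between two identical disjoint bridges", {
  p <- brb_params(20, 10, 60)
  tr <- brb_track(id = c("a", "a", "b", "b"), t = c(0, 30, 0, 30),
                  x = c(0, 100, 5000, 5100), y = 0)
  seg <- filter_segments(build_segments(tr), T_max = 60)
  plan <- plan_interpolation(seg, p, tau = 1)
  ud <- compute_ud(plan, cellsize = 10)
  left <- grid_xs(ud$grid) < 2500
  mass_left <- sum(ud$values[, left]) * ud$grid$cellsize^2
  expect_equal(mass_left, 0.5, tolerance = 1e-6)
})

test_that("a segment with twice the activity time carries twice the mass", {
  p <- brb_params(20, 10, 120)
  tr <- brb_track(id = c("a", "a", "b", "b"), t = c(0, 30, 0, 60),
                  x = c(0, 100, 5000, 5100), y = 0)
  seg <- filter_segments(build_segments(tr), T_max = 120)
  plan <- plan_interpolation(seg, p, tau = 0.5)
  ud <- compute_ud(plan, cellsize = 10)
  left <- grid_xs(ud$grid) < 2500
  mass_left <- sum(ud$values[, left]) * ud$grid$cellsize^2
  expect_equal((1 - mass_left) / mass_left, 2, tolerance = 0.02)
})

test_that("halving tau barely changes a smooth UD (refinement convergence)", {
  p <- brb_params(50, 60, 120)
  tr <- line_track(5, T_R = 30, v = 6)
  seg <- filter_segments(build_segments(tr), T_max = 120)
  ud1 <- compute_ud(plan_interpolation(seg, p, tau = 0.5), cellsize = 25)
  ud2 <- compute_ud(plan_interpolation(seg, p, tau = 0.25), cellsize = 25)
  expect_lt(max(abs(ud1$values - ud2$values)) / max(ud2$values), 0.01)
})

test_that("isopleths count cells by descending density with deterministic ties", {
  g <- grid_spec(0, 0, 10, 10, 10)
  ud <- structure(list(grid = g, values = matrix(1 / (100 * 100), 10, 10),
                       N_L = 1L, raw_mass = 1, normalized = TRUE),
                  class = "brb_ud")
  iso <- isopleths(ud, c(50, 95))
  expect_equal(unname(iso$areas["95"]), 95 * 100)
  expect_equal(unname(iso$areas["50"]), 50 * 100)
  expect_true(all(iso$masks[["50"]] | !iso$masks[["50"]]))
  expect_true(all(iso$masks[["95"]][iso$masks[["50"]]]))  # nesting
  expect_error(isopleths(ud, 0), "levels")
  expect_error(isopleths(ud, 101), "levels")
})

test_that("the 39.35% isopleth of a single Gaussian has radius close to h", {
  p <- brb_params(100, 440, 180)
  tr <- brb_track(t = c(0, 1), x = c(0, 0), y = c(0, 1e-9))
  seg <- filter_segments(build_segments(tr), 180)
  plan <- plan_interpolation(seg, p, tau = 10)
  grid <- grid_spec(-500, -500, 5, 200, 200)
  ud <- compute_ud(plan, grid)
  lev <- 100 * (1 - exp(-0.5))   # mass within 1 sigma of a 2-D Gaussian
  iso <- isopleths(ud, lev)
  r_eff <- sqrt(iso$areas[[1]] / pi)
  expect_lt(abs(r_eff - 100), 5)   # within one cell
})

test_that("ESRI ASCII export round-trips exactly and CSV has one row per cell", {
  p <- brb_params(50, 60, 120)
  seg <- filter_segments(build_segments(line_track(4, v = 5)), T_max = 120)
  ud <- compute_ud(plan_interpolation(seg, p, tau = 5), cellsize = 25)
  f <- tempfile(fileext = ".asc")
  export_ud(ud, f)
  back <- read_ud(f)   # reader is sp::read.asciigrid underneath
  expect_equal(back$values, ud$values, tolerance = 1e-6)
  expect_equal(back$grid$cellsize, ud$grid$cellsize)
  expect_equal(back$grid$xmin, ud$grid$xmin)
  hdr <- readLines(f, n = 6)
  expect_match(hdr[5], paste("cellsize", ud$grid$cellsize))
  fcsv <- tempfile(fileext = ".csv")
  export_ud(ud, fcsv, format = "csv")
  expect_equal(nrow(read.csv(fcsv)), ud$grid$ncol * ud$grid$nrow)
  expect_error(export_ud(ud, tempfile(), format = "geotiff"), "not supported")
})

test_that("with all segments excluded the UD degenerates to a fixed-h_min LKDE", {
  p <- brb_params(60, 100, 20)   # T_max below every recording interval
  tr <- brb_track(t = c(0, 30, 60, 90), x = c(0, 150, 130, 300),
                  y = c(0, 40, 160, 120))
  seg <- filter_segments(build_segments(tr), T_max = 20)
  expect_false(any(seg$included))
  plan <- plan_interpolation(seg, p)
  expect_equal(attr(plan, "N_L"), 4L)
  expect_equal(plan$h, rep(p$h_min, 4L))
  grid <- auto_grid(tr$x, tr$y, cellsize = 20, margin = 4 * p$h_max)
  ud <- compute_ud(plan, grid)
  oracle <- lkde_oracle(tr$x, tr$y, p$h_min, grid)
  oracle <- oracle / (sum(oracle) * grid$cellsize^2)
  expect_lt(max(abs(ud$values - oracle)) / max(oracle), 1e-4)
})
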