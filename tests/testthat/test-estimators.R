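# Diffusion-coefficient and drift-speed estimation.

test_that("diffusion couples honour the dismissal rules", {
  # balanced couple: hand-computed time-weighted chord point and deviation
  tr <- brb_track(t = c(0, 10, 20), x = c(0, 6, 12), y = c(0, 8, 0))
  cpl <- diffusion_couples(build_segments(tr), T_max = 180)
  expect_equal(nrow(cpl), 1L)
  expect_equal(cpl$delta_sq, 64)   # mu_B = (6, 0), z = (6, 8)
  expect_equal(cpl$D_couple, 64 * 20 / (4 * 100))  # 3.2 m^2/min

  # activity-time imbalance T1 < T2/2 dismisses the couple
  tr2 <- brb_track(t = c(0, 30, 100), x = c(0, 6, 12), y = c(0, 8, 0),
                   p = c(1, 1, 1))
  expect_equal(nrow(diffusion_couples(build_segments(tr2), T_max = 180)), 0L)

  # length imbalance L1 > 2 L2 dismisses the couple
  tr3 <- brb_track(t = c(0, 10, 20), x = c(0, 100, 110), y = 0)
  expect_equal(nrow(diffusion_couples(build_segments(tr3), T_max = 180)), 0L)

  # summed recording intervals above T_max dismiss the couple
  tr4 <- brb_track(t = c(0, 100, 200), x = c(0, 6, 12), y = c(0, 8, 0))
  expect_equal(nrow(diffusion_couples(build_segments(tr4), T_max = 180)), 0L)
  expect_equal(nrow(diffusion_couples(build_segments(tr4), T_max = 200)), 1L)

  # a middle fix exactly on the time-weighted chord point gives delta^2 = 0
  tr5 <- brb_track(t = c(0, 10, 30), x = c(0, 10, 30), y = 0)
  cpl5 <- diffusion_couples(build_segments(tr5), T_max = 180)
  expect_equal(cpl5$delta_sq, 0)
})

test_that("couples are never formed across animals or across gaps", {
  tr <- brb_track(id = rep(c("a", "b"), each = 3), t = rep(c(0, 10, 20), 2),
                  x = c(0, 6, 12, 100, 106, 112), y = c(0, 8, 0, 0, 8, 0))
  expect_equal(nrow(diffusion_couples(build_segments(tr), 180)), 2L)
  # removing the shared fix breaks contiguity
  seg <- build_segments(brb_track(t = c(0, 10, 20, 30), x = c(0, 6, 12, 18),
                                  y = c(0, 8, 0, 8)))
  seg_gap <- seg[c(1, 3), ]
  class(seg_gap) <- class(seg)
  expect_equal(nrow(diffusion_couples(seg_gap, 180)), 0L)
})

test_that("estimate_D averages per-couple unbiased ratios", {
  tr <- brb_track(t = c(0, 10, 20), x = c(0, 6, 12), y = c(0, 8, 0))
  cpl <- diffusion_couples(build_segments(tr), 180)
  est <- estimate_D(cpl)
  expect_equal(est$D_hat, 3.2)
  expect_equal(est$N_C, 1L)
  # immobile-but-active: all deviations zero, D = 0
  trz <- brb_track(t = c(0, 10, 20), x = c(0, 10, 20), y = 0)
  expect_equal(estimate_D(diffusion_couples(build_segments(trz), 180))$D_hat, 0)
  # no couples: undefined with a warning
  expect_warning(est0 <- estimate_D(diffusion_couples(
    build_segments(brb_track(t = c(0, 10), x = 0:1, y = 0)), 180)))
  expect_true(is.na(est0$D_hat))
  expect_equal(est0$N_C, 0L)
})

test_that("estimate_D is invariant under translation and rotation", {
  gps <- brownian_gps()
  sub <- gps[1:500, ]
  class(sub) <- class(gps)
  base <- estimate_D(diffusion_couples(build_segments(sub), 180))$D_hat
  th <- 0.7
  rot <- brb_track(id = sub$id,
                   t = sub$t,
                   x = cos(th) * sub$x - sin(th) * sub$y + 1e5,
                   y = sin(th) * sub$x + cos(th) * sub$y - 4e4,
                   p = sub$p)
  moved <- estimate_D(diffusion_couples(build_segments(rot), 180))$D_hat
  expect_equal(moved, base, tolerance = 1e-10)
})

test_that("D is recovered from a Brownian track and per-couple values have unit CV", {
  gps <- brownian_gps()
  cpl <- diffusion_couples(build_segments(gps), T_max = 180)
  expect_gt(nrow(cpl), 2000L)
  est <- estimate_D(cpl)
  D_true <- walk_diffusion(10, 0, 1)   # s^2 dt / 4 = 25 m^2/min
  expect_lt(abs(est$D_hat - D_true) / D_true, 0.10)
  # squared deviations are asymptotically exponential: CV close to 1
  expect_gt(est$cv, 0.8)
  expect_lt(est$cv, 1.2)
  # pooled variant agrees within sampling error
  pooled <- estimate_D(cpl, method = "pooled")
  expect_lt(abs(pooled$D_hat - est$D_hat) / est$D_hat, 0.1)
})

test_that("beta follows sqrt(D T_max / 2) and rounds for display", {
  expect_equal(beta_from_D(440, 180), sqrt(39600))
  expect_equal(beta_display(440, 180), 200)
  expect_equal(beta_display(220, 180), 140)
  expect_equal(beta_display(350, 180), 180)
  expect_equal(beta_from_D(0, 180), 0)
  # monotone in D and in T_max
  expect_true(all(diff(beta_from_D(c(100, 220, 350, 440), 180)) > 0))
  expect_true(all(diff(sapply(c(60, 180, 600), beta_from_D, D = 440)) > 0))
})

test_that("drift speed estimation inverts E(L^2) = v^2 T^2 + 4 D T", {
  seg <- build_segments(brb_track(t = c(0, 10), x = c(0, 100), y = 0))
  dr <- estimate_drift_speeds(seg, D = 5)
  expect_equal(dr$v_sq, (100^2 - 4 * 5 * 10) / 10^2)  # 98
  expect_equal(dr$v, sqrt(98))
  expect_equal(dr$N_H, 1L)
  # pure-diffusion boundary: L^2 = 4 D T gives exactly zero
  L0 <- sqrt(4 * 5 * 10)
  seg0 <- build_segments(brb_track(t = c(0, 10), x = c(0, L0), y = 0))
  expect_equal(estimate_drift_speeds(seg0, D = 5)$v_sq, 0)
  # over-large D: negative v_sq reported as-is, v undefined
  drn <- estimate_drift_speeds(seg, D = 500)
  expect_lt(drn$v_sq, 0)
  expect_true(is.na(drn$v))
})

test_that("habitat-specific estimates stratify and flag empty habitats", {
  gps <- brownian_gps()
  sub <- gps[1:800, ]
  class(sub) <- class(gps)
  seg <- build_segments(sub)
  # one habitat spanning everything: per-habitat D equals global D
  span <- max(abs(c(sub$x, sub$y))) + 1e4
  hab1 <- two_habitat_map(xmin = -span, ymin = -span,
                          cellsize = span / 50, ncol = 100L, nrow = 100L,
                          split = -span)  # all code 2
  per <- estimate_D_by_habitat(seg, hab1, T_max = 180)
  glob <- estimate_D(diffusion_couples(seg, 180))
  expect_equal(per$D_hat[per$habitat == 2], glob$D_hat)
  expect_equal(per$N_C[per$habitat == 2], glob$N_C)
  # a habitat containing no full couple is flagged undefined with N_C = 0
  hab2 <- two_habitat_map(xmin = -span, ymin = -span,
                          cellsize = span / 50, ncol = 100L, nrow = 100L,
                          split = span * 0.9)  # code-2 band holding no data
  per2 <- estimate_D_by_habitat(seg, hab2, T_max = 180)
  expect_true(is.na(per2$D_hat[per2$habitat == 2]))
  expect_equal(per2$N_C[per2$habitat == 2], 0L)
})

test_that("habitat-specific D separates two known diffusion regimes", {
  # two animals confined to opposite half-planes with different speeds
  trA <- simulate_walk(8000, dt = 1, s = sqrt(4 * 50), type = "brownian",
                       start = c(-5e5, 0), id = "A", seed = 101)
  trB <- simulate_walk(8000, dt = 1, s = sqrt(4 * 200), type = "brownian",
                       start = c(5e5, 0), id = "B", seed = 202)
  gA <- gps_subsample(trA, 10)
  gB <- gps_subsample(trB, 10)
  both <- brb_track(id = c(gA$id, gB$id), t = c(gA$t, gB$t),
                    x = c(gA$x, gB$x), y = c(gA$y, gB$y), p = 1)
  seg <- build_segments(both)
  hab <- two_habitat_map(xmin = -1e6, ymin = -1e6, cellsize = 2e4,
                         ncol = 100L, nrow = 100L, split = 0)
  per <- estimate_D_by_habitat(seg, hab, T_max = 30)
  expect_gt(min(per$N_C), 300L)
  expect_lt(abs(per$D_hat[per$habitat == 1] - 50) / 50, 0.15)
  expect_lt(abs(per$D_hat[per$habitat == 2] - 200) / 200, 0.15)
})

test_that("drift speed is recovered for a biased walk", {
  tr <- simulate_walk(30000, dt = 1, s = 10, type = "brw", c = 0.6, seed = 7)
  gps <- gps_subsample(tr, 30)
  seg <- build_segments(gps)
  dr <- estimate_drift_speeds(seg, D = walk_diffusion(10, 0.6, 1, "brw"))
  expect_gt(dr$N_H, 500L)
  expect_lt(abs(dr$v - 6) / 6, 0.10)   # v = s * c
})
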