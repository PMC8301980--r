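# Calibration curves, the waters-per-lipid mapping, sensing inversion,
# breakpoint and hysteresis.

single_curve <- function(branch = "dehydration") {
  build_calibration(
    calibration_points_from_table(default_d_rh_table("single", branch)),
    branch = branch
  )
}

test_that("calibration interpolates knot means exactly", {
  curve <- single_curve()
  expect_equal(as.numeric(predict(curve, 85)), 4.75)
  expect_equal(as.numeric(predict(curve, 0)), 0.25)
  expect_equal(as.numeric(predict(curve, 100)), 5.35)
})

test_that("identical replicates give a zero-width uncertainty band", {
  pts <- calibration_points_from_table(default_d_rh_table(), n_replicates = 2L)
  curve <- build_calibration(pts)
  expect_equal(curve$knots$d_sd, rep(0, nrow(curve$knots)))
  expect_equal(curve$knots$n, rep(2L, nrow(curve$knots)))
})

test_that("replicate scatter is summarized into the band", {
  pts <- data.frame(
    rh_percent = rep(c(0, 50, 100), each = 2),
    d_um2_per_s = c(0.2, 0.3, 1.0, 1.2, 5.0, 5.4)
  )
  curve <- build_calibration(pts)
  expect_equal(curve$knots$d_mean, c(0.25, 1.1, 5.2))
  expect_equal(curve$knots$d_sd,
               c(stats::sd(c(0.2, 0.3)), stats::sd(c(1.0, 1.2)), stats::sd(c(5.0, 5.4))))
})

test_that("a large non-monotone dip rejects the calibration", {
  pts <- data.frame(rh_percent = c(0, 30, 60, 100),
                    d_um2_per_s = c(0.3, 3, 0.5, 5))
  expect_error(build_calibration(pts), class = "hydrasense_calibration_error")
  # fewer than 3 levels also rejected
  expect_error(build_calibration(data.frame(rh_percent = c(0, 100),
                                            d_um2_per_s = c(0.3, 5))),
               class = "hydrasense_calibration_error")
})

test_that("branches are kept separate by the branch column", {
  both <- rbind(
    calibration_points_from_table(default_d_rh_table("single", "dehydration")),
    calibration_points_from_table(default_d_rh_table("single", "rehydration"))
  )
  de <- build_calibration(both, branch = "dehydration")
  re <- build_calibration(both, branch = "rehydration")
  expect_lt(as.numeric(predict(re, 65)), as.numeric(predict(de, 65)))
})

test_that("rh_to_waters reproduces all four anchors exactly", {
  expect_identical(rh_to_waters(25)$waters, 2.4)
  expect_identical(rh_to_waters(50)$waters, 3.6)
  expect_identical(rh_to_waters(75)$waters, 6.3)
  expect_identical(rh_to_waters(95)$waters, 10.5)
})

test_that("rh_to_waters applies the residual-water floor below 25% RH", {
  low <- rh_to_waters(c(0, 10, 24.9))
  expect_true(all(low$floor_applied))
  expect_equal(low$waters, rep(4, 3))
  expect_equal(low$waters_low, rep(3, 3))
  expect_true(all(low$waters <= 4))
})

test_that("rh_to_waters flags the bulk side as a lower bound", {
  hi <- rh_to_waters(100)
  expect_true(hi$extrapolated)
  expect_equal(hi$waters, 10.5)
  expect_true(is.na(hi$waters_high))
})

test_that("rh_to_waters is non-decreasing over the anchored range", {
  rh <- seq(25, 100, by = 0.5)
  w <- rh_to_waters(rh)$waters
  expect_true(all(diff(w) >= 0))
  expect_error(rh_to_waters(-1), class = "hydrasense_domain_error")
  expect_error(rh_to_waters(101), class = "hydrasense_domain_error")
})

test_that("sense inverts knots exactly and matches a grid-scan oracle", {
  curve <- single_curve()
  for (i in seq_len(nrow(curve$knots))) {
    est <- sense(curve$knots$d_fit[i], curve)
    expect_equal(est$rh_estimate, curve$knots$rh[i], tolerance = 1e-3)
  }
  # mid-curve query against an exhaustive 1e4-point grid scan
  d_query <- 2.9
  grid <- seq(0, 100, length.out = 1e4)
  rh_oracle <- grid[which.min(abs(curve$interpolant(grid) - d_query))]
  est <- sense(d_query, curve)
  expect_equal(est$rh_estimate, rh_oracle, tolerance = 0.1)
  expect_false(est$extrapolated)
})

test_that("sense is monotone in d", {
  curve <- single_curve()
  d_grid <- seq(0.26, 5.3, length.out = 40)
  rh <- vapply(d_grid, function(d) sense(d, curve)$rh_estimate, numeric(1))
  expect_true(all(diff(rh) >= 0))
})

test_that("out-of-range D is clamped and flagged, never silent", {
  curve <- single_curve()
  hi <- sense(10, curve)
  expect_true(hi$extrapolated)
  expect_equal(hi$rh_estimate, 100)
  lo <- sense(0.01, curve)
  expect_true(lo$extrapolated)
  expect_equal(lo$rh_estimate, 0)
  expect_true(lo$floor_applied)
})

test_that("a dried phase-separated membrane senses to ~0% RH, <= 4 waters", {
  curve <- build_calibration(
    calibration_points_from_table(default_d_rh_table("phase_separated"))
  )
  est <- sense(0.04, curve)
  expect_lt(est$rh_estimate, 1)
  expect_lte(est$waters_per_lipid, 4)
  expect_true(est$floor_applied)
})

test_that("CI on D propagates to an RH interval containing the point", {
  curve <- single_curve()
  est <- sense(2.0, curve, ci = c(1.6, 2.4))
  expect_lt(est$rh_low, est$rh_estimate)
  expect_gt(est$rh_high, est$rh_estimate)
})

test_that("breakpoint detection: constructed hinge, straight line, profile", {
  # perfect two-segment data hinged at 50
  rh <- c(0, 20, 35, 50, 70, 90, 100)
  d <- ifelse(rh <= 50, 0.3 + 0.002 * rh, 0.4 + 0.09 * (rh - 50))
  hinge <- build_calibration(data.frame(rh_percent = rh, d_um2_per_s = d))
  expect_equal(detect_breakpoint(hinge)$breakpoint_rh, 50)
  # single straight line -> degenerate, flagged
  line <- build_calibration(data.frame(rh_percent = rh,
                                       d_um2_per_s = 0.5 + 0.04 * rh))
  bp <- detect_breakpoint(line)
  expect_true(bp$no_breakpoint)
  expect_true(is.na(bp$breakpoint_rh))
  # the reference single-component profile has its knee near 50% RH
  bp2 <- detect_breakpoint(single_curve())
  expect_false(bp2$no_breakpoint)
  expect_gte(bp2$breakpoint_rh, 45)
  expect_lte(bp2$breakpoint_rh, 55)
  # exhaustive grid-search oracle agrees with the reported minimum
  kn <- single_curve()$knots
  sse <- vapply(seq(2, 99), function(psi) {
    fit <- stats::lm(d_mean ~ rh + pmax(rh - psi, 0), data = kn)
    sum(stats::resid(fit)^2)
  }, numeric(1))
  expect_equal(bp2$breakpoint_rh, seq(2, 99)[which.min(sse)])
  # too few knots
  small <- build_calibration(data.frame(rh_percent = c(0, 50, 100),
                                        d_um2_per_s = c(0.3, 1, 5)))
  expect_error(detect_breakpoint(small), class = "hydrasense_calibration_error")
})

test_that("hysteresis: identical branches are fully reversible", {
  de <- single_curve()
  h <- hysteresis_metric(de, de)
  expect_equal(h$mean_delta, 0)
  expect_equal(unname(h$sign_pattern[["zero"]]), 1)
  expect_true(h$bulk_reversible)
  expect_equal(h$verdict, "fully reversible")
})

test_that("hysteresis: a uniformly slower rehydration branch", {
  tab <- default_d_rh_table()
  tab_low <- transform(tab, d_um2_per_s = 0.9 * d_um2_per_s, branch = "rehydration")
  de <- single_curve()
  re <- build_calibration(calibration_points_from_table(tab_low),
                          branch = "rehydration")
  h <- hysteresis_metric(de, re)
  expect_true(all(h$grid$delta_d > 0))
  expect_equal(mean(h$grid$d_rehydration / h$grid$d_dehydration), 0.9,
               tolerance = 1e-6)
  expect_equal(h$verdict, "not reversible")  # bulk knot is 10% off, zero SD
})

test_that("the default branches show hysteresis resolved at bulk", {
  de <- single_curve("dehydration")
  re <- single_curve("rehydration")
  h <- hysteresis_metric(de, re)
  expect_gt(h$mean_delta, 0)
  expect_true(h$bulk_reversible)   # both branches end at the bulk value
  expect_equal(h$verdict, "reversible with hysteresis")
  expect_error(hysteresis_metric(de, build_calibration(
    data.frame(rh_percent = c(0, 10, 20), d_um2_per_s = c(0.1, 0.2, 0.3)))),
    NA)  # overlapping domains fine
})

test_that("simulated de/re cycle with equilibration lag shows hysteresis", {
  tab <- default_d_rh_table()
  cfg <- frap_sim_config(d_true = 1, noise_sd = 0.005, seed = 31)
  geom <- default_geom()
  levels_de <- c(85, 65, 45, 30, 0)
  levels_re <- rev(levels_de)
  run <- simulate_rh_series(tab, c(levels_de, levels_re), cfg,
                            lag_tau_s = 240, dwell_s = 300)
  d_fit <- vapply(run$traces, function(tr) fit_recovery(tr, geom)$d, numeric(1))
  pts <- data.frame(
    rh_percent = run$rh,
    d_um2_per_s = d_fit,
    branch = rep(c("dehydration", "rehydration"), each = 5)
  )
  de <- build_calibration(pts, "dehydration")
  re <- build_calibration(pts, "rehydration")
  h <- hysteresis_metric(de, re)
  expect_gt(h$mean_delta, 0)   # rehydrating membrane lags drier -> lower D
})

test_that("curve JSON round-trips knots, band and branch", {
  pts <- data.frame(
    rh_percent = rep(c(0, 40, 70, 100), each = 2),
    d_um2_per_s = c(0.2, 0.3, 0.9, 1.1, 3.0, 3.2, 5.2, 5.4)
  )
  curve <- build_calibration(pts)
  path <- withr::local_tempfile(fileext = ".json")
  write_curve_json(curve, path)
  back <- read_curve_json(path)
  expect_equal(back$knots$d_mean, curve$knots$d_mean)
  expect_equal(back$knots$d_sd, curve$knots$d_sd)
  expect_identical(back$branch, curve$branch)
  expect_equal(as.numeric(predict(back, 55)), as.numeric(predict(curve, 55)),
               tolerance = 1e-10)
})

test_that("round trip through the full curve: sense(D(rh)) returns rh", {
  curve <- single_curve()
  for (rh in c(5, 22, 47, 63, 88, 97)) {
    d <- as.numeric(predict(curve, rh))
    expect_equal(sense(d, curve)$rh_estimate, rh, tolerance = 1e-3)
  }
})
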