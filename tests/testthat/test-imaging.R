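# Trace extraction and double normalization from image stacks.

make_stack <- function(roi_means, n = 32L, roi_radius = 6) {
  # uniform frames whose ROI (and field) mean equals roi_means[i]
  frames <- array(0, dim = c(length(roi_means), n, n))
  for (i in seq_along(roi_means)) frames[i, , ] <- roi_means[i]
  frap_stack(frames, pixel_size = 1, frame_interval = 0.5,
             bleach_frame_index = 2L, roi_center = c(n / 2 + 0.5, n / 2 + 0.5),
             roi_radius = roi_radius)
}

test_that("detect_bleach_frame finds a constructed drop", {
  st <- make_stack(c(1, 1, 1, 1, 0.2, 0.3, 0.35, 0.4, 0.42, 0.45))
  expect_identical(detect_bleach_frame(st), 5L)
})

test_that("detect_bleach_frame rejects a constant stack", {
  st <- make_stack(rep(1, 10))
  expect_error(detect_bleach_frame(st), class = "hydrasense_no_bleach_error")
})

test_that("detect_bleach_frame recovers the simulator's ground truth", {
  sim <- simulate_stack(frap_sim_config(d_true = 1, n_frames = 30L,
                                        n_prebleach = 5L, grid_size = 64L,
                                        seed = 3))
  expect_identical(detect_bleach_frame(sim$stack), 6L)
})

test_that("extraction is the plain ROI mean", {
  st <- make_stack(rep(7, 5))
  tr <- extract_trace(st, "roi")
  expect_equal(tr$intensity, rep(7, 5))
  # value 1 inside ROI, 0 outside
  n <- 32L
  frames <- array(0, dim = c(3, n, n))
  mask <- outer((1:n - 16.5)^2, (1:n - 16.5)^2, `+`) <= 36
  for (i in 1:3) frames[i, , ][mask] <- 1
  st2 <- frap_stack(frames, 1, 0.5, 2L, c(16.5, 16.5), 6)
  expect_equal(extract_trace(st2, "roi")$intensity, rep(1, 3))
  expect_equal(extract_trace(st2, "reference")$intensity, rep(0, 3))
})

test_that("extraction matches a brute-force pixel loop on simulated data", {
  sim <- simulate_stack(frap_sim_config(d_true = 2, n_frames = 10L,
                                        grid_size = 64L, seed = 5))
  st <- sim$stack
  tr <- extract_trace(st, "roi")
  for (i in c(1L, 6L, 15L)) {
    expect_equal(tr$intensity[i],
                 pixel_loop_roi_mean(st$frames[i, , ], st$roi_center, st$roi_radius),
                 tolerance = 1e-12)
  }
})

test_that("times follow the mid-exposure convention around the bleach", {
  st <- make_stack(c(1, 1, 0.2, 0.4), roi_radius = 6)
  st$bleach_frame_index <- 3L
  tr <- extract_trace(st, "roi")
  expect_equal(tr$time_s, c(-0.75, -0.25, 0.25, 0.75))
})

test_that("normalization: identity, proportionality, idempotence", {
  t <- data.frame(frame = 1:6, time_s = c(-0.75, -0.25, 0.25, 0.75, 1.25, 1.75),
                  intensity = c(1, 1, 0.4, 0.5, 0.6, 0.7))
  ref_flat <- transform(t, intensity = 1)
  # roi == reference at all frames -> constant 1
  same <- normalize_trace(ref_flat, ref_flat, prebleach_frames = 2L)
  expect_equal(same$intensity_norm, rep(1, 4))
  # roi halves while reference constant -> trace halves
  halves <- transform(t, intensity = c(1, 1, 0.5, 0.5, 0.5, 0.5))
  nh <- normalize_trace(halves, ref_flat, prebleach_frames = 2L)
  expect_equal(nh$intensity_norm, rep(0.5, 4))
  # normalizing an already normalized trace (reference == 1) is identity
  once <- normalize_trace(t, ref_flat, prebleach_frames = 2L)
  again <- normalize_trace(
    data.frame(frame = 1:6, time_s = t$time_s,
               intensity = c(1, 1, once$intensity_norm)),
    ref_flat, prebleach_frames = 2L
  )
  expect_equal(again$intensity_norm, once$intensity_norm)
  # zero reference is an error
  ref_zero <- transform(t, intensity = c(1, 1, 0, 1, 1, 1))
  expect_error(normalize_trace(t, ref_zero, 2L), class = "hydrasense_stack_error")
})

test_that("double normalization cancels acquisition photobleaching", {
  cfg_clean <- frap_sim_config(d_true = 2, n_frames = 40L, grid_size = 64L,
                               noise_sd = 0, seed = 9)
  cfg_bleach <- frap_sim_config(d_true = 2, n_frames = 40L, grid_size = 64L,
                                noise_sd = 0, acquisition_bleach_rate = 0.02,
                                seed = 9)
  tr_clean <- stack_to_trace(simulate_stack(cfg_clean)$stack)
  tr_bleach <- stack_to_trace(simulate_stack(cfg_bleach)$stack)
  expect_equal(tr_bleach$intensity_norm, tr_clean$intensity_norm, tolerance = 1e-8)
})

test_that("stack pipeline recovers D through fit_recovery", {
  geom <- default_geom()
  # at the phase-separated fully hydrated value the pipeline is within 5%
  sim <- simulate_stack(frap_sim_config(d_true = 1.66, seed = 21))
  fit <- fit_recovery(stack_to_trace(sim$stack), geom)
  expect_equal(fit$d, 1.66, tolerance = 0.05)
  # across the hydrated range the conservative envelope is 10%: the
  # reference region dips while the bleached deficit diffuses through it,
  # which biases the double-normalized trace (see the methods vignette)
  for (d_true in c(0.25, 5.35)) {
    sim <- simulate_stack(frap_sim_config(d_true = d_true, seed = 22))
    fit <- fit_recovery(stack_to_trace(sim$stack), geom)
    expect_equal(fit$d, d_true, tolerance = 0.10)
  }
})

test_that("TIFF + sidecar round-trip preserves the stack", {
  sim <- simulate_stack(frap_sim_config(d_true = 1, n_frames = 6L,
                                        n_prebleach = 2L, grid_size = 32L,
                                        seed = 2))
  dir <- withr::local_tempdir()
  path <- file.path(dir, "stack.tif")
  write_frap_tiff(sim$stack, path)
  back <- read_frap_tiff(path)
  expect_equal(dim(back$frames), dim(sim$stack$frames))
  expect_equal(back$frames, sim$stack$frames, tolerance = 2e-4)  # 16-bit quantization
  expect_identical(back$bleach_frame_index, sim$stack$bleach_frame_index)
  expect_equal(back$roi_radius, sim$stack$roi_radius)
  expect_equal(back$pixel_size, sim$stack$pixel_size)
})

test_that("stack validation rejects out-of-frame ROIs and bad indices", {
  frames <- array(1, dim = c(3, 16, 16))
  expect_error(frap_stack(frames, 1, 0.5, 1L, c(8, 8), 4),
               class = "hydrasense_stack_error")
  expect_error(frap_stack(frames, 1, 0.5, 2L, c(2, 2), 4),
               class = "hydrasense_stack_error")
  frames[1, 1, 1] <- -1
  expect_error(frap_stack(frames, 1, 0.5, 2L, c(8, 8), 4),
               class = "hydrasense_stack_error")
})
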