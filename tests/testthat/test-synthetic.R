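test_that("cluster placement is seed-deterministic", {
  f <- emitter_field(n_clusters = 10, emitters_per_cluster = 20)
  a <- place_clusters(f, seed = 42)
  b <- place_clusters(f, seed = 42)
  expect_identical(a, b)
  c <- place_clusters(f, seed = 43)
  expect_false(identical(a$emitters, c$emitters))
})

test_that("a single emitter sits at the cluster center with zero realized Rg", {
  f <- emitter_field(field_size_nm = c(2000, 2000), n_clusters = 1,
                     emitters_per_cluster = 1, shape = "gaussian",
                     target_rg_nm = 0.001,
                     cluster_centers = matrix(c(1000, 1000), 1),
                     n_fiducials = 0, n_nuclei = 0)
  p <- place_clusters(f, seed = 1)
  expect_equal(p$clusters$realized_rg_nm, 0)
  expect_equal(p$emitters$x_nm, 1000, tolerance = 1e-2)
})

test_that("realized Rg converges to the target for disk and Gaussian shapes", {
  # uniform disk of radius R has Rg = R / sqrt(2); target 100/sqrt(2)
  f <- emitter_field(field_size_nm = c(4000, 4000), n_clusters = 1,
                     shape = "disk", emitters_per_cluster = 10000,
                     target_rg_nm = 100 / sqrt(2),
                     cluster_centers = matrix(c(2000, 2000), 1),
                     n_fiducials = 0, n_nuclei = 0)
  p <- place_clusters(f, seed = 7)
  expect_equal(p$clusters$realized_rg_nm, 100 / sqrt(2), tolerance = 0.02)
  expect_lt(max(sqrt((p$emitters$x_nm - 2000)^2 +
                     (p$emitters$y_nm - 2000)^2)), 100 + 1e-9)

  for (shape in c("gaussian", "gaussian_aniso")) {
    fg <- emitter_field(field_size_nm = c(4000, 4000), n_clusters = 1,
                        shape = shape, emitters_per_cluster = 10000,
                        target_rg_nm = 68,
                        cluster_centers = matrix(c(2000, 2000), 1),
                        n_fiducials = 0, n_nuclei = 0)
    pg <- place_clusters(fg, seed = 11)
    expect_equal(pg$clusters$realized_rg_nm, 68, tolerance = 0.02)
  }
})

test_that("emitters spilling outside the field raise an error naming the cluster", {
  f <- emitter_field(field_size_nm = c(1000, 1000), n_clusters = 1,
                     shape = "gaussian", emitters_per_cluster = 500,
                     target_rg_nm = 600,
                     cluster_centers = matrix(c(500, 500), 1),
                     n_fiducials = 0, n_nuclei = 0)
  expect_error(place_clusters(f, seed = 1), "cluster 1")
})

test_that("noise-free, drift-free localizations equal the ground truth exactly", {
  em <- data.frame(x_nm = c(500, 900), y_nm = c(700, 300))
  sim <- simulate_localizations(em, always_on(100), drift_model("none"),
                                precision_mean_nm = 0, seed = 3)
  expect_equal(nrow(sim$locs), 200)
  expect_identical(sim$locs$x_nm, sim$truth$true_x_nm)
  expect_identical(sim$locs$y_nm, sim$truth$true_y_nm)
  expect_true(all(sim$locs$precision_nm == 0))
  expect_true(!is.unsorted(sim$locs$frame))
})

test_that("linear drift moves an always-on emitter by its magnitude", {
  em <- data.frame(x_nm = 5000, y_nm = 5000)
  sim <- simulate_localizations(em, always_on(2000),
                                drift_model("linear", 100),
                                precision_mean_nm = 0, seed = 5)
  first <- sim$locs[sim$locs$frame == 1, ]
  last <- sim$locs[sim$locs$frame == 2000, ]
  expect_equal(last$x_nm - first$x_nm, 100, tolerance = 1e-9)
  expect_equal(last$y_nm - first$y_nm, 0, tolerance = 1e-9)
})

test_that("drift model none gives exactly zero and drift is defined per frame", {
  d <- simulate_drift(drift_model("none"), 500)
  expect_identical(d$frame, 1:500)
  expect_true(all(d$dx_nm == 0 & d$dy_nm == 0))
  d2 <- simulate_drift(drift_model("smooth-random", 150), 500, seed = 2)
  expect_equal(nrow(d2), 500)
  expect_equal(c(d2$dx_nm[1], d2$dy_nm[1]), c(0, 0))
  expect_equal(max(sqrt(d2$dx_nm^2 + d2$dy_nm^2)), 150, tolerance = 1e-9)
})

test_that("empirical localization error matches the drawn precisions", {
  em <- data.frame(x_nm = 5000, y_nm = 5000)
  sim <- simulate_localizations(em, always_on(10000), drift_model("none"),
                                precision_mean_nm = 10, seed = 8)
  rms <- sqrt(mean((sim$locs$x_nm - sim$truth$true_x_nm)^2 +
                   (sim$locs$y_nm - sim$truth$true_y_nm)^2) / 2)
  expect_equal(rms, sqrt(mean(sim$locs$precision_nm^2)), tolerance = 0.05)
  expect_equal(mean(sim$locs$precision_nm), 10, tolerance = 0.05)
})

test_that("simulated off-times follow the configured two-component mixture", {
  blink <- blink_model(frames_total = 5000)
  em <- data.frame(x_nm = runif(4000, 0, 10000), y_nm = runif(4000, 0, 10000))
  sim <- simulate_localizations(em, blink, drift_model("none"),
                                precision_mean_nm = 0, seed = 21)
  off <- sim$off_times
  expect_gt(length(off), 10000)
  breaks <- c(1:10, 20, 50, 100, 200, 400, 800, Inf)
  obs <- table(cut(off, c(0, breaks)))
  p <- vapply(seq_along(breaks), function(i) {
    lo <- if (i == 1) 1 else breaks[i - 1] + 1
    hi <- min(breaks[i], 50000)
    sum(off_time_pmf(lo:hi, blink))
  }, numeric(1))
  gof <- suppressWarnings(stats::chisq.test(as.integer(obs), p = p,
                                            rescale.p = TRUE))
  expect_gt(gof$p.value, 0.01)
})

test_that("localization simulation is seed-deterministic", {
  f <- emitter_field(n_clusters = 5, emitters_per_cluster = 10,
                     n_fiducials = 1)
  p <- place_clusters(f, seed = 2)
  blink <- blink_model(frames_total = 500)
  a <- simulate_localizations(p, blink, drift_model("smooth-random", 50),
                              seed = 9)
  b <- simulate_localizations(p, blink, drift_model("smooth-random", 50),
                              seed = 9)
  expect_identical(a, b)
})

test_that("fiducials emit exactly one localization per frame", {
  f <- emitter_field(field_size_nm = c(10000, 10000), n_clusters = 1,
                     emitters_per_cluster = 1, target_rg_nm = 10,
                     cluster_centers = matrix(c(1000, 1000), 1),
                     fiducial_positions = cbind(c(4400, 7700), c(5500, 2200)),
                     n_nuclei = 0)
  p <- place_clusters(f, seed = 1)
  sim <- simulate_localizations(p, blink_model(frames_total = 300),
                                drift_model("none"), seed = 4)
  fid <- sim$locs[sim$locs$true_cluster_id < 0, ]
  expect_equal(nrow(fid), 600)
  expect_true(all(table(fid$true_cluster_id, fid$frame) == 1))
})

test_that("widefield rendering places the maximum at the spot and conserves the empty case", {
  img <- render_widefield(matrix(c(5000, 5000), 1), c(10000, 10000),
                          poisson_noise = FALSE)
  pk <- which(img == max(img), arr.ind = TRUE)
  # pixel containing (5000, 5000) at 108-nm pixels is floor(5000/108)+1 = 47
  expect_equal(unname(pk[1, ]), c(47, 47))

  bg <- render_widefield(matrix(numeric(0), 0, 2), c(10000, 10000),
                         background_adu = 100, seed = 6)
  expect_equal(mean(bg), 100, tolerance = 3 * 10 / sqrt(length(bg)) / 100)
})

test_that("well-separated clusters give one wide-field peak each", {
  centers <- cbind(c(3000, 9000, 15000), c(4000, 12000, 6000))
  img <- render_widefield(centers, c(18000, 18000), poisson_noise = FALSE)
  pk <- detect_peaks(img, threshold = 50)
  expect_equal(nrow(pk), 3)
})

test_that("the DDR channel only shows DDR-positive clusters", {
  f <- emitter_field(field_size_nm = c(20000, 20000), n_clusters = 4,
                     emitters_per_cluster = 5, target_rg_nm = 60,
                     cluster_centers = cbind(c(4000, 8000, 12000, 16000),
                                             rep(10000, 4)),
                     ddr_positive = c(2, 4), n_fiducials = 0, n_nuclei = 0)
  sim <- simulate_fov(f, blink_model(frames_total = 50),
                      drift_model("none"), channel_offset_nm = c(0, 0),
                      seed = 3)
  pk <- detect_peaks(sim$ddr_widefield, threshold = 100, large_sigma_px = 4)
  expect_equal(nrow(pk), 2)
  # peaks at x of clusters 2 and 4
  expect_equal(sort(pk$col), floor(c(8000, 16000) / 108) + 1, tolerance = 1)

  # empty DDR set renders pure background
  f0 <- emitter_field(field_size_nm = c(20000, 20000), n_clusters = 2,
                      emitters_per_cluster = 5, target_rg_nm = 60,
                      cluster_centers = cbind(c(4000, 8000), c(5000, 5000)),
                      ddr_positive = logical(2), n_fiducials = 0, n_nuclei = 0)
  sim0 <- simulate_fov(f0, blink_model(frames_total = 50),
                       drift_model("none"), seed = 3)
  expect_lt(abs(mean(sim0$ddr_widefield) - 100),
            3 * 10 / sqrt(length(sim0$ddr_widefield)))
})

test_that("localization tables round-trip through CSV", {
  sim <- simulate_localizations(data.frame(x_nm = 100, y_nm = 200),
                                always_on(20), drift_model("none"), seed = 1)
  path <- tempfile(fileext = ".csv")
  write_localizations(sim$locs, path)
  back <- read_localizations(path)
  expect_equal(back$x_nm, sim$locs$x_nm)
  expect_equal(back$frame, sim$locs$frame)
})
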