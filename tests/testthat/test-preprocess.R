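test_that("fiducial search keeps always-on beads and rejects blinkers", {
  frames <- 2000
  # one always-on bead: one localization per frame
  bead <- loc_table(1:frames, rnorm(frames, 5500, 5), rnorm(frames, 5500, 5))
  tr <- find_fiducials(bead, frames)
  expect_length(tr, 1)
  expect_equal(tr[[1]]$bin_origin_nm, c(5000, 5000))
  expect_length(tr[[1]]$frames, frames)

  # blinking emitters at 1% duty cycle never reach the count threshold
  blinkers <- loc_table(sort(sample(frames, 60, replace = TRUE)),
                        rnorm(60, 3500, 5), rnorm(60, 3500, 5))
  expect_length(find_fiducials(blinkers, frames), 0)

  # two beads 5 um apart give two tracks with the right bin origins
  two <- rbind(bead,
               loc_table(1:frames, rnorm(frames, 10500, 5),
                         rnorm(frames, 5500, 5)))
  tr2 <- find_fiducials(two, frames)
  expect_length(tr2, 2)
  origins <- sort(vapply(tr2, function(t) t$bin_origin_nm[1], numeric(1)))
  expect_equal(origins, c(5000, 10000))
})

test_that("drift spline reproduces a linear track and suppresses jitter", {
  frames <- 1:4000
  lin <- loc_table(frames, 1000 + 0.01 * frames, 2000 - 0.005 * frames)
  tr <- find_fiducials(lin, 4000, bin_size_um = 2)[[1]]
  s <- fit_drift_spline(tr)
  expect_equal(s$x_nm, 1000 + 0.01 * frames, tolerance = 0.1 / 1000)
  expect_lt(max(abs(s$y_nm - (2000 - 0.005 * frames))), 0.1)

  set.seed(3)
  noisy <- loc_table(frames, 1000 + 0.01 * frames + rnorm(4000, 0, 10),
                     2500 + rnorm(4000, 0, 10))
  trn <- find_fiducials(noisy, 4000, bin_size_um = 2)[[1]]
  sn <- fit_drift_spline(trn)
  expect_lt(sqrt(mean((sn$x_nm - (1000 + 0.01 * frames))^2)), 3)
  expect_lt(sqrt(mean((sn$y_nm - 2500)^2)), 3)
})

test_that("too-short fiducial tracks are rejected with the frame count", {
  short <- loc_table(1:1000, rnorm(1000, 500, 5), rnorm(1000, 500, 5))
  tr <- find_fiducials(short, 1000)[[1]]
  expect_error(fit_drift_spline(tr), "1000 frames")
})

test_that("drift averaging re-zeroes tracks and cancels opposite noise", {
  frames <- 1:4000
  drift_x <- 50 * sin(frames / 1500)
  noise <- rep(c(2, -2), 2000)
  t1 <- find_fiducials(loc_table(frames, 2500 + drift_x + noise, 2500),
                       4000, bin_size_um = 2)[[1]]
  t2 <- find_fiducials(loc_table(frames, 2500 + drift_x - noise, 2500),
                       4000, bin_size_um = 2)[[1]]
  # identical injected drift, equal-and-opposite noise: average matches truth
  d <- build_drift(list(t1, t2), 4000)
  expect_equal(attr(d, "n_fiducials"), 2)
  expect_lt(max(abs(d$dx_nm - (drift_x - drift_x[1]))), 0.5)
  expect_lt(max(abs(d$dy_nm)), 1e-6)
  # absolute bead positions cancel: two tracks at different positions with
  # the same drift give the same trajectory
  t3 <- find_fiducials(loc_table(frames, 8500 + drift_x, 8500),
                       4000, bin_size_um = 2)[[1]]
  d3 <- build_drift(list(t1, t3), 4000)
  expect_equal(d3$dx_nm, d$dx_nm, tolerance = 0.1)
})

test_that("a FOV without usable fiducials is discarded with a typed error", {
  err <- tryCatch(build_drift(list(), 1000), condition = identity)
  expect_s3_class(err, "telostorm_no_fiducials")
})

test_that("drift application is an exact identity for zero drift and invertible", {
  locs <- loc_table(c(1, 5, 9), c(100, 200, 300), c(400, 500, 600))
  zero <- data.frame(frame = 1:10, dx_nm = 0, dy_nm = 0)
  expect_identical(apply_drift(locs, zero), locs)

  set.seed(8)
  d <- data.frame(frame = 1:10, dx_nm = rnorm(10, 0, 30),
                  dy_nm = rnorm(10, 0, 30))
  roundtrip <- apply_drift(apply_drift(locs, d), d, undo = TRUE)
  expect_equal(roundtrip, locs, tolerance = 1e-12)

  outside <- loc_table(11, 1, 1)
  expect_error(apply_drift(outside, d), "cover frame")
})

test_that("end-to-end drift correction recovers an injected trajectory", {
  frames_total <- 4000
  f <- emitter_field(field_size_nm = c(20000, 20000), n_clusters = 1,
                     emitters_per_cluster = 1, target_rg_nm = 10,
                     cluster_centers = matrix(c(600, 600), 1),
                     fiducial_positions = cbind(c(5500, 15300),
                                                c(5400, 14600)),
                     n_nuclei = 0)
  p <- place_clusters(f, seed = 1)
  sim <- simulate_localizations(p, blink_model(frames_total = frames_total),
                                drift_model("smooth-random", 150),
                                precision_mean_nm = 10,
                                fiducial_precision_nm = 10, seed = 31)
  tracks <- find_fiducials(sim$locs, frames_total)
  expect_length(tracks, 2)
  drift <- build_drift(tracks, frames_total)
  rms <- sqrt(mean((drift$dx_nm - sim$drift$dx_nm)^2 +
                   (drift$dy_nm - sim$drift$dy_nm)^2))
  expect_lt(rms, 5)
  # corrected fiducials are stationary to ~the localization noise
  corr <- apply_drift(sim$locs, drift)
  for (t in tracks) {
    expect_lt(sd(corr$x_nm[t$idx]), 12)
    expect_lt(sd(corr$y_nm[t$idx]), 12)
  }
})

test_that("quality filtering uses strict thresholds and tallies rejections", {
  locs <- loc_table(1:5, 1:5, 1:5,
                    precision = c(35, 30, 10, 10, 10),
                    sigma = c(150, 175, 150, 176, 150),
                    loglike = c(100, 250, 300, 100, 100))
  res <- filter_localizations(locs)
  # row 1 fails precision, row 3 loglike, row 4 sigma; boundary row 2 kept
  expect_equal(res$locs$frame, c(2, 5))
  expect_equal(res$rejected,
               c(precision = 1, loglike = 1, sigma = 1, total = 3))

  expect_error(filter_localizations(locs[, setdiff(names(locs), "loglike")]),
               "loglike")
})

test_that("loosening any filter threshold never reduces the retained count", {
  set.seed(12)
  locs <- loc_table(1:500, runif(500), runif(500),
                    precision = rgamma(500, 4, scale = 5),
                    sigma = rnorm(500, 150, 20),
                    loglike = rgamma(500, 4, scale = 50))
  base <- filter_params()
  n0 <- nrow(filter_localizations(locs, base)$locs)
  for (loose in list(filter_params(max_precision_nm = 60),
                     filter_params(max_loglike = 500),
                     filter_params(max_sigma_nm = 250))) {
    expect_gte(nrow(filter_localizations(locs, loose)$locs), n0)
  }
})

test_that("blink merging collapses tracks, honours gaps, and conserves photons", {
  # 3 consecutive-frame localizations within 5 nm merge into one
  tight <- loc_table(1:3, c(100, 102, 99), c(200, 201, 198),
                     precision = c(10, 10, 10), photons = c(500, 600, 700))
  m <- merge_localizations(tight)
  expect_equal(nrow(m), 1)
  expect_equal(m$photons, 1800)
  expect_equal(m$frame, 1)
  expect_equal(m$n_merged, 3)
  expect_equal(m$x_nm, mean(c(100, 102, 99)))  # equal precisions
  expect_equal(m$precision_nm, 10 / sqrt(3))

  # two dark frames between events exceed the one-frame gap: no merging
  gapped <- tight
  gapped$frame <- c(1, 4, 7)
  expect_equal(nrow(merge_localizations(gapped)), 3)
  # exactly one dark frame still merges
  onegap <- tight
  onegap$frame <- c(1, 3, 5)
  expect_equal(nrow(merge_localizations(onegap)), 1)

  # singleton passes through (up to the merge bookkeeping column)
  single <- loc_table(7, 123, 456)
  ms <- merge_localizations(single)
  expect_equal(ms$n_merged, 1)
  expect_equal(ms[names(single)], single, tolerance = 1e-12)
})

test_that("merging with radius zero is the identity and never grows the table", {
  set.seed(4)
  locs <- loc_table(sort(sample(50, 200, replace = TRUE)),
                    runif(200, 0, 1000), runif(200, 0, 1000))
  m0 <- merge_localizations(locs, radius_nm = 0)
  expect_equal(m0[names(locs)], locs, tolerance = 1e-12,
               ignore_attr = "row.names")
  m <- merge_localizations(locs, radius_nm = 30)
  expect_lte(nrow(m), nrow(locs))
  expect_equal(sum(m$photons), sum(locs$photons))
  expect_equal(sum(m$n_merged), nrow(locs))
  expect_error(merge_localizations(locs, radius_nm = -1), "non-negative")
})

test_that("merged positions use inverse-variance weighting", {
  two <- loc_table(1:2, c(0, 10), c(0, 0), precision = c(1, 3))
  m <- merge_localizations(two)
  w <- c(1, 1 / 9) / sum(c(1, 1 / 9))
  expect_equal(m$x_nm, sum(w * c(0, 10)))
  expect_equal(m$precision_nm, sqrt(1 / (1 + 1 / 9)))
})
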