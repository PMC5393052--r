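test_that("histograms conserve counts and use half-open bins", {
  one <- loc_table(1, 5, 5)
  h <- render_histogram(one, bin_nm = 22)
  expect_equal(sum(h), 1)
  expect_equal(h[1, 1], 1L)

  set.seed(6)
  many <- loc_table(1:500, runif(500, 0, 5000), runif(500, 0, 5000))
  expect_equal(sum(render_histogram(many, 22)), 500)

  # a localization exactly on a bin boundary goes to the higher bin
  edge <- loc_table(1, 22, 44)
  he <- render_histogram(edge, 22, dims = c(4, 4))
  expect_equal(which(he == 1, arr.ind = TRUE)[1, ], c(row = 3, col = 2))

  expect_error(render_histogram(loc_table(integer(0), numeric(0),
                                          numeric(0))), "empty")
})

test_that("nearest-neighbour upsampling replicates pixels", {
  m <- matrix(1:4, 2)
  u <- upsample_nn(m, 3)
  expect_equal(dim(u), c(6, 6))
  expect_true(all(u[1:3, 1:3] == 1))
  expect_equal(upsample_nn(m, 1), m)
})

test_that("zero shift gives zero offset; integer-bin shifts are recovered exactly", {
  set.seed(4)
  locs <- loc_table(1:2000, runif(2000, 0, 20000), runif(2000, 0, 20000))
  h <- render_histogram(locs, 22, dims = c(1024, 1024))

  same <- h
  attr(same, "pixel_size_nm") <- 22
  o0 <- estimate_offset(h, same, params = register_params(upsample_factor = 1))
  expect_equal(as.vector(o0), c(0, 0))

  # +3 bins in x, +2 bins in y (66 and 44 nm)
  shifted <- matrix(0, 1024, 1024)
  shifted[3:1024, 4:1024] <- h[1:1022, 1:1021]
  attr(shifted, "pixel_size_nm") <- 22
  o <- estimate_offset(h, shifted,
                       params = register_params(upsample_factor = 1))
  expect_equal(as.vector(o), c(66, 44))
})

test_that("the sign convention aligns localizations with the wide-field image", {
  set.seed(19)
  pos <- cbind(runif(60, 2000, 18000), runif(60, 2000, 18000))
  locs <- loc_table(seq_len(nrow(pos)), pos[, 1], pos[, 2])
  true_off <- c(55, -44)
  wf <- render_widefield(pos, c(20000, 20000), pixel_size_nm = 110,
                         offset_nm = true_off, poisson_noise = FALSE)
  off <- estimate_offset(locs, wf, params = register_params())
  expect_lt(max(abs(off - true_off)), 22 + 1e-9)
  # adding the offset moves localizations onto bright wide-field pixels
  px <- cbind(pmin(floor((locs$y_nm + off[2]) / 110) + 1, nrow(wf)),
              pmin(floor((locs$x_nm + off[1]) / 110) + 1, ncol(wf)))
  expect_gt(mean(wf[px]), mean(wf) * 2)
})

test_that("offset estimation rejects an empty histogram", {
  img <- matrix(1, 64, 64)
  attr(img, "pixel_size_nm") <- 22
  h <- matrix(0L, 64, 64)
  attr(h, "bin_nm") <- 22
  expect_error(estimate_offset(h, img,
                               params = register_params(upsample_factor = 1)),
               "empty")
})

test_that("automated QC keeps self-consistent clusters and rejects misplaced ones", {
  set.seed(23)
  # three clusters; wide-field rendered from the first two only
  centers <- rbind(c(5000, 5000), c(12000, 11000), c(16000, 3000))
  pts <- do.call(rbind, lapply(1:3, function(i)
    cbind(rnorm(80, centers[i, 1], 50), rnorm(80, centers[i, 2], 50))))
  locs <- loc_table(seq_len(240), pts[, 1], pts[, 2])
  clusters <- list(1:80, 81:160, 161:240)
  wf <- render_widefield(centers[1:2, ], c(20000, 20000),
                         poisson_noise = FALSE)
  mask <- matrix(TRUE, nrow(wf), ncol(wf))
  mask[, floor(14000 / 108):ncol(wf)] <- FALSE  # cluster 3 outside "nucleus"
  qc <- qc_clusters(clusters, locs, wf, mask = mask)
  expect_equal(qc$qc_status, c("kept", "kept", "rejected"))
  expect_equal(qc$qc_fail[3], "locus")  # on background, fails criterion 1

  # same background cluster inside a locus but outside the mask
  mask2 <- matrix(FALSE, nrow(wf), ncol(wf))
  mask2[, seq_len(floor(9000 / 108))] <- TRUE
  qc2 <- qc_clusters(clusters[1:2], locs, wf, mask = mask2)
  expect_equal(qc2$qc_status, c("kept", "rejected"))
  expect_equal(qc2$qc_fail[2], "nucleus")

  expect_warning(qc_clusters(clusters[1], locs, wf, mask = NULL),
                 "criterion 2")
})

test_that("DDR classification maps overlap fractions to classes", {
  set.seed(29)
  mask <- matrix(FALSE, 100, 100)
  mask[30:50, 30:50] <- TRUE  # locus covering x,y in [2900, 5000] nm approx
  inside <- cbind(rnorm(100, 4000, 80), rnorm(100, 4000, 80))
  outside <- cbind(rnorm(100, 8000, 80), rnorm(100, 8000, 80))
  straddle <- cbind(rnorm(100, 5000, 300), rnorm(100, 4000, 300))
  locs <- loc_table(1:300, rbind(inside, outside, straddle)[, 1],
                    rbind(inside, outside, straddle)[, 2])
  cl <- list(1:100, 101:200, 201:300)
  res <- classify_ddr_mask(cl, locs, mask, pixel_size_nm = 100)
  expect_equal(as.character(res$ddr_class),
               c("complete", "none", "partial"))
  expect_equal(res$ddr_fraction[1], 1)
  expect_equal(res$ddr_fraction[2], 0)

  # growing the mask never moves a cluster toward "none"
  bigger <- mask
  bigger[25:60, 25:60] <- TRUE
  res2 <- classify_ddr_mask(cl, locs, bigger, pixel_size_nm = 100)
  rank <- function(x) as.integer(factor(x, c("none", "partial", "complete")))
  expect_true(all(rank(res2$ddr_class) >= rank(res$ddr_class)))
})

test_that("classify_ddr thresholds a rendered DDR image sensibly", {
  set.seed(33)
  pos <- rbind(c(4000, 4000), c(12000, 12000))
  ddr <- render_widefield(pos[1, , drop = FALSE], c(16000, 16000),
                          psf_sigma_nm = 300, peak_adu = 600, seed = 2)
  attr(ddr, "pixel_size_nm") <- 108
  pts <- rbind(cbind(rnorm(80, 4000, 50), rnorm(80, 4000, 50)),
               cbind(rnorm(80, 12000, 50), rnorm(80, 12000, 50)))
  locs <- loc_table(1:160, pts[, 1], pts[, 2])
  res <- classify_ddr(list(1:80, 81:160), locs, ddr)
  expect_equal(as.character(res$ddr_class), c("complete", "none"))
})
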