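#' Render localizations into a 2D count histogram
#'
#' Bins are half-open: a localization at coordinate `v` falls in bin
#' `floor(v / bin_nm)`, so values exactly on a boundary go to the higher
#' bin. Rows index y, columns index x; bin (1,1) starts at `origin_nm`.
#' The histogram total equals the number of localizations.
#'
#' @param locs localization table (columns `x_nm`, `y_nm`).
#' @param bin_nm bin side length (nm).
#' @param dims optional c(n_rows, n_cols); localizations outside are
#'   clipped into the edge bins so counts are conserved.
#' @param origin_nm length-2 lower-left origin of the grid (nm).
#' @return integer matrix with attributes `bin_nm` and `origin_nm`.
#' @export
render_histogram <- function(locs, bin_nm = 22, dims = NULL,
                             origin_nm = c(0, 0)) {
  stopifnot(bin_nm > 0)
  if (nrow(locs) == 0) stop("empty localization table")
  ix <- floor((locs$x_nm - origin_nm[1]) / bin_nm) + 1L
  iy <- floor((locs$y_nm - origin_nm[2]) / bin_nm) + 1L
  if (is.null(dims)) dims <- c(max(iy), max(ix))
  ix <- pmin(pmax(ix, 1L), dims[2])
  iy <- pmin(pmax(iy, 1L), dims[1])
  h <- matrix(0L, dims[1], dims[2])
  tab <- table(iy + (ix - 1L) * dims[1])
  h[as.integer(names(tab))] <- as.integer(tab)
  attr(h, "bin_nm") <- bin_nm
  attr(h, "origin_nm") <- origin_nm
  h
}

#' Upsample an image by an integer factor (nearest neighbour)
#'
#' Each pixel is replicated into a `factor` x `factor` block, preserving
#' local intensity structure without interpolation bias.
#'
#' @param img numeric matrix.
#' @param factor integer upsampling factor (>= 1).
#' @return upsampled matrix.
#' @export
upsample_nn <- function(img, factor) {
  stopifnot(factor >= 1, factor == round(factor))
  if (factor == 1) return(img)
  kronecker(img, matrix(1, factor, factor))
}

# circular FFT cross-correlation; returns the shift (rows, cols) of b
# relative to a that maximizes sum(a * shift(b)), as signed integers
cross_correlation_peak <- function(a, b) {
  # circular correlation on a 2-3-5-smooth grid: offsets are far smaller
  # than the field, so wraparound cannot displace the peak
  nr <- stats::nextn(max(nrow(a), nrow(b)), c(2, 3, 5))
  nc <- stats::nextn(max(ncol(a), ncol(b)), c(2, 3, 5))
  pad <- function(m) {
    p <- matrix(0, nr, nc)
    p[seq_len(nrow(m)), seq_len(ncol(m))] <- m
    p
  }
  A <- fft(pad(a)); B <- fft(pad(b))
  cc <- Re(fft(Conj(A) * B, inverse = TRUE))
  k <- which.max(cc)
  r <- (k - 1L) %% nr
  c <- (k - 1L) %/% nr
  if (r > nr / 2) r <- r - nr
  if (c > nc / 2) c <- c - nc
  c(row = r, col = c)
}

#' Registration parameters
#'
#' @param hist_bin_nm localization-histogram bin side (nm).
#' @param upsample_factor wide-field upsampling factor so its grid matches
#'   the histogram bins.
#' @param expected_offset_range_nm diagnostic range (nm); offsets outside it
#'   are flagged in the result attribute, not rejected.
#' @return An object of class `register_params`.
#' @export
register_params <- function(hist_bin_nm = 22, upsample_factor = 5,
                            expected_offset_range_nm = c(40, 60)) {
  stopifnot(hist_bin_nm > 0, upsample_factor >= 1)
  structure(list(hist_bin_nm = hist_bin_nm,
                 upsample_factor = upsample_factor,
                 expected_offset_range_nm = expected_offset_range_nm),
            class = "register_params")
}

#' Estimate the localization-to-wide-field offset
#'
#' Cross-correlates (via FFT) a localization histogram with the wide-field
#' image upsampled (nearest neighbour) to the histogram bin size. The
#' returned offset is the vector to \emph{add} to localization coordinates
#' to maximize their overlap with the wide-field image.
#'
#' @param hist localization histogram from [render_histogram()], or a
#'   localization table (then the histogram is rendered at the matching bin
#'   size internally).
#' @param widefield wide-field image matrix.
#' @param pixel_size_nm wide-field pixel size (nm); defaults to the image's
#'   `pixel_size_nm` attribute.
#' @param params a [register_params()].
#' @return c(dx_nm, dy_nm), with attribute `bin_nm` (the offset
#'   quantization) and `in_expected_range`.
#' @export
estimate_offset <- function(hist, widefield, pixel_size_nm = NULL,
                            params = register_params()) {
  if (is.null(pixel_size_nm)) pixel_size_nm <- attr(widefield, "pixel_size_nm")
  stopifnot(!is.null(pixel_size_nm))
  bin <- pixel_size_nm / params$upsample_factor
  if (is.data.frame(hist)) {
    up_dims <- dim(widefield) * params$upsample_factor
    hist <- render_histogram(hist, bin_nm = bin, dims = up_dims)
  }
  if (sum(hist) == 0) stop("empty histogram")
  hbin <- attr(hist, "bin_nm")
  if (!is.null(hbin) && abs(hbin - bin) > 1e-9)
    stop("histogram bin size does not match widefield pixel / upsample")
  # remove the background pedestal so zero-padded correlation is driven by
  # image structure rather than the constant offset
  up <- upsample_nn(widefield - mean(widefield), params$upsample_factor)
  pk <- cross_correlation_peak(hist, up)
  off <- c(dx_nm = unname(pk["col"]) * bin, dy_nm = unname(pk["row"]) * bin)
  rng <- params$expected_offset_range_nm
  attr(off, "bin_nm") <- bin
  attr(off, "in_expected_range") <-
    all(abs(off) >= rng[1] & abs(off) <= rng[2])
  off
}

#' Otsu intensity threshold
#'
#' @param img numeric matrix.
#' @return threshold on the image's intensity scale.
#' @export
otsu_threshold <- function(img) {
  rng <- range(img)
  if (diff(rng) == 0) return(rng[1])
  m <- (img - rng[1]) / diff(rng)
  EBImage::otsu(m, range = c(0, 1)) * diff(rng) + rng[1]
}

#' Segment a nucleus mask from a wide-field image
#'
#' Heavily blurs the image and applies an Otsu threshold; the smooth bright
#' regions (nuclei full of foci, or a DNA counterstain) become the mask.
#'
#' @param img wide-field matrix.
#' @param blur_sigma_px Gaussian blur sigma (pixels).
#' @return logical matrix of the same size.
#' @export
nucleus_mask <- function(img, blur_sigma_px = 10) {
  sm <- EBImage::gblur(img, sigma = blur_sigma_px)
  sm > otsu_threshold(sm)
}

# pixel indices (row, col) of coordinates on an image grid; clipped
coords_to_pixels <- function(x_nm, y_nm, pixel_size_nm, dims) {
  j <- pmin(pmax(floor(x_nm / pixel_size_nm) + 1L, 1L), dims[2])
  i <- pmin(pmax(floor(y_nm / pixel_size_nm) + 1L, 1L), dims[1])
  cbind(i, j)
}

#' Automated cluster quality control against the wide-field image
#'
#' Replays the analyst's accept/reject criteria as deterministic rules. A
#' cluster is kept iff (1) at least `f_locus` of its localizations fall on
#' wide-field pixels above the locus threshold (Otsu by default), (2) its
#' centroid lies inside the nucleus mask, and (3) the correlation between
#' the cluster's binned image and the corresponding wide-field patch
#' exceeds `r_min` (shape agreement). The first failing criterion is
#' recorded.
#'
#' @param clusters list of member-index vectors (e.g. from
#'   [gate_clusters()]).
#' @param locs localization table the indices refer to.
#' @param widefield probe-channel wide-field matrix.
#' @param offset_nm offset from [estimate_offset()], added to localization
#'   coordinates before comparison.
#' @param pixel_size_nm wide-field pixel size (nm); defaults to the image
#'   attribute.
#' @param mask optional logical nucleus mask (criterion 2 is skipped with a
#'   warning when `NULL`).
#' @param f_locus minimum on-locus localization fraction.
#' @param r_min minimum cluster/wide-field patch correlation.
#' @param locus_threshold intensity threshold; default Otsu of `widefield`.
#' @return data.frame: `cluster`, `qc_status` ("kept"/"rejected"),
#'   `qc_fail` (NA, "locus", "nucleus" or "shape"), `f_locus`, `shape_r`.
#' @export
qc_clusters <- function(clusters, locs, widefield, offset_nm = c(0, 0),
                        pixel_size_nm = NULL, mask = NULL,
                        f_locus = 0.5, r_min = 0.3,
                        locus_threshold = NULL) {
  if (is.null(pixel_size_nm)) pixel_size_nm <- attr(widefield, "pixel_size_nm")
  stopifnot(!is.null(pixel_size_nm))
  if (is.null(locus_threshold)) locus_threshold <- otsu_threshold(widefield)
  if (is.null(mask))
    warning("no nucleus mask supplied; QC criterion 2 skipped")
  dims <- dim(widefield)
  out <- data.frame(cluster = seq_along(clusters),
                    qc_status = "kept", qc_fail = NA_character_,
                    f_locus = NA_real_, shape_r = NA_real_)
  for (ci in seq_along(clusters)) {
    idx <- clusters[[ci]]
    x <- locs$x_nm[idx] + offset_nm[1]
    y <- locs$y_nm[idx] + offset_nm[2]
    px <- coords_to_pixels(x, y, pixel_size_nm, dims)
    frac <- mean(widefield[px] > locus_threshold)
    out$f_locus[ci] <- frac
    if (frac < f_locus) {
      out$qc_status[ci] <- "rejected"; out$qc_fail[ci] <- "locus"
      next
    }
    if (!is.null(mask)) {
      cpx <- coords_to_pixels(mean(x), mean(y), pixel_size_nm, dims)
      if (!mask[cpx]) {
        out$qc_status[ci] <- "rejected"; out$qc_fail[ci] <- "nucleus"
        next
      }
    }
    # shape agreement on the cluster's bounding patch (padded)
    i0 <- max(1L, min(px[, 1]) - 2L); i1 <- min(dims[1], max(px[, 1]) + 2L)
    j0 <- max(1L, min(px[, 2]) - 2L); j1 <- min(dims[2], max(px[, 2]) + 2L)
    patch <- widefield[i0:i1, j0:j1, drop = FALSE]
    ch <- matrix(0, i1 - i0 + 1L, j1 - j0 + 1L)
    tab <- table((px[, 1] - i0 + 1L) + (px[, 2] - j0) * nrow(ch))
    ch[as.integer(names(tab))] <- as.integer(tab)
    r <- if (sd(patch) == 0 || sd(ch) == 0) 0 else cor(as.vector(ch),
                                                       as.vector(patch))
    out$shape_r[ci] <- r
    if (r <= r_min) {
      out$qc_status[ci] <- "rejected"; out$qc_fail[ci] <- "shape"
    }
  }
  out
}

#' Classify clusters by DDR-marker overlap
#'
#' Thresholds the DDR-channel wide-field image (mild blur + Otsu) into a
#' binary locus mask and computes, per cluster, the fraction `f` of its
#' (offset-corrected) localizations falling inside the mask. Classes:
#' `none` if `f < f_lo`, `complete` if `f > f_hi`, otherwise `partial`.
#' The same channel offset as the probe channel is used, since both
#' wide-field images are acquired back-to-back at the same stage position.
#'
#' @param clusters list of member-index vectors.
#' @param locs localization table.
#' @param ddr_widefield DDR-channel wide-field matrix.
#' @param offset_nm offset added to localization coordinates.
#' @param pixel_size_nm DDR image pixel size (nm); defaults to attribute.
#' @param f_lo,f_hi class boundaries on the overlap fraction.
#' @param threshold intensity threshold; default Otsu of the blurred image.
#' @param blur_sigma_px blur applied before thresholding (pixels).
#' @return data.frame `cluster`, `ddr_fraction`, `ddr_class` (factor with
#'   levels none/partial/complete).
#' @export
classify_ddr <- function(clusters, locs, ddr_widefield, offset_nm = c(0, 0),
                         pixel_size_nm = NULL, f_lo = 0.1, f_hi = 0.9,
                         threshold = NULL, blur_sigma_px = 1) {
  if (is.null(pixel_size_nm))
    pixel_size_nm <- attr(ddr_widefield, "pixel_size_nm")
  stopifnot(!is.null(pixel_size_nm), f_lo <= f_hi)
  img <- if (blur_sigma_px > 0)
    EBImage::gblur(ddr_widefield, sigma = blur_sigma_px) else ddr_widefield
  if (is.null(threshold)) threshold <- otsu_threshold(img)
  mask <- img > threshold
  classify_ddr_mask(clusters, locs, mask, offset_nm, pixel_size_nm,
                    f_lo, f_hi)
}

#' @rdname classify_ddr
#' @param mask logical DDR locus mask (already thresholded).
#' @export
classify_ddr_mask <- function(clusters, locs, mask, offset_nm = c(0, 0),
                              pixel_size_nm, f_lo = 0.1, f_hi = 0.9) {
  dims <- dim(mask)
  f <- vapply(clusters, function(idx) {
    px <- coords_to_pixels(locs$x_nm[idx] + offset_nm[1],
                           locs$y_nm[idx] + offset_nm[2],
                           pixel_size_nm, dims)
    mean(mask[px])
  }, numeric(1))
  cls <- ifelse(f < f_lo, "none", ifelse(f > f_hi, "complete", "partial"))
  data.frame(cluster = seq_along(clusters), ddr_fraction = f,
             ddr_class = factor(cls, levels = c("none", "partial",
                                                "complete")))
}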