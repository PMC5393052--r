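#' Detect single-molecule candidates in one frame
#'
#' Band-passes the frame with a difference of Gaussian smoothing filters
#' (sigma `small_sigma_px` minus sigma `large_sigma_px`) and returns local
#' maxima of the filtered image above `threshold`. Candidates closer than
#' `min_distance_px` are deduplicated, keeping the brighter one.
#'
#' @param frame numeric matrix of pixel intensities (ADU).
#' @param small_sigma_px,large_sigma_px Gaussian sigmas of the band-pass
#'   (pixels, small < large).
#' @param threshold minimum band-passed amplitude for a candidate.
#' @param min_distance_px deduplication distance (default: the fitting
#'   window size, 7 px).
#' @return data.frame `row`, `col`, `value` (band-passed amplitude),
#'   ordered by decreasing value.
#' @export
detect_peaks <- function(frame, small_sigma_px = 1, large_sigma_px = 2,
                         threshold = 10, min_distance_px = 7) {
  stopifnot(small_sigma_px < large_sigma_px, threshold >= 0)
  support <- 2 * ceiling(4 * large_sigma_px) + 1
  if (any(dim(frame) < support))
    stop(sprintf("frame (%d x %d) smaller than the filter support (%d px)",
                 nrow(frame), ncol(frame), support))
  bp <- EBImage::gblur(frame, sigma = small_sigma_px) -
        EBImage::gblur(frame, sigma = large_sigma_px)
  nr <- nrow(bp); nc <- ncol(bp)
  # strict local maximum over the 8-neighbourhood (ties broken by position
  # via >= on forward neighbours)
  ge <- function(di, dj) {
    shifted <- matrix(-Inf, nr, nc)
    si <- seq_len(nr) + di; sj <- seq_len(nc) + dj
    ok_i <- si >= 1 & si <= nr; ok_j <- sj >= 1 & sj <= nc
    shifted[which(ok_i), which(ok_j)] <- bp[si[ok_i], sj[ok_j]]
    bp >= shifted
  }
  ismax <- bp > threshold
  for (di in -1:1) for (dj in -1:1) {
    if (di == 0 && dj == 0) next
    ismax <- ismax & ge(di, dj)
  }
  idx <- which(ismax)
  if (!length(idx))
    return(data.frame(row = integer(0), col = integer(0),
                      value = numeric(0)))
  cand <- data.frame(row = ((idx - 1L) %% nr) + 1L,
                     col = ((idx - 1L) %/% nr) + 1L,
                     value = bp[idx])
  cand <- cand[order(-cand$value), , drop = FALSE]
  keep <- logical(nrow(cand))
  for (i in seq_len(nrow(cand))) {
    if (i == 1) { keep[1] <- TRUE; next }
    prev <- which(keep)
    d2 <- (cand$row[prev] - cand$row[i])^2 + (cand$col[prev] - cand$col[i])^2
    keep[i] <- all(d2 >= min_distance_px^2)
  }
  out <- cand[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

# Poisson negative log-likelihood of the isotropic-Gaussian + constant
# background model on a ROI; theta = (x, y, log sigma, log N, log bg),
# positions in local pixel units (pixel j center at j - 0.5)
roi_model <- function(theta, xg, yg) {
  s <- exp(theta[3]); N <- exp(theta[4]); b <- exp(theta[5])
  gx <- exp(-(xg - theta[1])^2 / (2 * s^2))
  gy <- exp(-(yg - theta[2])^2 / (2 * s^2))
  b + (N / (2 * pi * s^2)) * outer(gy, gx)
}

#' Fit an isotropic 2D Gaussian to a candidate ROI by Poisson MLE
#'
#' Maximum-likelihood fit of position, PSF sigma, photon count and constant
#' background under a Poisson noise model. The localization precision is
#' the CRLB-style uncertainty from the Fisher information at the optimum,
#' and `loglike` is the likelihood-ratio statistic of the fit against the
#' saturated model (larger values mean the spot resembles a 2D Gaussian
#' less).
#'
#' @param roi square numeric matrix of pixel counts around a candidate.
#' @param pixel_size_nm camera pixel size (nm).
#' @param init_sigma_px initial PSF sigma (pixels).
#' @param max_iter,reltol optimizer budget and relative tolerance.
#' @return one-row data.frame `x_px`, `y_px` (local, pixel units, origin at
#'   the ROI corner), `precision_nm`, `sigma_nm`, `loglike`, `photons`,
#'   `background`, `converged`; or `NULL` if the fit failed.
#' @export
fit_gaussian_mle <- function(roi, pixel_size_nm, init_sigma_px = 1.3,
                             max_iter = 50, reltol = 1e-10) {
  nr <- nrow(roi); nc <- ncol(roi)
  xg <- seq_len(nc) - 0.5; yg <- seq_len(nr) - 0.5
  b0 <- max(min(roi), 1e-3)
  n0 <- max(sum(roi - b0), 10)
  w <- pmax(roi - b0, 0)
  x0 <- if (sum(w) > 0) sum(outer(rep(1, nr), xg) * w) / sum(w) else nc / 2
  y0 <- if (sum(w) > 0) sum(outer(yg, rep(1, nc)) * w) / sum(w) else nr / 2
  nll <- function(theta) {
    mu <- roi_model(theta, xg, yg)
    sum(mu) - sum(roi * log(mu))
  }
  fit <- try(optim(c(x0, y0, log(init_sigma_px), log(n0), log(b0)), nll,
                   method = "BFGS",
                   control = list(maxit = max_iter, reltol = reltol)),
             silent = TRUE)
  if (inherits(fit, "try-error")) return(NULL)
  th <- fit$par
  s <- exp(th[3]); N <- exp(th[4]); b <- exp(th[5])
  if (!all(is.finite(th)) || th[1] < 0 || th[1] > nc || th[2] < 0 ||
      th[2] > nr || s <= 0)
    return(NULL)
  mu <- roi_model(th, xg, yg)
  # Fisher information in the natural parameters (x, y, sigma, N, b)
  dx <- outer(rep(1, nr), xg - th[1])
  dy <- outer(yg - th[2], rep(1, nc))
  g <- (mu - b)                       # Gaussian part
  d <- list(x = g * dx / s^2,
            y = g * dy / s^2,
            s = g * ((dx^2 + dy^2) / s^3 - 2 / s),
            N = g / N,
            b = matrix(1, nr, nc))
  info <- matrix(0, 5, 5)
  for (i in 1:5) for (j in i:5) {
    info[i, j] <- info[j, i] <- sum(d[[i]] * d[[j]] / mu)
  }
  prec_px <- tryCatch({
    v <- solve(info)
    sqrt(max(mean(c(v[1, 1], v[2, 2])), 0))
  }, error = function(e) NA_real_)
  if (!is.finite(prec_px) || prec_px <= 0) prec_px <- nc  # degenerate fit
  k <- roi
  lr <- 2 * sum(mu - k + ifelse(k > 0, k * log(k / mu), 0))
  data.frame(x_px = th[1], y_px = th[2],
             precision_nm = prec_px * pixel_size_nm,
             sigma_nm = s * pixel_size_nm,
             loglike = lr, photons = N, background = b,
             converged = fit$convergence == 0)
}

#' Localize a raw frame stack
#'
#' Runs [detect_peaks()] and [fit_gaussian_mle()] on every frame from
#' `start_frame` on (earlier frames are skipped: at the start of an
#' acquisition too many molecules are still emitting for isolated-spot
#' fitting). Candidates whose fitting window would cross the frame border
#' and fits that fail to converge are dropped and counted.
#'
#' @param stack 3D array (frame, row, col), or the list returned by
#'   [simulate_frame_stack()].
#' @param pixel_size_nm camera pixel size (nm).
#' @param start_frame first frame to process (default 500).
#' @param small_sigma_px,large_sigma_px,threshold peak detection settings.
#' @param roi_px fitting window side (odd, default 7).
#' @return localization table (shared schema; `x_nm`/`y_nm` relative to the
#'   frame's lower-left corner) with attribute `diagnostics` = counts of
#'   dropped candidates. Empty stacks or no processed frames give an empty
#'   table with a warning.
#' @export
localize_stack <- function(stack, pixel_size_nm = NULL, start_frame = 500,
                           small_sigma_px = 1, large_sigma_px = 2,
                           threshold = 10, roi_px = 7) {
  if (is.list(stack) && !is.null(stack$frames)) {
    if (is.null(pixel_size_nm)) pixel_size_nm <- stack$pixel_size_nm
    stack <- stack$frames
  }
  stopifnot(length(dim(stack)) == 3, !is.null(pixel_size_nm),
            start_frame >= 1)
  empty <- data.frame(frame = integer(0), x_nm = numeric(0),
                      y_nm = numeric(0), precision_nm = numeric(0),
                      sigma_nm = numeric(0), loglike = numeric(0),
                      photons = numeric(0))
  nf <- dim(stack)[1]
  if (nf == 0 || nf < start_frame) {
    warning("no frames to process")
    attr(empty, "diagnostics") <- c(border = 0L, failed = 0L)
    return(empty)
  }
  half <- (roi_px - 1L) %/% 2L
  nr <- dim(stack)[2]; nc <- dim(stack)[3]
  dropped_border <- dropped_fit <- 0L
  out <- list()
  for (f in start_frame:nf) {
    fr <- stack[f, , ]
    pk <- detect_peaks(fr, small_sigma_px, large_sigma_px, threshold,
                       min_distance_px = roi_px)
    for (i in seq_len(nrow(pk))) {
      r <- pk$row[i]; c <- pk$col[i]
      if (r - half < 1 || r + half > nr || c - half < 1 || c + half > nc) {
        dropped_border <- dropped_border + 1L
        next
      }
      roi <- fr[(r - half):(r + half), (c - half):(c + half)]
      fit <- fit_gaussian_mle(roi, pixel_size_nm)
      if (is.null(fit) || !fit$converged) {
        dropped_fit <- dropped_fit + 1L
        next
      }
      out[[length(out) + 1L]] <- data.frame(
        frame = f,
        x_nm = (c - half - 1 + fit$x_px) * pixel_size_nm,
        y_nm = (r - half - 1 + fit$y_px) * pixel_size_nm,
        precision_nm = fit$precision_nm,
        sigma_nm = fit$sigma_nm,
        loglike = fit$loglike,
        photons = fit$photons)
    }
  }
  res <- if (length(out)) do.call(rbind, out) else empty
  if (nrow(res) == 0 && nf >= start_frame)
    warning("no localizations found")
  attr(res, "diagnostics") <- c(border = dropped_border,
                                failed = dropped_fit)
  res
}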