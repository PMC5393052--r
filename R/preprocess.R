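#' Quality-filter parameters
#'
#' Thresholds for localization quality filtering and blink merging. The
#' defaults follow common practice for 2D STORM of nuclear foci: precision
#' above 30 nm (about three times the typical mean precision) or a
#' log-likelihood goodness score above 250 discards the localization; fitted
#' PSF widths above 175 nm (standard deviation of the 2D Gaussian) indicate
#' out-of-focus emitters and are removed. Comparisons are strict, so values
#' exactly at a threshold are retained. Merging links localizations within
#' 30 nm across frames, tolerating at most one dark frame.
#'
#' @param max_precision_nm discard precision > this (nm).
#' @param max_loglike discard log-likelihood ratio > this (larger = worse
#'   fit).
#' @param max_sigma_nm discard fitted PSF sigma > this (nm).
#' @param merge_radius_nm blink-merge linking radius (nm).
#' @param gap_frames maximum dark frames a track may span.
#' @return An object of class `filter_params`.
#' @export
filter_params <- function(max_precision_nm = 30, max_loglike = 250,
                          max_sigma_nm = 175, merge_radius_nm = 30,
                          gap_frames = 1) {
  stopifnot(max_precision_nm > 0, max_loglike > 0, max_sigma_nm > 0,
            merge_radius_nm >= 0, gap_frames >= 0)
  structure(list(max_precision_nm = max_precision_nm,
                 max_loglike = max_loglike, max_sigma_nm = max_sigma_nm,
                 merge_radius_nm = merge_radius_nm, gap_frames = gap_frames),
            class = "filter_params")
}

#' Identify fiducial bead tracks
#'
#' Renders the localization table into a coarse 2D histogram (default
#' 1 x 1 um bins) and keeps bins whose localization count is at least
#' `min_fraction` of the number of frames: an always-on bead contributes
#' roughly one localization per frame, so its bin count is approximately the
#' frame count, whereas blinking fluorophores fall far below it.
#'
#' @param locs localization table.
#' @param frames_total number of frames in the acquisition.
#' @param bin_size_um histogram bin side (micrometres).
#' @param min_fraction minimum bin count as a fraction of `frames_total`.
#' @return list of `fiducial_track` objects, each with the bin origin (nm),
#'   member row indices into `locs`, and per-frame mean positions (`frames`,
#'   `x_nm`, `y_nm`; frame duplicates averaged).
#' @export
find_fiducials <- function(locs, frames_total, bin_size_um = 1.0,
                           min_fraction = 0.8) {
  stopifnot(frames_total >= 1, bin_size_um > 0,
            min_fraction > 0, min_fraction <= 1)
  if (nrow(locs) == 0) return(list())
  b <- bin_size_um * 1000
  ix <- floor(locs$x_nm / b); iy <- floor(locs$y_nm / b)
  key <- paste(ix, iy)
  cnt <- table(key)
  good <- names(cnt)[cnt >= min_fraction * frames_total]
  lapply(good, function(k) {
    idx <- which(key == k)
    xf <- tapply(locs$x_nm[idx], locs$frame[idx], mean)
    yf <- tapply(locs$y_nm[idx], locs$frame[idx], mean)
    fr <- as.integer(names(xf))
    o <- order(fr)
    structure(list(
      bin_origin_nm = as.numeric(strsplit(k, " ")[[1]]) * b,
      idx = idx,
      frames = fr[o], x_nm = as.numeric(xf)[o], y_nm = as.numeric(yf)[o]
    ), class = "fiducial_track")
  })
}

# Gaussian-kernel weighted local linear regression of y over frames,
# evaluated at integer frames eval_frames. Exact on linear signals
# (including at the track edges); suppresses jitter above the 1/window
# frequency scale. Interior frames use convolution; edges use direct fits.
kernel_local_linear <- function(frames, y, eval_frames,
                                sigma = 200, window = 800) {
  hw <- floor(window / 2)
  f0 <- min(frames); f1 <- max(frames)
  grid <- f0:f1
  n <- length(grid)
  w <- numeric(n); yg <- numeric(n)
  pos <- frames - f0 + 1L
  # average duplicates onto the grid
  cnt <- tabulate(pos, nbins = n)
  ysum <- numeric(n)
  ysum[sort(unique(pos))] <- tapply(y, pos, sum)
  has <- cnt > 0
  w[has] <- 1
  yg[has] <- ysum[has] / cnt[has]

  d <- (-hw):hw
  kern <- dnorm(d, sd = sigma)
  fit_at <- function(t) {           # direct weighted linear fit at grid pos t
    lo <- max(1L, t - hw); hi <- min(n, t + hw)
    sel <- lo:hi
    sel <- sel[w[sel] > 0]
    dd <- sel - t
    kk <- dnorm(dd, sd = sigma)
    S0 <- sum(kk); S1 <- sum(kk * dd); S2 <- sum(kk * dd^2)
    T0 <- sum(kk * yg[sel]); T1 <- sum(kk * dd * yg[sel])
    den <- S0 * S2 - S1^2
    if (abs(den) < 1e-12 * max(S0 * S2, 1e-300)) {
      c(T0 / S0, 0)                 # degenerate: fall back to weighted mean
    } else {
      c((S2 * T0 - S1 * T1) / den, (S0 * T1 - S1 * T0) / den)
    }
  }

  est <- numeric(n)
  if (n > 2 * hw + 2) {
    conv <- function(x, k) {
      # centered moving weighted sum; NA outside full-support region
      as.numeric(stats::filter(x, rev(k), method = "convolution", sides = 2))
    }
    S0 <- conv(w, kern); S1 <- conv(w, kern * d); S2 <- conv(w, kern * d^2)
    T0 <- conv(yg * w, kern); T1 <- conv(yg * w, kern * d)
    den <- S0 * S2 - S1^2
    interior <- which(!is.na(den) & abs(den) > 1e-12 * pmax(S0 * S2, 1e-300))
    est[interior] <- (S2[interior] * T0[interior] -
                        S1[interior] * T1[interior]) / den[interior]
    todo <- setdiff(seq_len(n), interior)
  } else {
    todo <- seq_len(n)
  }
  for (t in todo) est[t] <- fit_at(t)[1]

  # evaluate: inside the track span use the smoothed grid; outside,
  # extrapolate linearly with the local slope at the nearest end
  out <- numeric(length(eval_frames))
  inside <- eval_frames >= f0 & eval_frames <= f1
  out[inside] <- est[eval_frames[inside] - f0 + 1L]
  if (any(!inside)) {
    bL <- fit_at(1L); bR <- fit_at(n)
    left <- !inside & eval_frames < f0
    right <- !inside & eval_frames > f1
    out[left] <- bL[1] + bL[2] * (eval_frames[left] - f0)
    out[right] <- bR[1] + bR[2] * (eval_frames[right] - f1)
  }
  out
}

#' Smooth a fiducial track into per-frame drift curves
#'
#' Fits the track's x(t) and y(t) with a Gaussian-weighted local linear
#' smoother (weight standard deviation `weight_sigma_frames`, support window
#' `window_frames`), the smoothing-spline analogue used for fiducial drift
#' trajectories. The smoother reproduces linear drift exactly and suppresses
#' frame-to-frame localization jitter.
#'
#' @param track a `fiducial_track` from [find_fiducials()].
#' @param weight_sigma_frames Gaussian weight SD (frames).
#' @param window_frames weight window size (frames).
#' @param eval_frames frames at which to evaluate (default: the track's own
#'   frame range).
#' @return data.frame `frame`, `x_nm`, `y_nm` of the smoothed trajectory.
#' @export
fit_drift_spline <- function(track, weight_sigma_frames = 200,
                             window_frames = 800, eval_frames = NULL) {
  stopifnot(inherits(track, "fiducial_track"))
  span <- max(track$frames) - min(track$frames) + 1L
  if (span < 2 * window_frames)
    stop(sprintf("track covers %d frames; need at least %d (2 x window)",
                 span, 2 * window_frames))
  if (is.null(eval_frames)) eval_frames <- min(track$frames):max(track$frames)
  data.frame(
    frame = eval_frames,
    x_nm = kernel_local_linear(track$frames, track$x_nm, eval_frames,
                               sigma = weight_sigma_frames,
                               window = window_frames),
    y_nm = kernel_local_linear(track$frames, track$y_nm, eval_frames,
                               sigma = weight_sigma_frames,
                               window = window_frames))
}

#' Average fiducial splines into the FOV drift trajectory
#'
#' Each track's smoothed trajectory is evaluated on every frame, re-zeroed
#' to its own value at frame 1 (so the beads' absolute positions cancel) and
#' averaged across tracks.
#'
#' @param tracks list of `fiducial_track`s (must be non-empty; a FOV with no
#'   usable fiducials is discarded with an error of class
#'   `telostorm_no_fiducials`).
#' @param frames_total number of frames; the trajectory covers
#'   `1:frames_total`.
#' @param weight_sigma_frames,window_frames smoothing parameters passed to
#'   [fit_drift_spline()].
#' @return An object of class `drift_trajectory`: data.frame `frame`,
#'   `dx_nm`, `dy_nm` with attribute `n_fiducials`.
#' @export
build_drift <- function(tracks, frames_total, weight_sigma_frames = 200,
                        window_frames = 800) {
  if (length(tracks) == 0)
    stop(structure(class = c("telostorm_no_fiducials", "error", "condition"),
                   list(message = "no usable fiducials: FOV discarded",
                        call = sys.call())))
  fr <- seq_len(frames_total)
  dx <- dy <- matrix(0, frames_total, length(tracks))
  for (j in seq_along(tracks)) {
    s <- fit_drift_spline(tracks[[j]], weight_sigma_frames, window_frames,
                          eval_frames = fr)
    dx[, j] <- s$x_nm - s$x_nm[1]
    dy[, j] <- s$y_nm - s$y_nm[1]
  }
  out <- data.frame(frame = fr,
                    dx_nm = rowMeans(dx), dy_nm = rowMeans(dy))
  attr(out, "n_fiducials") <- length(tracks)
  class(out) <- c("drift_trajectory", "data.frame")
  out
}

#' Apply (or undo) a drift correction
#'
#' Subtracts the per-frame drift from localization coordinates; with
#' `undo = TRUE` adds it back, so correcting and then undoing returns the
#' original table exactly.
#'
#' @param locs localization table.
#' @param drift a `drift_trajectory` (or data.frame `frame`, `dx_nm`,
#'   `dy_nm` covering every frame present in `locs`).
#' @param undo add the drift back instead of subtracting.
#' @return the corrected localization table, record order preserved.
#' @export
apply_drift <- function(locs, drift, undo = FALSE) {
  if (nrow(locs) == 0) return(locs)
  pos <- match(locs$frame, drift$frame)
  if (anyNA(pos))
    stop("drift trajectory does not cover frame(s): ",
         paste(utils::head(unique(locs$frame[is.na(pos)]), 5), collapse = ", "))
  s <- if (undo) 1 else -1
  locs$x_nm <- locs$x_nm + s * drift$dx_nm[pos]
  locs$y_nm <- locs$y_nm + s * drift$dy_nm[pos]
  locs
}

#' Remove localizations inside fiducial bins
#'
#' After drift correction the fiducial localizations have served their
#' purpose; this drops every localization falling in the 2D-histogram bins
#' identified as fiducials so beads are not mistaken for clusters.
#'
#' @param locs localization table.
#' @param tracks fiducial tracks from [find_fiducials()] computed on the
#'   same table (row indices must still be valid).
#' @return localization table without the fiducial rows.
#' @export
drop_fiducial_localizations <- function(locs, tracks) {
  if (!length(tracks)) return(locs)
  idx <- unique(unlist(lapply(tracks, `[[`, "idx")))
  if (!length(idx)) return(locs)
  locs[-idx, , drop = FALSE]
}

#' Quality-filter a localization table
#'
#' Discards localizations whose precision, log-likelihood goodness score or
#' fitted PSF width exceed (strictly) the thresholds in
#' [filter_params()]. Values exactly at a threshold are retained.
#'
#' @param locs localization table with columns `precision_nm`, `loglike`,
#'   `sigma_nm`.
#' @param params a [filter_params()].
#' @return list with `locs` (retained rows) and `rejected`, a named count of
#'   rows failing each rule (a row can fail several) plus the total removed.
#' @export
filter_localizations <- function(locs, params = filter_params()) {
  stopifnot(inherits(params, "filter_params"))
  for (col in c("precision_nm", "loglike", "sigma_nm")) {
    if (is.null(locs[[col]]))
      stop("missing quality column: ", col)
  }
  bad_prec <- locs$precision_nm > params$max_precision_nm
  bad_ll <- locs$loglike > params$max_loglike
  bad_sig <- locs$sigma_nm > params$max_sigma_nm
  bad <- bad_prec | bad_ll | bad_sig
  list(locs = locs[!bad, , drop = FALSE],
       rejected = c(precision = sum(bad_prec), loglike = sum(bad_ll),
                    sigma = sum(bad_sig), total = sum(bad)))
}

#' Merge blinking localizations across frames
#'
#' Links localizations into tracks by greedy nearest-neighbour association:
#' a localization joins the nearest active track whose last position lies
#' within `radius_nm`, where a track stays active while its dark time does
#' not exceed `gap_frames`. Ties are broken by smaller localization index
#' for determinism. Each track is collapsed to a single localization at the
#' inverse-variance (precision-) weighted mean position; photons are summed,
#' the combined precision is that of the weighted mean, the frame is the
#' track's first frame, and `n_merged` records the track length.
#'
#' With `radius_nm = 0` the table is returned unchanged (every localization
#' is its own track).
#'
#' @param locs drift-corrected, filtered localization table sorted by frame.
#' @param radius_nm linking radius (nm, >= 0).
#' @param gap_frames maximum dark frames within a track (>= 0).
#' @return merged localization table (sorted by frame) with an added
#'   `n_merged` column. Total photons are conserved exactly.
#' @export
merge_localizations <- function(locs, radius_nm = 30, gap_frames = 1) {
  if (radius_nm < 0 || gap_frames < 0)
    stop("radius_nm and gap_frames must be non-negative")
  n <- nrow(locs)
  if (n == 0) {
    locs$n_merged <- integer(0)
    return(locs)
  }
  locs <- locs[order(locs$frame), , drop = FALSE]
  track <- integer(n)
  if (radius_nm == 0) {
    track <- seq_len(n)
  } else {
    # active track state
    cap <- 256L
    a_x <- a_y <- numeric(cap); a_frame <- integer(cap); a_id <- integer(cap)
    n_active <- 0L
    n_tracks <- 0L
    x <- locs$x_nm; y <- locs$y_nm; fr <- locs$frame
    r2 <- radius_nm^2
    starts <- c(which(c(TRUE, diff(fr) > 0)), n + 1L)
    for (b in seq_len(length(starts) - 1L)) {
      i0 <- starts[b]; i1 <- starts[b + 1L] - 1L
      f <- fr[i0]
      # retire tracks whose gap is exceeded
      if (n_active > 0L) {
        keep <- which(a_frame[seq_len(n_active)] >= f - gap_frames - 1L)
        if (length(keep) < n_active) {
          a_x[seq_along(keep)] <- a_x[keep]
          a_y[seq_along(keep)] <- a_y[keep]
          a_frame[seq_along(keep)] <- a_frame[keep]
          a_id[seq_along(keep)] <- a_id[keep]
          n_active <- length(keep)
        }
      }
      claimed <- integer(0)
      for (i in i0:i1) {
        assigned <- 0L
        if (n_active > 0L) {
          act <- seq_len(n_active)
          # a track can absorb at most one localization per frame
          free <- if (length(claimed)) act[!(act %in% claimed)] else act
          if (length(free)) {
            d2 <- (a_x[free] - x[i])^2 + (a_y[free] - y[i])^2
            jmin <- which(d2 <= r2)
            if (length(jmin)) {
              j <- free[jmin[which.min(d2[jmin])]]
              assigned <- j
            }
          }
        }
        if (assigned > 0L) {
          track[i] <- a_id[assigned]
          a_x[assigned] <- x[i]; a_y[assigned] <- y[i]
          a_frame[assigned] <- f
          claimed <- c(claimed, assigned)
        } else {
          n_tracks <- n_tracks + 1L
          n_active <- n_active + 1L
          if (n_active > cap) {
            cap <- cap * 2L
            length(a_x) <- cap; length(a_y) <- cap
            length(a_frame) <- cap; length(a_id) <- cap
          }
          a_x[n_active] <- x[i]; a_y[n_active] <- y[i]
          a_frame[n_active] <- f; a_id[n_active] <- n_tracks
          track[i] <- n_tracks
          claimed <- c(claimed, n_active)
        }
      }
    }
  }

  # collapse tracks, vectorized; group ids in first-appearance (frame) order
  tid <- match(track, unique(track))
  first <- !duplicated(tid)
  cnt <- tabulate(tid)
  pr <- locs$precision_nm
  z <- pr <= 0
  grp_has_zero <- as.numeric(rowsum(as.numeric(z), tid)) > 0
  # noise-free records (precision 0) carry infinite weight: average them alone
  w <- ifelse(grp_has_zero[tid], as.numeric(z), 1 / pr^2)
  W <- as.numeric(rowsum(w, tid))
  merged <- locs[first, , drop = FALSE]      # carries extra columns through
  merged$x_nm <- as.numeric(rowsum(w * locs$x_nm, tid)) / W
  merged$y_nm <- as.numeric(rowsum(w * locs$y_nm, tid)) / W
  merged$precision_nm <- ifelse(grp_has_zero, 0, 1 / sqrt(W))
  merged$sigma_nm <- as.numeric(rowsum(locs$sigma_nm, tid)) / cnt
  merged$loglike <- as.numeric(rowsum(locs$loglike, tid)) / cnt
  merged$photons <- as.numeric(rowsum(locs$photons, tid))
  merged$n_merged <- cnt
  rownames(merged) <- NULL
  merged
}
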