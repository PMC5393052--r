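#' Describe a synthetic field of telomere-like emitter clusters
#'
#' Configuration for one simulated field of view (FOV): cluster centers,
#' per-cluster shape and target radius of gyration, fiducial bead positions,
#' and which clusters carry a DNA-damage-response (DDR) marker. Positions not
#' supplied explicitly are drawn by [place_clusters()].
#'
#' The default geometry emulates a few-nucleus subregion of a large-FOV
#' STORM acquisition: clusters (telomeres) are placed inside circular
#' "nuclei", with a minimum pairwise separation so that neighbouring
#' telomeres remain resolvable, and always-on fiducial beads sit on the
#' field outside the nuclei.
#'
#' @param field_size_nm numeric length-2, field width and height in nm.
#' @param n_clusters number of telomere-like clusters.
#' @param mean_rg_nm,sd_rg_nm mean and SD of the per-cluster target radius of
#'   gyration (nm); targets are drawn from a Normal truncated below at
#'   `min_rg_nm`.
#' @param min_rg_nm lower truncation for target Rg (nm).
#' @param shape one of `"gaussian_aniso"` (anisotropic 2D Gaussian with axis
#'   ratio drawn uniformly in \[1, 2.5\], mimicking ovoid telomeres),
#'   `"gaussian"` (isotropic) or `"disk"` (uniform disk).
#' @param emitters_per_cluster fluorophores per cluster (>= 1).
#' @param n_fiducials number of always-on fiducial beads.
#' @param n_nuclei,nucleus_radius_nm number and radius of circular nuclei the
#'   clusters are confined to; `n_nuclei = 0` places clusters uniformly.
#' @param ddr_fraction fraction of clusters labelled DDR-positive.
#' @param min_separation_nm minimum center-to-center distance between
#'   clusters (nm).
#' @param cluster_centers,fiducial_positions optional n x 2 matrices of
#'   explicit positions (nm); when given they override random placement.
#' @param target_rg_nm optional vector of explicit per-cluster target Rg.
#' @param ddr_positive optional logical/index vector marking DDR-positive
#'   clusters.
#'
#' @return An object of class `emitter_field`.
#' @seealso [place_clusters()], [simulate_fov()]
#' @export
emitter_field <- function(field_size_nm = c(40000, 40000),
                          n_clusters = 90,
                          mean_rg_nm = 68, sd_rg_nm = 21, min_rg_nm = 25,
                          shape = c("gaussian_aniso", "gaussian", "disk"),
                          emitters_per_cluster = 40,
                          n_fiducials = 3,
                          n_nuclei = 4, nucleus_radius_nm = 8000,
                          ddr_fraction = 0.3,
                          min_separation_nm = 1200,
                          cluster_centers = NULL,
                          fiducial_positions = NULL,
                          target_rg_nm = NULL,
                          ddr_positive = NULL) {
  shape <- match.arg(shape)
  stopifnot(length(field_size_nm) == 2, all(field_size_nm > 0),
            n_clusters >= 1, emitters_per_cluster >= 1,
            mean_rg_nm > 0, sd_rg_nm >= 0, min_rg_nm > 0,
            n_fiducials >= 0, ddr_fraction >= 0, ddr_fraction <= 1)
  if (!is.null(target_rg_nm) && any(target_rg_nm <= 0))
    stop("target Rg must be positive")
  inside <- function(p) {
    !is.null(p) && all(p[, 1] >= 0 & p[, 1] <= field_size_nm[1] &
                       p[, 2] >= 0 & p[, 2] <= field_size_nm[2])
  }
  if (!is.null(cluster_centers) && !inside(cluster_centers))
    stop("cluster_centers outside field")
  if (!is.null(fiducial_positions) && !inside(fiducial_positions))
    stop("fiducial_positions outside field")
  structure(list(
    field_size_nm = field_size_nm, n_clusters = n_clusters,
    mean_rg_nm = mean_rg_nm, sd_rg_nm = sd_rg_nm, min_rg_nm = min_rg_nm,
    shape = shape, emitters_per_cluster = emitters_per_cluster,
    n_fiducials = n_fiducials, n_nuclei = n_nuclei,
    nucleus_radius_nm = nucleus_radius_nm, ddr_fraction = ddr_fraction,
    min_separation_nm = min_separation_nm,
    cluster_centers = cluster_centers,
    fiducial_positions = fiducial_positions,
    target_rg_nm = target_rg_nm, ddr_positive = ddr_positive
  ), class = "emitter_field")
}

#' Fluorophore blinking model
#'
#' Photoswitching is modelled as alternating on/off periods. On-times are
#' geometric with mean `mean_on_frames`. Off-times follow a two-component
#' geometric mixture -- a short pronounced peak near the origin plus a long
#' tail -- the qualitative shape observed for Alexa 647 off-time histograms.
#' After each on-period the fluorophore survives (does not photobleach) with
#' probability `survival_prob_per_frame` per emitted frame.
#'
#' @param mean_on_frames mean on-time (frames, > 0).
#' @param off_mean_short,off_mean_long mean of the short and long off-time
#'   components (frames, >= 1).
#' @param off_weight_short weight of the short component in \[0, 1\].
#' @param survival_prob_per_frame per-on-frame photobleaching survival
#'   probability in (0, 1\].
#' @param frames_total number of camera frames in the acquisition.
#' @param activation `"uniform"` (each fluorophore's first on-event starts
#'   at a frame drawn uniformly over the acquisition, emulating stochastic
#'   photoswitching onset) or `"immediate"` (on from frame 1; useful for
#'   always-on references).
#' @return An object of class `blink_model`.
#' @export
blink_model <- function(mean_on_frames = 2,
                        off_mean_short = 2, off_mean_long = 200,
                        off_weight_short = 0.8,
                        survival_prob_per_frame = 0.85,
                        frames_total = 20000,
                        activation = c("uniform", "immediate")) {
  activation <- match.arg(activation)
  stopifnot(mean_on_frames > 0, off_mean_short >= 1, off_mean_long >= 1,
            off_weight_short >= 0, off_weight_short <= 1,
            survival_prob_per_frame > 0, survival_prob_per_frame <= 1,
            frames_total >= 1)
  structure(list(mean_on_frames = mean_on_frames,
                 off_mean_short = off_mean_short,
                 off_mean_long = off_mean_long,
                 off_weight_short = off_weight_short,
                 survival_prob_per_frame = survival_prob_per_frame,
                 frames_total = frames_total, activation = activation),
            class = "blink_model")
}

#' Theoretical off-time probability mass function
#'
#' P(off = k frames), k >= 1, for the two-component geometric mixture of a
#' [blink_model()]. Used by goodness-of-fit checks of simulated blinking.
#'
#' @param k positive integer vector of off-times (frames).
#' @param blink a [blink_model()].
#' @return numeric vector of probabilities.
#' @export
off_time_pmf <- function(k, blink) {
  stopifnot(all(k >= 1))
  dgeom1 <- function(k, mean) {
    p <- 1 / mean
    p * (1 - p)^(k - 1)
  }
  w <- blink$off_weight_short
  w * dgeom1(k, blink$off_mean_short) +
    (1 - w) * dgeom1(k, blink$off_mean_long)
}

#' Lateral stage drift model
#'
#' @param kind `"none"`, `"linear"` (drift of `magnitude_nm` along x over the
#'   acquisition) or `"smooth-random"` (a sum of three low-frequency
#'   sinusoids per axis with random phases, scaled so the maximum
#'   displacement from the start equals `magnitude_nm`).
#' @param magnitude_nm total drift magnitude over the acquisition (nm).
#' @return An object of class `drift_model`.
#' @export
drift_model <- function(kind = c("smooth-random", "linear", "none"),
                        magnitude_nm = 100) {
  kind <- match.arg(kind)
  stopifnot(magnitude_nm >= 0)
  structure(list(kind = kind, magnitude_nm = magnitude_nm),
            class = "drift_model")
}

#' Realize a drift trajectory from a drift model
#'
#' @param model a [drift_model()].
#' @param frames_total number of frames; the trajectory is defined for every
#'   frame `1:frames_total` and is zero at frame 1.
#' @param seed integer seed (only used for `"smooth-random"`).
#' @return data.frame with columns `frame`, `dx_nm`, `dy_nm`.
#' @export
simulate_drift <- function(model, frames_total, seed = 1) {
  stopifnot(inherits(model, "drift_model"), frames_total >= 1)
  t <- seq_len(frames_total)
  if (model$kind == "none" || model$magnitude_nm == 0) {
    return(data.frame(frame = t, dx_nm = 0, dy_nm = 0))
  }
  if (model$kind == "linear") {
    s <- if (frames_total == 1) 0 else (t - 1) / (frames_total - 1)
    return(data.frame(frame = t, dx_nm = model$magnitude_nm * s, dy_nm = 0))
  }
  set.seed(seed %% .Machine$integer.max)
  axis <- function() {
    y <- rep(0, frames_total)
    for (k in 1:3) {
      a <- rnorm(1)
      phi <- runif(1, 0, 2 * pi)
      # periods >= 2/3 of the acquisition: smooth on the fiducial-spline scale
      y <- y + a / k * sin(2 * pi * k * t / (2 * frames_total) + phi)
    }
    y - y[1]
  }
  dx <- axis(); dy <- axis()
  r <- sqrt(dx^2 + dy^2)
  if (max(r) > 0) {
    sc <- model$magnitude_nm / max(r)
    dx <- dx * sc; dy <- dy * sc
  }
  data.frame(frame = t, dx_nm = dx, dy_nm = dy)
}

# truncated-normal draw (lower bound only)
rnorm_trunc <- function(n, mean, sd, lower) {
  if (sd == 0) return(rep(pmax(mean, lower), n))
  x <- rnorm(n, mean, sd)
  while (any(bad <- x < lower)) x[bad] <- rnorm(sum(bad), mean, sd)
  x
}

#' Place cluster emitters and fiducials in a field
#'
#' Draws per-cluster emitter positions from the configured shape model so
#' that the population-level expected radius of gyration equals the target
#' Rg: for a uniform disk of radius R, Rg = R/sqrt(2); for a 2D Gaussian
#' with per-axis sigmas, Rg^2 = sigma_x^2 + sigma_y^2 (isotropic: Rg =
#' sigma * sqrt(2)).
#'
#' @param field an [emitter_field()].
#' @param seed integer seed; identical field + seed gives identical output.
#' @return list with elements
#'   \describe{
#'     \item{emitters}{data.frame `x_nm`, `y_nm`, `cluster_id`}
#'     \item{clusters}{data.frame of per-cluster ground truth: center,
#'       target and realized Rg, shape parameters, `ddr_positive`}
#'     \item{fiducials}{data.frame `id`, `x_nm`, `y_nm`}
#'     \item{nuclei}{data.frame of nucleus centers and radius (or NULL)}
#'     \item{field}{the input configuration}
#'   }
#' @export
place_clusters <- function(field, seed = 1) {
  stopifnot(inherits(field, "emitter_field"))
  set.seed(seed %% .Machine$integer.max)
  W <- field$field_size_nm[1]; H <- field$field_size_nm[2]
  n <- field$n_clusters

  nuclei <- NULL
  if (field$n_nuclei > 0 && is.null(field$cluster_centers)) {
    r <- field$nucleus_radius_nm
    nuclei <- data.frame(
      x_nm = runif(field$n_nuclei, r, W - r),
      y_nm = runif(field$n_nuclei, r, H - r),
      radius_nm = r)
  }

  centers <- field$cluster_centers
  if (is.null(centers)) {
    centers <- matrix(NA_real_, n, 2)
    placed <- 0
    tries <- 0
    while (placed < n) {
      tries <- tries + 1
      if (tries > 200 * n) stop("could not place clusters with the requested separation")
      if (is.null(nuclei)) {
        p <- c(runif(1, 0, W), runif(1, 0, H))
      } else {
        k <- sample.int(nrow(nuclei), 1)
        rr <- nuclei$radius_nm[k] * sqrt(runif(1))
        th <- runif(1, 0, 2 * pi)
        p <- c(nuclei$x_nm[k] + rr * cos(th), nuclei$y_nm[k] + rr * sin(th))
      }
      if (p[1] < 0 || p[1] > W || p[2] < 0 || p[2] > H) next
      if (placed > 0) {
        d2 <- (centers[seq_len(placed), 1] - p[1])^2 +
              (centers[seq_len(placed), 2] - p[2])^2
        if (min(d2) < field$min_separation_nm^2) next
      }
      placed <- placed + 1
      centers[placed, ] <- p
    }
  }
  centers <- matrix(as.numeric(centers), ncol = 2)

  targets <- field$target_rg_nm
  if (is.null(targets)) {
    targets <- rnorm_trunc(n, field$mean_rg_nm, field$sd_rg_nm,
                           field$min_rg_nm)
  }
  if (length(targets) == 1) targets <- rep(targets, n)
  stopifnot(length(targets) == n)

  ddr <- field$ddr_positive
  if (is.null(ddr)) {
    ddr <- rep(FALSE, n)
    npos <- round(field$ddr_fraction * n)
    if (npos > 0) ddr[sample.int(n, npos)] <- TRUE
  } else if (!is.logical(ddr)) {
    tmp <- rep(FALSE, n); tmp[ddr] <- TRUE; ddr <- tmp
  }

  m <- field$emitters_per_cluster
  ratio <- theta <- numeric(n)
  ex <- ey <- cid <- vector("list", n)
  realized <- numeric(n)
  for (i in seq_len(n)) {
    rg <- targets[i]
    if (field$shape == "disk") {
      ratio[i] <- 1; theta[i] <- 0
      R <- rg * sqrt(2)
      rr <- R * sqrt(runif(m)); th <- runif(m, 0, 2 * pi)
      dx <- rr * cos(th); dy <- rr * sin(th)
    } else {
      q <- if (field$shape == "gaussian") 1 else runif(1, 1, 2.5)
      ratio[i] <- q
      theta[i] <- if (q == 1) 0 else runif(1, 0, pi)
      s_min <- rg / sqrt(1 + q^2)
      s_maj <- q * s_min
      u <- rnorm(m, 0, s_maj); v <- rnorm(m, 0, s_min)
      dx <- u * cos(theta[i]) - v * sin(theta[i])
      dy <- u * sin(theta[i]) + v * cos(theta[i])
    }
    x <- centers[i, 1] + dx; y <- centers[i, 2] + dy
    if (any(x < 0 | x > W | y < 0 | y > H))
      stop(sprintf("cluster %d: emitters spill outside the field (Rg too large for its position)", i))
    ex[[i]] <- x; ey[[i]] <- y; cid[[i]] <- rep.int(i, m)
    if (m == 1) {
      realized[i] <- 0
    } else {
      realized[i] <- sqrt(mean((x - mean(x))^2 + (y - mean(y))^2))
    }
  }

  fid <- field$fiducial_positions
  if (is.null(fid) && field$n_fiducials > 0) {
    fid <- cbind(runif(field$n_fiducials, 0.02 * W, 0.98 * W),
                 runif(field$n_fiducials, 0.02 * H, 0.98 * H))
  }
  fiducials <- if (is.null(fid) || nrow(fid) == 0) {
    data.frame(id = integer(0), x_nm = numeric(0), y_nm = numeric(0))
  } else {
    data.frame(id = seq_len(nrow(fid)), x_nm = fid[, 1], y_nm = fid[, 2])
  }

  list(
    emitters = data.frame(x_nm = unlist(ex), y_nm = unlist(ey),
                          cluster_id = unlist(cid)),
    clusters = data.frame(id = seq_len(n),
                          x_nm = centers[, 1], y_nm = centers[, 2],
                          target_rg_nm = targets, realized_rg_nm = realized,
                          axis_ratio = ratio, theta = theta,
                          ddr_positive = ddr),
    fiducials = fiducials,
    nuclei = nuclei,
    field = field
  )
}

#' Simulate a STORM localization table from placed emitters
#'
#' Each emitter blinks according to the [blink_model()]; every on-frame
#' yields one localization at the true position plus the frame's drift plus
#' isotropic Gaussian localization error whose per-axis standard deviation is
#' the localization's own precision, drawn from a right-skewed Gamma
#' distribution with mean `precision_mean_nm`. Fiducial beads emit exactly
#' one localization per frame with `fiducial_precision_nm` error. Quality
#' columns (fitted PSF width, log-likelihood score, photons) are populated
#' with values typical of in-focus single molecules so that default quality
#' filters retain them.
#'
#' @param placed output of [place_clusters()], or a data.frame of emitter
#'   positions with columns `x_nm`, `y_nm` (and optionally `cluster_id`).
#' @param blink a [blink_model()].
#' @param drift a [drift_model()] or a realized drift data.frame from
#'   [simulate_drift()]; `NULL` means no drift.
#' @param precision_mean_nm mean localization precision (nm); `0` gives the
#'   noise-free limit (localizations exactly at truth + drift).
#' @param precision_shape Gamma shape of the precision distribution.
#' @param fiducial_precision_nm localization error of fiducial beads (nm).
#' @param psf_sigma_nm typical fitted PSF width (nm) used to populate the
#'   `sigma_nm` quality column.
#' @param photons_median,photons_sdlog log-normal photon-count parameters.
#' @param seed integer seed.
#' @return list with elements
#'   \describe{
#'     \item{locs}{localization table: `frame`, `x_nm`, `y_nm`,
#'       `precision_nm`, `sigma_nm`, `loglike`, `photons`,
#'       `true_cluster_id` (negative ids are fiducials), sorted by frame}
#'     \item{truth}{data.frame of per-localization true positions
#'       (`true_x_nm`, `true_y_nm`, `source_id`), in the same order}
#'     \item{drift}{realized drift trajectory data.frame}
#'     \item{off_times}{all realized off-times (frames) across emitters}
#'     \item{frames_total}{number of frames}
#'   }
#' @export
simulate_localizations <- function(placed, blink = blink_model(),
                                   drift = drift_model("none"),
                                   precision_mean_nm = 10,
                                   precision_shape = 4,
                                   fiducial_precision_nm = 2,
                                   psf_sigma_nm = 150,
                                   photons_median = 3000,
                                   photons_sdlog = 0.4,
                                   seed = 1) {
  stopifnot(inherits(blink, "blink_model"), precision_mean_nm >= 0)
  frames_total <- blink$frames_total
  if (frames_total < 1) stop("frames_total must be >= 1")
  if (is.data.frame(placed)) {
    emitters <- placed
    if (is.null(emitters$cluster_id)) emitters$cluster_id <- seq_len(nrow(emitters))
    fiducials <- data.frame(id = integer(0), x_nm = numeric(0), y_nm = numeric(0))
  } else {
    emitters <- placed$emitters
    fiducials <- placed$fiducials
  }

  if (is.null(drift)) drift <- drift_model("none")
  dtab <- if (inherits(drift, "drift_model")) {
    simulate_drift(drift, frames_total, seed = seed + 101)
  } else {
    stopifnot(is.data.frame(drift), nrow(drift) >= frames_total)
    drift
  }

  set.seed((seed + 211) %% .Machine$integer.max)

  # blinking: per-emitter on-event start frames and durations
  rgeom1 <- function(n, mean) 1 + rgeom(n, 1 / mean)  # support 1,2,...
  ne <- nrow(emitters)
  ev_emitter <- ev_start <- ev_len <- list()
  off_times <- list()
  k <- 0
  immediate <- identical(blink$activation, "immediate")
  for (i in seq_len(ne)) {
    f <- if (immediate) 1L else sample.int(frames_total, 1)
    while (f <= frames_total) {
      len <- rgeom1(1, blink$mean_on_frames)
      len <- min(len, frames_total - f + 1)
      k <- k + 1
      ev_emitter[[k]] <- i; ev_start[[k]] <- f; ev_len[[k]] <- len
      if (runif(1) > blink$survival_prob_per_frame^len) break  # bleached
      use_short <- runif(1) < blink$off_weight_short
      off <- rgeom1(1, if (use_short) blink$off_mean_short else blink$off_mean_long)
      off_times[[length(off_times) + 1]] <- off
      f <- f + len + off
    }
  }
  if (k > 0) {
    ev_emitter <- unlist(ev_emitter); ev_start <- unlist(ev_start)
    ev_len <- unlist(ev_len)
    frame <- unlist(lapply(seq_len(k), function(j)
      seq.int(ev_start[j], length.out = ev_len[j])))
    src <- rep.int(ev_emitter, ev_len)
  } else {
    frame <- integer(0); src <- integer(0)
  }
  nl <- length(frame)

  prec <- if (precision_mean_nm == 0) rep(0, nl) else
    rgamma(nl, shape = precision_shape,
           scale = precision_mean_nm / precision_shape)
  ex <- emitters$x_nm[src]; ey <- emitters$y_nm[src]
  x <- ex + dtab$dx_nm[frame] + rnorm(nl, 0, 1) * prec
  y <- ey + dtab$dy_nm[frame] + rnorm(nl, 0, 1) * prec
  locs <- data.frame(
    frame = frame, x_nm = x, y_nm = y,
    precision_nm = prec,
    sigma_nm = rnorm_trunc(nl, psf_sigma_nm, 10, 50),
    loglike = rgamma(nl, shape = 4, scale = 25),
    photons = rlnorm(nl, log(photons_median), photons_sdlog),
    true_cluster_id = emitters$cluster_id[src])
  truth <- data.frame(true_x_nm = ex, true_y_nm = ey, source_id = src)

  # fiducials: exactly one localization per frame, bright and precise
  if (nrow(fiducials) > 0) {
    nf <- nrow(fiducials)
    ff <- rep(seq_len(frames_total), times = nf)
    fid <- rep(fiducials$id, each = frames_total)
    fx <- fiducials$x_nm[fid] + dtab$dx_nm[ff] +
      rnorm(length(ff), 0, fiducial_precision_nm)
    fy <- fiducials$y_nm[fid] + dtab$dy_nm[ff] +
      rnorm(length(ff), 0, fiducial_precision_nm)
    flocs <- data.frame(
      frame = ff, x_nm = fx, y_nm = fy,
      precision_nm = pmax(fiducial_precision_nm, 0.5),
      sigma_nm = rnorm_trunc(length(ff), psf_sigma_nm, 5, 50),
      loglike = rgamma(length(ff), shape = 4, scale = 25),
      photons = rlnorm(length(ff), log(20000), 0.2),
      true_cluster_id = -fid)
    ftruth <- data.frame(true_x_nm = fiducials$x_nm[fid],
                         true_y_nm = fiducials$y_nm[fid],
                         source_id = -fid)
    locs <- rbind(locs, flocs)
    truth <- rbind(truth, ftruth)
  }

  ord <- order(locs$frame)
  locs <- locs[ord, , drop = FALSE]
  truth <- truth[ord, , drop = FALSE]
  rownames(locs) <- rownames(truth) <- NULL
  list(locs = locs, truth = truth,
       drift = dtab[seq_len(frames_total), , drop = FALSE],
       off_times = if (length(off_times)) unlist(off_times) else integer(0),
       frames_total = frames_total)
}

#' Render a diffraction-limited wide-field reference image
#'
#' Sums isotropic Gaussian spots (one per source position, intensity
#' proportional to its weight) onto a pixel grid, adds a constant background
#' and, optionally, Poisson shot noise. Image rows index y, columns index x;
#' pixel (1,1) covers \[0, pixel) in both axes.
#'
#' @param positions n x 2 matrix or data.frame of spot centers (nm).
#' @param field_size_nm field width/height (nm).
#' @param weights per-spot relative intensity (default 1).
#' @param pixel_size_nm camera pixel size (nm).
#' @param psf_sigma_nm Gaussian spot sigma (nm).
#' @param peak_adu peak amplitude (ADU) of a weight-1 spot.
#' @param background_adu constant background level (ADU).
#' @param poisson_noise add Poisson noise?
#' @param offset_nm length-2 shift (nm) added to all spot positions before
#'   rendering; emulates the channel offset between the localization frame
#'   and the wide-field acquisition.
#' @param seed integer seed for the noise.
#' @return numeric matrix (ADU) with attributes `pixel_size_nm`.
#' @export
render_widefield <- function(positions, field_size_nm,
                             weights = NULL,
                             pixel_size_nm = 108, psf_sigma_nm = 130,
                             peak_adu = 400, background_adu = 100,
                             poisson_noise = TRUE,
                             offset_nm = c(0, 0), seed = 1) {
  stopifnot(pixel_size_nm > 0, psf_sigma_nm > 0)
  positions <- as.matrix(positions)
  nx <- ceiling(field_size_nm[1] / pixel_size_nm)
  ny <- ceiling(field_size_nm[2] / pixel_size_nm)
  img <- matrix(background_adu, nrow = ny, ncol = nx)
  n <- nrow(positions)
  if (is.null(weights)) weights <- rep(1, max(n, 1))
  if (n > 0) {
    cx <- (seq_len(nx) - 0.5) * pixel_size_nm
    cy <- (seq_len(ny) - 0.5) * pixel_size_nm
    half <- ceiling(4 * psf_sigma_nm / pixel_size_nm)
    for (i in seq_len(n)) {
      px <- positions[i, 1] + offset_nm[1]
      py <- positions[i, 2] + offset_nm[2]
      jc <- round(px / pixel_size_nm + 0.5)
      ic <- round(py / pixel_size_nm + 0.5)
      jj <- max(1, jc - half):min(nx, jc + half)
      ii <- max(1, ic - half):min(ny, ic + half)
      if (!length(jj) || !length(ii)) next
      gx <- exp(-(cx[jj] - px)^2 / (2 * psf_sigma_nm^2))
      gy <- exp(-(cy[ii] - py)^2 / (2 * psf_sigma_nm^2))
      img[ii, jj] <- img[ii, jj] + (peak_adu * weights[i]) * outer(gy, gx)
    }
  }
  if (poisson_noise) {
    set.seed((seed + 307) %% .Machine$integer.max)
    img[] <- rpois(length(img), lambda = img)
  }
  attr(img, "pixel_size_nm") <- pixel_size_nm
  img
}

#' Simulate a raw single-molecule frame stack
#'
#' Desk-scale raw-data generator for the localization stage: each frame
#' contains PSF-sized Gaussian spots of the emitters that are "on" in that
#' frame (each emitter is on independently with probability `duty_cycle`),
#' plus constant background, all corrupted by Poisson noise.
#'
#' @param emitters data.frame/matrix with emitter positions (nm).
#' @param n_frames number of frames.
#' @param field_size_nm field width/height (nm).
#' @param pixel_size_nm camera pixel size (nm).
#' @param psf_sigma_nm PSF Gaussian sigma (nm).
#' @param photons expected photons per on-emitter per frame.
#' @param background_adu expected background per pixel.
#' @param duty_cycle per-frame on-probability of each emitter.
#' @param seed integer seed.
#' @return list with `frames` (3D array frame x row x col),
#'   `pixel_size_nm`, and `on_truth` (data.frame `frame`, `emitter`,
#'   `x_nm`, `y_nm` of every on-event).
#' @export
simulate_frame_stack <- function(emitters, n_frames = 20,
                                 field_size_nm = c(6000, 6000),
                                 pixel_size_nm = 108, psf_sigma_nm = 140,
                                 photons = 3000, background_adu = 20,
                                 duty_cycle = 0.2, seed = 1) {
  emitters <- as.matrix(emitters)
  set.seed((seed + 401) %% .Machine$integer.max)
  nx <- ceiling(field_size_nm[1] / pixel_size_nm)
  ny <- ceiling(field_size_nm[2] / pixel_size_nm)
  frames <- array(0, dim = c(n_frames, ny, nx))
  cx <- (seq_len(nx) - 0.5) * pixel_size_nm
  cy <- (seq_len(ny) - 0.5) * pixel_size_nm
  amp <- photons / (2 * pi * (psf_sigma_nm / pixel_size_nm)^2)
  on_truth <- list()
  for (f in seq_len(n_frames)) {
    img <- matrix(background_adu, ny, nx)
    on <- which(runif(nrow(emitters)) < duty_cycle)
    for (i in on) {
      gx <- exp(-(cx - emitters[i, 1])^2 / (2 * psf_sigma_nm^2))
      gy <- exp(-(cy - emitters[i, 2])^2 / (2 * psf_sigma_nm^2))
      img <- img + amp * outer(gy, gx)
    }
    img[] <- rpois(length(img), img)
    frames[f, , ] <- img
    if (length(on))
      on_truth[[length(on_truth) + 1]] <-
        data.frame(frame = f, emitter = on,
                   x_nm = emitters[on, 1], y_nm = emitters[on, 2])
  }
  list(frames = frames, pixel_size_nm = pixel_size_nm,
       on_truth = if (length(on_truth)) do.call(rbind, on_truth) else
         data.frame(frame = integer(0), emitter = integer(0),
                    x_nm = numeric(0), y_nm = numeric(0)))
}

#' Simulate one complete synthetic FOV
#'
#' Convenience wrapper producing everything downstream stages consume:
#' placed ground truth, the localization table, and wide-field reference
#' images for the telomere-probe channel (all clusters) and the DDR-marker
#' channel (DDR-positive clusters only, rendered with a larger PSF to mimic
#' the large 53BP1/gamma-H2AX foci). Both wide-field images are rendered
#' with the same `channel_offset_nm` relative to the localization frame, as
#' the two acquisitions share the stage position.
#'
#' @param field an [emitter_field()].
#' @param blink a [blink_model()].
#' @param drift a [drift_model()].
#' @param channel_offset_nm true offset (nm) between localization
#'   coordinates and the wide-field images.
#' @param pixel_size_nm wide-field pixel size (nm).
#' @param psf_sigma_nm probe-channel spot sigma (nm).
#' @param ddr_psf_sigma_nm DDR-channel locus sigma (nm).
#' @param precision_mean_nm mean localization precision (nm).
#' @param seed integer seed; all stage sub-streams derive from it.
#' @param ... further arguments passed to [simulate_localizations()].
#' @return list with `locs`, `truth` (per-localization), `ground_truth`
#'   (placed clusters/fiducials/nuclei, drift, channel offset), `widefield`
#'   (probe image), `ddr_widefield`, `frames_total`, `field`.
#' @export
simulate_fov <- function(field = emitter_field(),
                         blink = blink_model(),
                         drift = drift_model("smooth-random", 100),
                         channel_offset_nm = c(50, 45),
                         pixel_size_nm = 108,
                         psf_sigma_nm = 130,
                         ddr_psf_sigma_nm = 300,
                         precision_mean_nm = 10,
                         seed = 1, ...) {
  placed <- place_clusters(field, seed = seed)
  sim <- simulate_localizations(placed, blink = blink, drift = drift,
                                precision_mean_nm = precision_mean_nm,
                                seed = seed, ...)
  wf <- render_widefield(placed$clusters[, c("x_nm", "y_nm")],
                         field_size_nm = field$field_size_nm,
                         weights = rep(field$emitters_per_cluster,
                                       nrow(placed$clusters)) / 40,
                         pixel_size_nm = pixel_size_nm,
                         psf_sigma_nm = psf_sigma_nm,
                         offset_nm = channel_offset_nm, seed = seed + 1)
  pos_ddr <- placed$clusters[placed$clusters$ddr_positive,
                             c("x_nm", "y_nm"), drop = FALSE]
  ddr <- render_widefield(pos_ddr,
                          field_size_nm = field$field_size_nm,
                          pixel_size_nm = pixel_size_nm,
                          psf_sigma_nm = ddr_psf_sigma_nm,
                          peak_adu = 600,
                          offset_nm = channel_offset_nm, seed = seed + 2)
  list(locs = sim$locs, truth = sim$truth,
       ground_truth = list(clusters = placed$clusters,
                           fiducials = placed$fiducials,
                           nuclei = placed$nuclei,
                           drift = sim$drift,
                           channel_offset_nm = channel_offset_nm,
                           off_times = sim$off_times),
       widefield = wf, ddr_widefield = ddr,
       frames_total = sim$frames_total, field = field)
}
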