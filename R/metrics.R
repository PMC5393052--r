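#' Radius of gyration of a point set
#'
#' Root-mean-square distance of the points from their (unweighted) center
#' of mass: `rg = sqrt(mean(|r_i - rbar|^2))`. This is the primary telomere
#' size statistic: unlike the convex hull it uses every localization and
#' assumes nothing about cluster shape.
#'
#' @param points n x 2 matrix or data.frame of coordinates (nm).
#' @return non-negative scalar (nm); 0 iff all points coincide.
#' @export
radius_of_gyration <- function(points) {
  points <- as.matrix(points)
  if (nrow(points) == 0) stop("empty point set")
  cx <- mean(points[, 1]); cy <- mean(points[, 2])
  sqrt(mean((points[, 1] - cx)^2 + (points[, 2] - cy)^2))
}

#' Convex hull area of a point set
#'
#' Area of the convex hull (shoelace formula on the hull vertices from
#' [grDevices::chull()]). Degenerate sets (fewer than 3 distinct points, or
#' collinear points) have area 0.
#'
#' @param points n x 2 matrix or data.frame of coordinates (nm).
#' @return hull area (nm^2).
#' @export
convex_hull_area <- function(points) {
  points <- as.matrix(points)
  if (nrow(points) == 0) stop("empty point set")
  if (nrow(points) < 3) return(0)
  h <- chull(points[, 1], points[, 2])
  if (length(h) < 3) return(0)
  x <- points[h, 1]; y <- points[h, 2]
  abs(sum(x * c(y[-1], y[1]) - c(x[-1], x[1]) * y)) / 2
}

#' Hull-volume proxy
#'
#' Approximate 3D volume for 2D clusters: the convex hull area raised to
#' the power 3/2 (volume scales with the third power of linear size, area
#' with the second).
#'
#' @param area hull area (nm^2, >= 0).
#' @return `area^(3/2)` (nm^3).
#' @export
hull_volume_proxy <- function(area) {
  if (any(area < 0)) stop("negative area")
  area^1.5
}

#' Per-cluster morphometrics
#'
#' Computes, for each cluster of localizations: the number of
#' localizations, radius of gyration, convex hull area and its volume
#' proxy, and the centroid. Optional condition and per-cluster DDR labels
#' are carried through for downstream grouping.
#'
#' @param clusters list of member-index vectors into `locs`.
#' @param locs localization table.
#' @param condition optional condition label (recycled).
#' @param ddr_class optional per-cluster DDR class vector.
#' @return data.frame of class `cluster_metrics`: `cluster_id`,
#'   `condition`, `ddr_class`, `n_localizations`, `rg_nm`, `hull_area_nm2`,
#'   `hull_volume_proxy_nm3`, `centroid_x_nm`, `centroid_y_nm`.
#' @export
compute_metrics <- function(clusters, locs, condition = NA_character_,
                            ddr_class = NULL) {
  n <- length(clusters)
  if (n == 0) {
    out <- data.frame(cluster_id = integer(0), condition = character(0),
                      ddr_class = character(0), n_localizations = integer(0),
                      rg_nm = numeric(0), hull_area_nm2 = numeric(0),
                      hull_volume_proxy_nm3 = numeric(0),
                      centroid_x_nm = numeric(0), centroid_y_nm = numeric(0))
    class(out) <- c("cluster_metrics", "data.frame")
    return(out)
  }
  if (is.null(ddr_class)) ddr_class <- rep("unlabeled", n)
  nmax <- nrow(locs)
  rows <- lapply(seq_len(n), function(ci) {
    idx <- clusters[[ci]]
    if (any(idx < 1 | idx > nmax))
      stop(sprintf("cluster %d references missing localization indices", ci))
    pts <- cbind(locs$x_nm[idx], locs$y_nm[idx])
    a <- convex_hull_area(pts)
    data.frame(cluster_id = ci,
               n_localizations = length(idx),
               rg_nm = radius_of_gyration(pts),
               hull_area_nm2 = a,
               hull_volume_proxy_nm3 = hull_volume_proxy(a),
               centroid_x_nm = mean(pts[, 1]),
               centroid_y_nm = mean(pts[, 2]))
  })
  out <- do.call(rbind, rows)
  out$condition <- rep_len(condition, n)
  out$ddr_class <- as.character(rep_len(ddr_class, n))
  out <- out[, c("cluster_id", "condition", "ddr_class", "n_localizations",
                 "rg_nm", "hull_area_nm2", "hull_volume_proxy_nm3",
                 "centroid_x_nm", "centroid_y_nm")]
  class(out) <- c("cluster_metrics", "data.frame")
  out
}

#' Expected Rg inflation from localization noise
#'
#' For a cluster with true radius of gyration `rg_true` whose localizations
#' carry isotropic Gaussian error with per-axis standard deviation `sigma`,
#' the expected squared measured Rg is `rg_true^2 + 2 sigma^2`. Provided as
#' a diagnostic for interpreting measured sizes near the localization
#' precision; no correction is applied to reported Rg values.
#'
#' @param rg_true_nm true radius of gyration (nm).
#' @param sigma_nm per-axis localization error SD (nm).
#' @return expected measured Rg (nm).
#' @export
expected_rg_noisy <- function(rg_true_nm, sigma_nm) {
  sqrt(rg_true_nm^2 + 2 * sigma_nm^2)
}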