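#' Spatial clustering parameters
#'
#' DBSCAN parameters for grouping merged localizations into telomere
#' candidate clusters. Defaults: neighbourhood radius 90 nm, a core point
#' needs at least 8 neighbours within that radius (counting itself), and
#' clusters with fewer than 50 localizations are removed afterwards because
#' such groups rarely coincide with a wide-field telomere focus.
#'
#' @param eps_nm neighbourhood radius (nm, > 0).
#' @param min_samples minimum neighbours (self-inclusive) for a core point.
#' @param min_cluster_size minimum localizations per kept cluster
#'   (>= `min_samples`).
#' @return An object of class `cluster_params`.
#' @export
cluster_params <- function(eps_nm = 90, min_samples = 8,
                           min_cluster_size = 50) {
  stopifnot(eps_nm > 0, min_samples >= 1, min_cluster_size >= min_samples)
  structure(list(eps_nm = eps_nm, min_samples = min_samples,
                 min_cluster_size = min_cluster_size),
            class = "cluster_params")
}

# eps-ball neighbour lists (self-inclusive, closed ball) via grid binning:
# points are hashed into eps-sized cells and neighbours searched in the
# 3 x 3 surrounding cells only.
eps_neighbours <- function(x, y, eps) {
  n <- length(x)
  ix <- floor(x / eps); iy <- floor(y / eps)
  ix <- ix - min(ix) + 1L; iy <- iy - min(iy) + 1L
  ncx <- max(ix)
  key <- ix + (iy - 1L) * ncx
  cells <- split(seq_len(n), key)
  cell_of <- match(key, as.integer(names(cells)))
  # candidate pool per cell: indices in the 3x3 neighbourhood
  keys <- as.integer(names(cells))
  kx <- ((keys - 1L) %% ncx) + 1L
  ky <- ((keys - 1L) %/% ncx) + 1L
  keymap <- new.env(hash = TRUE, size = length(keys))
  for (j in seq_along(keys)) assign(as.character(keys[j]), j, envir = keymap)
  eps2 <- eps^2
  adj <- vector("list", n)
  for (j in seq_along(cells)) {
    cand <- integer(0)
    for (dx in -1:1) for (dy in -1:1) {
      cx <- kx[j] + dx; cy <- ky[j] + dy
      if (cx < 1L || cx > ncx || cy < 1L) next
      kk <- as.character(cx + (cy - 1L) * ncx)
      jj <- keymap[[kk]]
      if (!is.null(jj)) cand <- c(cand, cells[[jj]])
    }
    cand <- sort(cand)
    for (i in cells[[j]]) {
      d2 <- (x[cand] - x[i])^2 + (y[cand] - y[i])^2
      adj[[i]] <- cand[d2 <= eps2]
    }
  }
  adj
}

#' Cluster localizations with DBSCAN
#'
#' Standard DBSCAN semantics with a closed eps-ball and self-inclusive
#' neighbour counting: a point is a core point if at least `min_samples`
#' points (itself included) lie within `eps_nm`; clusters are the maximal
#' density-connected sets of core points plus any border points (non-core
#' points with a core neighbour); all remaining points are noise. Points
#' are processed in index order and border points join the
#' first-discovered eligible cluster, making the labelling deterministic.
#'
#' @param locs localization table (columns `x_nm`, `y_nm`), or a two-column
#'   matrix of coordinates in nm.
#' @param params a [cluster_params()].
#' @return An object of class `storm_clusters`: list with
#'   \describe{
#'     \item{labels}{integer vector, cluster id per point (-1 = noise)}
#'     \item{clusters}{list of member index vectors, one per cluster id}
#'     \item{is_core}{logical vector of core-point status}
#'     \item{params}{the clustering parameters}
#'   }
#' @export
cluster_dbscan <- function(locs, params = cluster_params()) {
  stopifnot(inherits(params, "cluster_params"))
  if (is.matrix(locs)) {
    x <- locs[, 1]; y <- locs[, 2]
  } else {
    x <- locs$x_nm; y <- locs$y_nm
  }
  n <- length(x)
  if (n == 0) stop("empty localization table")
  adj <- eps_neighbours(x, y, params$eps_nm)
  is_core <- lengths(adj) >= params$min_samples
  labels <- rep.int(-1L, n)
  cid <- 0L
  for (i in seq_len(n)) {
    if (!is_core[i] || labels[i] != -1L) next
    cid <- cid + 1L
    labels[i] <- cid
    queue <- adj[[i]]
    head <- 1L
    labels[queue[labels[queue] == -1L]] <- cid
    while (head <= length(queue)) {
      p <- queue[head]; head <- head + 1L
      if (is_core[p]) {
        nb <- adj[[p]]
        fresh <- nb[labels[nb] == -1L]
        if (length(fresh)) {
          labels[fresh] <- cid
          queue <- c(queue, fresh)
        }
      }
    }
  }
  clusters <- if (cid > 0) split(seq_len(n), factor(labels, levels = seq_len(cid)))
              else list()
  structure(list(labels = labels, clusters = unname(clusters),
                 is_core = is_core, params = params),
            class = "storm_clusters")
}

#' Remove clusters below the minimum size
#'
#' Strict inequality: clusters with exactly `min_cluster_size`
#' localizations are kept.
#'
#' @param clustering a `storm_clusters` from [cluster_dbscan()], or a plain
#'   list of member-index vectors.
#' @param min_cluster_size minimum localizations per cluster.
#' @return list with `clusters` (kept member-index list), `labels`
#'   (relabelled, dropped members become noise; only for `storm_clusters`
#'   input) and `dropped` (number of clusters removed).
#' @export
gate_clusters <- function(clustering, min_cluster_size = 50) {
  cl <- if (inherits(clustering, "storm_clusters")) clustering$clusters
        else clustering
  keep <- lengths(cl) >= min_cluster_size
  kept <- cl[keep]
  labels <- NULL
  if (inherits(clustering, "storm_clusters")) {
    labels <- rep.int(-1L, length(clustering$labels))
    for (j in seq_along(kept)) labels[kept[[j]]] <- j
  }
  list(clusters = kept, labels = labels, dropped = sum(!keep))
}

#' @export
print.storm_clusters <- function(x, ...) {
  cat(sprintf("DBSCAN clustering: %d points, %d clusters, %d noise (eps=%g nm, min_samples=%d)\n",
              length(x$labels), length(x$clusters), sum(x$labels == -1L),
              x$params$eps_nm, x$params$min_samples))
  invisible(x)
}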