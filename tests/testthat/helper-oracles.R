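# Independent brute-force DBSCAN oracle: full O(n^2) distance matrix,
# self-inclusive closed-ball neighbour counts, clusters = connected
# components of the core-core adjacency graph (igraph).
oracle_dbscan <- function(pts, eps, min_samples) {
  n <- nrow(pts)
  d <- as.matrix(dist(pts))
  nb <- d <= eps
  core <- rowSums(nb) >= min_samples
  comp <- rep(NA_integer_, n)
  if (any(core)) {
    adj <- nb & outer(core, core, "&")
    g <- igraph::graph_from_adjacency_matrix(adj[core, core, drop = FALSE],
                                             mode = "undirected")
    comp[core] <- igraph::components(g)$membership
  }
  border <- !core & apply(nb & matrix(core, n, n, byrow = TRUE), 1, any)
  list(core = core, comp = comp, border = border,
       noise = !core & !border, nb = nb)
}

# Compare a cluster_dbscan() result against the oracle partition, allowing
# border points to differ in tie cases (they must still sit next to a core
# point of their assigned cluster).
expect_dbscan_matches_oracle <- function(pts, params) {
  res <- cluster_dbscan(pts, params)
  orc <- oracle_dbscan(pts, params$eps_nm, params$min_samples)
  expect_identical(res$is_core, unname(orc$core))
  expect_identical(res$labels == -1L, unname(orc$noise))
  # core partitions identical up to label permutation: canonicalize each
  # cluster by the smallest core index it contains
  core_idx <- which(orc$core)
  if (length(core_idx)) {
    canon <- function(lab) {
      key <- tapply(core_idx, lab[core_idx], min)
      unname(key[as.character(lab[core_idx])])
    }
    expect_identical(canon(res$labels), canon(orc$comp))
  }
  # border points: assigned cluster must contain one of their core
  # eps-neighbours
  for (i in which(orc$border)) {
    lab <- res$labels[i]
    expect_true(lab != -1L)
    nbc <- which(orc$nb[i, ] & orc$core)
    expect_true(lab %in% res$labels[nbc])
  }
  invisible(res)
}

# synthetic frame with isotropic Gaussian spots (pixel j center at j - 0.5)
gauss_frame <- function(n, spots, sigma_px = 1.3, background = 5) {
  xg <- seq_len(n) - 0.5
  fr <- matrix(background, n, n)
  for (k in seq_len(nrow(spots))) {
    gx <- exp(-(xg - spots[k, 1])^2 / (2 * sigma_px^2))
    gy <- exp(-(xg - spots[k, 2])^2 / (2 * sigma_px^2))
    fr <- fr + spots[k, 3] / (2 * pi * sigma_px^2) * outer(gy, gx)
  }
  fr
}

# blink model for an emitter that stays on for the whole acquisition
always_on <- function(frames_total) {
  blink_model(mean_on_frames = 10 * frames_total, off_mean_short = 1,
              off_mean_long = 1, off_weight_short = 1,
              survival_prob_per_frame = 1, frames_total = frames_total,
              activation = "immediate")
}

# minimal localization table
loc_table <- function(frame, x, y, precision = 10, sigma = 150,
                      loglike = 100, photons = 1000) {
  data.frame(frame = frame, x_nm = x, y_nm = y,
             precision_nm = rep_len(precision, length(frame)),
             sigma_nm = rep_len(sigma, length(frame)),
             loglike = rep_len(loglike, length(frame)),
             photons = rep_len(photons, length(frame)))
}
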