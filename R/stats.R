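#' Summarize the Rg distribution of one condition
#'
#' Mean, SD, quartiles, Gaussian kernel density estimate (Silverman
#' bandwidth by default) and tail fractions of the per-cluster radius of
#' gyration, plus the mean localization count. Tail fractions use a strict
#' inequality (`rg > threshold`).
#'
#' @param metrics a [compute_metrics()] data.frame.
#' @param condition optional condition label to subset on (default: all
#'   rows).
#' @param thresholds_nm thresholds for the `fraction_rg_above` tail
#'   fractions (nm).
#' @param bw KDE bandwidth rule or value (see [stats::density()]).
#' @param kde_n KDE grid size.
#' @return An object of class `condition_summary`: list with `condition`,
#'   `n_telomeres`, `mean_rg_nm`, `sd_rg_nm`, `quartiles_nm`,
#'   `mean_n_localizations`, `fraction_rg_above` (named), and `kde`
#'   (data.frame `rg_nm`, `density`, integrating to 1; NULL when the
#'   sample is constant).
#' @export
summarize_condition <- function(metrics, condition = NULL,
                                thresholds_nm = c(80, 100),
                                bw = "nrd0", kde_n = 512) {
  d <- metrics
  if (!is.null(condition)) d <- d[d$condition %in% condition, , drop = FALSE]
  if (nrow(d) < 2) stop("need at least 2 clusters in the condition")
  rg <- d$rg_nm
  kde <- NULL
  if (sd(rg) > 0) {
    k <- density(rg, bw = bw, n = kde_n)
    kde <- data.frame(rg_nm = k$x, density = k$y)
  }
  fr <- vapply(thresholds_nm, function(t) mean(rg > t), numeric(1))
  structure(list(
    condition = if (is.null(condition)) unique(d$condition) else condition,
    n_telomeres = nrow(d),
    mean_rg_nm = mean(rg),
    sd_rg_nm = sd(rg),
    quartiles_nm = quantile(rg, c(0.25, 0.5, 0.75)),
    mean_n_localizations = mean(d$n_localizations),
    fraction_rg_above = setNames(fr, paste0(">", thresholds_nm, "nm")),
    kde = kde
  ), class = "condition_summary")
}

#' @export
print.condition_summary <- function(x, ...) {
  cat(sprintf("Condition %s: %d telomeres\n",
              paste(x$condition, collapse = "/"), x$n_telomeres))
  cat(sprintf("  mean Rg %.1f nm (SD %.1f), quartiles %.1f/%.1f/%.1f nm\n",
              x$mean_rg_nm, x$sd_rg_nm,
              x$quartiles_nm[1], x$quartiles_nm[2], x$quartiles_nm[3]))
  cat(sprintf("  mean localizations per telomere %.0f\n",
              x$mean_n_localizations))
  for (i in seq_along(x$fraction_rg_above))
    cat(sprintf("  fraction Rg %s: %.1f%%\n",
                names(x$fraction_rg_above)[i],
                100 * x$fraction_rg_above[i]))
  invisible(x)
}

#' Chromatin density ratio between two telomere populations
#'
#' Treating each telomere as a sphere whose radius scales with its radius
#' of gyration, the ratio of chromatin volume densities between a
#' long-telomere population L (mean length `N_L` kb, mean radius of
#' gyration `Rg_L` um) and a short-telomere population S is
#' \deqn{\rho_L/\rho_S = (N_L / Rg_L^3) \cdot (Rg_S^3 / N_S).}
#' The experiment-to-experiment variation of the mean Rg (`delta_um`,
#' default 0.005 um) yields an upper bound (shrink `Rg_L`, grow `Rg_S` by
#' `delta`) and a lower bound (the converse).
#'
#' @param length_L_kb,length_S_kb mean telomere lengths (kb, > 0).
#' @param rg_L_um,rg_S_um mean radii of gyration (um, > 0).
#' @param delta_um mean-Rg variation (um, >= 0 and < both radii).
#' @return An object of class `density_ratio_estimate`: list with `ratio`,
#'   `upper`, `lower` (full precision), their 2-significant-figure display
#'   values, and the inputs.
#' @export
density_ratio <- function(length_L_kb, rg_L_um, length_S_kb, rg_S_um,
                          delta_um = 0.005) {
  stopifnot(length_L_kb > 0, length_S_kb > 0, rg_L_um > 0, rg_S_um > 0,
            delta_um >= 0)
  if (delta_um >= rg_L_um || delta_um >= rg_S_um)
    stop("delta must be smaller than both radii of gyration")
  est <- function(rgL, rgS) (length_L_kb / rgL^3) * (rgS^3 / length_S_kb)
  ratio <- est(rg_L_um, rg_S_um)
  upper <- est(rg_L_um - delta_um, rg_S_um + delta_um)
  lower <- est(rg_L_um + delta_um, rg_S_um - delta_um)
  structure(list(
    ratio = ratio, upper = upper, lower = lower,
    ratio_display = signif(ratio, 2),
    upper_display = signif(upper, 2),
    lower_display = signif(lower, 2),
    inputs = list(length_L_kb = length_L_kb, rg_L_um = rg_L_um,
                  length_S_kb = length_S_kb, rg_S_um = rg_S_um,
                  delta_um = delta_um)
  ), class = "density_ratio_estimate")
}

#' @export
print.density_ratio_estimate <- function(x, ...) {
  cat(sprintf("Chromatin density ratio rho_L/rho_S = %.2g (range %.2g-%.2g at delta = %g um)\n",
              x$ratio_display, x$lower_display, x$upper_display,
              x$inputs$delta_um))
  invisible(x)
}

#' B-DNA contour length
#'
#' Contour length of a B-form double helix: `n_bp x rise` nm. The default
#' helical rise of 0.332 nm/bp is the constant consistent with a 3650-nm
#' contour for an 11,000-bp telomere; the textbook 0.34 nm/bp is
#' selectable.
#'
#' @param n_bp number of base pairs (>= 0).
#' @param rise_nm_per_bp helical rise (nm/bp, > 0).
#' @return contour length in nm (full precision; display-round with
#'   `signif(x, 3)`).
#' @export
contour_length <- function(n_bp, rise_nm_per_bp = 0.332) {
  stopifnot(n_bp >= 0, rise_nm_per_bp > 0)
  n_bp * rise_nm_per_bp
}

#' Compaction-in-length factor
#'
#' Upper bound on the linear compaction of chromatin: the DNA contour
#' length divided by the cluster's linear extent, taken as the 2 Rg
#' diameter. Dividing by the diameter (the largest linear proxy consistent
#' with the measured Rg) makes the factor an upper bound.
#'
#' @param contour_nm DNA contour length (nm, > 0).
#' @param rg_nm measured radius of gyration (nm, > 0).
#' @return fold-compaction factor.
#' @export
compaction_factor <- function(contour_nm, rg_nm) {
  stopifnot(contour_nm > 0)
  if (any(rg_nm <= 0)) stop("rg must be positive")
  contour_nm / (2 * rg_nm)
}

#' Association between cluster size and localization count
#'
#' Spearman rank correlation of per-cluster Rg versus the number of
#' localizations, plus the joint table for plotting. Telomere clusters
#' containing more DNA yield both more localizations and larger Rg, so a
#' positive association is the expected signature of telomere-telomere
#' associations among large clusters.
#'
#' @param metrics a [compute_metrics()] data.frame.
#' @return list with `spearman_rho`, `n`, `table` (data.frame
#'   `n_localizations`, `rg_nm`), `small_sample` (TRUE below 10 clusters)
#'   and `note` (e.g. when a variable is constant and the correlation is
#'   undefined).
#' @export
rg_vs_n <- function(metrics) {
  n <- nrow(metrics)
  if (n < 2) stop("need at least 2 clusters")
  tab <- data.frame(n_localizations = metrics$n_localizations,
                    rg_nm = metrics$rg_nm)
  note <- NULL
  if (var(tab$n_localizations) == 0 || var(tab$rg_nm) == 0) {
    rho <- NA_real_
    note <- "correlation undefined: a variable is constant"
  } else {
    rho <- cor(tab$n_localizations, tab$rg_nm, method = "spearman")
  }
  list(spearman_rho = rho, n = n, table = tab,
       small_sample = n < 10, note = note)
}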