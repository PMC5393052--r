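#' Build a pipeline configuration
#'
#' A `storm_config` gathers every stage's parameters plus the experimental
#' conditions to simulate (or the localization CSVs to read). Invariants
#' are checked by [validate_config()]; [run_pipeline()] refuses to run an
#' invalid configuration.
#'
#' @param seed global integer seed; every stage derives its own sub-stream
#'   from it deterministically.
#' @param mode `"simulate"` (conditions are generated by the synthetic
#'   module) or `"localization-csv"` (conditions name CSV files).
#' @param conditions list of condition descriptions. For `"simulate"`:
#'   `list(label =, n_fov =, mean_rg_nm =, sd_rg_nm =, length_kb =)` (plus
#'   optional overrides of [emitter_field()] arguments, e.g. `n_clusters`,
#'   `n_fiducials`). For `"localization-csv"`: `list(label =, files =,
#'   widefield =, ddr_widefield =, frames_total =)`.
#' @param field named list of default [emitter_field()] arguments shared by
#'   all simulated conditions.
#' @param blink named list of [blink_model()] arguments.
#' @param drift named list of [drift_model()] arguments.
#' @param precision_mean_nm mean localization precision (nm).
#' @param channel_offset_nm true localization-to-wide-field offset (nm)
#'   used by the simulator.
#' @param filter named list of [filter_params()] arguments.
#' @param cluster named list of [cluster_params()] arguments.
#' @param register named list of [register_params()] arguments.
#' @param qc named list: `f_locus`, `r_min`.
#' @param ddr named list: `f_lo`, `f_hi`.
#' @param thresholds_nm Rg tail-fraction thresholds for the summaries.
#' @param out_dir optional output directory for stage artifacts.
#' @return An object of class `storm_config`.
#' @export
storm_config <- function(seed = 1,
                         mode = c("simulate", "localization-csv"),
                         conditions = list(list(label = "control",
                                                n_fov = 1)),
                         field = list(),
                         blink = list(),
                         drift = list(kind = "smooth-random",
                                      magnitude_nm = 100),
                         precision_mean_nm = 10,
                         channel_offset_nm = c(50, 45),
                         filter = list(),
                         cluster = list(),
                         register = list(),
                         qc = list(f_locus = 0.5, r_min = 0.3),
                         ddr = list(f_lo = 0.1, f_hi = 0.9),
                         thresholds_nm = c(80, 100),
                         out_dir = NULL) {
  structure(list(seed = seed, mode = match.arg(mode),
                 conditions = conditions, field = field, blink = blink,
                 drift = drift, precision_mean_nm = precision_mean_nm,
                 channel_offset_nm = channel_offset_nm, filter = filter,
                 cluster = cluster, register = register, qc = qc,
                 ddr = ddr, thresholds_nm = thresholds_nm,
                 out_dir = out_dir),
            class = "storm_config")
}

#' Validate a pipeline configuration
#'
#' Checks every stage block's invariants and the cross-field rules without
#' throwing; each problem is reported as `"path: description"`.
#'
#' @param config a [storm_config()].
#' @return character vector of problems (empty when the config is valid).
#' @export
validate_config <- function(config) {
  problems <- character(0)
  add <- function(path, msg) problems <<- c(problems,
                                            paste0(path, ": ", msg))
  if (!inherits(config, "storm_config")) {
    return("config: not a storm_config object")
  }
  if (!is.numeric(config$seed) || length(config$seed) != 1)
    add("seed", "must be a single number")
  if (length(config$conditions) == 0)
    add("conditions", "at least one condition required")
  for (i in seq_along(config$conditions)) {
    cond <- config$conditions[[i]]
    if (is.null(cond$label))
      add(sprintf("conditions[[%d]].label", i), "missing")
    if (config$mode == "simulate") {
      if (!is.null(cond$n_fov) && cond$n_fov < 1)
        add(sprintf("conditions[[%d]].n_fov", i), "must be >= 1")
      if (!is.null(cond$mean_rg_nm) && cond$mean_rg_nm <= 0)
        add(sprintf("conditions[[%d]].mean_rg_nm", i), "must be > 0")
    } else if (is.null(cond$files)) {
      add(sprintf("conditions[[%d]].files", i), "missing")
    }
  }
  check_ctor <- function(args, ctor, path) {
    ok <- tryCatch({ do.call(ctor, args); TRUE },
                   error = function(e) { add(path, conditionMessage(e)); FALSE })
    invisible(ok)
  }
  check_ctor(config$field, emitter_field, "field")
  check_ctor(config$blink, blink_model, "blink")
  check_ctor(config$drift, function(kind = "smooth-random",
                                    magnitude_nm = 100)
    drift_model(kind, magnitude_nm), "drift")
  check_ctor(config$filter, filter_params, "filter")
  check_ctor(config$cluster, cluster_params, "cluster")
  check_ctor(config$register, register_params, "register")
  if (!is.null(config$cluster$min_cluster_size) &&
      !is.null(config$cluster$min_samples) &&
      config$cluster$min_cluster_size < config$cluster$min_samples)
    add("cluster.min_cluster_size", "must be >= cluster.min_samples")
  if (config$precision_mean_nm < 0)
    add("precision_mean_nm", "must be >= 0")
  if (!is.null(config$ddr$f_lo) && !is.null(config$ddr$f_hi) &&
      config$ddr$f_lo > config$ddr$f_hi)
    add("ddr.f_lo", "must be <= ddr.f_hi")
  problems
}

#' Process one FOV through the analysis stages
#'
#' Drift correction (fiducial tracks, spline averaging, subtraction),
#' fiducial removal, quality filtering, blink merging, DBSCAN clustering,
#' size gating, wide-field registration, automated QC and DDR
#' classification, and per-cluster metrics.
#'
#' @param locs localization table for the FOV.
#' @param frames_total frames in the acquisition.
#' @param widefield,ddr_widefield wide-field reference matrices (with
#'   `pixel_size_nm` attributes); either may be `NULL` to skip the
#'   corresponding stage.
#' @param config a [storm_config()].
#' @param condition condition label carried into the metrics.
#' @param fov_id FOV identifier for the report.
#' @return list with `metrics`, `merged` (merged localization table with a
#'   `cluster_id` column; -1 = noise), `clusters` (kept member-index
#'   lists), `offset_nm`, `qc`, `ddr`, `drift`, and `counts` (named stage
#'   tallies).
#' @export
process_fov <- function(locs, frames_total, widefield = NULL,
                        ddr_widefield = NULL, config = storm_config(),
                        condition = NA_character_, fov_id = 1) {
  fpar <- do.call(filter_params, config$filter)
  cpar <- do.call(cluster_params, config$cluster)
  rpar <- do.call(register_params, config$register)
  counts <- c(input = nrow(locs))

  tracks <- find_fiducials(locs, frames_total)
  drift <- build_drift(tracks, frames_total)   # may signal no-fiducial error
  locs <- apply_drift(locs, drift)
  locs <- drop_fiducial_localizations(locs, tracks)
  counts["fiducials"] <- length(tracks)

  filt <- filter_localizations(locs, fpar)
  counts["post_filter"] <- nrow(filt$locs)
  merged <- merge_localizations(filt$locs, fpar$merge_radius_nm,
                                fpar$gap_frames)
  counts["post_merge"] <- nrow(merged)

  clustering <- cluster_dbscan(merged, cpar)
  counts["clusters_found"] <- length(clustering$clusters)
  gated <- gate_clusters(clustering, cpar$min_cluster_size)
  counts["clusters_gated"] <- length(gated$clusters)

  offset <- c(dx_nm = 0, dy_nm = 0)
  qc <- NULL
  kept <- gated$clusters
  if (!is.null(widefield)) {
    offset <- estimate_offset(merged, widefield, params = rpar)
    mask <- nucleus_mask(widefield)
    qc <- qc_clusters(kept, merged, widefield, offset_nm = offset,
                      mask = mask, f_locus = config$qc$f_locus,
                      r_min = config$qc$r_min)
    kept <- kept[qc$qc_status == "kept"]
  }
  counts["clusters_qc_kept"] <- length(kept)

  ddr <- NULL
  ddr_class <- NULL
  if (!is.null(ddr_widefield) && length(kept)) {
    ddr <- classify_ddr(kept, merged, ddr_widefield, offset_nm = offset,
                        f_lo = config$ddr$f_lo, f_hi = config$ddr$f_hi)
    ddr_class <- as.character(ddr$ddr_class)
    tab <- table(ddr$ddr_class)
    counts[paste0("ddr_", names(tab))] <- as.integer(tab)
  }

  metrics <- compute_metrics(kept, merged, condition = condition,
                             ddr_class = ddr_class)
  if (nrow(metrics)) metrics$fov_id <- fov_id

  merged$cluster_id <- gated$labels %||% clustering$labels
  list(metrics = metrics, merged = merged, clusters = kept,
       offset_nm = offset, qc = qc, ddr = ddr, drift = drift,
       counts = counts)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Run the full pipeline
#'
#' Simulates (or loads) every FOV of every condition, processes each FOV
#' independently through [process_fov()], aggregates per-cluster metrics,
#' and produces per-condition summaries. FOVs without usable fiducials are
#' discarded and listed in the report rather than silently dropped; any
#' other FOV-level error likewise aborts only that FOV.
#'
#' @param config a [storm_config()]; must pass [validate_config()].
#' @return An object of class `run_report`: list with
#'   \describe{
#'     \item{fovs}{data.frame of per-FOV stage counts}
#'     \item{discarded}{data.frame of discarded FOVs and reasons}
#'     \item{metrics}{combined [compute_metrics()] table}
#'     \item{summaries}{named list of [summarize_condition()] objects}
#'     \item{truth}{per-FOV ground truth (simulate mode)}
#'     \item{offsets}{per-FOV estimated offsets}
#'     \item{config, seed}{parameter echo}
#'     \item{version}{package version string}
#'   }
#' @export
run_pipeline <- function(config) {
  problems <- validate_config(config)
  if (length(problems))
    stop("invalid config:\n  ", paste(problems, collapse = "\n  "))
  all_metrics <- list()
  fov_rows <- list()
  discarded <- list()
  truth <- list()
  offsets <- list()
  results <- list()
  fov_global <- 0
  for (ci in seq_along(config$conditions)) {
    cond <- config$conditions[[ci]]
    n_fov <- cond$n_fov %||% 1
    for (f in seq_len(n_fov)) {
      fov_global <- fov_global + 1
      fov_id <- sprintf("%s_fov%d", cond$label, f)
      fov_seed <- (config$seed + 1009L * ci + 97L * f) %%
        .Machine$integer.max
      sim <- NULL
      if (config$mode == "simulate") {
        fargs <- config$field
        for (nm in intersect(names(cond),
                             names(formals(emitter_field))))
          fargs[[nm]] <- cond[[nm]]
        field <- do.call(emitter_field, fargs)
        blink <- do.call(blink_model, config$blink)
        drift <- do.call(drift_model, config$drift)
        sim <- simulate_fov(field, blink, drift,
                            channel_offset_nm = config$channel_offset_nm,
                            precision_mean_nm = config$precision_mean_nm,
                            seed = fov_seed)
        locs <- sim$locs
        frames_total <- sim$frames_total
        wf <- sim$widefield
        ddrwf <- sim$ddr_widefield
        truth[[fov_id]] <- sim$ground_truth
      } else {
        locs <- read_localizations(cond$files[[f]])
        frames_total <- cond$frames_total %||% max(locs$frame)
        wf <- if (!is.null(cond$widefield))
          read_image(cond$widefield[[f]], cond$pixel_size_nm %||% 108)
          else NULL
        ddrwf <- if (!is.null(cond$ddr_widefield))
          read_image(cond$ddr_widefield[[f]], cond$pixel_size_nm %||% 108)
          else NULL
      }
      res <- tryCatch(
        process_fov(locs, frames_total, wf, ddrwf, config,
                    condition = cond$label, fov_id = fov_id),
        telostorm_no_fiducials = function(e) e,
        error = function(e) e)
      if (inherits(res, "condition")) {
        discarded[[length(discarded) + 1]] <-
          data.frame(fov_id = fov_id, reason = conditionMessage(res))
        message(sprintf("[%s] discarded: %s", fov_id,
                        conditionMessage(res)))
        next
      }
      message(sprintf(
        "[%s] locs %d -> filtered %d -> merged %d; clusters %d -> gated %d -> kept %d",
        fov_id, res$counts["input"], res$counts["post_filter"],
        res$counts["post_merge"], res$counts["clusters_found"],
        res$counts["clusters_gated"], res$counts["clusters_qc_kept"]))
      all_metrics[[fov_id]] <- res$metrics
      offsets[[fov_id]] <- res$offset_nm
      results[[fov_id]] <- res
      row <- as.data.frame(as.list(res$counts))
      row <- cbind(data.frame(fov_id = fov_id, condition = cond$label),
                   row)
      fov_rows[[fov_id]] <- row
    }
  }
  metrics <- if (length(all_metrics)) {
    m <- do.call(rbind, all_metrics)
    rownames(m) <- NULL
    m
  } else compute_metrics(list(), data.frame(x_nm = numeric(0),
                                            y_nm = numeric(0)))
  summaries <- list()
  for (cond in config$conditions) {
    sub <- metrics[metrics$condition == cond$label, , drop = FALSE]
    if (nrow(sub) >= 2)
      summaries[[cond$label]] <-
        summarize_condition(sub, cond$label,
                            thresholds_nm = config$thresholds_nm)
  }
  fovs <- if (length(fov_rows)) {
    cols <- unique(unlist(lapply(fov_rows, names)))
    filled <- lapply(fov_rows, function(r) {
      r[setdiff(cols, names(r))] <- 0L
      r[cols]
    })
    out <- do.call(rbind, filled); rownames(out) <- NULL; out
  } else data.frame()
  report <- structure(list(
    fovs = fovs,
    discarded = if (length(discarded)) do.call(rbind, discarded)
      else data.frame(fov_id = character(0), reason = character(0)),
    metrics = metrics, summaries = summaries, truth = truth,
    offsets = offsets, results = results,
    config = config, seed = config$seed,
    version = as.character(utils::packageVersion("telostorm"))
  ), class = "run_report")
  if (!is.null(config$out_dir)) write_report(report, config$out_dir)
  report
}

#' Write pipeline artifacts to a directory
#'
#' Flat-file outputs so any stage can be audited: combined metrics CSV,
#' per-FOV merged localization CSVs with cluster ids, per-FOV offsets and
#' stage counts as JSON, and per-condition summaries as JSON.
#'
#' @param report a `run_report`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_report <- function(report, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write.csv(report$metrics, file.path(dir, "cluster_metrics.csv"),
            row.names = FALSE)
  for (fov in names(report$results))
    write_localizations(report$results[[fov]]$merged,
                        file.path(dir, paste0(fov, "_merged.csv")))
  jsonlite::write_json(
    list(fovs = report$fovs, discarded = report$discarded,
         offsets = report$offsets, seed = report$seed,
         version = report$version),
    file.path(dir, "run_report.json"),
    dataframe = "rows", auto_unbox = TRUE, digits = NA)
  summaries <- lapply(report$summaries, function(s)
    s[c("condition", "n_telomeres", "mean_rg_nm", "sd_rg_nm",
        "mean_n_localizations", "fraction_rg_above")])
  jsonlite::write_json(summaries, file.path(dir, "summaries.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' @export
print.run_report <- function(x, ...) {
  cat(sprintf("telostorm run (seed %s): %d FOVs processed, %d discarded\n",
              format(x$seed), nrow(x$fovs), nrow(x$discarded)))
  for (s in x$summaries)
    cat(sprintf("  %s: %d telomeres, mean Rg %.1f nm (SD %.1f)\n",
                paste(s$condition, collapse = "/"), s$n_telomeres,
                s$mean_rg_nm, s$sd_rg_nm))
  invisible(x)
}

#' Match detected clusters to simulated ground-truth clusters
#'
#' Assigns each detected cluster the ground-truth cluster id held by the
#' majority of its member localizations (`true_cluster_id` column carried
#' through the pipeline). Used for parameter-recovery validation.
#'
#' @param clusters list of member-index vectors.
#' @param merged merged localization table with `true_cluster_id`.
#' @return integer vector of ground-truth ids (NA if a cluster has no
#'   majority source, e.g. merged fiducial remnants).
#' @export
match_truth <- function(clusters, merged) {
  vapply(clusters, function(idx) {
    ids <- merged$true_cluster_id[idx]
    ids <- ids[!is.na(ids) & ids > 0]
    if (!length(ids)) return(NA_integer_)
    tab <- table(ids)
    as.integer(names(tab)[which.max(tab)])
  }, integer(1))
}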