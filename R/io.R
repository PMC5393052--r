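#' Write / read a localization table as CSV
#'
#' The shared on-disk schema is `frame, x_nm, y_nm, precision_nm, sigma_nm,
#' loglike, photons` plus optional extra columns (e.g. `true_cluster_id`,
#' `cluster_id`, `n_merged`).
#'
#' @param locs localization data.frame.
#' @param path file path.
#' @return `write_localizations` returns `path` invisibly;
#'   `read_localizations` returns the data.frame sorted by frame.
#' @export
write_localizations <- function(locs, path) {
  write.csv(locs, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_localizations
#' @export
read_localizations <- function(path) {
  locs <- read.csv(path)
  need <- c("frame", "x_nm", "y_nm", "precision_nm", "sigma_nm",
            "loglike", "photons")
  miss <- setdiff(need, names(locs))
  if (length(miss))
    stop("localization CSV missing column(s): ", paste(miss, collapse = ", "))
  locs[order(locs$frame), , drop = FALSE]
}

#' Write a wide-field image as 16-bit grayscale TIFF
#'
#' Intensities are stored as ADU counts clipped to \[0, 65535\].
#'
#' @param img numeric matrix (ADU).
#' @param path file path.
#' @return `path`, invisibly. `read_image` returns the ADU matrix with the
#'   `pixel_size_nm` attribute if given.
#' @param pixel_size_nm pixel size to attach on read (nm).
#' @export
write_image <- function(img, path) {
  m <- pmin(pmax(img, 0), 65535) / 65535
  tiff::writeTIFF(m, path, bits.per.sample = 16)
  invisible(path)
}

#' @rdname write_image
#' @export
read_image <- function(path, pixel_size_nm = NULL) {
  m <- tiff::readTIFF(path) * 65535
  if (!is.null(pixel_size_nm)) attr(m, "pixel_size_nm") <- pixel_size_nm
  m
}

#' Write simulation ground truth as JSON
#'
#' @param ground_truth the `ground_truth` element of [simulate_fov()].
#' @param path file path.
#' @return `path`, invisibly.
#' @export
write_ground_truth <- function(ground_truth, path) {
  jsonlite::write_json(ground_truth, path, dataframe = "columns",
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}
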