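#' Read and write tidy profile tables
#'
#' Profiles are stored as tidy CSV with columns `disc_id`, `genotype`,
#' `x_um`, `channel`, `intensity` (positions in µm, boundary near 0); in
#' memory the position column is `x`.
#'
#' @param profiles Tidy profile tibble.
#' @param path File path.
#' @return `read_profiles()` returns a tibble; `write_profiles()` its input,
#'   invisibly.
#' @export
write_profiles <- function(profiles, path) {
  out <- profiles
  names(out)[names(out) == "x"] <- "x_um"
  readr::write_csv(out, path)
  invisible(profiles)
}

#' @rdname write_profiles
#' @export
read_profiles <- function(path) {
  d <- readr::read_csv(path, show_col_types = FALSE)
  need <- c("disc_id", "x_um", "channel", "intensity")
  missing <- setdiff(need, names(d))
  if (length(missing)) {
    abort(sprintf("profile CSV lacks column(s): %s",
                  paste(missing, collapse = ", ")),
          class = "cidecomp_io_error")
  }
  names(d)[names(d) == "x_um"] <- "x"
  as_tibble(d)
}

#' Write an aligned profile set as CSV
#'
#' Writes the per-position summary (`x`, `channel`, `mean`, `sem`, `n`) and,
#' optionally alongside it, the aligned per-disc traces.
#'
#' @param aligned An `aligned_profiles` object.
#' @param path Summary CSV path.
#' @param per_disc_path Optional path for the per-disc CSV.
#' @export
write_aligned <- function(aligned, path, per_disc_path = NULL) {
  stopifnot(inherits(aligned, "aligned_profiles"))
  readr::write_csv(aligned$summary, path)
  if (!is.null(per_disc_path)) {
    readr::write_csv(aligned$per_disc, per_disc_path)
  }
  invisible(aligned)
}

#' Read and write region-mean tables for clone analysis
#'
#' Columns: `disc_id`, `genotype`, `channel`, `region`, `replicate_idx`,
#' `mean_intensity` (and optionally `scenario`).
#'
#' @param regions Tidy region tibble.
#' @param path File path.
#' @export
write_regions <- function(regions, path) {
  readr::write_csv(regions, path)
  invisible(regions)
}

#' @rdname write_regions
#' @export
read_regions <- function(path) {
  d <- readr::read_csv(path, show_col_types = FALSE)
  need <- c("disc_id", "channel", "region", "mean_intensity")
  missing <- setdiff(need, names(d))
  if (length(missing)) {
    abort(sprintf("region CSV lacks column(s): %s",
                  paste(missing, collapse = ", ")),
          class = "cidecomp_io_error")
  }
  as_tibble(d)
}

#' Write a decomposition result as CSV + JSON
#'
#' The per-position curves go to `curves_path` (via [tidy()]); the scalars,
#' landmarks and provenance go to `json_path`.
#'
#' @param result A `ci_decomposition` object.
#' @param curves_path CSV path for curves.
#' @param json_path JSON path for scalars/landmarks/provenance.
#' @export
write_decomposition <- function(result, curves_path, json_path) {
  stopifnot(inherits(result, "ci_decomposition"))
  readr::write_csv(tidy(result), curves_path)
  g <- glance(result)
  jsonlite::write_json(
    list(summary = as.list(g),
         anterior_window = result$anterior_window,
         provenance = result$provenance),
    json_path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(result)
}

#' Write a single-channel image as TIFF
#'
#' @param image Numeric matrix from [render_image()].
#' @param path TIFF path; intensities are rescaled to `[0, 1]` for storage
#'   (the scale factor is not preserved).
#' @export
write_image_tiff <- function(image, path) {
  if (!requireNamespace("tiff", quietly = TRUE)) {
    abort("the 'tiff' package is required to write TIFF images",
          class = "cidecomp_io_error")
  }
  m <- image / max(image)
  attr(m, "x") <- NULL
  tiff::writeTIFF(m, path)
  invisible(image)
}
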