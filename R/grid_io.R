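## Grid-map and ROI-mask persistence. Grids: JSON header + CSV values in
## x-fastest order. Masks: run-length-encoded JSON. DICOM import is out of
## scope by design; these plain-text formats are the exchange surface.

#' Write a voxel grid (or score map) to disk
#'
#' @param grid a `voxel_grid`.
#' @param path base path; writes `<path>.json` (shape, spacing, origin,
#'   value_kind, units) and `<path>.csv` (flat values, x fastest).
#' @param units optional units tag stored in the header (e.g. `"Gy"`,
#'   `"Gy (RBE)"`).
#' @return `path`, invisibly.
#' @export
write_grid <- function(grid, path, units = NULL) {
  stopifnot(inherits(grid, "voxel_grid"))
  hdr <- list(format_version = "1.0", shape = dim(grid$values),
              spacing = grid$spacing, origin = grid$origin,
              value_kind = grid$value_kind)
  if (!is.null(units)) hdr$units <- units
  jsonlite::write_json(hdr, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  df <- data.frame(value = .fmt_full(as.numeric(grid$values)))
  write.csv(df, paste0(path, ".csv"), row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a voxel grid written by [write_grid()]
#'
#' @param path base path used at write time.
#' @return a `voxel_grid`; the `units` header, when present, is attached as
#'   an attribute.
#' @export
read_grid <- function(path) {
  hdr <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  v <- read.csv(paste0(path, ".csv"))$value
  if (length(v) != prod(hdr$shape))
    stop(sprintf("%s.csv: expected %d values, found %d", path,
                 prod(hdr$shape), length(v)))
  g <- voxel_grid(array(v, hdr$shape), hdr$spacing, hdr$origin,
                  hdr$value_kind)
  if (!is.null(hdr$units)) attr(g, "units") <- hdr$units
  g
}

#' Write an ROI mask as run-length-encoded JSON
#'
#' @param roi an `roi_mask`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_roi <- function(roi, path) {
  r <- rle(as.logical(roi$mask))
  jsonlite::write_json(
    list(format_version = "1.0", name = roi$name, shape = dim(roi$mask),
         lengths = r$lengths, values = r$values),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read an ROI mask written by [write_roi()]
#'
#' @param path file written by [write_roi()].
#' @return an `roi_mask`.
#' @export
read_roi <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  v <- inverse.rle(structure(list(lengths = x$lengths,
                                  values = as.logical(x$values)),
                             class = "rle"))
  if (length(v) != prod(x$shape))
    stop(sprintf("%s: RLE length %d does not match shape", path, length(v)))
  roi_mask(x$name, array(v, x$shape))
}
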