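#' Read a linescan image from TIFF or delimited text
#'
#' Text files are whitespace-, comma- or tab-delimited numeric matrices
#' (rows = space, columns = time).  TIFF files must be single-plane;
#' pixel size and line period come either from the arguments or from a
#' JSON sidecar `<path>.json` written by [write_linescan()] (which also
#' restores the intensity scaling of the 16-bit encoding).
#'
#' @param path Image file.
#' @param pixel_um,line_ms Metadata; required unless a sidecar provides them.
#' @param annotations Optional annotations (override sidecar values).
#' @return A [linescan_image()].
#' @export
read_linescan <- function(path, pixel_um = NULL, line_ms = NULL,
                          annotations = list()) {
  if (!file.exists(path)) stop("read_linescan: no such file: ", path,
                               call. = FALSE)
  sidecar <- paste0(path, ".json")
  meta <- if (file.exists(sidecar)) jsonlite::read_json(sidecar,
                                                        simplifyVector = TRUE)
          else list()
  if (is.null(pixel_um)) pixel_um <- meta$pixel_um
  if (is.null(line_ms)) line_ms <- meta$line_ms
  if (is.null(pixel_um) || is.null(line_ms))
    stop("read_linescan: pixel_um and line_ms must be given (or present in ",
         "a sidecar)", call. = FALSE)
  if (grepl("\\.tiff?$", path, ignore.case = TRUE)) {
    if (!requireNamespace("tiff", quietly = TRUE))
      stop("the 'tiff' package is required to read TIFF images", call. = FALSE)
    raw <- tiff::readTIFF(path)
    if (length(dim(raw)) != 2L)
      stop("read_linescan: TIFF must be single-plane greyscale", call. = FALSE)
    scale <- if (!is.null(meta$scale)) meta$scale else 1
    values <- raw * scale
    if (isTRUE(meta$integer_counts)) values <- round(values)
  } else {
    first <- readLines(path, n = 1L)
    sep <- if (grepl(",", first)) "," else ""
    values <- as.matrix(utils::read.table(path, sep = sep, header = FALSE))
    dimnames(values) <- NULL
    storage.mode(values) <- "double"
  }
  ann <- modifyList(as.list(meta$annotations %||% list()),
                    as.list(annotations))
  linescan_image(values, pixel_um = pixel_um, line_ms = line_ms,
                 annotations = ann)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write a linescan image (TIFF or text) with a JSON sidecar
#'
#' TIFF output uses a 16-bit encoding when all values are integers below
#' 2^16 (exact round trip for photon-counting data) and a 32-bit float
#' encoding otherwise (round trip to single precision); the scaling, the
#' metadata and any annotations go to `<path>.json`.  Text output writes
#' full-precision tab-separated values.
#'
#' @param image A [linescan_image()].
#' @param path Destination; format chosen by extension (`.tif`/`.tiff`
#'   vs anything else for text).
#' @param extra Extra named fields stored in the sidecar (e.g. the seed
#'   and synthesis parameters).
#' @return `path`, invisibly.
#' @export
write_linescan <- function(image, path, extra = list()) {
  stopifnot(inherits(image, "linescan_image"))
  v <- image$values
  meta <- c(list(pixel_um = image$pixel_um, line_ms = image$line_ms,
                 dwell_us = image$dwell_us, annotations = image$annotations),
            extra)
  if (grepl("\\.tiff?$", path, ignore.case = TRUE)) {
    if (!requireNamespace("tiff", quietly = TRUE))
      stop("the 'tiff' package is required to write TIFF images", call. = FALSE)
    integer_counts <- all(v == round(v)) && max(v) < 65536
    if (integer_counts) {
      scale <- 65535
      tiff::writeTIFF(v / scale, path, bits.per.sample = 16L)
    } else {
      scale <- max(v, 1)
      tiff::writeTIFF(v / scale, path, bits.per.sample = 32L)
    }
    meta$scale <- scale
    meta$integer_counts <- integer_counts
  } else {
    utils::write.table(v, path, sep = "\t", row.names = FALSE,
                       col.names = FALSE)
  }
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA, null = "null", na = "null")
  invisible(path)
}

#' Read / write moment-sample tables
#'
#' Moment tables are CSV files with the fixed column order `image_id`,
#' `type`, `power_rel`, `region`, `ca_added`, `mean_F`, `var_F`,
#' `n_pixels` (extra columns such as embedded fixture ground truth are
#' preserved after these).
#'
#' @param samples Data frame of moment samples (rows from
#'   [bright_moments()] or a [moment_ensemble()]).
#' @param path CSV file path.
#' @return `read_moment_table` returns a data frame; if it carries a
#'   `type` column with a single value the result is a
#'   [moment_ensemble()].
#' @export
write_moment_table <- function(samples, path) {
  stopifnot(is.data.frame(samples))
  fixed <- c("image_id", "type", "power_rel", "region", "ca_added",
             "mean_F", "var_F", "n_pixels")
  cols <- c(intersect(fixed, names(samples)),
            setdiff(names(samples), fixed))
  utils::write.csv(samples[, cols, drop = FALSE], path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_moment_table
#' @export
read_moment_table <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("mean_F", "var_F") %in% names(df)))
    stop("read_moment_table: file lacks mean_F/var_F columns", call. = FALSE)
  types <- unique(df$type)
  if (length(types) == 1L && types %in% c("I", "II", "III") && nrow(df) >= 5L)
    moment_ensemble(df, type = types)
  else df
}
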