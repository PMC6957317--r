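# File formats: localization/track CSV (comma-separated, header, '.'
# decimal, coordinates in um, 0-based frames) and mask TIFF (single page,
# 0/1) with a JSON geometry sidecar.

.io_error <- function(code, msg) {
  stop(errorCondition(msg, class = c(code, "nucspt_io_error")))
}

.check_columns <- function(df, required, what) {
  miss <- setdiff(required, names(df))
  if (length(miss))
    .io_error("missing_columns",
              sprintf("%s lacks required columns: %s", what,
                      paste(miss, collapse = ", ")))
}

#' Write / read localization tables
#'
#' Localization CSVs carry `cell_id`, `frame`, `t_s`, `x_um`, `y_um`
#' (plus optional columns such as `molecule_id`, which round-trip).
#'
#' @param recording a `cell_recording` or a localization data.frame (a
#'   `cell_id` column is added from the recording when absent).
#' @param path output CSV path.
#' @return `write_localizations()` returns `path` invisibly;
#'   `read_localizations()` the validated data.frame.
#' @export
write_localizations <- function(recording, path) {
  loc <- if (inherits(recording, "cell_recording")) {
    cbind(data.frame(cell_id = recording$cell_id), recording$localizations)
  } else recording
  .check_columns(loc, c("cell_id", "frame", "t_s", "x_um", "y_um"),
                 "localization table")
  write.csv(loc, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_localizations
#' @export
read_localizations <- function(path) {
  df <- read.csv(path)
  .check_columns(df, c("cell_id", "frame", "t_s", "x_um", "y_um"),
                 "localization file")
  df
}

#' Write / read track tables
#'
#' Track CSVs add a `track_id` column to the localization schema. Frames
#' must be strictly increasing within each track.
#'
#' @param tracks a `track_set` (or compatible data.frame).
#' @param path CSV path.
#' @param cell_id cell identifier used when the table lacks one.
#' @return `write_tracks()` returns `path` invisibly; `read_tracks()`
#'   the validated data.frame.
#' @export
write_tracks <- function(tracks, path, cell_id = "cell_1") {
  df <- as.data.frame(tracks)
  if (is.null(df$cell_id)) df <- cbind(data.frame(cell_id = cell_id), df)
  .check_columns(df, c("cell_id", "track_id", "frame", "t_s", "x_um", "y_um"),
                 "track table")
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_tracks
#' @export
read_tracks <- function(path) {
  df <- read.csv(path)
  .check_columns(df, c("cell_id", "track_id", "frame", "t_s", "x_um", "y_um"),
                 "track file")
  bad <- vapply(split(df$frame, interaction(df$cell_id, df$track_id, drop = TRUE)),
                function(f) any(diff(sort(f)) == 0) || is.unsorted(f), TRUE)
  if (any(bad))
    .io_error("nonmonotone_frames",
              "non-monotone frames within a track")
  df
}

#' Write / read a region mask as TIFF plus JSON sidecar
#'
#' The mask is a single-page TIFF with pixel values 0/1; the sidecar
#' `<path>.json` records `pixel_size_um`, `origin_x_um`, `origin_y_um`.
#'
#' @param mask a `region_mask` or `chromatin_map`.
#' @param path TIFF path (the sidecar is written next to it).
#' @return `write_mask()` returns `path` invisibly; `read_mask()` a
#'   `region_mask`.
#' @export
write_mask <- function(mask, path) {
  stopifnot(inherits(mask, "chromatin_map"))
  tiff::writeTIFF(matrix(as.numeric(mask$grid), nrow(mask$grid)),
                  path, bits.per.sample = 8)
  jsonlite::write_json(list(pixel_size_um = mask$pixel_size_um,
                            origin_x_um = mask$origin_x_um,
                            origin_y_um = mask$origin_y_um),
                       paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_mask
#' @export
read_mask <- function(path) {
  sidecar <- paste0(path, ".json")
  if (!file.exists(sidecar))
    .io_error("missing_sidecar", "mask TIFF lacks its JSON geometry sidecar")
  meta <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
  img <- tiff::readTIFF(path)
  grid <- matrix(as.integer(img > 0.5), nrow(img))
  structure(list(grid = grid, pixel_size_um = meta$pixel_size_um,
                 origin_x_um = meta$origin_x_um,
                 origin_y_um = meta$origin_y_um,
                 method = list(type = "file")),
            class = c("region_mask", "chromatin_map"))
}
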