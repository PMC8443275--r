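#' Write / read a point pattern as CSV
#'
#' Columns `x_um`, `y_um`, `subline`, `caspase_pos`. Field bounds, border
#' position and generation mode travel in a JSON sidecar
#' (`<path>.json`); when the sidecar is absent on read, bounds are
#' inferred from the data extent.
#'
#' @param pattern A [point_pattern()].
#' @param path CSV path.
#' @return `path`, invisibly (writer); a `point_pattern` (reader).
#' @export
write_point_pattern <- function(pattern, path) {
  stopifnot(inherits(pattern, "point_pattern"))
  write.csv(pattern$points, path, row.names = FALSE)
  meta <- list(bounds = pattern$bounds, border_x = pattern$border_x,
               mode = pattern$mode)
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname write_point_pattern
#' @export
read_point_pattern <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("x_um", "y_um", "subline", "caspase_pos")
  miss <- setdiff(need, names(df))
  if (length(miss) > 0)
    stopf("%s: missing column(s) %s", path, paste(miss, collapse = ", "))
  sidecar <- paste0(path, ".json")
  if (file.exists(sidecar)) {
    meta <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
    bounds <- as.numeric(meta$bounds)
    border_x <- as.numeric(meta$border_x %||% NA_real_)
    mode <- meta$mode %||% "unknown"
  } else {
    bounds <- c(max(df$x_um, 1), max(df$y_um, 1))
    border_x <- NA_real_
    mode <- "unknown"
  }
  point_pattern(df$x_um, df$y_um, df$subline, df$caspase_pos,
                bounds = bounds, border_x = border_x, mode = mode)
}

#' Write / read a two-channel cell image as multi-page TIFF + JSON
#'
#' Page 1 is the nuclei channel, later pages the marker channels, stored
#' as 32-bit float; pixel size, channel names and the generator truth
#' table go to a `<path>.json` sidecar.
#'
#' @param image A `cell_image`.
#' @param path TIFF path.
#' @return `path`, invisibly (writer); a `cell_image` (reader).
#' @export
write_cell_image <- function(image, path) {
  stopifnot(inherits(image, "cell_image"))
  pages <- c(list(image$nuclei), unname(image$markers))
  # TIFF pages live in [0, 1]; per-channel scale factors go to the sidecar
  scales <- vapply(pages, function(p) max(max(p), 1), numeric(1))
  pages <- Map(function(p, s) p / s, pages, scales)
  tiff::writeTIFF(pages, path, bits.per.sample = 32)
  meta <- list(pixel_size = image$pixel_size,
               channels = c("nuclei", names(image$markers)),
               channel_scale = scales,
               truth = image$truth)
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA, dataframe = "columns")
  invisible(path)
}

#' @rdname write_cell_image
#' @export
read_cell_image <- function(path) {
  pages <- tiff::readTIFF(path, all = TRUE, as.is = FALSE)
  sidecar <- paste0(path, ".json")
  if (!file.exists(sidecar))
    stopf("%s: missing JSON sidecar with pixel size", path)
  meta <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
  chans <- meta$channels
  if (length(pages) != length(chans))
    stopf("%s: %d TIFF pages but %d channel names in sidecar", path,
          length(pages), length(chans))
  truth <- if (!is.null(meta$truth)) as.data.frame(meta$truth) else NULL
  scales <- as.numeric(meta$channel_scale %||% rep(1, length(pages)))
  pages <- Map(function(p, s) matrix(p, nrow(p), ncol(p)) * s,
               pages, scales)
  markers <- pages[-1]
  names(markers) <- chans[-1]
  structure(list(nuclei = pages[[1]], markers = markers,
                 pixel_size = as.numeric(meta$pixel_size), truth = truth),
            class = "cell_image")
}

#' Write / read an AFM force curve as CSV + JSON metadata
#'
#' Columns `indentation_um`, `force_nN`; probe radius, Poisson ratio and
#' approach speed go to a `<path>.json` sidecar.
#'
#' @param curve A `force_curve`.
#' @param path CSV path.
#' @return `path`, invisibly (writer); a `force_curve` (reader).
#' @export
write_force_curve <- function(curve, path) {
  stopifnot(inherits(curve, "force_curve"))
  write.csv(curve$data, path, row.names = FALSE)
  jsonlite::write_json(
    list(probe_radius = curve$probe_radius, poisson = curve$poisson,
         approach_speed = curve$approach_speed),
    paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_force_curve
#' @export
read_force_curve <- function(path) {
  df <- read.csv(path)
  need <- c("indentation_um", "force_nN")
  miss <- setdiff(need, names(df))
  if (length(miss) > 0)
    stopf("%s: missing column(s) %s", path, paste(miss, collapse = ", "))
  sidecar <- paste0(path, ".json")
  meta <- if (file.exists(sidecar))
    jsonlite::read_json(sidecar, simplifyVector = TRUE) else list()
  structure(list(data = df,
                 probe_radius = as.numeric(meta$probe_radius %||% 2.5),
                 poisson = as.numeric(meta$poisson %||% 0.5),
                 approach_speed = as.numeric(meta$approach_speed %||% 2)),
            class = "force_curve")
}

#' Write / read competition counts as tidy CSV
#'
#' Columns `day`, `condition`, `subline`, `count`, `replicate` (and
#' optionally `plating_density`).
#'
#' @param counts Counts data frame.
#' @param path CSV path.
#' @return `path`, invisibly (writer); a data frame (reader).
#' @export
write_counts <- function(counts, path) {
  write.csv(counts, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_counts
#' @export
read_counts <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("day", "condition", "subline", "count")
  miss <- setdiff(need, names(df))
  if (length(miss) > 0)
    stopf("%s: missing column(s) %s", path, paste(miss, collapse = ", "))
  if (any(df$count < 0))
    stopf("%s: negative counts at row(s) %s", path,
          paste(head(which(df$count < 0)), collapse = ", "))
  df
}
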