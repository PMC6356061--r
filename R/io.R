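#' Read and write trajectory tables
#'
#' Trajectories travel as delimited text with headers
#' `traj_id, frame, x_um, y_um[, state]`; positions in um. The frame
#' interval is stored in the companion config when written with
#' [write_config()] or passed explicitly on read.
#'
#' @param tracks an `"sm_tracks"` object.
#' @param path CSV file path.
#' @export
write_tracks_csv <- function(tracks, path) {
  stopifnot(inherits(tracks, "sm_tracks"))
  df <- as.data.frame(tracks)
  names(df)[names(df) == "x"] <- "x_um"
  names(df)[names(df) == "y"] <- "y_um"
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_tracks_csv
#' @param path CSV file path.
#' @param frame_interval frame interval in seconds.
#' @return [read_tracks_csv()]: an `"sm_tracks"` object.
#' @export
read_tracks_csv <- function(path, frame_interval) {
  df <- utils::read.csv(path)
  names(df)[names(df) == "x_um"] <- "x"
  names(df)[names(df) == "y_um"] <- "y"
  sm_tracks(df, frame_interval)
}

#' Read and write localization tables
#'
#' Localization clouds travel as CSV with headers `x_nm, y_nm, frame` (plus
#' any ground-truth columns present).
#'
#' @param cloud a `"storm_cloud"`.
#' @param path CSV file path.
#' @export
write_localizations_csv <- function(cloud, path) {
  stopifnot(inherits(cloud, "storm_cloud"))
  utils::write.csv(as.data.frame(cloud), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_localizations_csv
#' @param roi_area_um2 ROI area in um^2.
#' @return [read_localizations_csv()]: a `"storm_cloud"`.
#' @export
read_localizations_csv <- function(path, roi_area_um2) {
  storm_cloud(utils::read.csv(path), roi_area_um2)
}

#' Read and write images as TIFF with a pixel-size sidecar
#'
#' Images are written as 32-bit float TIFF; the pixel size (nm) goes into a
#' plain-text sidecar config `<path>.meta` so it survives round trips.
#'
#' @param image numeric matrix with attribute `pixel_size_nm` (or supply
#'   `pixel_size_nm`).
#' @param path TIFF file path.
#' @param pixel_size_nm pixel size, nm.
#' @export
write_image_tiff <- function(image, path,
                             pixel_size_nm = attr(image, "pixel_size_nm")) {
  m <- image
  attributes(m) <- list(dim = dim(m))
  scale <- max(abs(m), 1)
  tiff::writeTIFF(m / scale, path, bits.per.sample = 32L)
  meta <- list(scale = scale)
  if (!is.null(pixel_size_nm)) meta$pixel_size_nm <- pixel_size_nm
  write_config(meta, paste0(path, ".meta"))
  invisible(path)
}

#' @rdname write_image_tiff
#' @return [read_image_tiff()]: numeric matrix with `pixel_size_nm`
#'   attribute when the sidecar is present.
#' @export
read_image_tiff <- function(path) {
  img <- tiff::readTIFF(path)
  if (length(dim(img)) == 3L) img <- img[, , 1]
  meta_path <- paste0(path, ".meta")
  if (file.exists(meta_path)) {
    meta <- read_config(meta_path)
    if (!is.null(meta$scale)) img <- img * as.numeric(meta$scale)
    if (!is.null(meta$pixel_size_nm))
      attr(img, "pixel_size_nm") <- as.numeric(meta$pixel_size_nm)
  }
  img
}

#' Plain-text key-value configuration files
#'
#' One `key = value` pair per line; values are scalars (numbers kept at full
#' precision). Used for simulation specs, analysis parameters and image
#' sidecars.
#'
#' @param x named list of scalar values.
#' @param path file path.
#' @export
write_config <- function(x, path) {
  stopifnot(is.list(x), !is.null(names(x)))
  lines <- vapply(names(x), function(k) {
    v <- x[[k]]
    sprintf("%s = %s", k,
            if (is.numeric(v)) format(v, digits = 17) else as.character(v))
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_config
#' @return [read_config()]: named list; numeric-looking values are
#'   converted to numbers.
#' @export
read_config <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines)) & !startsWith(trimws(lines), "#")]
  out <- list()
  for (ln in lines) {
    kv <- strsplit(ln, "=", fixed = TRUE)[[1]]
    key <- trimws(kv[1])
    val <- trimws(paste(kv[-1], collapse = "="))
    num <- suppressWarnings(as.numeric(val))
    out[[key]] <- if (!is.na(num)) num else val
  }
  out
}
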