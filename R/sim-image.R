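#' Specification of a synthetic diffraction-limited image
#'
#' Parameters for [render_synthetic_image()]: image size in pixels, pixel
#' size and PSF SD in nm, a list of point emitters (positions in nm,
#' amplitudes in integrated counts), a constant background per pixel, and
#' optional Poisson noise.
#'
#' @param shape image dimensions in pixels, `c(n_rows, n_cols)`.
#' @param pixel_size_nm pixel pitch, nm.
#' @param psf_sigma_nm PSF standard deviation, nm; must be positive.
#' @param spots data frame (or NULL) with columns `x_nm`, `y_nm`,
#'   `amplitude`; amplitude is the emitter's integrated photon count.
#' @param background constant background counts per pixel.
#' @param noise `"none"` or `"poisson"`.
#' @param seed integer seed used when `noise == "poisson"`.
#' @return an object of class `"image_sim_spec"`.
#' @export
image_sim_spec <- function(shape = c(64, 64),
                           pixel_size_nm = 160,
                           psf_sigma_nm = 200,
                           spots = NULL,
                           background = 0,
                           noise = c("none", "poisson"),
                           seed = NULL) {
  noise <- match.arg(noise)
  if (psf_sigma_nm <= 0) stop("psf_sigma_nm must be positive")
  if (background < 0) stop("background must be >= 0")
  if (!is.null(spots)) {
    if (!all(c("x_nm", "y_nm", "amplitude") %in% names(spots)))
      stop("spots need columns x_nm, y_nm, amplitude")
    if (any(spots$amplitude < 0)) stop("amplitudes must be >= 0")
  }
  structure(list(shape = as.integer(shape), pixel_size_nm = pixel_size_nm,
                 psf_sigma_nm = psf_sigma_nm, spots = spots,
                 background = background, noise = noise, seed = seed),
            class = "image_sim_spec")
}

#' Render a synthetic image of point emitters
#'
#' Each spot contributes a pixel-integrated isotropic Gaussian of SD
#' `psf_sigma_nm` scaled to its amplitude (integrated counts), on top of a
#' constant background; Poisson noise is applied per pixel when requested.
#' Coordinates use the pixel-center convention: the center of pixel
#' `(row r, col c)` (0-based) is at `x = c * pixel_size`, `y = r * pixel_size`;
#' x increases with column index.
#'
#' With `noise = "none"` the total image counts equal the summed amplitudes
#' plus `background * n_pixels`, up to the Gaussian mass falling outside the
#' frame.
#'
#' @param spec an [image_sim_spec()].
#' @return numeric matrix (rows = y, columns = x) with attributes
#'   `pixel_size_nm` and `psf_sigma_nm`.
#' @export
render_synthetic_image <- function(spec) {
  stopifnot(inherits(spec, "image_sim_spec"))
  nr <- spec$shape[1]; nc <- spec$shape[2]
  px <- spec$pixel_size_nm
  img <- matrix(spec$background, nr, nc)
  if (!is.null(spec$spots) && nrow(spec$spots) > 0) {
    xmax <- (nc - 1) * px; ymax <- (nr - 1) * px
    if (any(spec$spots$x_nm < -px / 2 | spec$spots$x_nm > xmax + px / 2 |
            spec$spots$y_nm < -px / 2 | spec$spots$y_nm > ymax + px / 2))
      stop("spot position outside the image frame")
    col_centers <- (seq_len(nc) - 1) * px
    row_centers <- (seq_len(nr) - 1) * px
    for (i in seq_len(nrow(spec$spots))) {
      gx <- .pixel_gauss_1d(col_centers, spec$spots$x_nm[i],
                            spec$psf_sigma_nm, px)
      gy <- .pixel_gauss_1d(row_centers, spec$spots$y_nm[i],
                            spec$psf_sigma_nm, px)
      img <- img + spec$spots$amplitude[i] * outer(gy, gx)
    }
  }
  if (spec$noise == "poisson") {
    if (!is.null(spec$seed)) set.seed(spec$seed)
    img <- matrix(stats::rpois(length(img), img), nr, nc)
  }
  attr(img, "pixel_size_nm") <- px
  attr(img, "psf_sigma_nm") <- spec$psf_sigma_nm
  img
}
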