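#' Convert an RGB image to CIELAB
#'
#' Per-pixel sRGB (D65) to CIELAB conversion. The L* plane is on its
#' native `[0, 100]` scale and a*/b* on `[-128, 127]`; no 8-bit
#' rescaling is applied, so colour distances downstream (e.g. the
#' mean-shift bandwidth) are in native Lab units.
#'
#' @param image An `rgb_image`.
#' @return A `lab_image`: list with matrices `L`, `a`, `b`.
#' @export
rgb_to_lab <- function(image) {
  if (!inherits(image, "rgb_image")) stop("image must be an rgb_image")
  d <- dim(image)
  rgb <- cbind(as.vector(image[, , 1]), as.vector(image[, , 2]), as.vector(image[, , 3])) / 255
  lab <- grDevices::convertColor(rgb, from = "sRGB", to = "Lab")
  lab_image(
    L = matrix(lab[, 1], d[1], d[2]),
    a = matrix(lab[, 2], d[1], d[2]),
    b = matrix(lab[, 3], d[1], d[2])
  )
}

#' Construct a lab_image
#'
#' @param L,a,b Numeric matrices of identical dimension holding the
#'   CIELAB planes on native scales (`L` in `[0,100]`, `a`/`b` in
#'   `[-128,127]`).
#' @return A `lab_image`.
#' @export
lab_image <- function(L, a, b) {
  if (!all(dim(L) == dim(a)) || !all(dim(L) == dim(b)))
    stop("L, a, b must share dimensions")
  structure(list(L = L, a = a, b = b), class = "lab_image")
}

#' @export
print.lab_image <- function(x, ...) {
  cat(sprintf("<lab_image %d x %d>\n", nrow(x$L), ncol(x$L)))
  invisible(x)
}

#' @export
dim.lab_image <- function(x) dim(x$L)

#' Convert a CIELAB image back to an 8-bit RGB image
#'
#' Inverse of [rgb_to_lab()]; out-of-gamut values are clipped to
#' `[0, 255]`. Used by the synthetic-scene renderer.
#'
#' @param lab A `lab_image`.
#' @return An `rgb_image`.
#' @export
lab_to_rgb <- function(lab) {
  d <- dim(lab$L)
  m <- cbind(as.vector(lab$L), as.vector(lab$a), as.vector(lab$b))
  rgb <- grDevices::convertColor(m, from = "Lab", to = "sRGB")
  rgb <- pmin(pmax(rgb, 0), 1)
  rgb_image(array(round(rgb * 255), c(d, 3L)))
}
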