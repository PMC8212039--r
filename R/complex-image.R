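#' Complex-valued MRI slice
#'
#' A `complex_image` holds one 2-D slice of complex-valued MRI data in image
#' space (the inverse Fourier transform of the acquired k-space), together
#' with the multiplicative scale factor already applied to it. The real and
#' imaginary parts are the two channels every network in the package consumes;
#' converting to a magnitude image would turn the additive complex Gaussian
#' noise into Rician noise, which is exactly what working in the complex image
#' space avoids.
#'
#' @param data complex matrix (height x width); a numeric matrix is promoted
#'   to complex with zero imaginary part.
#' @param scale_applied multiplicative factor already applied to `data`
#'   (1 = raw acquisition units).
#' @return An object of class `complex_image`.
#' @export
complex_image <- function(data, scale_applied = 1) {
  if (is.matrix(data) && is.numeric(data)) data <- data + 0i
  if (!is.matrix(data) || !is.complex(data))
    stop("`data` must be a complex (or numeric) matrix", call. = FALSE)
  if (nrow(data) < 2L || ncol(data) < 2L)
    stop("image must be at least 2 x 2", call. = FALSE)
  if (any(!is.finite(Re(data))) || any(!is.finite(Im(data))))
    stop("image contains non-finite values", call. = FALSE)
  if (!is.numeric(scale_applied) || length(scale_applied) != 1L ||
      !is.finite(scale_applied) || scale_applied <= 0)
    stop("`scale_applied` must be a positive scalar", call. = FALSE)
  structure(list(data = data, scale_applied = as.numeric(scale_applied)),
            class = "complex_image")
}

#' @export
print.complex_image <- function(x, ...) {
  cat(sprintf("<complex_image> %d x %d, scale_applied = %g, max |.| = %g\n",
              nrow(x$data), ncol(x$data), x$scale_applied,
              max(Mod(x$data))))
  invisible(x)
}

#' @export
dim.complex_image <- function(x) dim(x$data)

as_complex_image <- function(x) {
  if (inherits(x, "complex_image")) return(x)
  complex_image(x)
}

#' Per-pixel magnitude of a complex image
#'
#' Returns the modulus of every pixel. Note that additive Gaussian noise in
#' the complex image becomes Rician in this representation, which is why all
#' denoising in the package happens before this step.
#'
#' @param img a [complex_image()] or complex matrix.
#' @return numeric matrix of non-negative values.
#' @export
magnitude <- function(img) {
  if (inherits(img, "complex_image")) img <- img$data
  Mod(img)
}

#' Rescale a complex image
#'
#' Multiplies the data by `factor` and records it in `scale_applied`, so the
#' operation is exactly invertible with `apply_scale(img, 1/factor)`. Scaling
#' matters because the SURE training loss is highly sensitive to the absolute
#' input scale; each acquisition protocol fixes its own factor (e.g. 500 for
#' raw knee k-space data with ~1e-5 magnitudes, 1/25000 for simulated brain
#' volumes with ~1e3 intensities).
#'
#' @param img a [complex_image()].
#' @param factor positive scalar.
#' @return a [complex_image()] in the new units.
#' @export
apply_scale <- function(img, factor) {
  img <- as_complex_image(img)
  if (!is.numeric(factor) || length(factor) != 1L || !is.finite(factor) ||
      factor <= 0)
    stop("`factor` must be a positive scalar", call. = FALSE)
  complex_image(img$data * factor, img$scale_applied * factor)
}

#' Centered crop of a complex image
#'
#' Returns the centered `size` x `size` window. When a dimension minus `size`
#' is odd, the extra row/column is dropped from the high-index side.
#'
#' @param img a [complex_image()].
#' @param size side length in pixels, at most `min(dim(img))`.
#' @return a [complex_image()].
#' @export
center_crop <- function(img, size) {
  img <- as_complex_image(img)
  h <- nrow(img$data); w <- ncol(img$data)
  size <- as.integer(size)
  if (size > h || size > w)
    stop("crop size exceeds image dimensions", call. = FALSE)
  r0 <- (h - size) %/% 2L
  c0 <- (w - size) %/% 2L
  complex_image(img$data[(r0 + 1L):(r0 + size), (c0 + 1L):(c0 + size),
                         drop = FALSE],
                img$scale_applied)
}

# complex matrix <-> H x W x 2 real channel array (network representation)
as_channel_array <- function(img) {
  if (inherits(img, "complex_image")) img <- img$data
  array(c(Re(img), Im(img)), dim = c(nrow(img), ncol(img), 2L))
}

channels_to_complex <- function(a) {
  matrix(complex(real = a[, , 1L], imaginary = a[, , 2L]),
         nrow = dim(a)[1L], ncol = dim(a)[2L])
}

#' Display the magnitude of a complex image
#'
#' @param x a [complex_image()].
#' @param ... passed on to [graphics::image()].
#' @export
plot.complex_image <- function(x, ...) {
  m <- magnitude(x)
  graphics::image(t(m[nrow(m):1, , drop = FALSE]),
                  col = grDevices::gray.colors(256L, 0, 1),
                  axes = FALSE, asp = nrow(m) / ncol(m), ...)
  invisible(x)
}
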