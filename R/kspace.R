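#' K-space slice
#'
#' The 2-D spatial-frequency dual of a [complex_image()]. MRI data are
#' acquired here; the image is recovered with an inverse Fourier transform.
#' The package uses the unitary (orthonormal) transform with the zero
#' frequency at the array centre, so total power is identical in both domains
#' and i.i.d. complex Gaussian noise keeps its per-channel variance across the
#' transform.
#'
#' @param data complex matrix indexed by spatial frequency.
#' @return An object of class `kspace_slice`.
#' @export
kspace_slice <- function(data) {
  if (is.matrix(data) && is.numeric(data)) data <- data + 0i
  if (!is.matrix(data) || !is.complex(data))
    stop("`data` must be a complex matrix", call. = FALSE)
  if (any(!is.finite(Re(data))) || any(!is.finite(Im(data))))
    stop("k-space contains non-finite values", call. = FALSE)
  structure(list(data = data), class = "kspace_slice")
}

#' @export
print.kspace_slice <- function(x, ...) {
  cat(sprintf("<kspace_slice> %d x %d frequency bins\n",
              nrow(x$data), ncol(x$data)))
  invisible(x)
}

#' @export
dim.kspace_slice <- function(x) dim(x$data)

# circular shifts moving the zero-frequency bin to/from the array centre
fftshift2 <- function(m) {
  h <- nrow(m); w <- ncol(m)
  m[c((h %/% 2L + 1L):h, 1L:(h %/% 2L)),
    c((w %/% 2L + 1L):w, 1L:(w %/% 2L)), drop = FALSE]
}

ifftshift2 <- function(m) {
  h <- nrow(m); w <- ncol(m)
  sh <- (h + 1L) %/% 2L; sw <- (w + 1L) %/% 2L
  m[c((sh + 1L):h, 1L:sh), c((sw + 1L):w, 1L:sw), drop = FALSE]
}

fft2 <- function(m, inverse = FALSE) {
  stats::fft(m, inverse = inverse) / sqrt(length(m))
}

#' Reconstruct the complex image from a k-space slice
#'
#' Centered, unitary inverse 2-D Fourier transform. Unitarity preserves total
#' power (Parseval) and therefore the variance of Gaussian noise: noise that
#' is i.i.d. Gaussian in k-space is still i.i.d. Gaussian in the complex
#' image.
#'
#' @param k a [kspace_slice()].
#' @return a [complex_image()] of the same dimensions.
#' @export
kspace_to_image <- function(k) {
  if (!inherits(k, "kspace_slice")) k <- kspace_slice(k)
  complex_image(fftshift2(fft2(ifftshift2(k$data), inverse = TRUE)))
}

#' Transform a complex image to k-space
#'
#' Exact inverse of [kspace_to_image()] (same centering, same unitary
#' normalisation).
#'
#' @param img a [complex_image()].
#' @return a [kspace_slice()] of the same dimensions.
#' @export
image_to_kspace <- function(img) {
  img <- as_complex_image(img)
  kspace_slice(fftshift2(fft2(ifftshift2(img$data))))
}

#' Zero-pad a k-space slice to a square
#'
#' Pads the smaller dimension symmetrically with zeros until both dimensions
#' equal the larger one, keeping the original data in the centered block.
#' Used to feed rectangular acquisitions to networks that expect square
#' input; padding with zeros adds no energy.
#'
#' @param k a [kspace_slice()].
#' @return a square [kspace_slice()].
#' @export
zero_pad_square <- function(k) {
  if (!inherits(k, "kspace_slice")) k <- kspace_slice(k)
  h <- nrow(k$data); w <- ncol(k$data)
  n <- max(h, w)
  if (h == n && w == n) return(k)
  out <- matrix(0 + 0i, n, n)
  r0 <- (n - h) %/% 2L
  c0 <- (n - w) %/% 2L
  out[(r0 + 1L):(r0 + h), (c0 + 1L):(c0 + w)] <- k$data
  kspace_slice(out)
}
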