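#' Non-local means parameters
#'
#' The reference parameterisation for the MRI experiments is `h = 0.71`,
#' 5x5 patches and a patch search distance of 6. `h` is dimensionless: when
#' a noise level is available the filtering bandwidth is `h * sigma` (the
#' classical patch-similarity convention, which makes a single `h` work for
#' raw k-space-derived magnitudes (~1e-5) and simulated intensities (~1e3)
#' alike); without a noise level `h` falls back to being relative to the
#' \[0, 1\]-normalised image range.
#'
#' @param h filtering strength (dimensionless, relative to the normalised
#'   range), `> 0`.
#' @param patch_size square patch side in pixels, odd and `>= 3`.
#' @param patch_distance search radius in pixels, `>= 1`.
#' @param compensate_sigma subtract `2 * sigma^2` from squared patch
#'   distances (the variance-compensated fast-NLM weighting) when a noise
#'   level is supplied.
#' @return An object of class `nlm_params`.
#' @export
nlm_params <- function(h = 0.71, patch_size = 5L, patch_distance = 6L,
                       compensate_sigma = TRUE) {
  stopifnot(h > 0, patch_size %% 2L == 1L, patch_size >= 3L,
            patch_distance >= 1L)
  structure(list(h = h, patch_size = as.integer(patch_size),
                 patch_distance = as.integer(patch_distance),
                 compensate_sigma = isTRUE(compensate_sigma)),
            class = "nlm_params")
}

#' Non-local means denoising of a magnitude image
#'
#' Each pixel is replaced by the weight-normalised average of the centre
#' pixels of all patches within `patch_distance`; weights are
#' `exp(-max(d2 - 2*sigma^2, 0) / (h*sigma)^2)` with `d2` the mean squared
#' patch difference (the `2*sigma^2` subtraction is the variance
#' compensation of the fast-NLM formulation; disable it via
#' [nlm_params()]). `sigma = 0` is the zero-bandwidth limit, which returns
#' the image unchanged; with `sigma = NULL` (unknown noise) the bandwidth
#' falls back to `h` times the image range.
#'
#' @param img numeric matrix of finite values.
#' @param params an [nlm_params()].
#' @param sigma noise standard deviation in the units of `img` (used both
#'   for the filtering bandwidth and the variance compensation), or `NULL`.
#' @return the filtered matrix, same units as the input.
#' @export
nlm_denoise <- function(img, params = nlm_params(), sigma = NULL) {
  stopifnot(inherits(params, "nlm_params"), is.matrix(img), is.numeric(img))
  if (any(!is.finite(img))) stop("non-finite input", call. = FALSE)
  if (nrow(img) < params$patch_size || ncol(img) < params$patch_size)
    stop("image smaller than the patch", call. = FALSE)
  lo <- min(img); hi <- max(img)
  if (hi <= lo) return(img)  # constant image is a fixed point
  if (!is.null(sigma) && sigma == 0) return(img)  # zero-bandwidth limit
  xn <- (img - lo) / (hi - lo)
  sig_n <- if (!is.null(sigma)) sigma / (hi - lo) else 0
  h_n <- if (sig_n > 0) params$h * sig_n else params$h
  comp <- if (params$compensate_sigma) 2 * sig_n^2 else 0
  out <- cpp_nlm(xn, (params$patch_size - 1L) %/% 2L, params$patch_distance,
                 h_n^2, comp)
  out * (hi - lo) + lo
}

#' Non-local means on a complex image, channel by channel
#'
#' Applies [nlm_denoise()] independently to the real and imaginary channels
#' so the baseline can run inside the complex-space pipeline.
#'
#' @param img a [complex_image()].
#' @param params an [nlm_params()].
#' @param sigma noise standard deviation in the units of `img`, or `"auto"`
#'   to use [estimate_sigma_background()].
#' @return the filtered [complex_image()].
#' @export
nlm_denoise_complex <- function(img, params = nlm_params(), sigma = "auto") {
  img <- as_complex_image(img)
  if (identical(sigma, "auto")) sigma <- estimate_sigma_background(img)
  re <- nlm_denoise(Re(img$data), params, sigma)
  im <- nlm_denoise(Im(img$data), params, sigma)
  complex_image(matrix(complex(real = re, imaginary = im),
                       nrow(img$data), ncol(img$data)),
                img$scale_applied)
}
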