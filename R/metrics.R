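#' Mean squared error between two images
#'
#' `sum((I1 - I2)^2) / (M * N)` over the `M x N` pixel grid. Complex inputs
#' use the squared modulus of the difference, which equals the summed squared
#' error of the two real channels.
#'
#' @param i1,i2 numeric or complex matrices of equal dimensions (or
#'   [complex_image()] objects).
#' @return scalar `>= 0`.
#' @export
mse <- function(i1, i2) {
  if (inherits(i1, "complex_image")) i1 <- i1$data
  if (inherits(i2, "complex_image")) i2 <- i2$data
  if (!all(dim(i1) == dim(i2))) stop("image shapes differ", call. = FALSE)
  d <- i1 - i2
  if (is.complex(d)) mean(Mod(d)^2) else mean(d^2)
}

#' Peak signal-to-noise ratio in dB
#'
#' `10 * log10(MAX^2 / MSE)`. `max_value` is the maximum achievable value of
#' the image data; for magnitude MRI the package uses the ground-truth
#' volume's maximum magnitude. Identical images give `Inf`.
#'
#' @param i1,i2 numeric matrices of equal dimensions.
#' @param max_value positive scalar MAX.
#' @return scalar in dB (`Inf` when the images are identical).
#' @export
psnr <- function(i1, i2, max_value) {
  stopifnot(max_value > 0)
  m <- mse(i1, i2)
  if (m == 0) return(Inf)
  10 * log10(max_value^2 / m)
}

gaussian_window <- function(size, sigma) {
  r <- (size - 1) / 2
  g <- exp(-(seq(-r, r)^2) / (2 * sigma^2))
  k <- outer(g, g)
  k / sum(k)
}

# valid-mode weighted local filtering of a matrix
local_filter <- function(m, kernel) {
  a <- array(m, dim = c(nrow(m), ncol(m), 1L))
  w <- array(kernel, dim = c(nrow(kernel), ncol(kernel), 1L, 1L))
  cpp_conv_fwd(a, w, 0, 0L, 0L, 0L, 0L, FALSE)$y[, , 1L]
}

#' Structural similarity index
#'
#' Local means, standard deviations and cross-covariance are computed over a
#' sliding Gaussian-weighted window and combined into the luminance,
#' contrast and structure terms
#' `l = (2 mu1 mu2 + C1) / (mu1^2 + mu2^2 + C1)`,
#' `c = (2 s1 s2 + C2) / (s1^2 + s2^2 + C2)`,
#' `s = (s12 + C3) / (s1 s2 + C3)`; the index per window is
#' `l^alpha * c^beta * s^gamma` and the returned value is its mean over all
#' (valid) windows. Under the defaults `alpha = beta = gamma = 1` and
#' `C3 = C2 / 2` this reduces algebraically to the familiar single-fraction
#' form, which is used directly unless `general = TRUE`.
#'
#' @param i1,i2 numeric matrices of equal dimensions.
#' @param max_value data range MAX used in the stabilising constants.
#' @param window odd window side (default 7).
#' @param window_sigma Gaussian window standard deviation (default 1.5).
#' @param C1,C2,C3 stabilising constants; defaults `(0.01*MAX)^2`,
#'   `(0.03*MAX)^2` and `C2/2`.
#' @param alpha,beta,gamma exponents of the three terms.
#' @param general force the three-term product path even when the defaults
#'   would allow the simplified formula.
#' @return scalar in \[-1, 1\].
#' @export
ssim <- function(i1, i2, max_value, window = 7L, window_sigma = 1.5,
                 C1 = NULL, C2 = NULL, C3 = NULL,
                 alpha = 1, beta = 1, gamma = 1, general = FALSE) {
  if (!all(dim(i1) == dim(i2))) stop("image shapes differ", call. = FALSE)
  stopifnot(window %% 2L == 1L, max_value > 0)
  if (is.null(C1)) C1 <- (0.01 * max_value)^2
  if (is.null(C2)) C2 <- (0.03 * max_value)^2
  if (is.null(C3)) C3 <- C2 / 2
  k <- gaussian_window(window, window_sigma)
  mu1 <- local_filter(i1, k); mu2 <- local_filter(i2, k)
  s11 <- pmax(local_filter(i1 * i1, k) - mu1^2, 0)
  s22 <- pmax(local_filter(i2 * i2, k) - mu2^2, 0)
  s12 <- local_filter(i1 * i2, k) - mu1 * mu2
  simplified <- !general && alpha == 1 && beta == 1 && gamma == 1 &&
    isTRUE(all.equal(C3, C2 / 2))
  if (simplified) {
    idx <- ((2 * mu1 * mu2 + C1) * (2 * s12 + C2)) /
      ((mu1^2 + mu2^2 + C1) * (s11 + s22 + C2))
  } else {
    sd1 <- sqrt(s11); sd2 <- sqrt(s22)
    l <- (2 * mu1 * mu2 + C1) / (mu1^2 + mu2^2 + C1)
    cc <- (2 * sd1 * sd2 + C2) / (s11 + s22 + C2)
    ss <- (s12 + C3) / (sd1 * sd2 + C3)
    idx <- sign(l)^alpha * abs(l)^alpha * sign(cc)^beta * abs(cc)^beta *
      sign(ss)^gamma * abs(ss)^gamma
  }
  mean(idx)
}

# one row of the evaluation grid
metrics_record <- function(method, sigma, truth_mag, out_mag, max_value,
                           truth_cx = NULL, out_cx = NULL) {
  data.frame(method = method, sigma = sigma,
             mse = mse(truth_mag, out_mag),
             psnr = psnr(truth_mag, out_mag, max_value),
             ssim = ssim(truth_mag, out_mag, max_value),
             mse_complex = if (!is.null(truth_cx)) mse(truth_cx, out_cx)
             else NA_real_)
}
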