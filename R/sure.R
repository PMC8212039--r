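#' Configuration for the SURE-trained U-Net
#'
#' Defaults follow the reference training protocol for complex MRI slices:
#' depth-5 U-Net, 3x3 kernels, 48 initial feature maps, batches of 10, 300
#' epochs, Adam with learning rate 3e-4, and a known per-channel noise
#' standard deviation `sigma` in the (scaled) units the network sees.
#' `epsilon` is the magnitude of the Monte-Carlo perturbation used by the
#' divergence probe; `NULL` selects 1e-3 times the maximum magnitude of each
#' batch, which keeps the finite difference meaningful under any data scale.
#'
#' @param depth number of encoder/decoder levels (`>= 1`).
#' @param kernel_size convolution kernel size in pixels (odd).
#' @param base_features feature maps at the first level (doubled per level).
#' @param batch_size,epochs,learning_rate optimiser protocol.
#' @param epsilon Monte-Carlo perturbation magnitude, or `NULL` for the
#'   relative default.
#' @param sigma known noise standard deviation in scaled units (`>= 0`).
#' @param seed integer seed controlling initialisation, shuffling and probes.
#' @return An object of class `sure_config`.
#' @export
sure_config <- function(depth = 5L, kernel_size = 3L, base_features = 48L,
                        batch_size = 10L, epochs = 300L,
                        learning_rate = 3e-4, epsilon = NULL,
                        sigma = 0, seed = 1L) {
  stopifnot(depth >= 1L, kernel_size %% 2L == 1L, base_features >= 1L,
            sigma >= 0)
  if (!is.null(epsilon) && epsilon <= 0)
    stop("`epsilon` must be positive", call. = FALSE)
  structure(list(depth = as.integer(depth),
                 kernel_size = as.integer(kernel_size),
                 base_features = as.integer(base_features),
                 batch_size = as.integer(batch_size),
                 epochs = as.integer(epochs),
                 learning_rate = learning_rate, epsilon = epsilon,
                 sigma = sigma, seed = as.integer(seed)),
            class = "sure_config")
}

#' Build an (untrained) SURE U-Net denoiser
#'
#' Two input and two output channels (real, imaginary); LeakyReLU after every
#' convolution except the last, which is linear; global additive input skip
#' with a zero-initialised output convolution, so the fresh model is the
#' identity map. Inputs whose sides are not divisible by `2^depth` are
#' reflect-padded internally and the output cropped back.
#'
#' @param cfg a [sure_config()].
#' @return An object of class `denoiser_model`.
#' @export
build_sure_unet <- function(cfg) {
  stopifnot(inherits(cfg, "sure_config"))
  params <- with_seed(cfg$seed, unet_init_params(cfg))
  structure(list(kind = "sure_unet", config = cfg, params = params,
                 train_scale = NA_real_, sigma_trained = NA_real_,
                 train_mag = NA_real_, trained = FALSE,
                 history = numeric(0)),
            class = "denoiser_model")
}

#' @export
print.denoiser_model <- function(x, ...) {
  np <- sum(vapply(x$params, length, 1L))
  cat(sprintf("<denoiser_model> %s, %d parameters, %s\n", x$kind, np,
              if (isTRUE(x$trained))
                sprintf("trained (sigma = %g, scale = %g)",
                        x$sigma_trained, x$train_scale)
              else "untrained"))
  invisible(x)
}

model_forward <- function(model, x, want_cache = FALSE) {
  if (model$kind == "sure_unet") {
    unet_forward(model$params, x, model$config, want_cache)
  } else {
    stop("not a SURE U-Net", call. = FALSE)
  }
}

# coerce a denoiser argument (model or function on complex_image) to a
# function on H x W x 2 channel arrays
as_array_denoiser <- function(denoiser) {
  if (inherits(denoiser, "denoiser_model")) {
    if (denoiser$kind == "sure_unet")
      return(function(a) model_forward(denoiser, a)$y)
    if (denoiser$kind == "blindspot")
      stop("use denoise_blindspot() for blindspot models", call. = FALSE)
  }
  if (is.function(denoiser)) {
    return(function(a) {
      out <- denoiser(complex_image(channels_to_complex(a)))
      as_channel_array(out)
    })
  }
  stop("`denoiser` must be a denoiser_model or a function", call. = FALSE)
}

as_image_batch <- function(y) {
  if (inherits(y, "complex_image")) list(y) else lapply(y, as_complex_image)
}

#' Supervised mean squared error over a batch (oracle loss)
#'
#' `(1/M) * sum_j || pred_j - truth_j ||^2`, where the squared norm runs over
#' all real scalar entries (both channels of every pixel). This is the loss
#' SURE estimates without ground truth; it is exported for testing and
#' evaluation only.
#'
#' @param pred,truth a [complex_image()] or list of them, matching shapes.
#' @return scalar.
#' @export
mse_supervised <- function(pred, truth) {
  pred <- as_image_batch(pred); truth <- as_image_batch(truth)
  if (length(pred) != length(truth)) stop("batch sizes differ", call. = FALSE)
  per <- mapply(function(p, t) {
    if (!all(dim(p$data) == dim(t$data)))
      stop("image shapes differ", call. = FALSE)
    sum(Mod(p$data - t$data)^2)
  }, pred, truth)
  mean(per)
}

#' Monte-Carlo SURE loss
#'
#' Unbiased estimate of the batch risk `(1/M) sum_j ||h(y_j) - x_j||^2` that
#' uses only the noisy observations: per sample,
#' `||y - h(y)||^2 - K*sigma^2 + (2*sigma^2/eps) * n~' (h(y + eps*n~) - h(y))`
#' with `n~` a fresh standard-normal field and `K` the number of real scalar
#' entries (2 per complex pixel). The last term is a randomised
#' finite-difference probe of the divergence `2*sigma^2 * sum_i dh_i/dy_i`.
#'
#' @param denoiser a `denoiser_model` (SURE U-Net) or a function mapping a
#'   [complex_image()] to a [complex_image()].
#' @param y a [complex_image()] or list of them (one batch).
#' @param sigma per-channel noise standard deviation in the units of `y`.
#' @param epsilon perturbation magnitude; `NULL` for 1e-3 * max magnitude.
#' @param seed optional seed for the probe draw.
#' @param return_parts return the loss decomposition instead of a scalar.
#' @return scalar loss, or (with `return_parts`) a list with elements
#'   `loss`, `residual`, `divergence` (the Monte-Carlo term), and `K`.
#' @export
mc_sure_loss <- function(denoiser, y, sigma, epsilon = NULL, seed = NULL,
                         return_parts = FALSE) {
  if (sigma < 0) stop("`sigma` must be >= 0", call. = FALSE)
  if (!is.null(epsilon) && epsilon <= 0)
    stop("`epsilon` must be > 0 (divergence probe undefined)", call. = FALSE)
  f <- as_array_denoiser(denoiser)
  batch <- lapply(as_image_batch(y), as_channel_array)
  if (is.null(epsilon)) {
    epsilon <- 1e-3 * max(vapply(batch, function(a) max(abs(a)), 1.0))
    if (epsilon <= 0) epsilon <- 1e-6
  }
  res <- with_seed(seed, {
    vapply(batch, function(a) {
      K <- length(a)
      h1 <- f(a)
      nt <- array(rnorm(K), dim = dim(a))
      h2 <- f(a + epsilon * nt)
      resid <- sum((a - h1)^2)
      div <- (2 * sigma^2 / epsilon) * sum(nt * (h2 - h1))
      c(resid, div, K)
    }, numeric(3))
  })
  residual <- mean(res[1L, ]); div <- mean(res[2L, ]); K <- mean(res[3L, ])
  loss <- residual - K * sigma^2 + div
  if (return_parts)
    list(loss = loss, residual = residual, divergence = div, K = K)
  else loss
}

# loss and parameter gradients of the MC-SURE objective for one image
sure_grads <- function(model, a, sigma, epsilon) {
  K <- length(a)
  f1 <- model_forward(model, a, want_cache = TRUE)
  nt <- array(rnorm(K), dim = dim(a))
  f2 <- model_forward(model, a + epsilon * nt, want_cache = TRUE)
  r <- a - f1$y
  loss <- sum(r^2) - K * sigma^2 +
    (2 * sigma^2 / epsilon) * sum(nt * (f2$y - f1$y))
  d1 <- -2 * r - (2 * sigma^2 / epsilon) * nt
  d2 <- (2 * sigma^2 / epsilon) * nt
  g1 <- unet_backward(model$params, f1$cache, d1, model$config)
  g2 <- unet_backward(model$params, f2$cache, d2, model$config)
  list(loss = loss, grads = add_grads(g1, g2))
}

#' Train a SURE U-Net with the Monte-Carlo SURE loss
#'
#' Minimises [mc_sure_loss()] by Adam over the training slices; no clean
#' targets are used anywhere. Training images must already be in the units
#' the protocol prescribes (see [apply_scale()]); the applied scale factor is
#' recorded in the returned model so [denoise_sure()] can reconcile units at
#' test time. Deterministic for a fixed seed and thread count.
#'
#' @param model an untrained model from [build_sure_unet()].
#' @param train_imgs list of (noisy, scaled) [complex_image()] slices.
#' @param cfg a [sure_config()]; defaults to the one inside `model`.
#' @return the trained `denoiser_model`, with per-epoch mean loss in
#'   `$history`.
#' @export
train_sure <- function(model, train_imgs, cfg = model$config) {
  stopifnot(inherits(model, "denoiser_model"), model$kind == "sure_unet")
  train_imgs <- as_image_batch(train_imgs)
  if (length(train_imgs) < 1L) stop("no training slices", call. = FALSE)
  arrs <- lapply(train_imgs, as_channel_array)
  scale <- train_imgs[[1L]]$scale_applied
  model$config <- cfg
  params <- model$params
  state <- adam_init(params)
  lr <- cfg$learning_rate
  history <- numeric(cfg$epochs)
  if (cfg$epochs > 0L) with_seed(cfg$seed + 1L, {
    for (ep in seq_len(cfg$epochs)) {
      ord <- sample.int(length(arrs))
      ep_loss <- 0; nb <- 0L
      for (start in seq(1L, length(ord), by = cfg$batch_size)) {
        idx <- ord[start:min(start + cfg$batch_size - 1L, length(ord))]
        eps <- cfg$epsilon
        if (is.null(eps)) {
          eps <- 1e-3 * max(vapply(arrs[idx], function(a) max(abs(a)), 1.0))
          if (eps <= 0) eps <- 1e-6
        }
        gsum <- NULL; bloss <- 0
        mtmp <- model; mtmp$params <- params
        for (i in idx) {
          sg <- sure_grads(mtmp, arrs[[i]], cfg$sigma, eps)
          gsum <- add_grads(gsum, sg$grads)
          bloss <- bloss + sg$loss
        }
        bloss <- bloss / length(idx)
        if (!is.finite(bloss))
          stop("non-finite SURE loss; check the input scale factor",
               call. = FALSE)
        upd <- adam_step(params, scale_grads(gsum, 1 / length(idx)),
                         state, lr)
        params <- upd$params; state <- upd$state
        ep_loss <- ep_loss + bloss; nb <- nb + 1L
      }
      history[ep] <- ep_loss / nb
    }
  })
  model$params <- params
  model$train_scale <- scale
  model$sigma_trained <- cfg$sigma
  model$train_mag <- max(vapply(arrs, function(a) max(abs(a)), 1.0))
  model$trained <- TRUE
  model$history <- history
  model
}

#' Denoise a complex image with a trained SURE U-Net
#'
#' The input may be in any units: the factor `train_scale / scale_applied`
#' brings it to the units the network was trained in, and the output is
#' mapped back to the input's units. A warning is raised when the input
#' magnitude differs from the training magnitude by more than a factor of
#' 100 after reconciliation, which usually means a wrong scale factor.
#'
#' @param model a trained `denoiser_model` of kind `sure_unet`.
#' @param y a [complex_image()].
#' @return the denoised [complex_image()] in the input's units.
#' @export
denoise_sure <- function(model, y) {
  stopifnot(inherits(model, "denoiser_model"), model$kind == "sure_unet")
  y <- as_complex_image(y)
  f <- if (is.finite(model$train_scale)) model$train_scale / y$scale_applied
  else 1
  a <- as_channel_array(y) * f
  if (is.finite(model$train_mag) && model$train_mag > 0) {
    ratio <- max(abs(a)) / model$train_mag
    if (is.finite(ratio) && (ratio > 100 || ratio < 0.01))
      warning(sprintf(paste0("input magnitude differs from training ",
                             "magnitude by a factor of %.3g; ",
                             "check the scale factor"), ratio))
  }
  out <- model_forward(model, a)$y / f
  complex_image(channels_to_complex(out), y$scale_applied)
}
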