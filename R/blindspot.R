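#' Configuration for the blindspot denoiser
#'
#' Defaults follow the reference protocol: 5 convolution layers per branch,
#' 3x3 kernels, 48 initial feature maps, batches of 5 for 300 epochs, Adam
#' with initial learning rate 3e-4, and the learning rate halved when the
#' validation loss has not decreased for `lr_patience` epochs. `sigma` is the
#' known per-channel noise standard deviation in the (scaled) units the
#' network sees; in practice it comes from [estimate_sigma_background()].
#'
#' @param depth convolution layers per half-plane branch (`>= 1`).
#' @param kernel_size convolution kernel size (odd).
#' @param base_features feature maps per branch.
#' @param batch_size,epochs,learning_rate optimiser protocol.
#' @param lr_patience epochs without validation improvement before the
#'   learning rate is reduced (`>= 1`).
#' @param lr_factor multiplicative learning-rate reduction on plateau.
#' @param sigma known noise standard deviation in scaled units.
#' @param var_floor additive floor on the predicted prior variance
#'   (scaled units squared); guards the closed-form posterior against
#'   division blow-ups.
#' @param seed integer seed.
#' @return An object of class `blindspot_config`.
#' @export
blindspot_config <- function(depth = 5L, kernel_size = 3L,
                             base_features = 48L, batch_size = 5L,
                             epochs = 300L, learning_rate = 3e-4,
                             lr_patience = 10L, lr_factor = 0.5,
                             sigma = 0, var_floor = 1e-8, seed = 1L) {
  stopifnot(depth >= 1L, kernel_size %% 2L == 1L, lr_patience >= 1L,
            lr_factor > 0, lr_factor < 1, sigma >= 0, var_floor > 0)
  structure(list(depth = as.integer(depth),
                 kernel_size = as.integer(kernel_size),
                 base_features = as.integer(base_features),
                 batch_size = as.integer(batch_size),
                 epochs = as.integer(epochs),
                 learning_rate = learning_rate,
                 lr_patience = as.integer(lr_patience),
                 lr_factor = lr_factor, sigma = sigma,
                 var_floor = var_floor, seed = as.integer(seed)),
            class = "blindspot_config")
}

#' Build an (untrained) blindspot denoiser
#'
#' Four half-plane branches realised as one shared, vertically-restricted
#' convolution stack applied to the 0/90/180/270-degree rotations of the
#' input, fused by 1x1 convolutions into a per-pixel Gaussian prior: a
#' two-channel mean `mu` and a per-channel variance obtained through a
#' softplus positivity map plus `var_floor`. By construction the prior at a
#' pixel is independent of that pixel's own value.
#'
#' @param cfg a [blindspot_config()].
#' @return An object of class `denoiser_model`.
#' @export
build_blindspot_net <- function(cfg) {
  stopifnot(inherits(cfg, "blindspot_config"))
  params <- with_seed(cfg$seed, blindspot_init_params(cfg))
  structure(list(kind = "blindspot", config = cfg, params = params,
                 train_scale = NA_real_, sigma_trained = NA_real_,
                 trained = FALSE, history = NULL),
            class = "denoiser_model")
}

new_gaussian_prior <- function(mu, var) {
  structure(list(mu = mu, var = var), class = "gaussian_prior")
}

#' @export
print.gaussian_prior <- function(x, ...) {
  cat(sprintf("<gaussian_prior> %d x %d, median var = %g\n",
              nrow(x$mu), ncol(x$mu), median(x$var)))
  invisible(x)
}

#' Predict the per-pixel Gaussian prior from the pixel's context
#'
#' Runs the blindspot network on a complex image and returns the prior
#' `p(x | context, sigma)` it parameterises: per-pixel mean (complex) and
#' per-channel variance, in the units of the input image (scale reconciled
#' through the model's recorded training scale).
#'
#' @param model a `denoiser_model` of kind `blindspot`.
#' @param img a [complex_image()] (square).
#' @return a `gaussian_prior` with fields `mu` (complex matrix) and `var`
#'   (H x W x 2 array).
#' @export
predict_prior <- function(model, img) {
  stopifnot(inherits(model, "denoiser_model"), model$kind == "blindspot")
  img <- as_complex_image(img)
  f <- if (is.finite(model$train_scale)) model$train_scale / img$scale_applied
  else 1
  fw <- blindspot_forward(model$params, as_channel_array(img) * f,
                          model$config)
  new_gaussian_prior(channels_to_complex(fw$mu / f), fw$var / f^2)
}

#' Blindspot training loss (negative log-likelihood)
#'
#' Per-channel negative log-likelihood of the observed pixel under the
#' predictive marginal `y ~ N(mu, var + sigma^2)`: the mean over pixels and
#' channels of `0.5 * log(var + sigma^2) + (y - mu)^2 / (2 * (var + sigma^2))`,
#' additive constants dropped. Because the prior never sees the centre
#' pixel, minimising this trains `mu` towards the clean signal and `var`
#' towards the prior uncertainty, without clean targets.
#'
#' @param prior a `gaussian_prior` (e.g. from [predict_prior()]).
#' @param y the observed noisy [complex_image()].
#' @param sigma per-channel noise standard deviation (same units as `y`).
#' @return scalar loss.
#' @export
blindspot_train_loss <- function(prior, y, sigma) {
  stopifnot(inherits(prior, "gaussian_prior"))
  y <- as_complex_image(y)
  mu <- as_channel_array(prior$mu)
  ya <- as_channel_array(y)
  v <- prior$var + sigma^2
  mean(0.5 * log(v) + (ya - mu)^2 / (2 * v))
}

#' Closed-form posterior mean under the conjugate Gaussian model
#'
#' Combines the blindspot prior `x ~ N(mu, var)` with the observation model
#' `y | x ~ N(x, sigma^2)` per pixel and channel:
#' `E[x | y] = (mu * sigma^2 + y * var) / (var + sigma^2)`.
#' This is how the centre pixel — excluded from the receptive field during
#' training — is exploited at test time. With `sigma = 0` the observation is
#' exact and `y` is returned unchanged; as `var -> 0` the output approaches
#' `mu`.
#'
#' @param prior a `gaussian_prior`.
#' @param y the observed noisy [complex_image()].
#' @param sigma per-channel noise standard deviation (same units as `y`).
#' @return the posterior-mean [complex_image()].
#' @export
posterior_mean <- function(prior, y, sigma) {
  stopifnot(inherits(prior, "gaussian_prior"), sigma >= 0)
  y <- as_complex_image(y)
  if (sigma == 0) return(y)
  mu <- as_channel_array(prior$mu)
  ya <- as_channel_array(y)
  post <- (mu * sigma^2 + ya * prior$var) / (prior$var + sigma^2)
  complex_image(channels_to_complex(post), y$scale_applied)
}

# NLL loss + parameter grads for one image (channel array, scaled units)
blindspot_grads <- function(params, a, sigma, cfg) {
  fw <- blindspot_forward(params, a, cfg, want_cache = TRUE)
  v <- fw$var + sigma^2
  n <- length(a)
  r <- a - fw$mu
  loss <- mean(0.5 * log(v) + r^2 / (2 * v))
  dmu <- -r / v / n
  dvar <- (1 / (2 * v) - r^2 / (2 * v^2)) / n
  g <- blindspot_backward(params, fw$cache, dmu, dvar, cfg)
  list(loss = loss, grads = g)
}

blindspot_eval_loss <- function(params, arrs, sigma, cfg) {
  mean(vapply(arrs, function(a) {
    fw <- blindspot_forward(params, a, cfg)
    v <- fw$var + sigma^2
    mean(0.5 * log(v) + (a - fw$mu)^2 / (2 * v))
  }, 1.0))
}

#' Train a blindspot denoiser
#'
#' Minimises [blindspot_train_loss()] by Adam over the training slices. A
#' held-out validation set drives the learning-rate schedule: when the
#' validation loss has not decreased for `cfg$lr_patience` epochs the
#' learning rate is multiplied by `cfg$lr_factor`. If `val_imgs` is `NULL`,
#' roughly one sixth of the training slices (at least one) is split off.
#'
#' @param model an untrained model from [build_blindspot_net()].
#' @param train_imgs list of (noisy, scaled) [complex_image()] slices.
#' @param cfg a [blindspot_config()]; defaults to the one inside `model`.
#' @param val_imgs optional list of validation slices.
#' @return the trained `denoiser_model`; `$history` is a data.frame with
#'   per-epoch training loss, validation loss and learning rate.
#' @export
train_blindspot <- function(model, train_imgs, cfg = model$config,
                            val_imgs = NULL) {
  stopifnot(inherits(model, "denoiser_model"), model$kind == "blindspot")
  train_imgs <- as_image_batch(train_imgs)
  if (is.null(val_imgs)) {
    if (length(train_imgs) < 2L)
      stop("need at least two slices to split off validation", call. = FALSE)
    nval <- max(1L, length(train_imgs) %/% 6L)
    val_imgs <- train_imgs[seq_len(nval)]
    train_imgs <- train_imgs[-seq_len(nval)]
  } else {
    val_imgs <- as_image_batch(val_imgs)
  }
  scale <- train_imgs[[1L]]$scale_applied
  arrs <- lapply(train_imgs, as_channel_array)
  varrs <- lapply(val_imgs, as_channel_array)
  model$config <- cfg
  params <- model$params
  state <- adam_init(params)
  lr <- cfg$learning_rate
  hist <- data.frame(epoch = integer(0), train_loss = numeric(0),
                     val_loss = numeric(0), lr = numeric(0))
  best_val <- Inf; stall <- 0L
  if (cfg$epochs > 0L) with_seed(cfg$seed + 1L, {
    for (ep in seq_len(cfg$epochs)) {
      ord <- sample.int(length(arrs))
      ep_loss <- 0; nb <- 0L
      for (start in seq(1L, length(ord), by = cfg$batch_size)) {
        idx <- ord[start:min(start + cfg$batch_size - 1L, length(ord))]
        gsum <- NULL; bloss <- 0
        for (i in idx) {
          bg <- blindspot_grads(params, arrs[[i]], cfg$sigma, cfg)
          gsum <- add_grads(gsum, bg$grads)
          bloss <- bloss + bg$loss
        }
        bloss <- bloss / length(idx)
        if (!is.finite(bloss))
          stop("non-finite blindspot loss; check the input scale factor",
               call. = FALSE)
        upd <- adam_step(params, scale_grads(gsum, 1 / length(idx)),
                         state, lr)
        params <- upd$params; state <- upd$state
        ep_loss <- ep_loss + bloss; nb <- nb + 1L
      }
      vl <- blindspot_eval_loss(params, varrs, cfg$sigma, cfg)
      hist[nrow(hist) + 1L, ] <- list(ep, ep_loss / nb, vl, lr)
      if (vl < best_val - 1e-12) {
        best_val <- vl; stall <- 0L
      } else {
        stall <- stall + 1L
        if (stall >= cfg$lr_patience) {
          lr <- lr * cfg$lr_factor
          stall <- 0L
        }
      }
    }
  })
  model$params <- params
  model$train_scale <- scale
  model$sigma_trained <- cfg$sigma
  model$trained <- TRUE
  model$history <- hist
  model
}

#' Denoise a complex image with a trained blindspot network
#'
#' Forward pass to the per-pixel Gaussian prior, then the closed-form
#' posterior mean with the observed pixel. `sigma = "auto"` estimates the
#' noise level from the image background.
#'
#' @param model a trained `denoiser_model` of kind `blindspot`.
#' @param y a [complex_image()] (square).
#' @param sigma per-channel noise standard deviation in the units of `y`,
#'   or `"auto"` to use [estimate_sigma_background()].
#' @return the denoised [complex_image()] in the input's units.
#' @export
denoise_blindspot <- function(model, y, sigma = "auto") {
  y <- as_complex_image(y)
  if (identical(sigma, "auto")) sigma <- estimate_sigma_background(y)
  prior <- predict_prior(model, y)
  posterior_mean(prior, y, sigma)
}
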