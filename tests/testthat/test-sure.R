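test_that("supervised batch MSE follows its definition", {
  img <- tiny_phantom()
  expect_equal(mse_supervised(img, img), 0)
  # one offending pixel of difference 3 + 4i contributes 25
  a <- matrix(0 + 0i, 8, 8)
  b <- a; b[2, 3] <- 3 + 4i
  expect_equal(mse_supervised(complex_image(b), complex_image(a)), 25)
  # batch of two equal contributions averages them
  c1 <- a; c1[1, 1] <- 1 + 0i        # ||.||^2 = 1
  c2 <- a; c2[1, 1] <- 0 + 3i        # ||.||^2 = 9
  expect_equal(mse_supervised(list(complex_image(c1), complex_image(c2)),
                              list(complex_image(a), complex_image(a))),
               5)
  expect_error(mse_supervised(complex_image(a),
                              complex_image(matrix(0 + 0i, 9, 9))),
               "shapes")
})

test_that("untrained U-Net is the identity and preserves any even shape", {
  cfg <- sure_config(depth = 2L, base_features = 4L, sigma = 1, seed = 3)
  m <- build_sure_unet(cfg)
  for (n in c(16L, 20L, 64L)) {
    a <- array(rnorm(n * (n + 2) * 2), c(n, n + 2L, 2L))
    out <- mrdenoise:::unet_forward(m$params, a, cfg)$y
    expect_equal(dim(out), dim(a))
    expect_equal(out, a)  # zero-initialised head + input skip
  }
})

test_that("mc-sure of the identity denoiser equals the noisy risk K*sigma^2", {
  truth <- tiny_phantom(32)
  sg <- 100
  K <- 2 * 32 * 32
  ls <- vapply(1:60, function(i) {
    y <- add_gaussian_noise(truth, noise_model(sg, seed = i))
    mc_sure_loss(function(img) img, y, sg, seed = 500 + i)
  }, 1.0)
  se <- sd(ls) / sqrt(length(ls))
  expect_lt(abs(mean(ls) - K * sg^2), 3 * se + 0.01 * K * sg^2)
})

test_that("mc-sure of the zero denoiser on pure noise estimates zero risk", {
  zero_img <- complex_image(matrix(0 + 0i, 16, 16))
  sg <- 50
  ls <- vapply(1:100, function(i) {
    y <- add_gaussian_noise(zero_img, noise_model(sg, seed = i))
    mc_sure_loss(function(img) complex_image(matrix(0 + 0i, 16, 16)),
                 y, sg, seed = 900 + i)
  }, 1.0)
  se <- sd(ls) / sqrt(length(ls))
  expect_lt(abs(mean(ls)), 3 * se)
})

test_that("mc divergence of an explicit linear filter matches its trace", {
  n <- 8L
  A <- box_blur_matrix(n)
  den <- matrix_denoiser(A, n)
  y0 <- random_cimage(n, seed = 4)
  sg <- 1.5
  divs <- vapply(1:400, function(i)
    mc_sure_loss(den, y0, sg, seed = i, return_parts = TRUE)$divergence,
    1.0)
  # the operator acts on both channels: trace of blockdiag(A, A)
  target <- 2 * sg^2 * (2 * sum(diag(A)))
  se <- sd(divs) / sqrt(length(divs))
  expect_lt(abs(mean(divs) - target), 3 * se)
})

test_that("mc-sure is epsilon-invariant for a linear denoiser", {
  n <- 8L
  den <- matrix_denoiser(box_blur_matrix(n), n)
  y0 <- random_cimage(n, seed = 6)
  vals <- vapply(c(1e-4, 1e-3, 1e-2),
                 function(e) mc_sure_loss(den, y0, 2, epsilon = e, seed = 7),
                 1.0)
  expect_lt(max(vals) - min(vals), 1e-6 * abs(mean(vals)) + 1e-6)
  expect_error(mc_sure_loss(den, y0, 2, epsilon = 0), "epsilon")
})

test_that("training contract: zero epochs is a no-op, seeds reproduce", {
  spec <- phantom_spec(size = 32L, n_slices = 1L, n_subjects = 4L, seed = 8)
  imgs <- lapply(1:4, function(s) {
    apply_scale(add_gaussian_noise(generate_phantom_slice(spec, s, 1),
                                   noise_model(100, seed = s)), 1 / 2000)
  })
  cfg0 <- sure_config(depth = 1L, base_features = 4L, batch_size = 2L,
                      epochs = 0L, sigma = 0.05, seed = 5)
  m0 <- build_sure_unet(cfg0)
  t0 <- train_sure(m0, imgs, cfg0)
  expect_identical(t0$params, m0$params)
  expect_length(t0$history, 0L)
  cfg <- sure_config(depth = 1L, base_features = 4L, batch_size = 2L,
                     epochs = 3L, learning_rate = 1e-3, sigma = 0.05,
                     seed = 5)
  t1 <- train_sure(build_sure_unet(cfg), imgs, cfg)
  t2 <- train_sure(build_sure_unet(cfg), imgs, cfg)
  expect_identical(t1$params, t2$params)
  expect_identical(t1$history, t2$history)
})

test_that("short training reduces the sure loss on the desk-style task", {
  spec <- phantom_spec(size = 32L, n_slices = 2L, n_subjects = 8L, seed = 14)
  imgs <- unlist(lapply(1:8, function(s) lapply(1:2, function(k) {
    apply_scale(add_gaussian_noise(generate_phantom_slice(spec, s, k),
                                   noise_model(100, seed = 10 * s + k)),
                1 / 2000)
  })), recursive = FALSE)
  cfg <- sure_config(depth = 2L, base_features = 8L, batch_size = 2L,
                     epochs = 12L, learning_rate = 1e-3, sigma = 0.05,
                     seed = 2)
  tr <- train_sure(build_sure_unet(cfg), imgs, cfg)
  h <- tr$history
  expect_lte(median(tail(h, 5)), median(head(h, 5)))
})

test_that("denoise_sure reconciles units and flags gross scale mismatch", {
  spec <- phantom_spec(size = 32L, n_slices = 1L, n_subjects = 2L, seed = 6)
  truth <- generate_phantom_slice(spec, 1, 1)
  imgs <- list(apply_scale(add_gaussian_noise(truth,
                                              noise_model(100, seed = 1)),
                           1 / 2000))
  cfg <- sure_config(depth = 1L, base_features = 4L, batch_size = 1L,
                     epochs = 1L, sigma = 0.05, seed = 1)
  tr <- train_sure(build_sure_unet(cfg), imgs, cfg)
  noisy_raw <- add_gaussian_noise(truth, noise_model(100, seed = 2))
  out <- denoise_sure(tr, noisy_raw)          # raw units in, raw units out
  expect_equal(out$scale_applied, 1)
  expect_identical(denoise_sure(tr, noisy_raw)$data, out$data)
  big <- complex_image(noisy_raw$data * 1e4)
  expect_warning(denoise_sure(tr, big), "scale")
})
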