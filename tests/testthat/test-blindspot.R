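test_that("the centre pixel never influences its own prior", {
  m <- random_head_model()
  expect_lt(jacobian_diag_max(m), 1e-6)
})

test_that("all off-centre pixels within the field radius do influence it", {
  m <- random_head_model()
  set.seed(4)
  a <- array(rnorm(16 * 16 * 2), c(16, 16, 2L))
  fw <- mrdenoise:::blindspot_forward(m$params, a, m$config)
  offs <- expand.grid(di = -2:2, dj = -2:2)
  offs <- offs[!(offs$di == 0 & offs$dj == 0), ]
  infl <- apply(offs, 1, function(o) {
    ap <- a; ap[8 + o[1], 8 + o[2], 1L] <- ap[8 + o[1], 8 + o[2], 1L] + 1
    fp <- mrdenoise:::blindspot_forward(m$params, ap, m$config)
    max(abs(fp$mu[8, 8, ] - fw$mu[8, 8, ]))
  })
  expect_true(all(infl > 0))
})

test_that("training loss follows the predictive gaussian likelihood", {
  n <- 8L
  mu <- matrix(0.3 + 0.1i, n, n)
  y <- complex_image(mu)  # y == mu
  # var + sigma^2 = 1: loss is exactly zero
  pr <- mrdenoise:::new_gaussian_prior(mu, array(0.75, c(n, n, 2L)))
  expect_equal(blindspot_train_loss(pr, y, 0.5), 0)
  # quadratic term scales exactly with the squared residual
  y2 <- complex_image(mu + (0.2 + 0i))
  l1 <- blindspot_train_loss(pr, y2, 0.5)
  expect_equal(l1, 0.2^2 / 2 / 2)  # halved: only the real channel deviates
  # minimising over mu recovers y; over var recovers (y-mu)^2 - sigma^2
  yv <- 1.3; sg <- 0.4
  f_mu <- function(m) 0.5 * log(0.25 + sg^2) + (yv - m)^2 / (2 * (0.25 + sg^2))
  expect_equal(optimize(f_mu, c(-5, 5))$minimum, yv, tolerance = 1e-4)
  f_v <- function(v) 0.5 * log(v + sg^2) + (yv - 0.2)^2 / (2 * (v + sg^2))
  expect_equal(optimize(f_v, c(1e-6, 10))$minimum,
               (yv - 0.2)^2 - sg^2, tolerance = 1e-4)
})

test_that("posterior mean matches the conjugate closed form and its limits", {
  n <- 8L
  mu <- matrix(10 + 0i, n, n)
  pr <- mrdenoise:::new_gaussian_prior(mu, array(4, c(n, n, 2L)))
  y <- complex_image(matrix(20 + 0i, n, n))
  out <- posterior_mean(pr, y, 2)  # sigma^2 = 4
  expect_equal(Re(out$data), matrix(15, n, n))  # (10*4 + 20*4) / 8
  # sigma = 0: observation fully trusted
  expect_identical(posterior_mean(pr, y, 0)$data, y$data)
  # var -> 0: prior fully trusted
  pr0 <- mrdenoise:::new_gaussian_prior(mu, array(1e-12, c(n, n, 2L)))
  expect_equal(Re(posterior_mean(pr0, y, 2)$data), Re(mu),
               tolerance = 1e-9)
})

test_that("posterior mean agrees with numerical integration of the posterior", {
  set.seed(31)
  for (i in 1:100) {
    mu <- rnorm(1, 0, 5); v <- runif(1, 0.01, 9)
    yv <- rnorm(1, 0, 5); sg <- runif(1, 0.05, 3)
    cf <- (mu * sg^2 + yv * v) / (v + sg^2)
    expect_equal(numeric_posterior_mean(mu, v, yv, sg), cf,
                 tolerance = 1e-6)
  }
})

test_that("posterior mean is a channel-wise convex combination of mu and y", {
  set.seed(17)
  n <- 8L
  mu <- matrix(complex(real = rnorm(n * n), imaginary = rnorm(n * n)), n, n)
  pr <- mrdenoise:::new_gaussian_prior(mu,
                                       array(runif(n * n * 2, 0.01, 4),
                                             c(n, n, 2L)))
  y <- random_cimage(n, seed = 18)
  out <- posterior_mean(pr, y, 0.8)
  for (chan in list(Re, Im)) {
    lo <- pmin(chan(mu), chan(y$data)); hi <- pmax(chan(mu), chan(y$data))
    expect_true(all(chan(out$data) >= lo - 1e-12))
    expect_true(all(chan(out$data) <= hi + 1e-12))
  }
})

test_that("learning-rate schedule only ever decreases, seeds reproduce", {
  spec <- phantom_spec(size = 32L, n_slices = 1L, n_subjects = 6L, seed = 23)
  imgs <- lapply(1:6, function(s) {
    apply_scale(add_gaussian_noise(generate_phantom_slice(spec, s, 1),
                                   noise_model(100, seed = s)), 1 / 2000)
  })
  cfg <- blindspot_config(depth = 1L, base_features = 4L, batch_size = 2L,
                          epochs = 6L, learning_rate = 1e-3,
                          lr_patience = 1L, sigma = 0.05, seed = 3)
  t1 <- train_blindspot(build_blindspot_net(cfg), imgs, cfg)
  expect_true(all(diff(t1$history$lr) <= 0))
  expect_equal(nrow(t1$history), 6L)
  t2 <- train_blindspot(build_blindspot_net(cfg), imgs, cfg)
  expect_identical(t1$params, t2$params)
  # epochs = 0: untouched parameters, empty history
  cfg0 <- cfg; cfg0$epochs <- 0L
  m0 <- build_blindspot_net(cfg0)
  t0 <- train_blindspot(m0, imgs, cfg0)
  expect_identical(t0$params, m0$params)
  expect_equal(nrow(t0$history), 0L)
})

test_that("trained variance is higher at sharp edges than in flat regions", {
  # piecewise-constant rectangles with hard edges: context prediction fails
  # exactly at the discontinuities, so the learned prior variance must
  # concentrate there — the mechanism behind posterior-mean edge
  # preservation
  mk <- function(seed) {
    set.seed(seed)
    m <- matrix(0.5, 32, 32)
    for (k in 1:3) {
      r0 <- sample(4:20, 1); c0 <- sample(4:20, 1)
      h <- sample(6:10, 1); w <- sample(6:10, 1)
      m[r0:(r0 + h), c0:(c0 + w)] <- runif(1, 1, 2)
    }
    complex_image(m + 0i)
  }
  sg <- 0.1
  imgs <- lapply(1:14, function(s)
    add_gaussian_noise(mk(s), noise_model(sg, seed = 100 + s)))
  bcfg <- blindspot_config(depth = 2L, base_features = 16L, batch_size = 1L,
                           epochs = 60L, learning_rate = 5e-3,
                           lr_patience = 20L, sigma = sg, seed = 3)
  bs <- train_blindspot(build_blindspot_net(bcfg), imgs, bcfg)
  truth <- mk(99)
  noisy <- add_gaussian_noise(truth, noise_model(sg, seed = 999))
  pr <- predict_prior(bs, noisy)
  g <- mrdenoise:::grad_mag(magnitude(truth))
  edge_mask <- g > 0.1
  flat_mask <- !mrdenoise:::dilate1(mrdenoise:::dilate1(edge_mask))
  v <- (pr$var[, , 1] + pr$var[, , 2]) / 2
  expect_gt(median(v[edge_mask]), median(v[flat_mask]))
})

test_that("on constant images the prior mean recovers the constant", {
  cval <- 1; sg <- 0.1
  imgs <- lapply(1:8, function(s)
    add_gaussian_noise(complex_image(matrix(cval + 0i, 24, 24)),
                       noise_model(sg, seed = s)))
  cfg <- blindspot_config(depth = 1L, base_features = 8L, batch_size = 1L,
                          epochs = 150L, learning_rate = 5e-3,
                          lr_patience = 15L, sigma = sg, seed = 3)
  m <- train_blindspot(build_blindspot_net(cfg), imgs, cfg)
  pr <- predict_prior(m, imgs[[8]])
  interior <- pr$mu[5:20, 5:20]
  # the prediction error sits well below the noise level on both channels
  expect_lt(mean(abs(Re(interior) - cval)), 0.25 * sg)
  expect_lt(mean(abs(Im(interior))), 0.25 * sg)
})

test_that("blindspot inference is deterministic and degrades gracefully", {
  m <- random_head_model()
  m$train_scale <- 1
  y <- random_cimage(16, seed = 5)
  o1 <- denoise_blindspot(m, y, 0.5)
  o2 <- denoise_blindspot(m, y, 0.5)
  expect_identical(o1$data, o2$data)
  expect_identical(denoise_blindspot(m, y, 0)$data, y$data)
})

test_that("checkpoints round-trip through the descriptor and weights", {
  m <- random_head_model(seed = 13)
  m$train_scale <- 1 / 2000; m$sigma_trained <- 0.05; m$trained <- TRUE
  f <- tempfile(fileext = ".rds")
  save_denoiser(m, f)
  m2 <- load_denoiser(f)
  expect_identical(m2$params, m$params)
  expect_equal(m2$train_scale, m$train_scale)
  expect_equal(m2$config$depth, m$config$depth)
  y <- random_cimage(16, seed = 9)
  expect_identical(denoise_blindspot(m, y, 0.3)$data,
                   denoise_blindspot(m2, y, 0.3)$data)
  unlink(f)
})
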