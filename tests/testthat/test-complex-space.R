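test_that("Fourier pair is unitary, centered and self-inverse", {
  k <- random_cimage(64, seed = 11)
  k <- kspace_slice(k$data)
  img <- kspace_to_image(k)
  k2 <- image_to_kspace(img)
  expect_lt(max(Mod(k2$data - k$data)) / max(Mod(k$data)), 1e-6)
  # Parseval: total power preserved
  expect_lt(abs(sum(Mod(img$data)^2) - sum(Mod(k$data)^2)) /
              sum(Mod(k$data)^2), 1e-6)
  img2 <- kspace_to_image(image_to_kspace(img))
  expect_lt(max(Mod(img2$data - img$data)), 1e-9)
})

test_that("Fourier identities: center delta, constant, flat spectrum", {
  kd <- matrix(0 + 0i, 16, 16); kd[9, 9] <- 3 + 0i  # center bin (n/2+1)
  im <- kspace_to_image(kspace_slice(kd))
  expect_lt(diff(range(Mod(im$data))), 1e-12)
  kc <- image_to_kspace(complex_image(matrix(2 + 0i, 16, 16)))
  en <- Mod(kc$data)^2
  expect_gt(en[9, 9] / sum(en), 1 - 1e-12)
  di <- matrix(0 + 0i, 16, 16); di[4, 6] <- 1 + 0i
  kdel <- image_to_kspace(complex_image(di))
  expect_lt(diff(range(Mod(kdel$data))), 1e-12)
})

test_that("gaussian noise has the requested per-channel level and seed", {
  img <- complex_image(matrix(0 + 0i, 192, 192))
  expect_identical(add_gaussian_noise(img, noise_model(0))$data, img$data)
  noisy <- add_gaussian_noise(img, noise_model(100, seed = 5))
  expect_lt(abs(sd(Re(noisy$data)) / 100 - 1), 0.02)
  expect_lt(abs(sd(Im(noisy$data)) / 100 - 1), 0.02)
  again <- add_gaussian_noise(img, noise_model(100, seed = 5))
  expect_identical(noisy$data, again$data)
  expect_error(noise_model(-1), "non-negative")
})

test_that("noise stays gaussian across the fourier transform", {
  # per-channel variance of image-space noise vs k-space-injected noise
  sg <- 10
  v_img <- v_k <- numeric(50)
  for (s in seq_len(50)) {
    n_img <- add_gaussian_noise(complex_image(matrix(0 + 0i, 32, 32)),
                                noise_model(sg, seed = s))
    n_k <- kspace_to_image(kspace_slice(
      add_gaussian_noise(complex_image(matrix(0 + 0i, 32, 32)),
                         noise_model(sg, seed = 1000 + s))$data))
    v_img[s] <- (var(as.vector(Re(n_img$data))) +
                   var(as.vector(Im(n_img$data)))) / 2
    v_k[s] <- (var(as.vector(Re(n_k$data))) +
                 var(as.vector(Im(n_k$data)))) / 2
  }
  se <- sqrt(var(v_img) / 50 + var(v_k) / 50)
  expect_lt(abs(mean(v_img) - mean(v_k)), 3 * se)
})

test_that("apply_scale is exactly invertible and bookkept", {
  img <- tiny_phantom()
  s <- apply_scale(img, 500)
  expect_equal(s$scale_applied, 500)
  back <- apply_scale(s, 1 / 500)
  expect_lt(max(Mod(back$data - img$data)), 1e-9 * max(Mod(img$data)))
  expect_error(apply_scale(img, 0), "positive")
  expect_error(apply_scale(img, -2), "positive")
})

test_that("center_crop keeps the centered window, dropping high side", {
  img <- tiny_phantom()
  expect_identical(center_crop(img, 32L)$data, img$data)
  m4 <- matrix(complex(real = 1:16, imaginary = 0), 4, 4)
  cr <- center_crop(complex_image(m4), 2L)  # rows/cols 2:3 retained
  expect_identical(cr$data, m4[2:3, 2:3])
  m <- matrix(complex(real = 1:64, imaginary = 0), 8, 8)
  cr1 <- center_crop(complex_image(m), 4L)  # even remainder: symmetric
  expect_identical(cr1$data, m[3:6, 3:6])
  m16 <- matrix(complex(real = 1:(16 * 16), imaginary = 0), 16, 16)
  cr2 <- center_crop(complex_image(m16), 9L)  # odd remainder
  expect_identical(cr2$data, m16[4:12, 4:12])  # extra dropped high side
  expect_error(center_crop(img, 33L), "exceeds")
})

test_that("zero_pad_square pads symmetrically without adding energy", {
  spec <- phantom_spec(size = 216L, n_slices = 1L, n_subjects = 1L, seed = 2)
  rect <- generate_phantom_slice(spec, 1, 1, width = 180L)
  ksq <- image_to_kspace(center_crop(rect, 180L))
  expect_identical(zero_pad_square(ksq)$data, ksq$data)  # square: identity
  kr <- kspace_slice(t(rect$data))  # 180 x 216
  padded <- zero_pad_square(kr)
  expect_equal(dim(padded), c(216L, 216L))
  expect_true(all(padded$data[1:18, ] == 0))
  expect_true(all(padded$data[199:216, ] == 0))
  expect_equal(sum(Mod(padded$data)^2), sum(Mod(kr$data)^2))
})

test_that("magnitude is the per-pixel modulus, phase-invariant", {
  m <- matrix(complex(real = 3, imaginary = 4), 8, 8)
  expect_equal(magnitude(complex_image(m)), matrix(5, 8, 8))
  img <- random_cimage(16, seed = 3)
  rot <- complex_image(img$data * exp(1i * 0.7))
  expect_equal(magnitude(rot), magnitude(img), tolerance = 1e-12)
})

test_that("background sigma estimation recovers the injected level", {
  # pure noise
  est <- vapply(1:20, function(s) {
    noisy <- add_gaussian_noise(complex_image(matrix(0 + 0i, 96, 96)),
                                noise_model(50, seed = s))
    estimate_sigma_background(noisy)
  }, 1.0)
  expect_true(all(abs(est / 50 - 1) < 0.1))
  # noise-free phantom with true zero background
  expect_equal(estimate_sigma_background(tiny_phantom(64)), 0)
  # phantom + noise
  ph <- tiny_phantom(96)
  est2 <- vapply(1:20, function(s) {
    estimate_sigma_background(add_gaussian_noise(ph,
                                                 noise_model(100,
                                                             seed = 50 + s)))
  }, 1.0)
  expect_true(all(abs(est2 / 100 - 1) < 0.1))
  expect_error(estimate_sigma_background(ph, 0.7), "0, 0.5")
})

test_that("sigma estimation error shrinks with image size", {
  err_at <- function(n) {
    mean(vapply(1:12, function(s) {
      noisy <- add_gaussian_noise(complex_image(matrix(0 + 0i, n, n)),
                                  noise_model(50, seed = s))
      abs(estimate_sigma_background(noisy) / 50 - 1)
    }, 1.0))
  }
  errs <- vapply(c(64L, 128L, 256L), err_at, 1.0)
  expect_true(errs[3] < errs[1])
})
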