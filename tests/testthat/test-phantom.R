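test_that("phantom slices are deterministic and anatomically structured", {
  spec <- phantom_spec(size = 64L, n_slices = 3L, n_subjects = 4L, seed = 9)
  a <- generate_phantom_slice(spec, 2, 2)
  b <- generate_phantom_slice(spec, 2, 2)
  expect_identical(a$data, b$data)
  # different subjects / slices differ
  expect_false(identical(generate_phantom_slice(spec, 1, 1)$data, a$data))
  expect_false(identical(generate_phantom_slice(spec, 2, 1)$data, a$data))
  expect_error(generate_phantom_slice(spec, 5, 1), "out of range")
  expect_error(generate_phantom_slice(spec, 1, 4), "out of range")
})

test_that("background margin guarantees exact zero-signal pixels", {
  spec <- phantom_spec(size = 64L, background_margin = 0.2, seed = 3)
  m <- magnitude(generate_phantom_slice(spec, 1, 1))
  expect_gte(mean(m == 0), 0.2)
  # noise-free ground truth: background sigma estimate is zero
  expect_equal(estimate_sigma_background(generate_phantom_slice(spec, 1, 1)),
               0)
})

test_that("default brain-protocol spec emits 192 x 192 complex slices", {
  spec <- phantom_spec(seed = 1)
  sl <- generate_phantom_slice(spec, 1, 1)
  expect_equal(dim(sl), c(192L, 192L))
  # phase is genuinely non-constant inside the head
  ph <- Arg(sl$data[magnitude(sl) > 0])
  expect_gt(sd(ph), 0.05)
})

test_that("tissue intensities span the requested range with several modes", {
  spec <- phantom_spec(size = 128L, tissue_count = 5L,
                       intensity_range = c(300, 2000), seed = 12)
  m <- magnitude(generate_phantom_slice(spec, 1, 1))
  v <- m[m > 0]
  expect_gt(max(v), 0.5 * 2000)
  expect_lt(max(v), 2000 * 1.05)
  # loose multi-modality check: several well-separated intensity clusters
  d <- stats::density(v, bw = 40)
  peaks <- sum(diff(sign(diff(d$y))) == -2)
  expect_gte(peaks, 2L)
})

test_that("generate_dataset writes volumes, split and reproducible manifest", {
  spec <- phantom_spec(size = 32L, n_slices = 2L, n_subjects = 4L, seed = 21)
  d1 <- file.path(tempdir(), "ph1"); d2 <- file.path(tempdir(), "ph2")
  m1 <- generate_dataset(spec, d1, n_train = 3L)
  m2 <- generate_dataset(spec, d2, n_train = 3L)
  expect_length(m1$files, 4L)
  expect_true(all(file.exists(file.path(d1, m1$files))))
  expect_equal(m1$split$train, 1:3)
  expect_equal(m1$split$test, 4L)
  expect_identical(m1$md5, m2$md5)  # same spec -> identical content hashes
  ds <- read_dataset(d1)
  expect_length(ds$subjects, 4L)
  sl <- ds$subjects[[2]][[1]]
  expect_equal(sl$data, generate_phantom_slice(spec, 2, 1)$data,
               tolerance = 1e-6)
  unlink(c(d1, d2), recursive = TRUE)
})

test_that("standard 16-subject spec splits 12 train / 4 test", {
  spec <- phantom_spec(size = 32L, n_slices = 1L, n_subjects = 16L, seed = 2)
  d <- file.path(tempdir(), "ph16")
  m <- generate_dataset(spec, d)
  expect_equal(m$split$train, 1:12)
  expect_equal(m$split$test, 13:16)
  unlink(d, recursive = TRUE)
})

test_that("magnitude export writes non-negative magnitude volumes", {
  spec <- phantom_spec(size = 32L, n_slices = 1L, n_subjects = 2L, seed = 6)
  d <- file.path(tempdir(), "phmag")
  generate_dataset(spec, d, magnitude_nifti = TRUE)
  f <- file.path(d, "subject01_mag.nii")
  expect_true(file.exists(f))
  mag <- as.array(RNifti::readNifti(f))
  expect_true(all(mag >= 0))
  expect_equal(matrix(as.vector(mag)[1:(32 * 32)], 32, 32),
               magnitude(generate_phantom_slice(spec, 1, 1)),
               tolerance = 1e-6)
  unlink(d, recursive = TRUE)
})
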