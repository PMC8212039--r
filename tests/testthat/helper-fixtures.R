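# Shared fixtures, built in code. The desk-scale end-to-end run (training
# both networks at three noise levels) is expensive, so it is computed once
# per session and cached for every test that needs it.

.cache <- new.env(parent = emptyenv())

desk_run <- function() {
  if (is.null(.cache$desk)) {
    cfg <- experiment_config("desk", seed = 1L)
    .cache$desk <- list(cfg = cfg, res = run_experiment(cfg))
  }
  .cache$desk
}

# a small noise-free phantom slice, deterministic
tiny_phantom <- function(size = 32L, seed = 7L) {
  spec <- phantom_spec(size = size, n_slices = 2L, n_subjects = 2L,
                       seed = seed)
  generate_phantom_slice(spec, 1L, 1L)
}

random_cimage <- function(n = 16L, seed = 1L, sd = 1) {
  set.seed(seed)
  complex_image(matrix(complex(real = rnorm(n * n, 0, sd),
                               imaginary = rnorm(n * n, 0, sd)), n, n))
}

# explicit local-mean (box blur) filter matrix acting on an n x n plane;
# the brute-force linear operator used as a SURE oracle
box_blur_matrix <- function(n, radius = 1L) {
  A <- matrix(0, n * n, n * n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      r <- (j - 1L) * n + i
      idx <- c()
      for (dj in -radius:radius) {
        for (di in -radius:radius) {
          ii <- i + di; jj <- j + dj
          if (ii >= 1L && ii <= n && jj >= 1L && jj <= n)
            idx <- c(idx, (jj - 1L) * n + ii)
        }
      }
      A[r, idx] <- 1 / length(idx)
    }
  }
  A
}

# apply a plane-wise filter matrix to both channels of a complex image
matrix_denoiser <- function(A, n) {
  function(img) {
    d <- img$data
    complex_image(matrix(as.vector(A %*% as.vector(Re(d))) +
                           1i * as.vector(A %*% as.vector(Im(d))), n, n))
  }
}

# blindspot model with a randomised (non-zero) output head, so exclusion
# tests are non-trivial
random_head_model <- function(seed = 11) {
  cfg <- blindspot_config(depth = 2L, base_features = 6L, sigma = 0.1,
                          seed = seed)
  m <- build_blindspot_net(cfg)
  set.seed(seed)
  m$params$f2_w <- array(rnorm(length(m$params$f2_w)) * 0.3,
                         dim(m$params$f2_w))
  m$params$f2_b <- rnorm(4L) * 0.1
  m
}

# worst relative change of the prior at a pixel when that pixel is perturbed
jacobian_diag_max <- function(model, n = 16L, seed = 2) {
  set.seed(seed)
  a <- array(rnorm(n * n * 2), c(n, n, 2L))
  fw <- mrdenoise:::blindspot_forward(model$params, a, model$config)
  worst <- 0
  for (i in seq_len(n)) for (j in seq_len(n)) for (ch in 1:2) {
    ap <- a; ap[i, j, ch] <- ap[i, j, ch] + 1
    fp <- mrdenoise:::blindspot_forward(model$params, ap, model$config)
    worst <- max(worst,
                 abs(fp$mu[i, j, ] - fw$mu[i, j, ]) /
                   (1 + abs(fw$mu[i, j, ])),
                 abs(fp$var[i, j, ] - fw$var[i, j, ]) /
                   (1 + abs(fw$var[i, j, ])))
  }
  worst
}

# underflow-safe numerical posterior mean of the 1-D conjugate model
numeric_posterior_mean <- function(mu, v, y, sg) {
  s2 <- v + sg^2
  cf_guess <- (mu * sg^2 + y * v) / s2
  w <- function(x) exp(-(y - x)^2 / (2 * sg^2) - (x - mu)^2 / (2 * v) +
                         (y - mu)^2 / (2 * s2))
  hw <- 12 * sqrt(v * sg^2 / s2) + 1e-8
  stats::integrate(function(x) x * w(x), cf_guess - hw, cf_guess + hw,
                   rel.tol = 1e-12)$value /
    stats::integrate(w, cf_guess - hw, cf_guess + hw, rel.tol = 1e-12)$value
}
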