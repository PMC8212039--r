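# Blindspot network: one shared "half-plane" convolution stack applied to the
# four 90-degree rotations of the input. Every convolution in the stack is
# vertically shifted so that an output pixel depends only on input rows
# strictly above it; after counter-rotation the four branches see the four
# half-planes (above / left / below / right), whose union is the whole image
# minus the centre pixel. The branches are fused by 1x1 convolutions (no
# spatial mixing), so the receptive field of the mu / variance heads excludes
# the centre pixel by construction.

# "causal" convolution: output row i depends on input rows i-(k-1) .. i,
# i.e. the kernel is shifted so it never looks below its own row. A stack of
# these has receptive-field rows i-L*(k-1) .. i; one final 1-pixel downward
# shift (shift_down) then excludes row i itself while keeping row i-1.
hp_conv_fwd <- function(x, w, b, k, want_cache = TRUE) {
  pad <- (k - 1L) %/% 2L
  conv_fwd(x, w, b, c(k - 1L, 0L, pad, pad), want_cache)
}

hp_conv_bwd <- function(s, dy) conv_bwd(s, dy)

shift_down_fwd <- function(x) {
  d <- dim(x)
  y <- array(0, dim = d)
  y[2:d[1L], , ] <- x[seq_len(d[1L] - 1L), , , drop = FALSE]
  y
}

shift_down_bwd <- function(dy) {
  d <- dim(dy)
  dx <- array(0, dim = d)
  dx[seq_len(d[1L] - 1L), , ] <- dy[2:d[1L], , , drop = FALSE]
  dx
}

blindspot_forward <- function(p, x, cfg, want_cache = FALSE) {
  d <- dim(x)
  if (d[1L] != d[2L])
    stop("blindspot network expects square input; use zero_pad_square()",
         call. = FALSE)
  k <- cfg$kernel_size
  nf <- cfg$base_features
  branches <- vector("list", 4L)
  bcache <- if (want_cache) vector("list", 4L) else NULL
  for (r in 0:3) {
    h <- rot90_arr(x, r)
    layers <- if (want_cache) vector("list", cfg$depth) else NULL
    for (i in seq_len(cfg$depth)) {
      cf <- hp_conv_fwd(h, p[[sprintf("br%d_w", i)]],
                        p[[sprintf("br%d_b", i)]], k, want_cache)
      af <- lrelu_fwd(cf$y)
      h <- af$y
      if (want_cache) layers[[i]] <- list(conv = cf$cache, act = af$cache)
    }
    h <- shift_down_fwd(h)  # exclude the centre row
    branches[[r + 1L]] <- rot90_arr(h, 4L - r)
    if (want_cache) bcache[[r + 1L]] <- layers
  }
  feat <- array(unlist(branches, use.names = FALSE),
                dim = c(d[1L], d[2L], 4L * nf))
  f1 <- conv_fwd(feat, p$f1_w, p$f1_b, c(0L, 0L, 0L, 0L), want_cache)
  a1 <- lrelu_fwd(f1$y)
  f2 <- conv_fwd(a1$y, p$f2_w, p$f2_b, c(0L, 0L, 0L, 0L), want_cache)
  out <- f2$y
  mu <- out[, , 1:2, drop = FALSE]
  sv <- out[, , 3:4, drop = FALSE]
  var <- softplus(sv) + cfg$var_floor
  res <- list(mu = mu, var = var)
  if (want_cache)
    res$cache <- list(branches = bcache, f1 = f1$cache, a1 = a1$cache,
                      f2 = f2$cache, sv = sv, nf = nf)
  res
}

blindspot_backward <- function(p, cache, dmu, dvar, cfg) {
  g <- list()
  take <- function(nm, r) {
    wn <- paste0(nm, "_w"); bn <- paste0(nm, "_b")
    if (is.null(g[[wn]])) {
      g[[wn]] <<- r$dw; g[[bn]] <<- r$db
    } else {
      g[[wn]] <<- g[[wn]] + r$dw; g[[bn]] <<- g[[bn]] + r$db
    }
  }
  dsv <- dvar * sigmoid(cache$sv)
  dout <- concat_ch(dmu, dsv)
  r2 <- conv_bwd(cache$f2, dout); take("f2", r2)
  dpre <- lrelu_bwd(cache$a1, r2$dx)
  r1 <- conv_bwd(cache$f1, dpre); take("f1", r1)
  dfeat <- r1$dx
  nf <- cache$nf
  for (r in 0:3) {
    dback <- dfeat[, , (r * nf + 1L):((r + 1L) * nf), drop = FALSE]
    dh <- rot90_arr(dback, r)  # inverse of the forward counter-rotation
    dh <- shift_down_bwd(dh)
    layers <- cache$branches[[r + 1L]]
    for (i in rev(seq_len(cfg$depth))) {
      dh <- lrelu_bwd(layers[[i]]$act, dh)
      rr <- hp_conv_bwd(layers[[i]]$conv, dh)
      take(sprintf("br%d", i), rr)
      dh <- rr$dx
    }
  }
  g
}

blindspot_init_params <- function(cfg) {
  k <- cfg$kernel_size
  nf <- cfg$base_features
  p <- list()
  cin <- 2L
  for (i in seq_len(cfg$depth)) {
    l <- init_conv(k, k, cin, nf)
    p[[sprintf("br%d_w", i)]] <- l$w
    p[[sprintf("br%d_b", i)]] <- l$b
    cin <- nf
  }
  l1 <- init_conv(1L, 1L, 4L * nf, 2L * nf)
  p$f1_w <- l1$w; p$f1_b <- l1$b
  # zero-initialised head: the fresh prior is mu = 0; the variance bias
  # starts at the natural scale sigma^2 so the softplus map (whose gradient
  # is multiplicative in this regime) can calibrate it within a short
  # schedule
  l2 <- init_conv(1L, 1L, 2L * nf, 4L, zero = TRUE)
  p$f2_w <- l2$w; p$f2_b <- l2$b
  v0 <- max(cfg$sigma^2, 1e-6)
  p$f2_b[3:4] <- if (v0 > 30) v0 else log(expm1(v0))
  p
}
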