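# U-Net used by the SURE denoiser: `depth` levels of 2x downsampling with
# feature doubling, LeakyReLU after every convolution except the final one,
# skip connections by channel concatenation, max-pool down / nearest-upsample
# up. The network is parameterised residually: the output is the input plus
# the final convolution's result, with that convolution zero-initialised, so
# an untrained model is exactly the identity map (whose SURE risk equals the
# noisy risk K*sigma^2) and training can only improve on it.

unet_channels <- function(cfg) {
  cfg$base_features * 2L^(seq_len(cfg$depth) - 1L)
}

unet_init_params <- function(cfg) {
  k <- cfg$kernel_size
  ch <- unet_channels(cfg)
  d <- cfg$depth
  p <- list()
  put <- function(nm, cin, cout, zero = FALSE) {
    l <- init_conv(k, k, cin, cout, zero = zero)
    p[[paste0(nm, "_w")]] <<- l$w
    p[[paste0(nm, "_b")]] <<- l$b
  }
  cin <- 2L
  for (l in seq_len(d)) {
    put(sprintf("d%d_c1", l), cin, ch[l])
    put(sprintf("d%d_c2", l), ch[l], ch[l])
    cin <- ch[l]
  }
  put("b_c1", ch[d], 2L * ch[d])
  put("b_c2", 2L * ch[d], 2L * ch[d])
  for (l in rev(seq_len(d))) {
    put(sprintf("u%d_c0", l), 2L * ch[l], ch[l])
    put(sprintf("u%d_c1", l), 2L * ch[l], ch[l])
    put(sprintf("u%d_c2", l), ch[l], ch[l])
  }
  put("out", ch[1L], 2L, zero = TRUE)
  p
}

unet_forward <- function(p, x, cfg, want_cache = FALSE) {
  d <- cfg$depth
  k <- cfg$kernel_size
  pads <- rep((k - 1L) %/% 2L, 4L)
  H0 <- dim(x)[1L]; W0 <- dim(x)[2L]
  pm <- pad_to_multiple(x, 2L^d)
  h <- pm$y
  cc <- if (want_cache) list(H0 = H0, W0 = W0, enc = vector("list", d),
                             dec = vector("list", d)) else NULL
  conv_act <- function(h, nm) {
    cf <- conv_fwd(h, p[[paste0(nm, "_w")]], p[[paste0(nm, "_b")]], pads,
                   want_cache)
    af <- lrelu_fwd(cf$y)
    list(y = af$y, conv = cf$cache, act = af$cache)
  }
  skips <- vector("list", d)
  for (l in seq_len(d)) {
    s1 <- conv_act(h, sprintf("d%d_c1", l))
    s2 <- conv_act(s1$y, sprintf("d%d_c2", l))
    skips[[l]] <- s2$y
    mp <- maxpool_fwd(s2$y)
    h <- mp$y
    if (want_cache) cc$enc[[l]] <- list(c1 = s1, c2 = s2, pool = mp$cache)
  }
  b1 <- conv_act(h, "b_c1")
  b2 <- conv_act(b1$y, "b_c2")
  h <- b2$y
  if (want_cache) cc$bot <- list(c1 = b1, c2 = b2)
  for (l in rev(seq_len(d))) {
    h <- upsample2_fwd(h)
    s0 <- conv_act(h, sprintf("u%d_c0", l))
    hcat <- concat_ch(s0$y, skips[[l]])
    s1 <- conv_act(hcat, sprintf("u%d_c1", l))
    s2 <- conv_act(s1$y, sprintf("u%d_c2", l))
    h <- s2$y
    if (want_cache)
      cc$dec[[l]] <- list(c0 = s0, c1 = s1, c2 = s2,
                          ncat = dim(s0$y)[3L])
  }
  oc <- conv_fwd(h, p$out_w, p$out_b, pads, want_cache)
  y <- pm$y + oc$y                       # residual connection
  y <- y[seq_len(H0), seq_len(W0), , drop = FALSE]
  if (want_cache) {
    cc$out <- oc$cache
    cc$pdim <- dim(pm$y)
    list(y = y, cache = cc)
  } else {
    list(y = y)
  }
}

# parameter gradients of a scalar loss given d(loss)/d(output)
unet_backward <- function(p, cache, dout, cfg) {
  d <- cfg$depth
  g <- list()
  take <- function(nm, r) {
    wn <- paste0(nm, "_w"); bn <- paste0(nm, "_b")
    if (is.null(g[[wn]])) {
      g[[wn]] <<- r$dw; g[[bn]] <<- r$db
    } else {
      g[[wn]] <<- g[[wn]] + r$dw; g[[bn]] <<- g[[bn]] + r$db
    }
  }
  bwd_conv_act <- function(s, nm, dh) {
    dpre <- lrelu_bwd(s$act, dh)
    r <- conv_bwd(s$conv, dpre)
    take(nm, r)
    r$dx
  }
  dh <- array(0, dim = cache$pdim)
  dh[seq_len(cache$H0), seq_len(cache$W0), ] <- dout
  r <- conv_bwd(cache$out, dh)           # residual path only affects dx
  take("out", r)
  dh <- r$dx
  dskips <- vector("list", d)
  for (l in seq_len(d)) {                # reverse of the up path (l = 1..d)
    sc <- cache$dec[[l]]
    dh <- bwd_conv_act(sc$c2, sprintf("u%d_c2", l), dh)
    dh <- bwd_conv_act(sc$c1, sprintf("u%d_c1", l), dh)
    nc <- sc$ncat
    dskips[[l]] <- dh[, , (nc + 1L):(2L * nc), drop = FALSE]
    dh <- dh[, , seq_len(nc), drop = FALSE]
    dh <- bwd_conv_act(sc$c0, sprintf("u%d_c0", l), dh)
    dh <- upsample2_bwd(dh)
  }
  dh <- bwd_conv_act(cache$bot$c2, "b_c2", dh)
  dh <- bwd_conv_act(cache$bot$c1, "b_c1", dh)
  for (l in rev(seq_len(d))) {           # reverse of the down path
    sc <- cache$enc[[l]]
    dh <- maxpool_bwd(sc$pool, dh)
    dh <- dh + dskips[[l]]
    dh <- bwd_conv_act(sc$c2, sprintf("d%d_c2", l), dh)
    dh <- bwd_conv_act(sc$c1, sprintf("d%d_c1", l), dh)
  }
  g
}
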