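# Primitive differentiable ops used by the U-Net and the blindspot network.
# Tensors are H x W x C arrays; parameters live in flat named lists with
# entries <name>_w (kh x kw x Cin x Cout) and <name>_b (Cout). Every op has a
# forward returning (y, cache) and a backward mapping dy -> (dx, dparams).

conv_fwd <- function(x, w, b, pads, want_cache = TRUE) {
  out <- cpp_conv_fwd(x, w, b, pads[1L], pads[2L], pads[3L], pads[4L],
                      want_cache)
  if (want_cache) {
    list(y = out$y, cache = list(col = out$col, w = w,
                                 H = dim(x)[1L], W = dim(x)[2L], pads = pads))
  } else {
    list(y = out$y)
  }
}

conv_bwd <- function(cache, dy, want_dx = TRUE) {
  p <- cache$pads
  r <- cpp_conv_bwd(cache$col, cache$w, dy, cache$H, cache$W,
                    p[1L], p[2L], p[3L], p[4L], want_dx)
  r$db <- as.vector(r$db)
  r
}

lrelu_fwd <- function(x, slope = 0.1) {
  pos <- x > 0
  list(y = x * ifelse(pos, 1, slope), cache = list(pos = pos, slope = slope))
}

lrelu_bwd <- function(cache, dy) {
  dy * ifelse(cache$pos, 1, cache$slope)
}

maxpool_fwd <- function(x) {
  out <- cpp_maxpool2(x)
  list(y = out$y, cache = list(idx = out$idx))
}

maxpool_bwd <- function(cache, dy) cpp_maxpool2_bwd(dy, cache$idx)

upsample2_fwd <- function(x) {
  d <- dim(x)
  x[rep(seq_len(d[1L]), each = 2L), rep(seq_len(d[2L]), each = 2L), ,
    drop = FALSE]
}

upsample2_bwd <- function(dy) {
  d <- dim(dy)
  io <- seq(1L, d[1L], by = 2L); jo <- seq(1L, d[2L], by = 2L)
  dy[io, jo, , drop = FALSE] + dy[io + 1L, jo, , drop = FALSE] +
    dy[io, jo + 1L, , drop = FALSE] + dy[io + 1L, jo + 1L, , drop = FALSE]
}

concat_ch <- function(a, b) {
  da <- dim(a); db <- dim(b)
  array(c(a, b), dim = c(da[1L], da[2L], da[3L] + db[3L]))
}

# counter-clockwise rotation by k * 90 degrees of an H x W x C array;
# inverse of rot90_arr(., k) is rot90_arr(., 4 - k)
rot90_arr <- function(a, k) {
  k <- ((k %% 4L) + 4L) %% 4L
  if (k == 0L) return(a)
  for (i in seq_len(k)) {
    a <- aperm(a, c(2L, 1L, 3L))
    a <- a[dim(a)[1L]:1L, , , drop = FALSE]
  }
  a
}

# reflect-pad bottom/right so spatial dims become multiples of m
pad_to_multiple <- function(x, m) {
  d <- dim(x)
  pb <- (m - d[1L] %% m) %% m
  pr <- (m - d[2L] %% m) %% m
  if (pb > 0L) {
    idx <- c(seq_len(d[1L]), d[1L] - seq_len(pb))
    x <- x[idx, , , drop = FALSE]
  }
  if (pr > 0L) {
    idx <- c(seq_len(d[2L]), d[2L] - seq_len(pr))
    x <- x[, idx, , drop = FALSE]
  }
  list(y = x, pb = pb, pr = pr)
}

softplus <- function(x) ifelse(x > 30, x, log1p(exp(pmin(x, 30))))
sigmoid <- function(x) 1 / (1 + exp(-x))

# He-style initialisation for one conv layer
init_conv <- function(kh, kw, cin, cout, gain = sqrt(2), zero = FALSE) {
  w <- if (zero) array(0, dim = c(kh, kw, cin, cout))
  else array(rnorm(kh * kw * cin * cout, 0, gain / sqrt(kh * kw * cin)),
             dim = c(kh, kw, cin, cout))
  b <- numeric(cout)
  list(w = w, b = b)
}

adam_init <- function(params) {
  zero_like <- lapply(params, function(p) {
    z <- p; z[] <- 0; z
  })
  list(m = zero_like, v = zero_like, t = 0L)
}

adam_step <- function(params, grads, state, lr,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (nm in names(params)) {
    g <- grads[[nm]]
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g * g
    params[[nm]] <- params[[nm]] -
      lr * (state$m[[nm]] / bc1) / (sqrt(state$v[[nm]] / bc2) + eps)
  }
  list(params = params, state = state)
}

# sum two flat grad lists (shared weights applied several times)
add_grads <- function(a, b) {
  if (is.null(a)) return(b)
  for (nm in names(b)) a[[nm]] <- a[[nm]] + b[[nm]]
  a
}

scale_grads <- function(g, f) lapply(g, function(x) x * f)
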