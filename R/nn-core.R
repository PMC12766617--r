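# Minimal neural-network primitives (forward + hand-derived backward passes)
# used by the tensor de-noising generator and the patch critic. Feature maps
# are numeric arrays (H, W, C); token/pixel matrices are (N, C) with R's
# column-major pixel order. All backward passes are validated against
# finite differences in the test suite.

.nn_idx_cache <- new.env(parent = emptyenv())

# im2col gather indices for a k x k convolution at the given stride/padding.
# idx[patch, col] indexes the zero-padded (Hp, Wp, Cin) block as one vector,
# covering all kernel offsets of all input channels.
conv_indices <- function(H, W, k, stride, pad, Cin) {
  key <- paste(H, W, k, stride, pad, Cin, sep = "_")
  hit <- .nn_idx_cache[[key]]
  if (!is.null(hit)) return(hit)
  Hp <- H + 2 * pad; Wp <- W + 2 * pad
  Ho <- (Hp - k) %/% stride + 1
  Wo <- (Wp - k) %/% stride + 1
  r0 <- rep((seq_len(Ho) - 1) * stride + 1, times = Wo)
  c0 <- rep((seq_len(Wo) - 1) * stride + 1, each = Ho)
  offs <- as.matrix(expand.grid(dr = 0:(k - 1), dc = 0:(k - 1)))
  k2 <- k * k
  idx <- matrix(0L, Ho * Wo, k2 * Cin)
  plane <- Hp * Wp
  for (c in seq_len(Cin)) for (j in seq_len(k2)) {
    idx[, (c - 1) * k2 + j] <-
      (r0 + offs[j, 1]) + (c0 + offs[j, 2] - 1) * Hp + (c - 1) * plane
  }
  out <- list(idx = idx, Hp = Hp, Wp = Wp, Ho = Ho, Wo = Wo, k = k,
              stride = stride, pad = pad, Cin = Cin)
  .nn_idx_cache[[key]] <- out
  out
}

# column-wise bias add without sweep's aperm overhead
addb <- function(m, b) m + rep(b, each = nrow(m))

pad_array <- function(x, pad) {
  if (pad == 0) return(x)
  d <- dim(x)
  out <- array(0, c(d[1] + 2 * pad, d[2] + 2 * pad, d[3]))
  out[pad + seq_len(d[1]), pad + seq_len(d[2]), ] <- x
  out
}

# x: (H, W, Cin); W_mat: (k*k*Cin, Cout); returns y (Ho, Wo, Cout) + cache
conv2d_fwd <- function(x, W_mat, b, k, stride = 1, pad = (k - 1) %/% 2) {
  d <- dim(x); H <- d[1]; Wd <- d[2]; Cin <- d[3]
  ci <- conv_indices(H, Wd, k, stride, pad, Cin)
  xp <- pad_array(x, pad)
  col <- im2col_cpp(as.vector(xp), ci$idx)
  y <- addb(col %*% W_mat, b)
  list(y = array(y, c(ci$Ho, ci$Wo, ncol(W_mat))),
       cache = list(col = col, ci = ci, dimx = d))
}

conv2d_bwd <- function(dout, cache, W_mat) {
  ci <- cache$ci; d <- cache$dimx
  Cin <- d[3]
  doutm <- matrix(dout, nrow(cache$col), ncol(W_mat))
  dW <- crossprod(cache$col, doutm)
  db <- colSums(doutm)
  dcol <- tcrossprod(doutm, W_mat)
  dxp <- array(col2im_cpp(dcol, ci$idx, ci$Hp * ci$Wp * Cin),
               c(ci$Hp, ci$Wp, Cin))
  dx <- if (ci$pad > 0)
    dxp[ci$pad + seq_len(d[1]), ci$pad + seq_len(d[2]), , drop = FALSE]
  else dxp
  list(dx = array(dx, d), dW = dW, db = db)
}

# 2 x 2 stride-2 transposed convolution (exact 2x upsampling, non-overlapping)
# W: array (4, Cin, Cout), offsets ordered (dr, dc) in (0,0),(1,0),(0,1),(1,1)
convT2_fwd <- function(x, W, b) {
  d <- dim(x); H <- d[1]; Wd <- d[2]; Cin <- d[3]; Cout <- dim(W)[3]
  xm <- matrix(x, H * Wd, Cin)
  y <- array(0, c(2 * H, 2 * Wd, Cout))
  offs <- list(c(0, 0), c(1, 0), c(0, 1), c(1, 1))
  for (o in 1:4) {
    yo <- addb(xm %*% matrix(W[o, , ], Cin, Cout), b / 4)
    y[seq(1 + offs[[o]][1], 2 * H, 2), seq(1 + offs[[o]][2], 2 * Wd, 2), ] <-
      array(yo, c(H, Wd, Cout))
  }
  list(y = y, cache = list(xm = xm, dimx = d))
}

convT2_bwd <- function(dout, cache, W) {
  d <- cache$dimx; H <- d[1]; Wd <- d[2]; Cin <- d[3]; Cout <- dim(W)[3]
  offs <- list(c(0, 0), c(1, 0), c(0, 1), c(1, 1))
  dW <- array(0, dim(W)); db <- numeric(Cout)
  dxm <- matrix(0, H * Wd, Cin)
  for (o in 1:4) {
    dyo <- matrix(dout[seq(1 + offs[[o]][1], 2 * H, 2),
                       seq(1 + offs[[o]][2], 2 * Wd, 2), ], H * Wd, Cout)
    dW[o, , ] <- crossprod(cache$xm, dyo)
    db <- db + colSums(dyo) / 4
    dxm <- dxm + tcrossprod(dyo, matrix(W[o, , ], Cin, Cout))
  }
  list(dx = array(dxm, d), dW = dW, db = db)
}

# channel layer normalization on an (N, C) matrix
layernorm_fwd <- function(xm, g, b, eps = 1e-6) {
  mu <- rowMeans(xm)
  xc <- xm - mu
  v <- rowMeans(xc^2)
  inv <- 1 / sqrt(v + eps)
  xhat <- xc * inv
  y <- addb(xhat * rep(g, each = nrow(xhat)), b)
  list(y = y, cache = list(xhat = xhat, inv = inv, g = g))
}

layernorm_bwd <- function(dout, cache) {
  xhat <- cache$xhat; inv <- cache$inv
  dg <- colSums(dout * xhat)
  db <- colSums(dout)
  dxhat <- dout * rep(cache$g, each = nrow(dout))
  dx <- inv * (dxhat - rowMeans(dxhat) - xhat * rowMeans(dxhat * xhat))
  list(dx = dx, dg = dg, db = db)
}

# sigmoid-form GELU (x * sigmoid(1.702 x)), the cheap standard approximation
gelu_fwd <- function(x) {
  s <- 1 / (1 + exp(-1.702 * x))
  list(y = x * s, cache = list(x = x, s = s))
}

gelu_bwd <- function(dout, cache) {
  s <- cache$s
  dout * (s + 1.702 * cache$x * s * (1 - s))
}

lrelu_fwd <- function(x, slope = 0.2) {
  y <- ifelse(x >= 0, x, slope * x)
  list(y = y, cache = list(neg = x < 0, slope = slope))
}

lrelu_bwd <- function(dout, cache) {
  dout * ifelse(cache$neg, cache$slope, 1)
}

# token rows of each non-overlapping w x w window; I[t, win] indexes (N, C)
win_indices <- function(H, W, w) {
  key <- paste("win", H, W, w, sep = "_")
  hit <- .nn_idx_cache[[key]]
  if (!is.null(hit)) return(hit)
  stop_if_not(H %% w == 0 && W %% w == 0,
              sprintf("window size %d does not divide the %d x %d feature map", w, H, W))
  nwr <- H %/% w; nwc <- W %/% w
  I <- matrix(0L, w * w, nwr * nwc)
  win <- 0L
  for (wc in seq_len(nwc)) for (wr in seq_len(nwr)) {
    win <- win + 1L
    rows <- (wr - 1) * w + seq_len(w)
    cols <- (wc - 1) * w + seq_len(w)
    I[, win] <- as.integer(outer(rows, (cols - 1) * H, `+`))
  }
  .nn_idx_cache[[key]] <- I
  I
}

# windowed multi-head self-attention on an (N, C) matrix
wmsa_fwd <- function(xm, p, prefix, H, W, wsize, heads) {
  C <- ncol(xm)
  dh <- C %/% heads
  I <- win_indices(H, W, wsize)
  qkv <- addb(xm %*% p[[paste0(prefix, ".qkv.W")]], p[[paste0(prefix, ".qkv.b")]])
  T <- nrow(I)
  scl <- 1 / sqrt(dh)
  qkv_w <- qkv[as.vector(I), , drop = FALSE]   # contiguous T-row window blocks
  at <- attn_fwd_cpp(qkv_w, T, heads, scl)
  om <- matrix(0, nrow(xm), C)
  om[as.vector(I), ] <- at$om
  y <- addb(om %*% p[[paste0(prefix, ".proj.W")]], p[[paste0(prefix, ".proj.b")]])
  list(y = y, cache = list(xm = xm, qkv_w = qkv_w, om = om, P = at$P,
                           I = I, heads = heads, dh = dh, scl = scl))
}

wmsa_bwd <- function(dout, cache, p, prefix, grads) {
  C <- ncol(cache$xm)
  dh <- cache$dh; heads <- cache$heads; I <- cache$I; scl <- cache$scl
  Wp <- p[[paste0(prefix, ".proj.W")]]
  grads[[paste0(prefix, ".proj.W")]] <- crossprod(cache$om, dout)
  grads[[paste0(prefix, ".proj.b")]] <- colSums(dout)
  dom <- tcrossprod(dout, Wp)
  T <- nrow(I)
  dom_w <- dom[as.vector(I), , drop = FALSE]
  dqkv_w <- attn_bwd_cpp(dom_w, cache$qkv_w, cache$P, T, heads, scl)
  dqkv <- matrix(0, nrow(cache$xm), 3 * C)
  dqkv[as.vector(I), ] <- dqkv_w
  Wqkv <- p[[paste0(prefix, ".qkv.W")]]
  grads[[paste0(prefix, ".qkv.W")]] <- crossprod(cache$xm, dqkv)
  grads[[paste0(prefix, ".qkv.b")]] <- colSums(dqkv)
  list(dx = tcrossprod(dqkv, Wqkv), grads = grads)
}

# one windowed-attention transformer block: x + MSA(LN(x)), then x + MLP(LN(x))
lewin_fwd <- function(xm, p, prefix, H, W, wsize, heads) {
  ln1 <- layernorm_fwd(xm, p[[paste0(prefix, ".ln1.g")]], p[[paste0(prefix, ".ln1.b")]])
  att <- wmsa_fwd(ln1$y, p, prefix, H, W, wsize, heads)
  x1 <- xm + att$y
  ln2 <- layernorm_fwd(x1, p[[paste0(prefix, ".ln2.g")]], p[[paste0(prefix, ".ln2.b")]])
  h1 <- addb(ln2$y %*% p[[paste0(prefix, ".fc1.W")]], p[[paste0(prefix, ".fc1.b")]])
  ge <- gelu_fwd(h1)
  h2 <- addb(ge$y %*% p[[paste0(prefix, ".fc2.W")]], p[[paste0(prefix, ".fc2.b")]])
  list(y = x1 + h2,
       cache = list(ln1 = ln1$cache, att = att$cache, ln2 = ln2$cache,
                    ge = ge$cache, ln1y = ln1$y, ln2y = ln2$y, gey = ge$y))
}

lewin_bwd <- function(dout, cache, p, prefix, grads) {
  grads[[paste0(prefix, ".fc2.W")]] <- crossprod(cache$gey, dout)
  grads[[paste0(prefix, ".fc2.b")]] <- colSums(dout)
  dge <- tcrossprod(dout, p[[paste0(prefix, ".fc2.W")]])
  dh1 <- gelu_bwd(dge, cache$ge)
  grads[[paste0(prefix, ".fc1.W")]] <- crossprod(cache$ln2y, dh1)
  grads[[paste0(prefix, ".fc1.b")]] <- colSums(dh1)
  dln2y <- tcrossprod(dh1, p[[paste0(prefix, ".fc1.W")]])
  l2 <- layernorm_bwd(dln2y, cache$ln2)
  grads[[paste0(prefix, ".ln2.g")]] <- l2$dg
  grads[[paste0(prefix, ".ln2.b")]] <- l2$db
  dx1 <- dout + l2$dx
  aw <- wmsa_bwd(dx1, cache$att, p, prefix, grads)
  grads <- aw$grads
  l1 <- layernorm_bwd(aw$dx, cache$ln1)
  grads[[paste0(prefix, ".ln1.g")]] <- l1$dg
  grads[[paste0(prefix, ".ln1.b")]] <- l1$db
  list(dx = dx1 + l1$dx, grads = grads)
}

# parameter initializers -------------------------------------------------

init_conv <- function(k, cin, cout, zero = FALSE) {
  if (zero) return(matrix(0, k * k * cin, cout))
  matrix(stats::rnorm(k * k * cin * cout, 0, sqrt(2 / (k * k * cin))),
         k * k * cin, cout)
}

init_linear <- function(cin, cout) {
  matrix(stats::rnorm(cin * cout, 0, sqrt(1 / cin)), cin, cout)
}

init_lewin <- function(p, prefix, C, mlp_ratio) {
  p[[paste0(prefix, ".ln1.g")]] <- rep(1, C)
  p[[paste0(prefix, ".ln1.b")]] <- rep(0, C)
  p[[paste0(prefix, ".qkv.W")]] <- init_linear(C, 3 * C)
  p[[paste0(prefix, ".qkv.b")]] <- rep(0, 3 * C)
  p[[paste0(prefix, ".proj.W")]] <- init_linear(C, C)
  p[[paste0(prefix, ".proj.b")]] <- rep(0, C)
  p[[paste0(prefix, ".ln2.g")]] <- rep(1, C)
  p[[paste0(prefix, ".ln2.b")]] <- rep(0, C)
  hid <- mlp_ratio * C
  p[[paste0(prefix, ".fc1.W")]] <- init_linear(C, hid)
  p[[paste0(prefix, ".fc1.b")]] <- rep(0, hid)
  p[[paste0(prefix, ".fc2.W")]] <- init_linear(hid, C)
  p[[paste0(prefix, ".fc2.b")]] <- rep(0, C)
  p
}

# AdamW (decoupled weight decay) ------------------------------------------

adam_init <- function(params) {
  list(m = lapply(params, function(x) x * 0),
       v = lapply(params, function(x) x * 0), t = 0)
}

adam_step <- function(params, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8, weight_decay = 0) {
  state$t <- state$t + 1
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (nm in names(params)) {
    g <- grads[[nm]]
    if (is.null(g)) next
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g^2
    upd <- (state$m[[nm]] / bc1) / (sqrt(state$v[[nm]] / bc2) + eps)
    if (weight_decay > 0) upd <- upd + weight_decay * params[[nm]]
    params[[nm]] <- params[[nm]] - lr * upd
  }
  list(params = params, state = state)
}
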