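# U-shaped windowed-attention generator for tensor-to-tensor de-noising.
#
# Layout (one down/up level; widths C and 2C):
#   in_conv 3x3 (6 -> C)
#   encoder: depths[1] windowed-attention blocks at full resolution, width C
#   down: 2x2 stride-2 conv (C -> 2C)
#   bottleneck: depths[2] blocks at half resolution, width 2C
#   up: 2x2 stride-2 transposed conv (2C -> C), skip concat, 1x1 fuse (2C -> C)
#   decoder: depths[3] blocks at full resolution, width C
#   out_conv 3x3 (C -> 6), zero-initialized
# With residual learning the output is a correction added to the input, so
# the untrained generator is exactly the identity.

#' Generator configuration
#'
#' @param base_width channel width C at full resolution (bottleneck runs 2C).
#' @param depths integer length-3: attention blocks in the encoder,
#'   bottleneck and decoder stages.
#' @param window attention window size in pixels (must divide the feature-map
#'   side at both resolutions).
#' @param heads attention heads (must divide the stage width).
#' @param mlp_ratio hidden expansion of the per-block MLP.
#' @param in_channels,out_channels tensor channels (6 in, 6 out).
#' @param residual add the network output to its input (identity at init).
#' @return Class \code{gen_config}.
#' @export
gen_config <- function(base_width = 12, depths = c(1, 1, 1), window = 8,
                       heads = 2, mlp_ratio = 2, in_channels = 6,
                       out_channels = 6, residual = TRUE) {
  stop_if_not(length(depths) == 3 && all(depths >= 1), "depths must be 3 positive counts")
  stop_if_not(base_width %% heads == 0 && (2 * base_width) %% heads == 0,
              "heads must divide the stage widths")
  structure(list(base_width = base_width, depths = as.integer(depths),
                 window = window, heads = heads, mlp_ratio = mlp_ratio,
                 in_channels = in_channels, out_channels = out_channels,
                 residual = isTRUE(residual)),
            class = "gen_config")
}

#' Generator presets
#'
#' \code{"tiny"} is the desk-scale preset (about 1.2e4 parameters, under the
#' 2e5 budget) used throughout the synthetic experiments; \code{"reference"}
#' mirrors the full-scale model class at roughly 4e7 parameters and is
#' provided as a configuration only.
#'
#' @param name \code{"tiny"} or \code{"reference"}.
#' @return A \code{gen_config}.
#' @export
gen_preset <- function(name = c("tiny", "reference")) {
  name <- match.arg(name)
  switch(name,
         tiny = gen_config(base_width = 12, depths = c(1, 1, 1), window = 8,
                           heads = 2, mlp_ratio = 2),
         reference = gen_config(base_width = 320, depths = c(6, 9, 6),
                                window = 8, heads = 8, mlp_ratio = 2))
}

# closed-form parameter count for a gen_config
lewin_param_count <- function(C, mlp_ratio) {
  4 * C +                       # two layer norms
    (C * 3 * C + 3 * C) +       # qkv
    (C * C + C) +               # projection
    (C * mlp_ratio * C + mlp_ratio * C) +
    (mlp_ratio * C * C + C)
}

#' Analytic generator parameter count
#'
#' Exact weight count of \code{\link{build_generator}} for a configuration,
#' computed without allocating the network.
#'
#' @param config a \code{gen_config}.
#' @return Integer-valued numeric.
#' @export
generator_param_count <- function(config) {
  C <- config$base_width
  n <- 9 * config$in_channels * C + C                        # in_conv
  n <- n + config$depths[1] * lewin_param_count(C, config$mlp_ratio)
  n <- n + 4 * C * 2 * C + 2 * C                             # down 2x2
  n <- n + config$depths[2] * lewin_param_count(2 * C, config$mlp_ratio)
  n <- n + 4 * 2 * C * C + C                                 # up convT 2x2
  n <- n + 2 * C * C + C                                     # fuse 1x1
  n <- n + config$depths[3] * lewin_param_count(C, config$mlp_ratio)
  n + 9 * C * config$out_channels + config$out_channels      # out_conv
}

#' Build (initialize) a generator
#'
#' Random initialization from the current RNG stream (seed it for
#' reproducibility); the final projection is zero-initialized so the
#' untrained residual generator is the identity map.
#'
#' @param config a \code{gen_config}.
#' @param seed optional seed for the initialization stream.
#' @return Class \code{generator}: flat named parameter list + config.
#' @export
build_generator <- function(config, seed = NULL) {
  stopifnot(inherits(config, "gen_config"))
  with_seed(seed, {
    C <- config$base_width
    p <- list()
    p[["in_conv.W"]] <- init_conv(3, config$in_channels, C)
    p[["in_conv.b"]] <- rep(0, C)
    for (i in seq_len(config$depths[1]))
      p <- init_lewin(p, sprintf("enc%d", i), C, config$mlp_ratio)
    p[["down.W"]] <- init_conv(2, C, 2 * C)
    p[["down.b"]] <- rep(0, 2 * C)
    for (i in seq_len(config$depths[2]))
      p <- init_lewin(p, sprintf("bot%d", i), 2 * C, config$mlp_ratio)
    p[["up.W"]] <- array(stats::rnorm(4 * 2 * C * C, 0, sqrt(1 / (2 * C))),
                         c(4, 2 * C, C))
    p[["up.b"]] <- rep(0, C)
    p[["fuse.W"]] <- init_conv(1, 2 * C, C)
    p[["fuse.b"]] <- rep(0, C)
    for (i in seq_len(config$depths[3]))
      p <- init_lewin(p, sprintf("dec%d", i), C, config$mlp_ratio)
    p[["out_conv.W"]] <- init_conv(3, C, config$out_channels, zero = TRUE)
    p[["out_conv.b"]] <- rep(0, config$out_channels)
    structure(list(params = p, config = config), class = "generator")
  })
}

#' Generator forward pass
#'
#' @param gen a \code{generator} (or its parameter list via \code{params}).
#' @param x input array (H, W, in_channels) in normalized tensor units.
#' @param params optional parameter list overriding \code{gen$params}.
#' @return List \code{y} (H, W, out_channels) and \code{cache} for backward.
#' @export
generator_forward <- function(gen, x, params = NULL) {
  cfg <- gen$config
  p <- params %||% gen$params
  d <- dim(x); H <- d[1]; W <- d[2]
  stop_if_not(d[3] == cfg$in_channels, "wrong input channel count")
  win_indices(H, W, cfg$window)          # errors early if indivisible
  win_indices(H / 2, W / 2, cfg$window)
  C <- cfg$base_width
  cache <- list(dimx = d)

  inc <- conv2d_fwd(x, p[["in_conv.W"]], p[["in_conv.b"]], 3)
  cache$inc <- inc$cache
  e <- matrix(inc$y, H * W, C)
  cache$enc <- vector("list", cfg$depths[1])
  for (i in seq_len(cfg$depths[1])) {
    blk <- lewin_fwd(e, p, sprintf("enc%d", i), H, W, cfg$window, cfg$heads)
    cache$enc[[i]] <- blk$cache
    e <- blk$y
  }
  dn <- conv2d_fwd(array(e, c(H, W, C)), p[["down.W"]], p[["down.b"]], 2,
                   stride = 2, pad = 0)
  cache$dn <- dn$cache
  bmat <- matrix(dn$y, (H / 2) * (W / 2), 2 * C)
  cache$bot <- vector("list", cfg$depths[2])
  for (i in seq_len(cfg$depths[2])) {
    blk <- lewin_fwd(bmat, p, sprintf("bot%d", i), H / 2, W / 2, cfg$window, cfg$heads)
    cache$bot[[i]] <- blk$cache
    bmat <- blk$y
  }
  up <- convT2_fwd(array(bmat, c(H / 2, W / 2, 2 * C)), p[["up.W"]], p[["up.b"]])
  cache$up <- up$cache
  skip <- array(0, c(H, W, 2 * C))
  skip[, , seq_len(C)] <- up$y
  skip[, , C + seq_len(C)] <- array(e, c(H, W, C))
  fu <- conv2d_fwd(skip, p[["fuse.W"]], p[["fuse.b"]], 1, pad = 0)
  cache$fu <- fu$cache
  dmat <- matrix(fu$y, H * W, C)
  cache$dec <- vector("list", cfg$depths[3])
  for (i in seq_len(cfg$depths[3])) {
    blk <- lewin_fwd(dmat, p, sprintf("dec%d", i), H, W, cfg$window, cfg$heads)
    cache$dec[[i]] <- blk$cache
    dmat <- blk$y
  }
  oc <- conv2d_fwd(array(dmat, c(H, W, C)), p[["out_conv.W"]], p[["out_conv.b"]], 3)
  cache$oc <- oc$cache
  y <- if (cfg$residual) x + oc$y else oc$y
  list(y = y, cache = cache)
}

#' Generator backward pass
#'
#' @param gen a \code{generator}.
#' @param cache forward cache.
#' @param dy upstream gradient (H, W, out_channels).
#' @param params optional parameter list.
#' @return List \code{grads} (named like the parameters) and \code{dx}.
#' @export
generator_backward <- function(gen, cache, dy, params = NULL) {
  cfg <- gen$config
  p <- params %||% gen$params
  d <- cache$dimx; H <- d[1]; W <- d[2]; C <- cfg$base_width
  grads <- list()

  bo <- conv2d_bwd(dy, cache$oc, p[["out_conv.W"]])
  grads[["out_conv.W"]] <- bo$dW; grads[["out_conv.b"]] <- bo$db
  dmat <- matrix(bo$dx, H * W, C)
  for (i in rev(seq_len(cfg$depths[3]))) {
    bb <- lewin_bwd(dmat, cache$dec[[i]], p, sprintf("dec%d", i), grads)
    grads <- bb$grads; dmat <- bb$dx
  }
  bf <- conv2d_bwd(array(dmat, c(H, W, C)), cache$fu, p[["fuse.W"]])
  grads[["fuse.W"]] <- bf$dW; grads[["fuse.b"]] <- bf$db
  dskip <- bf$dx
  dup <- dskip[, , seq_len(C), drop = FALSE]
  de_skip <- matrix(dskip[, , C + seq_len(C)], H * W, C)
  bu <- convT2_bwd(array(dup, c(H, W, C)), cache$up, p[["up.W"]])
  grads[["up.W"]] <- bu$dW; grads[["up.b"]] <- bu$db
  bmat <- matrix(bu$dx, (H / 2) * (W / 2), 2 * C)
  for (i in rev(seq_len(cfg$depths[2]))) {
    bb <- lewin_bwd(bmat, cache$bot[[i]], p, sprintf("bot%d", i), grads)
    grads <- bb$grads; bmat <- bb$dx
  }
  bd <- conv2d_bwd(array(bmat, c(H / 2, W / 2, 2 * C)), cache$dn, p[["down.W"]])
  grads[["down.W"]] <- bd$dW; grads[["down.b"]] <- bd$db
  emat <- matrix(bd$dx, H * W, C) + de_skip
  for (i in rev(seq_len(cfg$depths[1]))) {
    bb <- lewin_bwd(emat, cache$enc[[i]], p, sprintf("enc%d", i), grads)
    grads <- bb$grads; emat <- bb$dx
  }
  bi <- conv2d_bwd(array(emat, c(H, W, C)), cache$inc, p[["in_conv.W"]])
  grads[["in_conv.W"]] <- bi$dW; grads[["in_conv.b"]] <- bi$db
  dx <- bi$dx
  if (cfg$residual) dx <- dx + dy
  list(grads = grads, dx = dx)
}

#' Apply a generator to a normalized tensor grid
#'
#' @param gen a \code{generator}.
#' @param x (H, W, 6) normalized array.
#' @return (H, W, 6) de-noised normalized array.
#' @export
generator_predict <- function(gen, x) generator_forward(gen, x)$y
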