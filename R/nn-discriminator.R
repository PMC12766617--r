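# Patch critic: a small strided convolutional network emitting a spatial
# grid of unbounded realism scores, one per receptive patch (Wasserstein
# critic, no final squashing).

#' Patch-critic configuration
#'
#' Three 4x4 stride-2 leaky-ReLU convolution stages with doubling width,
#' followed by a 3x3 stride-1 projection to one score channel; a
#' 128 x 128 input yields a 16 x 16 score grid.
#'
#' @param base_width first-stage channel width.
#' @param in_channels input channels (6 tensor elements).
#' @param lrelu_slope negative slope of the leaky ReLU.
#' @return Class \code{disc_config}.
#' @export
disc_config <- function(base_width = 8, in_channels = 6, lrelu_slope = 0.2) {
  structure(list(base_width = base_width, in_channels = in_channels,
                 lrelu_slope = lrelu_slope),
            class = "disc_config")
}

#' Build (initialize) a patch critic
#'
#' @param config a \code{disc_config}.
#' @param seed optional initialization seed.
#' @return Class \code{discriminator}: flat parameter list + config.
#' @export
build_discriminator <- function(config = disc_config(), seed = NULL) {
  stopifnot(inherits(config, "disc_config"))
  with_seed(seed, {
    C <- config$base_width
    p <- list()
    p[["c1.W"]] <- init_conv(4, config$in_channels, C); p[["c1.b"]] <- rep(0, C)
    p[["c2.W"]] <- init_conv(4, C, 2 * C); p[["c2.b"]] <- rep(0, 2 * C)
    p[["c3.W"]] <- init_conv(4, 2 * C, 4 * C); p[["c3.b"]] <- rep(0, 4 * C)
    p[["out.W"]] <- init_conv(3, 4 * C, 1); p[["out.b"]] <- 0
    structure(list(params = p, config = config), class = "discriminator")
  })
}

#' Patch-critic forward pass
#'
#' @param disc a \code{discriminator}.
#' @param x input array (H, W, in_channels); H and W must be at least 8
#'   (one receptive field).
#' @param params optional parameter override.
#' @return List \code{y} (H/8, W/8, 1) score grid and \code{cache}.
#' @export
discriminator_forward <- function(disc, x, params = NULL) {
  cfg <- disc$config
  p <- params %||% disc$params
  d <- dim(x)
  stop_if_not(d[1] >= 8 && d[2] >= 8 && d[1] %% 8 == 0 && d[2] %% 8 == 0,
              "critic input smaller than one receptive field (needs multiples of 8, >= 8)")
  cache <- list()
  c1 <- conv2d_fwd(x, p[["c1.W"]], p[["c1.b"]], 4, stride = 2, pad = 1)
  a1 <- lrelu_fwd(c1$y, cfg$lrelu_slope)
  c2 <- conv2d_fwd(a1$y, p[["c2.W"]], p[["c2.b"]], 4, stride = 2, pad = 1)
  a2 <- lrelu_fwd(c2$y, cfg$lrelu_slope)
  c3 <- conv2d_fwd(a2$y, p[["c3.W"]], p[["c3.b"]], 4, stride = 2, pad = 1)
  a3 <- lrelu_fwd(c3$y, cfg$lrelu_slope)
  oc <- conv2d_fwd(a3$y, p[["out.W"]], p[["out.b"]], 3)
  list(y = oc$y,
       cache = list(c1 = c1$cache, a1 = a1$cache, c2 = c2$cache, a2 = a2$cache,
                    c3 = c3$cache, a3 = a3$cache, oc = oc$cache))
}

#' Patch-critic backward pass
#'
#' @param disc a \code{discriminator}.
#' @param cache forward cache.
#' @param dy upstream gradient on the score grid.
#' @param params optional parameter override.
#' @return List \code{grads} and \code{dx} (gradient w.r.t. the input).
#' @export
discriminator_backward <- function(disc, cache, dy, params = NULL) {
  p <- params %||% disc$params
  grads <- list()
  bo <- conv2d_bwd(dy, cache$oc, p[["out.W"]])
  grads[["out.W"]] <- bo$dW; grads[["out.b"]] <- bo$db
  d3 <- lrelu_bwd(bo$dx, cache$a3)
  b3 <- conv2d_bwd(d3, cache$c3, p[["c3.W"]])
  grads[["c3.W"]] <- b3$dW; grads[["c3.b"]] <- b3$db
  d2 <- lrelu_bwd(b3$dx, cache$a2)
  b2 <- conv2d_bwd(d2, cache$c2, p[["c2.W"]])
  grads[["c2.W"]] <- b2$dW; grads[["c2.b"]] <- b2$db
  d1 <- lrelu_bwd(b2$dx, cache$a1)
  b1 <- conv2d_bwd(d1, cache$c1, p[["c1.W"]])
  grads[["c1.W"]] <- b1$dW; grads[["c1.b"]] <- b1$db
  list(grads = grads, dx = b1$dx)
}

# mean critic score of one sample and the gradient of that mean w.r.t. input
critic_score_and_input_grad <- function(disc, x, params = NULL) {
  fw <- discriminator_forward(disc, x, params)
  np <- length(fw$y)
  dy <- array(1 / np, dim(fw$y))
  bw <- discriminator_backward(disc, fw$cache, dy, params)
  list(score = mean(fw$y), dx = bw$dx)
}
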