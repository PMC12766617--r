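# Forward simulation of STEAM diffusion-weighted magnitude images:
# acquisition protocols with the clinical repetition structure, Rician noise,
# breath-hold subset regimes and repetition averaging.

#' Fixed six-direction diffusion-encoding scheme
#'
#' The classic icosahedral-style pairwise scheme (normalized (1,1,0)
#' permutations), used for both b = 150 and b = 600 shells. Together with a
#' b = 0 image it spans tensor space (design matrix rank 7).
#'
#' @return 6 x 3 matrix of unit gradient directions.
#' @export
cdti_directions <- function() {
  g <- rbind(c(1, 1, 0), c(1, -1, 0),
             c(1, 0, 1), c(1, 0, -1),
             c(0, 1, 1), c(0, 1, -1))
  g / sqrt(2)
}

#' Breath-hold regime definitions
#'
#' Repetition counts (n_b0, n_b600, n_b150) for the full-acquisition
#' reference and the three reduced regimes: full = (12, 10, 2),
#' 5BH = (4, 4, 1), 3BH = (2, 2, 1), 1BH = (1, 1, 0).
#'
#' @param name one of \code{"full"}, \code{"5BH"}, \code{"3BH"}, \code{"1BH"}.
#' @return List with \code{name} and integer \code{reps} =
#'   (n_b0, n_b600, n_b150).
#' @export
breath_hold_regime <- function(name) {
  tab <- list(full = c(12L, 10L, 2L),
              `5BH` = c(4L, 4L, 1L),
              `3BH` = c(2L, 2L, 1L),
              `1BH` = c(1L, 1L, 0L))
  if (!name %in% names(tab))
    stop(sprintf("unknown breath-hold regime '%s' (use full, 5BH, 3BH or 1BH)", name),
         call. = FALSE)
  list(name = name, reps = stats::setNames(tab[[name]], c("n_b0", "n_b600", "n_b150")))
}

#' Acquisition protocol for a breath-hold regime
#'
#' One row per image to acquire: b-value (s/mm^2), gradient direction (zero
#' vector for b = 0), direction index (0 for b = 0) and repetition index.
#' Image count is n_b0 + 6 n_b600 + 6 n_b150.
#'
#' @param regime regime name or a list as returned by
#'   \code{\link{breath_hold_regime}}.
#' @param b_values diffusion weightings for (b0, high, low) shells.
#' @return Class \code{acq_protocol}: data frame \code{entries} and the
#'   \code{directions} matrix.
#' @export
make_protocol <- function(regime = "full", b_values = c(0, 600, 150)) {
  if (is.character(regime)) regime <- breath_hold_regime(regime)
  reps <- regime$reps
  dirs <- cdti_directions()
  rows <- list()
  add <- function(b, dir_index, g, n) {
    if (n == 0) return(invisible())
    rows[[length(rows) + 1]] <<- data.frame(
      b = b, dir_index = dir_index, gx = g[1], gy = g[2], gz = g[3],
      repetition = seq_len(n))
  }
  add(b_values[1], 0L, c(0, 0, 0), reps[["n_b0"]])
  for (k in 1:6) add(b_values[2], k, dirs[k, ], reps[["n_b600"]])
  if (reps[["n_b150"]] > 0)
    for (k in 1:6) add(b_values[3], k, dirs[k, ], reps[["n_b150"]])
  entries <- do.call(rbind, rows)
  rownames(entries) <- NULL
  structure(list(entries = entries, directions = dirs, regime = regime$name),
            class = "acq_protocol")
}

# quadratic form g^T D g per voxel for one direction, vectorized over voxels
gdg_rows <- function(d6, g) {
  d6[, 1] * g[1]^2 + d6[, 2] * g[2]^2 + d6[, 3] * g[3]^2 +
    2 * (d6[, 4] * g[1] * g[2] + d6[, 5] * g[1] * g[3] + d6[, 6] * g[2] * g[3])
}

#' Simulate a diffusion-weighted image series
#'
#' Noiseless magnitude signal \code{S = S0 exp(-b g^T D g)} per image, then
#' Rician noise \code{sqrt((S + n1)^2 + n2^2)} with n1, n2 ~ N(0, sigma^2).
#' Each image draws from its own counter-based substream of the master seed,
#' so an image's noise realization is a function of its (image index, seed)
#' identity alone and the series is bit-reproducible.
#'
#' @param tf ground-truth \code{tensor_field}.
#' @param s0_map non-negative b = 0 signal map (matrix).
#' @param protocol an \code{acq_protocol}.
#' @param noise_sigma Gaussian channel noise sigma (signal units, >= 0);
#'   b0-image SNR is \code{s0 / noise_sigma}.
#' @param seed master seed.
#' @return Class \code{dwi_series}: image stack (rows, cols, n_images),
#'   per-image \code{meta} data frame, \code{noise_sigma}, \code{seed}.
#' @export
simulate_dwi <- function(tf, s0_map, protocol, noise_sigma, seed = 1) {
  stopifnot(inherits(tf, "tensor_field"), inherits(protocol, "acq_protocol"))
  stop_if_not(all(s0_map >= 0), "s0_map must be non-negative")
  stop_if_not(noise_sigma >= 0, "noise_sigma must be non-negative")
  ent <- protocol$entries
  bad_dir <- ent$b > 0 & abs(ent$gx^2 + ent$gy^2 + ent$gz^2 - 1) > 1e-8
  stop_if_not(!any(bad_dir), "direction missing or non-unit for a b > 0 entry")
  gs <- dim(tf$d)[1:2]
  n_img <- nrow(ent)
  imgs <- array(0, c(gs, n_img))
  idx <- which(tf$mask | s0_map > 0)
  d6 <- tensor_rows(tf, idx)
  s0v <- s0_map[idx]
  nvox_img <- prod(gs)
  for (i in seq_len(n_img)) {
    sig <- matrix(0, gs[1], gs[2])
    if (ent$b[i] == 0) {
      sig[idx] <- s0v
    } else {
      g <- c(ent$gx[i], ent$gy[i], ent$gz[i])
      sig[idx] <- s0v * exp(-ent$b[i] * gdg_rows(d6, g))
    }
    if (noise_sigma > 0) {
      sub_seed <- (seed + 1000003 * i) %% 2147483647
      noisy <- with_seed(sub_seed, {
        n1 <- stats::rnorm(nvox_img, 0, noise_sigma)
        n2 <- stats::rnorm(nvox_img, 0, noise_sigma)
        sqrt((as.vector(sig) + n1)^2 + n2^2)
      })
      sig <- matrix(noisy, gs[1], gs[2])
    }
    imgs[, , i] <- sig
  }
  structure(list(images = imgs, meta = ent, noise_sigma = noise_sigma,
                 seed = seed), class = "dwi_series")
}

#' Select a repetition subset per (b, direction) group
#'
#' Emulates reduced-breath-hold datasets and the repetition-subset training
#' augmentation: for each (b-value, direction) group with R available
#' repetitions, keep the first n (\code{position = "first"}), the block
#' starting at \code{floor((R - n)/2)} (\code{"central"}) or the last n
#' (\code{"last"}). \code{n} may be a single count or a vector named by
#' b-value (e.g. \code{c("0" = 1, "600" = 1, "150" = 0)}); a count of 0 drops
#' the group.
#'
#' @param series a \code{dwi_series}.
#' @param n repetitions to keep (scalar or named by b-value).
#' @param position one of \code{"first"}, \code{"central"}, \code{"last"}.
#' @return A \code{dwi_series} with the selected images.
#' @export
select_repetition_subset <- function(series, n, position = c("first", "central", "last")) {
  stopifnot(inherits(series, "dwi_series"))
  position <- match.arg(position)
  ent <- series$meta
  key <- paste(ent$b, ent$dir_index)
  keep <- logical(nrow(ent))
  for (k in unique(key)) {
    rows <- which(key == k)
    b_k <- ent$b[rows[1]]
    n_k <- if (length(n) == 1 && is.null(names(n))) n
           else if (as.character(b_k) %in% names(n)) n[[as.character(b_k)]]
           else stop(sprintf("no repetition count given for b=%g", b_k), call. = FALSE)
    if (n_k == 0) next
    R <- length(rows)
    if (n_k > R)
      stop(sprintf("group b=%g dir=%d has %d repetitions, %d requested",
                   b_k, ent$dir_index[rows[1]], R, n_k), call. = FALSE)
    start <- switch(position, first = 0L, central = floor((R - n_k) / 2),
                    last = R - n_k)
    ord <- rows[order(ent$repetition[rows])]
    keep[ord[(start + 1):(start + n_k)]] <- TRUE
  }
  stop_if_not(any(keep), "subset selection removed every image")
  structure(list(images = series$images[, , keep, drop = FALSE],
                 meta = ent[keep, , drop = FALSE],
                 noise_sigma = series$noise_sigma, seed = series$seed),
            class = "dwi_series")
}

#' Subset a series to a breath-hold regime
#'
#' Maps a regime's (n_b0, n_b600, n_b150) counts onto
#' \code{\link{select_repetition_subset}}.
#'
#' @param series a full-acquisition \code{dwi_series}.
#' @param regime regime name or \code{breath_hold_regime} list.
#' @param position repetition block to keep.
#' @return A \code{dwi_series}.
#' @export
regime_subset <- function(series, regime, position = "first") {
  if (is.character(regime)) regime <- breath_hold_regime(regime)
  bs <- sort(unique(series$meta$b))
  stop_if_not(length(bs) >= 2, "series does not contain multiple b-values")
  n <- stats::setNames(c(regime$reps[["n_b0"]], regime$reps[["n_b150"]],
                         regime$reps[["n_b600"]])[match(bs, sort(c(0, 150, 600)))],
                       as.character(bs))
  select_repetition_subset(series, n, position)
}

#' Average repetitions per (b, direction) key
#'
#' Arithmetic mean of the repeated magnitude images for every (b-value,
#' direction) pair, ordered by ascending b then direction index.
#'
#' @param series a \code{dwi_series}.
#' @return Class \code{dwi_avg}: image stack (rows, cols, n_keys) and a
#'   \code{table} data frame (b, dir_index, gx, gy, gz, n_averaged).
#' @export
average_repetitions <- function(series) {
  stopifnot(inherits(series, "dwi_series"))
  ent <- series$meta
  stop_if_not(nrow(ent) > 0, "empty series")
  keys <- unique(ent[, c("b", "dir_index", "gx", "gy", "gz")])
  keys <- keys[order(keys$b, keys$dir_index), , drop = FALSE]
  gs <- dim(series$images)[1:2]
  out <- array(0, c(gs, nrow(keys)))
  n_avg <- integer(nrow(keys))
  for (i in seq_len(nrow(keys))) {
    sel <- ent$b == keys$b[i] & ent$dir_index == keys$dir_index[i]
    n_avg[i] <- sum(sel)
    out[, , i] <- rowMeans(series$images[, , sel, drop = FALSE], dims = 2)
  }
  keys$n_averaged <- n_avg
  rownames(keys) <- NULL
  structure(list(images = out, table = keys), class = "dwi_avg")
}
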