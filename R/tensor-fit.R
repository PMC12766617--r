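# Linear least-squares tensor estimation from averaged DWIs, plus the two
# tensor normalization schemes used to condition the de-noising model's
# input/output.

#' Log-linear design matrix for tensor fitting
#'
#' One row per averaged image with columns
#' \code{[1, -b gx^2, -b gy^2, -b gz^2, -2b gx gy, -2b gx gz, -2b gy gz]};
#' the intercept estimates \code{ln S0} and the remaining six columns the
#' unique tensor elements (Dxx, Dyy, Dzz, Dxy, Dxz, Dyz). b = 0 rows reduce
#' to \code{[1, 0, 0, 0, 0, 0, 0]}.
#'
#' @param x an \code{acq_protocol}, a \code{dwi_avg}, or a data frame with
#'   columns b, gx, gy, gz (one row per distinct averaged image).
#' @return Class \code{design_matrix}: the matrix \code{X} and its key
#'   \code{table}.
#' @export
build_design_matrix <- function(x) {
  tab <- if (inherits(x, "acq_protocol")) {
    unique(x$entries[, c("b", "dir_index", "gx", "gy", "gz")])
  } else if (inherits(x, "dwi_avg")) {
    x$table[, c("b", "dir_index", "gx", "gy", "gz")]
  } else {
    as.data.frame(x)
  }
  stop_if_not(nrow(tab) >= 7, "protocol must provide at least 7 distinct (b, direction) keys")
  stop_if_not(any(tab$b == 0), "protocol must include a b = 0 entry")
  X <- cbind(1,
             -tab$b * tab$gx^2, -tab$b * tab$gy^2, -tab$b * tab$gz^2,
             -2 * tab$b * tab$gx * tab$gy,
             -2 * tab$b * tab$gx * tab$gz,
             -2 * tab$b * tab$gy * tab$gz)
  colnames(X) <- c("lnS0", "Dxx", "Dyy", "Dzz", "Dxy", "Dxz", "Dyz")
  if (qr(X)$rank < 7)
    stop("rank-deficient protocol: the (b, direction) set does not span tensor space",
         call. = FALSE)
  structure(list(X = X, table = tab), class = "design_matrix")
}

#' Linear least-squares tensor fit
#'
#' Per masked voxel, ordinary least squares of the log-signal on the design
#' matrix; the intercept exponentiates to S0 and the remaining coefficients
#' are the tensor elements. No positivity projection is applied: negative
#' eigenvalues are permitted. Voxels with any non-positive signal (log
#' undefined) are excluded from the fit, zero-filled and counted; it is an
#' error if every masked voxel is excluded. Voxels outside the mask are
#' zero-filled.
#'
#' @param avg a \code{dwi_avg} averaged stack.
#' @param design a \code{design_matrix} matching the stack's key table.
#' @param mask logical matrix of voxels to fit.
#' @return List: \code{tensor} (a \code{tensor_field} on the mask minus
#'   exclusions), \code{s0} matrix, and \code{report} with
#'   \code{n_excluded}, \code{excluded_idx} and the design condition number.
#' @export
fit_lls <- function(avg, design, mask) {
  stopifnot(inherits(avg, "dwi_avg"), inherits(design, "design_matrix"))
  K <- dim(avg$images)[3]
  stop_if_not(K == nrow(design$X), "averaged stack and design matrix disagree")
  idx <- which(mask)
  stop_if_not(length(idx) > 0, "empty fitting mask")
  gs <- dim(avg$images)[1:2]
  nvox <- prod(gs)
  # signals as K x N matrix over masked voxels
  S <- matrix(avg$images[outer(idx, (0:(K - 1)) * nvox, `+`)],
              nrow = length(idx))
  ok <- rowSums(S <= 0) == 0
  if (!any(ok))
    stop("all masked voxels have non-positive signals; nothing to fit", call. = FALSE)
  beta <- qr.coef(qr(design$X), t(log(S[ok, , drop = FALSE])))   # 7 x N_ok
  d <- array(0, c(gs, 6))
  fit_idx <- idx[ok]
  d[outer(fit_idx, (0:5) * nvox, `+`)] <- t(beta[2:7, , drop = FALSE])
  s0 <- matrix(0, gs[1], gs[2])
  s0[fit_idx] <- exp(beta[1, ])
  fit_mask <- matrix(FALSE, gs[1], gs[2])
  fit_mask[fit_idx] <- TRUE
  list(tensor = tensor_field(d, fit_mask), s0 = s0,
       report = list(n_excluded = sum(!ok), excluded_idx = idx[!ok],
                     condition = kappa(design$X, exact = TRUE)))
}

#' Tensor normalization specification
#'
#' Two conditioning schemes for network input/output: \code{"scale"}
#' multiplies every element by a fixed factor (default 1500 s/mm^2, chosen to
#' bring typical myocardial tensor elements into roughly [-1, 1]);
#' \code{"zscore"} standardizes each of the six channels with statistics
#' fitted on a training set.
#'
#' @param mode \code{"scale"} or \code{"zscore"}.
#' @param scale_factor scale-mode factor (> 0), s/mm^2.
#' @param channel_mean,channel_sd length-6 statistics (zscore mode).
#' @return Class \code{norm_spec}.
#' @export
norm_spec <- function(mode = c("scale", "zscore"), scale_factor = 1500,
                      channel_mean = NULL, channel_sd = NULL) {
  mode <- match.arg(mode)
  if (mode == "scale") {
    stop_if_not(scale_factor > 0, "scale_factor must be positive")
  } else {
    stop_if_not(!is.null(channel_mean) && !is.null(channel_sd),
                "zscore mode requires fitted channel statistics")
    stop_if_not(length(channel_mean) == 6 && length(channel_sd) == 6 &&
                  all(channel_sd > 0),
                "channel statistics must be 6-vectors with positive sd")
  }
  structure(list(mode = mode, scale_factor = scale_factor,
                 channel_mean = channel_mean, channel_sd = channel_sd),
            class = "norm_spec")
}

#' Fit z-score channel statistics on a training set
#'
#' Per-channel mean and standard deviation over the masked voxels of the
#' supplied tensor fields.
#'
#' @param fields list of \code{tensor_field}s (training split).
#' @return A zscore \code{norm_spec}.
#' @export
fit_tensor_normalization <- function(fields) {
  rows <- do.call(rbind, lapply(fields, function(tf) tensor_rows(tf)))
  m <- colMeans(rows)
  s <- apply(rows, 2, stats::sd)
  norm_spec("zscore", channel_mean = m, channel_sd = s)
}

#' Normalize a tensor field for the network
#'
#' Applies the conditioning scheme on the masked voxels; voxels outside the
#' mask are zeroed (non-cardiac regions carry no signal into the model).
#'
#' @param tf a \code{tensor_field}.
#' @param spec a \code{norm_spec}.
#' @return Numeric array (rows, cols, 6) in normalized units.
#' @export
normalize_tensor <- function(tf, spec) {
  stopifnot(inherits(tf, "tensor_field"), inherits(spec, "norm_spec"))
  idx <- which(tf$mask)
  nvox <- prod(dim(tf$d)[1:2])
  out <- array(0, dim(tf$d))
  pos <- outer(idx, (0:5) * nvox, `+`)
  rows <- matrix(tf$d[pos], ncol = 6)
  rows <- if (spec$mode == "scale") rows * spec$scale_factor
          else sweep(sweep(rows, 2, spec$channel_mean), 2, spec$channel_sd, `/`)
  out[pos] <- rows
  out
}

#' Invert tensor normalization
#'
#' Exact inverse of \code{\link{normalize_tensor}} on the masked voxels.
#'
#' @param arr normalized (rows, cols, 6) array.
#' @param spec the \code{norm_spec} used to normalize.
#' @param mask logical matrix of valid voxels.
#' @return A \code{tensor_field} in physical units (mm^2/s).
#' @export
denormalize_tensor <- function(arr, spec, mask) {
  stopifnot(inherits(spec, "norm_spec"))
  idx <- which(mask)
  nvox <- prod(dim(arr)[1:2])
  pos <- outer(idx, (0:5) * nvox, `+`)
  rows <- matrix(arr[pos], ncol = 6)
  rows <- if (spec$mode == "scale") rows / spec$scale_factor
          else sweep(sweep(rows, 2, spec$channel_sd, `*`), 2, spec$channel_mean, `+`)
  d <- array(0, dim(arr))
  d[pos] <- rows
  tensor_field(d, mask)
}
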