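# shared fixtures: small phantoms and tiny network configs, built in code

small_phantom <- function(grid = c(32, 32), r_endo = 6, r_epi = 12, ...) {
  lv_phantom(grid_shape = grid, r_endo = r_endo, r_epi = r_epi, ...)
}

# generator config small enough for finite-difference checks
fd_gen_config <- function() {
  gen_config(base_width = 4, depths = c(1, 1, 1), window = 4, heads = 2,
             mlp_ratio = 2)
}

fd_disc_config <- function(slope = 0.2) {
  disc_config(base_width = 4, lrelu_slope = slope)
}

# central finite difference of f at x[i]
num_deriv <- function(f, x, i, eps = 1e-6) {
  xp <- x; xp[i] <- xp[i] + eps
  xm <- x; xm[i] <- xm[i] - eps
  (f(xp) - f(xm)) / (2 * eps)
}

rel_err <- function(a, b, floor = 1e-8) abs(a - b) / pmax(floor, abs(a) + abs(b))

adam_init_test <- function(p) cdtidenoise:::adam_init(p)
adam_step_test <- function(...) cdtidenoise:::adam_step(...)

# random admissible tensor rows: random orthonormal triad + positive
# descending eigenvalues of physiological magnitude
random_tensor_rows <- function(n) {
  t(vapply(seq_len(n), function(i) {
    q <- qr.Q(qr(matrix(stats::rnorm(9), 3, 3)))
    lam <- sort(stats::runif(3, 0.3e-3, 2.5e-3), decreasing = TRUE)
    D <- q %*% diag(lam) %*% t(q)
    c(D[1, 1], D[2, 2], D[3, 3], D[1, 2], D[1, 3], D[2, 3])
  }, numeric(6)))
}

# place N tensor rows on an N x 1-ish grid as a tensor_field
field_from_rows <- function(rows) {
  n <- nrow(rows)
  nr <- ceiling(sqrt(n)); nc <- ceiling(n / nr)
  d <- array(0, c(nr, nc, 6))
  mask <- matrix(FALSE, nr, nc)
  for (i in seq_len(n)) {
    r <- ((i - 1) %% nr) + 1; c <- ((i - 1) %/% nr) + 1
    d[r, c, ] <- rows[i, ]
    mask[r, c] <- TRUE
  }
  tensor_field(d, mask)
}
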