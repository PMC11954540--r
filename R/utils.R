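#' @keywords internal
#' @importFrom rlang .data
#' @importFrom tibble tibble
"_PACKAGE"

## NULL coalescing used throughout
`%||%` <- function(x, y) if (is.null(x)) y else x

abort_shape <- function(msg) stop(structure(
  class = c("octdistill_shape_error", "error", "condition"),
  list(message = msg, call = sys.call(-1))
))

abort_config <- function(msg) stop(structure(
  class = c("octdistill_config_error", "error", "condition"),
  list(message = msg, call = sys.call(-1))
))

assert_scalar_num <- function(x, name, min = -Inf, strict = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    abort_config(sprintf("`%s` must be a finite numeric scalar", name))
  }
  if (strict && x <= min) abort_config(sprintf("`%s` must be > %g", name, min))
  if (!strict && x < min) abort_config(sprintf("`%s` must be >= %g", name, min))
  invisible(x)
}

assert_count <- function(x, name, min = 1L) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x != round(x) || x < min) {
    abort_config(sprintf("`%s` must be an integer >= %d", name, min))
  }
  invisible(as.integer(x))
}

#' Derive a per-module seed from a global seed
#'
#' A single run seed fans out to independent per-purpose seeds so that modules
#' can be re-run in isolation while the full pipeline stays reproducible.
#' The derivation hashes `(seed, purpose)` into a 31-bit integer via a
#' Lehmer-style multiplicative step, keeping results valid R seeds.
#'
#' @param seed integer global seed.
#' @param purpose character tag naming the consumer (e.g. `"phantom"`).
#' @return integer in `[1, 2^31 - 2]`.
#' @export
derive_seed <- function(seed, purpose) {
  stopifnot(is.character(purpose), length(purpose) == 1L)
  h <- as.double(as.integer(seed)) %% 2147483647
  for (ch in utf8ToInt(purpose)) {
    h <- (h * 48271 + ch) %% 2147483647
  }
  as.integer(h %% 2147483645 + 1)
}

## Corner-aligned bilinear interpolation of a matrix to a new size.
## Output grid point j (1-based) maps to input coordinate
## 1 + (j-1) * (n_in - 1) / (n_out - 1); a single-point axis maps to 1.
bilinear_resize <- function(m, out_h, out_w) {
  stopifnot(is.matrix(m))
  in_h <- nrow(m); in_w <- ncol(m)
  if (in_h == out_h && in_w == out_w) return(m)
  src <- function(n_out, n_in) {
    if (n_out == 1L) return(rep(1, 1L))
    1 + (seq_len(n_out) - 1) * (n_in - 1) / (n_out - 1)
  }
  ry <- src(out_h, in_h); rx <- src(out_w, in_w)
  y0 <- pmin(floor(ry), in_h - 1L); y0[in_h == 1L] <- 1L
  x0 <- pmin(floor(rx), in_w - 1L); x0[in_w == 1L] <- 1L
  wy <- ry - y0; wx <- rx - x0
  y1 <- pmin(y0 + 1L, in_h); x1 <- pmin(x0 + 1L, in_w)
  ## outer-product blend of the four corner grids
  m00 <- m[y0, x0, drop = FALSE]; m01 <- m[y0, x1, drop = FALSE]
  m10 <- m[y1, x0, drop = FALSE]; m11 <- m[y1, x1, drop = FALSE]
  WY <- matrix(wy, out_h, out_w); WX <- matrix(wx, out_h, out_w, byrow = TRUE)
  m00 * (1 - WY) * (1 - WX) + m01 * (1 - WY) * WX +
    m10 * WY * (1 - WX) + m11 * WY * WX
}

## Discrete Gaussian kernel, radius 3*sigma, normalized to sum 1.
gaussian_kernel <- function(sigma) {
  r <- max(1L, ceiling(3 * sigma))
  x <- seq(-r, r)
  k <- exp(-x^2 / (2 * sigma^2))
  k / sum(k)
}

## 1D convolution with reflect padding (edge handling pinned for determinism).
convolve_reflect <- function(v, k) {
  r <- (length(k) - 1L) %/% 2L
  n <- length(v)
  idx <- c(rev(seq_len(min(r, n))), seq_len(n), n + 1 - rev(seq_len(min(r, n))))
  if (r > n) { # very short vectors: clamp-pad the remainder
    pre <- rep(v[1L], r - n); post <- rep(v[n], r - n)
    idx_v <- c(pre, v[idx], post)
  } else idx_v <- v[idx]
  out <- stats::filter(idx_v, k, method = "convolution", sides = 2)
  as.numeric(out[(r + 1L):(r + n)])
}

## Separable Gaussian smoothing of a matrix; sigma = 0 is the identity.
gaussian_smooth <- function(m, sigma) {
  if (sigma <= 0) return(m)
  k <- gaussian_kernel(sigma)
  m1 <- apply(m, 2L, convolve_reflect, k = k)
  t(apply(m1, 1L, convolve_reflect, k = k))
}

## Smooth a vector of iid noise into a random curve with correlation length
## `smoothness` (pixels), rescaled to unit sd when the smoothed sd is nonzero.
smooth_noise_1d <- function(n, smoothness, rng_values) {
  v <- convolve_reflect(rng_values, gaussian_kernel(max(smoothness, 0.5)))
  s <- stats::sd(v)
  if (is.na(s) || s == 0) return(rep(0, n))
  v / s
}
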