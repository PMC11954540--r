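## Shared fixtures: everything is generated in code at test time.

## small, fast phantom configuration used across tests
tiny_phantom <- function(seed = 1L, ...) {
  phantom_config(height = 32L, width = 32L, n_bscans = 4L,
                 boundary_smoothness = 4, seed = seed, ...)
}

## small encoder spec matched to 16x16 inputs
tiny_spec <- function(...) {
  encoder_spec(n_levels = 2L, channels = c(6L, 10L), strides = c(2L, 4L),
               bottleneck_channels = 6L, ...)
}

## deterministic random feature pyramid pair with matching shapes
random_pyramids <- function(shapes, seed = 1L, scale = 1) {
  set.seed(seed)
  mk <- function() lapply(shapes, function(d) array(stats::rnorm(prod(d), sd = scale), dim = d))
  list(t = mk(), s = mk())
}

## brute-force scalar-loop oracle for distance_map
distance_map_oracle <- function(level_t, level_s, cfg) {
  d <- dim(level_t)
  out <- matrix(0, d[1], d[2])
  for (i in seq_len(d[1])) for (j in seq_len(d[2])) {
    out[i, j] <- feature_distance(level_t[i, j, ], level_s[i, j, ], cfg)
  }
  out
}

## O(n^2) Mann-Whitney concordance oracle for the ROC AUC
auc_concordance_oracle <- function(score, label) {
  pos <- score[label == 1]; neg <- score[label == 0]
  tot <- 0
  for (p in pos) for (n in neg) tot <- tot + (p > n) + 0.5 * (p == n)
  tot / (length(pos) * length(neg))
}

## literal step-weighted average-precision oracle
ap_oracle <- function(score, label) {
  thr <- sort(unique(score), decreasing = TRUE)
  rec_prev <- 0; ap <- 0
  for (t in thr) {
    pred <- score >= t
    tp <- sum(pred & label == 1)
    prec <- tp / sum(pred)
    rec <- tp / sum(label == 1)
    ap <- ap + (rec - rec_prev) * prec
    rec_prev <- rec
  }
  ap
}

## independent corner-aligned bilinear interpolation (scalar loops)
bilinear_oracle <- function(m, out_h, out_w) {
  in_h <- nrow(m); in_w <- ncol(m)
  out <- matrix(0, out_h, out_w)
  for (i in seq_len(out_h)) for (j in seq_len(out_w)) {
    y <- if (out_h == 1) 1 else 1 + (i - 1) * (in_h - 1) / (out_h - 1)
    x <- if (out_w == 1) 1 else 1 + (j - 1) * (in_w - 1) / (out_w - 1)
    y0 <- min(floor(y), in_h - 1); x0 <- min(floor(x), in_w - 1)
    if (in_h == 1) y0 <- 1
    if (in_w == 1) x0 <- 1
    fy <- y - y0; fx <- x - x0
    y1 <- min(y0 + 1, in_h); x1 <- min(x0 + 1, in_w)
    out[i, j] <- m[y0, x0] * (1 - fy) * (1 - fx) + m[y0, x1] * (1 - fy) * fx +
      m[y1, x0] * fy * (1 - fx) + m[y1, x1] * fy * fx
  }
  out
}
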