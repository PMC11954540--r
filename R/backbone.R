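## Network primitives --------------------------------------------------------
##
## All convolutions are non-overlapping patch convolutions (kernel == stride),
## so forward and backward passes reduce to reshapes plus BLAS matrix products.
## A feature map is an (H, W, C) array; a patch matrix collects the k x k x C
## values under each output position as one row.

## (H, W, C) -> (Ho*Wo, k*k*C); rows ordered column-major over (ho, wo),
## columns ordered (dy fastest, then dx, then channel)
im2patch <- function(x, k) {
  d <- dim(x); H <- d[1]; W <- d[2]; C <- d[3]
  Ho <- H %/% k; Wo <- W %/% k
  if (k == 1L) return(matrix(x, H * W, C))
  dim(x) <- c(k, Ho, k, Wo, C)
  matrix(aperm(x, c(2L, 4L, 1L, 3L, 5L)), Ho * Wo, k * k * C)
}

## inverse scatter of im2patch for gradients
patch2im <- function(P, k, H, W, C) {
  if (k == 1L) return(array(P, dim = c(H, W, C)))
  Ho <- H %/% k; Wo <- W %/% k
  dim(P) <- c(Ho, Wo, k, k, C)
  array(aperm(P, c(3L, 1L, 4L, 2L, 5L)), dim = c(H, W, C))
}

leaky_relu <- function(x, alpha = 0.1) ifelse(x > 0, x, alpha * x)
leaky_relu_grad <- function(x, alpha = 0.1) ifelse(x > 0, 1, alpha)

## He-style initialization. lowpass in [0, 1] mixes in a window-constant
## component (one draw per channel pair, replicated over the k x k window):
## such filters respond to local patch means rather than per-pixel noise,
## making a random frozen teacher robust to multiplicative speckle while
## keeping the response variance of a plain He init.
init_layer <- function(fan_in, n_out, k, kind, activated = TRUE, lowpass = 0,
                       bias_offset = 0) {
  s0 <- sqrt(2 / fan_in)
  w <- matrix(stats::rnorm(fan_in * n_out, sd = s0), fan_in, n_out)
  if (lowpass > 0 && k > 1L) {
    c_in <- fan_in %/% (k * k)
    v <- matrix(stats::rnorm(c_in * n_out, sd = s0 / k), c_in, n_out)
    w_const <- v[rep(seq_len(c_in), each = k * k), , drop = FALSE]
    w <- sqrt(1 - lowpass^2) * w + lowpass * w_const
  }
  ## positive bias offsets keep frozen-teacher features away from zero, where
  ## the cosine term of the feature distance is ill-conditioned
  b <- if (bias_offset > 0) stats::runif(n_out, 0.5, 1.5) * bias_offset
       else rep(0, n_out)
  list(w = w, b = b, k = as.integer(k), kind = kind, activated = activated)
}

## Patch convolution forward. Returns output array and the cache needed for
## backprop (input patch matrix and pre-activation).
conv_forward <- function(layer, x) {
  d <- dim(x); k <- layer$k
  if (d[1] %% k != 0 || d[2] %% k != 0 || d[1] < k || d[2] < k) {
    abort_shape(sprintf("input %dx%d not divisible by patch size %d", d[1], d[2], k))
  }
  P <- im2patch(x, k)
  Z <- sweep(P %*% layer$w, 2L, layer$b, "+")
  A <- if (layer$activated) leaky_relu(Z) else Z
  Ho <- d[1] %/% k; Wo <- d[2] %/% k
  list(out = array(A, dim = c(Ho, Wo, ncol(layer$w))),
       cache = list(P = P, Z = Z, in_dim = d))
}

conv_backward <- function(layer, cache, d_out) {
  dA <- matrix(d_out, nrow(cache$P), ncol(layer$w))
  dZ <- if (layer$activated) dA * leaky_relu_grad(cache$Z) else dA
  list(
    dw = crossprod(cache$P, dZ),
    db = colSums(dZ),
    dx = patch2im(dZ %*% t(layer$w), layer$k, cache$in_dim[1], cache$in_dim[2],
                  cache$in_dim[3])
  )
}

## Transposed patch convolution (upsampling by factor k): each input position
## emits a k x k output block. Weight shape: C_in x (k*k*C_out).
tconv_forward <- function(layer, x) {
  d <- dim(x); k <- layer$k
  X <- matrix(x, d[1] * d[2], d[3])
  Z <- sweep(X %*% layer$w, 2L, layer$b, "+")
  A <- if (layer$activated) leaky_relu(Z) else Z
  C_out <- ncol(layer$w) %/% (k * k)
  out <- patch2im(A, k, d[1] * k, d[2] * k, C_out)
  list(out = out, cache = list(X = X, Z = Z, in_dim = d))
}

tconv_backward <- function(layer, cache, d_out) {
  k <- layer$k; d <- cache$in_dim
  dA <- im2patch(d_out, k)
  dZ <- if (layer$activated) dA * leaky_relu_grad(cache$Z) else dA
  list(
    dw = crossprod(cache$X, dZ),
    db = colSums(dZ),
    dx = array(dZ %*% t(layer$w), dim = d)
  )
}

layer_forward <- function(layer, x) {
  if (layer$kind == "tconv") tconv_forward(layer, x) else conv_forward(layer, x)
}
layer_backward <- function(layer, cache, d_out) {
  if (layer$kind == "tconv") tconv_backward(layer, cache, d_out)
  else conv_backward(layer, cache, d_out)
}

n_params_layers <- function(layers) {
  sum(vapply(layers, function(l) length(l$w) + length(l$b), numeric(1)))
}

## Architecture specification -------------------------------------------------

#' Encoder specification
#'
#' Defines the multi-level layout shared by teacher and student: the number of
#' intermediary levels of interest, per-level channel counts and cumulative
#' downsampling strides (level n has spatial size `H/stride_n` x `W/stride_n`).
#'
#' @param n_levels number of intermediary levels N.
#' @param channels per-level feature channels, length `n_levels`.
#' @param strides per-level cumulative downsampling factors, strictly
#'   increasing; each must divide the next.
#' @param in_channels input image channels (1 for grayscale B-scans).
#' @param bottleneck_channels channels of the compact code produced by the
#'   bottleneck aggregator.
#' @param student_width width multiplier (< 1) for the student's hidden
#'   channels, enforcing its lower representation capacity.
#' @param teacher_lowpass in `[0, 1]`: fraction of window-constant (low-pass)
#'   structure mixed into the random frozen teacher's filters. Speckle is
#'   per-pixel multiplicative noise, so filters that pool over their window
#'   respond to anatomy rather than noise the student could never predict.
#' @param input_smoothing standard deviation (pixels) of a Gaussian
#'   speckle-reduction filter applied to the input before encoding (0
#'   disables).
#' @param teacher_bias scale of positive random bias offsets in the frozen
#'   teacher's layers. Nonzero offsets keep teacher features away from the
#'   origin, where the cosine term of the feature distance is
#'   direction-unstable under noise.
#' @return an object of class `encoder_spec`.
#' @export
encoder_spec <- function(n_levels = 3L, channels = c(16L, 32L, 64L),
                         strides = c(4L, 8L, 16L), in_channels = 1L,
                         bottleneck_channels = 32L, student_width = 0.6,
                         teacher_lowpass = 1, input_smoothing = 0,
                         teacher_bias = 0) {
  n_levels <- assert_count(n_levels, "n_levels")
  if (length(channels) != n_levels || any(channels < 1)) {
    abort_config("`channels` must have n_levels positive entries")
  }
  if (length(strides) != n_levels || any(diff(strides) <= 0) || any(strides < 1)) {
    abort_config("`strides` must be strictly increasing positive integers")
  }
  ratio <- strides / c(1L, strides[-n_levels])
  if (any(ratio != round(ratio))) {
    abort_config("each stride must be a multiple of the previous one")
  }
  if (student_width <= 0 || student_width >= 1) {
    abort_config("`student_width` must be in (0, 1)")
  }
  if (teacher_lowpass < 0 || teacher_lowpass > 1) {
    abort_config("`teacher_lowpass` must be in [0, 1]")
  }
  structure(list(
    n_levels = n_levels, channels = as.integer(channels),
    strides = as.integer(strides), in_channels = assert_count(in_channels, "in_channels"),
    bottleneck_channels = assert_count(bottleneck_channels, "bottleneck_channels"),
    student_width = student_width, teacher_lowpass = teacher_lowpass,
    input_smoothing = assert_scalar_num(input_smoothing, "input_smoothing", min = 0),
    teacher_bias = assert_scalar_num(teacher_bias, "teacher_bias", min = 0),
    stage_k = as.integer(ratio)
  ), class = "encoder_spec")
}

#' Build a teacher/bottleneck/student model bundle
#'
#' The teacher is a frozen convolutional encoder (randomly initialized unless
#' weights are supplied); the bottleneck aggregates all teacher levels into a
#' compact code at the deepest resolution; the student is a decoder that runs
#' deepest-to-shallowest and emits a pyramid shape-matched to the teacher's.
#' Student capacity is strictly below teacher capacity, asserted at
#' construction.
#'
#' @param spec an [encoder_spec()].
#' @param seed integer seed for weight initialization.
#' @param teacher_weights optional list of teacher layers (e.g. from a saved
#'   checkpoint) to plug in instead of random initialization.
#' @return an object of class `model_bundle`.
#' @export
model_bundle <- function(spec = encoder_spec(), seed = 1L, teacher_weights = NULL) {
  if (!inherits(spec, "encoder_spec")) abort_config("`spec` must be an encoder_spec")
  N <- spec$n_levels
  cb <- max(4L, spec$bottleneck_channels %/% 2L)
  with_local_seed(derive_seed(seed, "bundle_init"), {
    ## teacher: one activated patch conv per level
    in_ch <- c(spec$in_channels, spec$channels[-N])
    teacher <- purrr::map(seq_len(N), function(n) {
      k <- spec$stage_k[n]
      init_layer(k * k * in_ch[n], spec$channels[n], k, "conv",
                 lowpass = spec$teacher_lowpass %||% 0,
                 bias_offset = spec$teacher_bias %||% 0)
    })
    if (!is.null(teacher_weights)) teacher <- teacher_weights
    ## bottleneck: project every level to the deepest resolution, then fuse
    proj <- purrr::map(seq_len(N), function(n) {
      k <- spec$strides[N] %/% spec$strides[n]
      init_layer(max(k, 1L)^2 * spec$channels[n], cb, max(k, 1L), "conv")
    })
    fuse <- init_layer(N * cb, spec$bottleneck_channels, 1L, "conv")
    ## student: decoder from the code, deepest -> shallowest, reduced width
    hid <- pmax(2L, as.integer(ceiling(spec$channels * spec$student_width)))
    stages <- vector("list", N)   # stage N: 1x1 from code; others: upsampling
    heads <- vector("list", N)    # linear 1x1 projections to teacher channels
    stages[[N]] <- init_layer(spec$bottleneck_channels, hid[N], 1L, "conv")
    heads[[N]] <- init_layer(hid[N], spec$channels[N], 1L, "conv", activated = FALSE)
    if (N > 1L) for (n in seq(N - 1L, 1L)) {
      k <- spec$stage_k[n + 1L]
      stages[[n]] <- list(
        w = matrix(stats::rnorm(hid[n + 1L] * k * k * hid[n],
                                sd = sqrt(2 / hid[n + 1L])),
                   hid[n + 1L], k * k * hid[n]),
        b = rep(0, k * k * hid[n]), k = k, kind = "tconv", activated = TRUE
      )
      heads[[n]] <- init_layer(hid[n], spec$channels[n], 1L, "conv", activated = FALSE)
    }
    bundle <- structure(list(
      spec = spec, teacher = teacher,
      bottleneck = list(proj = proj, fuse = fuse),
      student = list(stages = stages, heads = heads),
      seed = as.integer(seed)
    ), class = "model_bundle")
    np_t <- n_params_layers(teacher)
    np_s <- n_params_layers(stages) + n_params_layers(heads)
    if (np_s >= np_t) {
      abort_config(sprintf(
        "student capacity (%d params) must be below teacher capacity (%d params)",
        np_s, np_t))
    }
    bundle$n_params <- c(teacher = np_t, student = np_s,
                         bottleneck = n_params_layers(c(proj, list(fuse))))
    bundle
  })
}

#' @export
print.model_bundle <- function(x, ...) {
  cat(sprintf(
    "<model_bundle> N = %d levels, channels (%s), strides (%s)\n  params: teacher %d (frozen), student %d, bottleneck %d\n",
    x$spec$n_levels, paste(x$spec$channels, collapse = ", "),
    paste(x$spec$strides, collapse = ", "),
    x$n_params["teacher"], x$n_params["student"], x$n_params["bottleneck"]))
  invisible(x)
}

#' Checksum of the frozen teacher parameters
#'
#' Used to assert the frozen-teacher contract: a full training run must leave
#' this value unchanged.
#'
#' @param bundle a [model_bundle()].
#' @return character digest of all teacher parameter values.
#' @export
teacher_checksum <- function(bundle) {
  vals <- unlist(purrr::map(bundle$teacher, function(l) c(as.vector(l$w), l$b)))
  sprintf("%.12e|%.12e|%d", sum(vals), sum(vals^2), length(vals))
}

## Normalize a grayscale image to [0,1] per image (min-max) after optional
## speckle-reduction smoothing, as an (H, W, C) array
prepare_input <- function(image, spec) {
  if (is.matrix(image) && (spec$input_smoothing %||% 0) > 0) {
    image <- gaussian_smooth(image, spec$input_smoothing)
  }
  if (is.matrix(image)) image <- array(image, dim = c(dim(image), 1L))
  rng <- range(image)
  if (rng[2] > rng[1]) image <- (image - rng[1]) / (rng[2] - rng[1])
  d <- dim(image)
  if (d[3] != spec$in_channels) {
    image <- array(rep(image[, , 1L], spec$in_channels), dim = c(d[1], d[2], spec$in_channels))
  }
  image
}

## Forward passes -------------------------------------------------------------

teacher_forward_cached <- function(bundle, image) {
  x <- prepare_input(image, bundle$spec)
  sN <- bundle$spec$strides[bundle$spec$n_levels]
  if (dim(x)[1] < sN || dim(x)[2] < sN) {
    abort_shape(sprintf("input %dx%d smaller than total downsampling %d",
                        dim(x)[1], dim(x)[2], sN))
  }
  levels <- vector("list", bundle$spec$n_levels)
  for (n in seq_len(bundle$spec$n_levels)) {
    r <- conv_forward(bundle$teacher[[n]], x)
    levels[[n]] <- r$out
    x <- r$out
  }
  levels
}

#' Teacher forward pass
#'
#' @param bundle a [model_bundle()].
#' @param image grayscale matrix (or (H, W, C) array) to encode.
#' @return a `feature_pyramid`: ordered list of N `(H_n, W_n, C_n)` arrays,
#'   shallow to deep, with `origin = "teacher"`.
#' @export
teacher_forward <- function(bundle, image) {
  structure(list(levels = teacher_forward_cached(bundle, image),
                 origin = "teacher"), class = "feature_pyramid")
}

bottleneck_forward_cached <- function(bundle, levels) {
  N <- bundle$spec$n_levels
  if (length(levels) != N) abort_shape("pyramid level count does not match spec")
  proj_res <- purrr::map(seq_len(N), function(n) {
    conv_forward(bundle$bottleneck$proj[[n]], levels[[n]])
  })
  cat_code <- array(
    unlist(purrr::map(proj_res, "out")),
    dim = c(dim(proj_res[[N]]$out)[1:2],
            sum(vapply(proj_res, function(r) dim(r$out)[3], numeric(1))))
  )
  fuse_res <- conv_forward(bundle$bottleneck$fuse, cat_code)
  list(code = fuse_res$out, proj_res = proj_res, fuse_res = fuse_res,
       cat_dim = dim(cat_code))
}

#' Bottleneck forward pass
#'
#' Aggregates all N teacher levels into one compact code at the deepest
#' spatial resolution.
#'
#' @param bundle a [model_bundle()].
#' @param pyramid a teacher `feature_pyramid`.
#' @return `(H_N, W_N, bottleneck_channels)` array.
#' @export
bottleneck_forward <- function(bundle, pyramid) {
  if (!inherits(pyramid, "feature_pyramid")) abort_shape("`pyramid` must be a feature_pyramid")
  bottleneck_forward_cached(bundle, pyramid$levels)$code
}

student_forward_cached <- function(bundle, code) {
  N <- bundle$spec$n_levels
  stage_res <- vector("list", N)
  head_res <- vector("list", N)
  x <- code
  for (n in seq(N, 1L)) {
    stage_res[[n]] <- layer_forward(bundle$student$stages[[n]], x)
    x <- stage_res[[n]]$out
    head_res[[n]] <- conv_forward(bundle$student$heads[[n]], x)
  }
  list(levels = purrr::map(head_res, "out"),
       stage_res = stage_res, head_res = head_res)
}

#' Student forward pass
#'
#' Decodes the bottleneck code deepest-to-shallowest into a pyramid whose
#' level shapes match the teacher's exactly (the reverse-distillation layout).
#'
#' @param bundle a [model_bundle()].
#' @param code output of [bottleneck_forward()].
#' @return a `feature_pyramid` with `origin = "student"`.
#' @export
student_forward <- function(bundle, code) {
  structure(list(levels = student_forward_cached(bundle, code)$levels,
                 origin = "student"), class = "feature_pyramid")
}

#' @export
print.feature_pyramid <- function(x, ...) {
  shp <- vapply(x$levels, function(l) paste(dim(l), collapse = "x"), character(1))
  cat(sprintf("<feature_pyramid> origin = %s, levels: %s\n", x$origin,
              paste(shp, collapse = " | ")))
  invisible(x)
}
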