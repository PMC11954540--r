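#' Distance metric configuration
#'
#' @param lambda_weight weight of the cosine-distance term (the Euclidean term
#'   is unweighted); default 1.
#' @param epsilon small positive constant guarding the cosine denominator.
#' @return an object of class `distance_config`.
#' @export
distance_config <- function(lambda_weight = 1, epsilon = 1e-8) {
  assert_scalar_num(lambda_weight, "lambda_weight", min = 0)
  assert_scalar_num(epsilon, "epsilon", min = 0, strict = TRUE)
  structure(list(lambda_weight = lambda_weight, epsilon = epsilon),
            class = "distance_config")
}

#' Training configuration
#'
#' @param epochs,batch_size,learning_rate optimizer settings (Adam).
#' @param optimizer_name currently `"adam"`.
#' @param lr_schedule `"constant"` or `"cosine"` (cosine decay of the
#'   learning rate to zero over the run, settling the student into a sharper
#'   minimum within a fixed epoch budget).
#' @param weight_decay decoupled (AdamW-style) weight decay applied to the
#'   student and bottleneck parameters; regularizes the decoder when the
#'   normal training set covers few distinct retinal geometries.
#' @param seed seed controlling shuffling (training is otherwise
#'   deterministic).
#' @param checkpoint_dir optional directory for checkpoints and the loss
#'   history CSV.
#' @return an object of class `train_config`.
#' @export
train_config <- function(epochs = 20L, batch_size = 2L, learning_rate = 2e-2,
                         optimizer_name = "adam",
                         lr_schedule = c("cosine", "constant"),
                         weight_decay = 1e-3, seed = 1L,
                         checkpoint_dir = NULL) {
  epochs <- assert_count(epochs, "epochs")
  batch_size <- assert_count(batch_size, "batch_size")
  assert_scalar_num(learning_rate, "learning_rate", min = 0)
  assert_scalar_num(weight_decay, "weight_decay", min = 0)
  optimizer_name <- match.arg(optimizer_name, "adam")
  lr_schedule <- match.arg(lr_schedule)
  structure(list(epochs = epochs, batch_size = batch_size,
                 learning_rate = learning_rate, optimizer_name = optimizer_name,
                 lr_schedule = lr_schedule, weight_decay = weight_decay,
                 seed = as.integer(seed), checkpoint_dir = checkpoint_dir),
            class = "train_config")
}

#' Per-position feature distance
#'
#' Distance between one teacher feature vector and the paired student vector:
#' a weighted sum of the cosine distance and the Euclidean (L2) distance,
#' \deqn{D = \lambda\left(1 - \frac{f_T \cdot f_S}{\max(\|f_T\|_2\|f_S\|_2,
#' \varepsilon)}\right) + \|f_T - f_S\|_2.}
#' Zero iff the vectors are identical (and nonzero); finite for zero vectors
#' thanks to \eqn{\varepsilon}.
#'
#' @param f_t,f_s equal-length numeric vectors (one spatial position's channel
#'   vector from the teacher and student pyramids).
#' @param cfg a [distance_config()].
#' @return nonnegative scalar.
#' @export
feature_distance <- function(f_t, f_s, cfg = distance_config()) {
  if (length(f_t) != length(f_s)) abort_shape("feature vectors differ in length")
  nt <- sqrt(sum(f_t^2)); ns <- sqrt(sum(f_s^2))
  cosine <- sum(f_t * f_s) / max(nt * ns, cfg$epsilon)
  cfg$lambda_weight * (1 - cosine) + sqrt(sum((f_t - f_s)^2))
}

## Row-wise distance over matrices (I x C): returns D vector; with gradient
## d D_i / d f_s,i if grad = TRUE.
distance_rows <- function(Tm, Sm, cfg, grad = FALSE) {
  dot <- rowSums(Tm * Sm)
  nt <- sqrt(rowSums(Tm^2)); ns <- sqrt(rowSums(Sm^2))
  denom_raw <- nt * ns
  denom <- pmax(denom_raw, cfg$epsilon)
  cosine <- dot / denom
  diff <- Sm - Tm
  l2 <- sqrt(rowSums(diff^2))
  D <- cfg$lambda_weight * (1 - cosine) + l2
  if (!grad) return(list(D = D))
  ## d cos / d f_s: t/denom - cos * s / ns^2 when the denominator is not
  ## clipped; t/eps when it is (cos = dot/eps there).
  clipped <- denom_raw <= cfg$epsilon
  ns2 <- pmax(ns^2, cfg$epsilon^2)
  dcos <- Tm / denom - (cosine / ns2) * Sm
  if (any(clipped)) dcos[clipped, ] <- Tm[clipped, , drop = FALSE] / cfg$epsilon
  dl2 <- diff / pmax(l2, cfg$epsilon)
  list(D = D, dS = -cfg$lambda_weight * dcos + dl2)
}

level_as_rows <- function(x) {
  d <- dim(x)
  matrix(x, d[1] * d[2], d[3])
}

#' Per-level anomaly distance map
#'
#' Evaluates [feature_distance()] at every spatial position of a shape-paired
#' teacher/student level, producing the raw anomaly score map for that level.
#'
#' @param level_t,level_s `(H_n, W_n, C_n)` arrays with identical shapes.
#' @param cfg a [distance_config()].
#' @return `(H_n, W_n)` matrix of nonnegative distances.
#' @export
distance_map <- function(level_t, level_s, cfg = distance_config()) {
  if (!identical(dim(level_t), dim(level_s))) {
    abort_shape("teacher and student level shapes differ")
  }
  d <- dim(level_t)
  D <- distance_rows(level_as_rows(level_t), level_as_rows(level_s), cfg)$D
  matrix(D, d[1], d[2])
}

#' Multi-level distillation loss
#'
#' Sum over levels of the spatial mean of [distance_map()]:
#' \deqn{L = \sum_{n=1}^{N} \frac{1}{I_n} \sum_{i=1}^{I_n}
#' D(F^T_{n,i}, F^S_{n,i}), \quad I_n = H_n W_n.}
#'
#' @param pyr_t,pyr_s shape-paired `feature_pyramid`s (teacher / student).
#' @param cfg a [distance_config()].
#' @return nonnegative scalar; zero iff all levels are identical.
#' @export
distillation_loss <- function(pyr_t, pyr_s, cfg = distance_config()) {
  lt <- if (inherits(pyr_t, "feature_pyramid")) pyr_t$levels else pyr_t
  ls <- if (inherits(pyr_s, "feature_pyramid")) pyr_s$levels else pyr_s
  if (length(lt) != length(ls)) abort_shape("pyramids differ in level count")
  sum(vapply(seq_along(lt), function(n) mean(distance_map(lt[[n]], ls[[n]], cfg)),
             numeric(1)))
}

## Loss and gradient wrt the student levels (teacher fixed).
loss_with_grad <- function(t_levels, s_levels, cfg) {
  loss <- 0
  grads <- vector("list", length(t_levels))
  for (n in seq_along(t_levels)) {
    d <- dim(t_levels[[n]])
    r <- distance_rows(level_as_rows(t_levels[[n]]), level_as_rows(s_levels[[n]]),
                       cfg, grad = TRUE)
    I_n <- d[1] * d[2]
    loss <- loss + mean(r$D)
    grads[[n]] <- array(r$dS / I_n, dim = d)
  }
  list(loss = loss, d_levels = grads)
}

## Trainable parameter plumbing ----------------------------------------------

trainable_params <- function(bundle) {
  list(stages = purrr::map(bundle$student$stages, function(l) list(w = l$w, b = l$b)),
       heads = purrr::map(bundle$student$heads, function(l) list(w = l$w, b = l$b)),
       proj = purrr::map(bundle$bottleneck$proj, function(l) list(w = l$w, b = l$b)),
       fuse = list(list(w = bundle$bottleneck$fuse$w, b = bundle$bottleneck$fuse$b)))
}

set_trainable_params <- function(bundle, p) {
  for (n in seq_along(p$stages)) {
    bundle$student$stages[[n]]$w <- p$stages[[n]]$w
    bundle$student$stages[[n]]$b <- p$stages[[n]]$b
    bundle$student$heads[[n]]$w <- p$heads[[n]]$w
    bundle$student$heads[[n]]$b <- p$heads[[n]]$b
    bundle$bottleneck$proj[[n]]$w <- p$proj[[n]]$w
    bundle$bottleneck$proj[[n]]$b <- p$proj[[n]]$b
  }
  bundle$bottleneck$fuse$w <- p$fuse[[1]]$w
  bundle$bottleneck$fuse$b <- p$fuse[[1]]$b
  bundle
}

zero_like <- function(p) rapply(p, function(x) x * 0, how = "replace")

add_grads <- function(a, b) {
  if (is.list(a)) return(purrr::map2(a, b, add_grads))
  a + b
}
scale_grads <- function(a, s) rapply(a, function(x) x * s, how = "replace")

## Backward pass through student + bottleneck given gradients wrt the student
## levels. Returns gradients in trainable_params() structure.
backward_trainables <- function(bundle, bcache, scache, d_levels) {
  N <- bundle$spec$n_levels
  g <- zero_like(trainable_params(bundle))
  d_x <- vector("list", N)   # grad wrt output of student stage n
  carry <- NULL              # grad flowing from stage n-1 back into x_n
  for (n in seq_len(N)) {
    hb <- conv_backward(bundle$student$heads[[n]], scache$head_res[[n]]$cache,
                        d_levels[[n]])
    g$heads[[n]]$w <- hb$dw; g$heads[[n]]$b <- hb$db
    d_x[[n]] <- if (is.null(carry)) hb$dx else hb$dx + carry
    sb <- layer_backward(bundle$student$stages[[n]], scache$stage_res[[n]]$cache,
                         d_x[[n]])
    g$stages[[n]]$w <- sb$dw; g$stages[[n]]$b <- sb$db
    carry <- sb$dx
  }
  d_code <- carry
  fb <- conv_backward(bundle$bottleneck$fuse, bcache$fuse_res$cache, d_code)
  g$fuse[[1]]$w <- fb$dw; g$fuse[[1]]$b <- fb$db
  ## split the concatenated-code gradient back into per-level projections
  off <- 0L
  for (n in seq_len(N)) {
    cn <- dim(bcache$proj_res[[n]]$out)[3]
    d_proj <- fb$dx[, , off + seq_len(cn), drop = FALSE]
    off <- off + cn
    pb <- conv_backward(bundle$bottleneck$proj[[n]], bcache$proj_res[[n]]$cache,
                        d_proj)
    g$proj[[n]]$w <- pb$dw; g$proj[[n]]$b <- pb$db
    ## pb$dx is the gradient wrt the frozen teacher level: discarded by design
  }
  g
}

adam_init <- function(p) list(m = zero_like(p), v = zero_like(p), t = 0L)

adam_step <- function(p, g, state, lr, beta1 = 0.9, beta2 = 0.999, eps = 1e-8,
                      weight_decay = 0) {
  state$t <- state$t + 1L
  upd <- function(pp, gg, mm, vv) {
    if (is.list(pp)) {
      out <- purrr::pmap(list(pp, gg, mm, vv), upd)
      return(list(p = purrr::map(out, "p"), m = purrr::map(out, "m"),
                  v = purrr::map(out, "v")))
    }
    m2 <- beta1 * mm + (1 - beta1) * gg
    v2 <- beta2 * vv + (1 - beta2) * gg^2
    mh <- m2 / (1 - beta1^state$t)
    vh <- v2 / (1 - beta2^state$t)
    ## decoupled weight decay (AdamW)
    list(p = pp - lr * (mh / (sqrt(vh) + eps) + weight_decay * pp),
         m = m2, v = v2)
  }
  out <- upd(p, g, state$m, state$v)
  list(p = out$p, state = list(m = out$m, v = out$v, t = state$t))
}

## Forward + loss + gradient for one image given its precomputed teacher levels
student_pass <- function(bundle, t_levels, cfg, grad = TRUE) {
  bc <- bottleneck_forward_cached(bundle, t_levels)
  sc <- student_forward_cached(bundle, bc$code)
  lg <- loss_with_grad(t_levels, sc$levels, cfg)
  if (!grad) return(list(loss = lg$loss))
  list(loss = lg$loss,
       grads = backward_trainables(bundle, bc, sc, lg$d_levels))
}

#' Train the student and bottleneck on normal images
#'
#' Fits the student decoder and bottleneck to replicate the frozen teacher's
#' feature pyramid, minimizing [distillation_loss()] over minibatches with
#' Adam. Only normal (lesion-free) material may be used; passing anomalous
#' labels is a contract violation. Gradients flow into the student and
#' bottleneck only — the teacher is structurally untouched.
#'
#' @param bundle a [model_bundle()].
#' @param normal_images list of grayscale matrices, or a list of
#'   `phantom_volume`s (all labelled `"normal"`), whose slices are pooled.
#' @param tcfg a [train_config()].
#' @param dcfg a [distance_config()].
#' @param labels optional per-image labels; any `"anomalous"` entry errors.
#' @param verbose print one line per epoch.
#' @return an object of class `octdistill_fit`: the trained `bundle`, a
#'   `history` tibble (`epoch`, `mean_loss`), and the configurations used.
#' @export
train_student <- function(bundle, normal_images, tcfg = train_config(),
                          dcfg = distance_config(), labels = NULL,
                          verbose = FALSE) {
  if (length(normal_images) > 0 && inherits(normal_images[[1]], "phantom_volume")) {
    bad <- purrr::keep(normal_images, function(v) v$label != "normal")
    if (length(bad) > 0) {
      stop("training set contains anomalous-labelled volumes: ",
           paste(vapply(bad, `[[`, character(1), "volume_id"), collapse = ", "),
           call. = FALSE)
    }
    normal_images <- purrr::flatten(purrr::map(normal_images, "images"))
  }
  if (length(normal_images) == 0) stop("empty training set", call. = FALSE)
  if (!is.null(labels) && any(labels != "normal")) {
    stop("training set contains anomalous-labelled images", call. = FALSE)
  }
  checksum_before <- teacher_checksum(bundle)
  ## teacher is frozen: its pyramids are computed once and reused every epoch
  t_levels <- purrr::map(normal_images, function(im) teacher_forward_cached(bundle, im))
  p <- trainable_params(bundle)
  state <- adam_init(p)
  history <- numeric(tcfg$epochs)
  n <- length(normal_images)
  with_local_seed(derive_seed(tcfg$seed, "train_shuffle"), {
    for (ep in seq_len(tcfg$epochs)) {
      ord <- sample.int(n)
      lr_ep <- if ((tcfg$lr_schedule %||% "constant") == "cosine") {
        tcfg$learning_rate * 0.5 * (1 + cos(pi * (ep - 1) / tcfg$epochs))
      } else {
        tcfg$learning_rate
      }
      batch_losses <- c()
      for (start in seq(1L, n, by = tcfg$batch_size)) {
        idx <- ord[start:min(start + tcfg$batch_size - 1L, n)]
        acc <- NULL; loss_sum <- 0
        for (i in idx) {
          r <- student_pass(bundle, t_levels[[i]], dcfg, grad = TRUE)
          loss_sum <- loss_sum + r$loss
          acc <- if (is.null(acc)) r$grads else add_grads(acc, r$grads)
        }
        acc <- scale_grads(acc, 1 / length(idx))
        if (lr_ep > 0) {
          st <- adam_step(p, acc, state, lr_ep,
                          weight_decay = tcfg$weight_decay %||% 0)
          p <- st$p; state <- st$state
          bundle <- set_trainable_params(bundle, p)
        }
        batch_losses <- c(batch_losses, loss_sum / length(idx))
      }
      history[ep] <- mean(batch_losses)
      if (verbose) {
        message(sprintf("[train] epoch %d/%d mean_loss %.5f", ep, tcfg$epochs,
                        history[ep]))
      }
    }
  })
  stopifnot(identical(teacher_checksum(bundle), checksum_before))
  fit <- structure(list(
    bundle = bundle,
    history = tibble::tibble(epoch = seq_len(tcfg$epochs), mean_loss = history),
    train_config = tcfg, distance_config = dcfg,
    n_images = n, teacher_checksum = checksum_before
  ), class = "octdistill_fit")
  if (!is.null(tcfg$checkpoint_dir)) {
    dir.create(tcfg$checkpoint_dir, showWarnings = FALSE, recursive = TRUE)
    save_checkpoint(fit, file.path(tcfg$checkpoint_dir, "checkpoint.rds"))
    readr::write_csv(fit$history, file.path(tcfg$checkpoint_dir, "loss_history.csv"))
  }
  fit
}

#' @export
print.octdistill_fit <- function(x, ...) {
  cat(sprintf(
    "<octdistill_fit> %d images, %d epochs; loss %.5f -> %.5f\n",
    x$n_images, nrow(x$history), x$history$mean_loss[1],
    x$history$mean_loss[nrow(x$history)]))
  invisible(x)
}

#' Save / load a trained checkpoint
#'
#' The checkpoint archives the full bundle (spec + parameters), training and
#' distance configurations, and the loss history.
#'
#' @param fit an `octdistill_fit`.
#' @param path file path for the checkpoint.
#' @return `save_checkpoint` returns `path` invisibly; `load_checkpoint`
#'   returns the fit.
#' @export
save_checkpoint <- function(fit, path) {
  saveRDS(fit, path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  fit <- readRDS(path)
  if (!inherits(fit, "octdistill_fit")) stop("not an octdistill checkpoint: ", path,
                                             call. = FALSE)
  fit
}
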