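#' Scoring configuration
#'
#' @param aggregation_rule per-level aggregation `P` used by [bscan_score()]:
#'   `"max"` (default; robust to lesions of very different sizes) or `"mean"`.
#' @param gaussian_sigma standard deviation (pixels, at input resolution) of
#'   the Gaussian used to smooth composed anomaly maps; 0 disables smoothing.
#' @param score_source `"composed_map"` (default: aggregate the composed,
#'   Gaussian-smoothed anomaly map, which pools evidence over a lesion's
#'   spatial extent) or `"per_level_raw"` (aggregate each raw level map
#'   before resizing/smoothing and sum over levels).
#' @return an object of class `score_config`.
#' @export
score_config <- function(aggregation_rule = c("max", "mean"), gaussian_sigma = 4,
                         score_source = c("composed_map", "per_level_raw")) {
  aggregation_rule <- match.arg(aggregation_rule)
  score_source <- match.arg(score_source)
  assert_scalar_num(gaussian_sigma, "gaussian_sigma", min = 0)
  structure(list(aggregation_rule = aggregation_rule,
                 gaussian_sigma = gaussian_sigma, score_source = score_source),
            class = "score_config")
}

#' Compose an anomaly explanation map
#'
#' Bilinearly resizes each per-level distance map to the input size
#' (corner-aligned sampling), sums them elementwise, and smooths the sum with
#' a Gaussian kernel.
#'
#' @param level_maps list of nonnegative per-level matrices from
#'   [distance_map()].
#' @param input_shape `(H, W)` of the input B-scan.
#' @param cfg a [score_config()].
#' @return `(H, W)` nonnegative matrix of class `anomaly_map`.
#' @export
compose_anomaly_map <- function(level_maps, input_shape, cfg = score_config()) {
  if (length(level_maps) == 0) stop("empty level map list", call. = FALSE)
  H <- input_shape[1]; W <- input_shape[2]
  total <- matrix(0, H, W)
  for (m in level_maps) total <- total + bilinear_resize(m, H, W)
  total <- gaussian_smooth(total, cfg$gaussian_sigma)
  total[total < 0] <- 0  # guard tiny negative ringing from the kernel tails
  structure(total, class = c("anomaly_map", "matrix", "array"))
}

#' B-scan anomaly score
#'
#' Sum over levels of the aggregation `P` applied to each raw level map:
#' `score = sum_n P(M_n)` with `P = max` by default.
#'
#' @param level_maps list of nonnegative per-level matrices.
#' @param cfg a [score_config()].
#' @return nonnegative scalar.
#' @export
bscan_score <- function(level_maps, cfg = score_config()) {
  if (length(level_maps) == 0) stop("empty level map list", call. = FALSE)
  P <- if (cfg$aggregation_rule == "max") max else mean
  sum(vapply(level_maps, function(m) P(m), numeric(1)))
}

#' Volume anomaly score
#'
#' The maximum of the per-B-scan anomaly scores.
#'
#' @param slice_scores nonempty numeric vector of per-slice scores, in slice
#'   order.
#' @return scalar.
#' @export
volume_score <- function(slice_scores) {
  if (length(slice_scores) == 0) stop("empty slice score list", call. = FALSE)
  max(slice_scores)
}

#' Stack per-B-scan anomaly maps into a volumetric map
#'
#' Maps are concatenated along the slice axis in the given order; each slice
#' is left untouched (no cross-slice smoothing: every B-scan is processed
#' independently).
#'
#' @param bscan_maps ordered list of `(H, W)` matrices sharing one shape.
#' @return `(n_slices, H, W)` array.
#' @export
volume_anomaly_map <- function(bscan_maps) {
  if (length(bscan_maps) == 0) stop("empty map list", call. = FALSE)
  dims <- purrr::map(bscan_maps, dim)
  if (length(unique(purrr::map_chr(dims, paste, collapse = "x"))) != 1L) {
    stop("anomaly maps have heterogeneous shapes", call. = FALSE)
  }
  H <- dims[[1]][1]; W <- dims[[1]][2]
  out <- array(0, dim = c(length(bscan_maps), H, W))
  for (s in seq_along(bscan_maps)) out[s, , ] <- bscan_maps[[s]]
  out
}

## Distance maps for one image under a trained bundle
image_level_maps <- function(bundle, image, dcfg) {
  t_levels <- teacher_forward_cached(bundle, image)
  code <- bottleneck_forward_cached(bundle, t_levels)$code
  s_levels <- student_forward_cached(bundle, code)$levels
  purrr::map(seq_along(t_levels),
             function(n) distance_map(t_levels[[n]], s_levels[[n]], dcfg))
}

#' Score an OCT volume end to end
#'
#' For each B-scan: compute the teacher and student pyramids, their per-level
#' distance maps, the scalar B-scan score and the composed anomaly map; then
#' aggregate to the volume score (max over slices) and stack the maps into a
#' volumetric anomaly map. Deterministic for fixed weights.
#'
#' @param bundle a trained [model_bundle()] (or an `octdistill_fit`).
#' @param images ordered list of grayscale B-scan matrices.
#' @param dcfg a [distance_config()].
#' @param scfg a [score_config()].
#' @param volume_id identifier carried into the score records.
#' @return list with `volume_record` (tibble: `volume_id`, `score`),
#'   `slice_records` (tibble: `volume_id`, `slice_index`, `score`), `maps`
#'   (list of per-slice anomaly maps) and `volume_map` (slice-stacked array).
#' @export
score_volume <- function(bundle, images, dcfg = distance_config(),
                         scfg = score_config(), volume_id = "vol_001") {
  if (inherits(bundle, "octdistill_fit")) bundle <- bundle$bundle
  if (length(images) == 0) stop("empty volume", call. = FALSE)
  maps <- vector("list", length(images))
  scores <- numeric(length(images))
  for (s in seq_along(images)) {
    lm <- image_level_maps(bundle, images[[s]], dcfg)
    maps[[s]] <- compose_anomaly_map(lm, dim(images[[s]]), scfg)
    scores[s] <- if (scfg$score_source == "per_level_raw") {
      bscan_score(lm, scfg)
    } else {
      P <- if (scfg$aggregation_rule == "max") max else mean
      P(maps[[s]])
    }
  }
  list(
    volume_record = tibble::tibble(volume_id = volume_id,
                                   score = volume_score(scores)),
    slice_records = tibble::tibble(volume_id = volume_id,
                                   slice_index = seq_along(images),
                                   score = scores),
    maps = maps,
    volume_map = volume_anomaly_map(maps)
  )
}

#' Score a set of volumes into tidy tables
#'
#' Convenience driver over [score_volume()] for a list of volumes (either
#' `phantom_volume`s or plain lists with `images` and `volume_id`).
#'
#' @inheritParams score_volume
#' @param volumes list of volumes.
#' @param keep_maps retain per-slice anomaly maps in the result.
#' @return list with `slice_scores` and `volume_scores` tibbles and (when
#'   `keep_maps`) `maps`, a per-volume list of anomaly-map lists.
#' @export
score_volumes <- function(bundle, volumes, dcfg = distance_config(),
                          scfg = score_config(), keep_maps = TRUE) {
  res <- purrr::map(volumes, function(v) {
    score_volume(bundle, v$images, dcfg, scfg,
                 volume_id = v$volume_id %||% "vol")
  })
  out <- list(
    slice_scores = dplyr::bind_rows(purrr::map(res, "slice_records")),
    volume_scores = dplyr::bind_rows(purrr::map(res, "volume_record"))
  )
  if (keep_maps) {
    out$maps <- purrr::map(res, "maps")
    names(out$maps) <- out$volume_scores$volume_id
  }
  out
}

#' Write / read anomaly map stacks as 32-bit float TIFF
#'
#' One multi-page TIFF per volume, one page per B-scan, 32-bit float samples.
#' Raw anomaly intensities are unbounded, so the stack is stored divided by a
#' single scale factor (its maximum) recorded in a `.scale.txt` sidecar next
#' to the TIFF; reading multiplies it back.
#'
#' @param maps list of `(H, W)` matrices.
#' @param path TIFF file path.
#' @return `write_anomaly_maps` returns `path` invisibly; `read_anomaly_maps`
#'   returns the list of matrices.
#' @export
write_anomaly_maps <- function(maps, path) {
  sc <- max(1e-12, max(vapply(maps, max, numeric(1))))
  tiff::writeTIFF(
    purrr::map(maps, function(m) matrix(as.numeric(m) / sc, nrow(m), ncol(m))),
    path, bits.per.sample = 32L, compression = "none", reduce = FALSE)
  writeLines(sprintf("%.17g", sc), paste0(path, ".scale.txt"))
  invisible(path)
}

#' @rdname write_anomaly_maps
#' @export
read_anomaly_maps <- function(path) {
  out <- tiff::readTIFF(path, all = TRUE, as.is = FALSE)
  if (!is.list(out)) out <- list(out)
  scale_file <- paste0(path, ".scale.txt")
  sc <- if (file.exists(scale_file)) as.numeric(readLines(scale_file)[1]) else 1
  purrr::map(out, function(m) matrix(as.numeric(m) * sc, nrow(m), ncol(m)))
}
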