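## Evaluation statistics -----------------------------------------------------

check_labeled <- function(data, need_both = TRUE) {
  if (!all(c("score", "label") %in% names(data))) {
    stop("`data` needs `score` and `label` columns", call. = FALSE)
  }
  lab <- as.integer(data$label %in% c(1, "1", TRUE, "anomalous"))
  if (need_both && (sum(lab) == 0 || sum(lab) == length(lab))) {
    stop("both classes must be present", call. = FALSE)
  }
  lab
}

#' ROC curve and AUC
#'
#' Threshold sweep over the unique observed scores (rule: positive iff
#' `score >= threshold`) plus a `+Inf` sentinel, ties grouped. The resulting
#' AUC equals the Mann-Whitney concordance
#' `P(score_anom > score_norm) + 0.5 * P(tie)`.
#'
#' @param data data frame with numeric `score` and binary `label` columns
#'   (1/"anomalous" = anomalous).
#' @return a `curve_result`: tibble `points` (`threshold`, `fpr`, `tpr`) with
#'   attributes; `area` holds the AUC.
#' @export
roc_curve_auc <- function(data) {
  lab <- check_labeled(data)
  sc <- data$score
  thr <- c(Inf, sort(unique(sc), decreasing = TRUE))
  n_pos <- sum(lab); n_neg <- sum(1 - lab)
  tp <- vapply(thr, function(t) sum(sc >= t & lab == 1L), numeric(1))
  fp <- vapply(thr, function(t) sum(sc >= t & lab == 0L), numeric(1))
  pts <- tibble::tibble(threshold = thr, fpr = fp / n_neg, tpr = tp / n_pos)
  auc <- sum(diff(pts$fpr) * (utils::head(pts$tpr, -1) + utils::tail(pts$tpr, -1)) / 2)
  new_curve_result(pts, auc, "roc")
}

#' Precision-recall curve and average precision
#'
#' Average precision is the step-weighted mean of precisions over the
#' threshold sweep: `AP = sum_k (R_k - R_{k-1}) * P_k`, with the increase in
#' recall from the previous threshold as the weight (not a trapezoidal
#' interpolation).
#'
#' @inheritParams roc_curve_auc
#' @return a `curve_result` with `points` (`threshold`, `recall`,
#'   `precision`); `area` holds the AP.
#' @export
pr_curve_ap <- function(data) {
  if (!all(c("score", "label") %in% names(data))) {
    stop("`data` needs `score` and `label` columns", call. = FALSE)
  }
  lab <- as.integer(data$label %in% c(1, "1", TRUE, "anomalous"))
  if (sum(lab) == 0) stop("at least one positive is required", call. = FALSE)
  sc <- data$score
  thr <- sort(unique(sc), decreasing = TRUE)
  n_pos <- sum(lab)
  tp <- vapply(thr, function(t) sum(sc >= t & lab == 1L), numeric(1))
  pred_pos <- vapply(thr, function(t) sum(sc >= t), numeric(1))
  precision <- tp / pred_pos
  recall <- tp / n_pos
  ap <- sum(diff(c(0, recall)) * precision)
  pts <- tibble::tibble(threshold = thr, recall = recall, precision = precision)
  new_curve_result(pts, ap, "pr")
}

new_curve_result <- function(points, area, type) {
  structure(list(points = points, area = area, type = type),
            class = "curve_result")
}

#' @export
print.curve_result <- function(x, ...) {
  metric <- if (x$type == "roc") "AUC" else "AP"
  cat(sprintf("<curve_result> %s curve, %d points, %s = %.4f\n",
              toupper(x$type), nrow(x$points), metric, x$area))
  invisible(x)
}

#' Optimal ROC cutoff
#'
#' The threshold whose `(FPR, TPR)` point lies closest (Euclidean distance) to
#' the perfect-classifier corner `(0, 1)`. Ties are broken toward the higher
#' threshold, i.e. fewer samples flagged positive.
#'
#' @param curve a ROC `curve_result` from [roc_curve_auc()].
#' @return scalar threshold (binarize with `score >= threshold`).
#' @export
optimal_cutoff <- function(curve) {
  stopifnot(inherits(curve, "curve_result"), curve$type == "roc")
  p <- curve$points
  d2 <- p$fpr^2 + (1 - p$tpr)^2
  best <- which(d2 <= min(d2) + 1e-12)
  max(p$threshold[best])
}

#' Leave-one-volume-out PPV and NPV
#'
#' For every volume in turn: (i) build a single ROC curve from the B-scans of
#' all other volumes, (ii) take its optimal cutoff (closest point to `(0,1)`),
#' (iii) binarize the held-out volume's scores at that threshold, and report
#' PPV = TP/(TP+FP) and NPV = TN/(TN+FN). Ratios with a zero denominator are
#' reported as missing and excluded from the summary means, with counts
#' logged; folds whose training B-scans are single-class are skipped with a
#' warning.
#'
#' @param data data frame with `score`, `label`, and `volume_id` columns.
#' @return an `octdistill_loo` object: `per_volume` tibble (`volume_id`,
#'   `threshold`, `tp`, `fp`, `tn`, `fn`, `ppv`, `npv`), `summary` tibble
#'   (mean, sd, missing counts), and `skipped` volume ids.
#' @export
loo_ppv_npv <- function(data) {
  if (!"volume_id" %in% names(data)) {
    stop("`data` needs a `volume_id` column", call. = FALSE)
  }
  lab <- check_labeled(data, need_both = FALSE)
  data <- dplyr::mutate(data, .lab = lab)
  vols <- unique(data$volume_id)
  if (length(vols) < 2L) stop("at least 2 volumes are required", call. = FALSE)
  skipped <- character(0)
  rows <- purrr::map(vols, function(v) {
    train <- dplyr::filter(data, .data$volume_id != v)
    if (length(unique(train$.lab)) < 2L) {
      warning("fold for volume ", v, " skipped: training B-scans are single-class",
              call. = FALSE)
      skipped <<- c(skipped, v)
      return(NULL)
    }
    thr <- optimal_cutoff(roc_curve_auc(train))
    test <- dplyr::filter(data, .data$volume_id == v)
    pred <- test$score >= thr
    tp <- sum(pred & test$.lab == 1L); fp <- sum(pred & test$.lab == 0L)
    tn <- sum(!pred & test$.lab == 0L); fn <- sum(!pred & test$.lab == 1L)
    tibble::tibble(volume_id = v, threshold = thr, tp = tp, fp = fp, tn = tn,
                   fn = fn,
                   ppv = if (tp + fp > 0) tp / (tp + fp) else NA_real_,
                   npv = if (tn + fn > 0) tn / (tn + fn) else NA_real_)
  })
  per_volume <- dplyr::bind_rows(rows)
  summ <- tibble::tibble(
    metric = c("ppv", "npv"),
    mean = c(mean(per_volume$ppv, na.rm = TRUE), mean(per_volume$npv, na.rm = TRUE)),
    sd = c(stats::sd(per_volume$ppv, na.rm = TRUE),
           stats::sd(per_volume$npv, na.rm = TRUE)),
    n_missing = c(sum(is.na(per_volume$ppv)), sum(is.na(per_volume$npv))),
    n_volumes = nrow(per_volume)
  )
  structure(list(per_volume = per_volume, summary = summ, skipped = skipped),
            class = "octdistill_loo")
}

#' @export
print.octdistill_loo <- function(x, ...) {
  s <- x$summary
  cat(sprintf("<octdistill_loo> %d volumes: PPV %.3f +/- %.3f (%d missing), NPV %.3f +/- %.3f (%d missing)\n",
              s$n_volumes[1], s$mean[1], s$sd[1], s$n_missing[1],
              s$mean[2], s$sd[2], s$n_missing[2]))
  if (length(x$skipped)) cat("  skipped folds:", paste(x$skipped, collapse = ", "), "\n")
  invisible(x)
}

#' Relative-position anomaly profiles
#'
#' Each volume's ordered slice-score sequence is linearly interpolated onto
#' `target_length` equispaced relative positions in `[0, 1]`; the pointwise
#' mean across volumes is returned per class.
#'
#' @param data data frame with `volume_id`, `slice_index`, `score`, and
#'   optionally `class` (defaults to one class).
#' @param target_length number of relative positions L (>= 2).
#' @return tibble with `class`, `position` (relative, in `[0,1]`),
#'   `mean_score`, `n_volumes`.
#' @export
anomaly_profile <- function(data, target_length = 100L) {
  target_length <- assert_count(target_length, "target_length", min = 2L)
  if (!all(c("volume_id", "slice_index", "score") %in% names(data))) {
    stop("`data` needs volume_id, slice_index, score columns", call. = FALSE)
  }
  if (!"class" %in% names(data)) data$class <- "all"
  pos <- seq(0, 1, length.out = target_length)
  interp <- data |>
    dplyr::group_by(.data$class, .data$volume_id) |>
    dplyr::group_modify(function(g, key) {
      g <- dplyr::arrange(g, .data$slice_index)
      if (nrow(g) < 2L) stop("each volume needs >= 2 slices", call. = FALSE)
      x <- seq(0, 1, length.out = nrow(g))
      tibble::tibble(position = pos,
                     score = stats::approx(x, g$score, xout = pos)$y)
    }) |>
    dplyr::ungroup()
  interp |>
    dplyr::group_by(.data$class, .data$position) |>
    dplyr::summarise(mean_score = mean(.data$score),
                     n_volumes = dplyr::n(), .groups = "drop")
}

#' Map-derived severity scores and correlation with lesion area
#'
#' Per slice, the anomaly-map severity score is the mean of all map values
#' strictly above `threshold` (0 if none exceed it — slices with no
#' activation rank lowest), and the relative lesion area is the positive mask
#' fraction. Returns both series with Pearson's and Spearman's correlation
#' coefficients between them; constant series yield missing coefficients.
#'
#' @param maps list of anomaly-map matrices.
#' @param masks list of binary lesion-mask matrices, aligned with `maps`.
#' @param threshold activation threshold, typically from
#'   [training_threshold()].
#' @return an `octdistill_severity` object: `records` tibble (`slice`,
#'   `relative_lesion_area`, `map_score`), `pearson`, `spearman`,
#'   `threshold`.
#' @export
severity_scores <- function(maps, masks, threshold) {
  if (length(maps) != length(masks)) stop("maps and masks differ in length", call. = FALSE)
  recs <- purrr::map2(maps, masks, function(mp, mk) {
    if (!identical(dim(mp)[1:2], dim(mk)[1:2])) {
      stop("map and mask shapes differ", call. = FALSE)
    }
    above <- mp[mp > threshold]
    tibble::tibble(
      relative_lesion_area = sum(mk > 0) / length(mk),
      map_score = if (length(above)) mean(above) else 0
    )
  }) |> dplyr::bind_rows()
  recs <- dplyr::mutate(recs, slice = dplyr::row_number(), .before = 1L)
  safe_cor <- function(method) {
    sd_a <- stats::sd(recs$relative_lesion_area)
    sd_s <- stats::sd(recs$map_score)
    if (nrow(recs) < 2L || is.na(sd_a) || is.na(sd_s) || sd_a == 0 || sd_s == 0) {
      return(NA_real_)
    }
    stats::cor(recs$relative_lesion_area, recs$map_score, method = method)
  }
  structure(list(records = recs, pearson = safe_cor("pearson"),
                 spearman = safe_cor("spearman"), threshold = threshold),
            class = "octdistill_severity")
}

#' @export
print.octdistill_severity <- function(x, ...) {
  cat(sprintf("<octdistill_severity> %d slices, threshold %.4f: Pearson r = %.3f, Spearman rho = %.3f\n",
              nrow(x$records), x$threshold, x$pearson, x$spearman))
  invisible(x)
}

#' Data-driven severity threshold
#'
#' The pixel-weighted mean over all anomaly-map values of the (normal)
#' training set — the data-driven counterpart of an absolute activation
#' cutoff.
#'
#' @param train_maps nonempty list of anomaly-map matrices from normal
#'   training data.
#' @return scalar threshold.
#' @export
training_threshold <- function(train_maps) {
  if (length(train_maps) == 0) stop("empty training map list", call. = FALSE)
  tot <- sum(vapply(train_maps, sum, numeric(1)))
  npix <- sum(vapply(train_maps, length, numeric(1)))
  tot / npix
}
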