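#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a trained fit into its loss history
#'
#' @param x an `octdistill_fit`.
#' @param ... unused.
#' @return tibble with `epoch` and `mean_loss`.
#' @export
tidy.octdistill_fit <- function(x, ...) x$history

#' One-row summary of a trained fit
#'
#' @param x an `octdistill_fit`.
#' @param ... unused.
#' @return tibble with training size, epochs, first/final loss and parameter
#'   counts.
#' @export
glance.octdistill_fit <- function(x, ...) {
  tibble::tibble(
    n_images = x$n_images,
    epochs = nrow(x$history),
    first_loss = x$history$mean_loss[1],
    final_loss = x$history$mean_loss[nrow(x$history)],
    loss_ratio = x$history$mean_loss[nrow(x$history)] / x$history$mean_loss[1],
    teacher_params = unname(x$bundle$n_params["teacher"]),
    student_params = unname(x$bundle$n_params["student"])
  )
}

#' Tidy a curve result into its swept points
#'
#' @param x a `curve_result`.
#' @param ... unused.
#' @return the points tibble (`threshold` plus `fpr`/`tpr` or
#'   `recall`/`precision`).
#' @export
tidy.curve_result <- function(x, ...) x$points

#' One-row summary of a curve result
#'
#' @param x a `curve_result`.
#' @param ... unused.
#' @return tibble with curve type, area (AUC or AP) and point count.
#' @export
glance.curve_result <- function(x, ...) {
  tibble::tibble(type = x$type, area = x$area, n_points = nrow(x$points))
}

#' Tidy leave-one-out results into per-volume rows
#'
#' @param x an `octdistill_loo`.
#' @param ... unused.
#' @return the per-volume tibble.
#' @export
tidy.octdistill_loo <- function(x, ...) x$per_volume

#' One-row summary of leave-one-out PPV/NPV
#'
#' @param x an `octdistill_loo`.
#' @param ... unused.
#' @return tibble with PPV/NPV means, sds, missing counts and skipped folds.
#' @export
glance.octdistill_loo <- function(x, ...) {
  s <- x$summary
  tibble::tibble(
    ppv_mean = s$mean[s$metric == "ppv"], ppv_sd = s$sd[s$metric == "ppv"],
    npv_mean = s$mean[s$metric == "npv"], npv_sd = s$sd[s$metric == "npv"],
    n_missing_ppv = s$n_missing[s$metric == "ppv"],
    n_missing_npv = s$n_missing[s$metric == "npv"],
    n_volumes = s$n_volumes[1], n_skipped = length(x$skipped)
  )
}

#' Tidy severity results into per-slice rows
#'
#' @param x an `octdistill_severity`.
#' @param ... unused.
#' @return the records tibble.
#' @export
tidy.octdistill_severity <- function(x, ...) x$records

#' One-row summary of the severity association
#'
#' @param x an `octdistill_severity`.
#' @param ... unused.
#' @return tibble with Pearson r, Spearman rho, threshold and slice count.
#' @export
glance.octdistill_severity <- function(x, ...) {
  tibble::tibble(pearson = x$pearson, spearman = x$spearman,
                 threshold = x$threshold, n_slices = nrow(x$records))
}
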