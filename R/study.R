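## Study-condition dataset --------------------------------------------------

#' Simulate a labelled phantom study set
#'
#' Generates the desk-scale study conditions end to end: `n_normal` lesion-free
#' volumes plus `n_anomalous` volumes carrying injected lesions whose target
#' areas span a 16-fold range, mixing drusen-like bumps, hyporeflective fluid
#' pockets and layer-stack deformations. Each anomalous volume has one to
#' three lesioned slices. Fully deterministic given `seed`.
#'
#' @param n_normal,n_anomalous volume counts.
#' @param config a [phantom_config()] template; each volume gets its own
#'   derived seed.
#' @param seed integer master seed.
#' @param lesion_areas candidate lesion target areas (pixels squared).
#' @param prefix volume-id prefix.
#' @return list of `phantom_volume`s (normals first).
#' @export
simulate_study_set <- function(n_normal = 25L, n_anomalous = 25L,
                               config = phantom_config(),
                               seed = 1L,
                               lesion_areas = c(100, 200, 400, 800, 1600),
                               prefix = "vol") {
  n_normal <- assert_count(n_normal, "n_normal", min = 0L)
  n_anomalous <- assert_count(n_anomalous, "n_anomalous", min = 0L)
  h <- config$height; w <- config$width
  kinds <- c("bump", "fluid_pocket", "deformation")
  make_cfg <- function(i) {
    cfg <- config
    cfg$seed <- derive_seed(seed, paste0("volume", i))
    cfg
  }
  vols <- vector("list", n_normal + n_anomalous)
  for (i in seq_len(n_normal)) {
    vols[[i]] <- generate_volume(make_cfg(i), NULL,
                                 volume_id = sprintf("%s_norm_%03d", prefix, i))
  }
  for (j in seq_len(n_anomalous)) {
    i <- n_normal + j
    cfg <- make_cfg(i)
    specs <- with_local_seed(derive_seed(seed, paste0("lesions", i)), {
      sl <- rep(list(list()), cfg$n_bscans)
      n_lesioned <- sample(1:3, 1)
      lesioned <- sample.int(cfg$n_bscans, min(n_lesioned, cfg$n_bscans))
      for (s in lesioned) {
        kind <- sample(kinds, 1)
        area <- sample(lesion_areas, 1)
        center <- c(stats::runif(1, 0.35 * h, 0.65 * h),
                    stats::runif(1, 0.25 * w, 0.75 * w))
        shift <- switch(kind, bump = 0.3, fluid_pocket = -0.5, deformation = 0.2)
        sl[[s]] <- list(lesion_spec(kind, center, area, shift))
      }
      sl
    })
    vols[[i]] <- generate_volume(cfg, specs,
                                 volume_id = sprintf("%s_anom_%03d", prefix, j))
  }
  vols
}
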