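#' Phantom generator configuration
#'
#' Describes a synthetic layered-retina volume: image geometry, per-band
#' reflectivity, boundary smoothness, speckle noise concentration, and slice
#' count. The generator is a pure function of the configuration (including its
#' seed): identical configurations produce bit-identical volumes.
#'
#' @param height,width image size in pixels.
#' @param n_layers number of synthetic retinal bands.
#' @param layer_reflectivities per-band mean intensity in `[0, 1]`; defaults to
#'   an alternating dark/bright stack with a bright outermost band, the pattern
#'   hyperreflective and hyporeflective retinal layers show in OCT.
#' @param boundary_smoothness spatial correlation length (pixels) of the random
#'   layer-boundary perturbations.
#' @param speckle_shape concentration of the multiplicative gamma speckle noise
#'   (unit mean, variance `1/speckle_shape`); `Inf` disables noise.
#' @param n_bscans slices per volume.
#' @param seed integer seed; the generator derives all randomness from it.
#' @return an object of class `phantom_config`.
#' @export
phantom_config <- function(height = 64L, width = 64L, n_layers = 5L,
                           layer_reflectivities = NULL,
                           boundary_smoothness = 8, speckle_shape = 20,
                           n_bscans = 8L, seed = 1L) {
  height <- assert_count(height, "height")
  width <- assert_count(width, "width")
  n_layers <- assert_count(n_layers, "n_layers")
  n_bscans <- assert_count(n_bscans, "n_bscans")
  assert_scalar_num(boundary_smoothness, "boundary_smoothness", min = 0)
  if (!(is.numeric(speckle_shape) && length(speckle_shape) == 1L &&
        (is.infinite(speckle_shape) || speckle_shape > 0))) {
    abort_config("`speckle_shape` must be a positive real (Inf disables noise)")
  }
  if (is.null(layer_reflectivities)) {
    layer_reflectivities <- rep(c(0.6, 0.3), length.out = n_layers)
    layer_reflectivities[n_layers] <- 0.8  # bright RPE-like outer band
  }
  if (length(layer_reflectivities) != n_layers ||
      any(layer_reflectivities < 0 | layer_reflectivities > 1)) {
    abort_config("`layer_reflectivities` must have n_layers entries in [0, 1]")
  }
  structure(list(
    height = height, width = width, n_layers = n_layers,
    layer_reflectivities = as.numeric(layer_reflectivities),
    boundary_smoothness = as.numeric(boundary_smoothness),
    speckle_shape = as.numeric(speckle_shape),
    n_bscans = n_bscans, seed = as.integer(seed),
    background_intensity = 0.08
  ), class = "phantom_config")
}

#' Lesion specification
#'
#' Describes one injected lesion: a drusen-like boundary elevation (`bump`), a
#' hyporeflective fluid pocket (`fluid_pocket`, use a negative
#' `intensity_shift`), or a smooth warp of the whole layer stack
#' (`deformation`).
#'
#' @param kind one of `"bump"`, `"fluid_pocket"`, `"deformation"`.
#' @param center `(row, col)` lesion center in pixels, 0-based not required;
#'   1-based indices inside the image.
#' @param target_area intended lesion area in pixels squared; the realized mask
#'   area is within about 20% of this for interior placements (discretized
#'   shapes cannot hit it exactly).
#' @param intensity_shift signed intensity change in `[-1, 1]` applied inside
#'   the lesion.
#' @return an object of class `lesion_spec`.
#' @export
lesion_spec <- function(kind, center, target_area, intensity_shift = 0.3) {
  kind <- match.arg(kind, c("bump", "fluid_pocket", "deformation"))
  if (length(center) != 2L || any(!is.finite(center)) || any(center < 1)) {
    abort_config("`center` must be (row, col), both >= 1")
  }
  assert_scalar_num(target_area, "target_area", min = 0, strict = TRUE)
  if (abs(intensity_shift) > 1) abort_config("`intensity_shift` must be in [-1, 1]")
  structure(list(kind = kind, center = as.numeric(center),
                 target_area = as.numeric(target_area),
                 intensity_shift = as.numeric(intensity_shift)),
            class = "lesion_spec")
}

## Run expr with a private RNG stream; the caller's RNG state is untouched.
with_local_seed <- function(seed, expr) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

## Full boundary field for a volume: array (n_layers+1, n_bscans, width) of
## per-column row positions, strictly increasing across boundaries per column.
## Smooth along both the column axis (boundary_smoothness) and the slice axis,
## so neighboring B-scans share coherent geometry.
phantom_boundaries <- function(config) {
  h <- config$height; w <- config$width
  nb <- config$n_layers + 1L; ns <- config$n_bscans
  top <- 0.22 * h; bottom <- 0.78 * h
  base <- seq(top, bottom, length.out = nb)
  with_local_seed(derive_seed(config$seed, "boundaries"), {
    smooth_field <- function(amp, sigma_col) {
      f <- matrix(stats::rnorm(ns * w), ns, w)
      f <- t(apply(f, 1L, convolve_reflect, k = gaussian_kernel(max(sigma_col, 0.5))))
      if (ns > 1L) {
        f <- apply(f, 2L, convolve_reflect, k = gaussian_kernel(max(ns / 6, 0.5)))
        f <- matrix(f, ns, w)
      }
      s <- stats::sd(f)
      if (is.na(s) || s == 0) return(matrix(0, ns, w))
      ## saturate at 2 sd so rare excursions cannot push the retina out of
      ## frame (degenerate near-edge anatomy is not a valid normal phantom)
      2 * tanh(f / s / 2) * amp
    }
    ## shared tilt/curvature + a shallow foveal pit denting the inner
    ## boundaries down toward the outer retina
    shared <- smooth_field(0.05 * h, 2 * config$boundary_smoothness)
    dip <- 0.04 * h * exp(-((seq_len(w) - (w + 1) / 2)^2) / (2 * (w / 6)^2))
    bnd <- array(0, dim = c(nb, ns, w))
    for (b in seq_len(nb)) {
      own <- smooth_field(0.02 * h, config$boundary_smoothness)
      dip_w <- (nb - b) / (nb - 1)  # dip strongest at the inner (top) boundary
      bnd[b, , ] <- base[b] + shared + own + matrix(dip * dip_w, ns, w, byrow = TRUE)
    }
    ## enforce strict monotonicity and keep inside the image
    for (s in seq_len(ns)) {
      m <- bnd[, s, , drop = TRUE]
      if (is.null(dim(m))) m <- matrix(m, nb, w)
      for (b in 2:nb) m[b, ] <- pmax(m[b, ], m[b - 1L, ] + 1)
      m <- pmin(pmax(m, 2), h - 1)
      for (b in 2:nb) m[b, ] <- pmax(m[b, ], m[b - 1L, ] + 1e-6)
      bnd[, s, ] <- m
    }
    bnd
  })
}

## Band-label matrix: 0 = background above, 1..n_layers = bands,
## n_layers+1 = background below. boundaries: (n_layers+1) x width.
band_labels <- function(boundaries, height) {
  w <- ncol(boundaries)
  rows <- matrix(seq_len(height), height, w)
  lab <- matrix(0L, height, w)
  for (b in seq_len(nrow(boundaries))) {
    lab <- lab + (rows >= matrix(boundaries[b, ], height, w, byrow = TRUE))
  }
  lab
}

fill_from_labels <- function(labels, config) {
  pal <- c(config$background_intensity, config$layer_reflectivities,
           config$background_intensity)
  matrix(pal[labels + 1L], nrow(labels), ncol(labels))
}

apply_speckle <- function(img, shape, seed) {
  if (is.infinite(shape)) return(pmin(pmax(img, 0), 1))
  with_local_seed(seed, {
    fac <- matrix(stats::rgamma(length(img), shape = shape, rate = shape),
                  nrow(img), ncol(img))
    pmin(pmax(img * fac, 0), 1)
  })
}

#' Generate one normal (lesion-free) synthetic B-scan
#'
#' @param config a [phantom_config()].
#' @param slice_index 1-based slice position within the volume.
#' @return list with `image` (height x width matrix in `[0, 1]`) and
#'   `boundaries` ((n_layers + 1) x width matrix of per-column row positions,
#'   strictly increasing top to bottom in every column).
#' @export
generate_normal_bscan <- function(config, slice_index = 1L) {
  if (!inherits(config, "phantom_config")) abort_config("`config` must be a phantom_config")
  slice_index <- assert_count(slice_index, "slice_index")
  if (slice_index > config$n_bscans) abort_config("`slice_index` exceeds n_bscans")
  bnd <- phantom_boundaries(config)[, slice_index, , drop = TRUE]
  if (is.null(dim(bnd))) bnd <- matrix(bnd, config$n_layers + 1L, config$width)
  labels <- band_labels(bnd, config$height)
  img <- fill_from_labels(labels, config)
  img <- apply_speckle(img, config$speckle_shape,
                       derive_seed(config$seed, paste0("speckle", slice_index)))
  list(image = img, boundaries = bnd)
}

## ---- lesion injection -------------------------------------------------------

#' Inject a lesion into a B-scan
#'
#' @param image height x width intensity matrix in `[0, 1]`.
#' @param boundaries (n_layers + 1) x width boundary matrix for this slice.
#' @param spec a [lesion_spec()].
#' @param seed integer seed for the lesion's own texture noise.
#' @param config the [phantom_config()] the slice was generated with (used for
#'   reflectivities when refilling displaced bands).
#' @return list with `image` (modified) and `mask` (binary matrix of modified
#'   pixels).
#' @export
inject_lesion <- function(image, boundaries, spec, seed = 1L, config = NULL) {
  if (!inherits(spec, "lesion_spec")) abort_config("`spec` must be a lesion_spec")
  h <- nrow(image); w <- ncol(image)
  r0 <- spec$center[1]; c0 <- spec$center[2]
  if (r0 > h || c0 > w) abort_config("lesion center lies outside the image")
  out <- switch(spec$kind,
    bump = inject_bump(image, boundaries, spec, seed),
    fluid_pocket = inject_fluid(image, boundaries, spec, seed),
    deformation = inject_deformation(image, boundaries, spec, seed, config)
  )
  if (sum(out$mask) < 1) {
    stop("lesion placement failed: no pixels inside the band stack were modified",
         call. = FALSE)
  }
  out
}

## Drusen-like elevation: one boundary is displaced upward by a Gaussian bump
## and the opened region filled with bright reflective material.
inject_bump <- function(image, boundaries, spec, seed) {
  h <- nrow(image); w <- ncol(image)
  r0 <- spec$center[1]; c0 <- spec$center[2]
  b_idx <- which.min(abs(boundaries[, max(1L, min(w, round(c0)))] - r0))
  b <- boundaries[b_idx, ]
  ## Gaussian displacement with area A*sigma*sqrt(2*pi); aspect A = 1.6*sigma
  sigma <- sqrt(spec$target_area / (1.6 * sqrt(2 * pi)))
  A <- 1.6 * sigma
  d <- A * exp(-((seq_len(w) - c0)^2) / (2 * sigma^2))
  new_b <- pmax(b - d, 2)
  mask <- matrix(0L, h, w)
  for (cc in seq_len(w)) {
    lo <- ceiling(new_b[cc]); hi <- ceiling(b[cc]) - 1L
    if (lo <= hi) mask[lo:hi, cc] <- 1L
  }
  with_local_seed(seed, {
    idx <- which(mask == 1L)
    base_val <- 0.75 + abs(spec$intensity_shift) * 0.2
    image[idx] <- pmin(pmax(base_val + stats::rnorm(length(idx), sd = 0.03), 0), 1)
  })
  list(image = image, mask = mask)
}

## Hyporeflective ellipse (IRF/SRF-like) inside the band stack.
inject_fluid <- function(image, boundaries, spec, seed) {
  h <- nrow(image); w <- ncol(image)
  r0 <- spec$center[1]; c0 <- spec$center[2]
  ## semi-axes: twice as wide as tall, pi*a*b = target_area
  b_ax <- sqrt(spec$target_area / (2 * pi))
  a_ax <- 2 * b_ax
  rows <- matrix(seq_len(h), h, w)
  cols <- matrix(seq_len(w), h, w, byrow = TRUE)
  inside <- ((rows - r0) / b_ax)^2 + ((cols - c0) / a_ax)^2 <= 1
  ## restrict to the retinal band stack
  top <- matrix(boundaries[1L, ], h, w, byrow = TRUE)
  bot <- matrix(boundaries[nrow(boundaries), ], h, w, byrow = TRUE)
  stack <- rows >= top & rows < bot
  mask <- matrix(as.integer(inside & stack), h, w)
  if (sum(mask) == 0L) {
    stop("lesion placement failed: fluid pocket lies entirely outside the band stack",
         call. = FALSE)
  }
  idx <- which(mask == 1L)
  with_local_seed(seed, {
    shifted <- image[idx] + spec$intensity_shift +
      stats::rnorm(length(idx), sd = 0.01)
    image[idx] <- pmin(pmax(shifted, 0.005), 1)
  })
  list(image = image, mask = mask)
}

## Smooth vertical warp of the whole boundary stack near the center; the mask
## is the set of pixels whose band assignment changed.
inject_deformation <- function(image, boundaries, spec, seed, config) {
  h <- nrow(image); w <- ncol(image)
  r0 <- spec$center[1]; c0 <- spec$center[2]
  nb <- nrow(boundaries)
  sigma_c <- max(3, w / 8)
  sigma_r <- max(3, h / 4)
  wgt <- exp(-((rowMeans(boundaries) - r0)^2) / (2 * sigma_r^2))
  ## total displaced pixels ~ sum_b w_b * A * sigma_c * sqrt(2*pi)
  A <- spec$target_area / (sum(wgt) * sigma_c * sqrt(2 * pi))
  d <- A * exp(-((seq_len(w) - c0)^2) / (2 * sigma_c^2))
  new_bnd <- boundaries - outer(wgt, d)
  new_bnd <- pmin(pmax(new_bnd, 2), h - 1)
  for (b in 2:nb) new_bnd[b, ] <- pmax(new_bnd[b, ], new_bnd[b - 1L, ] + 1e-6)
  old_lab <- band_labels(boundaries, h)
  new_lab <- band_labels(new_bnd, h)
  mask <- matrix(as.integer(old_lab != new_lab), h, w)
  if (sum(mask) == 0L) {
    stop("lesion placement failed: deformation displaced no pixels", call. = FALSE)
  }
  bg <- if (is.null(config)) 0.08 else config$background_intensity
  refl <- if (is.null(config)) rep(0.5, nb - 1L) else config$layer_reflectivities
  pal <- c(bg, refl, bg)
  idx <- which(mask == 1L)
  with_local_seed(seed, {
    vals <- pal[new_lab[idx] + 1L] + spec$intensity_shift * 0.5 +
      stats::rnorm(length(idx), sd = 0.02)
    image[idx] <- pmin(pmax(vals, 0), 1)
  })
  list(image = image, mask = mask)
}

## ---- volumes ----------------------------------------------------------------

#' Generate a synthetic OCT volume
#'
#' Slices share smoothly varying boundary geometry along the slice axis.
#' Lesions are injected per slice according to `lesion_specs`; the volume label
#' is `"anomalous"` iff any mask has a positive pixel.
#'
#' @param config a [phantom_config()].
#' @param lesion_specs either `NULL` (all slices normal) or a list of length
#'   `n_bscans`, each element a (possibly empty) list of [lesion_spec()]s.
#' @param volume_id identifier carried into tables and manifests.
#' @return an object of class `phantom_volume`: `images`, `masks` (lists of
#'   matrices), `boundaries`, `lesion_areas` (tibble), `label`, `config`.
#' @export
generate_volume <- function(config, lesion_specs = NULL, volume_id = "vol_001") {
  if (!inherits(config, "phantom_config")) abort_config("`config` must be a phantom_config")
  ns <- config$n_bscans
  if (is.null(lesion_specs)) lesion_specs <- rep(list(list()), ns)
  if (length(lesion_specs) != ns) {
    abort_config("`lesion_specs` must have one (possibly empty) list per B-scan")
  }
  bnd <- phantom_boundaries(config)
  images <- vector("list", ns); masks <- vector("list", ns)
  for (s in seq_len(ns)) {
    slice_bnd <- bnd[, s, , drop = TRUE]
    if (is.null(dim(slice_bnd))) slice_bnd <- matrix(slice_bnd, config$n_layers + 1L, config$width)
    labels <- band_labels(slice_bnd, config$height)
    img <- fill_from_labels(labels, config)
    img <- apply_speckle(img, config$speckle_shape,
                         derive_seed(config$seed, paste0("speckle", s)))
    mask <- matrix(0L, config$height, config$width)
    specs <- lesion_specs[[s]]
    for (j in seq_along(specs)) {
      res <- inject_lesion(img, slice_bnd, specs[[j]],
                           seed = derive_seed(config$seed, paste0("lesion", s, "_", j)),
                           config = config)
      img <- res$image
      mask <- pmax(mask, res$mask)
    }
    images[[s]] <- img
    masks[[s]] <- mask
  }
  areas <- vapply(masks, function(m) sum(m > 0), numeric(1))
  lesion_areas <- tibble::tibble(
    volume_id = volume_id,
    slice_index = seq_len(ns),
    lesion_area_px = areas,
    relative_lesion_area = areas / (config$height * config$width)
  )
  structure(list(
    images = images, masks = masks, boundaries = bnd,
    lesion_areas = lesion_areas,
    label = if (all(areas == 0)) "normal" else "anomalous",
    volume_id = volume_id, config = config
  ), class = "phantom_volume")
}

#' @export
print.phantom_volume <- function(x, ...) {
  cat(sprintf("<phantom_volume> %s: %d B-scans of %dx%d, label = %s, total lesion area = %d px\n",
              x$volume_id, length(x$images), x$config$height, x$config$width,
              x$label, as.integer(sum(x$lesion_areas$lesion_area_px))))
  invisible(x)
}

## ---- disk I/O ---------------------------------------------------------------

#' Write phantom volumes to disk
#'
#' Each volume becomes a subdirectory of per-slice images and masks, plus a CSV
#' manifest. 8-bit depth uses PNG; 16-bit depth uses 16-bit TIFF (round-trip
#' error at most 1/65535). Masks are always written losslessly as binary PNG.
#'
#' @param volumes a `phantom_volume` or list of them.
#' @param out_dir output directory (created if missing).
#' @param depth `"8"` or `"16"` bits per image sample.
#' @return the manifest tibble (columns `volume_id`, `slice_index`, `label`,
#'   `volume_label`, `lesion_area_px`, `relative_lesion_area`, `image_path`,
#'   `mask_path`), also written to `out_dir/manifest.csv`.
#' @export
write_dataset <- function(volumes, out_dir, depth = c("8", "16")) {
  depth <- match.arg(depth)
  if (inherits(volumes, "phantom_volume")) volumes <- list(volumes)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(out_dir)) stop("cannot create output directory: ", out_dir, call. = FALSE)
  rows <- purrr::map(volumes, function(v) {
    vdir <- file.path(out_dir, v$volume_id)
    dir.create(vdir, showWarnings = FALSE)
    if (!dir.exists(vdir)) stop("cannot create volume directory: ", vdir, call. = FALSE)
    ext <- if (depth == "8") "png" else "tiff"
    purrr::map(seq_along(v$images), function(s) {
      ipath <- file.path(vdir, sprintf("slice_%03d.%s", s, ext))
      mpath <- file.path(vdir, sprintf("mask_%03d.png", s))
      img <- pmin(pmax(v$images[[s]], 0), 1)
      if (depth == "8") {
        png::writePNG(img, ipath)
      } else {
        tiff::writeTIFF(img, ipath, bits.per.sample = 16L, compression = "none")
      }
      png::writePNG(matrix(as.numeric(v$masks[[s]] > 0), nrow(img), ncol(img)), mpath)
      tibble::tibble(
        volume_id = v$volume_id, slice_index = s,
        label = ifelse(v$lesion_areas$lesion_area_px[s] > 0, "anomalous", "normal"),
        volume_label = v$label,
        lesion_area_px = v$lesion_areas$lesion_area_px[s],
        relative_lesion_area = v$lesion_areas$relative_lesion_area[s],
        image_path = file.path(v$volume_id, basename(ipath)),
        mask_path = file.path(v$volume_id, basename(mpath))
      )
    }) |> dplyr::bind_rows()
  })
  manifest <- dplyr::bind_rows(rows)
  readr::write_csv(manifest, file.path(out_dir, "manifest.csv"))
  manifest
}

#' Read a phantom dataset back from disk
#'
#' @param dir dataset directory containing `manifest.csv`.
#' @return list with `manifest` (tibble) and `volumes`: per volume a list of
#'   `images` and `masks` matrices in manifest order.
#' @export
read_dataset <- function(dir) {
  mf <- file.path(dir, "manifest.csv")
  if (!file.exists(mf)) stop("no manifest.csv in ", dir, call. = FALSE)
  manifest <- readr::read_csv(mf, show_col_types = FALSE)
  read_img <- function(p) {
    full <- file.path(dir, p)
    if (grepl("\\.png$", p)) png::readPNG(full) else tiff::readTIFF(full)
  }
  vols <- manifest |>
    dplyr::group_by(.data$volume_id) |>
    dplyr::group_map(function(g, key) {
      g <- dplyr::arrange(g, .data$slice_index)
      list(
        volume_id = key$volume_id[[1]],
        label = g$volume_label[[1]],
        images = purrr::map(g$image_path, read_img),
        masks = purrr::map(g$mask_path, function(p) {
          m <- read_img(p); matrix(as.integer(m > 0.5), nrow(m), ncol(m))
        }),
        slice_labels = g$label,
        lesion_area_px = g$lesion_area_px
      )
    })
  names(vols) <- vapply(vols, `[[`, character(1), "volume_id")
  list(manifest = manifest, volumes = vols)
}
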