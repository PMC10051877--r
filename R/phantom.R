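# Phantom generator: axial T2-weighted-like prostate slices built from
# ellipse composites (dark background, mid-bright body, mid-intensity
# prostate with a hyperintense peripheral rim, hyperintense bladder,
# optional hypointense lesion), plus degenerate variants and simulated
# rater responses.  Every downstream stage is testable on these without any
# external data.

#' Phantom generation parameters
#'
#' Geometry is expressed as fractions of the image side so behaviour is
#' size-invariant.  Defaults target desk-scale work (128 px; 500 works too).
#'
#' @param image_size pixels per side (>= 32).
#' @param prostate_radius_range sampled prostate radius, as a fraction of the
#'   image side; both ends in (0, 0.5), low < high.
#' @param pz_rim_thickness peripheral-zone rim thickness as a fraction of the
#'   prostate radius.
#' @param lesion_probability probability that a slice carries a hypointense
#'   lesion.
#' @param lesion_contrast intensity drop of the lesion below prostate tissue,
#'   in `[0, 1]` units.
#' @param noise_sd standard deviation of additive Gaussian noise.
#' @param bias_field_amplitude amplitude of the smooth low-order polynomial
#'   bias field added to the image.
#' @param seed optional default seed used when generation functions are not
#'   given one explicitly.
#' @return an object of class `phantom_params`.
#' @examples
#' p <- phantom_params(image_size = 64, lesion_probability = 0)
#' s <- generate_phantom_slice(p, seed = 1)
#' range(s$image)
#' @export
phantom_params <- function(image_size = 128L,
                           prostate_radius_range = c(0.12, 0.22),
                           pz_rim_thickness = 0.25,
                           lesion_probability = 0.3,
                           lesion_contrast = 0.25,
                           noise_sd = 0.03,
                           bias_field_amplitude = 0.05,
                           seed = NULL) {
  image_size <- as.integer(image_size)
  if (image_size < 32L) stop("image_size must be at least 32")
  r <- prostate_radius_range
  if (length(r) != 2 || r[1] >= r[2] || any(r <= 0) || any(r >= 0.5))
    stop("prostate_radius_range must satisfy 0 < low < high < 0.5")
  if (pz_rim_thickness < 0 || pz_rim_thickness >= 1)
    stop("pz_rim_thickness must be in [0, 1)")
  if (lesion_probability < 0 || lesion_probability > 1)
    stop("lesion_probability must be in [0, 1]")
  if (lesion_contrast < 0 || lesion_contrast > 1)
    stop("lesion_contrast must be in [0, 1]")
  if (noise_sd < 0) stop("noise_sd must be non-negative")
  if (bias_field_amplitude < 0 || bias_field_amplitude > 1)
    stop("bias_field_amplitude must be in [0, 1]")
  structure(list(image_size = image_size,
                 prostate_radius_range = r,
                 pz_rim_thickness = pz_rim_thickness,
                 lesion_probability = lesion_probability,
                 lesion_contrast = lesion_contrast,
                 noise_sd = noise_sd,
                 bias_field_amplitude = bias_field_amplitude,
                 seed = seed),
            class = "phantom_params")
}

#' @export
print.phantom_params <- function(x, ...) {
  cat("Phantom parameters:", x$image_size, "x", x$image_size, "px\n")
  cat("  prostate radius", paste(x$prostate_radius_range, collapse = "-"),
      "| rim", x$pz_rim_thickness, "| lesion p =", x$lesion_probability,
      "(contrast", x$lesion_contrast, ")\n")
  cat("  noise sd", x$noise_sd, "| bias amplitude", x$bias_field_amplitude, "\n")
  invisible(x)
}

# Filled ellipse indicator on an S x S grid (row = y, col = x).
ellipse_mask <- function(S, cy, cx, ry, rx) {
  y <- matrix(seq_len(S), S, S)
  x <- t(y)
  ((y - cy) / ry)^2 + ((x - cx) / rx)^2 <= 1
}

# Radial coordinate relative to an ellipse (1 on the boundary).
ellipse_r <- function(S, cy, cx, ry, rx) {
  y <- matrix(seq_len(S), S, S)
  x <- t(y)
  sqrt(((y - cy) / ry)^2 + ((x - cx) / rx)^2)
}

# Tissue intensity levels (piecewise-constant construction before noise/bias).
PHANTOM_LEVELS <- list(background = 0.05, body = 0.35, prostate = 0.5,
                       rim = 0.75, bladder = 0.85)

# Draws the anatomy given already-sampled geometry; returns image + mask.
draw_phantom <- function(params, geo, rscale = 1, with_prostate = TRUE,
                         lesion = FALSE) {
  S <- params$image_size
  lv <- PHANTOM_LEVELS
  img <- matrix(lv$background, S, S)
  img[ellipse_mask(S, S * 0.52, S * 0.5, S * 0.40, S * 0.46)] <- lv$body
  img[ellipse_mask(S, geo$bl_cy, geo$bl_cx, geo$bl_ry, geo$bl_rx)] <- lv$bladder
  mask <- matrix(0, S, S)
  if (with_prostate && rscale > 0) {
    ry <- geo$ry * rscale
    rx <- geo$rx * rscale
    er <- ellipse_r(S, geo$cy, geo$cx, ry, rx)
    inside <- er <= 1
    if (any(inside)) {
      img[inside] <- lv$prostate
      img[inside & er > (1 - params$pz_rim_thickness)] <- lv$rim
      if (lesion) {
        lrad_y <- geo$les_frac * ry
        lrad_x <- geo$les_frac * rx
        inner <- 1 - params$pz_rim_thickness - geo$les_frac
        lcy <- geo$cy + geo$les_off[1] * inner * ry
        lcx <- geo$cx + geo$les_off[2] * inner * rx
        les <- ellipse_mask(S, lcy, lcx, lrad_y, lrad_x)
        img[les] <- max(lv$prostate - params$lesion_contrast, 0)
      }
      mask[inside] <- 1
    }
  }
  list(image = img, mask = mask)
}

sample_geometry <- function(params) {
  S <- params$image_size
  r <- stats::runif(1, params$prostate_radius_range[1],
                    params$prostate_radius_range[2]) * S
  aspect <- stats::runif(1, 0.8, 1.25)
  # area-preserving aspect: pi * ry * rx = pi * r^2 exactly
  list(cy = S * (0.58 + stats::runif(1, -0.03, 0.03)),
       cx = S * (0.5 + stats::runif(1, -0.03, 0.03)),
       ry = r / sqrt(aspect), rx = r * sqrt(aspect), r = r,
       bl_cy = S * 0.32, bl_cx = S * (0.5 + stats::runif(1, -0.02, 0.02)),
       bl_ry = S * stats::runif(1, 0.08, 0.12),
       bl_rx = S * stats::runif(1, 0.10, 0.15),
       les_frac = stats::runif(1, 0.18, 0.3),
       les_off = stats::runif(2, -1, 1))
}

bias_field <- function(params) {
  S <- params$image_size
  u <- matrix(seq(-1, 1, length.out = S), S, S)
  v <- t(u)
  cf <- stats::runif(5, -1, 1)
  params$bias_field_amplitude *
    (cf[1] * u + cf[2] * v + cf[3] * u * v + cf[4] * u^2 + cf[5] * v^2)
}

finish_phantom <- function(img, params) {
  img <- img + bias_field(params)
  if (params$noise_sd > 0)
    img <- img + matrix(stats::rnorm(length(img), sd = params$noise_sd),
                        nrow(img))
  clamp01(img)
}

#' Generate one phantom prostate slice
#'
#' Builds a piecewise-constant anatomy (background, body, bladder, prostate
#' with hyperintense peripheral rim, optional hypointense lesion strictly
#' inside the gland), then adds a smooth bias field and Gaussian noise and
#' clamps to `[0, 1]`.  The returned mask is the filled prostate ellipse
#' before noise.  Output is bit-identical for identical `(params, seed)`.
#'
#' @param params a [phantom_params()] object.
#' @param seed integer seed (falls back to `params$seed`).
#' @return list with `image` (matrix in `[0, 1]`), `mask` (binary matrix) and
#'   `tumor` (logical lesion flag); also records the sampled prostate radius
#'   as attribute `"radius_px"` on the mask.
#' @export
generate_phantom_slice <- function(params, seed = params$seed) {
  stopifnot(inherits(params, "phantom_params"))
  with_seed(seed, {
    geo <- sample_geometry(params)
    tumor <- stats::runif(1) < params$lesion_probability
    dr <- draw_phantom(params, geo, lesion = tumor)
    img <- finish_phantom(dr$image, params)
    attr(dr$mask, "radius_px") <- geo$r
    list(image = img, mask = dr$mask, tumor = tumor)
  })
}

#' Generate a phantom volume with contour ground truth
#'
#' Stacks `n_slices` slices sharing one anatomy whose prostate cross-section
#' follows a smooth elliptic profile peaking at the middle slice; the first
#' and last slices may have empty contours.  Deterministic given
#' `(params, n_slices, seed)`.
#'
#' @param params a [phantom_params()] object.
#' @param n_slices number of z slices (>= 3).
#' @param seed integer seed.
#' @return object of class `phantom_volume`: `slices` and `contours` (lists of
#'   matrices), `lesion_labels` (logical per slice), `params`, `seed`.
#' @export
generate_phantom_volume <- function(params, n_slices = 9L, seed = params$seed) {
  stopifnot(inherits(params, "phantom_params"))
  n_slices <- as.integer(n_slices)
  if (n_slices < 3L) stop("n_slices must be at least 3 (middle slice undefined)")
  with_seed(seed, {
    geo <- sample_geometry(params)
    tumor <- stats::runif(1) < params$lesion_probability
    zc <- (n_slices + 1) / 2
    zr <- (n_slices - 1) / 2 + 0.25
    slices <- vector("list", n_slices)
    contours <- vector("list", n_slices)
    lesion_labels <- logical(n_slices)
    for (z in seq_len(n_slices)) {
      prof <- 1 - ((z - zc) / zr)^2
      rscale <- if (prof > 0) sqrt(prof) else 0
      has_lesion <- tumor && rscale > 0.6
      dr <- draw_phantom(params, geo, rscale = rscale,
                         with_prostate = rscale * geo$r >= 2,
                         lesion = has_lesion)
      slices[[z]] <- finish_phantom(dr$image, params)
      contours[[z]] <- dr$mask
      lesion_labels[z] <- has_lesion
    }
    structure(list(slices = slices, contours = contours,
                   lesion_labels = lesion_labels, params = params,
                   n_slices = n_slices, seed = seed),
              class = "phantom_volume")
  })
}

#' @export
print.phantom_volume <- function(x, ...) {
  areas <- vapply(x$contours, sum, numeric(1))
  cat("Phantom volume:", x$n_slices, "slices of",
      x$params$image_size, "x", x$params$image_size, "px\n")
  cat("  contour areas:", paste(areas, collapse = " "), "\n")
  cat("  lesion slices:", sum(x$lesion_labels), "\n")
  invisible(x)
}

#' Generate a degenerate phantom image
#'
#' Fixtures for the failure modes the quality gate must reject:
#' `no_prostate` omits the gland entirely; `fragmented` replaces it with
#' three disjoint blobs, each smaller than the gate's 4% area threshold;
#' `blurred` applies heavy smoothing and contrast collapse to a normal slice.
#'
#' @param kind one of `"no_prostate"`, `"fragmented"`, `"blurred"`.
#' @param params a [phantom_params()] object.
#' @param seed integer seed.
#' @return list with `image`, `mask` (ground truth: empty, the fragmented
#'   blobs, or the pre-blur prostate) and `kind`.
#' @export
generate_degenerate_image <- function(kind = c("no_prostate", "fragmented",
                                               "blurred"),
                                      params, seed = params$seed) {
  kind <- match.arg(kind)
  stopifnot(inherits(params, "phantom_params"))
  S <- params$image_size
  with_seed(seed, {
    geo <- sample_geometry(params)
    if (kind == "no_prostate") {
      dr <- draw_phantom(params, geo, with_prostate = FALSE)
      img <- finish_phantom(dr$image, params)
      return(list(image = img, mask = dr$mask, kind = kind))
    }
    if (kind == "fragmented") {
      dr <- draw_phantom(params, geo, with_prostate = FALSE)
      img <- dr$image
      mask <- dr$mask
      # three blobs, each well below 4% of the image area (r = 0.055 S
      # gives ~0.95% each), spread around the gland position
      rb <- 0.055 * S
      offs <- list(c(-0.13, -0.12), c(-0.02, 0.14), c(0.13, -0.04))
      for (o in offs) {
        bl <- ellipse_mask(S, geo$cy + o[1] * S, geo$cx + o[2] * S, rb, rb)
        img[bl] <- PHANTOM_LEVELS$prostate
        mask[bl] <- 1
      }
      img <- finish_phantom(img, params)
      return(list(image = img, mask = mask, kind = kind))
    }
    # blurred: normal anatomy, heavy smoothing + contrast collapse
    tumor <- stats::runif(1) < params$lesion_probability
    dr <- draw_phantom(params, geo, lesion = tumor)
    img <- finish_phantom(dr$image, params)
    img <- EBImage::imageData(EBImage::gblur(EBImage::Image(img),
                                             sigma = S / 8))
    dim(img) <- c(S, S)
    img <- clamp01(0.45 + 0.08 * (img - mean(img)))
    list(image = img, mask = dr$mask, kind = kind)
  })
}

#' Simulate blinded rater responses
#'
#' Each rater answers each image independently and is correct with
#' probability equal to that rater's accuracy; wrong answers flip the class.
#' Serves as the Monte-Carlo oracle for the study-scoring functions.
#'
#' @param truth character vector of true classes, `"conventional"` or
#'   `"synthetic"` (one per image).
#' @param per_rater_accuracy numeric vector of per-rater accuracies in
#'   `[0, 1]`.
#' @param seed integer seed.
#' @param groups experience group per rater (recycled); defaults to one
#'   `"ten_year"` group.
#' @param image_ids optional image identifiers.
#' @return a `study_table` data frame with columns `rater_id`, `group`,
#'   `image_id`, `true_class`, `answer`.
#' @export
simulate_raters <- function(truth, per_rater_accuracy, seed = NULL,
                            groups = "ten_year", image_ids = NULL) {
  if (length(truth) == 0) stop("truth must be non-empty")
  truth <- as.character(truth)
  if (!all(truth %in% c("conventional", "synthetic")))
    stop("truth values must be 'conventional' or 'synthetic'")
  acc <- as.numeric(per_rater_accuracy)
  if (length(acc) == 0 || any(acc < 0 | acc > 1))
    stop("per_rater_accuracy values must be in [0, 1]")
  groups <- rep_len(as.character(groups), length(acc))
  if (is.null(image_ids)) image_ids <- sprintf("img%03d", seq_along(truth))
  with_seed(seed, {
    rows <- lapply(seq_along(acc), function(r) {
      correct <- stats::runif(length(truth)) < acc[r]
      flip <- c(conventional = "synthetic", synthetic = "conventional")
      data.frame(rater_id = sprintf("rater%02d", r), group = groups[r],
                 image_id = image_ids, true_class = truth,
                 answer = ifelse(correct, truth, flip[truth]),
                 stringsAsFactors = FALSE)
    })
    tab <- do.call(rbind, rows)
    rownames(tab) <- NULL
    class(tab) <- c("study_table", "data.frame")
    tab
  })
}

#' Export a phantom cohort to disk
#'
#' Writes per-volume NRRD image/mask pairs on the same grid plus a
#' `manifest.csv` (volume id, slice count, tumor flags).
#'
#' @param n number of volumes.
#' @param params a [phantom_params()] object.
#' @param n_slices slices per volume.
#' @param seed integer seed; per-volume seeds are derived from it.
#' @param dir output directory (created if needed).
#' @return the manifest data frame, invisibly.
#' @export
export_phantom_cohort <- function(n, params, n_slices = 9L, seed = 1L,
                                  dir = ".") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  man <- lapply(seq_len(n), function(i) {
    vol <- generate_phantom_volume(params, n_slices,
                                   seed = derive_seed(seed, paste0("vol", i)))
    id <- sprintf("vol%03d", i)
    img <- simplify2array(vol$slices)
    msk <- simplify2array(vol$contours)
    write_nrrd(img, file.path(dir, paste0(id, "_image.nrrd")))
    write_nrrd(msk, file.path(dir, paste0(id, "_mask.nrrd")))
    data.frame(volume_id = id, n_slices = n_slices,
               tumor = any(vol$lesion_labels),
               tumor_slices = paste(which(vol$lesion_labels), collapse = ";"),
               stringsAsFactors = FALSE)
  })
  man <- do.call(rbind, man)
  utils::write.csv(man, file.path(dir, "manifest.csv"), row.names = FALSE)
  invisible(man)
}
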