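# Preprocessing: volume-wide min-max intensity normalization, centered
# proportional square crop + resize, and the slice-selection rules used to
# pick GAN training slices and segmentation training pairs.

#' Normalize volume intensities to [0, 1]
#'
#' Min-max normalization over the whole volume: the global minimum maps to 0
#' and the global maximum to 1, preserving inter-slice contrast.  A constant
#' volume maps to all zeros with a warning.
#'
#' @param volume numeric array (any dimensionality), finite values.
#' @return array of the same shape with values in `[0, 1]`.
#' @export
normalize_intensity <- function(volume) {
  if (length(volume) == 0) stop("volume must be non-empty")
  if (!all(is.finite(volume))) stop("volume must contain only finite values")
  lo <- min(volume)
  hi <- max(volume)
  if (hi == lo) {
    warning("constant volume: normalizing to all zeros")
    return(volume * 0)
  }
  (volume - lo) / (hi - lo)
}

#' Center-crop to a square and resize
#'
#' Crops to the centered square of side `min(h, w)` then resizes to
#' `target_size` x `target_size`: bilinear interpolation for images,
#' nearest-neighbour for masks (so masks stay strictly binary).
#'
#' @param img numeric matrix (image in `[0, 1]` or binary mask).
#' @param target_size output side length in pixels (>= 8).
#' @param kind `"image"` (bilinear) or `"mask"` (nearest).
#' @return a `target_size` x `target_size` matrix.
#' @export
crop_square_resize <- function(img, target_size, kind = c("image", "mask")) {
  kind <- match.arg(kind)
  if (!is.matrix(img)) stop("img must be a matrix")
  if (target_size < 8) stop("target_size must be at least 8")
  h <- nrow(img)
  w <- ncol(img)
  if (min(h, w) < 2) stop("image must be at least 2 pixels per side")
  side <- min(h, w)
  r0 <- (h - side) %/% 2
  c0 <- (w - side) %/% 2
  sq <- img[(r0 + 1):(r0 + side), (c0 + 1):(c0 + side), drop = FALSE]
  if (kind == "mask") stop_if_not_mask(sq, "mask input")
  out <- resize_matrix(sq, target_size, target_size,
                       method = if (kind == "image") "bilinear" else "nearest")
  if (kind == "mask") out <- (out > 0.5) + 0
  out
}

contour_areas <- function(volume) {
  stopifnot(inherits(volume, "phantom_volume") || is.list(volume))
  contours <- if (inherits(volume, "phantom_volume")) volume$contours
              else volume
  vapply(contours, sum, numeric(1))
}

#' Select the slice with the largest prostate contour
#'
#' Returns the (1-based) z index whose contour has the largest area; ties
#' break to the lowest index.  This is the slice used to train the
#' single-image GAN for a volume.
#'
#' @param volume a `phantom_volume` (or plain list of contour masks).
#' @return integer z index.
#' @export
select_largest_prostate_slice <- function(volume) {
  areas <- contour_areas(volume)
  if (all(areas == 0)) stop("all contours are empty")
  which.max(areas)
}

#' Middle contoured slices of a volume
#'
#' Let Z be the sorted indices of slices with non-empty contours and m the
#' median position in Z (lower median for even counts); returns the `k`
#' consecutive members of Z centred on m.  With `k = 3` and 45 volumes this
#' yields the 135 training pairs used by the segmenter.
#'
#' @param volume a `phantom_volume` (or plain list of contour masks).
#' @param k number of slices to return (default 3).
#' @return integer vector of `k` z indices (1-based).
#' @export
middle_contour_slices <- function(volume, k = 3L) {
  areas <- contour_areas(volume)
  z <- which(areas > 0)
  if (length(z) < k)
    stop("need at least ", k, " contoured slices, found ", length(z))
  m <- (length(z) + 1L) %/% 2L
  start <- m - (k - 1L) %/% 2L
  start <- min(max(start, 1L), length(z) - k + 1L)
  z[start:(start + k - 1L)]
}

#' Build segmentation training pairs from phantom volumes
#'
#' Extracts the `k` middle contoured slices of each volume as
#' (image, contour) pairs, optionally cropped/resized to `target_size`.
#'
#' @param volumes list of `phantom_volume` objects.
#' @param k middle slices per volume.
#' @param target_size optional output side; `NULL` keeps native size.
#' @return list of pairs, each `list(image =, mask =, volume =, z =)`.
#' @export
training_pairs <- function(volumes, k = 3L, target_size = NULL) {
  pairs <- list()
  for (vi in seq_along(volumes)) {
    vol <- volumes[[vi]]
    for (z in middle_contour_slices(vol, k)) {
      img <- vol$slices[[z]]
      msk <- vol$contours[[z]]
      if (!is.null(target_size)) {
        img <- crop_square_resize(img, target_size, "image")
        msk <- crop_square_resize(msk, target_size, "mask")
      }
      pairs[[length(pairs) + 1L]] <- list(image = img, mask = msk,
                                          volume = vi, z = z)
    }
  }
  pairs
}
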