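# Preprocessing chain: 3-D multi-modal volumes -> normalized 2-D network
# inputs.  A case is reduced to one axial slice per modality, center-cropped,
# Gaussian-denoised, z-scored and stacked in the fixed modality order
# [t1, t1ce, t2]; the paired label slice is cropped identically.

MODALITIES <- c("t1", "t1ce", "t2", "flair")
INPUT_ORDER <- c("t1", "t1ce", "t2")

#' Create a modality volume
#'
#' A light container for one 3-D MRI intensity volume.
#'
#' @param voxels 3-D numeric array (H x W x D).
#' @param modality one of `"t1"`, `"t1ce"`, `"t2"`, `"flair"`.
#' @param voxel_spacing numeric length-3 voxel spacing in mm.
#' @return an object of class `modality_volume`.
#' @export
modality_volume <- function(voxels, modality, voxel_spacing = c(1, 1, 1)) {
  stopifnot(length(dim(voxels)) == 3, all(dim(voxels) > 0))
  if (!all(is.finite(voxels))) stop("volume intensities must be finite")
  modality <- match.arg(modality, MODALITIES)
  structure(list(voxels = voxels, modality = modality,
                 voxel_spacing = as.numeric(voxel_spacing)),
            class = "modality_volume")
}

#' @export
print.modality_volume <- function(x, ...) {
  d <- dim(x$voxels)
  cat(sprintf("<modality_volume %s: %d x %d x %d, spacing %s mm>\n",
              x$modality, d[1], d[2], d[3],
              paste(x$voxel_spacing, collapse = "x")))
  invisible(x)
}

#' Default axial slice index for a volume of given depth
#'
#' For the standard 155-slice BraTS depth the 90th axial plane is used (the
#' plane where all tumor compartments are typically visible); for any other
#' depth the middle plane `floor(D/2)`.  Indices are 0-based.
#' @param depth number of axial slices D.
#' @return 0-based slice index.
#' @export
default_slice_index <- function(depth) {
  if (depth == 155L) 90L else as.integer(depth %/% 2)
}

#' Extract one axial plane from a modality volume
#'
#' @param volume a [modality_volume()] (or bare 3-D array).
#' @param index 0-based slice position; defaults to
#'   [default_slice_index()] of the volume depth.
#' @return 2-D intensity matrix with a `modality` attribute when the input
#'   carries one.
#' @export
extract_slice <- function(volume, index = NULL) {
  vox <- if (inherits(volume, "modality_volume")) volume$voxels else volume
  D <- dim(vox)[3]
  if (is.null(index)) index <- default_slice_index(D)
  index <- as.integer(index)
  if (index < 0L || index >= D)
    stop(sprintf("slice index %d out of range for volume depth %d", index, D))
  sl <- vox[, , index + 1L]
  if (inherits(volume, "modality_volume"))
    attr(sl, "modality") <- volume$modality
  sl
}

#' Center-crop a 2-D array
#'
#' Margins are split evenly; for an odd difference the extra pixel is removed
#' from the trailing side.
#'
#' @param slice2d 2-D array.
#' @param target side length of the square output (default 224).
#' @return `target x target` array.
#' @export
crop_center <- function(slice2d, target = 224L) {
  d <- dim(slice2d)
  target <- as.integer(target)
  if (d[1] < target || d[2] < target)
    stop(sprintf("crop target %d exceeds input size %d x %d",
                 target, d[1], d[2]))
  r0 <- (d[1] - target) %/% 2L
  c0 <- (d[2] - target) %/% 2L
  out <- slice2d[r0 + seq_len(target), c0 + seq_len(target), drop = FALSE]
  attr(out, "modality") <- attr(slice2d, "modality")
  out
}

#' Z-score normalize an image
#'
#' Subtracts the image mean and divides by its population standard deviation,
#' so the output has mean 0 and standard deviation 1.
#'
#' @param image numeric array with at least two distinct values.
#' @return array of the same shape.
#' @export
zscore_normalize <- function(image) {
  mu <- mean(image)
  sigma <- sqrt(mean((image - mu)^2))
  if (sigma == 0)
    stop("cannot z-score a constant image (zero standard deviation)")
  out <- (image - mu) / sigma
  attr(out, "modality") <- attr(image, "modality")
  out
}

gaussian_kernel_1d <- function(sigma, radius = ceiling(3 * sigma)) {
  k <- exp(-((-radius:radius)^2) / (2 * sigma^2))
  k / sum(k)
}

#' Gaussian denoising of a 2-D image
#'
#' Separable Gaussian blur with kernel radius `3*sigma`; near the borders the
#' truncated kernel is renormalized so constant regions are preserved exactly.
#'
#' @param image 2-D array.
#' @param sigma blur standard deviation in pixels; 0 returns the input.
#' @return blurred array of the same shape.
#' @export
gaussian_denoise <- function(image, sigma = 0.5) {
  if (sigma < 0) stop("sigma must be non-negative")
  if (sigma == 0) return(image)
  k <- gaussian_kernel_1d(sigma)
  r <- (length(k) - 1L) %/% 2L
  blur1 <- function(m) { # along rows (dim 1), edge-renormalized
    n <- nrow(m)
    out <- matrix(0, n, ncol(m))
    for (off in -r:r) {
      i <- seq_len(n)
      src <- i + off
      ok <- src >= 1 & src <= n
      out[i[ok], ] <- out[i[ok], ] + k[off + r + 1] * m[src[ok], ]
    }
    wsum <- numeric(n)
    for (off in -r:r) {
      src <- seq_len(n) + off
      ok <- src >= 1 & src <= n
      wsum[ok] <- wsum[ok] + k[off + r + 1]
    }
    # renormalize rows whose kernel support was cropped by the border
    sweep(out, 1, wsum, "/")
  }
  out <- t(blur1(t(blur1(image))))
  attr(out, "modality") <- attr(image, "modality")
  out
}

#' Stack the three input modalities into a network input
#'
#' Channels are stacked in the fixed order `[t1, t1ce, t2]`.  If the slices
#' carry a `modality` attribute (as produced by [extract_slice()]) it is
#' checked against the expected order.
#'
#' @param t1,t1ce,t2 2-D arrays of one common shape, already cropped,
#'   denoised and normalized.
#' @return `H x W x 3` array of class `multimodal_slice` with attributes
#'   `channel_order` and `normalized`.
#' @export
assemble_input <- function(t1, t1ce, t2) {
  slices <- list(t1 = t1, t1ce = t1ce, t2 = t2)
  d <- dim(t1)
  for (nm in names(slices)) {
    if (!identical(dim(slices[[nm]]), d))
      stop(sprintf("modality %s shape differs from t1; cannot align", nm))
    tag <- attr(slices[[nm]], "modality")
    if (!is.null(tag) && !identical(tag, nm))
      stop(sprintf("slice tagged '%s' passed where '%s' expected", tag, nm))
  }
  x <- array(0, c(d[1], d[2], 3))
  for (i in 1:3) x[, , i] <- slices[[i]]
  structure(x, channel_order = INPUT_ORDER, normalized = TRUE,
            class = "multimodal_slice")
}

#' Remap file-level segmentation codes to contiguous class labels
#'
#' BraTS label files code the enhancing tumor as 4; internally the classes
#' are the contiguous set 0 (background), 1 (necrotic core),
#' 2 (edema/non-enhancing), 3 (enhancing).
#' @param labels integer array with values in \{0, 1, 2, 4\}.
#' @return array with values in \{0, 1, 2, 3\}.
#' @export
remap_labels_from_file <- function(labels) {
  bad <- setdiff(unique(as.vector(labels)), c(0, 1, 2, 4))
  if (length(bad))
    stop("unexpected label values: ", paste(bad, collapse = ", "))
  labels[labels == 4] <- 3
  labels
}

#' @rdname remap_labels_from_file
#' @export
remap_labels_to_file <- function(labels) {
  bad <- setdiff(unique(as.vector(labels)), 0:3)
  if (length(bad))
    stop("unexpected internal label values: ", paste(bad, collapse = ", "))
  labels[labels == 3] <- 4
  labels
}

#' Preprocess one multi-modal case into a training pair
#'
#' Runs the full chain on a case: extract the axial slice from each modality,
#' center-crop, Gaussian-denoise, z-score, stack `[t1, t1ce, t2]`; the label
#' volume (if present) is sliced and cropped identically and remapped to
#' internal classes.
#'
#' @param case list with elements `t1`, `t1ce`, `t2` (and optionally `flair`,
#'   unused as a network channel) of class [modality_volume()], plus
#'   optionally `seg`, an integer label volume (3-D array).
#' @param slice_index 0-based axial index; default per
#'   [default_slice_index()].
#' @param sigma Gaussian denoising standard deviation in pixels.
#' @param target crop side length.
#' @return list with `x` (a `multimodal_slice`) and `y` (an integer label
#'   matrix, or NULL when the case has no segmentation).
#' @export
preprocess_case <- function(case, slice_index = NULL, sigma = 0.5,
                            target = 224L) {
  chans <- lapply(INPUT_ORDER, function(m) {
    if (is.null(case[[m]])) stop("case is missing modality ", m)
    sl <- crop_center(extract_slice(case[[m]], slice_index), target)
    zscore_normalize(gaussian_denoise(sl, sigma))
  })
  x <- assemble_input(chans[[1]], chans[[2]], chans[[3]])
  y <- NULL
  if (!is.null(case$seg)) {
    seg <- case$seg
    if (inherits(seg, "modality_volume")) seg <- seg$voxels
    ysl <- crop_center(extract_slice(seg, slice_index), target)
    y <- remap_labels_from_file(round(ysl))
    storage.mode(y) <- "integer"
  }
  list(x = x, y = y)
}

# ---- augmentation ----------------------------------------------------------

flip_h <- function(m) m[, rev(seq_len(ncol(m))), drop = FALSE]
flip_v <- function(m) m[rev(seq_len(nrow(m))), , drop = FALSE]
rot90k <- function(m, k) {
  k <- k %% 4
  for (i in seq_len(k)) m <- t(m)[, rev(seq_len(nrow(m))), drop = FALSE]
  m
}
translate2d <- function(m, dh, dw, fill = 0) {
  out <- matrix(fill, nrow(m), ncol(m))
  src_r <- seq_len(nrow(m)) - dh
  src_c <- seq_len(ncol(m)) - dw
  ok_r <- src_r >= 1 & src_r <= nrow(m)
  ok_c <- src_c >= 1 & src_c <= ncol(m)
  out[which(ok_r), which(ok_c)] <- m[src_r[ok_r], src_c[ok_c]]
  out
}

apply_chan <- function(x, f) {
  out <- x
  for (c in seq_len(dim(x)[3])) out[, , c] <- f(x[, , c])
  out
}

#' Augment an aligned slice/mask pair
#'
#' Emits the original pair plus horizontal and vertical flips, rotations by
#' 90/180/270 degrees, an additive-Gaussian-noise copy (image only) and an
#' integer translation with zero padding.  Geometric transforms are applied
#' identically to image and mask (labels moved as values, no interpolation);
#' the output is deterministic for a fixed seed.
#'
#' @param slice `H x W x 3` image array.
#' @param mask `H x W` integer label matrix.
#' @param seed integer RNG seed for the noise and translation draws.
#' @param noise_sd additive noise standard deviation (image is in z-score
#'   units, default 0.05).
#' @param max_shift maximum absolute translation in pixels (default 10).
#' @return list of `list(x = slice, y = mask)` pairs (8 in total).
#' @export
augment_pair <- function(slice, mask, seed = 0L, noise_sd = 0.05,
                         max_shift = 10L) {
  stopifnot(identical(dim(slice)[1:2], dim(mask)[1:2]))
  x <- unclass(slice)
  geoms <- list(
    identity,
    flip_h,
    flip_v,
    function(m) rot90k(m, 1),
    function(m) rot90k(m, 2),
    function(m) rot90k(m, 3)
  )
  out <- lapply(geoms, function(f)
    list(x = apply_chan(x, f), y = f(mask)))
  rs <- local_rng(seed)
  on.exit(restore_rng(rs))
  noisy <- x + array(stats::rnorm(length(x), 0, noise_sd), dim(x))
  out[[length(out) + 1L]] <- list(x = noisy, y = mask)
  max_shift <- min(max_shift, nrow(mask) %/% 2L)
  dh <- sample(-max_shift:max_shift, 1)
  dw <- sample(-max_shift:max_shift, 1)
  out[[length(out) + 1L]] <- list(
    x = apply_chan(x, function(m) translate2d(m, dh, dw)),
    y = translate2d(mask, dh, dw))
  out
}

# save/restore the global RNG state around seeded sections
local_rng <- function(seed) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  set.seed(seed)
  old
}
restore_rng <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
  invisible(NULL)
}
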