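# Synthetic multi-modal brain phantoms with nested tumor compartments.
#
# Each phantom emulates the structure of a BraTS case: four co-registered
# modality volumes plus an integer label volume with file-level codes
# {0 background, 1 necrotic core, 2 edema/non-enhancing, 4 enhancing}.
# The tumor is a set of nested ellipsoids: necrotic core innermost, an
# enhancing rim around it, and an edema shell forming the whole-tumor
# extent.  Intensities are per-tissue means plus additive Gaussian noise,
# with contrasts chosen so t1ce is brightest in the enhancing rim and flair
# brightest in edema, mimicking clinical appearance.

#' Default per-modality, per-tissue mean intensities
#' @keywords internal
default_contrasts <- function() {
  # rows: tissue; columns follow MODALITIES order
  matrix(c(
    # t1, t1ce, t2, flair
    100, 100, 100, 100,   # normal brain
    80,   90, 140, 170,   # edema
    40,   50, 120,  90,   # necrotic core
    90,  180, 110, 110),  # enhancing rim
    nrow = 4, byrow = TRUE,
    dimnames = list(c("brain", "edema", "necrotic", "enhancing"),
                    MODALITIES))
}

#' Phantom configuration
#'
#' @param shape integer (H, W, D) voxel counts; default `c(64, 64, 32)`
#'   (a desk-scale phantom; use `c(240, 240, 155)` for a full-size case).
#' @param brain_radius brain ellipsoid in-plane radius as a fraction of H.
#' @param tumor_center voxel triple; default is slightly off-center in-plane,
#'   at the default extracted slice depth.
#' @param radii three strictly decreasing in-plane radii (voxels): whole
#'   tumor extent, tumor-core boundary, and the inner (necrotic) boundary of
#'   the enhancing rim.
#' @param modality_contrasts 4 x 4 matrix of tissue-by-modality mean
#'   intensities (see `triunet:::default_contrasts`).
#' @param noise_std additive Gaussian noise standard deviation.
#' @param voxel_spacing mm triple.
#' @param seed integer seed making the phantom deterministic.
#' @return object of class `phantom_config`.
#' @export
phantom_config <- function(shape = c(64L, 64L, 32L),
                           brain_radius = 0.45,
                           tumor_center = NULL,
                           radii = NULL,
                           modality_contrasts = default_contrasts(),
                           noise_std = 5,
                           voxel_spacing = c(1, 1, 1),
                           seed = 0L) {
  shape <- as.integer(shape)
  stopifnot(length(shape) == 3, all(shape > 0), noise_std >= 0)
  if (is.null(radii)) radii <- round(shape[1] * c(0.22, 0.14, 0.08))
  if (any(diff(radii) >= 0)) stop("radii must be strictly decreasing")
  if (is.null(tumor_center))
    tumor_center <- c(round(shape[1] * 0.55), round(shape[2] * 0.45),
                      default_slice_index(shape[3]) + 1L)
  # the whole-tumor ellipsoid must fit inside the brain mask
  brain_r <- brain_radius * shape[1]
  off <- sqrt(sum((tumor_center[1:2] - (shape[1:2] + 1) / 2)^2))
  if (off + radii[1] > brain_r)
    stop("tumor ellipsoids do not fit inside the brain mask; ",
         "reduce radii or recenter")
  structure(list(shape = shape, brain_radius = brain_radius,
                 tumor_center = tumor_center, radii = radii,
                 modality_contrasts = modality_contrasts,
                 noise_std = noise_std, voxel_spacing = voxel_spacing,
                 seed = as.integer(seed)),
            class = "phantom_config")
}

# squared normalized ellipsoid distance field for in-plane radius r;
# the axial semi-axis is scaled by D/H so the tumor spans the volume depth
# proportionally
ellipse_field <- function(shape, center, r, axial_scale) {
  H <- shape[1]; W <- shape[2]; D <- shape[3]
  hz <- (seq_len(H) - center[1]) / r
  wz <- (seq_len(W) - center[2]) / r
  dz <- (seq_len(D) - center[3]) / (r * axial_scale)
  outer(outer(hz^2, wz^2, `+`), dz^2, `+`)
}

#' Generate a multi-modal phantom case
#'
#' @param config a [phantom_config()].
#' @return list with `volumes` (named list of four [modality_volume()]s in
#'   t1/t1ce/t2/flair order) and `labels` (integer 3-D array with file-level
#'   codes \{0, 1, 2, 4\}).
#' @export
generate_phantom <- function(config = phantom_config()) {
  stopifnot(inherits(config, "phantom_config"))
  shape <- config$shape
  axial_scale <- shape[3] / shape[1]
  center3 <- c((shape[1] + 1) / 2, (shape[2] + 1) / 2, (shape[3] + 1) / 2)
  brain <- ellipse_field(shape, center3, config$brain_radius * shape[1],
                         axial_scale / (2 * config$brain_radius)) <= 1
  fields <- lapply(config$radii, function(r)
    ellipse_field(shape, config$tumor_center, r, axial_scale) <= 1)
  labels <- array(0L, shape)
  labels[brain] <- 0L
  labels[fields[[1]]] <- 2L            # edema / whole-tumor shell
  labels[fields[[2]]] <- 4L            # enhancing rim
  labels[fields[[3]]] <- 1L            # necrotic core, innermost
  tissue <- array(1L, shape)           # 1 = brain
  tissue[labels == 2L] <- 2L
  tissue[labels == 1L] <- 3L
  tissue[labels == 4L] <- 4L
  rs <- local_rng(config$seed)
  on.exit(restore_rng(rs))
  volumes <- list()
  for (m in MODALITIES) {
    means <- config$modality_contrasts[, m]
    vox <- array(0, shape)
    vox[brain] <- means[tissue[brain]]
    vox <- vox + array(stats::rnorm(prod(shape), 0, config$noise_std), shape)
    vox[!brain] <- 0
    volumes[[m]] <- modality_volume(vox, m, config$voxel_spacing)
  }
  list(volumes = volumes, labels = labels)
}

# ---- NIfTI case I/O --------------------------------------------------------

#' Write a case to a directory as BraTS-style NIfTI files
#'
#' Files are named `<case_id>_<suffix>.nii.gz` with suffixes `_t1`, `_t1ce`,
#' `_t2`, `_flair` and `_seg`.
#'
#' @param volumes named list of four [modality_volume()]s.
#' @param labels integer 3-D label array (file-level codes), or NULL.
#' @param directory output directory (created if absent).
#' @param case_id file-name stem.
#' @return character vector of the written paths, invisibly.
#' @export
write_case <- function(volumes, labels, directory, case_id = "case") {
  dir.create(directory, showWarnings = FALSE, recursive = TRUE)
  paths <- character(0)
  for (m in names(volumes)) {
    p <- file.path(directory, sprintf("%s_%s.nii.gz", case_id, m))
    v <- volumes[[m]]
    img <- RNifti::asNifti(v$voxels, pixdim = v$voxel_spacing)
    RNifti::writeNifti(img, p)
    paths <- c(paths, p)
  }
  if (!is.null(labels)) {
    p <- file.path(directory, sprintf("%s_seg.nii.gz", case_id))
    img <- RNifti::asNifti(array(as.integer(labels), dim(labels)),
                           datatype = "int16")
    RNifti::writeNifti(img, p)
    paths <- c(paths, p)
  }
  invisible(paths)
}

#' Read a BraTS-style case directory
#'
#' Recognizes the `_t1`, `_t1ce`, `_t2`, `_flair` and `_seg` file-name
#' suffixes.  All four modalities must be present; the segmentation is
#' optional.
#'
#' @param directory directory holding one case.
#' @return list with one [modality_volume()] per modality plus `seg` (an
#'   integer label array or NULL).
#' @export
read_case <- function(directory) {
  files <- list.files(directory, pattern = "\\.nii(\\.gz)?$",
                      full.names = TRUE)
  find1 <- function(suffix) {
    hit <- grep(sprintf("_%s\\.nii(\\.gz)?$", suffix), files, value = TRUE)
    if (length(hit)) hit[[1]] else NA_character_
  }
  paths <- vapply(c(MODALITIES, "seg"), find1, character(1))
  missing <- setdiff(MODALITIES, names(paths)[!is.na(paths)])
  if (length(missing))
    stop("case directory ", directory, " is missing modality file(s): ",
         paste0("_", missing, collapse = ", "))
  out <- list()
  for (m in MODALITIES) {
    img <- RNifti::readNifti(paths[[m]])
    out[[m]] <- modality_volume(array(as.numeric(img), dim(img)), m,
                                RNifti::pixdim(img)[1:3])
  }
  out$seg <- if (!is.na(paths[["seg"]])) {
    seg <- RNifti::readNifti(paths[["seg"]])
    array(as.integer(round(seg)), dim(seg))
  } else NULL
  out
}

#' Generate and write a set of phantom cases
#'
#' @param out_dir output directory; one subdirectory per case.
#' @param n_cases number of cases.
#' @param shape voxel shape passed to [phantom_config()].
#' @param seed base seed; case i uses `seed + i`, with per-case jitter of the
#'   tumor center and radii so cases differ geometrically.
#' @return character vector of case directories, invisibly.
#' @export
synthesize_cases <- function(out_dir, n_cases = 4L, shape = c(64L, 64L, 32L),
                             seed = 0L) {
  dirs <- character(n_cases)
  for (i in seq_len(n_cases)) {
    rs <- local_rng(seed + i)
    jitter <- stats::runif(3, 0.9, 1.1)
    restore_rng(rs)
    base <- round(shape[1] * c(0.22, 0.14, 0.08) * jitter)
    base <- pmax(base, c(5, 3, 2))
    base[2] <- min(base[2], base[1] - 1)
    base[3] <- min(base[3], base[2] - 1)
    cfg <- phantom_config(shape = shape, radii = base, seed = seed + i)
    ph <- generate_phantom(cfg)
    d <- file.path(out_dir, sprintf("phantom_%03d", i))
    write_case(ph$volumes, ph$labels, d, case_id = sprintf("phantom_%03d", i))
    dirs[i] <- d
  }
  invisible(dirs)
}
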