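#' Construct a volume image object
#'
#' Light container for one participant's gray-matter map in MNI space: a 3D
#' voxel array plus the 4x4 affine mapping 0-based voxel indices to mm
#' coordinates.
#'
#' @param data 3D numeric array of gray-matter volume/density.
#' @param affine 4x4 numeric matrix, voxel-index (0-based) to mm transform.
#' @param participant_id Optional identifier carried through extraction.
#' @return An object of class `sb_volume`.
#' @export
sb_volume <- function(data, affine, participant_id = NA_character_) {
  if (length(dim(data)) != 3L) {
    stop("volume data must be a 3D array", call. = FALSE)
  }
  if (!all(is.finite(data))) {
    stop("volume contains non-finite voxels (NaN/Inf)", call. = FALSE)
  }
  affine <- as.matrix(affine)
  if (!all(dim(affine) == c(4L, 4L))) {
    stop("affine must be a 4x4 matrix", call. = FALSE)
  }
  if (abs(det(affine[1:3, 1:3])) < .Machine$double.eps * 1e3) {
    stop("affine is singular", call. = FALSE)
  }
  structure(list(data = data, affine = affine,
                 participant_id = participant_id),
            class = "sb_volume")
}

#' Read a NIfTI gray-matter map
#'
#' @param path Path to a 3D NIfTI-1 file (`.nii` or `.nii.gz`).
#' @param participant_id Identifier; defaults to the file name without
#'   extension.
#' @return `sb_volume` object.
#' @export
read_volume <- function(path, participant_id = NULL) {
  img <- RNifti::readNifti(path)
  if (is.null(participant_id)) {
    participant_id <- sub("\\.nii(\\.gz)?$", "", basename(path))
  }
  sb_volume(as.array(img), RNifti::xform(img), participant_id)
}

#' Write an `sb_volume` to NIfTI
#'
#' @param img `sb_volume` object.
#' @param path Output path (`.nii` or `.nii.gz`).
#' @return `path`, invisibly.
#' @export
write_volume <- function(img, path) {
  nim <- RNifti::asNifti(img$data)
  RNifti::sform(nim) <- structure(img$affine, code = 2L)
  RNifti::qform(nim) <- structure(img$affine, code = 2L)
  RNifti::writeNifti(nim, path)
  invisible(path)
}

voxel_sizes <- function(affine) {
  sqrt(colSums(affine[1:3, 1:3]^2))
}

# 1D zero-padded convolution along the first axis of a 3D array,
# implemented as a banded-matrix product.
conv_axis1 <- function(arr, kernel) {
  d <- dim(arr)
  n <- d[1]
  r <- (length(kernel) - 1L) / 2L
  band <- matrix(0, n, n)
  for (off in -r:r) {
    idx <- seq_len(n - abs(off))
    if (off >= 0) {
      band[cbind(idx + off, idx)] <- kernel[off + r + 1L]
    } else {
      band[cbind(idx, idx - off)] <- kernel[off + r + 1L]
    }
  }
  array(band %*% matrix(arr, nrow = n), dim = d)
}

#' Gaussian-smooth a volume image
#'
#' Separable Gaussian convolution with a kernel of the given full width at
#' half maximum, the standard pre-extraction homogenization step for
#' structural maps. Per axis, sigma in voxels is
#' `fwhm_mm / (2 * sqrt(2 * log(2))) / voxel_size`; the discrete kernel is
#' sampled out to 4 sigma and normalized to unit mass, so constant regions
#' are preserved away from the grid boundary and total intensity of
#' interior structure is conserved. Boundaries use zero padding.
#'
#' @param img `sb_volume` object.
#' @param fwhm_mm Positive kernel FWHM in mm (default 5).
#' @return Smoothed `sb_volume`.
#' @export
gaussian_smooth <- function(img, fwhm_mm = 5) {
  stopifnot(inherits(img, "sb_volume"))
  if (!is.numeric(fwhm_mm) || length(fwhm_mm) != 1L || fwhm_mm <= 0) {
    stop("fwhm_mm must be a positive scalar", call. = FALSE)
  }
  vox <- voxel_sizes(img$affine)
  sigma_vox <- fwhm_mm / (2 * sqrt(2 * log(2))) / vox
  out <- img$data
  for (axis in 1:3) {
    r <- max(1L, as.integer(ceiling(4 * sigma_vox[axis])))
    kernel <- stats::dnorm(-r:r, sd = sigma_vox[axis])
    kernel <- kernel / sum(kernel)
    perm <- switch(axis, c(1, 2, 3), c(2, 1, 3), c(3, 2, 1))
    out <- aperm(conv_axis1(aperm(out, perm), kernel), perm)
  }
  sb_volume(out, img$affine, img$participant_id)
}

#' Spherical voxel mask around an MNI coordinate
#'
#' A voxel belongs to the sphere iff the mm distance from its center to
#' `center_mni` is at most `diameter_mm / 2`.
#'
#' @param center_mni Numeric length-3 mm coordinate in the image's space.
#' @param diameter_mm Positive sphere diameter in mm.
#' @param img `sb_volume` object.
#' @param allow_clipped If `FALSE` (default), a sphere that extends past the
#'   voxel grid is an error; if `TRUE`, the in-grid part is returned.
#' @param label Optional region name used in error messages.
#' @return Integer vector of linear (1-based) indices into `img$data`.
#' @export
sphere_mask <- function(center_mni, diameter_mm, img,
                        allow_clipped = FALSE, label = NULL) {
  stopifnot(inherits(img, "sb_volume"))
  if (!is.numeric(diameter_mm) || diameter_mm <= 0) {
    stop("diameter_mm must be positive", call. = FALSE)
  }
  what <- if (is.null(label)) "sphere" else paste0("region '", label, "'")
  radius <- diameter_mm / 2
  dims <- dim(img$data)
  inv <- solve(img$affine)
  vc <- (inv %*% c(center_mni, 1))[1:3]   # fractional 0-based voxel coord
  vox <- voxel_sizes(img$affine)
  half <- radius / vox + 1                # voxel-space bounding half-width
  lo <- floor(vc - half)
  hi <- ceiling(vc + half)
  grid <- expand.grid(i = lo[1]:hi[1], j = lo[2]:hi[2], k = lo[3]:hi[3])
  mm <- t(img$affine %*% rbind(grid$i, grid$j, grid$k, 1))[, 1:3,
                                                           drop = FALSE]
  d2 <- (mm[, 1] - center_mni[1])^2 + (mm[, 2] - center_mni[2])^2 +
    (mm[, 3] - center_mni[3])^2
  inside <- d2 <= radius^2 + 1e-9
  if (!any(inside)) {
    stop(what, ": sphere at (", paste(center_mni, collapse = ", "),
         ") mm contains no voxel centers", call. = FALSE)
  }
  sel <- grid[inside, , drop = FALSE]
  in_grid <- sel$i >= 0 & sel$i <= dims[1] - 1 &
    sel$j >= 0 & sel$j <= dims[2] - 1 &
    sel$k >= 0 & sel$k <= dims[3] - 1
  if (!any(in_grid)) {
    stop(what, ": sphere at (", paste(center_mni, collapse = ", "),
         ") mm lies entirely outside the voxel grid", call. = FALSE)
  }
  if (!all(in_grid) && !allow_clipped) {
    stop(what, ": sphere is clipped by the voxel grid; ",
         "use allow_clipped = TRUE to average over in-grid voxels",
         call. = FALSE)
  }
  sel <- sel[in_grid, , drop = FALSE]
  idx <- 1L + sel$i + dims[1] * (sel$j + dims[2] * sel$k)
  as.integer(idx)
}

#' Mean gray-matter volume per atlas region
#'
#' Smooths the image (unless `smooth_fwhm_mm` is 0 or `NULL`) and averages
#' voxel values inside a sphere of `diameter_mm` around each region's
#' MNI center, in `region_id` order.
#'
#' @param img `sb_volume` object.
#' @param atlas `sb_atlas` object.
#' @param diameter_mm Sphere diameter in mm (default 5).
#' @param smooth_fwhm_mm Smoothing kernel FWHM in mm (default 5); 0 or
#'   `NULL` disables smoothing.
#' @param allow_clipped Passed to [sphere_mask()].
#' @return Named numeric vector of length `nrow(atlas)`.
#' @export
extract_region_means <- function(img, atlas, diameter_mm = 5,
                                 smooth_fwhm_mm = 5,
                                 allow_clipped = FALSE) {
  stopifnot(inherits(img, "sb_volume"), inherits(atlas, "sb_atlas"))
  if (!is.null(smooth_fwhm_mm) && smooth_fwhm_mm > 0) {
    img <- gaussian_smooth(img, smooth_fwhm_mm)
  }
  means <- vapply(seq_len(nrow(atlas)), function(r) {
    idx <- sphere_mask(c(atlas$x[r], atlas$y[r], atlas$z[r]), diameter_mm,
                       img, allow_clipped = allow_clipped,
                       label = atlas$name[r])
    vals <- img$data[idx]
    if (!all(is.finite(vals))) {
      stop("region '", atlas$name[r], "': non-finite voxels inside sphere",
           call. = FALSE)
    }
    mean(vals)
  }, numeric(1))
  stats::setNames(means, atlas$name)
}

#' Z-score matrix columns
#'
#' Centers each column to zero mean and scales to unit variance using the
#' population standard deviation (divisor n).
#'
#' @param m Numeric matrix (or data frame of numerics), at least 2 rows.
#' @return Matrix of the same shape.
#' @export
zscore_columns <- function(m) {
  m <- as.matrix(m)
  if (nrow(m) < 2L) {
    stop("zscore_columns needs at least 2 rows", call. = FALSE)
  }
  mu <- colMeans(m)
  centered <- sweep(m, 2, mu)
  sd_pop <- sqrt(colMeans(centered^2))
  zero <- which(sd_pop <= 0 | !is.finite(sd_pop))
  if (length(zero) > 0) {
    nm <- colnames(m)[zero]
    if (is.null(nm)) nm <- as.character(zero)
    stop("zero-variance column(s): ", paste(nm, collapse = ", "),
         call. = FALSE)
  }
  sweep(centered, 2, sd_pop, "/")
}

#' Extract region volumes for a cohort of images
#'
#' Batch driver over [extract_region_means()]: reads each NIfTI file,
#' extracts the 36 region means, and assembles the participants x regions
#' matrix together with its z-scored version. Per-file failures are
#' collected and reported together.
#'
#' @param image_paths Character vector of NIfTI paths.
#' @param atlas `sb_atlas` object.
#' @param diameter_mm,smooth_fwhm_mm,allow_clipped Passed through to
#'   [extract_region_means()].
#' @param participant_ids Optional ids (default: file names).
#' @param verbose Log per-file progress to stderr.
#' @return Object of class `sb_region_volumes`: list with `raw` and
#'   `zscored` matrices (rows named by participant), and `atlas_source`.
#' @export
extract_cohort <- function(image_paths, atlas, diameter_mm = 5,
                           smooth_fwhm_mm = 5, allow_clipped = FALSE,
                           participant_ids = NULL, verbose = FALSE) {
  stopifnot(inherits(atlas, "sb_atlas"))
  n <- length(image_paths)
  if (n == 0L) stop("no image paths given", call. = FALSE)
  if (is.null(participant_ids)) {
    participant_ids <- sub("\\.nii(\\.gz)?$", "", basename(image_paths))
  }
  stopifnot(length(participant_ids) == n)
  raw <- matrix(NA_real_, n, nrow(atlas),
                dimnames = list(participant_ids, atlas$name))
  failures <- character(0)
  for (f in seq_len(n)) {
    if (verbose) message("extracting [", f, "/", n, "] ", image_paths[f])
    res <- tryCatch(
      extract_region_means(read_volume(image_paths[f], participant_ids[f]),
                           atlas, diameter_mm, smooth_fwhm_mm,
                           allow_clipped),
      error = function(e) e)
    if (inherits(res, "error")) {
      failures <- c(failures,
                    paste0(image_paths[f], ": ", conditionMessage(res)))
    } else {
      raw[f, ] <- res
    }
  }
  if (length(failures) > 0) {
    stop("extraction failed for ", length(failures), " image(s):\n",
         paste(failures, collapse = "\n"), call. = FALSE)
  }
  region_volumes(raw, atlas_source = attr(atlas, "source"))
}

#' Assemble a region-volume matrix object
#'
#' @param raw Participants x regions numeric matrix with participant row
#'   names and region column names.
#' @param atlas_source Provenance string.
#' @return `sb_region_volumes` object with `raw` and `zscored` components.
#' @export
region_volumes <- function(raw, atlas_source = "unknown") {
  raw <- as.matrix(raw)
  structure(list(raw = raw, zscored = zscore_columns(raw),
                 atlas_source = atlas_source),
            class = "sb_region_volumes")
}

#' Write / read a raw region-volume matrix as CSV
#'
#' Header `participant_id,<region names...>`.
#'
#' @param volumes `sb_region_volumes` object.
#' @param path CSV path.
#' @return `path` (write) or `sb_region_volumes` (read).
#' @export
write_region_volumes <- function(volumes, path) {
  df <- data.frame(participant_id = rownames(volumes$raw),
                   volumes$raw, check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_region_volumes
#' @param atlas_source Provenance recorded on the read object.
#' @export
read_region_volumes <- function(path, atlas_source = path) {
  df <- utils::read.csv(path, check.names = FALSE)
  raw <- as.matrix(df[, -1, drop = FALSE])
  rownames(raw) <- as.character(df$participant_id)
  region_volumes(raw, atlas_source = atlas_source)
}
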