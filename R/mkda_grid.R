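# Volume grid plumbing: an axis-aligned isotropic voxel grid with an
# in-brain mask, plus NIfTI-1 I/O.  World coordinates are mm; voxel (1,1,1)
# has world coordinate `origin` at its center.

#' Construct a volume grid
#'
#' @param dim Integer voxel counts per axis (length 3).
#' @param voxel_size Isotropic voxel edge length in mm (> 0).
#' @param origin mm world coordinate of the center of voxel (1,1,1).
#' @param mask Logical array of dimension `dim` flagging in-brain voxels;
#'   default all `TRUE`.
#' @return An object of class `volume_grid`.
#' @export
volume_grid <- function(dim, voxel_size, origin = c(0, 0, 0), mask = NULL) {
  dim <- as.integer(dim)
  stopifnot(length(dim) == 3, all(dim >= 1),
            length(voxel_size) == 1, voxel_size > 0,
            length(origin) == 3)
  if (is.null(mask)) mask <- array(TRUE, dim)
  stopifnot(is.logical(mask), all(base::dim(mask) == dim))
  if (!any(mask)) stop("mask is empty", call. = FALSE)
  structure(list(dim = dim, voxel_size = as.numeric(voxel_size),
                 origin = as.numeric(origin), mask = mask),
            class = "volume_grid")
}

#' Standard MNI bounding-box grid
#'
#' Axis-aligned grid spanning x in \[-90, 90\], y in \[-126, 90\],
#' z in \[-72, 108\] mm at the requested isotropic resolution (default
#' 2 mm), with an all-in mask unless one is supplied.
#'
#' @param voxel_size Isotropic voxel size in mm.
#' @param mask Optional logical mask array matching the resulting dims.
#' @return A `volume_grid`.
#' @export
mni_grid <- function(voxel_size = 2, mask = NULL) {
  lo <- c(-90, -126, -72); hi <- c(90, 90, 108)
  dim <- floor((hi - lo) / voxel_size) + 1
  volume_grid(dim, voxel_size, origin = lo, mask = mask)
}

#' @export
print.volume_grid <- function(x, ...) {
  cat(sprintf("volume_grid: %d x %d x %d voxels @ %g mm, %d in mask\n",
              x$dim[1], x$dim[2], x$dim[3], x$voxel_size, sum(x$mask)))
  invisible(x)
}

# world mm -> fractional (1-based) voxel coordinates
.world_to_vox <- function(xyz, grid) {
  sweep(xyz, 2, grid$origin) / grid$voxel_size + 1
}

# 1-based voxel coordinates (matrix) -> world mm of voxel centers
.vox_to_world <- function(ijk, grid) {
  sweep((ijk - 1) * grid$voxel_size, 2, grid$origin, "+")
}

.grid_affine <- function(grid) {
  aff <- diag(c(rep(grid$voxel_size, 3), 1))
  aff[1:3, 4] <- grid$origin
  aff
}

.same_grid <- function(a, b) {
  all(a$dim == b$dim) && isTRUE(all.equal(a$voxel_size, b$voxel_size)) &&
    isTRUE(all.equal(a$origin, b$origin))
}

#' Write a volume to a NIfTI-1 file
#'
#' Writes a density map or plain array on a `volume_grid` as NIfTI-1 with
#' the grid's (axis-aligned) affine.
#'
#' @param map A `density_map`, or a numeric/logical array whose dimension
#'   matches `grid$dim` (then `grid` is required).
#' @param path Output path (`.nii` or `.nii.gz`).
#' @param grid The `volume_grid`; taken from `map` when it is a
#'   `density_map`.
#' @export
write_volume <- function(map, path, grid = NULL) {
  if (inherits(map, "density_map")) {
    grid <- map$grid
    arr <- map$value
  } else arr <- map
  stopifnot(inherits(grid, "volume_grid"), all(dim(arr) == grid$dim))
  storage.mode(arr) <- "double"
  img <- RNifti::asNifti(arr)
  img <- RNifti::`sform<-`(img, structure(.grid_affine(grid), code = 2L))
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Read a mask volume from a NIfTI-1 file
#'
#' Nonzero voxels are in-brain.  The affine must be axis-aligned with
#' isotropic positive voxel size; anything else (oblique or anisotropic
#' volumes would need resampling) is an error.
#'
#' @param path Path to a `.nii`/`.nii.gz` file.
#' @return A `volume_grid` with the file's mask.
#' @export
read_mask <- function(path) {
  img <- RNifti::readNifti(path)
  aff <- RNifti::xform(img)
  R <- aff[1:3, 1:3]
  offdiag <- R; diag(offdiag) <- 0
  if (max(abs(offdiag)) > 1e-6 || any(diag(R) <= 0))
    stop("mask affine must be axis-aligned with positive voxel sizes",
         call. = FALSE)
  vs <- diag(R)
  if (max(vs) - min(vs) > 1e-6)
    stop("mask voxels must be isotropic", call. = FALSE)
  arr <- as.array(img)
  if (length(dim(arr)) != 3) stop("mask must be a 3D volume", call. = FALSE)
  volume_grid(dim(arr), vs[1], origin = aff[1:3, 4], mask = arr != 0)
}
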