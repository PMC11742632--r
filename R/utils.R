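# internal helpers shared across modules

deg2rad <- function(deg) deg * pi / 180

`%||%` <- function(a, b) if (is.null(a)) b else a

# Accept a VolumeGrid or a bare array and return the voxel array.
.vox <- function(x) {
  if (is(x, "VolumeGrid")) x@voxels else x
}

.affineOf <- function(x, default = diag(4)) {
  if (is(x, "VolumeGrid")) x@affine else default
}

# Grid compatibility: identical shape, affines equal within tol (mm).
sameGrid <- function(a, b, tol = 1e-4) {
  dimsEqual <- identical(dim(.vox(a)), dim(.vox(b)))
  affA <- .affineOf(a, NULL)
  affB <- .affineOf(b, NULL)
  affEqual <- is.null(affA) || is.null(affB) ||
    max(abs(affA - affB)) <= tol
  dimsEqual && affEqual
}

assertSameGrid <- function(a, b, what = "volumes", tol = 1e-4) {
  if (!sameGrid(a, b, tol = tol)) {
    stop("grid mismatch between ", what,
         ": shapes and affines must agree (tolerance ", tol, " mm)",
         call. = FALSE)
  }
  invisible(TRUE)
}

.checkAffine <- function(affine) {
  if (!is.matrix(affine) || !all(dim(affine) == c(4L, 4L))) {
    stop("affine must be a 4x4 matrix", call. = FALSE)
  }
  if (!all(is.finite(affine)) || abs(det(affine)) < .Machine$double.eps) {
    stop("affine must be finite and invertible", call. = FALSE)
  }
  invisible(TRUE)
}

# Flatten a 4D array to a (voxels x frames) matrix and back.
.asVoxelMatrix <- function(arr4d) {
  d <- dim(arr4d)
  dim(arr4d) <- c(prod(d[1:3]), d[4])
  arr4d
}

.asVolume4D <- function(mat, shape3d) {
  dim(mat) <- c(shape3d, ncol(mat))
  mat
}
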