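#' Voxel grid of a 3D image
#'
#' An `image_grid` ties a voxel lattice to world space: the array shape, the
#' voxel dimensions in mm, and the 4x4 voxel-to-world affine. All masks and
#' volumes in this package carry a grid, and every pairwise operation checks
#' that the two grids agree before touching voxel data.
#'
#' @param shape Integer vector of length 3, voxels per axis.
#' @param voxel_dims Numeric vector of length 3, mm per axis (all > 0).
#' @param affine 4x4 voxel-to-world matrix; default is a diagonal affine built
#'   from `voxel_dims` (0-based voxel indices map to world mm).
#' @param orientation_code Canonical axis-order tag (informational), default
#'   `"RAS"`.
#'
#' @return An object of class `image_grid`.
#' @export
image_grid <- function(shape, voxel_dims, affine = NULL,
                       orientation_code = "RAS") {
  shape <- as.integer(shape)
  voxel_dims <- as.numeric(voxel_dims)
  if (length(shape) != 3L || any(shape < 1L))
    stop("'shape' must be three positive integers")
  if (length(voxel_dims) != 3L || any(!is.finite(voxel_dims)) ||
      any(voxel_dims <= 0))
    stop("'voxel_dims' must be three positive numbers (mm)")
  if (is.null(affine)) affine <- diag(c(voxel_dims, 1))
  affine <- as.matrix(affine)
  if (!identical(dim(affine), c(4L, 4L)))
    stop("'affine' must be a 4x4 matrix")
  det3 <- abs(det(affine[1:3, 1:3]))
  if (abs(det3 - prod(voxel_dims)) > 1e-6 * prod(voxel_dims))
    stop("|det| of the affine 3x3 block (", signif(det3, 8),
         ") does not match prod(voxel_dims) (", signif(prod(voxel_dims), 8),
         ")")
  structure(list(shape = shape, voxel_dims = voxel_dims, affine = affine,
                 orientation_code = orientation_code),
            class = "image_grid")
}

#' @export
print.image_grid <- function(x, ...) {
  cat("<image_grid> ", paste(x$shape, collapse = " x "),
      " voxels, ", paste(signif(x$voxel_dims, 4), collapse = " x "),
      " mm (", x$orientation_code, ")\n", sep = "")
  invisible(x)
}

#' Voxel volume of a grid in mm^3
#'
#' Computed as the absolute determinant of the affine's 3x3 block, which stays
#' correct for oblique headers where the pixdim fields can disagree with the
#' affine after reorientation.
#'
#' @param grid An [image_grid].
#' @return Voxel volume in mm^3.
#' @export
voxel_volume_mm3 <- function(grid) {
  stopifnot(inherits(grid, "image_grid"))
  abs(det(grid$affine[1:3, 1:3]))
}

#' Test or assert that two objects share a voxel grid
#'
#' Grids agree when the shapes are identical and the affines agree elementwise
#' within `tol`. The default tolerance of 1e-4 mm absorbs float noise from
#' header round-trips while still rejecting any real translation or rotation.
#'
#' @param a,b Objects with a grid: [image_grid]s, masks or volumes.
#' @param tol Absolute tolerance on affine entries (mm), default `1e-4`.
#' @return `same_grid()` returns `TRUE`/`FALSE`; `assert_same_grid()` returns
#'   `TRUE` invisibly or throws a grid-mismatch error naming both sources.
#' @export
same_grid <- function(a, b, tol = 1e-4) {
  ga <- as_grid(a); gb <- as_grid(b)
  identical(ga$shape, gb$shape) &&
    all(abs(ga$affine - gb$affine) <= tol)
}

#' @rdname same_grid
#' @export
assert_same_grid <- function(a, b, tol = 1e-4) {
  if (!same_grid(a, b, tol))
    stop("grid mismatch between '", deparse(substitute(a)), "' and '",
         deparse(substitute(b)), "': shapes or affines differ beyond tol = ",
         tol)
  invisible(TRUE)
}

as_grid <- function(x) {
  if (inherits(x, "image_grid")) return(x)
  if (!is.null(x$grid) && inherits(x$grid, "image_grid")) return(x$grid)
  stop("cannot extract an image_grid from object of class ",
       paste(class(x), collapse = "/"))
}
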