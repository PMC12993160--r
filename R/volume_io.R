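#' 3D volumes tied to a grid
#'
#' Three thin containers share the `vol3d` class: `label_volume` (non-negative
#' integer labels, 0 = background), `binary_mask` (logical), and
#' `intensity_volume` (real scalar per voxel, e.g. an R1 map). Construction
#' validates the data against the grid shape.
#'
#' @param data 3D array matching `grid$shape`.
#' @param grid An [image_grid].
#' @return An object of class `c("<subclass>", "vol3d")`.
#' @export
label_volume <- function(data, grid) {
  data <- check_vol_data(data, grid)
  if (any(data < 0) || any(data != round(data)))
    stop("label data must be non-negative integers")
  structure(list(data = array(as.integer(data), dim = grid$shape),
                 grid = grid),
            class = c("label_volume", "vol3d"))
}

#' @rdname label_volume
#' @export
binary_mask <- function(data, grid) {
  data <- check_vol_data(data, grid)
  structure(list(data = array(as.logical(data), dim = grid$shape),
                 grid = grid),
            class = c("binary_mask", "vol3d"))
}

#' @rdname label_volume
#' @export
intensity_volume <- function(data, grid) {
  data <- check_vol_data(data, grid)
  structure(list(data = array(as.numeric(data), dim = grid$shape),
                 grid = grid),
            class = c("intensity_volume", "vol3d"))
}

check_vol_data <- function(data, grid) {
  stopifnot(inherits(grid, "image_grid"))
  if (is.null(dim(data)) && length(data) == prod(grid$shape))
    dim(data) <- grid$shape
  if (!identical(as.integer(dim(data)), grid$shape))
    stop("data dimensions (", paste(dim(data), collapse = "x"),
         ") do not match grid shape (", paste(grid$shape, collapse = "x"), ")")
  data
}

#' @export
print.vol3d <- function(x, ...) {
  kind <- class(x)[1]
  cat("<", kind, "> ", paste(x$grid$shape, collapse = " x "), " voxels", sep = "")
  if (kind == "binary_mask")
    cat(", ", sum(x$data), " foreground (", signif(mask_volume_ml(x), 5),
        " mL)", sep = "")
  if (kind == "label_volume")
    cat(", labels: ", paste(sort(unique(x$data[x$data > 0])), collapse = " "),
        sep = "")
  cat("\n")
  invisible(x)
}

#' Read a 3D NIfTI volume
#'
#' Reads a NIfTI-1 file and returns a [label_volume] (when every value is a
#' non-negative integer) or an [intensity_volume] otherwise, with the grid
#' populated from the header. Use `as_binary_mask()` to threshold a read
#' volume into a mask.
#'
#' @param path Path to a `.nii` or `.nii.gz` file.
#' @param kind `"auto"` (default), `"label"`, `"intensity"`, or `"mask"`
#'   (nonzero voxels become foreground).
#' @return A `vol3d` object.
#' @export
read_volume <- function(path, kind = c("auto", "label", "intensity", "mask")) {
  kind <- match.arg(kind)
  if (!file.exists(path)) stop("file not found: ", path)
  img <- RNifti::readNifti(path)
  d <- dim(img)
  if (length(d) != 3L)
    stop("expected a 3D volume, got ", length(d), "D data in ", path)
  aff <- structure(RNifti::xform(img), imagedim = NULL, code = NULL)
  aff <- matrix(as.numeric(aff), 4, 4)
  vd <- sqrt(colSums(aff[1:3, 1:3]^2))
  grid <- image_grid(d, vd, aff)
  arr <- as.array(img)
  attributes(arr) <- list(dim = d)
  if (kind == "mask") return(binary_mask(arr != 0, grid))
  if (kind == "intensity") return(intensity_volume(arr, grid))
  is_lab <- all(is.finite(arr)) && all(arr >= 0) && all(arr == round(arr))
  if (kind == "label" && !is_lab)
    stop("volume in ", path, " contains non-integer or negative values")
  if (is_lab) label_volume(arr, grid) else intensity_volume(arr, grid)
}

#' Write a volume or mask to NIfTI-1
#'
#' Masks are written as uint8 0/1; labels as integers; intensities as float.
#' The grid's affine is stored as both sform and qform.
#'
#' @param vol A `vol3d` object.
#' @param path Output path ending in `.nii` or `.nii.gz`.
#' @return `path`, invisibly.
#' @export
write_volume <- function(vol, path) {
  stopifnot(inherits(vol, "vol3d"))
  arr <- vol$data
  if (is.logical(arr)) arr <- array(as.integer(arr), dim = dim(arr))
  img <- RNifti::asNifti(arr)
  RNifti::pixdim(img) <- vol$grid$voxel_dims
  aff <- structure(vol$grid$affine, code = 2L)
  RNifti::`sform<-`(img, aff) -> img
  RNifti::`qform<-`(img, aff) -> img
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Label scheme of a segmentation method
#'
#' Different tools emit different label conventions for the same structure
#' (e.g. left/right thalamus as 10/49 in an aseg-style scheme, or a set of
#' thalamus-related labels 24, 25, 26, 27, 30, 31 in a deep-brain scheme).
#' A `label_scheme` records the method name and the integer IDs that together
#' make up the structure.
#'
#' @param method_name Method tag.
#' @param structure_label_ids Non-empty vector of unique positive integers.
#' @return An object of class `label_scheme`.
#' @export
label_scheme <- function(method_name, structure_label_ids) {
  ids <- as.integer(structure_label_ids)
  if (length(ids) == 0L || anyNA(ids) || any(ids < 1L) || anyDuplicated(ids))
    stop("'structure_label_ids' must be non-empty, unique integers >= 1")
  structure(list(method_name = as.character(method_name),
                 structure_label_ids = ids),
            class = "label_scheme")
}

#' Read label schemes from a JSON config
#'
#' The config maps method name to integer ID list, e.g.
#' `{"freesurfer": [10, 49], "dbsegment": [24, 25, 26, 27, 30, 31]}`.
#'
#' @param path Path to a JSON file.
#' @return Named list of [label_scheme] objects.
#' @export
read_label_schemes <- function(path) {
  cfg <- jsonlite::read_json(path, simplifyVector = TRUE)
  out <- lapply(names(cfg), function(nm) label_scheme(nm, cfg[[nm]]))
  names(out) <- names(cfg)
  out
}

#' Extract a binary structure mask from a labelled volume
#'
#' A voxel is foreground iff its label is one of the scheme's structure IDs;
#' this merges e.g. left and right labels into a single bilateral mask. An
#' empty result is not an error (downstream metrics define behaviour for it)
#' but is flagged with a warning and an `empty` attribute.
#'
#' @param vol A [label_volume].
#' @param scheme A [label_scheme] (or bare integer vector of label IDs).
#' @return A [binary_mask]; attribute `empty` is `TRUE` when no voxel matched.
#' @export
extract_mask <- function(vol, scheme) {
  stopifnot(inherits(vol, "label_volume"))
  if (!inherits(scheme, "label_scheme")) scheme <- label_scheme("adhoc", scheme)
  m <- array(vol$data %in% scheme$structure_label_ids, dim = vol$grid$shape)
  out <- binary_mask(m, vol$grid)
  if (!any(m)) {
    warning("no voxel matched label IDs {",
            paste(scheme$structure_label_ids, collapse = ", "),
            "} for method '", scheme$method_name, "': empty mask")
    attr(out, "empty") <- TRUE
  }
  out
}

#' Mask volume in millilitres
#'
#' Foreground voxel count times the voxel volume derived from the header
#' affine, converted to mL (1 mL = 1000 mm^3).
#'
#' @param mask A [binary_mask].
#' @return Volume in mL.
#' @export
mask_volume_ml <- function(mask) {
  stopifnot(inherits(mask, "binary_mask"))
  sum(mask$data) * voxel_volume_mm3(mask$grid) / 1000
}
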