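#' Volumetric image container
#'
#' A light wrapper around a 3-D or 4-D numeric array carrying the voxel
#' dimensions (mm), a free-text units tag and an axis-order descriptor.
#' The first array axis is the fastest-varying (x), and any fourth axis
#' holds time frames, echoes or diffusion directions, in acquisition order.
#' No reorientation or resampling is ever performed.
#'
#' @param data numeric array, 3-D `(x, y, z)` or 4-D `(x, y, z, t)`.
#' @param voxel_dims numeric length-3, voxel edge lengths in mm; all `> 0`.
#' @param units free-text units tag, e.g. `"a.u."`, `"ms"`, `"mm^2/s"`,
#'   `"mL/g/min"`.
#' @param orientation axis-order descriptor; kept as metadata only.
#' @return An object of class `vol_image`.
#' @examples
#' img <- vol_image(array(1, dim = c(4, 4, 4)), voxel_dims = c(0.2, 0.2, 1))
#' voxel_volume(img)
#' @export
vol_image <- function(data, voxel_dims, units = "a.u.", orientation = "xyz") {
  if (!is.array(data) || !(length(dim(data)) %in% c(3L, 4L)))
    stop("`data` must be a 3-D or 4-D array", call. = FALSE)
  voxel_dims <- as.numeric(voxel_dims)
  if (length(voxel_dims) != 3L || any(!is.finite(voxel_dims)) || any(voxel_dims <= 0))
    stop("`voxel_dims` must be three positive lengths in mm", call. = FALSE)
  structure(
    list(data = data, voxel_dims = voxel_dims, units = units,
         orientation = orientation),
    class = "vol_image"
  )
}

#' @export
print.vol_image <- function(x, ...) {
  cat("<vol_image> ", paste(dim(x$data), collapse = " x "),
      " voxels, ", paste(signif(x$voxel_dims, 4), collapse = " x "),
      " mm, units: ", x$units, "\n", sep = "")
  invisible(x)
}

#' @export
dim.vol_image <- function(x) dim(x$data)

#' Voxel volume in mm^3
#'
#' @param x a `vol_image`, `label_map`, or numeric length-3 voxel dimensions.
#' @return Scalar voxel volume in mm^3.
#' @export
voxel_volume <- function(x) {
  dims <- if (is.numeric(x)) x else x$voxel_dims
  prod(dims)
}

#' Read a NIfTI-1 volume
#'
#' Voxel dimensions are taken from the NIfTI header -- the single source of
#' truth for mm^3 volumetry. A fourth (time/echo/direction) axis is preserved
#' in file order.
#'
#' @param path path to a `.nii` or `.nii.gz` file.
#' @param units units tag to attach (NIfTI carries no quantitative units).
#' @return A [vol_image].
#' @export
read_volume <- function(path, units = "a.u.") {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  nii <- tryCatch(RNifti::readNifti(path),
                  error = function(e) stop("not a readable NIfTI-1 file: ", path,
                                           call. = FALSE))
  data <- as.array(nii)
  data <- array(as.vector(data), dim = dim(data))  # drop header attributes
  nd <- length(dim(data))
  if (nd == 2L) { dim(data) <- c(dim(data), 1L); nd <- 3L }
  if (!(nd %in% c(3L, 4L)))
    stop("expected a 3-D or 4-D volume, got ", nd, " dimensions", call. = FALSE)
  vd <- RNifti::pixdim(nii)[1:3]
  if (any(!is.finite(vd)) || any(vd <= 0))
    stop("zero or negative voxel dimension in NIfTI header", call. = FALSE)
  vol_image(unclass(data), voxel_dims = abs(vd), units = units)
}

#' Write a volume as NIfTI-1
#'
#' Data are stored as 64-bit floats so write/read round-trips are exact;
#' voxel dimensions go into the header `pixdim` field.
#'
#' @param img a [vol_image].
#' @param path output path (`.nii` or `.nii.gz`).
#' @return `path`, invisibly.
#' @export
write_volume <- function(img, path) {
  stopifnot(inherits(img, "vol_image"))
  nii <- RNifti::asNifti(img$data)
  nd <- length(dim(img$data))
  pd <- c(img$voxel_dims, if (nd == 4L) 1)
  RNifti::pixdim(nii) <- pd
  dir <- dirname(path)
  if (!dir.exists(dir)) stop("unwritable path (no such directory): ", path,
                             call. = FALSE)
  RNifti::writeNifti(nii, path, datatype = "double")
  invisible(path)
}

#' Region label map
#'
#' Integer labels on a 3-D grid, 0 meaning background, with a lookup from
#' label to region name. Region voxel sets are disjoint by construction
#' (one label per voxel).
#'
#' @param labels integer 3-D array, non-negative; 0 = background.
#' @param names named character vector, names are label integers as strings.
#' @param voxel_dims voxel edge lengths in mm.
#' @return An object of class `label_map`.
#' @export
label_map <- function(labels, names, voxel_dims) {
  if (!is.array(labels) || length(dim(labels)) != 3L)
    stop("`labels` must be a 3-D array", call. = FALSE)
  lv <- as.vector(labels)
  if (any(!is.finite(lv)) || any(lv < 0) || any(lv != round(lv)))
    stop("labels must be non-negative integers", call. = FALSE)
  present <- sort(unique(lv[lv > 0]))
  if (anyDuplicated(base::names(names)))
    stop("duplicate labels in names table", call. = FALSE)
  missing <- setdiff(as.character(present), base::names(names))
  if (length(missing))
    stop("labels present in image but absent from names: ",
         paste(missing, collapse = ", "), call. = FALSE)
  storage.mode(labels) <- "integer"
  structure(
    list(labels = labels, names = names,
         voxel_dims = as.numeric(voxel_dims)),
    class = "label_map"
  )
}

#' @export
print.label_map <- function(x, ...) {
  cat("<label_map> ", paste(dim(x$labels), collapse = " x "), " voxels, ",
      length(x$names), " named regions\n", sep = "")
  invisible(x)
}

#' Read a label map and its region-name table
#'
#' @param path_img NIfTI-1 file of integer labels (0 = background).
#' @param path_names two-column delimited text file (CSV with header
#'   `label,name`) mapping each nonzero label to a region name.
#' @return A [label_map].
#' @export
read_label_map <- function(path_img, path_names) {
  img <- read_volume(path_img, units = "label")
  tab <- utils::read.csv(path_names, stringsAsFactors = FALSE)
  if (ncol(tab) < 2L) stop("names file must have two columns (label, name)",
                           call. = FALSE)
  lbl <- as.integer(tab[[1]])
  if (anyDuplicated(lbl)) stop("duplicate labels in names table", call. = FALSE)
  nm <- stats::setNames(as.character(tab[[2]]), as.character(lbl))
  label_map(img$data, nm, img$voxel_dims)
}

#' Write a label map to NIfTI plus a CSV name table
#'
#' @param lm a [label_map].
#' @param path_img output NIfTI path.
#' @param path_names output CSV path for the (label, name) table.
#' @return `path_img`, invisibly.
#' @export
write_label_map <- function(lm, path_img, path_names) {
  stopifnot(inherits(lm, "label_map"))
  write_volume(vol_image(lm$labels, lm$voxel_dims, units = "label"), path_img)
  utils::write.csv(
    data.frame(label = as.integer(names(lm$names)), name = unname(lm$names)),
    path_names, row.names = FALSE)
  invisible(path_img)
}

#' Region names of a label map
#' @param lm a [label_map].
#' @return Character vector of region names, ordered by label.
#' @export
region_names <- function(lm) unname(lm$names[order(as.integer(names(lm$names)))])

#' Logical mask of one region
#' @param lm a [label_map].
#' @param region region name (as in the name table) or integer label.
#' @return Logical 3-D array.
#' @export
region_mask <- function(lm, region) {
  if (is.character(region)) {
    hit <- names(lm$names)[lm$names == region]
    if (!length(hit)) stop("unknown region: ", region, call. = FALSE)
    region <- as.integer(hit[1])
  }
  lm$labels == region
}

#' Brain mask implied by a label map (all nonzero labels)
#' @param lm a [label_map].
#' @return Logical 3-D array.
#' @export
brain_mask <- function(lm) lm$labels > 0L

#' Read a cohort table
#'
#' The cohort table is the tidy per-animal record of every quantified value:
#' one row per (animal, region, parameter), columns `animal_id`, `group`,
#' `region`, `parameter`, `value`, `units`.
#'
#' @param path CSV file with a header row.
#' @return A tibble.
#' @export
read_cohort <- function(path) {
  tab <- tibble::as_tibble(utils::read.csv(path, stringsAsFactors = FALSE))
  req <- c("animal_id", "group", "region", "parameter", "value")
  miss <- setdiff(req, names(tab))
  if (length(miss)) stop("cohort table missing columns: ",
                         paste(miss, collapse = ", "), call. = FALSE)
  if (any(!is.finite(tab$value))) stop("non-finite values in cohort table",
                                       call. = FALSE)
  if (anyDuplicated(tab[, c("animal_id", "region", "parameter")]))
    stop("duplicate (animal_id, region, parameter) rows", call. = FALSE)
  tab
}

#' Write a cohort table
#' @param tab tibble as produced by [simulate_cohort()] or [read_cohort()].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(tab, path) {
  utils::write.csv(tab, path, row.names = FALSE)
  invisible(path)
}
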