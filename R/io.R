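# NIfTI-1 I/O with YAML sidecars. The volume format has no TSL field, so
# series metadata (tsl_ms, field_T, b1sl_hz) and the container kind live in a
# sidecar <path>.yaml next to the image; reading never guesses units.

sidecar_path <- function(path) {
  paste0(sub("\\.nii(\\.gz)?$", "", path), ".yaml")
}

side_file_path <- function(path) {
  gz <- grepl("\\.nii\\.gz$", path)
  paste0(sub("\\.nii(\\.gz)?$", "", path), "_side", if (gz) ".nii.gz" else ".nii")
}

#' Read a pipeline volume from NIfTI
#'
#' Reads a NIfTI file and its YAML sidecar and reconstructs the matching
#' container. The sidecar's `kind` field selects the container
#' (`tsl_series`, `b0_hz`, `b1rel`, `region_mask`); a 4D file requires
#' `tsl_ms` in the sidecar and fails with an explicit error when it is
#' missing rather than guessing.
#'
#' @param path path to a `.nii`/`.nii.gz` file written by [write_volume()]
#'   (or any NIfTI plus a hand-written sidecar).
#' @param kind optional override of the sidecar `kind`.
#' @return A [tsl_series()], [field_map()] or [region_mask()].
#' @export
read_volume <- function(path, kind = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  img <- RNifti::readNifti(path)
  pd <- RNifti::pixdim(img)
  vox <- c(pd, 1, 1, 1)[1:3]  # trailing singleton dims are dropped on disk
  arr <- array(as.vector(as.array(img)), dim(img))
  sc <- sidecar_path(path)
  meta <- if (file.exists(sc)) yaml::read_yaml(sc) else list()
  if (is.null(kind)) kind <- meta$kind
  if (is.null(kind)) {
    kind <- if (length(dim(arr)) == 4L) "tsl_series" else
      stop("cannot infer container kind: no sidecar at ", sc,
           " and no 'kind' given", call. = FALSE)
  }
  switch(kind,
    tsl_series = {
      if (is.null(meta$tsl_ms)) {
        stop("4D series at ", path, " has no TSL metadata: sidecar key 'tsl_ms' ",
             "missing from ", sc, call. = FALSE)
      }
      arr <- as_array4d(arr)
      if (dim(arr)[4] != length(meta$tsl_ms)) {
        stop("sidecar tsl_ms has ", length(meta$tsl_ms), " entries but file has ",
             dim(arr)[4], " volumes", call. = FALSE)
      }
      tsl_series(arr, unlist(meta$tsl_ms), voxel_size_mm = vox,
                 field_T = meta$field_T %||% 7,
                 b1sl_hz = meta$b1sl_hz %||% 500)
    },
    b0_hz = field_map(arr, "b0_hz", voxel_size_mm = vox),
    b1rel = field_map(arr, "b1rel", voxel_size_mm = vox),
    region_mask = {
      sf <- meta$side_file %||% side_file_path(path)
      sf <- if (file.exists(sf)) sf else file.path(dirname(path), basename(sf))
      side <- if (file.exists(sf)) {
        simg <- RNifti::readNifti(sf)
        array(as.vector(as.array(simg)), dim(simg))
      } else NULL
      region_mask(round(arr), side = if (is.null(side)) NULL else round(side),
                  voxel_size_mm = vox)
    },
    stop("unknown container kind: ", kind, call. = FALSE)
  )
}

#' Write a pipeline volume to NIfTI
#'
#' Writes the container's array as NIfTI (float for signal/field data, the
#' label volume plus a `_side` companion file for masks) and a YAML sidecar
#' carrying the kind and series metadata, so that
#' `read_volume(write_volume(x, p))` reproduces `x` to storage precision
#' with voxel size preserved. NaN voxels are preserved as NaN.
#'
#' @param object a [tsl_series()], [field_map()], [region_mask()], or bare
#'   numeric array (written as a plain map).
#' @param path output `.nii`/`.nii.gz` path.
#' @return `path`, invisibly.
#' @export
write_volume <- function(object, path) {
  dir.create(dirname(path), showWarnings = FALSE, recursive = TRUE)
  write_one <- function(arr, vox, out = path, datatype = "float") {
    img <- RNifti::asNifti(arr)
    # RNifti drops trailing singleton dims; match the pixdim length to what
    # it will store
    RNifti::pixdim(img) <- c(vox, 1)[seq_along(dim(img))]
    RNifti::writeNifti(img, out, datatype = datatype)
  }
  if (inherits(object, "tsl_series")) {
    write_one(object$volumes, object$voxel_size_mm)
    yaml::write_yaml(list(kind = "tsl_series", tsl_ms = object$tsl_ms,
                          field_T = object$field_T, b1sl_hz = object$b1sl_hz),
                     sidecar_path(path))
  } else if (inherits(object, "field_map")) {
    write_one(object$values, object$voxel_size_mm)
    yaml::write_yaml(list(kind = object$kind), sidecar_path(path))
  } else if (inherits(object, "region_mask")) {
    write_one(object$labels, object$voxel_size_mm, datatype = "int16")
    sf <- side_file_path(path)
    write_one(object$side, object$voxel_size_mm, out = sf, datatype = "int16")
    yaml::write_yaml(list(kind = "region_mask", side_file = basename(sf)),
                     sidecar_path(path))
  } else if (is.array(object) || is.numeric(object)) {
    write_one(as.array(object), c(1, 1, 1))
  } else {
    stop("cannot write object of class ", paste(class(object), collapse = "/"),
         call. = FALSE)
  }
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
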