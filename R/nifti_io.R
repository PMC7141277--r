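#' Read and write index maps as NIfTI-1
#'
#' Index maps are stored as 3D NIfTI volumes (float32) with the map type
#' encoded as a filename suffix, e.g. `sub-001_GFA.nii.gz`. Loading
#' recovers the map type from that suffix.
#'
#' @param map an `index_map`.
#' @param path output path (`.nii` or `.nii.gz`); should end in
#'   `_<TYPE>.nii[.gz]` so the type survives a round trip.
#' @return `save_index_map` returns the path invisibly; `load_index_map`
#'   returns an `index_map`.
#' @export
save_index_map <- function(map, path) {
  stopifnot(inherits(map, "index_map"))
  img <- RNifti::asNifti(map$data)
  if (!is.null(map$voxel_size))
    RNifti::pixdim(img) <- rep(map$voxel_size, 3)
  RNifti::writeNifti(img, path, datatype = "float")
  invisible(path)
}

#' @rdname save_index_map
#' @export
load_index_map <- function(path) {
  if (!file.exists(path)) stop_invalid("no such file: %s", path)
  img <- tryCatch(RNifti::readNifti(path),
                  error = function(e)
                    stop_invalid("malformed NIfTI file %s: %s", path,
                                 conditionMessage(e)))
  if (length(dim(img)) != 3)
    stop_invalid("index maps are 3D; %s has %d dimensions", path,
                 length(dim(img)))
  stem <- sub("\\.nii(\\.gz)?$", "", basename(path))
  m <- regmatches(stem, regexpr("(GFA|ISO|NQA|QA)$", stem))
  if (length(m) == 0)
    stop_invalid("cannot infer map type from filename: %s", basename(path))
  vox <- RNifti::pixdim(img)[1]
  index_map(array(as.numeric(img), dim = dim(img)), m,
            voxel_size = if (is.finite(vox) && vox > 0) vox else NULL)
}

#' Write / read a diffusion-weighted volume with its gradient table
#'
#' The 4D signal array goes to NIfTI-1 (float32) and the gradient table
#' to FSL-style plain-text `bval` / `bvec` files next to it.
#'
#' @param dwi a `dwi_volume`.
#' @param path NIfTI path; the bval/bvec paths replace its extension.
#' @return `write_dwi_nifti` returns the three paths invisibly;
#'   `read_dwi_nifti` returns a `dwi_volume`.
#' @export
write_dwi_nifti <- function(dwi, path) {
  validate_dwi_volume(dwi)
  img <- RNifti::asNifti(dwi$data)
  RNifti::pixdim(img) <- c(rep(dwi$voxel_size, 3), 1)
  RNifti::writeNifti(img, path, datatype = "float")
  stem <- sub("\\.nii(\\.gz)?$", "", path)
  write_bval_bvec(dwi$gtab, paste0(stem, ".bval"), paste0(stem, ".bvec"))
  invisible(c(path, paste0(stem, ".bval"), paste0(stem, ".bvec")))
}

#' @param bval_path,bvec_path gradient-table files; default: next to `path`.
#' @param voxel_size override for the voxel size in mm.
#' @rdname write_dwi_nifti
#' @export
read_dwi_nifti <- function(path, bval_path = NULL, bvec_path = NULL,
                           voxel_size = NULL) {
  stem <- sub("\\.nii(\\.gz)?$", "", path)
  if (is.null(bval_path)) bval_path <- paste0(stem, ".bval")
  if (is.null(bvec_path)) bvec_path <- paste0(stem, ".bvec")
  img <- RNifti::readNifti(path)
  if (length(dim(img)) != 4)
    stop_invalid("expected a 4D diffusion volume in %s", path)
  gtab <- read_bval_bvec(bval_path, bvec_path)
  if (is.null(voxel_size)) {
    vox <- RNifti::pixdim(img)[1]
    voxel_size <- if (is.finite(vox) && vox > 0) vox else 1
  }
  structure(list(data = array(as.numeric(img), dim = dim(img)),
                 gtab = gtab, voxel_size = voxel_size),
            class = "dwi_volume")
}
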