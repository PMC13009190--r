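#' Write / read a metric volume as NIfTI
#'
#' @param volume 3-D (or 4-D) numeric array.
#' @param path Output path (`.nii` / `.nii.gz`).
#' @param voxel_size Isotropic voxel edge (mm).
#' @returns `write_metric_nifti()` the path invisibly; `read_metric_nifti()`
#'   the array with a `voxel_size` attribute.
#' @export
write_metric_nifti <- function(volume, path, voxel_size = 1) {
  img <- RNifti::asNifti(unclass_array(volume))
  RNifti::pixdim(img) <- rep(voxel_size, length(dim(volume)))
  RNifti::writeNifti(img, path)
  invisible(path)
}

unclass_array <- function(x) {
  attributes(x) <- list(dim = dim(x))
  x
}

#' @rdname write_metric_nifti
#' @export
read_metric_nifti <- function(path) {
  img <- RNifti::readNifti(path)
  out <- array(as.numeric(img), dim = dim(img))
  attr(out, "voxel_size") <- RNifti::pixdim(img)[1]
  out
}

#' Write / read a surface and its per-vertex maps as TSV
#'
#' Plain-text surface exchange format: one row per vertex with the unfolded
#' and native coordinates, labels and any per-vertex metric columns. Faces
#' are written alongside as `<path>.faces.tsv` (three 1-based vertex indices
#' per row).
#'
#' @param surface A [build_midthickness_surface()] result.
#' @param path Output TSV path.
#' @param maps Optional named list of per-vertex vectors appended as columns.
#' @returns The path, invisibly.
#' @export
write_surface_tsv <- function(surface, path, maps = NULL) {
  v <- surface$vertices
  if (!is.null(maps)) for (nm in names(maps)) v[[nm]] <- maps[[nm]]
  utils::write.table(v, path, sep = "\t", row.names = FALSE, quote = FALSE)
  utils::write.table(surface$faces, paste0(path, ".faces.tsv"), sep = "\t",
                     row.names = FALSE, col.names = c("v1", "v2", "v3"),
                     quote = FALSE)
  invisible(path)
}

#' Write / read a tidy results table as TSV (lossless round trip)
#' @param table Data frame.
#' @param path TSV path.
#' @returns The path invisibly / a tibble.
#' @export
write_table_tsv <- function(table, path) {
  utils::write.table(table, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_table_tsv
#' @export
read_table_tsv <- function(path) {
  tibble::as_tibble(utils::read.table(path, sep = "\t", header = TRUE,
                                      check.names = FALSE))
}

#' Write a JSON run manifest
#' @param x Named list (config, seeds, versions, hashes).
#' @param path JSON path.
#' @returns The path, invisibly.
#' @export
write_manifest <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, pretty = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}
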