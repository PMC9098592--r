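## Minimal I/O: NIfTI volumes, text meshes, JSON reports.

#' Write a volume as NIfTI-1
#'
#' @param vol 3-D array.
#' @param space a `toy_source_space` supplying the affine.
#' @param path output path (.nii or .nii.gz).
#' @export
write_volume_nifti <- function(vol, space, path) {
  img <- RNifti::asNifti(vol)
  RNifti::qform(img) <- structure(space$affine, code = 2L)
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Read a NIfTI volume as a plain array
#'
#' @param path NIfTI file path.
#' @export
read_volume_nifti <- function(path) {
  as.array(RNifti::readNifti(path))
}

#' Write a mesh as an indexed-triangle text file
#'
#' Plain TSV with a 2-line header (vertex and triangle counts), vertex
#' coordinates in mm, then 1-based triangle indices.
#'
#' @param space a `toy_source_space`.
#' @param path output path.
#' @export
write_mesh_text <- function(space, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("vertices\t%d", nrow(space$vertices)), con)
  writeLines(sprintf("triangles\t%d", nrow(space$triangles)), con)
  utils::write.table(space$vertices, con, sep = "\t", row.names = FALSE,
                     col.names = FALSE)
  utils::write.table(space$triangles, con, sep = "\t", row.names = FALSE,
                     col.names = FALSE)
  invisible(path)
}

#' Read an indexed-triangle text mesh
#'
#' @param path file written by [write_mesh_text()].
#' @return list with `vertices` and `triangles`.
#' @export
read_mesh_text <- function(path) {
  hdr <- utils::read.delim(path, header = FALSE, nrows = 2)
  nv <- as.integer(hdr[1, 2]); nt <- as.integer(hdr[2, 2])
  v <- as.matrix(utils::read.delim(path, header = FALSE, skip = 2,
                                   nrows = nv))
  f <- as.matrix(utils::read.delim(path, header = FALSE, skip = 2 + nv,
                                   nrows = nt))
  dimnames(v) <- dimnames(f) <- NULL
  storage.mode(f) <- "integer"
  list(vertices = v, triangles = f)
}
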