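## Decomposition of reconstructed source dynamics into spatial source
## components (SCs), z-scoring, and surface-to-volume transfer for
## overlap scoring.

#' Decompose reconstructed sources into spatial components
#'
#' Spatial ICA of S' (time by vertices): S' = U S_IC with independent
#' spatial maps in the rows of S_IC. The number of components is bounded
#' by the temporal-reduction rank; `n_components = NULL` uses that bound.
#'
#' @param S V x r (reduced) or V x T source estimate, or a
#'   `source_inversion`.
#' @param n_components number of SCs (<= rank of S); NULL for the bound.
#' @param seed integer seed.
#' @return object of class `source_components`: `maps` (I x V,
#'   z-scored), `maps_raw`, `mixing` (time x I), `I`.
#' @export
decompose_sources <- function(S, n_components = NULL, seed = 1) {
  if (inherits(S, "source_inversion")) S <- S$S
  S <- as.matrix(S)
  rk <- qr(S)$rank
  if (is.null(n_components)) n_components <- rk
  if (n_components > rk) stop_invalid("n_components exceeds the rank of S")
  ica <- spatial_ica(S, n_components, seed = seed)
  structure(list(maps = ica$maps, maps_raw = ica$maps_raw,
                 mixing = ica$timecourses, center = ica$center,
                 I = n_components, explained = ica$explained),
            class = "source_components")
}

#' Z-score source-component maps
#'
#' Per component, (x - mean) / sd over vertices. Constant maps are
#' dropped with a warning and the component count decremented.
#'
#' @param sc a `source_components` (or bare I x V matrix).
#' @return the z-scored object (idempotent up to numerical tolerance).
#' @export
zscore_maps <- function(sc) {
  maps <- if (inherits(sc, "source_components")) sc$maps_raw else as.matrix(sc)
  sds <- apply(maps, 1, sd)
  keep <- sds > 0
  if (!all(keep)) warning(sum(!keep), " constant map(s) dropped")
  z <- (maps[keep, , drop = FALSE] - rowMeans(maps[keep, , drop = FALSE])) /
    sds[keep]
  if (inherits(sc, "source_components")) {
    sc$maps <- z
    sc$maps_raw <- maps[keep, , drop = FALSE]
    sc$mixing <- sc$mixing[, keep, drop = FALSE]
    sc$I <- sum(keep)
    sc
  } else z
}

#' Transfer a per-vertex map into the atlas volume
#'
#' Each atlas-labelled voxel takes the value of its nearest vertex
#' (precomputed during space construction); background stays 0.
#'
#' @param values length-V per-vertex map.
#' @param space a `toy_source_space`.
#' @return numeric 3-D array.
#' @export
surface_to_volume <- function(values, space) {
  if (length(values) != nrow(space$vertices))
    stop_invalid("one value per vertex required")
  vol <- array(0, dim = space$grid_shape)
  sel <- space$vertex_of_voxel > 0
  if (!any(sel)) {
    warning("space has no labelled voxels; all-zero volume")
    return(vol)
  }
  vol[sel] <- values[space$vertex_of_voxel[sel]]
  vol
}
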