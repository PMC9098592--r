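## Conversion of binary fMRI spatial priors (activation maps, RSNs, dFC
## modules) into source-space covariance components, and assembly of the
## algorithm-specific component sets S1/S2/S3.

#' Project a volume prior onto the cortical surface
#'
#' Nearest-neighbour interpolation: vertex v receives 1 iff its nearest
#' voxel (by mm distance of centers; rounding in voxel coordinates for
#' the diagonal affine) is non-zero. Non-binary inputs are binarized at
#' > 0 first.
#'
#' @param vol 3-D array on the space's grid.
#' @param space a `toy_source_space`.
#' @return object of class `surface_prior`: `q` (length-V 0/1 weights),
#'   `label`, `provenance`.
#' @export
volume_to_surface <- function(vol, space, label = "prior",
                              provenance = "activation") {
  if (!identical(dim(vol), dim(space$parcel_of_voxel)))
    stop_invalid("volume grid does not match the space grid")
  bin <- vol > 0
  vox <- mm_to_voxel(space$vertices, space$affine, space$grid_shape)
  lin <- vox[, 1] + 1L + space$grid_shape[1] *
    (vox[, 2] + space$grid_shape[2] * vox[, 3])
  q <- as.numeric(bin[lin])
  if (!any(q > 0)) stop("empty prior: no vertex projects onto the support")
  structure(list(q = q, label = label, provenance = provenance),
            class = "surface_prior")
}

#' Green's-function smoothing kernel of the mesh adjacency
#'
#' Truncated-exponential kernel K = sum_{i=0}^{radius} (sigma M)^i / i!
#' of the binary vertex adjacency M, with entries below 1e-8 zeroed and a
#' symmetric diagonal rescale K <- D^{-1/2} K D^{-1/2} (D = diag(K)) so
#' the kernel has unit diagonal. `literal = TRUE` instead returns
#' sigma * M itself.
#'
#' @param space a `toy_source_space`.
#' @param sigma smoothing parameter (default 0.6).
#' @param radius graph-distance support cutoff in vertices (default 8).
#' @param literal use the raw first-order form sigma * M.
#' @return object of class `green_smoother`: sparse `K`, `sigma`,
#'   `radius`.
#' @export
green_kernel <- function(space, sigma = 0.6, radius = 8, literal = FALSE) {
  if (sigma < 0) stop_invalid("sigma must be >= 0")
  if (radius < 0 || radius != round(radius)) stop_invalid("radius must be a non-negative integer")
  M <- space$adjacency
  V <- nrow(M)
  if (literal) {
    K <- sigma * M
  } else {
    sM <- sigma * M
    term <- Diagonal(V)
    K <- Diagonal(V)
    if (radius >= 1) for (i in seq_len(radius)) {
      term <- (term %*% sM) / i
      K <- K + term
    }
    K <- as(K, "CsparseMatrix")
    K@x[abs(K@x) < 1e-8] <- 0
    K <- Matrix::drop0(K)
    d <- 1 / sqrt(Matrix::diag(K))
    K <- Diagonal(V, d) %*% K %*% Diagonal(V, d)
  }
  structure(list(K = K, sigma = sigma, radius = as.integer(radius)),
            class = "green_smoother")
}

#' Smooth a surface prior with a Green's-function kernel
#'
#' @param prior a `surface_prior`.
#' @param g a `green_smoother`.
#' @return the smoothed `surface_prior` (q' = K q, non-negative).
#' @export
smooth_prior <- function(prior, g) {
  if (length(prior$q) != nrow(g$K)) stop_invalid("prior/kernel size mismatch")
  prior$q <- pmax(as.numeric(g$K %*% prior$q), 0)
  prior
}

#' Covariance component from a surface prior
#'
#' V_p = q q' (rank 1), kept in factored form and normalized to unit
#' trace (||q|| = 1) so that ReML hyperparameters are comparable across
#' priors of different spatial extent.
#'
#' @param prior a `surface_prior` with at least one positive weight.
#' @return object of class `covariance_component`; see
#'   [make_cc()] for the representation.
#' @export
prior_to_cc <- function(prior) {
  if (!any(prior$q > 0)) stop("cannot form a covariance component from an empty prior")
  q <- prior$q / sqrt(sum(prior$q^2))
  make_cc("factor", q, label = prior$label, provenance = prior$provenance)
}

#' Construct a covariance component
#'
#' Representation types: `"identity"` (V_p = I/V), `"diag"` (diagonal,
#' stored as its diagonal), `"factor"` (rank 1, V_p = q q'), `"full"`
#' (dense symmetric PSD). All are normalized to unit trace.
#'
#' @param type one of "identity", "diag", "factor", "full".
#' @param value NULL, diagonal vector, factor vector or full matrix.
#' @param label character label.
#' @param provenance one of "algorithm-intrinsic", "activation", "rsn",
#'   "dfc-module".
#' @param dim_v source-space dimension (required for "identity").
#' @export
make_cc <- function(type = c("identity", "diag", "factor", "full"),
                    value = NULL, label = "cc",
                    provenance = "algorithm-intrinsic", dim_v = NULL) {
  type <- match.arg(type)
  if (type == "identity") {
    if (is.null(dim_v)) stop_invalid("dim_v required for identity CC")
  } else if (type == "diag") {
    value <- as.numeric(value)
    if (any(value < 0)) stop_invalid("diagonal CC must be non-negative")
    value <- value / sum(value)
  } else if (type == "factor") {
    value <- as.numeric(value)
    value <- value / sqrt(sum(value^2))
  } else {
    value <- as.matrix(value)
    value <- (value + t(value)) / 2
    value <- value / sum(diag(value))
  }
  structure(list(type = type, value = value, label = label,
                 provenance = provenance, dim_v = dim_v),
            class = "covariance_component")
}

#' Materialize a covariance component as a dense matrix
#'
#' @param cc a `covariance_component`.
#' @param dim_v source dimension (for identity CCs).
#' @export
cc_matrix <- function(cc, dim_v = NULL) {
  V <- dim_v %||% cc$dim_v %||%
    switch(cc$type, diag = length(cc$value), factor = length(cc$value),
           full = nrow(cc$value),
           stop_invalid("dim_v required"))
  switch(cc$type,
         identity = diag(V) / V,
         diag = diag(cc$value, V),
         factor = tcrossprod(cc$value),
         full = cc$value)
}

## L V_p L' for a covariance component, without materializing V_p
cc_channel_projection <- function(cc, L) {
  switch(cc$type,
         identity = tcrossprod(L) / ncol(L),
         diag = tcrossprod(L %*% diag(cc$value, length(cc$value)), L),
         factor = tcrossprod(as.numeric(L %*% cc$value)),
         full = L %*% cc$value %*% t(L))
}

## V_p L' (V x C), used when forming the posterior source estimate
cc_source_projection <- function(cc, L) {
  switch(cc$type,
         identity = t(L) / ncol(L),
         diag = cc$value * t(L),
         factor = outer(cc$value, as.numeric(L %*% cc$value)),
         full = cc$value %*% t(L))
}

#' Assemble an algorithm-specific covariance-component set
#'
#' S1 holds only the algorithm's intrinsic components; S2 adds RSN
#' components (plus activation components on task runs); S3 adds the
#' dFC-state module components and is defined for task runs only.
#'
#' @param algorithm one of "MN", "LORETA", "EBB", "MSP".
#' @param intrinsic list of algorithm-intrinsic `covariance_component`s.
#' @param rsn,activation,dfc_modules lists of fMRI-prior components.
#' @param set_name one of "S1", "S2", "S3".
#' @param run_type "task" or "rest".
#' @return object of class `cc_set`: ordered `ccs`, `algorithm`,
#'   `set_name`, `run_type`, `counts`.
#' @export
assemble_cc_set <- function(algorithm, intrinsic, rsn = list(),
                            activation = list(), dfc_modules = list(),
                            set_name = c("S1", "S2", "S3"),
                            run_type = c("task", "rest")) {
  algorithm <- match.arg(algorithm, c("MN", "LORETA", "EBB", "MSP"))
  set_name <- match.arg(set_name)
  run_type <- match.arg(run_type)
  if (set_name == "S3" && run_type == "rest")
    stop_invalid("S3 includes task-derived dFC modules and is only defined for task runs")
  ccs <- intrinsic
  counts <- c(intrinsic = length(intrinsic), rsn = 0L, activation = 0L,
              dfc = 0L)
  if (set_name %in% c("S2", "S3")) {
    ccs <- c(ccs, rsn)
    counts["rsn"] <- length(rsn)
    if (run_type == "task") {
      ccs <- c(ccs, activation)
      counts["activation"] <- length(activation)
    }
  }
  if (set_name == "S3") {
    ccs <- c(ccs, dfc_modules)
    counts["dfc"] <- length(dfc_modules)
  }
  structure(list(ccs = ccs, algorithm = algorithm, set_name = set_name,
                 run_type = run_type, counts = counts),
            class = "cc_set")
}
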