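## Synthetic paradigms, EEG and parcel-BOLD generators, ROI spheres and
## surrogate network templates. Everything is seed-reproducible.

#' Construct a block paradigm
#'
#' @param conditions character vector of condition names.
#' @param onsets list (one numeric vector per condition) of block onsets in
#'   seconds.
#' @param durations list of block durations in seconds (recycled scalars
#'   allowed).
#' @param n_samples run length in samples.
#' @param TR sampling interval in seconds.
#' @return object of class `paradigm`.
#' @export
make_paradigm <- function(conditions, onsets, durations, n_samples, TR) {
  if (!length(conditions)) stop_invalid("at least one condition required")
  if (length(onsets) != length(conditions) ||
      length(durations) != length(conditions))
    stop_invalid("onsets/durations must match conditions")
  durations <- lapply(seq_along(onsets), function(i) {
    d <- durations[[i]]
    if (length(d) == 1) rep(d, length(onsets[[i]])) else d
  })
  run_s <- n_samples * TR
  for (i in seq_along(onsets)) {
    if (any(onsets[[i]] < 0) || any(onsets[[i]] + durations[[i]] > run_s))
      stop_invalid("blocks must fit within the run")
  }
  structure(list(conditions = conditions, onsets = onsets,
                 durations = durations, n_samples = as.integer(n_samples),
                 TR = TR), class = "paradigm")
}

#' Default block paradigm emulating an alternating two-condition task run
#'
#' Twelve 40 s blocks (six per condition, interleaved) after a 10 s
#' lead-in, at TR = 1 s over 500 samples.
#'
#' @param n_samples run length in samples.
#' @param TR sampling interval (s).
#' @param n_conditions number of interleaved conditions.
#' @param block_s block duration (s).
#' @param n_blocks total number of blocks.
#' @param lead_in_s initial rest period (s).
#' @export
default_paradigm <- function(n_samples = 500, TR = 1, n_conditions = 2,
                             block_s = 40, n_blocks = 12, lead_in_s = 10) {
  fit_blocks <- floor((n_samples * TR - lead_in_s) / block_s)
  n_blocks <- max(n_conditions, min(n_blocks, fit_blocks))
  onsets_all <- lead_in_s + block_s * (0:(n_blocks - 1))
  conds <- paste0("cond", seq_len(n_conditions))
  onsets <- lapply(seq_len(n_conditions), function(i)
    onsets_all[seq(i, n_blocks, by = n_conditions)])
  make_paradigm(conds, onsets, as.list(rep(block_s, n_conditions)),
                n_samples, TR)
}

## per-sample condition index (0 = no block) for a paradigm
paradigm_schedule <- function(paradigm) {
  sched <- integer(paradigm$n_samples)
  t_s <- (seq_len(paradigm$n_samples) - 1) * paradigm$TR
  for (i in seq_along(paradigm$conditions)) {
    for (b in seq_along(paradigm$onsets[[i]])) {
      on <- paradigm$onsets[[i]][b]
      off <- on + paradigm$durations[[i]][b]
      sched[t_s >= on & t_s < off] <- i
    }
  }
  sched
}

#' Construct a synthetic EEG scene
#'
#' A scene is a set of active cortical patches (vertex index sets), one
#' source time-course per patch, and a channel noise level.
#'
#' @param patches list of integer vertex index vectors.
#' @param timecourses matrix with one row per patch (n_patches x T).
#' @param noise_sd channel noise standard deviation (>= 0).
#' @param seed integer seed for the noise stream.
#' @export
make_scene <- function(patches, timecourses, noise_sd = 0, seed = 1) {
  if (!length(patches)) stop_invalid("scene needs at least one patch")
  if (is.vector(timecourses)) timecourses <- matrix(timecourses, nrow = 1)
  if (nrow(timecourses) != length(patches))
    stop_invalid("one time-course row per patch required")
  if (noise_sd < 0) stop_invalid("noise_sd must be >= 0")
  structure(list(patches = patches, timecourses = timecourses,
                 noise_sd = noise_sd, seed = as.integer(seed)),
            class = "synthetic_scene")
}

#' Simulate EEG from planted patch sources
#'
#' Realizes the generative model Y = L S + noise with S supported on the
#' scene's patches; returns both the channel data and the ground-truth
#' source array.
#'
#' @param space a `toy_source_space`.
#' @param leadfield C x V leadfield.
#' @param scene a `synthetic_scene`.
#' @param fs sampling rate in Hz (metadata only).
#' @return list with `Y` (C x T), `S_true` (V x T), `fs`, `scene`.
#' @export
simulate_eeg <- function(space, leadfield, scene, fs = 60) {
  V <- nrow(space$vertices)
  if (!inherits(scene, "synthetic_scene")) stop_invalid("scene must be a synthetic_scene")
  for (p in scene$patches) {
    if (!length(p)) stop_invalid("empty patch in scene")
    if (any(p < 1 | p > V)) stop_invalid("patch vertex index out of range")
  }
  T_ <- ncol(scene$timecourses)
  S <- matrix(0, V, T_)
  for (i in seq_along(scene$patches))
    S[scene$patches[[i]], ] <- S[scene$patches[[i]], , drop = FALSE] +
      matrix(scene$timecourses[i, ], length(scene$patches[[i]]), T_, byrow = TRUE)
  Y <- leadfield %*% S
  if (scene$noise_sd > 0) {
    set.seed(sub_seed(scene$seed, 3))
    Y <- Y + scene$noise_sd * matrix(rnorm(length(Y)), nrow(Y), ncol(Y))
  }
  list(Y = unclass(Y), S_true = S, fs = fs, scene = scene)
}

#' Simulate parcel-averaged BOLD with planted connectivity states
#'
#' During blocks of condition i the parcels share a common narrow-band
#' oscillation multiplied by the sign/magnitude pattern of planted state i,
#' plus independent Gaussian noise; this is the minimal structure that
#' makes instantaneous phase coherence recover the state.
#'
#' @param n_parcels number of parcels N.
#' @param paradigm a `paradigm`; condition i drives planted state i.
#' @param planted_states list of N-vectors (state patterns).
#' @param snr amplitude-to-noise-sd ratio; `Inf` for noiseless.
#' @param seed integer seed.
#' @param f_osc oscillation frequency (Hz), inside the 0.01-0.1 Hz band.
#' @param active_parcels optional list (one integer vector per condition)
#'   of parcels that additionally receive an HRF-convolved boxcar
#'   response of amplitude `task_amplitude` during that condition's
#'   blocks.
#' @param task_amplitude amplitude of the planted task response.
#' @return list of class `parcel_timeseries` with `values` (N x T), `TR`,
#'   `labels` and attribute-like fields `schedule` and `states`.
#' @export
simulate_parcel_bold <- function(n_parcels, paradigm, planted_states,
                                 snr = 2, seed = 1, f_osc = 0.05,
                                 active_parcels = NULL,
                                 task_amplitude = 1) {
  if (!inherits(paradigm, "paradigm")) stop_invalid("paradigm required")
  for (s in planted_states)
    if (length(s) != n_parcels) stop_invalid("planted state length must equal n_parcels")
  if (length(planted_states) < length(paradigm$conditions))
    stop_invalid("need one planted state per condition")
  N <- n_parcels; T_ <- paradigm$n_samples; TR <- paradigm$TR
  sched <- paradigm_schedule(paradigm)
  set.seed(sub_seed(seed, 4))
  t_s <- (seq_len(T_) - 1) * TR
  X <- matrix(0, N, T_)
  ## fresh oscillation phase per block keeps blocks independent
  blocks <- rle(sched)
  pos <- cumsum(c(1, head(blocks$lengths, -1)))
  ## states are rescaled to unit maximum magnitude so that `snr` is the
  ## per-parcel oscillation-amplitude to noise-sd ratio
  scaled <- lapply(planted_states, function(s) s / max(abs(s)))
  for (b in seq_along(blocks$values)) {
    ci <- blocks$values[b]
    if (ci == 0) next
    idx <- pos[b]:(pos[b] + blocks$lengths[b] - 1)
    osc <- sin(2 * pi * f_osc * t_s[idx] + runif(1, 0, 2 * pi))
    X[, idx] <- scaled[[ci]] %o% osc
  }
  if (!is.null(active_parcels)) {
    design <- build_design(paradigm)
    for (ci in seq_along(active_parcels)) {
      reg <- design[, ci]
      for (p in active_parcels[[ci]])
        X[p, ] <- X[p, ] + task_amplitude * reg
    }
  }
  if (is.finite(snr)) X <- X + matrix(rnorm(N * T_, sd = 1 / snr), N, T_)
  structure(list(values = X, TR = TR, labels = paste0("parcel", seq_len(N)),
                 schedule = sched, states = planted_states,
                 seed = as.integer(seed)),
            class = "parcel_timeseries")
}

#' Spherical ROI volume
#'
#' Binary volume on the space's grid: a voxel is included iff its center
#' lies within `radius_mm` of `center_mm`.
#'
#' @param center_mm length-3 mm coordinates.
#' @param radius_mm sphere radius in mm (> 0).
#' @param space a `toy_source_space` supplying grid and affine.
#' @return 3-D 0/1 array; warns (not errors) when the result is empty.
#' @export
make_roi_volume <- function(center_mm, radius_mm, space) {
  if (radius_mm <= 0) stop_invalid("radius_mm must be > 0")
  centers <- voxel_centers(space$grid_shape, space$affine)
  d2 <- rowSums(sweep(centers, 2, center_mm)^2)
  vol <- array(0L, dim = space$grid_shape)
  vol[d2 <= radius_mm^2] <- 1L
  if (!sum(vol)) warning("ROI sphere does not intersect the voxel grid; empty map")
  vol
}

#' Bundled motion-sensitive ROI definitions
#'
#' The eight 10 mm spherical regions of interest used for overlap scoring:
#' bilateral anterior insula (aINS), extrastriate body area (EBA),
#' fusiform body area (FBA) and fusiform gyrus (FFG), at their standard
#' MNI coordinates.
#'
#' @return data.frame with columns `name`, `x`, `y`, `z`, `radius_mm`.
#' @export
motion_rois <- function() {
  path <- system.file("extdata", "motion_rois.tsv", package = "fmripeb")
  utils::read.delim(path, stringsAsFactors = FALSE)
}

#' Surrogate network template volumes
#'
#' Generates `n_templates` binary template volumes as contiguous blobs of
#' parcels, regenerating (up to 100 attempts) until all pairwise Dice
#' coefficients are below 0.2.
#'
#' @param space a `toy_source_space`.
#' @param n_templates number of templates (>= 2).
#' @param seed integer seed.
#' @param max_dice pairwise Dice bound (default 0.2).
#' @return list of binary 3-D arrays.
#' @export
make_template_set <- function(space, n_templates, seed = 1, max_dice = 0.2) {
  if (n_templates < 2) stop_invalid("n_templates must be >= 2")
  N <- space$n_parcels
  ## parcel adjacency graph from vertex adjacency
  pl <- space$parcel_of_vertex
  Z <- sparseMatrix(i = seq_along(pl), j = pl, x = 1,
                    dims = c(length(pl), N))
  P <- as.matrix(Matrix::t(Z) %*% space$adjacency %*% Z)
  padj <- lapply(seq_len(N), function(p) setdiff(which(P[p, ] > 0), p))
  size <- max(2L, floor(N / (n_templates + 1)))
  grow_blob <- function() {
    blob <- sample.int(N, 1)
    while (length(blob) < size) {
      cand <- setdiff(unique(unlist(padj[blob])), blob)
      if (!length(cand)) break
      blob <- c(blob, cand[sample.int(length(cand), 1)])
    }
    v <- array(0L, dim = space$grid_shape)
    v[space$parcel_of_voxel %in% blob] <- 1L
    v
  }
  ## sequential: each template is regenerated until it clears the Dice
  ## bound against the accepted ones
  set.seed(sub_seed(seed, 100))
  vols <- list()
  for (i in seq_len(n_templates)) {
    placed <- FALSE
    for (attempt in seq_len(100)) {
      v <- grow_blob()
      if (!sum(v)) next
      ok <- all(vapply(vols, function(u) dice_overlap(u, v)$d < max_dice,
                       TRUE))
      if (ok) { vols[[i]] <- v; placed <- TRUE; break }
    }
    if (!placed)
      stop("could not generate templates satisfying the pairwise Dice ",
           "bound after 100 attempts")
  }
  vols
}
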