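## Task-activation mapping: canonical double-gamma HRF, boxcar design
## matrices, per-unit OLS, contrast Z-maps and cluster-extent thresholding.

#' Canonical double-gamma HRF kernel
#'
#' h(t) = dgamma(t, peak_delay/disp, scale = disp) -
#' dgamma(t, under_delay/disp_u, scale = disp_u)/ratio, sampled at `dt`
#' over `length_s` seconds and scaled to unit peak.
#'
#' @param dt sampling interval (s).
#' @param peak_delay response peak delay (s, default 6).
#' @param under_delay undershoot delay (s, default 16).
#' @param dispersion,under_dispersion gamma dispersions (default 1).
#' @param ratio peak-to-undershoot ratio (default 6).
#' @param length_s kernel length (s, default 32).
#' @return numeric kernel vector.
#' @export
canonical_hrf <- function(dt, peak_delay = 6, under_delay = 16,
                          dispersion = 1, under_dispersion = 1,
                          ratio = 6, length_s = 32) {
  t <- seq(0, length_s, by = dt)
  h <- dgamma(t, shape = peak_delay / dispersion, scale = dispersion) -
    dgamma(t, shape = under_delay / under_dispersion,
           scale = under_dispersion) / ratio
  h / max(h)
}

#' Build a design matrix from a block paradigm
#'
#' Per condition, a unit boxcar (ones during blocks, zeros elsewhere)
#' sampled at TR is convolved with the canonical double-gamma HRF and
#' truncated to the run length; an intercept column is appended.
#'
#' @param paradigm a `paradigm`.
#' @param hrf optional kernel (default [canonical_hrf()] at the
#'   paradigm's TR); pass `NULL` to skip convolution (raw boxcars).
#' @return T x (n_conditions + 1) matrix with named columns, class
#'   `design_matrix`; the HRF kernel is kept in attribute `hrf`.
#' @export
build_design <- function(paradigm, hrf = canonical_hrf(paradigm$TR)) {
  T_ <- paradigm$n_samples
  ## reject overlapping blocks within a condition
  for (i in seq_along(paradigm$conditions)) {
    on <- paradigm$onsets[[i]]; du <- paradigm$durations[[i]]
    o <- order(on)
    if (length(on) > 1 && any(on[o][-1] < (on[o] + du[o])[-length(on)]))
      stop_invalid("overlapping blocks within condition ",
                   paradigm$conditions[i])
  }
  t_s <- (seq_len(T_) - 1) * paradigm$TR
  X <- sapply(seq_along(paradigm$conditions), function(i) {
    box <- numeric(T_)
    for (b in seq_along(paradigm$onsets[[i]])) {
      on <- paradigm$onsets[[i]][b]
      box[t_s >= on & t_s < on + paradigm$durations[[i]][b]] <- 1
    }
    if (is.null(hrf)) box else convolve(box, rev(hrf), type = "open")[seq_len(T_)]
  })
  X <- cbind(X, 1)
  colnames(X) <- c(paradigm$conditions, "intercept")
  structure(X, hrf = hrf, class = c("design_matrix", "matrix", "array"))
}

#' Contrast time-course
#'
#' Weighted combination of task regressors (intercept excluded), used for
#' correlating dFC-state weights with the task.
#'
#' @param design a `design_matrix`.
#' @param weights contrast weights over the task regressors.
#' @return numeric vector of length T.
#' @export
contrast_timecourse <- function(design, weights) {
  taskcols <- setdiff(colnames(design), "intercept")
  if (length(weights) != length(taskcols))
    stop_invalid("weights must match the task regressors")
  as.numeric(design[, taskcols, drop = FALSE] %*% weights)
}

#' Fit a mass-univariate GLM
#'
#' Ordinary least squares per unit (parcel or voxel).
#'
#' @param ts units x T data matrix.
#' @param X T x R design matrix, full column rank.
#' @return object of class `glm_fit`: `betas` (R x units), `sigma2`
#'   (residual variances), `df` (T - rank), `X`, `XtXinv`.
#' @export
fit_glm <- function(ts, X) {
  ts <- as.matrix(ts); X <- unclass(X)
  if (ncol(ts) != nrow(X)) stop_invalid("time dimensions disagree")
  qx <- qr(X)
  if (qx$rank < ncol(X)) stop_invalid("design matrix is rank-deficient")
  betas <- qr.coef(qx, t(ts))
  fitted <- X %*% betas
  rss <- colSums((t(ts) - fitted)^2)
  df <- nrow(X) - qx$rank
  structure(list(betas = betas, sigma2 = rss / df, df = df, X = X,
                 XtXinv = chol2inv(qr.R(qx)),
                 data_scale = rowMeans(ts^2)),
            class = "glm_fit")
}

#' Contrast Z-map from a GLM fit
#'
#' t = c'beta / se(c'beta) per unit, converted to a Z score through the
#' normal quantile of the t cumulative distribution (log-scale tails for
#' numerical stability). Zero-variance units receive Z = 0 and are
#' flagged.
#'
#' @param glm a `glm_fit`.
#' @param cvec contrast weights, one per regressor.
#' @return object of class `stat_map`: `z` per unit, `t`, `df`,
#'   `contrast`, `flagged` (zero-variance unit indices).
#' @export
contrast_zmap <- function(glm, cvec) {
  if (length(cvec) != nrow(glm$betas))
    stop_invalid("contrast length must equal the number of regressors")
  eff <- as.numeric(cvec %*% glm$betas)
  vfac <- as.numeric(t(cvec) %*% glm$XtXinv %*% cvec)
  se <- sqrt(glm$sigma2 * vfac)
  ## residual variance at numerical-noise level relative to the data:
  ## the t ratio is 0/0 garbage there
  flagged <- which(glm$sigma2 <= 1e-20 * (glm$data_scale + 1e-300))
  tval <- ifelse(se > 0, eff / se, 0)
  z <- t_to_z(tval, glm$df)
  z[flagged] <- 0
  structure(list(z = z, t = tval, df = glm$df, contrast = cvec,
                 flagged = flagged), class = "stat_map")
}

## t -> Z via matched tail probabilities, stable for large |t|
t_to_z <- function(t, df) {
  logp <- pt(abs(t), df, lower.tail = FALSE, log.p = TRUE)
  sign(t) * qnorm(logp, lower.tail = FALSE, log.p = TRUE)
}

#' 26-connected component labelling of a 3-D mask
#'
#' @param mask logical/0-1 3-D array.
#' @return integer array of component labels (0 = background).
#' @export
label_components <- function(mask) {
  dm <- dim(mask)
  lab <- array(0L, dm)
  off <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
  off <- off[rowSums(abs(off)) > 0, ]
  idx_all <- which(mask != 0, arr.ind = TRUE)
  if (!nrow(idx_all)) return(lab)
  inside <- array(FALSE, dm); inside[mask != 0] <- TRUE
  nextlab <- 0L
  for (r in seq_len(nrow(idx_all))) {
    v <- idx_all[r, ]
    if (lab[v[1], v[2], v[3]] != 0L) next
    nextlab <- nextlab + 1L
    frontier <- matrix(v, 1)
    lab[v[1], v[2], v[3]] <- nextlab
    while (nrow(frontier)) {
      cand <- do.call(rbind, lapply(seq_len(nrow(off)), function(o)
        sweep(frontier, 2, off[o, ], `+`)))
      keep <- cand[, 1] >= 1 & cand[, 1] <= dm[1] &
        cand[, 2] >= 1 & cand[, 2] <= dm[2] &
        cand[, 3] >= 1 & cand[, 3] <= dm[3]
      cand <- cand[keep, , drop = FALSE]
      if (!nrow(cand)) break
      lin <- cand[, 1] + dm[1] * (cand[, 2] - 1L + dm[2] * (cand[, 3] - 1L))
      new <- cand[inside[lin] & lab[lin] == 0L, , drop = FALSE]
      if (!nrow(new)) break
      new <- new[!duplicated(new), , drop = FALSE]
      lin <- new[, 1] + dm[1] * (new[, 2] - 1L + dm[2] * (new[, 3] - 1L))
      lab[lin] <- nextlab
      frontier <- new
    }
  }
  lab
}

#' Threshold a Z volume with a cluster-extent rule
#'
#' Keeps voxels with Z > `z_thresh`, then removes 26-connected clusters
#' smaller than `min_cluster_voxels`. The extent rule is a configurable
#' stand-in for random-field cluster p-values; see
#' [calibrate_cluster_extent()].
#'
#' @param zvol 3-D array of Z values.
#' @param z_thresh voxel threshold (default 2.5).
#' @param min_cluster_voxels minimum surviving cluster size.
#' @return binary 3-D array.
#' @export
threshold_map <- function(zvol, z_thresh = 2.5, min_cluster_voxels = 1) {
  mask <- zvol > z_thresh
  if (!any(mask)) return(array(0L, dim(zvol)))
  lab <- label_components(mask)
  sizes <- tabulate(lab[lab > 0])
  keep <- which(sizes >= min_cluster_voxels)
  out <- array(0L, dim(zvol))
  out[lab %in% keep] <- 1L
  out
}

#' Calibrate a cluster-extent threshold on pure noise
#'
#' Chooses the smallest extent such that at most `alpha` of the
#' supra-threshold clusters observed on `n_sim` seeded white-noise volumes
#' of the same grid survive.
#'
#' @param grid_shape 3-D grid dimensions.
#' @param z_thresh voxel threshold.
#' @param alpha surviving-cluster fraction (default 0.05).
#' @param n_sim noise simulations (default 50).
#' @param seed integer seed.
#' @return integer extent (voxels).
#' @export
calibrate_cluster_extent <- function(grid_shape, z_thresh = 2.5,
                                     alpha = 0.05, n_sim = 50, seed = 1) {
  set.seed(sub_seed(seed, 7))
  sizes <- integer(0)
  for (s in seq_len(n_sim)) {
    z <- array(rnorm(prod(grid_shape)), grid_shape)
    lab <- label_components(z > z_thresh)
    if (max(lab) > 0) sizes <- c(sizes, tabulate(lab[lab > 0]))
  }
  if (!length(sizes)) return(1L)
  as.integer(stats::quantile(sizes, 1 - alpha, type = 1)) + 1L
}

#' Map per-parcel values into a volume
#'
#' @param values one value per parcel.
#' @param space a `toy_source_space`.
#' @return 3-D array (background 0).
#' @export
parcel_to_volume <- function(values, space) {
  if (length(values) != space$n_parcels)
    stop_invalid("one value per parcel required")
  vol <- array(0, dim = space$grid_shape)
  sel <- space$parcel_of_voxel > 0
  vol[sel] <- values[space$parcel_of_voxel[sel]]
  vol
}
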