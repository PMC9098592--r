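## Spatial ICA (fixed-point negentropy extraction) and mutually exclusive
## Dice-based template assignment of independent-component maps.

## Symmetric FastICA with the logcosh contrast. X is n x p with the
## sources along rows of the returned S (n.comp x p). Deterministic for a
## fixed seed; each source row's largest-magnitude element is made
## positive for a stable sign convention.
fastica_core <- function(X, n.comp, seed = 1, maxit = 500, tol = 1e-9) {
  n <- nrow(X); p <- ncol(X)
  if (n.comp > min(n, p)) stop_invalid("n.comp exceeds min(dim(X))")
  Xc <- X - rowMeans(X)
  cv <- tcrossprod(Xc) / p
  e <- eigen(cv, symmetric = TRUE)
  pos <- e$values[seq_len(n.comp)]
  if (any(pos <= 0)) stop_invalid("data rank below n.comp")
  Kw <- diag(1 / sqrt(pos), n.comp) %*% t(e$vectors[, seq_len(n.comp), drop = FALSE])
  Z <- Kw %*% Xc                              # whitened, n.comp x p
  set.seed(sub_seed(seed, 8))
  W <- matrix(rnorm(n.comp^2), n.comp)
  sym_decorrelate <- function(W) {
    s <- La.svd(W)
    s$u %*% s$vt
  }
  W <- sym_decorrelate(W)
  for (it in seq_len(maxit)) {
    WZ <- W %*% Z
    g <- tanh(WZ)
    gp <- 1 - g^2
    W1 <- g %*% t(Z) / p - diag(rowMeans(gp), n.comp) %*% W
    W1 <- sym_decorrelate(W1)
    delta <- max(abs(abs(diag(W1 %*% t(W))) - 1))
    W <- W1
    if (delta < tol) break
  }
  S <- W %*% Z
  flip <- apply(S, 1, function(s) sign(s[which.max(abs(s))]))
  S <- S * flip
  A <- MASS::ginv(W %*% Kw) # n x n.comp mixing (columns)
  A <- sweep(A, 2, flip, `*`)
  list(S = S, A = A, center = rowMeans(X), iterations = it,
       converged = delta < tol)
}

#' Spatial independent component analysis
#'
#' Decomposes a units x T data matrix into spatially independent
#' component maps (over units) and mixing time-courses, using symmetric
#' fixed-point negentropy (logcosh) extraction on the transposed data.
#' Components are ordered by explained variance and the maps are
#' z-scored over units.
#'
#' @param data units x T matrix (parcels/voxels by time). Runs may be
#'   temporally concatenated beforehand for group-level decomposition.
#' @param n_components number of components (<= min(units, T)).
#' @param seed integer seed.
#' @return object of class `spatial_ica`: `maps` (I x units, z-scored),
#'   `maps_raw`, `timecourses` (T x I), `explained`, `converged`.
#' @export
spatial_ica <- function(data, n_components, seed = 1) {
  X <- as.matrix(data)
  if (n_components > min(dim(X)))
    stop_invalid("n_components exceeds min(units, T)")
  res <- fastica_core(t(X), n_components, seed = seed)
  ## explained variance of each component's rank-1 term
  ev <- vapply(seq_len(n_components), function(i)
    fnorm2(outer(res$A[, i], res$S[i, ])), 0)
  ord <- order(ev, decreasing = TRUE)
  maps_raw <- res$S[ord, , drop = FALSE]
  maps <- (maps_raw - rowMeans(maps_raw)) / apply(maps_raw, 1, sd)
  structure(list(maps = maps, maps_raw = maps_raw,
                 timecourses = res$A[, ord, drop = FALSE],
                 center = res$center,
                 explained = ev[ord] / sum(ev),
                 converged = res$converged),
            class = "spatial_ica")
}

#' Mutually exclusive template assignment by Dice overlap
#'
#' Binarizes IC maps at |Z| >= `z_thresh` and computes their Dice overlap
#' with each binary template. If the per-template best ICs are already
#' distinct, that greedy assignment is returned. Otherwise template
#' orderings are evaluated (all permutations when `n!` <= `max_perm`,
#' otherwise `max_perm` seeded random orderings): per ordering, templates
#' sequentially claim their best remaining IC, and the ordering with the
#' highest mean Dice across all templates wins.
#'
#' @param ic_vols list of numeric 3-D arrays (IC z-maps in volume space).
#' @param templates list of binary 3-D arrays on the same grid.
#' @param z_thresh IC binarization threshold (default 3.0, two-sided).
#' @param max_perm ordering cap (default 10000).
#' @param seed integer seed for sampled orderings.
#' @return object of class `template_assignment`: `assignment` (template
#'   -> IC index, NA when unassigned), `dice` (template x IC matrix),
#'   `mean_dice`, `n_orderings`, `exhaustive`.
#' @export
assign_templates <- function(ic_vols, templates, z_thresh = 3.0,
                             max_perm = 10000, seed = 1) {
  if (!length(ic_vols) || !length(templates))
    stop_invalid("need at least one IC map and one template")
  dm <- dim(templates[[1]])
  for (v in c(ic_vols, templates))
    if (!identical(dim(v), dm)) stop_invalid("all maps must share one grid")
  nT <- length(templates); nI <- length(ic_vols)
  ics <- lapply(ic_vols, function(v) (abs(v) >= z_thresh) * 1L)
  D <- matrix(0, nT, nI)
  for (i in seq_len(nT)) for (j in seq_len(nI)) {
    if (sum(templates[[i]]) == 0) next
    D[i, j] <- dice_overlap(templates[[i]], ics[[j]])$d
  }
  greedy <- apply(D, 1, which.max)
  if (!anyDuplicated(greedy) && nT <= nI) {
    return(structure(list(assignment = greedy, dice = D,
                          mean_dice = mean(D[cbind(seq_len(nT), greedy)]),
                          n_orderings = 0L, exhaustive = TRUE),
                     class = "template_assignment"))
  }
  exhaustive <- factorial(nT) <= max_perm
  orders <- if (exhaustive) all_permutations(nT) else {
    set.seed(sub_seed(seed, 9))
    t(replicate(max_perm, sample.int(nT)))
  }
  eval_order <- function(ord) {
    taken <- logical(nI)
    asg <- rep(NA_integer_, nT)
    for (ti in ord) {
      avail <- which(!taken)
      if (!length(avail)) break
      j <- avail[which.max(D[ti, avail])]
      asg[ti] <- j
      taken[j] <- TRUE
    }
    asg
  }
  best <- NULL; best_mean <- -Inf
  for (r in seq_len(nrow(orders))) {
    asg <- eval_order(orders[r, ])
    got <- !is.na(asg)
    md <- sum(D[cbind(which(got), asg[got])]) / nT
    if (md > best_mean) { best_mean <- md; best <- asg }
  }
  structure(list(assignment = best, dice = D, mean_dice = best_mean,
                 n_orderings = nrow(orders), exhaustive = exhaustive),
            class = "template_assignment")
}
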