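## Signed-modularity community detection for dFC-state connectivity.
## Positive and negative edge weights are handled with the asymmetric
## weighting convention: the positive-part modularity is weighted by
## 1/v+ and the negative part by 1/(v+ + v-), where v+ and v- are the
## total positive and negative strengths.

#' Signed modularity of a partition
#'
#' Q = Q+ / v+ - Q- / (v+ + v-), where Q+- sum (W+- - s s' / v+-) over
#' same-community ordered pairs (self-pairs included, as in the standard
#' configuration-null convention; they are partition-invariant).
#'
#' @param W square symmetric weight matrix (may contain negative entries).
#' @param labels integer community labels, one per node.
#' @return scalar Q.
#' @export
signed_modularity <- function(W, labels) {
  Wp <- pmax(W, 0); Wn <- -pmin(W, 0)
  sp <- rowSums(Wp); sn <- rowSums(Wn)
  vp <- sum(sp); vn <- sum(sn)
  q <- 0
  for (c in unique(labels)) {
    idx <- labels == c
    if (vp > 0)
      q <- q + (sum(Wp[idx, idx]) - sum(sp[idx])^2 / vp) / vp
    if (vn > 0)
      q <- q - (sum(Wn[idx, idx]) - sum(sn[idx])^2 / vn) / (vp + vn)
  }
  q
}

## One optimization run: greedy local moving from singletons (seeded node
## order, moves to any existing or a fresh community) alternated with
## best-pair community merging, until neither phase improves Q.
louvain_signed_once <- function(W, seed) {
  n <- nrow(W)
  Wp <- pmax(W, 0); Wn <- -pmin(W, 0)
  sp <- rowSums(Wp); sn <- rowSums(Wn)
  vp <- sum(sp); vn <- sum(sn)
  cp <- if (vp > 0) 1 / vp else 0
  cn <- if (vn > 0) 1 / (vp + vn) else 0
  nullp <- if (vp > 0) 1 / vp else 0
  nulln <- if (vn > 0) 1 / vn else 0
  labels <- seq_len(n)
  set.seed(sub_seed(seed, 6))
  gain_eps <- 1e-12
  repeat {
    improved <- FALSE
    ## --- local moving ---
    repeat {
      moved <- FALSE
      for (i in sample.int(n)) {
        ids <- sort(unique(labels))
        Sp <- vapply(ids, function(c) sum(sp[labels == c]), 0)
        Sn <- vapply(ids, function(c) sum(sn[labels == c]), 0)
        wip <- vapply(ids, function(c) sum(Wp[i, labels == c]), 0)
        win <- vapply(ids, function(c) sum(Wn[i, labels == c]), 0)
        cur <- match(labels[i], ids)
        ## contribution of node i when placed in community c (i excluded)
        contrib <- function(j, excl_self) {
          Spc <- Sp[j]; Snc <- Sn[j]; wp <- wip[j]; wn <- win[j]
          if (excl_self) { Spc <- Spc - sp[i]; Snc <- Snc - sn[i]
                           wp <- wp - Wp[i, i]; wn <- wn - Wn[i, i] }
          cp * 2 * (wp - sp[i] * Spc * nullp) -
            cn * 2 * (wn - sn[i] * Snc * nulln)
        }
        base <- contrib(cur, TRUE)
        gains <- vapply(seq_along(ids), function(j)
          if (j == cur) 0 else contrib(j, FALSE) - base, 0)
        new_gain <- 0 - base  # move to a fresh singleton community
        bestj <- which.max(gains)
        if (new_gain > gains[bestj] + gain_eps && new_gain > gain_eps) {
          labels[i] <- max(labels) + 1L
          moved <- TRUE
        } else if (gains[bestj] > gain_eps) {
          labels[i] <- ids[bestj]
          moved <- TRUE
        }
      }
      if (!moved) break
      improved <- TRUE
    }
    ## --- merge phase ---
    merged_any <- FALSE
    repeat {
      ids <- sort(unique(labels))
      m <- length(ids)
      if (m < 2) break
      Sp <- vapply(ids, function(c) sum(sp[labels == c]), 0)
      Sn <- vapply(ids, function(c) sum(sn[labels == c]), 0)
      best <- c(0, 0, gain_eps)
      for (a in seq_len(m - 1)) for (b in (a + 1):m) {
        ia <- labels == ids[a]; ib <- labels == ids[b]
        dq <- cp * 2 * (sum(Wp[ia, ib]) - Sp[a] * Sp[b] * nullp) -
          cn * 2 * (sum(Wn[ia, ib]) - Sn[a] * Sn[b] * nulln)
        if (dq > best[3]) best <- c(a, b, dq)
      }
      if (best[1] == 0) break
      labels[labels == ids[best[2]]] <- ids[best[1]]
      merged_any <- TRUE
    }
    if (merged_any) improved <- TRUE else break
    if (!improved) break
  }
  labels
}

#' Signed Louvain community detection
#'
#' @param W square symmetric signed weight matrix (diagonal ignored).
#' @param seed integer seed.
#' @param n_restarts seeded restarts; the partition with maximum Q wins.
#' @return list with `labels` (relabelled 1..m by decreasing community
#'   size), `Q`, `m`.
#' @export
louvain_signed <- function(W, seed = 1, n_restarts = 10) {
  W <- as.matrix(W)
  diag(W) <- 0
  best_q <- -Inf; best_lab <- NULL
  for (r in seq_len(n_restarts)) {
    lab <- louvain_signed_once(W, sub_seed(seed, 600 + r))
    q <- signed_modularity(W, lab)
    if (q > best_q + 1e-15) { best_q <- q; best_lab <- lab }
  }
  ## relabel 1..m by decreasing size (ties: first appearance)
  tab <- sort(table(best_lab), decreasing = TRUE)
  new <- setNames(seq_along(tab), names(tab))
  labels <- as.integer(new[as.character(best_lab)])
  list(labels = labels, Q = best_q, m = length(tab))
}

#' Modular decomposition of a dFC state
#'
#' Reconstructs the state's connectivity matrix as the outer product
#' d d' (diagonal zeroed) and partitions the parcels with signed-Louvain
#' modularity, which uses the positive and negative weights of the
#' unthresholded matrix. Invariant to a global sign flip of `d`.
#'
#' @param d non-zero numeric state vector (length N).
#' @param seed integer seed for tie-breaking/restarts.
#' @param n_restarts restarts (default 10).
#' @return object of class `module_partition`: `labels` (1..m, decreasing
#'   module size), `Q`, `m`.
#' @export
state_modules <- function(d, seed = 1, n_restarts = 10) {
  if (all(d == 0)) stop_invalid("state vector must be non-zero")
  W <- tcrossprod(d)
  diag(W) <- 0
  res <- louvain_signed(W, seed = seed, n_restarts = n_restarts)
  structure(res, class = "module_partition")
}

#' Project parcel modules into binary volumes
#'
#' One binary volume per module: voxels whose parcel is assigned to that
#' module. Module volumes are disjoint and their union equals the atlas
#' support.
#'
#' @param part a `module_partition` (or bare integer label vector).
#' @param space a `toy_source_space`; `part` must label all its parcels.
#' @return list of binary 3-D arrays, one per module label 1..m.
#' @export
modules_to_volumes <- function(part, space) {
  labels <- if (inherits(part, "module_partition")) part$labels else part
  if (length(labels) != space$n_parcels)
    stop_invalid("partition length must equal the number of parcels")
  lapply(sort(unique(labels)), function(m) {
    v <- array(0L, dim = space$grid_shape)
    v[space$parcel_of_voxel %in% which(labels == m)] <- 1L
    v
  })
}
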