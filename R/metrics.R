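## Overlap-based reconstruction quality: Dice coefficient and target
## coverage between binarized source components and ROI/template maps,
## best-match selection, and long-format aggregation.

#' Dice coefficient and target coverage
#'
#' d = 2 N_ov / (N_target + N_sc); p_RS = N_ov / N_target, where N_ov is
#' the number of overlapping non-zero voxels. The target (ROI or
#' template) is the first argument and owns the p_RS denominator.
#'
#' @param target binary array (ROI/template).
#' @param sc binary array (source-component map), same grid.
#' @return list with `d`, `p_rs`, `n_ov`, `n_target`, `n_sc`.
#' @export
dice_overlap <- function(target, sc) {
  if (!identical(dim(target), dim(sc)))
    stop_invalid("maps must share one grid (resample first)")
  a <- target != 0; b <- sc != 0
  n_t <- sum(a); n_s <- sum(b)
  if (n_t == 0) stop("p_RS undefined for an empty target map")
  if (n_s == 0) return(list(d = 0, p_rs = 0, n_ov = 0L,
                            n_target = n_t, n_sc = 0L))
  n_ov <- sum(a & b)
  list(d = 2 * n_ov / (n_t + n_s), p_rs = n_ov / n_t,
       n_ov = n_ov, n_target = n_t, n_sc = n_s)
}

#' Best-matching source component per target map
#'
#' Binarizes SC z-volumes at |z| >= `z_thresh`; for each target the SC
#' with the highest Dice is kept (ties broken by lower SC index), and its
#' d* and p*_RS reported.
#'
#' @param sc_vols list of numeric 3-D arrays (SC z-maps in volume space).
#' @param targets named list of binary 3-D arrays.
#' @param z_thresh binarization threshold (default 3.0).
#' @return object of class `best_match`: data.frame `table` (target,
#'   sc, d_star, p_star), `all_empty` flag.
#' @export
best_match <- function(sc_vols, targets, z_thresh = 3.0) {
  if (!length(sc_vols) || !length(targets))
    stop_invalid("need at least one SC map and one target")
  bins <- lapply(sc_vols, function(v) (abs(v) >= z_thresh) * 1L)
  all_empty <- all(vapply(bins, sum, 0) == 0)
  nm <- names(targets) %||% paste0("target", seq_along(targets))
  rows <- lapply(seq_along(targets), function(ti) {
    ds <- vapply(bins, function(b) dice_overlap(targets[[ti]], b)$d, 0)
    j <- which.max(ds)   # ties: first (lowest) index
    ov <- dice_overlap(targets[[ti]], bins[[j]])
    data.frame(target = nm[ti], sc = j, d_star = ov$d, p_star = ov$p_rs)
  })
  structure(list(table = do.call(rbind, rows), all_empty = all_empty,
                 z_thresh = z_thresh),
            class = "best_match")
}

#' Aggregate best-match scores into a long-format results row set
#'
#' Computes mean d* and mean p*_RS per map type and binds the run
#' metadata, yielding rows of the results table exported for external
#' statistics.
#'
#' @param matches named list of `best_match` objects, one per map type
#'   (e.g. `roi`, `template`).
#' @param metadata named list (subject, run, run_type, algorithm,
#'   cc_set, VE, logev, seed, ...) recycled onto every row.
#' @return data.frame with one row per map type.
#' @export
aggregate_scores <- function(matches, metadata = list()) {
  rows <- lapply(names(matches), function(mt) {
    tb <- matches[[mt]]$table
    cbind(as.data.frame(metadata, stringsAsFactors = FALSE),
          data.frame(map_type = mt,
                     mean_d_star = mean(tb$d_star),
                     mean_p_star = mean(tb$p_star),
                     n_targets = nrow(tb)))
  })
  do.call(rbind, rows)
}
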