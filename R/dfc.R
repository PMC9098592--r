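## Dynamic functional connectivity: instantaneous phase coherence,
## leading-eigenvector reduction (LEiDA), l1-regularised dictionary
## learning of dFC states, and contrast-correlated state selection.

#' Band-pass filter and instantaneous phase
#'
#' Applies a zero-phase (forward-backward) Butterworth band-pass to each
#' parcel time series and extracts the instantaneous phase of the analytic
#' signal.
#'
#' @param ts a `parcel_timeseries` (or plain N x T matrix plus `TR`).
#' @param low,high band edges in Hz (defaults 0.01-0.1).
#' @param order Butterworth order (default 2).
#' @param TR sampling interval, required when `ts` is a bare matrix.
#' @return N x T matrix of phases in (-pi, pi], with attribute
#'   `degenerate_rows` flagging near-constant inputs.
#' @export
bandpass_phase <- function(ts, low = 0.01, high = 0.1, order = 2, TR = NULL) {
  if (inherits(ts, "parcel_timeseries")) {
    X <- ts$values; TR <- ts$TR
  } else {
    X <- as.matrix(ts)
    if (is.null(TR)) stop_invalid("TR required for matrix input")
  }
  fs <- 1 / TR
  if (!(low > 0 && low < high)) stop_invalid("need 0 < low < high")
  if (high >= fs / 2) stop_invalid("high band edge must be below Nyquist")
  bf <- signal::butter(order, c(low, high) / (fs / 2), type = "pass")
  filt <- t(apply(X, 1, function(x) signal::filtfilt(bf, x)))
  ## (near-)constant inputs have no oscillatory content: their phases are
  ## defined but meaningless, so they are flagged
  degenerate <- apply(X, 1, function(x) sd(x) < 1e-12 * (1 + max(abs(x))))
  ph <- t(apply(filt, 1, function(x) Arg(analytic_signal(x))))
  attr(ph, "degenerate_rows") <- which(degenerate)
  ph
}

#' Instantaneous phase-coherence stack
#'
#' For each sample t, C(n, p, t) = cos(theta(n, t) - theta(p, t)). Each
#' slice is symmetric with unit diagonal, entries in [-1, 1], and has rank
#' at most 2 (it is cos cos' + sin sin').
#'
#' @param ph N x T phase matrix.
#' @return N x N x T array.
#' @export
phase_coherence <- function(ph) {
  N <- nrow(ph); T_ <- ncol(ph)
  co <- cos(ph); si <- sin(ph)
  out <- array(0, dim = c(N, N, T_))
  for (t in seq_len(T_))
    out[, , t] <- tcrossprod(co[, t]) + tcrossprod(si[, t])
  out
}

#' Leading eigenvectors of the phase-coherence stack
#'
#' Reduces each N x N slice to its unit-norm leading eigenvector. The
#' explained-variance share is lambda_1 / sum(|lambda_i|) by default
#' (configurable to lambda_1 / trace); the rank-2 positive-semidefinite
#' structure of phase-coherence slices forces the share above 50%. The
#' eigenvector sign is fixed so that the majority of its elements are
#' negative (ties: first element non-positive).
#'
#' @param stack N x N x T array (from [phase_coherence()]).
#' @param share one of "abs" (lambda1/sum|lambda|) or "trace"
#'   (lambda1/trace).
#' @return list with `C_R` (N x T, unit-norm columns) and `share`
#'   (length-T explained-variance fractions).
#' @export
leading_eigenvectors <- function(stack, share = c("abs", "trace")) {
  share <- match.arg(share)
  N <- dim(stack)[1]; T_ <- dim(stack)[3]
  C_R <- matrix(0, N, T_)
  shares <- numeric(T_)
  for (t in seq_len(T_)) {
    e <- eigen(stack[, , t], symmetric = TRUE)
    v <- e$vectors[, 1]
    npos <- sum(v > 0); nneg <- sum(v < 0)
    if (npos > nneg || (npos == nneg && v[1] > 0)) v <- -v
    C_R[, t] <- v
    denom <- if (share == "abs") sum(abs(e$values)) else sum(diag(stack[, , t]))
    shares[t] <- e$values[1] / denom
  }
  list(C_R = C_R, share = shares)
}

#' Sparsity penalty grid
#'
#' Ten l1 penalties from 1 down to ~0.1259 in equal exponential steps:
#' lambda_j = 10^(-(j - 1)/10).
#'
#' @return numeric vector of length 10.
#' @export
lambda_grid <- function() 10^(-(0:9) / 10)

#' Fit a dFC-state dictionary by l1-regularised alternating minimization
#'
#' Factorizes the leading-eigenvector series C_R (N x T) as D A with k
#' unit-norm atoms (columns of D, the dFC states) and sparse weights A,
#' minimizing ||C_R - D A||_F^2 + lambda * sum|A|. Sparse coding uses
#' vectorized coordinate descent across all columns; the dictionary update
#' solves each atom's isotropic quadratic subproblem in closed form on the
#' unit sphere, so the objective is non-increasing across outer
#' iterations by construction.
#'
#' @param cr N x T matrix or the list returned by
#'   [leading_eigenvectors()].
#' @param k number of atoms (1 <= k <= min(N, T)).
#' @param lambda l1 penalty (>= 0).
#' @param seed integer seed (atom initialization from random data columns).
#' @param n_iter maximum outer iterations (default 100).
#' @param tol relative objective-change stopping tolerance.
#' @param sweeps coordinate-descent sweeps per sparse-coding step.
#' @return object of class `dfc_dictionary`: `D` (N x k, unit-norm
#'   columns), `A` (k x T), `lambda`, `E` (squared Frobenius
#'   reconstruction error), `objective` (per-iteration trace), `k`,
#'   `seed`, `iterations`.
#' @export
fit_dictionary <- function(cr, k, lambda, seed = 1, n_iter = 100,
                           tol = 1e-10, sweeps = 10) {
  if (is.list(cr)) cr <- cr$C_R
  N <- nrow(cr); T_ <- ncol(cr)
  if (k < 1 || k > min(N, T_)) stop_invalid("k must lie in 1..min(N, T)")
  if (lambda < 0) stop_invalid("lambda must be >= 0")
  set.seed(sub_seed(seed, 5))
  D <- cr[, sample.int(T_, k), drop = FALSE]
  nrm <- sqrt(colSums(D^2)); nrm[nrm == 0] <- 1
  D <- sweep(D, 2, nrm, `/`)
  A <- matrix(0, k, T_)
  obj <- function(D, A) fnorm2(cr - D %*% A) + lambda * sum(abs(A))
  trace <- numeric(0)
  prev <- Inf
  for (it in seq_len(n_iter)) {
    ## --- sparse coding (exact LS for lambda = 0, CD otherwise) ---
    if (lambda == 0) {
      A <- tryCatch(qr.coef(qr(D), cr),
                    error = function(e) MASS::ginv(D) %*% cr)
      A[is.na(A)] <- 0
    } else {
      DtD <- crossprod(D)
      DtC <- crossprod(D, cr)
      for (sw in seq_len(sweeps)) {
        delta <- 0
        for (j in seq_len(k)) {
          rho <- DtC[j, ] - DtD[j, ] %*% A + DtD[j, j] * A[j, ]
          new <- soft_threshold(as.numeric(rho), lambda / 2) / DtD[j, j]
          delta <- max(delta, max(abs(new - A[j, ])))
          A[j, ] <- new
        }
        if (delta < 1e-9) break
      }
    }
    ## --- dictionary update: per-atom closed form on the unit sphere ---
    B <- tcrossprod(cr, A)       # N x k
    G <- tcrossprod(A)           # k x k
    for (j in seq_len(k)) {
      if (G[j, j] < 1e-14) next  # unused atom: keep
      rj <- B[, j] - D %*% G[, j] + D[, j] * G[j, j]
      nr <- sqrt(sum(rj^2))
      if (nr > 0) D[, j] <- rj / nr
    }
    cur <- obj(D, A)
    trace <- c(trace, cur)
    if (is.finite(prev) && prev - cur < tol * max(1, abs(prev))) { prev <- cur; break }
    prev <- cur
  }
  structure(list(D = D, A = A, lambda = lambda,
                 E = fnorm2(cr - D %*% A), objective = trace,
                 k = as.integer(k), seed = as.integer(seed),
                 iterations = length(trace)),
            class = "dfc_dictionary")
}

#' Grid search over (k, lambda) with contrast-correlated state selection
#'
#' Fits dictionaries over the full (k, lambda) grid, computes the Pearson
#' correlation between every weight time-course and every contrast, picks
#' the single (k, lambda) whose fit contains the globally most correlated
#' (absolute r) state-contrast pair, then selects within that fit the most
#' correlated state for each contrast, collapsing duplicates (several
#' contrasts mapping to one state yield that state once).
#'
#' @param cr N x T matrix or [leading_eigenvectors()] output.
#' @param contrasts T x n_contrasts matrix of contrast time-courses
#'   (typically HRF-convolved; pass raw boxcars if preferred).
#' @param k_grid integer state counts (default 5:10).
#' @param lambdas l1 penalties (default [lambda_grid()]).
#' @param seed integer seed.
#' @param n_iter dictionary iterations per fit.
#' @return object of class `state_selection`: `k`, `lambda`,
#'   `state_of_contrast`, `r_of_contrast`, `states` (N x n_unique,
#'   deduplicated), `fit` (the winning `dfc_dictionary`), `r_table`.
#' @export
grid_search_states <- function(cr, contrasts, k_grid = 5:10,
                               lambdas = lambda_grid(), seed = 1,
                               n_iter = 60) {
  if (is.list(cr)) cr <- cr$C_R
  contrasts <- as.matrix(contrasts)
  if (nrow(contrasts) != ncol(cr))
    stop_invalid("contrast length must equal the number of samples")
  best <- list(r = -Inf)
  idx <- 0L
  for (k in k_grid) for (lam in lambdas) {
    idx <- idx + 1L
    fit <- fit_dictionary(cr, k, lam, seed = sub_seed(seed, idx),
                          n_iter = n_iter)
    R <- matrix(NA_real_, k, ncol(contrasts))
    for (s in seq_len(k)) for (cc in seq_len(ncol(contrasts)))
      R[s, cc] <- safe_cor(fit$A[s, ], contrasts[, cc])
    if (all(is.na(R))) next
    top <- max(abs(R), na.rm = TRUE)
    if (top > best$r) best <- list(r = top, k = k, lambda = lam,
                                   fit = fit, R = R)
  }
  if (!is.finite(best$r))
    stop("degenerate selection: all state-contrast correlations undefined")
  R <- best$R
  state_of <- integer(ncol(contrasts))
  r_of <- numeric(ncol(contrasts))
  for (cc in seq_len(ncol(contrasts))) {
    a <- abs(R[, cc]); a[is.na(a)] <- -Inf
    state_of[cc] <- which.max(a)
    r_of[cc] <- R[state_of[cc], cc]
  }
  uniq <- unique(state_of)
  structure(list(k = best$k, lambda = best$lambda,
                 state_of_contrast = state_of, r_of_contrast = r_of,
                 states = best$fit$D[, uniq, drop = FALSE],
                 state_indices = uniq, fit = best$fit, r_table = R),
            class = "state_selection")
}
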