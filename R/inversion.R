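## Parametric empirical Bayes EEG inversion: temporal reduction,
## algorithm-intrinsic covariance components (MN, LORETA, EBB, MSP), ReML
## hyperparameter estimation by Fisher scoring on log-hyperparameters,
## posterior source estimation and model-level scores.

#' SVD-based temporal reduction
#'
#' Projects the data onto the smallest right-singular subspace whose
#' cumulative squared singular values reach `retain`, reducing noise
#' while keeping a temporally continuous source estimate.
#'
#' @param Y C x T data matrix.
#' @param retain retained squared-singular-value fraction (0 < retain <= 1).
#' @return list with `basis` (T x r orthonormal), `reduced` (C x r,
#'   = Y basis), `r`, `retained` (achieved fraction).
#' @export
temporal_reduce <- function(Y, retain = 0.99) {
  Y <- as.matrix(Y)
  if (ncol(Y) < 2) stop_invalid("need at least 2 samples")
  if (!(retain > 0 && retain <= 1)) stop_invalid("retain must lie in (0, 1]")
  sv <- svd(Y)
  d2 <- sv$d^2
  tolr <- max(dim(Y)) * max(sv$d) * .Machine$double.eps
  rank <- sum(sv$d > tolr)
  cum <- cumsum(d2) / sum(d2)
  r <- if (retain == 1) rank else min(which(cum >= retain), rank)
  basis <- sv$v[, seq_len(r), drop = FALSE]
  list(basis = basis, reduced = Y %*% basis, r = r, retained = cum[r])
}

#' Algorithm-intrinsic covariance components
#'
#' MN: a single identity component (equal variance, no covariance).
#' LORETA: identity plus the smoothness/coherence component K K' of the
#' Green's kernel. EBB: one data-driven diagonal component with entries
#' 1 / (l_i' Sigma_Y^{-1} l_i) (regularized sample covariance). MSP: a
#' library of rank-1 patch components K[, v_j] K[, v_j]' on evenly
#' sampled vertices.
#'
#' @param algorithm one of "MN", "LORETA", "EBB", "MSP".
#' @param L C x V leadfield.
#' @param Y C x T data (required for EBB).
#' @param g a `green_smoother` (required for LORETA and MSP).
#' @param n_patch number of MSP patches (default 64).
#' @param ebb_reg EBB covariance regularization factor (default 1e-6,
#'   times trace/C on the identity).
#' @return list of `covariance_component`s.
#' @export
algorithm_ccs <- function(algorithm, L, Y = NULL, g = NULL, n_patch = 64,
                          ebb_reg = 1e-6) {
  algorithm <- match.arg(algorithm, c("MN", "LORETA", "EBB", "MSP"))
  V <- ncol(L)
  if (algorithm == "MN")
    return(list(make_cc("identity", dim_v = V, label = "MN identity")))
  if (algorithm == "LORETA") {
    if (is.null(g)) stop_invalid("LORETA requires a green_smoother")
    KK <- as.matrix(Matrix::tcrossprod(g$K))
    return(list(make_cc("identity", dim_v = V, label = "LORETA identity"),
                make_cc("full", KK, label = "LORETA coherence")))
  }
  if (algorithm == "EBB") {
    if (is.null(Y)) stop_invalid("EBB requires data Y")
    C <- nrow(L)
    Sy <- tcrossprod(Y) / ncol(Y)
    if (ncol(Y) < C && ebb_reg <= 0)
      stop("ill-conditioned sample covariance: T < C and regularization disabled")
    Sy <- Sy + ebb_reg * sum(diag(Sy)) / C * diag(C)
    Si <- solve(Sy)
    w <- 1 / colSums(L * (Si %*% L))
    return(list(make_cc("diag", w, label = "EBB beamformer power")))
  }
  ## MSP
  if (is.null(g)) stop_invalid("MSP requires a green_smoother")
  n_patch <- min(n_patch, V)
  centers <- unique(round(seq(1, V, length.out = n_patch)))
  K <- g$K
  lapply(seq_along(centers), function(i)
    make_cc("factor", as.numeric(K[, centers[i]]),
            label = sprintf("MSP patch %d", centers[i])))
}

#' ReML estimation of covariance hyperparameters
#'
#' Maximizes the ReML free energy (Gaussian log-evidence up to constants)
#' of the channel-space model Sigma(gamma) = gamma_0 I_C + sum_p gamma_p
#' L V_p L' over log-hyperparameters, by Fisher scoring with step
#' halving; the accepted free-energy trace is non-decreasing.
#'
#' @param Yr C x r (temporally reduced) data.
#' @param L C x V leadfield.
#' @param cc_set a `cc_set` (or bare list of `covariance_component`s).
#' @param tol convergence tolerance on the free-energy change.
#' @param max_iter maximum iterations (default 128).
#' @param gamma_floor relative pruning floor: hyperparameters are clamped
#'   below `gamma_floor` times the largest (default 1e-8).
#' @return object of class `reml_result`: `gamma` (noise first, then one
#'   per source CC), `F`, `F_trace`, `iterations`, `converged`, `Sigma`,
#'   `Q` (the channel-space component list, noise first).
#' @export
reml_estimate <- function(Yr, L, cc_set, tol = 1e-4, max_iter = 128,
                          gamma_floor = 1e-8) {
  ccs <- if (inherits(cc_set, "cc_set")) cc_set$ccs else cc_set
  if (!length(ccs)) stop_invalid("at least one source covariance component required")
  C <- nrow(Yr); n <- ncol(Yr)
  Q <- c(list(diag(C)), lapply(ccs, cc_channel_projection, L = L))
  P <- length(Q)
  S <- tcrossprod(Yr) / n
  scale_s <- sum(diag(S)) / C
  ## scale-aware initialization: each term starts at a fraction of the
  ## data power
  lam <- vapply(Q, function(q) log(scale_s / P / (sum(diag(q)) / C)), 0)
  free_energy <- function(lam) {
    g <- exp(lam)
    Sg <- Reduce(`+`, Map(`*`, Q, g))
    ch <- tryCatch(chol(Sg), error = function(e) NULL)
    if (is.null(ch)) return(list(F = -Inf))
    logdet <- 2 * sum(log(diag(ch)))
    Si <- chol2inv(ch)
    Fv <- -n / 2 * (logdet + sum(Si * S)) - n * C / 2 * log(2 * pi)
    list(F = Fv, Si = Si)
  }
  cur <- free_energy(lam)
  if (!is.finite(cur$F)) stop("optimization failure: non-finite initial free energy")
  trace <- cur$F
  converged <- FALSE
  floor_lam <- log(gamma_floor) + max(lam)
  for (it in seq_len(max_iter)) {
    Si <- cur$Si
    g <- exp(lam)
    R <- Si - Si %*% S %*% Si
    grad <- vapply(seq_len(P), function(p) -n / 2 * g[p] * sum(R * Q[[p]]), 0)
    SiQ <- lapply(seq_len(P), function(p) Si %*% Q[[p]])
    info <- matrix(0, P, P)
    for (p in seq_len(P)) for (q in p:P) {
      info[p, q] <- n / 2 * g[p] * g[q] * sum(SiQ[[p]] * t(SiQ[[q]]))
      info[q, p] <- info[p, q]
    }
    info <- info + diag(P) * max(diag(info)) * 1e-8
    step <- tryCatch(solve(info, grad), error = function(e) grad / max(diag(info)))
    ## step halving: accept only non-decreasing free energy
    accepted <- FALSE
    for (h in 0:16) {
      lam_new <- lam + step / 2^h
      floor_lam <- log(gamma_floor) + max(lam_new)
      lam_new <- pmax(lam_new, floor_lam)
      cand <- free_energy(lam_new)
      if (is.finite(cand$F) && cand$F >= cur$F - 1e-12 * abs(cur$F)) {
        accepted <- TRUE
        break
      }
    }
    if (!accepted) { converged <- TRUE; break }
    dF <- cand$F - cur$F
    lam <- lam_new
    cur <- cand
    trace <- c(trace, cur$F)
    if (abs(dF) < tol) { converged <- TRUE; break }
  }
  g <- exp(lam)
  Sg <- Reduce(`+`, Map(`*`, Q, g))
  structure(list(gamma = g, F = cur$F, F_trace = trace,
                 iterations = length(trace) - 1L, converged = converged,
                 Sigma = Sg, Q = Q, n = n),
            class = "reml_result")
}

#' Solve the EEG inverse problem for one algorithm and CC set
#'
#' Temporally reduces the data, estimates hyperparameters by ReML, and
#' returns the posterior mean source estimate
#' S = C_D L' (L C_D L' + gamma_0 I)^{-1} Y_r together with the ReML
#' result and model scores (variance explained on reduced and full data,
#' free energy).
#'
#' @param Y C x T EEG data.
#' @param L C x V leadfield.
#' @param cc_set a `cc_set`.
#' @param retain temporal-reduction retained-variance fraction.
#' @param reduction optional precomputed [temporal_reduce()] output
#'   (shared across algorithms for comparability).
#' @param ... passed to [reml_estimate()].
#' @return list of class `source_inversion`: `S` (V x r), `S_full`
#'   (V x T), `reml`, `scores` (`VE`, `VE_full`, `logev`), `reduction`,
#'   `cc_set`.
#' @export
invert_eeg <- function(Y, L, cc_set, retain = 0.99, reduction = NULL, ...) {
  Y <- as.matrix(Y)
  if (nrow(Y) != nrow(L)) stop_invalid("channel counts disagree")
  if (all(Y == 0)) {
    return(structure(list(S = matrix(0, ncol(L), 1),
                          S_full = matrix(0, ncol(L), ncol(Y)),
                          reml = NULL,
                          scores = list(VE = NA_real_, VE_full = NA_real_,
                                        logev = NA_real_),
                          reduction = NULL, cc_set = cc_set),
                     class = "source_inversion"))
  }
  red <- reduction %||% temporal_reduce(Y, retain)
  reml <- reml_estimate(red$reduced, L, cc_set, ...)
  g <- reml$gamma
  ccs <- if (inherits(cc_set, "cc_set")) cc_set$ccs else cc_set
  ## C_D L' = sum_p gamma_p V_p L'  (V x C), gamma[1] is channel noise
  M <- matrix(0, ncol(L), nrow(L))
  for (p in seq_along(ccs)) M <- M + g[p + 1] * cc_source_projection(ccs[[p]], L)
  S_r <- M %*% solve(reml$Sigma, red$reduced)
  S_full <- S_r %*% t(red$basis)
  ve <- variance_explained(red$reduced, L, S_r)
  ve_full <- variance_explained(Y, L, S_full)
  structure(list(S = S_r, S_full = S_full, reml = reml,
                 scores = list(VE = ve, VE_full = ve_full, logev = reml$F),
                 reduction = red, cc_set = cc_set),
            class = "source_inversion")
}

#' Variance explained by a source estimate
#'
#' VE = 100 (1 - ||Y - L S||_F^2 / ||Y||_F^2), clipped at 0 (with a
#' `clipped` attribute) when the reconstruction overshoots.
#'
#' @param Y data (C x T or reduced C x r).
#' @param L leadfield.
#' @param S source estimate matching Y's time dimension.
#' @return percent VE in [0, 100].
#' @export
variance_explained <- function(Y, L, S) {
  if (fnorm2(Y) == 0) stop("variance explained undefined for zero data")
  ve <- 100 * (1 - fnorm2(Y - L %*% S) / fnorm2(Y))
  out <- max(ve, 0)
  attr(out, "clipped") <- ve < 0
  out
}

#' Random-effects posterior model probabilities
#'
#' Variational Bayesian model selection over a subjects x models
#' log-evidence table: a symmetric Dirichlet prior over model frequencies
#' is updated until convergence, and the expected model frequencies
#' (normalized to sum to one) are returned. A fixed-effects alternative
#' (softmax of summed log-evidence) is available behind `method`.
#'
#' @param logev subjects x models matrix of log-evidence values.
#' @param method "random" (default) or "fixed".
#' @param alpha0 Dirichlet prior count (default 1).
#' @param max_iter,tol iteration controls.
#' @return numeric vector of posterior model probabilities (sums to 1).
#' @export
model_posterior <- function(logev, method = c("random", "fixed"),
                            alpha0 = 1, max_iter = 500, tol = 1e-10) {
  method <- match.arg(method)
  logev <- as.matrix(logev)
  M <- ncol(logev)
  if (M < 2) {
    warning("single model: posterior probability is 1")
    return(1)
  }
  if (any(!is.finite(logev))) stop_invalid("log-evidences must be finite")
  if (method == "fixed") {
    s <- colSums(logev)
    s <- s - max(s)
    p <- exp(s) / sum(exp(s))
    return(p)
  }
  alpha <- rep(alpha0, M)
  for (it in seq_len(max_iter)) {
    lu <- sweep(logev, 2, digamma(alpha) - digamma(sum(alpha)), `+`)
    lu <- lu - apply(lu, 1, max)
    gmat <- exp(lu) / rowSums(exp(lu))
    alpha_new <- alpha0 + colSums(gmat)
    if (max(abs(alpha_new - alpha)) < tol) { alpha <- alpha_new; break }
    alpha <- alpha_new
  }
  p <- alpha / sum(alpha)
  p / sum(p)
}
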