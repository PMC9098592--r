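test_that("temporal reduction is lossless at retain = 1 and finds low rank", {
  set.seed(1)
  Y <- matrix(rnorm(10 * 50), 10, 50)
  tr <- temporal_reduce(Y, retain = 1)
  expect_equal(Y, tr$reduced %*% t(tr$basis), tolerance = 1e-8)
  expect_lt(max(abs(crossprod(tr$basis) - diag(tr$r))), 1e-10)
  ## rank-3 data
  Y3 <- matrix(rnorm(10 * 3), 10, 3) %*% matrix(rnorm(3 * 50), 3, 50)
  tr3 <- temporal_reduce(Y3, retain = 0.999)
  expect_equal(tr3$r, 3)
  expect_error(temporal_reduce(matrix(1, 3, 1)),
               class = "fmripeb_invalid_argument")
})

test_that("intrinsic covariance components match each algorithm's definition", {
  sp <- fixture_space_mid()
  L <- fixture_leadfield_mid()
  g <- green_kernel(sp)
  mn <- algorithm_ccs("MN", L)
  expect_length(mn, 1)
  expect_equal(cc_matrix(mn[[1]]), diag(162) / 162)
  lor <- algorithm_ccs("LORETA", L, g = g)
  expect_length(lor, 2)
  KK <- as.matrix(Matrix::tcrossprod(g$K))
  expect_equal(cc_matrix(lor[[2]]), KK / sum(diag(KK)), tolerance = 1e-12)
  msp <- algorithm_ccs("MSP", L, g = g, n_patch = 64)
  expect_length(msp, 64)
  for (cc in msp[c(1, 32, 64)]) {
    M <- cc_matrix(cc)
    ev <- eigen(M, symmetric = TRUE, only.values = TRUE)$values
    expect_gt(min(ev), -1e-12)
  }
})

test_that("EBB weights are near-uniform for white noise under a flat leadfield", {
  ## partial Fourier leadfield: cos/sin row pairs are orthonormal and give
  ## exactly constant column norms
  C <- 16; V <- 128
  L <- do.call(rbind, lapply(1:(C / 2), function(k) rbind(
    sqrt(2 / V) * cos(2 * pi * k * (0:(V - 1)) / V),
    sqrt(2 / V) * sin(2 * pi * k * (0:(V - 1)) / V))))
  set.seed(7)
  Y <- matrix(rnorm(C * 5000), C, 5000)
  w <- algorithm_ccs("EBB", L, Y = Y)[[1]]$value
  expect_lt(max(w) / min(w), 1.5)
})

test_that("ReML scales correctly and keeps a non-decreasing free energy", {
  sp <- fixture_space_mid()
  L <- fixture_leadfield_mid()
  set.seed(8)
  patch <- c(40, sp$neighbors[[40]])
  tc <- sin(2 * pi * 8 * (0:199) / 60)
  eeg <- simulate_eeg(sp, L, make_scene(list(patch), matrix(tc, 1), 0.2, 1))
  red <- temporal_reduce(eeg$Y)
  s1 <- assemble_cc_set("MN", algorithm_ccs("MN", L), set_name = "S1",
                        run_type = "task")
  r1 <- reml_estimate(red$reduced, L, s1)
  expect_true(all(diff(r1$F_trace) >= -1e-9 * pmax(1, abs(r1$F_trace[-1]))))
  ## scaling Y by 2 scales every hyperparameter by 4
  r2 <- reml_estimate(2 * red$reduced, L, s1)
  expect_equal(r2$gamma / r1$gamma, rep(4, 2), tolerance = 0.01)
})

test_that("two-component ReML recovers the planted variance ratio", {
  ## data generated from gamma_s * L q q' L' + gamma_n * I; grid-search
  ## maximum-likelihood oracle over the same free energy surface
  set.seed(9)
  C <- 16; V <- 60; T_ <- 400
  L <- matrix(rnorm(C * V), C, V)
  q <- pmax(rnorm(V), 0); q <- q / sqrt(sum(q^2))
  cc <- list(make_cc("factor", q, label = "true prior"))
  gamma_s <- 4; gamma_n <- 1
  rel_err <- c(); oracle_agree <- c()
  for (seed in 1:10) {
    set.seed(seed)
    s_t <- sqrt(gamma_s) * rnorm(T_)
    Y <- as.numeric(L %*% q) %o% s_t +
      sqrt(gamma_n) * matrix(rnorm(C * T_), C, T_)
    r <- reml_estimate(Y, L, cc, tol = 1e-6)
    ratio <- r$gamma[2] / r$gamma[1]
    rel_err <- c(rel_err, abs(ratio - gamma_s / gamma_n) / (gamma_s / gamma_n))
    ## grid-search oracle on (log gn, log gs)
    Qs <- tcrossprod(as.numeric(L %*% q))
    S <- tcrossprod(Y) / T_
    fe <- function(gn, gs) {
      Sg <- gn * diag(C) + gs * Qs
      -T_ / 2 * (determinant(Sg)$modulus + sum(solve(Sg) * S))
    }
    grid <- expand.grid(gn = exp(seq(-2, 2, length.out = 41)),
                        gs = exp(seq(-2, 4, length.out = 41)))
    fv <- mapply(fe, grid$gn, grid$gs)
    top <- grid[which.max(fv), ]
    oracle_agree <- c(oracle_agree,
                      abs(log(ratio) - log(top$gs / top$gn)))
  }
  expect_lt(median(rel_err), 0.25)
  ## ReML optimum agrees with the grid-search ML oracle (grid resolution
  ## is 0.15 in log space)
  expect_lt(median(oracle_agree), 0.2)
})

test_that("minimum-norm inversion equals the analytic Tikhonov solution", {
  sp <- fixture_space_mid()
  L <- fixture_leadfield_mid()
  set.seed(10)
  for (seed in 1:5) {
    set.seed(seed)
    patch <- sample.int(162, 3)
    tc <- matrix(rnorm(3 * 150), 3, 150)
    eeg <- simulate_eeg(sp, L, make_scene(as.list(patch),
                                          tc, 0.3, seed))
    s1 <- assemble_cc_set("MN", algorithm_ccs("MN", L), set_name = "S1",
                          run_type = "task")
    inv <- invert_eeg(eeg$Y, L, s1)
    gam <- inv$reml$gamma
    lam <- gam[1] * ncol(L) / gam[2]   # identity CC carries a 1/V trace norm
    S_ref <- t(L) %*% solve(tcrossprod(L) + lam * diag(nrow(L)),
                            inv$reduction$reduced)
    expect_lt(norm(S_ref - inv$S, "F") / norm(S_ref, "F"), 1e-6)
  }
})

test_that("inversion degenerate regimes behave as documented", {
  sp <- fixture_space_small()
  L <- make_leadfield(sp, 16, seed = 1)
  s1 <- assemble_cc_set("MN", algorithm_ccs("MN", L), set_name = "S1",
                        run_type = "task")
  z <- invert_eeg(matrix(0, 16, 20), L, s1)
  expect_true(all(z$S_full == 0))
  ## noiseless planted source with its matching prior: VE essentially 100%
  g <- green_kernel(sp, radius = 2)
  patch <- c(5, sp$neighbors[[5]])
  tc <- sin((1:100) / 4)
  eeg <- simulate_eeg(sp, L, make_scene(list(patch), matrix(tc, 1), 0, 1))
  pv <- as.numeric(seq_len(42) %in% patch)
  ccm <- prior_to_cc(structure(list(q = pv, label = "true",
                                    provenance = "activation"),
                               class = "surface_prior"))
  s2 <- assemble_cc_set("MN", algorithm_ccs("MN", L), activation = list(ccm),
                        set_name = "S2", run_type = "task")
  inv <- invert_eeg(eeg$Y, L, s2)
  expect_gte(inv$scores$VE, 99.9)
})

test_that("variance explained follows the Pythagorean decomposition", {
  expect_error(variance_explained(matrix(0, 2, 2), diag(2), matrix(0, 2, 2)),
               "undefined")
  Y <- diag(2); L <- diag(2)
  expect_equal(as.numeric(variance_explained(Y, L, Y)), 100)
  expect_equal(as.numeric(variance_explained(Y, L, 0 * Y)), 0)
  ## reconstruction explaining exactly half the energy via an orthogonal
  ## residual: Y = u + v with u'v = 0 and |u| = |v|
  u <- c(1, 0); v <- c(0, 1)
  Y <- matrix(u + v, 2, 1)
  S <- matrix(u, 2, 1)
  expect_equal(as.numeric(variance_explained(Y, diag(2), S)), 50)
})

test_that("model posteriors are symmetric, dominated, and normalized", {
  lev <- matrix(0, 15, 4)
  p <- model_posterior(lev)
  expect_equal(p, rep(0.25, 4), tolerance = 1e-3)
  lev2 <- matrix(0, 20, 2); lev2[, 1] <- 20
  p2 <- model_posterior(lev2)
  expect_gt(p2[1], 0.95)
  expect_equal(sum(p2), 1, tolerance = 1e-9)
  ## agrees with the independently written variational updates
  set.seed(11)
  lev3 <- matrix(rnorm(30), 10, 3)
  expect_equal(model_posterior(lev3), oracle_bms(lev3), tolerance = 1e-6)
  expect_warning(p1 <- model_posterior(matrix(0, 5, 1)), "single model")
  expect_equal(p1, 1)
})

test_that("evidence favours the generating prior over a mismatched one", {
  sp <- fixture_space_mid()
  L <- fixture_leadfield_mid()
  g <- green_kernel(sp)
  wins <- 0L
  n_seeds <- 10L
  for (seed in seq_len(n_seeds)) {
    set.seed(seed)
    ctr <- sample.int(162, 1)
    patch <- c(ctr, sp$neighbors[[ctr]])
    far <- which.max(colSums((t(sp$vertices) - sp$vertices[ctr, ])^2))
    bad_patch <- c(far, sp$neighbors[[far]])
    tc <- sin(2 * pi * 8 * (0:149) / 60 + runif(1, 0, 2 * pi))
    eeg <- simulate_eeg(sp, L, make_scene(list(patch), matrix(tc, 1),
                                          0.3, seed))
    red <- temporal_reduce(eeg$Y)
    mk <- function(vs) prior_to_cc(smooth_prior(
      structure(list(q = as.numeric(seq_len(162) %in% vs), label = "p",
                     provenance = "activation"), class = "surface_prior"), g))
    intr <- algorithm_ccs("MN", L)
    good <- invert_eeg(eeg$Y, L,
                       assemble_cc_set("MN", intr, activation = list(mk(patch)),
                                       set_name = "S2", run_type = "task"),
                       reduction = red)
    bad <- invert_eeg(eeg$Y, L,
                      assemble_cc_set("MN", intr,
                                      activation = list(mk(bad_patch)),
                                      set_name = "S2", run_type = "task"),
                      reduction = red)
    if (good$scores$logev > bad$scores$logev) wins <- wins + 1L
  }
  expect_gte(wins, ceiling(0.9 * n_seeds))
})
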