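test_that("band-passed phase of an in-band sinusoid advances linearly", {
  TR <- 1; T_ <- 400; f <- 0.05
  x <- sin(2 * pi * f * (0:(T_ - 1)) * TR)
  X <- rbind(x, x)
  ph <- bandpass_phase(X, TR = TR)
  ## interior samples: phase increment 2*pi*f*TR per sample
  d <- diff(ph[1, 100:300])
  d <- (d + pi) %% (2 * pi) - pi
  expect_true(all(abs(d - 2 * pi * f * TR) < 0.01 * 2 * pi * f * TR))
  expect_equal(ph[1, ], ph[2, ])
})

test_that("constant rows are flagged degenerate", {
  X <- rbind(rep(1, 100), sin((1:100) / 4))
  ph <- bandpass_phase(X, TR = 1, low = 0.01, high = 0.2)
  expect_true(1 %in% attr(ph, "degenerate_rows"))
})

test_that("phase coherence realizes the cosine-difference identity", {
  ph <- matrix(c(0, 0, pi, pi / 3), nrow = 4, ncol = 1)
  C <- phase_coherence(ph)
  expect_equal(C[1, 2, 1], 1)
  expect_equal(C[1, 3, 1], -1)
  expect_equal(C[1, 4, 1], 0.5)
  expect_equal(diag(C[, , 1]), rep(1, 4))
  expect_identical(C[, , 1], t(C[, , 1]))
})

test_that("phase-coherence slices are rank-2 PSD with trace N", {
  set.seed(3)
  ph <- matrix(runif(8 * 20, -pi, pi), 8, 20)
  C <- phase_coherence(ph)
  for (t in c(1, 7, 20)) {
    ev <- eigen(C[, , t], symmetric = TRUE, only.values = TRUE)$values
    expect_equal(sum(ev), 8, tolerance = 1e-10)
    expect_gt(min(ev), -1e-10)
    expect_lt(abs(ev[3]) / ev[1], 1e-8)   # numerical rank <= 2
  }
})

test_that("leading eigenvectors split anti-phase groups and bound the share", {
  ## all phases equal -> uniform eigenvector, share 1
  ph <- matrix(0.3, 4, 1)
  lev <- leading_eigenvectors(phase_coherence(ph))
  expect_equal(abs(lev$C_R[, 1]), rep(1 / 2, 4))
  expect_equal(lev$share[1], 1)
  ## two anti-phase groups: verified against the full eigendecomposition
  ph2 <- matrix(c(0, 0, pi, pi), 4, 1)
  C2 <- phase_coherence(ph2)[, , 1]
  e <- eigen(C2, symmetric = TRUE)
  lev2 <- leading_eigenvectors(phase_coherence(ph2))
  expect_equal(abs(lev2$C_R[, 1]), abs(e$vectors[, 1]))
  expect_true(all(sign(lev2$C_R[1:2, 1]) != sign(lev2$C_R[3:4, 1])))
  ## share >= 0.5 on arbitrary seeded input
  set.seed(11)
  ph3 <- matrix(runif(10 * 50, -pi, pi), 10, 50)
  lev3 <- leading_eigenvectors(phase_coherence(ph3))
  expect_true(all(lev3$share >= 0.5))
  expect_equal(colSums(lev3$C_R^2), rep(1, 50), tolerance = 1e-12)
})

test_that("eigenvector sign convention makes the majority negative", {
  set.seed(4)
  ph <- matrix(runif(9 * 30, -pi, pi), 9, 30)
  lev <- leading_eigenvectors(phase_coherence(ph))
  for (t in 1:30) {
    v <- lev$C_R[, t]
    expect_true(sum(v > 0) < sum(v < 0) ||
                  (sum(v > 0) == sum(v < 0) && v[1] <= 0))
  }
})

test_that("the sparsity penalty grid is the stated geometric sequence", {
  lg <- lambda_grid()
  expect_equal(lg[1], 1)
  expect_equal(lg[10], 0.1259, tolerance = 1e-4)
  expect_equal(diff(log10(lg)), rep(-0.1, 9), tolerance = 1e-12)
})

test_that("dictionary learning is exact at lambda = 0 and monotone", {
  set.seed(5)
  X <- matrix(rnorm(20 * 3), 20, 3) %*% matrix(rnorm(3 * 80), 3, 80)
  fit <- fit_dictionary(X, 3, lambda = 0, seed = 1)
  expect_lt(fit$E, 1e-6 * sum(X^2))
  fitl <- fit_dictionary(X + 0.05 * matrix(rnorm(20 * 80), 20, 80),
                         4, lambda = 0.3, seed = 2)
  o <- fitl$objective
  expect_true(all(diff(o) <= 1e-10 * pmax(1, abs(o[-length(o)]))))
})

test_that("stored reconstruction error matches recomputation and atoms are unit norm", {
  set.seed(6)
  X <- matrix(rnorm(15 * 60), 15, 60)
  fit <- fit_dictionary(X, 5, lambda = 0.2, seed = 3)
  expect_equal(fit$E, sum((X - fit$D %*% fit$A)^2),
               tolerance = 1e-9)
  expect_equal(sqrt(colSums(fit$D^2)), rep(1, 5), tolerance = 1e-9)
  expect_error(fit_dictionary(X, 100, 0.1), class = "fmripeb_invalid_argument")
})

test_that("planted orthogonal states are recovered by dictionary learning", {
  N <- 24; T_ <- 240
  D0 <- cbind(rep(c(1, -1), each = 12), rep(c(1, -1), 12),
              rep(c(1, 1, -1, -1), 6))
  D0 <- sweep(D0, 2, sqrt(colSums(D0^2)), `/`)
  ok <- 0L
  for (seed in 1:5) {
    set.seed(seed + 100)
    A0 <- matrix(0, 3, T_)
    for (t in seq_len(T_)) A0[sample.int(3, 1), t] <- runif(1, 0.5, 1.5)
    X <- D0 %*% A0 + 0.02 * matrix(rnorm(N * T_), N, T_)
    fit <- fit_dictionary(X, 3, lambda = 0.05, seed = seed, n_iter = 100)
    r <- match_components(t(fit$D), t(D0))
    if (all(r > 0.9)) ok <- ok + 1L
  }
  expect_gte(ok, 4L)
})

test_that("grid search selects the planted state and deduplicates", {
  ## one weight row equal to the contrast -> r = 1 and that state selected
  set.seed(7)
  N <- 12; T_ <- 120
  contrast <- as.numeric(sin((1:T_) / 8) > 0)
  D0 <- cbind(rep(c(1, -1), 6), rep(c(1, 1, -1, -1), 3)) / sqrt(12)
  A0 <- rbind(contrast, 0.2 * abs(rnorm(T_)))
  X <- D0 %*% A0 + 0.01 * matrix(rnorm(N * T_), N, T_)
  sel <- grid_search_states(X, cbind(contrast), k_grid = 2:3,
                            lambdas = c(0.1, 0.05), seed = 1, n_iter = 80)
  best_atom <- sel$fit$D[, sel$state_of_contrast[1]]
  expect_gt(abs(cor(best_atom, D0[, 1])), 0.95)
  expect_gt(abs(sel$r_of_contrast[1]), 0.95)
  ## two identical contrasts map to the same state -> one unique state
  sel2 <- grid_search_states(X, cbind(contrast, contrast), k_grid = 2:3,
                             lambdas = c(0.1, 0.05), seed = 1, n_iter = 80)
  expect_equal(ncol(sel2$states), 1)
})

test_that("grid search equals a brute-force re-scan of the full grid", {
  set.seed(8)
  N <- 10; T_ <- 80
  X <- matrix(rnorm(N * T_), N, T_)
  contrasts <- cbind(rnorm(T_), rnorm(T_))
  kg <- 2:4; lg <- c(0.3, 0.1)
  sel <- grid_search_states(X, contrasts, k_grid = kg, lambdas = lg,
                            seed = 5, n_iter = 40)
  ## brute force: refit every (k, lambda) with the same sub-seeds and scan
  best <- -Inf; best_k <- NA; best_l <- NA
  idx <- 0L
  for (k in kg) for (lam in lg) {
    idx <- idx + 1L
    fit <- fit_dictionary(X, k, lam, seed = fmripeb:::sub_seed(5, idx),
                          n_iter = 40)
    for (s in seq_len(k)) for (cc in 1:2) {
      r <- suppressWarnings(abs(cor(fit$A[s, ], contrasts[, cc])))
      if (is.finite(r) && r > best) { best <- r; best_k <- k; best_l <- lam }
    }
  }
  expect_equal(sel$k, best_k)
  expect_equal(sel$lambda, best_l)
})
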