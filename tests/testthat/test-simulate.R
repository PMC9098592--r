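test_that("EEG simulation is exact and linear in the noiseless regime", {
  sp <- fixture_space_small()
  L <- make_leadfield(sp, 16, seed = 1)
  tc <- sin((1:200) / 7)
  sc <- make_scene(list(1:3), matrix(tc, 1), noise_sd = 0, seed = 1)
  e <- simulate_eeg(sp, L, sc)
  expect_equal(max(abs(e$Y - L %*% e$S_true)), 0)
  sc2 <- make_scene(list(1:3), matrix(2 * tc, 1), noise_sd = 0, seed = 1)
  e2 <- simulate_eeg(sp, L, sc2)
  expect_equal(e2$Y, 2 * e$Y)
  expect_error(make_scene(list(), matrix(tc, 1)),
               class = "fmripeb_invalid_argument")
})

test_that("disjoint noiseless scenes superpose", {
  sp <- fixture_space_small()
  L <- make_leadfield(sp, 16, seed = 1)
  t1 <- sin((1:100) / 5); t2 <- cos((1:100) / 9)
  eA <- simulate_eeg(sp, L, make_scene(list(1:3), matrix(t1, 1), 0, 1))
  eB <- simulate_eeg(sp, L, make_scene(list(10:12), matrix(t2, 1), 0, 1))
  eAB <- simulate_eeg(sp, L, make_scene(list(1:3, 10:12), rbind(t1, t2), 0, 1))
  expect_equal(eA$Y + eB$Y, eAB$Y, tolerance = 1e-12)
})

test_that("requested channel noise level is realized empirically", {
  sp <- fixture_space_small()
  L <- make_leadfield(sp, 8, seed = 1)
  tc <- rep(0, 5000)
  e <- simulate_eeg(sp, L, make_scene(list(1L), matrix(tc, 1), noise_sd = 2, seed = 3))
  emp <- sd(as.numeric(e$Y))
  expect_lt(abs(emp - 2) / 2, 0.05)
})

test_that("single planted state at infinite SNR is recovered by LEiDA", {
  par <- default_paradigm(200, 1, n_conditions = 1, block_s = 40,
                          n_blocks = 4, lead_in_s = 0)
  s <- rep(c(1, -1), 6) / sqrt(12)
  b <- simulate_parcel_bold(12, par, list(s), snr = Inf, seed = 2)
  expect_equal(dim(b$values), c(12L, 200L))
  expect_true(all(is.finite(b$values)))
  lev <- leading_eigenvectors(phase_coherence(bandpass_phase(b)))
  inblock <- which(b$schedule == 1)
  ## drop filter edge transients
  inblock <- inblock[inblock > 10 & inblock < 190]
  cosim <- abs(colSums(lev$C_R[, inblock] * s))
  expect_true(all(cosim > 0.99))
  expect_error(simulate_parcel_bold(10, par, list(s)),
               class = "fmripeb_invalid_argument")
})

test_that("two orthogonal planted states yield block-locked weights", {
  ## Monte-Carlo: state-wise weight/contrast correlation at snr = 2
  par <- default_paradigm(300, 1, n_conditions = 2, block_s = 30,
                          n_blocks = 8, lead_in_s = 10)
  states <- planted_states_pair(20)
  hits <- 0L
  for (seed in 0:9) {
    b <- simulate_parcel_bold(20, par, states, snr = 2, seed = seed)
    lev <- leading_eigenvectors(phase_coherence(bandpass_phase(b)))
    fit <- fit_dictionary(lev$C_R, k = 4, lambda = 0.2, seed = seed,
                          n_iter = 50)
    ok <- TRUE
    for (ci in 1:2) {
      reg <- as.numeric(b$schedule == ci)
      rr <- apply(fit$A, 1, function(a) abs(cor(a, reg)))
      if (max(rr, na.rm = TRUE) <= 0.7) ok <- FALSE
    }
    if (ok) hits <- hits + 1L
  }
  expect_gte(hits, 7L)
})

test_that("ROI spheres match an exhaustive voxel-distance oracle", {
  sp <- fixture_space_mid()
  rois <- motion_rois()
  expect_equal(nrow(rois), 8L)
  inv <- solve(sp$affine)
  for (i in seq_len(nrow(rois))) {
    ctr <- as.numeric(rois[i, c("x", "y", "z")])
    vol <- make_roi_volume(ctr, rois$radius_mm[i], sp)
    ## brute-force scan over every voxel center
    oracle <- array(0L, sp$grid_shape)
    for (ix in 0:(sp$grid_shape[1] - 1))
      for (iy in 0:(sp$grid_shape[2] - 1))
        for (iz in 0:(sp$grid_shape[3] - 1)) {
          mm <- (sp$affine %*% c(ix, iy, iz, 1))[1:3]
          if (sum((mm - ctr)^2) <= rois$radius_mm[i]^2)
            oracle[ix + 1, iy + 1, iz + 1] <- 1L
        }
    expect_identical(vol, oracle)
  }
})

test_that("degenerate ROI requests behave as specified", {
  sp <- fixture_space_small()
  ## center on a voxel center with sub-voxel radius -> exactly 1 voxel
  ctr <- (sp$affine %*% c(4, 4, 4, 1))[1:3]
  vol <- make_roi_volume(ctr, min(diag(sp$affine)[1:3]) / 4, sp)
  expect_equal(sum(vol), 1)
  expect_warning(out <- make_roi_volume(c(500, 500, 500), 10, sp), "empty")
  expect_equal(sum(out), 0)
  expect_error(make_roi_volume(c(0, 0, 0), -1, sp),
               class = "fmripeb_invalid_argument")
})

test_that("surrogate templates are distinct, non-empty and reproducible", {
  sp <- fixture_space_mid()
  tpl <- make_template_set(sp, 4, seed = 0)
  expect_length(tpl, 4)
  for (i in 1:3) for (j in (i + 1):4) {
    expect_gt(sum(tpl[[i]]), 0)
    expect_lt(dice_overlap(tpl[[i]], tpl[[j]])$d, 0.2)
  }
  tpl2 <- make_template_set(sp, 4, seed = 0)
  expect_identical(tpl, tpl2)
  expect_error(make_template_set(sp, 1), class = "fmripeb_invalid_argument")
})
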