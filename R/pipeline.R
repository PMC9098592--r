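## End-to-end orchestration: the algorithm x CC-set run matrix and the
## full synthetic pipeline (priors -> covariance components -> inversion
## -> source components -> overlap scores).

#' Default pipeline configuration
#'
#' Desk-scale defaults: 642-vertex source space, 32 channels, 90 parcels,
#' 500 fMRI samples at TR = 1 s and 3000 EEG samples. Every stage is
#' seeded from `seed`.
#'
#' @param run_type "task" or "rest".
#' @param seed master seed.
#' @param ... overrides for any default field.
#' @return named list of class `run_config`.
#' @export
default_config <- function(run_type = "task", seed = 1, ...) {
  cfg <- list(
    run_type = run_type, seed = as.integer(seed),
    n_vertices = 642, n_channels = 32, n_parcels = 90,
    grid_shape = c(20, 20, 20),
    t_fmri = 500, tr_fmri = 1, t_eeg = 3000, fs_eeg = 60,
    snr_bold = 2, eeg_noise_sd = 0.5,
    k_grid = 5:10, lambdas = lambda_grid(), dl_iter = 60,
    n_contrasts = 2, n_templates = 4, n_ica = 6,
    z_thresh_activation = 2.5, min_cluster_voxels = 2,
    z_thresh_rsn = 3.0, z_thresh_sc = 3.0,
    retain = 0.99, n_patch = 64,
    algorithms = c("MN", "LORETA", "EBB", "MSP"))
  over <- list(...)
  cfg[names(over)] <- over
  structure(cfg, class = c("run_config", "list"))
}

#' Enumerate the inversion run matrix
#'
#' Task runs yield 4 algorithms x 3 CC sets = 12 jobs; resting-state
#' runs exclude S3, yielding 8. Ordering is deterministic (algorithms by
#' configuration order, sets S1 < S2 < S3).
#'
#' @param cfg a `run_config`.
#' @return data.frame with columns `algorithm`, `cc_set`.
#' @export
run_matrix <- function(cfg) {
  if (!cfg$run_type %in% c("task", "rest"))
    stop_invalid("unknown run type: ", cfg$run_type)
  sets <- if (cfg$run_type == "task") c("S1", "S2", "S3") else c("S1", "S2")
  expand.grid(cc_set = sets, algorithm = cfg$algorithms,
              stringsAsFactors = FALSE)[, c("algorithm", "cc_set")]
}

## stable hash of a configuration (for output provenance)
config_hash <- function(cfg) {
  f <- tempfile()
  on.exit(unlink(f))
  saveRDS(cfg[order(names(cfg))], f)
  unname(tools::md5sum(f))
}

#' Run the full synthetic pipeline
#'
#' Generates a source space, leadfield, parcel BOLD with planted dFC
#' states and EEG with a planted patch source; derives the three fMRI
#' prior families (GLM activation maps, ICA maps matched to surrogate
#' templates, dFC-state modules); assembles S1/S2/S3 covariance-component
#' sets; runs every job of the run matrix; decomposes each reconstruction
#' into source components and scores them against the planted-patch ROI
#' and the surrogate templates.
#'
#' @param cfg a `run_config` from [default_config()].
#' @param out_dir optional directory for artifacts (results TSV + JSON
#'   manifest); NULL keeps everything in memory.
#' @return list of class `pipeline_result`: `table` (long-format results,
#'   one row per job x map type), `jobs`, `priors`, `manifest`.
#' @export
run_all <- function(cfg = default_config(), out_dir = NULL) {
  seed <- cfg$seed
  space <- make_source_space(cfg$n_vertices, cfg$n_parcels, cfg$grid_shape,
                             seed = seed)
  L <- make_leadfield(space, cfg$n_channels, seed = seed)
  g <- green_kernel(space)

  ## ---- fMRI side: BOLD with planted states, GLM, RSN-ICA, dFC ----
  paradigm <- default_paradigm(cfg$t_fmri, cfg$tr_fmri,
                               n_conditions = cfg$n_contrasts)
  N <- cfg$n_parcels
  set.seed(sub_seed(seed, 20))
  states <- lapply(seq_len(cfg$n_contrasts), function(i) {
    s <- rep(-1, N)
    s[sample.int(N, N %/% 2)] <- 1
    s / sqrt(N)
  })
  active <- lapply(seq_len(cfg$n_contrasts), function(i)
    sample.int(N, max(2, N %/% 10)))
  bold <- simulate_parcel_bold(N, paradigm, states, snr = cfg$snr_bold,
                               seed = seed, active_parcels = active)
  design <- build_design(paradigm)
  contrasts <- sapply(seq_len(cfg$n_contrasts), function(i) {
    w <- rep(0, cfg$n_contrasts); w[i] <- 1
    contrast_timecourse(design, w)
  })

  ## activation priors: per-condition contrast z-maps, cluster-thresholded
  glm <- fit_glm(bold$values, design)
  act_vols <- list()
  for (i in seq_len(cfg$n_contrasts)) {
    cv <- c(rep(0, cfg$n_contrasts), 0); cv[i] <- 1
    zmap <- contrast_zmap(glm, cv)
    vol <- threshold_map(parcel_to_volume(zmap$z, space),
                         cfg$z_thresh_activation, cfg$min_cluster_voxels)
    if (sum(vol) > 0) act_vols[[paste0("activation", i)]] <- vol
  }

  ## RSN priors: spatial ICA on parcel BOLD, matched to surrogate templates
  templates <- make_template_set(space, cfg$n_templates, seed = seed)
  ica <- spatial_ica(bold$values, cfg$n_ica, seed = seed)
  ic_vols <- lapply(seq_len(cfg$n_ica), function(i)
    parcel_to_volume(ica$maps[i, ], space))
  asg <- assign_templates(ic_vols, templates, z_thresh = cfg$z_thresh_rsn,
                          seed = seed)
  rsn_vols <- list()
  for (ti in seq_along(templates)) {
    j <- asg$assignment[ti]
    if (is.na(j)) next
    vol <- (abs(ic_vols[[j]]) >= cfg$z_thresh_rsn) * 1L
    if (sum(vol) > 0) rsn_vols[[paste0("rsn", ti)]] <- vol
  }

  ## dFC priors: phase coherence -> LEiDA -> dictionary grid -> modules
  dfc_vols <- list()
  if (cfg$run_type == "task") {
    ph <- bandpass_phase(bold)
    lev <- leading_eigenvectors(phase_coherence(ph))
    sel <- grid_search_states(lev, contrasts, k_grid = cfg$k_grid,
                              lambdas = cfg$lambdas, seed = seed,
                              n_iter = cfg$dl_iter)
    for (si in seq_len(ncol(sel$states))) {
      part <- state_modules(sel$states[, si], seed = seed)
      mv <- modules_to_volumes(part, space)
      for (mi in seq_along(mv))
        dfc_vols[[sprintf("dfc_state%d_module%d", si, mi)]] <- mv[[mi]]
    }
  } else sel <- NULL

  ## ---- priors -> covariance components ----
  to_cc <- function(vols, provenance) {
    out <- list()
    for (nm in names(vols)) {
      pr <- tryCatch(volume_to_surface(vols[[nm]], space, label = nm,
                                       provenance = provenance),
                     error = function(e) NULL)
      if (is.null(pr)) next
      out[[nm]] <- prior_to_cc(smooth_prior(pr, g))
    }
    out
  }
  act_ccs <- to_cc(act_vols, "activation")
  rsn_ccs <- to_cc(rsn_vols, "rsn")
  dfc_ccs <- to_cc(dfc_vols, "dfc-module")

  ## ---- EEG side: planted patch source ----
  set.seed(sub_seed(seed, 21))
  patch_center <- sample.int(nrow(space$vertices), 1)
  patch <- c(patch_center, space$neighbors[[patch_center]])
  tc <- sin(2 * pi * 8 * (seq_len(cfg$t_eeg) - 1) / cfg$fs_eeg)
  scene <- make_scene(list(patch), matrix(tc, 1), cfg$eeg_noise_sd, seed)
  eeg <- simulate_eeg(space, L, scene, fs = cfg$fs_eeg)
  red <- temporal_reduce(eeg$Y, cfg$retain)

  ## scoring targets: planted-patch ROI + surrogate templates
  patch_vol <- surface_to_volume(as.numeric(seq_len(nrow(space$vertices))
                                            %in% patch), space)
  targets_roi <- list(planted_patch = (patch_vol > 0) * 1L)
  targets_tpl <- setNames(templates, paste0("template", seq_along(templates)))

  ## ---- run matrix ----
  jobs <- run_matrix(cfg)
  rows <- list(); job_info <- list()
  for (jb in seq_len(nrow(jobs))) {
    alg <- jobs$algorithm[jb]; setn <- jobs$cc_set[jb]
    res <- tryCatch({
      intr <- algorithm_ccs(alg, L, Y = eeg$Y, g = g, n_patch = cfg$n_patch)
      ccset <- assemble_cc_set(alg, intr, rsn = rsn_ccs,
                               activation = act_ccs, dfc_modules = dfc_ccs,
                               set_name = setn, run_type = cfg$run_type)
      inv <- invert_eeg(eeg$Y, L, ccset, reduction = red)
      sc <- decompose_sources(inv$S, n_components = min(inv$reduction$r, 8),
                              seed = seed)
      sc_vols <- lapply(seq_len(sc$I), function(i)
        surface_to_volume(sc$maps[i, ], space))
      m_roi <- best_match(sc_vols, targets_roi, cfg$z_thresh_sc)
      m_tpl <- best_match(sc_vols, targets_tpl, cfg$z_thresh_sc)
      aggregate_scores(list(roi = m_roi, template = m_tpl),
                       list(run_type = cfg$run_type, algorithm = alg,
                            cc_set = setn, VE = as.numeric(inv$scores$VE),
                            logev = inv$scores$logev, seed = seed,
                            n_cc = length(ccset$ccs)))
    }, error = function(e) {
      warning(sprintf("job %s/%s failed: %s", alg, setn, conditionMessage(e)))
      NULL
    })
    job_info[[jb]] <- list(algorithm = alg, cc_set = setn,
                           ok = !is.null(res))
    if (!is.null(res)) rows[[length(rows) + 1]] <- res
  }
  table <- do.call(rbind, rows)
  manifest <- list(config_hash = config_hash(cfg), seed = seed,
                   n_jobs = nrow(jobs),
                   n_failed = sum(!vapply(job_info, `[[`, TRUE, "ok")),
                   n_priors = c(activation = length(act_ccs),
                                rsn = length(rsn_ccs),
                                dfc = length(dfc_ccs)),
                   timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"))
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    utils::write.table(table, file.path(out_dir, "results.tsv"),
                       sep = "\t", row.names = FALSE, quote = FALSE)
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE)
  }
  structure(list(table = table, jobs = jobs, manifest = manifest,
                 selection = sel,
                 priors = list(activation = act_ccs, rsn = rsn_ccs,
                               dfc = dfc_ccs)),
            class = "pipeline_result")
}
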