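# Config-driven end-to-end pipeline: simulate a dose series, phase every
# pattern with an OSS ensemble, select by clustering, measure quality and
# damage trends, and write a report. Every stochastic stage receives a seed
# derived deterministically from the one global seed, so a config plus a
# seed reproduces every number byte for byte.

pipeline_defaults <- function() {
  list(
    simulate = list(grid_size = 64L, object_fraction = 0.08, n_blobs = 6L,
                    density_range = c(0.5, 1.5), pixel_nm = 20,
                    n_steps = 4L, high_decay = 0.05, low_swell = 0.05,
                    swell_peak_step = 2L, photon_budget = 1e6,
                    stop_halfwidth = 0L, stop_offset = c(0L, 0L),
                    binning = 1L),
    reconstruct = list(n_runs = 6L, n_iterations = 300L, n_stages = 5L,
                       beta = 0.9, constraint_mode = "real_nonneg"),
    cluster = list(k = 2L, n_components = 10L, n_best = 24L),
    metrics = list(shell_width = 1, tail_fraction = 0.1,
                   threshold = exp(-1)),
    damage = list(regions = NULL)
  )
}

validate_config <- function(config) {
  defaults <- pipeline_defaults()
  unknown <- setdiff(names(config), names(defaults))
  if (length(unknown) > 0L)
    stop_sk("unknown config section(s): ", paste(unknown, collapse = ", "))
  for (sec in names(config)) {
    bad <- setdiff(names(config[[sec]]), names(defaults[[sec]]))
    if (length(bad) > 0L)
      stop_sk("unknown key(s) in section '", sec, "': ",
              paste(bad, collapse = ", "))
    defaults[[sec]] <- utils::modifyList(defaults[[sec]], config[[sec]])
  }
  defaults
}

#' Run the full simulation-to-damage pipeline
#'
#' Simulates a dose series of phantoms, produces noisy masked patterns,
#' phases each with an OSS ensemble, selects the consistent cluster and
#' averages it, measures wPRTF resolutions and cross-correlations, and
#' quantifies electron loss and region density trajectories. All stage
#' seeds derive from `seed`, so results are reproducible end to end.
#'
#' @param config named list (or path to a YAML file) overriding any subset
#'   of the stage parameters; unknown keys are rejected. Sections:
#'   `simulate`, `reconstruct`, `cluster`, `metrics`, `damage`.
#' @param seed single integer driving every stochastic stage.
#' @param out_dir optional directory; when given, a schema-versioned JSON
#'   report, tidy CSV curves and PNG previews are written there.
#' @return A list with the phantoms, patterns, per-step averages, curves,
#'   CC matrix, damage summaries and the resolved config.
#' @export
run_pipeline <- function(config = list(), seed = 1L, out_dir = NULL) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  cfg <- validate_config(config)
  seed <- as.integer(seed)
  sim <- cfg$simulate
  sim$swell_peak_step <- min(sim$swell_peak_step, sim$n_steps - 1L)

  ph0 <- make_phantom(seed = seed, grid_size = sim$grid_size,
                      object_fraction = sim$object_fraction,
                      n_blobs = sim$n_blobs,
                      density_range = sim$density_range,
                      pixel_nm = sim$pixel_nm)
  series_ph <- simulate_damage_series(ph0, n_steps = sim$n_steps,
                                      high_decay = sim$high_decay,
                                      low_swell = sim$low_swell,
                                      swell_peak_step = sim$swell_peak_step,
                                      seed = seed + 1L)
  # one common photon scale (set by the undamaged step) so absolute
  # intensity differences between dose steps survive the noise step
  photon_scale <- sim$photon_budget /
    sum(diffract(series_ph[[1L]])$intensity)
  patterns <- lapply(seq_along(series_ph), function(t) {
    p <- diffract(series_ph[[t]])
    p <- add_poisson_noise(p, sim$photon_budget, seed = seed + 100L + t,
                           scale = photon_scale)
    if (sim$stop_halfwidth > 0L)
      p <- apply_beamstop_and_symmetrize(p, sim$stop_halfwidth,
                                         sim$stop_offset)
    if (sim$binning > 1L) p <- bin_and_deconvolve(p, sim$binning)
    p
  })

  rec <- cfg$reconstruct
  schedule <- oss_schedule(n_iterations = rec$n_iterations,
                           n_stages = rec$n_stages, beta = rec$beta)
  support <- ph0$support
  cl <- cfg$cluster
  steps <- lapply(seq_along(patterns), function(t) {
    ens <- run_ensemble(patterns[[t]], support, schedule,
                        n_runs = rec$n_runs,
                        base_seed = seed + 1000L * t,
                        constraint_mode = rec$constraint_mode)
    sel <- cluster_ensemble(ens, k = min(cl$k, rec$n_runs),
                            n_components = cl$n_components,
                            n_best = cl$n_best, seed = seed + 7L)
    sel
  })

  met <- cfg$metrics
  shells <- build_shells(dim(patterns[[1L]]$intensity),
                         patterns[[1L]]$freq_per_pixel,
                         shell_width = met$shell_width)
  resolutions <- vapply(seq_along(steps), function(t) {
    pr <- prtf(steps[[t]]$average, patterns[[t]], shells)
    w <- wiener_weight(patterns[[t]], shells)
    res <- resolution_from_curve(wprtf(pr, w), threshold = met$threshold)
    res$d_nm
  }, numeric(1))
  cc <- global_cc(patterns)

  # damage analysis in the frame of the step-1 average
  avg_recs <- lapply(steps, function(s) {
    new_reconstruction(s$average$image, support, 0, 0L)
  })
  series <- register_series(
    dose_series(avg_recs, doses = seq_along(steps), calibration = 1))
  loss <- electron_loss_series(series, support = support)
  regions <- cfg$damage$regions
  region_series <- if (!is.null(regions)) {
    lapply(regions, function(r) {
      region_density_series(series, do.call(region_spec, r))
    })
  }

  out <- list(phantoms = series_ph, patterns = patterns, steps = steps,
              shells = shells, resolutions_nm = resolutions,
              cc_matrix = cc, electron_loss = loss,
              region_series = region_series, config = cfg, seed = seed)
  if (!is.null(out_dir)) {
    report <- list(
      seed = seed,
      resolutions_nm = resolutions,
      cc_matrix = cc,
      electron_loss_fraction = loss,
      cluster_members = lapply(steps, function(s) s$average$members),
      mean_rfactors = vapply(steps, function(s) s$average$mean_rfactor,
                             numeric(1)))
    previews <- list(phantom = ph0$density,
                     reconstruction = Re(steps[[1L]]$average$image))
    write_report(report, out_dir, previews = previews)
  }
  out
}
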