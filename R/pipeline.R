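# Pipeline orchestration: composes the generators, torque model, filtering
# cascade, simulator and comparison into named stages with on-disk
# artifacts, a reproducibility manifest and stderr logging.

log_msg <- function(level, ...) {
  message(sprintf("[%s] %s %s", level, format(Sys.time(), "%H:%M:%S"),
                  paste0(...)))
}

write_manifest <- function(out_dir, config, artifacts) {
  manifest <- list(
    package = "hybridgait",
    version = as.character(utils::packageVersion("hybridgait")),
    r_version = paste(R.version$major, R.version$minor, sep = "."),
    config = {
      v <- unclass(config)
      v[!vapply(v, is.null, logical(1))]
    },
    artifacts = artifacts
  )
  path <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  path
}

pipeline_controller <- function(config, model) {
  ref_table <- if (!is.null(config$reference_table_path)) {
    read_reference_table(config$reference_table_path)
  } else default_reference_table()
  env_TA <- if (!is.null(config$envelope_TA_path)) {
    read_envelope_model(config$envelope_TA_path)
  } else default_envelope_model("TA")
  env_sol <- if (!is.null(config$envelope_sol_path)) {
    read_envelope_model(config$envelope_sol_path)
  } else default_envelope_model("soleus")
  sim_controller(model, ref_table = ref_table, env_TA = env_TA,
                 env_sol = env_sol, k_min = config$k_min,
                 k_max = config$k_max, zeta = config$zeta,
                 damping_mode = config$damping_mode,
                 fes_rate = config$fes_rate)
}

pipeline_model <- function(config) {
  if (!is.null(config$model_path)) {
    log_msg("INFO", "loading torque model from ", config$model_path)
    load_cnn(config$model_path)
  } else {
    path <- file.path(config$out_dir, "cnn_model.rds")
    if (file.exists(path)) {
      log_msg("INFO", "loading torque model from ", path)
      load_cnn(path)
    } else {
      abort("no trained torque model found; run the train-cnn stage first",
            "hybridgait_stage_error")
    }
  }
}

write_run <- function(res, out_dir, tag) {
  f_series <- file.path(out_dir, paste0("run_", tag, ".csv"))
  f_cycles <- file.path(out_dir, paste0("cycles_", tag, ".csv"))
  f_meta <- file.path(out_dir, paste0("meta_", tag, ".json"))
  series <- res$series
  series$theta_deg <- rad2deg(series$theta)
  series$theta_d_deg <- rad2deg(series$theta_d)
  utils::write.csv(series, f_series, row.names = FALSE)
  utils::write.csv(res$cycles, f_cycles, row.names = FALSE)
  jsonlite::write_json(list(mode = res$mode, speed = res$speed,
                            n_cycles = res$n_cycles, seed = res$seed,
                            alpha = res$alpha, dt = res$dt),
                       f_meta, auto_unbox = TRUE, digits = NA)
  c(f_series, f_cycles, f_meta)
}

read_run <- function(out_dir, tag) {
  f_cycles <- file.path(out_dir, paste0("cycles_", tag, ".csv"))
  f_meta <- file.path(out_dir, paste0("meta_", tag, ".json"))
  if (!file.exists(f_cycles) || !file.exists(f_meta)) {
    abort(paste0("missing simulate artifacts for tag '", tag, "'"),
          "hybridgait_stage_error")
  }
  meta <- jsonlite::read_json(f_meta, simplifyVector = TRUE)
  structure(list(cycles = utils::read.csv(f_cycles), mode = meta$mode,
                 speed = meta$speed, n_cycles = meta$n_cycles,
                 seed = meta$seed, alpha = meta$alpha, dt = meta$dt),
            class = "sim_result")
}

#' Ankle-angle peaks at canonical gait-phase landmarks
#'
#' Local extremum of the angle within a `+/- window`% phase window centred
#' at each landmark phase (default 15, 45, 65 and 90% of the cycle).
#'
#' @param phase gait-phase series, percent (`NA` allowed; those samples are
#'   ignored).
#' @param theta_deg ankle angle series, degrees, aligned with `phase`.
#' @param phases landmark phases, percent.
#' @param window half-width of each search window, percent.
#' @return data frame with `phase` (landmark) and `peak_deg` (the extremum
#'   of largest magnitude in the window).
#' @export
angle_peaks <- function(phase, theta_deg, phases = c(15, 45, 65, 90),
                        window = 5) {
  stopifnot(length(phase) == length(theta_deg))
  peak <- vapply(phases, function(p) {
    sel <- !is.na(phase) & abs(phase - p) <= window
    if (!any(sel)) return(NA_real_)
    x <- theta_deg[sel]
    x[which.max(abs(x))]
  }, numeric(1))
  data.frame(phase = phases, peak_deg = peak)
}

run_stage_gen_data <- function(config) {
  fsr <- gen_fsr_traces(config$speed, config$cycles, seed = config$seed)
  f_fsr <- file.path(config$out_dir, "fsr.csv")
  utils::write.csv(cbind(fsr$frames, phase = fsr$phase), f_fsr,
                   row.names = FALSE)
  ds <- gen_isometric_dataset(n_samples = config$n_train,
                              seed = config$seed)
  f_ds <- file.path(config$out_dir, "isometric_dataset.rds")
  saveRDS(ds, f_ds)
  log_msg("INFO", "gen-data: ", config$cycles, " cycles of FSR, ",
          config$n_train, " isometric windows")
  c(f_fsr, f_ds)
}

run_stage_train_cnn <- function(config) {
  f_ds <- file.path(config$out_dir, "isometric_dataset.rds")
  ds <- if (file.exists(f_ds)) readRDS(f_ds) else {
    gen_isometric_dataset(n_samples = config$n_train, seed = config$seed)
  }
  model <- build_model(cnn_config(seed = config$seed))
  trained <- train(model, ds, max_epochs = config$max_epochs)
  f_model <- file.path(config$out_dir, "cnn_model.rds")
  save_cnn(trained$model, f_model)
  log_msg("INFO", sprintf(
    "train-cnn: test RMSE %.3f Nm, peak accuracy %.1f%%",
    trained$metrics$rmse, trained$metrics$peak_accuracy))
  f_model
}

run_stage_filter_emg <- function(config) {
  params <- emg_synthesis_params()
  env_sol <- default_envelope_model("soleus")
  fsr <- gen_fsr_traces(config$speed, 3, seed = config$seed)
  act <- clamp(config$alpha * emg_envelope(env_sol, config$speed,
                                           fsr$phase), 0, 1)
  vol <- gen_volitional_emg(params, act, seed = config$seed)
  pulses <- seq(0, max(vol$t), by = 1 / config$fes_rate)
  stim <- gen_stimulated_emg(vol, pulses, rep(10, length(pulses)), params)
  ext <- extract_volitional_envelope(stim, filter_config())
  f_env <- file.path(config$out_dir, "volitional_envelope.csv")
  utils::write.csv(data.frame(t = ext$t, envelope = ext$envelope[, 1],
                              truth = vol$envelope),
                   f_env, row.names = FALSE)
  log_msg("INFO", "filter-emg: wrote reconstructed envelope")
  f_env
}

run_stage_simulate <- function(config, mode = config$mode) {
  model <- pipeline_model(config)
  ctrl <- pipeline_controller(config, model)
  plant <- plant_params(participation_alpha = config$alpha,
                        seed = config$seed)
  res <- simulate_gait(mode, config$cycles, config$speed, plant, ctrl,
                       dt = config$dt)
  log_msg("INFO", sprintf(
    "simulate [%s]: %d cycles, mean device energy %.3f J/cycle",
    mode, nrow(res$cycles),
    mean(res$cycles$energy_pafo + res$cycles$energy_fes)))
  list(result = res,
       files = write_run(res, config$out_dir, tolower(mode)))
}

run_stage_compare <- function(config) {
  pf <- read_run(config$out_dir, "pf")
  pfv <- read_run(config$out_dir, "pfv")
  cmp <- compare_modes(pf, pfv)
  f_cmp <- file.path(config$out_dir, "comparison.csv")
  utils::write.csv(as.data.frame(cmp), f_cmp, row.names = FALSE)
  log_msg("INFO", "compare: wrote PF/PFV energy comparison")
  f_cmp
}

run_stage_report <- function(config) {
  f_cmp <- file.path(config$out_dir, "comparison.csv")
  if (!file.exists(f_cmp)) {
    abort("report stage requires the compare stage's artifacts",
          "hybridgait_stage_error")
  }
  cmp <- utils::read.csv(f_cmp)
  peaks <- list()
  for (tag in c("pf", "pfv")) {
    f_series <- file.path(config$out_dir, paste0("run_", tag, ".csv"))
    if (file.exists(f_series)) {
      s <- utils::read.csv(f_series)
      peaks[[tag]] <- angle_peaks(s$phase, s$theta_deg)
    }
  }
  report <- list(
    config = {
      v <- unclass(config)
      v[!vapply(v, is.null, logical(1))]
    },
    angle_peaks = peaks,
    energy_comparison = cmp
  )
  f_rep <- file.path(config$out_dir, "report.json")
  jsonlite::write_json(report, f_rep, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  log_msg("INFO", "report: wrote ", f_rep)
  f_rep
}

#' Run the hybrid-gait pipeline
#'
#' Executes the requested stages in order, writing all artifacts and a
#' reproducibility manifest (configuration, seeds, versions) under
#' `config$out_dir`. Stages: `gen-data` (FSR traces and isometric EMG
#' dataset), `train-cnn` (torque model), `filter-emg` (volitional-envelope
#' extraction demo), `simulate` (closed-loop run in `config$mode`),
#' `compare` (paired PF/PFV energies; requires both `run_pf`/`run_pfv`
#' artifacts, which `simulate` produces for the configured mode — pass
#' `stages = "simulate-both"` to run both modes), `report` (angle-peak and
#' energy tables as JSON).
#'
#' @param config a `run_config` (see [load_config()]), or a named list.
#' @param stages character vector of stage names, a subset of
#'   `c("gen-data", "train-cnn", "filter-emg", "simulate",
#'   "simulate-both", "compare", "report")`, executed in the given order.
#' @return invisibly, a named list of artifact paths per stage (plus the
#'   manifest path); errors are raised with the failing stage named.
#' @export
run_pipeline <- function(config,
                         stages = c("gen-data", "train-cnn",
                                    "simulate-both", "compare", "report")) {
  if (!inherits(config, "run_config")) config <- validate_config(config)
  known <- c("gen-data", "train-cnn", "filter-emg", "simulate",
             "simulate-both", "compare", "report")
  bad <- setdiff(stages, known)
  if (length(bad) > 0) {
    abort(paste0("unknown stage(s): ", paste(bad, collapse = ", ")),
          "hybridgait_stage_error")
  }
  if (!dir.exists(config$out_dir)) {
    dir.create(config$out_dir, recursive = TRUE)
  }
  artifacts <- list()
  for (st in stages) {
    log_msg("INFO", "stage ", st, " starting")
    out <- tryCatch(
      switch(st,
             "gen-data" = run_stage_gen_data(config),
             "train-cnn" = run_stage_train_cnn(config),
             "filter-emg" = run_stage_filter_emg(config),
             "simulate" = run_stage_simulate(config)$files,
             "simulate-both" = c(run_stage_simulate(config, "PF")$files,
                                 run_stage_simulate(config, "PFV")$files),
             "compare" = run_stage_compare(config),
             "report" = run_stage_report(config)),
      error = function(e) {
        abort(paste0("stage '", st, "' failed: ", conditionMessage(e)),
              "hybridgait_stage_error")
      })
    artifacts[[st]] <- out
  }
  artifacts$manifest <- write_manifest(config$out_dir, config, artifacts)
  invisible(artifacts)
}
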