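# Pipeline orchestration: a YAML-configurable driver that loads or
# synthesizes a system, runs the requested analysis stages in dependency
# order, and writes one CSV per stage (each with a commented header naming
# units and the conventions in force) plus a JSON manifest recording the
# software version, seed and configuration hash.

#' Load and validate a run configuration
#'
#' The configuration is a YAML file (or an equivalent list) with fields:
#' `structure`/`trajectory` input paths (or a `simulate` block with
#' [toy_channel_spec()] fields and optional `n_frames`, `dt`,
#' `hydration_program`, `tilt_degrees`), `stages` (any of `contacts`,
#' `events`, `occupancy`, `pore`, `hydration`, `tilt`, `phases`,
#' `membrane_width`), `sites` (named blocks with `members` and optional
#' cutoffs), stage `parameters`, `out_dir` and `seed`.
#'
#' @param config path to a YAML file, or a list.
#' @return validated config list of class `run_config`.
#' @export
run_config <- function(config) {
  cfg_path <- NULL
  if (is.character(config)) {
    cfg_path <- config
    if (!file.exists(config)) stop("config file not found: ", config)
    config <- yaml::read_yaml(config)
  }
  if (is.null(config$out_dir)) stop("config must set out_dir")
  if (is.null(config$seed)) config$seed <- 1L
  if (is.null(config$stages)) config$stages <- "hydration"
  known <- c("contacts", "events", "occupancy", "pore", "hydration", "tilt",
             "phases", "membrane_width")
  bad <- setdiff(config$stages, known)
  if (length(bad) > 0) stop("unknown stage(s): ", paste(bad, collapse = ", "))
  if (is.null(config$simulate)) {
    if (is.null(config$structure) || !file.exists(config$structure))
      stop("config structure path missing or not found")
    if (is.null(config$trajectory) || !file.exists(config$trajectory))
      stop("config trajectory path missing or not found")
  }
  config$path <- cfg_path
  class(config) <- c("run_config", "list")
  config
}

.config_sites <- function(config) {
  sites <- default_sites()
  for (nm in names(config$sites)) {
    blk <- config$sites[[nm]]
    sites[[nm]] <- site_definition(
      nm, as.integer(unlist(blk$members)),
      contact_enter_cutoff = blk$contact_enter_cutoff %||% 3.5,
      dissociation_cutoff = blk$dissociation_cutoff %||% 5.0)
  }
  sites
}

`%||%` <- function(a, b) if (is.null(a)) b else a

.write_stage_csv <- function(df, path, header_lines) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("# ", header_lines), con)
  utils::write.csv(df, con, row.names = FALSE)
  invisible(path)
}

#' Run the analysis pipeline from a configuration
#'
#' Stages run in dependency order (input -> per-frame analyses ->
#' summaries); every output CSV names its units and conventions in a
#' commented header, and `manifest.json` records the package version, seed,
#' configuration hash and the convention decisions in force.
#'
#' @param config a [run_config()], YAML path or list.
#' @return invisibly, a list of the objects computed per stage.
#' @export
run_pipeline <- function(config) {
  config <- run_config(config)
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  set.seed(config$seed)
  sites <- .config_sites(config)
  pars <- config$parameters %||% list()

  if (!is.null(config$simulate)) {
    sim <- config$simulate
    spec_args <- sim[intersect(names(sim), names(formals(toy_channel_spec)))]
    spec <- do.call(toy_channel_spec, spec_args)
    built <- build_toy_channel(spec)
    scripted <- script_trajectory(
      built$topology, built$frame,
      script = NULL,
      tilt_program = sim$tilt_degrees %||% NULL,
      hydration_program = sim$hydration_program %||% NULL,
      noise_amplitude = sim$noise_amplitude %||% 0,
      seed = config$seed, dt = sim$dt %||% 1000,
      n_frames = sim$n_frames %||% NULL)
    traj <- scripted$trajectory
    topo <- built$topology
  } else {
    loaded <- load_structure(config$structure)
    topo <- loaded$topology
    traj <- load_trajectory(topo, config$trajectory,
                            dialect = config$dialect %||% "multi-pdb",
                            frame_interval = pars$frame_interval %||% 1000)
  }

  conventions <- list(
    axis_orientation = "extracellular at high z; pore axis ~ +z",
    distance_metric = "minimum image, orthorhombic box",
    contact_cutoff_A = 3.5, dissociation_cutoff_A = 5.0,
    contact_atoms = "heavy atoms only",
    turn_windows = default_turn_windows(),
    hydration_cylinder_radius_A = pars$cylinder_radius %||% 4,
    dehydration_threshold = pars$hydration_threshold %||% 5)

  results <- list()
  outputs <- character(0)
  emit <- function(df, name, hdr) {
    p <- file.path(config$out_dir, paste0(name, ".csv"))
    .write_stage_csv(df, p, c(hdr, paste0("seed: ", config$seed)))
    outputs <<- c(outputs, p)
  }

  for (stage in config$stages) {
    res <- switch(stage,
      contacts = {
        ct <- contact_probability(traj, sites[[pars$contact_site %||% "TM1"]],
                                  stride = pars$contact_stride %||% 1000)
        emit(as.data.frame(ct), "contacts",
             c("contact probability (% of sampled frames), per subunit",
               "cutoff 3.5 A to heavy atoms; sd uses n-1 across subunits"))
        ct
      },
      events = {
        ev <- detect_all_binding_events(
          traj, sites[[pars$event_site %||% "TM2"]])
        emit(as.data.frame(ev), "events",
             c("binding events; times ps, residence ns",
               "enter <= 3.5 A to site, exit > 5.0 A from protein"))
        ev
      },
      occupancy = {
        oc <- occupancy_series(traj, sites[[pars$event_site %||% "TM2"]])
        emit(as.data.frame(oc), "occupancy",
             c("bound-ligand count per frame; time ps",
               sprintf("series mean %.4f sd %.4f (population)",
                       attr(oc, "mean"), attr(oc, "sd"))))
        oc
      },
      pore = {
        zr <- pars$pore_z_range %||% c(-12, 10)
        pp <- pore_radius_profile(topo, get_frame(traj, n_frames(traj)),
                                  z_range = as.numeric(zr),
                                  z_step = pars$pore_z_step %||% 0.5)
        emit(as.data.frame(pp), "pore_profile",
             c("pore radius profile; z and radius in angstrom",
               "probe centered on the fitted pore axis"))
        pp
      },
      hydration = {
        hs <- hydration_series(traj,
                               cylinder_radius = pars$cylinder_radius %||% 4,
                               threshold = pars$hydration_threshold %||% 5)
        emit(as.data.frame(hs), "hydration",
             c("gate water count; time ps",
               sprintf("cylinder radius %g A between 9'/16' C-beta rings; dehydrated when n < %d",
                       pars$cylinder_radius %||% 4,
                       pars$hydration_threshold %||% 5)))
        hs
      },
      tilt = {
        ts <- tilt_series(traj)
        emit(ts, "tilt",
             c("M2 tilt angles vs membrane normal, degrees; time ps",
               "turns: intracellular 222-225, middle 230-233, extracellular 237-240"))
        ts
      },
      phases = {
        pf <- phase_fractions(traj)
        emit(as.data.frame(pf), "phases",
             c("ligand phase counts and fractions per frame; time ps",
               "protein (<= 3.5 A) takes precedence over membrane (between phosphate planes)"))
        pf
      },
      membrane_width = {
        w <- vapply(seq_len(n_frames(traj)), function(f)
          membrane_width(topo, get_frame(traj, f)), numeric(1))
        df <- data.frame(time = traj$times, width = w)
        emit(df, "membrane_width",
             "membrane width (phosphate plane separation), angstrom; time ps")
        df
      })
    results[[stage]] <- res
  }

  cfg_json <- jsonlite::toJSON(unclass(config), auto_unbox = TRUE,
                               digits = NA, force = TRUE)
  tf <- tempfile(); writeLines(cfg_json, tf)
  manifest <- list(
    package = "channelprobe",
    version = as.character(utils::packageVersion("channelprobe")),
    seed = config$seed,
    config_md5 = unname(tools::md5sum(tf)),
    stages = config$stages,
    conventions = conventions,
    outputs = basename(outputs))
  unlink(tf)
  jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(results)
}
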