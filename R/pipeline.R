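#' Pipeline configuration
#'
#' Validated configuration for the end-to-end workflow: generate (or load)
#' a saturated volume, drain it over a matric-potential schedule, extract
#' REV subsamples and dyadic levels, solve the cell problem, compute pore
#' metrics and fit the van Genuchten model. All seeds are explicit (no
#' wall-clock seeding) and the configuration is serialised alongside the
#' outputs.
#'
#' @param spec A [synthetic_spec()], or a path to a labelled TIFF volume.
#' @param schedule A [drainage_schedule()].
#' @param n_subsamples Number of REV cubes.
#' @param subsample_side_mm Cube side length (mm); `NULL` takes the largest
#'   cube that fits.
#' @param j_max Deepest dyadic level.
#' @param directions Driving directions for the solver.
#' @param solver_tol Stokes relative residual tolerance.
#' @param seed Seed for subsample origins.
#' @param out_dir Output directory (`NULL` = no files written).
#' @return Object of class `pipeline_config`.
#' @export
pipeline_config <- function(spec, schedule = drainage_schedule(),
                            n_subsamples = 2, subsample_side_mm = NULL,
                            j_max = 2, directions = 3, solver_tol = 1e-8,
                            seed = 1L, out_dir = NULL) {
  if (!(inherits(spec, "synthetic_spec") ||
        (is.character(spec) && length(spec) == 1L)))
    stop("spec must be a synthetic_spec or a volume path")
  stopifnot(inherits(schedule, "drainage_schedule"),
            n_subsamples >= 1, j_max >= 0, solver_tol > 0,
            all(directions %in% 1:3))
  if (is.character(spec) && !file.exists(spec))
    stop("volume path does not exist: ", spec)
  structure(list(spec = spec, schedule = schedule,
                 n_subsamples = as.integer(n_subsamples),
                 subsample_side_mm = subsample_side_mm,
                 j_max = as.integer(j_max),
                 directions = as.integer(directions),
                 solver_tol = solver_tol, seed = as.integer(seed),
                 out_dir = out_dir),
            class = "pipeline_config")
}

#' Read a pipeline configuration from YAML
#'
#' @param path YAML file with fields mirroring [pipeline_config()]
#'   (`texture`, `grid_shape`, `voxel_size_um`, `target_porosity`,
#'   `potentials_kpa`, `n_subsamples`, `j_max`, `directions`,
#'   `solver_tol`, `seed`, `out_dir`).
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  spec <- if (!is.null(y$volume_path)) y$volume_path else {
    args <- list(texture = y$texture, rng_seed = y$seed %||% 1L)
    if (!is.null(y$grid_shape)) args$grid_shape <- unlist(y$grid_shape)
    if (!is.null(y$voxel_size_um)) args$voxel_size_um <- y$voxel_size_um
    if (!is.null(y$target_porosity)) args$target_porosity <- y$target_porosity
    do.call(synthetic_spec, args)
  }
  sched <- if (!is.null(y$potentials_kpa))
    drainage_schedule(unlist(y$potentials_kpa)) else drainage_schedule()
  pipeline_config(spec, sched,
                  n_subsamples = y$n_subsamples %||% 2,
                  subsample_side_mm = y$subsample_side_mm,
                  j_max = y$j_max %||% 2,
                  directions = unlist(y$directions) %||% 3,
                  solver_tol = y$solver_tol %||% 1e-8,
                  seed = y$seed %||% 1L, out_dir = y$out_dir)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Run the full analysis pipeline
#'
#' Generate/load -> drain over the schedule -> extract REV subsamples
#' (same origins at every potential) -> dyadic series -> Stokes solves ->
#' pore metrics -> convergence statistics -> van Genuchten fit. Rerunning
#' with an identical configuration reproduces identical outputs.
#'
#' @param config A [pipeline_config()].
#' @param verbose Print per-stage progress.
#' @return A report list: `volumes`, `metrics` (data frame),
#'   `conductivity` (per subsample/level/potential data frame),
#'   `convergence` (per potential), `wrc` (data frame), `vg` (fitted
#'   [vg_params()] or NULL), `config`.
#' @export
run_pipeline <- function(config, verbose = FALSE) {
  stopifnot(inherits(config, "pipeline_config"))
  say <- function(...) if (verbose) message(sprintf(...))
  t0 <- Sys.time()
  # stage: source volume
  vol <- if (inherits(config$spec, "synthetic_spec"))
    generate_volume(config$spec) else read_volume(config$spec)
  if (!inherits(vol, "phase_volume"))
    stop("input volume must be labelled (three-phase)")
  say("generate: %s voxels, porosity %.3f",
      paste(dim(vol$labels), collapse = "x"), porosity(vol))
  # stage: drainage series
  series <- drainage_series(vol, config$schedule)
  say("drainage: %d potentials", length(series))
  # stage: metrics
  metrics <- metrics_series(series, check_filtered = FALSE)
  # stage: subsampling + solves
  side_mm <- config$subsample_side_mm %||%
    (min(dim(vol$labels)) * vol$voxel_size_um / 1e3)
  origins <- NULL
  cond <- list()
  for (ip in seq_along(series)) {
    pv <- series[[ip]]
    subs <- extract_subsamples(pv, config$n_subsamples, side_mm,
                               seed = config$seed, origins = origins)
    origins <- do.call(rbind, lapply(subs, `[[`, "origin"))
    for (s in subs) {
      dser <- suppressWarnings(dyadic_series(s, config$j_max))
      for (dj in dser) {
        kh <- hydraulic_conductivity(dj, directions = config$directions,
                                     tol = config$solver_tol)
        for (a in config$directions)
          cond[[length(cond) + 1L]] <- data.frame(
            potential_kpa = pv$potential_kpa, sample_id = s$sample_id,
            j = dj$level, direction = c("x", "y", "z")[a],
            volume_mm3 = dj$nominal_volume_mm3,
            side_mm = dj$side_mm,
            K_h_cm_s = unname(kh$K_h_cm_s[a]),
            percolating = kh$percolating)
      }
    }
    say("solve: potential %g kPa done", pv$potential_kpa)
  }
  cond <- do.call(rbind, cond)
  # stage: convergence statistics per potential (largest direction set)
  convergence <- lapply(split(cond, cond$potential_kpa), function(df) {
    if (length(unique(df$sample_id)) < 2) return(NULL)
    convergence_stats(df)
  })
  # stage: WRC + fit
  pots <- vapply(series, `[[`, numeric(1), "potential_kpa")
  wrc <- data.frame(potential_kpa = pots,
                    head_cm = head_from_potential(pots),
                    theta = vapply(series, water_content, numeric(1)))
  k0 <- cond[cond$j == 0, ]
  kmean <- stats::aggregate(K_h_cm_s ~ potential_kpa, k0, mean)
  ktab <- data.frame(head_cm = head_from_potential(kmean$potential_kpa),
                     K_cm_s = kmean$K_h_cm_s)
  vg <- tryCatch(
    fit_vg(wrc, k = ktab[ktab$K_cm_s > 0, , drop = FALSE]),
    error = function(e) NULL)
  report <- list(volumes = series, metrics = metrics, conductivity = cond,
                 convergence = convergence, wrc = wrc, vg = vg,
                 config = config,
                 elapsed_s = as.numeric(difftime(Sys.time(), t0, units = "secs")))
  if (!is.null(config$out_dir)) write_pipeline_outputs(report, config)
  report
}

write_pipeline_outputs <- function(report, config) {
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  write.csv(as.data.frame(report$metrics),
            file.path(config$out_dir, "pore_metrics.csv"), row.names = FALSE)
  write.csv(report$conductivity,
            file.path(config$out_dir, "conductivity.csv"), row.names = FALSE)
  write.csv(report$wrc, file.path(config$out_dir, "wrc.csv"),
            row.names = FALSE)
  if (!is.null(report$vg))
    jsonlite::write_json(
      list(Ksat_cm_s = report$vg$Ksat, theta_s = report$vg$theta_s,
           alpha_cm = report$vg$alpha, n = report$vg$n),
      file.path(config$out_dir, "vg_fit.json"), auto_unbox = TRUE,
      digits = NA)
  cfg <- config
  cfg$schedule <- unclass(cfg$schedule)
  if (inherits(cfg$spec, "synthetic_spec")) cfg$spec <- unclass(cfg$spec)
  yaml::write_yaml(unclass(cfg), file.path(config$out_dir, "config.yaml"))
  invisible(NULL)
}
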