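#' Read a run configuration (YAML or JSON)
#'
#' Loads a configuration file for [run_pipeline()] and validates it. Physical
#' parameters must be positive; the `"merging"` variance mode is checked
#' against its applicability bound `D > 2 sigma_min^2 / T_max` at load time
#' when `D` is given.
#'
#' Recognized fields (defaults in parentheses): `track` (input CSV path) or
#' `simulate` (a list of [simulate_walk()] / [gps_subsample()] arguments:
#' `n_steps, dt, s, type, phi, c, T_R, activity, dropout`), `sigma_min`,
#' `D` or `estimate_D: true`, `T_max`, `tau` (auto), `L_min` (0),
#' `immobile` ("drop"), `global_ud` (false), `variance_mode` ("constant"),
#' `cellsize` (`sigma_min/2`), `isopleth_levels` (50, 95), `habitat`
#' (raster path), `legend` (CSV path), `seed` (1), `out_dir` (NULL: no files
#' written).
#'
#' @param path path to a `.yaml`/`.yml` or `.json` file.
#' @return A validated configuration list.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop(sprintf("config file not found: %s", path))
  cfg <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    yaml::read_yaml(path)
  } else {
    jsonlite::fromJSON(path, simplifyVector = TRUE)
  }
  validate_config(cfg)
}

validate_config <- function(cfg) {
  defaults <- list(L_min = 0, immobile = "drop", global_ud = FALSE,
                   variance_mode = "constant", isopleth_levels = c(50, 95),
                   seed = 1L, estimate_D = FALSE)
  for (nm in names(defaults)) if (is.null(cfg[[nm]])) cfg[[nm]] <- defaults[[nm]]
  if (is.null(cfg$sigma_min) || cfg$sigma_min <= 0)
    stop("config: `sigma_min` must be given and > 0")
  if (is.null(cfg$T_max) || cfg$T_max <= 0)
    stop("config: `T_max` must be given and > 0")
  if (!isTRUE(cfg$estimate_D) && is.null(cfg$D))
    stop("config: give `D` or set `estimate_D: true`")
  if (!is.null(cfg$D) && cfg$D < 0) stop("config: `D` must be >= 0")
  if (!cfg$variance_mode %in% c("constant", "merging"))
    stop("config: `variance_mode` must be \"constant\" or \"merging\"")
  if (cfg$variance_mode == "merging" && !is.null(cfg$D) &&
      cfg$D <= 2 * cfg$sigma_min^2 / cfg$T_max)
    stop("config: variance mode \"merging\" requires D > 2*sigma_min^2/T_max")
  if (!is.null(cfg$tau) && cfg$tau <= 0) stop("config: `tau` must be > 0")
  if (is.null(cfg$track) && is.null(cfg$simulate))
    stop("config: give an input `track` or a `simulate` block")
  cfg
}

#' Run the full BRB/MKDE pipeline
#'
#' Orchestrates simulate (or read) -> build/filter segments -> estimate D ->
#' interpolate -> UD raster -> isopleths -> habitat preferences, and returns
#' a run report. When `config$out_dir` is set, the segments table, UD raster
#' (ESRI ASCII), isopleth areas, preference table and the JSON report are
#' written there. All randomness is governed by `config$seed`, so identical
#' configurations yield identical reports.
#'
#' @param config a configuration list (see [read_run_config()]) or a path to
#'   a YAML/JSON configuration file.
#' @param quiet suppress progress messages.
#' @return The run report, invisibly when `out_dir` is set: a list with the
#'   parameters used, segment/couple/location counts, excluded activity time,
#'   `D_hat`, `beta_Tmax`, `h_max`, UD mass, isopleth areas and (if a habitat
#'   raster was given) the preference table.
#' @export
run_pipeline <- function(config, quiet = FALSE) {
  if (is.character(config)) config <- read_run_config(config)
  config <- validate_config(config)
  say <- function(...) if (!quiet) message(sprintf(...))
  set.seed(config$seed)

  # --- input track -----------------------------------------------------
  if (!is.null(config$track)) {
    track <- read_track(config$track)
    say("read %d fixes from %s", nrow(track), config$track)
  } else {
    sm <- config$simulate
    track <- simulate_walk(
      n_steps = sm$n_steps %||% 5000L, dt = sm$dt %||% 1,
      s = sm$s %||% 10, type = sm$type %||% "brownian",
      phi = sm$phi %||% 0, c = sm$c %||% 0)
    if (!is.null(sm$T_R)) {
      track <- gps_subsample(track, sm$T_R, activity = sm$activity,
                             dropout = sm$dropout %||% 0)
    }
    say("simulated %d fixes (%s walk)", nrow(track), sm$type %||% "brownian")
  }

  # --- segments --------------------------------------------------------
  segments <- build_segments(track)
  segments <- filter_segments(segments, T_max = config$T_max,
                              L_min = config$L_min, immobile = config$immobile)
  if (isTRUE(config$global_ud)) segments <- as_global_segments(segments)
  n_excl <- sum(!segments$included)
  t_removed <- sum(segments$T[!segments$included])
  say("built %d segments; %d excluded (%.1f min of activity time removed)",
      nrow(segments), n_excl, t_removed)
  lkde_mode <- !any(segments$included)
  if (lkde_mode)
    say("all segments excluded: UD degenerates to a fixed-bandwidth (h_min) LKDE")

  # --- diffusion -------------------------------------------------------
  if (isTRUE(config$estimate_D)) {
    est <- estimate_D(diffusion_couples(segments, config$T_max))
    if (is.na(est$D_hat)) stop("D could not be estimated (no usable couples); give `D`")
    D <- est$D_hat
    N_C <- est$N_C
    say("estimated D = %.4g m^2/min from %d couples", D, N_C)
  } else {
    D <- config$D
    N_C <- NA_integer_
  }
  params <- brb_params(config$sigma_min, D, config$T_max,
                       mode = config$variance_mode)

  # --- UD --------------------------------------------------------------
  plan <- plan_interpolation(segments, params, tau = config$tau)
  ud <- compute_ud(plan, cellsize = config$cellsize)
  iso <- isopleths(ud, config$isopleth_levels)
  mass <- sum(ud$values) * ud$grid$cellsize^2
  say("UD: %d locations, %d x %d cells, mass %.6f",
      attr(plan, "N_L"), ud$grid$ncol, ud$grid$nrow, mass)

  # --- habitat ---------------------------------------------------------
  prefs <- NULL
  if (!is.null(config$habitat)) {
    hab <- read_habitat(config$habitat, legend = config$legend)
    hab <- align_habitat(hab, ud$grid)
    mask <- iso$masks[[as.character(max(config$isopleth_levels))]]
    avail <- availability(hab, mask)
    use <- ud_weighted_use(ud, hab, mask)
    D_h <- estimate_D_by_habitat(segments, hab, config$T_max)
    drift <- estimate_drift_speeds(segments, hab, D = D, D_by_habitat = D_h)
    prefs <- preference_table(avail, use, D_by_habitat = D_h, drift = drift)
  }

  report <- list(
    parameters = list(sigma_min = params$sigma_min, D = D,
                      T_max = params$T_max, variance_mode = params$mode,
                      tau = attr(plan, "tau"), L_min = config$L_min,
                      cellsize = ud$grid$cellsize, seed = config$seed,
                      global_ud = isTRUE(config$global_ud)),
    derived = list(beta_Tmax = params$beta_Tmax, h_min = params$h_min,
                   h_max = params$h_max),
    counts = list(N_fixes = nrow(track), N_S = nrow(segments),
                  N_excluded = n_excl, activity_time_removed_min = t_removed,
                  N_C = N_C, N_L = attr(plan, "N_L")),
    lkde_degeneration = lkde_mode,
    ud = list(mass = mass, ncol = ud$grid$ncol, nrow = ud$grid$nrow),
    isopleth_areas_m2 = as.list(iso$areas),
    preferences = if (!is.null(prefs)) as.data.frame(prefs) else NULL)

  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
    write_segments(segments, file.path(config$out_dir, "segments.csv"))
    export_ud(ud, file.path(config$out_dir, "ud.asc"))
    utils::write.csv(data.frame(level = iso$levels, area_m2 = iso$areas),
                     file.path(config$out_dir, "isopleths.csv"),
                     row.names = FALSE)
    if (!is.null(prefs))
      utils::write.csv(as.data.frame(prefs),
                       file.path(config$out_dir, "preferences.csv"),
                       row.names = FALSE)
    jsonlite::write_json(report, file.path(config$out_dir, "report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE,
                         null = "null")
    say("outputs written to %s", config$out_dir)
    return(invisible(report))
  }
  report
}

`%||%` <- function(a, b) if (is.null(a)) b else a
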