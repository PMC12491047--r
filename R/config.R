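# Run configuration loading/validation and the command dispatcher behind the
# command-line entry point.

config_defaults <- function() {
  list(
    seed = 1L,
    scale = 1.0,
    output_dir = ".",
    scenario = list(weather_csv = NULL, days = 180L, start_doy = 115L,
                    wet_prob = 0.08, rain_mean = 4,
                    latitude = 45.77, elevation = 270),
    crop = list(path = NULL),
    soil = list(theta_fc = 0.3607, theta_wp = 0.17, theta_sat = 0.45,
                depth = 2.05, tau = 1),
    treatment = list(plan = "CK", quota = NULL, schedule_csv = NULL),
    efast = list(ns = 3500L, m = 4L, range_frac = 0.25,
                 parameters = c("wp", "cgc", "cdc", "psen", "kcb", "mcc"),
                 output = "yield"),
    dpinn = list(n_runs = 50L, epochs = 2000L, nf = 400L, stride = 10L),
    dynrec = list(patience = 200L, eps_rel = 1e-3, gamma = 2, sigma_d = 0.05),
    bilevel = list(pop = 24L, generations = 60L, mode = "simulator",
                   objective = "yield", max_event_mm = 60)
  )
}

#' Load and validate a run configuration
#'
#' Reads a YAML (or JSON) configuration, applies documented defaults for every
#' unspecified field, rejects unknown keys, and aggregates invariant
#' violations into a single validation report.
#'
#' @param path Path to a YAML/JSON configuration file, or NULL for defaults.
#' @param overrides Named list merged over the file contents.
#' @return An object of class \code{run_config}.
#' @export
load_config <- function(path = NULL, overrides = list()) {
  user <- if (is.null(path)) list() else {
    stop_if(!file.exists(path), "config file not found: ", path)
    if (grepl("[.]json$", path)) jsonlite::read_json(path, simplifyVector = TRUE)
    else yaml::read_yaml(path)
  }
  user <- modifyList(user, overrides)
  defaults <- config_defaults()

  unknown <- setdiff(names(user), names(defaults))
  stop_if(length(unknown) > 0,
          "unknown configuration keys: ", paste(unknown, collapse = ", "))
  for (blk in names(user)) {
    if (is.list(defaults[[blk]]) && is.list(user[[blk]])) {
      bad <- setdiff(names(user[[blk]]), names(defaults[[blk]]))
      stop_if(length(bad) > 0, "unknown keys in block '", blk, "': ",
              paste(bad, collapse = ", "))
    }
  }
  cfg <- modifyList(defaults, user)

  problems <- character(0)
  note <- function(msg) problems <<- c(problems, msg)
  if (!is.numeric(cfg$seed) || cfg$seed != round(cfg$seed))
    note("seed must be an integer")
  if (!(cfg$scale > 0 && cfg$scale <= 1))
    note("scale must be in (0, 1]")
  if (!is.null(cfg$scenario$weather_csv) && !file.exists(cfg$scenario$weather_csv))
    note(paste0("weather_csv does not exist: ", cfg$scenario$weather_csv))
  if (!is.null(cfg$crop$path) && !file.exists(cfg$crop$path))
    note(paste0("crop path does not exist: ", cfg$crop$path))
  soil_ok <- with(cfg$soil, theta_wp < theta_fc && theta_fc < theta_sat)
  if (!soil_ok)
    note("soil must satisfy theta_wp < theta_fc < theta_sat")
  crop <- tryCatch(
    if (is.null(cfg$crop$path)) default_crop() else default_crop(cfg$crop$path),
    error = function(e) { note(conditionMessage(e)); NULL })
  if (length(problems) > 0)
    stop("configuration validation failed:\n  - ",
         paste(problems, collapse = "\n  - "), call. = FALSE)
  cfg$seed <- as.integer(cfg$seed)
  # drop NULL-valued keys recursively so a dump/reload round-trip is exact
  drop_nulls <- function(x) {
    if (!is.list(x)) return(x)
    x <- x[!vapply(x, is.null, logical(1))]
    lapply(x, drop_nulls)
  }
  structure(drop_nulls(cfg), class = "run_config")
}

config_objects <- function(cfg) {
  crop <- if (is.null(cfg$crop$path)) default_crop() else
    default_crop(cfg$crop$path)
  soil <- soil_profile(cfg$soil$theta_fc, cfg$soil$theta_wp,
                       cfg$soil$theta_sat, cfg$soil$depth, cfg$soil$tau)
  site <- site_info(cfg$scenario$latitude, cfg$scenario$elevation)
  weather <- if (!is.null(cfg$scenario$weather_csv))
    read_weather_csv(cfg$scenario$weather_csv)
  else generate_season(weather_gen_config(
    days = cfg$scenario$days, start_doy = cfg$scenario$start_doy,
    wet_prob = cfg$scenario$wet_prob, rain_mean = cfg$scenario$rain_mean,
    seed = module_seed(cfg$seed, "scenario")), site)
  list(crop = crop, soil = soil, site = site, weather = weather)
}

write_manifest <- function(cfg, command, dir, extra = list()) {
  cfg_file <- file.path(dir, paste0(command, "_config.yaml"))
  yaml::write_yaml(unclass(cfg), cfg_file)
  manifest <- c(list(command = command, seed = cfg$seed, scale = cfg$scale,
                     package_version = as.character(utils::packageVersion("aquadeficit")),
                     r_version = as.character(getRversion()),
                     config_md5 = unname(tools::md5sum(cfg_file))), extra)
  jsonlite::write_json(manifest, file.path(dir, paste0(command, "_manifest.json")),
                       auto_unbox = TRUE, digits = NA)
  invisible(manifest)
}

#' Dispatch a command
#'
#' Runs one of the pipeline commands against a validated configuration and
#' writes its artifacts plus a reproducibility manifest (seed, versions,
#' config hash) into the output directory. Idempotent for fixed seeds.
#'
#' @param command One of \code{"simulate"}, \code{"evaluate"},
#'   \code{"sensitivity"}, \code{"train"}, \code{"optimize"}.
#' @param config A \code{\link{load_config}} object.
#' @param evaluate_csv For \code{"evaluate"}: CSV with \code{observed} and
#'   \code{simulated} columns (defaults to the shipped yield table).
#' @return Invisibly, the command's primary result object.
#' @export
dispatch <- function(command, config = load_config(), evaluate_csv = NULL) {
  cmds <- c("simulate", "evaluate", "sensitivity", "train", "optimize")
  stop_if(!command %in% cmds,
          "unknown command '", command, "'; expected one of: ",
          paste(cmds, collapse = ", "))
  dir <- config$output_dir
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)

  if (command == "evaluate") {
    d <- if (is.null(evaluate_csv)) {
      tab <- yield_validation_table()
      data.frame(observed = tab$observed_kg_hm2, simulated = tab$simulated_kg_hm2)
    } else read.csv(evaluate_csv)
    fit <- evaluate_fit(d$observed, d$simulated)
    out <- c(unclass(fit),
             list(re_pct = round(relative_error(d$observed, d$simulated), 2)))
    jsonlite::write_json(out, file.path(dir, "evaluate_report.json"),
                         auto_unbox = TRUE, digits = NA)
    write_manifest(config, command, dir)
    return(invisible(fit))
  }

  obj <- config_objects(config)
  if (command == "simulate") {
    sched <- if (!is.null(config$treatment$schedule_csv)) {
      read_schedule_csv(config$treatment$schedule_csv)
    } else {
      plan <- treatment_plans()[[config$treatment$plan]]
      stop_if(is.null(plan), "unknown treatment plan: ", config$treatment$plan)
      etc <- unstressed_stage_etc(obj$crop, obj$soil, obj$weather)
      s <- build_treatment_schedule(plan, setNames(etc, STAGE_NAMES),
                                    stage_windows(obj$crop, obj$weather))
      if (!is.null(config$treatment$quota)) s <- scale_schedule(s, config$treatment$quota)
      s
    }
    sim <- run_season(obj$crop, obj$soil, obj$weather, sched)
    export_sim_result(sim, file.path(dir, "simulate_daily.csv"),
                      file.path(dir, "simulate_summary.json"))
    write_schedule_csv(sched, file.path(dir, "simulate_schedule.csv"))
    write_manifest(config, command, dir,
                   list(yield = sim$yield, et = sim$et, wue = sim$wue))
    return(invisible(sim))
  }

  if (command == "sensitivity") {
    ns <- max(65L * length(config$efast$parameters),
              as.integer(config$efast$ns * config$scale))
    specs <- crop_param_ranges(obj$crop, config$efast$parameters,
                               config$efast$range_frac)
    sched <- build_treatment_schedule(
      stage_plan(), setNames(unstressed_stage_etc(obj$crop, obj$soil, obj$weather),
                             STAGE_NAMES),
      stage_windows(obj$crop, obj$weather))
    model <- function(x) {
      p <- do.call(crop_params, c(as.list(setNames(x, specs$name)),
                                  list(base = obj$crop)))
      sim <- run_season(p, obj$soil, obj$weather, sched, .with_reference = FALSE)
      switch(config$efast$output, yield = sim$yield, biomass = sim$biomass,
             cc = max(sim$daily$cc), swc = mean(sim$daily$theta))
    }
    res <- efast_run(model, specs, ns = ns, m = config$efast$m,
                     seed = module_seed(config$seed, "efast"))
    write.csv(res, file.path(dir, "sensitivity_indices.csv"), row.names = FALSE)
    jsonlite::write_json(list(selected = screen_parameters(res)),
                         file.path(dir, "sensitivity_selected.json"),
                         auto_unbox = TRUE)
    write_manifest(config, command, dir, list(ns = ns))
    return(invisible(res))
  }

  if (command == "train") {
    train <- build_training_set(obj$crop, obj$soil, obj$weather,
                                n_runs = config$dpinn$n_runs,
                                stride = config$dpinn$stride,
                                seed = config$seed)
    sur <- surrogate_init(seed = config$seed)
    sur <- train_surrogate(sur, train,
                           epochs = as.integer(config$dpinn$epochs * config$scale),
                           nf = config$dpinn$nf, seed = config$seed)
    ckpt <- list(theta_net = mlp_flatten(sur$theta_net),
                 crop_net = mlp_flatten(sur$crop_net),
                 hidden = sur$theta_net$hidden, layers = sur$theta_net$layers,
                 scaling = sur$scaling, hi = sur$hi,
                 loss = unclass(sur$loss), initial_loss = unclass(sur$initial_loss),
                 adapt_log = sur$adapt_log)
    jsonlite::write_json(ckpt, file.path(dir, "train_checkpoint.json"),
                         auto_unbox = TRUE, digits = NA)
    write_manifest(config, command, dir,
                   list(final_loss = sur$loss$total,
                        initial_loss = sur$initial_loss$total))
    return(invisible(sur))
  }

  # optimize
  quota <- config$treatment$quota %||% 472
  rep <- optimize_irrigation(
    quota, obj$crop, obj$soil, obj$weather,
    mode = config$bilevel$mode,
    ga = ga_config(pop = config$bilevel$pop,
                   generations = as.integer(config$bilevel$generations *
                                              max(config$scale, 1 / config$bilevel$generations))),
    objective = config$bilevel$objective,
    max_event_mm = config$bilevel$max_event_mm, seed = config$seed)
  export_optimization_report(rep, file.path(dir, "optimize_report.json"),
                             file.path(dir, "optimize_table.csv"))
  write_manifest(config, command, dir,
                 list(quota = quota, yield_gain_pct = rep$yield_gain_pct))
  invisible(rep)
}
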