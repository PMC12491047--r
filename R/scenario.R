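# Scenario module: synthetic arid-site weather, FAO-56 reference
# evapotranspiration, and stage-wise deficit irrigation schedules.

#' Site description
#'
#' Location metadata needed by the FAO-56 radiation terms. Defaults describe
#' the arid experimental site (45°46'N, 270 m elevation, 2-m anemometer).
#'
#' @param latitude Latitude in decimal degrees, in \[-90, 90\].
#' @param elevation Elevation above sea level (m).
#' @param anemometer_height Wind measurement height (m); fixed at 2 m.
#' @return An object of class \code{site_info}.
#' @export
site_info <- function(latitude = 45.77, elevation = 270, anemometer_height = 2) {
  stop_if(!is.numeric(latitude) || abs(latitude) > 90,
          "latitude must be in [-90, 90] degrees")
  stop_if(anemometer_height != 2, "wind speed must be supplied at 2 m")
  structure(list(latitude = latitude, elevation = elevation,
                 anemometer_height = 2),
            class = "site_info")
}

#' Weather generator configuration
#'
#' A sinusoidal temperature climate with Gaussian daily noise and a compound
#' Bernoulli-exponential rainfall process, parameterized for a continental
#' arid site: hot mid-summer (annual-fit mean 12 degC, amplitude 17 degC,
#' peak at DOY 197 gives ~29 degC July means) and a sparse rain regime whose
#' growing-season total (~58 mm expected over 180 d) is the warm-season share
#' of a ~100 mm annual normal.
#'
#' @param days Season length in days (>= 1).
#' @param start_doy Day of year of sowing (default 115, late April).
#' @param t_mean,t_amplitude,t_peak_doy Annual temperature sinusoid: mean,
#'   amplitude (degC) and day-of-year of the warm peak.
#' @param t_noise_sd Daily mean-temperature noise s.d. (degC).
#' @param diurnal_range Mean tmax - tmin spread (degC).
#' @param wet_prob Probability that a day is wet, in \[0, 1\].
#' @param rain_mean Mean depth of a wet-day rainfall event (mm).
#' @param sunshine_mean,sunshine_sd Daily bright-sunshine hours (truncated to
#'   \[0, daylength\]).
#' @param wind_mean Mean 2-m wind speed (m s^-1).
#' @param rh_mean,rh_sd Daily mean relative humidity (%, truncated to
#'   \[5, 95\]); wet days are shifted +25 points.
#' @param seed Integer seed; generation is bit-reproducible for a fixed seed.
#' @return An object of class \code{weather_gen_config}.
#' @export
weather_gen_config <- function(days = 180, start_doy = 115,
                               t_mean = 12, t_amplitude = 17, t_peak_doy = 197,
                               t_noise_sd = 1.5, diurnal_range = 13,
                               wet_prob = 0.08, rain_mean = 4,
                               sunshine_mean = 10, sunshine_sd = 1.5,
                               wind_mean = 3.7, rh_mean = 45, rh_sd = 8,
                               seed = 1L) {
  stop_if(days < 1, "season length must be >= 1 day")
  stop_if(wet_prob < 0 || wet_prob > 1, "wet_prob must be in [0, 1]")
  stop_if(rain_mean < 0, "rain_mean must be non-negative")
  structure(list(days = as.integer(days), start_doy = as.integer(start_doy),
                 t_mean = t_mean, t_amplitude = t_amplitude,
                 t_peak_doy = t_peak_doy, t_noise_sd = t_noise_sd,
                 diurnal_range = diurnal_range, wet_prob = wet_prob,
                 rain_mean = rain_mean, sunshine_mean = sunshine_mean,
                 sunshine_sd = sunshine_sd, wind_mean = wind_mean,
                 rh_mean = rh_mean, rh_sd = rh_sd, seed = as.integer(seed)),
            class = "weather_gen_config")
}

#' Generate one synthetic weather season
#'
#' Draws a daily series from the configured climate and appends FAO-56
#' reference evapotranspiration. Deterministic for a fixed seed.
#'
#' @param config A \code{\link{weather_gen_config}}.
#' @param site A \code{\link{site_info}}.
#' @return A \code{data.frame} of class \code{daily_weather} with columns
#'   \code{day, doy, tmax, tmin, tavg, precip, sunshine, wind2m, rh, et0}.
#' @export
generate_season <- function(config = weather_gen_config(), site = site_info()) {
  stopifnot(inherits(config, "weather_gen_config"), inherits(site, "site_info"))
  n <- config$days
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(config$seed)

  doy <- ((config$start_doy - 1L + seq_len(n) - 1L) %% 365L) + 1L
  tclim <- config$t_mean +
    config$t_amplitude * cos(2 * pi * (doy - config$t_peak_doy) / 365)
  tavg <- tclim + rnorm(n, 0, config$t_noise_sd)
  half <- pmax(0, config$diurnal_range / 2 + rnorm(n, 0, 1))
  tmax <- tavg + half
  tmin <- tavg - half

  wet <- rbinom(n, 1L, config$wet_prob) == 1L
  precip <- numeric(n)
  if (config$rain_mean > 0 && any(wet))
    precip[wet] <- rexp(sum(wet), rate = 1 / config$rain_mean)

  dl <- daylength_hours(doy, site$latitude)
  sunshine <- pmin(dl, pmax(0, rnorm(n, config$sunshine_mean, config$sunshine_sd)))
  sunshine[wet] <- sunshine[wet] * 0.35   # overcast on rain days
  wind2m <- pmax(0.1, rnorm(n, config$wind_mean, 0.8))
  rh <- pmin(95, pmax(5, rnorm(n, config$rh_mean, config$rh_sd) + 25 * wet))

  wx <- data.frame(day = seq_len(n), doy = doy,
                   tmax = tmax, tmin = tmin, tavg = tavg,
                   precip = precip, sunshine = sunshine,
                   wind2m = wind2m, rh = rh)
  wx$et0 <- et0_penman_monteith(wx$tmax, wx$tmin, wx$tavg, wx$rh, wx$wind2m,
                                sunshine = wx$sunshine, doy = wx$doy,
                                latitude = site$latitude,
                                elevation = site$elevation)
  class(wx) <- c("daily_weather", "data.frame")
  validate_weather(wx)
  wx
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
}
.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}

validate_weather <- function(wx) {
  need <- c("tmax", "tmin", "tavg", "precip", "wind2m", "rh")
  stop_if(!all(need %in% names(wx)), "weather is missing required columns")
  stop_if(any(wx$tmin > wx$tavg + 1e-9) || any(wx$tavg > wx$tmax + 1e-9),
          "weather violates tmin <= tavg <= tmax")
  stop_if(any(wx$precip < 0), "negative precipitation")
  stop_if(any(wx$rh < 0 | wx$rh > 100), "relative humidity outside [0, 100]")
  stop_if(any(wx$wind2m < 0), "negative wind speed")
  invisible(wx)
}

# --- FAO-56 daily Penman-Monteith -------------------------------------------

sat_vp <- function(t) 0.6108 * exp(17.27 * t / (t + 237.3))

daylength_hours <- function(doy, latitude) {
  phi <- latitude * pi / 180
  delta <- 0.409 * sin(2 * pi / 365 * doy - 1.39)
  x <- pmin(1, pmax(-1, -tan(phi) * tan(delta)))
  24 / pi * acos(x)
}

extraterrestrial_radiation <- function(doy, latitude) {
  phi <- latitude * pi / 180
  dr <- 1 + 0.033 * cos(2 * pi / 365 * doy)
  delta <- 0.409 * sin(2 * pi / 365 * doy - 1.39)
  ws <- acos(pmin(1, pmax(-1, -tan(phi) * tan(delta))))
  24 * 60 / pi * 0.0820 * dr *
    (ws * sin(phi) * sin(delta) + cos(phi) * cos(delta) * sin(ws))
}

#' FAO-56 daily reference evapotranspiration (Penman-Monteith)
#'
#' The standard daily computation for a 0.12-m grass reference: psychrometric
#' constant from elevation, vapour pressure from the Tmax/Tmin means and mean
#' relative humidity, net radiation from sunshine duration through the
#' Angstrom relation (a = 0.25, b = 0.50) or from measured solar radiation,
#' and soil heat flux taken as zero at the daily step. Vectorized over days.
#'
#' @param tmax,tmin,tavg Daily air temperatures (degC), \code{tmin <= tmax}.
#' @param rh Daily mean relative humidity (%).
#' @param wind2m Wind speed at 2 m (m s^-1).
#' @param sunshine Bright sunshine duration (h); ignored when
#'   \code{solar_rad} is given.
#' @param solar_rad Measured incoming solar radiation (MJ m^-2 d^-1), optional.
#' @param doy Day of year (1-366).
#' @param latitude,elevation Site latitude (deg) and elevation (m).
#' @return Reference evapotranspiration ET0 (mm d^-1).
#' @export
et0_penman_monteith <- function(tmax, tmin, tavg = (tmax + tmin) / 2, rh,
                                wind2m, sunshine = NULL, solar_rad = NULL,
                                doy, latitude = 45.77, elevation = 270) {
  stop_if(any(rh < 0 | rh > 100), "relative humidity outside [0, 100]")
  stop_if(any(tmin > tmax), "tmin exceeds tmax")
  stop_if(is.null(sunshine) && is.null(solar_rad),
          "either sunshine hours or solar radiation is required")

  p_kpa <- 101.3 * ((293 - 0.0065 * elevation) / 293)^5.26
  gamma <- 0.000665 * p_kpa
  es <- (sat_vp(tmax) + sat_vp(tmin)) / 2
  ea <- rh / 100 * es
  delta <- 4098 * sat_vp(tavg) / (tavg + 237.3)^2

  ra <- extraterrestrial_radiation(doy, latitude)
  if (is.null(solar_rad)) {
    nmax <- daylength_hours(doy, latitude)
    rs <- (0.25 + 0.50 * pmin(sunshine, nmax) / nmax) * ra
  } else rs <- solar_rad
  rso <- (0.75 + 2e-5 * elevation) * ra
  rns <- 0.77 * rs
  rel <- ifelse(rso > 0, pmin(1, rs / rso), 0)
  rnl <- 4.903e-9 * ((tmax + 273.16)^4 + (tmin + 273.16)^4) / 2 *
    (0.34 - 0.14 * sqrt(ea)) * (1.35 * rel - 0.35)
  rn <- rns - rnl

  (0.408 * delta * rn + gamma * 900 / (tavg + 273) * wind2m * (es - ea)) /
    (delta + gamma * (1 + 0.34 * wind2m))
}

# --- Growth-stage plans and irrigation schedules ----------------------------

STAGE_NAMES <- c("initial", "rapid", "mid", "late")
STAGE_EVENTS <- c(initial = 2L, rapid = 4L, mid = 3L, late = 3L)

#' Stage-wise deficit irrigation plan
#'
#' Four growth stages (initial, rapid, mid, late) with fixed event counts
#' 2/4/3/3 (12 drip events per season) and an ETc fraction per stage.
#' Non-regulated ("NC") stages are full supply, i.e. fraction 1.
#'
#' @param fractions Named numeric vector of per-stage ETc fractions; each must
#'   be one of 0.6, 0.8 or 1.0 (or 0 for an all-zero plan).
#' @return An object of class \code{stage_plan}.
#' @export
stage_plan <- function(fractions = c(initial = 1, rapid = 1, mid = 1, late = 1)) {
  stop_if(!all(STAGE_NAMES %in% names(fractions)),
          "fractions must name all four stages")
  fr <- fractions[STAGE_NAMES]
  ok <- vapply(fr, function(f) isTRUE(all.equal(f, 0)) ||
                 any(abs(f - c(0.6, 0.8, 1.0)) < 1e-9), logical(1))
  stop_if(!all(ok), "stage fractions must be 0.6, 0.8, 1.0 (NC) or 0")
  structure(list(fractions = fr, events = STAGE_EVENTS), class = "stage_plan")
}

#' The nine deficit irrigation treatments
#'
#' CK plus T1-T8: full supply in the non-regulated initial and late stages and
#' 60/80/100% of crop evapotranspiration in the rapid and mid stages.
#'
#' @return Named list of \code{\link{stage_plan}} objects.
#' @export
treatment_plans <- function() {
  rapid <- c(CK = 1.0, T1 = 0.8, T2 = 0.6, T3 = 1.0, T4 = 1.0,
             T5 = 0.8, T6 = 0.8, T7 = 0.6, T8 = 0.6)
  mid   <- c(CK = 1.0, T1 = 1.0, T2 = 1.0, T3 = 0.8, T4 = 0.6,
             T5 = 0.8, T6 = 0.6, T7 = 0.8, T8 = 0.6)
  setNames(lapply(names(rapid), function(k)
    stage_plan(c(initial = 1, rapid = rapid[[k]], mid = mid[[k]], late = 1))),
    names(rapid))
}

#' Irrigation schedule constructor
#'
#' Twelve drip events grouped 2/4/3/3 by growth stage; the quota is the sum of
#' the event depths.
#'
#' @param day Integer vector of 12 event days (chronological).
#' @param stage Character vector of stage labels.
#' @param depth_mm Non-negative event depths (mm).
#' @return An object of class \code{irrigation_schedule} (a data.frame with a
#'   \code{quota} attribute).
#' @export
irrigation_schedule <- function(day, stage, depth_mm) {
  stop_if(length(day) != 12 || length(stage) != 12 || length(depth_mm) != 12,
          "an irrigation schedule has exactly 12 events")
  stop_if(any(depth_mm < 0), "event depths must be non-negative")
  stop_if(is.unsorted(day), "events must be in chronological order")
  cnt <- table(factor(stage, levels = STAGE_NAMES))
  stop_if(!all(cnt == STAGE_EVENTS), "events must be grouped 2/4/3/3 by stage")
  out <- data.frame(event = 1:12, day = as.integer(day),
                    stage = as.character(stage), depth_mm = depth_mm)
  attr(out, "quota") <- sum(depth_mm)
  class(out) <- c("irrigation_schedule", "data.frame")
  out
}

#' Build a treatment schedule from stage ETc totals
#'
#' Each stage receives \code{fraction x stage ETc} millimetres, split equally
#' across that stage's events; events sit evenly inside the stage's calendar
#' window.
#'
#' @param plan A \code{\link{stage_plan}}.
#' @param stage_etc Named non-negative vector: crop evapotranspiration total
#'   per stage (mm) under full supply.
#' @param stage_days Named list of integer day vectors, the calendar window of
#'   each stage (e.g. from \code{\link{stage_windows}}).
#' @return An \code{\link{irrigation_schedule}}.
#' @export
build_treatment_schedule <- function(plan, stage_etc, stage_days) {
  stopifnot(inherits(plan, "stage_plan"))
  stop_if(!all(STAGE_NAMES %in% names(stage_etc)), "stage_etc must name all stages")
  stop_if(any(stage_etc < 0), "stage ETc totals must be non-negative")
  days <- integer(0); stages <- character(0); depths <- numeric(0)
  for (st in STAGE_NAMES) {
    k <- STAGE_EVENTS[[st]]
    win <- stage_days[[st]]
    stop_if(length(win) < 1, "empty stage window for stage ", st)
    # evenly spaced event days inside the window
    pos <- win[pmin(length(win), pmax(1, round((seq_len(k) - 0.5) / k * length(win))))]
    days <- c(days, pos)
    stages <- c(stages, rep(st, k))
    depths <- c(depths, rep(plan$fractions[[st]] * stage_etc[[st]] / k, k))
  }
  irrigation_schedule(days, stages, depths)
}

#' Rescale a schedule to a total quota
#'
#' Multiplies every event depth by a common factor so the depths sum to
#' \code{quota} mm (used to express the ETc-proportional baseline at a given
#' quota).
#'
#' @param schedule An \code{\link{irrigation_schedule}}.
#' @param quota Target seasonal total (mm).
#' @return A rescaled \code{\link{irrigation_schedule}}.
#' @export
scale_schedule <- function(schedule, quota) {
  stopifnot(inherits(schedule, "irrigation_schedule"))
  tot <- sum(schedule$depth_mm)
  stop_if(tot <= 0 && quota > 0, "cannot rescale an all-zero schedule")
  f <- if (tot > 0) quota / tot else 0
  irrigation_schedule(schedule$day, schedule$stage, schedule$depth_mm * f)
}

#' Read/write helpers for the weather and schedule CSV interfaces
#'
#' @param path File path.
#' @param wx,schedule Objects to write.
#' @return The read object, or (invisibly) the written path.
#' @name scenario_io
NULL

#' @rdname scenario_io
#' @export
read_weather_csv <- function(path) {
  wx <- read.csv(path)
  class(wx) <- c("daily_weather", "data.frame")
  validate_weather(wx)
  wx
}

#' @rdname scenario_io
#' @export
write_weather_csv <- function(wx, path) {
  write.csv(as.data.frame(wx), path, row.names = FALSE)
  invisible(path)
}

#' @rdname scenario_io
#' @export
read_schedule_csv <- function(path) {
  d <- read.csv(path)
  irrigation_schedule(d$day, d$stage, d$depth_mm)
}

#' @rdname scenario_io
#' @export
write_schedule_csv <- function(schedule, path) {
  write.csv(as.data.frame(schedule)[, c("event", "day", "stage", "depth_mm")],
            path, row.names = FALSE)
  invisible(path)
}

#' @export
print.irrigation_schedule <- function(x, ...) {
  cat("Irrigation schedule: 12 events, quota",
      sprintf("%.1f mm\n", attr(x, "quota")))
  print.data.frame(x, ...)
  invisible(x)
}
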