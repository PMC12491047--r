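# Water-driven daily maize simulator: GDD phenology, canopy cover with
# depletion-threshold stress physiology, a soil-water bucket, a
# transpiration/evaporation partition, normalized-water-productivity biomass
# and harvest-index yield.

#' Crop parameter set
#'
#' The calibrated maize profile. Values are the shipped defaults for the
#' "Xinnong 008" variety (see \code{\link{default_crop}}); units follow the
#' crop parameter file. Percent-type parameters are fractions here.
#'
#' @param ... Named parameter overrides (flat names, e.g. \code{wp = 40}).
#' @param base A crop parameter list to start from.
#' @return An object of class \code{crop_params} (a named list).
#' @export
crop_params <- function(..., base = default_crop()) {
  p <- modifyList(unclass(base), list(...))
  validate_crop(p)
  structure(p, class = "crop_params")
}

#' Load the shipped calibrated maize profile
#'
#' Reads the crop parameter YAML shipped with the package (or a user file of
#' the same layout) and flattens it to a \code{crop_params} object.
#'
#' @param path Path to a crop parameter YAML; default is the shipped profile.
#' @return A \code{crop_params} object.
#' @export
default_crop <- function(path = system.file("extdata", "xinnong008.yaml",
                                            package = "aquadeficit")) {
  y <- yaml::read_yaml(path)
  p <- c(list(name = y$name %||% "crop"),
         y$phenology, y$canopy, y$roots, y$transpiration,
         y$productivity, y$stress, y$temperature, y$salinity)
  validate_crop(p)
  structure(p, class = "crop_params")
}

validate_crop <- function(p) {
  need <- c("mat", "eme", "sen", "flo", "flolen", "hilen", "stbio", "root",
            "cgc", "cdc", "cge", "mcc", "ccs", "den",
            "rinx", "rtx", "rtexup", "rtexhw", "rtshp",
            "kcb", "kcdcl", "evladc", "wp", "hi", "hinc", "hinsveg",
            "hipsflo", "exc", "puexp", "plexp", "pexshp", "psto", "pstoshp",
            "psen", "psenshp", "ppol", "anaer", "tbase", "utemp",
            "polmn", "polmx")
  miss <- setdiff(need, names(p))
  stop_if(length(miss) > 0, "missing crop parameters: ",
          paste(miss, collapse = ", "))
  stop_if(!(p$puexp > 0 && p$puexp < p$plexp && p$plexp <= 1),
          "need 0 < puexp < plexp <= 1 (puexp=", p$puexp, ", plexp=", p$plexp, ")")
  stop_if(!(p$psto > 0 && p$psto <= 1 && p$psen > 0 && p$psen <= 1 &&
              p$ppol > 0 && p$ppol <= 1), "stress thresholds must be in (0, 1]")
  stop_if(!(p$mcc > 0 && p$mcc <= 1), "mcc must be in (0, 1]")
  stop_if(!(p$eme < p$flo && p$flo < p$sen && p$sen < p$mat),
          "phenology must satisfy eme < flo < sen < mat")
  stop_if(p$wp <= 0, "wp must be positive")
  stop_if(!(p$hi > 0 && p$hi < 1), "hi must be in (0, 1)")
  stop_if(p$tbase >= p$utemp, "tbase must be below utemp")
  invisible(p)
}

#' Soil profile
#'
#' A single-bucket root-zone soil. The water balance is kept over a fixed
#' profile depth (default: the crop's maximum root depth) so daily closure is
#' exact; root growth enters through the depletion fraction and extraction cap
#' computed over the currently rooted depth.
#'
#' @param theta_fc Volumetric field capacity (m3 m-3); site value 0.3607.
#' @param theta_wp Volumetric wilting point (m3 m-3).
#' @param theta_sat Volumetric saturation (m3 m-3).
#' @param depth Profile (bucket) depth (m); default the 1.0-m monitored
#'   root-zone profile. Roots deeper than the bucket draw from it unchanged.
#' @param tau Drainage coefficient in (0, 1]: fraction of the above-field-
#'   capacity excess released per day (1 = instantaneous).
#' @param theta_init Initial water content (m3 m-3); default 30% of total
#'   available water depleted at sowing (arid-site pre-season condition).
#' @param wetted_frac Fraction of the soil surface wetted by a drip event
#'   (0-1); rain wets the whole surface. Limits the evaporation supply.
#' @param bulk_density Dry bulk density (g cm-3), metadata only.
#' @return An object of class \code{soil_profile}.
#' @export
soil_profile <- function(theta_fc = 0.3607, theta_wp = 0.17, theta_sat = 0.45,
                         depth = 1.0, tau = 1,
                         theta_init = theta_fc - 0.3 * (theta_fc - theta_wp),
                         wetted_frac = 0.3, bulk_density = 1.47) {
  stop_if(!(theta_wp < theta_fc && theta_fc < theta_sat),
          "need theta_wp < theta_fc < theta_sat")
  stop_if(depth <= 0, "profile depth must be positive")
  stop_if(tau <= 0 || tau > 1, "tau must be in (0, 1]")
  stop_if(theta_init < theta_wp || theta_init > theta_sat,
          "theta_init outside [theta_wp, theta_sat]")
  stop_if(wetted_frac <= 0 || wetted_frac > 1, "wetted_frac must be in (0, 1]")
  structure(list(theta_fc = theta_fc, theta_wp = theta_wp,
                 theta_sat = theta_sat, depth = depth, tau = tau,
                 theta_init = theta_init, wetted_frac = wetted_frac,
                 bulk_density = bulk_density),
            class = "soil_profile")
}

# --- Elementary process operations ------------------------------------------

#' Growing degree days for one day
#'
#' \code{max(0, min(tavg, tupper) - tbase)}: thermal time accrues above the
#' base temperature and is capped at the upper development threshold.
#'
#' @param tavg Daily mean temperature (degC).
#' @param tbase Base temperature (degC).
#' @param tupper Upper temperature threshold (degC).
#' @return GDD (degC d), vectorized over \code{tavg}.
#' @export
growing_degree_days <- function(tavg, tbase = 8, tupper = 30) {
  stop_if(tbase >= tupper, "tbase must be below tupper")
  pmax(0, pmin(tavg, tupper) - tbase)
}

#' Leaf area index from leaf measurements
#'
#' LAI = (1/m) * sum(L_i * D_i) * K * density / 10000, with leaf length and
#' width in cm, the leaf-area correction coefficient K (default 0.75), and
#' plant density in plants per square metre.
#'
#' @param length_cm,width_cm Leaf lengths and widths (cm), one entry per leaf
#'   across all sampled plants.
#' @param m Number of sampled plants (>= 1).
#' @param k Leaf-area correction coefficient.
#' @param density Plant density (plants m-2).
#' @return The dimensionless leaf area index.
#' @export
lai_from_leaves <- function(length_cm, width_cm, m, k = 0.75, density) {
  stop_if(m < 1, "at least one sampled plant is required")
  stop_if(length(length_cm) != length(width_cm),
          "leaf length and width vectors differ in length")
  stop_if(any(length_cm <= 0) || any(width_cm <= 0),
          "leaf dimensions must be positive")
  sum(length_cm * width_cm) / m * k * density / 10000
}

#' Canopy cover from leaf area index
#'
#' CC = 1.005 * (1 - exp(-0.6 LAI))^1.2, clipped to at most 1.
#'
#' @param lai Leaf area index (>= 0), vectorized.
#' @return Canopy cover fraction in \[0, 1\].
#' @export
lai_to_cc <- function(lai) {
  stop_if(any(lai < 0), "LAI must be non-negative")
  pmin(1, 1.005 * (1 - exp(-0.6 * lai))^1.2)
}

#' Depletion-threshold water-stress coefficient
#'
#' Ks = 1 while root-zone depletion p (fraction of total available water) is
#' at or below the upper threshold, 0 at or beyond the lower threshold, and in
#' between follows the convex form
#' \code{1 - (exp(s * Drel) - 1) / (exp(s) - 1)} with
#' \code{Drel = (p - p_upper) / (p_lower - p_upper)}.
#'
#' @param p Depletion fraction of TAW, in \[0, 1\] (vectorized).
#' @param p_upper Upper (stress onset) threshold.
#' @param p_lower Lower (full stress) threshold; single-threshold stresses use
#'   \code{p_lower = 1}.
#' @param shape Positive curvature factor \code{s}.
#' @return Ks in \[0, 1\].
#' @export
stress_coefficient <- function(p, p_upper, p_lower = 1, shape = 3) {
  stop_if(shape <= 0, "shape must be positive")
  stop_if(p_upper >= p_lower, "p_upper must be below p_lower")
  drel <- pmin(1, pmax(0, (p - p_upper) / (p_lower - p_upper)))
  ks <- 1 - (exp(shape * drel) - 1) / (exp(shape) - 1)
  pmin(1, pmax(0, ks))
}

#' One day of canopy development
#'
#' Exponential growth at rate \code{Ks_exp * cgc} below half the maximum
#' cover, exponential approach to the maximum above it, and exponential decay
#' at rate \code{cdc} after the senescence thermal threshold (or, before it,
#' an early-senescence decay scaled by \code{1 - Ks_sen} when depletion
#' exceeds the senescence threshold). No growth after maturity.
#'
#' @param cc Current canopy cover fraction in \[0, mcc\].
#' @param params A \code{crop_params} object.
#' @param dgdd Thermal time of the day (degC d).
#' @param cum_gdd Cumulative thermal time at the end of the day.
#' @param ks_exp Expansion stress coefficient in \[0, 1\].
#' @param ks_sen Early-senescence stress coefficient in \[0, 1\] (1 = none).
#' @return Updated canopy cover in \[0, mcc\].
#' @export
canopy_step <- function(cc, params, dgdd, cum_gdd, ks_exp = 1, ks_sen = 1) {
  mcc <- params$mcc
  cc <- min(mcc, max(0, cc))
  senescing <- cum_gdd >= params$sen
  mature <- cum_gdd >= params$mat
  if (!senescing && !mature) {
    if (ks_exp > 0 && cc > 0) {
      if (cc < mcc / 2) {
        cc <- cc * exp(ks_exp * params$cgc * dgdd)
      } else {
        cc <- mcc - (mcc - cc) * exp(-ks_exp * params$cgc * dgdd)
      }
      cc <- min(cc, mcc)
    }
    if (ks_sen < 1) cc <- cc * exp(-(1 - ks_sen) * params$cdc * dgdd)
  } else if (!mature) {
    cc <- cc * exp(-params$cdc * dgdd)
  } else {
    cc <- cc * exp(-params$cdc * dgdd)  # no growth after maturity
  }
  min(mcc, max(0, cc))
}

#' One day of the soil-water bucket
#'
#' Adds irrigation and rain, removes actual evapotranspiration, routes the
#' excess above saturation to surface runoff and a \code{tau} fraction of the
#' excess above field capacity to deep drainage. The returned components close
#' the balance exactly:
#' \code{storage' = storage + I + P - ETa - D - R}.
#'
#' @param storage Root-zone storage (mm) within physical bounds.
#' @param irrigation,precip Water inputs of the day (mm).
#' @param eta Actual evapotranspiration (mm), pre-limited by the extraction
#'   rule so storage cannot fall below wilting point.
#' @param soil A \code{soil_profile}.
#' @return List with \code{storage} (mm), \code{drainage} (mm),
#'   \code{runoff} (mm).
#' @export
soil_water_step <- function(storage, irrigation, precip, eta, soil) {
  stop_if(irrigation < 0 || precip < 0 || eta < 0,
          "water fluxes must be non-negative")
  zmm <- soil$depth * 1000
  s <- storage + irrigation + precip - eta
  runoff <- max(0, s - soil$theta_sat * zmm)
  s <- s - runoff
  drainage <- soil$tau * max(0, s - soil$theta_fc * zmm)
  s <- s - drainage
  list(storage = s, drainage = drainage, runoff = runoff)
}

#' Transpiration/evaporation partition for one day
#'
#' Transpiration \code{Tr = Ks_sto * kcb_eff * CC * ET0} with the basal crop
#' coefficient reduced by \code{kcdcl} in proportion to canopy loss once
#' senescence has begun; soil evaporation \code{E = Ke (1 - CC) ET0} with
#' Ke = 1.1 and a late-season suppression factor driven by \code{evladc}.
#'
#' @param cc Canopy cover in \[0, 1\].
#' @param et0 Reference evapotranspiration (mm d-1).
#' @param ks_sto Stomatal stress coefficient in \[0, 1\].
#' @param params A \code{crop_params} object.
#' @param cum_gdd Cumulative thermal time (for the senescence corrections).
#' @return List with \code{tr} and \code{e} (mm d-1).
#' @export
crop_et <- function(cc, et0, ks_sto, params, cum_gdd = 0) {
  stop_if(cc < 0 || cc > 1, "CC must be in [0, 1]")
  kcb_eff <- params$kcb
  f_late <- 1
  if (cum_gdd >= params$sen) {
    kcb_eff <- params$kcb * (1 - params$kcdcl * (1 - cc / params$mcc))
    prog <- min(1, (cum_gdd - params$sen) / (params$mat - params$sen))
    f_late <- max(0, 1 - params$evladc / 100 * prog)
  }
  list(tr = max(0, ks_sto * kcb_eff * cc * et0),
       e = max(0, 1.1 * (1 - cc) * et0 * f_late))
}

#' One day of biomass accumulation
#'
#' \code{dB = wp * Tr / ET0} grams per square metre once cumulative thermal
#' time has passed the minimum requirement \code{stbio}; returned in t ha-1.
#'
#' @param b Biomass so far (t ha-1).
#' @param tr Transpiration of the day (mm).
#' @param et0 Reference evapotranspiration of the day (mm); a zero-ET0 day
#'   contributes nothing (with a warning).
#' @param params A \code{crop_params} object.
#' @param cum_gdd Cumulative thermal time.
#' @return Updated biomass (t ha-1), never below \code{b}.
#' @export
biomass_step <- function(b, tr, et0, params, cum_gdd) {
  stop_if(tr < 0, "transpiration must be non-negative")
  if (cum_gdd < params$stbio) return(b)
  if (et0 <= 0) {
    warning("ET0 is zero; skipping biomass accumulation for the day")
    return(b)
  }
  b + params$wp * (tr / et0) / 100  # g m-2 -> t ha-1
}

#' Harvest-index adjusted yield
#'
#' The harvest index builds linearly over \code{hilen} thermal units after
#' flowering; mild pre-flowering expansion stress raises it by at most
#' \code{hipsflo}; pollination failure (depletion beyond \code{ppol} or
#' temperatures outside \[polmn, polmx\] during flowering) reduces it
#' multiplicatively. The adjusted index never exceeds \code{hi * (1 + hinc)}.
#'
#' @param b_final Final biomass (t ha-1).
#' @param params A \code{crop_params} object.
#' @param hi_frac Fraction of the HI build-up window completed, in \[0, 1\].
#' @param preflo_stress Mean pre-flowering expansion stress (1 - Ks), in
#'   \[0, 1\].
#' @param ks_pol Mean pollination success coefficient in \[0, 1\].
#' @return Yield (kg hm-2) and the adjusted harvest index, as a list.
#' @export
yield_and_hi <- function(b_final, params, hi_frac = 1, preflo_stress = 0,
                         ks_pol = 1) {
  stop_if(b_final < 0, "biomass must be non-negative")
  # pre-flowering stress bonus capped at hipsflo and damped by hinsveg when
  # vegetative growth is limited, then pollination penalty and the thermal
  # build fraction
  bonus <- min(params$hipsflo, preflo_stress) /
    (1 + params$hinsveg * preflo_stress)
  hi_adj <- params$hi * (1 + bonus)
  hi_adj <- hi_adj * ks_pol * min(1, max(0, hi_frac))
  hi_adj <- min(hi_adj, params$hi * (1 + params$hinc))
  list(yield = hi_adj * b_final * 1000, hi = hi_adj)  # t/ha -> kg hm-2
}

# --- Phenological stages -----------------------------------------------------

#' Thermal-time boundaries of the four growth stages
#'
#' Initial: sowing to a jointing proxy at 0.35 x flowering GDD; rapid: to
#' flowering; mid: to senescence onset; late: to maturity.
#'
#' @param params A \code{crop_params} object.
#' @return Named numeric vector of upper GDD bounds per stage.
#' @export
stage_gdd_bounds <- function(params) {
  c(initial = 0.35 * params$flo, rapid = params$flo,
    mid = params$sen, late = params$mat)
}

stage_of_gdd <- function(cum_gdd, params) {
  b <- stage_gdd_bounds(params)
  ifelse(cum_gdd < b[["initial"]], "initial",
         ifelse(cum_gdd < b[["rapid"]], "rapid",
                ifelse(cum_gdd < b[["mid"]], "mid", "late")))
}

#' Calendar windows of the growth stages for a weather series
#'
#' Maps the GDD stage bounds onto calendar days of the given weather.
#'
#' @param params A \code{crop_params} object.
#' @param weather A \code{daily_weather} data frame.
#' @return Named list of integer day vectors (one per stage).
#' @export
stage_windows <- function(params, weather) {
  gdd <- cumsum(growing_degree_days(weather$tavg, params$tbase, params$utemp))
  st <- stage_of_gdd(gdd, params)
  mature <- which(gdd >= params$mat)
  last <- if (length(mature)) mature[1] else nrow(weather)
  out <- lapply(STAGE_NAMES, function(s) which(st == s & seq_along(st) <= last))
  names(out) <- STAGE_NAMES
  out
}

# --- The season loop ---------------------------------------------------------

#' Run one growing season
#'
#' Daily loop from sowing until maturity (cumulative GDD reaches \code{mat}).
#' When \code{unstressed = TRUE} the profile is refilled to field capacity
#' every evening (recorded as irrigation, so the daily balance still closes)
#' and no water stress occurs; such a run supplies the maximum
#' evapotranspiration \code{ETm} and maximum yield \code{Ym}. A stressed run
#' automatically performs its own parallel unstressed companion run to record
#' stage-wise \code{ETm,i}.
#'
#' @param params A \code{crop_params} object.
#' @param soil A \code{soil_profile}.
#' @param weather A \code{daily_weather} covering sowing to maturity GDD.
#' @param schedule An \code{\link{irrigation_schedule}} or NULL (rainfed).
#' @param unstressed If TRUE, simulate full-supply (auto-refill) conditions.
#' @param temp_pollination If TRUE, activate the pollination temperature
#'   switch (tmax above polmx or tmin below polmn during flowering halves the
#'   day's pollination success); inactive by default.
#' @param .with_reference Internal: attach the unstressed companion run.
#' @return An object of class \code{sim_result}: list with \code{daily}
#'   (data.frame), \code{yield} (kg hm-2), \code{biomass} (t ha-1),
#'   \code{et} (mm), \code{wue} (kg hm-2 mm-1), \code{stage_eta},
#'   \code{stage_etm} (mm), and bookkeeping scalars.
#' @export
run_season <- function(params, soil, weather, schedule = NULL,
                       unstressed = FALSE, temp_pollination = FALSE,
                       .with_reference = !unstressed) {
  stopifnot(inherits(params, "crop_params"), inherits(soil, "soil_profile"))
  validate_weather(weather)
  n <- nrow(weather)
  irr <- numeric(n)
  if (!is.null(schedule)) {
    stopifnot(inherits(schedule, "irrigation_schedule"))
    stop_if(any(schedule$day > n), "schedule events fall outside the weather series")
    for (i in seq_len(nrow(schedule)))
      irr[schedule$day[i]] <- irr[schedule$day[i]] + schedule$depth_mm[i]
  }

  zmm <- soil$depth * 1000
  cc0 <- params$den * params$ccs / 1e8  # plants/ha * cm2 -> cover fraction
  gdd_day <- growing_degree_days(weather$tavg, params$tbase, params$utemp)

  storage <- soil$theta_init * zmm
  # evaporable water in the top 0.10 m; drip only wets `wetted_frac` of the
  # surface, so evaporation is supply-limited between events
  surf_cap <- (soil$theta_fc - soil$theta_wp / 2) * 0.10 * 1000
  surf <- surf_cap
  cc <- 0; b <- 0; cum_gdd <- 0
  preflo_stress_sum <- 0; preflo_days <- 0
  pol_ks_sum <- 0; pol_days <- 0
  cols <- c("gdd", "cc", "biomass", "root_depth", "storage", "theta",
            "depletion", "p", "tr", "e", "eta", "irrigation", "precip",
            "drainage", "runoff", "balance_err")
  M <- matrix(NA_real_, nrow = n, ncol = length(cols),
              dimnames = list(NULL, cols))
  stage_vec <- character(n)
  last_day <- n
  # hoisted scalars (the loop mirrors the exported per-day operations, which
  # remain the tested reference implementations)
  pr <- unclass(params)
  eme <- pr$eme; flo <- pr$flo; sen <- pr$sen; mat <- pr$mat
  rinx <- pr$rinx; rtx <- pr$rtx; rootg <- max(1, pr$root - eme)
  fc <- soil$theta_fc; wp_ <- soil$theta_wp
  mcc <- pr$mcc; cgc <- pr$cgc; cdc <- pr$cdc
  kcb <- pr$kcb; kcdcl <- pr$kcdcl; evladc <- pr$evladc
  excap <- (pr$rtexup + pr$rtexhw) / 2 * 1000
  bounds <- stage_gdd_bounds(params)
  ks1 <- function(p, pu, pl, s) {
    if (p <= pu) return(1)
    if (p >= pl) return(0)
    drel <- (p - pu) / (pl - pu)
    min(1, max(0, 1 - (exp(s * drel) - 1) / (exp(s) - 1)))
  }
  et0v <- weather$et0; pcv <- weather$precip
  tmaxv <- weather$tmax; tminv <- weather$tmin

  for (d in seq_len(n)) {
    cum_gdd_prev <- cum_gdd
    cum_gdd <- cum_gdd + gdd_day[d]
    stage <- if (cum_gdd < bounds[[1]]) "initial" else
      if (cum_gdd < bounds[[2]]) "rapid" else
        if (cum_gdd < bounds[[3]]) "mid" else "late"

    # root depth over thermal time (post-emergence)
    zr <- if (cum_gdd <= eme) rinx else
      min(rtx, rinx + (rtx - rinx) * (cum_gdd - eme) / rootg)
    zr <- min(zr, soil$depth)

    theta <- storage / zmm
    taw <- (fc - wp_) * zr * 1000
    dr <- max(0, (fc - theta) * zr * 1000)
    p <- if (unstressed) 0 else min(1, dr / taw)

    ks_exp <- ks1(p, pr$puexp, pr$plexp, pr$pexshp)
    ks_sto <- ks1(p, pr$psto, 1, pr$pstoshp)
    ks_sen <- ks1(p, pr$psen, 1, pr$psenshp)

    # canopy (exponential growth / approach / decay; cf. canopy_step)
    if (cum_gdd_prev < eme && cum_gdd >= eme) cc <- cc0
    if (cum_gdd >= eme) {
      if (cum_gdd < sen) {
        if (ks_exp > 0 && cc > 0) {
          cc <- if (cc < mcc / 2) cc * exp(ks_exp * cgc * gdd_day[d]) else
            mcc - (mcc - cc) * exp(-ks_exp * cgc * gdd_day[d])
          cc <- min(cc, mcc)
        }
        if (ks_sen < 1) cc <- cc * exp(-(1 - ks_sen) * cdc * gdd_day[d])
      } else {
        cc <- cc * exp(-cdc * gdd_day[d])
      }
      cc <- min(mcc, max(0, cc))
    }

    # transpiration + evaporation (cf. crop_et), limited by extractable water
    kcb_eff <- kcb; f_late <- 1
    if (cum_gdd >= sen) {
      kcb_eff <- kcb * (1 - kcdcl * (1 - cc / mcc))
      f_late <- max(0, 1 - evladc / 100 * min(1, (cum_gdd - sen) / (mat - sen)))
    }
    tr <- max(0, ks_sto * kcb_eff * cc * et0v[d])
    ev <- min(max(0, 1.1 * (1 - cc) * et0v[d] * f_late), surf)
    if (!unstressed)
      tr <- min(tr, max(0, (theta - wp_)) * zr * 1000, excap * zr)
    eta <- tr + ev

    # water bucket (cf. soil_water_step)
    irr_d <- irr[d]
    s1 <- storage + irr_d + pcv[d] - eta
    runoff <- max(0, s1 - soil$theta_sat * zmm); s1 <- s1 - runoff
    drainage <- soil$tau * max(0, s1 - fc * zmm); s1 <- s1 - drainage
    if (unstressed) {
      # refill to field capacity, booked as irrigation so the balance closes
      refill <- max(0, fc * zmm - s1)
      irr_d <- irr_d + refill
      s1 <- s1 + refill
    }
    bal <- s1 - storage - irr_d - pcv[d] + eta + drainage + runoff
    storage <- s1
    surf <- min(surf_cap, surf - ev + soil$wetted_frac * irr_d + pcv[d])

    # biomass (cf. biomass_step) and yield bookkeeping
    if (et0v[d] > 0 && cum_gdd >= pr$stbio) b <- b + pr$wp * (tr / et0v[d]) / 100
    if (cum_gdd < flo) {
      preflo_stress_sum <- preflo_stress_sum + (1 - ks_exp)
      preflo_days <- preflo_days + 1
    }
    if (cum_gdd >= flo && cum_gdd <= flo + pr$flolen) {
      ks_pol_d <- ks1(p, pr$ppol, 1, 3)
      if (temp_pollination && (tmaxv[d] > pr$polmx || tminv[d] < pr$polmn))
        ks_pol_d <- ks_pol_d * 0.5
      pol_ks_sum <- pol_ks_sum + ks_pol_d
      pol_days <- pol_days + 1
    }

    M[d, ] <- c(cum_gdd, cc, b, zr, storage, storage / zmm, dr, p, tr, ev,
                eta, irr_d, pcv[d], drainage, runoff, bal)
    stage_vec[d] <- stage

    if (cum_gdd >= mat) { last_day <- d; break }
  }
  stop_if(cum_gdd < params$mat,
          sprintf("weather series too short: reached %.0f of %.0f GDD at maturity",
                  cum_gdd, params$mat))
  daily <- data.frame(day = seq_len(last_day),
                      M[seq_len(last_day), , drop = FALSE],
                      stage = stage_vec[seq_len(last_day)],
                      stringsAsFactors = FALSE)

  hi_frac <- min(1, max(0, (cum_gdd - params$flo) / params$hilen))
  preflo_stress <- if (preflo_days > 0) preflo_stress_sum / preflo_days else 0
  ks_pol <- if (pol_days > 0) pol_ks_sum / pol_days else 1
  yh <- yield_and_hi(b, params, hi_frac, preflo_stress, ks_pol)

  stage_f <- factor(daily$stage, levels = STAGE_NAMES)
  stage_eta <- tapply(daily$eta, stage_f, sum, default = 0)
  stage_eta[is.na(stage_eta)] <- 0

  et_total <- sum(daily$eta)
  dsws <- daily$storage[last_day] - soil$theta_init * zmm
  res <- structure(list(
    daily = daily, yield = yh$yield, hi = yh$hi, biomass = b,
    et = et_total, wue = if (et_total > 0) yh$yield / et_total else 0,
    stage_eta = as.numeric(stage_eta)[seq_along(STAGE_NAMES)],
    stage_etm = NULL, season_days = last_day, cum_gdd = cum_gdd,
    irrigation_total = sum(daily$irrigation),
    precip_total = sum(daily$precip),
    drainage_total = sum(daily$drainage),
    runoff_total = sum(daily$runoff),
    dsws = dsws, unstressed = unstressed), class = "sim_result")
  names(res$stage_eta) <- STAGE_NAMES

  if (unstressed) {
    res$stage_etm <- res$stage_eta
    res$ym <- res$yield
  } else if (.with_reference) {
    ref <- run_season(params, soil, weather, schedule = NULL,
                      unstressed = TRUE, .with_reference = FALSE)
    res$stage_etm <- ref$stage_eta
    res$ym <- ref$yield
  }
  res
}

#' Stage-wise crop evapotranspiration under full supply
#'
#' Convenience wrapper: runs the unstressed companion season and returns its
#' stage ET totals (the \code{ETc} totals that parameterize the deficit
#' treatment schedules).
#'
#' @param params,soil,weather As in \code{\link{run_season}}.
#' @return Named numeric vector of per-stage ETc totals (mm).
#' @export
unstressed_stage_etc <- function(params, soil, weather) {
  run_season(params, soil, weather, unstressed = TRUE)$stage_eta
}

#' @export
print.sim_result <- function(x, ...) {
  cat(sprintf(paste0("Season simulation: %d days, %.0f GDD\n",
                     "  yield %.0f kg hm-2 (HI %.3f, biomass %.2f t ha-1)\n",
                     "  ET %.1f mm, WUE %.2f kg hm-2 mm-1\n",
                     "  irrigation %.1f mm, rain %.1f mm\n"),
              x$season_days, x$cum_gdd, x$yield, x$hi, x$biomass,
              x$et, x$wue, x$irrigation_total, x$precip_total))
  invisible(x)
}

#' Export a season result
#'
#' Writes the daily trajectory as tidy CSV and the scalar summary as JSON.
#'
#' @param result A \code{sim_result}.
#' @param csv_path,json_path Output paths (NULL skips either file).
#' @return Invisibly, the summary list.
#' @export
export_sim_result <- function(result, csv_path = NULL, json_path = NULL) {
  stopifnot(inherits(result, "sim_result"))
  if (!is.null(csv_path))
    write.csv(result$daily, csv_path, row.names = FALSE)
  summ <- list(yield_kg_hm2 = result$yield, biomass_t_ha = result$biomass,
               hi = result$hi, et_mm = result$et, wue = result$wue,
               irrigation_mm = result$irrigation_total,
               precip_mm = result$precip_total,
               season_days = result$season_days,
               stage_eta_mm = as.list(result$stage_eta),
               stage_etm_mm = as.list(result$stage_etm %||% result$stage_eta),
               stage_et_ratio = as.list((result$stage_eta + 1e-12) /
                                          ((result$stage_etm %||% result$stage_eta) + 1e-12)))
  if (!is.null(json_path))
    jsonlite::write_json(summ, json_path, auto_unbox = TRUE, digits = NA)
  invisible(summ)
}
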