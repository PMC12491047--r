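# Shared fixtures, built once per test run: the default crop/soil, one
# deterministic weather season, its stage windows and full-supply stage ETc,
# and a treatment schedule builder.

fx_crop <- default_crop()
fx_soil <- soil_profile()
fx_weather <- generate_season(weather_gen_config(seed = 42), site_info())
fx_windows <- stage_windows(fx_crop, fx_weather)
fx_etc <- unstressed_stage_etc(fx_crop, fx_soil, fx_weather)

fx_schedule <- function(plan = stage_plan(), etc = fx_etc) {
  build_treatment_schedule(plan, setNames(etc, names(etc)), fx_windows)
}

fx_sim <- function(schedule = fx_schedule(), ...) {
  run_season(fx_crop, fx_soil, fx_weather, schedule, ...)
}
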