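# Calibrated maize profile "Xinnong 008" (drip-irrigated, northern Xinjiang).
# Percent-type entries are stored as fractions (e.g. reference harvest index 49% -> 0.49).
name: xinnong008
phenology:
  mat: 2521      # GDD, sowing -> maturity
  eme: 151       # GDD, sowing -> emergence
  sen: 1822      # GDD, sowing -> start of canopy senescence
  flo: 1607      # GDD, sowing -> flowering
  flolen: 270    # GDD, flowering duration
  hilen: 900     # GDD, harvest-index build-up after flowering
  stbio: 12      # GDD, minimum thermal time before biomass formation
  root: 1516     # GDD, time to maximum effective root depth
canopy:
  cgc: 0.006     # frac GDD^-1, canopy growth coefficient
  cdc: 0.004     # frac GDD^-1, canopy senescence coefficient
  cge: 0.0062    # frac GDD^-1, canopy expansion rate coefficient
  mcc: 0.967     # frac, maximum canopy cover
  ccs: 1.5       # cm2 per plant, cover at 90% emergence
  den: 250516    # plants ha^-1, density used for initial cover (den * ccs)
roots:
  rinx: 0.3      # m, minimum effective root depth
  rtx: 2.05      # m, maximum effective root depth
  rtexup: 0.025  # volumetric extraction fraction d^-1, top quarter
  rtexhw: 0.007  # volumetric extraction fraction d^-1, bottom quarter
  rtshp: 15      # shape factor, root-zone expansion
transpiration:
  kcb: 1.1       # crop coefficient at full, non-senescent cover
  kcdcl: 0.3     # kcb reduction factor under senescence
  evladc: 50     # late-season soil-evaporation suppression coefficient
productivity:
  wp: 39.7       # g m^-2, normalized water productivity
  hi: 0.49       # frac, reference harvest index
  hinc: 0.15     # frac, maximum allowed HI increase
  hinsveg: 4     # HI penalty coefficient when vegetative growth is limited
  hipsflo: 0.03  # frac, max positive pre-flowering stress effect on HI
  exc: 1.0       # frac, potential excess fruit
stress:
  puexp: 0.2     # frac TAW, upper depletion threshold, canopy expansion
  plexp: 0.65    # frac TAW, lower depletion threshold, canopy expansion
  pexshp: 3      # shape factor, expansion stress
  psto: 0.65     # frac TAW, depletion threshold, stomatal closure
  pstoshp: 2.5   # shape factor, stomatal stress
  psen: 0.5      # frac TAW, depletion threshold, early senescence
  psenshp: 3     # shape factor, senescence stress
  ppol: 0.8      # frac TAW, depletion threshold, pollination failure
  anaer: 0.05    # frac, anaerobic point (switch inactive by default)
temperature:
  tbase: 8       # degC, base temperature for development
  utemp: 30      # degC, upper temperature threshold for development
  polmn: 5       # degC, minimum pollination temperature
  polmx: 35      # degC, maximum pollination temperature
salinity:        # stored but inert
  uelecon: 5     # dS m^-1
  elecon: 20     # dS m^-1
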