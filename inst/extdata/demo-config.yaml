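# Packaged demo configuration: a desk-scale synthetic study. One 20 x 20 km
# region of 1 km^2 block groups in 3 counties, 16 regulated facilities across
# the five NAICS categories, a 14-day hurricane window with matched reference
# windows in the surrounding years, random wind, and scaled-down MCMC.
region:
  n_rows: 20
  n_cols: 20
  cell_km: 1
  n_counties: 3
facilities:
  petrochemical manufacturing: 6
  petroleum refineries: 3
  plastics, resin, and other manufacturing: 3
  fossil fuel extraction, transmission, and power generation: 2
  warehousing, storage, and other: 2
reports:
  rate_hurricane: 0.06
  rate_reference: 0.02
  p_air: 0.5
  contamination: 0.2
hurricane:
  label: hurricane
  start: "2017-08-23"
  end: "2017-09-05"
reference_years: [2016, 2018]
wind:
  regime: random
  grid_step_km: 6
thresholds:
  r_near: 2
  r_far: 10
  half_width: 45
  rain_mm: 141
  wind_knots: 64
  facilities: 24
mcmc:
  chains: 3
  n_iter: 6000
  burn_in: 3000
  # weakly informative fixed-effect prior: desk-scale exposure clusters are
  # small enough that the spatial field can separate them perfectly, and a
  # near-flat prior would let the coefficients diffuse
  beta_prior_var: 10
seed: 1
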