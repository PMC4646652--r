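# birdscape run configuration template.
# Every key is optional; unset keys fall back to the packaged defaults
# (calibrated demography, documented utility matrix). Unknown keys are
# rejected. Command-line flags override config keys.

choice:
  temperature: 0.15        # softmax sharpness on the 0-1 utility scale
  deterministic: false     # true = argmax cover choice (ties split evenly)

# Utility of each land cover under each objective, all in [0, 1].
# utility:
#   GRASSLAND:   {BIRDS: 0.90, CARBON: 0.80, WATER_QUALITY: 0.80, FINANCIAL_PROFIT: 0.20, BIODIVERSITY: 0.90}
#   AGRICULTURE: {BIRDS: 0.05, CARBON: 0.10, WATER_QUALITY: 0.10, FINANCIAL_PROFIT: 1.00, BIODIVERSITY: 0.05}
#   FOREST:      {BIRDS: 0.30, CARBON: 0.90, WATER_QUALITY: 0.70, FINANCIAL_PROFIT: 0.30, BIODIVERSITY: 0.60}

# Demographic parameters (defaults are the calibrated set; see
# ?demographic_params for units).
# demography:
#   nest_density: 0.2
#   nest_survival: 0.3
#   edge_penalty: 0.5
#   fledglings_per_nest: 3
#   occupancy:         {GRASSLAND: 0.9, AGRICULTURE: 0.2, FOREST: 0.1}
#   stopover_survival: {GRASSLAND: 0.99, AGRICULTURE: 0.93, FOREST: 0.95}
#   winter_survival:   {GRASSLAND: 0.80, AGRICULTURE: 0.55, FOREST: 0.65}
#   k_breeding: 2
#   k_stopover: 10
#   k_winter: 4
#   matrix_survival_floor: 0.3

landscape:
  n_rows: 40
  n_cols: 40
  pixel_size_m: 30

simulation:
  horizon: 30              # years
  n0: 100                  # birds at the start of year 0
  replicates: 100          # replicate landscape sets per consequence cell
  stochastic: false        # true = Poisson births / binomial survival

# How non-grassland mass is split in the grassland response curve.
curve_split:
  agriculture: 0.5
  forest: 0.5

# Experimental: per-role cover distributions overriding the landowner
# model's output for specific annual-cycle stages.
# stage_distributions:
#   WINTERING: {GRASSLAND: 0.2, AGRICULTURE: 0.7, FOREST: 0.1}

output_dir: "."
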