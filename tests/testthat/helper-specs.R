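# random valid batch specs for property tests; parameters drawn wide but
# always satisfying the type invariants
random_cm_spec <- function() {
  vol <- runif(1, 1, 25)
  d0 <- 10^runif(1, 5, 6.3)
  df <- d0 * 10^runif(1, 0.3, 1.7)
  cw <- runif(1, 3e-9, 4.4e-9)
  mass <- df * vol * 1e6 * cw / 1000
  suppressWarnings(cm_batch_spec(
    reactor_volume = vol,
    initial_cell_density = d0,
    final_cell_density = df,
    cell_wet_mass = cw,
    proliferation_duration = runif(1, 48, 240),
    maturation_duration = runif(1, 24, 240),
    batch_meat_mass = mass,
    meat_protein_fraction = runif(1, 0.12, 0.25),
    water_per_batch = mass * runif(1, 0.05, 0.12),
    oxygen_uptake_rate = runif(1, 100, 500),
    meat_energy_density = runif(1, 1000, 3000),
    protein_conversion_efficiency = runif(1, 0.1, 0.9),
    calorie_conversion_efficiency = runif(1, 0.1, 0.4),
    glucose_energy_density = 4000,
    batch_days = 11
  ))
}

baseline_batch <- function() preset_cm_batch("baseline")
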