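# Shared fixtures: all built in code at test time.

# Small synthetic dataset reused across tests.
tiny_dataset <- function(n = 200, seed = 7) {
  generate_dataset(synthetic_config(n_samples = n, seed = seed))
}

# A single harmonized record with controllable fields.
one_record <- function(shape = "sphere", dopant_element = "none",
                       dopant_x = 0, H = 150, f = 150, C_SPION = 2,
                       d_TEM = 12, Ms = 60, Mr = 6, has_coating = 1L,
                       SAR = 100) {
  data.frame(
    H = H, f = f, C_SPION = C_SPION, T = 300, d_TEM = d_TEM,
    std_dTEM = d_TEM * 0.1, shape = shape, dopant_element = dopant_element,
    dopant_x = dopant_x, Ms = Ms, Mr = Mr, Hc = 10,
    has_coating = as.integer(has_coating),
    coating_multilayer_composite = 0L, coating_oil_soluble = 0L,
    coating_water_soluble = as.integer(has_coating), coating_inorganic = 0L,
    medium_non_aqueous = 0L, medium_low_viscosity = 1L,
    medium_contains_stabilizer = 0L, SAR = SAR,
    stringsAsFactors = FALSE
  )
}

# Fast boosting parameters for tests that need a competent predictor quickly.
fast_gb_params <- list(eta = 0.1, max_depth = 5, nrounds = 200)

# Minimal screening lexicons for detector tests.
toy_lexicons <- function() {
  list(
    feature_lexicon = list(
      Ms = c("saturation magnetization"),
      f = c("frequency", "khz"),
      SAR = c("sar", "specific absorption rate")
    ),
    unit_lexicon = list(
      Ms = c("emu g-1" = "emu/g", "emu/g" = "emu/g"),
      f = c("khz" = "kHz"),
      SAR = c("w g-1" = "W/g")
    )
  )
}
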