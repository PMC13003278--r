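# Synthetic-data generator.
#
# Emulates the statistical structure of a literature-curated SPION
# hyperthermia dataset: right-skewed numeric marginals (truncated
# log-normals), a dominant spherical / organic-coating category structure,
# dopant fractions concentrated near zero, field amplitude mostly below
# 500 Oe, frequency mostly below 400 kHz, SAR mostly below 500 W/g. A known
# ground-truth SAR function (power law in H and f, log-normal size bell,
# dopant and concentration modifiers - the qualitative shape of
# linear-response-theory heating) makes every downstream stage testable
# against a recoverable signal.

#' Configuration for the synthetic SPION dataset generator
#'
#' @param n_samples Number of records to generate (>= 0).
#' @param seed Integer RNG seed; identical configurations and seeds give
#'   bit-identical datasets.
#' @param shape_mix Named probability vector over the five shape classes;
#'   must sum to 1.
#' @param dopant_element_probs Named probability vector over
#'   `c("none", "Zn", "Mn", "Co", "Mg")`; must sum to 1.
#' @param dopant_x_shape Two Beta shape parameters for the doping fraction,
#'   concentrated near zero by default.
#' @param noise_sd_relative Relative standard deviation of the multiplicative
#'   observation noise on SAR (>= 0).
#' @param truth Named list of ground-truth coefficients: `kappa` (overall
#'   scale), `a` (field exponent), `b` (frequency exponent), `d_opt` (optimal
#'   core diameter, nm), `width` (log-width of the size bell), `gamma_Co`
#'   (cobalt doping gain), `gamma_Zn` (zinc doping penalty beyond x = 0.1),
#'   `delta` (concentration decay, mL/mg).
#' @param bounds Named list of `c(lo, hi)` truncation bounds for H (Oe),
#'   f (kHz), C_SPION (mg/mL), d_TEM (nm) and Ms (emu/g).
#' @return An object of class `synthetic_config`.
#' @export
synthetic_config <- function(n_samples = 2000,
                             seed = 1,
                             shape_mix = c(sphere = 0.70, cube = 0.12,
                                           nanoflower = 0.06, octahedron = 0.08,
                                           octopod = 0.04),
                             dopant_element_probs = c(none = 0.65, Zn = 0.12,
                                                      Mn = 0.10, Co = 0.08,
                                                      Mg = 0.05),
                             dopant_x_shape = c(1.2, 6),
                             noise_sd_relative = 0.1,
                             truth = list(kappa = 7e-5, a = 2, b = 1,
                                          d_opt = 16, width = 0.6,
                                          gamma_Co = 0.5, gamma_Zn = 0.8,
                                          delta = 0.04),
                             bounds = list(H = c(20, 500), f = c(40, 800),
                                           C_SPION = c(0.1, 20),
                                           d_TEM = c(4, 30),
                                           Ms = c(5, 100))) {
  check_probs <- function(p, names_expected, what) {
    if (!is.numeric(p) || anyNA(p) || any(p < 0) ||
        abs(sum(p) - 1) > 1e-8 || !setequal(names(p), names_expected)) {
      stopf("%s must be a nonnegative named probability vector over {%s} summing to 1",
            what, paste(names_expected, collapse = ", "))
    }
  }
  if (!is_number(n_samples) || n_samples < 0 || n_samples != round(n_samples)) {
    stopf("n_samples must be a nonnegative integer")
  }
  check_probs(shape_mix, SHAPES, "shape_mix")
  check_probs(dopant_element_probs, c("none", "Zn", "Mn", "Co", "Mg"),
              "dopant_element_probs")
  if (!is_number(noise_sd_relative) || noise_sd_relative < 0) {
    stopf("noise_sd_relative must be >= 0")
  }
  needed <- c("kappa", "a", "b", "d_opt", "width", "gamma_Co", "gamma_Zn", "delta")
  if (!all(needed %in% names(truth))) {
    stopf("truth must contain: %s", paste(needed, collapse = ", "))
  }
  structure(
    list(n_samples = as.integer(n_samples), seed = as.integer(seed),
         shape_mix = shape_mix[SHAPES],
         dopant_element_probs = dopant_element_probs[c("none", "Zn", "Mn", "Co", "Mg")],
         dopant_x_shape = dopant_x_shape,
         noise_sd_relative = noise_sd_relative,
         truth = truth, bounds = bounds),
    class = "synthetic_config"
  )
}

#' Noiseless ground-truth SAR of the generator
#'
#' `kappa * H^a * f^b * bell(d_TEM) * dopant_factor * exp(-delta * C)` where
#' `bell(d) = exp(-(log(d / d_opt))^2 / (2 width^2))` and the dopant factor is
#' `1 + gamma_Co * x_Co - gamma_Zn * max(0, x_Zn - 0.1)`. Strictly increasing
#' in H and f, strictly decreasing in C, and maximal at `d_opt`.
#'
#' @param records Data frame with columns `H`, `f`, `C_SPION`, `d_TEM`,
#'   `dopant_element`, `dopant_x`.
#' @param truth Ground-truth coefficient list (see [synthetic_config()]).
#' @return Numeric vector of noiseless SAR values, W/g.
#' @export
sar_ground_truth <- function(records, truth) {
  x_co <- ifelse(records$dopant_element == "Co", records$dopant_x, 0)
  x_zn <- ifelse(records$dopant_element == "Zn", records$dopant_x, 0)
  bell <- exp(-(log(records$d_TEM / truth$d_opt))^2 / (2 * truth$width^2))
  dop <- 1 + truth$gamma_Co * x_co - truth$gamma_Zn * pmax(0, x_zn - 0.1)
  truth$kappa * records$H^truth$a * records$f^truth$b * bell * dop *
    exp(-truth$delta * records$C_SPION)
}

#' Generate a synthetic SPION dataset with known ground truth
#'
#' @param config A [synthetic_config()].
#' @return A list with `records` (a data frame of harmonized records, one row
#'   per sample, canonical units, including the observed `SAR`) and `truth`
#'   (class `ground_truth`: the noiseless SAR per row plus the generative
#'   parameters).
#' @examples
#' ds <- generate_dataset(synthetic_config(n_samples = 50, seed = 7))
#' head(ds$records)
#' @export
generate_dataset <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  n <- config$n_samples
  if (n == 0L) {
    rec <- empty_records()
    truth <- structure(list(sar_noiseless = numeric(0), config = config),
                       class = "ground_truth")
    return(list(records = rec, truth = truth))
  }
  b <- config$bounds
  with_seed(config$seed, {
    shape <- sample(SHAPES, n, replace = TRUE, prob = config$shape_mix)
    dopant_element <- sample(names(config$dopant_element_probs), n,
                             replace = TRUE, prob = config$dopant_element_probs)
    dopant_x <- ifelse(dopant_element == "none", 0,
                       stats::rbeta(n, config$dopant_x_shape[1],
                                    config$dopant_x_shape[2]))
    H <- rlnorm_trunc(n, log(150), 0.50, b$H[1], b$H[2])
    f <- rlnorm_trunc(n, log(150), 0.55, b$f[1], b$f[2])
    C_SPION <- rlnorm_trunc(n, log(2), 0.80, b$C_SPION[1], b$C_SPION[2])
    d_TEM <- rlnorm_trunc(n, log(12), 0.30, b$d_TEM[1], b$d_TEM[2])
    std_dTEM <- d_TEM * stats::runif(n, 0.05, 0.25)
    T_K <- ifelse(stats::runif(n) < 0.9, 300,
                  round(stats::runif(n, 5, 350)))
    Ms <- rlnorm_trunc(n, log(55), 0.35, b$Ms[1], b$Ms[2])
    squareness <- stats::rbeta(n, 1, 8) # small Mr/Ms: superparamagnetic regime
    Mr <- Ms * squareness
    Hc <- rlnorm_trunc(n, log(15), 1.0, 0.01, 500)
    has_coating <- as.integer(stats::runif(n) < 0.8)
    ctype <- sample(c("water_soluble", "oil_soluble", "inorganic",
                      "multilayer_composite"),
                    n, replace = TRUE, prob = c(0.60, 0.15, 0.15, 0.10))
    coating_multilayer_composite <- as.integer(has_coating == 1L & ctype == "multilayer_composite")
    coating_oil_soluble <- as.integer(has_coating == 1L & ctype == "oil_soluble")
    coating_water_soluble <- as.integer(has_coating == 1L & ctype == "water_soluble")
    coating_inorganic <- as.integer(has_coating == 1L & ctype == "inorganic")
    medium_non_aqueous <- as.integer(stats::runif(n) < 0.10)
    medium_low_viscosity <- as.integer(stats::runif(n) < 0.80)
    medium_contains_stabilizer <- as.integer(stats::runif(n) < 0.30)

    records <- data.frame(
      H = H, f = f, C_SPION = C_SPION, T = T_K, d_TEM = d_TEM,
      std_dTEM = std_dTEM, shape = shape, dopant_element = dopant_element,
      dopant_x = dopant_x, Ms = Ms, Mr = Mr, Hc = Hc,
      has_coating = has_coating,
      coating_multilayer_composite = coating_multilayer_composite,
      coating_oil_soluble = coating_oil_soluble,
      coating_water_soluble = coating_water_soluble,
      coating_inorganic = coating_inorganic,
      medium_non_aqueous = medium_non_aqueous,
      medium_low_viscosity = medium_low_viscosity,
      medium_contains_stabilizer = medium_contains_stabilizer,
      stringsAsFactors = FALSE
    )
    sar_noiseless <- sar_ground_truth(records, config$truth)
    eps <- stats::rnorm(n, 0, config$noise_sd_relative)
    records$SAR <- sar_noiseless * (1 + eps)

    truth <- structure(list(sar_noiseless = sar_noiseless, config = config),
                       class = "ground_truth")
    list(records = records, truth = truth)
  })
}

empty_records <- function() {
  data.frame(
    H = numeric(0), f = numeric(0), C_SPION = numeric(0), T = numeric(0),
    d_TEM = numeric(0), std_dTEM = numeric(0), shape = character(0),
    dopant_element = character(0), dopant_x = numeric(0), Ms = numeric(0),
    Mr = numeric(0), Hc = numeric(0), has_coating = integer(0),
    coating_multilayer_composite = integer(0), coating_oil_soluble = integer(0),
    coating_water_soluble = integer(0), coating_inorganic = integer(0),
    medium_non_aqueous = integer(0), medium_low_viscosity = integer(0),
    medium_contains_stabilizer = integer(0), SAR = numeric(0),
    stringsAsFactors = FALSE
  )
}

#' Per-feature marginal summary of a record set
#'
#' Numeric columns are summarized by min / median / max / skewness (skewness
#' is `NA` with a `constant` flag for zero-variance columns); categorical and
#' binary columns by their modal level and its frequency.
#'
#' @param records Nonempty data frame of records.
#' @return A data frame with one row per feature: `feature`, `type`, `min`,
#'   `median`, `max`, `skewness`, `constant`, `top_level`, `top_freq`. The
#'   full level-frequency tables are attached as attribute `"frequencies"`.
#' @export
summarize_marginals <- function(records) {
  if (!is.data.frame(records) || nrow(records) == 0L) {
    stopf("records must be a nonempty data frame")
  }
  freqs <- list()
  rows <- lapply(names(records), function(nm) {
    x <- records[[nm]]
    if (is.numeric(x) && length(unique(x)) > 2L) {
      data.frame(feature = nm, type = "numeric",
                 min = min(x), median = stats::median(x), max = max(x),
                 skewness = sample_skewness(x),
                 constant = length(unique(x)) == 1L,
                 top_level = NA_character_, top_freq = NA_real_,
                 stringsAsFactors = FALSE)
    } else {
      tab <- sort(table(x) / length(x), decreasing = TRUE)
      freqs[[nm]] <<- tab
      is_const <- length(tab) == 1L
      num_type <- if (all(x %in% c(0, 1))) "binary" else "numeric"
      data.frame(feature = nm, type = if (is.numeric(x)) num_type else "categorical",
                 min = if (is.numeric(x)) min(x) else NA_real_,
                 median = if (is.numeric(x)) stats::median(x) else NA_real_,
                 max = if (is.numeric(x)) max(x) else NA_real_,
                 skewness = if (is.numeric(x) && !is_const) sample_skewness(x) else NA_real_,
                 constant = is_const,
                 top_level = names(tab)[1], top_freq = as.numeric(tab[1]),
                 stringsAsFactors = FALSE)
    }
  })
  out <- do.call(rbind, rows)
  attr(out, "frequencies") <- freqs
  out
}

#' Write a generated dataset to plain-text files
#'
#' Records go to CSV; the ground truth and configuration to a JSON sidecar.
#'
#' @param dataset A list from [generate_dataset()].
#' @param csv_path Output CSV path for the records.
#' @param json_path Output JSON path for truth + configuration.
#' @return Invisibly, the two paths.
#' @export
write_dataset <- function(dataset, csv_path, json_path) {
  utils::write.csv(dataset$records, csv_path, row.names = FALSE)
  cfg <- dataset$truth$config
  jsonlite::write_json(
    list(sar_noiseless = dataset$truth$sar_noiseless,
         config = cfg[setdiff(names(cfg), character(0))]),
    json_path, auto_unbox = TRUE, digits = NA
  )
  invisible(c(csv_path, json_path))
}
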