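# Assembly of the 30-feature predictive matrix (plus the SAR target) from
# harmonized records.
#
# Feature inventory: 17 numeric columns (field amplitude H, frequency f,
# concentration C_SPION, measurement temperature T, core diameter d_TEM and
# its spread std_dTEM, geometry descriptors A_core / V_core / AV_ratio,
# magnetic Ms / Mr / Hc and the squareness ratio Mr/Ms, and the four
# dopant-iron ratios) and 13 binary columns (five mutually exclusive shape
# indicators, five coating descriptors, three medium descriptors).

#' Frozen schema of the predictive feature table
#'
#' @return A list with `numeric_features` (17 names), `binary_features`
#'   (13 names), `features` (all 30, in canonical order) and `target`.
#' @export
feature_schema <- function() {
  numeric_features <- c(
    "H", "f", "C_SPION", "T", "d_TEM", "std_dTEM",
    "A_core", "V_core", "AV_ratio",
    "Ms", "Mr", "Hc", "MrMs_ratio",
    "Zn_Fe", "Mn_Fe", "Co_Fe", "Mg_Fe"
  )
  binary_features <- c(
    paste0("shape_", SHAPES),
    "has_coating", "coating_multilayer_composite", "coating_oil_soluble",
    "coating_water_soluble", "coating_inorganic",
    "medium_non_aqueous", "medium_low_viscosity", "medium_contains_stabilizer"
  )
  list(
    numeric_features = numeric_features,
    binary_features = binary_features,
    features = c(numeric_features, binary_features),
    target = "SAR"
  )
}

#' Build the predictive feature table from harmonized records
#'
#' Computes geometry descriptors via [core_area_volume()], the squareness
#' ratio Mr/Ms (0, with a flag, when Ms = 0), the dopant-iron ratio vector,
#' and one-hot shape indicators. Records with `d_TEM` above `max_d_tem`
#' (default 30 nm, the superparamagnetic size constraint) are rejected with a
#' reason, as are maghemite records when a `phase` column is present.
#' Irregular or unknown-polyhedral shape labels can be mapped to `"sphere"`
#' upstream; unknown shapes here are an error.
#'
#' @param records Data frame of harmonized records (see [generate_dataset()]
#'   for the column contract).
#' @param max_d_tem Upper bound on core diameter, nm.
#' @param beta1,beta2 Model angles (degrees) passed to the geometry module.
#' @param ratio_mode Dopant-ratio encoding, `"x"` or `"molar"`
#'   (see [dopant_ratio_features()]).
#' @return A data frame of class `feature_table` with the 30 predictive
#'   columns of [feature_schema()] plus the `SAR` target; rejected rows are
#'   attached as attribute `"rejected"` (row index + reason).
#' @export
build_feature_table <- function(records, max_d_tem = 30,
                                beta1 = DEFAULT_BETA_DEG,
                                beta2 = DEFAULT_BETA_DEG,
                                ratio_mode = c("x", "molar")) {
  ratio_mode <- match.arg(ratio_mode)
  stopifnot(is.data.frame(records))
  bad_shape <- setdiff(unique(records$shape), SHAPES)
  if (length(bad_shape) > 0L) {
    stopf("unknown shape(s): %s", paste(bad_shape, collapse = ", "))
  }
  reject <- data.frame(row = integer(0), reason = character(0),
                       stringsAsFactors = FALSE)
  drop <- rep(FALSE, nrow(records))
  too_big <- which(records$d_TEM > max_d_tem)
  if (length(too_big) > 0L) {
    reject <- rbind(reject, data.frame(
      row = too_big, reason = sprintf("d_TEM > %g nm", max_d_tem)
    ))
    drop[too_big] <- TRUE
  }
  if ("phase" %in% names(records)) {
    magh <- which(tolower(records$phase) == "maghemite")
    if (length(magh) > 0L) {
      reject <- rbind(reject, data.frame(row = magh, reason = "maghemite phase"))
      drop[magh] <- TRUE
    }
  }
  rec <- records[!drop, , drop = FALSE]
  n <- nrow(rec)

  A_core <- V_core <- numeric(n)
  for (sh in unique(rec$shape)) {
    idx <- which(rec$shape == sh)
    g <- core_area_volume(sh, d_tem = rec$d_TEM[idx], beta1 = beta1, beta2 = beta2)
    A_core[idx] <- g$A_core
    V_core[idx] <- g$V_core
  }

  ms_zero <- rec$Ms == 0
  mrms <- ifelse(ms_zero, 0, rec$Mr / rec$Ms)

  ratios <- matrix(0, nrow = n, ncol = 4,
                   dimnames = list(NULL, c("Zn_Fe", "Mn_Fe", "Co_Fe", "Mg_Fe")))
  doped <- which(rec$dopant_element != "none")
  for (i in doped) {
    ratios[i, ] <- dopant_ratio_features(
      composition(rec$dopant_element[i], rec$dopant_x[i]), mode = ratio_mode
    )
  }

  shape_onehot <- vapply(SHAPES, function(sh) as.integer(rec$shape == sh),
                         integer(n))
  if (n == 1L) shape_onehot <- matrix(shape_onehot, nrow = 1,
                                      dimnames = list(NULL, SHAPES))
  colnames(shape_onehot) <- paste0("shape_", SHAPES)

  out <- data.frame(
    H = rec$H, f = rec$f, C_SPION = rec$C_SPION, T = rec$T,
    d_TEM = rec$d_TEM, std_dTEM = rec$std_dTEM,
    A_core = A_core, V_core = V_core, AV_ratio = av_ratio(A_core, V_core),
    Ms = rec$Ms, Mr = rec$Mr, Hc = rec$Hc, MrMs_ratio = mrms,
    ratios,
    shape_onehot,
    has_coating = as.integer(rec$has_coating),
    coating_multilayer_composite = as.integer(rec$coating_multilayer_composite),
    coating_oil_soluble = as.integer(rec$coating_oil_soluble),
    coating_water_soluble = as.integer(rec$coating_water_soluble),
    coating_inorganic = as.integer(rec$coating_inorganic),
    medium_non_aqueous = as.integer(rec$medium_non_aqueous),
    medium_low_viscosity = as.integer(rec$medium_low_viscosity),
    medium_contains_stabilizer = as.integer(rec$medium_contains_stabilizer),
    SAR = rec$SAR,
    stringsAsFactors = FALSE
  )
  sch <- feature_schema()
  out <- out[, c(sch$features, sch$target)]
  class(out) <- c("feature_table", "data.frame")
  attr(out, "rejected") <- reject
  attr(out, "ms_zero_flag") <- which(ms_zero)
  out
}

#' Validate a feature table against the frozen schema
#'
#' Checks column inventory and order-free presence, exactly 30 predictive
#' columns plus the target, shape one-hot exclusivity, coating-flag
#' consistency (type flags 0 when `has_coating` is 0), binary domains and
#' absence of missing values.
#'
#' @param table A data frame (usually from [build_feature_table()]).
#' @return Character vector of violation messages; empty if and only if the
#'   table is valid.
#' @export
validate_schema <- function(table) {
  sch <- feature_schema()
  v <- character(0)
  missing_cols <- setdiff(c(sch$features, sch$target), names(table))
  if (length(missing_cols) > 0L) {
    v <- c(v, sprintf("missing column(s): %s", paste(missing_cols, collapse = ", ")))
  }
  pred <- intersect(names(table), sch$features)
  if (length(pred) != 30L) {
    v <- c(v, sprintf("schema width %d != 30 predictive columns", length(pred)))
  }
  present <- intersect(sch$features, names(table))
  if (length(present) > 0L && anyNA(table[, present])) {
    v <- c(v, "missing values in predictive columns")
  }
  onehots <- intersect(paste0("shape_", SHAPES), names(table))
  if (length(onehots) == 5L && nrow(table) > 0L) {
    s <- rowSums(table[, onehots])
    if (any(s != 1)) v <- c(v, "shape one-hot columns must sum to 1 per row")
  }
  coatings <- c("coating_multilayer_composite", "coating_oil_soluble",
                "coating_water_soluble", "coating_inorganic")
  if (all(c("has_coating", coatings) %in% names(table)) && nrow(table) > 0L) {
    uncoated <- table$has_coating == 0
    if (any(uncoated & rowSums(table[, coatings]) > 0)) {
      v <- c(v, "coating type flags must be 0 when has_coating = 0")
    }
  }
  bin <- intersect(sch$binary_features, names(table))
  if (length(bin) > 0L && nrow(table) > 0L) {
    vals <- unlist(table[, bin], use.names = FALSE)
    if (!all(vals %in% c(0L, 1L))) v <- c(v, "binary columns must be 0/1")
  }
  v
}

#' Split a feature table into predictor matrix and target
#'
#' @param table A feature table.
#' @return List with `X` (numeric matrix, 30 columns) and `y` (SAR vector).
#' @export
table_xy <- function(table) {
  sch <- feature_schema()
  X <- as.matrix(as.data.frame(table)[, sch$features])
  storage.mode(X) <- "double"
  list(X = X, y = as.numeric(table[[sch$target]]))
}
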