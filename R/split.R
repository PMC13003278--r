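# Stratified 70/10/10/10 splitting, class weights, feature scaling and the
# Yeo-Johnson target transform.
#
# The stratify label is the concatenation shape|dopant|coating. Class weights
# follow a five-step scheme: (1) reciprocal of per-class counts, (2) divide by
# the minimum weight, (3) log1p, (4) divide again by the minimum, (5) assign
# per row by label. The most frequent class therefore gets weight exactly 1
# and rarer classes monotonically larger weights.

#' Stratification label for a record
#'
#' Deterministic concatenation `shape|doped|coating` where `doped` is the
#' dopant element or `"undoped"` and `coating` is `"coated"`/`"uncoated"`.
#'
#' @param records Data frame with `shape`, `dopant_element`, `has_coating`
#'   columns, or individual vectors via the other arguments.
#' @param shape,dopant_element,has_coating Vectors, used when `records` is
#'   missing.
#' @return Character vector of labels.
#' @examples
#' build_stratify_label(shape = "sphere", dopant_element = "Zn", has_coating = 1)
#' @export
build_stratify_label <- function(records = NULL, shape = NULL,
                                 dopant_element = NULL, has_coating = NULL) {
  if (!is.null(records)) {
    shape <- records$shape
    dopant_element <- records$dopant_element
    has_coating <- records$has_coating
  }
  doped <- ifelse(dopant_element == "none", "undoped", dopant_element)
  coat <- ifelse(as.integer(has_coating) == 1L, "coated", "uncoated")
  paste(shape, doped, coat, sep = "|")
}

#' Five-step class weights from stratification labels
#'
#' @param labels Nonempty character vector of class labels.
#' @return Named numeric vector of per-class weights; every weight >= 1 and
#'   the most frequent class has weight exactly 1.
#' @examples
#' compute_class_weights(rep(c("A", "B"), c(100, 10)))
#' @export
compute_class_weights <- function(labels) {
  if (length(labels) == 0L) stopf("labels must be nonempty")
  counts <- table(labels)
  w <- 1 / as.numeric(counts)           # step 1: reciprocal counts
  w <- w / min(w)                       # step 2: normalize by minimum
  w <- log1p(w)                         # step 3: damp extremes
  w <- w / min(w)                       # step 4: renormalize by minimum
  stats::setNames(w, names(counts))     # step 5: assign by label
}

#' Stratified train/validation/calibration/test split
#'
#' Splits rows into the four subsets with fractions 0.70/0.10/0.10/0.10,
#' preserving the per-label proportions up to integer rounding (controlled
#' rounding: each label's subset counts are within 1 of the exact proportion
#' while the global subset totals equal the largest-remainder apportionment
#' of n, e.g. exactly 700/100/100/100 for n = 1000). Labels with fewer than
#' `min_label_size` members are pooled into a `"rare"` stratum before
#' splitting, since a four-way stratified split needs at least four members.
#'
#' @param labels Character vector of stratification labels (one per row).
#' @param seed Integer RNG seed (default 42); identical seeds give identical
#'   assignments.
#' @param fractions Subset fractions, must sum to 1.
#' @param min_label_size Labels below this size are pooled into `"rare"`.
#' @return An object of class `stratified_split`: a data frame with `row`,
#'   `label` (possibly pooled), `weight` and `subset` (factor with levels
#'   train/validation/calibration/test).
#' @export
stratified_split <- function(labels, seed = 42,
                             fractions = c(train = 0.70, validation = 0.10,
                                           calibration = 0.10, test = 0.10),
                             min_label_size = 4L) {
  n <- length(labels)
  if (n < 10L) stopf("need at least 10 rows to split, got %d", n)
  if (abs(sum(fractions) - 1) > 1e-8) stopf("fractions must sum to 1")
  subsets <- names(fractions)
  counts <- table(labels)
  rare <- names(counts)[counts < min_label_size]
  lab <- ifelse(labels %in% rare, "rare", labels)
  wmap <- compute_class_weights(lab)
  assignment <- character(n)
  lab_sizes <- vapply(sort(unique(lab)), function(lv) sum(lab == lv), integer(1))
  alloc <- controlled_round(lab_sizes, fractions)
  with_seed(seed, {
    for (lv in rownames(alloc)) {
      idx <- sample(which(lab == lv))
      assignment[idx] <- rep(subsets, times = alloc[lv, ])
    }
  })
  structure(
    data.frame(
      row = seq_len(n), label = lab, weight = unname(wmap[lab]),
      subset = factor(assignment, levels = subsets),
      stringsAsFactors = FALSE
    ),
    class = c("stratified_split", "data.frame"),
    seed = seed
  )
}

#' Subset row indices from a split
#'
#' @param split A [stratified_split()] result.
#' @param subset One of `"train"`, `"validation"`, `"calibration"`, `"test"`.
#' @return Integer row indices.
#' @export
split_rows <- function(split, subset) {
  split$row[split$subset == subset]
}

# ---- scaling and target transform ------------------------------------------

yj_forward <- function(y, lambda) {
  out <- numeric(length(y))
  pos <- y >= 0
  if (abs(lambda) > 1e-12) {
    out[pos] <- ((y[pos] + 1)^lambda - 1) / lambda
  } else {
    out[pos] <- log1p(y[pos])
  }
  if (any(!pos)) {
    l2 <- 2 - lambda
    if (abs(l2) > 1e-12) {
      out[!pos] <- -((1 - y[!pos])^l2 - 1) / l2
    } else {
      out[!pos] <- -log1p(-y[!pos])
    }
  }
  out
}

yj_inverse <- function(z, lambda) {
  out <- numeric(length(z))
  pos <- z >= 0
  if (abs(lambda) > 1e-12) {
    out[pos] <- (lambda * z[pos] + 1)^(1 / lambda) - 1
  } else {
    out[pos] <- expm1(z[pos])
  }
  if (any(!pos)) {
    l2 <- 2 - lambda
    if (abs(l2) > 1e-12) {
      out[!pos] <- 1 - (1 - l2 * z[!pos])^(1 / l2)
    } else {
      out[!pos] <- -expm1(-z[!pos])
    }
  }
  out
}

#' Fit the feature scaler and target transform on the training subset
#'
#' Features are affinely mapped to [-1, 1] from the training minima/maxima
#' (a value outside the training range maps outside [-1, 1]); zero-range
#' features map to the constant 0 with a warning. The SAR target is
#' transformed by a Yeo-Johnson power transform whose exponent lambda is
#' fitted on the training target by maximum likelihood. Fitting on the
#' training subset only prevents leakage of test statistics.
#'
#' @param train_table Feature table (or plain data frame with the schema
#'   columns) of training rows.
#' @return An object of class `scaler_state` with the per-feature ranges and
#'   the fitted `lambda`.
#' @export
fit_feature_scaler <- function(train_table) {
  sch <- feature_schema()
  X <- as.data.frame(train_table)[, sch$features, drop = FALSE]
  if (nrow(X) == 0L) stopf("training subset is empty")
  mins <- vapply(X, min, numeric(1))
  maxs <- vapply(X, max, numeric(1))
  degenerate <- maxs - mins <= 0
  if (any(degenerate)) {
    warning(sprintf("zero-range feature(s) mapped to constant 0: %s",
                    paste(names(X)[degenerate], collapse = ", ")),
            call. = FALSE)
  }
  y <- as.data.frame(train_table)[[sch$target]]
  lambda <- as.numeric(car::powerTransform(y, family = "yjPower")$lambda)
  structure(
    list(mins = mins, maxs = maxs, degenerate = degenerate, lambda = lambda,
         features = sch$features, target = sch$target),
    class = "scaler_state"
  )
}

#' Apply a fitted scaler to a table
#'
#' @param scaler A [fit_feature_scaler()] result.
#' @param table Feature table to transform.
#' @return List with `X` (scaled feature matrix) and `y` (transformed target,
#'   or `NULL` when the target column is absent).
#' @export
transform_features <- function(scaler, table) {
  stopifnot(inherits(scaler, "scaler_state"))
  df <- as.data.frame(table)
  X <- as.matrix(df[, scaler$features, drop = FALSE])
  storage.mode(X) <- "double"
  rng <- scaler$maxs - scaler$mins
  for (j in seq_along(scaler$features)) {
    X[, j] <- if (scaler$degenerate[j]) {
      0
    } else {
      2 * (X[, j] - scaler$mins[j]) / rng[j] - 1
    }
  }
  y <- NULL
  if (scaler$target %in% names(df)) {
    y <- yj_forward(df[[scaler$target]], scaler$lambda)
  }
  list(X = X, y = y)
}

#' Transform a target vector with a fitted scaler
#'
#' @param scaler A `scaler_state`.
#' @param y SAR values in W/g.
#' @return Transformed target values.
#' @export
transform_target <- function(scaler, y) yj_forward(y, scaler$lambda)

#' Invert the target transform back to W/g
#'
#' @param scaler A `scaler_state`.
#' @param z Transformed target values.
#' @return SAR values in original units (W/g).
#' @export
inverse_target <- function(scaler, z) yj_inverse(z, scaler$lambda)

#' Fit scaler on train and transform all subsets
#'
#' @param train_table Training feature table.
#' @param ... Further feature tables (named) to transform with the same
#'   scaler.
#' @return List with `scaler`, `train` (transformed) and one transformed
#'   entry per `...` argument.
#' @export
fit_transform_features <- function(train_table, ...) {
  scaler <- fit_feature_scaler(train_table)
  others <- list(...)
  out <- c(
    list(scaler = scaler, train = transform_features(scaler, train_table)),
    lapply(others, transform_features, scaler = scaler)
  )
  out
}
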