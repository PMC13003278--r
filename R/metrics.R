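# Regression metrics and diagnostics. All headline metrics are computed on
# inverse-transformed (original W/g) values by the pipeline; the formulas
# here are scale-agnostic.

#' Weighted root-mean-squared error
#'
#' `sqrt(sum(w * (y - yhat)^2) / sum(w))`; reduces to RMSE under uniform
#' weights and is invariant to rescaling the weights.
#'
#' @param y Observed values.
#' @param yhat Predicted values.
#' @param w Nonnegative weights, not all zero (default uniform).
#' @return Nonnegative scalar.
#' @export
wrmse <- function(y, yhat, w = NULL) {
  if (length(y) != length(yhat)) stopf("y and yhat must have equal length")
  if (is.null(w)) w <- rep(1, length(y))
  if (length(w) != length(y)) stopf("w must match y in length")
  if (any(w < 0) || sum(w) == 0) stopf("weights must be >= 0 and not all zero")
  sqrt(sum(w * (y - yhat)^2) / sum(w))
}

#' Regression metric report
#'
#' R-squared, MAE, MedAE, RMSE, weighted RMSE and the standard deviation of
#' the absolute errors (population form). Metrics other than R-squared share
#' the units of `y`.
#'
#' @param y Observed values (length >= 2).
#' @param yhat Predicted values.
#' @param w Weights for the wRMSE component (default uniform).
#' @return A one-row data frame: `r2`, `mae`, `medae`, `rmse`, `wrmse`,
#'   `ae_sd`.
#' @examples
#' compute_metrics(c(0, 2), c(0, 0), w = c(1, 3))
#' @export
compute_metrics <- function(y, yhat, w = NULL) {
  if (length(y) != length(yhat)) stopf("y and yhat must have equal length")
  if (length(y) < 2L) stopf("need at least 2 observations")
  ae <- abs(y - yhat)
  ss_res <- sum((y - yhat)^2)
  ss_tot <- sum((y - mean(y))^2)
  data.frame(
    r2 = 1 - ss_res / ss_tot,
    mae = mean(ae),
    medae = stats::median(ae),
    rmse = sqrt(mean(ae^2)),
    wrmse = wrmse(y, yhat, w),
    ae_sd = sqrt(mean((ae - mean(ae))^2))
  )
}

#' Check that wRMSE reduces to RMSE under uniform weights
#'
#' @param y,yhat Numeric vectors.
#' @param tol Tolerance (default 1e-12).
#' @return TRUE when the identity holds to `tol`.
#' @export
wrmse_equals_rmse_check <- function(y, yhat, tol = 1e-12) {
  abs(wrmse(y, yhat) - sqrt(mean((y - yhat)^2))) <= tol
}

#' Mean k-fold cross-validated R-squared
#'
#' Seeded k-fold partition of the training rows; the family is refit on each
#' training complement and scored by R-squared on the held-out fold.
#'
#' @param family Family id.
#' @param params Hyperparameters (defaults where missing).
#' @param X Feature matrix.
#' @param y Target vector.
#' @param w Optional weights passed to fitting.
#' @param k Number of folds (2 <= k <= n).
#' @param seed Integer seed.
#' @return Mean held-fold R-squared.
#' @export
kfold_cv_r2 <- function(family, params = list(), X, y, w = NULL, k = 5,
                        seed = 1) {
  n <- nrow(X)
  if (k < 2) stopf("k must be >= 2")
  if (k > n) stopf("k must not exceed the number of rows")
  if (is.null(w)) w <- rep(1, n)
  with_seed(seed, {
    folds <- sample(rep(seq_len(k), length.out = n))
    scores <- vapply(seq_len(k), function(fold) {
      hold <- folds == fold
      m <- train_final(family, params, X[!hold, , drop = FALSE], y[!hold],
                       w[!hold])
      yh <- predict(m, X[hold, , drop = FALSE])
      1 - sum((y[hold] - yh)^2) / sum((y[hold] - mean(y[hold]))^2)
    }, numeric(1))
    mean(scores)
  })
}

#' Intrinsic loss power
#'
#' `ILP = SAR / (H^2 * f)`; the field-normalized heating efficiency that
#' enables cross-study comparison. Units follow the inputs (with SAR in W/g,
#' H in A/m and f in Hz, ILP is in nH m^2 / kg up to the SI prefix).
#'
#' @param sar SAR values (>= 0).
#' @param H Field amplitude (> 0).
#' @param f Field frequency (> 0).
#' @return ILP values.
#' @export
compute_ilp <- function(sar, H, f) {
  if (any(H <= 0) || any(f <= 0)) stopf("H and f must be positive")
  sar / (H^2 * f)
}
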