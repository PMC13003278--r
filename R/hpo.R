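# Sequential model-based hyperparameter search with overfitting-gap trial
# selection.
#
# The sampler is a univariate tree-structured-Parzen-style estimator: after a
# random startup phase, observed trials are split into a "good" fraction
# (lowest validation wRMSE) and the rest; candidate values are drawn from a
# kernel density over the good values and ranked by the good/bad density
# ratio, independently per parameter. Every proposal is therefore conditioned
# on the full trial history, and the whole search is deterministic under a
# fixed seed.

sample_param <- function(spec) {
  switch(spec$type,
    num = {
      if (isTRUE(spec$log)) {
        exp(stats::runif(1, log(spec$lo), log(spec$hi)))
      } else {
        stats::runif(1, spec$lo, spec$hi)
      }
    },
    int = {
      if (isTRUE(spec$log)) {
        as.integer(round(exp(stats::runif(1, log(spec$lo), log(spec$hi)))))
      } else {
        as.integer(stats::runif(1, spec$lo, spec$hi + 1) %/% 1)
      }
    },
    cat = sample(spec$choices, 1)[[1]]
  )
}

random_params <- function(space) lapply(space, sample_param)

kde_score <- function(x, centers, bw) {
  rowMeans(vapply(centers, function(c0) stats::dnorm(x, c0, bw), numeric(length(x)))) +
    1e-12
}

tpe_param <- function(spec, good_vals, bad_vals, n_candidates = 24) {
  if (spec$type == "cat") {
    tab_g <- table(factor(unlist(good_vals), levels = spec$choices))
    tab_b <- table(factor(unlist(bad_vals), levels = spec$choices))
    pg <- (as.numeric(tab_g) + 1) / (sum(tab_g) + length(spec$choices))
    pb <- (as.numeric(tab_b) + 1) / (sum(tab_b) + length(spec$choices))
    cand <- sample(spec$choices, n_candidates, replace = TRUE, prob = pg)
    ratio <- (pg / pb)[match(cand, spec$choices)]
    return(cand[[which.max(ratio)]])
  }
  to_internal <- function(v) if (isTRUE(spec$log)) log(v) else v
  from_internal <- function(v) if (isTRUE(spec$log)) exp(v) else v
  lo <- to_internal(spec$lo)
  hi <- to_internal(spec$hi)
  g <- to_internal(as.numeric(unlist(good_vals)))
  b <- to_internal(as.numeric(unlist(bad_vals)))
  prior_bw <- (hi - lo) / 5
  bw_of <- function(v) {
    s <- stats::sd(v)
    if (!is.finite(s) || s < 1e-12) return(prior_bw)
    max(1.06 * s * length(v)^(-0.2), (hi - lo) / 100)
  }
  bw_g <- bw_of(g)
  centers <- g[sample.int(length(g), n_candidates, replace = TRUE)]
  cand <- pmin(pmax(stats::rnorm(n_candidates, centers, bw_g), lo), hi)
  lx <- kde_score(cand, g, bw_g)
  gx <- if (length(b) > 0) kde_score(cand, b, bw_of(b)) else rep(1, n_candidates)
  best <- cand[which.max(lx / gx)]
  out <- min(max(from_internal(best), spec$lo), spec$hi)
  if (spec$type == "int") out <- as.integer(max(spec$lo, min(spec$hi, round(out))))
  out
}

suggest_params <- function(space, history_params, history_obj,
                           n_startup = 10, gamma = 0.25, n_candidates = 24) {
  n <- length(history_obj)
  if (n < n_startup) return(random_params(space))
  n_good <- max(2L, ceiling(gamma * n))
  ord <- order(history_obj)
  good <- ord[seq_len(n_good)]
  bad <- ord[-seq_len(n_good)]
  out <- list()
  for (nm in names(space)) {
    gv <- lapply(history_params[good], `[[`, nm)
    bv <- lapply(history_params[bad], `[[`, nm)
    out[[nm]] <- tpe_param(space[[nm]], gv, bv, n_candidates)
  }
  out
}

#' Sequential model-based hyperparameter search
#'
#' Runs `n_trials` trials of the family on the training subset, scoring each
#' by weighted RMSE (wRMSE) on the validation subset; proposals after a
#' random startup phase are drawn from a Parzen-estimator sampler conditioned
#' on the trial history. The boosting families additionally early-stop each
#' trial's boosting when validation wRMSE fails to improve for the family's
#' patience (20 rounds for the depth-wise and DART variants, 30 for the
#' leaf-wise one). Deterministic under a fixed seed.
#'
#' @param family Family id from [model_families()].
#' @param train,val Lists with elements `X` (feature matrix) and `y` (target
#'   on the transformed scale), e.g. from [transform_features()].
#' @param weights_train,weights_val Per-row class weights (default 1).
#' @param n_trials Number of trials (>= 1). 100 is a desk-scale default;
#'   full-scale studies use 1000.
#' @param seed Integer seed.
#' @param space Search space; defaults to [family_search_space()].
#' @param n_startup Random trials before the model-based sampler engages.
#' @return An object of class `hpo_trials`: a data frame with one row per
#'   trial (`trial`, `wrmse_train`, `wrmse_val`, `gap`), the per-trial
#'   parameter lists in attribute `"params"`, and the family/space in
#'   attributes.
#' @export
run_search <- function(family, train, val, weights_train = NULL,
                       weights_val = NULL, n_trials = 100, seed = 1,
                       space = NULL, n_startup = 10) {
  fam <- get_family(family)
  if (is.null(space)) space <- fam$space
  if (length(space) == 0L) stopf("search space is empty")
  if (!is_number(n_trials) || n_trials < 1) stopf("n_trials must be >= 1")
  if (is.null(weights_train)) weights_train <- rep(1, nrow(train$X))
  if (is.null(weights_val)) weights_val <- rep(1, nrow(val$X))
  params_hist <- vector("list", n_trials)
  obj <- numeric(n_trials)
  wrmse_tr <- numeric(n_trials)
  with_seed(seed, {
    for (t in seq_len(n_trials)) {
      params <- suggest_params(space, params_hist[seq_len(t - 1L)],
                               obj[seq_len(t - 1L)], n_startup = n_startup)
      model <- train_final(family, params, train$X, train$y, weights_train,
                           Xval = val$X, yval = val$y)
      wrmse_tr[t] <- wrmse(train$y, predict(model, train$X), weights_train)
      obj[t] <- wrmse(val$y, predict(model, val$X), weights_val)
      params_hist[[t]] <- params
    }
  })
  out <- data.frame(
    trial = seq_len(n_trials),
    wrmse_train = wrmse_tr,
    wrmse_val = obj,
    gap = obj - wrmse_tr
  )
  structure(out, class = c("hpo_trials", "data.frame"),
            params = params_hist, family = family, space = space)
}

#' Parameters of a given trial
#'
#' @param trials An `hpo_trials` object.
#' @param trial Trial index.
#' @return Named list of hyperparameters.
#' @export
trial_params <- function(trials, trial) attr(trials, "params")[[trial]]

#' Gap-based selection of the best trial
#'
#' Four steps: (1) find the lowest validation wRMSE and set a threshold 10%
#' above it; (2) keep only trials whose validation wRMSE is within the
#' threshold; (3) sort the survivors by overfitting gap (validation minus
#' training wRMSE, taken in absolute value so that underfitting flukes with
#' large negative gaps are not rewarded); (4) return the trial with the
#' smallest gap, ties broken by trial index. With `mode = "top_fraction"`
#' step (1)-(2) instead keep the best 10% of trials by validation wRMSE.
#'
#' @param trials An `hpo_trials` object or a data frame with `trial`,
#'   `wrmse_train`, `wrmse_val` columns.
#' @param threshold_factor Multiplier on the best validation wRMSE
#'   (default 1.1).
#' @param mode `"threshold"` (default) or `"top_fraction"`.
#' @param top_fraction Fraction kept under `mode = "top_fraction"`.
#' @return One-row data frame for the selected trial, with the trial's
#'   parameters in attribute `"params"` when available.
#' @export
select_best_trial <- function(trials, threshold_factor = 1.1,
                              mode = c("threshold", "top_fraction"),
                              top_fraction = 0.1) {
  mode <- match.arg(mode)
  df <- as.data.frame(trials)
  if (nrow(df) == 0L) stopf("no trials")
  keep <- if (mode == "threshold") {
    thr <- min(df$wrmse_val) * threshold_factor
    which(df$wrmse_val <= thr)
  } else {
    ord <- order(df$wrmse_val, df$trial)
    sort(ord[seq_len(max(1L, ceiling(top_fraction * nrow(df))))])
  }
  cand <- df[keep, , drop = FALSE]
  gaps <- abs(cand$wrmse_val - cand$wrmse_train)
  sel <- cand[order(gaps, cand$trial)[1], , drop = FALSE]
  p <- attr(trials, "params")
  if (!is.null(p)) attr(sel, "params") <- p[[sel$trial]]
  sel
}

#' Choose the training epoch count from a learning curve
#'
#' Restricted to `search_range` (where the validation loss has plateaued),
#' returns the epoch minimizing the absolute train/validation wRMSE gap;
#' ties resolve to the earliest such epoch.
#'
#' @param learning_curve Data frame with columns `epoch`, `wrmse_train`,
#'   `wrmse_val`.
#' @param search_range Length-2 numeric `c(lo, hi)`, inclusive.
#' @return The selected epoch (integer).
#' @export
choose_epochs <- function(learning_curve, search_range = c(400, 590)) {
  stopifnot(is.data.frame(learning_curve),
            all(c("epoch", "wrmse_train", "wrmse_val") %in% names(learning_curve)))
  lo <- search_range[1]
  hi <- search_range[2]
  inside <- learning_curve$epoch >= lo & learning_curve$epoch <= hi
  covered <- any(learning_curve$epoch <= lo) && any(learning_curve$epoch >= hi)
  if (!any(inside) || !covered) {
    stopf("learning curve does not cover the search range [%g, %g]", lo, hi)
  }
  cur <- learning_curve[inside, ]
  gap <- abs(cur$wrmse_val - cur$wrmse_train)
  as.integer(cur$epoch[order(gap, cur$epoch)[1]])
}
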