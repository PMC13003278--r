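# Redundancy analysis and model interpretation: Spearman correlation
# clustering, permutation importance, Shapley attributions and impact
# categories.

#' Spearman correlation matrix over predictive features
#'
#' Rank-based correlation with average ranks for ties. Entries involving a
#' constant column are `NA` and the column is flagged.
#'
#' @param X Numeric matrix or data frame (>= 3 rows).
#' @return Correlation matrix with attribute `"constant"` (names of
#'   zero-variance columns).
#' @export
spearman_matrix <- function(X) {
  X <- as.matrix(X)
  if (nrow(X) < 3L) stopf("need at least 3 rows")
  sds <- apply(X, 2, stats::sd)
  const <- colnames(X)[sds == 0]
  rho <- suppressWarnings(stats::cor(X, method = "spearman"))
  diag(rho) <- 1
  attr(rho, "constant") <- const
  rho
}

# Pairwise minimum |rho| within a set of features.
min_abs_rho <- function(rho, members) {
  sub <- abs(rho[members, members, drop = FALSE])
  min(sub[upper.tri(sub)])
}

#' Cluster highly correlated features
#'
#' Minimum-variance (Ward) agglomeration on the distance `1 - |rho|` (so that
#' strong negative correlations also group; set `absolute = FALSE` for
#' `1 - rho`). Reported clusters are the maximal dendrogram nodes whose
#' members are all pairwise correlated at `|rho| >= threshold`.
#'
#' @param rho Correlation matrix (e.g. [spearman_matrix()]); constant-column
#'   `NA` rows/columns are dropped.
#' @param threshold Absolute-correlation threshold (default 0.7).
#' @param absolute Use `|rho|` in the distance and the threshold test.
#' @return List of character vectors (feature ids), possibly empty.
#' @export
cluster_correlated <- function(rho, threshold = 0.7, absolute = TRUE) {
  keep <- colnames(rho)[colSums(is.na(rho)) < nrow(rho) - 1]
  rho <- rho[keep, keep, drop = FALSE]
  if (anyNA(rho)) {
    ok <- !apply(rho, 1, anyNA)
    rho <- rho[ok, ok, drop = FALSE]
  }
  p <- ncol(rho)
  if (p < 2L) return(list())
  sim <- if (absolute) abs(rho) else rho
  d <- stats::as.dist(1 - sim)
  hc <- stats::hclust(d, method = "ward.D2")
  merge <- hc$merge
  n_nodes <- nrow(merge)
  members <- vector("list", n_nodes)
  node_members <- function(i) {
    if (i < 0) colnames(rho)[-i] else members[[i]]
  }
  qualifies <- logical(n_nodes)
  for (i in seq_len(n_nodes)) {
    members[[i]] <- c(node_members(merge[i, 1]), node_members(merge[i, 2]))
    sub <- sim[members[[i]], members[[i]]]
    qualifies[i] <- min(sub[upper.tri(sub)]) >= threshold
  }
  parent <- rep(NA_integer_, n_nodes)
  for (i in seq_len(n_nodes)) {
    for (j in merge[i, ]) if (j > 0) parent[j] <- i
  }
  maximal <- which(qualifies &
                     vapply(seq_len(n_nodes), function(i) {
                       is.na(parent[i]) || !qualifies[parent[i]]
                     }, logical(1)))
  lapply(maximal, function(i) members[[i]])
}

#' Permutation importance of each feature
#'
#' Mean increase in RMSE over `n_repeats` random shuffles of each feature
#' column, with the standard deviation over repeats. Features the model does
#' not use score (near) zero.
#'
#' @param predictor Function mapping a feature matrix to predictions, on the
#'   same scale as `y`.
#' @param X Feature matrix.
#' @param y Target values.
#' @param n_repeats Shuffles per feature (default 10).
#' @param seed Integer seed.
#' @return Data frame `feature`, `importance`, `sd`, sorted by importance.
#' @export
permutation_importance <- function(predictor, X, y, n_repeats = 10, seed = 1) {
  X <- as.matrix(X)
  base_rmse <- sqrt(mean((y - predictor(X))^2))
  with_seed(seed, {
    imp <- matrix(NA_real_, nrow = n_repeats, ncol = ncol(X))
    for (r in seq_len(n_repeats)) {
      perm <- sample(nrow(X))
      for (j in seq_len(ncol(X))) {
        Xp <- X
        Xp[, j] <- X[perm, j]
        imp[r, j] <- sqrt(mean((y - predictor(Xp))^2)) - base_rmse
      }
    }
    out <- data.frame(
      feature = colnames(X),
      importance = colMeans(imp),
      sd = apply(imp, 2, stats::sd),
      stringsAsFactors = FALSE
    )
    out[order(-out$importance), ]
  })
}

#' Shapley attributions by permutation sampling
#'
#' Monte-Carlo Shapley values of `predictor` at each explained row, against a
#' background sample: for each of `n_perm` (permutation, background row)
#' pairs - fixed across explained rows - features are switched one by one
#' from the background value to the explained value and the marginal
#' prediction changes are credited to the switched feature. Because the
#' telescoping sums are exact, local accuracy (base value plus attribution
#' sum equals the prediction) holds to floating-point precision for every
#' row; the attribution values themselves converge to exact Shapley values as
#' `n_perm` grows and are exact for additive (e.g. linear) predictors at any
#' `n_perm`. Attributions are in the units of the predictor's output; the
#' pipeline explains inverse-transformed predictions so values are in W/g.
#'
#' @param predictor Function mapping a feature matrix to predictions.
#' @param X_background Background feature matrix (subsampled to
#'   `max_background` rows).
#' @param X_explain Rows to explain.
#' @param n_perm Number of (permutation, background) pairs (default 32).
#' @param seed Integer seed.
#' @param max_background Cap on background rows (default 500).
#' @return An object of class `attribution_report`: list with `base` (scalar
#'   base value), `phi` (matrix rows x features, W/g), `prediction`
#'   (per-row prediction), `mean_abs` (named per-feature mean absolute
#'   attribution, sorted), `categories` (impact category per feature).
#' @export
shapley_attributions <- function(predictor, X_background, X_explain,
                                 n_perm = 32, seed = 1, max_background = 500) {
  X_background <- as.matrix(X_background)
  X_explain <- as.matrix(X_explain)
  p <- ncol(X_explain)
  n <- nrow(X_explain)
  with_seed(seed, {
    if (nrow(X_background) > max_background) {
      X_background <- X_background[sample(nrow(X_background), max_background), ,
                                   drop = FALSE]
    }
    perms <- replicate(n_perm, sample.int(p), simplify = FALSE)
    bg_idx <- sample.int(nrow(X_background), n_perm, replace = TRUE)
    phi <- matrix(0, nrow = n, ncol = p, dimnames = list(NULL, colnames(X_explain)))
    base_acc <- 0
    for (k in seq_len(n_perm)) {
      ord <- perms[[k]]
      bg <- X_background[bg_idx[k], ]
      # stack of n * (p + 1) rows: background -> progressively switched to x
      Z <- matrix(rep(bg, each = n * (p + 1L)), nrow = n * (p + 1L))
      colnames(Z) <- colnames(X_explain)
      for (step in seq_len(p)) {
        j <- ord[step]
        rows <- (n * step + 1L):(n * (p + 1L))
        Z[rows, j] <- rep(X_explain[, j], times = p + 1L - step)
      }
      f <- predictor(Z)
      fm <- matrix(f, nrow = n) # column s = prediction after s - 1 switches
      base_acc <- base_acc + mean(fm[, 1])
      for (step in seq_len(p)) {
        j <- ord[step]
        phi[, j] <- phi[, j] + (fm[, step + 1L] - fm[, step]) / n_perm
      }
    }
    base <- base_acc / n_perm
    pred <- base + rowSums(phi)
    mean_abs <- sort(colMeans(abs(phi)), decreasing = TRUE)
    categories <- if (sum(mean_abs) > 0) {
      categorize_impact(mean_abs)
    } else { # constant predictor: nothing contributes
      stats::setNames(
        factor(rep("negligible", length(mean_abs)),
               levels = c("considerable", "moderate", "weak", "negligible")),
        names(mean_abs)
      )
    }
    structure(
      list(base = base, phi = phi, prediction = pred, mean_abs = mean_abs,
           categories = categories),
      class = "attribution_report"
    )
  })
}

#' @exportS3Method base::print
print.attribution_report <- function(x, ...) {
  cat(sprintf("<attribution_report> %d rows, base value %.3f\n",
              nrow(x$phi), x$base))
  top <- utils::head(x$mean_abs, 5)
  cat("  top features (mean |attribution|):\n")
  for (nm in names(top)) {
    cat(sprintf("    %-28s %10.3f  [%s]\n", nm, top[[nm]], x$categories[[nm]]))
  }
  invisible(x)
}

#' Impact category of per-feature attribution magnitudes
#'
#' Shares of the total mean absolute attribution are banded as considerable
#' (> 10%), moderate (5-10%), weak (1.5-5%) and negligible (< 1.5%); band
#' boundaries are lower-inclusive (a share of exactly 5% is moderate). With
#' attributions in W/g the corresponding absolute bands quoted alongside are
#' > 35, 15-35, 5-15 and < 5 W/g.
#'
#' @param mean_abs Named vector of per-feature mean absolute attributions.
#' @param total Normalizing total (default `sum(mean_abs)`); must be > 0.
#' @return Named factor with levels considerable/moderate/weak/negligible.
#' @export
categorize_impact <- function(mean_abs, total = sum(mean_abs)) {
  if (total <= 0) stopf("total must be positive")
  share <- mean_abs / total
  lab <- ifelse(share > 0.10, "considerable",
                ifelse(share >= 0.05, "moderate",
                       ifelse(share >= 0.015, "weak", "negligible")))
  stats::setNames(
    factor(lab, levels = c("considerable", "moderate", "weak", "negligible")),
    names(mean_abs)
  )
}

#' Attribution dependence profile of one feature
#'
#' @param feature Feature name.
#' @param report An `attribution_report`.
#' @param X The explained feature matrix (same rows as the report).
#' @return Data frame `value`, `attribution`, sorted by `value`.
#' @export
dependence_profile <- function(feature, report, X) {
  X <- as.matrix(X)
  if (!feature %in% colnames(X)) stopf("feature '%s' not in table", feature)
  out <- data.frame(value = X[, feature], attribution = report$phi[, feature])
  out[order(out$value), ]
}
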