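test_that("Spearman matrix honours rank-correlation identities", {
  set.seed(31)
  x <- rnorm(1000)
  X <- cbind(a = x, b = -x, c = x^3, d = rnorm(1000), e = rnorm(1000))
  rho <- spearman_matrix(X)
  expect_equal(rho["a", "a"], 1)
  expect_equal(rho["a", "b"], -1)
  expect_equal(rho["a", "c"], 1) # monotone invariance
  expect_lt(abs(rho["d", "e"]), 0.1)
  expect_error(spearman_matrix(X[1:2, ]), "3 rows")

  Xc <- cbind(X, f = rep(1, 1000))
  rc <- spearman_matrix(Xc)
  expect_identical(attr(rc, "constant"), "f")
  expect_true(all(is.na(rc["f", setdiff(colnames(Xc), "f")])))
})

test_that("correlated features cluster together, orthogonal ones do not", {
  set.seed(32)
  n <- 600
  base <- rnorm(n)
  X <- cbind(
    v1 = base + rnorm(n, 0, 0.05), # mutually |rho| >= 0.96 triple
    v2 = base + rnorm(n, 0, 0.05),
    v3 = base + rnorm(n, 0, 0.05),
    neg = -base + rnorm(n, 0, 0.6), # strong negative partner (~ -0.77)
    ind1 = rnorm(n),
    ind2 = rnorm(n)
  )
  rho <- spearman_matrix(X)
  expect_true(all(abs(rho[c("v1", "v2", "v3"), c("v1", "v2", "v3")]) >= 0.96))
  cl <- cluster_correlated(rho, threshold = 0.7)
  hit <- Filter(function(g) all(c("v1", "v2", "v3") %in% g), cl)
  expect_length(hit, 1L)
  expect_false(any(c("ind1", "ind2") %in% unlist(cl)))
  # the negatively correlated partner joins under the |rho| rule ...
  expect_true(abs(rho["v1", "neg"]) >= 0.7)
  expect_true("neg" %in% unlist(cluster_correlated(rho, threshold = 0.7)))
  # ... but not under the signed rule
  cl_signed <- cluster_correlated(rho, threshold = 0.7, absolute = FALSE)
  expect_false("neg" %in% unlist(cl_signed))

  ortho <- spearman_matrix(matrix(rnorm(600 * 4), 600,
                                  dimnames = list(NULL, paste0("o", 1:4))))
  expect_length(cluster_correlated(ortho, threshold = 0.7), 0L)
})

test_that("permutation importance is null for unused and noise features", {
  set.seed(33)
  n <- 400
  X <- cbind(used = runif(n, -1, 1), unused = runif(n, -1, 1),
             noise = runif(n, -1, 1))
  y <- ifelse(X[, "used"] > 0, 5, -5)
  m <- train_final("decision_tree", list(maxdepth = 1, cp = 1e-6), X, y)
  predictor <- function(X) predict(m, X)
  imp <- permutation_importance(predictor, X, y, n_repeats = 10, seed = 1)
  expect_equal(imp$importance[imp$feature == "unused"], 0)
  expect_gt(imp$importance[imp$feature == "used"], 1)
  # noise feature in a fitted boosting model stays within 2 sd of zero
  yb <- X[, "used"]^2 + rnorm(n, 0, 0.05)
  mb <- train_final("gb_depthwise", fast_gb_params, X, yb)
  impb <- permutation_importance(function(X) predict(mb, X), X, yb,
                                 n_repeats = 10, seed = 2)
  row <- impb[impb$feature == "noise", ]
  expect_lt(abs(row$importance), 2 * row$sd + 0.02)
  # determinism
  imp2 <- permutation_importance(predictor, X, y, n_repeats = 10, seed = 1)
  expect_identical(imp, imp2)
})

test_that("attributions are exactly additive and vanish for constant models", {
  set.seed(34)
  X <- matrix(runif(300, -1, 1), 100, 3, dimnames = list(NULL, c("a", "b", "c")))
  rep0 <- shapley_attributions(function(X) rep(7, nrow(X)), X, X[1:10, ],
                               n_perm = 8, seed = 1)
  expect_equal(max(abs(rep0$phi)), 0)
  expect_equal(rep0$base, 7)

  f <- function(X) 2 * X[, 1] - 3 * X[, 2] + 0.5 * X[, 1] * X[, 3]
  rep1 <- shapley_attributions(f, X, X, n_perm = 16, seed = 2)
  expect_lt(max(abs(rep1$prediction - f(X))), 1e-6) # local accuracy, 100 rows
})

test_that("linear-model attributions match exhaustive-subset Shapley values", {
  coefs <- c(a = 2, b = -1.5, c = 0.7)
  f <- function(X) as.numeric(X %*% coefs) + 4
  bg <- matrix(c(0.3, -0.2, 0.8), nrow = 1,
               dimnames = list(NULL, names(coefs)))
  set.seed(35)
  Xe <- matrix(runif(15, -1, 1), 5, 3, dimnames = list(NULL, names(coefs)))

  # brute-force Shapley over all 2^3 feature subsets against the background
  brute <- function(x) {
    p <- 3
    phi <- numeric(p)
    subsets <- expand.grid(rep(list(c(FALSE, TRUE)), p))
    val <- function(mask) {
      z <- bg[1, ]
      z[mask] <- x[mask]
      f(matrix(z, 1))
    }
    for (j in seq_len(p)) {
      for (si in seq_len(nrow(subsets))) {
        S <- as.logical(subsets[si, ])
        if (S[j]) next
        wgt <- factorial(sum(S)) * factorial(p - sum(S) - 1) / factorial(p)
        Sj <- S
        Sj[j] <- TRUE
        phi[j] <- phi[j] + wgt * (val(Sj) - val(S))
      }
    }
    phi
  }
  rep1 <- shapley_attributions(f, bg, Xe, n_perm = 12, seed = 3)
  for (i in 1:5) {
    expect_equal(unname(rep1$phi[i, ]), brute(Xe[i, ]), tolerance = 1e-10)
  }
  # closed form for a linear model: coefficient times displacement
  expect_equal(unname(rep1$phi[1, ]),
               unname(coefs * (Xe[1, ] - bg[1, ])), tolerance = 1e-10)

  # multi-row background: sampled-background mean converges on the closed form
  set.seed(36)
  bg_big <- matrix(rnorm(3 * 200, 0, 0.5), 200, 3,
                   dimnames = list(NULL, names(coefs)))
  rep2 <- shapley_attributions(f, bg_big, Xe, n_perm = 200, seed = 4)
  closed <- sweep(Xe, 2, colMeans(bg_big)) %*% diag(coefs)
  expect_lt(max(abs(rep2$phi - closed)), 0.2)
})

test_that("impact categories follow the lower-inclusive share bands", {
  ma <- c(a = 12, b = 5, c = 3, d = 0.5) # total 20.5 - use explicit total
  cat1 <- categorize_impact(c(a = 12, b = 88))
  expect_equal(as.character(cat1[["a"]]), "considerable")
  shares <- c(big = 0.12, mid = 0.05, low = 0.02, tiny = 0.005, edge = 0.10)
  cats <- categorize_impact(shares, total = 1)
  expect_equal(as.character(cats[["big"]]), "considerable")
  expect_equal(as.character(cats[["mid"]]), "moderate") # exactly 5% -> moderate
  expect_equal(as.character(cats[["edge"]]), "moderate") # exactly 10% -> moderate
  expect_equal(as.character(cats[["low"]]), "weak")
  expect_equal(as.character(cats[["tiny"]]), "negligible")
  expect_error(categorize_impact(c(a = 0), total = 0), "positive")
})

test_that("dependence profiles sort by feature value and keep all rows", {
  X <- matrix(c(3, 1, 2, 9, 8, 7), 3, 2, dimnames = list(NULL, c("u", "v")))
  rep1 <- shapley_attributions(function(X) X[, 1], X, X, n_perm = 4, seed = 1)
  prof <- dependence_profile("u", rep1, X)
  expect_equal(nrow(prof), 3L)
  expect_equal(prof$value, c(1, 2, 3))
  flat <- dependence_profile("v", shapley_attributions(function(X) rep(1, nrow(X)),
                                                       X, X, n_perm = 4, seed = 1), X)
  expect_true(all(flat$attribution == 0))
  expect_error(dependence_profile("w", rep1, X), "not in table")
})

test_that("the generator's field amplitude dominates a monotone dependence profile", {
  ds <- tiny_dataset(n = 600, seed = 9)
  tab <- build_feature_table(ds$records)
  scaler <- fit_feature_scaler(tab)
  tr <- transform_features(scaler, tab)
  m <- train_final("gb_depthwise", fast_gb_params, tr$X, tr$y)
  predictor <- function(X) inverse_target(scaler, predict(m, X))
  rep1 <- shapley_attributions(predictor, tr$X, tr$X[1:150, ], n_perm = 16,
                               seed = 5)
  prof <- dependence_profile("H", rep1, tr$X[1:150, ])
  expect_gt(cor(prof$value, prof$attribution, method = "spearman"), 0.5)
})
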