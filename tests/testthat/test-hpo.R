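test_that("gap selection reproduces the worked example and its tie rules", {
  trials <- data.frame(trial = 1:3,
                       wrmse_val = c(10, 10.5, 12),
                       wrmse_train = c(9, 10.4, 6))
  trials$gap <- trials$wrmse_val - trials$wrmse_train
  sel <- select_best_trial(trials)
  expect_equal(sel$trial, 2L) # threshold 11 keeps trials 1-2; gap 0.1 < 1.0

  one <- trials[1, ]
  expect_equal(select_best_trial(one)$trial, 1L)

  same <- data.frame(trial = 1:4, wrmse_val = rep(2, 4), wrmse_train = rep(1.5, 4))
  expect_equal(select_best_trial(same)$trial, 1L)
})

test_that("gap selection agrees with a brute-force oracle on random trial sets", {
  oracle <- function(df, factor = 1.1) {
    keep <- df[df$wrmse_val <= min(df$wrmse_val) * factor, ]
    keep <- keep[order(abs(keep$wrmse_val - keep$wrmse_train), keep$trial), ]
    keep$trial[1]
  }
  set.seed(11)
  for (i in 1:1000) {
    n <- sample(1:25, 1)
    df <- data.frame(trial = 1:n,
                     wrmse_val = round(rlnorm(n, 1, 0.5), sample(0:3, 1)),
                     wrmse_train = round(rlnorm(n, 1, 0.6), sample(0:3, 1)))
    sel <- select_best_trial(df)
    expect_equal(sel$trial, oracle(df))
    # the winner always satisfies the 1.1x threshold constraint
    expect_lte(sel$wrmse_val, min(df$wrmse_val) * 1.1 + 1e-12)
  }
})

test_that("the top-fraction selection mode filters by validation rank", {
  df <- data.frame(trial = 1:20,
                   wrmse_val = seq(1, 2, length.out = 20),
                   wrmse_train = rep(0.9, 20))
  sel <- select_best_trial(df, mode = "top_fraction", top_fraction = 0.1)
  expect_lte(sel$trial, 2L) # only the best ceiling(2) trials survive
})

test_that("search proposals stay inside the declared space", {
  space <- family_search_space("gb_depthwise")
  set.seed(2)
  hist_p <- list()
  hist_o <- numeric(0)
  for (i in 1:40) {
    p <- sarqspr:::suggest_params(space, hist_p, hist_o, n_startup = 10)
    for (nm in names(space)) {
      s <- space[[nm]]
      if (s$type %in% c("num", "int")) {
        expect_gte(p[[nm]], s$lo)
        expect_lte(p[[nm]], s$hi)
        if (s$type == "int") expect_equal(p[[nm]], round(p[[nm]]))
      }
    }
    hist_p[[i]] <- p
    hist_o <- c(hist_o, runif(1))
  }
})

test_that("run_search is deterministic, records every trial, and improves", {
  ds <- tiny_dataset(n = 400, seed = 5)
  tab <- build_feature_table(ds$records)
  scaler <- fit_feature_scaler(tab[1:280, ])
  tr <- transform_features(scaler, tab[1:280, ])
  va <- transform_features(scaler, tab[281:400, ])

  one <- run_search("decision_tree", tr, va, n_trials = 1, seed = 9)
  expect_equal(nrow(one), 1L)

  a <- run_search("decision_tree", tr, va, n_trials = 20, seed = 9)
  b <- run_search("decision_tree", tr, va, n_trials = 20, seed = 9)
  expect_identical(as.data.frame(a), as.data.frame(b))
  expect_true(all(a$wrmse_val >= 0) && all(a$wrmse_train >= 0))
  expect_equal(a$gap, a$wrmse_val - a$wrmse_train)

  # non-degradation: searched configuration beats the family defaults
  m_def <- train_final("decision_tree", list(), tr$X, tr$y)
  def_val <- wrmse(va$y, predict(m_def, va$X))
  expect_lte(min(a$wrmse_val), def_val + 1e-12)

  expect_error(run_search("decision_tree", tr, va, n_trials = 0), ">= 1")
  expect_error(run_search("decision_tree", tr, va, space = list()), "empty")
})

test_that("epoch choice minimizes the gap inside the plateau range", {
  curve <- data.frame(epoch = 1:600)
  curve$wrmse_train <- 1 / sqrt(curve$epoch)
  curve$wrmse_val <- curve$wrmse_train + abs(curve$epoch - 450) / 1000
  expect_equal(choose_epochs(curve, c(400, 590)), 450L)

  flat <- data.frame(epoch = 1:600, wrmse_train = 0.5, wrmse_val = 0.5)
  expect_equal(choose_epochs(flat, c(400, 590)), 400L) # ties -> earliest
  expect_equal(choose_epochs(flat, c(512, 512)), 512L)
  expect_error(choose_epochs(flat[1:100, ], c(400, 590)), "cover")
})
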