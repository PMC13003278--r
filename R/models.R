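# The twelve regression families.
#
# Families are established learners called through their packages; only the
# surrounding contract (hyperparameter spaces, weighted fitting, early
# stopping, persistence) is defined here. Per-row class weights are consumed
# by the fitting routine where the learner supports them (penalized linear
# models, trees, forests, boosting, the network); for kernel SVR, KNN and PLS
# the weights enter only the search objective (wRMSE).
#
# The three gradient-boosting families are distinct boosting variants:
# depth-wise tree growth, DART (dropout trees), and leaf-wise ("lossguide")
# growth. Early-stopping patience is 20 rounds for the first two and 30 for
# the leaf-wise family. The feed-forward family is a single-hidden-layer
# network with searched width and weight decay.

sp_num <- function(lo, hi, log = FALSE) list(type = "num", lo = lo, hi = hi, log = log)
sp_int <- function(lo, hi, log = FALSE) list(type = "int", lo = lo, hi = hi, log = log)
sp_cat <- function(choices) list(type = "cat", choices = choices)

xgb_fit <- function(extra_params, patience) {
  function(params, X, y, w, Xval = NULL, yval = NULL) {
    p <- c(list(objective = "reg:squarederror", nthread = 1), extra_params,
           params[setdiff(names(params), "nrounds")])
    dtrain <- xgboost::xgb.DMatrix(X, label = y, weight = w, nthread = 1)
    nrounds <- if (!is.null(params$nrounds)) params$nrounds else 600
    if (!is.null(Xval)) {
      dval <- xgboost::xgb.DMatrix(Xval, label = yval, nthread = 1)
      xgboost::xgb.train(params = p, data = dtrain, nrounds = nrounds,
                         evals = list(val = dval),
                         early_stopping_rounds = patience, verbose = 0)
    } else {
      xgboost::xgb.train(params = p, data = dtrain, nrounds = nrounds,
                         verbose = 0)
    }
  }
}

xgb_space <- function(extra = list()) {
  c(list(
    eta = sp_num(1e-3, 0.3, log = TRUE),
    max_depth = sp_int(2, 12),
    min_child_weight = sp_num(0.5, 20, log = TRUE),
    subsample = sp_num(0.5, 1),
    colsample_bytree = sp_num(0.5, 1),
    lambda = sp_num(1e-3, 10, log = TRUE)
  ), extra)
}

# glmnet requires >= 2 predictor columns; single-feature designs get a
# constant dummy column (coefficient shrinks to 0, predictions unaffected).
pad_single_column <- function(X) {
  if (ncol(X) >= 2L) return(X)
  cbind(X, `.pad` = 0)
}

glmnet_fit <- function(alpha_fixed = NULL) {
  function(params, X, y, w, Xval = NULL, yval = NULL) {
    alpha <- if (is.null(alpha_fixed)) params$alpha else alpha_fixed
    fit <- glmnet::glmnet(pad_single_column(X), y, alpha = alpha,
                          lambda = params$lambda, weights = w)
    list(fit = fit, lambda = params$lambda)
  }
}

glmnet_predict <- function(m, X) {
  as.numeric(glmnet::predict.glmnet(m$fit, pad_single_column(X), s = m$lambda))
}

family_registry <- function() {
  list(
    l1_linear = list(
      label = "L1-penalized linear regression",
      space = list(lambda = sp_num(1e-4, 10, log = TRUE)),
      defaults = list(lambda = 0.01),
      fit = glmnet_fit(alpha_fixed = 1),
      predict = glmnet_predict
    ),
    l2_linear = list(
      label = "L2-penalized linear regression",
      space = list(lambda = sp_num(1e-4, 10, log = TRUE)),
      defaults = list(lambda = 0.01),
      fit = glmnet_fit(alpha_fixed = 0),
      predict = glmnet_predict
    ),
    elastic_net = list(
      label = "Elastic-net linear regression",
      space = list(alpha = sp_num(0, 1), lambda = sp_num(1e-4, 10, log = TRUE)),
      defaults = list(alpha = 0.5, lambda = 0.01),
      fit = glmnet_fit(),
      predict = glmnet_predict
    ),
    partial_least_squares = list(
      label = "Partial least squares regression",
      space = list(ncomp = sp_int(1, 15)),
      defaults = list(ncomp = 5),
      fit = function(params, X, y, w, Xval = NULL, yval = NULL) {
        ncomp <- min(params$ncomp, ncol(X), nrow(X) - 1L)
        fit <- mixOmics::pls(X, matrix(y, ncol = 1), ncomp = ncomp,
                             mode = "regression")
        list(fit = fit, ncomp = ncomp)
      },
      predict = function(m, X) {
        as.numeric(stats::predict(m$fit, X)$predict[, 1, m$ncomp])
      }
    ),
    kernel_svr = list(
      label = "Kernel (RBF) support vector regression",
      space = list(cost = sp_num(0.1, 100, log = TRUE),
                   gamma = sp_num(1e-3, 1, log = TRUE),
                   epsilon = sp_num(0.01, 0.3)),
      defaults = list(cost = 1, gamma = 1 / 30, epsilon = 0.1),
      fit = function(params, X, y, w, Xval = NULL, yval = NULL) {
        e1071::svm(X, y, type = "eps-regression", kernel = "radial",
                   cost = params$cost, gamma = params$gamma,
                   epsilon = params$epsilon, scale = FALSE)
      },
      predict = function(m, X) as.numeric(stats::predict(m, X))
    ),
    k_nearest_neighbors = list(
      label = "k-nearest-neighbors regression",
      space = list(k = sp_int(1, 30)),
      defaults = list(k = 5),
      fit = function(params, X, y, w, Xval = NULL, yval = NULL) {
        caret::knnreg(X, y, k = params$k)
      },
      predict = function(m, X) as.numeric(stats::predict(m, X))
    ),
    decision_tree = list(
      label = "Decision-tree regression",
      space = list(maxdepth = sp_int(2, 20), minsplit = sp_int(5, 40),
                   cp = sp_num(1e-5, 0.1, log = TRUE)),
      defaults = list(maxdepth = 8, minsplit = 20, cp = 0.001),
      fit = function(params, X, y, w, Xval = NULL, yval = NULL) {
        df <- data.frame(y = y, X)
        rpart::rpart(y ~ ., data = df, weights = w, method = "anova",
                     control = rpart::rpart.control(
                       maxdepth = params$maxdepth, minsplit = params$minsplit,
                       cp = params$cp, xval = 0))
      },
      predict = function(m, X) as.numeric(stats::predict(m, data.frame(X)))
    ),
    random_forest = list(
      label = "Random-forest regression",
      space = list(num_trees = sp_int(100, 800), mtry = sp_int(2, 20),
                   min_node_size = sp_int(1, 20)),
      defaults = list(num_trees = 500, mtry = 10, min_node_size = 5),
      fit = function(params, X, y, w, Xval = NULL, yval = NULL) {
        ranger::ranger(
          x = data.frame(X), y = y, num.trees = params$num_trees,
          mtry = min(params$mtry, ncol(X)),
          min.node.size = params$min_node_size,
          case.weights = w, num.threads = 1,
          seed = sample.int(.Machine$integer.max, 1)
        )
      },
      predict = function(m, X) {
        as.numeric(stats::predict(m, data.frame(X), num.threads = 1)$predictions)
      }
    ),
    gb_depthwise = list(
      label = "Gradient boosting, depth-wise tree growth",
      space = xgb_space(),
      defaults = list(eta = 0.1, max_depth = 6, min_child_weight = 1,
                      subsample = 1, colsample_bytree = 1, lambda = 1),
      fit = xgb_fit(list(), patience = 20),
      predict = function(m, X) as.numeric(stats::predict(m, X)),
      persist = xgboost::xgb.save.raw,
      restore = xgboost::xgb.load.raw
    ),
    gb_dart = list(
      label = "Gradient boosting, DART (dropout trees)",
      space = xgb_space(list(rate_drop = sp_num(0, 0.3))),
      defaults = list(eta = 0.1, max_depth = 6, min_child_weight = 1,
                      subsample = 1, colsample_bytree = 1, lambda = 1,
                      rate_drop = 0.1),
      fit = xgb_fit(list(booster = "dart"), patience = 20),
      predict = function(m, X) as.numeric(stats::predict(m, X)),
      persist = xgboost::xgb.save.raw,
      restore = xgboost::xgb.load.raw
    ),
    gb_lossguide = list(
      label = "Gradient boosting, leaf-wise (lossguide) growth",
      space = xgb_space(list(max_leaves = sp_int(8, 128)))[
        c("eta", "min_child_weight", "subsample", "colsample_bytree",
          "lambda", "max_leaves")],
      defaults = list(eta = 0.1, min_child_weight = 1, subsample = 1,
                      colsample_bytree = 1, lambda = 1, max_leaves = 31),
      fit = xgb_fit(list(tree_method = "hist", grow_policy = "lossguide",
                         max_depth = 0), patience = 30),
      predict = function(m, X) as.numeric(stats::predict(m, X)),
      persist = xgboost::xgb.save.raw,
      restore = xgboost::xgb.load.raw
    ),
    feedforward_net = list(
      label = "Feed-forward neural network (single hidden layer)",
      space = list(size = sp_int(4, 64), decay = sp_num(1e-5, 1, log = TRUE),
                   maxit = sp_int(100, 500)),
      defaults = list(size = 16, decay = 1e-3, maxit = 300),
      fit = function(params, X, y, w, Xval = NULL, yval = NULL) {
        nnet::nnet(X, y, size = params$size, decay = params$decay,
                   maxit = params$maxit, weights = w, linout = TRUE,
                   trace = FALSE, MaxNWts = 10000)
      },
      predict = function(m, X) as.numeric(stats::predict(m, X))
    )
  )
}

#' Names of the twelve regression families
#'
#' @return Character vector of family ids.
#' @export
model_families <- function() names(family_registry())

get_family <- function(family) {
  reg <- family_registry()
  if (!family %in% names(reg)) {
    stopf("unknown family '%s'; see model_families()", family)
  }
  reg[[family]]
}

#' Default hyperparameters of a family
#'
#' @param family A family id from [model_families()].
#' @return Named list of default hyperparameter values.
#' @export
family_defaults <- function(family) get_family(family)$defaults

#' Default hyperparameter search space of a family
#'
#' Each entry is a range/choice specification (`type` num/int/cat, bounds,
#' optional log scaling). Override by passing a modified list to
#' [run_search()].
#'
#' @param family A family id from [model_families()].
#' @return Named list of parameter specifications.
#' @export
family_search_space <- function(family) get_family(family)$space

#' Fit a final predictor with fixed hyperparameters
#'
#' Fits the family on the (transformed-target) training data with per-row
#' weights. A constant target short-circuits every family to a constant
#' predictor. Non-finite feature values are an error.
#'
#' @param family Family id.
#' @param params Named list of hyperparameters (defaults where missing).
#' @param X Numeric feature matrix (scaled).
#' @param y Numeric target (transformed scale).
#' @param w Per-row weights (default 1).
#' @param Xval,yval Optional validation set, used for early stopping by the
#'   boosting families.
#' @return An object of class `sar_model`.
#' @export
train_final <- function(family, params = list(), X, y, w = NULL,
                        Xval = NULL, yval = NULL) {
  fam <- get_family(family)
  if (!all(is.finite(X))) stopf("non-finite values in feature matrix")
  if (is.null(w)) w <- rep(1, nrow(X))
  params <- utils::modifyList(fam$defaults, params)
  if (stats::sd(y) < 1e-12) {
    return(structure(list(family = family, params = params,
                          constant = mean(y), inner = NULL),
                     class = "sar_model"))
  }
  inner <- fam$fit(params, X, y, w, Xval, yval)
  structure(list(family = family, params = params, constant = NULL,
                 inner = inner),
            class = "sar_model")
}

#' Predict from a fitted model
#'
#' @param object A `sar_model`.
#' @param newdata Numeric feature matrix on the same scale as training.
#' @param ... Unused.
#' @return Numeric predictions on the transformed-target scale.
#' @export
predict.sar_model <- function(object, newdata, ...) {
  if (!is.matrix(newdata)) newdata <- as.matrix(newdata)
  if (!is.null(object$constant)) {
    return(rep(object$constant, nrow(newdata)))
  }
  get_family(object$family)$predict(object$inner, newdata)
}

#' @exportS3Method base::print
print.sar_model <- function(x, ...) {
  fam <- get_family(x$family)
  cat(sprintf("<sar_model> %s\n", fam$label))
  if (!is.null(x$constant)) {
    cat(sprintf("  constant predictor: %g\n", x$constant))
  } else {
    cat("  params:", paste(names(x$params), unlist(x$params),
                           sep = "=", collapse = ", "), "\n")
  }
  invisible(x)
}

#' Persist a fitted model to disk
#'
#' Models whose backends hold external pointers (the boosting families) are
#' serialized through their raw-bytes representation so a reloaded model
#' returns bit-identical predictions.
#'
#' @param model A `sar_model`.
#' @param path File path.
#' @return Invisibly, `path`.
#' @export
save_sar_model <- function(model, path) {
  fam <- get_family(model$family)
  if (!is.null(fam$persist) && !is.null(model$inner)) {
    model$inner <- fam$persist(model$inner)
    model$serialized <- TRUE
  }
  saveRDS(model, path)
  invisible(path)
}

#' Load a model saved with [save_sar_model()]
#'
#' @param path File path.
#' @return A `sar_model`.
#' @export
load_sar_model <- function(path) {
  model <- readRDS(path)
  fam <- get_family(model$family)
  if (isTRUE(model$serialized)) {
    model$inner <- fam$restore(model$inner)
    model$serialized <- NULL
  }
  model
}
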