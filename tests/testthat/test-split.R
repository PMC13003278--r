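test_that("stratify labels concatenate shape, doping and coating", {
  expect_equal(build_stratify_label(shape = "sphere", dopant_element = "Zn",
                                    has_coating = 1),
               "sphere|Zn|coated")
  expect_equal(build_stratify_label(shape = "cube", dopant_element = "none",
                                    has_coating = 0),
               "cube|undoped|uncoated")
  rec <- rbind(one_record(), one_record())
  lab <- build_stratify_label(rec)
  expect_equal(lab[1], lab[2])
})

test_that("five-step class weights match hand execution", {
  w <- compute_class_weights(rep(c("A", "B"), c(100, 10)))
  expect_equal(unname(w["A"]), 1.0, tolerance = 1e-12)
  expect_equal(unname(w["B"]), 3.4594, tolerance = 1e-4) # log(11)/log(2)
  expect_equal(unname(w["B"]), log(11) / log(2), tolerance = 1e-12)

  eq <- compute_class_weights(rep(c("A", "B", "C"), each = 7))
  expect_equal(unname(eq), rep(1, 3))
  expect_equal(unname(compute_class_weights(rep("solo", 5))), 1)
  expect_error(compute_class_weights(character(0)), "nonempty")
})

test_that("rarer labels never get smaller weights than frequent ones", {
  set.seed(3)
  for (i in 1:20) {
    counts <- sample(1:500, sample(2:8, 1))
    labels <- rep(paste0("L", seq_along(counts)), counts)
    w <- compute_class_weights(labels)
    tab <- table(labels)
    ord <- order(as.numeric(tab)) # rarest first
    expect_true(all(diff(w[names(tab)[ord]]) <= 1e-12))
    expect_true(all(w >= 1 - 1e-12))
    expect_equal(min(w), 1, tolerance = 1e-12)
  }
})

test_that("split hits 70/10/10/10 within per-label rounding, reproducibly", {
  labels <- rep(c("a", "b", "c", "d"), each = 250)
  sp <- stratified_split(labels, seed = 42)
  expect_equal(unname(table(sp$subset)), c(700, 100, 100, 100),
               ignore_attr = TRUE)
  tab <- table(sp$label, sp$subset)
  expect_true(all(abs(tab - outer(rowSums(tab), c(0.7, 0.1, 0.1, 0.1))) <= 1))

  sp2 <- stratified_split(labels, seed = 42)
  expect_identical(sp$subset, sp2$subset)
  sp3 <- stratified_split(labels, seed = 43)
  expect_false(identical(sp$subset, sp3$subset))
  expect_error(stratified_split(labels[1:5]), "at least 10")
})

test_that("imbalanced labels keep their prevalence in every subset", {
  labels <- rep(c("common", "tenpct"), c(900, 100))
  sp <- stratified_split(labels, seed = 1)
  tab <- table(sp$label, sp$subset)
  expect_true(all(abs(tab["tenpct", ] - c(70, 10, 10, 10)) <= 1))
  # labels below the pooling size end up in the rare stratum
  labels2 <- c(rep("big", 97), rep("tiny", 3))
  sp2 <- stratified_split(labels2, seed = 1)
  expect_true(all(sp2$label[98:100] == "rare"))
})

test_that("feature scaling maps train extrema to [-1, 1] and midpoints to 0", {
  tab <- build_feature_table(tiny_dataset(n = 120)$records)
  scaler <- fit_feature_scaler(tab)
  tr <- transform_features(scaler, tab)
  expect_equal(max(tr$X), 1, tolerance = 1e-12)
  expect_equal(min(tr$X), -1, tolerance = 1e-12)
  j <- match("H", colnames(tr$X))
  mid <- (scaler$mins[["H"]] + scaler$maxs[["H"]]) / 2
  probe <- tab[1, ]
  probe$H <- mid
  expect_equal(transform_features(scaler, probe)$X[1, j], 0, tolerance = 1e-12)
  # values beyond the training range legitimately exceed [-1, 1]
  probe$H <- scaler$maxs[["H"]] * 2
  expect_gt(transform_features(scaler, probe)$X[1, j], 1)
})

test_that("zero-range features map to constant zero with a warning", {
  tab <- build_feature_table(tiny_dataset(n = 60)$records)
  tab$T <- 300
  expect_warning(scaler <- fit_feature_scaler(tab), "zero-range")
  tr <- transform_features(scaler, tab)
  expect_true(all(tr$X[, "T"] == 0))
})

test_that("target transform round-trips and the scaler sees only train rows", {
  tab <- build_feature_table(tiny_dataset(n = 200)$records)
  scaler <- fit_feature_scaler(tab[1:140, ])
  y <- c(0.01, 1, 57.3, 500, 2302)
  expect_equal(inverse_target(scaler, transform_target(scaler, y)), y,
               tolerance = 1e-9)
  # leakage check: perturbing a non-train row leaves the state untouched
  tab2 <- tab
  tab2$SAR[150] <- tab2$SAR[150] * 100
  tab2$H[160] <- 1e4
  scaler2 <- fit_feature_scaler(tab2[1:140, ])
  expect_identical(scaler$mins, scaler2$mins)
  expect_identical(scaler$maxs, scaler2$maxs)
  expect_identical(scaler$lambda, scaler2$lambda)
})

test_that("fit_transform_features carries one scaler across subsets", {
  tab <- build_feature_table(tiny_dataset(n = 100)$records)
  out <- fit_transform_features(tab[1:70, ], val = tab[71:100, ])
  expect_s3_class(out$scaler, "scaler_state")
  expect_equal(nrow(out$train$X), 70L)
  expect_equal(nrow(out$val$X), 30L)
  expect_equal(max(out$train$X), 1, tolerance = 1e-12)
})
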