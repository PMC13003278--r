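test_that("generator is deterministic and honours the empty case", {
  cfg <- synthetic_config(n_samples = 0, seed = 1)
  ds <- generate_dataset(cfg)
  expect_equal(nrow(ds$records), 0L)
  expect_length(ds$truth$sar_noiseless, 0L)

  cfg <- synthetic_config(n_samples = 150, seed = 11)
  a <- generate_dataset(cfg)
  b <- generate_dataset(cfg)
  expect_identical(a$records, b$records)
  expect_identical(a$truth$sar_noiseless, b$truth$sar_noiseless)

  c2 <- generate_dataset(synthetic_config(n_samples = 150, seed = 12))
  expect_false(identical(a$records$SAR, c2$records$SAR))
})

test_that("invalid configurations are rejected", {
  expect_error(synthetic_config(shape_mix = c(sphere = 1, cube = 0.5,
                                              nanoflower = 0, octahedron = 0,
                                              octopod = 0)),
               "probability vector")
  expect_error(synthetic_config(n_samples = -1), "nonnegative")
  expect_error(synthetic_config(noise_sd_relative = -0.1), ">= 0")
})

test_that("observed SAR is right-skewed and marginals respect bounds", {
  ds <- generate_dataset(synthetic_config(n_samples = 2000, seed = 1))
  r <- ds$records
  ae <- abs(r$SAR)
  skew <- mean((r$SAR - mean(r$SAR))^3) / mean((r$SAR - mean(r$SAR))^2)^1.5
  expect_gt(skew, 0.5)
  b <- synthetic_config()$bounds
  expect_true(all(r$H >= b$H[1] & r$H <= b$H[2]))
  expect_true(all(r$f >= b$f[1] & r$f <= b$f[2]))
  expect_true(all(r$C_SPION >= b$C_SPION[1] & r$C_SPION <= b$C_SPION[2]))
  expect_true(all(r$d_TEM <= 30))
  expect_true(all(r$Mr <= r$Ms))
  expect_true(all(ds$truth$sar_noiseless >= 0))
})

test_that("ground-truth SAR is monotone in H, f (up) and C (down)", {
  truth <- synthetic_config()$truth
  base <- data.frame(H = 150, f = 150, C_SPION = 2, d_TEM = 12,
                     dopant_element = "none", dopant_x = 0)
  for (col in c("H", "f")) {
    grid <- base[rep(1, 25), ]
    grid[[col]] <- seq(20, 500, length.out = 25)
    expect_true(all(diff(sar_ground_truth(grid, truth)) > 0), info = col)
  }
  grid <- base[rep(1, 25), ]
  grid$C_SPION <- seq(0.1, 20, length.out = 25)
  expect_true(all(diff(sar_ground_truth(grid, truth)) < 0))
})

test_that("dopant fractions concentrate at zero under the default mixture", {
  ds <- generate_dataset(synthetic_config(n_samples = 2000, seed = 1))
  expect_gt(mean(ds$records$dopant_x == 0), 0.5)
})

test_that("marginal summaries report skew, constants and category frequencies", {
  df <- data.frame(
    num = c(1, 2, 3, 10),
    const = rep(5, 4),
    bin = c(1, 1, 1, 0),
    cat = c("a", "a", "b", "a"),
    stringsAsFactors = FALSE
  )
  s <- summarize_marginals(df)
  expect_equal(nrow(s), 4L)
  expect_true(s$constant[s$feature == "const"])
  expect_true(is.na(s$skewness[s$feature == "const"]))
  expect_equal(s$top_freq[s$feature == "bin"], 0.75)
  expect_equal(s$top_level[s$feature == "cat"], "a")
  expect_error(summarize_marginals(df[0, ]), "nonempty")
})

test_that("dataset round-trips through the CSV/JSON writers", {
  ds <- tiny_dataset(n = 20)
  csv <- tempfile(fileext = ".csv")
  js <- tempfile(fileext = ".json")
  write_dataset(ds, csv, js)
  back <- read.csv(csv, stringsAsFactors = FALSE)
  expect_equal(nrow(back), 20L)
  expect_equal(back$SAR, ds$records$SAR, tolerance = 1e-12)
  meta <- jsonlite::read_json(js, simplifyVector = TRUE)
  expect_equal(meta$sar_noiseless, ds$truth$sar_noiseless, tolerance = 1e-12)
})
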