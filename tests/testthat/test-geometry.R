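test_that("closed forms reproduce the elementary solids", {
  g <- core_area_volume(geometry_spec("sphere", 2))
  expect_equal(g$A_core, 4 * pi, tolerance = 1e-12)
  expect_equal(g$V_core, 4 * pi / 3, tolerance = 1e-12)

  g <- core_area_volume(geometry_spec("cube", 1))
  expect_equal(g$A_core, 6)
  expect_equal(g$V_core, 1)

  g <- core_area_volume(geometry_spec("nanoflower", 6))
  expect_equal(g$A_core, 48 * pi, tolerance = 1e-12)
  expect_equal(g$V_core, 13 * (4 * pi / 3), tolerance = 1e-12)

  # edge length 1 when d equals the projected diameter at cos(beta1) = 1/3
  b <- acos(1 / 3) * 180 / pi
  d <- sqrt(3 / 4) * (1 + 1 / 3)
  g <- core_area_volume(geometry_spec("octahedron", d, beta1 = b))
  expect_equal(g$A_core, 2 * sqrt(3), tolerance = 1e-9)
  expect_equal(g$V_core, sqrt(2) / 3, tolerance = 1e-9)
})

test_that("area scales as k^2 and volume as k^3 for every shape", {
  for (sh in c("sphere", "cube", "nanoflower", "octahedron", "octopod")) {
    g1 <- core_area_volume(geometry_spec(sh, 7))
    for (k in c(0.5, 2, 10)) {
      gk <- core_area_volume(geometry_spec(sh, 7 * k))
      expect_equal(gk$A_core, k^2 * g1$A_core, tolerance = 1e-9, info = sh)
      expect_equal(gk$V_core, k^3 * g1$V_core, tolerance = 1e-9, info = sh)
    }
  }
})

test_that("the sphere has minimal area among the shapes at equal volume", {
  shapes <- c("sphere", "cube", "nanoflower", "octahedron", "octopod")
  target_v <- 1000
  areas <- vapply(shapes, function(sh) {
    g0 <- core_area_volume(geometry_spec(sh, 1))
    d <- (target_v / g0$V_core)^(1 / 3) # scale law: V ~ d^3
    g <- core_area_volume(geometry_spec(sh, d))
    expect_equal(g$V_core, target_v, tolerance = 1e-6)
    g$A_core
  }, numeric(1))
  expect_equal(which.min(areas), c(sphere = 1L))
})

test_that("surface-to-volume ratio follows the closed forms", {
  g <- core_area_volume(geometry_spec("sphere", 2))
  expect_equal(av_ratio(g$A_core, g$V_core), 3, tolerance = 1e-12)
  g <- core_area_volume(geometry_spec("cube", 1))
  expect_equal(av_ratio(g$A_core, g$V_core), 6, tolerance = 1e-12)
  expect_equal(av_ratio(0, 2), 0)
  expect_error(av_ratio(1, 0), "positive")
})

test_that("the nanoflower model is 13 tangent non-overlapping spheres", {
  v <- sarqspr:::icosahedron_vertices()
  expect_equal(nrow(v), 12L)
  expect_equal(unname(sqrt(rowSums(v^2))), rep(1, 12), tolerance = 1e-12)
  r <- 1
  centers <- rbind(c(0, 0, 0), 2 * r * v)
  dists <- as.matrix(dist(centers))
  diag(dists) <- Inf
  expect_gte(min(dists), 2 * r - 1e-12) # pairwise non-overlapping
  expect_equal(min(dists[1, -1]), 2 * r, tolerance = 1e-12) # petals touch core
  g <- core_area_volume(geometry_spec("nanoflower", 6))
  expect_equal(g$V_core / ((4 / 3) * pi * 1^3), 13, tolerance = 1e-12)
})

test_that("Monte-Carlo oracle confirms the closed forms (desk-scale draw)", {
  for (sh in c("sphere", "cube", "octahedron", "octopod", "nanoflower")) {
    spec <- geometry_spec(sh, 10)
    cf <- core_area_volume(spec)
    mc <- mc_area_volume_oracle(spec, n_points = 1e5, seed = 42)
    expect_lte(abs(mc$V_est - cf$V_core), 3 * mc$V_se + 1e-9 * cf$V_core)
    expect_lte(abs(mc$A_est - cf$A_core), 3 * mc$A_se + 1e-9 * cf$A_core)
  }
  expect_error(mc_area_volume_oracle(geometry_spec("cube", 1), n_points = 100),
               "1e4")
})

test_that("geometry specs validate their inputs", {
  expect_error(geometry_spec("sphere", -1), "positive")
  expect_error(geometry_spec("pyramid", 1))
  expect_error(geometry_spec("octahedron", 1, beta1 = 95), "beta1")
  expect_error(geometry_spec("octopod", 1, beta2 = 0), "beta2")
})
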