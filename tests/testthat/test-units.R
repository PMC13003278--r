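test_that("magnetization converts to emu/g under the documented equivalences", {
  expect_equal(magnetization_to_emu_per_g(7, "Am2/kg"), 7, tolerance = 1e-12)
  expect_equal(magnetization_to_emu_per_g(50, "emu/cm3"), 10, tolerance = 1e-12)
  expect_equal(magnetization_to_emu_per_g(50, "kA/m"), 10, tolerance = 1e-12)
  expect_equal(magnetization_to_emu_per_g(100, "emu/gFe", composition()),
               72.36, tolerance = 1e-2)
  expect_error(magnetization_to_emu_per_g(1, "tesla"))
  expect_error(magnetization_to_emu_per_g(1, "emu/gFe"), "composition")
})

test_that("coercivity converts to Oe and round-trips", {
  expect_equal(coercivity_to_oe(1, "mT"), 10, tolerance = 1e-12)
  expect_equal(coercivity_to_oe(0.7958, "kA/m"), 10, tolerance = 1e-12)
  expect_equal(coercivity_to_oe(0, "mT"), 0)
  for (u in c("Oe", "mT", "kA/m")) {
    v <- 3.7
    expect_equal(oe_to_coercivity_unit(coercivity_to_oe(v, u), u), v,
                 tolerance = 1e-12, info = u)
  }
})

test_that("all converters are linear and map zero to zero", {
  comps <- list(composition(), composition("Co", 1), composition("Zn", 0.5))
  for (comp in comps) {
    for (u in c("emu/g", "emu/gFe", "emu/cm3", "Am2/kg", "kA/m")) {
      f <- function(v) magnetization_to_emu_per_g(v, u, comp)
      expect_equal(f(0), 0, info = u)
      expect_equal(f(2) + f(3), f(5), tolerance = 1e-12, info = u)
    }
    for (b in c("per_g_np", "per_g_Fe", "per_g_metal")) {
      g <- function(v) sar_to_w_per_g_np(v, b, comp)
      expect_equal(g(0), 0, info = b)
      expect_equal(2 * g(10), g(20), tolerance = 1e-12, info = b)
    }
  }
})

test_that("temperature and remanence markers parse to canonical values", {
  expect_equal(temperature_to_kelvin("room temperature"), 300)
  expect_equal(temperature_to_kelvin(5), 5)
  expect_equal(temperature_to_kelvin("77"), 77)
  expect_error(temperature_to_kelvin("negligible"), "parse")
  expect_equal(remanence_value("negligible"), 0)
  expect_equal(remanence_value(4.2), 4.2)
})

test_that("molar mass and mass fractions follow the formula weights", {
  expect_equal(molar_mass(composition()), 231.516, tolerance = 1e-9)
  expect_equal(molar_mass(composition("Zn", 0.5)), 236.296, tolerance = 1e-9)
  for (el in c("Zn", "Mn", "Co", "Mg")) {
    expect_equal(molar_mass(composition(el, 0)), molar_mass(composition()),
                 info = el)
  }
  expect_equal(sar_to_w_per_g_np(100, "per_g_np"), 100)
  expect_equal(sar_to_w_per_g_np(100, "per_g_Fe", composition()), 72.36,
               tolerance = 1e-2)
  expect_equal(sar_to_w_per_g_np(100, "per_g_metal", composition("Zn", 0.5)),
               72.92, tolerance = 1e-2)
  # Fe fraction < 1 so the per-Fe basis always shrinks the value
  for (x in c(0, 0.3, 1)) {
    comp <- composition("Mn", x)
    expect_lt(sar_to_w_per_g_np(100, "per_g_Fe", comp), 100)
  }
})

test_that("dopant-iron ratios place x at the dopant's slot", {
  expect_equal(unname(dopant_ratio_features(composition())), rep(0, 4))
  r <- dopant_ratio_features(composition("Zn", 0.5))
  expect_equal(unname(r), c(0.5, 0, 0, 0))
  r <- dopant_ratio_features(composition("Co", 1))
  expect_equal(unname(r), c(0, 0, 1, 0))
  r <- dopant_ratio_features(composition("Co", 1), mode = "molar")
  expect_equal(unname(r), c(0, 0, 0.5, 0))
  expect_error(composition("none", 0.2), "x must be 0")
  expect_error(composition("Zn", 3), "\\[0, 3\\)")
})
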