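# Geometry, coalescence, compliant radius, torque, Poiseuille pressure,
# interstitial profiles.

test_that("segment geometry matches the published dimensions", {
  g <- segment_geometry()
  expect_equal(g$name, c("PT-S1S2", "PT-S3", "DL", "mTAL", "cTAL", "DCT",
                         "CNT", "CCD", "OMCD", "IMCD"))
  # proximal tubule total 1.7 cm at 37 um diameter
  expect_equal(sum(g$length_cm[1:2]), 1.7)
  expect_true(all(g$diameter_um[1:2] == 37))
  expect_equal(g$length_cm[3:10], c(0.32, 0.5, 0.5, 0.2, 0.4, 0.4, 0.5, 1.2))
  expect_equal(g$diameter_um[3:10], c(26, 26, 26, 20, 24, 45, 45, 50))
  # only the proximal segments are compliant and torque-scaled
  expect_equal(g$compliant, c(TRUE, TRUE, rep(FALSE, 8)))
  expect_equal(g$torque_s[1:2], c(1.5, 0.75))
  expect_true(all(g$torque_s[3:10] == 0))
})

test_that("connecting-tubule coalescence leaves 10% at the segment end", {
  expect_equal(cnt_population_fraction(0, 0.4), 1)
  expect_equal(cnt_population_fraction(0.4, 0.4), 0.1, tolerance = 0.002)
  expect_equal(cnt_population_fraction(0.2, 0.4), 2^-1.66, tolerance = 1e-12)
  # the 10:1 loop-to-CCD ratio, to 1%
  expect_equal(cnt_population_fraction(0.4, 0.4) * 10, 1, tolerance = 0.01)
  expect_error(cnt_population_fraction(-0.1, 0.4), "outside")
  expect_error(cnt_population_fraction(0.5, 0.4), "outside")
})

test_that("IMCD population represents eight convergences", {
  expect_equal(imcd_population_fraction(0, 1.2), 0.1)
  expect_equal(imcd_population_fraction(1.2, 1.2), 0.1 * 0.05 * exp(-2.75),
               tolerance = 1e-12)
  x <- seq(0, 1.2, length.out = 200)
  expect_true(all(diff(imcd_population_fraction(x, 1.2)) < 0))
})

test_that("compliant radius follows the linear law with a collapse floor", {
  expect_equal(compliant_radius(20), 14)
  expect_equal(compliant_radius(30), 18.2)
  expect_equal(compliant_radius(10), 9.8)
  # collapse guard: radius never drops below the floor fraction
  expect_equal(compliant_radius(-5), 0.7 * 14)
})

test_that("microvillous torque scales linearly with flow", {
  expect_equal(microvillous_torque(0, 14), 0)
  expect_equal(microvillous_torque(200, 14), 2 * microvillous_torque(100, 14))
  # independent dimensional-analysis oracle in SI units:
  # tau = 8 mu Q l / r^2 * (1 + (l+d)/r + l^2/(2 r^2))
  mu_Pa_s <- 6.4e-6 * 133.322          # mmHg s -> Pa s
  Q_m3s <- 100 * 1e-9 * 1e-3 / 60      # 100 nl/min = 1e-10 m^3/min
  r <- 14e-6; l <- 2.5e-6; d <- 0.15e-6
  tau_SI <- 8 * mu_Pa_s * Q_m3s * l / r^2 * (1 + (l + d) / r + l^2 / (2 * r^2))
  # convert Pa m^2 -> mmHg cm^2
  tau_expected <- tau_SI / 133.322 * 1e4
  expect_equal(microvillous_torque(100, 14), tau_expected, tolerance = 1e-10)
})

test_that("torque scale factor is floored at zero", {
  expect_equal(torque_scale_factor(1, 1, 1.5), 1)
  expect_equal(torque_scale_factor(0, 1, 1.5), 0)   # raw value would be -0.5
  expect_equal(torque_scale_factor(1.1, 1, 1.5), 1.15)
  expect_error(torque_scale_factor(1, 0, 1.5), "positive")
})

test_that("Poiseuille gradient matches an independent unit conversion", {
  expect_equal(poiseuille_pressure_gradient(0, 14), 0)
  # r^-4 scaling
  expect_equal(poiseuille_pressure_gradient(50, 7),
               16 * poiseuille_pressure_gradient(50, 14), tolerance = 1e-12)
  # independent cm-g-s oracle: -8 mu Q / (pi r^4)
  mu <- 6.4e-6                        # mmHg s
  Q <- 100 * 1e-6 / 60                # nl/min -> cm^3/s
  r <- 14e-4                          # um -> cm
  expect_equal(poiseuille_pressure_gradient(100, 14),
               -8 * mu * Q / (pi * r^4), tolerance = 1e-12)
  expect_equal(round(poiseuille_pressure_gradient(100, 14), 1), -7.1)
})

test_that("interstitial concentrations interpolate linearly with depth", {
  prof <- interstitial_profile()
  expect_equal(interstitial_concentration(0.5, "Na", prof), 299)
  expect_equal(interstitial_concentration(0.25, "Na", prof), (140 + 299) / 2)
  expect_equal(interstitial_concentration(1.7, "urea", prof), 200)
  expect_equal(interstitial_concentration(0, "Na", prof), 140)
  expect_error(interstitial_concentration(0.5, "vitaminC", prof), "unknown")
  expect_error(interstitial_concentration(2.0, "Na", prof), "outside")
  # interpolated values bounded by the zone's anchors
  for (s in c("Na", "K", "urea", "glucose")) {
    om <- vapply(seq(0, 0.5, length.out = 11),
                 interstitial_concentration, numeric(1), s, prof)
    expect_true(all(om >= min(om[1], om[11]) - 1e-12 &
                      om <= max(om[1], om[11]) + 1e-12))
  }
})

test_that("profile osmolality at the anchors reproduces the printed row", {
  prof <- interstitial_profile()
  osm <- vapply(c(0, 0.5, 1.7), function(d) {
    osmolality(nephrosim:::interstitial_species(d, prof))
  }, numeric(1))
  expect_equal(round(osm, 1), c(285.9, 688.5, 737.9))
})

test_that("NKCC2 washout profile overrides only Na, K, Cl and urea", {
  w <- interstitial_profile(washout = TRUE)
  b <- interstitial_profile()
  expect_equal(w$anchors$omim[["Na"]], 204)
  expect_equal(w$anchors$omim[["K"]], 5.6)
  expect_equal(w$anchors$omim[["Cl"]], 193)
  expect_equal(w$anchors$omim[["urea"]], 28)
  expect_equal(w$anchors$tip[c("Na", "K", "Cl", "urea")],
               c(Na = 160, K = 7.0, Cl = 149, urea = 56))
  keep <- setdiff(names(b$anchors$tip), c("Na", "K", "Cl", "urea"))
  expect_equal(w$anchors$tip[keep], b$anchors$tip[keep])
})
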