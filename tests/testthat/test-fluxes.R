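# Flux laws: Kedem-Katchalsky, GHK electrodiffusion, SGLT2 and NKCC2
# kinetic carriers, generic pumps and cotransporters.

test_that("volume flux reduces to its limiting forms", {
  sig <- c(Na = 1, Cl = 1)
  expect_equal(volume_flux(0.1, 1e-7, sig, c(Na = 0, Cl = 0), 0), 0)
  # hydraulic-only limit: sigma = 0, dP = 1 mmHg -> A Lp (in nl/min)
  expect_equal(volume_flux(0.1, 1e-7, c(Na = 0), c(Na = 100), 1),
               nephrosim:::cm3s_to_nlmin(0.1 * 1e-7))
  # pure osmosis, one solute at sigma 1
  expect_equal(volume_flux(0.1, 1e-7, c(Na = 1), c(Na = 5), 0),
               nephrosim:::cm3s_to_nlmin(0.1 * 1e-7 *
                                           ns_const$RT_mmHg_per_mM * 5))
  expect_error(volume_flux(0.1, 1e-7, c(Na = 1.2), c(Na = 5), 0), "0,1")
})

test_that("GHK flux has a smooth Fick limit at zero voltage", {
  A <- 0.1; rho <- 1e-5
  fick <- neutral_diffusion(rho, A, 10, 4)
  # two-sided limit: the genuine O(dV) drift term vanishes as dV -> 0
  for (dV in c(1e-9, -1e-9)) {
    expect_equal(ghk_flux(rho, A, 1, dV, 10, 4), fick,
                 tolerance = 1e-10)
  }
  expect_equal(mean(c(ghk_flux(rho, A, 1, 1e-6, 10, 4),
                      ghk_flux(rho, A, 1, -1e-6, 10, 4))), fick,
               tolerance = 1e-12)
  # the series branch agrees with a direct evaluation of the exact
  # expression at the same voltage, just inside the branch threshold
  u <- 0.999e-4
  direct <- rho * A * u * (10 - 4 * exp(-u)) / (1 - exp(-u))
  expect_equal(ghk_flux(rho, A, 1, u * ns_const$RT_over_F_mV, 10, 4),
               direct, tolerance = 1e-12)
})

test_that("GHK flux vanishes at the Nernst potential", {
  for (z in c(1, -1, 2)) {
    dV <- 15
    Cb <- 7 * exp(z * dV / ns_const$RT_over_F_mV)
    expect_equal(ghk_flux(1e-5, 0.1, z, dV, 7, Cb), 0, tolerance = 1e-18)
  }
  # z = 1, dV = RT/F, C_a = 1, C_b = 0 -> A rho e/(e-1)
  expect_equal(ghk_flux(1, 1, 1, ns_const$RT_over_F_mV, 1, 0),
               exp(1) / (exp(1) - 1), tolerance = 1e-10)
})

test_that("flux laws are antisymmetric under compartment swap", {
  set.seed(7)
  for (i in 1:10) {
    ca <- runif(1, 1, 200); cb <- runif(1, 1, 200)
    dV <- runif(1, -80, 80); z <- sample(c(-2, -1, 1, 2), 1)
    expect_equal(ghk_flux(1e-5, 0.1, z, dV, ca, cb),
                 -ghk_flux(1e-5, 0.1, z, -dV, cb, ca), tolerance = 1e-12)
    expect_equal(neutral_diffusion(1e-5, 0.1, ca, cb),
                 -neutral_diffusion(1e-5, 0.1, cb, ca))
  }
})

test_that("neutral diffusion is Fickian", {
  expect_equal(neutral_diffusion(1e-5, 0.1, 5, 5), 0)
  expect_equal(neutral_diffusion(2e-5, 0.1, 6, 2),
               2 * neutral_diffusion(1e-5, 0.1, 6, 2))
})

test_that("SGLT2 flux is zero on its thermodynamic equilibrium manifold", {
  p <- sglt2_params(1e-5)
  # C_glu_l C_Na_l e^zeta = C_glu_c C_Na_c
  dV <- 30; ez <- exp(dV / ns_const$RT_over_F_mV)
  fx <- sglt2_flux(p, 1, 50, ez * 0.5, 100, psi_lum = 0, psi_cyt = -dV)
  expect_equal(fx$J_glu, 0, tolerance = 1e-20)
  # 1:1 stoichiometry always
  set.seed(8)
  for (i in 1:10) {
    fx <- sglt2_flux(p, runif(1, 0.1, 10), runif(1, 10, 200),
                     runif(1, 0.1, 10), runif(1, 5, 50),
                     runif(1, -10, 10), runif(1, -90, -40))
    expect_identical(fx$J_Na, fx$J_glu)
  }
})

test_that("SGLT2 flux matches an independent transcription of the kinetics", {
  # literal re-evaluation of the carrier equations, written separately
  oracle <- function(p, gl, nl, gc, nc, psil, psic) {
    zeta <- (psil - psic) / ns_const$RT_over_F_mV
    n1 <- nl / p$Km_Na; n2 <- nc / p$Km_Na
    g1 <- gl / p$Km_glu; g2 <- gc / p$Km_glu
    Phi <- (1 + n1 + g1 + n1 * g1) * (1 + n2 * g2) +
      (1 + n2 + g2 + n2 * g2) * (1 + n1 * g1 * exp(zeta))
    p$density * p$k_uf * (n1 * g1 * exp(zeta) - n2 * g2) / Phi
  }
  set.seed(9)
  for (i in 1:25) {
    p <- sglt2_params(10^runif(1, -6, -4), k_uf = runif(1, 0.5, 5),
                      Km_Na = runif(1, 5, 60), Km_glu = runif(1, 0.2, 5))
    gl <- runif(1, 0.01, 10); nl <- runif(1, 5, 250)
    gc <- runif(1, 0.01, 10); nc <- runif(1, 2, 60)
    psil <- runif(1, -20, 10); psic <- runif(1, -90, -30)
    expect_equal(sglt2_flux(p, gl, nl, gc, nc, psil, psic)$J_glu,
                 oracle(p, gl, nl, gc, nc, psil, psic),
                 tolerance = 1e-12)
  }
})

test_that("NKCC2 carrier obeys detailed balance and 1:1:2 stoichiometry", {
  p <- nkcc2_params(1e-6)
  eq <- nkcc2_flux(p, c(Na = 80, K = 5, Cl = 90), c(Na = 80, K = 5, Cl = 90))
  expect_equal(eq$J_Na, 0, tolerance = 1e-18)
  fx <- nkcc2_flux(p, c(Na = 140, K = 5, Cl = 110), c(Na = 20, K = 130, Cl = 25))
  expect_gt(fx$J_Na, 0)
  expect_identical(fx$J_K, fx$J_Na)
  expect_equal(fx$J_Cl, fx$J_Na + fx$J_K)
  # an inconsistent rate set is rejected
  expect_error(nkcc2_params(1e-6, k_ff = 1000, k_bf = 2000, k_fe = 2000,
                            k_be = 2000), "detailed balance")
})

test_that("NKCC2 state solver matches the master-equation null space", {
  set.seed(10)
  for (i in 1:100) {
    p <- random_nkcc2()
    lum <- c(Na = runif(1, 10, 300), K = runif(1, 1, 40),
             Cl = runif(1, 10, 300))
    cyt <- c(Na = runif(1, 5, 60), K = runif(1, 60, 160),
             Cl = runif(1, 5, 60))
    a <- nkcc2_flux(p, lum, cyt)
    b <- nkcc2_nullspace_flux(p, lum, cyt)
    expect_equal(a$J_Na, b$J_Na, tolerance = 1e-10)
    expect_equal(a$J_Cl, b$J_Cl, tolerance = 1e-10)
  }
})

test_that("NKCC2 flux carries the sign of its chemical driving force", {
  set.seed(11)
  for (i in 1:20) {
    p <- random_nkcc2()
    lum <- c(Na = runif(1, 10, 300), K = runif(1, 1, 40),
             Cl = runif(1, 10, 300))
    cyt <- c(Na = runif(1, 5, 60), K = runif(1, 60, 160),
             Cl = runif(1, 5, 60))
    drive <- log(lum[["Na"]] * lum[["K"]] * lum[["Cl"]]^2 /
                   (cyt[["Na"]] * cyt[["K"]] * cyt[["Cl"]]^2))
    J <- nkcc2_flux(p, lum, cyt)$J_Na
    if (abs(drive) > 1e-6) expect_equal(sign(J), sign(drive))
  }
})

test_that("generic transporters keep exact stoichiometry", {
  Cout <- c(Na = 140, K = 4, Cl = 100, H = 4e-5, NH4 = 1, glucose = 5)
  Cin <- c(Na = 20, K = 130, Cl = 30, H = 6e-5, NH4 = 0.5, glucose = 1)
  # zero density -> zero flux for every registered kind
  for (kind in c("NaKATPase", "NHE3", "HATPase", "HKATPase", "KCC", "NCC",
                 "ENaC")) {
    J <- generic_transporter_flux(kind, 0, Cout, Cin, dV = -60)
    expect_true(all(J == 0))
  }
  # Na:K = 3 : -2 exactly
  J <- generic_transporter_flux("NaKATPase", 1e-4, Cout, Cin)
  expect_equal(J[["Na"]] / J[["K"]], -3 / 2, tolerance = 1e-14)
  # NHE3 conserves exchange stoichiometry; with no NH4 anywhere it is a
  # pure Na+/H+ exchanger
  J <- generic_transporter_flux("NHE3", 1e-4, Cout, Cin)
  expect_equal(J[["Na"]] + J[["H"]] + J[["NH4"]], 0, tolerance = 1e-18)
  C0o <- Cout; C0o[["NH4"]] <- 0
  C0i <- Cin; C0i[["NH4"]] <- 0
  J0 <- generic_transporter_flux("NHE3", 1e-4, C0o, C0i)
  expect_equal(J0[["NH4"]], 0)
  expect_equal(J0[["Na"]], -J0[["H"]], tolerance = 1e-18)
  # H-K pump is a strict 1:1 exchanger
  J <- generic_transporter_flux("HKATPase", 1e-5, Cout, Cin)
  expect_equal(J[["H"]], -J[["K"]])
  expect_error(generic_transporter_flux("UT-A1", 1, Cout, Cin),
               "unknown transporter")
})
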