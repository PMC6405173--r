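# Steady-state epithelial solve: residual structure, equilibrium oracle,
# conservation identities, solver robustness.

pt_case <- function() {
  params <- reference_parameters()
  list(params = params,
       seg = params$segments[["PT-S1S2"]],
       lum = list(conc = inflow_composition(), P = 21),
       bath = list(conc = interstitial_profile()$anchors$cortex, P = 5))
}

converged_pt <- function() {
  cached("pt_state", function() {
    cs <- pt_case()
    solve_epithelium(cs$lum, cs$bath, cs$seg, tscale = 1)
  })
}

test_that("residual vector has the documented structure", {
  cs <- pt_case()
  r <- epithelial_residuals(cs$seg$init_state, cs$lum, cs$bath, cs$seg)
  # per compartment: water + 5 non-reacting + 4 buffer totals + proton +
  # 4 pair equilibria + hydration + electroneutrality = 17
  expect_length(r$residuals, 34L)
  expect_length(grep("^cell\\.", names(r$residuals)), 17L)
  expect_length(grep("^lat\\.", names(r$residuals)), 17L)
  expect_length(grep("equil", names(r$residuals)), 10L)
  expect_true(is.finite(r$lumen_current))
})

test_that("isolated membranes give identically zero conservation residuals", {
  cs <- pt_case()
  seg <- cs$seg
  for (ifc in names(seg$interfaces)) {
    seg$interfaces[[ifc]]$rhoA[] <- 0
    seg$interfaces[[ifc]]$Lp <- 0
  }
  seg$transporters <- list()
  r <- epithelial_residuals(seg$init_state, cs$lum, cs$bath, seg)
  cons <- r$residuals[!grepl("equil|electroneutrality",
                             names(r$residuals))]
  expect_true(all(cons == 0))
  expect_equal(r$lumen_current, 0)
})

test_that("perturbing one cell solute moves only the coupled residual rows", {
  cs <- pt_case()
  st <- converged_pt()
  base <- epithelial_residuals(st, cs$lum, cs$bath, cs$seg)
  st2 <- st
  st2$cell$conc[["urea"]] <- st2$cell$conc[["urea"]] * 1.3
  pert <- epithelial_residuals(st2, cs$lum, cs$bath, cs$seg)
  d <- abs(pert$residuals - base$residuals)
  expect_gt(d[["cell.urea"]], 1e-4)
  # Na has no flux pathway coupled to urea: its balance is untouched
  expect_lt(d[["cell.Na"]], 1e-14)
  expect_lt(d[["cell.K"]], 1e-14)
})

test_that("passive epithelium settles at the Nernst-Donnan equilibrium", {
  set.seed(21)
  dc <- donnan_case()
  st <- solve_epithelium(list(conc = dc$bath[nephrosim:::SOLUTES], P = dc$P),
                         list(conc = dc$bath, P = dc$P),
                         dc$seg, tol = 1e-8, max_iter = 300)
  # every net flux vanishes (the defining property of the equilibrium;
  # the potential basin around it is extremely shallow)
  expect_lt(max(abs(st$net$J_L)), 1e-10)
  expect_lt(abs(st$net$Jv_L), 1e-9)
  expect_lt(max(abs(st$net$J_C)), 1e-10)
  # cell potential near the analytically predicted Donnan value and
  # transepithelial potential near zero
  expect_lt(abs(st$cell$V - dc$u_star), 0.5)
  expect_lt(abs(st$V_L), 2)
  expect_lt(abs(st$lat$V), 2)
  # concentrations at the Boltzmann-scaled bath values
  expect_equal(unname(st$cell$conc), unname(dc$cell_eq), tolerance = 0.02)
})

test_that("converged state conserves charge and water exactly", {
  st <- converged_pt()
  z <- nephrosim:::VALENCE[nephrosim:::SOLUTES]
  scale_J <- max(abs(st$net$J_C))
  # zero net current into each compartment (exact identity of the
  # residual closure)
  expect_lt(abs(sum(z * st$net$J_C)) / scale_J, 1e-8)
  expect_lt(abs(sum(z * st$net$J_P)) / scale_J, 1e-8)
  expect_lt(abs(sum(z * st$net$J_L)) / scale_J, 1e-8)
  # water entering each compartment equals water leaving
  expect_lt(abs(st$net$Jv_C) / max(abs(st$fluxes$Jv)), 1e-9)
  expect_lt(abs(st$net$Jv_P) / max(abs(st$fluxes$Jv)), 1e-9)
  # compartments are electroneutral
  expect_lt(abs(sum(z * st$lat$conc)), 1e-6)
  expect_lt(abs(sum(z * st$cell$conc) +
                  pt_case()$seg$cell$imp_z * st$cell$imp), 1e-6)
})

test_that("solution is invariant under a tighter tolerance", {
  cs <- pt_case()
  a <- solve_epithelium(cs$lum, cs$bath, cs$seg, tol = 1e-9)
  b <- solve_epithelium(cs$lum, cs$bath, cs$seg, tol = 1e-11)
  expect_equal(a$cell$conc, b$cell$conc, tolerance = 1e-6)
  expect_equal(a$cell$V, b$cell$V, tolerance = 1e-5)
})

test_that("warm start reproduces the cold-start solution", {
  cs <- pt_case()
  cold <- converged_pt()
  lum2 <- cs$lum
  lum2$conc["Na"] <- lum2$conc["Na"] * 0.98
  near <- solve_epithelium(lum2, cs$bath, cs$seg, guess = cold)
  warm <- solve_epithelium(cs$lum, cs$bath, cs$seg, guess = near)
  expect_equal(warm$cell$conc, cold$cell$conc, tolerance = 1e-7)
  expect_equal(warm$V_L, cold$V_L, tolerance = 1e-6)
  expect_equal(warm$lat$P, cold$lat$P, tolerance = 1e-5)
})

test_that("solver failure reports the worst residual rows", {
  cs <- pt_case()
  bad <- cs$seg
  bad$init_state$cell$conc["Na"] <- 1e6   # absurd start, tiny budget
  expect_error(solve_epithelium(cs$lum, cs$bath, bad, max_iter = 1),
               "worst residuals")
})
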