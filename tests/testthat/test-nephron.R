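# Axial march: luminal right-hand side, CCD merge, full baseline run,
# conservation audits and grid convergence.

test_that("an impermeable segment carries flows unchanged under falling pressure", {
  params <- reference_parameters()
  seg <- params$segments[["DCT"]]
  for (ifc in names(seg$interfaces)) {
    seg$interfaces[[ifc]]$rhoA[] <- 0
    seg$interfaces[[ifc]]$Lp <- 0
  }
  seg$transporters <- list()
  y <- nephrosim:::lstate_pack(nlmin_to_cm3s(10), 8, inflow_composition())
  k <- luminal_rhs(0.1, y, seg, params, interstitial_profile())
  flows <- k$dy[setdiff(names(k$dy), "P")]
  expect_true(all(flows == 0))
  expect_lt(k$dy[["P"]], 0)
  expect_equal(k$dy[["P"]],
               poiseuille_pressure_gradient(10, seg$geom$diameter_um / 2))
})

test_that("a water-only segment concentrates the lumen at constant solute flows", {
  params <- reference_parameters()
  seg <- params$segments[["DL"]]
  for (ifc in names(seg$interfaces)) seg$interfaces[[ifc]]$rhoA[] <- 0
  seg$transporters <- list()
  y <- nephrosim:::lstate_pack(nlmin_to_cm3s(20), 8, inflow_composition())
  k <- luminal_rhs(0.16, y, seg, params, interstitial_profile())
  # hypertonic medullary bath pulls water out; all solute flows constant
  expect_lt(k$dy[["wQ"]], 0)
  expect_true(all(k$dy[nephrosim:::LUMPED] == 0))
})

test_that("the CCD merge scales flow tenfold and conserves composition", {
  m <- merge_into_ccd(0.5, inflow_composition())
  expect_equal(m$Q_ccd, 5)
  expect_equal(as.numeric(m$conc), as.numeric(inflow_composition()),
               tolerance = 1e-9)
  # group totals conserved through re-equilibration
  set.seed(31)
  conc <- random_composition()
  m2 <- merge_into_ccd(1, conc)
  for (g in names(nephrosim:::GROUP_MEMBERS)) {
    mem <- nephrosim:::GROUP_MEMBERS[[g]]
    expect_equal(sum(m2$conc[mem]), sum(conc[mem]), tolerance = 1e-12)
  }
  expect_equal(sum(m2$conc[nephrosim:::PROTON_SPECIES]),
               sum(conc[nephrosim:::PROTON_SPECIES]), tolerance = 1e-12)
})

test_that("baseline run closes the per-segment mass audits", {
  sol <- baseline_solution()
  expect_lt(max(sol$audit$rel_error), 1e-6)
})

test_that("baseline water audit closes from filtration to urine", {
  sol <- baseline_solution()
  ss <- sol$segment_summary
  reab <- sum(ss$reabsorption[ss$quantity == "water"])
  expect_equal(sol$boundary$SNGFR_nlmin - reab,
               sol$urine$flow_nl_min_nephron, tolerance = 1e-6)
})

test_that("per-solute kidney mass balance closes for every carried quantity", {
  sol <- baseline_solution()
  ss <- sol$segment_summary
  filt <- ss[ss$segment == "PT-S1S2", ]
  urine <- ss[ss$segment == "IMCD", ]
  for (q in setdiff(unique(ss$quantity), "water")) {
    reab <- sum(ss$reabsorption[ss$quantity == q])
    expect_equal(filt$delivery_in[filt$quantity == q] - reab,
                 urine$delivery_out[urine$quantity == q],
                 tolerance = 1e-6)
  }
})

test_that("baseline flow stays positive and pressure falls within segments", {
  sol <- baseline_solution()
  pr <- sol$profile
  expect_true(all(pr$Q_nlmin > 0))
  expect_true(all(pr$wQ_nlmin > 0))
  for (s in unique(pr$segment)) {
    expect_true(all(diff(pr$P_mmHg[pr$segment == s]) < 0))
  }
})

test_that("glucose uptake is dominated by the convoluted proximal segment", {
  sol <- baseline_solution()
  ss <- sol$segment_summary
  g1 <- ss$reabsorption[ss$segment == "PT-S1S2" & ss$quantity == "glucose"]
  g3 <- ss$reabsorption[ss$segment == "PT-S3" & ss$quantity == "glucose"]
  filt <- ss$delivery_in[ss$segment == "PT-S1S2" & ss$quantity == "glucose"]
  # roughly a 90/10 split between SGLT2 (S1-S2) and SGLT1 (S3)
  expect_gt(g1 / filt, 0.7)
  expect_gt(g1, 4 * g3)
  expect_gt(g3, 0)
})

test_that("luminal osmolality tracks the interstitium in water-permeable segments", {
  sol <- baseline_solution()
  pr <- sol$profile
  prof <- interstitial_profile()
  geom <- segment_geometry()
  for (s in c("DL", "CCD", "OMCD", "IMCD")) {
    rows <- pr[pr$segment == s, ]
    g <- geom[geom$name == s, ]
    depth <- g$depth0 + (rows$x_seg / g$length_cm) * (g$depth1 - g$depth0)
    osm_int <- vapply(depth, function(d) {
      osmolality(nephrosim:::interstitial_species(d, prof))
    }, numeric(1))
    # within a 30% band of the local interstitial osmolality
    expect_true(all(abs(rows$osmolality / osm_int - 1) < 0.3))
  }
})

test_that("halving the axial step changes the urine by less than 0.1%", {
  a <- baseline_solution()$urine
  b <- halved_grid_solution()$urine
  keysp <- c("Na", "K", "Cl", "urea", "glucose", "HCO3")
  expect_lt(max(abs(a$conc[keysp] / b$conc[keysp] - 1)), 1e-3)
  expect_lt(abs(a$flow_ml_min_kidney / b$flow_ml_min_kidney - 1), 1e-3)
})

test_that("luminal fluid remains electroneutral along the whole nephron", {
  sol <- baseline_solution()
  pr <- sol$profile
  z <- nephrosim:::VALENCE[nephrosim:::SOLUTES]
  charge <- as.matrix(pr[, nephrosim:::SOLUTES]) %*% z
  expect_lt(max(abs(charge)) / max(pr$Na), 1e-5)
})

test_that("errors during the march carry segment and position", {
  params <- reference_parameters()
  # too coarse a grid with a perturbed start eventually defeats the
  # stage solves; the structured error names the segment and position
  params$segments[["PT-S1S2"]]$init_state$cell$conc["Na"] <- 1e9
  err <- tryCatch(
    simulate_nephron(params, steps_per_segment = 4, tol = 1e-10),
    error = function(e) e)
  expect_s3_class(err, "nephron_error")
  expect_match(conditionMessage(err), "segment .+ at x = ")
})
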