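# Scenario machinery, urine report arithmetic, fold changes, and the
# directional behaviour of the inhibition and SNGFR experiments.

test_that("experiment presets carry the study design values", {
  sg <- experiment_preset("sglt2")
  expect_equal(sg$sngfr_scale, 0.97)
  expect_equal(unname(sg$inhibit["SGLT2"]), 0.9)
  expect_false(sg$washout)
  nk <- experiment_preset("nkcc2")
  expect_equal(unname(nk$inhibit["NKCC2"]), 0.8)
  expect_true(nk$washout)
  expect_equal(experiment_preset("sngfr+10")$sngfr_scale, 1.1)
  expect_error(experiment_spec("x", sngfr_scale = -1), "positive")
  expect_error(experiment_spec("x", inhibit = c(SGLT2 = 1.2)), "0, 1")
  expect_error(experiment_preset("remnant"), "unknown")
})

test_that("an identity spec reproduces the plain baseline run exactly", {
  r <- experiment_run("baseline", n = 24)
  direct <- cached("direct24",
                   function() simulate_nephron(steps_per_segment = 24,
                                               tol = 1e-9))
  expect_identical(r$solution$urine$conc, direct$urine$conc)
  expect_identical(r$solution$urine$flow_ml_min_kidney,
                   direct$urine$flow_ml_min_kidney)
})

test_that("excretion arithmetic reproduces the conventional bookkeeping", {
  plasma <- interstitial_profile()$anchors$cortex
  rep <- excretion_report(0.62, c(Na = 73, K = 72), 100, plasma)
  tb <- rep$table
  # per person: 2 kidneys; 91 umol/min Na after rounding
  expect_equal(round(tb$excretion_umol_min_person[tb$solute == "Na"]), 91)
  expect_equal(tb$excretion_umol_min_person[tb$solute == "Na"],
               0.62 * 73 * 2)
  # fractional K excretion 11.2% -> 11%
  feK <- tb$fractional_excretion_pct[tb$solute == "K"]
  expect_equal(round(feK), 11)
  expect_equal(feK, 100 * 0.62 * 72 / (100 * 4), tolerance = 1e-12)
  # 1.8 L/24h per person
  expect_equal(round(rep$flow_L_day_person, 1), 1.8)
  # zero urine concentration -> zero excretion
  rep0 <- excretion_report(0.62, c(Na = 0), 100, plasma)
  expect_equal(rep0$table$excretion_umol_min_kidney, 0)
  expect_equal(rep0$table$fractional_excretion_pct, 0)
  expect_error(excretion_report(0, c(Na = 73), 100, plasma), "positive")
})

test_that("report comparison recovers printed fold changes", {
  plasma <- interstitial_profile()$anchors$cortex
  base <- excretion_report(0.62, c(Na = 73, K = 72, Cl = 69), 100, plasma)
  same <- compare_reports(base, base)
  expect_true(all(same$fold == 1))
  nk <- excretion_report(1.7, c(Na = 47, K = 62, Cl = 87), 100, plasma)
  cmp <- compare_reports(nk, base)
  expect_equal(cmp$fold_rounded[cmp$quantity == "Na"], 1.8)
  expect_equal(cmp$fold_rounded[cmp$quantity == "K"], 2.4)
  sg <- excretion_report(1.5, c(Na = 44, K = 52, Cl = 69), 97, plasma)
  cmp2 <- compare_reports(sg, base)
  expect_equal(round(cmp2$percent_change[cmp2$quantity == "Na"]), 46)
})

test_that("SGLT2 inhibition produces osmotic diuresis and glucosuria", {
  base <- experiment_run("baseline")$report
  sg <- experiment_run("sglt2")$report
  cmp <- compare_reports(sg, base)
  for (q in c("flow", "Na", "K", "glucose")) {
    expect_gt(cmp$fold[cmp$quantity == q], 1)
  }
  # most filtered glucose escapes reabsorption
  expect_gt(sg$table$fractional_excretion_pct[sg$table$solute == "glucose"],
            30)
})

test_that("NKCC2 inhibition with washout produces diuresis and natriuresis", {
  base <- experiment_run("baseline")$report
  nk <- experiment_run("nkcc2")$report
  cmp <- compare_reports(nk, base)
  for (q in c("flow", "Na", "K", "Cl")) {
    expect_gt(cmp$fold[cmp$quantity == q], 1)
  }
})

test_that("proximal sodium reabsorption rises with SNGFR", {
  reab_pt <- function(run) {
    ss <- run$solution$segment_summary
    sum(ss$reabsorption[ss$segment %in% c("PT-S1S2", "PT-S3") &
                          ss$quantity == "Na"])
  }
  up <- experiment_run("sngfr+10")
  dn <- experiment_run("sngfr-10")
  base <- experiment_run("baseline")
  r0 <- reab_pt(base); r_up <- reab_pt(up); r_dn <- reab_pt(dn)
  expect_gt(r_up, r0)
  expect_gt(r0, r_dn)
  # approximate glomerulotubular balance: fractional reabsorption moves
  # by less than 5 percentage points across the +-10% sweep
  frac <- function(run) {
    ss <- run$solution$segment_summary
    reab_pt(run) / ss$delivery_in[ss$segment == "PT-S1S2" &
                                    ss$quantity == "Na"]
  }
  expect_lt(abs(frac(up) - frac(base)), 0.05)
  expect_lt(abs(frac(dn) - frac(base)), 0.05)
})

test_that("torque scaling carries the SNGFR response of the proximal tubule", {
  ab <- ablation_reab()
  change_on <- ab$on_110 - ab$on_100
  change_off <- ab$off_110 - ab$off_100
  expect_gt(change_on, 0)
  # disabling the torque mechanism removes most of the response
  expect_lt(abs(change_off), 0.5 * abs(change_on))
})

test_that("baseline urine flow lies in the physiological window", {
  flow <- experiment_run("baseline")$report$flow_ml_min_kidney
  expect_gte(flow, 0.55)
  expect_lte(flow, 1.4)
})
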