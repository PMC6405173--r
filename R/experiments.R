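# The study scenarios: baseline, SNGFR variation, SGLT2 inhibition and
# NKCC2 inhibition, plus the urine report arithmetic (excretions,
# fractional excretions, fold changes).

#' Experiment descriptor
#'
#' @param name experiment label
#' @param sngfr_scale multiplicative SNGFR scaling (1 = baseline; the
#'   SGLT2-inhibition scenario uses 0.97)
#' @param inhibit named vector of inhibition fractions in [0, 1] applied
#'   to transporter kinds (e.g. \code{c(SGLT2 = 0.9)}); densities are
#'   multiplied by (1 - fraction)
#' @param washout if TRUE, use the NKCC2 medullary-washout interstitial
#'   profile
#' @param torque_off if TRUE, disable the flow-dependent torque scaling
#'   (ablation runs)
#' @return an object of class \code{experiment_spec}
#' @export
experiment_spec <- function(name = "baseline", sngfr_scale = 1,
                            inhibit = c(), washout = FALSE,
                            torque_off = FALSE) {
  if (sngfr_scale <= 0) stop("SNGFR scale must be positive")
  if (length(inhibit) && (any(inhibit < 0) || any(inhibit > 1))) {
    stop("inhibition fractions must lie in [0, 1]")
  }
  structure(list(name = name, sngfr_scale = sngfr_scale,
                 inhibit = inhibit, washout = washout,
                 torque_off = torque_off),
            class = "experiment_spec")
}

#' Named experiment presets
#'
#' \code{"baseline"}; \code{"sngfr+10"} / \code{"sngfr-10"} (SNGFR varied
#' by 10\%); \code{"sglt2"} (90\% SGLT2 inhibition with SNGFR reduced by
#' 3\%); \code{"nkcc2"} (80\% NKCC2 inhibition with the medullary washout
#' interstitium).
#'
#' @param name preset name
#' @return an \code{\link{experiment_spec}}
#' @export
experiment_preset <- function(name) {
  switch(name,
    baseline   = experiment_spec("baseline"),
    `sngfr+10` = experiment_spec("sngfr+10", sngfr_scale = 1.1),
    `sngfr-10` = experiment_spec("sngfr-10", sngfr_scale = 0.9),
    sglt2      = experiment_spec("sglt2", sngfr_scale = 0.97,
                                 inhibit = c(SGLT2 = 0.9)),
    nkcc2      = experiment_spec("nkcc2", inhibit = c(NKCC2 = 0.8),
                                 washout = TRUE),
    stop("unknown experiment preset: ", name))
}

apply_inhibition <- function(params, inhibit) {
  if (!length(inhibit)) return(params)
  for (s in names(params$segments)) {
    params$segments[[s]]$transporters <-
      lapply(params$segments[[s]]$transporters, function(tr) {
        f <- unname(inhibit[tr$kind])
        if (is.na(f)) return(tr)
        if (tr$kind %in% c("SGLT2", "SGLT1")) {
          tr$params$density <- tr$params$density * (1 - f)
        } else if (tr$kind == "NKCC2") {
          tr$params$E_T <- tr$params$E_T * (1 - f)
        } else {
          tr$density <- tr$density * (1 - f)
        }
        tr
      })
  }
  params
}

disable_torque <- function(params) {
  for (s in names(params$segments)) {
    params$segments[[s]]$geom$torque_s <- 0
  }
  params
}

#' Run one experiment
#'
#' Applies the descriptor to the parameter set (SNGFR scaling, transporter
#' inhibition, interstitial profile selection), runs the nephron, and
#' builds the urine report against the cortical plasma concentrations.
#'
#' @param spec an \code{\link{experiment_spec}} or preset name
#' @param params base parameter set
#' @param steps_per_segment axial resolution
#' @param tol epithelial solver tolerance
#' @return list with the \code{solution} (axial_solution) and
#'   \code{report} (urine_report)
#' @export
run_experiment <- function(spec = "baseline",
                           params = reference_parameters(),
                           steps_per_segment = 200, tol = 1e-10) {
  if (is.character(spec)) spec <- experiment_preset(spec)
  prof <- interstitial_profile(washout = spec$washout)
  p <- apply_inhibition(params, spec$inhibit)
  if (spec$torque_off) p <- disable_torque(p)
  sngfr <- params$SNGFR_nlmin * spec$sngfr_scale
  sol <- simulate_nephron(p, boundary = list(
    SNGFR_nlmin = sngfr,
    pressure_mmHg = params$inflow_pressure_mmHg
  ), profile = prof, steps_per_segment = steps_per_segment, tol = tol)
  plasma <- interstitial_profile()$anchors$cortex
  rep <- excretion_report(sol$urine$flow_ml_min_kidney, sol$urine$conc,
                          sngfr, plasma, pH = sol$urine$pH,
                          osmolality = sol$urine$osmolality,
                          name = spec$name)
  list(solution = sol, report = rep)
}

#' Urine excretion report
#'
#' Converts a urine flow and composition into excretions and fractional
#' excretions: excretion = flow x concentration per kidney; per-person
#' values assume 2 kidneys x 1e6 nephrons and 1440 min per day; filtered
#' load per kidney = SNGFR x 1e6 x plasma concentration. Raw values are
#' reported alongside the conventionally rounded ones.
#'
#' @param flow_ml_min urine flow per kidney, ml/min
#' @param urine_conc named urine concentrations, mM
#' @param SNGFR_nlmin single-nephron GFR, nl/min
#' @param plasma_conc named cortical plasma concentrations, mM
#' @param pH,osmolality optional urine pH and osmolality to carry along
#' @param name report label
#' @return an object of class \code{urine_report}: flows (per kidney and
#'   per person), a per-solute table with excretion (umol/min per kidney
#'   and per person) and fractional excretion (\% of filtered load)
#' @export
excretion_report <- function(flow_ml_min, urine_conc, SNGFR_nlmin,
                             plasma_conc, pH = NA, osmolality = NA,
                             name = "urine") {
  if (flow_ml_min <= 0) stop("urine flow must be positive")
  solutes <- names(urine_conc)
  gfr_ml_min <- SNGFR_nlmin * ns_const$nephrons_per_kidney * 1e-6
  exc_kidney <- flow_ml_min * unlist(urine_conc)       # umol/min per kidney
  exc_person <- exc_kidney * ns_const$kidneys_per_person
  filtered <- gfr_ml_min * unlist(plasma_conc[solutes])
  fe <- ifelse(filtered > 0, 100 * exc_kidney / filtered, NA)
  structure(list(
    name = name,
    flow_ml_min_kidney = flow_ml_min,
    flow_ml_min_person = flow_ml_min * ns_const$kidneys_per_person,
    flow_L_day_person = flow_ml_min * ns_const$kidneys_per_person *
      ns_const$min_per_day / 1000,
    SNGFR_nlmin = SNGFR_nlmin,
    pH = pH, osmolality = osmolality,
    table = data.frame(
      solute = solutes,
      conc_mM = unname(unlist(urine_conc)),
      excretion_umol_min_kidney = unname(exc_kidney),
      excretion_umol_min_person = unname(exc_person),
      filtered_umol_min_kidney = unname(filtered),
      fractional_excretion_pct = unname(fe),
      stringsAsFactors = FALSE
    )
  ), class = "urine_report")
}

#' Compare two urine reports
#'
#' Fold changes and percent changes of urine flow and per-solute
#' excretion of a test report against a reference report. Raw ratios are
#' reported with conventionally rounded companions (2 significant figures
#' for folds).
#'
#' @param test,reference \code{urine_report} objects over the same solutes
#' @return data.frame of fold changes and percent changes
#' @export
compare_reports <- function(test, reference) {
  stopifnot(identical(test$table$solute, reference$table$solute))
  flow_fold <- test$flow_ml_min_kidney / reference$flow_ml_min_kidney
  folds <- test$table$excretion_umol_min_kidney /
    reference$table$excretion_umol_min_kidney
  out <- data.frame(
    quantity = c("flow", test$table$solute),
    fold = c(flow_fold, folds),
    fold_rounded = signif(c(flow_fold, folds), 2),
    percent_change = 100 * (c(flow_fold, folds) - 1),
    stringsAsFactors = FALSE
  )
  out
}

#' @export
print.urine_report <- function(x, ...) {
  cat(sprintf("Urine report '%s': flow %.3g ml/min/kidney (%.2g L/24h/person)\n",
              x$name, x$flow_ml_min_kidney, x$flow_L_day_person))
  if (is.finite(x$pH)) {
    cat(sprintf("  pH %.3g, osmolality %.4g mosm/kg\n", x$pH, x$osmolality))
  }
  key <- x$table[x$table$solute %in% c("Na", "K", "Cl", "urea", "glucose"), ]
  print(key, row.names = FALSE, digits = 3)
  invisible(x)
}
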