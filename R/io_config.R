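# Configuration serialization, validation, deterministic outputs and the
# reference fixture writer.

#' Write the reference fixture to a config directory
#'
#' Serializes the complete reference configuration as four human-diffable
#' YAML files: \code{architecture.yaml} (segment geometry, compliance,
#' torque constants, coalescence rules), \code{interstitium.yaml} (anchor
#' tables and the NKCC2 washout overrides), \code{parameters.yaml}
#' (per-segment membrane and transporter parameters, pKa values, cell
#' impermeants) and \code{experiments.yaml} (the four scenario
#' descriptors). Every leaf carries a provenance flag: \code{"paper"} for
#' values printed in the source model description (geometry, SNGFR,
#' inflow pressure, viscosity, compliance and torque constants,
#' interstitial anchors), \code{"fixture"} for the stand-in transport
#' parameter set. Output is deterministic.
#'
#' @param dir output directory (created if needed)
#' @return invisibly, the vector of file paths written
#' @export
generate_reference_fixture <- function(dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  params <- reference_parameters()
  geom <- segment_geometry()

  arch <- list(
    provenance = list(geometry = "paper", medulla = "paper",
                      pt_split = "fixture", depth_map = "fixture"),
    medulla_cm = MEDULLA_CM, outer_medulla_cm = OM_DEPTH_CM,
    viscosity_mmHg_s = ns_const$visc_mmHg_s,
    SNGFR_nlmin = params$SNGFR_nlmin,
    inflow_pressure_mmHg = params$inflow_pressure_mmHg,
    interstitial_pressure_mmHg = params$P_interstitium_mmHg,
    nephrons_per_kidney = params$nephrons_per_kidney,
    segments = lapply(seq_len(nrow(geom)), function(i) as.list(geom[i, ]))
  )

  inter <- list(
    provenance = list(anchors = "paper", washout = "paper",
                      pKa = "fixture (phosphate 6.8 paper-fixed)"),
    pKa = list(co2pair = PKA_CO2PAIR, phosphate = PKA_PHOS,
               ammonia = PKA_AMMONIA, formate = PKA_FORMATE),
    anchors = TABLE2,
    nkcc2_washout = NKCC2_WASHOUT
  )

  ser_tr <- function(tr) {
    out <- list(interface = tr$interface, kind = tr$kind,
                torque_scalable = isTRUE(tr$torque_scalable))
    if (!is.null(tr$density)) out$density <- tr$density
    if (!is.null(tr$params)) out$params <- unclass(tr$params)
    out
  }
  ser_seg <- function(seg) {
    list(
      cell_impermeant_mM = seg$cell$imp_mM,
      cell_impermeant_valence = seg$cell$imp_z,
      interfaces = lapply(seg$interfaces, function(ifc) {
        list(A_cm2_per_cm = ifc$A, Lp_cm_s_mmHg = ifc$Lp,
             rho_cm_s = as.list(ifc$rho), sigma = as.list(ifc$sigma))
      }),
      transporters = lapply(seg$transporters, ser_tr)
    )
  }
  pars <- list(
    provenance = list(transport = "fixture",
                      note = paste("densities/permeabilities are the",
                                   "documented stand-in set; the source",
                                   "rodent values are unpublished here")),
    segments = lapply(params$segments, ser_seg)
  )

  expts <- list(
    provenance = list(descriptors = "paper"),
    experiments = lapply(c("baseline", "sngfr+10", "sngfr-10",
                           "sglt2", "nkcc2"),
                         function(n) unclass(experiment_preset(n)))
  )

  paths <- file.path(dir, c("architecture.yaml", "interstitium.yaml",
                            "parameters.yaml", "experiments.yaml"))
  yaml::write_yaml(arch, paths[1], precision = 12)
  yaml::write_yaml(inter, paths[2], precision = 12)
  yaml::write_yaml(pars, paths[3], precision = 12)
  yaml::write_yaml(expts, paths[4], precision = 12)
  invisible(paths)
}

#' Load and validate a configuration directory
#'
#' Reads the four YAML files written by
#' \code{\link{generate_reference_fixture}}, validates them (every
#' segment present with positive geometry; every solute given a
#' permeability and an in-range reflection coefficient on every
#' interface; transporter kinds registered; experiment descriptors
#' well-formed) and materializes the parameter objects.
#'
#' @param dir configuration directory
#' @return a \code{model_config} list with \code{params} (materialized
#'   parameter set), \code{experiments}, and the raw parsed files
#' @export
load_and_validate <- function(dir) {
  need <- c("architecture.yaml", "interstitium.yaml", "parameters.yaml",
            "experiments.yaml")
  paths <- file.path(dir, need)
  missing <- need[!file.exists(paths)]
  if (length(missing)) {
    stop("config error: missing file(s) ", paste(missing, collapse = ", "),
         " in ", dir)
  }
  arch <- yaml::read_yaml(paths[1])
  inter <- yaml::read_yaml(paths[2])
  pars <- yaml::read_yaml(paths[3])
  expts <- yaml::read_yaml(paths[4])

  segnames <- vapply(arch$segments, function(s) s$name, character(1))
  for (s in SEGMENT_ORDER) {
    if (!s %in% segnames) {
      stop("config error in architecture.yaml: segment '", s, "' missing")
    }
  }
  for (s in SEGMENT_ORDER) {
    blk <- pars$segments[[s]]
    if (is.null(blk)) {
      stop("config error in parameters.yaml: segment '", s, "' missing")
    }
    for (ifc in INTERFACES) {
      mp <- blk$interfaces[[ifc]]
      if (is.null(mp)) {
        stop("config error in parameters.yaml: segment '", s,
             "' interface '", ifc, "' missing")
      }
      if (!is.numeric(mp$A_cm2_per_cm) || mp$A_cm2_per_cm <= 0) {
        stop("config error: non-positive area for ", s, "/", ifc)
      }
      sg <- unlist(mp$sigma)
      if (any(sg < 0 | sg > 1)) {
        stop("config error: reflection coefficient outside [0,1] for ",
             s, "/", ifc, " (", paste(names(sg)[sg < 0 | sg > 1],
                                      collapse = ","), ")")
      }
      rho <- unlist(mp$rho_cm_s)
      lack <- setdiff(SOLUTES, names(rho))
      if (length(lack)) {
        stop("config error: missing permeability for ",
             paste(lack, collapse = ","), " on ", s, "/", ifc)
      }
      if (any(rho < 0)) stop("config error: negative permeability on ",
                             s, "/", ifc)
    }
    for (tr in blk$transporters) {
      if (!tr$kind %in% c(names(NS_KINETICS), "ENaC", "SGLT2", "SGLT1",
                          "NKCC2")) {
        stop("config error: unknown transporter kind '", tr$kind,
             "' in segment ", s)
      }
      if (!tr$interface %in% CELL_MEMBRANES) {
        stop("config error: transporter on non-cell interface ",
             tr$interface, " in segment ", s)
      }
    }
  }
  for (ex in expts$experiments) {
    if (!is.null(ex$inhibit) && length(ex$inhibit) &&
        (any(unlist(ex$inhibit) < 0) || any(unlist(ex$inhibit) > 1))) {
      stop("config error: inhibition fraction outside [0,1] in experiment ",
           ex$name)
    }
  }

  # materialize: rebuild the in-memory set and overlay the file's
  # transport parameters (the file is authoritative for densities etc.)
  params <- reference_parameters()
  for (s in SEGMENT_ORDER) {
    blk <- pars$segments[[s]]
    for (ifc in INTERFACES) {
      mp <- blk$interfaces[[ifc]]
      rho <- unlist(mp$rho_cm_s)[SOLUTES]
      sig <- unlist(mp$sigma)[SPECIES]
      params$segments[[s]]$interfaces[[ifc]]$A <- mp$A_cm2_per_cm
      params$segments[[s]]$interfaces[[ifc]]$Lp <- mp$Lp_cm_s_mmHg
      params$segments[[s]]$interfaces[[ifc]]$rho <- rho
      params$segments[[s]]$interfaces[[ifc]]$rhoA <- rho * mp$A_cm2_per_cm
      params$segments[[s]]$interfaces[[ifc]]$sigma <- sig
    }
    params$segments[[s]]$cell$imp_mM <- blk$cell_impermeant_mM
    params$segments[[s]]$cell$imp_z <- blk$cell_impermeant_valence
    params$segments[[s]]$transporters <-
      lapply(blk$transporters, function(tr) {
        p <- NULL
        if (tr$kind %in% c("SGLT2", "SGLT1")) {
          p <- do.call(sglt2_params, tr$params)
        } else if (tr$kind == "NKCC2") {
          pp <- tr$params
          p <- nkcc2_params(E_T = pp$E_T,
                            kon_lum = unlist(pp$kon_lum),
                            koff_lum = unlist(pp$koff_lum),
                            kon_cyt = unlist(pp$kon_cyt),
                            koff_cyt = unlist(pp$koff_cyt),
                            k_ff = pp$k_ff, k_bf = pp$k_bf,
                            k_fe = pp$k_fe, k_be = pp$k_be)
        }
        mk_tr(tr$interface, tr$kind, density = tr$density, params = p,
              torque_scalable = isTRUE(tr$torque_scalable))
      })
  }
  params$SNGFR_nlmin <- arch$SNGFR_nlmin
  params$inflow_pressure_mmHg <- arch$inflow_pressure_mmHg
  params$P_interstitium_mmHg <- arch$interstitial_pressure_mmHg

  structure(list(params = params,
                 experiments = expts$experiments,
                 architecture = arch, interstitium = inter,
                 parameters = pars),
            class = "model_config")
}

#' Write axial profiles and summaries
#'
#' Writes the axial profile as a CSV (fixed column order, \code{\%.12g}
#' float format) and the segment summary plus urine report as a JSON
#' file. Output is byte-deterministic for a given solution.
#'
#' @param solution an \code{axial_solution}
#' @param dir output directory
#' @return invisibly, the paths written
#' @export
write_profiles <- function(solution, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  csv <- file.path(dir, "axial_profile.csv")
  df <- solution$profile
  num <- vapply(df, is.numeric, logical(1))
  out <- df
  out[num] <- lapply(df[num], function(x) sprintf("%.12g", x))
  utils::write.csv(out, csv, row.names = FALSE, quote = FALSE)

  js <- file.path(dir, "summary.json")
  summary <- list(
    boundary = solution$boundary,
    urine = list(
      flow_ml_min_kidney = solution$urine$flow_ml_min_kidney,
      flow_nl_min_nephron = solution$urine$flow_nl_min_nephron,
      pH = solution$urine$pH,
      osmolality = solution$urine$osmolality,
      pressure_mmHg = solution$urine$pressure_mmHg,
      conc = as.list(solution$urine$conc)
    ),
    segment_summary = solution$segment_summary,
    audit = solution$audit
  )
  jsonlite::write_json(summary, js, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(c(csv, js))
}

#' Read back a written axial profile
#'
#' @param path CSV path written by \code{\link{write_profiles}}
#' @return data.frame
#' @export
read_profile_csv <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}
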