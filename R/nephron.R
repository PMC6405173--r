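# Axial integration of the luminal conservation equations along the
# segment sequence PT-S1S2 -> PT-S3 -> DL -> mTAL -> cTAL -> DCT -> CNT ->
# (CCD merge) -> CCD -> OMCD -> IMCD, with the epithelial algebraic solve
# embedded at every evaluation point (quasi-static coupling).
#
# The marched state is expressed in per-nephron flows (omega * Q and
# omega * Q * C), which is algebraically equivalent to the coalescing
# luminal equations and makes segment mass audits telescope exactly:
#   d(omega Q)/dx = -omega Jv_L,  d(omega Q C_k)/dx = -omega J_k,L
# Reacting solutes are carried as buffer-group totals plus the proton
# total; species are recovered at each point by re-equilibrating the four
# pairs (a strictly monotone scalar pH solve).

# luminal state vector layout: wQ (cm^3/s per nephron), P (mmHg), then
# per-nephron flows of the 6 solo solutes, 4 pair totals and proton total.
LSTATE <- c("wQ", "P", LUMPED)

lstate_pack <- function(wQ, P, conc) {
  lump <- lump_species(conc)
  y <- c(wQ, P, wQ * unlist(lump))
  names(y) <- LSTATE
  y
}

lstate_conc <- function(y) {
  lump <- as.list(y[LUMPED] / y[["wQ"]])
  unlump_species(lump)
}

#' Luminal conservation right-hand side
#'
#' Derivatives of the marched luminal state at one axial position:
#' per-nephron water and solute flows (non-reacting solutes individually,
#' reacting solutes as buffer-group totals plus the proton total) and the
#' Poiseuille pressure equation, with coalescence entering through the
#' tubule population fraction. The embedded epithelial steady state is
#' solved as part of the evaluation.
#'
#' @param x_seg position within the segment, cm
#' @param y named luminal state vector (\code{wQ}, \code{P}, flows)
#' @param seg segment parameter block
#' @param params full model parameter set
#' @param profile interstitial profile
#' @param guess warm-start epithelial state (NULL for the segment default)
#' @param tol epithelial solver tolerance
#' @return list with \code{dy}, the converged epithelial \code{state}, and
#'   geometry diagnostics (\code{omega}, \code{Q_nlmin}, \code{r_um},
#'   \code{tscale}, luminal concentrations and pH)
#' @export
luminal_rhs <- function(x_seg, y, seg, params, profile, guess = NULL,
                        tol = 1e-10, cache = NULL) {
  g <- seg$geom
  L <- g$length_cm
  omega <- population_fraction(g$population_rule, x_seg, L) * g$omega0
  wQ <- y[["wQ"]]
  if (wQ <= 0) stop("luminal flow became non-positive in ", seg$name)
  Q_cm3s <- wQ / omega
  Q_nl <- cm3s_to_nlmin(Q_cm3s)
  P <- y[["P"]]
  r_um <- if (g$compliant) {
    compliant_radius(P, g$r0_um, g$P0_mmHg, g$nu_per_mmHg)
  } else g$diameter_um / 2
  tscale <- 1
  if (g$torque_s > 0) {
    tau <- microvillous_torque(Q_nl, r_um, g$lmv_um, g$dmv_um)
    tscale <- torque_scale_factor(tau, params$tau0, g$torque_s)
  }
  conc <- lstate_conc(y)
  depth <- g$depth0 + (x_seg / L) * (g$depth1 - g$depth0)
  bath <- interstitial_species(depth, profile)
  st <- solve_epithelium(
    luminal = list(conc = conc, P = P),
    interstitial = list(conc = bath, P = params$P_interstitium_mmHg),
    params = seg, guess = guess, tscale = tscale, tol = tol, cache = cache
  )
  J_L <- st$net$J_L
  dy <- numeric(length(LSTATE)); names(dy) <- LSTATE
  dy[["wQ"]] <- -omega * st$net$Jv_L
  dy[["P"]] <- poiseuille_pressure_gradient(Q_nl, r_um)
  for (k in NONREACTING) dy[[k]] <- -omega * J_L[[k]]
  for (gname in names(GROUP_MEMBERS)) {
    dy[[gname]] <- -omega * sum(J_L[GROUP_MEMBERS[[gname]]])
  }
  dy[["Mproton"]] <- -omega * sum(J_L[PROTON_SPECIES])
  list(dy = dy, state = st, omega = omega, Q_nlmin = Q_nl, r_um = r_um,
       tscale = tscale, conc = conc, pH = attr(conc, "pH"))
}

#' Cortical collecting duct merge
#'
#' Applies the 10:1 junction between the surviving connecting tubules and
#' the cortical collecting duct: per-tubule flow is multiplied by 10,
#' non-reacting solute flows scale with it (concentrations preserved),
#' buffer-group totals and the proton total are conserved, and the pairs
#' are re-equilibrated.
#'
#' @param Q_cnt per-nephron CNT outflow, nl/min
#' @param conc named luminal species concentrations at the CNT exit, mM
#' @return list with \code{Q_ccd} (per-tubule CCD inflow, nl/min) and
#'   re-equilibrated \code{conc}
#' @export
merge_into_ccd <- function(Q_cnt, conc) {
  lump <- lump_species(conc)
  conc2 <- unlump_species(as.list(lump))
  list(Q_ccd = 10 * Q_cnt, conc = conc2)
}

# --- stiffly stable axial integrator ---------------------------------------
#
# The luminal system is stiff: highly permeant species (CO2, NH3) relax to
# quasi-equilibrium with the epithelium over length scales much shorter
# than practical axial steps, especially at low distal flows. Steps are
# therefore taken with TR-BDF2 (one-step, L-stable, second order), each
# implicit stage solved by simplified Newton with a lazily refreshed
# finite-difference Jacobian of the luminal right-hand side.

TRBDF2_GAMMA <- 2 - sqrt(2)

# finite-difference Jacobian of dy with respect to y (13 x 13)
luminal_fd_jacobian <- function(x, y, f0, seg, params, profile, warm, tol,
                                cache = NULL) {
  n <- length(y)
  B <- matrix(0, n, n, dimnames = list(LSTATE, LSTATE))
  for (i in seq_len(n)) {
    h <- 1e-6 * max(abs(y[[i]]), 1e-10)
    yi <- y; yi[[i]] <- yi[[i]] + h
    fi <- tryCatch(
      luminal_rhs(x, yi, seg, params, profile, guess = warm, tol = tol,
                  cache = cache),
      error = function(e) NULL)
    if (is.null(fi)) next
    B[, i] <- (fi$dy - f0$dy) / h
  }
  B
}

# solve z = const + beta*h*f(x_z, z) by simplified Newton
solve_stage <- function(zg, const, beta, h, x_z, seg, params, profile,
                        warm, B, tol, cache = NULL) {
  M <- diag(length(zg)) - beta * h * B
  lu <- tryCatch(qr(M), error = function(e) NULL)
  if (is.null(lu)) return(list(ok = FALSE))
  z <- zg
  fz <- NULL
  sc <- pmax(abs(const), 1e-14)
  pos <- setdiff(seq_along(z), 2L)   # all flows positive; P unconstrained
  for (it in 1:14) {
    fz <- tryCatch(
      luminal_rhs(x_z, z, seg, params, profile, guess = warm, tol = tol,
                  cache = cache),
      error = function(e) NULL)
    if (is.null(fz)) return(list(ok = FALSE))
    warm <- fz$state
    g <- z - const - beta * h * fz$dy
    if (max(abs(g) / sc) < 1e-9) {
      return(list(ok = TRUE, z = z, f = fz, warm = warm, iters = it))
    }
    dz <- -qr.coef(lu, g)
    if (any(is.na(dz))) return(list(ok = FALSE))
    lam <- 1
    while (any(z[pos] + lam * dz[pos] <= 0) && lam > 2^-12) lam <- lam / 2
    if (lam <= 2^-12) return(list(ok = FALSE))
    z <- z + lam * dz
  }
  list(ok = FALSE)
}

# One TR-BDF2 step from x over width h. Returns the new state, the
# right-hand sides at the three stage points (for flux accumulation with
# the scheme's own quadrature weights) and the warm state.
trbdf2_step <- function(x, h, y, fn0, seg, params, profile, warm, B, tol,
                        cache = NULL, depth = 0) {
  g <- TRBDF2_GAMMA
  d <- g * (2 - g)
  w_tr <- g / (2 * d)              # weight of f_n and f* in y_{n+1}-y_n
  w_bdf <- (1 - g) / (2 - g)       # weight of f_{n+1}
  fail <- function() {
    if (depth >= 5) stop("axial step failed after repeated halving")
    # refresh the right-hand-side Jacobian before sub-stepping: a stale
    # one is the usual cause of a rejected stage
    Bf <- luminal_fd_jacobian(x, y, fn0, seg, params, profile, warm, tol,
                              cache)
    s1 <- trbdf2_step(x, h / 2, y, fn0, seg, params, profile, warm, Bf, tol,
                      cache, depth + 1)
    s2 <- trbdf2_step(x + h / 2, h / 2, s1$y, s1$fend, seg, params, profile,
                      s1$warm, Bf, tol, cache, depth + 1)
    list(y = s2$y, fend = s2$fend, warm = s2$warm,
         flux = s1$flux + s2$flux)
  }

  # stage 1: trapezoid to x + gamma*h
  const1 <- y + (g * h / 2) * fn0$dy
  zg <- y + (g * h) * fn0$dy
  s1 <- solve_stage(zg, const1, g / 2, h, x + g * h, seg, params, profile,
                    warm, B, tol, cache)
  if (!s1$ok) return(fail())
  ystar <- s1$z
  # stage 2: BDF2-like over the full step
  const2 <- ystar / d - ((1 - g)^2 / d) * y
  s2 <- solve_stage(ystar, const2, w_bdf, h, x + h, seg, params, profile,
                    s1$warm, B, tol, cache)
  if (!s2$ok) return(fail())
  ynew <- s2$z
  # flux integral consistent with the update:
  # y_{n+1} - y_n = h [ w_tr (f_n + f*) + w_bdf f_{n+1} ]
  flux <- h * (w_tr * (fn0$dy + s1$f$dy) + w_bdf * s2$f$dy)
  list(y = ynew, fend = s2$f, warm = s2$warm, flux = flux)
}

#' Simulate the full nephron
#'
#' Marches the luminal conservation equations along the ten-segment
#' sequence with the epithelial steady state solved at every evaluation
#' point, applying tubule coalescence along the CNT and IMCD and the 10:1
#' CCD merge. Fixed-step midpoint (RK2) integration; the per-step midpoint
#' fluxes are accumulated so that segment mass audits telescope exactly.
#'
#' @param params model parameter set (\code{\link{reference_parameters}})
#' @param boundary list with \code{SNGFR_nlmin} and
#'   \code{pressure_mmHg}; defaults taken from \code{params}
#' @param profile interstitial profile (baseline unless an experiment
#'   selects the washout profile)
#' @param steps_per_segment axial steps per segment (default 200)
#' @param tol epithelial solver tolerance
#' @return an object of class \code{axial_solution}: \code{profile}
#'   (grid data.frame), \code{segment_summary}, \code{urine},
#'   \code{audit}, \code{boundary} and \code{diagnostics}
#' @export
simulate_nephron <- function(params = reference_parameters(),
                             boundary = NULL,
                             profile = interstitial_profile(),
                             steps_per_segment = 200,
                             tol = 1e-10) {
  if (is.null(boundary)) {
    boundary <- list(SNGFR_nlmin = params$SNGFR_nlmin,
                     pressure_mmHg = params$inflow_pressure_mmHg)
  }
  inflow <- inflow_composition(profile)
  y <- lstate_pack(nlmin_to_cm3s(boundary$SNGFR_nlmin),
                   boundary$pressure_mmHg, inflow)

  rows <- list(); summaries <- list(); audits <- list()
  x_global <- 0
  n_iter <- 0; n_solves <- 0
  prev_state <- NULL

  for (segname in SEGMENT_ORDER) {
    seg <- params$segments[[segname]]
    L <- seg$geom$length_cm
    n <- steps_per_segment
    h <- L / n
    warm <- NULL

    if (segname == "CCD") {
      # 10:1 merge: per-nephron flows are continuous; re-equilibrate pairs
      m <- merge_into_ccd(cm3s_to_nlmin(y[["wQ"]]), lstate_conc(y))
      y <- lstate_pack(y[["wQ"]], y[["P"]], m$conc)
    }

    y_in <- y
    reab <- numeric(length(LSTATE))
    names(reab) <- LSTATE

    # cold-start the new cell type from its shipped composition, but keep
    # the lateral space and luminal potential continuous from upstream
    guess0 <- seg$init_state
    if (!is.null(prev_state)) {
      guess0$lat <- prev_state$lat
      guess0$V_L <- prev_state$V_L
    }
    cache <- new.env(parent = emptyenv())
    k0 <- tryCatch(
      luminal_rhs(0, y, seg, params, profile, guess = guess0, tol = tol,
                  cache = cache),
      error = function(e) stop(nephron_error(segname, 0, e, rows)))
    warm <- k0$state
    rows[[length(rows) + 1L]] <- profile_row(x_global, segname, 0, y, k0)
    B <- luminal_fd_jacobian(0, y, k0, seg, params, profile, warm, tol,
                             cache)
    fn0 <- k0

    for (i in seq_len(n)) {
      x <- (i - 1L) * h
      if (i %% 25L == 0L) {
        B <- luminal_fd_jacobian(x, y, fn0, seg, params, profile, warm, tol,
                                 cache)
      }
      stp <- tryCatch(
        trbdf2_step(x, h, y, fn0, seg, params, profile, warm, B, tol, cache),
        error = function(e) stop(nephron_error(segname, x, e, rows)))
      y <- stp$y
      warm <- stp$warm
      fn0 <- stp$fend
      n_iter <- n_iter + fn0$state$iterations
      n_solves <- n_solves + 2L
      # accumulate reabsorption with the scheme's own quadrature weights
      reab <- reab - stp$flux
      rows[[length(rows) + 1L]] <-
        profile_row(x_global + i * h, segname, i * h, y,
                    luminal_eval(y, fn0))
    }
    x_global <- x_global + L
    prev_state <- warm
    summaries[[segname]] <- segment_summary_row(segname, y_in, y, reab)
    audits[[segname]] <- segment_audit(y_in, y, reab)
  }

  conc_urine <- lstate_conc(y)
  omega_end <- imcd_population_fraction(seg$geom$length_cm,
                                        seg$geom$length_cm) * 0.1 / 0.1
  urine_flow_nl <- cm3s_to_nlmin(y[["wQ"]])   # per nephron
  urine <- list(
    flow_ml_min_kidney = urine_flow_nl * ns_const$nephrons_per_kidney * 1e-6,
    flow_nl_min_nephron = urine_flow_nl,
    conc = conc_urine[SOLUTES],
    pH = attr(conc_urine, "pH"),
    osmolality = osmolality(conc_urine[SOLUTES], partial = TRUE),
    pressure_mmHg = y[["P"]],
    ducts_per_kidney = imcd_population_fraction(1.2, 1.2) *
      ns_const$nephrons_per_kidney
  )

  structure(list(
    profile = do.call(rbind, rows),
    segment_summary = do.call(rbind, summaries),
    audit = do.call(rbind, audits),
    urine = urine,
    boundary = boundary,
    inflow = inflow,
    diagnostics = list(newton_iterations = n_iter,
                       epithelial_solves = n_solves,
                       steps_per_segment = steps_per_segment)
  ), class = "axial_solution")
}

#' Proximal tubule inflow composition
#'
#' The tubular fluid entering the proximal tubule equals the cortical
#' interstitial composition without protein. Because protein carried the
#' balancing impermeant charge, a Donnan-style adjustment is applied:
#' half of the excess positive charge is removed from Na+ and half added
#' to Cl-, which restores exact electroneutrality while leaving the
#' filtrate osmolality unchanged (protein-free plasma water).
#'
#' @param profile interstitial profile
#' @return named species concentration vector, mM (no protein)
#' @export
inflow_composition <- function(profile = interstitial_profile()) {
  conc <- profile$anchors$cortex[SOLUTES]
  imbalance <- sum(VALENCE[SOLUTES] * conc)
  conc[["Na"]] <- conc[["Na"]] - imbalance / 2
  conc[["Cl"]] <- conc[["Cl"]] + imbalance / 2
  conc
}

# --- bookkeeping helpers ----------------------------------------------------

luminal_eval <- function(y, mid) {
  # approximate end-point diagnostics with the midpoint epithelial state
  conc <- lstate_conc(y)
  list(state = mid$state, omega = mid$omega,
       Q_nlmin = cm3s_to_nlmin(y[["wQ"]] / mid$omega),
       r_um = mid$r_um, tscale = mid$tscale, conc = conc,
       pH = attr(conc, "pH"))
}

profile_row <- function(x, segname, x_seg, y, ev) {
  conc <- ev$conc
  df <- data.frame(
    x = x, segment = segname, x_seg = x_seg,
    omega = ev$omega,
    Q_nlmin = ev$Q_nlmin,
    wQ_nlmin = cm3s_to_nlmin(y[["wQ"]]),
    P_mmHg = y[["P"]],
    r_um = ev$r_um,
    tscale = ev$tscale,
    pH = ev$pH,
    osmolality = osmolality(conc[SOLUTES], partial = TRUE),
    V_L = ev$state$V_L, V_C = ev$state$cell$V, V_P = ev$state$lat$V,
    stringsAsFactors = FALSE
  )
  for (k in SOLUTES) df[[k]] <- conc[[k]]
  df
}

# per-nephron flows in pmol/min, per-kidney in umol/min
segment_summary_row <- function(segname, y_in, y_out, reab) {
  to_pmol <- 60e6          # umol/s -> pmol/min
  to_kidney <- 60 * ns_const$nephrons_per_kidney  # umol/s -> umol/min/kidney
  qty <- LUMPED
  data.frame(
    segment = segname, quantity = c("water", qty),
    delivery_in = c(cm3s_to_nlmin(y_in[["wQ"]]),
                    unname(y_in[qty]) * to_pmol),
    delivery_out = c(cm3s_to_nlmin(y_out[["wQ"]]),
                     unname(y_out[qty]) * to_pmol),
    reabsorption = c(cm3s_to_nlmin(reab[["wQ"]]),
                     unname(reab[qty]) * to_pmol),
    delivery_in_kidney = c(cm3s_to_nlmin(y_in[["wQ"]]) * 1e6 * 1e-6,
                           unname(y_in[qty]) * to_kidney),
    delivery_out_kidney = c(cm3s_to_nlmin(y_out[["wQ"]]) * 1e6 * 1e-6,
                            unname(y_out[qty]) * to_kidney),
    stringsAsFactors = FALSE
  )
}

segment_audit <- function(y_in, y_out, reab) {
  qty <- c("wQ", LUMPED)
  err <- abs((y_in[qty] - y_out[qty]) - reab[qty])
  rel <- err / pmax(abs(y_in[qty]), abs(y_out[qty]), 1e-30)
  data.frame(quantity = qty, abs_error = unname(err),
             rel_error = unname(rel), stringsAsFactors = FALSE)
}

nephron_error <- function(segname, x, e, rows) {
  structure(class = c("nephron_error", "error", "condition"),
            list(message = sprintf("segment %s at x = %.4f cm: %s",
                                   segname, x, conditionMessage(e)),
                 call = NULL,
                 partial = if (length(rows)) do.call(rbind, rows) else NULL))
}

#' @export
print.axial_solution <- function(x, ...) {
  u <- x$urine
  cat("Nephron steady-state solution\n")
  cat(sprintf("  SNGFR %.5g nl/min; urine flow %.3g ml/min per kidney\n",
              x$boundary$SNGFR_nlmin, u$flow_ml_min_kidney))
  cat(sprintf("  urine: Na %.3g  K %.3g  Cl %.3g  urea %.3g mM; pH %.3g; osm %.4g\n",
              u$conc[["Na"]], u$conc[["K"]], u$conc[["Cl"]],
              u$conc[["urea"]], u$pH, u$osmolality))
  invisible(x)
}
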