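# Steady-state epithelial solve at one axial position: cell and lateral
# (paracellular) compartment compositions and potentials, plus the luminal
# potential, such that every conservation law closes.
#
# Compartments: L = lumen (composition and pressure given, potential
# solved), C = cell, P = lateral interspace, B = interstitium (grounded
# boundary condition). Interfaces, oriented first -> second: LC, LP, BC,
# BP, CP. Transporters sit on the three cell membranes (LC, BC, CP);
# LP and BP are passive paracellular pathways.
#
# Closure: per compartment, 17 residuals -- water balance; individual
# balances for the five non-reacting solutes; total-buffer balances per
# group (the CO2 group holds CO2, HCO3- and H2CO3); the four pair
# equilibria plus the CO2 hydration equilibrium; the acid-content (proton)
# balance over {H+, NH4+, H2PO4-, H2CO3, H2CO2, CO2}; and
# electroneutrality -- for 17 unknowns: 15 concentrations, the potential,
# and one slack unknown (the cell's impermeant concentration, i.e. an
# effective-volume adjustment at fixed impermeant amount; the lateral
# interspace's hydrostatic pressure). The luminal potential is closed by
# zero net transmembrane current out of the lumen. Zero net current into
# cell and lateral compartments is an exact linear consequence of the
# solute/proton rows, so both electroneutrality and current conservation
# hold at a converged state.

INTERFACES <- c("LC", "LP", "BC", "BP", "CP")
CELL_MEMBRANES <- c("LC", "BC", "CP")

# Fluxes across all five interfaces for a candidate state.
# Returns volume fluxes (cm^3/s/cm) and a species x interface matrix of
# solute fluxes (umol/s/cm), oriented first -> second compartment.
epithelial_fluxes <- function(seg, lum, cell, lat, bath, tscale = 1) {
  nsol <- length(SOLUTES)
  J <- matrix(0, nsol, 5L, dimnames = list(SOLUTES, INTERFACES))
  Jv <- c(LC = 0, LP = 0, BC = 0, BP = 0, CP = 0)

  comp_a <- list(LC = lum, LP = lum, BC = bath, BP = bath, CP = cell)
  comp_b <- list(LC = cell, LP = lat, BC = cell, BP = lat, CP = lat)

  for (ifc in INTERFACES) {
    mp <- seg$interfaces[[ifc]]
    a <- comp_a[[ifc]]; b <- comp_b[[ifc]]
    fac <- if (ifc %in% CELL_MEMBRANES) tscale else 1
    dC <- b$spec - a$spec                       # length 16 incl protein
    # torque modulates transporter densities and channel permeabilities,
    # not the water pathway or the paracellular route
    Jv[[ifc]] <- jv_internal(mp$A, mp$Lp, mp$sigma, dC,
                             a$P - b$P)
    u <- VALENCE[SOLUTES] * (a$V - b$V) / ns_const$RT_over_F_mV
    J[, ifc] <- ghk_core(mp$rhoA * fac, u,
                         a$spec[SOLUTES], b$spec[SOLUTES])
  }

  # carrier / pump fluxes on the cell membranes
  for (tr in seg$transporters) {
    ifc <- tr$interface
    a <- comp_a[[ifc]]; b <- comp_b[[ifc]]
    fac <- if (isTRUE(tr$torque_scalable)) tscale else 1
    # natural orientation: out = non-cytosolic side, in = cytosol
    if (ifc == "CP") { out <- comp_b[[ifc]]; cyt <- comp_a[[ifc]]; sgn <- -1 }
    else             { out <- a;             cyt <- b;             sgn <- 1 }
    Jt <- switch(tr$kind,
      SGLT2 = ,
      SGLT1 = {
        p <- tr$params; p$density <- p$density * fac
        fx <- sglt2_flux(p, out$spec[["glucose"]], out$spec[["Na"]],
                         cyt$spec[["glucose"]], cyt$spec[["Na"]],
                         out$V, cyt$V)
        c(glucose = fx$J_glu, Na = fx$J_Na)
      },
      NKCC2 = {
        p <- tr$params; p$E_T <- p$E_T * fac
        fx <- nkcc2_flux(p, out$spec[c("Na", "K", "Cl")],
                         cyt$spec[c("Na", "K", "Cl")])
        c(Na = fx$J_Na, K = fx$J_K, Cl = fx$J_Cl)
      },
      generic_transporter_flux(tr$kind, tr$density * fac,
                               out$spec, cyt$spec,
                               dV = out$V - cyt$V, kinetics = tr$kinetics)
    )
    J[names(Jt), ifc] <- J[names(Jt), ifc] + sgn * Jt
  }
  list(Jv = Jv, J = J)
}

# Net fluxes into cell / lateral compartments and out of the lumen.
net_fluxes <- function(fx) {
  list(
    Jv_C = fx$Jv[["LC"]] + fx$Jv[["BC"]] - fx$Jv[["CP"]],
    Jv_P = fx$Jv[["LP"]] + fx$Jv[["BP"]] + fx$Jv[["CP"]],
    Jv_L = fx$Jv[["LC"]] + fx$Jv[["LP"]],
    J_C  = fx$J[, "LC"] + fx$J[, "BC"] - fx$J[, "CP"],
    J_P  = fx$J[, "LP"] + fx$J[, "BP"] + fx$J[, "CP"],
    J_L  = fx$J[, "LC"] + fx$J[, "LP"]
  )
}

# Fixed characteristic scales for the conservation rows, built once per
# solve from boundary concentrations and transporter densities. Using
# state-independent scales keeps the scaled residual smooth (a
# flux-magnitude normalisation would saturate at +-1 whenever all terms
# share a sign).
residual_scales <- function(params, C_L, C_B, tscale = 1) {
  cref <- pmax(C_L[SOLUTES], C_B[SOLUTES], 1e-6)
  zero <- rep(1e-14, length(SOLUTES)); names(zero) <- SOLUTES
  osm_ref <- max(sum(C_L), sum(C_B))
  # per-compartment accumulation: a row's scale reflects only the
  # pathways that actually touch that compartment
  s <- list(cell = zero, lat = zero)
  wsc <- c(cell = 1e-14, lat = 1e-14)
  touches <- list(LC = "cell", BC = "cell", LP = "lat", BP = "lat",
                  CP = c("cell", "lat"))
  for (ifc in INTERFACES) {
    mp <- params$interfaces[[ifc]]
    fac <- if (ifc %in% CELL_MEMBRANES) tscale else 1
    for (m in touches[[ifc]]) {
      s[[m]] <- s[[m]] + mp$rhoA * fac * cref
      wsc[[m]] <- wsc[[m]] + mp$A * mp$Lp *
        (ns_const$RT_mmHg_per_mM * osm_ref + 30)
    }
  }
  for (tr in params$transporters) {
    d <- switch(tr$kind,
                SGLT2 = , SGLT1 = tr$params$density * tr$params$k_uf,
                NKCC2 = tr$params$E_T * tr$params$k_ff / 10,
                tr$density)
    if (isTRUE(tr$torque_scalable)) d <- d * tscale
    add <- switch(tr$kind,
                  NaKATPase = c(Na = 3, K = 2),
                  NHE3 = c(Na = 1, H = 1, NH4 = 1),
                  HATPase = c(H = 1),
                  HKATPase = c(H = 1, K = 1),
                  KCC = c(K = 1, Cl = 1),
                  NCC = c(Na = 1, Cl = 1),
                  ENaC = c(Na = cref[["Na"]]),
                  SGLT2 = , SGLT1 = c(Na = 1, glucose = 1),
                  NKCC2 = c(Na = 1, K = 1, Cl = 2))
    for (m in touches[[tr$interface]]) {
      s[[m]][names(add)] <- s[[m]][names(add)] + d * add
    }
  }
  mk <- function(m) {
    grp <- vapply(names(GROUP_MEMBERS),
                  function(g) sum(s[[m]][GROUP_MEMBERS[[g]]]), numeric(1))
    list(species = s[[m]], water = wsc[[m]], group = grp,
         proton = sum(s[[m]][PROTON_SPECIES]),
         charge = sum(abs(VALENCE[SOLUTES]) * cref))
  }
  list(cell = mk("cell"), lat = mk("lat"),
       current = sum(abs(VALENCE[SOLUTES]) * (s$cell + s$lat)))
}

# One compartment's 17 scaled residual rows. imp_charge is the impermeant
# charge concentration (z_imp * C_imp for the cell, 0 for the lateral
# space).
compartment_residuals <- function(tag, Jv_net, J_net, conc, pH, sc,
                                  imp_charge = 0) {
  res <- numeric(0)
  res["water"] <- Jv_net / sc$water
  for (k in NONREACTING) res[[k]] <- J_net[[k]] / sc$species[[k]]
  for (g in names(GROUP_MEMBERS)) {
    res[[paste0("total_", g)]] <- sum(J_net[GROUP_MEMBERS[[g]]]) / sc$group[[g]]
  }
  res["proton"] <- sum(J_net[PROTON_SPECIES]) / sc$proton
  for (g in names(BUFFER_PAIRS)) {
    p <- BUFFER_PAIRS[[g]]
    res[[paste0("equil_", g)]] <-
      buffer_equilibrium_residual(pH, conc[[p$base]], conc[[p$acid]],
                                  p$pKa, pair = c(p$base, p$acid))
  }
  # hydration equilibrium ties dissolved CO2 to H2CO3
  res["equil_hydration"] <- log10(conc[["CO2"]] / (K_HYD * conc[["H2CO3"]]))
  res["electroneutrality"] <-
    (sum(VALENCE[SOLUTES] * conc[SOLUTES]) + imp_charge) / sc$charge
  names(res) <- paste0(tag, ".", names(res))
  res
}

#' Epithelial conservation residuals
#'
#' Evaluates the steady-state residual vector of the cellular and lateral
#' compartments at one axial position: per-compartment water balance, the
#' five non-reacting solute balances (Na, K, Cl, urea, glucose), the four
#' total-buffer balances, the four pair-equilibrium residuals, the CO2
#' hydration-equilibrium residual and the acid-content (proton) balance
#' -- 16 rows per compartment, 32 in all, each conservation row scaled by
#' the magnitude of its contributing fluxes. The
#' residual closing the luminal potential (zero net transmembrane current
#' out of the lumen) is returned separately as \code{lumen_current}.
#'
#' @param state list with \code{cell} (\code{conc}, a named 15-solute
#'   vector in mM; \code{V} in mV; \code{imp}, the impermeant
#'   concentration in mM), \code{lat} (\code{conc}; \code{V}; \code{P},
#'   the interspace pressure in mmHg) and \code{V_L}, the luminal
#'   potential
#' @param luminal list with \code{conc} (named, mM; no protein), \code{P}
#'   (mmHg)
#' @param interstitial list with \code{conc} (named, mM; includes protein)
#'   and \code{P} (mmHg)
#' @param params a segment parameter block (see
#'   \code{\link{reference_parameters}})
#' @param tscale torque scale factor applied to cell-membrane transport
#' @return list with \code{residuals} (named length-32 vector),
#'   \code{lumen_current} (scaled), \code{fluxes} (volume and solute flux
#'   tables) and \code{net} (per-compartment net fluxes)
#' @export
epithelial_residuals <- function(state, luminal, interstitial, params,
                                 tscale = 1, scales = NULL) {
  cellpars <- params$cell
  lum <- list(spec = c(state_conc(luminal$conc), protein = 0),
              V = state$V_L, P = luminal$P)
  bath <- list(spec = state_conc(interstitial$conc, protein = TRUE),
               V = 0, P = interstitial$P)
  if (is.null(scales)) {
    scales <- residual_scales(params, lum$spec[SOLUTES],
                              bath$spec[SOLUTES], tscale)
  }
  cell <- list(spec = c(state$cell$conc[SOLUTES],
                        protein = unname(state$cell$imp)),
               V = state$cell$V, P = params$P_cell)
  lat <- list(spec = c(state$lat$conc[SOLUTES], protein = 0),
              V = state$lat$V, P = state$lat$P)

  fx <- epithelial_fluxes(params, lum, cell, lat, bath, tscale)
  if (!all(is.finite(fx$J)) || !all(is.finite(fx$Jv))) {
    bad <- INTERFACES[!is.finite(fx$Jv) |
                        colSums(!is.finite(fx$J)) > 0]
    stop("non-finite flux at interface ", paste(bad, collapse = ","))
  }
  nf <- net_fluxes(fx)

  res <- c(
    compartment_residuals("cell", nf$Jv_C, nf$J_C,
                          state$cell$conc, species_ph(state$cell$conc),
                          scales$cell,
                          imp_charge = cellpars$imp_z * state$cell$imp),
    compartment_residuals("lat", nf$Jv_P, nf$J_P,
                          state$lat$conc, species_ph(state$lat$conc),
                          scales$lat, imp_charge = 0)
  )
  zJ <- VALENCE[SOLUTES] * nf$J_L
  list(residuals = res,
       lumen_current = sum(zJ) / scales$current,
       fluxes = fx, net = nf)
}

# Coerce a named concentration vector to canonical solute order; optionally
# carry a protein entry.
state_conc <- function(conc, protein = FALSE) {
  out <- conc[SOLUTES]
  if (any(is.na(out))) {
    stop("missing solute entry: ",
         paste(SOLUTES[is.na(out)], collapse = ", "))
  }
  names(out) <- SOLUTES
  if (protein) c(out, protein = unname(conc[["protein"]])) else out
}

# pack / unpack the 35-component unknown vector:
# log cell concentrations (15), V_C, log C_imp, log lateral
# concentrations (15), V_P, P_P, V_L
pack_state <- function(state) {
  c(log(state$cell$conc[SOLUTES]), state$cell$V, log(state$cell$imp),
    log(state$lat$conc[SOLUTES]), state$lat$V, state$lat$P, state$V_L)
}

unpack_state <- function(x) {
  n <- length(SOLUTES)
  cc <- exp(x[1:n]); names(cc) <- SOLUTES
  lc <- exp(x[(n + 3):(2 * n + 2)]); names(lc) <- SOLUTES
  list(cell = list(conc = cc, V = x[[n + 1]], imp = exp(x[[n + 2]])),
       lat = list(conc = lc, V = x[[2 * n + 3]], P = x[[2 * n + 4]]),
       V_L = x[[2 * n + 5]])
}

# indices of unknowns that are potentials / pressures (wider step caps)
linear_unknowns <- function() {
  n <- length(SOLUTES)
  c(n + 1L, 2L * n + 3L, 2L * n + 4L, 2L * n + 5L)
}

resid_vector <- function(x, luminal, interstitial, params, tscale,
                         scales = NULL) {
  st <- unpack_state(x)
  r <- epithelial_residuals(st, luminal, interstitial, params, tscale,
                            scales)
  c(r$residuals, lumen_current = r$lumen_current)
}

# forward-difference Jacobian of the residual vector
num_jacobian <- function(fn, x, f0) {
  n <- length(x)
  Jm <- matrix(0, length(f0), n)
  for (i in seq_len(n)) {
    h <- 1e-6 * max(1, abs(x[[i]]))
    xi <- x; xi[[i]] <- xi[[i]] + h
    Jm[, i] <- (fn(xi) - f0) / h
  }
  Jm
}

# Newton / Levenberg-Marquardt step: mu = 0 is the pure Newton direction;
# positive mu regularises near-singular Jacobians (e.g. the thermodynamic
# equilibrium point, where the pair-equilibrium rows become linearly
# dependent on the species balances). Solved through the QR of the
# ridge-augmented system for stability.
lm_step <- function(Jm, f, mu) {
  n <- ncol(Jm)
  if (mu == 0) {
    dx <- tryCatch(-solve(Jm, f), error = function(e) NULL)
    if (!is.null(dx)) return(dx)
    mu <- 1e-10
  }
  scale <- sqrt(mu) * sqrt(mean(Jm^2)) * sqrt(n)
  A <- rbind(Jm, diag(scale, n))
  b <- c(-f, rep(0, n))
  qr.coef(qr(A, LAPACK = TRUE), b)
}

# Damped quasi-Newton iteration on the packed unknowns. The Jacobian is
# refreshed lazily (kept while full steps make good progress), which cuts
# the cost of the warm-started axial march substantially; when even the
# fresh-Jacobian Newton direction fails the line search, Levenberg-
# Marquardt regularisation takes over.
newton_solve <- function(fn, x0, tol = 1e-10, max_iter = 80,
                         fresh_every = 6, J0 = NULL) {
  x <- x0
  f <- fn(x)
  Jm <- J0
  stale <- is.null(J0)
  # trust-region style cap: 2 log-units on concentrations, 30 mV/mmHg on
  # potentials and the interspace pressure
  ncap <- length(x0)
  cap <- rep(2, ncap)
  cap[linear_unknowns()] <- 30

  for (iter in seq_len(max_iter)) {
    nrm <- max(abs(f))
    if (nrm < tol) {
      return(list(x = x, f = f, iterations = iter - 1L, converged = TRUE,
                  J = Jm))
    }
    if (is.null(Jm) || stale || iter %% fresh_every == 0L) {
      Jm <- num_jacobian(fn, x, f)
      stale <- FALSE
    }
    accepted <- FALSE
    for (mu in c(0, 1e-8, 1e-5, 1e-2, 1)) {
      dx <- lm_step(Jm, f, mu)
      if (is.null(dx) || any(is.na(dx))) next
      over <- max(abs(dx) / cap)
      if (over > 1) dx <- dx / over
      lam <- 1
      while (lam >= 2^-10) {
        xn <- x + lam * dx
        fnew <- tryCatch(fn(xn), error = function(e) NULL)
        if (!is.null(fnew) && all(is.finite(fnew)) &&
            max(abs(fnew)) < nrm * (1 - 1e-4 * lam) + 1e-16) {
          if (lam < 0.49 && mu == 0) stale <- TRUE
          x <- xn; f <- fnew
          accepted <- TRUE
          break
        }
        lam <- lam / 2
      }
      if (accepted) break
      if (mu == 0 && !stale) {
        # the quasi-Newton direction was stale; refresh and restart
        Jm <- num_jacobian(fn, x, f)
        stale <- FALSE
        dx <- lm_step(Jm, f, 0)
        if (!is.null(dx) && !any(is.na(dx))) {
          over <- max(abs(dx) / cap)
          if (over > 1) dx <- dx / over
          lam <- 1
          while (lam >= 2^-10) {
            xn <- x + lam * dx
            fnew <- tryCatch(fn(xn), error = function(e) NULL)
            if (!is.null(fnew) && all(is.finite(fnew)) &&
                max(abs(fnew)) < nrm * (1 - 1e-4 * lam) + 1e-16) {
              x <- xn; f <- fnew; accepted <- TRUE; break
            }
            lam <- lam / 2
          }
        }
        if (accepted) break
      }
    }
    if (!accepted) {
      return(list(x = x, f = f, iterations = iter, converged = FALSE,
                  J = Jm))
    }
  }
  list(x = x, f = f, iterations = max_iter,
       converged = max(abs(f)) < tol, J = Jm)
}

#' Solve the epithelial steady state at one position
#'
#' Damped Newton solve of the 33 coupled algebraic unknowns (15 cell and
#' 15 lateral log-concentrations, the two compartment potentials and the
#' luminal potential) against the residuals of
#' \code{\link{epithelial_residuals}}. If a cold start fails, the solve is
#' retried along a homotopy that ramps all active transporter densities
#' from 30\% to 100\%.
#'
#' @inheritParams epithelial_residuals
#' @param guess starting \code{state}; defaults to the segment's shipped
#'   initial composition
#' @param tol convergence tolerance on the scaled residuals
#' @param max_iter damped-Newton iteration budget
#' @return converged state, with the flux tables of the converged point,
#'   residual norm and iteration count attached
#' @export
solve_epithelium <- function(luminal, interstitial, params, guess = NULL,
                             tscale = 1, tol = 1e-10, max_iter = 80,
                             cache = NULL) {
  if (is.null(guess)) guess <- params$init_state
  x0 <- pack_state(guess)
  scales <- residual_scales(params, state_conc(luminal$conc),
                            state_conc(interstitial$conc), tscale)
  fn <- function(x) resid_vector(x, luminal, interstitial, params, tscale,
                                 scales)
  J0 <- if (!is.null(cache)) cache$J else NULL
  sol <- newton_solve(fn, x0, tol = tol, max_iter = max_iter, J0 = J0)
  if (!sol$converged && !is.null(J0)) {
    # the cached Jacobian may be stale; retry cold
    sol <- newton_solve(fn, x0, tol = tol, max_iter = max_iter)
  }
  if (!sol$converged) {
    # homotopy on transporter densities
    x <- x0
    for (lam_t in c(0.1, 0.3, 0.6, 1)) {
      pl <- scale_transporters(params, lam_t)
      scl <- residual_scales(pl, state_conc(luminal$conc),
                             state_conc(interstitial$conc), tscale)
      fnl <- function(x) resid_vector(x, luminal, interstitial, pl, tscale,
                                      scl)
      sl <- newton_solve(fnl, x, tol = if (lam_t < 1) 1e-8 else tol,
                         max_iter = max_iter)
      if (!sl$converged) break
      x <- sl$x
      if (lam_t == 1) sol <- sl
    }
  }
  if (!sol$converged) {
    worst <- order(abs(sol$f), decreasing = TRUE)[1:3]
    stop("epithelial solve failed (", params$name, "): worst residuals ",
         paste(names(sol$f)[worst], "=", signif(sol$f[worst], 3),
               collapse = ", "))
  }
  if (!is.null(cache) && !is.null(sol$J)) cache$J <- sol$J
  st <- unpack_state(sol$x)
  r <- epithelial_residuals(st, luminal, interstitial, params, tscale)
  st$fluxes <- r$fluxes
  st$net <- r$net
  st$residual_norm <- max(abs(c(r$residuals, r$lumen_current)))
  st$iterations <- sol$iterations
  st
}

scale_transporters <- function(params, lam) {
  params$transporters <- lapply(params$transporters, function(tr) {
    if (tr$kind %in% c("SGLT2", "SGLT1")) {
      tr$params$density <- tr$params$density * lam
    } else if (tr$kind == "NKCC2") {
      tr$params$E_T <- tr$params$E_T * lam
    } else {
      tr$density <- tr$density * lam
    }
    tr
  })
  params
}
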