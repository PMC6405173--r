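# Transmembrane flux laws: Kedem-Katchalsky volume flux, GHK
# electrodiffusion, neutral diffusion, the kinetic SGLT2 and NKCC2 carrier
# models, and saturable forms for the remaining pumps and cotransporters.
#
# Sign convention: every flux across an interface (a, b) is positive from
# compartment a to compartment b. Solute fluxes are in umol/(s . cm tubule),
# volume fluxes in cm^3/(s . cm tubule) internally (nl/min at the exported
# surface where noted).

#' Kedem-Katchalsky volume flux
#'
#' \deqn{J_v = A L_p (RT \sum_k \sigma_k \Delta C_k + \Delta P)}
#' with per-solute reflection coefficients inside the osmotic sum.
#' Positive from compartment a to b, i.e. a positive hydrostatic or
#' osmotic drive on the a side pushes water towards b.
#'
#' @param A membrane area, cm^2 per cm tubule
#' @param Lp hydraulic permeability, cm/(s mmHg)
#' @param sigma per-solute reflection coefficients (in [0,1])
#' @param dC per-solute concentration differences C_b - C_a, mM (the
#'   osmotic pull towards b)
#' @param dP hydrostatic pressure difference P_a - P_b, mmHg
#' @return volume flux in nl/min per cm tubule
#' @export
volume_flux <- function(A, Lp, sigma, dC, dP) {
  if (any(A <= 0)) stop("membrane area must be positive")
  if (any(sigma < 0 | sigma > 1)) stop("reflection coefficient outside [0,1]")
  cm3s_to_nlmin(jv_internal(A, Lp, sigma, dC, dP))
}

# internal volume flux in cm^3/(s cm)
jv_internal <- function(A, Lp, sigma, dC, dP) {
  A * Lp * (ns_const$RT_mmHg_per_mM * sum(sigma * dC) + dP)
}

#' Goldman-Hodgkin-Katz electrodiffusive flux
#'
#' \deqn{J = A \rho \frac{z F \Delta V}{RT}
#'  \frac{C_a - C_b e^{-zF\Delta V/RT}}{1 - e^{-zF\Delta V/RT}}}
#' with \eqn{\Delta V = V_a - V_b}. The singularity at \eqn{\Delta V = 0}
#' is removed with a series branch, so the function is smooth across zero
#' and reduces to the Fick form \eqn{A\rho(C_a - C_b)} for uncharged
#' solutes or vanishing voltage.
#'
#' @param rho membrane permeability, cm/s
#' @param A membrane area, cm^2 per cm tubule
#' @param z integer valence
#' @param dV potential difference V_a - V_b, mV
#' @param C_a,C_b concentrations in compartments a and b, mM
#' @return solute flux in umol/(s cm tubule), positive a to b
#' @export
ghk_flux <- function(rho, A, z, dV, C_a, C_b) {
  if (any(rho < 0) || any(A < 0)) stop("negative permeability or area")
  u <- z * dV / ns_const$RT_over_F_mV
  ghk_core(rho * A, u, C_a, C_b)
}

# core GHK on the reduced voltage u = zF dV / RT; vectorised over solutes
ghk_core <- function(rhoA, u, C_a, C_b) {
  small <- abs(u) < 1e-4
  out <- numeric(length(u))
  if (any(small)) {
    us <- u[small]
    out[small] <- rhoA[small] * ((C_a[small] - C_b[small]) * (1 + us^2 / 12) +
                                   us * (C_a[small] + C_b[small]) / 2)
  }
  if (any(!small)) {
    ub <- u[!small]
    em <- exp(-ub)
    out[!small] <- rhoA[!small] * ub * (C_a[!small] - C_b[!small] * em) / (1 - em)
  }
  out
}

#' Fick diffusion of an uncharged solute
#'
#' \code{J = A rho (C_a - C_b)}, the zero-valence limit of the GHK flux.
#'
#' @inheritParams ghk_flux
#' @return flux in umol/(s cm tubule), positive a to b
#' @export
neutral_diffusion <- function(rho, A, C_a, C_b) {
  if (any(rho < 0) || any(A < 0)) stop("negative permeability or area")
  A * rho * (C_a - C_b)
}

# --- SGLT2 / SGLT1 ----------------------------------------------------------

#' SGLT2 kinetic parameters
#'
#' Simultaneous 1:1 Na-glucose carrier with equal luminal and cytosolic
#' affinities; the translocation-rate constraints of the underlying
#' sodium-alanine carrier (equal unloaded forward/backward and loaded
#' backward rates; loaded forward rate carrying the full voltage
#' dependence) are built into the flux expression rather than left to
#' configuration.
#'
#' @param density carrier density; carries the flux scale,
#'   umol/(s cm tubule)
#' @param k_uf unloaded-carrier forward translocation rate, 1/s (enters
#'   only through the product with density)
#' @param Km_Na Na+ affinity, mM
#' @param Km_glu glucose affinity, mM
#' @return an object of class \code{sglt2_params}
#' @export
sglt2_params <- function(density, k_uf = 1, Km_Na = 30, Km_glu = 2) {
  stopifnot(density >= 0, k_uf > 0, Km_Na > 0, Km_glu > 0)
  structure(list(density = density, k_uf = k_uf,
                 Km_Na = Km_Na, Km_glu = Km_glu), class = "sglt2_params")
}

#' SGLT2/SGLT1 carrier flux
#'
#' Na+-glucose cotransport with 1:1 stoichiometry:
#' \deqn{J_{glu} = \frac{X k_{uf}}{\Phi}
#'   (n_{lum} g_{lum} e^{\zeta} - n_{cyt} g_{cyt})}
#' where \eqn{n = C_{Na}/K_{m,Na}}, \eqn{g = C_{glu}/K_{m,glu}},
#' \eqn{\zeta = F(\Psi_{lum}-\Psi_{cyt})/RT} and
#' \deqn{\Phi = (1+n_l+g_l+n_l g_l)(1+n_c g_c)
#'            + (1+n_c+g_c+n_c g_c)(1+n_l g_l e^{\zeta})}
#' The driving term uses affinity-normalised concentrations, so the zero
#' flux manifold is \eqn{C_{glu,l} C_{Na,l} e^{\zeta} = C_{glu,c} C_{Na,c}}
#' and the density parameter carries flux units. J_Na = J_glu always.
#'
#' @param p an \code{\link{sglt2_params}} object
#' @param C_glu_lum,C_Na_lum luminal glucose and Na+ concentrations, mM
#' @param C_glu_cyt,C_Na_cyt cytosolic concentrations, mM
#' @param psi_lum,psi_cyt luminal and cytosolic potentials, mV
#' @return list with \code{J_glu} and \code{J_Na} (equal), positive lumen
#'   to cell, umol/(s cm tubule)
#' @export
sglt2_flux <- function(p, C_glu_lum, C_Na_lum, C_glu_cyt, C_Na_cyt,
                       psi_lum, psi_cyt) {
  if (min(C_glu_lum, C_Na_lum, C_glu_cyt, C_Na_cyt) <= 0) {
    stop("SGLT2 substrate concentrations must be positive")
  }
  zeta <- (psi_lum - psi_cyt) / ns_const$RT_over_F_mV
  nl <- C_Na_lum / p$Km_Na;  nc <- C_Na_cyt / p$Km_Na
  gl <- C_glu_lum / p$Km_glu; gc <- C_glu_cyt / p$Km_glu
  ez <- exp(zeta)
  Phi <- (1 + nl + gl + nl * gl) * (1 + nc * gc) +
         (1 + nc + gc + nc * gc) * (1 + nl * gl * ez)
  J <- p$density * p$k_uf / Phi * (nl * gl * ez - nc * gc)
  list(J_glu = J, J_Na = J)
}

# --- NKCC2 ------------------------------------------------------------------

#' NKCC2 kinetic parameters
#'
#' Ten-state alternating-access cycle for the apical Na-K-2Cl cotransporter
#' of the thick ascending limb: sequential luminal binding in the order
#' Na+, Cl-, K+, Cl-, translocation of the fully loaded carrier
#' (\code{k_ff}/\code{k_bf}), cytosolic release in the same order, and
#' return translocation of the empty carrier (\code{k_fe}/\code{k_be}).
#' All steps are reversible. The constructor enforces the detailed-balance
#' constraint: the product of clockwise rate-constant ratios around the
#' cycle must be 1, so that net flux vanishes exactly when luminal and
#' cytosolic compositions are equal.
#'
#' @param E_T total carrier density; carries the flux scale,
#'   umol/(s cm tubule)
#' @param kon_lum,koff_lum on-rate (1/(mM s)) and off-rate (1/s) constants
#'   for the four luminal binding steps, in binding order Na, Cl, K, Cl
#' @param kon_cyt,koff_cyt the same for the cytosolic release steps
#' @param k_ff,k_bf forward/backward translocation of the loaded carrier, 1/s
#' @param k_fe,k_be forward/backward translocation of the empty carrier, 1/s
#' @return an object of class \code{nkcc2_params}
#' @export
nkcc2_params <- function(E_T,
                         kon_lum = c(Na = 10, Cl = 10, K = 50, Cl2 = 10),
                         koff_lum = c(Na = 1000, Cl = 1000, K = 500, Cl2 = 1000),
                         kon_cyt = kon_lum, koff_cyt = koff_lum,
                         k_ff = 2000, k_bf = 2000, k_fe = 2000, k_be = 2000) {
  rates <- c(E_T, kon_lum, koff_lum, kon_cyt, koff_cyt, k_ff, k_bf, k_fe, k_be)
  if (any(rates[-1] <= 0)) stop("NKCC2 rate constants must be positive")
  if (E_T < 0) stop("NKCC2 density must be non-negative")
  cyc <- prod(kon_lum / koff_lum) * prod(koff_cyt / kon_cyt) *
    (k_ff * k_fe) / (k_bf * k_be)
  if (abs(log(cyc)) > 1e-8) {
    stop("NKCC2 rate set violates detailed balance (cycle ratio ",
         signif(cyc, 6), ")")
  }
  structure(list(E_T = E_T, kon_lum = kon_lum, koff_lum = koff_lum,
                 kon_cyt = kon_cyt, koff_cyt = koff_cyt,
                 k_ff = k_ff, k_bf = k_bf, k_fe = k_fe, k_be = k_be),
            class = "nkcc2_params")
}

# Forward/backward rate vectors around the 10-state cycle for given ion
# concentrations (named vectors with Na, K, Cl).
nkcc2_cycle_rates <- function(p, lum, cyt) {
  clum <- c(lum[["Na"]], lum[["Cl"]], lum[["K"]], lum[["Cl"]])
  ccyt <- c(cyt[["Na"]], cyt[["Cl"]], cyt[["K"]], cyt[["Cl"]])
  fwd <- c(p$kon_lum * clum,      # 1->2 .. 4->5 luminal binding
           p$k_ff,                # 5->6 loaded translocation
           p$koff_cyt,            # 6->7 .. 9->10 cytosolic release
           p$k_fe)                # 10->1 empty return
  bwd <- c(p$koff_lum,            # 2->1 .. 5->4
           p$k_bf,                # 6->5
           p$kon_cyt * ccyt,      # 7->6 .. 10->9 rebinding from cytosol
           p$k_be)                # 1->10
  list(fwd = unname(fwd), bwd = unname(bwd))
}

# Master-equation matrix of the cycle (10 x 10).
nkcc2_rate_matrix <- function(rates) {
  n <- length(rates$fwd)
  W <- matrix(0, n, n)
  for (i in seq_len(n)) {
    j <- if (i == n) 1L else i + 1L
    W[j, i] <- W[j, i] + rates$fwd[i]   # i -> i+1
    W[i, j] <- W[i, j] + rates$bwd[i]   # i+1 -> i
  }
  diag(W) <- -colSums(W)
  W
}

#' NKCC2 carrier flux
#'
#' Solves the linear steady state of the ten-state carrier cycle
#' (occupancies summing to the total density) and returns the cycle rate
#' times the 1 Na : 1 K : 2 Cl stoichiometry, positive lumen to cell.
#'
#' @param p an \code{\link{nkcc2_params}} object
#' @param lum named luminal concentrations (\code{Na}, \code{K},
#'   \code{Cl}), mM
#' @param cyt named cytosolic concentrations, mM
#' @return list with \code{J_Na}, \code{J_K}, \code{J_Cl} in
#'   umol/(s cm tubule)
#' @export
nkcc2_flux <- function(p, lum, cyt) {
  if (min(lum[c("Na", "K", "Cl")], cyt[c("Na", "K", "Cl")]) <= 0) {
    stop("NKCC2 substrate concentrations must be positive")
  }
  if (p$E_T == 0) return(list(J_Na = 0, J_K = 0, J_Cl = 0))
  rates <- nkcc2_cycle_rates(p, lum, cyt)
  W <- nkcc2_rate_matrix(rates)
  A <- rbind(W[-1, , drop = FALSE], rep(1, ncol(W)))
  b <- c(rep(0, nrow(W) - 1L), p$E_T)
  E <- tryCatch(solve(A, b), error = function(e) {
    stop("singular NKCC2 state system; occupancy dump: ",
         paste(signif(rates$fwd, 4), collapse = ","), " / ",
         paste(signif(rates$bwd, 4), collapse = ","))
  })
  # one step of iterative refinement (the rate matrix can be poorly
  # scaled when binding and translocation rates differ by decades)
  E <- E + solve(A, b - A %*% E)[, 1]
  J <- rates$fwd[5] * E[5] - rates$bwd[5] * E[6]  # loaded translocation step
  list(J_Na = J, J_K = J, J_Cl = 2 * J)
}

# --- generic pumps / cotransporters ----------------------------------------

# Default kinetic constants of the saturable transporter forms (mM).
NS_KINETICS <- list(
  NaKATPase = list(Km_Na = 15, Km_K = 1.5),
  NHE3      = list(Km_Na = 30, Km_H = 7.0e-5, Km_NH4 = 25),
  HATPase   = list(Km_H = 6.0e-5),
  HKATPase  = list(Km_H = 6.0e-5, Km_K = 1.5),
  KCC       = list(Km_K = 15, Km_Cl = 50),
  NCC       = list(Km_Na = 30, Km_Cl = 30)
)

#' Generic transporter flux
#'
#' Saturable Michaelis-Menten-style forms with fixed stoichiometry for the
#' pumps, exchangers and cotransporters that are not given a full kinetic
#' state model: \code{NaKATPase} (3 Na out : 2 K in), \code{NHE3} (Na+/H+
#' exchange with NH4+ competing at the proton site), \code{HATPase},
#' \code{HKATPase}, \code{KCC}, \code{NCC}, and \code{ENaC} (an
#' electrodiffusive Na+ channel, dispatched to the GHK law). Fluxes are
#' positive from the non-cytosolic side ("out") to the cytosol ("in");
#' the ATP-driven pumps move their substrates against that orientation and
#' return negative values accordingly.
#'
#' @param kind registered transporter name
#' @param density transporter density, umol/(s cm tubule) flux scale
#' @param C_out named concentrations on the non-cytosolic side, mM
#' @param C_in named cytosolic concentrations, mM
#' @param dV potential difference V_out - V_in, mV (used by ENaC)
#' @param kinetics optional list overriding the default Km constants
#' @return named per-solute flux vector, umol/(s cm tubule), positive
#'   out to in
#' @export
generic_transporter_flux <- function(kind, density, C_out, C_in, dV = 0,
                                     kinetics = NULL) {
  if (!kind %in% c(names(NS_KINETICS), "ENaC")) {
    stop("unknown transporter kind: ", kind)
  }
  if (density < 0) stop("negative transporter density")
  if (kind == "ENaC") {
    return(c(Na = ghk_core(density, dV / ns_const$RT_over_F_mV,
                           C_out[["Na"]], C_in[["Na"]])))
  }
  kin <- NS_KINETICS[[kind]]
  if (!is.null(kinetics)) kin[names(kinetics)] <- kinetics
  switch(kind,
    NaKATPase = {
      # pumps 3 Na from cytosol out, 2 K from outside in
      R <- density * (C_in[["Na"]] / (C_in[["Na"]] + kin$Km_Na))^3 *
        (C_out[["K"]] / (C_out[["K"]] + kin$Km_K))^2
      c(Na = -3 * R, K = 2 * R)
    },
    NHE3 = {
      fr <- function(conc) {
        b <- c(Na = conc[["Na"]] / kin$Km_Na,
               H = conc[["H"]] / kin$Km_H,
               NH4 = conc[["NH4"]] / kin$Km_NH4)
        b / (1 + sum(b))
      }
      fo <- fr(C_out); fi <- fr(C_in)
      JNa <- density * (fo[["Na"]] * (fi[["H"]] + fi[["NH4"]]) -
                          fi[["Na"]] * (fo[["H"]] + fo[["NH4"]]))
      JH <- -density * (fo[["Na"]] * fi[["H"]] - fi[["Na"]] * fo[["H"]])
      JNH4 <- -density * (fo[["Na"]] * fi[["NH4"]] - fi[["Na"]] * fo[["NH4"]])
      c(Na = JNa, H = JH, NH4 = JNH4)
    },
    HATPase = {
      # pumps H+ from cytosol out
      c(H = -density * C_in[["H"]] / (C_in[["H"]] + kin$Km_H))
    },
    HKATPase = {
      R <- density * (C_in[["H"]] / (C_in[["H"]] + kin$Km_H)) *
        (C_out[["K"]] / (C_out[["K"]] + kin$Km_K))
      c(H = -R, K = R)
    },
    KCC = {
      k_o <- C_out[["K"]] / kin$Km_K;  k_i <- C_in[["K"]] / kin$Km_K
      c_o <- C_out[["Cl"]] / kin$Km_Cl; c_i <- C_in[["Cl"]] / kin$Km_Cl
      J <- density * (k_o * c_o - k_i * c_i) /
        ((1 + k_o) * (1 + c_o) + (1 + k_i) * (1 + c_i))
      c(K = J, Cl = J)
    },
    NCC = {
      n_o <- C_out[["Na"]] / kin$Km_Na; n_i <- C_in[["Na"]] / kin$Km_Na
      c_o <- C_out[["Cl"]] / kin$Km_Cl; c_i <- C_in[["Cl"]] / kin$Km_Cl
      J <- density * (n_o * c_o - n_i * c_i) /
        ((1 + n_o) * (1 + c_o) + (1 + n_i) * (1 + c_i))
      c(Na = J, Cl = J)
    })
}
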