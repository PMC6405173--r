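# Solute registry, buffer-pair equilibria, proton bookkeeping, osmolality.
#
# The model carries 15 transported solutes plus (impermeant) protein. Four
# acid/base pairs are kept at equilibrium: (HCO3-, H2CO3), (HPO4--, H2PO4-),
# (NH3, NH4+), (HCO2-, H2CO2). CO2 belongs to the CO2 buffer group for
# total-buffer accounting but not to the pH equilibrium pair, and no
# hydration kinetics (carbonic anhydrase) are modelled, so CO2 is treated as
# individually conserved wherever balances are written.

# pKa of the explicit (HCO3-, H2CO3) pair. Fixed by requiring the cortical
# interstitial composition (HCO3 = 25 mM, H2CO3 = 4.41e-3 mM) to sit at
# pH 7.4; close to the true first dissociation constant of carbonic acid.
PKA_CO2PAIR  <- 7.4 - log10(25 / 4.41e-3)   # 3.6464
PKA_PHOS     <- 6.8                          # fixed by the titratable-acid formula
PKA_AMMONIA  <- 9.15
PKA_FORMATE  <- 3.75

# Hydration equilibrium constant CO2/H2CO3 (dimensionless). Fixed by the
# constant ratio the interstitial table prints in every column
# (1.45 / 4.41e-3); dissolved CO2 is kept at equilibrium with H2CO3, so the
# effective pKa of the CO2 group is PKA_CO2PAIR + log10(K_HYD) = 6.16.
K_HYD <- 1.45 / 4.41e-3

# Canonical solute order used by every concentration vector in the package.
SOLUTES <- c("Na", "K", "Cl", "HCO3", "H2CO3", "CO2", "HPO4", "H2PO4",
             "urea", "NH3", "NH4", "H", "HCO2", "H2CO2", "glucose")
SPECIES <- c(SOLUTES, "protein")

VALENCE <- c(Na = 1, K = 1, Cl = -1, HCO3 = -1, H2CO3 = 0, CO2 = 0,
             HPO4 = -2, H2PO4 = -1, urea = 0, NH3 = 0, NH4 = 1, H = 1,
             HCO2 = -1, H2CO2 = 0, glucose = 0, protein = 0)

# Solutes with an individual (non-reacting) conservation law.
NONREACTING <- c("Na", "K", "Cl", "urea", "glucose")

# Buffer pairs: base listed first, acid second. CO2 belongs to the CO2
# group (its total and the group's acid content include it) but not to the
# pH equilibrium pair; it is tied to H2CO3 by the hydration equilibrium.
BUFFER_PAIRS <- list(
  co2pair = list(base = "HCO3", acid = "H2CO3", pKa = PKA_CO2PAIR),
  phos    = list(base = "HPO4", acid = "H2PO4", pKa = PKA_PHOS),
  amm     = list(base = "NH3",  acid = "NH4",   pKa = PKA_AMMONIA),
  form    = list(base = "HCO2", acid = "H2CO2", pKa = PKA_FORMATE)
)

# All members of each buffer group (conservation is applied to these sums).
GROUP_MEMBERS <- list(
  co2pair = c("HCO3", "H2CO3", "CO2"),
  phos    = c("HPO4", "H2PO4"),
  amm     = c("NH3", "NH4"),
  form    = c("HCO2", "H2CO2")
)

# Species whose fluxes carry acid equivalents (proton conservation). CO2
# counts because CO2 + H2O = H2CO3: with hydration at equilibrium, every
# internal reaction leaves this sum invariant.
PROTON_SPECIES <- c("H", "NH4", "H2PO4", "H2CO3", "H2CO2", "CO2")

#' Registry of model solutes
#'
#' Returns the registry of the 15 transported solutes plus protein: integer
#' valence, buffer-group membership, the pKa governing each acid/base pair,
#' and the osmotic coefficient (1 for every species, forced by the
#' interstitial osmolality column sums).
#'
#' @return A data.frame with one row per species and columns \code{name},
#'   \code{valence}, \code{buffer_group}, \code{pair_role}
#'   (\code{"base"}, \code{"acid"}, \code{"free"} or \code{"none"}),
#'   \code{pKa} (NA outside a pair) and \code{osmotic_coefficient}.
#' @export
solute_table <- function() {
  grp <- c(Na = "none", K = "none", Cl = "none", HCO3 = "co2", H2CO3 = "co2",
           CO2 = "co2", HPO4 = "phosphate", H2PO4 = "phosphate", urea = "none",
           NH3 = "ammonia", NH4 = "ammonia", H = "none", HCO2 = "formate",
           H2CO2 = "formate", glucose = "none", protein = "none")
  role <- c(Na = "none", K = "none", Cl = "none", HCO3 = "base",
            H2CO3 = "acid", CO2 = "free", HPO4 = "base", H2PO4 = "acid",
            urea = "none", NH3 = "base", NH4 = "acid", H = "none",
            HCO2 = "base", H2CO2 = "acid", glucose = "none", protein = "none")
  pka <- c(Na = NA, K = NA, Cl = NA, HCO3 = PKA_CO2PAIR, H2CO3 = PKA_CO2PAIR,
           CO2 = NA, HPO4 = PKA_PHOS, H2PO4 = PKA_PHOS, urea = NA,
           NH3 = PKA_AMMONIA, NH4 = PKA_AMMONIA, H = NA, HCO2 = PKA_FORMATE,
           H2CO2 = PKA_FORMATE, glucose = NA, protein = NA)
  data.frame(name = SPECIES,
             valence = unname(VALENCE[SPECIES]),
             buffer_group = unname(grp[SPECIES]),
             pair_role = unname(role[SPECIES]),
             pKa = unname(pka[SPECIES]),
             osmotic_coefficient = 1,
             stringsAsFactors = FALSE)
}

#' Buffer-pair equilibrium residual
#'
#' Residual of the Henderson-Hasselbalch relation for one acid/base pair,
#' written \code{pH - pKa - log10(C_base / C_acid)}. The residual is zero
#' exactly when the pair is at equilibrium, and is strictly increasing in pH
#' for fixed concentrations.
#'
#' @param pH compartment pH (dimensionless)
#' @param C_base concentration of the base member, mM (> 0)
#' @param C_acid concentration of the acid member, mM (> 0)
#' @param pKa dissociation constant of the pair (dimensionless)
#' @param pair optional character(2) naming (base, acid), used in error
#'   messages
#' @return dimensionless residual
#' @export
buffer_equilibrium_residual <- function(pH, C_base, C_acid, pKa,
                                        pair = c("base", "acid")) {
  if (any(C_base <= 0)) {
    stop("non-positive concentration for buffer base '", pair[[1L]], "'")
  }
  if (any(C_acid <= 0)) {
    stop("non-positive concentration for buffer acid '", pair[[2L]], "'")
  }
  pH - pKa - log10(C_base / C_acid)
}

#' Osmolality of a solution
#'
#' Plain (coefficient-1) sum of all registered species concentrations,
#' including protein, CO2 and H2CO3.
#'
#' @param concentrations named numeric vector of concentrations in mM; must
#'   contain every registered species (protein may be omitted only if
#'   \code{partial = TRUE}).
#' @param partial if TRUE, sum whatever subset is supplied (used internally
#'   for luminal fluid, which has no protein).
#' @return osmolality in mosm/(kg H2O)
#' @export
osmolality <- function(concentrations, partial = FALSE) {
  if (!partial) {
    missing <- setdiff(SPECIES, names(concentrations))
    if (length(missing) > 0) {
      stop("missing solute entr", if (length(missing) > 1) "ies: " else "y: ",
           paste(missing, collapse = ", "))
    }
    concentrations <- concentrations[SPECIES]
  } else {
    unknown <- setdiff(names(concentrations), SPECIES)
    if (length(unknown) > 0) {
      stop("unregistered solute: ", paste(unknown, collapse = ", "))
    }
  }
  if (any(concentrations < 0)) stop("negative concentration in osmolality()")
  sum(concentrations)
}

#' Titratable acid
#'
#' Titratable acid of the phosphate buffer, i.e. the acid that would be
#' consumed titrating the urine back to plasma pH 7.4 with phosphate
#' pKa 6.8:
#' \deqn{TA = (10^{7.4-6.8} C_{H2PO4} - C_{HPO4}) / (1 + 10^{7.4-6.8})}
#'
#' @param C_H2PO4 H2PO4- concentration, mM (>= 0)
#' @param C_HPO4 HPO4-- concentration, mM (>= 0)
#' @return titratable acid, mM (negative when the urine is more alkaline
#'   than the pH-7.4 phosphate ratio)
#' @export
titratable_acid <- function(C_H2PO4, C_HPO4) {
  if (any(C_H2PO4 < 0) || any(C_HPO4 < 0)) {
    stop("negative phosphate concentration")
  }
  r <- 10^(7.4 - 6.8)
  (r * C_H2PO4 - C_HPO4) / (1 + r)
}

#' Electroneutrality residual
#'
#' Signed charge sum of a composition, \code{sum(z_k C_k) + impermeant}.
#' Used as a diagnostic and to choose the impermeant charge of cell
#' compartments; the solver itself closes compartment potentials with zero
#' net transmembrane current.
#'
#' @param concentrations named numeric vector, mM; any subset of the
#'   registered species
#' @param impermeant_charge fixed impermeant charge, mEq/L
#' @return residual in mEq/L
#' @export
electroneutrality_residual <- function(concentrations, impermeant_charge = 0) {
  unknown <- setdiff(names(concentrations), SPECIES)
  if (length(unknown) > 0) {
    stop("unregistered solute: ", paste(unknown, collapse = ", "))
  }
  sum(VALENCE[names(concentrations)] * concentrations) + impermeant_charge
}

# --- internal helpers -------------------------------------------------------

# pH <-> free H+ concentration in mM (1 mM = 1e-3 mol/L).
ph_from_h <- function(h_mM) 3 - log10(h_mM)
h_from_ph <- function(pH) 10^(3 - pH)

# Split a pair total into (base, acid) at a given pH.
split_pair <- function(total, pH, pKa) {
  r <- 10^(pH - pKa)              # base/acid ratio
  base <- total * r / (1 + r)
  c(base = base, acid = total - base)
}

# Lumped representation of a full species vector: the 5 individually
# conserved solutes, the 4 buffer-group totals and the acid-content
# (proton) total.
LUMPED <- c(NONREACTING, names(BUFFER_PAIRS), "Mproton")

lump_species <- function(conc) {
  tot <- vapply(names(GROUP_MEMBERS),
                function(g) sum(conc[GROUP_MEMBERS[[g]]]), numeric(1))
  c(conc[NONREACTING], tot,
    Mproton = sum(conc[PROTON_SPECIES]))
}

# Acid fraction of one group's total at a given pH: the share of the total
# held by the acid member (plus CO2 for the CO2 group). Strictly
# decreasing in pH for every group.
group_acid_fraction <- function(g, pH) {
  r <- 10^(pH - BUFFER_PAIRS[[g]]$pKa)
  if (g == "co2pair") (1 + K_HYD) / (1 + K_HYD + r) else 1 / (1 + r)
}

# Split one group's total into member species at a given pH.
split_group <- function(g, total, pH) {
  r <- 10^(pH - BUFFER_PAIRS[[g]]$pKa)
  if (g == "co2pair") {
    h2co3 <- total / (1 + K_HYD + r)
    c(HCO3 = r * h2co3, H2CO3 = h2co3, CO2 = K_HYD * h2co3)
  } else {
    acid <- total / (1 + r)
    stats::setNames(c(total - acid, acid),
                    c(BUFFER_PAIRS[[g]]$base, BUFFER_PAIRS[[g]]$acid))
  }
}

# Recover the full 15-solute vector from the lumped representation by
# solving the scalar acid-content equation for pH. The acid content
# h + sum over groups of (acid share) is strictly decreasing in pH, so the
# root is unique.
unlump_species <- function(lumped, pH_lower = 1.5, pH_upper = 12.5) {
  M <- lumped[["Mproton"]]
  totals <- vapply(names(BUFFER_PAIRS), function(g) lumped[[g]], numeric(1))
  acid_content <- function(pH) {
    a <- h_from_ph(pH)
    for (g in names(BUFFER_PAIRS)) {
      a <- a + totals[[g]] * group_acid_fraction(g, pH)
    }
    a - M
  }
  lo <- acid_content(pH_upper)    # most alkaline -> least acid
  hi <- acid_content(pH_lower)
  if (!(lo <= 0 && hi >= 0)) {
    stop("proton total ", signif(M, 6),
         " mM outside the attainable range for the given buffer totals")
  }
  pH <- stats::uniroot(acid_content, c(pH_lower, pH_upper),
                       tol = 1e-13)$root
  conc <- numeric(length(SOLUTES))
  names(conc) <- SOLUTES
  conc[NONREACTING] <- unlist(lumped[NONREACTING])
  for (g in names(BUFFER_PAIRS)) {
    s <- split_group(g, totals[[g]], pH)
    conc[names(s)] <- s
  }
  conc["H"] <- h_from_ph(pH)
  attr(conc, "pH") <- pH
  conc
}

# Convenience: build a full species vector from totals at a prescribed pH.
composition_at_ph <- function(pH, Na, K, Cl, urea, glucose,
                              co2 = 26.45, phos = 1.45, amm = 1,
                              form = 1) {
  totals <- c(co2pair = co2, phos = phos, amm = amm, form = form)
  conc <- numeric(length(SOLUTES)); names(conc) <- SOLUTES
  conc[NONREACTING] <- c(Na, K, Cl, urea, glucose)
  for (g in names(BUFFER_PAIRS)) {
    s <- split_group(g, totals[[g]], pH)
    conc[names(s)] <- s
  }
  conc["H"] <- h_from_ph(pH)
  attr(conc, "pH") <- pH
  conc
}

# pH of a full species vector (from its free H+).
species_ph <- function(conc) ph_from_h(conc[["H"]])
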