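# Nephron architecture: segment geometry, tubule coalescence, the compliant
# proximal tubule, microvillous torque, Poiseuille pressure, and the imposed
# interstitial concentration profiles.

SEGMENT_ORDER <- c("PT-S1S2", "PT-S3", "DL", "mTAL", "cTAL", "DCT", "CNT",
                   "CCD", "OMCD", "IMCD")

# Medullary axis: 1.7 cm total, outer medulla 0.5 cm, inner medulla 1.2 cm.
OM_DEPTH_CM  <- 0.5
MEDULLA_CM   <- 1.7

#' Nephron segment geometry
#'
#' Segment lengths and luminal diameters of the model human nephron, plus
#' compliance and torque parameters of the proximal tubule and the
#' population (coalescence) rule of each segment. The 1.7 cm proximal
#' tubule is split into a 1.2 cm convoluted (S1-S2) part and a 0.5 cm
#' straight (S3) part. \code{depth0}/\code{depth1} map each segment's arc
#' length linearly onto corticomedullary depth (0 = cortex, 1.7 cm =
#' papillary tip) for interstitial lookups.
#'
#' @return data.frame with one row per segment in flow order.
#' @export
segment_geometry <- function() {
  g <- data.frame(
    name      = SEGMENT_ORDER,
    length_cm = c(1.2, 0.5, 0.32, 0.5, 0.5, 0.2, 0.4, 0.4, 0.5, 1.2),
    diameter_um = c(37, 37, 26, 26, 26, 20, 24, 45, 45, 50),
    compliant = c(TRUE, TRUE, rep(FALSE, 8)),
    nu_per_mmHg = c(0.03, 0.03, rep(0, 8)),
    r0_um     = c(14, 14, rep(NA_real_, 8)),
    P0_mmHg   = c(20, 20, rep(NA_real_, 8)),
    torque_s  = c(1.5, 0.75, rep(0, 8)),
    lmv_um    = c(2.5, 2.5, rep(NA_real_, 8)),
    dmv_um    = c(0.15, 0.15, rep(NA_real_, 8)),
    population_rule = c(rep("constant", 6), "CNT-exponential",
                        "constant", "constant", "IMCD-profile"),
    # population fraction at segment entry (exit of CNT feeds the CCD merge)
    omega0    = c(rep(1, 6), 1, 0.1, 0.1, 0.1),
    depth0    = c(0, 0.00, 0.18, 0.5, 0, 0, 0, 0, 0.0, 0.5),
    depth1    = c(0, 0.18, 0.50, 0.0, 0, 0, 0, 0, 0.5, 1.7),
    stringsAsFactors = FALSE
  )
  g
}

#' Connecting-tubule population fraction
#'
#' Fraction of connecting tubules remaining at distance \code{x} from the
#' CNT entrance: \code{2^(-3.32 x/L)}, so that 10\% of the population
#' remains at the segment end (the 10:1 loop-to-CCD ratio).
#'
#' @param x distance from segment entrance, cm (0 <= x <= L)
#' @param L segment length, cm
#' @return dimensionless fraction in (0, 1]
#' @export
cnt_population_fraction <- function(x, L) {
  if (any(x < 0 | x > L)) stop("x outside [0, L] in cnt_population_fraction")
  2^(-3.32 * x / L)
}

#' Inner-medullary collecting-duct population
#'
#' Collecting ducts per nephron at distance \code{x} from the IMCD
#' entrance: \code{0.1 (1 - 0.95 (x/L)^2) exp(-2.75 x/L)}, representing 8
#' successive convergences along the inner medulla.
#'
#' @inheritParams cnt_population_fraction
#' @return ducts per nephron (dimensionless)
#' @export
imcd_population_fraction <- function(x, L) {
  if (any(x < 0 | x > L)) stop("x outside [0, L] in imcd_population_fraction")
  0.1 * (1 - 0.95 * (x / L)^2) * exp(-2.75 * x / L)
}

# d(log omega)/dx for a segment, used by the coalescing luminal equations.
population_fraction <- function(rule, x, L) {
  switch(rule,
         constant = rep(1, length(x)),
         `CNT-exponential` = cnt_population_fraction(x, L),
         `IMCD-profile` = imcd_population_fraction(x, L),
         stop("unknown population rule: ", rule))
}

#' Compliant proximal tubule radius
#'
#' \code{r = r0 (1 + nu (P - P0))} with reference radius 14 um at reference
#' pressure 20 mmHg and compliance 0.03 /mmHg.
#'
#' The radius is floored at a fraction of the reference radius: an
#' unguarded linear compliance law has a collapse instability (falling
#' pressure shrinks the radius, which steepens the Poiseuille gradient as
#' r^-4, which drops pressure further), whereas a real tubule is splinted
#' by the surrounding parenchyma.
#'
#' @param P luminal pressure, mmHg
#' @param r0_um reference radius, um
#' @param P0_mmHg reference pressure, mmHg
#' @param nu_per_mmHg compliance, 1/mmHg
#' @param floor_frac lower bound on r as a fraction of r0
#' @return radius in um
#' @export
compliant_radius <- function(P, r0_um = 14, P0_mmHg = 20, nu_per_mmHg = 0.03,
                             floor_frac = 0.7) {
  r <- r0_um * (1 + nu_per_mmHg * (P - P0_mmHg))
  if (any(r <= 0)) stop("compliant radius became non-positive (solver failure)")
  pmax(r, floor_frac * r0_um)
}

#' Microvillous torque
#'
#' Hydrodynamic torque on proximal-tubule microvilli,
#' \deqn{\tau = \frac{8\mu Q l_{mv}}{r^2}\left(1 + \frac{l_{mv}+\delta_{mv}}{r}
#'   + \frac{l_{mv}^2}{2 r^2}\right)}
#' evaluated in the internal cm-g-s/mmHg system (result in mmHg cm^2).
#' Only the ratio to a reference torque is ever used.
#'
#' @param Q_nlmin luminal flow, nl/min (>= 0)
#' @param r_um luminal radius, um (> 0)
#' @param lmv_um microvillous length, um
#' @param dmv_um height above the microvillous tip where drag acts, um
#' @param mu viscosity, mmHg s
#' @return torque in mmHg cm^2
#' @export
microvillous_torque <- function(Q_nlmin, r_um, lmv_um = 2.5, dmv_um = 0.15,
                                mu = ns_const$visc_mmHg_s) {
  if (any(Q_nlmin < 0)) stop("negative flow in microvillous_torque")
  if (any(r_um <= 0)) stop("non-positive radius in microvillous_torque")
  Q <- nlmin_to_cm3s(Q_nlmin)
  r <- um_to_cm(r_um)
  l <- um_to_cm(lmv_um)
  d <- um_to_cm(dmv_um)
  (8 * mu * Q * l / r^2) * (1 + (l + d) / r + l^2 / (2 * r^2))
}

#' Torque scale factor for proximal transporter density
#'
#' \code{1 + s (tau/tau0 - 1)}, floored at zero (a negative transporter
#' density is unphysical; the raw formula goes negative at very low
#' torque).
#'
#' @param tau current torque (same units as \code{tau0})
#' @param tau0 reference torque (> 0)
#' @param s torque sensitivity (1.5 for S1-S2, 0.75 for S3)
#' @return dimensionless scale factor >= 0
#' @export
torque_scale_factor <- function(tau, tau0, s) {
  if (any(tau0 <= 0)) stop("reference torque must be positive")
  pmax(0, 1 + s * (tau / tau0 - 1))
}

#' Poiseuille pressure gradient
#'
#' \code{dP/dx = -8 mu Q / (pi r^4)} for pressure-driven laminar flow.
#'
#' @param Q_nlmin flow per tubule, nl/min
#' @param r_um luminal radius, um (> 0)
#' @param mu viscosity, mmHg s
#' @return pressure gradient in mmHg/cm (negative for positive flow)
#' @export
poiseuille_pressure_gradient <- function(Q_nlmin, r_um,
                                         mu = ns_const$visc_mmHg_s) {
  if (any(r_um <= 0)) stop("non-positive radius")
  Q <- nlmin_to_cm3s(Q_nlmin)
  r <- um_to_cm(r_um)
  -8 * mu * Q / (pi * r^4)
}

# --- interstitial profile ---------------------------------------------------

# Printed interstitial anchor compositions (mM; pH dimensionless).
# Totals rows are split into species at the printed anchor pH.
TABLE2 <- list(
  cortex = list(Na = 140, K = 4, Cl = 100, HCO3 = 25, H2CO3 = 4.41e-3,
                CO2 = 1.45, phos_total = 1.45, urea = 5, amm_total = 1.0,
                form_total = 1.0, glucose = 5, protein = 2, pH = 7.4),
  omim   = list(Na = 299, K = 8, Cl = 280.4, HCO3 = 25, H2CO3 = 4.41e-3,
                CO2 = 1.45, phos_total = 1.45, urea = 60, amm_total = 3.9,
                form_total = 1.0, glucose = 6.25, protein = 2, pH = 7.4),
  tip    = list(Na = 239, K = 15, Cl = 236.5, HCO3 = 25, H2CO3 = 4.41e-3,
                CO2 = 1.45, phos_total = 1.45, urea = 200, amm_total = 8.95,
                form_total = 1.0, glucose = 7.5, protein = 2, pH = 7.3)
)

# Medullary washout overrides used by the NKCC2-inhibition experiment: only
# Na, K, Cl and urea change at the two medullary anchors.
NKCC2_WASHOUT <- list(
  omim = list(Na = 204, K = 5.6, Cl = 193, urea = 28),
  tip  = list(Na = 160, K = 7.0, Cl = 149, urea = 56)
)

anchor_species <- function(a) {
  conc <- numeric(length(SPECIES))
  names(conc) <- SPECIES
  for (k in c("Na", "K", "Cl", "HCO3", "H2CO3", "CO2", "urea", "glucose",
              "protein")) conc[k] <- a[[k]]
  sp <- split_pair(a$phos_total, a$pH, PKA_PHOS)
  conc["HPO4"] <- sp[["base"]]; conc["H2PO4"] <- sp[["acid"]]
  sa <- split_pair(a$amm_total, a$pH, PKA_AMMONIA)
  conc["NH3"] <- sa[["base"]]; conc["NH4"] <- sa[["acid"]]
  sf <- split_pair(a$form_total, a$pH, PKA_FORMATE)
  conc["HCO2"] <- sf[["base"]]; conc["H2CO2"] <- sf[["acid"]]
  conc["H"] <- h_from_ph(a$pH)
  conc
}

#' Interstitial concentration profile
#'
#' Builds the imposed interstitial boundary-condition profile: homogeneous
#' cortex, species concentrations varying linearly with corticomedullary
#' depth between the cortico-medullary junction and the outer-inner
#' medullary boundary (0.5 cm) and again between that boundary and the
#' papillary tip (1.7 cm). Anchor compositions are the printed interstitial
#' table; pair totals are split into species at the printed anchor pH.
#'
#' @param washout if TRUE, apply the NKCC2 medullary washout overrides
#'   (Na/K/Cl/urea = 204/5.6/193/28 mM at the OM-IM boundary and
#'   160/7.0/149/56 mM at the tip).
#' @return an object of class \code{interstitial_profile}
#' @export
interstitial_profile <- function(washout = FALSE) {
  anchors <- TABLE2
  if (washout) {
    for (w in names(NKCC2_WASHOUT)) {
      anchors[[w]][names(NKCC2_WASHOUT[[w]])] <- NKCC2_WASHOUT[[w]]
    }
  }
  prof <- list(
    depth = c(cortex = 0, omim = OM_DEPTH_CM, tip = MEDULLA_CM),
    anchors = lapply(anchors, anchor_species),
    pH = vapply(anchors, function(a) a$pH, numeric(1)),
    washout = washout
  )
  class(prof) <- "interstitial_profile"
  prof
}

# Full species vector at a corticomedullary depth (cm).
interstitial_species <- function(depth, profile) {
  d <- profile$depth
  if (depth <= 0) return(profile$anchors$cortex)
  if (depth >= d[["tip"]]) return(profile$anchors$tip)
  if (depth <= d[["omim"]]) {
    w <- depth / d[["omim"]]
    (1 - w) * profile$anchors$cortex + w * profile$anchors$omim
  } else {
    w <- (depth - d[["omim"]]) / (d[["tip"]] - d[["omim"]])
    (1 - w) * profile$anchors$omim + w * profile$anchors$tip
  }
}

#' Interstitial concentration of one solute
#'
#' Piecewise-linear interpolation of the interstitial profile at a
#' corticomedullary depth.
#'
#' @param x corticomedullary depth, cm (0 = cortex side, 1.7 = papillary tip)
#' @param solute canonical solute name
#' @param profile an \code{\link{interstitial_profile}}
#' @return concentration in mM
#' @export
interstitial_concentration <- function(x, solute, profile = interstitial_profile()) {
  if (!solute %in% SPECIES) stop("unknown solute: ", solute)
  if (x < 0 || x > MEDULLA_CM) stop("depth outside the modelled axis")
  interstitial_species(x, profile)[[solute]]
}
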