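#' Default material parameter set for the multi-layered aortic wall
#'
#' Returns the default constituent parameters for the three particle groups
#' (medial elastic lamellae `M_el`, medial intra-lamellar `M_int`,
#' adventitia `A`) plus the GAG-pool material: elastin shear modulus and
#' volumetric penalty, four collagen/SMC fiber families with separate
#' tension/compression constants, deposition prestretches, active-tone
#' parameters, and the Gibbs-Donnan swelling constants.  All stresses in
#' kPa, lengths in micrometres, concentrations in mEq/l (= mol/m^3 for
#' monovalent ions), temperature in kelvin.
#'
#' @param ... named overrides of any top-level entry.
#' @return a list of class `wall_materials`.
#' @export
wall_materials <- function(...) {
  mat <- list(
    mu           = 89.71,     # elastin shear modulus, kPa
    lambda_ratio = 1000,      # volumetric penalty ratio lambda_hat / mu
    alpha0_deg   = 29.91,     # diagonal fiber angle from the axial direction
    # collagen constants: c1 tension/compression in kPa, c2 dimensionless
    med_axdiag   = c(c1p = 234.9, c2p = 4.08, c1m = 29.14, c2m = 4.08),
    med_circ     = c(c1p = 261.4, c2p = 0.242, c1m = 49.5, c2m = 0.15),
    adv_col      = c(c1p = 234.9, c2p = 4.08, c1m = 29.14, c2m = 4.08),
    # mass fractions per group
    phi_Mel      = c(e = 1, c2 = 0, c134 = 0),
    phi_Mint     = c(e = 0.1, c2 = 0.84, c134 = 0.06),
    phi_A        = c(e = 0.04, c = 0.96),
    # direction fractions (axial / diagonal / circumferential)
    beta_Mint    = c(z = 0.056, d = 0.944),
    beta_A       = c(z = 0.067, d = 0.877, th = 0.056),
    # deposition prestretches
    Ge           = c(r = 0.32, th = 1.90, z = 1.62),
    Gk_circ_med  = 1.20,
    Gk_other     = 1.25,
    # active tone
    Tmax         = 500,       # kPa
    lambda_max   = 1.1,
    lambda_min   = 0.6,
    # GAG pool
    mu_gag       = 0.1,       # kPa
    cFC          = 200,       # fixed-charge concentration, mEq/l
    cstar        = 300,       # bath ionic concentration, mEq/l
    Temp         = 310,       # K
    lambda_z     = 1          # axial stretch relative to the reference
  )
  ov <- list(...)
  if (length(ov)) {
    bad <- setdiff(names(ov), names(mat))
    if (length(bad)) stop("unknown material parameter(s): ",
                          paste(bad, collapse = ", "))
    mat <- modifyList(mat, ov)
  }
  if (mat$lambda_max <= mat$lambda_min)
    stop("active tone: lambda_max must exceed lambda_min")
  class(mat) <- "wall_materials"
  mat
}

#' Gibbs-Donnan swelling pressure
#'
#' Osmotic pressure of a fixed-charge (GAG) phase in equilibrium with an
#' ionic bath, \eqn{\pi = R T (\sqrt{c_{FC}^2 + c^{*2}} - c^*)}, with
#' concentrations in mEq/l (1 mEq/l = 1 mol/m^3 for monovalent species) and
#' the result in kPa.
#'
#' @param cFC fixed-charge concentration, mEq/l.
#' @param cstar bath ionic concentration, mEq/l.
#' @param Temp absolute temperature, K.
#' @return swelling pressure in kPa.
#' @export
swelling_pressure <- function(cFC = 200, cstar = 300, Temp = 310) {
  if (any(c(cFC, cstar) < 0)) stop("swelling_pressure: negative concentration")
  Rgas <- 8.314  # J / (mol K)
  Rgas * Temp * (sqrt(cFC^2 + cstar^2) - cstar) / 1000  # Pa -> kPa
}

# Constituent spec (R-side view of one particle's mixture) ------------------

#' Constituent specification for one particle group
#'
#' Assembles the mixture description used by the constitutive functions:
#' elastin fraction and moduli, the four fiber families with their
#' direction, prestretch and tension/compression constants, active-tone
#' parameters, and (for GAG particles) the pool constants.
#'
#' @param group one of `"M_el"`, `"M_int"`, `"A"`, `"GAG"`.
#' @param mat a [wall_materials] list.
#' @param theta_ref reference polar angle of the particle (radians).
#' @return list of class `constituent_spec`.
#' @export
constituent_spec <- function(group = c("M_el", "M_int", "A", "GAG"),
                             mat = wall_materials(), theta_ref = 0) {
  group <- match.arg(group)
  s2d <- sin(mat$alpha0_deg * pi / 180)^2
  fib <- function(w, G, sin2a, cc)
    c(w = unname(w), G = unname(G), sin2a = unname(sin2a),
      cc[c("c1p", "c2p", "c1m", "c2m")])
  fibers <- switch(group,
    M_el = NULL,
    M_int = rbind(
      fib(mat$phi_Mint["c134"] * mat$beta_Mint["z"], mat$Gk_other, 0, mat$med_axdiag),
      fib(mat$phi_Mint["c2"], mat$Gk_circ_med, 1, mat$med_circ),
      fib(mat$phi_Mint["c134"] * mat$beta_Mint["d"] / 2, mat$Gk_other, s2d, mat$med_axdiag),
      fib(mat$phi_Mint["c134"] * mat$beta_Mint["d"] / 2, mat$Gk_other, s2d, mat$med_axdiag)),
    A = rbind(
      fib(mat$phi_A["c"] * mat$beta_A["z"], mat$Gk_other, 0, mat$adv_col),
      fib(mat$phi_A["c"] * mat$beta_A["th"], mat$Gk_other, 1, mat$adv_col),
      fib(mat$phi_A["c"] * mat$beta_A["d"] / 2, mat$Gk_other, s2d, mat$adv_col),
      fib(mat$phi_A["c"] * mat$beta_A["d"] / 2, mat$Gk_other, s2d, mat$adv_col)),
    GAG = NULL)
  phi_e <- switch(group, M_el = 1, M_int = unname(mat$phi_Mint["e"]),
                  A = unname(mat$phi_A["e"]), GAG = 0)
  spec <- list(
    group = group,
    phi_e = phi_e,
    mu = if (group == "GAG") 0 else mat$mu,
    lambda_hat = if (group == "GAG") 0 else mat$lambda_ratio * mat$mu,
    Ge = mat$Ge,
    fibers = fibers,
    theta_ref = theta_ref,
    active = (group == "M_int"),
    phi_c2 = if (group == "M_int") unname(mat$phi_Mint["c2"]) else 0,
    Tmax = mat$Tmax, lambda_max = mat$lambda_max, lambda_min = mat$lambda_min,
    mu_gag = mat$mu_gag, cFC = mat$cFC, cstar = mat$cstar, Temp = mat$Temp,
    lambda_z = mat$lambda_z)
  class(spec) <- "constituent_spec"
  spec
}

# columns of the per-particle material matrix consumed by the C++ core
MP_COLS <- c("group", "phi_e", "mu", "lambda_hat", "Ger", "Get", "Gez",
             paste0(rep(paste0("f", 1:4, "_"), each = 7),
                    c("w", "G", "sin2a", "c1p", "c2p", "c1m", "c2m")),
             "act_on", "act_phi", "Tmax", "lmax", "lmin",
             "mu_gag", "pi_swell", "theta_ref")

# build one row of the material matrix from a constituent_spec
mp_row <- function(spec) {
  row <- numeric(length(MP_COLS))
  names(row) <- MP_COLS
  row["group"] <- switch(spec$group, M_el = 1, M_int = 2, A = 3, GAG = 4)
  row["phi_e"] <- spec$phi_e
  row["mu"] <- spec$mu
  row["lambda_hat"] <- spec$lambda_hat
  row[c("Ger", "Get", "Gez")] <- spec$Ge
  if (!is.null(spec$fibers)) {
    for (k in 1:4) {
      row[(8 + 7 * (k - 1)):(14 + 7 * (k - 1))] <- spec$fibers[k, ]
    }
  }
  row["act_on"] <- as.numeric(isTRUE(spec$active))
  row["act_phi"] <- spec$phi_c2
  row[c("Tmax", "lmax", "lmin")] <- c(spec$Tmax, spec$lambda_max, spec$lambda_min)
  row["mu_gag"] <- if (spec$group == "GAG") spec$mu_gag else 0
  row["pi_swell"] <- 0
  row["theta_ref"] <- spec$theta_ref
  row
}
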