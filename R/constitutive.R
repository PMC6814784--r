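# Reference (R-level) constitutive relations.  The relaxation loop uses the
# compiled equivalents; these are the documented single-particle versions
# used for analysis, the thin-wall oracle, and verification against finite
# differences.

# polar basis vectors at a reference angle
polar_basis <- function(theta) {
  list(er = c(cos(theta), sin(theta)), et = c(-sin(theta), cos(theta)))
}

# in-plane right Cauchy-Green components in the particle's polar basis
polar_C <- function(F2, theta) {
  C2 <- crossprod(F2)
  b <- polar_basis(theta)
  list(C2 = C2,
       Crr = drop(b$er %*% C2 %*% b$er),
       Ctt = drop(b$et %*% C2 %*% b$et))
}

#' Fourth (fiber) pseudo-invariant
#'
#' \eqn{I_4^k = (G^k)^2 \, (C : M^k \otimes M^k)}: the squared total fiber
#' stretch of family `k`, including its deposition prestretch `G`.
#'
#' @param C right Cauchy-Green tensor: 3x3 matrix in the (r, theta, z) basis.
#' @param M unit fiber direction, length 3.
#' @param G scalar deposition prestretch of the family.
#' @return scalar `I4`.
#' @export
fiber_invariant <- function(C, M, G = 1) {
  stopifnot(is.matrix(C), all(dim(C) == c(3, 3)), length(M) == 3)
  if (abs(sum(M^2) - 1) > 1e-8) stop("fiber_invariant: M must be unit length")
  G^2 * drop(t(M) %*% C %*% M)
}

#' Tension/compression branch selection
#'
#' Collagen and SMC families stiffen differently in tension and compression
#' (compressed fibers are supported only by the surrounding GAG matrix).
#' Tension constants apply for \eqn{I_4 \ge 1}; at exactly \eqn{I_4 = 1}
#' both branches give zero fiber stress, so the response is continuous.
#'
#' @param I4 fiber pseudo-invariant.
#' @param pars named vector with `c1p`, `c2p`, `c1m`, `c2m`.
#' @return named vector `c(c1, c2)`.
#' @export
select_branch <- function(I4, pars) {
  if (I4 >= 1) c(c1 = unname(pars["c1p"]), c2 = unname(pars["c2p"]))
  else         c(c1 = unname(pars["c1m"]), c2 = unname(pars["c2m"]))
}

#' Passive strain energy density of a mixture particle
#'
#' Constrained-mixture strain energy: an elastin-dominated modified
#' neo-Hookean term (evaluated on \eqn{F^e = F G^e}, with the volumetric
#' terms penalizing the particle-motion volume ratio \eqn{J}) plus four
#' exponential fiber families evaluated on \eqn{C^k = (G^k)^2 C}.
#'
#' @param F2 in-plane deformation gradient, 2x2 matrix (cartesian).
#' @param spec a [constituent_spec()].
#' @param lambda_z axial stretch (defaults to the spec's).
#' @return strain energy density, kPa.
#' @export
passive_energy <- function(F2, spec, lambda_z = spec$lambda_z) {
  if (spec$group == "GAG")
    stop("passive_energy: GAG particles use gag_stress()")
  J <- det(F2) * lambda_z
  if (J <= 0) stop("passive_energy: J <= 0")
  pc <- polar_C(F2, spec$theta_ref)
  Ge <- spec$Ge
  I1e <- Ge["r"]^2 * pc$Crr + Ge["th"]^2 * pc$Ctt + Ge["z"]^2 * lambda_z^2
  W <- spec$phi_e * (spec$mu / 2 * (I1e - 3) - spec$mu * log(J) +
                     spec$lambda_hat / 2 * log(J)^2)
  if (!is.null(spec$fibers)) {
    for (k in seq_len(nrow(spec$fibers))) {
      f <- spec$fibers[k, ]
      I4 <- f["G"]^2 * (f["sin2a"] * pc$Ctt + (1 - f["sin2a"]) * lambda_z^2)
      cc <- select_branch(I4, f)
      W <- W + f["w"] * cc["c1"] / (4 * cc["c2"]) *
        (exp(cc["c2"] * (I4 - 1)^2) - 1)
    }
  }
  unname(W)
}

#' Passive first Piola-Kirchhoff and Cauchy stress
#'
#' Analytic derivative of the mixture strain energy,
#' \eqn{P = 2 F \, \partial W/\partial C} and \eqn{\sigma = P F^T / J}.
#' In-plane components drive the particle forces; the out-of-plane Cauchy
#' component `szz` is reported only.
#'
#' @inheritParams passive_energy
#' @return list with `P` (2x2), `sigma` (2x2), `W`, `szz`.
#' @export
passive_stress <- function(F2, spec, lambda_z = spec$lambda_z) {
  if (spec$group == "GAG")
    stop("passive_stress: GAG particles use gag_stress()")
  J <- det(F2) * lambda_z
  if (J <= 0) stop("passive_stress: J <= 0")
  pc <- polar_C(F2, spec$theta_ref)
  b <- polar_basis(spec$theta_ref)
  Ge <- spec$Ge
  lnJ <- log(J)
  C2inv <- solve(pc$C2)
  vol <- -spec$mu + spec$lambda_hat * lnJ
  S <- spec$phi_e * (spec$mu * (Ge["r"]^2 * tcrossprod(b$er) +
                                Ge["th"]^2 * tcrossprod(b$et)) + vol * C2inv)
  szz <- spec$phi_e * (spec$mu * Ge["z"]^2 * lambda_z^2 + vol)
  if (!is.null(spec$fibers)) {
    for (k in seq_len(nrow(spec$fibers))) {
      f <- spec$fibers[k, ]
      if (f["w"] <= 0) next
      I4 <- f["G"]^2 * (f["sin2a"] * pc$Ctt + (1 - f["sin2a"]) * lambda_z^2)
      cc <- select_branch(I4, f)
      dW2 <- unname(f["w"] * cc["c1"] * (I4 - 1) * exp(cc["c2"] * (I4 - 1)^2))
      S <- S + dW2 * f["G"]^2 * f["sin2a"] * tcrossprod(b$et)
      szz <- szz + dW2 * f["G"]^2 * (1 - f["sin2a"]) * lambda_z^2
    }
  }
  P <- F2 %*% S
  list(P = P, sigma = P %*% t(F2) / J,
       W = passive_energy(F2, spec, lambda_z), szz = unname(szz / J))
}

#' Active smooth-muscle circumferential Cauchy stress
#'
#' Parabolic length-tension relation,
#' \eqn{\sigma^{act}_\theta = \phi^{c_2} T_{max} \lambda_\theta
#' [1 - ((\lambda_{max}-\lambda_\theta)/(\lambda_{max}-\lambda_{min}))^2]},
#' clamped to zero outside \eqn{[\lambda_{min}, \lambda_{max}]}.  The stretch
#' is measured against the passive reference configuration.
#'
#' @param lambda_theta circumferential stretch of the particle.
#' @param spec a [constituent_spec()] (uses `phi_c2`, `Tmax`, `lambda_max`,
#'   `lambda_min`).
#' @return active circumferential Cauchy stress, kPa.
#' @export
active_stress <- function(lambda_theta, spec) {
  if (spec$lambda_max <= spec$lambda_min)
    stop("active_stress: lambda_max must exceed lambda_min")
  q <- (spec$lambda_max - lambda_theta) / (spec$lambda_max - spec$lambda_min)
  s <- spec$phi_c2 * spec$Tmax * lambda_theta * (1 - q^2)
  ifelse(lambda_theta <= spec$lambda_min | lambda_theta > spec$lambda_max,
         0, s)
}

#' GAG-pool Cauchy stress with optional Gibbs-Donnan swelling
#'
#' Modified neo-Hookean pool response
#' \eqn{\sigma = \mu^{GAG} (B - I)/J} plus, when swelling is on, the
#' deformation-independent isotropic osmotic term
#' \eqn{-RT(\sqrt{c_{FC}^2+c^{*2}}-c^*) I}.
#'
#' @param F2 in-plane deformation gradient (2x2).
#' @param spec a [constituent_spec()] with group `"GAG"` (or pool constants).
#' @param swelling_on logical; include the osmotic term?
#' @param lambda_z axial stretch.
#' @return list with `sigma` (2x2 in-plane Cauchy), `P` (2x2), `szz`.
#' @export
gag_stress <- function(F2, spec, swelling_on = FALSE,
                       lambda_z = spec$lambda_z) {
  J <- det(F2) * lambda_z
  if (J <= 0) stop("gag_stress: J <= 0")
  B <- tcrossprod(F2)
  pisw <- if (swelling_on)
    swelling_pressure(spec$cFC, spec$cstar, spec$Temp) else 0
  sigma <- spec$mu_gag / J * (B - diag(2)) - pisw * diag(2)
  list(sigma = sigma, P = J * sigma %*% t(solve(F2)),
       szz = spec$mu_gag / J * (lambda_z^2 - 1) - pisw)
}

#' Viscous (stabilization) first Piola-Kirchhoff stress
#'
#' \eqn{P^{visc} = 2 \eta J d F^{-T}} with
#' \eqn{d = \mathrm{sym}(\dot F F^{-1})}.  This is numerical dissipation for
#' the dynamic relaxation, not tissue viscoelasticity; it vanishes at
#' equilibrium and for rigid motions.
#'
#' @param F2 in-plane deformation gradient (2x2).
#' @param Fdot rate of the deformation gradient (2x2).
#' @param eta artificial viscosity (kPa x time).
#' @param lambda_z axial stretch.
#' @return 2x2 matrix `P^visc`.
#' @export
viscous_stress <- function(F2, Fdot, eta, lambda_z = 1) {
  J <- det(F2) * lambda_z
  l <- Fdot %*% solve(F2)
  d <- (l + t(l)) / 2
  2 * eta * J * d %*% t(solve(F2))
}
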