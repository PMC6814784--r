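# Damage protocols: severance of elastic lamellae and staged replacement of
# intra-lamellar SMC pools by swelling GAGs.

ang_interval <- function(center_deg, extent_deg) {
  c(lo = (center_deg - extent_deg / 2) * pi / 180,
    hi = (center_deg + extent_deg / 2) * pi / 180)
}

#' Disrupt a segment of an elastic lamella
#'
#' Implements lamellar rupture without a constitutive damage law:
#' (i) the neo-Hookean parameters of the selected segment's particles are
#' set to zero (their strain energy and stress vanish); (ii) the ruptured
#' particles are removed from every neighbour list; (iii) intact particles
#' of the same lamella on opposite sides of the gap are severed from each
#' other's lists, completing the disconnection across the segment.  A
#' relaxation then dissipates the released elastic energy.
#'
#' @param model an `sph_model` at equilibrium.
#' @param lamella lamella index (1 = innermost).
#' @param extent_deg angular extent of the disrupted segment, degrees.
#' @param center_deg angular centre of the segment, degrees (defaults to
#'   the sector midline, maximizing distance from the periodic edges).
#' @param relax run the post-disruption relaxation (default `TRUE`).
#' @param ... passed to the relaxation driver.
#' @return the updated model.
#' @export
disrupt_lamella <- function(model, lamella, extent_deg,
                            center_deg = model$geom$sector_deg / 2,
                            relax = TRUE, ...) {
  if (extent_deg <= 0 || extent_deg > model$geom$sector_deg)
    stop("disrupt_lamella: extent must lie in (0, sector]")
  if (!lamella %in% seq_len(model$geom$n_lamellae))
    stop("disrupt_lamella: no lamella ", lamella)
  iv <- ang_interval(center_deg, extent_deg)
  in_lam <- model$lamella == lamella
  sel <- which(in_lam & model$mp[, "group"] == 1 &
               model$theta_ref >= iv["lo"] & model$theta_ref <= iv["hi"])
  if (!length(sel))
    stop("disrupt_lamella: extent ", extent_deg,
         " deg selects no particles (below lattice resolution)")

  # (i) zero the strain energy of the segment
  model$mp[sel, c("group", "phi_e", "mu", "lambda_hat")] <- 0
  model$state$frozen[sel] <- TRUE
  # (ii) remove ruptured particles from all neighbour lists
  model <- sever_all(model, sel)
  # (iii) sever intact same-lamella particles on opposite sides of the gap
  nb <- model$nbr
  src <- rep.int(seq_len(nrow(model$X)), diff(nb$ptr))
  tgt <- nb$idx + 1L
  intact <- in_lam & model$mp[, "group"] == 1
  th_s <- model$theta_ref[src]
  th_t <- model$theta_ref[tgt] + nb$rot * model$geom$sector
  cross <- intact[src] & intact[tgt] &
    ((th_s < iv["lo"] & th_t > iv["hi"]) | (th_t < iv["lo"] & th_s > iv["hi"]))
  model$nbr$alive <- model$nbr$alive & !cross

  model <- refresh_corrections(model)
  model$damage[[length(model$damage) + 1L]] <-
    list(lamella = lamella, lo = unname(iv["lo"]), hi = unname(iv["hi"]),
         radius = model$rings$r[match(lamella, model$rings$lamella)])
  if (relax) {
    r_now <- mean(sqrt(rowSums(model$state$x[model$inner_rim, , drop = FALSE]^2)))
    model <- relax(model, r_rim = r_now, ...)
    model$record <- bulk_observables(model)
  }
  model
}

#' Define an intra-lamellar particle pool
#'
#' Registers a contiguous angular pool of intra-lamellar (`M_int`)
#' particles within one layer, the unit that subsequently undergoes the
#' staged SMC-apoptosis/GAG-replacement protocol.
#'
#' @param model an `sph_model`.
#' @param band intra-lamellar layer index (1 = innermost of the 5 layers);
#'   the default is the band bounded by the middle and next-outer lamellae.
#' @param extent_deg angular extent of the pool, degrees.
#' @param center_deg angular centre, degrees.
#' @return the model with the pool registered in `model$pools`.
#' @export
define_pool <- function(model, extent_deg, band = 4,
                        center_deg = model$geom$sector_deg / 2) {
  if (!band %in% seq_len(model$geom$n_layers))
    stop("define_pool: no intra-lamellar layer ", band)
  iv <- ang_interval(center_deg, extent_deg)
  idx <- which(model$layer == band & model$group == 2L &
               model$theta_ref >= iv["lo"] & model$theta_ref <= iv["hi"])
  if (!length(idx))
    stop("define_pool: extent ", extent_deg, " deg selects no particles")
  model$pools[[length(model$pools) + 1L]] <-
    list(idx = idx, band = band, lo = unname(iv["lo"]), hi = unname(iv["hi"]),
         stage = 0L)
  model
}

#' Apply one step of the SMC-to-GAG replacement protocol
#'
#' Step I (loss of contractility): the pool's active stress is switched
#' off.  Step II (stiffness reduction): the pool particles' mixture is
#' replaced by the GAG material (isotropic modified neo-Hookean,
#' `mu_gag` = 0.1 kPa); all passive anisotropic terms are removed.
#' Step III (GAG swelling): the Gibbs-Donnan osmotic pressure is switched
#' on and ramped in during the relaxation.  Steps must be applied in
#' order; each step ends with a relaxation to equilibrium.  Several pools
#' may be stepped together (they share one relaxation).
#'
#' @param model an `sph_model` with registered pools.
#' @param step 1, 2 or 3 (equivalently `"I"`, `"II"`, `"III"`).
#' @param pools integer indices into `model$pools` (default: all).
#' @param ... passed to the relaxation driver.
#' @return the updated model.
#' @export
pool_step <- function(model, step, pools = seq_along(model$pools), ...) {
  if (is.character(step))
    step <- match(step, c("I", "II", "III"))
  if (!step %in% 1:3) stop("pool_step: step must be 1, 2 or 3 (I/II/III)")
  if (!length(pools)) stop("pool_step: no pools defined")
  for (p in pools) {
    pool <- model$pools[[p]]
    if (pool$stage != step - 1L)
      stop("pool_step: pool ", p, " is at stage ", pool$stage,
           "; steps must be applied in order I, II, III")
    idx <- pool$idx
    if (step == 1L) {
      model$mp[idx, "act_on"] <- 0
    } else if (step == 2L) {
      model$mp[idx, "group"] <- 4
      model$mp[idx, c("phi_e", "mu", "lambda_hat")] <- 0
      model$mp[idx, grep("^f[1-4]_w$", MP_COLS)] <- 0
      model$mp[idx, "mu_gag"] <- model$mat$mu_gag
    } else {
      model$mp[idx, "pi_swell"] <-
        swelling_pressure(model$mat$cFC, model$mat$cstar, model$mat$Temp)
    }
    model$pools[[p]]$stage <- step
  }
  r_now <- mean(sqrt(rowSums(model$state$x[model$inner_rim, , drop = FALSE]^2)))
  sw0 <- if (step == 3L) 0 else 1
  model <- relax(model, r_rim = r_now, sw0 = sw0, sw1 = 1, ...)
  model$record <- bulk_observables(model)
  model
}

#' Rupture the lamellae bounding a pool (step IV)
#'
#' Disrupts both elastic lamellae adjacent to the given pool(s) over each
#' pool's full angular extent, simultaneously, then relaxes.
#'
#' @param model an `sph_model`.
#' @param pools integer indices into `model$pools` (default: all).
#' @param ... passed to the relaxation driver.
#' @return the updated model.
#' @export
disrupt_nearest_lamellae <- function(model, pools = seq_along(model$pools),
                                     ...) {
  if (!length(pools)) stop("disrupt_nearest_lamellae: no pools defined")
  for (p in pools) {
    pool <- model$pools[[p]]
    ext <- (pool$hi - pool$lo) * 180 / pi
    ctr <- (pool$hi + pool$lo) / 2 * 180 / pi
    for (lam in c(pool$band, pool$band + 1L)) {
      sel <- model$lamella == lam & model$mp[, "group"] == 1 &
        model$theta_ref >= pool$lo & model$theta_ref <= pool$hi
      if (any(sel))
        model <- disrupt_lamella(model, lam, ext, ctr, relax = FALSE)
    }
    model$pools[[p]]$stage <- 4L
  }
  r_now <- mean(sqrt(rowSums(model$state$x[model$inner_rim, , drop = FALSE]^2)))
  model <- relax(model, r_rim = r_now, ...)
  model$record <- bulk_observables(model)
  model
}
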