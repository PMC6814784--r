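# Bulk and transmural observables, the thin-wall homogenized oracle, and
# the declarative damage-scenario driver.

#' Thin-wall homogenized pressure oracle
#'
#' Laplace-law pressure of a thin homogeneous vessel whose wall response is
#' the thickness-weighted mixture of the lamellar, intra-lamellar and
#' adventitial constituent specifications, evaluated at a mean
#' circumferential stretch under incompressible plane-strain kinematics
#' (\eqn{\lambda_r = 1/(\lambda_\theta \lambda_z)}).  Used as a bulk
#' validation oracle for the particle model, not as part of the solver.
#'
#' @param model an `sph_model` (or `aorta_wall`): supplies the group volume
#'   fractions, materials and reference geometry.
#' @param lambda_theta mean circumferential stretch(es).
#' @param active include the smooth-muscle active stress.
#' @return data.frame with `lambda_theta`, `sigma_theta` (kPa), `r_in`,
#'   `r_out`, `thickness` (um), `pressure_kPa`, `pressure_mmHg`.
#' @export
thin_wall_oracle <- function(model, lambda_theta, active = FALSE) {
  g <- model$geom
  fr <- vapply(1:3, function(k) sum(model$V[model$group == k]), 0)
  fr <- fr / sum(fr)
  specs <- list(constituent_spec("M_el", model$mat),
                constituent_spec("M_int", model$mat),
                constituent_spec("A", model$mat))
  lz <- model$mat$lambda_z
  Rm <- g$R_in + g$H / 2
  out <- lapply(lambda_theta, function(lt) {
    F2 <- diag(c(1 / (lt * lz), lt))
    # incompressible membrane kinematics: the constitutive response fixes
    # sigma_theta - sigma_r; through-thickness radial equilibrium of a thin
    # pressurized wall sets the mean radial stress to -P/2
    dsig <- sum(fr * vapply(specs, function(sp) {
      s <- passive_stress(F2, sp)$sigma
      s[2, 2] - s[1, 1]
    }, 0))
    if (active) dsig <- dsig + fr[2] * active_stress(lt, specs[[2]])
    rm <- lt * Rm
    h <- g$H * Rm / rm      # incompressible thin-wall thickness
    r_in <- rm - h / 2
    P <- dsig * h / r_in / (1 + h / (2 * r_in))
    data.frame(lambda_theta = lt, sigma_theta = dsig - P / 2, r_in = r_in,
               r_out = rm + h / 2, thickness = h,
               pressure_kPa = P, pressure_mmHg = P / kPa_per_mmHg)
  })
  do.call(rbind, out)
}

# invert the oracle: inner radius at which the homogenized wall carries a
# given pressure (used to seed the semi-inverse pressure iteration)
thin_wall_inverse <- function(model, pressure_mmHg, active = FALSE) {
  f <- function(lt)
    thin_wall_oracle(model, lt, active = active)$pressure_mmHg - pressure_mmHg
  lt <- uniroot(f, c(0.62, 1.45), tol = 1e-5)$root
  thin_wall_oracle(model, lt, active = active)$r_in
}

#' Pressure-diameter curve
#'
#' Equilibrates the model over a grid of inner radii (displacement
#' control) and reports the bulk response: luminal pressure, outer
#' diameter, mean circumferential stretch and stress.
#'
#' @param model an `sph_model` at its reference state.
#' @param lambda_theta grid of mean circumferential stretches defining the
#'   inner-radius targets.
#' @param active smooth-muscle tone on?
#' @param ... passed to [equilibrate_at()].
#' @return data.frame, one row per equilibrium.
#' @export
pressure_diameter_curve <- function(model,
                                    lambda_theta = seq(0.96, 1.08, by = 0.02),
                                    active = FALSE, ...) {
  g <- model$geom
  rows <- list()
  for (lt in lambda_theta) {
    # map mean stretch to an inner-radius target (incompressible estimate)
    rm <- lt * (g$R_in + g$H / 2)
    h <- g$H * (g$R_in + g$H / 2) / rm
    model <- equilibrate_at(model, r_in = rm - h / 2,
                            active = active, ...)
    r <- model$record
    rows[[length(rows) + 1L]] <-
      data.frame(pressure_mmHg = r$pressure_mmHg,
                 pressure_kPa = r$pressure_kPa,
                 outer_diameter = r$outer_diameter,
                 r_in = r$r_in, thickness = r$thickness,
                 lambda_theta = r$lambda_theta,
                 mean_sigma_theta = r$mean_sigma_theta)
  }
  do.call(rbind, rows)
}

#' Maximum regional circumferential stress
#'
#' Maximum circumferential Cauchy stress over the particles of a lamella
#' or intra-lamellar layer, optionally restricted to an angular window
#' (material/reference angles, degrees) and excluding particles within one
#' kernel support of a disrupted-segment end, where collocation stresses
#' are least reliable.
#'
#' @param model an `sph_model` with a computed stress state.
#' @param kind `"lamella"` or `"layer"`.
#' @param index lamella or layer index.
#' @param theta_lo,theta_hi optional angular window, degrees.
#' @param exclude_tips drop particles within one kernel support of any
#'   disrupted-segment end.
#' @return maximum stress, kPa.
#' @export
regional_max_stress <- function(model, kind = c("lamella", "layer"), index,
                                theta_lo = NULL, theta_hi = NULL,
                                exclude_tips = TRUE) {
  kind <- match.arg(kind)
  sel <- if (kind == "lamella")
    model$lamella == index & model$mp[, "group"] == 1
  else
    model$layer == index & model$mp[, "group"] %in% c(2, 4)
  if (!is.null(theta_lo))
    sel <- sel & model$theta_ref >= theta_lo * pi / 180
  if (!is.null(theta_hi))
    sel <- sel & model$theta_ref <= theta_hi * pi / 180
  if (exclude_tips && length(model$damage)) {
    keep <- rep(TRUE, nrow(model$X))
    for (ev in model$damage) {
      ends <- rbind(ev$radius * c(cos(ev$lo), sin(ev$lo)),
                    ev$radius * c(cos(ev$hi), sin(ev$hi)))
      for (q in 1:2) {
        d2 <- (model$X[, 1] - ends[q, 1])^2 + (model$X[, 2] - ends[q, 2])^2
        keep <- keep & d2 > model$nbr$h^2
      }
    }
    sel <- sel & keep
  }
  if (!any(sel))
    stop("regional_max_stress: empty region (", kind, " ", index,
         if (exclude_tips) ", after tip exclusion" else "", ")")
  max(sigma_theta(model)[sel])
}

#' Transmural stress profile
#'
#' Circumferential and radial Cauchy stress against current radius for
#' particles within a narrow angular window around a radial line (by
#' default through the sector midline, i.e. through the midpoint of a
#' centred defect).
#'
#' @param model an `sph_model` with a computed stress state.
#' @param theta_deg centre of the angular window, degrees.
#' @param window_deg half-width of the window, degrees; widened if needed
#'   so the window spans at least one particle spacing.
#' @return data.frame sorted by radius: `radius`, `group`, `lamella`,
#'   `layer`, `sigma_theta`, `sigma_radial`.
#' @export
transmural_profile <- function(model, theta_deg = model$geom$sector_deg / 2,
                               window_deg = 1) {
  wmin <- model$spacing / model$geom$R_in * 180 / pi
  window_deg <- max(window_deg, wmin)
  sel <- abs(model$theta_ref - theta_deg * pi / 180) <= window_deg * pi / 180
  sel <- sel & model$mp[, "group"] != 0
  df <- data.frame(radius = sqrt(rowSums(model$state$x[sel, , drop = FALSE]^2)),
                   group = factor(model$mp[sel, "group"], 1:4,
                                  c("M_el", "M_int", "A", "GAG")),
                   lamella = model$lamella[sel], layer = model$layer[sel],
                   sigma_theta = sigma_theta(model)[sel],
                   sigma_radial = sigma_radial(model)[sel])
  df[order(df$radius), ]
}

# ---- declarative scenarios -------------------------------------------------

#' Define a damage scenario
#'
#' Declarative description of the staged damage experiments: sequential
#' lamellar rupture, a single SMC/GAG pool, two pools separated by an
#' intact span, or two merged pools (shared lamella removed first, pool
#' extents doubled).
#'
#' @param type one of `"lamellar_rupture"`, `"single_pool"`, `"two_pools"`,
#'   `"merged_pools"`.
#' @param extents angular extents (degrees) of the defect/pool; defaults
#'   are 2/4/8/20 deg (doubled for merged pools).
#' @param pressures evaluation pressures, mmHg.
#' @param band intra-lamellar layer of the pool (pool scenarios).  For
#'   `two_pools` the pools sit in layers `band - 2` and `band` (stacked
#'   radially, one intact layer between); for `merged_pools` in the
#'   adjacent layers `band - 1` and `band`, with the shared lamella `band`
#'   removed before the protocol.
#' @param include_step4 apply the final bounding-lamellae rupture (pool
#'   scenarios).
#' @param active run with smooth-muscle tone on.
#' @return list of class `wall_scenario`.
#' @export
scenario <- function(type = c("lamellar_rupture", "single_pool",
                              "two_pools", "merged_pools"),
                     extents = NULL, pressures = c(102, 136, 184),
                     band = 4, include_step4 = TRUE, active = TRUE) {
  type <- match.arg(type)
  if (is.null(extents))
    extents <- if (type == "merged_pools") c(4, 8, 16, 40) else c(2, 4, 8, 20)
  if (any(extents <= 0)) stop("scenario: extents must be positive")
  structure(list(type = type, extents = extents, pressures = pressures,
                 band = band, include_step4 = include_step4, active = active),
            class = "wall_scenario")
}

# angular half-window (degrees) equal to one kernel support at radius r
support_deg <- function(model, r) model$nbr$h / r * 180 / pi

# record the standard regions of a pool scenario
pool_regions <- function(model, band, lo_deg, hi_deg) {
  hdeg <- support_deg(model, model$geom$R_in + 0.4 * model$geom$H)
  win <- c(lo_deg - hdeg, hi_deg + hdeg)
  grab <- function(kind, idx) {
    idx <- idx[idx >= 1 & idx <= (if (kind == "lamella")
      model$geom$n_lamellae else model$geom$n_layers)]
    vals <- vapply(idx, function(i)
      tryCatch(regional_max_stress(model, kind, i, win[1], win[2]),
               error = function(e) NA_real_), 0)
    if (all(is.na(vals))) NA_real_ else max(vals, na.rm = TRUE)
  }
  c(nearest_lamella        = grab("lamella", c(band, band + 1L)),
    nearest_intralamellar  = grab("layer", c(band - 1L, band + 1L)),
    second_intralamellar   = grab("layer", c(band - 2L, band + 2L)),
    second_lamella         = grab("lamella", c(band - 1L, band + 2L)))
}

#' Run a damage scenario
#'
#' For each evaluation pressure and defect extent: equilibrate the healthy
#' wall, apply the scenario's events in order (each followed by a
#' relaxation), and record the regional maximum circumferential stresses
#' after every event.  Deterministic given the configuration.
#'
#' @param model an `sph_model` at its reference state ([set_reference()]).
#' @param scn a [scenario()].
#' @param ... passed to the relaxation driver.
#' @return tidy data.frame: one row per pressure x extent x event x region.
#' @export
run_scenario <- function(model, scn, ...) {
  stopifnot(inherits(scn, "wall_scenario"))
  rows <- list()
  note <- function(m, pressure, extent, event, vals) {
    rows[[length(rows) + 1L]] <<- data.frame(
      scenario = scn$type, pressure = pressure, extent = extent,
      event = event, region = names(vals), sigma_theta_max = unname(vals))
  }
  mid <- model$geom$sector_deg / 2
  for (P in scn$pressures) {
    for (ext in scn$extents) {
      m <- equilibrate_at(model, pressure = P, active = scn$active, ...)
      if (scn$type == "lamellar_rupture") {
        lam_mid <- locate_lamella(m, 0.4)$lamella
        seqs <- c(lam_mid, lam_mid + 1L, lam_mid - 1L)  # middle, outer, inner
        hdeg <- support_deg(m, model$geom$R_in + 0.4 * model$geom$H)
        win <- c(mid - ext / 2 - hdeg, mid + ext / 2 + hdeg)
        regs <- function(mm) c(
          outer_intralamellar = regional_max_stress(mm, "layer", lam_mid,
                                                    win[1], win[2]),
          inner_intralamellar = regional_max_stress(mm, "layer", lam_mid - 1L,
                                                    win[1], win[2]))
        note(m, P, ext, "baseline", regs(m))
        for (q in seq_along(seqs)) {
          m <- disrupt_lamella(m, seqs[q], ext, mid, ...)
          note(m, P, ext, paste0("rupture_", c("middle", "outer", "inner")[q]),
               regs(m))
        }
      } else if (scn$type == "single_pool") {
        b <- scn$band
        m <- define_pool(m, ext, band = b, center_deg = mid)
        lo <- mid - ext / 2; hi <- mid + ext / 2
        regs <- function(mm) pool_regions(mm, b, lo, hi)
        note(m, P, ext, "baseline", regs(m))
        for (s in 1:3) {
          m <- pool_step(m, s, ...)
          note(m, P, ext, paste0("step_", c("I", "II", "III")[s]), regs(m))
        }
        if (scn$include_step4) {
          m <- disrupt_nearest_lamellae(m, ...)
          note(m, P, ext, "step_IV", regs(m))
        }
      } else if (scn$type == "two_pools") {
        # two pools of equal angular extent stacked radially, separated by
        # one intact intra-lamellar layer; step IV ruptures the interior
        # lamellae bounding that intact layer
        b <- scn$band
        m <- define_pool(m, ext, band = b - 2L, center_deg = mid)
        m <- define_pool(m, ext, band = b, center_deg = mid)
        lo <- mid - ext / 2; hi <- mid + ext / 2
        regs <- function(mm) {
          hdeg <- support_deg(mm, model$geom$R_in + 0.4 * model$geom$H)
          win <- c(lo - hdeg, hi + hdeg)
          grab <- function(kind, idx) {
            vals <- vapply(idx, function(i)
              tryCatch(regional_max_stress(mm, kind, i, win[1], win[2]),
                       error = function(e) NA_real_), 0)
            if (all(is.na(vals))) NA_real_ else max(vals, na.rm = TRUE)
          }
          c(interior_lamella = grab("lamella", c(b - 1L, b)),
            exterior_lamella = grab("lamella", c(b - 2L, b + 1L)),
            interior_intralamellar = grab("layer", b - 1L),
            exterior_intralamellar = grab("layer", c(b - 3L, b + 1L)))
        }
        note(m, P, ext, "baseline", regs(m))
        for (s in 1:3) {
          m <- pool_step(m, s, ...)
          note(m, P, ext, paste0("step_", c("I", "II", "III")[s]), regs(m))
        }
        if (scn$include_step4) {
          m <- disrupt_lamella(m, b - 1L, ext, mid, relax = FALSE)
          m <- disrupt_lamella(m, b, ext, mid, ...)
          note(m, P, ext, "step_IV", regs(m))
        }
      } else { # merged_pools: adjacent layers, shared lamella removed first
        b <- scn$band
        lo <- mid - ext / 2; hi <- mid + ext / 2
        m <- disrupt_lamella(m, b, ext, mid, ...)
        m <- define_pool(m, ext, band = b - 1L, center_deg = mid)
        m <- define_pool(m, ext, band = b, center_deg = mid)
        regs <- function(mm) {
          hdeg <- support_deg(mm, model$geom$R_in + 0.4 * model$geom$H)
          win <- c(lo - hdeg, hi + hdeg)
          grab <- function(kind, idx) {
            vals <- vapply(idx, function(i)
              tryCatch(regional_max_stress(mm, kind, i, win[1], win[2]),
                       error = function(e) NA_real_), 0)
            if (all(is.na(vals))) NA_real_ else max(vals, na.rm = TRUE)
          }
          c(nearest_lamella = grab("lamella", c(b - 1L, b + 1L)),
            nearest_intralamellar = grab("layer", c(b - 2L, b + 1L)),
            second_intralamellar = grab("layer", c(b - 3L, b + 2L)),
            second_lamella = grab("lamella", c(b - 2L, b + 2L)))
        }
        note(m, P, ext, "baseline", regs(m))
        for (s in 1:3) {
          m <- pool_step(m, s, ...)
          note(m, P, ext, paste0("step_", c("I", "II", "III")[s]), regs(m))
        }
        if (scn$include_step4) {
          m <- disrupt_nearest_lamellae(m, ...)
          note(m, P, ext, "step_IV", regs(m))
        }
      }
    }
  }
  do.call(rbind, rows)
}
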