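#' Reference geometry of the aortic wall sector
#'
#' Collects the homeostatic reference geometry: inner/outer radii, medial
#' and adventitial thickness, sector angle, lamellar structure.  Defaults
#' are the murine descending thoracic aorta at the in vivo (102 mmHg) state.
#'
#' @param R_in inner homeostatic radius, micrometres.
#' @param R_out outer homeostatic radius, micrometres.
#' @param H_M medial thickness, micrometres.
#' @param H_A adventitial thickness, micrometres.
#' @param sector_deg angular extent of the simulated sector, degrees; the
#'   rest of the circumference is represented by rotational-periodic images.
#' @param n_lamellae number of elastic lamellae (rings) in the media.
#' @param lamella_th nominal lamella thickness, micrometres.
#' @return list of class `wall_geometry`.
#' @export
wall_geometry <- function(R_in = 646.8, R_out = 687.0,
                          H_M = 28.4, H_A = 11.8,
                          sector_deg = 90, n_lamellae = 6, lamella_th = 2) {
  H <- R_out - R_in
  if (abs((H_M + H_A) - H) > 1e-6)
    stop("wall_geometry: H_M + H_A must equal R_out - R_in")
  if (sector_deg <= 0 || sector_deg > 360 ||
      abs(360 / sector_deg - round(360 / sector_deg)) > 1e-9)
    stop("wall_geometry: sector_deg must divide 360")
  g <- list(R_in = R_in, R_out = R_out, H = H, H_M = H_M, H_A = H_A,
            sector_deg = sector_deg, sector = sector_deg * pi / 180,
            n_lamellae = n_lamellae, n_layers = n_lamellae - 1,
            lamella_th = lamella_th)
  class(g) <- "wall_geometry"
  g
}

#' Build the multi-layered particle lattice
#'
#' Generates concentric rings of particles for the quarter-sector wall:
#' `n_lamellae` elastic-lamella rings equally partitioning the media into
#' `n_lamellae - 1` intra-lamellar layers, one or more intra-lamellar rings
#' per layer, and adventitial rings outside the media.  Arc spacing is
#' chosen per ring so that the local particle area matches `1/density`, and
#' per-particle volumes are exact ring-sector areas (unit reference depth),
#' so the volumes tile the sector area.  The construction is deterministic.
#'
#' @param geometry a [wall_geometry].
#' @param density target particle density, particles per square micrometre.
#' @param mat a [wall_materials] parameter set.
#' @param lamella_rings number of particle rings per lamella (1 or 2).
#' @return object of class `aorta_wall`.
#' @export
build_wall <- function(geometry = wall_geometry(), density = 0.24,
                       mat = wall_materials(), lamella_rings = 1) {
  g <- geometry
  if (density <= 0) stop("build_wall: density must be positive")
  layer_h <- g$H_M / g$n_layers
  spacing <- 1 / sqrt(density)
  if (spacing > layer_h)
    stop("build_wall: density ", density, " cannot resolve ", g$n_lamellae,
         " lamellae and ", g$n_layers, " intra-lamellar layers ",
         "(particle spacing exceeds the layer thickness)")
  if (!lamella_rings %in% c(1, 2))
    stop("build_wall: lamella_rings must be 1 or 2")

  lam_r <- g$R_in + (0:(g$n_lamellae - 1)) * layer_h
  n_int <- max(1, round(layer_h * sqrt(density) - 0.75))
  n_adv <- max(1, round(g$H_A * sqrt(density)))

  rings <- list()
  add_ring <- function(r, type, lamella = 0L, layer = 0L)
    rings[[length(rings) + 1L]] <<- list(r = r, type = type,
                                         lamella = lamella, layer = layer)
  for (i in seq_len(g$n_lamellae)) {
    if (lamella_rings == 1L) {
      add_ring(lam_r[i], "el", lamella = i)
    } else {
      lo <- if (i == 1L) lam_r[i] else lam_r[i] - g$lamella_th / 4
      add_ring(lo, "el", lamella = i)
      add_ring(lo + g$lamella_th / 2, "el", lamella = i)
    }
    if (i < g$n_lamellae) {
      gap <- lam_r[i + 1] - lam_r[i]
      for (q in seq_len(n_int))
        add_ring(lam_r[i] + q * gap / (n_int + 1), "int", layer = i)
    }
  }
  R_mA <- g$R_in + g$H_M
  for (q in seq_len(n_adv))
    add_ring(R_mA + (q - 0.5) * g$H_A / n_adv, "adv")

  rr <- vapply(rings, `[[`, numeric(1), "r")
  o <- order(rr)
  rings <- rings[o]
  rr <- rr[o]
  nring <- length(rr)
  mid <- (rr[-1] + rr[-nring]) / 2
  r_lo <- c(g$R_in, mid)
  r_hi <- c(mid, g$R_out)

  specs <- list(
    el  = constituent_spec("M_el", mat),
    int = constituent_spec("M_int", mat),
    adv = constituent_spec("A", mat))

  X <- NULL; theta <- NULL; V <- NULL
  group <- integer(0); lamella <- integer(0); layer <- integer(0)
  ring_id <- integer(0)
  for (k in seq_len(nring)) {
    band <- r_hi[k] - r_lo[k]
    s_arc <- 1 / (density * band)
    n_th <- max(4L, as.integer(round(rr[k] * g$sector / s_arc)))
    th <- (seq_len(n_th) - 0.5) * g$sector / n_th
    area <- (r_hi[k]^2 - r_lo[k]^2) / 2 * g$sector
    X <- rbind(X, cbind(rr[k] * cos(th), rr[k] * sin(th)))
    theta <- c(theta, th)
    V <- c(V, rep(area / n_th, n_th))
    gcode <- switch(rings[[k]]$type, el = 1L, int = 2L, adv = 3L)
    group <- c(group, rep(gcode, n_th))
    lamella <- c(lamella, rep(rings[[k]]$lamella, n_th))
    layer <- c(layer, rep(rings[[k]]$layer, n_th))
    ring_id <- c(ring_id, rep(k, n_th))
  }
  n <- nrow(X)

  mp <- matrix(0, n, length(MP_COLS), dimnames = list(NULL, MP_COLS))
  base_rows <- rbind(mp_row(specs$el), mp_row(specs$int), mp_row(specs$adv))
  mp[] <- base_rows[group, ]
  mp[, "theta_ref"] <- theta

  arc_min <- min(vapply(seq_len(nring), function(k) {
    band <- r_hi[k] - r_lo[k]
    n_th <- max(4L, as.integer(round(rr[k] * g$sector * density * band)))
    rr[k] * g$sector / n_th
  }, 0))
  wall <- list(
    geom = g, mat = mat, density = density, spacing = spacing,
    dx_min = min(diff(rr), arc_min),
    n_int_rings = n_int, n_adv_rings = n_adv, lamella_rings = lamella_rings,
    rings = data.frame(r = rr, r_lo = r_lo, r_hi = r_hi,
                       type = vapply(rings, `[[`, character(1), "type"),
                       lamella = vapply(rings, `[[`, integer(1), "lamella"),
                       layer = vapply(rings, `[[`, integer(1), "layer")),
    X = X, theta_ref = theta, R_ref = sqrt(rowSums(X^2)), V = V,
    group = group, lamella = lamella, layer = layer, ring = ring_id,
    inner_rim = ring_id == 1L, outer_rim = ring_id == nring,
    outer_half_band = r_hi[nring] - rr[nring],
    mp = mp)
  class(wall) <- "aorta_wall"
  wall
}

#' @export
print.aorta_wall <- function(x, ...) {
  cat("<aorta_wall> ", nrow(x$X), " particles, sector ", x$geom$sector_deg,
      "°, density ", x$density, "/um^2\n", sep = "")
  cat("  R_in ", x$geom$R_in, " um, R_out ", x$geom$R_out, " um; ",
      x$geom$n_lamellae, " lamellae (", x$lamella_rings, " ring(s) each), ",
      x$n_int_rings, " intra-lamellar ring(s)/layer, ",
      x$n_adv_rings, " adventitial rings\n", sep = "")
  tab <- table(factor(x$group, 1:4, c("M_el", "M_int", "A", "GAG")))
  cat("  groups:", paste(names(tab), tab, sep = "=", collapse = ", "), "\n")
  invisible(x)
}

#' Locate a lamella by transmural position
#'
#' Maps a fractional depth `fraction` (of the full wall thickness `H`,
#' measured from the inner surface) to the nearest elastic lamella.
#'
#' @param wall an `aorta_wall` (or `sph_model`).
#' @param fraction dimensionless depth in `[0, H_M/H]`.
#' @return list with `lamella` (index, 1 = innermost) and `radius`.
#' @export
locate_lamella <- function(wall, fraction) {
  g <- wall$geom
  if (fraction < 0 || fraction > g$H_M / g$H + 1e-9)
    stop("locate_lamella: fraction ", fraction, " lies outside the media")
  r <- g$R_in + fraction * g$H
  lam_r <- g$R_in + (0:(g$n_lamellae - 1)) * g$H_M / g$n_layers
  i <- which.min(abs(lam_r - r))
  list(lamella = i, radius = lam_r[i])
}
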