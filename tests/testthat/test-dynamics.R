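# Force assembly, stabilization, integration, and the equilibrium layer.

test_that("leapfrog integration is second order and reversible", {
  # constant force, free particle: exact quadratic trajectory
  m1 <- 2; f0 <- c(1.5, -0.75)
  x <- matrix(0, 1, 2); v <- matrix(c(1, 0.5), 1, 2)
  dt <- 0.05
  for (k in 1:40) {
    s <- leapfrog_step(x, v, function(xx) matrix(f0, 1, 2), m1, dt)
    x <- s$x; v <- s$v
  }
  tend <- 40 * dt
  exact <- c(1, 0.5) * tend + 0.5 * f0 / m1 * tend^2
  expect_equal(drop(x), exact, tolerance = 1e-10)  # exact for constant force
  # zero force, zero velocity: state unchanged
  s <- leapfrog_step(matrix(1:2, 1), matrix(0, 1, 2),
                     function(xx) matrix(0, 1, 2), 1, 0.1)
  expect_equal(drop(s$x), c(1, 2))
  # time reversal of a frictionless trajectory returns to the start
  spring <- function(xx) -3 * xx
  x <- matrix(c(1, 0), 1, 2); v <- matrix(c(0, 0.6), 1, 2)
  for (k in 1:100) { s <- leapfrog_step(x, v, spring, 1, dt); x <- s$x; v <- s$v }
  v <- -v
  for (k in 1:100) { s <- leapfrog_step(x, v, spring, 1, dt); x <- s$x; v <- s$v }
  expect_equal(drop(x), c(1, 0), tolerance = 1e-9)
  expect_error(leapfrog_step(x, v, spring, -1, dt), "positive")
})

test_that("internal forces are pairwise antisymmetric (free boundaries)", {
  # free-edged sector (no periodic images): total force must vanish by the
  # antisymmetry of the pair forces, for any stress field
  w <- build_wall(wall_geometry(sector_deg = 8), density = 0.24)
  m <- sph_model(w, control = suite_control(), periodic = FALSE)
  set.seed(5)
  P <- cbind(200 * sin(m$X[, 1] / 30), 40 * cos(m$X[, 2] / 25),
             40 * sin(m$X[, 2] / 40), 150 + 100 * sin(m$X[, 1] / 50))
  f <- internal_forces(m, P)
  scale <- mean(sqrt(rowSums(f^2)))
  expect_lt(max(abs(colSums(f))) / (scale * nrow(f)), 1e-9)
  # zero stress: zero forces
  expect_equal(internal_forces(m, matrix(0, nrow(m$X), 4)),
               matrix(0, nrow(m$X), 2))
})

test_that("uniform stress produces no interior forces", {
  # on a point-symmetric (square) lattice the adjoint force form
  # annihilates a constant stress field: interior forces vanish while the
  # free surfaces feel the full traction imbalance
  w <- build_wall(wall_geometry(sector_deg = 8), density = 0.24)
  n_sq <- 21^2
  gsq <- as.matrix(expand.grid(x = seq(0, 40, by = 2), y = seq(0, 40, by = 2)))
  wsq <- w
  wsq$X <- gsq + 600
  wsq$theta_ref <- rep(0, n_sq)
  wsq$R_ref <- sqrt(rowSums(wsq$X^2))
  wsq$V <- rep(4, n_sq)
  wsq$mp <- w$mp[rep(1, n_sq), ]
  msq <- sph_model(wsq, support = 3 * w$spacing, periodic = FALSE)
  P <- matrix(rep(c(120, 15, 15, 90), each = n_sq), ncol = 4)
  f <- internal_forces(msq, P)
  inter <- gsq[, 1] > 7 & gsq[, 1] < 33 & gsq[, 2] > 7 & gsq[, 2] < 33
  expect_lt(max(abs(f[inter, ])), 1e-3 * max(abs(f[!inter, ])))

  # the concentric-ring wall lattice is not point symmetric (curvature,
  # per-ring arc spacing): a bounded zeroth-order residual remains, still
  # well below the surface-traction force scale
  m <- sph_model(w, control = suite_control(), periodic = FALSE)
  Pw <- matrix(rep(c(120, 15, 15, 90), each = nrow(m$X)), ncol = 4)
  fw <- internal_forces(m, Pw)
  edge_ang <- m$nbr$h / m$R_ref
  interior <- m$R_ref > m$geom$R_in + m$nbr$h &
    m$R_ref < m$geom$R_out - m$nbr$h &
    m$theta_ref > edge_ang & m$theta_ref < m$geom$sector - edge_ang
  expect_lt(max(abs(fw[interior, ])), 0.3 * max(abs(fw[!interior, ])))
})

test_that("hourglass penalty vanishes for affine maps and scales with alpha", {
  w <- build_wall(wall_geometry(sector_deg = 8), density = 0.24)
  m <- sph_model(w, control = suite_control(), periodic = FALSE)
  F0 <- matrix(c(1.08, 0.04, -0.02, 0.95), 2, 2)
  x_aff <- t(F0 %*% t(m$X))
  mA <- m; mA$state$x <- x_aff
  FA <- deformation_gradient(m, x_aff)$F
  f_aff <- hourglass_forces(mA, FA)
  # alpha = 0: exactly zero
  mA$control$alpha <- 0
  expect_equal(hourglass_forces(mA, FA), matrix(0, nrow(m$X), 2))
  mA$control$alpha <- 25
  # zig-zag (alternating) perturbation on top of the affine map
  zig <- 0.05 * (-1)^(seq_len(nrow(m$X)))
  x_zig <- x_aff + cbind(zig, -zig)
  mZ <- m; mZ$state$x <- x_zig
  FZ <- deformation_gradient(m, x_zig)$F
  f_zig <- hourglass_forces(mZ, FZ)
  # affine forces are rounding noise next to the zig-zag response
  expect_lt(max(abs(f_aff)), 1e-6 * max(abs(f_zig)))
  # penalty is linear in alpha: 10x alpha -> 10x force (faster decay)
  mZ$control$alpha <- 50
  f50 <- hourglass_forces(mZ, FZ)
  mZ$control$alpha <- 5
  f5 <- hourglass_forces(mZ, FZ)
  expect_equal(f50, 10 * f5, tolerance = 1e-10)
  # the penalty opposes the perturbation (negative work on the zig-zag)
  expect_lt(sum(f_zig * cbind(zig, -zig)), 0)
})

test_that("alpha outside the validated range warns", {
  expect_warning(stabilization_params(alpha = 100), "\\[5, 50\\]")
  expect_silent(stabilization_params(alpha = 25))
})

test_that("the prestretched reference equilibrates at ~102 mmHg", {
  m <- ref_model()
  rec <- m$record
  expect_equal(rec$status, "converged")
  expect_equal(rec$pressure_mmHg, 102, tolerance = 0.10)
  expect_equal(rec$lambda_theta, 1, tolerance = 0.002)
  expect_equal(rec$outer_diameter, 2 * 687, tolerance = 0.005)
  # global force balance: constraint reaction pressure vs Laplace report
  expect_equal(rim_reaction_pressure(m), rec$pressure_kPa, tolerance = 0.05)
})

test_that("removing all prestretches leaves a stress-free wall", {
  plain <- wall_materials(Ge = c(r = 1, th = 1, z = 1),
                          Gk_circ_med = 1, Gk_other = 1)
  w <- build_wall(wall_geometry(sector_deg = 8), density = 0.24, mat = plain)
  m <- set_reference(sph_model(w, control = suite_control()))
  expect_lt(max(abs(m$state$sigma)), 0.5)      # kPa: rounding-level residual
  expect_lt(abs(m$record$pressure_mmHg), 1)
})

test_that("equilibrium stresses are insensitive to the artificial viscosity", {
  m0 <- ref_model()
  st0 <- sigma_theta(m0)
  eta0 <- aortasph:::resolve_control(m0, m0$control)$eta
  vals <- lapply(c(0.5, 2), function(fac) {
    w <- build_wall(wall_geometry(sector_deg = 15), density = 0.24)
    mm <- sph_model(w, control = suite_control(eta = fac * eta0))
    sigma_theta(set_reference(mm))
  })
  for (st in vals) {
    expect_lt(max(abs(st - st0)) / max(abs(st0)), 0.005)
  }
})

test_that("transmural stress patterns match the layered-wall mechanics", {
  m <- ref_model()
  tp <- transmural_profile(m)
  el <- tp$group == "M_el" & tp$radius < 646.8 + 28
  int <- tp$group == "M_int"
  # passive state: lamellae carry more circumferential stress than the
  # intra-lamellar tissue
  expect_gt(min(tp$sigma_theta[el]), max(tp$sigma_theta[int]))
  # radial stress: roughly zero in intra-lamellar bands, compressive in
  # lamellae
  expect_lt(mean(tp$sigma_radial[el]), -5)
  expect_gt(mean(tp$sigma_radial[int]), mean(tp$sigma_radial[el]))
  # full activation reverses the ordering: contracted SMCs carry more
  ma <- active_state(102)
  tpa <- transmural_profile(ma)
  ela <- tpa$group == "M_el" & tpa$radius < ma$record$r_in + 35
  inta <- tpa$group == "M_int"
  expect_gt(mean(tpa$sigma_theta[inta]), mean(tpa$sigma_theta[ela]))
})

test_that("the thin-wall oracle tracks the particle model within 5%", {
  m <- ref_model()
  sph <- cache_get("pd_curve",
    pressure_diameter_curve(m, lambda_theta = c(0.975, 1, 1.04, 1.08, 1.1)))
  grid <- thin_wall_oracle(m, seq(0.95, 1.15, by = 0.005))
  of <- stats::splinefun(2 * grid$r_out, grid$pressure_mmHg)
  rel <- abs(of(sph$outer_diameter) - sph$pressure_mmHg) / sph$pressure_mmHg
  expect_true(all(rel <= 0.05))
  # curve is monotone and strain-stiffening over the working range
  # (slopes computed with the actual, uneven stretch spacing)
  expect_true(all(diff(sph$pressure_mmHg) > 0))
  slopes <- diff(sph$pressure_mmHg) / diff(sph$lambda_theta)
  expect_true(all(diff(slopes) > 0))
  # trivial oracle limits
  expect_equal(thin_wall_oracle(m, 1)$pressure_mmHg, 102, tolerance = 0.10)
})

test_that("equilibrate_at matches a pressure target by displacement control", {
  m <- active_state(102)
  expect_equal(m$record$pressure_mmHg, 102, tolerance = 0.01)
  expect_equal(m$record$status, "converged")
  expect_error(equilibrate_at(ref_model()), "exactly one")
  expect_error(equilibrate_at(ref_model(), r_in = 640, pressure = 100),
               "exactly one")
})
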