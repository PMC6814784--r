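# Spiky kernel, corrected gradients, field approximation, deformation
# gradients: the discrete differential-operator layer.

test_that("kernel weight matches the cubic Spiky form", {
  h <- 6
  expect_equal(kernel_weight(h, h), 0)
  expect_equal(kernel_weight(1.5 * h, h), 0)
  expect_equal(kernel_weight(0, h), 10 / (pi * h^2))
  expect_equal(kernel_weight(h / 2, h), 10 / (8 * pi * h^2))
  # C0 continuity at the support boundary
  expect_lt(kernel_weight(h * (1 - 1e-8), h), 1e-20)
  expect_error(kernel_weight(-1, h), "negative")
  expect_error(kernel_weight(1, -2), "positive")
})

test_that("kernel gradient has the analytic magnitude and points inward", {
  h <- 6
  g <- kernel_gradient(c(h, 0), h)
  expect_equal(unname(g[1, ]), c(0, 0))
  g <- kernel_gradient(c(2 * h, 1), h)
  expect_equal(unname(g[1, ]), c(0, 0))
  # magnitude 30 (h - R)^2 / (pi h^5), direction along -offset
  off <- c(1.2, -0.7)
  R <- sqrt(sum(off^2))
  g <- kernel_gradient(off, h)
  expect_equal(sqrt(sum(g^2)), 30 * (h - R)^2 / (pi * h^5), tolerance = 1e-12)
  expect_equal(unname(g[1, ] / sqrt(sum(g^2))), -off / R, tolerance = 1e-12)
  # R -> 0 limit of the magnitude
  g0 <- kernel_gradient(c(1e-8, 0), h)
  expect_equal(abs(g0[1, 1]), 30 / (pi * h^3), tolerance = 1e-6)
})

test_that("correction matrices restore the discrete gradient identity", {
  m <- tiny_model()
  nb <- m$nbr
  n <- nrow(m$X)
  # sum_j V_j cgrad_j (x) R_j = I for every particle (algebraic identity)
  worst <- 0
  for (i in seq_len(n)) {
    e <- seq.int(nb$ptr[i] + 1L, length.out = nb$ptr[i + 1L] - nb$ptr[i])
    j <- nb$idx[e] + 1L
    S <- matrix(0, 2, 2)
    for (q in seq_along(e)) {
      S <- S + m$V[j[q]] * nb$cgrad[e[q], ] %o% nb$Rj[e[q], ]
    }
    worst <- max(worst, max(abs(S - diag(2))))
  }
  expect_lt(worst, 1e-10)
  expect_true(all(is.finite(correction_matrix(m)$cond)))
})

test_that("collinear neighbourhoods are rejected as rank-deficient", {
  # a straight line of particles: A_i has no transverse information
  X <- cbind(seq(0, 20, by = 2), 0)
  w <- build_wall(wall_geometry(sector_deg = 8), density = 0.24)
  w$X <- X
  w$theta_ref <- rep(0, nrow(X))
  w$R_ref <- X[, 1]
  w$V <- rep(4, nrow(X))
  w$mp <- w$mp[rep(1, nrow(X)), ]
  w$geom$sector <- 2 * pi  # rotation images coincide: keeps line collinear
  expect_error(sph_model(w, support = 5), "rank-deficient|collinear")
})

test_that("smoothed constant fields expose the partition-of-unity defect", {
  m <- tiny_model()
  interior <- m$R_ref > m$geom$R_in + m$nbr$h & m$R_ref < m$geom$R_out - m$nbr$h
  # all-zero field stays zero
  expect_equal(approximate_field(rep(0, nrow(m$X)), m), rep(0, nrow(m$X)))
  # at the default support (3 x spacing) the discrete Spiky sum overshoots
  # unity by ~8% on this lattice (midpoint-rule convexity); pinned here
  pu <- partition_of_unity(m)
  expect_true(all(abs(pu[interior] - 1) < 0.14))
  expect_equal(mean(pu[interior]), 1.08, tolerance = 0.02)
  # the 2D normalization is recovered (< 5% defect) at wider support
  w <- build_wall(wall_geometry(sector_deg = 8), density = 0.24)
  m45 <- sph_model(w, support = 4.5 * w$spacing, control = suite_control())
  pu45 <- partition_of_unity(m45)
  int45 <- m45$R_ref > m45$geom$R_in + m45$nbr$h &
           m45$R_ref < m45$geom$R_out - m45$nbr$h
  expect_true(all(abs(pu45[int45] - 1) < 0.05))
})

test_that("a single neighbour at the kernel centre reproduces the field", {
  # V = pi h^2 / 10 makes V * xi(0) = 1
  h <- 6
  expect_equal(pi * h^2 / 10 * kernel_weight(0, h), 1)
})

test_that("deformation gradients reproduce affine maps exactly", {
  # free-edged lattice: the corrected gradients make any affine map exact
  # at every particle, including wall surfaces and sector edges
  w <- build_wall(wall_geometry(sector_deg = 8), density = 0.24)
  mf <- sph_model(w, control = suite_control(), periodic = FALSE)
  set.seed(42)
  for (k in 1:6) {
    F0 <- diag(2) + matrix(rnorm(4, 0, 0.1), 2, 2)
    if (det(F0) <= 0.5) next
    d <- deformation_gradient(mf, t(F0 %*% t(mf$X)))
    err <- abs(sweep(d$F, 2, c(F0[1, 1], F0[1, 2], F0[2, 1], F0[2, 2])))
    expect_lt(max(err) / max(abs(F0)), 1e-10)
  }
  # on the periodic sector the same exactness holds away from the edges
  m <- tiny_model()
  edge_ang <- m$nbr$h / m$R_ref
  interior <- m$theta_ref > edge_ang & m$theta_ref < m$geom$sector - edge_ang
  F0 <- matrix(c(1.10, 0.05, -0.03, 0.95), 2, 2)
  d <- deformation_gradient(m, t(F0 %*% t(m$X)))
  err <- abs(sweep(d$F, 2, c(F0[1, 1], F0[1, 2], F0[2, 1], F0[2, 2])))
  expect_lt(max(err[interior, ]) / max(abs(F0)), 1e-10)
  # pure scaling commutes with the sector rotation: exact at the edges too
  d <- deformation_gradient(m, 1.07 * m$X)
  expect_lt(max(abs(sweep(d$F, 2, c(1.07, 0, 0, 1.07)))), 1e-10)
  expect_equal(d$J, rep(1.07^2, nrow(m$X)), tolerance = 1e-10)
})

test_that("rigid rotations give C = I and J = lambda_z", {
  m <- tiny_model()
  a <- 0.35
  Q <- matrix(c(cos(a), sin(a), -sin(a), cos(a)), 2, 2)
  d <- deformation_gradient(m, t(Q %*% t(m$X)))
  for (i in seq(1, nrow(m$X), by = 37)) {
    F <- matrix(d$F[i, ], 2, 2, byrow = TRUE)
    expect_equal(crossprod(F), diag(2), tolerance = 1e-10)
  }
  expect_equal(d$J, rep(m$control$lambda_z, nrow(m$X)), tolerance = 1e-10)
})

test_that("element inversion is reported as an error", {
  m <- tiny_model()
  x <- m$X
  x[, 1] <- -x[, 1]  # reflection: det(F) < 0 everywhere
  expect_error(deformation_gradient(m, x), "inversion")
})
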