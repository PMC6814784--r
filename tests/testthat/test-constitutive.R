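# Mixture constitutive relations: invariants, branch switching, stresses,
# active tone, GAG swelling, viscous stabilization.

mat <- wall_materials()

test_that("fiber invariant composes stretch and deposition prestretch", {
  C <- diag(3)
  M <- c(0, 1, 0)
  expect_equal(fiber_invariant(C, M), 1)
  expect_equal(fiber_invariant(C, M, G = 1.25), 1.5625)
  # circumferential family under pure circumferential stretch
  lt <- 1.13
  C <- diag(c(1 / lt^2, lt^2, 1))
  expect_equal(fiber_invariant(C, M, G = 1.2), (1.2 * lt)^2)
  expect_error(fiber_invariant(C, c(0, 2, 0)), "unit")
})

test_that("tension and compression branches switch at I4 = 1", {
  expect_equal(select_branch(1.2, mat$med_axdiag), c(c1 = 234.9, c2 = 4.08))
  expect_equal(select_branch(0.9, mat$med_axdiag), c(c1 = 29.14, c2 = 4.08))
  expect_equal(select_branch(1, mat$med_axdiag)[["c1"]], 234.9)
  # both branches give exactly zero fiber stress at I4 = 1: the (I4 - 1)
  # factor makes the response continuous across the switch
  for (dI in c(-1e-9, 0, 1e-9)) {
    cc <- select_branch(1 + dI, mat$med_circ)
    expect_lt(abs(cc[["c1"]] * dI * exp(cc[["c2"]] * dI^2)), 1e-6)
  }
})

test_that("strain energy vanishes only for an unprestretched reference", {
  plain <- wall_materials(Ge = c(r = 1, th = 1, z = 1),
                          Gk_circ_med = 1, Gk_other = 1, lambda_z = 1)
  for (g in c("M_el", "M_int", "A")) {
    sp0 <- constituent_spec(g, plain)
    expect_equal(passive_energy(diag(2), sp0), 0, tolerance = 1e-12)
  }
  # Table-valued prestretches store energy at F = I, and the prescribed
  # elastin prestretch is nearly isochoric (det G^e = 0.985)
  spE <- constituent_spec("M_el", mat)
  expect_gt(passive_energy(diag(2), spE), 0)
  expect_equal(prod(mat$Ge), 0.985, tolerance = 1e-3)
  expect_error(passive_energy(matrix(c(1, 0, 0, -1), 2), spE), "J <= 0")
})

test_that("lamellar particles are purely neo-Hookean", {
  spE <- constituent_spec("M_el", mat)
  expect_null(spE$fibers)      # phi^ck = 0: no fiber families at all
  # explicitly adding zero-weight fiber rows changes nothing
  spZ <- spE
  spZ$fibers <- constituent_spec("M_int", mat)$fibers
  spZ$fibers[, "w"] <- 0
  F2 <- matrix(c(1.1, 0.02, -0.01, 0.94), 2, 2)
  expect_equal(passive_stress(F2, spE)$P, passive_stress(F2, spZ)$P)
  expect_equal(passive_energy(F2, spE), passive_energy(F2, spZ))
})

test_that("analytic stress matches the closed-form neo-Hookean expression", {
  plain <- wall_materials(Ge = c(r = 1, th = 1, z = 1))
  sp <- constituent_spec("M_el", plain)
  F2 <- matrix(c(1.15, 0.08, -0.03, 0.9), 2, 2)
  J <- det(F2)
  B <- tcrossprod(F2)
  mu <- plain$mu; lh <- plain$lambda_ratio * plain$mu
  sig_ref <- (mu * (B - diag(2)) + lh * log(J) * diag(2)) / J
  expect_equal(passive_stress(F2, sp)$sigma, sig_ref, tolerance = 1e-8)
})

test_that("sigma equals P F^T / J and P equals dW/dF by finite differences", {
  set.seed(7)
  for (g in c("M_el", "M_int", "A")) {
    sp <- constituent_spec(g, mat, theta_ref = 0.6)
    for (k in 1:25) {
      F2 <- diag(2) + matrix(rnorm(4, 0, 0.08), 2, 2)
      if (det(F2) < 0.3) next
      s <- passive_stress(F2, sp)
      expect_equal(s$sigma, s$P %*% t(F2) / det(F2), tolerance = 1e-10)
      Pfd <- matrix(0, 2, 2)
      hh <- 1e-6
      for (a in 1:2) for (b in 1:2) {
        Fp <- F2; Fp[a, b] <- Fp[a, b] + hh
        Fm <- F2; Fm[a, b] <- Fm[a, b] - hh
        Pfd[a, b] <- (passive_energy(Fp, sp) - passive_energy(Fm, sp)) / (2 * hh)
      }
      expect_equal(s$P, Pfd, tolerance = 1e-5)
    }
  }
})

test_that("elastin carries no stress when its total stretch is the identity", {
  # with the volumetric penalty off, F = (G^e)^-1 (in-plane) and
  # lambda_z = 1/G^e_z null the elastin response entirely
  m0 <- wall_materials(lambda_ratio = 0)
  sp <- constituent_spec("M_el", m0, theta_ref = 0)
  Finv <- diag(c(1 / m0$Ge[["r"]], 1 / m0$Ge[["th"]]))
  s <- passive_stress(Finv, sp, lambda_z = 1 / m0$Ge[["z"]])
  expect_equal(s$P, matrix(0, 2, 2), tolerance = 1e-10)
  expect_equal(s$szz, 0, tolerance = 1e-10)
})

test_that("active tone follows the parabolic length-tension relation", {
  sp <- constituent_spec("M_int", mat)
  expect_equal(active_stress(0.6, sp), 0)           # vanishes at lambda_min
  expect_equal(active_stress(1.1, sp), 0.84 * 500 * 1.1)  # maximal
  expect_equal(active_stress(1.0, sp), 0.84 * 500 * 1.0 * (1 - (0.1 / 0.5)^2))
  expect_equal(active_stress(1.0, sp), 403.2)
  expect_equal(active_stress(0.5, sp), 0)           # clamped below
  expect_equal(active_stress(1.3, sp), 0)           # clamped above
  bad <- sp; bad$lambda_max <- 0.5
  expect_error(active_stress(1, bad), "lambda_max")
  expect_error(wall_materials(lambda_max = 0.5), "lambda_max")
})

test_that("GAG stress is neo-Hookean plus an isotropic swelling pressure", {
  sp <- constituent_spec("GAG", mat)
  # B = I, swelling off: zero
  expect_equal(gag_stress(diag(2), sp, FALSE)$sigma, matrix(0, 2, 2))
  # Gibbs-Donnan term: 8.314 * 310 * (sqrt(200^2+300^2) - 300) Pa = 156.1 kPa
  expect_equal(swelling_pressure(200, 300, 310), 156.07, tolerance = 1e-4)
  expect_equal(swelling_pressure(0, 300, 310), 0)
  expect_error(swelling_pressure(-5), "negative")
  # the swelling term is deformation-independent and purely isotropic
  set.seed(3)
  for (k in 1:10) {
    F2 <- diag(2) + matrix(rnorm(4, 0, 0.2), 2, 2)
    if (det(F2) < 0.3) next
    dsig <- gag_stress(F2, sp, TRUE)$sigma - gag_stress(F2, sp, FALSE)$sigma
    expect_equal(dsig, -swelling_pressure(200, 300, 310) * diag(2),
                 tolerance = 1e-10)
  }
})

test_that("viscous stabilization stress vanishes for rigid motion and rest", {
  F2 <- matrix(c(1.1, 0.05, -0.02, 0.95), 2, 2)
  expect_equal(viscous_stress(F2, matrix(0, 2, 2), eta = 50),
               matrix(0, 2, 2))
  # rigid rotation at constant rate: l is skew, d = 0
  a <- 0.4; om <- 0.3
  Q <- matrix(c(cos(a), sin(a), -sin(a), cos(a)), 2, 2)
  Qdot <- om * matrix(c(-sin(a), cos(a), -cos(a), -sin(a)), 2, 2)
  expect_equal(viscous_stress(Q, Qdot, eta = 50), matrix(0, 2, 2),
               tolerance = 1e-12)
})

test_that("compiled constitutive evaluation matches the reference one", {
  set.seed(11)
  for (g in c("M_el", "M_int", "A")) {
    sp <- constituent_spec(g, mat, theta_ref = 1.1)
    mp1 <- rbind(aortasph:::mp_row(sp))
    for (k in 1:10) {
      F2 <- diag(2) + matrix(rnorm(4, 0, 0.07), 2, 2)
      if (det(F2) < 0.3) next
      cs <- aortasph:::cpp_stress(
        matrix(c(F2[1, 1], F2[1, 2], F2[2, 1], F2[2, 2]), 1), mp1,
        matrix(c(1, 0), 1), 1, 0)
      rs <- passive_stress(F2, sp)
      expect_equal(matrix(cs$P[1, ], 2, 2, byrow = TRUE), rs$P,
                   tolerance = 1e-10)
      expect_equal(cs$W[1], rs$W, tolerance = 1e-10)
      expect_equal(cs$szz[1], rs$szz, tolerance = 1e-10)
    }
  }
  # GAG with swelling on
  spg <- constituent_spec("GAG", mat)
  mpg <- rbind(aortasph:::mp_row(spg))
  mpg[1, "pi_swell"] <- swelling_pressure(mat$cFC, mat$cstar, mat$Temp)
  F2 <- matrix(c(1.2, 0.1, -0.05, 0.9), 2, 2, byrow = TRUE)
  cs <- aortasph:::cpp_stress(
    matrix(c(F2[1, 1], F2[1, 2], F2[2, 1], F2[2, 2]), 1), mpg,
    matrix(c(1, 0), 1), 1, 0)
  rg <- gag_stress(F2, spg, TRUE)
  expect_equal(matrix(cs$sigma[1, ], 2, 2, byrow = TRUE), rg$sigma,
               tolerance = 1e-9)
})
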