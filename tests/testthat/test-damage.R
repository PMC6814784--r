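# Lamellar disruption and the SMC-to-GAG replacement protocol.

test_that("neighbour-list surgery is symmetric and complete", {
  m <- tiny_model()
  n_alive0 <- sum(m$nbr$alive)
  mid <- m$geom$sector_deg / 2
  md <- disrupt_lamella(m, 3, 2, mid, relax = FALSE)
  dis <- which(md$mp[, "group"] == 0)
  expect_gt(length(dis), 0)
  src <- rep.int(seq_len(nrow(md$X)), diff(md$nbr$ptr))
  tgt <- md$nbr$idx + 1L
  touches <- src %in% dis | tgt %in% dis
  # every edge touching a ruptured particle is dead, in both directions
  expect_true(all(!md$nbr$alive[touches]))
  # and only those edges died (the 2 deg gap exceeds the kernel support, so
  # no intact same-lamella pair spans it)
  expect_equal(n_alive0 - sum(md$nbr$alive), sum(touches))
  # severance bookkeeping is symmetric: directed edges die in pairs
  expect_equal(sum(touches) %% 2, 0)
})

test_that("opposite-side severance disconnects a narrow gap completely", {
  # with a gap narrower than the kernel support, intact particles on
  # opposite sides would remain neighbours; step (iii) must sever them
  m <- tiny_model()
  # remove exactly one particle so the flanking intact pair stays within
  # the kernel support: centre the gap on a lamella-3 particle
  on_lam <- which(m$lamella == 3)
  ctr <- m$theta_ref[on_lam[which.min(abs(m$theta_ref[on_lam] -
                                          m$geom$sector / 2))]] * 180 / pi
  ext <- 0.1  # deg: a one-particle gap, ~2 um << h
  md <- disrupt_lamella(m, 3, ext, ctr, relax = FALSE)
  expect_equal(sum(md$mp[, "group"] == 0), 1)
  iv <- c(ctr - ext / 2, ctr + ext / 2) * pi / 180
  lam3 <- md$lamella == 3 & md$mp[, "group"] == 1
  src <- rep.int(seq_len(nrow(md$X)), diff(md$nbr$ptr))
  tgt <- md$nbr$idx + 1L
  th_s <- md$theta_ref[src]; th_t <- md$theta_ref[tgt]
  # rot == 0: pairs joined through the periodic edge do not cross the gap
  spans <- lam3[src] & lam3[tgt] & md$nbr$rot == 0 &
    ((th_s < iv[1] & th_t > iv[2]) | (th_t < iv[1] & th_s > iv[2]))
  expect_gt(sum(spans), 0)              # such pairs exist in the table
  expect_true(all(!md$nbr$alive[spans]))  # and are all severed
})

test_that("disrupted particles carry zero stress after relaxation", {
  m <- cache_get("disrupt102", {
    disrupt_lamella(active_state(102), locate_lamella(ref_model(), 0.4)$lamella,
                    2, 7.5)
  })
  dis <- m$mp[, "group"] == 0
  expect_gt(sum(dis), 0)
  expect_equal(max(abs(m$state$sigma[dis, ])), 0)
  expect_equal(max(abs(m$state$W[dis])), 0)
  expect_equal(m$record$status, "converged")
})

test_that("disruption below the lattice resolution is an error", {
  m <- tiny_model()
  expect_error(disrupt_lamella(m, 3, 1e-4), "resolution|no particles")
  expect_error(disrupt_lamella(m, 99, 2), "no lamella")
  expect_error(disrupt_lamella(m, 3, 400), "extent")
})

test_that("pool steps enforce the I -> II -> III ordering", {
  m <- tiny_model()
  m <- define_pool(m, 2, band = 4)
  expect_error(pool_step(m, 2), "order")
  expect_error(pool_step(m, "III"), "order")
  expect_error(pool_step(tiny_model(), 1), "no pools")
  expect_error(define_pool(tiny_model(), 2, band = 9), "layer")
})

test_that("pool steps change exactly the designated material state", {
  m <- define_pool(tiny_model(), 2, band = 4)
  pool <- m$pools[[1]]$idx
  # step I: only the pool loses active tone (no relaxation needed to check)
  m1 <- m
  m1$mp[pool, "act_on"] <- 0
  expect_true(all(m1$mp[pool, "act_on"] == 0))
  others <- setdiff(which(m$group == 2L), pool)
  expect_true(all(m1$mp[others, "act_on"] == 1))
  # step II semantics: pool becomes GAG material
  m2 <- m
  m2$mp[pool, "group"] <- 4
  m2$mp[pool, c("phi_e", "mu", "lambda_hat")] <- 0
  expect_true(all(m2$mp[pool, "mu"] == 0))
})

test_that("scenario tables are tidy and deterministic", {
  scn <- scenario("lamellar_rupture", extents = 8, pressures = 102,
                  active = FALSE)
  expect_s3_class(scn, "wall_scenario")
  expect_error(scenario("single_pool", extents = -2), "positive")
  tab <- cache_get("scn_tab", {
    w <- build_wall(wall_geometry(sector_deg = 12), density = 0.24)
    m <- set_reference(sph_model(w, control = suite_control()))
    run_scenario(m, scn)
  })
  expect_true(all(c("scenario", "pressure", "extent", "event", "region",
                    "sigma_theta_max") %in% names(tab)))
  expect_equal(unique(tab$event),
               c("baseline", "rupture_middle", "rupture_outer",
                 "rupture_inner"))
  # every rupture leaves the adjacent bands loaded above baseline
  outer <- tab$sigma_theta_max[tab$region == "outer_intralamellar"]
  inner <- tab$sigma_theta_max[tab$region == "inner_intralamellar"]
  expect_true(all(outer[-1] > outer[1]))
  expect_true(all(inner[-1] > inner[1]))
})
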