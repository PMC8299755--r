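geom <- ref_geom()
mat <- material_params(3.2, 0.45)

test_that("zero prescribed displacement yields a zero stress field", {
  m <- annulus_mesh(geom, 12, 2, 1)
  bc <- boundary_condition(m, valve_size = 2 * m$inner_radius, theta = 0)
  f <- solve_stress(m, mat, bc)
  expect_equal(max(abs(f$von_mises)), 0)
  expect_equal(max(abs(f$displacement)), 0)
})

test_that("uniform inner displacement reproduces the Lame hoop stress", {
  u0 <- 0.5
  res <- list(c(16, 2, 2), c(24, 3, 3), c(36, 4, 5))
  err <- vapply(res, function(r) {
    m <- annulus_mesh(geom, r[1], r[2], r[3])
    bc <- boundary_condition(m, valve_size = 2 * (m$inner_radius + u0))
    f <- solve_stress(m, mat, bc)
    phi <- m$node_phi[m$inner_ids] * pi / 180
    s <- f$stress[m$inner_ids, ]
    hoop <- s[, 1] * sin(phi)^2 - 2 * s[, 4] * sin(phi) * cos(phi) +
      s[, 2] * cos(phi)^2
    ref <- lame_hoop(m$inner_radius, m$inner_radius, m$outer_radius,
                     mat$E, mat$nu, u0)
    abs(mean(hoop) / ref - 1)
  }, numeric(1))
  expect_lt(err[3], 0.05)
  expect_true(all(diff(err) < 0))  # uniform refinement improves the match
})

test_that("a rigid translation of all constrained nodes produces no stress", {
  m <- annulus_mesh(geom, 12, 2, 1)
  bc <- boundary_condition(m, valve_size = 26, theta = 0)
  sys <- assemble_system(m, mat$nu)
  tx <- 0.3; ty <- -0.2
  dofs <- c(3 * bc$nodes - 2, 3 * bc$nodes - 1, 3 * bc$nodes)
  vals <- cbind(c(rep(tx, length(bc$nodes)), rep(ty, length(bc$nodes)),
                  rep(0, length(bc$nodes))))
  ends <- which(m$node_ring %in% c(1L, m$n_axial + 1L))
  zd <- setdiff(3 * ends, dofs)
  con <- list(dofs = c(dofs, zd), vals = rbind(vals, matrix(0, length(zd))))
  o <- order(con$dofs)
  con <- list(dofs = con$dofs[o], vals = con$vals[o, , drop = FALSE])
  sol <- tavrisk:::fem_solve(m, sys, con, E = mat$E)
  scale_ref <- mat$E * sqrt(tx^2 + ty^2) / geom$wall_thickness
  expect_lt(max(tavrisk:::von_mises(sol$stress[[1]])), 1e-8 * scale_ref)
})

test_that("the solve is linear and deterministic", {
  m <- annulus_mesh(geom, 12, 2, 1)
  sys <- assemble_system(m, mat$nu)
  bc1 <- boundary_condition(m, valve_size = 2 * (m$inner_radius + 0.4))
  bc2 <- boundary_condition(m, valve_size = 2 * (m$inner_radius + 0.8))
  f1 <- solve_stress(m, mat, bc1, sys)
  f2 <- solve_stress(m, mat, bc2, sys)
  expect_equal(2 * f1$stress, f2$stress, tolerance = 1e-12)
  f1b <- solve_stress(m, mat, bc1, sys)
  expect_identical(f1$stress, f1b$stress)        # bitwise determinism
  expect_identical(f1$von_mises, f1b$von_mises)
  expect_lt(f1$residual, 1e-8)
  expect_true(all(f1$von_mises >= 0))
})

test_that("stress scales linearly with the Young modulus", {
  m <- annulus_mesh(geom, 12, 2, 1)
  bc <- boundary_condition(m, valve_size = 2 * (m$inner_radius + 0.5))
  fa <- solve_stress(m, material_params(2, 0.45), bc)
  fb <- solve_stress(m, material_params(8, 0.45), bc)
  expect_equal(4 * fa$von_mises, fb$von_mises, tolerance = 1e-12)
  expect_equal(fa$displacement, fb$displacement, tolerance = 1e-12)
})

test_that("conduction-zone feature count matches a brute-force predicate", {
  m <- annulus_mesh(geom, 24, 6, 2)
  bc <- boundary_condition(m, valve_size = 26)
  f <- solve_stress(m, mat, bc)
  s <- conduction_zone_features(f, m, sector_deg = 90, band_mm = 4)
  phi <- m$node_phi
  phi_s <- ifelse(phi > 180, phi - 360, phi)
  brute <- sum(abs(m$node_r - m$inner_radius) < 1e-12 &
                 abs(phi_s) < 45 - 1e-9 & m$node_z <= 4 + 1e-9)
  expect_identical(attr(s, "n"), brute)
  expect_identical(length(s), brute)
  # zero field maps to a zero vector of the same fixed length
  bc0 <- boundary_condition(m, valve_size = 2 * m$inner_radius)
  s0 <- conduction_zone_features(solve_stress(m, mat, bc0), m)
  expect_identical(length(s0), brute)
  expect_equal(max(abs(s0)), 0)
  expect_error(conduction_zone_features(f, m, band_mm = -1), "empty")
})

test_that("enlarging the vacancy angle never raises mean conduction-zone stress", {
  m <- annulus_mesh(geom, 24, 6, 2)
  sys <- assemble_system(m, mat$nu)
  prof <- rep(0, 24); prof[c(1, 24)] <- 3  # calcium inside the zone
  means <- vapply(c(0, 15, 30, 60), function(th) {
    bc <- boundary_condition(m, valve_size = 26, theta = th,
                             d_profile = prof)
    mean(conduction_zone_features(solve_stress(m, mat, bc, sys), m))
  }, numeric(1))
  expect_true(all(diff(means) <= 1e-9))
  expect_lt(means[4], means[1])  # strict drop with deposits in the sector
})

test_that("an unconstrained system raises a rigid-mode error", {
  m <- annulus_mesh(geom, 8, 1, 1)
  sys <- assemble_system(m, mat$nu)
  con <- list(dofs = integer(0),
              vals = matrix(numeric(0), 0, 1))
  suppressWarnings(
    expect_error(tavrisk:::fem_solve(m, sys, con),
                 "rigid|singular|constraints|residual"))
})
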