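geom <- ref_geom()  # inner radius 12 mm

test_that("radial displacement lands the slab outer face on the wall", {
  dep <- calcium_deposit(8, 30, 5, thickness = 2, length = 6, volume = 50,
                         cusp = "NCC")
  rem <- displace_deposit(dep, geom)
  expect_equal(rem$deposit$r, 11)      # 12 - 2/2, the worked construction
  expect_equal(rem$deposit$phi, 30)
  expect_equal(rem$deposit$z, 5)
  expect_equal(rem$deposit$volume, dep$volume)
  expect_equal(rem$deposit$length, dep$length)
  expect_true(rem$contacts_wall)
  # brute-force check along the radial line: the displaced position is the
  # largest centre radius whose outer face does not cross the wall
  rr <- seq(0, geom$inner_radius, by = 1e-4)
  feasible <- rr + dep$thickness / 2 <= geom$inner_radius
  expect_equal(rem$deposit$r, max(rr[feasible]), tolerance = 1e-3)
})

test_that("a deposit already touching the wall is unchanged", {
  dep <- calcium_deposit(11, 120, 3, thickness = 2, length = 6, volume = 50,
                         cusp = "RCC")
  rem <- displace_deposit(dep, geom)
  expect_equal(rem$deposit$r, dep$r)
  expect_equal(rem$rotation_angle, 0)
})

test_that("displacement rejects geometrically infeasible deposits", {
  fat <- calcium_deposit(5, 0, 5, thickness = 13, length = 6, volume = 50,
                         cusp = "NCC")
  expect_error(displace_deposit(fat, geom), "infeasibility")
  outside <- calcium_deposit(12.5, 0, 5, thickness = 2, length = 6,
                             volume = 50, cusp = "NCC")
  expect_error(displace_deposit(outside, geom), "outside")
})

irregular <- function(r, phi, z, len = 8, psi = 20, dz = 1,
                      thickness = 3, volume = 80) {
  ctr <- c(r * cospi(phi / 180), r * sinpi(phi / 180), z)
  dir <- c(cospi(psi / 180), sinpi(psi / 180), 0)
  h <- c(dir[1:2] * sqrt(len^2 / 4 - dz^2 / 4), dz / 2)
  to_cyl <- function(p) c(sqrt(p[1]^2 + p[2]^2),
                          (atan2(p[2], p[1]) * 180 / pi) %% 360, p[3])
  calcium_deposit(r, phi, z, thickness, len, volume, cusp = "NCC",
                  shape = "irregular",
                  endpoints = rbind(to_cyl(ctr + h), to_cyl(ctr - h)))
}

test_that("rotation places both endpoints of an irregular deposit on the wall", {
  dep <- irregular(8, 10, 5)
  rem <- rotate_irregular_deposit(dep, geom)
  ep <- rem$deposit$endpoints
  expect_equal(unname(ep[, 1]), rep(geom$inner_radius, 2), tolerance = 1e-9)
  expect_true(rem$contacts_wall)
  expect_equal(rem$deposit$volume, dep$volume)
  expect_equal(rem$deposit$length, dep$length)
})

test_that("rotation matches a brute-force grid search over angle and slide", {
  dep <- irregular(8, 10, 5, len = 6, psi = 55)
  rem <- rotate_irregular_deposit(dep, geom)
  # independent oracle: rotate the chord about its midpoint on a fine grid,
  # slide along the midpoint radial line to the best contact, minimise the
  # worst endpoint-to-wall distance
  ep <- cbind(dep$endpoints[, 1] * cospi(dep$endpoints[, 2] / 180),
              dep$endpoints[, 1] * sinpi(dep$endpoints[, 2] / 180))
  m <- colMeans(ep)
  u <- m / sqrt(sum(m^2))
  resid_at <- function(alpha_deg) {
    aa <- alpha_deg * pi / 180
    R <- matrix(c(cos(aa), sin(aa), -sin(aa), cos(aa)), 2, 2)
    ep2 <- t(R %*% (t(ep) - m) + m)
    f <- function(t) {
      e <- sweep(ep2, 2, -t * u)
      max(abs(sqrt(rowSums(e^2)) - geom$inner_radius))
    }
    stats::optimize(f, c(-25, 25), tol = 1e-10)$objective
  }
  grid <- seq(-90, 90, by = 0.05)
  vals <- vapply(grid, resid_at, numeric(1))
  best <- grid[which.min(vals)]
  expect_lt(abs(rem$rotation_angle - best), 0.1)
  expect_lt(min(vals), 1e-6)
})

test_that("mirror-image deposits rotate by opposite angles", {
  dep <- irregular(8, 40, 5, psi = 70)
  mir <- dep
  mir$phi <- (-dep$phi) %% 360
  mir$endpoints <- dep$endpoints
  mir$endpoints[, 2] <- (-dep$endpoints[, 2]) %% 360
  a1 <- rotate_irregular_deposit(dep, geom)$rotation_angle
  a2 <- rotate_irregular_deposit(mir, geom)$rotation_angle
  expect_equal(a1, -a2, tolerance = 1e-9)
})

test_that("endpoints already on the wall give zero rotation (idempotence)", {
  dep <- irregular(8, 10, 5)
  once <- rotate_irregular_deposit(dep, geom)
  twice <- rotate_irregular_deposit(once$deposit, geom)
  expect_equal(twice$rotation_angle, 0, tolerance = 1e-9)
  expect_equal(twice$deposit$endpoints, once$deposit$endpoints,
               tolerance = 1e-9)
})

test_that("chords longer than the lumen are rejected", {
  dep <- irregular(8, 10, 5, len = 30)
  expect_error(rotate_irregular_deposit(dep, geom), "chord")
  reg <- calcium_deposit(8, 0, 5, 2, 6, 50, cusp = "NCC")
  expect_error(rotate_irregular_deposit(reg, geom), "irregular")
})

test_that("table-level remodelling conserves mass and is idempotent", {
  coh <- make_planted_cohort()
  dep <- rbind(coh$deposits,
               within(coh$deposits[1, ], {
                 deposit_id <- 2L
                 shape <- "irregular"
                 end1_r <- 9.5; end1_phi <- 170; end1_z <- 5
                 end2_r <- 8.5; end2_phi <- 195; end2_z <- 6
               }))
  rem1 <- remodel_deposits(dep, geom)
  expect_equal(rem1$volume, dep$volume)
  expect_equal(rem1$thickness, dep$thickness)
  expect_true(all(rem1$contacts_wall))
  rem2 <- remodel_deposits(rem1, geom)
  for (col in c("r", "phi", "z", "end1_r", "end1_phi", "end2_r",
                "end2_phi")) {
    expect_equal(rem2[[col]], rem1[[col]], tolerance = 1e-9)
  }
  # an already-remodelled table needs no further rotation
  expect_equal(rem2$rotation_angle, rep(0, nrow(rem2)), tolerance = 1e-9)
  # regular deposits: outer face within 1e-6 of the wall
  reg <- rem1$shape == "regular"
  expect_equal(rem1$r[reg] + rem1$thickness[reg] / 2,
               rep(geom$inner_radius, sum(reg)), tolerance = 1e-6)
})

test_that("thickness profile takes the per-sector maximum", {
  expect_equal(local_thickness_profile(empty_deposits(), geom, 12),
               rep(0, 12))
  one <- data.frame(patient_id = 1L, deposit_id = 1L, r = 11, phi = 15,
                    z = 5, thickness = 3.2, length = 3, volume = 40,
                    cusp = "NCC", shape = "regular",
                    end1_r = NA_real_, end1_phi = NA_real_,
                    end1_z = NA_real_, end2_r = NA_real_,
                    end2_phi = NA_real_, end2_z = NA_real_)
  prof <- local_thickness_profile(one, geom, 12)  # 30 deg sectors
  expect_equal(prof[1], 3.2)                      # canonical mean thickness
  expect_equal(sum(prof > 0), 1)
  two <- rbind(one, within(one, { deposit_id <- 2L; thickness <- 4 }))
  two$thickness[1] <- 2
  prof2 <- local_thickness_profile(two, geom, 12)
  expect_equal(prof2[1], 4)                       # max, not sum
  expect_error(local_thickness_profile(one, geom, 3), "n_sectors")
})
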