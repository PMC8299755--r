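#' Calcium deposit
#'
#' A single calcific deposit of the native valve, located in cylindrical
#' coordinates (radius mm, angle degrees in [0, 360), height mm). Regular
#' deposits are modelled as slabs carrying the measured equivalent
#' thickness `d`; irregular deposits additionally carry two endpoints
#' (rows of a 2 x 3 matrix in (r, phi, z)) and are rotated until both
#' endpoints contact the aortic wall during virtual deployment.
#'
#' @param r,phi,z centre position (mm, degrees, mm).
#' @param thickness deposit thickness d, mm; must be positive.
#' @param length deposit length (circumferential extent for slabs, chord
#'   length scale for rods), mm.
#' @param volume deposit volume, mm3; positive.
#' @param cusp one of `"NCC"`, `"RCC"`, `"LCC"`.
#' @param shape `"regular"` or `"irregular"`.
#' @param endpoints 2 x 3 matrix of (r, phi, z); required iff irregular.
#' @return A list of class `"calcium_deposit"`.
#' @export
calcium_deposit <- function(r, phi, z, thickness, length, volume,
                            cusp = c("NCC", "RCC", "LCC"),
                            shape = c("regular", "irregular"),
                            endpoints = NULL) {
  cusp <- match.arg(cusp)
  shape <- match.arg(shape)
  if (!is.finite(thickness) || thickness <= 0) {
    stop("thickness must be positive", call. = FALSE)
  }
  if (!is.finite(volume) || volume <= 0) {
    stop("volume must be positive", call. = FALSE)
  }
  if (shape == "irregular") {
    if (is.null(endpoints) || !is.matrix(endpoints) ||
        !all(dim(endpoints) == c(2, 3))) {
      stop("irregular deposits require a 2 x 3 endpoints matrix (r, phi, z)",
           call. = FALSE)
    }
  } else if (!is.null(endpoints)) {
    stop("regular deposits must not carry endpoints", call. = FALSE)
  }
  structure(list(r = r, phi = phi %% 360, z = z, thickness = thickness,
                 length = length, volume = volume, cusp = cusp,
                 shape = shape, endpoints = endpoints),
            class = "calcium_deposit")
}

#' Radial displacement of a deposit onto the aortic wall
#'
#' Virtual stent expansion shifts each deposit along the radial line
#' through its centre until it contacts the wall: modelling the deposit as
#' a slab of thickness `d`, the displaced centre sits at
#' `inner_radius - d/2` so the outer face touches the wall. Angle, height,
#' volume, length and thickness are unchanged; endpoints of irregular
#' deposits are translated rigidly with the centre.
#'
#' @param dep a [calcium_deposit()].
#' @param geom a [root_geometry()].
#' @return A list of class `"remodeled_deposit"` with elements `original`,
#'   `deposit` (the displaced [calcium_deposit()]), `rotation_angle`
#'   (degrees; 0 here) and `contacts_wall`.
#' @export
displace_deposit <- function(dep, geom) {
  stopifnot(inherits(dep, "calcium_deposit"), inherits(geom, "root_geometry"))
  a <- geom$inner_radius
  if (dep$thickness > a) {
    stop(sprintf("geometric infeasibility: deposit thickness %.2f mm exceeds lumen radius %.2f mm",
                 dep$thickness, a), call. = FALSE)
  }
  if (dep$r > a + 1e-9) {
    stop("deposit centre lies outside the aortic wall", call. = FALSE)
  }
  r_new <- a - dep$thickness / 2
  out <- dep
  if (dep$shape == "irregular") {
    shift <- (r_new - dep$r) * c(cos(dep$phi * pi / 180),
                                 sin(dep$phi * pi / 180), 0)
    ep <- cyl_to_cart(dep$endpoints[, 1], dep$endpoints[, 2],
                      dep$endpoints[, 3])
    ep <- sweep(ep, 2, -shift)
    out$endpoints <- unname(cart_to_cyl(ep))
  }
  out$r <- r_new
  structure(list(original = dep, deposit = out, rotation_angle = 0,
                 contacts_wall = TRUE),
            class = "remodeled_deposit")
}

#' Rotation of an irregular deposit until both endpoints contact the wall
#'
#' An irregular deposit is idealised as a rigid rod between its two
#' endpoints. After stent expansion the rod realigns to the wall so that
#' both endpoints touch the inner surface, i.e. the rod's planar projection
#' becomes a chord of the lumen circle. The remodelling is the rigid motion
#' composed of a rotation about the vertical axis through the endpoint
#' midpoint (smallest-magnitude angle that turns the chord perpendicular to
#' its radial line) and a slide along that radial line placing the midpoint
#' at distance `sqrt(a^2 - l^2)` from the axis (`a` inner radius, `l` the
#' half-chord). Both endpoints then lie on the wall exactly; the solution
#' is closed-form, deterministic, and the identity when the endpoints
#' already rest on the wall. A pure rotation about a centroid held at
#' `a - d/2` cannot satisfy the both-ends-contact condition except at one
#' special chord length, hence the combined rotation + radial slide.
#'
#' @param dep an irregular [calcium_deposit()], or a `"remodeled_deposit"`
#'   produced by [displace_deposit()].
#' @param geom a [root_geometry()].
#' @return A `"remodeled_deposit"` whose `rotation_angle` is the applied
#'   rotation in degrees.
#' @export
rotate_irregular_deposit <- function(dep, geom) {
  if (inherits(dep, "remodeled_deposit")) dep <- dep$deposit
  stopifnot(inherits(dep, "calcium_deposit"), inherits(geom, "root_geometry"))
  if (dep$shape != "irregular") {
    stop("rotation applies to irregular deposits only", call. = FALSE)
  }
  a <- geom$inner_radius
  ep <- cyl_to_cart(dep$endpoints[, 1], dep$endpoints[, 2], dep$endpoints[, 3])
  m <- colMeans(ep)
  h <- (ep[1, ] - ep[2, ]) / 2
  l <- sqrt(sum(h[1:2]^2))  # planar half-chord
  if (l > a + 1e-9) {
    stop(sprintf("geometric infeasibility: endpoint chord %.2f mm exceeds wall diameter %.2f mm",
                 2 * l, 2 * a), call. = FALSE)
  }
  l <- min(l, a)
  # radial line through the current midpoint (fall back to the centre angle
  # for a midpoint on the axis)
  phi_u <- if (sum(m[1:2]^2) > 1e-24) {
    atan2(m[2], m[1]) * 180 / pi
  } else {
    dep$phi
  }
  # rotate the chord perpendicular to the radial direction
  beta <- atan2(h[2], h[1]) * 180 / pi
  cand <- c(ang_diff(phi_u + 90, beta), ang_diff(phi_u - 90, beta))
  alpha <- unname(cand[order(abs(cand), -cand)[1]])  # smallest magnitude, tie -> positive
  s <- sqrt(a^2 - l^2)
  m_new <- c(s * cos(phi_u * pi / 180), s * sin(phi_u * pi / 180), m[3])

  rot <- alpha * pi / 180
  Rz <- matrix(c(cos(rot), sin(rot), 0, -sin(rot), cos(rot), 0, 0, 0, 1), 3, 3)
  move <- function(p) as.numeric(Rz %*% (p - m) + m_new)
  ep_new <- t(apply(ep, 1, move))
  ctr_new <- move(as.numeric(cyl_to_cart(dep$r, dep$phi, dep$z)))

  out <- dep
  cyl <- cart_to_cyl(ep_new)
  out$endpoints <- unname(cyl)
  ctr <- cart_to_cyl(ctr_new)
  out$r <- ctr[1, "r"]; out$phi <- ctr[1, "phi"]; out$z <- ctr[1, "z"]
  resid <- max(abs(sqrt(ep_new[, 1]^2 + ep_new[, 2]^2) - a))
  structure(list(original = dep, deposit = out, rotation_angle = alpha,
                 contacts_wall = resid < 1e-6),
            class = "remodeled_deposit")
}

#' Remodel a table of deposits
#'
#' Applies [displace_deposit()] to every deposit and additionally
#' [rotate_irregular_deposit()] to the irregular ones, returning the
#' deposits table with updated positions plus `rotation_angle` and
#' `contacts_wall` columns. Volume, length and thickness are conserved
#' exactly, and remodelling an already remodelled table is the identity.
#'
#' @param deposits a deposits data frame (see [simulate_cohort()] for the
#'   column layout) for a single patient.
#' @param geom the patient's [root_geometry()].
#' @return The remodelled deposits data frame.
#' @export
remodel_deposits <- function(deposits, geom) {
  stopifnot(is.data.frame(deposits))
  if (nrow(deposits) == 0) {
    deposits$rotation_angle <- numeric(0)
    deposits$contacts_wall <- logical(0)
    return(deposits)
  }
  out <- deposits
  out$rotation_angle <- 0
  out$contacts_wall <- FALSE
  for (i in seq_len(nrow(deposits))) {
    dep <- deposit_from_row(deposits[i, ])
    rem <- if (dep$shape == "irregular") {
      # the rotation + radial slide fully determines the final pose, so the
      # preliminary radial displacement is subsumed (and idempotence exact)
      rotate_irregular_deposit(dep, geom)
    } else {
      displace_deposit(dep, geom)
    }
    d2 <- rem$deposit
    out$r[i] <- d2$r; out$phi[i] <- d2$phi; out$z[i] <- d2$z
    if (d2$shape == "irregular") {
      out$end1_r[i] <- d2$endpoints[1, 1]
      out$end1_phi[i] <- d2$endpoints[1, 2]
      out$end1_z[i] <- d2$endpoints[1, 3]
      out$end2_r[i] <- d2$endpoints[2, 1]
      out$end2_phi[i] <- d2$endpoints[2, 2]
      out$end2_z[i] <- d2$endpoints[2, 3]
    }
    out$rotation_angle[i] <- rem$rotation_angle
    out$contacts_wall[i] <- rem$contacts_wall
  }
  out
}

# Build a calcium_deposit from one row of a deposits data frame.
deposit_from_row <- function(row) {
  ep <- NULL
  if (row$shape == "irregular") {
    ep <- rbind(c(row$end1_r, row$end1_phi, row$end1_z),
                c(row$end2_r, row$end2_phi, row$end2_z))
  }
  calcium_deposit(row$r, row$phi, row$z, row$thickness, row$length,
                  row$volume, row$cusp, row$shape, ep)
}

#' Angular thickness profile of remodelled calcium
#'
#' Discretises the circumference into `n_sectors` equal sectors and
#' records, per sector, the maximum thickness of any deposit overlapping
#' it (zero where no deposit lies). The maximum — rather than the sum — is
#' used because stacked deposits pressed by a rigid stent cannot protrude
#' further than their thickest member. The profile drives the non-uniform
#' displacement boundary condition of the annulus model.
#'
#' Regular deposits span `length / r` radians about their centre angle;
#' irregular deposits span the shorter arc between their endpoint angles.
#'
#' @param deposits a (remodelled) deposits data frame.
#' @param geom a [root_geometry()].
#' @param n_sectors number of angular sectors; at least 4.
#' @return Numeric vector of length `n_sectors` (mm); sector `k` covers
#'   angles `[(k-1), k) * 360 / n_sectors`.
#' @export
local_thickness_profile <- function(deposits, geom, n_sectors) {
  n_sectors <- as.integer(n_sectors)
  if (is.na(n_sectors) || n_sectors < 4) {
    stop("n_sectors must be at least 4", call. = FALSE)
  }
  w <- 360 / n_sectors
  prof <- numeric(n_sectors)
  if (is.null(deposits) || nrow(deposits) == 0) return(prof)
  for (i in seq_len(nrow(deposits))) {
    row <- deposits[i, ]
    if (row$shape == "irregular" && is.finite(row$end1_phi)) {
      d12 <- ang_diff(row$end2_phi, row$end1_phi)
      start <- if (d12 >= 0) row$end1_phi else row$end2_phi
      len <- abs(d12)
    } else {
      half <- (row$length / 2) / row$r * 180 / pi
      start <- row$phi - half
      len <- 2 * half
    }
    len <- min(len, 360)
    start <- start %% 360
    # sectors overlapping the circular arc [start, start + len)
    sec_start <- (seq_len(n_sectors) - 1) * w
    ov <- ((sec_start - start) %% 360) < len |
      ((start - sec_start) %% 360) < w
    prof[ov] <- pmax(prof[ov], row$thickness)
  }
  prof
}
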