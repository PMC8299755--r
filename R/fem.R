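#' Structured hexahedral annulus mesh
#'
#' Builds a circumferentially periodic structured mesh of the annulus wall:
#' a cylindrical shell of inner radius `c_annu/(2*pi)`, thickness
#' `wall_thickness` and height `annulus_height`, discretised into
#' `n_circ * n_axial * n_radial` eight-node hexahedra. The default
#' resolution (92 x 17 x 5) yields the reference element count of 7,820.
#'
#' Node ordering is deterministic — angle-major, then axial, then radial —
#' so stress feature vectors align across patients at a fixed resolution.
#' Inner-surface nodes are the boundary nodes (displaced by the stent);
#' all others are free. Each inner node carries its tributary wall area.
#'
#' @param geom a [root_geometry()].
#' @param n_circ,n_axial,n_radial resolution (circumferential >= 4,
#'   axial >= 1, radial >= 1).
#' @return A list of class `"annulus_mesh"`; key fields: `coords` (n x 3,
#'   mm), `elems` (m x 8 node ids), `inner_ids`, `area` (tributary areas of
#'   inner nodes, mm2), `node_phi` (deg), `node_z`, `node_ring`.
#' @examples
#' g <- root_geometry(2 * pi * 12, 2.5, 10)
#' m <- annulus_mesh(g, 8, 2, 1)
#' nrow(m$elems)  # 16
#' @export
annulus_mesh <- function(geom, n_circ = 92L, n_axial = 17L, n_radial = 5L) {
  stopifnot(inherits(geom, "root_geometry"))
  n_circ <- as.integer(n_circ); n_axial <- as.integer(n_axial)
  n_radial <- as.integer(n_radial)
  if (n_circ < 4 || n_axial < 1 || n_radial < 1) {
    stop("resolution must satisfy n_circ >= 4, n_axial >= 1, n_radial >= 1",
         call. = FALSE)
  }
  if (geom$wall_thickness <= 0) stop("degenerate geometry", call. = FALSE)
  a <- geom$inner_radius
  b <- a + geom$wall_thickness
  h <- geom$annulus_height

  phi <- (seq_len(n_circ) - 1) * 2 * pi / n_circ
  zs <- seq(0, h, length.out = n_axial + 1)
  rs <- seq(a, b, length.out = n_radial + 1)

  nlay <- n_circ * (n_axial + 1)
  node_phi <- rep(phi, times = (n_axial + 1) * (n_radial + 1))
  node_z <- rep(rep(zs, each = n_circ), times = n_radial + 1)
  node_r <- rep(rs, each = nlay)
  node_ring <- rep(rep(seq_len(n_axial + 1), each = n_circ),
                   times = n_radial + 1)
  coords <- cbind(x = node_r * cos(node_phi), y = node_r * sin(node_phi),
                  z = node_z)

  nid <- function(i, j, k) (k - 1L) * nlay + (j - 1L) * n_circ + i
  ic <- rep(seq_len(n_circ), times = n_axial * n_radial)
  iz <- rep(rep(seq_len(n_axial), each = n_circ), times = n_radial)
  ir <- rep(seq_len(n_radial), each = n_circ * n_axial)
  ic2 <- ic %% n_circ + 1L
  elems <- cbind(nid(ic, iz, ir),      nid(ic, iz, ir + 1L),
                 nid(ic2, iz, ir + 1L), nid(ic2, iz, ir),
                 nid(ic, iz + 1L, ir), nid(ic, iz + 1L, ir + 1L),
                 nid(ic2, iz + 1L, ir + 1L), nid(ic2, iz + 1L, ir))
  storage.mode(elems) <- "integer"
  group <- (ir - 1L) * n_circ + ic

  inner_ids <- seq_len(nlay)
  dz <- h / n_axial
  darc <- a * 2 * pi / n_circ
  ring_w <- ifelse(node_ring[inner_ids] %in% c(1L, n_axial + 1L), 0.5, 1)
  area <- darc * dz * ring_w

  mesh <- structure(list(
    coords = coords, elems = elems, group = group,
    n_circ = n_circ, n_axial = n_axial, n_radial = n_radial,
    inner_radius = a, outer_radius = b, height = h,
    node_phi = node_phi * 180 / pi, node_z = node_z, node_r = node_r,
    node_ring = node_ring, inner_ids = inner_ids, area = area,
    geom = geom
  ), class = "annulus_mesh")

  bad <- check_jacobians(mesh)
  if (length(bad)) {
    stop("mesh has non-positive Jacobians in element group(s) ",
         paste(utils::head(bad, 5), collapse = ", "), call. = FALSE)
  }
  mesh
}

#' @export
print.annulus_mesh <- function(x, ...) {
  cat(sprintf(
    "annulus mesh: %d hex8 elements (%d x %d x %d), %d nodes, r = [%.2f, %.2f] mm, h = %.1f mm\n",
    nrow(x$elems), x$n_circ, x$n_axial, x$n_radial, nrow(x$coords),
    x$inner_radius, x$outer_radius, x$height))
  invisible(x)
}

# --- hex8 element machinery -------------------------------------------------

hex8_signs <- rbind(
  c(-1, -1, -1), c(1, -1, -1), c(1, 1, -1), c(-1, 1, -1),
  c(-1, -1, 1),  c(1, -1, 1),  c(1, 1, 1),  c(-1, 1, 1))

# derivative of shape functions wrt local coords at a local point, 3 x 8
hex8_dN <- function(xi, eta, ze) {
  s <- hex8_signs
  rbind(s[, 1] * (1 + eta * s[, 2]) * (1 + ze * s[, 3]),
        s[, 2] * (1 + xi * s[, 1]) * (1 + ze * s[, 3]),
        s[, 3] * (1 + xi * s[, 1]) * (1 + eta * s[, 2])) / 8
}

hex8_gauss <- function() {
  g <- 1 / sqrt(3)
  pts <- as.matrix(expand.grid(xi = c(-g, g), eta = c(-g, g), ze = c(-g, g)))
  lapply(seq_len(8), function(i) hex8_dN(pts[i, 1], pts[i, 2], pts[i, 3]))
}

# isotropic elasticity matrix, Voigt order (xx, yy, zz, xy, yz, zx),
# engineering shear strains
elasticity_matrix <- function(E, nu) {
  lam <- E * nu / ((1 + nu) * (1 - 2 * nu))
  mu <- E / (2 * (1 + nu))
  D <- matrix(0, 6, 6)
  D[1:3, 1:3] <- lam
  diag(D)[1:3] <- lam + 2 * mu
  diag(D)[4:6] <- mu
  D
}

# element stiffness (24 x 24) and mean stress operator (6 x 24) for unit E
hex8_element <- function(coords8, nu, dN_list) {
  D <- elasticity_matrix(1, nu)
  Ke <- matrix(0, 24, 24)
  Mm <- matrix(0, 6, 24)
  for (dN in dN_list) {
    J <- dN %*% coords8
    detJ <- det(J)
    if (!is.finite(detJ) || detJ <= 0) return(NULL)
    g <- solve(J, dN)  # 3 x 8, derivatives wrt x,y,z
    B <- matrix(0, 6, 24)
    ix <- seq(1, 24, by = 3)
    B[1, ix] <- g[1, ]; B[2, ix + 1] <- g[2, ]; B[3, ix + 2] <- g[3, ]
    B[4, ix] <- g[2, ]; B[4, ix + 1] <- g[1, ]
    B[5, ix + 1] <- g[3, ]; B[5, ix + 2] <- g[2, ]
    B[6, ix] <- g[3, ]; B[6, ix + 2] <- g[1, ]
    DB <- D %*% B
    Ke <- Ke + crossprod(B, DB) * detJ
    Mm <- Mm + DB / 8
  }
  list(Ke = Ke, M = Mm)
}

check_jacobians <- function(mesh) {
  dN0 <- list(hex8_dN(0, 0, 0))
  bad <- integer(0)
  for (g in unique(mesh$group)) {
    e <- which(mesh$group == g)[1]
    coords8 <- mesh$coords[mesh$elems[e, ], ]
    J <- dN0[[1]] %*% coords8
    if (det(J) <= 0) bad <- c(bad, g)
  }
  bad
}

#' Assemble the elasticity system for an annulus mesh
#'
#' Assembles the global stiffness matrix for unit Young's modulus (the
#' displacement solution of a displacement-driven problem is independent of
#' `E`, and stresses scale linearly with it) at the given Poisson ratio,
#' along with the per-element-group mean stress recovery operators.
#' Structured periodicity is exploited: element stiffness is computed once
#' per distinct (circumferential, radial) element geometry and reused
#' across axial layers.
#'
#' @param mesh an [annulus_mesh()].
#' @param nu Poisson's ratio.
#' @return A list of class `"fem_system"` with the sparse stiffness `K`
#'   (unit modulus), stress operators `M` per element group, and `nu`.
#' @export
assemble_system <- function(mesh, nu) {
  stopifnot(inherits(mesh, "annulus_mesh"))
  if (nu <= 0 || nu >= 0.5) stop("nu must lie in (0, 0.5)", call. = FALSE)
  dN_list <- hex8_gauss()
  groups <- sort(unique(mesh$group))
  KeF <- matrix(0, 576, length(groups))
  Ms <- vector("list", length(groups))
  first_of_group <- match(groups, mesh$group)
  for (gi in seq_along(groups)) {
    coords8 <- mesh$coords[mesh$elems[first_of_group[gi], ], ]
    el <- hex8_element(coords8, nu, dN_list)
    if (is.null(el)) {
      stop("non-positive Jacobian in element group ", groups[gi],
           call. = FALSE)
    }
    KeF[, gi] <- as.numeric(el$Ke)
    Ms[[gi]] <- el$M
  }
  xx <- as.numeric(t(KeF[, mesh$group]))
  pat <- assembly_pattern(mesh)
  x_u <- as.numeric(rowsum(xx[pat$ord], pat$slot, reorder = FALSE))
  K <- Matrix::sparseMatrix(i = pat$i_u, j = pat$j_u, x = x_u,
                            dims = rep(3L * nrow(mesh$coords), 2))
  structure(list(K = K, M = Ms, groups = groups, nu = nu),
            class = "fem_system")
}

# Triplet-deduplication pattern for a mesh topology; cached per resolution
# (all patients share one connectivity, only coordinates differ).
.fem_cache <- new.env(parent = emptyenv())

assembly_pattern <- function(mesh) {
  key <- paste(mesh$n_circ, mesh$n_axial, mesh$n_radial, sep = "x")
  pat <- .fem_cache[[key]]
  if (!is.null(pat)) return(pat)
  edof <- element_dofs(mesh)
  p <- seq_len(576) - 1L
  ii <- as.integer(edof[, p %% 24L + 1L])
  jj <- as.integer(edof[, p %/% 24L + 1L])
  ord <- order(jj, ii, method = "radix")
  i_s <- ii[ord]; j_s <- jj[ord]
  first <- c(TRUE, diff(i_s) != 0L | diff(j_s) != 0L)
  pat <- list(ord = ord, slot = cumsum(first),
              i_u = i_s[first], j_u = j_s[first])
  .fem_cache[[key]] <- pat
  pat
}

element_dofs <- function(mesh) {
  e <- mesh$elems
  out <- matrix(0L, nrow(e), 24)
  for (n in 1:8) {
    out[, 3 * n - 2] <- 3L * e[, n] - 2L
    out[, 3 * n - 1] <- 3L * e[, n] - 1L
    out[, 3 * n] <- 3L * e[, n]
  }
  out
}

#' Displacement boundary condition from a valve design
#'
#' Prescribes a radial displacement on every inner-surface node outside the
#' vacant cylindrical sector: `u(phi) = max(0, valve_size/2 - a) + d(phi)`,
#' where `a` is the annulus inner radius (stent oversize) and `d(phi)` the
#' remodelled calcium thickness profile. Nodes inside the vacant sector
#' `(-theta/2, theta/2)` about the NCC-RCC commissure carry no prescription
#' (the cut-out frame does not push there). The two axial end rings are
#' additionally held axially (`u_z = 0`) to remove rigid modes, which
#' realises a plane-strain-like support consistent with the thick-walled
#' cylinder verification solution.
#'
#' @param mesh an [annulus_mesh()].
#' @param valve_size nominal prosthesis size (diameter), mm; positive.
#' @param theta vacancy angle, degrees; `0 <= theta < 360`.
#' @param d_profile optional angular thickness profile (mm) as returned by
#'   [local_thickness_profile()]; sector `k` covers
#'   `[(k-1), k) * 360 / length(d_profile)`. `NULL` means no calcium.
#' @return A list of class `"boundary_condition"` with prescribed node ids
#'   and radial magnitudes.
#' @export
boundary_condition <- function(mesh, valve_size, theta = 0,
                               d_profile = NULL) {
  stopifnot(inherits(mesh, "annulus_mesh"))
  if (!is.numeric(theta) || theta < 0 || theta >= 360) {
    stop("theta must satisfy 0 <= theta < 360 degrees", call. = FALSE)
  }
  if (!is.numeric(valve_size) || valve_size <= 0) {
    stop("valve_size must be positive", call. = FALSE)
  }
  oversize <- max(0, valve_size / 2 - mesh$inner_radius)
  phi <- mesh$node_phi[mesh$inner_ids]
  vacant <- abs(ang_diff(phi, 0)) < theta / 2 - 1e-9
  d_node <- rep(0, length(phi))
  if (!is.null(d_profile)) {
    if (any(d_profile < 0)) stop("d_profile must be non-negative", call. = FALSE)
    w <- 360 / length(d_profile)
    d_node <- d_profile[pmin(floor((phi %% 360) / w) + 1, length(d_profile))]
  }
  nodes <- mesh$inner_ids[!vacant]
  u <- (oversize + d_node)[!vacant]
  structure(list(nodes = nodes, u = u, theta = theta,
                 valve_size = valve_size, oversize = oversize,
                 vacant_ids = mesh$inner_ids[vacant]),
            class = "boundary_condition")
}

# Constrained dof indices and values for one or more radial magnitudes.
# u_cols: matrix (length(bc$nodes) x nrhs) of radial magnitudes per column.
fem_constraints <- function(mesh, bc, u_cols = NULL) {
  if (is.null(u_cols)) u_cols <- matrix(bc$u, ncol = 1)
  phi <- mesh$node_phi[bc$nodes] * pi / 180
  n <- nrow(mesh$coords)
  dofs <- c(3 * bc$nodes - 2, 3 * bc$nodes - 1, 3 * bc$nodes)
  vals <- rbind(u_cols * cos(phi), u_cols * sin(phi),
                matrix(0, length(bc$nodes), ncol(u_cols)))
  ends <- which(mesh$node_ring %in% c(1L, mesh$n_axial + 1L))
  zd <- setdiff(3 * ends, dofs)
  dofs <- c(dofs, zd)
  vals <- rbind(vals, matrix(0, length(zd), ncol(u_cols)))
  o <- order(dofs)
  list(dofs = dofs[o], vals = vals[o, , drop = FALSE])
}

# Shared linear solve: returns per-rhs nodal displacement and stress tensors.
# `nodes` restricts stress recovery to elements adjacent to those nodes
# (recovered values are exact there; other rows are partial averages).
fem_solve <- function(mesh, system, con, E = 1, nodes = NULL) {
  ndof <- nrow(system$K)
  free <- setdiff(seq_len(ndof), con$dofs)
  nrhs <- ncol(con$vals)
  U <- matrix(0, ndof, nrhs)
  U[con$dofs, ] <- con$vals
  resid <- 0
  if (length(free)) {
    Kff <- Matrix::forceSymmetric(system$K[free, free])
    Kfc <- system$K[free, con$dofs, drop = FALSE]
    rhs <- -Kfc %*% con$vals
    ch <- tryCatch(Matrix::Cholesky(Kff, LDL = FALSE),
                   error = function(e) NULL)
    if (is.null(ch)) {
      stop("singular stiffness system: insufficient constraints leave rigid modes",
           call. = FALSE)
    }
    uf <- as.matrix(Matrix::solve(ch, rhs))
    U[free, ] <- uf
    num <- sqrt(sum(as.matrix(Kff %*% uf - rhs)^2))
    den <- max(1e-300, sqrt(sum(as.matrix(rhs)^2)))
    resid <- num / max(1, den)
    if (!is.finite(resid) || resid > 1e-8) {
      stop(sprintf("solver did not reach the required residual (%.3g)", resid),
           call. = FALSE)
    }
  }
  # stress recovery: element-mean tensors scattered to nodes by averaging
  nnode <- nrow(mesh$coords)
  edof <- element_dofs(mesh)
  el_keep <- NULL
  if (!is.null(nodes)) {
    node_in <- logical(nnode)
    node_in[nodes] <- TRUE
    hit <- node_in[mesh$elems[, 1]]
    for (cc in 2:8) hit <- hit | node_in[mesh$elems[, cc]]
    el_keep <- which(hit)
  }
  stress <- vector("list", nrhs)
  for (q in seq_len(nrhs)) stress[[q]] <- matrix(0, nnode, 6)
  counts <- if (is.null(el_keep)) {
    tabulate(as.integer(mesh$elems), nbins = nnode)
  } else {
    tabulate(as.integer(mesh$elems[el_keep, , drop = FALSE]), nbins = nnode)
  }
  for (gi in seq_along(system$groups)) {
    es <- which(mesh$group == system$groups[gi])
    if (!is.null(el_keep)) es <- intersect(es, el_keep)
    if (!length(es)) next
    Mg <- system$M[[gi]]
    idx <- t(edof[es, , drop = FALSE])  # 24 x ne
    nodes_g <- as.integer(t(mesh$elems[es, , drop = FALSE]))  # 8*ne
    for (q in seq_len(nrhs)) {
      Ue <- matrix(U[idx, q], nrow = 24)
      Sg <- E * (Mg %*% Ue)  # 6 x ne
      Srep <- Sg[, rep(seq_along(es), each = 8), drop = FALSE]
      for (cmp in 1:6) {
        stress[[q]][, cmp] <- stress[[q]][, cmp] +
          unname(rowsum_vec(Srep[cmp, ], nodes_g, nnode))
      }
    }
  }
  for (q in seq_len(nrhs)) {
    stress[[q]] <- stress[[q]] / pmax(counts, 1)
  }
  list(U = U, stress = stress, residual = resid)
}

rowsum_vec <- function(x, idx, n) {
  out <- numeric(n)
  tb <- rowsum(x, idx)
  out[as.integer(rownames(tb))] <- tb[, 1]
  out
}

von_mises <- function(s) {
  sqrt(pmax(0, 0.5 * ((s[, 1] - s[, 2])^2 + (s[, 2] - s[, 3])^2 +
                        (s[, 3] - s[, 1])^2) +
              3 * (s[, 4]^2 + s[, 5]^2 + s[, 6]^2)))
}

#' Solve the annulus elasticity problem
#'
#' Static small-strain isotropic linear elasticity (Hooke's law) on the
#' hexahedral annulus mesh under the displacement boundary condition of a
#' deployed prosthesis, using 2 x 2 x 2 Gauss quadrature and a sparse
#' Cholesky factorisation. Stress tensors are recovered at quadrature
#' points and averaged to nodes; the von Mises equivalent stress is
#' reported per node.
#'
#' @param mesh an [annulus_mesh()].
#' @param material homogenised [material_params()].
#' @param bc a [boundary_condition()].
#' @param system optional pre-assembled [assemble_system()] (must match
#'   `material$nu`); assembled on the fly when `NULL`.
#' @param nodes optional node ids to which stress recovery is restricted
#'   (values elsewhere are partial averages); `NULL` recovers everywhere.
#' @return A list of class `"stress_field"`: `displacement` (n x 3, mm),
#'   `stress` (n x 6 Voigt, MPa), `von_mises` (n, MPa), `residual`.
#' @export
solve_stress <- function(mesh, material, bc, system = NULL, nodes = NULL) {
  stopifnot(inherits(mesh, "annulus_mesh"),
            inherits(material, "material_params"),
            inherits(bc, "boundary_condition"))
  if (is.null(system)) {
    system <- assemble_system(mesh, material$nu)
  } else if (abs(system$nu - material$nu) > 1e-12) {
    stop("pre-assembled system has a different Poisson ratio", call. = FALSE)
  }
  con <- fem_constraints(mesh, bc)
  sol <- fem_solve(mesh, system, con, E = material$E, nodes = nodes)
  structure(list(
    displacement = matrix(sol$U[, 1], ncol = 3, byrow = TRUE),
    stress = sol$stress[[1]],
    von_mises = von_mises(sol$stress[[1]]),
    residual = sol$residual,
    E = material$E, nu = material$nu
  ), class = "stress_field")
}

#' @export
print.stress_field <- function(x, ...) {
  cat(sprintf(
    "stress field: %d nodes, max |u| = %.3g mm, von Mises = [%.3g, %.3g] MPa, residual %.2g\n",
    nrow(x$stress), max(abs(x$displacement)), min(x$von_mises),
    max(x$von_mises), x$residual))
  invisible(x)
}

#' Conduction-zone stress feature vector
#'
#' Extracts the ordered von Mises stresses at inner-surface nodes lying in
#' the conduction system zone: the interleaflet triangle between NCC and
#' RCC, modelled as the open 90 degree sector about the commissure midpoint
#' combined with an axial band above the annulus plane. The ordering (axial
#' ring, then signed angle) and the length `N` are fixed at a given mesh
#' resolution, so feature vectors align across patients.
#'
#' @param field a [solve_stress()] result.
#' @param mesh the [annulus_mesh()] it was solved on.
#' @param sector_deg angular width of the zone, degrees (default 90).
#' @param band_mm axial extent of the zone above the annulus plane, mm.
#' @return Numeric vector of von Mises stresses (MPa) with attributes
#'   `node_ids` and `n`.
#' @export
conduction_zone_features <- function(field, mesh, sector_deg = 90,
                                     band_mm = 4) {
  stopifnot(inherits(field, "stress_field"), inherits(mesh, "annulus_mesh"))
  ids <- conduction_zone_nodes(mesh, sector_deg, band_mm)
  if (!length(ids)) {
    stop("conduction zone is empty: degenerate sector or band", call. = FALSE)
  }
  out <- field$von_mises[ids]
  attr(out, "node_ids") <- ids
  attr(out, "n") <- length(ids)
  out
}

conduction_zone_nodes <- function(mesh, sector_deg = 90, band_mm = 4) {
  cand <- mesh$inner_ids
  dphi <- ang_diff(mesh$node_phi[cand], 0)
  keep <- abs(dphi) < sector_deg / 2 - 1e-9 &
    mesh$node_z[cand] <= band_mm + 1e-9
  ids <- cand[keep]
  ids[order(mesh$node_ring[ids], dphi[keep])]
}
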