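#' Aortic root geometry
#'
#' Per-patient geometry of the annulus region: circumference (hence inner
#' radius), wall thickness, axial extent of the modelled annulus band, wall
#' stiffness, and the root/leaflet volumes from which the homogenisation
#' fraction `P_root` is derived. All angles in the package are measured in
#' degrees from the NCC-RCC commissure midpoint (0 degrees), counter-
#' clockwise viewed from the aorta.
#'
#' @param c_annu annulus circumference, mm.
#' @param wall_thickness aortic wall thickness, mm.
#' @param annulus_height axial height of the modelled annulus band, mm.
#' @param k_wall wall stiffness K, N/mm.
#' @param root_volume,leaflet_volume tissue volumes, mm3.
#' @return A list of class `"root_geometry"` including the derived
#'   `inner_radius = c_annu / (2*pi)` and `p_root`.
#' @examples
#' g <- root_geometry(2 * pi * 12, 2.5, 10, 10, 4000, 1000)
#' g$inner_radius  # 12
#' g$p_root        # 0.8
#' @export
root_geometry <- function(c_annu, wall_thickness, annulus_height,
                          k_wall = 10, root_volume = 4000,
                          leaflet_volume = 1000) {
  vals <- c(c_annu = c_annu, wall_thickness = wall_thickness,
            annulus_height = annulus_height, k_wall = k_wall,
            root_volume = root_volume, leaflet_volume = leaflet_volume)
  if (any(!is.finite(vals)) || any(vals <= 0)) {
    stop("all geometry fields must be positive and finite", call. = FALSE)
  }
  structure(list(
    c_annu = c_annu,
    inner_radius = c_annu / (2 * pi),
    wall_thickness = wall_thickness,
    annulus_height = annulus_height,
    k_wall = k_wall,
    root_volume = root_volume,
    leaflet_volume = leaflet_volume,
    p_root = root_volume / (root_volume + leaflet_volume),
    commissure_angle_ncc_rcc = 0
  ), class = "root_geometry")
}

#' @export
print.root_geometry <- function(x, ...) {
  cat(sprintf(
    "aortic root: C_annu = %.2f mm (inner radius %.2f mm), wall %.2f mm, height %.1f mm, K = %g N/mm, P_root = %.3f\n",
    x$c_annu, x$inner_radius, x$wall_thickness, x$annulus_height,
    x$k_wall, x$p_root))
  invisible(x)
}

# Geometry helpers shared across modules -------------------------------------

cyl_to_cart <- function(r, phi_deg, z) {
  phi <- phi_deg * pi / 180
  cbind(x = r * cos(phi), y = r * sin(phi), z = z)
}

cart_to_cyl <- function(xyz) {
  xyz <- rbind(xyz)
  r <- sqrt(xyz[, 1]^2 + xyz[, 2]^2)
  phi <- atan2(xyz[, 2], xyz[, 1]) * 180 / pi
  cbind(r = r, phi = phi %% 360, z = xyz[, 3])
}

# signed angular difference a - b wrapped to (-180, 180]
ang_diff <- function(a, b) {
  d <- (a - b) %% 360
  d[d > 180] <- d[d > 180] - 360
  d
}
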