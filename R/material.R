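#' Isotropic material parameters
#'
#' Container for the linear-elastic constants of an aortic tissue component.
#' Poisson's ratio must lie strictly below the incompressible limit 0.5
#' (0.45, the tabulated value for both aortic root and valve, is allowed).
#'
#' @param E Young's modulus, MPa.
#' @param nu Poisson's ratio (dimensionless).
#' @param density mass density, kg/m3.
#' @return A list of class `"material_params"`.
#' @examples
#' material_params(2, 0.45, 2000)  # aortic root
#' material_params(8, 0.45, 1100)  # aortic valve
#' @export
material_params <- function(E, nu, density = NA_real_) {
  if (!is.numeric(E) || length(E) != 1 || !is.finite(E) || E <= 0) {
    stop("Young's modulus E must be a positive number (MPa)", call. = FALSE)
  }
  if (!is.numeric(nu) || length(nu) != 1 || !is.finite(nu) ||
      nu <= 0 || nu >= 0.5) {
    stop("Poisson's ratio nu must satisfy 0 < nu < 0.5", call. = FALSE)
  }
  structure(list(E = E, nu = nu, density = density),
            class = "material_params")
}

#' @export
print.material_params <- function(x, ...) {
  cat(sprintf("material: E = %g MPa, nu = %g, density = %g kg/m3\n",
              x$E, x$nu, x$density))
  invisible(x)
}

#' Volumetric homogenisation of aortic root and valve tissue
#'
#' After deployment the native leaflets are pressed against the aortic root,
#' so the composite tissue is modelled with volume-fraction-weighted
#' constants: `E = E_valve * (1 - P_root) + E_root * P_root`, and likewise
#' for Poisson's ratio and density.
#'
#' @param root,valve [material_params()] for the two components.
#' @param p_root volumetric fraction of aortic root tissue, in `[0, 1]`.
#' @return A `"material_params"` object with the homogenised constants.
#' @examples
#' root <- material_params(2, 0.45, 2000)
#' valve <- material_params(8, 0.45, 1100)
#' homogenize_material(root, valve, 1)$E    # 2, the root endpoint
#' homogenize_material(root, valve, 0.5)$E  # 5, the linear midpoint
#' @export
homogenize_material <- function(root, valve, p_root) {
  stopifnot(inherits(root, "material_params"),
            inherits(valve, "material_params"))
  if (!is.numeric(p_root) || length(p_root) != 1 || !is.finite(p_root) ||
      p_root < 0 || p_root > 1) {
    stop("p_root must lie in [0, 1]", call. = FALSE)
  }
  material_params(
    E = valve$E * (1 - p_root) + root$E * p_root,
    nu = valve$nu * (1 - p_root) + root$nu * p_root,
    density = valve$density * (1 - p_root) + root$density * p_root
  )
}

#' Scalar loading force of the deployed prosthesis
#'
#' The stent is assumed fully unfolded, so the radial interference between
#' prosthesis and annulus is geometric: `F = K * (R - C_annu/(2*pi) + d)`,
#' where `K` is the aortic wall stiffness (N/mm), `R` the prosthetic valve
#' radius, `C_annu` the annulus circumference and `d` the (maximum
#' remodelled) calcium thickness. Nominal valve sizes are diameters, so
#' `R = valve_size / 2`; it is differenced against the annulus *radius*
#' `C_annu/(2*pi)`.
#'
#' A negative force (valve undersizing the annulus) is returned as-is with
#' `undersized = TRUE`.
#'
#' @param k_wall aortic wall stiffness K, N/mm; must be positive.
#' @param valve_size nominal prosthesis size (diameter), mm.
#' @param c_annu annulus circumference, mm; must be positive.
#' @param d calcium thickness entering the force law, mm; non-negative.
#' @return A list of class `"loading_force"` with elements `F` (N), `K`,
#'   `R` (valve radius, mm), `annulus_radius` (mm), `d` and `undersized`.
#' @examples
#' loading_force(10, 26, 2 * pi * 12, 3.2)$F  # 10 * (13 - 12 + 3.2) = 42 N
#' @export
loading_force <- function(k_wall, valve_size, c_annu, d = 0) {
  if (!is.numeric(k_wall) || k_wall <= 0) {
    stop("k_wall must be positive (N/mm)", call. = FALSE)
  }
  if (!is.numeric(c_annu) || c_annu <= 0) {
    stop("c_annu must be positive (mm)", call. = FALSE)
  }
  if (!is.numeric(valve_size) || valve_size <= 0) {
    stop("valve_size must be positive (mm)", call. = FALSE)
  }
  if (!is.numeric(d) || d < 0) stop("d must be non-negative", call. = FALSE)
  R <- valve_size / 2
  r_ann <- c_annu / (2 * pi)
  f <- k_wall * (R - r_ann + d)
  structure(list(F = f, K = k_wall, R = R, annulus_radius = r_ann, d = d,
                 undersized = f < 0),
            class = "loading_force")
}

#' @export
print.loading_force <- function(x, ...) {
  cat(sprintf("loading force F = %.4g N (K = %g N/mm, R = %g mm, annulus radius = %.4g mm, d = %g mm)%s\n",
              x$F, x$K, x$R, x$annulus_radius, x$d,
              if (x$undersized) " [undersized]" else ""))
  invisible(x)
}

#' Invert the loading-force law to a valve size
#'
#' Exact inverse of [loading_force()] before snapping:
#' `R_radius = F/K + C_annu/(2*pi) - d`, nominal size `= 2 * R_radius`,
#' then snapped to the nearest available size (ties towards the smaller
#' size). A continuous size below the smallest available size triggers a
#' warning and is clamped to it.
#'
#' @param f loading force, N.
#' @param k_wall aortic wall stiffness, N/mm; positive.
#' @param c_annu annulus circumference, mm.
#' @param d calcium thickness, mm.
#' @param sizes available nominal sizes, mm.
#' @return A list with `size_continuous` (mm) and `size` (snapped, mm).
#' @examples
#' f <- loading_force(10, 26, 2 * pi * 12, 3.2)$F
#' force_to_size(f, 10, 2 * pi * 12, 3.2)$size_continuous  # 26
#' @export
force_to_size <- function(f, k_wall, c_annu, d = 0,
                          sizes = c(23, 26, 29, 31)) {
  if (!is.numeric(k_wall) || k_wall <= 0) {
    stop("k_wall must be positive (N/mm)", call. = FALSE)
  }
  r_radius <- f / k_wall + c_annu / (2 * pi) - d
  size_cont <- 2 * r_radius
  if (size_cont < min(sizes)) {
    warning(sprintf("continuous size %.2f mm below smallest available size %g mm; clamping",
                    size_cont, min(sizes)))
  }
  dist <- abs(sizes - size_cont)
  snapped <- sizes[order(dist, sizes)[1]]  # tie towards the smaller size
  list(size_continuous = size_cont, size = snapped)
}
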