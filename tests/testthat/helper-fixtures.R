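# Shared fixtures: coarse configurations keep the elasticity solves small in
# unit tests; the acceptance tests use the default resolution where a printed
# value depends on it.

coarse_cfg <- function(...) {
  tavr_config(mesh = list(n_circ = 24L, n_axial = 6L, n_radial = 2L), ...)
}

tiny_cfg <- function(...) {
  tavr_config(mesh = list(n_circ = 12L, n_axial = 3L, n_radial = 1L), ...)
}

ref_geom <- function() root_geometry(2 * pi * 12, 2.5, 10)

cosine <- function(a, b) {
  a <- a - mean(a); b <- b - mean(b)
  sum(a * b) / sqrt(sum(a^2) * sum(b^2))
}

# Plane-strain thick-walled cylinder with prescribed inner radial
# displacement u0 and traction-free outer surface: u(r) = A r + B / r.
lame_hoop <- function(r, a, b, E, nu, u0) {
  lam <- E * nu / ((1 + nu) * (1 - 2 * nu))
  mu <- E / (2 * (1 + nu))
  A <- u0 / (a + (lam + mu) * b^2 / (mu * a))
  B <- (lam + mu) * A * b^2 / mu
  2 * (lam + mu) * A + 2 * mu * B / r^2
}

# Minimal cohort wrapper around a plain feature matrix (for the model /
# evaluation layers, which only need labels + features).
make_matrix_cohort <- function(x, y) {
  n <- nrow(x)
  patients <- data.frame(
    id = seq_len(n), sex = "male", age = 79, bmi = 29.3,
    systolic_bp = 135, diastolic_bp = 75, lvef = 60,
    diabetes = 0L, afib_history = 0L, stroke_history = 0L,
    icb_history = 0L, calcified_volume = 400, c_annu = 2 * pi * 12,
    wall_thickness = 2.5, annulus_height = 10, k_wall = 10,
    root_volume = 4000, leaflet_volume = 1000, applied_valve_size = 26,
    avb_label = as.integer(y))
  structure(list(patients = patients,
                 deposits = empty_deposits()),
            class = "tavr_cohort")
}

empty_deposits <- function() {
  data.frame(patient_id = integer(0), deposit_id = integer(0),
             r = numeric(0), phi = numeric(0), z = numeric(0),
             thickness = numeric(0), length = numeric(0),
             volume = numeric(0), cusp = character(0),
             shape = character(0), end1_r = numeric(0),
             end1_phi = numeric(0), end1_z = numeric(0),
             end2_r = numeric(0), end2_phi = numeric(0),
             end2_z = numeric(0))
}

with_meta <- function(x, n_stress) {
  attr(x, "meta") <- list(stress_cols = seq_len(n_stress),
                          n_stress = n_stress, signature = "test")
  x
}

# A hand-built geometric test cohort: patient 1 carries calcium far from the
# conduction zone, patient 2 a thick deposit centred on it.
make_planted_cohort <- function() {
  base <- make_matrix_cohort(matrix(0, 2, 1), c(0, 1))
  base$deposits <- rbind(
    data.frame(patient_id = 1L, deposit_id = 1L, r = 9, phi = 180, z = 5,
               thickness = 3.2, length = 6, volume = 400, cusp = "LCC",
               shape = "regular", end1_r = NA_real_, end1_phi = NA_real_,
               end1_z = NA_real_, end2_r = NA_real_, end2_phi = NA_real_,
               end2_z = NA_real_),
    data.frame(patient_id = 2L, deposit_id = 1L, r = 9, phi = 0, z = 2,
               thickness = 6, length = 8, volume = 400, cusp = "NCC",
               shape = "regular", end1_r = NA_real_, end1_phi = NA_real_,
               end1_z = NA_real_, end2_r = NA_real_, end2_phi = NA_real_,
               end2_z = NA_real_))
  base
}

# Deterministic linear risk model over a feature matrix (white-box builder
# used by the optimiser / sensitivity unit tests).
make_linear_fit <- function(feature_names, selected, weights, bias = 0,
                            center = NULL, scale = NULL, tau = 0.5,
                            config = NULL) {
  if (is.null(center)) center <- rep(0, length(selected))
  if (is.null(scale)) scale <- rep(1, length(selected))
  structure(list(
    weights = stats::setNames(weights, feature_names[selected]),
    bias = bias, lambda = 1, epsilon = 0,
    selected = as.integer(selected), feature_names = feature_names,
    center = stats::setNames(center, feature_names[selected]),
    scale = stats::setNames(scale, feature_names[selected]),
    tau = tau, config = config, n = NA_integer_),
    class = "tavr_fit")
}
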