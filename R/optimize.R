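#' Inverse optimisation of prosthetic valve size and vacancy angle
#'
#' Searches the full design grid — available nominal sizes crossed with
#' vacancy angles `0, theta_step, ..., theta_max` — by running the forward
#' pipeline (boundary condition, elasticity solve, conduction-zone
#' features, risk prediction) at every grid point. One stiffness
#' factorisation per angle spans all sizes through linear superposition,
#' so the search is exhaustive yet cheap.
#'
#' The selected design is the *minimal sufficient modification*: among
#' grid points whose predicted risk does not exceed `risk_target`
#' (default: the classification threshold `tau`), the smallest vacancy
#' angle wins, then the size closest to `oversize_factor` times the
#' annulus diameter; if no grid point is feasible, the design with minimal
#' predicted risk is returned under the same tie-breaks. A pure risk
#' minimum would degenerate (risk decreases monotonically with the vacancy
#' angle and with smaller valves), which contradicts the clinical pattern
#' that low-risk patients receive an unmodified, conventionally oversized
#' valve.
#'
#' The optimal loading force `F* = K (R* - C_annu/(2 pi) + d)` is reported
#' alongside, and [force_to_size()] inverts it back to the chosen size.
#'
#' @param fit a [tavr_fit()].
#' @param cohort the `"tavr_cohort"` the patients come from.
#' @param ids patient ids to optimise (default: all).
#' @param config a [tavr_config()] (defaults to the model's).
#' @param sizes candidate nominal sizes, mm.
#' @param theta_max,theta_step vacancy-angle grid, degrees.
#' @param risk_target acceptable predicted risk; `NULL` uses `fit$tau`.
#' @return An object of class `"valve_plan"`: a per-patient design table
#'   (id, risk at the applied design, optimal size, vacancy angle, risk at
#'   the optimum, F*) plus the full risk grids.
#' @export
optimize_valve <- function(fit, cohort, ids = NULL, config = fit$config,
                           sizes = NULL, theta_max = NULL,
                           theta_step = NULL, risk_target = NULL) {
  stopifnot(inherits(fit, "tavr_fit"), inherits(cohort, "tavr_cohort"))
  if (is.null(config)) config <- tavr_config()
  if (is.null(sizes)) sizes <- config$valve$sizes
  if (is.null(theta_max)) theta_max <- config$valve$theta_max
  if (is.null(theta_step)) theta_step <- config$valve$theta_step
  if (is.null(risk_target)) {
    risk_target <- config$valve$risk_target
    if (is.null(risk_target) || is.na(risk_target)) risk_target <- fit$tau
  }
  thetas <- seq(0, theta_max, by = theta_step)
  if (!length(sizes) || !length(thetas)) {
    stop("empty design grid", call. = FALSE)
  }
  if (is.null(ids)) ids <- cohort$patients$id
  features <- tavr_features(cohort, config)
  meta <- attr(features, "meta")

  rows <- vector("list", length(ids))
  grids <- vector("list", length(ids))
  for (k in seq_along(ids)) {
    id <- ids[k]
    pt <- cohort$patients[cohort$patients$id == id, ]
    if (nrow(pt) != 1) stop("unknown patient id: ", id, call. = FALSE)
    base_row <- features[as.character(id), , drop = FALSE]
    risk_applied <- as.numeric(predict(fit, base_row, type = "risk"))

    grid <- matrix(NA_real_, length(sizes), length(thetas),
                   dimnames = list(size = sizes, theta = thetas))
    mesh <- NULL; system <- NULL
    for (t in seq_along(thetas)) {
      ph <- patient_physics(cohort, id, config, valve_size = sizes,
                            theta = thetas[t], mesh = mesh,
                            system = system)
      mesh <- ph$mesh; system <- ph$system
      xg <- base_row[rep(1, length(sizes)), , drop = FALSE]
      xg[, meta$stress_cols] <- ph$sigma
      grid[, t] <- predict(fit, xg, type = "risk")
    }

    pref <- config$valve$oversize_factor * pt$c_annu / pi
    cand <- expand.grid(si = seq_along(sizes), ti = seq_along(thetas))
    cand$risk <- grid[cbind(cand$si, cand$ti)]
    cand$theta <- thetas[cand$ti]
    cand$size <- sizes[cand$si]
    feas <- cand[cand$risk <= risk_target + 1e-12, ]
    pool <- if (nrow(feas)) feas else cand
    by_risk <- if (nrow(feas)) 0 else 1  # infeasible: risk leads the order
    o <- order(by_risk * pool$risk, pool$theta, abs(pool$size - pref),
               pool$size)
    best <- pool[o[1], ]
    d_max <- {
      geom <- patient_geometry(cohort, id)
      rem <- remodel_deposits(
        cohort$deposits[cohort$deposits$patient_id == id, , drop = FALSE],
        geom)
      if (nrow(rem)) max(rem$thickness) else 0
    }
    fstar <- loading_force(pt$k_wall, best$size, pt$c_annu, d_max)$F
    rows[[k]] <- data.frame(
      id = id, risk_applied = risk_applied,
      applied_size = pt$applied_valve_size,
      optimal_size = best$size, vacant_angle = best$theta,
      risk_optimal = best$risk, feasible = nrow(feas) > 0,
      f_star = fstar)
    grids[[k]] <- grid
  }
  structure(list(designs = do.call(rbind, rows), grids = grids,
                 sizes = sizes, thetas = thetas,
                 risk_target = risk_target),
            class = "valve_plan")
}

#' @export
print.valve_plan <- function(x, ...) {
  cat(sprintf(
    "valve design plan (%d patients; grid %d sizes x %d angles; risk target %.2f)\n",
    nrow(x$designs), length(x$sizes), length(x$thetas), x$risk_target))
  print(x$designs, row.names = FALSE, digits = 3)
  invisible(x)
}

#' @export
as.data.frame.valve_plan <- function(x, ...) x$designs
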