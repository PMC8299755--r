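# Truncated-normal sampling by inverse CDF: exact truncation, fixed number
# of RNG draws (keeps cohorts byte-reproducible for a given seed).
rtnorm <- function(n, spec) {
  lo <- stats::pnorm(spec$min, spec$mean, spec$sd)
  hi <- stats::pnorm(spec$max, spec$mean, spec$sd)
  stats::qnorm(stats::runif(n, lo, hi), spec$mean, spec$sd)
}

check_dist <- function(spec, name) {
  if (!all(c("mean", "sd", "min", "max") %in% names(spec)) ||
      spec$sd <= 0 || spec$min >= spec$max) {
    stop("invalid distribution bounds for generator parameter '", name, "'",
         call. = FALSE)
  }
  invisible(spec)
}

#' AVB label probability and draws under the generative ground truth
#'
#' The synthetic ground truth assigns the AVB outcome from a linear score
#' with a logistic link: `P(AVB) = plogis(score / noise)`. With noise scale
#' zero the label is deterministic in the sign of the score; the boundary
#' `score = 0` is resolved to label 0.
#'
#' @param score linear risk score(s).
#' @param noise non-negative noise scale.
#' @return `avb_label_prob` returns probabilities; `draw_avb_label` returns
#'   Bernoulli draws in `{0, 1}` (uses the current RNG state).
#' @examples
#' avb_label_prob(c(-1, 0, 1), 0)  # 0 0 1
#' @export
avb_label_prob <- function(score, noise) {
  if (noise < 0) stop("noise scale must be non-negative", call. = FALSE)
  if (noise == 0) return(as.numeric(score > 0))
  stats::plogis(score / noise)
}

#' @rdname avb_label_prob
#' @export
draw_avb_label <- function(score, noise) {
  p <- avb_label_prob(score, noise)
  stats::rbinom(length(p), 1L, p)
}

#' Simulate a synthetic TAVR cohort
#'
#' Generates `n` seeded synthetic patients — aortic root geometry, calcium
#' deposits and clinical factors — with AVB labels assigned by the
#' generative ground-truth model of [cohort_params()]: a linear score on
#' the mean conduction-zone von Mises stress (computed with the package's
#' own forward physics at the applied valve size and vacancy angle 0),
#' NCC/RCC-zone calcium fraction, calcified volume and clinical factors,
#' plus logistic noise. Class labels and sex are assigned by quota
#' (28/20 and 28M/20F at n = 48, proportional otherwise), which reproduces
#' the reference cohort split exactly.
#'
#' Identical `(n, seed, config)` yield byte-identical cohorts. The
#' stress features computed for the truth score are cached on the returned
#' object and reused by [tavr_features()] when the configuration matches.
#'
#' @param n number of patients; at least 2.
#' @param seed integer RNG seed.
#' @param config a [tavr_config()]; generator settings in
#'   `config$generator`.
#' @param physics run the biomechanical stage of the truth model (the
#'   default). `FALSE` skips the elasticity solves — the truth score then
#'   carries no stress term — and is intended for distribution-level
#'   checks of the generated marginals, which are identical either way
#'   (the physics consumes no random numbers).
#' @return An object of class `"tavr_cohort"`: a list with data frames
#'   `patients` and `deposits`, plus a `truth` attribute holding the
#'   noiseless scores, truth weights and stress summaries.
#' @examples
#' \donttest{
#' coh <- simulate_cohort(10, seed = 1,
#'   config = tavr_config(mesh = list(n_circ = 24, n_axial = 6, n_radial = 2)))
#' table(coh$patients$avb_label)
#' }
#' @export
simulate_cohort <- function(n = 48, seed = 1, config = tavr_config(),
                            physics = TRUE) {
  if (!is.numeric(n) || n < 2) {
    stop("n must be at least 2 (cannot form two outcome classes)",
         call. = FALSE)
  }
  n <- as.integer(n)
  p <- config$generator
  for (nm in c("age", "bmi", "sbp", "dbp", "lvef", "thickness",
               "deposit_length", "annulus_diameter", "wall_thickness")) {
    check_dist(p[[nm]], nm)
  }
  if (p$thickness$min <= 0) {
    stop("thickness truncation must be strictly positive", call. = FALSE)
  }

  old_seed <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                         envir = globalenv()))
  set.seed(seed)

  # --- clinical factors ----------------------------------------------------
  n_male <- round(n * p$male_frac)
  sex <- sample(rep(c("male", "female"), c(n_male, n - n_male)))
  age <- rtnorm(n, p$age)
  bmi <- rtnorm(n, p$bmi)
  sbp <- rtnorm(n, p$sbp)
  dbp <- rtnorm(n, p$dbp)
  lvef <- rtnorm(n, p$lvef)
  diabetes <- stats::rbinom(n, 1, p$prevalence$diabetes)
  afib <- stats::rbinom(n, 1, p$prevalence$afib)
  stroke <- stats::rbinom(n, 1, p$prevalence$stroke)
  icb <- stats::rbinom(n, 1, p$prevalence$icb)

  # --- geometry ------------------------------------------------------------
  diam <- rtnorm(n, p$annulus_diameter)
  c_annu <- pi * diam
  wall <- rtnorm(n, p$wall_thickness)
  height <- rep(p$annulus_height, n)
  p_root <- stats::runif(n, p$p_root_range[1], p$p_root_range[2])
  tissue_total <- rtnorm(n, list(mean = 5000, sd = 500, min = 3500,
                                 max = 6500))
  root_vol <- tissue_total * p_root
  leaflet_vol <- tissue_total * (1 - p_root)
  sizes <- config$valve$sizes
  applied <- vapply(diam, function(D) {
    tgt <- config$valve$oversize_factor * D
    sizes[order(abs(sizes - tgt), sizes)[1]]
  }, numeric(1))

  # --- calcium deposits ----------------------------------------------------
  ndep <- sample(seq(p$deposits_per_patient[1], p$deposits_per_patient[2]),
                 n, replace = TRUE)
  v_target <- stats::runif(n, p$total_volume_range[1], p$total_volume_range[2])
  dep_list <- vector("list", n)
  for (i in seq_len(n)) {
    k <- ndep[i]
    cusp <- sample(names(p$cusp_probs), k, replace = TRUE,
                   prob = as.numeric(p$cusp_probs))
    hw <- p$nccrcc_phi_halfwidth
    phi <- ifelse(cusp %in% c("NCC", "RCC"),
                  stats::runif(k, -hw, hw) %% 360,
                  stats::runif(k, hw, 360 - hw))
    a_i <- c_annu[i] / (2 * pi)
    r <- stats::runif(k, 0.5 * a_i, 0.9 * a_i)
    z <- stats::runif(k, 0.5, height[i] - 0.5)
    d <- rtnorm(k, p$thickness)
    len <- rtnorm(k, p$deposit_length)
    shape <- ifelse(stats::runif(k) < p$irregular_prob, "irregular",
                    "regular")
    width <- stats::runif(k, 2, 6)
    vol_raw <- d * len * width
    vol <- vol_raw * v_target[i] / sum(vol_raw)
    e1 <- e2 <- matrix(NA_real_, k, 3)
    for (j in which(shape == "irregular")) {
      ctr <- as.numeric(cyl_to_cart(r[j], phi[j], z[j]))
      psi <- stats::runif(1, 0, 2 * pi)
      tilt <- stats::runif(1, -0.3, 0.3)
      dir3 <- c(cos(psi), sin(psi), tilt)
      dir3 <- dir3 / sqrt(sum(dir3^2))
      h <- dir3 * len[j] / 2
      e1[j, ] <- cart_to_cyl(ctr + h)
      e2[j, ] <- cart_to_cyl(ctr - h)
    }
    dep_list[[i]] <- data.frame(
      patient_id = i, deposit_id = seq_len(k),
      r = r, phi = phi, z = z, thickness = d, length = len, volume = vol,
      cusp = cusp, shape = shape,
      end1_r = e1[, 1], end1_phi = e1[, 2], end1_z = e1[, 3],
      end2_r = e2[, 1], end2_phi = e2[, 2], end2_z = e2[, 3],
      stringsAsFactors = FALSE)
  }
  deposits <- do.call(rbind, dep_list)
  volume <- vapply(dep_list, function(d) sum(d$volume), numeric(1))

  patients <- data.frame(
    id = seq_len(n), sex = sex, age = age, bmi = bmi,
    systolic_bp = sbp, diastolic_bp = dbp, lvef = lvef,
    diabetes = diabetes, afib_history = afib, stroke_history = stroke,
    icb_history = icb, calcified_volume = volume,
    c_annu = c_annu, wall_thickness = wall, annulus_height = height,
    k_wall = config$k_wall, root_volume = root_vol,
    leaflet_volume = leaflet_vol, applied_valve_size = applied,
    avb_label = 0L, stringsAsFactors = FALSE)

  cohort <- structure(list(patients = patients, deposits = deposits),
                      class = "tavr_cohort")

  # --- ground-truth score and quota labels --------------------------------
  if (physics) {
    feats <- tavr_features(cohort, config, refresh = TRUE)
    meta <- attr(feats, "meta")
    sbar <- rowMeans(feats[, meta$stress_cols, drop = FALSE])
    czfrac <- feats[, "cz_ca_fraction"]
  } else {
    feats <- NULL
    sbar <- rep(config$generator$truth$stress_ref, n)
    czfrac <- vapply(seq_len(n), function(i) {
      geom <- patient_geometry(cohort, i)
      rem <- remodel_deposits(
        deposits[deposits$patient_id == i, , drop = FALSE], geom)
      v <- rem$volume
      in_cz <- abs(ang_diff(rem$phi, 0)) < config$zone$sector_deg / 2
      if (sum(v) > 0) sum(v[in_cz]) / sum(v) else 0
    }, numeric(1))
  }
  tw <- p$truth
  score <- tw$w_stress * (sbar - tw$stress_ref) +
    tw$w_czfrac * (czfrac - tw$czfrac_ref) +
    tw$w_volume * (volume - tw$volume_ref) +
    tw$w_bmi * (bmi - p$bmi$mean) +
    tw$w_sbp * (sbp - p$sbp$mean) +
    tw$w_lvef * (lvef - p$lvef$mean) +
    tw$w_male * (sex == "male") +
    tw$w_diabetes * diabetes + tw$w_afib * afib +
    tw$w_stroke * stroke + tw$w_icb * icb
  noisy <- score + tw$noise * stats::rlogis(n)
  n_avb <- round(n * p$avb_frac)
  lab <- integer(n)
  lab[order(-noisy, seq_len(n))[seq_len(n_avb)]] <- 1L
  cohort$patients$avb_label <- lab

  attr(cohort, "truth") <- list(score = score, noisy_score = noisy,
                                weights = tw, stress_summary = sbar,
                                cz_fraction = czfrac)
  if (!is.null(feats)) attr(cohort, "features") <- feats
  cohort
}

#' Sample deposit thicknesses from the generator distribution
#'
#' Direct draws from the truncated-normal calcium-thickness distribution
#' of [cohort_params()] (mean 3.2 mm, sd 1.2 mm, truncated to
#' (0.5, 6.8] mm by default), for distribution-level checks without
#' generating whole patients.
#'
#' @param n number of draws.
#' @param params a [cohort_params()].
#' @param seed optional RNG seed.
#' @return Numeric vector of thicknesses (mm).
#' @export
sample_deposit_thickness <- function(n, params = cohort_params(),
                                     seed = NULL) {
  if (!is.null(seed)) {
    old_seed <- get0(".Random.seed", envir = globalenv())
    on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                           envir = globalenv()))
    set.seed(seed)
  }
  check_dist(params$thickness, "thickness")
  rtnorm(n, params$thickness)
}

#' @export
print.tavr_cohort <- function(x, ...) {
  pt <- x$patients
  cat(sprintf(
    "synthetic TAVR cohort: %d patients (%d male / %d female), %d AVB / %d no-AVB, %d calcium deposits\n",
    nrow(pt), sum(pt$sex == "male"), sum(pt$sex == "female"),
    sum(pt$avb_label == 1), sum(pt$avb_label == 0), nrow(x$deposits)))
  invisible(x)
}

#' Extract one patient's root geometry from a cohort
#'
#' @param cohort a `"tavr_cohort"`.
#' @param id patient id.
#' @return A [root_geometry()].
#' @export
patient_geometry <- function(cohort, id) {
  row <- cohort$patients[cohort$patients$id == id, ]
  if (nrow(row) != 1) stop("unknown patient id: ", id, call. = FALSE)
  root_geometry(row$c_annu, row$wall_thickness, row$annulus_height,
                row$k_wall, row$root_volume, row$leaflet_volume)
}

# CSV serialisation ----------------------------------------------------------

fmt_num <- function(x) {
  ifelse(is.na(x), "NA", sprintf("%.17g", x))
}

write_table_exact <- function(df, path) {
  out <- df
  for (j in seq_along(out)) {
    if (is.double(out[[j]])) out[[j]] <- fmt_num(out[[j]])
  }
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write / read a cohort as a CSV pair
#'
#' Serialises a cohort to two UTF-8 comma-separated files with header rows:
#' `cohort.csv` (one row per patient) and `deposits.csv` (long format, keyed
#' by `patient_id`). Doubles are written with 17 significant digits so the
#' round trip `read_cohort(write_cohort(x, dir))` is exact field-for-field.
#' Malformed headers, non-numeric values in numeric columns and deposit
#' rows referencing unknown patient ids raise parse errors naming the file
#' and line.
#'
#' @param cohort a `"tavr_cohort"`.
#' @param dir directory for the two files (created if missing).
#' @return `write_cohort` returns `dir` invisibly; `read_cohort` returns a
#'   `"tavr_cohort"` (without generative-truth attributes).
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "tavr_cohort"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  write_table_exact(cohort$patients, file.path(dir, "cohort.csv"))
  write_table_exact(cohort$deposits, file.path(dir, "deposits.csv"))
  invisible(dir)
}

cohort_columns <- list(
  patients = c(id = "integer", sex = "character", age = "double",
               bmi = "double", systolic_bp = "double",
               diastolic_bp = "double", lvef = "double",
               diabetes = "integer", afib_history = "integer",
               stroke_history = "integer", icb_history = "integer",
               calcified_volume = "double", c_annu = "double",
               wall_thickness = "double", annulus_height = "double",
               k_wall = "double", root_volume = "double",
               leaflet_volume = "double", applied_valve_size = "double",
               avb_label = "integer"),
  deposits = c(patient_id = "integer", deposit_id = "integer",
               r = "double", phi = "double", z = "double",
               thickness = "double", length = "double", volume = "double",
               cusp = "character", shape = "character",
               end1_r = "double", end1_phi = "double", end1_z = "double",
               end2_r = "double", end2_phi = "double", end2_z = "double"))

read_cohort_table <- function(path, spec) {
  if (!file.exists(path)) stop("missing file: ", path, call. = FALSE)
  header <- strsplit(readLines(path, n = 1), ",", fixed = TRUE)[[1]]
  if (!identical(header, names(spec))) {
    stop("malformed header in ", basename(path), ": expected columns ",
         paste(names(spec), collapse = ","), call. = FALSE)
  }
  raw <- utils::read.csv(path, colClasses = "character")
  out <- raw
  for (j in seq_along(spec)) {
    cls <- spec[[j]]
    if (cls %in% c("double", "integer")) {
      suppressWarnings(v <- as.numeric(raw[[j]]))
      missing_ok <- is.na(raw[[j]]) | raw[[j]] %in% c("NA", "")
      bad <- which(is.na(v) & !missing_ok)
      if (length(bad)) {
        stop(sprintf("non-numeric value '%s' in column '%s' of %s, line %d",
                     raw[[j]][bad[1]], names(spec)[j], basename(path),
                     bad[1] + 1L), call. = FALSE)
      }
      out[[j]] <- if (cls == "integer") as.integer(v) else v
    }
  }
  out
}

#' @rdname write_cohort
#' @export
read_cohort <- function(dir) {
  patients <- read_cohort_table(file.path(dir, "cohort.csv"),
                                cohort_columns$patients)
  deposits <- read_cohort_table(file.path(dir, "deposits.csv"),
                                cohort_columns$deposits)
  orphan <- which(!(deposits$patient_id %in% patients$id))
  if (length(orphan)) {
    stop(sprintf("deposit row references unknown patient id %s (deposits.csv, line %d)",
                 deposits$patient_id[orphan[1]], orphan[1] + 1L),
         call. = FALSE)
  }
  structure(list(patients = patients, deposits = deposits),
            class = "tavr_cohort")
}
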