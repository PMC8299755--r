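#' Fit the biomechanical AVB risk model
#'
#' The central fitting routine: assembles (or reuses) the feature matrix —
#' conduction-zone stress vector, calcified volume and clinical factors,
#' with vacancy angle 0 in training, representing the complete valve —
#' ranks features by DX score, keeps the top `n_select`, z-scores them on
#' the training data, and fits a linear support vector regression
#' `g(x) = <w, x> + b` with squared epsilon-insensitive loss and ridge
#' penalty `lambda` to the binary AVB outcome. Predicted risks are the
#' linear scores clipped to `[0, 1]`; AVB is called when the risk exceeds
#' the threshold `tau` (default 0.5).
#'
#' When `lambda` is `NULL` it is chosen by an inner k-fold cross-validation
#' over `config$model$lambda_grid` with a fixed fold seed, making the whole
#' fit deterministic.
#'
#' @param cohort a `"tavr_cohort"` from [simulate_cohort()] or
#'   [read_cohort()].
#' @param features optional precomputed [tavr_features()] matrix.
#' @param config a [tavr_config()].
#' @param lambda ridge penalty; `NULL` for inner-CV selection.
#' @param epsilon insensitive-tube half width.
#' @param n_select number of features kept by DX selection.
#' @return An object of class `"tavr_fit"` with `print`, `summary`,
#'   `coef`, `predict`, `fitted`, `residuals`, `plot` and `simulate`
#'   methods.
#' @seealso [predict.tavr_fit()], [optimize_valve()], [loo_cv()]
#' @export
tavr_fit <- function(cohort, features = NULL, config = tavr_config(),
                     lambda = NULL, epsilon = NULL, n_select = NULL) {
  stopifnot(inherits(cohort, "tavr_cohort"))
  y <- cohort$patients$avb_label
  if (length(y) < 8) stop("at least 8 patients are required", call. = FALSE)
  if (length(unique(y)) < 2) {
    stop("outcome is single-class: cannot fit a risk model", call. = FALSE)
  }
  if (is.null(features)) features <- tavr_features(cohort, config)
  if (is.null(epsilon)) epsilon <- config$model$epsilon
  if (is.null(n_select)) n_select <- config$model$n_select

  fit <- fit_risk_core(features, y, config, lambda, epsilon, n_select)
  fit$config <- config
  fit$call <- match.call()
  fit$feature_meta <- attr(features, "meta")
  class(fit) <- "tavr_fit"
  fit
}

# Core fit on a plain feature matrix (shared with LOO / ablation paths).
fit_risk_core <- function(features, y, config, lambda = NULL,
                          epsilon = 0.01, n_select = 16,
                          skip_dx = FALSE) {
  if (skip_dx) {
    dx <- NULL
    sel <- structure(seq_len(ncol(features)), impact_pct = 100)
  } else {
    dx <- dx_score(features, y)
    sel <- dx_select(dx, n_select)
  }
  xs <- features[, sel, drop = FALSE]
  center <- colMeans(xs)
  scale_ <- apply(xs, 2, stats::sd)
  scale_[scale_ < 1e-12] <- 1
  z <- sweep(sweep(xs, 2, center), 2, scale_, "/")

  cv_tab <- NULL
  if (is.null(lambda)) {
    cv <- lambda_cv(z, y, config, epsilon)
    lambda <- cv$lambda
    cv_tab <- cv$table
  }
  sv <- svr_fit(z, y, lambda = lambda, epsilon = epsilon)
  raw <- drop(z %*% sv$w) + sv$b
  risk <- pmin(1, pmax(0, raw))
  list(weights = stats::setNames(sv$w, colnames(xs)), bias = sv$b,
       lambda = lambda, epsilon = epsilon, selected = as.integer(sel),
       impact_pct = attr(sel, "impact_pct"),
       feature_names = colnames(features), center = center,
       scale = scale_, dx = dx, tau = config$model$tau,
       grad_norm = sv$grad_norm, cv = cv_tab,
       y = y, raw = raw, fitted_risk = risk, n = length(y))
}

lambda_cv <- function(z, y, config, epsilon) {
  grid <- config$model$lambda_grid
  kf <- min(config$model$cv_folds, length(y))
  old_seed <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                         envir = globalenv()))
  set.seed(config$model$cv_seed)
  folds <- sample(rep(seq_len(kf), length.out = length(y)))
  mse <- vapply(grid, function(l) {
    se <- 0
    for (k in seq_len(kf)) {
      tr <- folds != k
      if (length(unique(y[tr])) < 2) next
      f <- svr_fit(z[tr, , drop = FALSE], y[tr], lambda = l,
                   epsilon = epsilon)
      pred <- drop(z[!tr, , drop = FALSE] %*% f$w) + f$b
      se <- se + sum((y[!tr] - pred)^2)
    }
    se / length(y)
  }, numeric(1))
  best <- max(grid[mse <= min(mse) + 1e-12])  # tie towards stronger penalty
  list(lambda = best, table = data.frame(lambda = grid, cv_mse = mse))
}

#' @export
print.tavr_fit <- function(x, ...) {
  cat(sprintf(
    "TAVR AVB risk model: %s patients, %d selected features%s, lambda = %g, epsilon = %g\n",
    ifelse(is.na(x$n), "?", x$n), length(x$selected),
    if (is.null(x$impact_pct)) "" else sprintf(" (impact %.1f%%)",
                                               x$impact_pct),
    x$lambda, x$epsilon))
  if (!is.null(x$fitted_risk)) {
    acc <- 100 * mean((x$fitted_risk > x$tau) == (x$y == 1))
    cat(sprintf("training accuracy at tau = %.2f: %.1f%%\n", x$tau, acc))
  }
  invisible(x)
}

#' @export
coef.tavr_fit <- function(object, ...) {
  c("(bias)" = object$bias, object$weights)
}

#' @export
fitted.tavr_fit <- function(object, ...) object$fitted_risk

#' @export
residuals.tavr_fit <- function(object, ...) object$y - object$fitted_risk

#' Predict AVB risk for new patients
#'
#' Applies the fitted linear risk model: selected features are normalised
#' with the training statistics, the linear score `<w, z> + b` is clipped
#' to `[0, 1]` (`type = "risk"`), returned unclipped (`type = "raw"`), or
#' thresholded at `tau` into `"AVB"` / `"no-AVB"` (`type = "class"`).
#'
#' @param object a [tavr_fit()].
#' @param newdata a `"tavr_cohort"` (features are recomputed with the
#'   model's configuration), or a feature matrix with the model's feature
#'   columns; `NULL` for the training data.
#' @param type `"risk"`, `"class"` or `"raw"`.
#' @param ... unused.
#' @return Numeric risks, raw scores, or a factor of class calls.
#' @export
predict.tavr_fit <- function(object, newdata = NULL,
                             type = c("risk", "class", "raw"), ...) {
  type <- match.arg(type)
  raw <- if (is.null(newdata)) {
    object$raw
  } else {
    x <- if (inherits(newdata, "tavr_cohort")) {
      tavr_features(newdata, object$config)
    } else {
      as.matrix(newdata)
    }
    if (ncol(x) != length(object$feature_names)) {
      stop(sprintf("feature length mismatch: got %d, model expects %d",
                   ncol(x), length(object$feature_names)), call. = FALSE)
    }
    xs <- x[, object$selected, drop = FALSE]
    z <- sweep(sweep(xs, 2, object$center), 2, object$scale, "/")
    drop(z %*% object$weights) + object$bias
  }
  switch(type,
         raw = raw,
         risk = pmin(1, pmax(0, raw)),
         class = classify_risk(pmin(1, pmax(0, raw)), object$tau))
}

#' Classify a predicted risk
#'
#' AVB is called when the risk percentage (0-1) exceeds the threshold
#' `tau`; 0.5 is the only threshold consistent with the reference
#' per-patient table (0.431 unflagged, 0.617 flagged).
#'
#' @param risk numeric risks in `[0, 1]`.
#' @param tau classification threshold in (0, 1).
#' @return Factor with levels `"no-AVB"`, `"AVB"`.
#' @examples
#' classify_risk(c(0.651, 0.235, 0.431))
#' @export
classify_risk <- function(risk, tau = 0.5) {
  if (any(risk < 0 | risk > 1)) {
    stop("risk must lie in [0, 1]", call. = FALSE)
  }
  if (tau <= 0 || tau >= 1) stop("tau must lie in (0, 1)", call. = FALSE)
  factor(ifelse(risk > tau, "AVB", "no-AVB"), levels = c("no-AVB", "AVB"))
}

#' @export
summary.tavr_fit <- function(object, ...) {
  pred <- classify_risk(object$fitted_risk, object$tau)
  truth <- factor(ifelse(object$y == 1, "AVB", "no-AVB"),
                  levels = c("no-AVB", "AVB"))
  tab <- table(predicted = pred, truth = truth)
  wt <- data.frame(feature = names(object$weights),
                   weight = unname(object$weights),
                   dx_rank = object$dx$rank[object$selected])
  out <- list(n = object$n, lambda = object$lambda,
              epsilon = object$epsilon, impact_pct = object$impact_pct,
              confusion = tab,
              accuracy = 100 * mean(pred == truth),
              auc = auc_trapezoid(object$fitted_risk, object$y),
              weights = wt[order(-abs(wt$weight)), ],
              grad_norm = object$grad_norm)
  class(out) <- "summary.tavr_fit"
  out
}

#' @export
print.summary.tavr_fit <- function(x, ...) {
  cat(sprintf("TAVR AVB risk model — n = %d, lambda = %g, epsilon = %g\n",
              x$n, x$lambda, x$epsilon))
  cat(sprintf("selected-feature impact: %.1f%%; training accuracy %.1f%%, AUC %.3f\n",
              x$impact_pct, x$accuracy, x$auc))
  cat("confusion (training):\n")
  print(x$confusion)
  cat("largest coefficients:\n")
  print(utils::head(x$weights, 8), row.names = FALSE)
  invisible(x)
}

#' @export
plot.tavr_fit <- function(x, ...) {
  op <- graphics::par(mfrow = c(1, 2), mar = c(4, 4, 2, 1))
  on.exit(graphics::par(op))
  top <- x$dx[order(x$dx$rank), ][seq_len(length(x$selected)), ]
  graphics::barplot(rev(top$score), names.arg = rev(top$feature),
                    horiz = TRUE, las = 1, cex.names = 0.55,
                    xlab = "DX score", main = "selected features")
  graphics::boxplot(x$fitted_risk ~ factor(x$y, labels = c("no-AVB", "AVB")),
                    xlab = "outcome", ylab = "fitted risk",
                    main = "fitted risk by class")
  graphics::abline(h = x$tau, lty = 2)
  invisible(x)
}

#' Simulate outcomes from a fitted risk model
#'
#' Draws Bernoulli AVB labels at the fitted (or newly predicted) risks.
#'
#' @param object a [tavr_fit()].
#' @param nsim number of simulated label vectors.
#' @param seed optional RNG seed.
#' @param newdata optional new cohort or feature matrix.
#' @param ... unused.
#' @return Data frame of `nsim` simulated 0/1 label columns.
#' @export
simulate.tavr_fit <- function(object, nsim = 1, seed = NULL,
                              newdata = NULL, ...) {
  if (!is.null(seed)) {
    old_seed <- get0(".Random.seed", envir = globalenv())
    on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                           envir = globalenv()))
    set.seed(seed)
  }
  p <- predict(object, newdata = newdata, type = "risk")
  out <- as.data.frame(replicate(nsim, stats::rbinom(length(p), 1L, p)))
  names(out) <- paste0("sim_", seq_len(nsim))
  out
}
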