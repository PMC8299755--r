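#' Linear support vector regression with squared epsilon-insensitive loss
#'
#' Solves
#' `min_{w,b}  lambda * ||w||^2 + sum_i max(0, |y_i - w.x_i - b| - epsilon)^2`
#' by an exact active-set Newton iteration: for a fixed set of points
#' outside the epsilon-tube (with fixed residual signs) the objective is an
#' ordinary ridge problem with shifted targets, solved in closed form; the
#' active set is then refreshed until stable. The objective is convex and
#' C1, so a stable active set certifies the global minimum; the final
#' gradient norm is returned as the optimality certificate. With
#' `epsilon = 0` the solution is exactly ridge regression (unpenalised
#' intercept), which is used as an independent cross-check in the tests.
#'
#' @param x numeric matrix (n x p), already normalised by the caller.
#' @param y numeric response.
#' @param lambda ridge penalty; must be positive.
#' @param epsilon half-width of the insensitive tube; non-negative.
#' @param max_iter iteration cap for the active-set loop.
#' @return List with `w`, `b`, `lambda`, `epsilon`, `objective`,
#'   `grad_norm`, `iterations`.
#' @export
svr_fit <- function(x, y, lambda, epsilon = 0, max_iter = 200L) {
  x <- as.matrix(x)
  n <- nrow(x); p <- ncol(x)
  if (length(y) != n) stop("length(y) must equal nrow(x)", call. = FALSE)
  if (!is.numeric(lambda) || lambda <= 0) {
    stop("lambda must be positive", call. = FALSE)
  }
  if (epsilon < 0) stop("epsilon must be non-negative", call. = FALSE)

  w <- numeric(p); b <- mean(y)
  obj <- function(w, b) {
    r <- y - drop(x %*% w) - b
    lambda * sum(w^2) + sum(pmax(0, abs(r) - epsilon)^2)
  }
  seen <- character(0)
  it <- 0L
  repeat {
    it <- it + 1L
    r <- y - drop(x %*% w) - b
    act <- abs(r) > epsilon
    sgn <- sign(r)
    key <- paste0(as.integer(act) * sgn, collapse = "")
    if (key %in% seen || it > max_iter) break
    seen <- c(seen, key)
    if (!any(act)) break  # zero loss at the current iterate
    xa <- x[act, , drop = FALSE]
    ya <- y[act] - sgn[act] * epsilon
    m <- sum(act)
    # ridge with unpenalised intercept, normal equations
    A <- rbind(cbind(crossprod(xa) + lambda * diag(p), colSums(xa)),
               c(colSums(xa), m))
    rhs <- c(crossprod(xa, ya), sum(ya))
    theta <- solve(A, rhs)
    w <- unname(theta[seq_len(p)]); b <- unname(theta[p + 1])
  }
  r <- y - drop(x %*% w) - b
  act <- abs(r) > epsilon
  g_w <- 2 * lambda * w - 2 * drop(crossprod(x[act, , drop = FALSE],
                                             (abs(r) - epsilon)[act] *
                                               sign(r)[act]))
  g_b <- -2 * sum(((abs(r) - epsilon)[act]) * sign(r)[act])
  list(w = w, b = b, lambda = lambda, epsilon = epsilon,
       objective = obj(w, b), grad_norm = sqrt(sum(g_w^2) + g_b^2),
       iterations = it)
}
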