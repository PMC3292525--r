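# Model acceptance/rejection statistics: incomplete-gamma Q test, numerical
# Gauss-Newton Hessian, SVD-based effective-parameter counting.

#' Regularized upper incomplete gamma function Q(a, x)
#'
#' Computes \eqn{Q(a,x) = \Gamma(a,x)/\Gamma(a) = 1 - P(a,x)} by the classical
#' series / continued-fraction split: the lower series for `x < a + 1`, the
#' Lentz continued fraction for the upper tail otherwise. This is the
#' probability that a chi-square variate with `2a` degrees of freedom exceeds
#' `2x`.
#'
#' @param a shape parameter, `a > 0`.
#' @param x nonnegative evaluation point.
#' @return `Q(a, x)` in `[0, 1]`.
#' @examples
#' gamma_q(3, 19.14)       # upper-tail probability
#' pgamma(19.14, 3, lower.tail = FALSE)  # reference
#' @export
gamma_q <- function(a, x) {
  stopifnot(is.numeric(a), is.numeric(x), length(a) == 1L, length(x) == 1L)
  if (a <= 0) stop("gamma_q: 'a' must be positive")
  if (x < 0) stop("gamma_q: 'x' must be nonnegative")
  if (x == 0) return(1)
  if (x < a + 1) {
    1 - .gamma_p_series(a, x)
  } else {
    .gamma_q_contfrac(a, x)
  }
}

# Lower regularized incomplete gamma by power series (x < a+1 regime).
.gamma_p_series <- function(a, x, itmax = 500L, eps = 3e-16) {
  ap <- a
  sum <- 1 / a
  del <- sum
  for (i in seq_len(itmax)) {
    ap <- ap + 1
    del <- del * x / ap
    sum <- sum + del
    if (abs(del) < abs(sum) * eps) break
  }
  sum * exp(-x + a * log(x) - lgamma(a))
}

# Upper regularized incomplete gamma by modified Lentz continued fraction.
.gamma_q_contfrac <- function(a, x, itmax = 500L, eps = 3e-16) {
  fpmin <- .Machine$double.xmin / eps
  b <- x + 1 - a
  c <- 1 / fpmin
  d <- 1 / b
  h <- d
  for (i in seq_len(itmax)) {
    an <- -i * (i - a)
    b <- b + 2
    d <- an * d + b
    if (abs(d) < fpmin) d <- fpmin
    c <- b + an / c
    if (abs(c) < fpmin) c <- fpmin
    d <- 1 / d
    del <- d * c
    h <- h * del
    if (abs(del - 1) < eps) break
  }
  exp(-x + a * log(x) - lgamma(a)) * h
}

#' Goodness-of-fit probability of a fitted chi-square
#'
#' The probability that, for a correct model with `F` degrees of freedom,
#' chi-square exceeds the fitted value by chance: `Q(F/2, chi2/2)` with `Q`
#' the regularized upper incomplete gamma function.
#'
#' @param f degrees of freedom (`>= 1`).
#' @param chi2 fitted chi-square minimum (`>= 0`).
#' @return `Q` in `[0, 1]`.
#' @examples
#' q_value(6, 38.28)   # ~1e-6: reject
#' q_value(4, 3.13)    # ~0.54: accept
#' @export
q_value <- function(f, chi2) {
  stopifnot(f >= 1, chi2 >= 0)
  gamma_q(f / 2, chi2 / 2)
}

#' Degrees of freedom of a fit
#'
#' `F = N - P`: independent data points minus effective (identifiable)
#' parameters.
#'
#' @param n number of data points.
#' @param p_eff number of effective parameters.
#' @return integer degrees of freedom.
#' @export
degrees_of_freedom <- function(n, p_eff) {
  stopifnot(n >= 0, p_eff >= 0)
  if (n < p_eff) {
    stop("degrees_of_freedom: underdetermined problem (N = ", n,
         " < P_eff = ", p_eff, "); no valid F")
  }
  as.integer(n - p_eff)
}

#' Acceptance verdict from a Q value
#'
#' A model is accepted when `Q > 0.05`; it is marginal (acceptable only if
#' measurement errors are non-normal or moderately underestimated) when
#' `0.001 < Q <= 0.05`; it must be rejected when `Q <= 0.001`.
#'
#' @param q goodness-of-fit probability in `[0, 1]`.
#' @return one of `"accept"`, `"marginal"`, `"reject"`.
#' @export
verdict <- function(q) {
  stopifnot(q >= 0, q <= 1)
  if (q > 0.05) "accept" else if (q > 0.001) "marginal" else "reject"
}

#' Gauss-Newton Hessian of a chi-square objective
#'
#' Approximates the curvature matrix of `chi2(a) = sum_i r_i(a)^2`, with
#' `r_i = (y_i - f_i(a)) / sigma_i`, by the first-derivative (Gauss-Newton)
#' form `alpha_kl = 2 sum_i (1/sigma_i^2) (df_i/da_k)(df_i/da_l)`, dropping
#' the second-derivative term as is standard near a minimum. The model
#' Jacobian is obtained by central finite differences with a relative step.
#'
#' @param predict_fn function mapping a named parameter vector to the vector
#'   of model predictions `f_i`.
#' @param params named numeric vector of parameter values at which to expand.
#' @param sd vector of measurement standard deviations `sigma_i` (recycled).
#' @param step relative finite-difference step (default `1e-4`).
#' @return object of class `hessian_analysis`: a list with the symmetric
#'   matrix, its singular values, condition number, and the SVD pieces used
#'   for covariance.
#' @export
gauss_newton_hessian <- function(predict_fn, params, sd, step = 1e-4) {
  stopifnot(is.numeric(params), length(params) >= 1)
  p <- length(params)
  f0 <- predict_fn(params)
  n <- length(f0)
  sd <- rep_len(sd, n)
  if (any(sd <= 0)) stop("gauss_newton_hessian: all sd must be > 0")
  jac <- matrix(NA_real_, n, p, dimnames = list(NULL, names(params)))
  for (k in seq_len(p)) {
    h <- step * max(abs(params[k]), 1e-12)
    up <- params; up[k] <- up[k] + h
    dn <- params; dn[k] <- dn[k] - h
    dk <- (predict_fn(up) - predict_fn(dn)) / (2 * h)
    if (any(!is.finite(dk))) {
      stop("gauss_newton_hessian: non-finite derivative for parameter '",
           names(params)[k] %||% k, "'")
    }
    jac[, k] <- dk
  }
  w <- jac / sd
  h_mat <- 2 * crossprod(w)           # positive-semidefinite by construction
  h_mat <- (h_mat + t(h_mat)) / 2
  hessian_analysis(h_mat)
}

#' Analyze a Hessian matrix by singular value decomposition
#'
#' @param h symmetric curvature matrix.
#' @param cond_threshold reciprocal-condition threshold below which the
#'   matrix is considered numerically singular and no covariance is formed.
#' @return object of class `hessian_analysis`.
#' @export
hessian_analysis <- function(h, cond_threshold = 1e-10) {
  stopifnot(is.matrix(h), nrow(h) == ncol(h))
  if (max(abs(h - t(h))) > 1e-8 * max(1, max(abs(h)))) {
    stop("hessian_analysis: matrix is not symmetric")
  }
  sv <- svd(h)
  w <- sv$d
  rcond <- if (w[1] > 0) w[length(w)] / w[1] else 0
  covariance <- NULL
  if (rcond > cond_threshold) {
    covariance <- sv$v %*% diag(1 / w, length(w)) %*% t(sv$u)
    dimnames(covariance) <- dimnames(h)
  }
  structure(
    list(matrix = h, singular_values = w,
         condition_number = if (rcond > 0) 1 / rcond else Inf,
         rcond = rcond, covariance = covariance,
         cond_threshold = cond_threshold),
    class = "hessian_analysis")
}

#' Count effective (identifiable) parameters from a Hessian
#'
#' Greedy forward selection: parameters are ranked by diagonal sensitivity
#' (ties broken lexicographically by name) and added one at a time while the
#' growing submatrix keeps a reciprocal condition number above
#' `cond_threshold`. The size of the maximal such subset is the number of
#' parameters jointly identifiable from the data; the remainder behave as
#' constants and do not reduce the degrees of freedom.
#'
#' @param hessian a matrix or a `hessian_analysis` object.
#' @param cond_threshold reciprocal condition number limit (default `1e-10`).
#' @return list with `p_eff` (integer) and `selected` (parameter names or
#'   indices in selection order).
#' @export
effective_parameter_count <- function(hessian, cond_threshold = 1e-10) {
  h <- if (inherits(hessian, "hessian_analysis")) hessian$matrix else hessian
  p <- ncol(h)
  nm <- colnames(h)
  if (is.null(nm)) nm <- as.character(seq_len(p))
  d <- diag(h)
  ord <- order(-d, nm)
  selected <- integer(0)
  for (k in ord) {
    trial <- c(selected, k)
    sub <- h[trial, trial, drop = FALSE]
    w <- svd(sub, nu = 0, nv = 0)$d
    rc <- if (w[1] > 0) w[length(w)] / w[1] else 0
    if (rc > cond_threshold) selected <- trial
  }
  list(p_eff = length(selected), selected = nm[selected])
}

#' Model discrimination report
#'
#' Assembles the acceptance/rejection statistics for a fitted model: data
#' points `N`, effective parameters `P_eff`, degrees of freedom `F = N -
#' P_eff`, the fitted chi-square, the incomplete-gamma probability `Q`, and
#' the verdict.
#'
#' @param n number of data points entering chi-square.
#' @param p_eff effective parameter count.
#' @param chi2 fitted chi-square minimum.
#' @param model optional label for the model variant.
#' @return object of class `discrimination_report`.
#' @examples
#' discrimination_report(22, 16, 38.28, model = "mixed")
#' @export
discrimination_report <- function(n, p_eff, chi2, model = NA_character_) {
  f <- degrees_of_freedom(n, p_eff)
  q <- q_value(max(f, 1L), chi2)
  structure(
    list(model = model, n = as.integer(n), p_eff = as.integer(p_eff),
         f = f, chi2 = chi2, q = q, verdict = verdict(q)),
    class = "discrimination_report")
}

#' @export
print.discrimination_report <- function(x, ...) {
  cat("Model discrimination report", if (!is.na(x$model)) paste0("[", x$model, "]"), "\n")
  cat(sprintf("  N = %d data points, P_eff = %d effective parameters, F = %d\n",
              x$n, x$p_eff, x$f))
  cat(sprintf("  chi2 = %.4g, Q = %.3g  ->  %s\n", x$chi2, x$q, x$verdict))
  invisible(x)
}

#' @export
tidy.discrimination_report <- function(x, ...) {
  tibble::tibble(model = x$model, n = x$n, p_eff = x$p_eff, f = x$f,
                 chi2 = x$chi2, q = x$q, verdict = x$verdict)
}

#' @export
glance.discrimination_report <- function(x, ...) tidy.discrimination_report(x)

# broom-style generics (broom is not a dependency; define the generics here).
#' Turn a labelflux result into a tidy tibble
#' @param x object to tidy.
#' @param ... passed to methods.
#' @export
tidy <- function(x, ...) UseMethod("tidy")

#' One-row model summary of a labelflux result
#' @param x object to summarize.
#' @param ... passed to methods.
#' @export
glance <- function(x, ...) UseMethod("glance")

`%||%` <- function(a, b) if (is.null(a)) b else a
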