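#' Fit a two-parameter retention function by weighted least squares
#'
#' Minimises `sum(w_i * (y_i - f(t_i; a, b))^2)`. With `weights = 1` on
#' trial-level (participant, delay) points and with `weights = n_i` on cell
#' means, the point estimates are identical (within/between decomposition of
#' the total sum of squares), so printed group means with their sample sizes
#' are first-class inputs.
#'
#' The linear and logarithmic forms are linear in `(a, b)` and solved in
#' closed form. The power and exponential forms are profiled: for fixed `b`
#' the optimal intercept has the closed form
#' `a(b) = sum(w y u) / sum(w u^2)` with `u` the slope basis, and the
#' one-dimensional profile RSS is minimised from a deterministic multi-start
#' grid of `b` values (log-spaced over 0.01--4, both signs, plus 0) followed
#' by a local polish, so fits are reproducible without a seed and robust to
#' local minima. `b` is not sign-constrained: a negative fitted slope is a
#' model-health signal, not an error.
#'
#' @param form One of [retention_forms()].
#' @param t Delays in hours (one per data point), `t >= 0`.
#' @param y Observed d-prime values (trial-level points or cell means).
#' @param weights Non-negative weights; defaults to 1 per point. Use cell
#'   sample sizes when `y` are cell means.
#' @param within_ss Optional within-cell sum of squares to add to the
#'   residual sum of squares when computing the residual variance behind the
#'   reported standard errors (see [reconstruct_within_ss()]). Does not
#'   affect the point estimates.
#' @param b_starts Optional numeric vector of starting values for the slope
#'   search (multiplicative forms only).
#'
#' @return An object of class `retention_fit`: a list with elements `form`,
#'   `a`, `b`, `se_a`, `se_b`, `constrained` (FALSE), `b_source` (`"free"`),
#'   `rss` (weighted residual sum of squares about the fitted curve),
#'   `n_obs` (total weight, i.e. the number of underlying observations),
#'   `n_cells`, and the data (`t`, `y`, `weights`).
#' @seealso [fit_retention_constrained()], [compare_slopes()],
#'   [goodness_of_fit()]
#' @export
#' @examples
#' t <- c(0, 0.5, 2, 24)
#' y <- c(2.61, 1.69, 1.59, 1.01)   # deep-condition cell means
#' fit_retention("power", t, y, weights = c(86, 30, 28, 28))
fit_retention <- function(form, t, y, weights = NULL, within_ss = 0,
                          b_starts = NULL) {
  form <- match.arg(form, retention_forms())
  if (is.null(weights)) weights <- rep(1, length(y))
  .check_fit_data(t, y, weights)

  if (form %in% c("linear", "logarithmic")) {
    g <- if (form == "linear") t else log(t + 1)
    X <- cbind(a = rep(1, length(t)), b = -g)
    fit <- stats::lm.wfit(X, y, weights)
    a <- unname(fit$coefficients[1])
    b <- unname(fit$coefficients[2])
    rss <- sum(weights * fit$residuals^2)
  } else {
    if (is.null(b_starts)) {
      grid <- exp(seq(log(0.01), log(4), length.out = 13))
      b_starts <- c(-rev(grid), 0, grid)
    }
    prof <- function(b) .profile_rss(form, b, t, y, weights)
    cand <- vapply(b_starts, function(b0) {
      o <- tryCatch(
        stats::optim(b0, prof, method = "BFGS",
                     control = list(reltol = 1e-14)),
        error = function(e) list(par = b0, value = prof(b0))
      )
      c(o$par, o$value)
    }, numeric(2))
    best <- which.min(cand[2, ])
    if (!is.finite(cand[2, best])) {
      stop("retention fit failed to converge from any start; best candidate b = ",
           cand[1, best])
    }
    b <- cand[1, best]
    # local polish on a bracket around the best start
    o <- stats::optimize(prof, interval = c(b - 0.5, b + 0.5), tol = 1e-12)
    if (o$objective <= cand[2, best]) b <- o$minimum
    a <- .conditional_a(form, b, t, y, weights)
    rss <- prof(b)
  }

  se <- .fit_standard_errors(form, a, b, t, y, weights, rss, within_ss,
                             n_free = 2)
  structure(
    list(form = form, a = a, b = b, se_a = se[1], se_b = se[2],
         constrained = FALSE, b_source = "free",
         rss = rss, n_obs = sum(weights), n_cells = length(y),
         t = t, y = y, weights = weights),
    class = "retention_fit"
  )
}

#' Fit a retention function with the slope fixed (constrained model)
#'
#' Refits a condition with the slope parameter `b` held at a value taken
#' from the unconstrained fit of another condition, leaving only the
#' intercept `a` free. For all four forms this is a one-parameter weighted
#' linear projection with a closed-form solution. The constrained fit is the
#' restricted member of the nested pair tested by [compare_slopes()]: equal
#' slopes across encoding conditions means equal forgetting rates.
#'
#' @inheritParams fit_retention
#' @param b_fixed Slope value to impose (typically the unconstrained
#'   estimate from the other encoding condition).
#' @param b_source Label recording where `b_fixed` came from.
#'
#' @return A `retention_fit` with `constrained = TRUE` and `se_b = NA`.
#' @export
#' @examples
#' t <- c(0, 0.5, 2, 24)
#' deep <- fit_retention("power", t, c(2.61, 1.69, 1.59, 1.01),
#'                       weights = c(86, 30, 28, 28))
#' fit_retention_constrained("power", t, c(2.10, 1.21, 1.32, 0.61),
#'                           weights = c(86, 30, 28, 28),
#'                           b_fixed = deep$b, b_source = "deep")
fit_retention_constrained <- function(form, t, y, weights = NULL, b_fixed,
                                      within_ss = 0, b_source = "fixed") {
  form <- match.arg(form, retention_forms())
  if (is.null(weights)) weights <- rep(1, length(y))
  .check_fit_data(t, y, weights, min_t = 1)
  stopifnot(is.numeric(b_fixed), length(b_fixed) == 1, is.finite(b_fixed))

  a <- .conditional_a(form, b_fixed, t, y, weights)
  rss <- .profile_rss(form, b_fixed, t, y, weights)
  se <- .fit_standard_errors(form, a, b_fixed, t, y, weights, rss, within_ss,
                             n_free = 1)
  structure(
    list(form = form, a = a, b = b_fixed, se_a = se[1], se_b = NA_real_,
         constrained = TRUE, b_source = b_source,
         rss = rss, n_obs = sum(weights), n_cells = length(y),
         t = t, y = y, weights = weights),
    class = "retention_fit"
  )
}

#' @export
print.retention_fit <- function(x, ...) {
  cat(sprintf("%s retention fit (%s)\n", x$form,
              if (x$constrained) paste0("constrained, b from ", x$b_source)
              else "unconstrained"))
  cat(sprintf("  a = %.4f (SE %.4f)\n", x$a, x$se_a))
  if (x$constrained) {
    cat(sprintf("  b = %.4f (fixed)\n", x$b))
  } else {
    cat(sprintf("  b = %.4f (SE %.4f)\n", x$b, x$se_b))
  }
  cat(sprintf("  weighted RSS = %.6g over %d cells (N = %g)\n",
              x$rss, x$n_cells, x$n_obs))
  invisible(x)
}

.check_fit_data <- function(t, y, weights, min_t = 3) {
  stopifnot(is.numeric(t), is.numeric(y), is.numeric(weights))
  if (length(t) != length(y) || length(y) != length(weights)) {
    stop("t, y and weights must have equal length")
  }
  if (any(!is.finite(t)) || any(!is.finite(y)) || any(!is.finite(weights))) {
    stop("t, y and weights must be finite")
  }
  if (any(t < 0)) stop("delays t must be non-negative")
  if (any(weights < 0)) stop("weights must be non-negative")
  if (length(unique(t[weights > 0])) < min_t) {
    stop("need at least ", min_t + 1, " distinct delays for a two-parameter fit",
         call. = FALSE)
  }
}

# Asymptotic least-squares standard errors from the Jacobian of the fitted
# curve: cov = sigma^2 (J' W J)^{-1}, sigma^2 = (RSS + within SS) / (N - k).
# With unit weights on trial-level points and within_ss = 0 this is the
# classic nonlinear-LS covariance; with cell means the within-cell sum of
# squares must be supplied for sigma^2 to be on the observation scale.
.fit_standard_errors <- function(form, a, b, t, y, w, rss, within_ss, n_free) {
  N <- sum(w)
  df <- N - n_free - 1  # a (, b), sigma
  if (df <= 0) return(c(NA_real_, NA_real_))
  sigma2 <- (rss + within_ss) / df
  bs <- .retention_basis(form, b, t)
  d_da <- bs$u
  d_db <- switch(form,
    linear      = -t,
    power       = -a * log(t + 1) * bs$u,
    exponential = -a * t * bs$u,
    logarithmic = -log(t + 1)
  )
  J <- if (n_free == 2) cbind(d_da, d_db) else cbind(d_da)
  JtWJ <- crossprod(J, w * J)
  cov <- tryCatch(sigma2 * solve(JtWJ), error = function(e) NULL)
  if (is.null(cov)) return(c(NA_real_, NA_real_))
  se <- sqrt(pmax(diag(cov), 0))
  if (n_free == 2) se else c(se, NA_real_)
}
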