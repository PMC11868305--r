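#' The four two-parameter retention functions
#'
#' Names of the candidate forgetting curves supported by the fitting
#' machinery. Each expresses retention performance `y` (d-prime units) as a
#' two-parameter function of delay `t` (hours since encoding):
#'
#' * `linear`:      `y = a - b * t`
#' * `power`:       `y = a * (t + 1)^(-b)`
#' * `exponential`: `y = a * exp(-b * t)`
#' * `logarithmic`: `y = a - b * log(t + 1)`
#'
#' `a` is the initial degree of learning (all four forms predict `y = a` at
#' `t = 0`) and `b` is the slope (forgetting-rate) parameter in
#' form-specific units.
#'
#' @return Character vector of form names.
#' @export
#' @examples
#' retention_forms()
retention_forms <- function() {
  c("linear", "power", "exponential", "logarithmic")
}

#' Evaluate a retention function
#'
#' @param form One of [retention_forms()].
#' @param a Intercept (initial learning, d-prime units).
#' @param b Slope parameter (form-specific units).
#' @param t Delay in hours, `t >= 0`. Vectorised.
#'
#' @return Predicted retention performance, same length as `t`.
#' @export
#' @examples
#' evaluate_retention("power", a = 2.47, b = 0.36, t = c(0, 0.5, 2, 24))
evaluate_retention <- function(form, a, b, t) {
  form <- match.arg(form, retention_forms())
  stopifnot(is.numeric(t), all(t >= 0))
  switch(form,
    linear      = a - b * t,
    power       = a * (t + 1)^(-b),
    exponential = a * exp(-b * t),
    logarithmic = a - b * log(t + 1)
  )
}

# Conditional-on-b linear representation y = a * u(t; b) + v(t; b).
# For the multiplicative forms the slope lives in the basis u; for the
# shifted-linear forms u is constant and the slope lives in the offset v.
.retention_basis <- function(form, b, t) {
  switch(form,
    linear      = list(u = rep(1, length(t)), v = -b * t),
    power       = list(u = (t + 1)^(-b),      v = rep(0, length(t))),
    exponential = list(u = exp(-b * t),       v = rep(0, length(t))),
    logarithmic = list(u = rep(1, length(t)), v = -b * log(t + 1))
  )
}

# Weighted RSS profiled over the conditionally-linear intercept a.
.profile_rss <- function(form, b, t, y, w) {
  bs <- .retention_basis(form, b, t)
  su2 <- sum(w * bs$u^2)
  if (su2 <= 0) return(Inf)
  a <- sum(w * (y - bs$v) * bs$u) / su2
  sum(w * (y - a * bs$u - bs$v)^2)
}

.conditional_a <- function(form, b, t, y, w) {
  bs <- .retention_basis(form, b, t)
  su2 <- sum(w * bs$u^2)
  if (su2 <= 0) stop("degenerate basis: all basis values are zero at b = ", b)
  sum(w * (y - bs$v) * bs$u) / su2
}
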