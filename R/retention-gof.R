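#' Reconstruct within-cell sums of squares from printed summaries
#'
#' Published tables report per-cell means, standard errors and sample sizes
#' rather than raw scores. The within-cell spread they imply is
#' `SD^2 = n * SE^2` and `SS = (n - 1) * SD^2` per cell; the sum across cells
#' is the within-cell component missing from a fit to cell means. Adding it
#' to the weighted between-cell residual sum of squares recovers (up to the
#' rounding of the printed values) the total RSS a trial-level fit would
#' produce, which is what the likelihood-ratio statistic and the information
#' criteria are defined on.
#'
#' @param n Per-cell sample sizes.
#' @param se Per-cell standard errors of the mean.
#' @return Total within-cell sum of squares (scalar).
#' @export
#' @examples
#' reconstruct_within_ss(n = c(86, 30, 28, 28), se = c(0.06, 0.10, 0.09, 0.10))
reconstruct_within_ss <- function(n, se) {
  stopifnot(length(n) == length(se), all(n >= 1), all(se >= 0))
  sum((n - 1) * n * se^2)
}

#' Goodness of fit of a retention fit
#'
#' Computes `AIC`, `BIC` and `R^2` under the Gaussian-likelihood convention
#' with profiled residual variance:
#' `AIC = N log(2 pi RSS/N) + N + 2k` and
#' `BIC = N log(2 pi RSS/N) + N + k log(N)`, where `N` is the number of
#' underlying observations, `RSS` the total residual sum of squares
#' (between-cell weighted RSS plus any within-cell component) and `k` counts
#' the free parameters including the residual standard deviation (3 for an
#' unconstrained fit, 2 for a constrained one). `R^2 = 1 - RSS/TSS` with the
#' total sum of squares taken about the weighted grand mean (plus the same
#' within-cell component).
#'
#' When the fit was computed from cell means but represents more underlying
#' observations than cells, the absolute likelihood is undefined without the
#' within-cell variability, so `AIC`/`BIC` are refused (returned as `NA`
#' with a warning) unless `within_ss` is supplied; `R^2` relative to the
#' between-cell variation is still emitted.
#'
#' @param fit A [fit_retention()] / [fit_retention_constrained()] result.
#' @param within_ss Within-cell sum of squares (see
#'   [reconstruct_within_ss()]); 0 for genuine trial-level fits.
#' @return A list of class `retention_gof` with `AIC`, `BIC`, `r_squared`,
#'   `rss_total`, `n_obs`, `k`, and a `convention` string recording the
#'   likelihood convention.
#' @export
goodness_of_fit <- function(fit, within_ss = NULL) {
  stopifnot(inherits(fit, "retention_fit"))
  N <- fit$n_obs
  k <- if (fit$constrained) 2L else 3L
  emit_ic <- TRUE
  if (is.null(within_ss)) {
    if (N > fit$n_cells) {
      warning("fit summarises more observations than cells but no within-cell ",
              "SS was supplied; AIC/BIC are not identified and are omitted")
      emit_ic <- FALSE
    }
    within_ss <- 0
  }
  stopifnot(within_ss >= 0)
  rss_total <- fit$rss + within_ss
  grand <- sum(fit$weights * fit$y) / sum(fit$weights)
  tss <- sum(fit$weights * (fit$y - grand)^2) + within_ss
  r2 <- if (tss > 0) 1 - rss_total / tss else NA_real_
  if (emit_ic && rss_total > 0) {
    base <- N * log(2 * pi * rss_total / N) + N
    aic <- base + 2 * k
    bic <- base + k * log(N)
  } else {
    aic <- NA_real_
    bic <- NA_real_
  }
  structure(
    list(AIC = aic, BIC = bic, r_squared = r2, rss_total = rss_total,
         n_obs = N, k = k,
         convention = "Gaussian likelihood, profiled sigma; k includes sigma"),
    class = "retention_gof"
  )
}

#' @export
print.retention_gof <- function(x, ...) {
  cat(sprintf("AIC = %.2f, BIC = %.2f, R^2 = %.3f (N = %g, k = %d)\n",
              x$AIC, x$BIC, x$r_squared, x$n_obs, x$k))
  invisible(x)
}

#' Likelihood-ratio test of slope equality between encoding conditions
#'
#' Compares a constrained retention fit (slope imposed from the other
#' condition) against its unconstrained counterpart on the same data.
#' Under the Gaussian likelihood with profiled variance the statistic is
#' `chi^2 = N * log(RSS_constrained / RSS_unconstrained)` on 1 degree of
#' freedom, where both RSS values include any within-cell component. A
#' significant result indicates the slope parameter -- the forgetting rate --
#' differs between conditions.
#'
#' @param unconstrained,constrained `retention_fit` objects on identical
#'   data; `constrained` must differ only by fixing `b`.
#' @param within_ss Within-cell sum of squares common to both fits
#'   (see [reconstruct_within_ss()]); 0 for trial-level fits.
#' @return A list of class `slope_comparison` with `chi_square`, `df` (1),
#'   `p_value`, `direction` (where the imposed slope came from), `n_obs`.
#' @export
#' @examples
#' t <- c(0, 0.5, 2, 24); w <- c(86, 30, 28, 28)
#' deep <- fit_retention("power", t, c(2.61, 1.69, 1.59, 1.01), w)
#' sh_u <- fit_retention("power", t, c(2.10, 1.21, 1.32, 0.61), w)
#' sh_c <- fit_retention_constrained("power", t, c(2.10, 1.21, 1.32, 0.61), w,
#'                                   b_fixed = deep$b, b_source = "deep")
#' compare_slopes(sh_u, sh_c,
#'                within_ss = reconstruct_within_ss(w, c(0.06, 0.10, 0.09, 0.10)))
compare_slopes <- function(unconstrained, constrained, within_ss = 0) {
  stopifnot(inherits(unconstrained, "retention_fit"),
            inherits(constrained, "retention_fit"))
  if (unconstrained$constrained || !constrained$constrained) {
    stop("pass the unconstrained fit first and the constrained fit second")
  }
  if (unconstrained$form != constrained$form) {
    stop("fits use different retention forms")
  }
  same_data <- isTRUE(all.equal(unconstrained$t, constrained$t)) &&
    isTRUE(all.equal(unconstrained$y, constrained$y)) &&
    isTRUE(all.equal(unconstrained$weights, constrained$weights))
  if (!same_data) stop("fits were not computed on identical data and weights")
  stopifnot(within_ss >= 0)

  rss_u <- unconstrained$rss + within_ss
  rss_c <- constrained$rss + within_ss
  if (rss_c < rss_u - 1e-8 * max(1, rss_u)) {
    stop("constrained RSS below unconstrained RSS: unconstrained optimizer ",
         "failed to find the global minimum")
  }
  N <- unconstrained$n_obs
  chi <- max(0, N * log(rss_c / rss_u))
  structure(
    list(chi_square = chi, df = 1L,
         p_value = stats::pchisq(chi, df = 1, lower.tail = FALSE),
         direction = constrained$b_source, n_obs = N,
         rss_unconstrained = rss_u, rss_constrained = rss_c),
    class = "slope_comparison"
  )
}

#' @export
print.slope_comparison <- function(x, ...) {
  cat(sprintf("slope-equality LR test: chi^2(1) = %.3f, p = %.4g (b from %s, N = %g)\n",
              x$chi_square, x$p_value, x$direction, x$n_obs))
  invisible(x)
}

#' Fit all retention functions and rank them
#'
#' Runs [fit_retention()] and [goodness_of_fit()] for every requested form
#' on one condition's data and ranks the forms by AIC, BIC and `R^2`. With a
#' common `N` and parameter count all three orderings are monotone in the
#' RSS and must agree; the function asserts this and records the result.
#'
#' @inheritParams fit_retention
#' @param forms Subset of [retention_forms()] to fit.
#' @param within_ss Within-cell SS added for the information criteria.
#' @return A data.frame (class `retention_ranking`) with one row per form:
#'   `form`, `a`, `b`, `rss`, `AIC`, `BIC`, `r_squared`, `rank`, ordered
#'   best-first. Attribute `fits` holds the underlying `retention_fit`
#'   objects; attribute `rank_agreement` is TRUE when AIC/BIC/R^2 agree.
#' @export
fit_all_retention <- function(t, y, weights = NULL, within_ss = NULL,
                              forms = retention_forms()) {
  forms <- match.arg(forms, retention_forms(), several.ok = TRUE)
  fits <- lapply(forms, function(f) fit_retention(f, t, y, weights,
                                                  within_ss = if (is.null(within_ss)) 0 else within_ss))
  gofs <- lapply(fits, goodness_of_fit, within_ss = within_ss)
  out <- data.frame(
    form = forms,
    a = vapply(fits, `[[`, numeric(1), "a"),
    b = vapply(fits, `[[`, numeric(1), "b"),
    rss = vapply(fits, `[[`, numeric(1), "rss"),
    AIC = vapply(gofs, `[[`, numeric(1), "AIC"),
    BIC = vapply(gofs, `[[`, numeric(1), "BIC"),
    r_squared = vapply(gofs, `[[`, numeric(1), "r_squared"),
    stringsAsFactors = FALSE
  )
  ord_rss <- order(out$rss)
  agreement <- TRUE
  if (all(is.finite(out$AIC))) {
    agreement <- identical(ord_rss, order(out$AIC)) &&
      identical(ord_rss, order(out$BIC)) &&
      identical(ord_rss, order(-out$r_squared))
    if (!agreement) warning("AIC/BIC/R^2 rankings disagree; flagged")
  }
  out <- out[ord_rss, , drop = FALSE]
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  attr(out, "fits") <- stats::setNames(fits, forms)
  attr(out, "rank_agreement") <- agreement
  class(out) <- c("retention_ranking", "data.frame")
  out
}
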