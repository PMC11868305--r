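#' Two-way mixed (split-plot) ANOVA
#'
#' Classical univariate split-plot decomposition for one within-participants
#' factor (each participant observed once per level) crossed with one
#' between-participants factor:
#'
#' * between-subjects stratum: the group effect tested against
#'   subjects-within-groups;
#' * within-subjects stratum: the within-factor main effect and the
#'   interaction tested against the level x subject residual.
#'
#' Group sizes may be unbalanced. Because every participant contributes all
#' within-factor levels, the cell frequencies are proportional, so the
#' reported sums of squares satisfy the marginality principle (Type II); on
#' balanced data they coincide with Type I. Partial eta squared is
#' `SS_effect / (SS_effect + SS_error)` using the error stratum the effect
#' is tested against. Sphericity corrections are not applied: the designs
#' this package targets have a two-level within factor, for which sphericity
#' holds trivially (asserted when `length(levels) > 2` would make it
#' matter).
#'
#' @param data Data.frame with one observation per participant x level.
#' @param dv Name of the response column (e.g. `"d_prime"`).
#' @param within Name of the within-participants factor column.
#' @param between Name of the between-participants factor column.
#' @param id Name of the participant identifier column.
#' @return A data.frame of class `anova_table` with columns `effect`,
#'   `stratum`, `ss`, `df`, `ms`, `f`, `p`, `partial_eta_sq`, and attribute
#'   `ss_type`. Participants missing any level are dropped listwise with a
#'   warning.
#' @export
mixed_anova <- function(data, dv, within, between, id) {
  stopifnot(all(c(dv, within, between, id) %in% names(data)))
  y <- data[[dv]]
  lev <- factor(data[[within]])
  grp <- factor(data[[between]])
  subj <- factor(data[[id]])
  L <- nlevels(lev)
  if (L < 2 || nlevels(grp) < 2) stop("need >= 2 within levels and >= 2 groups")
  if (L > 2) {
    warning("within factor has more than 2 levels: sphericity is assumed, ",
            "not corrected")
  }

  keep <- !is.na(y)
  complete <- names(which(tapply(lev[keep], subj[keep],
                                 function(l) length(unique(l)) == L)))
  complete <- complete[!is.na(complete)]
  if (length(complete) < nlevels(droplevels(subj[keep]))) {
    warning(nlevels(droplevels(subj[keep])) - length(complete),
            " participant(s) with missing cells dropped listwise")
  }
  sel <- keep & subj %in% complete
  y <- y[sel]; lev <- droplevels(lev[sel]); grp <- droplevels(grp[sel])
  subj <- droplevels(subj[sel])
  if (any(tapply(as.integer(grp), subj, function(g) length(unique(g))) != 1)) {
    stop("each participant must belong to exactly one group")
  }

  P <- nlevels(subj)
  G <- nlevels(grp)
  grand <- mean(y)
  ss_total <- sum((y - grand)^2)

  m_subj <- tapply(y, subj, mean)
  ss_subjects <- L * sum((m_subj - grand)^2)
  m_grp <- tapply(y, grp, mean)
  n_grp <- tapply(y, grp, length) / L
  ss_group <- L * sum(n_grp * (m_grp - grand)^2)
  ss_swg <- ss_subjects - ss_group

  m_lev <- tapply(y, lev, mean)
  ss_level <- P * sum((m_lev - grand)^2)
  m_cell <- tapply(y, list(grp, lev), mean)
  ss_cells <- sum(outer(n_grp, rep(1, L)) * (m_cell - grand)^2)
  ss_int <- ss_cells - ss_group - ss_level
  ss_werr <- ss_total - ss_cells - ss_swg

  df <- c(G - 1, P - G, L - 1, (G - 1) * (L - 1), (P - G) * (L - 1))
  ss <- c(ss_group, ss_swg, ss_level, ss_int, ss_werr)
  ms <- ss / df
  f <- c(ms[1] / ms[2], NA, ms[3] / ms[5], ms[4] / ms[5], NA)
  p <- c(stats::pf(f[1], df[1], df[2], lower.tail = FALSE), NA,
         stats::pf(f[3], df[3], df[5], lower.tail = FALSE),
         stats::pf(f[4], df[4], df[5], lower.tail = FALSE), NA)
  pes <- c(ss[1] / (ss[1] + ss[2]), NA,
           ss[3] / (ss[3] + ss[5]), ss[4] / (ss[4] + ss[5]), NA)

  out <- data.frame(
    effect = c(between, paste0("participant(", between, ")"),
               within, paste(between, within, sep = ":"), "residual(within)"),
    stratum = c("between", "between", "within", "within", "within"),
    ss = ss, df = df, ms = ms, f = f, p = p, partial_eta_sq = pes,
    stringsAsFactors = FALSE
  )
  attr(out, "ss_type") <- "II"
  attr(out, "design") <- "split-plot"
  class(out) <- c("anova_table", "data.frame")
  out
}

#' Two-way fully between-participants factorial ANOVA (Type II)
#'
#' Type II sums of squares by the model-comparison (marginality-respecting)
#' definition: each main effect is the RSS reduction from adding it to the
#' model containing the other main effect, and the interaction is the RSS
#' reduction from adding it to the additive model; all effects are tested
#' against the full-model residual. On balanced data Type II equals Type I,
#' and the result is invariant to the order of the factors.
#'
#' @param data Data.frame with one observation per participant.
#' @param dv Name of the response column.
#' @param factors Character vector of two factor column names.
#' @return A data.frame of class `anova_table` (same columns as
#'   [mixed_anova()]) with a single error stratum.
#' @export
factorial_anova <- function(data, dv, factors) {
  stopifnot(length(factors) == 2, all(c(dv, factors) %in% names(data)))
  df0 <- data.frame(y = data[[dv]],
                    A = factor(data[[factors[1]]]),
                    B = factor(data[[factors[2]]]))
  df0 <- df0[stats::complete.cases(df0), , drop = FALSE]
  if (nlevels(df0$A) < 2 || nlevels(df0$B) < 2) stop("each factor needs >= 2 levels")

  rss <- function(fm) sum(stats::lm(fm, data = df0)$residuals^2)
  rss_full <- rss(y ~ A * B)
  rss_add <- rss(y ~ A + B)
  ss <- c(A = rss(y ~ B) - rss_add,
          B = rss(y ~ A) - rss_add,
          `A:B` = rss_add - rss_full)
  n <- nrow(df0)
  a <- nlevels(df0$A); b <- nlevels(df0$B)
  df_eff <- c(a - 1, b - 1, (a - 1) * (b - 1))
  df_err <- n - a * b
  if (df_err < 1) stop("no residual degrees of freedom")
  ms_err <- rss_full / df_err
  f <- (ss / df_eff) / ms_err
  out <- data.frame(
    effect = c(factors, paste(factors, collapse = ":"), "residual"),
    stratum = "between",
    ss = c(ss, rss_full),
    df = c(df_eff, df_err),
    ms = c(ss / df_eff, ms_err),
    f = c(f, NA),
    p = c(stats::pf(f, df_eff, df_err, lower.tail = FALSE), NA),
    partial_eta_sq = c(ss / (ss + rss_full), NA),
    stringsAsFactors = FALSE,
    row.names = NULL
  )
  attr(out, "ss_type") <- "II"
  attr(out, "design") <- "factorial"
  class(out) <- c("anova_table", "data.frame")
  out
}

#' @export
print.anova_table <- function(x, digits = 4, ...) {
  cat(sprintf("%s ANOVA, Type %s sums of squares\n",
              attr(x, "design"), attr(x, "ss_type")))
  print.data.frame(x, digits = digits, row.names = FALSE)
  invisible(x)
}

#' Pairwise post hoc comparisons
#'
#' `bonferroni_pairwise()` performs all pairwise t comparisons between the
#' levels of a between-participants factor using a pooled error mean square,
#' multiplying each raw p by the number of pairs (capped at 1).
#' `tukey_hsd()` computes Tukey-Kramer honestly-significant-difference
#' comparisons on the studentized-range distribution. Both report Cohen's d
#' standardised by the square root of the pooled error mean square. By
#' default the error term is the residual of the one-way ANOVA on `dv`; pass
#' `ms_error`/`df_error` to use the error stratum of a larger design (e.g.
#' the subjects-within-groups term of a mixed ANOVA).
#'
#' @param data Data.frame with one observation per participant.
#' @param dv Response column name.
#' @param factor Grouping column name (>= 2 levels).
#' @param ms_error,df_error Optional error mean square and its df.
#' @return A data.frame of class `posthoc_table`: `pair`, `diff`,
#'   `statistic` (t or q), `p_raw` (t only), `p_adj`, `cohens_d`, with the
#'   adjustment recorded in attribute `"method"`.
#' @export
bonferroni_pairwise <- function(data, dv, factor, ms_error = NULL,
                                df_error = NULL) {
  pw <- .posthoc_setup(data, dv, factor, ms_error, df_error)
  m <- nrow(pw$pairs)
  res <- lapply(seq_len(m), function(k) {
    i <- pw$pairs[k, 1]; j <- pw$pairs[k, 2]
    d <- pw$means[i] - pw$means[j]
    se <- sqrt(pw$ms_error * (1 / pw$ns[i] + 1 / pw$ns[j]))
    tt <- d / se
    p_raw <- 2 * stats::pt(-abs(tt), pw$df_error)
    data.frame(pair = paste(pw$levels[i], pw$levels[j], sep = " - "),
               diff = d, statistic = tt, p_raw = p_raw,
               p_adj = min(1, m * p_raw),
               cohens_d = d / sqrt(pw$ms_error),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  attr(out, "method") <- "Bonferroni"
  class(out) <- c("posthoc_table", "data.frame")
  out
}

#' @rdname bonferroni_pairwise
#' @export
tukey_hsd <- function(data, dv, factor, ms_error = NULL, df_error = NULL) {
  pw <- .posthoc_setup(data, dv, factor, ms_error, df_error)
  k <- length(pw$levels)
  res <- lapply(seq_len(nrow(pw$pairs)), function(r) {
    i <- pw$pairs[r, 1]; j <- pw$pairs[r, 2]
    d <- pw$means[i] - pw$means[j]
    se <- sqrt(pw$ms_error / 2 * (1 / pw$ns[i] + 1 / pw$ns[j]))
    q <- abs(d) / se
    data.frame(pair = paste(pw$levels[i], pw$levels[j], sep = " - "),
               diff = d, statistic = q, p_raw = NA_real_,
               p_adj = stats::ptukey(q, nmeans = k, df = pw$df_error,
                                     lower.tail = FALSE),
               cohens_d = d / sqrt(pw$ms_error),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  attr(out, "method") <- "Tukey HSD"
  class(out) <- c("posthoc_table", "data.frame")
  out
}

.posthoc_setup <- function(data, dv, factor, ms_error, df_error) {
  stopifnot(all(c(dv, factor) %in% names(data)))
  y <- data[[dv]]
  g <- droplevels(factor(data[[factor]]))
  ok <- !is.na(y) & !is.na(g)
  y <- y[ok]; g <- droplevels(g[ok])
  if (nlevels(g) < 2) stop("post hoc comparisons need >= 2 groups")
  means <- tapply(y, g, mean)
  ns <- tapply(y, g, length)
  if (is.null(ms_error) != is.null(df_error)) {
    stop("supply both ms_error and df_error, or neither")
  }
  if (is.null(ms_error)) {
    res <- y - means[g]
    df_error <- length(y) - nlevels(g)
    if (df_error < 1) stop("no residual degrees of freedom for the error term")
    ms_error <- sum(res^2) / df_error
  }
  list(levels = levels(g), means = means, ns = ns,
       pairs = t(utils::combn(nlevels(g), 2)),
       ms_error = ms_error, df_error = df_error)
}

#' Per-participant mean log response times
#'
#' Natural-log transforms each trial's response time and averages per
#' participant x encoding level, the input shape for the RT ANOVA. Rows
#' with non-positive or missing RT are dropped and counted in a message.
#'
#' @inheritParams tabulate_counts
#' @return Data.frame with `participant_id`, `delay_group`, `lop_condition`,
#'   `mean_log_rt`, `n_trials`.
#' @export
log_transform_rt <- function(trials) {
  .check_trial_columns(trials)
  bad <- !is.finite(trials$rt_ms) | trials$rt_ms <= 0
  if (any(bad)) {
    message("dropping ", sum(bad), " trial(s) with non-positive or missing RT")
    trials <- trials[!bad, , drop = FALSE]
  }
  key <- interaction(trials$participant_id, trials$lop_condition,
                     drop = TRUE, lex.order = TRUE)
  lg <- log(trials$rt_ms)
  first <- match(levels(key), as.character(key))
  data.frame(
    participant_id = trials$participant_id[first],
    delay_group = trials$delay_group[first],
    lop_condition = trials$lop_condition[first],
    mean_log_rt = as.numeric(tapply(lg, key, mean)),
    n_trials = as.integer(tapply(lg, key, length)),
    stringsAsFactors = FALSE,
    row.names = NULL
  )
}
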