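#' Tabulate hits and false alarms per participant, level and phase
#'
#' Counts "old" responses to targets (hits) and to distractors (false
#' alarms) within each participant x encoding-level x test-phase cell of a
#' trial table. Every trial is assigned to exactly one cell; nothing is
#' dropped.
#'
#' @param trials A trial table as produced by [simulate_study()] or
#'   [read_trial_table()]: one row per test trial with columns
#'   `participant_id`, `lop_condition`, `delay_group`, `phase`,
#'   `delay_hours`, `item_id`, `item_role`, `response`, `rt_ms`.
#' @return A data.frame with one row per cell: the identifying columns plus
#'   `n_targets`, `hits`, `n_distractors`, `false_alarms`. Cells with zero
#'   targets or zero distractors are flagged with a warning (d-prime is not
#'   computable for them).
#' @export
tabulate_counts <- function(trials) {
  .check_trial_columns(trials)
  key <- interaction(trials$participant_id, trials$lop_condition,
                     trials$phase, drop = TRUE, lex.order = TRUE)
  tgt <- trials$item_role == "target"
  old <- trials$response == "old"
  counts <- rowsum(cbind(n_targets = as.numeric(tgt),
                         hits = as.numeric(tgt & old),
                         n_distractors = as.numeric(!tgt),
                         false_alarms = as.numeric(!tgt & old)),
                   group = key)
  first <- match(rownames(counts), as.character(key))
  out <- data.frame(
    participant_id = trials$participant_id[first],
    lop_condition = trials$lop_condition[first],
    delay_group = trials$delay_group[first],
    phase = trials$phase[first],
    delay_hours = trials$delay_hours[first],
    counts,
    stringsAsFactors = FALSE,
    row.names = NULL
  )
  bad <- out$n_targets == 0 | out$n_distractors == 0
  if (any(bad)) {
    warning(sum(bad), " cell(s) with zero targets or zero distractors: ",
            paste(out$participant_id[bad], out$lop_condition[bad],
                  out$phase[bad], sep = "/", collapse = ", "))
  }
  out
}

#' Correct hit and false-alarm rates for extreme values
#'
#' Raw rates of exactly 0 or 1 have infinite z-transforms. The log-linear
#' adjustment adds 0.5 to each count and 1 to each trial total, guaranteeing
#' rates strictly inside (0, 1). The default applies the adjustment to every
#' cell (the recommended usage, which keeps all cells on a common scale);
#' `"loglinear_extremes_only"` adjusts a rate only when it is exactly 0 or 1
#' and is provided for sensitivity analysis. Neither mode changes the
#' ordering of two cells' raw rates.
#'
#' @param counts Output of [tabulate_counts()], or any data.frame with
#'   columns `hits`, `n_targets`, `false_alarms`, `n_distractors`.
#' @param mode `"loglinear_all"` (default) or `"loglinear_extremes_only"`.
#' @return `counts` with columns `hit_rate` and `fa_rate` appended and the
#'   correction mode recorded in attribute `"correction"`.
#' @export
#' @examples
#' corrected_rates(data.frame(hits = 10, n_targets = 10,
#'                            false_alarms = 0, n_distractors = 40))
corrected_rates <- function(counts,
                            mode = c("loglinear_all", "loglinear_extremes_only")) {
  mode <- match.arg(mode)
  stopifnot(all(c("hits", "n_targets", "false_alarms", "n_distractors")
                %in% names(counts)))
  stopifnot(all(counts$hits >= 0), all(counts$hits <= counts$n_targets),
            all(counts$false_alarms >= 0),
            all(counts$false_alarms <= counts$n_distractors))
  adj <- function(x, n) (x + 0.5) / (n + 1)
  h_raw <- counts$hits / counts$n_targets
  f_raw <- counts$false_alarms / counts$n_distractors
  if (mode == "loglinear_all") {
    counts$hit_rate <- adj(counts$hits, counts$n_targets)
    counts$fa_rate <- adj(counts$false_alarms, counts$n_distractors)
  } else {
    counts$hit_rate <- ifelse(h_raw %in% c(0, 1),
                              adj(counts$hits, counts$n_targets), h_raw)
    counts$fa_rate <- ifelse(f_raw %in% c(0, 1),
                             adj(counts$false_alarms, counts$n_distractors),
                             f_raw)
  }
  attr(counts, "correction") <- mode
  counts
}

#' Equal-variance signal-detection scores
#'
#' Discriminability `d' = z(H) - z(FA)` and criterion location
#' `c = -0.5 * (z(H) + z(FA))`, with `z` the inverse standard normal CDF.
#' `d'` measures the ability to discriminate studied targets from new
#' distractors; `c` measures response bias (0 unbiased, positive values a
#' conservative, "new"-leaning respondent). Rates must lie strictly inside
#' (0, 1) -- correct them first with [corrected_rates()].
#'
#' @param hit_rate,fa_rate Numeric vectors in (0, 1).
#' @return A data.frame with columns `d_prime` and `criterion`.
#' @export
#' @examples
#' sdt_score(0.8, 0.2)  # symmetric: c = 0, d' = 2 * qnorm(0.8)
sdt_score <- function(hit_rate, fa_rate) {
  if (length(hit_rate) != length(fa_rate)) {
    if (length(hit_rate) == 1) hit_rate <- rep(hit_rate, length(fa_rate))
    else if (length(fa_rate) == 1) fa_rate <- rep(fa_rate, length(hit_rate))
    else stop("hit_rate and fa_rate must have equal length (or be scalar)")
  }
  if (any(hit_rate <= 0 | hit_rate >= 1 | fa_rate <= 0 | fa_rate >= 1)) {
    stop("rates must lie strictly inside (0, 1); apply corrected_rates() first")
  }
  zh <- stats::qnorm(hit_rate)
  zf <- stats::qnorm(fa_rate)
  data.frame(d_prime = zh - zf, criterion = -0.5 * (zh + zf))
}

#' Score a trial table end to end
#'
#' Convenience wrapper: [tabulate_counts()], [corrected_rates()], then
#' [sdt_score()] per participant x level x phase cell.
#'
#' @inheritParams tabulate_counts
#' @inheritParams corrected_rates
#' @return A scores data.frame: one row per cell with counts, corrected
#'   rates, `d_prime` and `criterion`.
#' @export
score_trials <- function(trials,
                         mode = c("loglinear_all", "loglinear_extremes_only")) {
  mode <- match.arg(mode)
  rates <- corrected_rates(tabulate_counts(trials), mode)
  out <- cbind(rates, sdt_score(rates$hit_rate, rates$fa_rate))
  attr(out, "correction") <- mode
  out
}

#' Apply the pre-registered participant exclusion screens
#'
#' A participant is excluded when their immediate-test performance signals
#' chance-level responding or an aberrant response pattern:
#'
#' * `chance_level`: immediate d-prime at or below 0 under either encoding
#'   level (after rate correction a continuous score never lands exactly on
#'   0, so the rule is `d' <= 0`);
#' * `hit_rate_outlier` / `fa_rate_outlier`: an immediate hit or
#'   false-alarm rate more than 2.5 sample standard deviations from the
#'   sample mean of that rate, computed over all participants' immediate
#'   cells with the two encoding levels pooled (one screen per rate).
#'
#' With fewer than 3 participants the SD screen is skipped with a warning;
#' a zero SD (all rates identical) flags no outliers.
#'
#' @param scores Output of [score_trials()]; immediate-phase rows must be
#'   present for every participant.
#' @return A list with `kept_scores` (rows of `scores` for retained
#'   participants), `kept` (their ids) and `exclusions` (a data.frame with
#'   `participant_id` and machine-readable `reason`, zero rows when nobody
#'   is excluded).
#' @export
exclude_participants <- function(scores) {
  stopifnot(all(c("participant_id", "phase", "d_prime",
                  "hit_rate", "fa_rate") %in% names(scores)))
  imm <- scores[scores$phase == "immediate", , drop = FALSE]
  ids <- unique(scores$participant_id)
  if (!all(ids %in% imm$participant_id)) {
    stop("immediate-phase scores missing for some participants")
  }
  excl <- list()

  chance <- unique(imm$participant_id[imm$d_prime <= 0])
  if (length(chance)) {
    excl$chance <- data.frame(participant_id = chance,
                              reason = "chance_level",
                              stringsAsFactors = FALSE)
  }

  if (length(unique(imm$participant_id)) < 3) {
    warning("fewer than 3 participants: 2.5-SD rate screen skipped")
  } else {
    for (rate in c("hit_rate", "fa_rate")) {
      x <- imm[[rate]]
      s <- stats::sd(x)
      if (is.finite(s) && s > 0) {
        out_rows <- abs(x - mean(x)) > 2.5 * s
        if (any(out_rows)) {
          excl[[rate]] <- data.frame(
            participant_id = unique(imm$participant_id[out_rows]),
            reason = paste0(sub("_rate", "", rate), "_rate_outlier"),
            stringsAsFactors = FALSE
          )
        }
      }
    }
  }

  exclusions <- if (length(excl)) {
    ex <- do.call(rbind, excl)
    rownames(ex) <- NULL
    ex[order(ex$participant_id, ex$reason), , drop = FALSE]
  } else {
    data.frame(participant_id = character(), reason = character(),
               stringsAsFactors = FALSE)
  }
  kept <- setdiff(ids, exclusions$participant_id)
  list(
    kept_scores = scores[scores$participant_id %in% kept, , drop = FALSE],
    kept = kept,
    exclusions = exclusions
  )
}

#' Cell summaries of d-prime (published-table shape)
#'
#' Aggregates per-participant scores into level x retention-interval cells:
#' sample size, mean d-prime and its standard error (`SD / sqrt(n)`). The
#' immediate test forms the `t = 0` cell for every delay group; delayed
#' cells are labelled by their group.
#'
#' @param scores Output of [score_trials()] (post-exclusion).
#' @return A data.frame with columns `level`, `label`, `delay_hours`, `n`,
#'   `mean_dprime`, `se_dprime`, ordered by level then delay. A cell with a
#'   single participant has `se_dprime = NA`.
#' @export
summarize_cells <- function(scores) {
  stopifnot(all(c("lop_condition", "phase", "delay_group", "delay_hours",
                  "d_prime") %in% names(scores)))
  label <- ifelse(scores$phase == "immediate", "immediate",
                  as.character(scores$delay_group))
  hours <- ifelse(scores$phase == "immediate", 0, scores$delay_hours)
  key <- interaction(scores$lop_condition, label, drop = TRUE)
  split_d <- split(scores$d_prime, key)
  first <- match(names(split_d), as.character(key))
  out <- data.frame(
    level = scores$lop_condition[first],
    label = label[first],
    delay_hours = hours[first],
    n = vapply(split_d, length, integer(1)),
    mean_dprime = vapply(split_d, mean, numeric(1)),
    se_dprime = vapply(split_d, function(d) {
      if (length(d) < 2) NA_real_ else stats::sd(d) / sqrt(length(d))
    }, numeric(1)),
    stringsAsFactors = FALSE,
    row.names = NULL
  )
  if (anyNA(out$se_dprime)) {
    warning("cell(s) with a single participant: SE reported as missing")
  }
  out[order(out$level, out$delay_hours), , drop = FALSE]
}

.trial_columns <- c("participant_id", "lop_condition", "delay_group", "phase",
                    "delay_hours", "item_id", "item_role", "response", "rt_ms")

.check_trial_columns <- function(trials) {
  missing <- setdiff(.trial_columns, names(trials))
  if (length(missing)) {
    stop("trial table is missing column(s): ", paste(missing, collapse = ", "))
  }
  invisible(TRUE)
}
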