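#' Describe a recognition-forgetting study design
#'
#' Captures the structural skeleton of the experiments the pipeline
#' analyses: an encoding phase of paced deep/shallow orienting judgements
#' followed by an immediate old/new recognition test and a single delayed
#' test on a disjoint subset of targets with fresh distractors (so no item
#' is retrieved twice). Depth of processing is manipulated within
#' participants (each participant encodes under both levels) or between
#' participants; the retention interval is always between participants, and
#' every participant additionally contributes the immediate (`t = 0`) test.
#'
#' @param lop_design `"within"` or `"between"` manipulation of the
#'   levels-of-processing factor.
#' @param delay_groups Named numeric vector of nominal delays in hours,
#'   strictly increasing, unique labels (e.g. `c("30min" = 0.5, "2h" = 2,
#'   "24h" = 24)`).
#' @param participants_per_group Participants per delay group (and per
#'   encoding condition when `lop_design = "between"`).
#' @param targets_per_level_per_phase Targets per encoding level in each test
#'   phase (10 in the within-participants designs, 20 in the
#'   between-participants design).
#' @param distractors_per_phase New distractors per test phase (40); in the
#'   within design they are split evenly between the two levels for
#'   per-level false-alarm rates, so the count must be even.
#' @param encoding_time_limit_ms Response window per trial (5000 ms);
#'   simulated response times are truncated at this limit.
#' @return An object of class `study_design`.
#' @export
#' @examples
#' study_design()  # the 2 x 3 mixed design with 30 participants per group
study_design <- function(lop_design = c("within", "between"),
                         delay_groups = c("30min" = 0.5, "2h" = 2, "24h" = 24),
                         participants_per_group = 30,
                         targets_per_level_per_phase = 10,
                         distractors_per_phase = 40,
                         encoding_time_limit_ms = 5000) {
  lop_design <- match.arg(lop_design)
  stopifnot(is.numeric(delay_groups), length(delay_groups) >= 1,
            !is.null(names(delay_groups)), all(nzchar(names(delay_groups))))
  if (anyDuplicated(names(delay_groups))) stop("delay group labels must be unique")
  if (any(delay_groups <= 0) || any(diff(delay_groups) <= 0)) {
    stop("nominal delays must be positive and strictly increasing")
  }
  .check_count(participants_per_group)
  .check_count(targets_per_level_per_phase)
  .check_count(distractors_per_phase)
  .check_count(encoding_time_limit_ms)
  if (lop_design == "within" && distractors_per_phase %% 2 != 0) {
    stop("within-participants design needs an even distractors_per_phase ",
         "(distractors are split between the two levels)")
  }
  structure(
    list(lop_design = lop_design,
         delay_groups = delay_groups,
         participants_per_group = as.integer(participants_per_group),
         targets_per_level_per_phase = as.integer(targets_per_level_per_phase),
         distractors_per_phase = as.integer(distractors_per_phase),
         encoding_time_limit_ms = as.integer(encoding_time_limit_ms)),
    class = "study_design"
  )
}

#' @rdname study_design
#' @export
exp1_design <- function() study_design()

#' @rdname study_design
#' @export
exp2_design <- function() study_design(participants_per_group = 24)

#' @rdname study_design
#' @export
exp3_design <- function() {
  study_design("between", c("30min" = 0.5, "2h" = 2, "6h" = 6),
               participants_per_group = 20,
               targets_per_level_per_phase = 20)
}

#' Generative parameters for the recognition simulator
#'
#' The simulator is a bi-normal equal-variance signal-detection model whose
#' latent discriminability decays along a retention function. Participant
#' `i` carries a shared ability deviation `delta_i ~ N(0, sd_a^2)`, giving a
#' latent intercept `a_{i,level} = max(0, a_level + delta_i)` under each
#' level (the shared deviation induces the within-participant correlation a
#' split-plot analysis assumes), and a response criterion
#' `c_i ~ N(criterion_mean, criterion_sd^2)`. At test delay `t` the latent
#' discriminability is `d'_i(t) = max(0, f(t; a_{i,level}, b_level))`:
#' target evidence is drawn from `N(d'_i(t), 1)`, distractor evidence from
#' `N(0, 1)`, and the response is "old" iff evidence exceeds `c_i`. With
#' probability `p_inattentive` a participant ignores the stimuli and
#' responds "old" with probability 0.5 on every trial (the pattern the
#' chance-level exclusion screen must catch). Response times are log-normal
#' per level, truncated at the design's response window.
#'
#' Defaults are calibrated to the first within-participants experiment:
#' power-law retention with the published fitted parameters
#' (deep `a = 2.47, b = 0.36`; shallow `a = 1.99, b = 0.44`), log-normal RT
#' location matching the printed encoding RT means (2937 ms deep, 2115 ms
#' shallow at `sdlog = 0.4`). Note `criterion_mean` is the raw evidence
#' threshold, not the measured bias index: an observer unbiased in the
#' `c = -0.5 (z(H) + z(FA))` sense places the threshold near half the
#' immediate discriminability, hence the default of 1.1. `sd_a`,
#' `criterion_mean/sd` and `p_inattentive` have no published counterparts
#' and are fixed calibration choices (see the package vignette).
#'
#' @param retention_form Retention function per level: a single form name or
#'   a named vector `c(deep = ..., shallow = ...)`; see [retention_forms()].
#' @param a_deep,a_shallow Latent initial discriminability (d-prime units),
#'   positive.
#' @param b_deep,b_shallow Slope parameters (form-specific units).
#' @param sd_a Between-participant SD of the intercept deviation (d-prime
#'   units), non-negative.
#' @param criterion_mean,criterion_sd Criterion distribution (c units).
#' @param rt_meanlog Log-ms location of the RT distribution: scalar or named
#'   vector `c(deep = ..., shallow = ...)`.
#' @param rt_sdlog Log-ms scale of the RT distribution: scalar or named
#'   vector.
#' @param p_inattentive Probability a participant is an inattentive
#'   coin-flip responder, in `[0, 1)`.
#' @param seed Integer seed; mandatory for simulation.
#' @return An object of class `generative_params`.
#' @export
generative_params <- function(retention_form = "power",
                              a_deep = 2.47, a_shallow = 1.99,
                              b_deep = 0.36, b_shallow = 0.44,
                              sd_a = 0.25,
                              criterion_mean = 1.10, criterion_sd = 0.30,
                              rt_meanlog = c(deep = log(2937) - 0.08,
                                             shallow = log(2115) - 0.08),
                              rt_sdlog = 0.4,
                              p_inattentive = 0.03,
                              seed = NULL) {
  form <- .per_level(retention_form, "retention_form")
  for (f in form) match.arg(f, retention_forms())
  stopifnot(a_deep > 0, a_shallow > 0, sd_a >= 0, criterion_sd >= 0,
            p_inattentive >= 0, p_inattentive < 1)
  structure(
    list(retention_form = form,
         a = c(deep = a_deep, shallow = a_shallow),
         b = c(deep = b_deep, shallow = b_shallow),
         sd_a = sd_a,
         criterion_mean = criterion_mean, criterion_sd = criterion_sd,
         rt_meanlog = .per_level(rt_meanlog, "rt_meanlog"),
         rt_sdlog = .per_level(rt_sdlog, "rt_sdlog"),
         p_inattentive = p_inattentive,
         seed = seed),
    class = "generative_params"
  )
}

.per_level <- function(x, what) {
  if (length(x) == 1) return(stats::setNames(rep(x, 2), c("deep", "shallow")))
  if (length(x) == 2 && all(c("deep", "shallow") %in% names(x))) {
    return(x[c("deep", "shallow")])
  }
  stop(what, " must be a scalar or a named vector with elements 'deep' and 'shallow'")
}

.check_count <- function(x) {
  nm <- deparse(substitute(x))
  if (!is.numeric(x) || length(x) != 1 || !is.finite(x) || x < 1 || x != round(x)) {
    stop(nm, " must be a positive integer")
  }
}

#' Simulate a trial-level recognition dataset
#'
#' Draws a full trial table with the statistical structure the analysis
#' pipeline assumes (see [generative_params()] for the generative model).
#' Targets of each level are randomly split between the immediate and
#' delayed tests per participant; each phase uses fresh distractors, so no
#' item appears in both phases. Fully reproducible: the same design, params
#' and seed give a byte-identical table.
#'
#' @param design A [study_design()].
#' @param params A [generative_params()]; `params$seed` must be set.
#' @return A trial table data.frame with columns `participant_id`,
#'   `lop_condition`, `delay_group`, `phase`, `delay_hours`, `item_id`,
#'   `item_role`, `response`, `rt_ms` (one row per test trial).
#' @export
#' @examples
#' trials <- simulate_study(exp1_design(), generative_params(seed = 42))
#' head(trials)
simulate_study <- function(design, params) {
  stopifnot(inherits(design, "study_design"), inherits(params, "generative_params"))
  if (is.null(params$seed)) stop("params$seed is mandatory for simulation")
  set.seed(params$seed)

  G <- length(design$delay_groups)
  labels <- names(design$delay_groups)
  tpp <- design$targets_per_level_per_phase
  dpp <- design$distractors_per_phase
  within <- design$lop_design == "within"
  npg <- design$participants_per_group

  if (within) {
    P <- G * npg
    group_of <- rep(seq_len(G), each = npg)
    level_of <- NULL                      # both levels per participant
    n_tgt_phase <- 2L * tpp               # tpp deep + tpp shallow
  } else {
    P <- 2L * G * npg
    grid <- expand.grid(group = seq_len(G), level = c("deep", "shallow"),
                        stringsAsFactors = FALSE)
    group_of <- rep(grid$group, each = npg)
    level_of <- rep(grid$level, each = npg)
    n_tgt_phase <- tpp
  }
  rows_per_phase <- n_tgt_phase + dpp
  rpp <- 2L * rows_per_phase
  n <- P * rpp
  width <- max(3L, nchar(as.character(P)))
  pids <- sprintf(paste0("P%0", width, "d"), seq_len(P))

  # participant-level draws (fixed order for reproducibility)
  delta <- stats::rnorm(P, 0, params$sd_a)
  crit <- stats::rnorm(P, params$criterion_mean, params$criterion_sd)
  inattentive <- stats::runif(P) < params$p_inattentive

  # per-participant random split of each level's targets across phases
  tgt_split <- lapply(seq_len(P), function(i) {
    if (within) list(deep = sample.int(2L * tpp), shallow = sample.int(2L * tpp))
    else list(own = sample.int(2L * tpp))
  })

  # row skeleton (identical layout for every participant)
  phase1 <- rep(c("immediate", "delayed"), each = rows_per_phase)
  role1 <- rep(rep(c("target", "distractor"), c(n_tgt_phase, dpp)), 2L)
  if (within) {
    lev_phase <- c(rep(c("deep", "shallow"), each = tpp),
                   rep(c("deep", "shallow"), each = dpp / 2L))
    lev1 <- rep(lev_phase, 2L)
  }

  pid_row <- rep(seq_len(P), each = rpp)
  phase <- rep(phase1, P)
  role <- rep(role1, P)
  level <- if (within) rep(lev1, P) else level_of[pid_row]

  # item identifiers: targets carry the per-participant phase assignment;
  # distractors are fresh per phase by construction
  item <- character(n)
  is_tgt <- role == "target"
  if (within) {
    tgt_idx <- unlist(lapply(tgt_split, function(s) {
      c(s$deep[seq_len(tpp)], s$shallow[seq_len(tpp)],          # immediate
        s$deep[tpp + seq_len(tpp)], s$shallow[tpp + seq_len(tpp)])  # delayed
    }), use.names = FALSE)
    tgt_lev <- rep(rep(c("deep", "shallow"), each = tpp), 2L * P)
    item[is_tgt] <- sprintf("t_%s_%02d", substr(tgt_lev, 1, 1), tgt_idx)
  } else {
    tgt_idx <- unlist(lapply(tgt_split, `[[`, "own"), use.names = FALSE)
    item[is_tgt] <- sprintf("t_%02d", tgt_idx)
  }
  d_phase_offset <- ifelse(phase[!is_tgt] == "immediate", 0L, dpp)
  item[!is_tgt] <- sprintf("d_%03d", d_phase_offset +
                             rep(seq_len(dpp), 2L * P))

  # latent discriminability per row
  a_mat <- cbind(deep = pmax(0, params$a["deep"] + delta),
                 shallow = pmax(0, params$a["shallow"] + delta))
  t_del <- design$delay_groups[group_of]
  t_row <- ifelse(phase == "immediate", 0, t_del[pid_row])
  dprime_row <- numeric(n)
  for (lev in c("deep", "shallow")) {
    idx <- level == lev
    if (!any(idx)) next
    dprime_row[idx] <- pmax(0, evaluate_retention(
      params$retention_form[[lev]],
      a = a_mat[pid_row[idx], lev],
      b = params$b[[lev]],
      t = t_row[idx]
    ))
  }

  # responses: evidence vs criterion; inattentive participants flip coins
  mu <- ifelse(is_tgt, dprime_row, 0)
  say_old <- (stats::rnorm(n) + mu) > crit[pid_row]
  inatt_row <- inattentive[pid_row]
  if (any(inatt_row)) {
    say_old[inatt_row] <- stats::runif(sum(inatt_row)) < 0.5
  }

  # truncated log-normal response times per level
  mulog <- params$rt_meanlog[level]
  sdlog <- params$rt_sdlog[level]
  cap <- stats::plnorm(design$encoding_time_limit_ms, mulog, sdlog)
  rt <- stats::qlnorm(stats::runif(n) * cap, mulog, sdlog)

  data.frame(
    participant_id = pids[pid_row],
    lop_condition = level,
    delay_group = labels[group_of[pid_row]],
    phase = phase,
    delay_hours = unname(t_row),
    item_id = item,
    item_role = role,
    response = ifelse(say_old, "old", "new"),
    rt_ms = unname(rt),
    stringsAsFactors = FALSE
  )
}

#' Read and write trial tables as CSV
#'
#' The on-disk format is a plain CSV with the fixed column order
#' `participant_id, lop_condition, delay_group, phase, delay_hours, item_id,
#' item_role, response, rt_ms`.
#'
#' @param trials A trial table data.frame.
#' @param path File path.
#' @return `write_trial_table()` returns `path` invisibly;
#'   `read_trial_table()` returns the trial table.
#' @export
write_trial_table <- function(trials, path) {
  .check_trial_columns(trials)
  utils::write.csv(trials[, .trial_columns], path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_trial_table
#' @export
read_trial_table <- function(path) {
  trials <- utils::read.csv(path, stringsAsFactors = FALSE,
                            colClasses = c(participant_id = "character",
                                           item_id = "character"))
  .check_trial_columns(trials)
  trials
}
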