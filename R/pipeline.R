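#' Validate a trial table
#'
#' Schema and invariant checks for trial-level recognition data: required
#' columns, legal factor values, delay/phase consistency (`delay_hours = 0`
#' exactly for immediate rows, positive for delayed rows), no item tested in
#' both phases for the same participant, and -- when a [study_design()] is
#' supplied -- per-phase target and distractor counts and delay-group
#' labels/delays against the declared design.
#'
#' @param trials A trial table data.frame or a path to a trial-table CSV.
#' @param design Optional [study_design()] to check counts against.
#' @return A data.frame of diagnostics with columns `check` and `detail`;
#'   zero rows means the table passed every check.
#' @export
validate_trial_table <- function(trials, design = NULL) {
  if (is.character(trials)) trials <- read_trial_table(trials)
  diags <- list()
  add <- function(check, detail) {
    diags[[length(diags) + 1]] <<- data.frame(check = check, detail = detail,
                                              stringsAsFactors = FALSE)
  }

  missing <- setdiff(.trial_columns, names(trials))
  if (length(missing)) {
    add("columns", paste("missing:", paste(missing, collapse = ", ")))
    return(do.call(rbind, diags))
  }

  enums <- list(lop_condition = c("deep", "shallow"),
                phase = c("immediate", "delayed"),
                item_role = c("target", "distractor"),
                response = c("old", "new"))
  for (col in names(enums)) {
    bad <- !trials[[col]] %in% enums[[col]]
    if (any(bad)) {
      add(paste0("enum:", col),
          sprintf("%d row(s) outside {%s}; first rows: %s", sum(bad),
                  paste(enums[[col]], collapse = ", "),
                  .first_rows(which(bad))))
    }
  }

  imm <- trials$phase == "immediate"
  bad0 <- imm & trials$delay_hours != 0
  if (any(bad0)) {
    add("delay:immediate",
        sprintf("%d immediate row(s) with delay_hours != 0; rows: %s",
                sum(bad0), .first_rows(which(bad0))))
  }
  badd <- !imm & trials$delay_hours <= 0
  if (any(badd)) {
    add("delay:delayed",
        sprintf("%d delayed row(s) with delay_hours <= 0; rows: %s",
                sum(badd), .first_rows(which(badd))))
  }

  both <- tapply(seq_len(nrow(trials)), trials$participant_id, function(i) {
    intersect(trials$item_id[i][trials$phase[i] == "immediate"],
              trials$item_id[i][trials$phase[i] == "delayed"])
  })
  hit <- vapply(both, length, integer(1)) > 0
  if (any(hit)) {
    for (p in names(both)[hit]) {
      add("item:both_phases",
          sprintf("participant %s: item(s) %s tested in both phases", p,
                  paste(both[[p]], collapse = ", ")))
    }
  }

  if (!is.null(design)) {
    stopifnot(inherits(design, "study_design"))
    labs <- names(design$delay_groups)
    badg <- !trials$delay_group %in% labs
    if (any(badg)) {
      add("design:group_label",
          sprintf("%d row(s) with delay_group outside {%s}", sum(badg),
                  paste(labs, collapse = ", ")))
    }
    del <- trials[!imm & trials$delay_group %in% labs, , drop = FALSE]
    wrong <- del$delay_hours != design$delay_groups[del$delay_group]
    if (any(wrong)) {
      add("design:delay_value",
          sprintf("%d delayed row(s) whose delay_hours do not match their group",
                  sum(wrong)))
    }
    tpp <- design$targets_per_level_per_phase
    exp_tgt <- if (design$lop_design == "within") 2L * tpp else tpp
    key <- interaction(trials$participant_id, trials$phase, drop = TRUE)
    n_tgt <- tapply(trials$item_role == "target", key, sum)
    n_dis <- tapply(trials$item_role == "distractor", key, sum)
    off <- n_tgt != exp_tgt | n_dis != design$distractors_per_phase
    if (any(off)) {
      add("design:counts",
          sprintf("%d participant-phase block(s) with unexpected counts: %s",
                  sum(off), paste(utils::head(names(off)[off], 10), collapse = ", ")))
    }
  }

  if (length(diags)) do.call(rbind, diags)
  else data.frame(check = character(), detail = character(),
                  stringsAsFactors = FALSE)
}

.first_rows <- function(idx, k = 10) {
  paste(utils::head(idx, k), collapse = ",")
}

#' Read a cell-summary table
#'
#' Cell-summary CSVs carry per-cell d-prime statistics, the shape in which
#' published results tables print them, with columns `level`, `label`,
#' `delay_hours`, `n`, `mean_dprime`, `se_dprime`. They are first-class
#' pipeline inputs: weighted least-squares fits to cell means with weights
#' `n` reproduce trial-level fits exactly, and within-cell variability is
#' reconstructed from the standard errors (see [reconstruct_within_ss()]).
#'
#' @param path CSV path.
#' @return The validated cell-summary data.frame.
#' @export
read_cell_summary <- function(path) {
  cs <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("level", "label", "delay_hours", "n", "mean_dprime", "se_dprime")
  missing <- setdiff(need, names(cs))
  if (length(missing)) {
    stop("cell summary is missing column(s): ", paste(missing, collapse = ", "))
  }
  stopifnot(all(cs$n >= 1), all(cs$delay_hours >= 0), all(cs$se_dprime >= 0))
  cs
}

#' Bundled cell summaries from a published levels-of-processing study
#'
#' Mean d-prime, standard error and sample size per encoding level and
#' retention interval for the three experiments of a published
#' levels-of-processing forgetting study (within-participants encoding
#' manipulation with 0.5/2/24-h delay groups in experiments 1--2,
#' between-participants with 0.5/2/6-h delays in experiment 3). These tables
#' are the package's worked-example inputs for summary-mode refits. Note the
#' experiment-3 table uses the pre-exclusion 20 participants per cell: the
#' published report does not attribute its six excluded participants to
#' delay groups, so exact post-exclusion weights are unavailable; supply
#' your own `n` column to override.
#'
#' @param experiment 1, 2 or 3.
#' @return A cell-summary data.frame (see [read_cell_summary()]).
#' @export
#' @examples
#' lop_cell_summaries(1)
lop_cell_summaries <- function(experiment = 1) {
  stopifnot(experiment %in% 1:3)
  path <- system.file("extdata", sprintf("lop_exp%d_cells.csv", experiment),
                      package = "lopforget", mustWork = TRUE)
  read_cell_summary(path)
}

`%||%` <- function(x, y) if (is.null(x)) y else x

#' Run the full analysis pipeline
#'
#' End-to-end orchestration: obtain a trial table (simulated or from file)
#' or a cell-summary table, score it, apply the exclusion screens, summarise
#' cells, run the ANOVA/Bayes-factor inference, fit the four retention
#' functions per encoding level, and test slope equality between conditions
#' with the likelihood-ratio comparison. All randomness flows from the
#' single `seed` entry of the config; rerunning the same config reproduces
#' the report exactly.
#'
#' The config is a plain list (or the path to a YAML file holding one) with
#' entries:
#' \describe{
#'   \item{mode}{`"simulate"`, `"trials"` (trial-level CSV) or `"summary"`
#'     (cell-summary CSV).}
#'   \item{design}{`"exp1"`, `"exp2"`, `"exp3"` or a list of
#'     [study_design()] arguments (simulate mode; optional validation aid in
#'     trials mode).}
#'   \item{params}{List of [generative_params()] arguments (simulate mode).}
#'   \item{input}{Input CSV path (trials/summary modes).}
#'   \item{seed}{Integer seed; mandatory in simulate mode.}
#'   \item{correction}{Rate-correction mode for [corrected_rates()].}
#'   \item{exclude}{Apply [exclude_participants()]? Default TRUE.}
#'   \item{forms}{Retention forms to fit; default all four.}
#'   \item{form}{Form used for the slope comparison; default the best
#'     (lowest-AIC) form across the two conditions.}
#'   \item{constrain}{List with `donor` and `target` levels; default the
#'     deep-condition slope imposed on the shallow condition.}
#'   \item{out_dir}{Optional directory for CSV/JSON outputs.}
#' }
#'
#' @param config A list or YAML file path as described above.
#' @return A list of class `lop_report`: `cell_summary`, `ranking` (per
#'   level goodness-of-fit tables), `fits`, `slope_comparison`, `anova`
#'   (immediate/delayed d-prime and log-RT tables), `bayes`, `posthoc`,
#'   `exclusions`, `diagnostics`, and `provenance` (config hash, package
#'   version, seed, conventions used).
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  stopifnot(is.list(config))
  mode <- match.arg(config$mode, c("simulate", "trials", "summary"))
  correction <- config$correction %||% "loglinear_all"
  forms <- config$forms %||% retention_forms()
  constrain <- config$constrain %||% list(donor = "deep", target = "shallow")

  provenance <- list(
    config_hash = .config_hash(config),
    package = paste("lopforget", as.character(utils::packageVersion("lopforget"))),
    seed = config$seed %||% NA,
    correction = correction,
    ss_type = "II",
    bf_method = "BIC-approximate (unit-information prior)"
  )

  report <- list(provenance = provenance)

  if (mode == "summary") {
    cells <- read_cell_summary(config$input)
    report <- c(report,
                .retention_stage(cells, forms, config$form, constrain,
                                 within_from_se = TRUE))
    report$cell_summary <- cells
    class(report) <- "lop_report"
    .write_report(report, config$out_dir)
    return(report)
  }

  design <- .resolve_design(config$design)
  if (mode == "simulate") {
    if (is.null(config$seed)) stop("config$seed is mandatory when simulating")
    pars <- do.call(generative_params,
                    c(config$params %||% list(), list(seed = config$seed)))
    trials <- simulate_study(design %||% exp1_design(), pars)
  } else {
    trials <- read_trial_table(config$input)
  }
  diagnostics <- validate_trial_table(trials, design)
  if (nrow(diagnostics)) {
    stop("trial table failed validation:\n",
         paste(diagnostics$check, diagnostics$detail, sep = ": ",
               collapse = "\n"))
  }
  report$diagnostics <- diagnostics

  scores <- score_trials(trials, mode = correction)
  if (config$exclude %||% TRUE) {
    excl <- exclude_participants(scores)
    report$exclusions <- excl$exclusions
    scores <- excl$kept_scores
    trials <- trials[trials$participant_id %in% excl$kept, , drop = FALSE]
  } else {
    report$exclusions <- data.frame(participant_id = character(),
                                    reason = character())
  }
  report$scores <- scores
  cells <- summarize_cells(scores)
  report$cell_summary <- cells

  within_design <- is.null(design) || design$lop_design == "within"
  report$anova <- list()
  report$bayes <- list()
  for (ph in c("immediate", "delayed")) {
    sub <- scores[scores$phase == ph, , drop = FALSE]
    if (within_design) {
      report$anova[[paste0("dprime_", ph)]] <-
        mixed_anova(sub, "d_prime", "lop_condition", "delay_group",
                    "participant_id")
      report$bayes[[paste0("dprime_", ph)]] <-
        mixed_anova_bayes(sub, "d_prime", "lop_condition", "delay_group",
                          "participant_id")
    } else {
      report$anova[[paste0("dprime_", ph)]] <-
        factorial_anova(sub, "d_prime", c("lop_condition", "delay_group"))
      report$bayes[[paste0("dprime_", ph)]] <-
        factorial_anova_bayes(sub, "d_prime", c("lop_condition", "delay_group"))
    }
  }
  rt <- log_transform_rt(trials)
  report$anova$log_rt <- if (within_design) {
    mixed_anova(rt, "mean_log_rt", "lop_condition", "delay_group",
                "participant_id")
  } else {
    factorial_anova(rt, "mean_log_rt", c("lop_condition", "delay_group"))
  }

  # delay-group post hocs on delayed performance: Bonferroni-adjusted
  # pairwise t for the mixed designs, Tukey HSD for the between design,
  # on participant-level delayed d-prime (averaged over levels when within)
  del <- scores[scores$phase == "delayed", , drop = FALSE]
  pm <- stats::aggregate(d_prime ~ participant_id + delay_group, del, mean)
  report$posthoc <- if (within_design) {
    bonferroni_pairwise(pm, "d_prime", "delay_group")
  } else {
    tukey_hsd(pm, "d_prime", "delay_group")
  }

  # exact within-cell SS from the retained participant scores
  report <- c(report,
              .retention_stage(cells, forms, config$form, constrain,
                               within_from_se = FALSE, scores = scores))
  class(report) <- "lop_report"
  .write_report(report, config$out_dir)
  report
}

.resolve_design <- function(design) {
  if (is.null(design)) return(NULL)
  if (inherits(design, "study_design")) return(design)
  if (is.character(design)) {
    return(switch(match.arg(design, c("exp1", "exp2", "exp3")),
                  exp1 = exp1_design(), exp2 = exp2_design(),
                  exp3 = exp3_design()))
  }
  if (is.list(design)) {
    if (!is.null(design$delay_groups)) {
      design$delay_groups <- unlist(design$delay_groups)
    }
    return(do.call(study_design, design))
  }
  stop("unrecognised design specification")
}

# Fits, goodness of fit and slope comparison for both encoding levels.
# within_from_se: reconstruct within-cell SS from the printed SEs (summary
# mode); otherwise compute it exactly from the participant scores.
.retention_stage <- function(cells, forms, form, constrain, within_from_se,
                             scores = NULL) {
  levels <- unique(cells$level)
  within_ss <- stats::setNames(numeric(length(levels)), levels)
  rankings <- list()
  for (lv in levels) {
    cc <- cells[cells$level == lv, , drop = FALSE]
    within_ss[lv] <- if (within_from_se) {
      reconstruct_within_ss(cc$n, cc$se_dprime)
    } else {
      .within_ss_from_scores(scores, lv)
    }
    rankings[[lv]] <- fit_all_retention(cc$delay_hours, cc$mean_dprime,
                                        weights = cc$n,
                                        within_ss = within_ss[lv],
                                        forms = forms)
  }
  if (is.null(form)) {
    mean_rank <- rowMeans(vapply(rankings, function(r) {
      r$rank[match(forms, r$form)]
    }, numeric(length(forms))))
    form <- forms[which.min(mean_rank)]
  }

  donor <- constrain$donor %||% "deep"
  target <- constrain$target %||% "shallow"
  stopifnot(donor %in% levels, target %in% levels)
  fit_of <- function(lv) {
    cc <- cells[cells$level == lv, , drop = FALSE]
    fit_retention(form, cc$delay_hours, cc$mean_dprime, weights = cc$n,
                  within_ss = within_ss[lv])
  }
  donor_fit <- fit_of(donor)
  target_fit <- fit_of(target)
  cc <- cells[cells$level == target, , drop = FALSE]
  target_con <- fit_retention_constrained(form, cc$delay_hours,
                                          cc$mean_dprime, weights = cc$n,
                                          b_fixed = donor_fit$b,
                                          within_ss = within_ss[target],
                                          b_source = donor)
  list(
    ranking = rankings,
    within_ss = within_ss,
    selected_form = form,
    fits = stats::setNames(
      list(donor_fit, target_fit, target_con),
      c(paste0(donor, "_unconstrained"), paste0(target, "_unconstrained"),
        paste0(target, "_constrained"))
    ),
    slope_comparison = compare_slopes(target_fit, target_con,
                                      within_ss = within_ss[[target]])
  )
}

.within_ss_from_scores <- function(scores, lv) {
  s <- scores[scores$lop_condition == lv, , drop = FALSE]
  label <- ifelse(s$phase == "immediate", "immediate",
                  as.character(s$delay_group))
  sum(unlist(lapply(split(s$d_prime, label), function(d) sum((d - mean(d))^2))))
}

.config_hash <- function(config) {
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  keys <- order(names(config))
  writeLines(jsonlite::toJSON(config[keys], auto_unbox = TRUE, digits = NA,
                              null = "null", force = TRUE), tmp)
  unname(tools::md5sum(tmp))
}

.write_report <- function(report, out_dir) {
  if (is.null(out_dir)) return(invisible(NULL))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  wcsv <- function(x, name) {
    utils::write.csv(x, file.path(out_dir, paste0(name, ".csv")),
                     row.names = FALSE)
  }
  wcsv(report$cell_summary, "cell_summary")
  if (!is.null(report$exclusions)) wcsv(report$exclusions, "exclusions")
  for (lv in names(report$ranking)) {
    wcsv(as.data.frame(report$ranking[[lv]]), paste0("gof_", lv))
  }
  for (nm in names(report$anova)) {
    wcsv(as.data.frame(report$anova[[nm]]), paste0("anova_", nm))
  }
  if (!is.null(report$posthoc)) wcsv(as.data.frame(report$posthoc), "posthoc")
  fits <- do.call(rbind, lapply(names(report$fits), function(nm) {
    f <- report$fits[[nm]]
    data.frame(fit = nm, form = f$form, a = f$a, b = f$b, se_a = f$se_a,
               se_b = f$se_b, rss = f$rss, n_obs = f$n_obs,
               stringsAsFactors = FALSE)
  }))
  wcsv(fits, "fits")
  sc <- report$slope_comparison
  json <- list(
    provenance = report$provenance,
    selected_form = report$selected_form,
    within_ss = as.list(report$within_ss),
    slope_comparison = list(chi_square = sc$chi_square, df = sc$df,
                            p_value = sc$p_value, direction = sc$direction,
                            n_obs = sc$n_obs)
  )
  jsonlite::write_json(json, file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(out_dir)
}

#' @export
print.lop_report <- function(x, ...) {
  cat("levels-of-processing forgetting analysis report\n")
  cat("  config hash:", x$provenance$config_hash, "\n")
  if (!is.null(x$exclusions)) {
    cat("  exclusions:", nrow(x$exclusions), "\n")
  }
  cat("  selected retention form:", x$selected_form, "\n")
  for (nm in names(x$fits)) {
    f <- x$fits[[nm]]
    cat(sprintf("  %s: a = %.3f, b = %.3f\n", nm, f$a, f$b))
  }
  print(x$slope_comparison)
  invisible(x)
}
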