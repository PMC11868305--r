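toy_trials <- function() {
  data.frame(
    participant_id = "P1",
    lop_condition = "deep",
    delay_group = "2h",
    phase = "immediate",
    delay_hours = 0,
    item_id = paste0("i", 1:6),
    item_role = c("target", "target", "target", "distractor", "distractor",
                  "distractor"),
    response = c("old", "old", "new", "old", "new", "new"),
    rt_ms = 1000,
    stringsAsFactors = FALSE
  )
}

test_that("counts partition trials exactly", {
  counts <- tabulate_counts(toy_trials())
  expect_equal(counts$hits, 2)
  expect_equal(counts$n_targets, 3)
  expect_equal(counts$false_alarms, 1)
  expect_equal(counts$n_distractors, 3)

  all_new <- toy_trials(); all_new$response <- "new"
  c2 <- tabulate_counts(all_new)
  expect_equal(c2$hits + c2$false_alarms, 0)

  all_old <- toy_trials(); all_old$response <- "old"
  c3 <- tabulate_counts(all_old)
  expect_equal(c3$hits, c3$n_targets)
  expect_equal(c3$false_alarms, c3$n_distractors)
})

test_that("log-linear correction behaves per mode and keeps rates in (0,1)", {
  counts <- data.frame(hits = 10, n_targets = 10, false_alarms = 0,
                       n_distractors = 40)
  all <- corrected_rates(counts, "loglinear_all")
  expect_equal(all$hit_rate, 10.5 / 11)
  expect_equal(all$fa_rate, 0.5 / 41)

  mid <- corrected_rates(data.frame(hits = 5, n_targets = 10,
                                    false_alarms = 20, n_distractors = 40),
                         "loglinear_extremes_only")
  expect_equal(mid$hit_rate, 0.5)
  expect_equal(mid$fa_rate, 0.5)

  zero <- corrected_rates(data.frame(hits = 0, n_targets = 20,
                                     false_alarms = 3, n_distractors = 40),
                          "loglinear_extremes_only")
  expect_equal(zero$hit_rate, 0.5 / 21)
  expect_equal(zero$fa_rate, 3 / 40)

  # correction never reorders two cells' raw rates
  set.seed(5)
  n <- 25
  cc <- data.frame(hits = rbinom(50, n, runif(50)), n_targets = n,
                   false_alarms = rbinom(50, 2 * n, runif(50)),
                   n_distractors = 2 * n)
  for (mode in c("loglinear_all", "loglinear_extremes_only")) {
    cr <- corrected_rates(cc, mode)
    expect_identical(order(cr$hit_rate, cc$hits), order(cc$hits / n, cc$hits))
  }
})

test_that("d-prime and criterion follow the z-transform identities", {
  # no discrimination: d' = 0, c = -z(H)
  s <- sdt_score(c(0.3, 0.6), c(0.3, 0.6))
  expect_equal(s$d_prime, c(0, 0))
  expect_equal(s$criterion, -qnorm(c(0.3, 0.6)))

  # symmetric rates: unbiased criterion
  s2 <- sdt_score(0.8, 0.2)
  expect_equal(s2$criterion, 0)
  expect_equal(s2$d_prime, 2 * qnorm(0.8), tolerance = 1e-10)

  # corrected ceiling cell, against the inverse-normal oracle directly
  s3 <- sdt_score(10.5 / 11, 0.5 / 41)
  expect_equal(s3$d_prime, qnorm(10.5 / 11) - qnorm(0.5 / 41),
               tolerance = 1e-10)
  expect_equal(round(s3$d_prime, 2), 3.94)

  expect_error(sdt_score(1, 0.5), "strictly inside")
  expect_error(sdt_score(0.5, 0), "strictly inside")
})

test_that("d-prime is antisymmetric in (H, FA) and monotone in each rate", {
  set.seed(8)
  H <- runif(50, 0.05, 0.95)
  FA <- runif(50, 0.05, 0.95)
  fwd <- sdt_score(H, FA)
  rev <- sdt_score(FA, H)
  expect_equal(rev$d_prime, -fwd$d_prime)
  expect_equal(rev$criterion, fwd$criterion)  # c is symmetric in (H, FA)

  hs <- seq(0.05, 0.95, by = 0.05)
  expect_true(all(diff(sdt_score(hs, 0.2)$d_prime) > 0))
  expect_true(all(diff(sdt_score(0.8, hs)$d_prime) < 0))
})

test_that("chance-level responders are excluded with a machine-readable reason", {
  # an all-"old" responder has equal corrected H and FA, hence d' = 0 exactly
  tr <- simulate_study(study_design(participants_per_group = 5),
                       generative_params(p_inattentive = 0, seed = 301))
  flat <- tr$participant_id == "P001"
  tr$response[flat] <- "old"
  res <- exclude_participants(score_trials(tr))
  expect_true("P001" %in% res$exclusions$participant_id)
  expect_true("chance_level" %in%
                res$exclusions$reason[res$exclusions$participant_id == "P001"])
  expect_false("P001" %in% res$kept)
})

test_that("the 2.5-SD screen flags exactly the planted rate outlier", {
  set.seed(21)
  n <- 30
  hit <- pmin(pmax(rnorm(n, 0.85, 0.03), 0.6), 0.97)
  fa <- pmin(pmax(rnorm(n, 0.12, 0.02), 0.03), 0.30)
  fa[17] <- 0.12 + 6 * sd(fa[-17])  # far beyond the 2.5-SD fence
  sc <- make_scores(sprintf("P%02d", 1:n), hit, fa)
  res <- exclude_participants(sc)
  expect_identical(res$exclusions$participant_id, "P17")
  expect_identical(res$exclusions$reason, "fa_rate_outlier")
  # direct z-score cross-check
  expect_gt(abs(fa[17] - mean(fa)) / sd(fa), 2.5)

  # identical rates: zero SD handled as "no outliers"
  same <- make_scores(sprintf("P%02d", 1:10), 0.8, 0.1)
  expect_equal(nrow(exclude_participants(same)$exclusions), 0)

  # too few participants: screen skipped with a warning
  two <- make_scores(c("A", "B"), c(0.9, 0.5), c(0.1, 0.4))
  expect_warning(exclude_participants(two), "skipped")
})

test_that("cell summaries report n, mean and SE in published-table shape", {
  sc <- rbind(
    make_scores(c("A", "B"), c(0.8, 0.9), c(0.2, 0.1)),
    make_scores(c("A", "B"), c(0.7, 0.8), c(0.3, 0.2), phase = "delayed")
  )
  sc$d_prime <- c(1.0, 2.0, 0.5, 1.5)  # fix scores for hand arithmetic
  cells <- summarize_cells(sc)
  imm <- cells[cells$label == "immediate", ]
  expect_equal(imm$n, 2)
  expect_equal(imm$mean_dprime, 1.5)
  expect_equal(imm$se_dprime, 0.5)

  solo <- make_scores("A", 0.8, 0.2)
  expect_warning(cs <- summarize_cells(solo), "single participant")
  expect_true(is.na(cs$se_dprime))
})
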