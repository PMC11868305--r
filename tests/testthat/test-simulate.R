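test_that("designs and params validate their invariants", {
  expect_error(study_design(delay_groups = c("a" = 2, "b" = 1)),
               "strictly increasing")
  expect_error(study_design(delay_groups = c("a" = 1, "a" = 2)), "unique")
  expect_error(study_design(participants_per_group = 0), "positive integer")
  expect_error(study_design(distractors_per_phase = 41), "even")
  expect_error(generative_params(retention_form = "hyperbolic"))
  expect_error(generative_params(a_deep = -1))
  expect_error(generative_params(p_inattentive = 1))
  expect_error(simulate_study(exp1_design(), generative_params()),
               "seed is mandatory")
})

test_that("the same seed reproduces a byte-identical trial table", {
  d <- study_design(participants_per_group = 4)
  p <- generative_params(seed = 99)
  expect_identical(simulate_study(d, p), simulate_study(d, p))
  # and a different seed does not
  p2 <- generative_params(seed = 100)
  expect_false(identical(simulate_study(d, p), simulate_study(d, p2)))
})

test_that("simulated tables satisfy the trial-table invariants", {
  for (spec in list(list(d = study_design(participants_per_group = 3), s = 1),
                    list(d = exp3_design(), s = 2))) {
    design <- spec$d
    design$participants_per_group <- 3L
    tr <- simulate_study(design, generative_params(seed = spec$s))
    diags <- validate_trial_table(tr, design)
    expect_equal(nrow(diags), 0)
    # per-level target counts in the within design
    if (design$lop_design == "within") {
      one <- tr[tr$participant_id == tr$participant_id[1] &
                  tr$phase == "immediate", ]
      expect_equal(sum(one$item_role == "target" & one$lop_condition == "deep"),
                   design$targets_per_level_per_phase)
    }
  }
})

test_that("a flat retention law yields delay-independent discriminability", {
  p <- generative_params(b_deep = 0, b_shallow = 0, sd_a = 0,
                         p_inattentive = 0, seed = 17)
  tr <- simulate_study(study_design(participants_per_group = 60), p)
  sc <- score_trials(tr)
  m <- tapply(sc$d_prime, list(sc$phase, sc$lop_condition), mean)
  # immediate and delayed cells estimate the same latent value; only
  # binomial sampling noise separates them
  expect_lt(abs(m["immediate", "deep"] - m["delayed", "deep"]), 0.15)
  expect_lt(abs(m["immediate", "shallow"] - m["delayed", "shallow"]), 0.15)
})

test_that("recovered d-prime matches the closed-form latent value", {
  # power form, a = 2, b = 0.4, no heterogeneity, criterion at 0:
  # latent d'(2 h) = 2 * 3^(-0.4); 200 targets + 200 distractors per phase
  # make per-participant estimates nearly unbiased
  d <- study_design("between", delay_groups = c("2h" = 2),
                    participants_per_group = 500,
                    targets_per_level_per_phase = 200,
                    distractors_per_phase = 200)
  p <- generative_params(a_deep = 2, a_shallow = 2, b_deep = 0.4,
                         b_shallow = 0.4, sd_a = 0, criterion_mean = 0,
                         criterion_sd = 0, p_inattentive = 0, seed = 11)
  sc <- score_trials(simulate_study(d, p))
  del <- sc$d_prime[sc$phase == "delayed"]
  expect_equal(mean(del), 2 * 3^(-0.4), tolerance = 0.05 / (2 * 3^(-0.4)))

  # marginal "old" rate for distractors is 1 - Phi(criterion)
  p2 <- generative_params(criterion_mean = 0.8, criterion_sd = 0,
                          p_inattentive = 0, seed = 12)
  tr2 <- simulate_study(study_design(participants_per_group = 30), p2)
  dis <- tr2[tr2$item_role == "distractor", ]
  expect_lt(abs(mean(dis$response == "old") - (1 - pnorm(0.8))), 0.02)
})

test_that("response times respect the encoding window and level locations", {
  tr <- simulate_study(study_design(participants_per_group = 20),
                       generative_params(seed = 5))
  expect_true(all(tr$rt_ms > 0 & tr$rt_ms <= 5000))
  rt <- log_transform_rt(tr)
  m <- tapply(rt$mean_log_rt, rt$lop_condition, mean)
  expect_gt(m["deep"], m["shallow"])  # semantic judgements are slower
})

test_that("trial tables round-trip through CSV", {
  tr <- simulate_study(study_design(participants_per_group = 2),
                       generative_params(seed = 3))
  path <- withr::local_tempfile(fileext = ".csv")
  write_trial_table(tr, path)
  back <- read_trial_table(path)
  expect_equal(back, tr, tolerance = 1e-12)
})

test_that("validation diagnostics name planted violations", {
  tr <- simulate_study(study_design(participants_per_group = 2),
                       generative_params(seed = 4))
  expect_equal(nrow(validate_trial_table(tr)), 0)

  bad <- tr
  bad$delay_hours[bad$phase == "delayed"][1:3] <- 0
  d1 <- validate_trial_table(bad)
  expect_true(any(d1$check == "delay:delayed"))

  bad2 <- tr
  imm_tgt <- which(bad2$phase == "immediate" & bad2$item_role == "target" &
                     bad2$participant_id == "P001")[1]
  del_tgt <- which(bad2$phase == "delayed" & bad2$item_role == "target" &
                     bad2$participant_id == "P001")[1]
  bad2$item_id[del_tgt] <- bad2$item_id[imm_tgt]
  d2 <- validate_trial_table(bad2)
  expect_true(any(d2$check == "item:both_phases"))
  expect_match(d2$detail[d2$check == "item:both_phases"], "P001")

  bad3 <- tr
  bad3$response[1] <- "maybe"
  expect_true(any(validate_trial_table(bad3)$check == "enum:response"))
})
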