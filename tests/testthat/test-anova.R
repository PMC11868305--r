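test_that("split-plot SS match hand formulas and aov strata on a balanced fixture", {
  # 3 delay groups x 4 participants x 2 levels, fixed values
  set.seed(42)
  cells <- list(
    matrix(c(2.6, 2.1, 2.4, 1.9, 2.8, 2.0, 2.2, 1.8), 4, 2, byrow = TRUE),
    matrix(c(1.8, 1.3, 1.6, 1.2, 2.0, 1.1, 1.7, 1.4), 4, 2, byrow = TRUE),
    matrix(c(1.2, 0.7, 1.0, 0.5, 1.4, 0.8, 0.9, 0.6), 4, 2, byrow = TRUE)
  )
  d <- make_split_plot_data(cells, 4)
  tab <- mixed_anova(d, "d_prime", "lop_condition", "delay_group",
                     "participant_id")

  # textbook sums of squares computed from scratch
  y <- d$d_prime
  grand <- mean(y)
  msub <- tapply(y, d$participant_id, mean)
  mgrp <- tapply(y, d$delay_group, mean)
  mlev <- tapply(y, d$lop_condition, mean)
  mcell <- tapply(y, list(d$delay_group, d$lop_condition), mean)
  ss_sub <- 2 * sum((msub - grand)^2)
  ss_grp <- 8 * sum((mgrp - grand)^2)
  ss_lev <- 12 * sum((mlev - grand)^2)
  ss_cell <- 4 * sum((mcell - grand)^2)
  expect_equal(tab$ss[tab$effect == "delay_group"], ss_grp, tolerance = 1e-10)
  expect_equal(tab$ss[tab$effect == "participant(delay_group)"],
               ss_sub - ss_grp, tolerance = 1e-10)
  expect_equal(tab$ss[tab$effect == "lop_condition"], ss_lev, tolerance = 1e-10)
  expect_equal(tab$ss[tab$effect == "delay_group:lop_condition"],
               ss_cell - ss_grp - ss_lev, tolerance = 1e-10)
  expect_equal(tab$ss[tab$effect == "residual(within)"],
               sum((y - grand)^2) - ss_cell - (ss_sub - ss_grp),
               tolerance = 1e-10)

  # independent route: base-R aov() error strata
  or <- aov_split_plot_ss(d, "d_prime", "lop_condition", "delay_group",
                          "participant_id")
  expect_equal(tab$ss[tab$effect == "delay_group"], or$ss_group, tolerance = 1e-10)
  expect_equal(tab$ss[tab$effect == "lop_condition"], or$ss_level, tolerance = 1e-10)
  expect_equal(tab$f[tab$effect == "delay_group:lop_condition"], or$f_int,
               tolerance = 1e-10)

  # partial eta squared identity on every emitted effect
  err_b <- tab$ss[tab$effect == "participant(delay_group)"]
  err_w <- tab$ss[tab$effect == "residual(within)"]
  expect_equal(tab$partial_eta_sq[1], tab$ss[1] / (tab$ss[1] + err_b))
  expect_equal(tab$partial_eta_sq[3], tab$ss[3] / (tab$ss[3] + err_w))
  expect_true(all(stats::na.omit(tab$partial_eta_sq) >= 0 &
                    stats::na.omit(tab$partial_eta_sq) <= 1))
})

test_that("null constructions give zero F", {
  # within-participant level differences balanced to exactly zero mean in
  # every group: level and interaction SS vanish while residual noise stays
  set.seed(9)
  cells <- lapply(1:3, function(g) {
    base <- rnorm(4, 2 - 0.3 * g, 0.5)
    diffs <- c(0.2, 0.2, -0.2, -0.2)
    cbind(base, base + diffs)
  })
  d <- make_split_plot_data(cells, 4)
  tab <- mixed_anova(d, "d_prime", "lop_condition", "delay_group",
                     "participant_id")
  expect_lt(abs(tab$f[tab$effect == "lop_condition"]), 1e-10)
  expect_lt(abs(tab$f[tab$effect == "delay_group:lop_condition"]), 1e-10)
  expect_gt(tab$ss[tab$effect == "residual(within)"], 0)

  # balanced factorial with equal cell means: all effect F vanish
  fd <- expand.grid(lop = c("deep", "shallow"), grp = c("a", "b", "c"),
                    rep = 1:4)
  fd$y <- rnorm(nrow(fd), 0, 0.5)
  fd$y <- fd$y - stats::ave(fd$y, fd$lop, fd$grp) + 1  # flatten cell means
  tab2 <- factorial_anova(fd, "y", c("lop", "grp"))
  expect_true(all(abs(tab2$f[1:3]) < 1e-10))
})

test_that("stratum sums of squares conserve the total", {
  set.seed(31)
  for (sizes in list(c(6, 6, 6), c(5, 8, 11))) {
    cells <- lapply(sizes, function(n) matrix(rnorm(2 * n, 1.5, 0.6), n, 2))
    d <- make_split_plot_data(cells, sizes)
    tab <- mixed_anova(d, "d_prime", "lop_condition", "delay_group",
                       "participant_id")
    expect_equal(sum(tab$ss), sum((d$d_prime - mean(d$d_prime))^2),
                 tolerance = 1e-10)
  }
})

test_that("Type II equals Type I on balanced data and is order-invariant", {
  set.seed(12)
  fd <- expand.grid(lop = c("deep", "shallow"), grp = c("a", "b", "c"),
                    rep = 1:5)
  fd$y <- rnorm(nrow(fd), 1.5, 0.4) + (fd$lop == "deep") * 0.5
  tab <- factorial_anova(fd, "y", c("lop", "grp"))
  t1 <- stats::anova(stats::lm(y ~ lop * grp, fd))
  expect_equal(tab$ss[tab$effect == "lop"], t1["lop", "Sum Sq"],
               tolerance = 1e-10)
  expect_equal(tab$ss[tab$effect == "grp"], t1["grp", "Sum Sq"],
               tolerance = 1e-10)
  swapped <- factorial_anova(fd, "y", c("grp", "lop"))
  expect_equal(sort(tab$ss), sort(swapped$ss), tolerance = 1e-12)
})

test_that("Type II SS on unbalanced data match the car::Anova oracle", {
  set.seed(13)
  n_cell <- c(4, 7, 5, 9, 6, 8)
  fd <- do.call(rbind, Map(function(l, g, n) {
    data.frame(lop = l, grp = g, y = rnorm(n, 1 + (l == "deep") * 0.4, 0.5))
  }, rep(c("deep", "shallow"), 3), rep(c("a", "b", "c"), each = 2), n_cell))
  tab <- factorial_anova(fd, "y", c("lop", "grp"))
  oracle <- car::Anova(stats::lm(y ~ lop * grp, fd), type = 2)
  expect_equal(tab$ss[tab$effect == "lop"], oracle["lop", "Sum Sq"],
               tolerance = 1e-10)
  expect_equal(tab$ss[tab$effect == "grp"], oracle["grp", "Sum Sq"],
               tolerance = 1e-10)
  expect_equal(tab$ss[tab$effect == "lop:grp"], oracle["lop:grp", "Sum Sq"],
               tolerance = 1e-10)
  expect_equal(tab$p[1:3],
               oracle[c("lop", "grp", "lop:grp"), "Pr(>F)"],
               tolerance = 1e-10, ignore_attr = TRUE)
})

test_that("participants with missing cells are dropped listwise", {
  cells <- list(matrix(rnorm(8), 4, 2), matrix(rnorm(8), 4, 2))
  d <- make_split_plot_data(cells, 4)
  d <- d[-1, ]  # S001 loses one level
  expect_warning(tab <- mixed_anova(d, "d_prime", "lop_condition",
                                    "delay_group", "participant_id"),
                 "listwise")
  expect_equal(tab$df[tab$effect == "participant(delay_group)"], 7 - 2)
})
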