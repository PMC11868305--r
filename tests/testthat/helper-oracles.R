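# Independent oracles and fixture builders shared across the test files.

# Brute-force grid search for the weighted power-law fit over an (a, b)
# lattice. For each grid slope the weighted RSS is quadratic in a, so the
# lattice minimum in a is attained at one of the two lattice points
# bracketing the continuous conditional optimum; evaluating just those two
# is an exact shortcut of the full scan.
grid_fit_power <- function(t, y, w, a_range = c(0, 4), b_range = c(0, 2),
                           step = 1e-3) {
  bs <- seq(b_range[1], b_range[2], by = step)
  best <- c(a = NA_real_, b = NA_real_, rss = Inf)
  for (b in bs) {
    u <- (t + 1)^(-b)
    s1 <- sum(w * y * u)
    s2 <- sum(w * u^2)
    a_star <- s1 / s2
    cands <- unique(pmin(pmax(
      c(floor(a_star / step), ceiling(a_star / step)) * step,
      a_range[1]), a_range[2]))
    for (a in cands) {
      rss <- sum(w * (y - a * u)^2)
      if (rss < best["rss"]) best <- c(a = a, b = b, rss = rss)
    }
  }
  best
}

# Split-plot sums of squares via base-R aov() error strata (independent of
# the package's own decomposition).
aov_split_plot_ss <- function(data, dv, within, between, id) {
  d <- data.frame(y = data[[dv]], lev = factor(data[[within]]),
                  grp = factor(data[[between]]), subj = factor(data[[id]]))
  fit <- stats::aov(y ~ grp * lev + Error(subj/lev), data = d)
  s <- summary(fit)
  btw <- s[["Error: subj"]][[1]]
  wth <- s[["Error: subj:lev"]][[1]]
  list(
    ss_group = btw["grp", "Sum Sq"],
    ss_swg = btw["Residuals", "Sum Sq"],
    ss_level = wth["lev", "Sum Sq"],
    ss_int = wth["grp:lev", "Sum Sq"],
    ss_werr = wth["Residuals", "Sum Sq"],
    f_group = btw["grp", "F value"],
    f_level = wth["lev", "F value"],
    f_int = wth["grp:lev", "F value"]
  )
}

# Long-format scores for a 2-level within x G-group split-plot design.
make_split_plot_data <- function(y_by_cell, n_per_group) {
  # y_by_cell: list of groups, each a matrix n x 2 (columns = levels)
  rows <- list()
  pid <- 0
  for (g in seq_along(y_by_cell)) {
    m <- y_by_cell[[g]]
    for (i in seq_len(nrow(m))) {
      pid <- pid + 1
      rows[[length(rows) + 1]] <- data.frame(
        participant_id = sprintf("S%03d", pid),
        delay_group = paste0("g", g),
        lop_condition = c("deep", "shallow"),
        d_prime = as.numeric(m[i, ]),
        stringsAsFactors = FALSE
      )
    }
  }
  do.call(rbind, rows)
}

# Minimal synthetic scores table (one row per participant x level x phase)
# for exclusion-rule tests; rates are plugged in directly.
make_scores <- function(ids, hit_rate, fa_rate, phase = "immediate",
                        level = "deep", delay_group = "2h",
                        delay_hours = 2) {
  sc <- data.frame(
    participant_id = ids,
    lop_condition = level,
    delay_group = delay_group,
    phase = phase,
    delay_hours = ifelse(phase == "immediate", 0, delay_hours),
    hit_rate = hit_rate,
    fa_rate = fa_rate,
    stringsAsFactors = FALSE
  )
  cbind(sc, sdt_score(sc$hit_rate, sc$fa_rate))
}

exp1_cells_path <- function() {
  system.file("extdata", "lop_exp1_cells.csv", package = "lopforget")
}

exp2_cells_path <- function() {
  system.file("extdata", "lop_exp2_cells.csv", package = "lopforget")
}
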