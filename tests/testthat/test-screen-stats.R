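test_that("chemotaxis indices follow the printed formulas", {
  expect_equal(chemotaxis_index_quadrant(80, 20), 0.6)
  expect_equal(chemotaxis_index_quadrant(50, 50), 0.0)
  expect_equal(chemotaxis_index_quadrant(0, 100), -1.0)
  expect_warning(na <- chemotaxis_index_quadrant(0, 0), "undefined")
  expect_true(is.na(na))

  expect_equal(chemotaxis_index_distal(30, 10, 100), 0.2)
  expect_equal(chemotaxis_index_distal(0, 0, 100), 0.0)
  expect_equal(chemotaxis_index_distal(60, 0, 60), 1.0)
  expect_true(is.na(chemotaxis_index_distal(0, 0, 0)))
})

test_that("quadrant CI is antisymmetric and range-bounded", {
  set.seed(3)
  for (i in 1:20) {
    a <- sample(0:100, 1); b <- sample(0:100, 1)
    if (a + b == 0) next
    ci <- chemotaxis_index_quadrant(a, b)
    expect_equal(ci, -chemotaxis_index_quadrant(b, a))
    expect_gte(ci, -1); expect_lte(ci, 1)
  }
})

test_that("single-worm sector scores sum the visited sector values", {
  expect_equal(single_worm_score(c("A", "B", "C")), 6)
  expect_equal(single_worm_score("F"), -3)
  expect_equal(single_worm_score(LETTERS[1:6]), 0)
  expect_equal(single_worm_score(character(0)), 0)
  expect_error(single_worm_score(c("A", "G")), "unknown sector")
})

test_that("lawn avoidance and occupancy are exact complements", {
  expect_equal(lawn_indices(12, 30), c(avoidance = 0.4, occupancy = 0.6))
  expect_equal(lawn_indices(30, 30), c(avoidance = 1.0, occupancy = 0.0))
  expect_equal(lawn_indices(0, 30), c(avoidance = 0.0, occupancy = 1.0))
  expect_error(lawn_indices(31, 30), "exceeds")
  set.seed(8)
  for (i in 1:10) {
    n <- sample(1:50, 1); off <- sample(0:n, 1)
    expect_equal(unname(sum(lawn_indices(off, n))), 1)
  }
})

test_that("relative change handles survival and index scales alike", {
  expect_equal(relative_change(0.2, 0.5), -0.6)
  expect_equal(relative_change(0.5, 0.5), 0.0)
  expect_equal(relative_change(4, 6), -1 / 3)
  expect_warning(na <- relative_change(1, 0), "undefined")
  expect_true(is.na(na))
})

test_that("repellent hit rule flags strictly above the CI threshold", {
  tab <- data.frame(strain_id = paste0("s", 1:5),
                    ci = c(-0.3, -0.9, -0.5, -0.499, -1.0))
  hits <- call_hits(tab, list(type = "ci_threshold", threshold = -0.5))
  expect_setequal(hits$strain_id, c("s1", "s4"))   # -0.5 itself excluded
  expect_identical(attr(hits, "flagged"), c(TRUE, FALSE, FALSE, TRUE, FALSE))
  empty <- call_hits(tab[0, ], list(type = "ci_threshold"))
  expect_equal(nrow(empty), 0)
})

test_that("quantile hit rule flags strict tails of relative change", {
  tab <- data.frame(strain_id = paste0("s", 1:21),
                    relative_change = seq(-1, 1, by = 0.1))
  lo <- call_hits(tab, list(type = "quantile", q = 0.05, tail = "low"))
  hi <- call_hits(tab, list(type = "quantile", q = 0.05, tail = "high"))
  expect_true(all(lo$relative_change <
                    quantile(tab$relative_change, 0.05, names = FALSE)))
  expect_true(all(hi$relative_change >
                    quantile(tab$relative_change, 0.95, names = FALSE)))
  both <- call_hits(tab, list(type = "quantile", q = 0.05, tail = "both"))
  expect_setequal(both$strain_id, c(lo$strain_id, hi$strain_id))
})

test_that("interval means use half-open windows and report the step response", {
  tr <- trace(seq(0, 90, by = 0.25), rep(0.1, 361), kind = "speed")
  r <- interval_mean_response(tr, c(0, 30), c(30, 60))
  expect_equal(unname(r["delta"]), 0)

  y <- ifelse(seq(0, 90, by = 0.25) >= 30, 0.3, 0.1)
  tr2 <- trace(seq(0, 90, by = 0.25), y, kind = "speed")
  r2 <- interval_mean_response(tr2, c(0, 30), c(30, 60))
  expect_equal(unname(r2["baseline_mean"]), 0.1)
  expect_equal(unname(r2["stimulus_mean"]), 0.3)
  expect_equal(unname(r2["delta"]), 0.2)

  r3 <- interval_mean_response(tr, c(100, 110), c(30, 60))
  expect_true(is.na(r3["baseline_mean"]))
})

test_that("bleach correction divides out a pure exponential to 1", {
  t <- seq(0, 90, by = 0.25)
  tr <- trace(t, 80 * exp(-0.012 * t))
  cor <- bleach_correct(tr)
  expect_true(attr(cor, "fit_ok"))
  expect_equal(attr(cor, "b"), 0.012, tolerance = 1e-9)
  expect_lt(max(abs(cor$y - 1)), 1e-6)

  ## constant input: degenerate decay, output 1
  tr2 <- trace(t, rep(5, length(t)))
  cor2 <- bleach_correct(tr2)
  expect_lt(max(abs(cor2$y - 1)), 1e-6)
  expect_equal(attr(cor2, "b"), 0, tolerance = 1e-12)

  ## non-positive values in a fit window: warned, returned uncorrected
  tr3 <- trace(t, c(-1, rep(2, length(t) - 1)))
  expect_warning(un <- bleach_correct(tr3), "uncorrected")
  expect_false(attr(un, "fit_ok"))
  expect_identical(un$y, tr3$y)
})

test_that("bleach fit excludes the response window", {
  t <- seq(0, 90, by = 0.25)
  box <- as.numeric(t >= 30 & t < 60)
  tr <- trace(t, 100 * exp(-0.01 * t) * (1 - 0.5 * box))
  cor <- bleach_correct(tr)
  outside <- t < 30 | t >= 60
  expect_lt(max(abs(cor$y[outside] - 1)), 0.01)
})

test_that("dF/F0 is zero at baseline and recovers step amplitudes", {
  t <- seq(0, 90, by = 0.25)
  flat <- trace(t, rep(1, length(t)))
  expect_equal(max(abs(delta_f_over_f0(flat, 30)$y)), 0)

  for (amp in c(1.0, -0.5)) {
    y <- 1 + amp * as.numeric(t >= 30 & t < 60)
    dff <- delta_f_over_f0(trace(t, y), 30)
    during <- t >= 31 & t < 59
    expect_equal(mean(dff$y[during]), amp, tolerance = 1e-12)
  }

  expect_error(delta_f_over_f0(trace(t[t > 28], rep(1, sum(t > 28))), 30),
               "5 s")
  zero <- trace(t, c(rep(0, 120), rep(1, length(t) - 120)))
  expect_warning(na <- delta_f_over_f0(zero, 30), "F0")
  expect_true(all(is.na(na$y)))
})

test_that("response correlation handles identical, negated and sparse profiles", {
  prof <- rbind(a = c(1, 2, 3, 4), b = c(1, 2, 3, 4), c = -c(1, 2, 3, 4),
                d = c(NA, NA, NA, 2))
  m <- response_correlation(prof)
  expect_equal(m["a", "b"], 1.0)
  expect_equal(m["a", "c"], -1.0)
  expect_true(is.na(m["a", "d"]))
  expect_equal(unname(diag(m)), rep(1, 4))
  expect_identical(m, t(m))
})

test_that("planted ligand/receptor pairs top the off-diagonal correlations", {
  set.seed(2024)
  n_cond <- 8
  top_hits <- 0
  n_sim <- 200
  for (i in seq_len(n_sim)) {
    effect <- rnorm(n_cond, sd = 1)
    prof <- rbind(
      lig = effect + rnorm(n_cond, sd = 0.1),
      rec = effect + rnorm(n_cond, sd = 0.1),
      o1 = rnorm(n_cond), o2 = rnorm(n_cond), o3 = rnorm(n_cond),
      o4 = rnorm(n_cond))
    m <- response_correlation(prof)
    diag(m) <- -Inf
    idx <- which(m == max(m), arr.ind = TRUE)[1, ]
    if (setequal(rownames(prof)[idx], c("lig", "rec"))) top_hits <- top_hits + 1
  }
  expect_gte(top_hits / n_sim, 0.95)
})

test_that("simulated quadrant plates match the binomial expectation", {
  counts <- simulate_quadrant_counts(0.5, n_worms = 150, n_plates = 1000,
                                     seed = 99)
  se <- sd(counts$ci) / sqrt(nrow(counts))
  expect_lt(abs(mean(counts$ci) - 0), 3 * se + 1e-3)
  counts9 <- simulate_quadrant_counts(0.9, n_worms = 150, n_plates = 1000,
                                      seed = 100)
  se9 <- sd(counts9$ci) / sqrt(nrow(counts9))
  expect_lt(abs(mean(counts9$ci) - 0.8), 3 * se9 + 1e-3)
})
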