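test_that("noise-free plates invert the depletion equation exactly", {
  targets <- c(none = 0, mid = 57.8, deep = 62, full = 100)
  runs <- simulate_plate(targets, noise_sd = 0, n_runs = 3, seed = 1)
  for (run in runs) {
    out <- run_depletion(run)
    expect_equal(out$raw_pct[match(names(targets), out$substance)],
                 unname(targets), tolerance = 1e-9)
  }
  # d = 0 means the test well carries the full probe signal C + (A - B)
  run1 <- runs[[1]]
  expect_equal(mean(run1$tc$none),
               mean(run1$ref_c$none) + (2.0 - 0.2), tolerance = 1e-9)
})

test_that("noise-free recovery holds across the whole depletion range", {
  d <- seq(0, 100, by = 12.5)
  targets <- stats::setNames(d, paste0("t", seq_along(d)))
  runs <- simulate_plate(targets, noise_sd = 0, n_runs = 1, seed = 3)
  out <- run_depletion(runs[[1]])
  expect_equal(out$raw_pct[match(names(targets), out$substance)],
               unname(d), tolerance = 1e-9)
})

test_that("same seed gives byte-identical plate files", {
  f1 <- withr::local_tempfile(fileext = ".csv")
  f2 <- withr::local_tempfile(fileext = ".csv")
  write_plate_csv(simulate_plate(c(x = 40), noise_sd = 0.05, seed = 11), f1)
  write_plate_csv(simulate_plate(c(x = 40), noise_sd = 0.05, seed = 11), f2)
  expect_identical(readLines(f1), readLines(f2))
  f3 <- withr::local_tempfile(fileext = ".csv")
  write_plate_csv(simulate_plate(c(x = 40), noise_sd = 0.05, seed = 12), f3)
  expect_false(identical(readLines(f1), readLines(f3)))
})

test_that("noisy recovery stays within sampling error of the target", {
  # signal noise sd = 1% of the dynamic range, 3 runs x 2 replicates
  span <- 2.0 - 0.2
  runs <- simulate_plate(c(x = 62), noise_sd = 0.01 * span,
                         n_replicates = 2, n_runs = 3, seed = 42)
  per_run <- vapply(runs, function(r) run_depletion(r)$raw_pct, numeric(1))
  est <- aggregate_runs(per_run)$raw
  # depletion-scale sd per run: TC (2 reps), C (2 reps), plus A/B noise;
  # conservatively 3x the TC-only propagation 100*sd/(span*sqrt(2))
  se <- 3 * 100 * 0.01 / sqrt(2) / sqrt(3)
  expect_lt(abs(est - 62), 3 * se)
})

test_that("targets outside [0, 100] and degenerate configs are rejected", {
  expect_error(simulate_plate(c(x = 101)), "\\[0, 100\\]")
  expect_error(simulate_plate(c(40)), "named")
  expect_error(simulate_plate(c(x = 40), a_signal = 0.1, b_signal = 0.2))
})

test_that("population simulator is reproducible and respects clamping", {
  pop1 <- simulate_population(50, 50, seed = 9)
  pop2 <- simulate_population(50, 50, seed = 9)
  expect_identical(pop1, pop2)
  expect_true(all(pop1$depletion >= 0 & pop1$depletion <= 100))
  expect_equal(table(pop1$label)[["sensitizer"]], 50)
})

test_that("point-mass classes make every separating threshold optimal", {
  pop <- tibble::tibble(label = rep(hazard_levels, each = 5),
                        depletion = rep(c(80, 10), each = 5))
  cut <- optimal_cutoff(roc_curve(pop$depletion, pop$label))
  expect_equal(cut$youden_j, 1)
  expect_equal(cut$tie_interval, c(10, 80))
  expect_gt(cut$threshold, 10)
  expect_lte(cut$threshold, 80)
})

test_that("empirical Youden threshold tracks the analytic density crossing", {
  analytic <- normal_optimal_threshold(5, 5, 60, 15)
  expect_gt(analytic, 5); expect_lt(analytic, 60)
  # at the crossing the two class densities are equal
  expect_equal(stats::dnorm(analytic, 5, 5), stats::dnorm(analytic, 60, 15),
               tolerance = 1e-9)
  pop <- simulate_population(200, 200, seed = 17)
  cut <- optimal_cutoff(roc_curve(pop$depletion, pop$label))
  expect_lt(abs(cut$threshold - analytic), 5)
  # the sample-optimal J can be no worse than J at the analytic optimum
  pos <- pop$label == "sensitizer"
  j_analytic <- mean(pop$depletion[pos] >= analytic) -
    mean(pop$depletion[!pos] >= analytic)
  expect_gte(cut$youden_j, j_analytic - 1e-12)
  # equal-variance case has the closed-form midpoint
  expect_equal(normal_optimal_threshold(10, 5, 30, 5), 20)
})

test_that("threshold estimation error shrinks with sample size", {
  analytic <- normal_optimal_threshold(5, 5, 60, 15)
  mean_err <- function(n) {
    errs <- vapply(1:8, function(s) {
      pop <- simulate_population(n, n, seed = 100 + s)
      abs(optimal_cutoff(roc_curve(pop$depletion, pop$label))$threshold -
            analytic)
    }, numeric(1))
    mean(errs)
  }
  e <- c(mean_err(50), mean_err(200), mean_err(1000))
  expect_lt(e[3], e[1])
})

test_that("identical class distributions leave only chance-level optima", {
  js <- vapply(1:40, function(s) {
    pop <- simulate_population(60, 60, sens_mean = 30, sens_sd = 10,
                               non_mean = 30, non_sd = 10, seed = 200 + s)
    optimal_cutoff(roc_curve(pop$depletion, pop$label))$youden_j
  }, numeric(1))
  expect_gt(mean(js), 0)      # maximisation induces a small positive bias
  expect_lt(mean(js), 0.25)   # but stays near chance
})
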