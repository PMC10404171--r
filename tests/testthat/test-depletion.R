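test_that("percent depletion follows the reference-control equation", {
  # direct hand evaluation: 1 - (1.2 - 0.3)/(2.0 - 0.2) = 0.5
  expect_equal(percent_depletion(1.2, a = 2.0, b = 0.2, c = 0.3), 50.0)
  # reading at full probe signal C + (A - B) -> no depletion
  expect_equal(percent_depletion(0.3 + 1.8, 2.0, 0.2, 0.3), 0)
  # reading collapsed to the interference control -> complete depletion
  expect_equal(percent_depletion(0.3, 2.0, 0.2, 0.3), 100)
  # readings below C exceed 100 raw
  expect_gt(percent_depletion(0.1, 2.0, 0.2, 0.3), 100)

  expect_error(percent_depletion(1, a = 0.2, b = 0.2, c = 0.1), "dynamic range")
  expect_error(percent_depletion(1, a = 0.1, b = 0.2, c = 0.1), "dynamic range")
  expect_error(percent_depletion(NaN, 2, 0.2, 0.3), "finite")
})

test_that("depletion is affine-invariant and monotone in the reading", {
  set.seed(41)
  for (i in 1:25) {
    b <- runif(1, 0, 1); a <- b + runif(1, 0.5, 2); cc <- runif(1, 0, 1)
    reading <- runif(1, 0, a + 1)
    d <- percent_depletion(reading, a, b, cc)
    k <- runif(1, 0.1, 10)
    # scale (reading - C) and (A - B) jointly by k
    d2 <- percent_depletion(cc + k * (reading - cc), b + k * (a - b), b, cc)
    expect_equal(d2, d, tolerance = 1e-10)
    # strictly decreasing in the reading
    expect_lt(percent_depletion(reading + 0.01, a, b, cc), d)
  }
})

test_that("clamping maps onto [0, 100] and is the identity inside", {
  expect_equal(clamp_depletion(-19.6), 0)
  expect_equal(clamp_depletion(150), 100)
  expect_equal(clamp_depletion(57.8), 57.8)
  expect_equal(clamp_depletion(c(-5, 0, 100, 101)), c(0, 0, 100, 100))
  expect_error(clamp_depletion(Inf), "finite")
})

test_that("run aggregation averages signed values then clamps once", {
  expect_equal(aggregate_runs(c(60, 62, 64))$raw, 62)
  r <- aggregate_runs(c(-5, -3, -1))
  expect_equal(r$raw, -3)
  expect_equal(r$clamped, 0)
  expect_equal(aggregate_runs(c(100, 100, 100))$clamped, 100)
  # per-run clamping is exposed as the alternative ordering
  expect_equal(aggregate_runs(c(-30, 60, 60), clamp_per_run = TRUE)$raw, 40)
  expect_error(aggregate_runs(c(1, 2)), "insufficient replication")
})

test_that("run_depletion uses each substance's own interference control", {
  run <- plate_run("cysteine",
                   ref_a = c(2.0, 2.0), ref_b = c(0.2, 0.2),
                   nc = 1.9, pc = 0.4,
                   tc = list(x = c(1.2, 1.2), y = 0.5),
                   ref_c = list(x = 0.3, y = 0.5))
  out <- run_depletion(run)
  expect_equal(out$raw_pct[out$substance == "x"], 50)
  expect_equal(out$raw_pct[out$substance == "y"], 100)
  expect_equal(nrow(out), 2)
  qc <- attr(out, "qc")
  expect_true(qc$valid)

  # reading below C forces > 100 raw, clamped to 100
  run2 <- plate_run("cysteine", ref_a = 2, ref_b = 0.2, nc = 1.9, pc = 0.4,
                    tc = list(x = 0.1), ref_c = list(x = 0.3))
  out2 <- run_depletion(run2)
  expect_gt(out2$raw_pct, 100)
  expect_equal(out2$clamped_pct, 100)

  expect_error(
    plate_run("cysteine", ref_a = 2, ref_b = 0.2, nc = 1.9, pc = 0.4,
              tc = list(x = 1, z = 1), ref_c = list(x = 0.3)),
    "missing reference control C.*z")
})

test_that("run-level QC flags inactive controls", {
  # NC showing strong depletion and PC showing weak depletion -> invalid
  run <- plate_run("cysteine", ref_a = 2, ref_b = 0.2, nc = 1.0, pc = 1.5,
                   tc = list(x = 1.2), ref_c = list(x = 0.3))
  qc <- attr(run_depletion(run), "qc")
  expect_false(qc$valid)
  expect_gt(clamp_depletion(qc$nc_pct), 10)
})

test_that("plate CSV round trip preserves run structure and values", {
  runs <- simulate_plate(c(sub1 = 40, sub2 = 75), noise_sd = 0.01,
                         seed = 7, n_runs = 2)
  f <- withr::local_tempfile(fileext = ".csv")
  write_plate_csv(runs, f)
  back <- read_plate_csv(f)
  expect_setequal(names(back), names(runs))
  for (key in names(runs)) {
    expect_equal(run_depletion(back[[key]])$raw_pct,
                 run_depletion(runs[[key]])$raw_pct, tolerance = 1e-12)
  }
})
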