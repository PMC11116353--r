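test_that("beat detection segments clean pulsatile records", {
  rec <- square_cycles(10, sys = 120, dia = 80)
  b <- detect_beats(rec)
  expect_equal(nrow(b), 10)
  expect_equal(b$pulse_pressure, rep(40, 10), tolerance = 0.02)
  expect_equal(b$systolic, rep(120, 10), tolerance = 0.01)
  expect_equal(b$diastolic, rep(80, 10), tolerance = 0.01)
  expect_true(!is.unsorted(b$t, strictly = TRUE))
})

test_that("flat or too-short records yield zero beats, not errors", {
  flat <- data.frame(t_s = seq(0, 10, by = 0.01), p_mmHg = 60)
  expect_equal(nrow(detect_beats(flat)), 0)
  # sustained pulse pressure below 5 mmHg counts as flat
  weak <- square_cycles(10, sys = 63, dia = 60)
  expect_equal(nrow(detect_beats(weak)), 0)
  short <- square_cycles(1, period = 1)
  expect_equal(nrow(detect_beats(short)), 0)
  expect_error(detect_beats(data.frame(t_s = c(0, 0.5, 0.5),
                                       p_mmHg = c(1, 2, 3))),
               "strictly increasing")
})

test_that("detected beats match the generator's own per-beat ledger", {
  p <- pig_params()
  st <- pig_init(p)
  st$ppv_true <- 30
  st$svv_true <- 35
  wf <- emit_waveform(st, duration = 30, params = p)
  b <- detect_beats(wf$samples)
  n <- nrow(b)
  expect_gt(n, 30)
  led <- wf$beats[seq_len(n), ]
  expect_lt(max(abs(b$systolic - led$sys_mmHg)), 1)
  expect_lt(max(abs(b$diastolic - led$dia_mmHg)), 1)
})

test_that("windowed PPV follows the printed ratio formula", {
  # zero variation
  b <- beat_table(t = 1:10, pp = rep(40, 10))
  expect_equal(compute_ppv(b, t = 10), 0)
  # PPmax 50, PPmin 30, PPmean 40 -> 50 %
  b <- beat_table(t = seq(2, 20, by = 2), pp = c(50, 30, rep(40, 8)))
  expect_equal(compute_ppv(b, t = 20), 100 * (50 - 30) / 40)
  # SV analogue: SVmax 30, SVmin 20, SVmean 25 -> 40 %
  b <- beat_table(t = 1:10, pp = 40, sv = c(30, 20, rep(25, 8)))
  expect_equal(compute_svv(b, t = 10), 40)
})

test_that("PPV equals a brute-force recomputation and is scale invariant", {
  set.seed(11)
  for (k in 1:20) {
    n <- sample(3:40, 1)
    b <- beat_table(t = cumsum(runif(n, 0.5, 1.2)),
                    pp = runif(n, 20, 60))
    t_eval <- max(b$t) + runif(1, -2, 1)
    expect_equal(compute_ppv(b, t_eval), brute_ppv(b, t_eval),
                 tolerance = 1e-12)
    # multiplying all pressures by a positive constant leaves PPV unchanged
    c_ <- runif(1, 0.2, 5)
    b2 <- b
    b2$pulse_pressure <- b2$pulse_pressure * c_
    v1 <- compute_ppv(b, t_eval)
    if (!is.na(v1)) expect_equal(compute_ppv(b2, t_eval), v1)
  }
})

test_that("too few beats in the window makes PPV undefined", {
  b <- beat_table(t = 1:4, pp = c(30, 40, 50, 35))
  expect_true(is.na(compute_ppv(b, t = 4)))
  s <- hemo_snapshot(b, t = 4)
  expect_false(s$valid)
  expect_true(is.na(s$map))
})

test_that("signal validity distinguishes dropout from a skipped beat", {
  b <- beat_table(t = seq(1, 100, by = 1), pp = 40)
  expect_true(signal_valid(b, t = 100))
  # one missing beat (1-s gap) is tolerated
  b2 <- b[b$t != 50, ]
  expect_true(signal_valid(b2, t = 51))
  # a 25-min gap is invalid throughout (beyond the 5-s horizon)
  b3 <- b[b$t <= 100, ]
  for (t in c(110, 600, 1600)) expect_false(signal_valid(b3, t))
  s <- hemo_snapshot(b3, t = 700)
  expect_false(s$valid)
})

test_that("snapshots aggregate MAP, HR and variation indices", {
  b <- beat_table(t = seq(1, 20, by = 1), pp = 40, sv = 30, dia = 80)
  s <- hemo_snapshot(b, t = 20)
  expect_true(s$valid)
  expect_equal(s$hr, 60)
  expect_equal(s$map, 80 + 40 / 3)
  expect_equal(s$ppv, 0)
  expect_equal(s$svv, 0)
  # Ea_dyn defined only when SVV > 0
  expect_true(is.na(s$eadyn))
  # simulator steady state reproduces the calibrated baseline MAP
  p <- pig_params()
  st <- pig_init(p)
  wf <- emit_waveform(st, duration = 30, params = p)
  lb <- data.frame(t = wf$beats$t_s, systolic = wf$beats$sys_mmHg,
                   diastolic = wf$beats$dia_mmHg,
                   pulse_pressure = wf$beats$sys_mmHg - wf$beats$dia_mmHg,
                   stroke_volume = wf$beats$sv_ml)
  s2 <- hemo_snapshot(lb, t = 30)
  expect_lt(abs(s2$map - 68.8), 2)
  expect_lt(abs(s2$hr - st$hr), 2)
})

test_that("SV modulation at twice the PP depth gives Ea_dyn of one half", {
  p <- pig_params()
  st <- pig_init(p)
  st$ppv_true <- 20
  st$svv_true <- 40
  wf <- emit_waveform(st, duration = 30, params = p)
  lb <- data.frame(t = wf$beats$t_s, systolic = wf$beats$sys_mmHg,
                   diastolic = wf$beats$dia_mmHg,
                   pulse_pressure = wf$beats$sys_mmHg - wf$beats$dia_mmHg,
                   stroke_volume = wf$beats$sv_ml)
  s <- hemo_snapshot(lb, t = 30)
  expect_equal(s$eadyn, 0.5, tolerance = 0.02)
})

test_that("hypotension trigger implements the >80 %-of-5-min rule", {
  tt <- 0:900
  # constant 38: fires as soon as the 5-min window is covered
  expect_equal(hypotension_trigger(data.frame(t = tt, map = 38)), 300)
  # constant 45: never
  expect_true(is.na(hypotension_trigger(data.frame(t = tt, map = 45))))
  # alternating 38/42: fraction 0.5 <= 0.80, never fires
  alt <- data.frame(t = tt, map = ifelse(tt %% 2 == 0, 38, 42))
  expect_true(is.na(hypotension_trigger(alt)))
  expect_error(hypotension_trigger(data.frame(t = numeric(0),
                                              map = numeric(0))),
               "unusable")
})

test_that("trigger agrees with a brute-force scan and is monotone", {
  set.seed(7)
  for (k in 1:10) {
    m <- 45 + cumsum(rnorm(900, -0.02, 0.3))
    ser <- data.frame(t = 0:899, map = m)
    expect_identical(hypotension_trigger(ser), brute_trigger(ser$t, ser$map))
    # lowering the trace pointwise never delays the trigger
    lower <- ser
    lower$map <- lower$map - runif(900, 0, 4)
    t1 <- hypotension_trigger(ser)
    t2 <- hypotension_trigger(lower)
    if (!is.na(t1)) {
      expect_false(is.na(t2))
      expect_lte(t2, t1)
    }
  }
})
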