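cfg <- controller_config(weight_kg = 30.8)

test_that("the crystalloid dose table is exact, including boundaries", {
  expect_identical(fluid_dose(5, cfg), 0)
  expect_identical(fluid_dose(15, cfg), 5)
  expect_identical(fluid_dose(35, cfg), 8)
  expect_identical(fluid_dose(55, cfg), 10)
  # left-closed bands, as printed
  expect_identical(fluid_dose(c(10, 30, 50), cfg), c(5, 8, 10))
  expect_identical(fluid_dose(c(9.999, 29.999, 49.999), cfg), c(0, 5, 8))
  expect_error(fluid_dose(-1, cfg), "non-negative")
  # non-decreasing, piecewise constant with breakpoints exactly {10, 30, 50}
  grid <- seq(0, 80, by = 0.25)
  d <- fluid_dose(grid, cfg)
  expect_true(all(diff(d) >= 0))
  expect_identical(grid[which(diff(d) > 0)] + 0.25, c(10, 30, 50))
})

test_that("norepinephrine titration starts, steps, caps and weans", {
  st <- controller_init(cfg)
  st$first_lr_given <- TRUE
  # start at 0.03 when MAP below target with no running infusion
  expect_equal(ne_adjust(snap(55), st, FALSE, cfg), 0.03)
  # never before the first crystalloid bolus
  st0 <- controller_init(cfg)
  expect_equal(ne_adjust(snap(55), st0, FALSE, cfg), 0)
  # 0.01 steps up
  st$ne_rate <- 0.05
  expect_equal(ne_adjust(snap(55), st, FALSE, cfg), 0.06)
  # cap at 0.3
  st$ne_rate <- 0.30
  expect_equal(ne_adjust(snap(55), st, FALSE, cfg), 0.30)
  # wean one step when MAP held, no fluid, Ea_dyn above threshold
  st$ne_rate <- 0.05
  st$map_held_above <- TRUE
  expect_equal(ne_adjust(snap(68, eadyn = 1.2), st, FALSE, cfg), 0.04)
  # wean gated on Ea_dyn
  expect_equal(ne_adjust(snap(68, eadyn = 0.8), st, FALSE, cfg), 0.05)
  # no wean when fluid was needed in the cycle
  expect_equal(ne_adjust(snap(68, eadyn = 1.2), st, TRUE, cfg), 0.05)
  # MAP above target but not held for the full cycle: unchanged
  st$map_held_above <- FALSE
  expect_equal(ne_adjust(snap(68, eadyn = 1.2), st, FALSE, cfg), 0.05)
})

test_that("initiation is a disjunction, stopping a conjunction", {
  expect_true(needs_resuscitation(snap(55, hr = 90), cfg))
  expect_false(needs_resuscitation(snap(65, hr = 100), cfg))
  expect_true(needs_resuscitation(snap(65, hr = 120), cfg))
  # strict comparisons at the printed thresholds
  expect_false(needs_resuscitation(snap(60, hr = 110), cfg))
  expect_true(needs_resuscitation(snap(59.999, hr = 100), cfg))
  expect_true(needs_resuscitation(snap(60, hr = 110.001), cfg))
  expect_error(needs_resuscitation(invalid_snap(), cfg), "failsafe")
})

test_that("activation emits blood then CaCl2, second blood iff rules unmet", {
  shocky <- function(t) snap(50, hr = 115, ppv = 20, t = t)
  r <- drive_controller(shocky, 1500, cfg)
  log <- r$log
  expect_identical(log$channel[1:3], c("whole_blood", "cacl2", "whole_blood"))
  expect_equal(log$t_issued[1:3], c(0, 300, 900))
  expect_equal(log$amount[1:2], c(250, 1))
  expect_equal(log$duration_min[1:3], c(5, 5, 5))
  # cycling begins after the second unit completes
  expect_equal(r$state$cycle_starts[1], 1200)

  # a responder (stopping rules met at the check) skips the second unit
  responder <- function(t) if (t < 500) snap(50, ppv = 20, t = t) else
    snap(66, hr = 95, ppv = 20, t = t)
  r2 <- drive_controller(responder, 1500, cfg)
  expect_identical(sum(r2$log$channel == "whole_blood"), 1L)
  expect_equal(r2$state$cycle_starts[1], 900)
})

test_that("cycles treat on the governing assessment and honor PPV gating", {
  # hypotensive and fluid responsive: LR every cycle while PPV >= 10
  shocky <- function(t) snap(50, hr = 115, ppv = 35, t = t)
  r <- drive_controller(shocky, 1200 + 3 * 900, cfg)
  lr <- r$log[r$log$channel == "ringers", ]
  expect_equal(lr$amount[1], 8 * 30.8)          # PPV 35 -> 8 ml/kg
  expect_equal(lr$t_issued[1], 1200)            # first TREAT tick
  # one bolus per cycle, all at cycle starts
  expect_true(all(lr$t_issued %in% r$state$cycle_starts))
  # NE starts only in the cycle after the first crystalloid
  ne <- r$log[r$log$channel == "norepinephrine", ]
  expect_equal(ne$amount[1], 0.03)
  expect_equal(ne$t_issued[1], 1200 + 900)
  # hypotensive but not volume responsive: no crystalloid, ever
  dry <- function(t) snap(50, hr = 115, ppv = 6, t = t)
  r2 <- drive_controller(dry, 1200 + 3 * 900, cfg)
  expect_identical(sum(r2$log$channel == "ringers"), 0L)
})

test_that("norepinephrine rate obeys bounds and step-size invariants", {
  # a stream that forces up-titration then weaning
  stream <- function(t) {
    if (t < 6000) snap(52, hr = 112, ppv = 15, t = t)
    else snap(67, hr = 85, ppv = 6, eadyn = 1.3, t = t)
  }
  r <- drive_controller(stream, 12000, cfg)
  ne <- r$log[r$log$channel == "norepinephrine", ]
  expect_true(all(ne$amount >= 0 & ne$amount <= cfg$ne_max))
  steps <- diff(c(0, ne$amount))
  first <- steps[1]
  expect_equal(first, cfg$ne_start)
  expect_true(all(abs(abs(steps[-1]) - cfg$ne_step) < 1e-12))
  # weaning happened after stabilization
  expect_lt(ne$amount[nrow(ne)], max(ne$amount))
})

test_that("failsafe holds the rate, blocks boluses, and observes on return", {
  pre <- function(t) snap(52, hr = 112, ppv = 15, t = t)
  post <- function(t) snap(70, hr = 85, ppv = 6, eadyn = 1.3, t = t)
  drop_start <- 1200 + 2 * 900
  drop_end <- drop_start + 25 * 60
  stream <- function(t) {
    if (t < drop_start) pre(t)
    else if (t < drop_end) invalid_snap(t)
    else post(t)
  }
  r <- drive_controller(stream, drop_end + 40 * 60, cfg)
  log <- r$log
  # zero commands from dropout start through the 15-min observation
  obs_end <- drop_end + 15 * 60
  expect_identical(sum(log$t_issued >= drop_start & log$t_issued < obs_end),
                   0L)
  # norepinephrine resumes at the held rate, then weans (MAP held high,
  # Ea_dyn above threshold during observation)
  ne <- log[log$channel == "norepinephrine", ]
  held <- ne$amount[max(which(ne$t_issued < drop_start))]
  after <- ne[ne$t_issued >= obs_end, ]
  expect_gt(nrow(after), 0)
  expect_equal(after$amount[1], held - cfg$ne_step)
})

test_that("controller trace is deterministic and rejects time regression", {
  stream <- function(t) snap(50 + 10 * sin(t / 500), hr = 112,
                             ppv = 20 + 10 * cos(t / 700), t = t)
  r1 <- drive_controller(stream, 8000, cfg)
  r2 <- drive_controller(stream, 8000, cfg)
  expect_identical(r1$log, r2$log)
  st <- controller_init(cfg)
  st <- controller_step(st, snap(50, t = 10), 10, cfg)$state
  expect_error(controller_step(st, snap(50, t = 5), 5, cfg), "regression")
})

test_that("time to initial stabilization scans the ledger by cycle", {
  mk <- function(t, channel = "ringers") {
    list(t_issued = t, channel = channel, kind = "bolus", amount = 100,
         unit = "ml", duration_min = 5)
  }
  starts <- seq(0, by = 900, length.out = 12)
  # first LR in cycle 2, quiet cycles {4, 7} -> start of cycle 4
  log <- list(mk(starts[1], "whole_blood"), mk(starts[2]), mk(starts[3]),
              mk(starts[5]), mk(starts[6]), mk(starts[8]))
  expect_equal(time_to_initial_stabilization(log, starts, 0),
               starts[4] / 60)
  # commands in every cycle: never stabilizes
  log2 <- lapply(starts, mk)
  expect_true(is.na(time_to_initial_stabilization(log2, starts, 0)))
  # no crystalloid at all: undefined
  log3 <- list(mk(starts[1], "whole_blood"))
  expect_true(is.na(time_to_initial_stabilization(log3, starts, 0)))
})

test_that("run totals integrate boluses and norepinephrine correctly", {
  empty <- summarize_run(list(), 30.8, c(0, 7200))
  expect_equal(empty$fluid_ml_per_kg, 0)
  expect_equal(empty$ne_total_ug_per_kg, 0)
  expect_equal(empty$ne_mean_rate, 0)
  # constant 0.05 ug/kg/min over 120 min -> 6 ug/kg total
  log <- list(list(t_issued = 0, channel = "norepinephrine",
                   kind = "rate_set", amount = 0.05, unit = "ug/kg/min",
                   duration_min = NA))
  s <- summarize_run(log, 30.8, c(0, 120 * 60))
  expect_equal(s$ne_total_ug_per_kg, 6)
  expect_equal(s$ne_mean_rate, 0.05)
  # two 5 ml/kg boluses fully inside the window -> 10 ml/kg
  w <- 30.8
  log2 <- list(
    list(t_issued = 600, channel = "ringers", kind = "bolus",
         amount = 5 * w, unit = "ml", duration_min = 5),
    list(t_issued = 3000, channel = "ringers", kind = "bolus",
         amount = 5 * w, unit = "ml", duration_min = 5))
  s2 <- summarize_run(log2, w, c(0, 7200))
  expect_equal(s2$fluid_ml_per_kg, 10)
})
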