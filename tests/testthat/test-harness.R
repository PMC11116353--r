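# shortened resuscitation keeps these end-to-end checks quick while
# exercising the full injury -> trigger -> delay -> closed-loop pipeline

test_that("identical configuration yields byte-identical logs", {
  cfg <- scenario_lab(seed = 3, resus_duration_min = 45)
  r1 <- run_scenario(cfg)
  r2 <- run_scenario(cfg)
  expect_identical(r1$trend, r2$trend)
  expect_identical(r1$ledger, r2$ledger)
  d1 <- file.path(tempdir(), "runA")
  d2 <- file.path(tempdir(), "runB")
  refitsim:::write_run(r1, d1)
  refitsim:::write_run(r2, d2)
  for (f in c("trend.csv", "ledger.csv")) {
    expect_identical(unname(tools::md5sum(file.path(d1, f))),
                     unname(tools::md5sum(file.path(d2, f))))
  }
  unlink(c(d1, d2), recursive = TRUE)
})

test_that("protocol ordering: injury, trigger, 30-min delay, activation", {
  run <- run_scenario(scenario_lab(seed = 1, resus_duration_min = 45))
  expect_gt(run$times$trigger, run$times$injury)
  expect_equal(run$times$resus_start, run$times$trigger + 30 * 60)
  # no command before activation
  expect_true(all(run$ledger$t_issued >= run$times$resus_start))
  # first action is the initial whole-blood unit at activation
  expect_identical(run$ledger$channel[1], "whole_blood")
  expect_equal(run$ledger$t_issued[1], run$times$resus_start)
  # trigger agrees with the exported detector on the recorded trend
  tr <- run$trend
  post <- tr[tr$t_s > run$times$injury & !is.na(tr$map), c("t_s", "map")]
  names(post) <- c("t", "map")
  expect_equal(hypotension_trigger(post), run$times$trigger)
})

test_that("untreated natural history ends in death or persistent shock", {
  run <- run_scenario(scenario_natural(seed = 1, follow_untreated_min = 90))
  final <- run$pig
  expect_true(!final$alive || final$map < 60)
  expect_identical(nrow(run$ledger), 0L)
})

test_that("crystalloid boluses only follow volume-responsive assessments", {
  run <- run_scenario(scenario_lab(seed = 1))
  lr <- run$ledger[run$ledger$channel == "ringers", ]
  expect_gt(nrow(lr), 0)
  for (t in lr$t_issued) {
    gov <- run$trend$ppv[run$trend$t_s %in% c(t - 1, t)]
    expect_true(any(gov >= 10, na.rm = TRUE))
  }
  # norepinephrine never precedes the first crystalloid bolus
  ne <- run$ledger[run$ledger$channel == "norepinephrine", ]
  if (nrow(ne) > 0) expect_gt(min(ne$t_issued), min(lr$t_issued))
  # and stays within protocol bounds throughout
  expect_true(all(run$trend$ne_rate >= 0 & run$trend$ne_rate <= 0.3))
  expect_true(run$survived_3h)
  expect_true(run$stabilized)
})

test_that("a transfer dip perturbs pressure without harming the subject", {
  base <- run_scenario(scenario_lab(seed = 4, resus_duration_min = 45))
  cfg <- scenario_config(seed = 4, resus_duration_min = 45,
                         disturbances = list(disturbance("transfer_dip",
                                                         12, 2)))
  run <- run_scenario(cfg)
  rs <- run$times$resus_start
  dip_win <- run$trend$t_s > rs + 12 * 60 & run$trend$t_s <= rs + 14 * 60
  before <- run$trend$map[run$trend$t_s > rs + 10 * 60 &
                            run$trend$t_s <= rs + 12 * 60]
  expect_lt(min(run$trend$map[dip_win], na.rm = TRUE),
            min(before, na.rm = TRUE) - 4)
  expect_true(run$pig$alive)
  expect_true(base$pig$alive)
})

test_that("cohort summaries aggregate per-subject outcomes", {
  res <- run_cohort(scenario_natural(seed = 2, follow_untreated_min = 30),
                    n = 8)
  expect_identical(nrow(res$subjects), 8L)
  expect_true(all(res$subjects$survived_60min))   # death takes > 30 min
  # single-subject treated cohort: means equal the single values, sd empty
  res1 <- run_cohort(scenario_lab(seed = 5, resus_duration_min = 45), n = 1)
  expect_identical(nrow(res1$subjects), 1L)
  expect_equal(res1$summary$time_to_stabilization_min$mean,
               res1$subjects$time_to_stabilization_min[1])
  expect_true(is.na(res1$summary$time_to_stabilization_min$sd))
})

test_that("untreated cohort stepping matches a per-subject scenario run", {
  # one-pig cohort through the vectorized path
  res <- run_cohort(scenario_natural(seed = 6, follow_untreated_min = 60),
                    n = 1, cv = 0)
  # the same animal through run_scenario with injury at time zero
  run <- run_scenario(scenario_natural(seed = 6, baseline_min = 0,
                                       follow_untreated_min = 60))
  expect_equal(res$final_state$map, run$pig$map, tolerance = 1e-9)
  expect_equal(res$final_state$V_blood, run$pig$V_blood, tolerance = 1e-9)
  expect_identical(res$final_state$alive, run$pig$alive)
})

test_that("trend plots render with bolus marks and phase shading", {
  run <- run_scenario(scenario_lab(seed = 1, resus_duration_min = 45))
  g <- render_trends(run)
  expect_s3_class(g, "patchwork")
  expect_error(render_trends(run$trend[0, ]), "empty")
})

test_that("JSON configuration round-trips and rejects unknown keys", {
  path <- file.path(tempdir(), "cfg.json")
  cfg <- refit_config()
  cfg$controller$map_target <- 65
  cfg$scenario$resus_duration_min <- 60
  write_config(cfg, path)
  sc <- read_config(path)
  expect_s3_class(sc, "scenario_config")
  expect_equal(sc$controller$map_target, 65)
  expect_equal(sc$resus_duration_min, 60)
  bad <- cfg
  bad$controller$typo_key <- 1
  write_config(bad, path)
  expect_error(read_config(path), "unknown key")
  unlink(path)
})
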