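#' Scenario configuration
#'
#' Defines a full experiment timeline: a baseline interval, the liver
#' laceration, observation until the hypotension trigger (MAP < 40 mmHg over
#' > 80 % of a 5-min moving window), liver packing (treated animals only), a
#' 30-min delay, then ~3 h of closed-loop resuscitation. Disturbances
#' (transient transfer dips in SVR, signal dropouts) are anchored relative to
#' the start of resuscitation, since the trigger time varies by subject.
#'
#' @param name scenario label
#' @param seed integer seed (used for cohort sampling; single runs are
#'   deterministic)
#' @param baseline_min baseline interval before injury (min)
#' @param trigger_delay_to_resus_min delay from hypotension trigger to
#'   controller activation (min)
#' @param resus_duration_min duration of closed-loop resuscitation (min)
#' @param follow_untreated_min follow-up for untreated runs, from injury (min)
#' @param max_trigger_wait_min abort horizon if the trigger never fires (min)
#' @param treatment_enabled logical: run the controller (and pack the liver
#'   at trigger) or record natural history
#' @param disturbances list of [disturbance()] entries
#' @param sao2 arterial O2 saturation during the run (%); e.g. 97 for the
#'   transport profile
#' @param cohort_n default cohort size for [run_cohort()]
#' @param output_dir optional directory for `trend.csv`, `ledger.csv`,
#'   `config.json`, `summary.json` (and `trends.png` if `write_plot`)
#' @param write_plot write the trend panel plot when `output_dir` is set
#' @param pig a [pig_params()] object
#' @param controller a [controller_config()] (weight defaults to the pig's)
#' @param signal a [signal_config()]
#' @return an object of class `scenario_config`
#' @export
scenario_config <- function(name = "lab",
                            seed = 1,
                            baseline_min = 30,
                            trigger_delay_to_resus_min = 30,
                            resus_duration_min = 180,
                            follow_untreated_min = 180,
                            max_trigger_wait_min = 60,
                            treatment_enabled = TRUE,
                            disturbances = list(),
                            sao2 = NULL,
                            cohort_n = 12,
                            output_dir = NULL,
                            write_plot = FALSE,
                            pig = pig_params(),
                            controller = controller_config(weight_kg = pig$weight),
                            signal = signal_config()) {
  stopifnot(baseline_min >= 0, trigger_delay_to_resus_min >= 0,
            resus_duration_min > 0, follow_untreated_min > 0)
  for (d in disturbances) {
    if (!d$kind %in% c("transfer_dip", "signal_dropout")) {
      stop("unknown disturbance kind: ", d$kind)
    }
    stopifnot(d$duration_min > 0)
  }
  structure(list(name = name, seed = seed, baseline_min = baseline_min,
                 trigger_delay_to_resus_min = trigger_delay_to_resus_min,
                 resus_duration_min = resus_duration_min,
                 follow_untreated_min = follow_untreated_min,
                 max_trigger_wait_min = max_trigger_wait_min,
                 treatment_enabled = treatment_enabled,
                 disturbances = disturbances, sao2 = sao2,
                 cohort_n = cohort_n, output_dir = output_dir,
                 write_plot = write_plot,
                 pig = pig, controller = controller, signal = signal),
            class = "scenario_config")
}

#' Scenario disturbance
#'
#' @param kind `"transfer_dip"` (transient multiplicative SVR drop, e.g.
#'   moving the subject onto a stretcher) or `"signal_dropout"` (arterial
#'   line disconnected: snapshots invalid, controller must hold in failsafe)
#' @param at_min_post_resus onset, minutes after resuscitation start
#' @param duration_min duration (min)
#' @param magnitude for `transfer_dip`, the SVR multiplier (default 0.85,
#'   about a 10 mmHg MAP dip); ignored for dropouts
#' @return a disturbance spec (list)
#' @export
disturbance <- function(kind, at_min_post_resus, duration_min,
                        magnitude = 0.85) {
  list(kind = kind, at_min_post_resus = at_min_post_resus,
       duration_min = duration_min, magnitude = magnitude)
}

#' Preset scenarios
#'
#' `scenario_lab()`: laboratory resuscitation, no disturbances.
#' `scenario_transport()`: two transfer dips (stretcher transfer shortly
#' after the initial blood/CaCl2 sequence, and the return transfer) with
#' mild desaturation. `scenario_natural()`: no packing, no treatment
#' (natural history). `scenario_dropout()`: a 25-min signal dropout starting
#' mid-cycling.
#'
#' @param ... overrides passed to [scenario_config()]
#' @return a `scenario_config`
#' @export
scenario_lab <- function(...) scenario_config(name = "lab", ...)

#' @rdname scenario_lab
#' @export
scenario_transport <- function(...) {
  scenario_config(
    name = "transport",
    disturbances = list(disturbance("transfer_dip", 12, 2),
                        disturbance("transfer_dip", 100, 2)),
    sao2 = 97, ...)
}

#' @rdname scenario_lab
#' @export
scenario_natural <- function(...) {
  scenario_config(name = "natural", treatment_enabled = FALSE, ...)
}

#' @rdname scenario_lab
#' @export
scenario_dropout <- function(dropout_at_min = 40, dropout_min = 25, ...) {
  scenario_config(
    name = "dropout",
    disturbances = list(disturbance("signal_dropout", dropout_at_min,
                                    dropout_min)),
    ...)
}

trend_cols <- c("t_s", "map", "hr", "ppv", "svv", "eadyn", "svo2", "lactate",
                "co", "hgb", "V_blood", "ne_rate", "alive")

#' Run one scenario end to end
#'
#' Closes the loop at a 1-s tick: the simulated pig is advanced by explicit
#' Euler substeps, per-beat systolic/diastolic/stroke-volume values are
#' synthesized at the ventilator-modulated heart rhythm, windowed snapshots
#' drive the hypotension trigger and (after activation) the controller, and
#' controller commands are executed by the virtual infusion pumps. Fully
#' deterministic for a given configuration.
#'
#' @param cfg a [scenario_config()]
#' @return an object of class `refit_run`: list with `trend` (1-Hz
#'   data.frame), `ledger` (command data.frame), `times` (injury, trigger,
#'   resuscitation start, end; s), `time_to_stabilization_min` (per the
#'   ledger definition; `NA` when no crystalloid was ever needed),
#'   `stabilized` (stabilization time defined, or no crystalloid needed and
#'   a command-free cycle reached),
#'   `survived_3h`, `totals` (to-stabilization and stabilization-to-2-h
#'   windows), `controller`, `pig`
#' @export
run_scenario <- function(cfg) {
  stopifnot(inherits(cfg, "scenario_config"))
  p <- cfg$pig
  ccfg <- cfg$controller
  scfg <- cfg$signal
  sao2 <- cfg$sao2 %||% p$sao2
  monitored <- cfg$treatment_enabled

  injury_t <- cfg$baseline_min * 60
  delay_s <- cfg$trigger_delay_to_resus_min * 60
  resus_s <- cfg$resus_duration_min * 60
  follow_end <- injury_t + cfg$follow_untreated_min * 60
  abort_t <- injury_t + cfg$max_trigger_wait_min * 60
  max_ticks <- ceiling(max(follow_end,
                           injury_t + cfg$max_trigger_wait_min * 60 +
                             delay_s + resus_s)) + 10

  st <- pig_init(p)
  trend <- matrix(NA_real_, nrow = max_ticks, ncol = length(trend_cols))

  # beat buffer (sensed beats only)
  cap <- 65536L
  bt <- bsys <- bdia <- bpp <- bsv <- numeric(cap)
  nb <- 0L
  lo <- 1L
  next_beat <- 0

  # hypotension-trigger ring buffer over the 5-min window, 1 Hz
  tw <- as.integer(scfg$trigger_window)
  ring <- integer(tw)
  rpos <- 0L
  rfill <- 0L
  rcnt <- 0L
  trigger_t <- NA_real_
  resus_start <- NA_real_
  end_t <- if (cfg$treatment_enabled) Inf else follow_end

  ctrl <- NULL
  ne_rate <- 0
  # active boluses: parallel vectors channel/rate/t_end
  ab_ch <- character(0)
  ab_rate <- numeric(0)
  ab_end <- numeric(0)
  dist_abs <- NULL
  alive_3h <- NA

  horizon <- max(scfg$window, scfg$validity_horizon)
  i <- 0L
  t1 <- 0
  while (t1 < end_t && i < max_ticks) {
    i <- i + 1L
    t0 <- t1
    t1 <- i * 1

    if (is.na(trigger_t) && cfg$treatment_enabled && t0 >= abort_t) {
      end_t <- t0                      # trigger never fired; abort run
      i <- i - 1L
      t1 <- t0
      break
    }

    # injury onset
    if (!st$injured[1] && t0 >= injury_t) st <- pig_injure(st)

    # disturbances active during this tick
    svr_factor <- 1
    dropout <- FALSE
    if (!is.null(dist_abs)) {
      for (d in dist_abs) {
        if (t0 >= d$t0 && t0 < d$t1) {
          if (d$kind == "transfer_dip") svr_factor <- d$magnitude
          if (d$kind == "signal_dropout") dropout <- TRUE
        }
      }
    }

    # pump rates for this tick
    inf <- list(blood_rate = 0, ringers_rate = 0, ne_rate = ne_rate,
                cacl2_rate = 0)
    if (length(ab_ch)) {
      act <- ab_end > t0
      if (any(act)) {
        for (k in which(act)) {
          ch <- ab_ch[k]
          if (ch == "whole_blood") inf$blood_rate <- inf$blood_rate + ab_rate[k]
          else if (ch == "ringers") inf$ringers_rate <- inf$ringers_rate + ab_rate[k]
          else if (ch == "cacl2") inf$cacl2_rate <- inf$cacl2_rate + ab_rate[k]
        }
      }
      if (!all(act)) {
        ab_ch <- ab_ch[act]; ab_rate <- ab_rate[act]; ab_end <- ab_end[act]
      }
    }

    for (s in 1:10) {
      st <- pig_step(st, inf, dt = 0.1, params = p, svr_factor = svr_factor,
                     sao2 = sao2)
    }

    snap <- NULL
    if (monitored) {
      # synthesize the beats of this tick; sensed only outside dropouts
      while (next_beat <= t1 && st$alive[1] && st$hr[1] > 0) {
        if (!dropout) {
          b <- beat_values(st$map[1], st$sv[1], st$ppv_true[1],
                           st$svv_true[1], next_beat, p)
          if (nb == cap) {
            cap <- cap * 2L
            length(bt) <- cap; length(bsys) <- cap; length(bdia) <- cap
            length(bpp) <- cap; length(bsv) <- cap
          }
          nb <- nb + 1L
          bt[nb] <- next_beat; bsys[nb] <- b$sys; bdia[nb] <- b$dia
          bpp[nb] <- b$pp; bsv[nb] <- b$sv
        }
        next_beat <- next_beat + 60 / st$hr[1]
      }
      while (lo <= nb && bt[lo] <= t1 - horizon) lo <- lo + 1L
      idx <- if (lo <= nb) lo:nb else integer(0)
      snap <- snapshot_core(bt[idx], bsys[idx], bdia[idx], bpp[idx],
                            bsv[idx], t1, scfg)
    }

    # hypotension trigger (post-injury, pre-trigger)
    if (is.na(trigger_t) && t0 >= injury_t) {
      m <- if (monitored) {
        if (isTRUE(snap$valid)) snap$map else NA_real_
      } else st$map[1]
      if (!is.na(m)) {
        bel <- as.integer(m < scfg$trigger_threshold)
        rpos <- rpos %% tw + 1L
        if (rfill == tw) rcnt <- rcnt - ring[rpos] else rfill <- rfill + 1L
        ring[rpos] <- bel
        rcnt <- rcnt + bel
        if (rfill == tw && rcnt / tw > scfg$trigger_frac) {
          trigger_t <- t1
          if (cfg$treatment_enabled) {
            st <- pig_pack(st)
            resus_start <- trigger_t + delay_s
            end_t <- resus_start + resus_s
            dist_abs <- lapply(cfg$disturbances, function(d) {
              list(kind = d$kind,
                   t0 = resus_start + d$at_min_post_resus * 60,
                   t1 = resus_start + (d$at_min_post_resus +
                                         d$duration_min) * 60,
                   magnitude = d$magnitude)
            })
          }
        }
      }
    }

    # controller
    if (cfg$treatment_enabled && !is.na(resus_start) && t1 >= resus_start) {
      if (is.null(ctrl)) ctrl <- controller_init(ccfg)
      res <- controller_step(ctrl, snap, t1, ccfg)
      ctrl <- res$state
      for (cmd in res$cmds) {
        if (cmd$kind == "bolus") {
          ab_ch <- c(ab_ch, cmd$channel)
          ab_rate <- c(ab_rate, cmd$amount / cmd$duration_min)
          ab_end <- c(ab_end, cmd$t_issued + cmd$duration_min * 60)
        } else if (cmd$kind == "rate_set") {
          ne_rate <- cmd$amount
        }
      }
    }

    if (is.na(alive_3h) && t1 >= injury_t + 180 * 60) alive_3h <- st$alive[1]

    if (monitored) {
      trend[i, ] <- c(t1, snap$map, snap$hr, snap$ppv, snap$svv, snap$eadyn,
                      st$svo2[1], st$lactate[1], st$co[1], st$hgb[1],
                      st$V_blood[1], ne_rate, as.numeric(st$alive[1]))
    } else {
      trend[i, ] <- c(t1, st$map[1], st$hr[1], st$ppv_true[1],
                      st$svv_true[1], st$eadyn_true[1], st$svo2[1],
                      st$lactate[1], st$co[1], st$hgb[1], st$V_blood[1],
                      ne_rate, as.numeric(st$alive[1]))
    }
  }

  trend <- as.data.frame(trend[seq_len(i), , drop = FALSE])
  names(trend) <- trend_cols

  ledger <- controller_log(ctrl %||% list())
  stab <- NA_real_
  stabilized <- FALSE
  totals <- NULL
  if (!is.null(ctrl)) {
    ctrl <- controller_stop(ctrl)
    stab <- time_to_initial_stabilization(ledger, ctrl$cycle_starts,
                                          ctrl$resus_start)
    # subjects for whom the two blood units alone met the stopping rules
    # never receive crystalloid, so the ledger-based stabilization time is
    # undefined; they count as stabilized if any full cycle was command-free
    quiet <- any(vapply(ctrl$cycle_starts, function(s) {
      sum(ledger$t_issued >= s & ledger$t_issued < s + 15 * 60) == 0
    }, TRUE))
    stabilized <- !is.na(stab) ||
      (!any(ledger$channel == "ringers") && quiet)
    stab_abs <- if (is.na(stab)) end_t else ctrl$resus_start + stab * 60
    totals <- list(
      to_stabilization = summarize_run(ledger, ccfg$weight_kg,
                                       c(ctrl$resus_start, stab_abs)),
      stabilization_to_2h = if (stab_abs < end_t) {
        summarize_run(ledger, ccfg$weight_kg,
                      c(stab_abs, min(stab_abs + 120 * 60, end_t)))
      } else NULL
    )
  }
  if (is.na(alive_3h)) alive_3h <- st$alive[1]

  run <- structure(list(
    trend = trend, ledger = ledger,
    times = list(injury = injury_t, trigger = trigger_t,
                 resus_start = resus_start, end = t1),
    time_to_stabilization_min = stab,
    stabilized = stabilized,
    survived_3h = isTRUE(as.logical(alive_3h)),
    totals = totals, controller = ctrl, pig = st, config = cfg
  ), class = "refit_run")

  if (!is.null(cfg$output_dir)) write_run(run, cfg$output_dir)
  run
}

# write the one-directory-per-run output layout
write_run <- function(run, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(run$trend, file.path(dir, "trend.csv"), row.names = FALSE)
  led <- run$ledger
  names(led) <- c("t_s", "channel", "kind", "amount", "unit", "duration_min")
  utils::write.csv(led, file.path(dir, "ledger.csv"), row.names = FALSE)
  cfg <- run$config
  cfg$output_dir <- NULL
  jsonlite::write_json(unclass_deep(cfg), file.path(dir, "config.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  jsonlite::write_json(
    list(name = run$config$name, times = run$times,
         time_to_stabilization_min = run$time_to_stabilization_min,
         stabilized = run$stabilized,
         survived_3h = run$survived_3h, totals = run$totals),
    file.path(dir, "summary.json"), auto_unbox = TRUE, digits = NA,
    null = "null")
  if (isTRUE(run$config$write_plot)) {
    ggplot2::ggsave(file.path(dir, "trends.png"), render_trends(run),
                    width = 8, height = 10, dpi = 120)
  }
  invisible(dir)
}

unclass_deep <- function(x) {
  if (is.list(x)) lapply(unclass(x), unclass_deep) else x
}

#' Run a cohort of subjects through a scenario
#'
#' Samples `n` pigs with the scenario seed and runs each through the
#' protocol. Treated cohorts run the full closed loop per subject; untreated
#' cohorts are advanced with the vectorized simulator (injury at time zero,
#' no monitoring), which is exactly equivalent to per-subject runs because
#' untreated physiology does not depend on the monitoring path.
#'
#' @param cfg a [scenario_config()]
#' @param n cohort size (default `cfg$cohort_n`)
#' @param cv cohort coefficient of variation passed to [sample_cohort()]
#' @return an object of class `refit_cohort_result`: `subjects` data.frame
#'   (per-subject outcomes), `summary` list of means and standard deviations
#'   plus the survival fractions, and for treated cohorts the list of runs
#' @export
run_cohort <- function(cfg, n = cfg$cohort_n, cv = 0.10) {
  stopifnot(inherits(cfg, "scenario_config"), n >= 1)
  cohort <- sample_cohort(n, cfg$seed, params0 = cfg$pig, cv = cv)

  if (!cfg$treatment_enabled) {
    pv <- bind_cohort(cohort)
    st <- pig_init(pv, n = n)
    st <- pig_injure(st)
    ticks <- cfg$follow_untreated_min * 60
    for (i in seq_len(ticks * 10)) {
      st <- pig_step(st, list(), dt = 0.1, params = pv,
                     sao2 = cfg$sao2 %||% pv$sao2)
    }
    death_min <- (st$death_time - 0) / 60
    subjects <- data.frame(
      id = seq_len(n), weight = pv$weight,
      survived_60min = is.na(death_min) | death_min > 60,
      survived_end = st$alive,
      death_time_min = death_min,
      map_end = st$map, hr_end = st$hr, lactate_end = st$lactate
    )
    summary <- list(
      n = n,
      mortality_60min_pct = 100 * mean(!subjects$survived_60min),
      mortality_end_pct = 100 * mean(!subjects$survived_end),
      follow_min = cfg$follow_untreated_min
    )
    return(structure(list(subjects = subjects, summary = summary,
                          cohort = cohort, final_state = st),
                     class = "refit_cohort_result"))
  }

  runs <- vector("list", n)
  rows <- vector("list", n)
  for (k in seq_len(n)) {
    pk <- cohort[[k]]
    ck <- cfg
    ck$pig <- pk
    ck$controller$weight_kg <- pk$weight
    ck$output_dir <- if (!is.null(cfg$output_dir)) {
      file.path(cfg$output_dir, sprintf("subject_%02d", k))
    } else NULL
    runs[[k]] <- run_scenario(ck)
    r <- runs[[k]]
    tot1 <- r$totals$to_stabilization
    tot2 <- r$totals$stabilization_to_2h
    rows[[k]] <- data.frame(
      id = k, weight = pk$weight,
      survived_3h = r$survived_3h,
      stabilized = r$stabilized,
      time_to_stabilization_min = r$time_to_stabilization_min,
      trigger_min_post_injury = (r$times$trigger - r$times$injury) / 60,
      fluid_to_stab_ml_kg = if (!is.null(tot1)) tot1$fluid_ml_per_kg else NA,
      ne_to_stab_ug_kg = if (!is.null(tot1)) tot1$ne_total_ug_per_kg else NA,
      fluid_stab_2h_ml_kg = if (!is.null(tot2)) tot2$fluid_ml_per_kg else NA,
      ne_stab_2h_ug_kg = if (!is.null(tot2)) tot2$ne_total_ug_per_kg else NA
    )
  }
  subjects <- do.call(rbind, rows)
  msd <- function(x) {
    x <- x[!is.na(x)]
    if (!length(x)) return(list(mean = NA_real_, sd = NA_real_))
    list(mean = mean(x), sd = if (length(x) > 1) stats::sd(x) else NA_real_)
  }
  summary <- list(
    n = n,
    survived_3h = sum(subjects$survived_3h),
    survival_fraction = mean(subjects$survived_3h),
    stabilized = sum(subjects$stabilized),
    time_to_stabilization_min = msd(subjects$time_to_stabilization_min),
    fluid_to_stab_ml_kg = msd(subjects$fluid_to_stab_ml_kg),
    ne_to_stab_ug_kg = msd(subjects$ne_to_stab_ug_kg),
    fluid_stab_2h_ml_kg = msd(subjects$fluid_stab_2h_ml_kg),
    ne_stab_2h_ug_kg = msd(subjects$ne_stab_2h_ug_kg)
  )
  structure(list(subjects = subjects, summary = summary, runs = runs,
                 cohort = cohort),
            class = "refit_cohort_result")
}
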