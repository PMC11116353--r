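#' Closed-loop controller configuration
#'
#' Thresholds, dose tables and cadence of the resuscitation decision engine.
#' Defaults are the published protocol values: resuscitation is needed when
#' MAP < 60 mmHg or HR > 110 min^-1 (stopping when both are within limits);
#' crystalloid boluses follow the PPV scale (>=10 to <30 % -> 5 ml/kg, >=30
#' to <50 % -> 8 ml/kg, >=50 % -> 10 ml/kg); norepinephrine starts at 0.03
#' and moves in 0.01 ug/kg/min steps up to 0.3, weaning only when MAP held
#' above target for a full cycle with no fluid and Ea_dyn > 1. The MAP
#' target is operator-settable.
#'
#' @param weight_kg subject weight (kg), used to scale ml/kg boluses
#' @param map_target MAP target (mmHg), default 60
#' @param hr_threshold HR threshold (min^-1), default 110
#' @param ppv_cuts PPV breakpoints (%), strictly increasing
#' @param fluid_doses crystalloid doses (ml/kg) for the PPV bands above each
#'   cut, strictly increasing
#' @param ne_start initial norepinephrine rate (ug/kg/min)
#' @param ne_step norepinephrine titration step (ug/kg/min)
#' @param ne_max maximal norepinephrine rate (ug/kg/min)
#' @param eadyn_wean_threshold Ea_dyn gate for weaning (dimensionless)
#' @param blood_bolus_ml whole-blood bolus volume (ml)
#' @param cacl2_dose_g CaCl2 dose (g)
#' @param bolus_duration_min bolus infusion duration (min)
#' @param phase_lengths_min lengths of the treat / equilibrate / assess
#'   phases (min)
#' @param observe_min post-failsafe observation interval before cycles
#'   resume (min)
#' @param tick_s control tick (s)
#' @return an object of class `controller_config`
#' @export
controller_config <- function(weight_kg = 30.8,
                              map_target = 60,
                              hr_threshold = 110,
                              ppv_cuts = c(10, 30, 50),
                              fluid_doses = c(5, 8, 10),
                              ne_start = 0.03,
                              ne_step = 0.01,
                              ne_max = 0.3,
                              eadyn_wean_threshold = 1.0,
                              blood_bolus_ml = 250,
                              cacl2_dose_g = 1,
                              bolus_duration_min = 5,
                              phase_lengths_min = c(5, 5, 5),
                              observe_min = 15,
                              tick_s = 1) {
  stopifnot(weight_kg > 0, ne_start > 0, ne_start <= ne_max, ne_step > 0,
            length(ppv_cuts) == length(fluid_doses),
            !is.unsorted(ppv_cuts, strictly = TRUE),
            !is.unsorted(fluid_doses, strictly = TRUE),
            length(phase_lengths_min) == 3, all(phase_lengths_min > 0))
  structure(list(weight_kg = weight_kg, map_target = map_target,
                 hr_threshold = hr_threshold, ppv_cuts = ppv_cuts,
                 fluid_doses = fluid_doses, ne_start = ne_start,
                 ne_step = ne_step, ne_max = ne_max,
                 eadyn_wean_threshold = eadyn_wean_threshold,
                 blood_bolus_ml = blood_bolus_ml, cacl2_dose_g = cacl2_dose_g,
                 bolus_duration_min = bolus_duration_min,
                 phase_lengths_min = phase_lengths_min,
                 observe_min = observe_min, tick_s = tick_s),
            class = "controller_config")
}

#' Does the subject need resuscitation?
#'
#' Initiation/continuation rule: MAP below target OR HR above threshold
#' (either abnormal vital sign indicates circulatory insufficiency). The
#' stopping condition is the negation: MAP at/above target AND HR at/below
#' threshold. Comparisons are strict, as printed.
#'
#' @param snap a valid [hemo_snapshot()]
#' @param cfg a [controller_config()]
#' @return logical
#' @export
needs_resuscitation <- function(snap, cfg) {
  if (!isTRUE(snap$valid)) {
    stop("invalid snapshot: route to failsafe, not to the decision rules")
  }
  snap$map < cfg$map_target || snap$hr > cfg$hr_threshold
}

#' PPV-proportional crystalloid dose
#'
#' The printed dose table: no infusion below 10 %, 5 ml/kg for PPV in
#' \[10, 30), 8 ml/kg in \[30, 50), 10 ml/kg at or above 50 % (left-closed
#' bands). Vectorized over `ppv`.
#'
#' @param ppv pulse pressure variation (%), non-negative
#' @param cfg a [controller_config()]
#' @return dose in ml/kg
#' @export
fluid_dose <- function(ppv, cfg = controller_config()) {
  if (any(is.na(ppv)) || any(ppv < 0)) stop("ppv must be non-negative")
  c(0, cfg$fluid_doses)[findInterval(ppv, cfg$ppv_cuts) + 1]
}

#' Norepinephrine titration rule
#'
#' Start at `ne_start` when MAP is below target and no norepinephrine is
#' running (only after the first crystalloid bolus has been given); step up
#' by `ne_step` to at most `ne_max` while MAP remains below target; wean one
#' step when MAP was held above target for the whole preceding cycle, no
#' fluid was needed, and Ea_dyn exceeds the wean threshold; otherwise leave
#' the rate unchanged.
#'
#' @param snap the governing [hemo_snapshot()]
#' @param state controller state (fields `ne_rate`, `first_lr_given`,
#'   `map_held_above` are read)
#' @param cycle_had_fluid logical: was a crystalloid bolus given in the
#'   evaluated cycle
#' @param cfg a [controller_config()]
#' @return the new norepinephrine rate (ug/kg/min)
#' @export
ne_adjust <- function(snap, state, cycle_had_fluid, cfg) {
  rate <- state$ne_rate
  if (isTRUE(snap$map < cfg$map_target)) {
    if (!isTRUE(state$first_lr_given)) return(rate)
    if (rate == 0) return(cfg$ne_start)
    return(min(rate + cfg$ne_step, cfg$ne_max))
  }
  if (isTRUE(state$map_held_above) && !isTRUE(cycle_had_fluid) &&
      isTRUE(snap$eadyn > cfg$eadyn_wean_threshold) && rate > 0) {
    return(max(rate - cfg$ne_step, 0))
  }
  rate
}

#' Initialize controller state
#'
#' @param cfg a [controller_config()]
#' @return an object of class `controller_state`, mode `IDLE`
#' @export
controller_init <- function(cfg) {
  structure(list(
    mode = "IDLE", phase = NA_character_,
    mode_entered = NA_real_, cycle_start = NA_real_, cycle_index = 0L,
    cycle_starts = numeric(0), resus_start = NA_real_,
    ne_rate = 0, first_lr_given = FALSE,
    map_held_above = FALSE,            # previous completed cycle
    prev_had_fluid = FALSE,
    cur_map_held = TRUE, cur_had_fluid = FALSE,
    last_valid_snap = NULL, assess_snap = NULL,
    obs_until = NA_real_, t_last = NA_real_,
    log = list()
  ), class = "controller_state")
}

new_command <- function(t, channel, kind, amount, unit, duration_min = NA) {
  list(t_issued = t, channel = channel, kind = kind, amount = amount,
       unit = unit, duration_min = duration_min)
}

#' Command ledger as a data frame
#'
#' @param state a `controller_state` (or a list of command lists)
#' @return data.frame `t_issued`, `channel`, `kind`, `amount`, `unit`,
#'   `duration_min`
#' @export
controller_log <- function(state) {
  log <- if (inherits(state, "controller_state")) state$log else state
  if (length(log) == 0) {
    return(data.frame(t_issued = numeric(0), channel = character(0),
                      kind = character(0), amount = numeric(0),
                      unit = character(0), duration_min = numeric(0)))
  }
  do.call(rbind, lapply(log, function(x) {
    data.frame(t_issued = x$t_issued, channel = x$channel, kind = x$kind,
               amount = x$amount, unit = x$unit,
               duration_min = x$duration_min)
  }))
}

# TREAT-phase decision, executed once at the start of each 15-min cycle
treat_decisions <- function(state, t, cfg) {
  cmds <- list()
  gov <- state$assess_snap %||% state$last_valid_snap
  if (is.null(gov) || !isTRUE(gov$valid)) {
    return(list(state = state, cmds = cmds))
  }
  needs <- needs_resuscitation(gov, cfg)
  gave_fluid <- FALSE
  if (needs && !is.na(gov$ppv) && gov$ppv >= cfg$ppv_cuts[1]) {
    dose <- fluid_dose(gov$ppv, cfg)
    if (dose > 0) {
      cmds[[length(cmds) + 1]] <- new_command(
        t, "ringers", "bolus", dose * cfg$weight_kg, "ml",
        cfg$bolus_duration_min)
      gave_fluid <- TRUE
    }
  }
  # norepinephrine is evaluated against the state as of cycle start: a bolus
  # just commanded has not infused yet, so the first crystalloid dose cannot
  # enable a norepinephrine start within the same TREAT phase
  eval_state <- state
  new_rate <- ne_adjust(gov, eval_state, state$prev_had_fluid, cfg)
  if (new_rate != state$ne_rate) {
    cmds[[length(cmds) + 1]] <- new_command(
      t, "norepinephrine", "rate_set", new_rate, "ug/kg/min")
    state$ne_rate <- new_rate
  }
  if (gave_fluid) {
    state$cur_had_fluid <- TRUE
    state$first_lr_given <- TRUE
  }
  list(state = state, cmds = cmds)
}

start_cycle <- function(state, t, cfg) {
  state$mode <- "CYCLING"
  state$phase <- "TREAT"
  state$cycle_start <- t
  state$cycle_index <- state$cycle_index + 1L
  state$cycle_starts <- c(state$cycle_starts, t)
  state$cur_map_held <- TRUE
  state$cur_had_fluid <- FALSE
  res <- treat_decisions(state, t, cfg)
  res$state$assess_snap <- NULL
  res
}

#' Advance the controller by one tick
#'
#' Runs the finite-state machine: on activation the initial whole-blood
#' bolus is emitted, followed by CaCl2 and one equilibration phase; a second
#' blood unit is given only if the stopping rules are still unmet; cycling
#' then proceeds in 15-min treat / equilibrate / assess cycles with
#' PPV-proportional crystalloid boluses and stepwise norepinephrine
#' titration. An invalid snapshot at any tick switches the controller into
#' FAILSAFE (norepinephrine held, no new boluses); after the signal returns,
#' one observation interval elapses before cycles resume.
#'
#' @param state a `controller_state`
#' @param snap the current [hemo_snapshot()]
#' @param t current time (s); must not regress
#' @param cfg a [controller_config()]
#' @return list with `state` (updated) and `cmds` (list of pump commands,
#'   possibly empty)
#' @export
controller_step <- function(state, snap, t, cfg) {
  if (!is.na(state$t_last) && t < state$t_last) {
    stop("controller tick time regression")
  }
  state$t_last <- t
  cmds <- list()
  emit <- function(cmd) cmds[[length(cmds) + 1]] <<- cmd

  if (state$mode == "STOPPED") {
    return(list(state = state, cmds = cmds))
  }

  if (state$mode == "IDLE") {
    # activation: initial whole-blood bolus regardless of monitoring state
    state$mode <- "INITIAL_BLOOD"
    state$mode_entered <- t
    state$resus_start <- t
    emit(new_command(t, "whole_blood", "bolus", cfg$blood_bolus_ml, "ml",
                     cfg$bolus_duration_min))
    if (isTRUE(snap$valid)) state$last_valid_snap <- snap
    state$log <- c(state$log, cmds)
    return(list(state = state, cmds = cmds))
  }

  # failsafe entry/exit
  if (!isTRUE(snap$valid)) {
    if (state$mode != "FAILSAFE") {
      state$mode <- "FAILSAFE"
      state$phase <- NA_character_
      state$cur_map_held <- TRUE          # observation tracker reused
    }
    state$obs_until <- NA_real_           # observation restarts on return
    return(list(state = state, cmds = cmds))
  }
  state$last_valid_snap <- snap

  if (state$mode == "FAILSAFE") {
    if (is.na(state$obs_until)) {
      state$obs_until <- t + cfg$observe_min * 60
      state$cur_map_held <- TRUE
    }
    state$cur_map_held <- state$cur_map_held && snap$map > cfg$map_target
    if (t >= state$obs_until) {
      # the observation interval stands in for the preceding cycle: no fluid
      # was given, and MAP held above target enables immediate weaning
      state$map_held_above <- state$cur_map_held
      state$prev_had_fluid <- FALSE
      state$obs_until <- NA_real_
      state$assess_snap <- snap
      res <- start_cycle(state, t, cfg)
      state <- res$state
      for (cmd in res$cmds) emit(cmd)
      state$log <- c(state$log, cmds)
    }
    return(list(state = state, cmds = cmds))
  }

  sec <- function(min) min * 60
  if (state$mode == "INITIAL_BLOOD") {
    if (t >= state$mode_entered + sec(cfg$bolus_duration_min)) {
      state$mode <- "CACL2"
      state$mode_entered <- t
      emit(new_command(t, "cacl2", "bolus", cfg$cacl2_dose_g, "g",
                       cfg$bolus_duration_min))
    }
  } else if (state$mode == "CACL2") {
    # CaCl2 infusion plus one equilibration phase, then the one-time
    # second-blood check against the stopping rules
    if (t >= state$mode_entered +
        sec(cfg$bolus_duration_min + cfg$phase_lengths_min[2])) {
      gov <- state$last_valid_snap
      if (needs_resuscitation(gov, cfg)) {
        state$mode <- "SECOND_BLOOD"
        state$mode_entered <- t
        emit(new_command(t, "whole_blood", "bolus", cfg$blood_bolus_ml, "ml",
                         cfg$bolus_duration_min))
      } else {
        state$assess_snap <- gov
        res <- start_cycle(state, t, cfg)
        state <- res$state
        for (cmd in res$cmds) emit(cmd)
      }
    }
  } else if (state$mode == "SECOND_BLOOD") {
    if (t >= state$mode_entered + sec(cfg$bolus_duration_min)) {
      state$assess_snap <- state$last_valid_snap
      res <- start_cycle(state, t, cfg)
      state <- res$state
      for (cmd in res$cmds) emit(cmd)
    }
  } else if (state$mode == "CYCLING") {
    state$cur_map_held <- state$cur_map_held && snap$map > cfg$map_target
    pos <- t - state$cycle_start
    pl <- sec(cfg$phase_lengths_min)
    if (pos >= sum(pl)) {
      state$map_held_above <- state$cur_map_held
      state$prev_had_fluid <- state$cur_had_fluid
      res <- start_cycle(state, t, cfg)
      state <- res$state
      for (cmd in res$cmds) emit(cmd)
    } else if (pos >= pl[1] + pl[2]) {
      state$phase <- "ASSESS"
      state$assess_snap <- snap
    } else if (pos >= pl[1]) {
      state$phase <- "EQUILIBRATE"
    } else {
      state$phase <- "TREAT"
    }
  }

  state$log <- c(state$log, cmds)
  list(state = state, cmds = cmds)
}

#' Stop the controller (scenario end)
#'
#' @param state a `controller_state`
#' @return state with mode `STOPPED`
#' @export
controller_stop <- function(state) {
  state$mode <- "STOPPED"
  state
}

#' Time to initial stabilization
#'
#' Minutes from the start of resuscitation to the start of the first 15-min
#' cycle, after the first crystalloid bolus was given, in which no treatment
#' was given or changed. `NA` if no crystalloid was ever given or no
#' qualifying cycle exists.
#'
#' @param log command ledger (data.frame from [controller_log()] or the raw
#'   list)
#' @param cycle_starts numeric vector of cycle start times (s)
#' @param resus_start resuscitation start time (s)
#' @param cycle_min cycle length (min), default 15
#' @return minutes, or `NA_real_`
#' @export
time_to_initial_stabilization <- function(log, cycle_starts, resus_start,
                                          cycle_min = 15) {
  if (!is.data.frame(log)) log <- controller_log(log)
  lr <- log$t_issued[log$channel == "ringers"]
  if (length(lr) == 0) return(NA_real_)
  t_lr <- min(lr)
  for (s in sort(cycle_starts)) {
    if (s <= t_lr) next
    n_cmd <- sum(log$t_issued >= s & log$t_issued < s + cycle_min * 60)
    if (n_cmd == 0) return((s - resus_start) / 60)
  }
  NA_real_
}

#' Totals of a treatment window
#'
#' Crystalloid volume per kg (bolus amounts prorated by the overlap of their
#' infusion interval with the window), whole blood and CaCl2 delivered, the
#' norepinephrine dose integral over the window and its mean rate.
#'
#' @param log command ledger (data.frame or raw list)
#' @param weight subject weight (kg)
#' @param window numeric `c(t_a, t_b)` in seconds, `t_a < t_b`
#' @return list: `fluid_ml_per_kg`, `blood_ml`, `cacl2_g`,
#'   `ne_total_ug_per_kg`, `ne_mean_rate`
#' @export
summarize_run <- function(log, weight, window) {
  stopifnot(length(window) == 2, window[1] < window[2])
  if (!is.data.frame(log)) log <- controller_log(log)
  ta <- window[1]
  tb <- window[2]
  bolus_in <- function(channel) {
    b <- log[log$channel == channel & log$kind == "bolus", , drop = FALSE]
    if (nrow(b) == 0) return(0)
    t0 <- b$t_issued
    t1 <- b$t_issued + b$duration_min * 60
    overlap <- pmax(0, pmin(t1, tb) - pmax(t0, ta))
    sum(b$amount * overlap / (t1 - t0))
  }
  rs <- log[log$channel == "norepinephrine" & log$kind == "rate_set", ,
            drop = FALSE]
  times <- c(ta, rs$t_issued[rs$t_issued > ta & rs$t_issued < tb], tb)
  rate_at <- function(t) {
    prior <- rs$amount[rs$t_issued <= t]
    if (length(prior) == 0) 0 else prior[length(prior)]
  }
  rates <- vapply(times[-length(times)], rate_at, 0)
  ne_total <- sum(rates * diff(times)) / 60          # ug/kg
  dur_min <- (tb - ta) / 60
  list(fluid_ml_per_kg = bolus_in("ringers") / weight,
       blood_ml = bolus_in("whole_blood"),
       cacl2_g = bolus_in("cacl2"),
       ne_total_ug_per_kg = ne_total,
       ne_mean_rate = ne_total / dur_min)
}
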