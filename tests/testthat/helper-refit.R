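# fixtures are built in code: waveforms, beat tables, scripted snapshot
# streams and independent brute-force oracles

# uniform-rate waveform of identical beats (sys/dia in mmHg), sampled at fs,
# ending exactly on a diastolic trough so every cycle closes
square_cycles <- function(n_cycles = 10, sys = 120, dia = 80, period = 1,
                          fs = 100) {
  t <- seq(0, n_cycles * period, by = 1 / fs)
  phi <- (t %% period) / period
  p <- dia + (sys - dia) * sin(pi * phi)^5
  p[length(p)] <- dia
  data.frame(t_s = t, p_mmHg = p)
}

# beat table straight from numbers (simulator-ledger shape)
beat_table <- function(t, pp, sv = NA_real_, dia = 80) {
  data.frame(t = t, systolic = dia + pp, diastolic = dia,
             pulse_pressure = pp, stroke_volume = sv)
}

# scripted snapshot
snap <- function(map, hr = 90, ppv = 5, svv = 5, eadyn = 1, t = 0,
                 valid = TRUE) {
  structure(list(t = t, map = map, hr = hr, ppv = ppv, svv = svv,
                 eadyn = eadyn, valid = valid), class = "hemo_snapshot")
}

invalid_snap <- function(t = 0) {
  structure(list(t = t, map = NA_real_, hr = NA_real_, ppv = NA_real_,
                 svv = NA_real_, eadyn = NA_real_, valid = FALSE),
            class = "hemo_snapshot")
}

# independent oracle: explicit loop over beats in the window
brute_ppv <- function(beats, t, window = 20, min_beats = 5) {
  mx <- -Inf; mn <- Inf; s <- 0; n <- 0
  for (i in seq_len(nrow(beats))) {
    if (beats$t[i] > t - window && beats$t[i] <= t) {
      x <- beats$pulse_pressure[i]
      if (x > mx) mx <- x
      if (x < mn) mn <- x
      s <- s + x; n <- n + 1
    }
  }
  if (n < min_beats) return(NA_real_)
  100 * (mx - mn) / (s / n)
}

# independent oracle: quadratic scan for the hypotension trigger
brute_trigger <- function(tt, map, threshold = 40, window = 300,
                          frac = 0.8) {
  for (i in seq_along(tt)) {
    if (tt[i] - tt[1] < window) next
    sel <- tt > tt[i] - window & tt <= tt[i]
    if (mean(map[sel] < threshold) > frac) return(tt[i])
  }
  NA_real_
}

# drive a controller against a function(t) -> snapshot at a 1-s tick,
# returning the final state and the full command data frame
drive_controller <- function(snap_fun, t_end, cfg, t_start = 0) {
  state <- controller_init(cfg)
  for (t in seq(t_start, t_end, by = 1)) {
    state <- controller_step(state, snap_fun(t), t, cfg)$state
  }
  list(state = state, log = controller_log(state))
}
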