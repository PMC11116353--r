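#' Signal-processing configuration
#'
#' Windowing and validity parameters for the feature extractor. One 20-s
#' moving window drives PPV, SVV, MAP and HR for control decisions; the
#' 5-min window is used only by the hypotension trigger.
#'
#' @param window feature window (s) for PPV/SVV/MAP/HR
#' @param validity_horizon seconds without a detected beat after which the
#'   signal is declared invalid (failsafe input)
#' @param min_beats minimum beats in the window for PPV/SVV to be defined
#' @param min_pp minimum pulse pressure (mmHg) for a detected beat
#' @param refractory beat-detection refractory period (s)
#' @param trigger_threshold hypotension trigger MAP threshold (mmHg)
#' @param trigger_window hypotension trigger moving window (s)
#' @param trigger_frac fraction of window samples that must be below
#'   threshold (strictly exceeded)
#' @param sample_hz default waveform sampling rate (Hz)
#' @return an object of class `signal_config`
#' @export
signal_config <- function(window = 20, validity_horizon = 5, min_beats = 5,
                          min_pp = 5, refractory = 0.25,
                          trigger_threshold = 40, trigger_window = 300,
                          trigger_frac = 0.8, sample_hz = 100) {
  stopifnot(window > 0, validity_horizon > 0, min_beats >= 2,
            trigger_window > 0, trigger_frac > 0, trigger_frac < 1)
  structure(list(window = window, validity_horizon = validity_horizon,
                 min_beats = min_beats, min_pp = min_pp,
                 refractory = refractory,
                 trigger_threshold = trigger_threshold,
                 trigger_window = trigger_window,
                 trigger_frac = trigger_frac, sample_hz = sample_hz),
            class = "signal_config")
}

#' Detect beats in an arterial-pressure record
#'
#' Trough-to-trough segmentation: diastolic troughs are local pressure
#' minima, separated by at least the refractory period; each segment between
#' successive troughs yields one beat whose systolic/diastolic values are the
#' local max/min. Segments with pulse pressure below `min_pp` are discarded,
#' so a flat (non-pulsatile) record returns zero beats, which feeds the
#' validity logic rather than raising an error.
#'
#' @param record data.frame with columns `t_s` and `p_mmHg` (or any two
#'   columns taken as time in seconds and pressure in mmHg), time strictly
#'   increasing
#' @param cfg a [signal_config()]
#' @return data.frame of beats: `t` (systolic-peak time, s), `systolic`,
#'   `diastolic`, `pulse_pressure` (mmHg), `stroke_volume` (ml, `NA` for raw
#'   pressure records)
#' @export
detect_beats <- function(record, cfg = signal_config()) {
  nm <- names(record)
  tt <- record[[if ("t_s" %in% nm) "t_s" else 1]]
  p <- record[[if ("p_mmHg" %in% nm) "p_mmHg" else 2]]
  if (any(!is.finite(p))) stop("pressure samples must be finite")
  if (is.unsorted(tt, strictly = TRUE)) stop("time must be strictly increasing")
  empty <- data.frame(t = numeric(0), systolic = numeric(0),
                      diastolic = numeric(0), pulse_pressure = numeric(0),
                      stroke_volume = numeric(0))
  n <- length(p)
  if (n < 3 || (tt[n] - tt[1]) < 2) return(empty)

  i <- 2:(n - 1)
  trough <- c(p[1] <= p[2], p[i] < p[i - 1] & p[i] <= p[i + 1],
              p[n] <= p[n - 1])
  idx <- which(trough)
  if (length(idx) < 2) return(empty)
  # enforce refractory period, keeping the lower of two close troughs
  keep <- idx[1]
  for (j in idx[-1]) {
    last <- keep[length(keep)]
    if (tt[j] - tt[last] >= cfg$refractory) {
      keep <- c(keep, j)
    } else if (p[j] < p[last]) {
      keep[length(keep)] <- j
    }
  }
  if (length(keep) < 2) return(empty)
  a <- keep[-length(keep)]
  b <- keep[-1]
  beats <- lapply(seq_along(a), function(k) {
    seg <- a[k]:b[k]
    sys <- max(p[seg])
    dia <- min(p[seg])
    c(t = tt[seg[which.max(p[seg])]], systolic = sys, diastolic = dia,
      pulse_pressure = sys - dia)
  })
  out <- as.data.frame(do.call(rbind, beats))
  out$stroke_volume <- NA_real_
  out <- out[out$pulse_pressure >= cfg$min_pp, , drop = FALSE]
  rownames(out) <- NULL
  out
}

# shared windowed variation: 100 * (max - min) / mean over beats in
# (t - window, t]; NA when fewer than min_beats values are available
windowed_variation <- function(values, times, t, window, min_beats) {
  sel <- times > t - window & times <= t
  x <- values[sel]
  if (length(x) < min_beats || anyNA(x)) return(NA_real_)
  100 * (max(x) - min(x)) / mean(x)
}

#' Pulse pressure variation over a moving window
#'
#' PPV = 100 x (PPmax - PPmin) / PPmean over the beats falling in the
#' trailing window `(t - window, t]`. Undefined (NA) with fewer than
#' `min_beats` beats in the window.
#'
#' @param beats beat data.frame from [detect_beats()] or a simulator ledger
#'   (needs columns `t` and `pulse_pressure`)
#' @param t evaluation time (s)
#' @param window window length (s), default 20
#' @param min_beats minimum beats required, default 5
#' @return PPV in percent, or `NA_real_`
#' @export
compute_ppv <- function(beats, t, window = 20, min_beats = 5) {
  windowed_variation(beats$pulse_pressure, beats$t, t, window, min_beats)
}

#' Stroke volume variation over a moving window
#'
#' Same contract as [compute_ppv()] applied to the per-beat stroke volume:
#' SVV = 100 x (SVmax - SVmin) / SVmean over the trailing window.
#'
#' @inheritParams compute_ppv
#' @return SVV in percent, or `NA_real_`
#' @export
compute_svv <- function(beats, t, window = 20, min_beats = 5) {
  windowed_variation(beats$stroke_volume, beats$t, t, window, min_beats)
}

#' Signal validity
#'
#' The monitored signal is declared invalid when no beat has been detected in
#' the trailing validity horizon; the controller must then fall back to its
#' fixed (failsafe) mode. A single skipped beat does not invalidate the
#' signal.
#'
#' @param beats beat data.frame (column `t`)
#' @param t evaluation time (s)
#' @param horizon validity horizon (s), default 5
#' @return logical
#' @export
signal_valid <- function(beats, t, horizon = 5) {
  any(beats$t > t - horizon & beats$t <= t)
}

# vectorized core used both by hemo_snapshot() and the harness hot loop
snapshot_core <- function(bt, bsys, bdia, bpp, bsv, t, cfg) {
  valid <- any(bt > t - cfg$validity_horizon & bt <= t)
  sel <- bt > t - cfg$window & bt <= t
  n <- sum(sel)
  if (!valid || n < cfg$min_beats) {
    return(list(t = t, map = NA_real_, hr = NA_real_, ppv = NA_real_,
                svv = NA_real_, eadyn = NA_real_, valid = FALSE))
  }
  pp <- bpp[sel]
  map <- mean(bdia[sel] + pp / 3)
  tw <- bt[sel]
  hr <- 60 * (n - 1) / (tw[n] - tw[1])
  ppv <- 100 * (max(pp) - min(pp)) / mean(pp)
  sv <- bsv[sel]
  svv <- if (anyNA(sv)) NA_real_ else 100 * (max(sv) - min(sv)) / mean(sv)
  eadyn <- if (!is.na(svv) && svv > 0) ppv / svv else NA_real_
  list(t = t, map = map, hr = hr, ppv = ppv, svv = svv, eadyn = eadyn,
       valid = TRUE)
}

#' Windowed hemodynamic snapshot
#'
#' Aggregates the monitored quantities the controller reads: MAP (mean of
#' per-beat diastolic + PP/3 over the feature window), HR (from the
#' inter-beat intervals spanned by the window), PPV, SVV and their ratio
#' Ea_dyn, plus a validity flag. When the signal is invalid (no beats within
#' the validity horizon, or too few beats to define PPV) every feature field
#' is `NA` and `valid` is `FALSE`.
#'
#' @param beats beat data.frame (columns `t`, `systolic`, `diastolic`,
#'   `pulse_pressure`, optionally `stroke_volume`)
#' @param t evaluation time (s)
#' @param cfg a [signal_config()]
#' @return an object of class `hemo_snapshot`: list with `t`, `map`, `hr`,
#'   `ppv`, `svv`, `eadyn`, `valid`
#' @export
hemo_snapshot <- function(beats, t, cfg = signal_config()) {
  sv <- beats$stroke_volume %||% rep(NA_real_, nrow(beats))
  s <- snapshot_core(beats$t, beats$systolic, beats$diastolic,
                     beats$pulse_pressure, sv, t, cfg)
  structure(s, class = "hemo_snapshot")
}

#' Hypotension trigger time
#'
#' Earliest time at which, within the trailing 5-min moving window, the
#' fraction of MAP samples strictly below the threshold exceeds
#' `trigger_frac` (strict comparisons, as specified: MAP < 40 mmHg over
#' > 80 % of the window). The window must be fully covered by the series
#' before the rule can fire.
#'
#' @param map_series data.frame with columns `t` (s) and `map` (mmHg)
#' @param cfg a [signal_config()]
#' @return trigger time (s), or `NA_real_` if the rule never fires
#' @export
hypotension_trigger <- function(map_series, cfg = signal_config()) {
  if (is.null(map_series) || nrow(map_series) == 0) {
    stop("empty MAP series: unusable input")
  }
  tt <- map_series$t
  below <- map_series$map < cfg$trigger_threshold
  w <- cfg$trigger_window
  j <- 1L
  cnt <- 0L
  tot <- 0L
  for (i in seq_along(tt)) {
    tot <- tot + 1L
    cnt <- cnt + as.integer(below[i])
    while (tt[j] <= tt[i] - w) {       # window is (t - w, t]
      cnt <- cnt - as.integer(below[j])
      tot <- tot - 1L
      j <- j + 1L
    }
    if (tt[i] - tt[1] >= w && cnt / tot > cfg$trigger_frac) return(tt[i])
  }
  NA_real_
}

#' Read an arterial waveform CSV
#'
#' Expects the header `t_s,p_mmHg`.
#'
#' @param path file path
#' @return data.frame with columns `t_s`, `p_mmHg`
#' @export
read_waveform_csv <- function(path) {
  x <- utils::read.csv(path)
  if (!all(c("t_s", "p_mmHg") %in% names(x))) {
    stop("waveform CSV must have columns t_s,p_mmHg")
  }
  x
}

#' Write a beat table CSV (`t_s,sys_mmHg,dia_mmHg,sv_ml`)
#'
#' @param beats beat data.frame from [detect_beats()]
#' @param path file path
#' @export
write_beats_csv <- function(beats, path) {
  utils::write.csv(
    data.frame(t_s = beats$t, sys_mmHg = beats$systolic,
               dia_mmHg = beats$diastolic, sv_ml = beats$stroke_volume),
    path, row.names = FALSE)
  invisible(path)
}
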