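#' Porcine hemorrhage simulator parameters
#'
#' Builds the parameter set for the lumped-parameter in-silico pig: a ~30 kg
#' mechanically ventilated animal with uncontrolled liver-laceration
#' hemorrhage. Defaults are calibrated so that the uninjured model sits at the
#' reported laboratory baseline (MAP ~68.8 mmHg, HR ~82 min^-1, CO ~2.75
#' l/min, SvO2 ~57 %, Hgb ~10.6 g/dl) and the untreated injury reproduces the
#' natural history: the MAP < 40 mmHg hypotension trigger is reached in under
#' 30 min and roughly half of a default cohort dies within the first hour.
#'
#' The quantitative physiology is deliberately minimal: a saturating
#' Frank-Starling relation between intravascular volume and cardiac output, a
#' piecewise-linear arterial baroreflex acting on SVR and HR, an Emax
#' norepinephrine effect on SVR, pressure- and time-dependent bleeding from
#' the laceration, transcapillary refill from a finite interstitial reserve,
#' and an oxygen-transport/lactate balance. CaCl2 is tracked for ledger
#' fidelity but has no modeled hemodynamic effect.
#'
#' @param weight body weight (kg)
#' @param blood_per_kg estimated blood volume per kg (ml/kg)
#' @param map0 baseline mean arterial pressure (mmHg); also the baroreflex
#'   setpoint
#' @param hr0 baseline heart rate (min^-1)
#' @param co0 baseline cardiac output (l/min); scaled from the 30.8 kg
#'   reference animal by default
#' @param svo2_0 baseline mixed venous O2 saturation (%)
#' @param hgb0 baseline hemoglobin (g/dl); also the donor-blood hemoglobin
#' @param sao2 arterial O2 saturation (%)
#' @param starling_vmax asymptotic cardiac output of the Frank-Starling
#'   relation (l/min)
#' @param starling_vu unstressed blood volume as a fraction of baseline volume
#' @param baro_gain_hr HR increase per mmHg of MAP below setpoint
#'   (min^-1 mmHg^-1)
#' @param baro_gain_svr fractional SVR increase per mmHg of MAP below setpoint
#' @param ne_emax maximal fractional SVR increase from norepinephrine
#' @param ne_ec50 norepinephrine rate of half-maximal effect (ug/kg/min)
#' @param bleed_rate0 initial hemorrhage rate at baseline pressure (ml/min)
#' @param bleed_decay exponential decay rate of hemorrhage (min^-1)
#' @param bleed_pressure_exp exponent of the (MAP/map0) pressure dependence of
#'   bleeding
#' @param packing_factor multiplicative reduction of bleeding after the liver
#'   is packed (0-1)
#' @param lr_retention fraction of infused crystalloid retained
#'   intravascularly
#' @param refill_rate_max maximal transcapillary refill rate at complete
#'   volume depletion (ml/min); actual refill scales with the fractional
#'   volume deficit
#' @param refill_reserve interstitial volume available for refill (ml)
#' @param o2er_max maximal systemic O2 extraction ratio (fraction)
#' @param lactate0 baseline arterial lactate (mmol/l)
#' @param lactate_gain lactate production per unit O2 deficit
#'   (mmol l^-1 min^-1 per ml O2 min^-1)
#' @param lactate_clear first-order lactate clearance (min^-1)
#' @param death_map MAP threshold below which death integration runs (mmHg)
#' @param death_duration continuous minutes below `death_map` that are lethal
#' @param pp0 baseline arterial pulse pressure (mmHg)
#' @param ppv_floor,ppv_range,ppv_vmid,ppv_vscale logistic mapping from
#'   normalized blood volume to true pulse pressure variation (%): ppv =
#'   floor + range / (1 + exp((v - vmid)/vscale)) with v = V/V0
#' @param vaso_gain fractional SVR loss per mmol/l of lactate above baseline
#'   (shock-induced vasoplegia); this is what makes vasopressor support
#'   necessary during recovery
#' @param vaso_max cap on the fractional vasoplegic SVR loss
#' @param eadyn_base dynamic arterial elastance (PPV/SVV) at baseline
#'   vasomotor tone; Ea_dyn scales with total SVR relative to baseline
#' @param resp_rate ventilator rate (breaths/min) driving the respiratory
#'   modulation of pulse pressure and stroke volume
#'
#' @return an object of class `pig_params` (a named list, with derived
#'   quantities `V_blood0`, `svr0`, `starling_k` and `vo2` attached)
#' @export
pig_params <- function(weight = 30.8,
                       blood_per_kg = 70,
                       map0 = 68.8,
                       hr0 = 82.2,
                       co0 = 2.75 * weight / 30.8,
                       svo2_0 = 57,
                       hgb0 = 10.6,
                       sao2 = 100,
                       starling_vmax = 4.0 * weight / 30.8,
                       starling_vu = 0.30,
                       baro_gain_hr = 1.0,
                       baro_gain_svr = 0.010,
                       ne_emax = 1.0,
                       ne_ec50 = 0.10,
                       bleed_rate0 = 78 * weight / 30.8,
                       bleed_decay = 0.028,
                       bleed_pressure_exp = 0.8,
                       packing_factor = 0.10,
                       lr_retention = 0.25,
                       refill_rate_max = 10 * weight / 30.8,
                       refill_reserve = 1000 * weight / 30.8,
                       o2er_max = 0.60,
                       lactate0 = 1.0,
                       lactate_gain = 5e-4,
                       lactate_clear = 0.02,
                       vaso_gain = 0.12,
                       vaso_max = 0.4,
                       death_map = 20,
                       death_duration = 5,
                       pp0 = 28,
                       ppv_floor = 2,
                       ppv_range = 60,
                       ppv_vmid = 0.78,
                       ppv_vscale = 0.06,
                       eadyn_base = 0.85,
                       resp_rate = 15) {
  stopifnot(weight > 0, map0 > 0, hr0 > 0, co0 > 0, hgb0 > 0,
            starling_vmax > co0, starling_vu >= 0, starling_vu < 1,
            packing_factor >= 0, packing_factor <= 1,
            lr_retention >= 0, lr_retention <= 1,
            death_map < map0, o2er_max > 0, o2er_max < 1)
  p <- list(
    weight = weight, blood_per_kg = blood_per_kg,
    map0 = map0, hr0 = hr0, co0 = co0, svo2_0 = svo2_0, hgb0 = hgb0,
    sao2 = sao2,
    starling_vmax = starling_vmax, starling_vu = starling_vu,
    baro_gain_hr = baro_gain_hr, baro_gain_svr = baro_gain_svr,
    ne_emax = ne_emax, ne_ec50 = ne_ec50,
    bleed_rate0 = bleed_rate0, bleed_decay = bleed_decay,
    bleed_pressure_exp = bleed_pressure_exp,
    packing_factor = packing_factor, lr_retention = lr_retention,
    refill_rate_max = refill_rate_max, refill_reserve = refill_reserve,
    o2er_max = o2er_max,
    lactate0 = lactate0, lactate_gain = lactate_gain,
    lactate_clear = lactate_clear,
    vaso_gain = vaso_gain, vaso_max = vaso_max,
    death_map = death_map, death_duration = death_duration,
    pp0 = pp0, ppv_floor = ppv_floor, ppv_range = ppv_range,
    ppv_vmid = ppv_vmid, ppv_vscale = ppv_vscale,
    eadyn_base = eadyn_base, resp_rate = resp_rate
  )
  # derived so that the uninjured model is a fixed point at the baseline row
  p$V_blood0 <- blood_per_kg * weight
  p$svr0 <- map0 / co0
  p$starling_k <- -log(1 - co0 / starling_vmax)
  p$vo2 <- (sao2 - svo2_0) / 100 * 1.34 * hgb0 * co0 * 10
  p$lactate_prod0 <- lactate_clear * lactate0
  class(p) <- "pig_params"
  p
}

#' Quasi-static hemodynamic closure
#'
#' Maps intravascular blood volume and the running norepinephrine rate to the
#' circulatory state. Cardiac output follows a saturating Frank-Starling
#' function of stressed volume; SVR combines the baseline value with a
#' piecewise-linear baroreflex term (active only below the MAP setpoint), an
#' Emax norepinephrine effect, and a lactate-coupled vasoplegia term (shock
#' erodes vasomotor tone, which is why vasopressor support becomes necessary
#' during recovery); MAP closes the loop as CO x SVR. Because SVR is linear
#' in MAP below the setpoint, the MAP fixed point is solved in closed form.
#' True PPV is a monotone decreasing logistic in normalized volume, and
#' Ea_dyn scales with total vasomotor tone.
#'
#' All arguments are vectorized over subjects.
#'
#' @param V_blood intravascular blood volume (ml)
#' @param ne_rate norepinephrine infusion rate (ug/kg/min)
#' @param params a [pig_params()] object (fields may be vectors for cohorts)
#' @param svr_factor exogenous multiplicative SVR disturbance (e.g. a
#'   transfer dip), default 1
#' @param lactate current arterial lactate (mmol/l), driving the vasoplegia
#'   term; defaults to baseline (no vasoplegia)
#' @return list with co (l/min), sv (ml), hr (min^-1), svr (mmHg min/l),
#'   map (mmHg), ppv_true (%), svv_true (%), eadyn_true
#' @export
derive_hemodynamics <- function(V_blood, ne_rate, params, svr_factor = 1,
                                lactate = params$lactate0) {
  v <- V_blood / params$V_blood0
  s <- pmax(0, (v - params$starling_vu) / (1 - params$starling_vu))
  co <- params$starling_vmax * (1 - exp(-params$starling_k * s))
  ne_mult <- 1 + params$ne_emax * ne_rate / (params$ne_ec50 + ne_rate)
  vaso_mult <- 1 - pmin(params$vaso_gain * pmax(lactate - params$lactate0, 0),
                        params$vaso_max)
  tone <- ne_mult * svr_factor * vaso_mult
  base <- co * params$svr0 * tone                       # MAP if baro inactive
  g <- params$baro_gain_svr
  ms <- params$map0
  map_lo <- base * (1 + g * ms) / (1 + base * g)        # branch: map < setpoint
  map <- map_lo
  hi <- base >= ms
  if (any(hi)) map[hi] <- base[hi]
  svr <- params$svr0 * (1 + g * pmax(0, ms - map)) * tone
  hr <- params$hr0 + params$baro_gain_hr * pmax(0, ms - map)
  sv <- co / hr * 1000
  ppv_true <- params$ppv_floor +
    params$ppv_range / (1 + exp((v - params$ppv_vmid) / params$ppv_vscale))
  eadyn_true <- params$eadyn_base * svr / params$svr0
  svv_true <- ppv_true / eadyn_true
  list(co = co, sv = sv, hr = hr, svr = svr, map = map,
       ppv_true = ppv_true, svv_true = svv_true, eadyn_true = eadyn_true)
}

#' Hemorrhage rate of the liver laceration
#'
#' Uncontrolled bleeding decays exponentially with time since injury (clot
#' maturation), scales with arterial pressure, and is reduced by the
#' `packing_factor` once the liver is packed.
#'
#' @param t_since_injury minutes since laceration (>= 0)
#' @param map current mean arterial pressure (mmHg)
#' @param packed logical, liver packed
#' @param params a [pig_params()] object
#' @return bleeding rate (ml/min)
#' @export
hemorrhage_rate <- function(t_since_injury, map, packed, params) {
  stopifnot(all(t_since_injury >= 0))
  r <- params$bleed_rate0 * exp(-params$bleed_decay * t_since_injury) *
    (pmax(map, 0) / params$map0)^params$bleed_pressure_exp
  r * (1 + (params$packing_factor - 1) * as.numeric(packed))
}

#' Initialize simulated pig state
#'
#' Returns the uninjured baseline state (a fixed point of [pig_step()] in the
#' absence of infusions). All fields are vectors so a whole cohort can be
#' stepped at once when `params` carries vectorized fields.
#'
#' @param params a [pig_params()] object
#' @param n number of subjects held in the state (default: inferred from
#'   params, else 1)
#' @return an object of class `pig_state`
#' @export
pig_init <- function(params, n = max(lengths(unclass(params)))) {
  one <- rep(1, n)
  h <- derive_hemodynamics(params$V_blood0 * one, 0 * one, params)
  st <- list(
    t = 0 * one,
    V_blood = params$V_blood0 * one,
    hgb = params$hgb0 * one,
    lactate = params$lactate0 * one,
    co = h$co, sv = h$sv, svr = h$svr, map = h$map, hr = h$hr,
    ppv_true = h$ppv_true, svv_true = h$svv_true, eadyn_true = h$eadyn_true,
    svo2 = params$svo2_0 * one,
    bleed_rate = 0 * one,
    injured = rep(FALSE, n), t_injury = rep(NA_real_, n),
    packed = rep(FALSE, n),
    alive = rep(TRUE, n),
    time_below = 0 * one, death_time = rep(NA_real_, n),
    bled_total = 0 * one, refill_total = 0 * one,
    infused_blood = 0 * one, infused_lr = 0 * one, infused_cacl2 = 0 * one
  )
  class(st) <- "pig_state"
  st
}

#' Mark the liver laceration
#'
#' @param state a `pig_state`
#' @param which logical or integer subject selector (default all)
#' @return updated state with bleeding active from the current time
#' @export
pig_injure <- function(state, which = TRUE) {
  state$injured[which] <- TRUE
  state$t_injury[which] <- state$t[which]
  state
}

#' Pack the liver (surgical pads), attenuating hemorrhage
#'
#' @param state a `pig_state`
#' @param which subject selector (default all)
#' @export
pig_pack <- function(state, which = TRUE) {
  state$packed[which] <- TRUE
  state
}

#' Advance the simulated pig by one Euler step
#'
#' Explicit-Euler update of the volume, hemoglobin-mass, oxygen-transport and
#' lactate balances, followed by the quasi-static hemodynamic closure and the
#' death check (MAP below `death_map` continuously for `death_duration`
#' minutes). Death is absorbing: after `alive` turns false only `t` advances.
#'
#' @param state a `pig_state` (vectorized over subjects)
#' @param infusions list with elements `blood_rate`, `ringers_rate`,
#'   `ne_rate`, `cacl2_rate` (ml/min, ml/min, ug/kg/min, g/min); missing
#'   elements default to 0
#' @param dt time step (s), must be positive and at most 1
#' @param params a [pig_params()] object
#' @param svr_factor exogenous SVR disturbance multiplier (transfer dip)
#' @param sao2 arterial O2 saturation override (%), default `params$sao2`
#' @return the updated `pig_state`
#' @export
pig_step <- function(state, infusions = list(), dt = 0.1, params,
                     svr_factor = 1, sao2 = params$sao2) {
  if (!is.numeric(dt) || dt <= 0) stop("dt must be positive")
  if (dt > 1) stop("dt must be <= 1 s")
  # drop S3 classes while working: avoids $-dispatch overhead in the hot loop
  cls <- oldClass(state)
  state <- unclass(state)
  params <- unclass(params)
  blood <- infusions$blood_rate %||% 0
  lr <- infusions$ringers_rate %||% 0
  ne <- infusions$ne_rate %||% 0
  cacl2 <- infusions$cacl2_rate %||% 0
  if (any(c(blood, lr, ne, cacl2) < 0)) stop("infusion rates must be >= 0")

  a <- state$alive
  dtm <- dt / 60                                   # minutes

  # scalar fast path: the closed-loop harness advances one subject at a
  # 0.1-s substep, so this branch carries most of the work; it mirrors the
  # vectorized arithmetic below exactly (asserted by tests)
  if (length(a) == 1L) {
    if (!a) {
      state$t <- state$t + dt
      class(state) <- cls
      return(state)
    }
    V <- state$V_blood
    bleed <- 0
    if (state$injured && V > 0) {
      tsi <- (state$t - state$t_injury) / 60
      bleed <- params$bleed_rate0 * exp(-params$bleed_decay * tsi) *
        (max(state$map, 0) / params$map0)^params$bleed_pressure_exp
      if (state$packed) bleed <- bleed * params$packing_factor
    }
    deficit <- (params$V_blood0 - V) / params$V_blood0
    refill <- if (deficit > 0) {
      min(params$refill_rate_max * deficit,
          max(0, params$refill_reserve - state$refill_total) / dtm)
    } else 0
    V_new <- max(V + (blood + params$lr_retention * lr + refill - bleed) * dtm,
                 0)
    mass <- state$hgb * V / 100 +
      (blood * params$hgb0 - bleed * state$hgb) / 100 * dtm
    hgb_new <- if (V_new > 0) max(mass, 0) / (V_new / 100) else 0

    v <- V_new / params$V_blood0
    s <- (v - params$starling_vu) / (1 - params$starling_vu)
    if (s < 0) s <- 0
    co <- params$starling_vmax * (1 - exp(-params$starling_k * s))
    ne_mult <- 1 + params$ne_emax * ne / (params$ne_ec50 + ne)
    vaso <- params$vaso_gain * max(state$lactate - params$lactate0, 0)
    if (vaso > params$vaso_max) vaso <- params$vaso_max
    tone <- ne_mult * svr_factor * (1 - vaso)
    base <- co * params$svr0 * tone
    g <- params$baro_gain_svr
    ms <- params$map0
    map <- if (base >= ms) base else base * (1 + g * ms) / (1 + base * g)
    svr <- params$svr0 * (1 + g * max(0, ms - map)) * tone
    hr <- params$hr0 + params$baro_gain_hr * max(0, ms - map)
    ppv <- params$ppv_floor +
      params$ppv_range / (1 + exp((v - params$ppv_vmid) / params$ppv_vscale))
    eadyn <- params$eadyn_base * svr / params$svr0

    do2_cap <- 1.34 * hgb_new * co * 10
    do2 <- do2_cap * sao2 / 100
    vo2_act <- min(params$vo2, params$o2er_max * do2)
    svo2 <- if (do2_cap > 0) sao2 - 100 * vo2_act / do2_cap else 0
    if (svo2 < 0) svo2 <- 0 else if (svo2 > 100) svo2 <- 100
    o2_deficit <- params$vo2 - vo2_act
    lact_new <- state$lactate +
      (params$lactate_prod0 + params$lactate_gain * o2_deficit -
         params$lactate_clear * state$lactate) * dtm

    t_new <- state$t + dt
    tb_new <- if (map < params$death_map) state$time_below + dt else 0

    state$V_blood <- V_new
    state$hgb <- hgb_new
    state$lactate <- lact_new
    state$co <- co
    state$sv <- co / hr * 1000
    state$svr <- svr
    state$map <- map
    state$hr <- hr
    state$ppv_true <- ppv
    state$svv_true <- ppv / eadyn
    state$eadyn_true <- eadyn
    state$svo2 <- svo2
    state$bleed_rate <- bleed
    state$time_below <- tb_new
    state$bled_total <- state$bled_total + bleed * dtm
    state$refill_total <- state$refill_total + refill * dtm
    state$infused_blood <- state$infused_blood + blood * dtm
    state$infused_lr <- state$infused_lr + lr * dtm
    state$infused_cacl2 <- state$infused_cacl2 + cacl2 * dtm
    state$t <- t_new
    if (tb_new >= params$death_duration * 60) {
      state$alive <- FALSE
      state$death_time <- t_new
    }
    class(state) <- cls
    return(state)
  }

  all_alive <- all(a)
  n <- length(a)
  bleed <- numeric(n)
  inj <- state$injured & a & state$V_blood > 0
  if (any(inj)) {
    tsi <- (state$t[inj] - state$t_injury[inj]) / 60
    pi_ <- function(x) if (length(x) == n) x[inj] else x
    bleed[inj] <- pi_(params$bleed_rate0) *
      exp(-pi_(params$bleed_decay) * tsi) *
      (pmax(state$map[inj], 0) / pi_(params$map0))^pi_(params$bleed_pressure_exp) *
      (1 + (pi_(params$packing_factor) - 1) * as.numeric(state$packed[inj]))
  }
  deficit_frac <- pmax(0, (params$V_blood0 - state$V_blood) / params$V_blood0)
  refill <- pmin(params$refill_rate_max * deficit_frac,
                 pmax(0, params$refill_reserve - state$refill_total) / dtm)
  refill[!a] <- 0

  dV <- (blood + params$lr_retention * lr + refill - bleed) * dtm
  dV[!a] <- 0
  V_new <- pmax(state$V_blood + dV, 0)
  # hemoglobin mass balance: bleeding removes at current conc, donor blood
  # carries hgb0, crystalloid and refill carry none
  mass <- state$hgb * state$V_blood / 100
  dmass <- (blood * params$hgb0 - bleed * state$hgb) / 100 * dtm
  dmass[!a] <- 0
  mass_new <- pmax(mass + dmass, 0)
  hgb_new <- numeric(n)
  pos <- V_new > 0
  hgb_new[pos] <- mass_new[pos] / (V_new[pos] / 100)

  h <- derive_hemodynamics(V_new, ne, params, svr_factor = svr_factor,
                           lactate = state$lactate)

  do2_cap <- 1.34 * hgb_new * h$co * 10            # ml O2/min at 100 % SaO2
  do2 <- do2_cap * sao2 / 100
  vo2_act <- pmin(params$vo2, params$o2er_max * do2)
  svo2 <- numeric(n)
  okc <- do2_cap > 0
  svo2[okc] <- (sao2 - 100 * vo2_act / do2_cap)[okc]
  svo2 <- pmin(pmax(svo2, 0), 100)
  o2_deficit <- params$vo2 - vo2_act
  lact_new <- state$lactate +
    (params$lactate_prod0 + params$lactate_gain * o2_deficit -
       params$lactate_clear * state$lactate) * dtm

  t_new <- state$t + dt
  below <- h$map < params$death_map
  tb_new <- ifelse(below, state$time_below + dt, 0)
  dies <- a & tb_new >= params$death_duration * 60

  keep <- if (all_alive) function(new, old) new else
    function(new, old) {
      new[!a] <- old[!a]
      new
    }
  state$V_blood <- keep(V_new, state$V_blood)
  state$hgb <- keep(hgb_new, state$hgb)
  state$lactate <- keep(lact_new, state$lactate)
  state$co <- keep(h$co, state$co)
  state$sv <- keep(h$sv, state$sv)
  state$svr <- keep(h$svr, state$svr)
  state$map <- keep(h$map, state$map)
  state$hr <- keep(h$hr, state$hr)
  state$ppv_true <- keep(h$ppv_true, state$ppv_true)
  state$svv_true <- keep(h$svv_true, state$svv_true)
  state$eadyn_true <- keep(h$eadyn_true, state$eadyn_true)
  state$svo2 <- keep(svo2, state$svo2)
  state$bleed_rate <- keep(bleed, state$bleed_rate)
  state$time_below <- keep(tb_new, state$time_below)
  state$bled_total <- keep(state$bled_total + bleed * dtm, state$bled_total)
  state$refill_total <- keep(state$refill_total + refill * dtm,
                             state$refill_total)
  state$infused_blood <- keep(state$infused_blood + blood * dtm,
                              state$infused_blood)
  state$infused_lr <- keep(state$infused_lr + lr * dtm, state$infused_lr)
  state$infused_cacl2 <- keep(state$infused_cacl2 + cacl2 * dtm,
                              state$infused_cacl2)
  state$t <- t_new
  state$alive[dies] <- FALSE
  state$death_time[dies] <- t_new[dies]
  class(state) <- cls
  state
}

# per-beat synthesis shared by emit_waveform() and the closed-loop harness:
# pulse pressure tracks stroke volume through the baseline arterial
# compliance, and both are modulated sinusoidally at the ventilator rate with
# fractional depths equal to the true PPV / SVV
beat_values <- function(map, sv, ppv_true, svv_true, t_beat, params) {
  pp_per_ml <- params$pp0 / (params$co0 / params$hr0 * 1000)
  phase <- sin(2 * pi * params$resp_rate / 60 * t_beat)
  pp_mean <- sv * pp_per_ml
  pp <- pp_mean * (1 + ppv_true / 100 / 2 * phase)
  sv_b <- sv * (1 + svv_true / 100 / 2 * phase)
  # the respiratory swing is carried by the systolic peak over a common
  # diastolic level, keeping the waveform continuous at the troughs; the
  # windowed mean of dia + pp/3 still equals map because the modulation
  # averages out over whole ventilator cycles
  dia <- rep(map - pp_mean / 3, length.out = length(pp))
  list(sys = dia + pp, dia = dia, sv = sv_b, pp = pp)
}

#' Synthesize an arterial-pressure waveform from the current state
#'
#' Emits a pulsatile pressure record around the current MAP with pulse
#' pressure proportional to stroke volume and beat-to-beat modulation at the
#' ventilator rate, with depth equal to the state's true PPV (and SVV for the
#' per-beat stroke volumes). Beat shape is sin(pi phi)^5, whose time-mean is
#' close to 1/3 so the waveform average matches the clinical MAP estimate
#' diastolic + PP/3. Intended for round-trip testing of the feature
#' extractor; the closed-loop harness generates the per-beat ledger directly.
#'
#' @param state a single-subject `pig_state`
#' @param duration record length (s)
#' @param params a [pig_params()] object
#' @param fs sampling rate (Hz)
#' @param t0 time of the first beat onset (s)
#' @return list with `samples` (data.frame `t_s`, `p_mmHg`) and `beats`
#'   (data.frame `t_s`, `sys_mmHg`, `dia_mmHg`, `sv_ml`), the generator's own
#'   per-beat ledger
#' @export
emit_waveform <- function(state, duration = 30, params, fs = 100, t0 = 0) {
  if (length(state$map) != 1) stop("emit_waveform expects a single subject")
  if (!state$alive) stop("subject is not alive")
  interval <- 60 / state$hr
  onsets <- seq(t0, t0 + duration, by = interval)
  b <- beat_values(state$map, state$sv, state$ppv_true, state$svv_true,
                   onsets, params)
  ts <- seq(t0, t0 + duration, by = 1 / fs)
  idx <- pmin(findInterval(ts, onsets), length(onsets))
  phi <- (ts - onsets[idx]) / interval
  p <- b$dia[idx] + b$pp[idx] * sin(pi * pmin(phi, 1))^5
  list(
    samples = data.frame(t_s = ts, p_mmHg = p),
    beats = data.frame(t_s = onsets, sys_mmHg = b$sys, dia_mmHg = b$dia,
                       sv_ml = b$sv)
  )
}

#' Sample a cohort of simulated pigs
#'
#' Body weight is drawn from the reported distribution (30.8 +/- 0.7 kg,
#' truncated positive). Parameters with a printed baseline dispersion (MAP,
#' hemoglobin, SvO2) are jittered with those standard deviations; invented
#' physiological parameters (Starling ceiling, baseline CO, bleeding
#' kinetics, refill, vasopressor sensitivity, volume-responsiveness midpoint)
#' are jittered with coefficient of variation `cv`. With `cv = 0` the cohort
#' is `n` identical copies of `params0`. Draws are reproducible under `seed`.
#'
#' @param n cohort size (>= 1)
#' @param seed integer RNG seed
#' @param params0 reference [pig_params()] object
#' @param cv coefficient of variation for invented parameters (default 0.10)
#' @return list of `n` `pig_params` objects (class `pig_cohort`)
#' @export
sample_cohort <- function(n, seed, params0 = pig_params(), cv = 0.10) {
  stopifnot(n >= 1)
  set.seed(seed)
  tnorm <- function(n, mean, sd, lo = mean - 3 * sd, hi = mean + 3 * sd) {
    pmin(pmax(stats::rnorm(n, mean, sd), lo), hi)
  }
  jit <- function(n) if (cv > 0) tnorm(n, 1, cv) else rep(1, n)
  if (cv > 0) {
    weight <- pmax(tnorm(n, params0$weight, 0.7), 1)
    map0 <- tnorm(n, params0$map0, 3.7)
    hgb0 <- pmax(tnorm(n, params0$hgb0, 1.2), 4)
    svo2_0 <- pmin(pmax(tnorm(n, params0$svo2_0, 6), 20), 80)
    hr0 <- pmin(pmax(tnorm(n, params0$hr0, params0$hr0 * cv), 55), 105)
  } else {
    weight <- rep(params0$weight, n)
    map0 <- rep(params0$map0, n)
    hgb0 <- rep(params0$hgb0, n)
    svo2_0 <- rep(params0$svo2_0, n)
    hr0 <- rep(params0$hr0, n)
  }
  wscale <- weight / params0$weight
  co0 <- params0$co0 * wscale * jit(n)
  vmax <- pmax(params0$starling_vmax * wscale * jit(n), co0 * 1.15)
  cohort <- vector("list", n)
  for (i in seq_len(n)) {
    cohort[[i]] <- pig_params(
      weight = weight[i], blood_per_kg = params0$blood_per_kg,
      map0 = map0[i], hr0 = hr0[i], co0 = co0[i],
      svo2_0 = svo2_0[i], hgb0 = hgb0[i], sao2 = params0$sao2,
      starling_vmax = vmax[i], starling_vu = params0$starling_vu,
      baro_gain_hr = params0$baro_gain_hr * jit(1),
      baro_gain_svr = params0$baro_gain_svr * jit(1),
      ne_emax = params0$ne_emax, ne_ec50 = params0$ne_ec50 * jit(1),
      bleed_rate0 = params0$bleed_rate0 * wscale[i] * jit(1),
      bleed_decay = params0$bleed_decay * jit(1),
      bleed_pressure_exp = params0$bleed_pressure_exp,
      packing_factor = params0$packing_factor,
      lr_retention = params0$lr_retention,
      refill_rate_max = params0$refill_rate_max * wscale[i] * jit(1),
      refill_reserve = params0$refill_reserve * wscale[i] * jit(1),
      o2er_max = params0$o2er_max,
      lactate0 = params0$lactate0, lactate_gain = params0$lactate_gain,
      lactate_clear = params0$lactate_clear,
      vaso_gain = params0$vaso_gain, vaso_max = params0$vaso_max,
      death_map = params0$death_map, death_duration = params0$death_duration,
      pp0 = params0$pp0, ppv_floor = params0$ppv_floor,
      ppv_range = params0$ppv_range,
      ppv_vmid = params0$ppv_vmid + (if (cv > 0) tnorm(1, 0, 0.02) else 0),
      ppv_vscale = params0$ppv_vscale,
      eadyn_base = params0$eadyn_base, resp_rate = params0$resp_rate
    )
  }
  class(cohort) <- c("pig_cohort", "list")
  cohort
}

# bind a list of pig_params into one vectorized parameter struct so a whole
# cohort can be advanced with a single pig_step() per substep
bind_cohort <- function(cohort) {
  fields <- names(unclass(cohort[[1]]))
  p <- lapply(fields, function(f) vapply(cohort, function(x) x[[f]], 0))
  names(p) <- fields
  class(p) <- "pig_params"
  p
}

`%||%` <- function(a, b) if (is.null(a)) b else a
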