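#' Titration policy configuration
#'
#' Encodes the attended-titration protocol: gradual pressure escalation to
#' abolish apneas, oxygen started to hold SpO2 at or above 89%, oxygen
#' tapered on a 5 mmHg pCO2 rise or once SpO2 exceeds 92%, and a switch to
#' bi-level support on residual events at high CPAP pressure (>= 15 cmH2O) or
#' pressure intolerance. Bi-level pressures respect an EPAP floor of 4 cmH2O
#' and an IPAP-EPAP differential between 4 and 10 cmH2O.
#'
#' @param pressure_step CPAP/IPAP increment in cmH2O (default 1).
#' @param min_step_interval_s Minimum seconds between setting changes.
#' @param o2_step,o2_max Oxygen-flow step and ceiling in L/min.
#' @param bipap_residual_pressure CPAP pressure at which residual apneas
#'   indicate bi-level transition (default 15 cmH2O).
#' @param ipap_epap_min_diff,ipap_epap_max_diff Differential bounds (cmH2O).
#' @param epap_min EPAP floor (cmH2O, >= 4).
#' @param intolerance_action What to do on CPAP intolerance:
#'   `"SWITCH_BIPAP"` (default) or `"PRESSURE_DOWN"`.
#' @return A `policy_config` list.
#' @export
policy_config <- function(pressure_step = 1, min_step_interval_s = 300,
                          o2_step = 1, o2_max = 5,
                          bipap_residual_pressure = 15,
                          ipap_epap_min_diff = 4, ipap_epap_max_diff = 10,
                          epap_min = 4,
                          intolerance_action = c("SWITCH_BIPAP", "PRESSURE_DOWN")) {
  if (ipap_epap_min_diff > ipap_epap_max_diff) abort("min differential > max differential")
  if (epap_min < 4) abort("epap_min must be >= 4")
  structure(
    list(pressure_step = pressure_step, min_step_interval_s = min_step_interval_s,
         o2_step = o2_step, o2_max = o2_max,
         bipap_residual_pressure = bipap_residual_pressure,
         ipap_epap_min_diff = ipap_epap_min_diff,
         ipap_epap_max_diff = ipap_epap_max_diff,
         epap_min = epap_min,
         intolerance_action = match.arg(intolerance_action)),
    class = "policy_config"
  )
}

decision_row <- function(category, magnitude, rule_id, rationale) {
  tibble(category = category, magnitude = magnitude,
         rule_id = rule_id, rationale = rationale)
}

split_state <- function(state) {
  parts <- strsplit(state, ".", fixed = TRUE)[[1]]
  list(apnea = parts[1], spo2_band = parts[2], pco2_trend = parts[3])
}

#' Decide the next titration action
#'
#' Deterministic rule cascade, in priority order (CO2 safety first, then
#' oxygenation, then airway patency):
#' \describe{
#'   \item{R1}{pCO2 RISING and O2 flowing: taper oxygen.}
#'   \item{R2}{SpO2 in TARGET band (> 92%) and O2 flowing: taper oxygen.}
#'   \item{R3}{Apnea on CPAP below the residual-pressure threshold: raise
#'     pressure.}
#'   \item{R4}{Apnea on CPAP at/above the threshold, or with intolerance:
#'     switch to bi-level.}
#'   \item{R5}{Apnea on bi-level: raise IPAP (EPAP follows when the
#'     differential would exceed its maximum).}
#'   \item{R6}{No apnea, SpO2 CRITICAL (< 89%), pCO2 not rising: add oxygen
#'     (capped at `o2_max`).}
#'   \item{R7}{CPAP intolerance without apnea: lower pressure or switch to
#'     bi-level, per `intolerance_action`.}
#' }
#' Otherwise HOLD. Any non-HOLD action is rate-limited: if the last setting
#' change is more recent than `min_step_interval_s` the decision is HOLD with
#' rule id `RATE_LIMIT`.
#'
#' @param state Patient state label (see [patient_states()]) or a one-row
#'   tibble from [classify_epoch()].
#' @param device One-row device-setting tibble.
#' @param context List with `pco2_delta` (mmHg above reference), `intolerance`
#'   (logical) and `time_since_last_change` (seconds).
#' @param config A [policy_config()].
#' @return One-row tibble: `category`, `magnitude`, `rule_id`, `rationale`.
#' @export
decide_action <- function(state, device,
                          context = list(pco2_delta = 0, intolerance = FALSE,
                                         time_since_last_change = Inf),
                          config = policy_config()) {
  if (is.data.frame(state)) state <- state$state[1]
  st <- split_state(state)
  if (!device$mode %in% c("CPAP", "BIPAP")) abort("invalid device mode")
  intol <- isTRUE(context$intolerance)
  tslc <- context$time_since_last_change %||% Inf
  pressure <- if (device$mode == "CPAP") device$cpap_pressure else device$epap

  raw <- NULL
  if (st$pco2_trend == "RISING" && device$o2_flow > 0) {
    raw <- decision_row("O2_DOWN", config$o2_step, "R1",
                        "pCO2 rising under supplemental oxygen: taper O2 to protect ventilatory drive")
  } else if (st$spo2_band == "TARGET" && device$o2_flow > 0) {
    raw <- decision_row("O2_DOWN", config$o2_step, "R2",
                        "SpO2 above 92% target: taper supplemental O2")
  } else if (st$apnea == "PRESENT" && device$mode == "CPAP" &&
             pressure < config$bipap_residual_pressure && !intol) {
    raw <- decision_row("PRESSURE_UP", config$pressure_step, "R3",
                        "apnea present: gradual CPAP pressure increase")
  } else if (st$apnea == "PRESENT" && device$mode == "CPAP" &&
             (pressure >= config$bipap_residual_pressure || intol)) {
    raw <- decision_row("SWITCH_BIPAP", config$ipap_epap_min_diff, "R4",
                        "residual apneas at high CPAP pressure or intolerance: switch to bi-level support")
  } else if (st$apnea == "PRESENT" && device$mode == "BIPAP") {
    raw <- decision_row("IPAP_UP", config$pressure_step, "R5",
                        "apnea on bi-level: raise IPAP within differential bounds")
  } else if (st$apnea == "ABSENT" && st$spo2_band == "CRITICAL" &&
             st$pco2_trend != "RISING" && device$o2_flow < config$o2_max) {
    raw <- decision_row("O2_UP", config$o2_step, "R6",
                        "SpO2 below 89% without apnea or pCO2 rise: add supplemental O2")
  } else if (intol && device$mode == "CPAP") {
    raw <- if (config$intolerance_action == "SWITCH_BIPAP") {
      decision_row("SWITCH_BIPAP", config$ipap_epap_min_diff, "R7",
                   "pressure intolerance: switch to bi-level support")
    } else {
      decision_row("PRESSURE_DOWN", config$pressure_step, "R7",
                   "pressure intolerance: lower pressure")
    }
  }
  if (is.null(raw)) {
    return(decision_row("HOLD", 0, "HOLD", "no rule fired: maintain current settings"))
  }
  if (tslc < config$min_step_interval_s) {
    return(decision_row("HOLD", 0, "RATE_LIMIT",
                        sprintf("action %s suppressed: last change %gs ago (< %gs)",
                                raw$category, tslc, config$min_step_interval_s)))
  }
  raw
}

#' Initialize bi-level settings from a CPAP level
#'
#' EPAP starts at the pressure at which obstructive apneas were eliminated
#' when that is known, otherwise at the current CPAP level, floored at
#' `epap_min`; IPAP starts at EPAP plus the minimum differential. The O2 flow
#' is carried over.
#'
#' @param cpap_level Current CPAP pressure (cmH2O).
#' @param apnea_elimination_pressure CPAP level at which apneas resolved, or
#'   `NA` when unknown.
#' @param o2_flow Oxygen flow to carry over (L/min).
#' @param t_start Start time of the new setting interval.
#' @param config A [policy_config()].
#' @return One-row BIPAP device-setting tibble.
#' @export
init_bipap <- function(cpap_level, apnea_elimination_pressure = NA,
                       o2_flow = 0, t_start = 0, config = policy_config()) {
  epap <- if (!is.na(apnea_elimination_pressure)) {
    apnea_elimination_pressure
  } else {
    cpap_level
  }
  epap <- max(config$epap_min, epap)
  if (epap > 20) {
    warn(sprintf("EPAP %g clamped to 20 cmH2O", epap))
    epap <- 20
  }
  ipap <- epap + config$ipap_epap_min_diff
  if (ipap > 20 + config$ipap_epap_max_diff) {
    warn(sprintf("IPAP %g clamped", ipap))
    ipap <- 20 + config$ipap_epap_max_diff
  }
  tibble(t_start = t_start, mode = "BIPAP", cpap_pressure = NA_real_,
         ipap = ipap, epap = epap, o2_flow = o2_flow)
}

#' Apply a decided action to a device setting
#'
#' Returns the new setting with all bounds clamped (CPAP 4-20 cmH2O, IPAP-EPAP
#' differential within its configured band, O2 flow within `[0, o2_max]`);
#' clamping is reported with a warning. HOLD returns the input unchanged.
#'
#' @param device One-row device-setting tibble.
#' @param decision One-row decision tibble from [decide_action()].
#' @param t_start Start time of the resulting setting interval.
#' @param config A [policy_config()].
#' @return One-row device-setting tibble.
#' @export
apply_action <- function(device, decision, t_start = device$t_start,
                         config = policy_config()) {
  d <- device
  d$t_start <- t_start
  cat_ <- decision$category
  mag <- decision$magnitude
  if (cat_ == "HOLD") return(d)
  if (cat_ == "PRESSURE_UP") {
    if (d$mode == "CPAP") {
      new <- d$cpap_pressure + mag
      if (new > 20) { warn("CPAP pressure clamped at 20 cmH2O"); new <- 20 }
      d$cpap_pressure <- new
    } else {
      d$epap <- min(20, d$epap + mag)
      d$ipap <- d$ipap + mag
    }
  } else if (cat_ == "PRESSURE_DOWN") {
    if (d$mode == "CPAP") {
      new <- d$cpap_pressure - mag
      if (new < 4) { warn("CPAP pressure clamped at 4 cmH2O"); new <- 4 }
      d$cpap_pressure <- new
    } else {
      new_epap <- max(config$epap_min, d$epap - mag)
      d$ipap <- d$ipap - (d$epap - new_epap)
      d$epap <- new_epap
    }
  } else if (cat_ == "O2_UP") {
    new <- d$o2_flow + mag
    if (new > config$o2_max) { warn("O2 flow clamped at maximum"); new <- config$o2_max }
    d$o2_flow <- new
  } else if (cat_ == "O2_DOWN") {
    new <- d$o2_flow - mag
    if (new < 0) { warn("O2 flow clamped at 0"); new <- 0 }
    d$o2_flow <- new
  } else if (cat_ == "SWITCH_BIPAP") {
    if (d$mode == "CPAP") {
      d <- init_bipap(d$cpap_pressure, NA, o2_flow = d$o2_flow,
                      t_start = t_start, config = config)
    }
  } else if (cat_ == "IPAP_UP") {
    if (d$mode == "BIPAP") {
      new_ipap <- d$ipap + mag
      new_epap <- d$epap
      if (new_ipap - new_epap > config$ipap_epap_max_diff) {
        new_epap <- new_ipap - config$ipap_epap_max_diff
      }
      if (new_epap > 20) {
        warn("EPAP clamped at 20 cmH2O; IPAP held at maximum differential")
        new_epap <- 20
        new_ipap <- 20 + config$ipap_epap_max_diff
      }
      d$ipap <- new_ipap
      d$epap <- new_epap
    }
  }
  d
}

#' Run the titration policy over a session or simulated patient
#'
#' With a [titration_session], replays the recorded night epoch by epoch:
#' each epoch is classified (events scored from airflow unless already
#' present) and the action the policy would take is logged; the recording
#' itself is not altered. With a [patient_phenotype], runs the policy closed
#' loop against the overnight simulator (see [simulate_session()]).
#'
#' @param x A [titration_session] to replay or a [patient_phenotype] to
#'   simulate.
#' @param ... Passed on to [simulate_session()] for phenotypes (`duration`,
#'   `seed`, `sim_config`, ...).
#' @param state_cfg A [state_config()].
#' @param policy_cfg A [policy_config()].
#' @param scoring_cfg A [scoring_config()]; used to score events when the
#'   replayed session carries none.
#' @return A [titration_session] whose `decisions` element is the decision
#'   log (`epoch_start`, `state`, `category`, `magnitude`, `rule_id`,
#'   `rationale`).
#' @export
run_titration <- function(x, ..., state_cfg = state_config(),
                          policy_cfg = policy_config(),
                          scoring_cfg = scoring_config()) {
  if (inherits(x, "patient_phenotype")) {
    return(simulate_session(x, controller = "protocol", ...,
                            state_cfg = state_cfg, policy_cfg = policy_cfg,
                            scoring_cfg = scoring_cfg))
  }
  if (!is_titration_session(x)) abort("x must be a titration_session or patient_phenotype")
  session <- x
  if (nrow(session$events) == 0) {
    session$events <- detect_events(session$samples, scoring_cfg)
  }
  traj <- state_trajectory(session, state_cfg)
  change_times <- session$settings$t_start[-1]
  log <- purrr::map_dfr(seq_len(nrow(traj)), function(i) {
    t0 <- traj$epoch_start[i]
    dev <- setting_at(session, t0)
    prior <- change_times[change_times <= t0]
    tslc <- if (length(prior)) t0 + state_cfg$epoch_s - max(prior) else Inf
    intol <- FALSE
    if (!is.null(session$intolerance)) {
      m <- session$intolerance$flag[session$intolerance$epoch_start == t0]
      intol <- length(m) > 0 && isTRUE(m[1])
    }
    dec <- decide_action(traj$state[i], dev,
                         context = list(pco2_delta = traj$pco2_delta[i],
                                        intolerance = intol,
                                        time_since_last_change = tslc),
                         config = policy_cfg)
    dplyr::bind_cols(tibble(epoch_start = t0, state = traj$state[i]), dec)
  })
  session$decisions <- log
  session
}
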