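#' State-discretization configuration
#'
#' An overnight session is cut into fixed epochs and each epoch is mapped to
#' a composite patient state over the three controlled conditions: apnea
#' presence, SpO2 band, and pCO2 trend. Band boundaries mirror the titration
#' protocol: SpO2 below `spo2_low` (default 89%) is CRITICAL, at most
#' `spo2_high` (default 92%) SUBOPTIMAL, above it TARGET; pCO2 is RISING once
#' the epoch mean exceeds the reference by `pco2_rise_units` (default 5 mmHg)
#' and FALLING once it is `pco2_fall_units` below it.
#'
#' @param epoch_s Epoch length in seconds (default 300).
#' @param spo2_low,spo2_high SpO2 band boundaries in percent.
#' @param pco2_rise_units,pco2_fall_units pCO2 trend thresholds in mmHg.
#' @param pco2_reference `"SESSION_BASELINE"` (mean of the first 10 min,
#'   default) or `"ROLLING"` (mean of the previous 30 min).
#' @return A `state_config` list.
#' @export
state_config <- function(epoch_s = 300, spo2_low = 89, spo2_high = 92,
                         pco2_rise_units = 5, pco2_fall_units = 2,
                         pco2_reference = c("SESSION_BASELINE", "ROLLING")) {
  if (!(spo2_low < spo2_high)) abort("spo2_low must be < spo2_high")
  if (pco2_rise_units <= 0) abort("pco2_rise_units must be > 0")
  structure(
    list(epoch_s = epoch_s, spo2_low = spo2_low, spo2_high = spo2_high,
         pco2_rise_units = pco2_rise_units, pco2_fall_units = pco2_fall_units,
         pco2_reference = match.arg(pco2_reference)),
    class = "state_config"
  )
}

#' The 18 composite patient states
#'
#' Cartesian product of apnea {PRESENT, ABSENT}, SpO2 band
#' {CRITICAL, SUBOPTIMAL, TARGET} and pCO2 trend {STABLE, RISING, FALLING},
#' encoded as `"APNEA.BAND.TREND"` labels.
#'
#' @return Character vector of 18 state labels.
#' @export
patient_states <- function() {
  g <- expand.grid(
    pco2 = c("STABLE", "RISING", "FALLING"),
    spo2 = c("CRITICAL", "SUBOPTIMAL", "TARGET"),
    apnea = c("PRESENT", "ABSENT"),
    stringsAsFactors = FALSE
  )
  paste(g$apnea, g$spo2, g$pco2, sep = ".")
}

#' @rdname patient_states
#' @details `target_state()` is the unique desired state: no apnea, SpO2 above
#'   the upper band boundary, stable pCO2.
#' @export
target_state <- function() "ABSENT.TARGET.STABLE"

#' The seven treatment action categories
#'
#' Order is fixed and used as the deterministic tie-break in policy
#' optimization.
#'
#' @return Character vector of 7 action labels.
#' @export
action_categories <- function() {
  c("PRESSURE_UP", "PRESSURE_DOWN", "O2_UP", "O2_DOWN",
    "SWITCH_BIPAP", "IPAP_UP", "HOLD")
}

#' Compose a patient state label
#' @param apnea `"PRESENT"` or `"ABSENT"`.
#' @param spo2_band `"CRITICAL"`, `"SUBOPTIMAL"` or `"TARGET"`.
#' @param pco2_trend `"STABLE"`, `"RISING"` or `"FALLING"`.
#' @return State label string.
#' @export
patient_state <- function(apnea, spo2_band, pco2_trend) {
  lbl <- paste(apnea, spo2_band, pco2_trend, sep = ".")
  if (!all(lbl %in% patient_states())) abort(sprintf("not a valid state: %s", lbl[1]))
  lbl
}

pco2_reference_value <- function(session, t_epoch_start, config) {
  s <- session$samples
  if (config$pco2_reference == "SESSION_BASELINE") {
    mean(s$pco2[s$t < 600])
  } else {
    idx <- s$t >= t_epoch_start - 1800 & s$t < t_epoch_start
    if (!any(idx)) mean(s$pco2[s$t < 600]) else mean(s$pco2[idx])
  }
}

#' Classify one epoch into a patient state
#'
#' Apnea is PRESENT when any scored event overlaps the epoch. The SpO2 band
#' is taken from the epoch-mean SpO2 (`< spo2_low` CRITICAL, up to
#' `spo2_high` inclusive SUBOPTIMAL, above TARGET). The pCO2 trend compares
#' the epoch-mean pCO2 with the configured reference.
#'
#' @param session A [titration_session] with scored events.
#' @param t_epoch_start Epoch start in seconds; the epoch must lie fully
#'   inside the session.
#' @param config A [state_config()].
#' @return One-row tibble: `epoch_start`, `apnea`, `spo2_band`, `pco2_trend`,
#'   `state`, `mean_spo2`, `mean_pco2`, `pco2_delta`.
#' @export
classify_epoch <- function(session, t_epoch_start, config = state_config()) {
  t0 <- t_epoch_start
  t1 <- t_epoch_start + config$epoch_s
  if (t0 < 0 || t1 > session$duration) {
    abort(sprintf("epoch [%g,%g) outside session [0,%d)", t0, t1, session$duration))
  }
  s <- session$samples
  idx <- s$t >= t0 & s$t < t1
  if (!any(idx)) abort(sprintf("no samples in epoch [%g,%g)", t0, t1))
  mean_spo2 <- mean(s$spo2[idx])
  mean_pco2 <- mean(s$pco2[idx])

  ev <- session$events
  apnea <- if (nrow(ev) && any(ev$t_start < t1 & ev$t_start + ev$duration > t0)) {
    "PRESENT"
  } else {
    "ABSENT"
  }
  spo2_band <- if (mean_spo2 < config$spo2_low) {
    "CRITICAL"
  } else if (mean_spo2 <= config$spo2_high) {
    "SUBOPTIMAL"
  } else {
    "TARGET"
  }
  ref <- pco2_reference_value(session, t0, config)
  delta <- mean_pco2 - ref
  pco2_trend <- if (delta >= config$pco2_rise_units) {
    "RISING"
  } else if (delta <= -config$pco2_fall_units) {
    "FALLING"
  } else {
    "STABLE"
  }
  tibble(
    epoch_start = t0, apnea = apnea, spo2_band = spo2_band,
    pco2_trend = pco2_trend,
    state = patient_state(apnea, spo2_band, pco2_trend),
    mean_spo2 = mean_spo2, mean_pco2 = mean_pco2, pco2_delta = delta
  )
}

action_between <- function(before, after) {
  if (before$mode == "CPAP" && after$mode == "BIPAP") return("SWITCH_BIPAP")
  if (before$mode == "CPAP") {
    if (after$cpap_pressure > before$cpap_pressure) return("PRESSURE_UP")
    if (after$cpap_pressure < before$cpap_pressure) return("PRESSURE_DOWN")
  } else {
    if (after$ipap > before$ipap) return("IPAP_UP")
    if (after$epap < before$epap || after$ipap < before$ipap) return("PRESSURE_DOWN")
  }
  if (after$o2_flow > before$o2_flow) return("O2_UP")
  if (after$o2_flow < before$o2_flow) return("O2_DOWN")
  "HOLD"
}

#' Epoch-by-epoch state/action trajectory of a session
#'
#' One row per full epoch. The action of an epoch is the category of the
#' device-setting change taking effect between this epoch's start and the
#' next one's (HOLD when unchanged); when several parameters change in one
#' epoch, modality changes take precedence over pressure, pressure over
#' oxygen.
#'
#' @param session A [titration_session] with a settings schedule and scored
#'   events.
#' @param config A [state_config()].
#' @return Tibble with the [classify_epoch()] columns plus `action` and the
#'   pressure/flow in force at the epoch start (`pressure`, `o2_flow`,
#'   `mode`).
#' @export
state_trajectory <- function(session, config = state_config()) {
  n_epochs <- session$duration %/% config$epoch_s
  if (n_epochs < 1) abort("session shorter than one epoch")
  starts <- (seq_len(n_epochs) - 1L) * config$epoch_s
  rows <- purrr::map_dfr(starts, function(t0) classify_epoch(session, t0, config))
  acts <- purrr::map_chr(seq_len(n_epochs), function(i) {
    before <- setting_at(session, starts[i])
    t_next <- starts[i] + config$epoch_s
    after <- if (t_next < session$duration) setting_at(session, t_next) else
      session$settings[nrow(session$settings), ]
    action_between(before, after)
  })
  dev <- purrr::map_dfr(starts, function(t0) {
    d <- setting_at(session, t0)
    tibble(mode = d$mode,
           pressure = if (d$mode == "CPAP") d$cpap_pressure else d$ipap,
           o2_flow = d$o2_flow)
  })
  dplyr::bind_cols(rows, tibble(action = acts), dev)
}
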