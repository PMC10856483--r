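#' Simulator cohort configuration
#'
#' Distribution parameters for sampling synthetic patient phenotypes. The
#' defaults describe the clinical population the package targets: severe OSA
#' with hypoxemia and frequent chronic hypercapnia — untreated AHI
#' 61.8 +/- 29.1 events/h, initial SpO2 79.7 +/- 7.72%, initial pCO2
#' 53 +/- 8 mmHg, with hypercapnia strata (normocapnic < 45 mmHg, moderate
#' 45-55, severe > 55) in 2:8:4 proportions.
#'
#' @param spo2_mean,spo2_sd Untreated baseline SpO2 distribution (%).
#' @param pco2_mean,pco2_sd Baseline pCO2 distribution (mmHg).
#' @param ahi_mean,ahi_sd Untreated AHI distribution (events/h).
#' @param class_probs Named proportions over `NORMO`, `HYPER_LOW`,
#'   `HYPER_HIGH` (must sum to 1).
#' @param dt Simulation step (seconds).
#' @param spo2_tau_s,pco2_tau_s Relaxation time constants toward the SpO2 /
#'   pCO2 setpoints (seconds). The defaults (60 s, 300 s) make 5-minute
#'   epochs near-steady-state.
#' @param noise_spo2,noise_pco2 Per-step Gaussian innovation SDs.
#' @param hypopnea_frac Fraction of generated events that are hypopneas.
#' @param spo2_o2_gain SpO2 gain per L/min of supplemental oxygen (%).
#' @param spo2_event_gain SpO2 recovered when the recent apnea burden clears (%).
#' @param spo2_ps_gain SpO2 gain per cmH2O of IPAP-EPAP differential (%).
#' @param spo2_cpap_penalty SpO2 cost per cmH2O of CPAP pressure above the
#'   patient's comfort pressure (%); models the impaired exhalation phase at
#'   high fixed pressure. Absent under bi-level support.
#' @param apnea_rate_scale Logistic scale (cmH2O per logit) of event-rate
#'   suppression around the apnea threshold pressure; small values give the
#'   sharp clinical transition from frequent events to none.
#' @return A `simulator_config` list.
#' @export
simulator_config <- function(spo2_mean = 79.7, spo2_sd = 7.72,
                             pco2_mean = 53, pco2_sd = 8,
                             ahi_mean = 61.8, ahi_sd = 29.1,
                             class_probs = c(NORMO = 2, HYPER_LOW = 8, HYPER_HIGH = 4) / 14,
                             dt = 1, spo2_tau_s = 60, pco2_tau_s = 300,
                             noise_spo2 = 0.5, noise_pco2 = 0.1,
                             hypopnea_frac = 0.3,
                             spo2_o2_gain = 1.5, spo2_event_gain = 1,
                             spo2_ps_gain = 1, spo2_cpap_penalty = 0.5,
                             apnea_rate_scale = 0.5) {
  if (abs(sum(class_probs) - 1) > 1e-9 || any(class_probs < 0)) {
    abort("class_probs must be non-negative and sum to 1")
  }
  if (spo2_sd <= 0 || pco2_sd <= 0 || ahi_sd <= 0) abort("SDs must be > 0")
  structure(
    list(spo2_mean = spo2_mean, spo2_sd = spo2_sd, pco2_mean = pco2_mean,
         pco2_sd = pco2_sd, ahi_mean = ahi_mean, ahi_sd = ahi_sd,
         class_probs = class_probs, dt = dt,
         spo2_tau_s = spo2_tau_s, pco2_tau_s = pco2_tau_s,
         noise_spo2 = noise_spo2, noise_pco2 = noise_pco2,
         hypopnea_frac = hypopnea_frac,
         spo2_o2_gain = spo2_o2_gain, spo2_event_gain = spo2_event_gain,
         spo2_ps_gain = spo2_ps_gain, spo2_cpap_penalty = spo2_cpap_penalty,
         apnea_rate_scale = apnea_rate_scale),
    class = "simulator_config"
  )
}

rtnorm <- function(n, mean, sd, lower, upper) {
  out <- numeric(n)
  for (i in seq_len(n)) {
    repeat {
      x <- rnorm(1, mean, sd)
      if (x >= lower && x <= upper) break
    }
    out[i] <- x
  }
  out
}

pco2_class <- function(pco2) {
  if (pco2 < 45) "NORMO" else if (pco2 < 55) "HYPER_LOW" else "HYPER_HIGH"
}

as_phenotype <- function(x) {
  structure(as.list(x), class = "patient_phenotype")
}

#' @export
print.patient_phenotype <- function(x, ...) {
  cat(sprintf(
    "<patient_phenotype> %s: SpO2 %.1f%%, pCO2 %.1f mmHg, AHI %.1f/h, apnea threshold %.1f cmH2O\n",
    x$hypercapnia_class, x$baseline_spo2, x$baseline_pco2, x$ahi_untreated,
    x$apnea_threshold_pressure
  ))
  invisible(x)
}

#' @method as_tibble patient_phenotype
#' @export
as_tibble.patient_phenotype <- function(x, ...) as_tibble(unclass(x))

#' Sample a synthetic patient phenotype
#'
#' Draws a hypercapnia class from the cohort proportions, then baselines from
#' truncated normals consistent with the class, and the sensitivity
#' parameters that shape the patient's response to pressure and oxygen:
#' oxygen-induced CO2 retention is substantial in hypercapnic classes and
#' near zero in normocapnic patients; pressure-induced CO2 retention occurs
#' in about half of the normocapnic/moderate patients and essentially never
#' in the severe class; ventilatory CO2 clearance per cmH2O of pressure
#' support is positive in everyone.
#'
#' @param config A [simulator_config()].
#' @param seed Optional RNG seed (draw is reproducible per seed).
#' @return A `patient_phenotype` list.
#' @export
sample_phenotype <- function(config = simulator_config(), seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  cls <- sample(names(config$class_probs), 1, prob = config$class_probs)
  bounds <- switch(cls,
    NORMO = c(30, 45 - 1e-6),
    HYPER_LOW = c(45, 55 - 1e-6),
    HYPER_HIGH = c(55, 90)
  )
  baseline_pco2 <- rtnorm(1, config$pco2_mean, config$pco2_sd, bounds[1], bounds[2])
  baseline_spo2 <- rtnorm(1, config$spo2_mean, config$spo2_sd, 60, 100)
  ahi_untreated <- rtnorm(1, config$ahi_mean, config$ahi_sd, 10, 130)
  o2_retention_sens <- if (cls == "NORMO") {
    abs(rnorm(1, 0, 0.15))
  } else {
    rtnorm(1, 2.5, 0.8, 0.5, 5)
  }
  pressure_retention_sens <- if (cls == "HYPER_HIGH") {
    abs(rnorm(1, 0, 0.1))
  } else if (runif(1) < 0.5) {
    rtnorm(1, 1.2, 0.4, 0.3, 2.5)
  } else {
    abs(rnorm(1, 0, 0.1))
  }
  as_phenotype(list(
    baseline_spo2 = baseline_spo2,
    baseline_pco2 = baseline_pco2,
    hypercapnia_class = cls,
    ahi_untreated = ahi_untreated,
    apnea_threshold_pressure = runif(1, 8, 14),
    o2_retention_sens = o2_retention_sens,
    pressure_retention_sens = pressure_retention_sens,
    vent_clearance_sens = rtnorm(1, 1.5, 0.5, 0.5, 3),
    comfort_pressure = runif(1, 6, 12),
    intolerance_rate = runif(1, 0.02, 0.10),
    noise_spo2 = config$noise_spo2,
    noise_pco2 = config$noise_pco2
  ))
}

phenotype_setpoints <- function(phen, pressure, dps, o2_flow, apnea_density,
                                gains = list(o2 = 1.5, event = 1, ps = 1,
                                             cpap_penalty = 0.5)) {
  # exhale-phase CO2 retention is a fixed-pressure phenomenon; under
  # pressure support the machine ventilates and clearance dominates
  pressure_retention <- if (dps > 0) 0 else
    phen$pressure_retention_sens * max(0, pressure - phen$comfort_pressure)
  cstar <- phen$baseline_pco2 +
    phen$o2_retention_sens * o2_flow +
    pressure_retention -
    phen$vent_clearance_sens * dps
  # the exhale-phase cost of high fixed pressure applies only without
  # pressure support
  penalty <- if (dps > 0) 0 else
    gains$cpap_penalty * max(0, pressure - phen$comfort_pressure)
  sstar <- min(100, max(60,
    phen$baseline_spo2 + gains$o2 * o2_flow +
      gains$event * (1 - apnea_density) + gains$ps * dps - penalty))
  list(cstar = cstar, sstar = sstar)
}

config_gains <- function(sim_config) {
  list(o2 = sim_config$spo2_o2_gain, event = sim_config$spo2_event_gain,
       ps = sim_config$spo2_ps_gain,
       cpap_penalty = sim_config$spo2_cpap_penalty)
}

#' Does a phenotype admit the SpO2 target under the taper rules?
#'
#' The titration protocol tapers oxygen whenever the pCO2 rise from baseline
#' reaches `pco2_rise_units`, so the largest oxygen flow a patient can hold
#' is the largest integer flow (capped at `o2_max`) whose steady-state CO2
#' load — oxygen-induced retention plus pressure-induced retention at the
#' working pressure the apnea ramp settles at (approximately the phenotype's
#' apnea threshold pressure) — stays below the taper threshold by at least
#' the CO2 process's epoch-mean fluctuation scale (about 1 mmHg at default
#' noise). A phenotype "admits" the oxygenation target when its apnea-free
#' steady-state SpO2 at that sustainable flow reaches `spo2_low` (89%).
#' Bi-level support (which only raises SpO2 and clears CO2) is ignored, so
#' the predicate is conservative.
#'
#' @param phen A `patient_phenotype`.
#' @param policy_cfg A [policy_config()] (for `o2_max`).
#' @param state_cfg A [state_config()] (for the pCO2 rise threshold and SpO2
#'   floor).
#' @param sim_config A [simulator_config()] (for the SpO2 gain coefficients).
#' @param noise_margin CO2 epoch-mean fluctuation allowance in mmHg.
#' @return Logical scalar.
#' @export
phenotype_admits_spo2_target <- function(phen, policy_cfg = policy_config(),
                                         state_cfg = state_config(),
                                         sim_config = simulator_config(),
                                         noise_margin = 1) {
  flows <- 0:policy_cfg$o2_max
  pressure_load <- phen$pressure_retention_sens *
    max(0, phen$apnea_threshold_pressure - phen$comfort_pressure)
  load <- phen$o2_retention_sens * flows + pressure_load
  sustainable <- flows[load <= state_cfg$pco2_rise_units - noise_margin]
  f <- if (length(sustainable)) max(sustainable) else 0
  sp <- phenotype_setpoints(phen, pressure = phen$apnea_threshold_pressure,
                            dps = 0, o2_flow = f,
                            apnea_density = 0, gains = config_gains(sim_config))
  sp$sstar >= state_cfg$spo2_low
}

#' Simulate one overnight titration session
#'
#' Discrete-time generative model at `dt`-second steps under the device
#' setting in force (pressure `P` = CPAP pressure or EPAP, pressure-support
#' differential `dPS` = IPAP - EPAP, oxygen flow `F`):
#' \itemize{
#'   \item Respiratory events arrive as a Poisson process with rate
#'     `(ahi_untreated/3600) *
#'     logistic((apnea_threshold_pressure - P)/apnea_rate_scale)`, corrected
#'     for event dead time; durations are uniform on 10-60 s; airflow is
#'     suppressed below 0.1 during apneas (to about half baseline during
#'     hypopneas).
#'   \item pCO2 relaxes (time constant `pco2_tau_s`) toward
#'     `baseline_pco2 + o2_retention_sens*F +
#'     pressure_retention_sens*max(0, P - comfort_pressure) -
#'     vent_clearance_sens*dPS`, plus Gaussian noise.
#'   \item SpO2 relaxes (time constant `spo2_tau_s`) toward
#'     `clamp(baseline_spo2 + spo2_o2_gain*F +
#'     spo2_event_gain*(1 - recent apnea density) + spo2_ps_gain*dPS,
#'     60, 100)`, dips 3-8 points during/after each event (desaturation
#'     develops faster than resaturation), plus noise.
#'   \item A pressure-intolerance flag is raised per epoch with probability
#'     `intolerance_rate * max(0, P - comfort_pressure)`.
#' }
#' With `controller = "protocol"` the rule-based policy closes the loop: at
#' each epoch boundary the elapsed epoch is scored ([detect_events()] over a
#' trailing window), classified ([classify_epoch()] semantics), and the
#' policy's action is applied to the device before the next epoch. The
#' injected ground-truth event log is stored in the returned session.
#'
#' @param phenotype A [patient_phenotype] (see [sample_phenotype()]).
#' @param duration Session length in seconds (>= 600).
#' @param seed RNG seed (bit-identical output per seed).
#' @param controller `"none"` (hold `init_setting` or follow `schedule`) or
#'   `"protocol"` (closed loop).
#' @param schedule Optional fixed settings tibble (overrides `init_setting`
#'   when `controller = "none"`).
#' @param init_setting One-row device-setting tibble at `t_start = 0`
#'   (default CPAP 4 cmH2O, no O2).
#' @param sim_config A [simulator_config()].
#' @param state_cfg,policy_cfg,scoring_cfg Configuration for the closed loop.
#' @param patient_id Identifier stored in the session.
#' @return A [titration_session]; under the protocol controller its
#'   `decisions` element holds the decision log.
#' @export
simulate_session <- function(phenotype, duration = 36000, seed = NULL,
                             controller = c("none", "protocol"),
                             schedule = NULL, init_setting = NULL,
                             sim_config = simulator_config(),
                             state_cfg = state_config(),
                             policy_cfg = policy_config(),
                             scoring_cfg = scoring_config(),
                             patient_id = "synthetic") {
  controller <- match.arg(controller)
  if (duration < 600) abort("duration must be >= 600 s")
  if (!is.null(seed)) set.seed(seed)
  if (is.null(init_setting)) {
    # the target population uses long-term home oxygen: patients enter the
    # titration night on CPAP 4 cmH2O with 1 L/min already flowing
    init_setting <- tibble(t_start = 0, mode = "CPAP", cpap_pressure = 4,
                           ipap = NA_real_, epap = NA_real_, o2_flow = 1)
  }
  if (!is.null(schedule)) {
    schedule <- normalize_settings(as_tibble(schedule))
  }
  phen <- phenotype
  epoch_s <- state_cfg$epoch_s
  n <- as.integer(duration)

  # state
  device <- if (!is.null(schedule)) schedule[1, ] else init_setting
  device$t_start <- 0
  settings_log <- device
  C <- phen$baseline_pco2
  S <- phen$baseline_spo2
  in_event_until <- -1
  dip_until <- -1
  dip <- 0
  ev_kind <- "APNEA"
  events <- list()
  recent_event <- integer(0)  # times of in-event seconds (last 120 s)

  gains <- config_gains(sim_config)
  t_v <- integer(n); flow_v <- numeric(n); spo2_v <- numeric(n); pco2_v <- numeric(n)
  decision_log <- list()
  intol_log <- list()
  last_change <- -Inf
  baseline_ref <- NULL  # session-baseline pCO2, fixed after first 600 s

  sched_next <- 2L  # next schedule row to apply

  for (t in 0:(n - 1L)) {
    # scheduled setting changes (controller "none" with schedule)
    if (!is.null(schedule)) {
      while (sched_next <= nrow(schedule) && schedule$t_start[sched_next] <= t) {
        device <- schedule[sched_next, ]
        settings_log <- dplyr::bind_rows(settings_log, device)
        sched_next <- sched_next + 1L
      }
    }
    P <- if (device$mode == "CPAP") device$cpap_pressure else device$epap
    dps <- if (device$mode == "CPAP") 0 else device$ipap - device$epap
    F <- device$o2_flow

    in_event <- t <= in_event_until
    if (!in_event) {
      lambda <- (phen$ahi_untreated / 3600) *
        plogis((phen$apnea_threshold_pressure - P) / sim_config$apnea_rate_scale)
      # arrivals pause during events (mean 35 s); compensate this dead time so
      # the realized untreated event rate matches the nominal intensity
      lambda <- lambda / max(0.2, 1 - lambda * 35)
      if (runif(1) < lambda * sim_config$dt) {
        ev_dur <- round(runif(1, 10, 60))
        ev_kind <- if (runif(1) < sim_config$hypopnea_frac) "HYPOPNEA" else "APNEA"
        in_event_until <- t + ev_dur - 1
        # dips deep enough that hypopnea desaturations stay detectable at the
        # 3% criterion under the fast desaturation kinetics
        dip <- runif(1, 4, 8)
        dip_until <- t + ev_dur - 1
        events[[length(events) + 1L]] <-
          tibble(kind = ev_kind, t_start = t, duration = ev_dur)
        in_event <- TRUE
      }
    }
    if (in_event) recent_event <- c(recent_event, t)
    recent_event <- recent_event[recent_event > t - 120]
    dens <- length(recent_event) / 120

    flow <- if (in_event) {
      if (ev_kind == "APNEA") runif(1, 0.02, 0.08) else 0.5 + rnorm(1, 0, 0.02)
    } else {
      1 + rnorm(1, 0, 0.02)
    }
    flow <- min(1.5, max(0, flow))

    sp <- phenotype_setpoints(phen, P, dps, F, dens, gains = gains)
    dip_active <- t <= dip_until
    sstar <- sp$sstar - if (dip_active) dip else 0
    # desaturation develops much faster than the resaturation time constant
    spo2_tau <- if (dip_active && sstar < S) 15 else sim_config$spo2_tau_s
    C <- C + (sp$cstar - C) * sim_config$dt / sim_config$pco2_tau_s +
      rnorm(1, 0, phen$noise_pco2)
    S <- S + (sstar - S) * sim_config$dt / spo2_tau +
      rnorm(1, 0, phen$noise_spo2)
    C <- min(149, max(25, C))
    S <- min(100, max(50, S))

    i <- t + 1L
    t_v[i] <- t; flow_v[i] <- flow; spo2_v[i] <- S; pco2_v[i] <- C

    # epoch boundary: closed-loop control
    if ((t + 1L) %% epoch_s == 0L) {
      ep0 <- t + 1L - epoch_s
      if (is.null(baseline_ref) && t + 1L >= 600L) {
        baseline_ref <- mean(pco2_v[seq_len(600L)])
      }
      intol <- runif(1) < phen$intolerance_rate * max(0, P - phen$comfort_pressure)
      intol_log[[length(intol_log) + 1L]] <- tibble(epoch_start = ep0, flag = intol)
      if (controller == "protocol") {
        # score the trailing window and classify this epoch
        w0 <- max(0L, ep0 - scoring_cfg$baseline_window_s)
        idx <- (w0 + 1L):(t + 1L)
        win <- tibble(t = t_v[idx], airflow = flow_v[idx], spo2 = spo2_v[idx])
        scored <- tryCatch(detect_events(win, scoring_cfg),
                           error = function(e) empty_events())
        apnea <- if (nrow(scored) &&
                     any(scored$t_start < t + 1L &
                         scored$t_start + scored$duration > ep0)) "PRESENT" else "ABSENT"
        ep_idx <- (ep0 + 1L):(t + 1L)
        mean_spo2 <- mean(spo2_v[ep_idx])
        mean_pco2 <- mean(pco2_v[ep_idx])
        spo2_band <- if (mean_spo2 < state_cfg$spo2_low) "CRITICAL"
          else if (mean_spo2 <= state_cfg$spo2_high) "SUBOPTIMAL" else "TARGET"
        ref <- baseline_ref %||% mean(pco2_v[seq_len(min(600L, t + 1L))])
        delta <- mean_pco2 - ref
        pco2_trend <- if (delta >= state_cfg$pco2_rise_units) "RISING"
          else if (delta <= -state_cfg$pco2_fall_units) "FALLING" else "STABLE"
        state <- patient_state(apnea, spo2_band, pco2_trend)
        dec <- decide_action(state, device,
                             context = list(pco2_delta = delta, intolerance = intol,
                                            time_since_last_change = t + 1L - last_change),
                             config = policy_cfg)
        decision_log[[length(decision_log) + 1L]] <-
          dplyr::bind_cols(tibble(epoch_start = ep0, state = state), dec)
        if (dec$category != "HOLD") {
          new_dev <- suppressWarnings(
            apply_action(device, dec, t_start = t + 1L, config = policy_cfg))
          if (!identical(new_dev[-1], device[-1])) {
            device <- new_dev
            settings_log <- dplyr::bind_rows(settings_log, device)
            last_change <- t + 1L
          }
        }
      }
    }
  }

  ev <- if (length(events)) dplyr::bind_rows(events) else empty_events()
  # truncate events running past the end
  if (nrow(ev)) {
    ev$duration <- pmin(ev$duration, n - ev$t_start)
    ev <- ev[ev$duration >= 10, ]
  }
  samples <- tibble(t = t_v, airflow = flow_v, spo2 = spo2_v, pco2 = pco2_v)
  settings_log <- settings_log[settings_log$t_start < n, ]
  titration_session(
    patient_id = patient_id,
    samples = samples,
    settings = settings_log,
    events = ev,
    duration = n,
    phenotype = phen,
    decisions = if (length(decision_log)) dplyr::bind_rows(decision_log) else NULL,
    intolerance = if (length(intol_log)) dplyr::bind_rows(intol_log) else NULL
  )
}

#' Simulate a cohort of overnight sessions
#'
#' Draws `n_patients` independent phenotypes and simulates each; per-patient
#' seeds are derived from the master seed by a fixed counter scheme, so
#' enlarging the cohort never reshuffles earlier patients.
#'
#' @param n_patients Cohort size (>= 1).
#' @param seed Master seed.
#' @param controller `"none"` or `"protocol"` (see [simulate_session()]).
#' @param duration Session length in seconds.
#' @param sim_config A [simulator_config()].
#' @param ... Passed to [simulate_session()].
#' @return List of [titration_session] objects.
#' @export
make_cohort <- function(n_patients, seed = 1, controller = "protocol",
                        duration = 36000, sim_config = simulator_config(), ...) {
  if (n_patients < 1) abort("n_patients must be >= 1")
  purrr::map(seq_len(n_patients), function(i) {
    child <- (seed + i * 10007L) %% .Machine$integer.max
    phen <- sample_phenotype(sim_config, seed = child)
    simulate_session(phen, duration = duration, seed = child + 1L,
                     controller = controller, sim_config = sim_config,
                     patient_id = sprintf("synthetic_%02d", i), ...)
  })
}

ramp <- function(from, to, len) from + (to - from) * seq_len(len) / len

#' Deterministic worked-example night
#'
#' A noise-free scripted session reproducing the canonical single-patient
#' titration narrative: CPAP is ramped 1 cmH2O per 5 minutes until apneas
#' disappear at 12 cmH2O; pCO2 transiently stabilizes near 60 mmHg and
#' settles back to 55; 1 L/min of oxygen lifts SpO2 from the high 80s to 92%;
#' increasing oxygen to 2 L/min drives pCO2 from 55 up to 60 mmHg (a 5-unit
#' rise) while SpO2 reaches 96%; tapering back to 1 L/min drops pCO2 to a
#' 53 mmHg plateau and SpO2 to an acceptable 92%.
#'
#' @return A [titration_session] of 6000 s with scripted ground-truth events.
#' @export
narrative_fixture <- function() {
  dur <- 6000L
  t <- 0:(dur - 1L)

  # CPAP ramp 4 -> 12 cmH2O, one step per 300 s, reaching 12 at t = 2400
  press_steps <- tibble(
    t_start = seq(0, 2400, by = 300),
    mode = "CPAP",
    cpap_pressure = 4:12,
    ipap = NA_real_, epap = NA_real_, o2_flow = 0
  )
  o2_steps <- tibble(
    t_start = c(3000, 3600, 4800),
    mode = "CPAP", cpap_pressure = 12,
    ipap = NA_real_, epap = NA_real_,
    o2_flow = c(1, 2, 1)
  )
  settings <- dplyr::bind_rows(press_steps, o2_steps)

  # apneas every 120 s while pressure < 12 (before t = 2400), 20 s each
  ev_starts <- seq(60, 2340, by = 120)
  events <- tibble(kind = "APNEA", t_start = ev_starts, duration = 20)

  airflow <- rep(1, dur)
  for (s in ev_starts) airflow[(s + 1):(s + 20)] <- 0.05

  # pCO2: baseline 55 (first 10 min), transient rise to 60 and decay back,
  # then O2-driven rise to 60 at 2 L/min and fall to 53 after the taper
  pco2 <- rep(55, dur)
  pco2[(600 + 1):1500] <- ramp(55, 60, 900)
  pco2[(1500 + 1):3000] <- ramp(60, 55, 1500)
  pco2[(3600 + 1):3900] <- ramp(55, 60, 300)
  pco2[(3900 + 1):4800] <- 60
  pco2[(4800 + 1):5100] <- ramp(60, 53, 300)
  pco2[(5100 + 1):6000] <- 53

  # SpO2: 85 with event dips while apneic, 87 once apneas resolve,
  # 92 on 1 L/min, 96 on 2 L/min, back to 92 after the taper
  spo2 <- rep(85, dur)
  for (s in ev_starts) spo2[(s + 1):min(dur, s + 40)] <- 80
  spo2[(2400 + 1):3000] <- 87
  spo2[(3000 + 1):3300] <- ramp(87, 92, 300)
  spo2[(3300 + 1):3600] <- 92
  spo2[(3600 + 1):3900] <- ramp(92, 96, 300)
  spo2[(3900 + 1):4800] <- 96
  spo2[(4800 + 1):5100] <- ramp(96, 92, 300)
  spo2[(5100 + 1):6000] <- 92

  titration_session(
    patient_id = "narrative",
    samples = tibble(t = t, airflow = airflow, spo2 = spo2, pco2 = pco2),
    settings = settings,
    events = events,
    duration = dur
  )
}
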