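# Shared fixtures and independent oracles, all built in code.

# flat session: constant vitals under a single CPAP setting
make_flat_session <- function(duration = 1800, spo2 = 95, pco2 = 40,
                              airflow = 1, cpap = 10, o2_flow = 0,
                              patient_id = "flat") {
  t <- 0:(duration - 1)
  titration_session(
    patient_id = patient_id,
    samples = tibble::tibble(t = t, airflow = airflow, spo2 = spo2, pco2 = pco2),
    settings = tibble::tibble(t_start = 0, mode = "CPAP", cpap_pressure = cpap,
                              ipap = NA_real_, epap = NA_real_, o2_flow = o2_flow),
    duration = duration
  )
}

# hand-built phenotype with explicit parameters (defaults: quiet, no noise)
make_phenotype <- function(baseline_spo2 = 85, baseline_pco2 = 50,
                           hypercapnia_class = NULL,
                           ahi_untreated = 30, apnea_threshold_pressure = 12,
                           o2_retention_sens = 0, pressure_retention_sens = 0,
                           vent_clearance_sens = 1.5, comfort_pressure = 20,
                           intolerance_rate = 0, noise_spo2 = 0, noise_pco2 = 0) {
  if (is.null(hypercapnia_class)) {
    hypercapnia_class <- if (baseline_pco2 < 45) "NORMO"
      else if (baseline_pco2 < 55) "HYPER_LOW" else "HYPER_HIGH"
  }
  structure(list(
    baseline_spo2 = baseline_spo2, baseline_pco2 = baseline_pco2,
    hypercapnia_class = hypercapnia_class, ahi_untreated = ahi_untreated,
    apnea_threshold_pressure = apnea_threshold_pressure,
    o2_retention_sens = o2_retention_sens,
    pressure_retention_sens = pressure_retention_sens,
    vent_clearance_sens = vent_clearance_sens,
    comfort_pressure = comfort_pressure,
    intolerance_rate = intolerance_rate,
    noise_spo2 = noise_spo2, noise_pco2 = noise_pco2
  ), class = "patient_phenotype")
}

# random row-stochastic S x A x S transition array with a designated target
random_model <- function(n_states, n_actions) {
  states <- paste0("S", seq_len(n_states))
  states[n_states] <- "GOAL"
  actions <- letters[seq_len(n_actions)]
  probs <- array(0, c(n_states, n_actions, n_states),
                 dimnames = list(states, actions, states))
  for (s in seq_len(n_states)) {
    for (a in seq_len(n_actions)) {
      w <- rexp(n_states)
      probs[s, a, ] <- w / sum(w)
    }
  }
  transition_model_from_probs(probs)
}

# Oracle 1: reach probability by explicit enumeration over all state paths.
# Sums, over every path of <= horizon steps that first hits the target, the
# product of its transition probabilities. Independent of the matrix
# recursion used by the implementation.
enum_reach <- function(model, policy_vec, horizon, target) {
  states <- model$states
  ti <- match(target, states)
  rec <- function(s, k) {
    if (s == ti) return(1)
    if (k == 0) return(0)
    a <- match(policy_vec[s], model$actions)
    p <- model$probs[s, a, ]
    tot <- 0
    for (nxt in seq_along(states)) {
      if (p[nxt] > 0) tot <- tot + p[nxt] * rec(nxt, k - 1)
    }
    tot
  }
  vapply(seq_along(states), function(s) rec(s, horizon), numeric(1))
}

# Oracle 2: optimal reach probability by exhaustive enumeration of all
# time-varying policies (one action per state per step), each evaluated by
# forward propagation of the state distribution with the target absorbing.
enum_optimal_reach <- function(model, horizon, target) {
  S <- length(model$states)
  A <- length(model$actions)
  ti <- match(target, model$states)
  n_cells <- S * horizon
  n_pol <- A^n_cells
  best <- rep(0, S)
  for (code in 0:(n_pol - 1)) {
    digits <- integer(n_cells)
    c0 <- code
    for (d in seq_len(n_cells)) {
      digits[d] <- c0 %% A
      c0 <- c0 %/% A
    }
    plan <- matrix(digits + 1L, nrow = S, ncol = horizon)
    # evaluate: reach prob from each start under this time-varying plan
    v <- matrix(0, S, S)  # row = start state, col = current distribution
    diag(v) <- 1
    for (step in seq_len(horizon)) {
      P <- matrix(0, S, S)
      for (s in seq_len(S)) {
        if (s == ti) P[s, ti] <- 1 else P[s, ] <- model$probs[s, plan[s, step], ]
      }
      v <- v %*% P
    }
    best <- pmax(best, v[, ti])
  }
  best
}

# memoized 14-patient cohort under the protocol controller (study conditions)
.cohort_cache <- new.env(parent = emptyenv())
get_test_cohort <- function() {
  if (is.null(.cohort_cache$cohort)) {
    .cohort_cache$cohort <- make_cohort(14, seed = 1, controller = "protocol",
                                        duration = 36000)
  }
  .cohort_cache$cohort
}
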