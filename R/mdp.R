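#' Estimate an empirical transition model from treatment trajectories
#'
#' Tallies consecutive `(state_t, action_t, state_t+1)` triples over a list
#' of state/action trajectories (as produced by [state_trajectory()]) and
#' converts the counts to row-stochastic probabilities with additive
#' (Laplace) smoothing: `P = (count + alpha) / (row_total + alpha * n_states)`.
#' With `alpha = 0`, `(state, action)` pairs never observed are kept as
#' missing rows (not silently uniform) so that downstream use can flag them —
#' an audit mode for models fit from sparse treatment records.
#'
#' @param trajectories List of data frames, each with columns `state` and
#'   `action` and at least two rows.
#' @param alpha Smoothing pseudo-count (>= 0, default 1).
#' @param states,actions State/action label sets; default to the 18 composite
#'   patient states and 7 action categories, or to the labels observed in the
#'   trajectories when those contain others (e.g. toy chains).
#' @return A `transition_model`: list with `states`, `actions`, `counts`
#'   (S x A x S integer array), `probs` (same shape; `NA` rows when
#'   unobserved and `alpha = 0`) and `alpha`.
#' @export
estimate_transitions <- function(trajectories, alpha = 1,
                                 states = NULL, actions = NULL) {
  if (is.data.frame(trajectories)) trajectories <- list(trajectories)
  if (!length(trajectories)) abort("trajectories must be nonempty")
  if (any(vapply(trajectories, nrow, 1L) < 2)) abort("each trajectory needs length >= 2")
  if (alpha < 0) abort("alpha must be >= 0")
  obs_states <- unique(unlist(lapply(trajectories, function(d) d$state)))
  obs_actions <- unique(unlist(lapply(trajectories, function(d) d$action)))
  if (is.null(states)) {
    states <- if (all(obs_states %in% patient_states())) patient_states() else sort(obs_states)
  }
  if (is.null(actions)) {
    actions <- if (all(obs_actions %in% action_categories())) action_categories() else sort(obs_actions)
  }
  if (!all(obs_states %in% states)) abort("trajectory contains states outside the state set")
  if (!all(obs_actions %in% actions)) abort("trajectory contains actions outside the action set")
  S <- length(states); A <- length(actions)
  counts <- array(0L, dim = c(S, A, S), dimnames = list(states, actions, states))
  for (d in trajectories) {
    n <- nrow(d)
    si <- match(d$state, states)
    ai <- match(d$action, actions)
    for (k in seq_len(n - 1L)) {
      counts[si[k], ai[k], si[k + 1L]] <- counts[si[k], ai[k], si[k + 1L]] + 1L
    }
  }
  new_transition_model(states, actions, counts, alpha)
}

new_transition_model <- function(states, actions, counts, alpha) {
  S <- length(states); A <- length(actions)
  probs <- array(NA_real_, dim = dim(counts), dimnames = dimnames(counts))
  for (s in seq_len(S)) {
    for (a in seq_len(A)) {
      tot <- sum(counts[s, a, ])
      denom <- tot + alpha * S
      if (denom > 0) probs[s, a, ] <- (counts[s, a, ] + alpha) / denom
    }
  }
  structure(list(states = states, actions = actions, counts = counts,
                 probs = probs, alpha = alpha),
            class = "transition_model")
}

#' Build a transition model directly from a probability array
#'
#' Mostly for tests and simulation studies with a known generating chain.
#'
#' @param probs S x A x S row-stochastic array (dimnames give labels).
#' @param states,actions Optional labels (taken from dimnames otherwise).
#' @return A `transition_model` with zero counts.
#' @export
transition_model_from_probs <- function(probs, states = NULL, actions = NULL) {
  states <- states %||% dimnames(probs)[[1]]
  actions <- actions %||% dimnames(probs)[[2]]
  dimnames(probs) <- list(states, actions, states)
  m <- structure(list(states = states, actions = actions,
                      counts = array(0L, dim = dim(probs), dimnames = dimnames(probs)),
                      probs = probs, alpha = 0),
                 class = "transition_model")
  check_row_stochastic(m)
  m
}

check_row_stochastic <- function(model, tol = 1e-9) {
  for (s in seq_along(model$states)) {
    for (a in seq_along(model$actions)) {
      p <- model$probs[s, a, ]
      if (all(is.na(p))) next
      if (any(p < -tol) || abs(sum(p) - 1) > tol) {
        abort(sprintf("row (%s, %s) is not a probability distribution",
                      model$states[s], model$actions[a]))
      }
    }
  }
  invisible(model)
}

#' @export
print.transition_model <- function(x, ...) {
  nobs <- sum(apply(x$counts, c(1, 2), sum) > 0)
  cat(sprintf("<transition_model> %d states x %d actions, %d transitions, %d observed rows, alpha=%g\n",
              length(x$states), length(x$actions), sum(x$counts), nobs, x$alpha))
  invisible(x)
}

#' Tidy a transition model into a long tibble
#' @param x A `transition_model`.
#' @param ... Unused.
#' @return Tibble with `state`, `action`, `next_state`, `count`, `prob`.
#' @method tidy transition_model
#' @export
tidy.transition_model <- function(x, ...) {
  g <- expand.grid(state = x$states, action = x$actions, next_state = x$states,
                   stringsAsFactors = FALSE)
  g$count <- as.vector(x$counts)
  g$prob <- as.vector(x$probs)
  as_tibble(g)
}

#' @rdname tidy.transition_model
#' @method glance transition_model
#' @export
glance.transition_model <- function(x, ...) {
  tibble(n_states = length(x$states), n_actions = length(x$actions),
         n_transitions = sum(x$counts),
         n_observed_rows = sum(apply(x$counts, c(1, 2), sum) > 0),
         alpha = x$alpha)
}

as_policy_vector <- function(policy, model) {
  if (is.data.frame(policy)) policy <- setNames(policy$action, policy$state)
  if (is.null(names(policy))) abort("policy must map state -> action (named vector or tibble)")
  miss <- setdiff(model$states, names(policy))
  if (length(miss)) abort(paste0("policy missing states: ", paste(miss, collapse = ", ")))
  policy[model$states]
}

step_matrix <- function(model, policy_vec, target) {
  S <- length(model$states)
  P <- matrix(0, S, S, dimnames = list(model$states, model$states))
  ti <- match(target, model$states)
  for (s in seq_len(S)) {
    if (!is.na(ti) && s == ti) {
      P[s, s] <- 1  # target forced absorbing
      next
    }
    ai <- match(policy_vec[s], model$actions)
    if (is.na(ai)) abort(sprintf("policy action %s unknown for state %s",
                                 policy_vec[s], model$states[s]))
    row <- model$probs[s, ai, ]
    if (all(is.na(row))) {
      abort(sprintf("(state %s, action %s) never observed and alpha = 0",
                    model$states[s], model$actions[ai]))
    }
    P[s, ] <- row
  }
  P
}

#' Probability of reaching the target state under a policy
#'
#' Backward recursion on the reach probability with the target state forced
#' absorbing: `v_0(target) = 1`, `v_0(other) = 0`,
#' `v_k+1(s) = sum_s' P(s' | s, policy(s)) v_k(s')`.
#'
#' @param model A `transition_model`.
#' @param policy Named character vector (state -> action) or tibble with
#'   `state`, `action` columns.
#' @param horizon Number of epochs (non-negative integer).
#' @param target Target state label (default [target_state()]).
#' @return Tibble with `state` and `reach_prob` (values in `[0, 1]`).
#' @export
reach_probability <- function(model, policy, horizon, target = target_state()) {
  if (!target %in% model$states) abort("target state not in model")
  pv <- as_policy_vector(policy, model)
  P <- step_matrix(model, pv, target)
  v <- as.numeric(model$states == target)
  for (k in seq_len(horizon)) v <- as.vector(P %*% v)
  tibble(state = model$states, reach_prob = pmin(1, pmax(0, v)))
}

available_actions <- function(model) {
  # S x A logical: row defined (observed or smoothed)
  apply(model$probs, c(1, 2), function(p) !all(is.na(p)))
}

#' Optimize the titration policy for reach probability
#'
#' Value iteration on the probability of reaching the (absorbing) target
#' state: `v_k+1(s) = max_a sum_s' P(s' | s, a) v_k(s')`. A finite horizon is
#' solved by exact backward induction; `horizon = Inf` iterates to a sup-norm
#' tolerance of `tol` (the values are bounded in `[0, 1]` and monotone
#' non-decreasing from `v_0`, so the iteration converges). Ties are broken
#' deterministically by the fixed action order of the model. When the model
#' carries the full clinical action set, the target state is assigned HOLD.
#'
#' @param model A `transition_model`.
#' @param horizon Number of epochs, or `Inf`.
#' @param target Target state label.
#' @param tol Sup-norm convergence tolerance for the infinite horizon.
#' @param max_iter Iteration cap for the infinite horizon.
#' @return An `mdp_policy`: tibble with `state`, `action`, `reach_prob`,
#'   carrying the horizon as an attribute.
#' @export
optimize_policy <- function(model, horizon = Inf, target = target_state(),
                            tol = 1e-10, max_iter = 100000L) {
  if (!target %in% model$states) abort("target state not in model")
  S <- length(model$states); A <- length(model$actions)
  avail <- available_actions(model)
  ti <- match(target, model$states)
  no_act <- which(!apply(avail, 1, any))
  no_act <- setdiff(no_act, ti)
  if (length(no_act)) {
    abort(paste0("no available action in state(s): ",
                 paste(model$states[no_act], collapse = ", ")))
  }
  # per-action step matrices with absorbing target
  Pa <- lapply(seq_len(A), function(a) {
    P <- matrix(NA_real_, S, S)
    for (s in seq_len(S)) {
      if (s == ti) { P[s, ] <- 0; P[s, ti] <- 1 } else if (avail[s, a]) P[s, ] <- model$probs[s, a, ]
    }
    P
  })
  v <- as.numeric(seq_len(S) == ti)
  best_a <- rep(1L, S)
  iter <- 0L
  while (horizon >= 1) {
    q <- vapply(seq_len(A), function(a) {
      qa <- as.vector(Pa[[a]] %*% v)
      qa[!avail[, a] & seq_len(S) != ti] <- -Inf
      qa
    }, numeric(S))
    q <- matrix(q, nrow = S)
    v_new <- apply(q, 1, max)
    best_a <- apply(q, 1, which.max)
    iter <- iter + 1L
    if (is.finite(horizon)) {
      if (iter >= horizon) { v <- v_new; break }
    } else if (max(abs(v_new - v)) < tol || iter >= max_iter) {
      v <- v_new; break
    }
    v <- v_new
  }
  actions <- model$actions[best_a]
  if ("HOLD" %in% model$actions) actions[ti] <- "HOLD"
  structure(
    tibble(state = model$states, action = actions,
           reach_prob = pmin(1, pmax(0, v))),
    class = c("mdp_policy", class(tibble())),
    horizon = horizon, target = target
  )
}

#' @method glance mdp_policy
#' @export
glance.mdp_policy <- function(x, ...) {
  tibble(n_states = nrow(x), horizon = attr(x, "horizon"),
         target = attr(x, "target"),
         mean_reach_prob = mean(x$reach_prob),
         min_reach_prob = min(x$reach_prob))
}

#' Monte-Carlo validation of a policy's reach probability
#'
#' Rolls the chain forward under the policy from a given start state and
#' returns the fraction of runs that hit the (absorbing) target within the
#' horizon.
#'
#' @param model A `transition_model`.
#' @param policy Policy (named vector or tibble).
#' @param start Start state label.
#' @param n_runs Number of rollouts (> 0).
#' @param horizon Epochs per rollout.
#' @param seed RNG seed.
#' @param target Target state label.
#' @return Empirical reach frequency (scalar in `[0, 1]`).
#' @export
simulate_policy <- function(model, policy, start, n_runs, horizon,
                            seed = NULL, target = target_state()) {
  if (n_runs <= 0) abort("n_runs must be > 0")
  if (!is.null(seed)) set.seed(seed)
  pv <- as_policy_vector(policy, model)
  P <- step_matrix(model, pv, target)
  S <- length(model$states)
  ti <- match(target, model$states)
  start_i <- match(start, model$states)
  if (is.na(start_i)) abort("start state not in model")
  hits <- 0L
  for (r in seq_len(n_runs)) {
    s <- start_i
    for (k in seq_len(horizon)) {
      if (s == ti) break
      s <- sample.int(S, 1L, prob = P[s, ])
    }
    if (s == ti) hits <- hits + 1L
  }
  hits / n_runs
}

#' Export the decision graph in DOT format
#'
#' Writes a directed graph of states with, for each state, the policy's
#' chosen action and its outgoing transition probabilities at or above a
#' display threshold.
#'
#' @param model A `transition_model`.
#' @param policy Policy (named vector or tibble).
#' @param path Output `.dot` file path.
#' @param threshold Minimum transition probability to draw (default 0.05).
#' @param target Target state label (drawn double-circled).
#' @return `path`, invisibly.
#' @export
export_decision_graph <- function(model, policy, path, threshold = 0.05,
                                  target = target_state()) {
  pv <- as_policy_vector(policy, model)
  P <- step_matrix(model, pv, target)
  esc <- function(x) gsub('"', '\\\\"', x)
  lines <- c("digraph titration_policy {", "  rankdir=LR;")
  for (s in model$states) {
    shape <- if (s == target) "doublecircle" else "ellipse"
    lines <- c(lines, sprintf('  "%s" [shape=%s];', esc(s), shape))
  }
  for (si in seq_along(model$states)) {
    s <- model$states[si]
    for (ni in seq_along(model$states)) {
      p <- P[si, ni]
      if (!is.na(p) && p >= threshold) {
        lines <- c(lines, sprintf('  "%s" -> "%s" [label="%s p=%.2f"];',
                                  esc(s), esc(model$states[ni]),
                                  esc(unname(pv[si])), p))
      }
    }
  }
  lines <- c(lines, "}")
  con <- tryCatch(file(path, "w"), error = function(e) {
    abort(sprintf("cannot open %s for writing", path), class = "paptitrate_io_error")
  })
  on.exit(close(con))
  writeLines(lines, con)
  invisible(path)
}

#' Serialize / restore a transition model as JSON
#'
#' @param model A `transition_model`.
#' @param path JSON file path.
#' @return `path` invisibly (`write_transition_model`) or the restored model
#'   (`read_transition_model`).
#' @export
write_transition_model <- function(model, path) {
  obj <- list(states = model$states, actions = model$actions,
              alpha = model$alpha,
              counts = as.vector(model$counts))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_transition_model
#' @export
read_transition_model <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  S <- length(obj$states); A <- length(obj$actions)
  counts <- array(as.integer(obj$counts), dim = c(S, A, S),
                  dimnames = list(obj$states, obj$actions, obj$states))
  new_transition_model(obj$states, obj$actions, counts, obj$alpha)
}

#' Heatmap of a transition model
#'
#' One tile panel per action; tile fill is the transition probability.
#'
#' @param object A `transition_model`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot transition_model
#' @export
autoplot.transition_model <- function(object, ...) {
  d <- tidy(object) |> dplyr::filter(!is.na(.data$prob))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$next_state, y = .data$state,
                                  fill = .data$prob)) +
    ggplot2::geom_tile() +
    ggplot2::facet_wrap(ggplot2::vars(.data$action)) +
    ggplot2::scale_fill_viridis_c(limits = c(0, 1)) +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90, vjust = 0.5)) +
    ggplot2::labs(x = "next state", y = "state", fill = "P")
}
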