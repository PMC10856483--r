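test_that("transition counts and smoothing follow the estimator definition", {
  # repeated self-loop: probability 1 without smoothing
  aa <- data.frame(state = rep("A", 11), action = "HOLD")
  m <- estimate_transitions(list(aa), alpha = 0, states = c("A", "B"),
                            actions = "HOLD")
  expect_equal(m$probs["A", "HOLD", "A"], 1)
  # unobserved row stays missing in audit mode, smoothed rows are proper
  expect_true(all(is.na(m$probs["B", "HOLD", ])))
  m1 <- estimate_transitions(list(aa), alpha = 1, states = c("A", "B"),
                             actions = "HOLD")
  expect_equal(m1$probs["B", "HOLD", ], c(A = 0.5, B = 0.5))
  expect_equal(m1$probs["A", "HOLD", "A"], 11 / 12)

  # symmetric successors: 0.5 / 0.5
  tr <- list(data.frame(state = c("A", "B"), action = "go"),
             data.frame(state = c("A", "C"), action = "go"))
  m2 <- estimate_transitions(tr, alpha = 0)
  expect_equal(unname(m2$probs["A", "go", c("B", "C")]), c(0.5, 0.5))

  expect_error(estimate_transitions(list(), 1), "nonempty")
  expect_error(estimate_transitions(list(data.frame(state = "A", action = "x"))),
               "length >= 2")
})

test_that("estimated rows stay row-stochastic after smoothing", {
  set.seed(5)
  traj <- data.frame(
    state = sample(patient_states()[1:5], 400, replace = TRUE),
    action = sample(action_categories()[1:3], 400, replace = TRUE))
  m <- estimate_transitions(list(traj), alpha = 1)
  sums <- apply(m$probs, c(1, 2), sum)
  expect_true(all(abs(sums[!is.na(sums)] - 1) < 1e-12))
  expect_true(all(m$counts >= 0))
})

test_that("reach probability matches hand-checkable chains", {
  states <- c("S1", "S2", "GOAL")
  probs <- array(0, c(3, 1, 3), dimnames = list(states, "a", states))
  probs["S1", "a", "S2"] <- 1
  probs["S2", "a", "GOAL"] <- 1
  probs["GOAL", "a", "GOAL"] <- 1
  m <- transition_model_from_probs(probs)
  pol <- setNames(rep("a", 3), states)
  v <- reach_probability(m, pol, 2, target = "GOAL")
  expect_equal(v$reach_prob[v$state == "S1"], 1)
  expect_equal(reach_probability(m, pol, 1, target = "GOAL")$reach_prob,
               c(0, 1, 1))

  probs2 <- array(0, c(2, 1, 2), dimnames = list(c("S", "GOAL"), "a", c("S", "GOAL")))
  probs2["S", "a", ] <- c(0.7, 0.3)
  probs2["GOAL", "a", "GOAL"] <- 1
  m2 <- transition_model_from_probs(probs2)
  v2 <- reach_probability(m2, c(S = "a", GOAL = "a"), 1, target = "GOAL")
  expect_equal(v2$reach_prob[v2$state == "S"], 0.3)
})

test_that("reach probability equals exhaustive path enumeration", {
  set.seed(17)
  m <- random_model(5, 3)
  pol <- setNames(sample(m$actions, 5, replace = TRUE), m$states)
  v <- reach_probability(m, pol, 4, target = "GOAL")
  expect_equal(v$reach_prob, enum_reach(m, pol, 4, "GOAL"), tolerance = 1e-12)
})

test_that("reach probability is monotone non-decreasing in the horizon", {
  set.seed(23)
  m <- random_model(4, 2)
  pol <- setNames(sample(m$actions, 4, replace = TRUE), m$states)
  vals <- vapply(0:6, function(h)
    reach_probability(m, pol, h, target = "GOAL")$reach_prob, numeric(4))
  expect_true(all(diff(t(vals)) >= -1e-12))
})

test_that("policy optimization picks dominant actions with a fixed tie-break", {
  states <- c("S", "GOAL")
  probs <- array(0, c(2, 2, 2), dimnames = list(states, c("a", "b"), states))
  probs["S", "a", ] <- c(0.8, 0.2)
  probs["S", "b", ] <- c(0.1, 0.9)
  probs["GOAL", "a", "GOAL"] <- 1
  probs["GOAL", "b", "GOAL"] <- 1
  m <- transition_model_from_probs(probs)
  pol <- optimize_policy(m, horizon = 1, target = "GOAL")
  expect_equal(pol$action[pol$state == "S"], "b")
  expect_equal(pol$reach_prob[pol$state == "S"], 0.9)

  # equivalent actions: first by declared order
  probs["S", "b", ] <- probs["S", "a", ]
  m2 <- transition_model_from_probs(probs)
  pol2 <- optimize_policy(m2, horizon = 3, target = "GOAL")
  expect_equal(pol2$action[pol2$state == "S"], "a")
})

test_that("optimized value dominates random policies and infinite horizon converges", {
  set.seed(31)
  m <- random_model(5, 3)
  opt <- optimize_policy(m, horizon = 6, target = "GOAL")
  for (i in 1:100) {
    pol <- setNames(sample(m$actions, 5, replace = TRUE), m$states)
    v <- reach_probability(m, pol, 6, target = "GOAL")
    expect_true(all(opt$reach_prob >= v$reach_prob - 1e-12))
  }
  inf_pol <- optimize_policy(m, horizon = Inf, target = "GOAL")
  expect_true(all(inf_pol$reach_prob >= opt$reach_prob - 1e-12))
  expect_true(all(inf_pol$reach_prob <= 1 + 1e-12))
})

test_that("audit mode surfaces unobserved state-action pairs instead of guessing", {
  tr <- data.frame(state = c("A", "B", "A"), action = c("x", "x", "x"))
  m <- estimate_transitions(list(tr), alpha = 0, states = c("A", "B"),
                            actions = c("x", "y"))
  expect_error(reach_probability(m, c(A = "y", B = "x"), 2, target = "B"),
               "never observed")
})

test_that("Monte-Carlo rollouts agree with the computed reach probability", {
  states <- c("S", "GOAL")
  probs <- array(0, c(2, 1, 2), dimnames = list(states, "a", states))
  probs["S", "a", ] <- c(0.7, 0.3)
  probs["GOAL", "a", "GOAL"] <- 1
  m <- transition_model_from_probs(probs)
  pol <- c(S = "a", GOAL = "a")
  f <- simulate_policy(m, pol, "S", n_runs = 10000, horizon = 1, seed = 4,
                       target = "GOAL")
  se <- sqrt(0.3 * 0.7 / 10000)
  expect_lt(abs(f - 0.3), 3 * se)

  # deterministic chain reaches with certainty
  set.seed(9)
  md <- random_model(3, 2)
  md$probs[1, , ] <- 0; md$probs[1, , 2] <- 1
  md$probs[2, , ] <- 0; md$probs[2, , 3] <- 1
  md$probs[3, , ] <- 0; md$probs[3, , 3] <- 1
  pol <- setNames(rep("a", 3), md$states)
  expect_equal(simulate_policy(md, pol, md$states[1], 200, 2, seed = 1,
                               target = "GOAL"), 1)

  # self-consistency on a random model
  m3 <- random_model(4, 2)
  pol3 <- setNames(sample(m3$actions, 4, replace = TRUE), m3$states)
  p_exact <- reach_probability(m3, pol3, 3, target = "GOAL")
  p_hat <- simulate_policy(m3, pol3, "S1", 4000, 3, seed = 6, target = "GOAL")
  p0 <- p_exact$reach_prob[p_exact$state == "S1"]
  expect_lt(abs(p_hat - p0), 3 * sqrt(p0 * (1 - p0) / 4000) + 1e-9)

  expect_error(simulate_policy(m3, pol3, "S1", 0, 3), "n_runs")
})

test_that("the decision graph export is well-formed DOT", {
  set.seed(2)
  m <- random_model(3, 2)
  pol <- optimize_policy(m, horizon = 4, target = "GOAL")
  path <- withr::local_tempfile(fileext = ".dot")
  export_decision_graph(m, pol, path)
  lines <- readLines(path)
  expect_equal(lines[1], "digraph titration_policy {")
  expect_equal(tail(lines, 1), "}")
  node_lines <- grep("shape=", lines, value = TRUE)
  expect_length(node_lines, 3)
  edge_lines <- grep("->", lines, value = TRUE)
  expect_gt(length(edge_lines), 0)
  # edge labels carry the model's probabilities
  lbl <- regmatches(edge_lines, regexpr("p=[0-9.]+", edge_lines))
  expect_true(all(as.numeric(sub("p=", "", lbl)) >= 0.05))

  # uniform smoothed 18-state model: every edge at 1/18 clears the threshold
  empty_traj <- data.frame(state = rep(target_state(), 2), action = "HOLD")
  mu <- estimate_transitions(list(empty_traj), alpha = 1)
  polu <- optimize_policy(mu, horizon = 2)
  path2 <- withr::local_tempfile(fileext = ".dot")
  export_decision_graph(mu, polu, path2)
  expect_gt(length(grep("->", readLines(path2))), 17 * 18 - 1)
})

test_that("model serialization round-trips through JSON", {
  set.seed(12)
  traj <- data.frame(state = sample(c("A", "B", "C"), 60, replace = TRUE),
                     action = sample(c("x", "y"), 60, replace = TRUE))
  m <- estimate_transitions(list(traj), alpha = 1)
  path <- withr::local_tempfile(fileext = ".json")
  write_transition_model(m, path)
  m2 <- read_transition_model(path)
  expect_equal(m2$states, m$states)
  expect_equal(m2$actions, m$actions)
  expect_equal(m2$counts, m$counts)
  expect_equal(m2$probs, m$probs)
  expect_equal(m2$alpha, m$alpha)
})
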