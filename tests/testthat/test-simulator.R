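test_that("phenotype sampling is reproducible and class-consistent", {
  p1 <- sample_phenotype(seed = 99)
  p2 <- sample_phenotype(seed = 99)
  expect_identical(unclass(p1), unclass(p2))

  for (i in 1:20) {
    p <- sample_phenotype(seed = 1000 + i)
    expect_true(p$baseline_spo2 >= 60 && p$baseline_spo2 <= 100)
    expect_true(p$baseline_pco2 >= 30 && p$baseline_pco2 <= 90)
    expect_true(all(c(p$o2_retention_sens, p$pressure_retention_sens,
                      p$vent_clearance_sens) >= 0))
    cls <- if (p$baseline_pco2 < 45) "NORMO"
      else if (p$baseline_pco2 < 55) "HYPER_LOW" else "HYPER_HIGH"
    expect_equal(p$hypercapnia_class, cls)
  }
})

test_that("sampled cohort baselines match the configured population", {
  set.seed(123)
  draws <- replicate(1000, sample_phenotype()$baseline_spo2)
  expect_lt(abs(mean(draws) - 79.7), 1.0)
  set.seed(124)
  classes <- replicate(1000, sample_phenotype()$hypercapnia_class)
  expect_lt(abs(mean(classes == "NORMO") - 2 / 14), 0.05)
  expect_lt(abs(mean(classes == "HYPER_HIGH") - 4 / 14), 0.05)
})

test_that("simulated sessions validate and are bit-identical per seed", {
  phen <- sample_phenotype(seed = 55)
  s1 <- simulate_session(phen, duration = 1800, seed = 56, controller = "protocol")
  s2 <- simulate_session(phen, duration = 1800, seed = 56, controller = "protocol")
  expect_identical(s1$samples, s2$samples)
  expect_identical(s1$settings, s2$settings)
  expect_identical(s1$events, s2$events)
  expect_s3_class(validate_session(s1), "titration_session")
  expect_error(simulate_session(phen, duration = 300), ">= 600")
})

test_that("steady-state responses to oxygen follow the phenotype sensitivities", {
  dev <- function(o2) tibble::tibble(t_start = 0, mode = "CPAP",
                                     cpap_pressure = 8, ipap = NA_real_,
                                     epap = NA_real_, o2_flow = o2)
  run_at <- function(phen, o2) {
    s <- simulate_session(phen, duration = 7200, seed = 14, controller = "none",
                          init_setting = dev(o2))
    idx <- s$samples$t >= 3600   # past the relaxation transient
    c(spo2 = mean(s$samples$spo2[idx]), pco2 = mean(s$samples$pco2[idx]))
  }
  # normocapnic: oxygen raises SpO2, leaves pCO2 unchanged
  normo <- make_phenotype(baseline_spo2 = 80, baseline_pco2 = 40,
                          ahi_untreated = 0, o2_retention_sens = 0)
  at0 <- run_at(normo, 0); at1 <- run_at(normo, 1)
  gain <- simulator_config()$spo2_o2_gain
  expect_equal(unname(at1["spo2"] - at0["spo2"]), gain, tolerance = 0.15)
  expect_lt(abs(at1["pco2"] - at0["pco2"]), 0.5)

  # CO2 retainer: each L/min raises steady-state pCO2 by its sensitivity,
  # reverting when the flow is tapered
  hyper <- make_phenotype(baseline_spo2 = 80, baseline_pco2 = 50,
                          ahi_untreated = 0, o2_retention_sens = 2.5)
  h1 <- run_at(hyper, 1); h2 <- run_at(hyper, 2)
  expect_equal(unname(h2["pco2"] - h1["pco2"]), 2.5, tolerance = 0.3)
  h1b <- run_at(hyper, 1)
  expect_equal(unname(h1b["pco2"]), unname(h1["pco2"]), tolerance = 0.3)
})

test_that("SpO2 and pCO2 setpoints are monotone in oxygen flow at zero noise", {
  phen <- make_phenotype(baseline_spo2 = 78, baseline_pco2 = 50,
                         ahi_untreated = 0, o2_retention_sens = 1.5)
  means <- vapply(0:3, function(f) {
    s <- simulate_session(phen, duration = 3600, seed = 3, controller = "none",
                          init_setting = tibble::tibble(
                            t_start = 0, mode = "CPAP", cpap_pressure = 8,
                            ipap = NA_real_, epap = NA_real_, o2_flow = f))
    idx <- s$samples$t >= 1800
    c(mean(s$samples$spo2[idx]), mean(s$samples$pco2[idx]))
  }, numeric(2))
  expect_true(all(diff(means[1, ]) > 0))
  expect_true(all(diff(means[2, ]) > 0))
})

test_that("high pressure suppresses events as the logistic rate dictates", {
  phen <- make_phenotype(ahi_untreated = 30, apnea_threshold_pressure = 12,
                         noise_spo2 = 0.1, noise_pco2 = 0.05)
  ahi_at <- function(p) {
    s <- simulate_session(phen, duration = 7200, seed = 31, controller = "none",
                          init_setting = tibble::tibble(
                            t_start = 0, mode = "CPAP", cpap_pressure = p,
                            ipap = NA_real_, epap = NA_real_, o2_flow = 0))
    compute_ahi(detect_events(s$samples), 7200)
  }
  # 3 cmH2O above threshold (-2 logits): an order of magnitude below untreated
  expect_lt(ahi_at(15), 0.3 * 30)
  # 6 cmH2O above threshold (-4 logits): clinically resolved
  expect_lt(ahi_at(18), 5)
})

test_that("cohorts are reproducible and treatment lowers the event burden", {
  c1 <- make_cohort(3, seed = 77, controller = "none", duration = 1800)
  c2 <- make_cohort(3, seed = 77, controller = "none", duration = 1800)
  for (i in 1:3) expect_identical(c1[[i]]$samples, c2[[i]]$samples)
  expect_length(c1, 3)

  cohort <- get_test_cohort()
  expect_length(cohort, 14)
  treated <- vapply(cohort, function(s) {
    compute_ahi(s$events[s$events$t_start >= s$duration - 3600, ], 3600)
  }, numeric(1))
  untreated <- vapply(cohort, function(s) s$phenotype$ahi_untreated, numeric(1))
  expect_lt(mean(treated), mean(untreated))
})

test_that("the worked-example night hits its scripted plateaus", {
  nf <- narrative_fixture()
  g <- function(t) nf$samples[nf$samples$t == t, ]
  expect_equal(g(4500)$pco2, 60)   # 2 L/min plateau
  expect_equal(g(4500)$spo2, 96)
  expect_equal(g(5500)$pco2, 53)   # after the 2 -> 1 L/min taper
  expect_equal(g(5500)$spo2, 92)
  # apneas stop once the ramp reaches 12 cmH2O
  expect_true(all(nf$events$t_start + nf$events$duration <= 2400))
  scored <- detect_events(nf$samples)
  expect_true(all(scored$t_start < 2400))
})

test_that("a titrated cohort reproduces the qualitative correlation pattern", {
  cohort <- get_test_cohort()
  recs <- suppressWarnings(
    dplyr::bind_rows(lapply(cohort, session_correlations)))
  bipap <- recs[recs$modality == "BIPAP", ]
  if (nrow(bipap) >= 2) {
    # pCO2 falls with IPAP in most bi-level patients
    expect_gt(mean(bipap$r_pco2 < 0, na.rm = TRUE), 0.5)
  }
  n_pos_bipap <- sum(bipap$strength_spo2 == "STRONG_POS", na.rm = TRUE)
  cpap <- recs[recs$modality == "CPAP", ]
  n_pos_cpap <- sum(cpap$strength_spo2 == "STRONG_POS", na.rm = TRUE)
  expect_gte(n_pos_bipap, n_pos_cpap)
})
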