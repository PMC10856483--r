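test_that("pearson_r matches the direct product-moment formula", {
  expect_equal(pearson_r(1:10, 1:10), 1)
  expect_equal(pearson_r(1:10, 7 - 2 * (1:10)), -1)
  expect_equal(pearson_r(c(1, 2, 3, 4), c(1, 3, 2, 4)), 0.8)
  expect_error(pearson_r(1:5, rep(2, 5)), class = "paptitrate_constant_series_error")
  expect_error(pearson_r(1:4, 1:5), "equal length")
  expect_error(pearson_r(1:2, 2:1), "at least 3")

  # brute-force formula oracle on random inputs
  set.seed(42)
  for (i in 1:25) {
    n <- sample(3:40, 1)
    x <- rnorm(n); y <- rnorm(n)
    r_direct <- sum((x - mean(x)) * (y - mean(y))) /
      sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
    expect_equal(pearson_r(x, y), r_direct, tolerance = 1e-12)
  }
})

test_that("strength classification has closed boundaries and odd symmetry", {
  expect_equal(classify_strength(0.50), "STRONG_POS")
  expect_equal(classify_strength(0.48), "WEAK")
  expect_equal(classify_strength(-0.77), "STRONG_NEG")
  expect_equal(classify_strength(c(-0.5, 0, NA)), c("STRONG_NEG", "WEAK", NA))
  expect_error(classify_strength(1.2), "<= 1")
  set.seed(8)
  r <- runif(50, -1, 1)
  mirror <- c(STRONG_POS = "STRONG_NEG", STRONG_NEG = "STRONG_POS", WEAK = "WEAK")
  expect_equal(unname(mirror[classify_strength(r)]), classify_strength(-r))
})

test_that("the packaged reference cohort loads as transcribed", {
  wide <- load_table2_fixture(long = FALSE)
  expect_equal(nrow(wide), 14)
  expect_equal(wide$r_pco2_cpap[wide$patient_id == "1"], 0.77)
  expect_equal(wide$r_pco2_bipap[wide$patient_id == "1"], -0.67)
  # BiPAP coefficients exist exactly for the transitioned patients
  expect_equal(!is.na(wide$r_pco2_bipap), wide$bipap_transition == "Yes")
  long <- load_table2_fixture()
  expect_equal(sum(long$modality == "BIPAP"), 7)
  expect_equal(nrow(long), 21)
})

test_that("session correlations recover engineered pressure couplings", {
  # retainer under a pure CPAP ramp at zero noise: near-perfect linearity
  # (comfort at the ramp start so pCO2 begins at its equilibrium)
  phen <- make_phenotype(baseline_pco2 = 50, ahi_untreated = 0,
                         pressure_retention_sens = 1.5, comfort_pressure = 8)
  sched <- tibble::tibble(t_start = seq(0, 4500, by = 900), mode = "CPAP",
                          cpap_pressure = 8:13, ipap = NA_real_,
                          epap = NA_real_, o2_flow = 0)
  s <- simulate_session(phen, duration = 5400, seed = 1, controller = "none",
                        schedule = sched)
  rec <- session_correlations(s)
  expect_equal(rec$modality, "CPAP")
  expect_equal(rec$stratum, "LT55")
  expect_gt(rec$r_pco2, 0.95)
  expect_equal(rec$strength_pco2, "STRONG_POS")

  # constant pressure: record omitted with a warning
  flatp <- simulate_session(phen, duration = 1800, seed = 2, controller = "none")
  expect_warning(none <- session_correlations(flatp), "constant")
  expect_equal(nrow(none), 0)

  # the worked-example night has a CPAP record and no BiPAP segment
  recs <- session_correlations(narrative_fixture())
  expect_equal(recs$modality, "CPAP")
})

test_that("summary statistics handle paired deltas and degenerate cases", {
  x <- c(3, 5, 7, 9)
  same <- summary_stats(x, x, paired = TRUE)
  expect_equal(same$delta_mean, 0)
  expect_equal(same$p, 1)

  expect_error(summary_stats(c(0, 2), c(1, 3), paired = TRUE),
               class = "paptitrate_degenerate_variance_error")
  expect_error(summary_stats(1:3, 1:4, paired = TRUE), "equal length")

  set.seed(13)
  b <- rnorm(12, 80, 5); a <- b + rnorm(12, 4, 2)
  st <- summary_stats(b, a, paired = TRUE)
  tt <- t.test(a, b, paired = TRUE)
  expect_equal(st$t, unname(tt$statistic))
  expect_equal(st$p, unname(tt$p.value))
  expect_equal(st$sd_before, sd(b))           # n-1 denominator
  expect_equal(st$delta_iqr,
               unname(diff(quantile(a - b, c(0.25, 0.75)))))
})

test_that("Welch t from summaries matches the long-form test", {
  same <- t_from_summary(10, 2, 8, 10, 2, 8)
  expect_equal(same$t, 0)
  expect_equal(same$p, 1)

  set.seed(77)
  x <- rnorm(14, 60, 25); y <- rnorm(14, 20, 12)
  ours <- t_from_summary(mean(x), sd(x), 14, mean(y), sd(y), 14)
  ref <- t.test(x, y, var.equal = FALSE)
  expect_equal(ours$t, unname(ref$statistic), tolerance = 1e-12)
  expect_equal(ours$df, unname(ref$parameter), tolerance = 1e-12)
  expect_equal(ours$p, unname(ref$p.value), tolerance = 1e-12)

  wider <- t_from_summary(10, 4, 8, 14, 6, 8)
  narrower <- t_from_summary(10, 2, 8, 14, 3, 8)
  expect_lt(abs(wider$t), abs(narrower$t))
  expect_error(t_from_summary(1, 0, 5, 2, 1, 5), "SD")
})

test_that("cohort counts summarize strong-correlation structure", {
  empty_strong <- tibble::tibble(
    patient_id = c("a", "b"), stratum = c("LT55", "GT55"), modality = "CPAP",
    r_pco2 = c(0.1, -0.2), r_spo2 = c(0.3, 0),
    strength_pco2 = "WEAK", strength_spo2 = "WEAK")
  cc <- cohort_counts(empty_strong)
  expect_equal(cc$n_bipap_transition, 0)
  expect_equal(cc$n_strong_pos_spo2_cpap, 0)
  expect_equal(cc$n_strong_pos_pco2_cpap_lt55, 0)
  expect_error(cohort_counts(empty_strong[0, ]), "nonempty")
})

test_that("a protocol-titrated cohort improves SpO2 and AHI significantly", {
  cohort <- get_test_cohort()
  ahi_before <- vapply(cohort, function(s) s$phenotype$ahi_untreated, numeric(1))
  ahi_after <- vapply(cohort, function(s)
    compute_ahi(s$events[s$events$t_start >= s$duration - 3600, ], 3600), numeric(1))
  spo2_before <- vapply(cohort, function(s) s$phenotype$baseline_spo2, numeric(1))
  spo2_after <- vapply(cohort, function(s)
    mean(s$samples$spo2[s$samples$t >= s$duration - 3600]), numeric(1))
  ahi_stats <- summary_stats(ahi_after, ahi_before, paired = TRUE)
  spo2_stats <- summary_stats(spo2_before, spo2_after, paired = TRUE)
  expect_gt(ahi_stats$delta_mean, 0)    # events removed by treatment
  expect_lt(ahi_stats$p, 0.05)
  expect_gt(spo2_stats$delta_mean, 0)   # oxygenation improves
  expect_lt(spo2_stats$p, 0.05)
})
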