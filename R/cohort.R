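#' Pearson product-moment correlation
#'
#' Thin wrapper around [stats::cor()] that rejects degenerate inputs instead
#' of silently returning `NA`: correlation against a constant series is
#' undefined and raises an error.
#'
#' @param x,y Numeric vectors of equal length >= 3.
#' @return Correlation coefficient in `[-1, 1]`.
#' @export
pearson_r <- function(x, y) {
  if (length(x) != length(y)) abort("x and y must have equal length")
  if (length(x) < 3) abort("need at least 3 paired observations")
  if (sd(x) == 0 || sd(y) == 0) {
    abort("correlation undefined for a constant series",
          class = "paptitrate_constant_series_error")
  }
  cor(x, y)
}

#' Classify correlation strength
#'
#' `STRONG_POS` for `r >= threshold`, `STRONG_NEG` for `r <= -threshold`
#' (closed boundaries), else `WEAK`. The default threshold of 0.5 is the
#' conventional cut-off for a strong correlation and is the boundary the
#' packaged reference cohort's strong/weak split is built on.
#'
#' @param r Correlation coefficient(s), `|r| <= 1`.
#' @param threshold Strength boundary (default 0.5).
#' @return Character vector (`NA` propagated).
#' @export
classify_strength <- function(r, threshold = 0.5) {
  if (any(abs(r) > 1, na.rm = TRUE)) abort("|r| must be <= 1")
  dplyr::case_when(
    is.na(r) ~ NA_character_,
    r >= threshold ~ "STRONG_POS",
    r <= -threshold ~ "STRONG_NEG",
    TRUE ~ "WEAK"
  )
}

stratum_from_pco2 <- function(pco2) {
  if (pco2 < 45) "NO" else if (pco2 < 55) "LT55" else "GT55"
}

#' Per-modality pressure correlations of one session
#'
#' For each modality segment present in the session (CPAP epochs, BiPAP
#' epochs), correlates the epoch-mean pCO2 and SpO2 with the pressure
#' covariate (CPAP pressure, or IPAP under BiPAP). The patient's hypercapnia
#' stratum is taken from the session-baseline pCO2 (< 45 mmHg normocapnic
#' `NO`, < 55 `LT55`, else `GT55`). Segments with fewer than 3 epochs or a
#' constant pressure covariate are omitted with a warning; a constant
#' response series yields `NA` for that coefficient with a warning.
#'
#' @param session A [titration_session] with a settings schedule.
#' @param config A [state_config()].
#' @param threshold Strength boundary for [classify_strength()].
#' @return Tibble of correlation records: `patient_id`, `stratum`,
#'   `modality`, `n_epochs`, `r_pco2`, `r_spo2`, `strength_pco2`,
#'   `strength_spo2`.
#' @export
session_correlations <- function(session, config = state_config(),
                                 threshold = 0.5) {
  traj <- state_trajectory(session, config)
  base_pco2 <- mean(session$samples$pco2[session$samples$t < 600])
  stratum <- stratum_from_pco2(base_pco2)
  safe_r <- function(x, y) {
    tryCatch(pearson_r(x, y),
             paptitrate_constant_series_error = function(e) {
               warn(conditionMessage(e))
               NA_real_
             })
  }
  recs <- lapply(c("CPAP", "BIPAP"), function(m) {
    seg <- traj[traj$mode == m, ]
    if (nrow(seg) == 0) return(NULL)
    if (nrow(seg) < 3) {
      warn(sprintf("patient %s: %s segment has fewer than 3 epochs; omitted",
                   session$patient_id, m))
      return(NULL)
    }
    if (sd(seg$pressure) == 0) {
      warn(sprintf("patient %s: constant %s pressure; record omitted",
                   session$patient_id, m))
      return(NULL)
    }
    tibble(
      patient_id = session$patient_id, stratum = stratum, modality = m,
      n_epochs = nrow(seg),
      r_pco2 = safe_r(seg$pressure, seg$mean_pco2),
      r_spo2 = safe_r(seg$pressure, seg$mean_spo2)
    )
  })
  recs <- dplyr::bind_rows(recs)
  if (nrow(recs)) {
    recs$strength_pco2 <- classify_strength(recs$r_pco2, threshold)
    recs$strength_spo2 <- classify_strength(recs$r_spo2, threshold)
  }
  recs
}

#' Load the packaged reference correlation table
#'
#' A transcribed 14-patient reference cohort of per-patient Pearson
#' correlation coefficients of pCO2 and SpO2 against pressure, under CPAP and
#' (for the seven patients transitioned) BiPAP, stratified by initial
#' hypercapnia (`NO` < 45 mmHg, `LT55` 45-55, `GT55` >= 55).
#'
#' @param long Return one row per (patient, modality) record (default);
#'   `FALSE` returns the wide table as transcribed.
#' @param threshold Strength boundary for [classify_strength()].
#' @return A tibble of correlation records.
#' @export
load_table2_fixture <- function(long = TRUE, threshold = 0.5) {
  path <- system.file("extdata", "table2_correlations.csv", package = "paptitrate")
  wide <- readr::read_csv(path, show_col_types = FALSE,
                          col_types = readr::cols(
                            patient_id = "c", stratum = "c",
                            spo2_gt88_before = "c", spo2_gt88_after = "c",
                            bipap_transition = "c", .default = "d"))
  if (!long) return(wide)
  cpap <- wide |>
    dplyr::transmute(
      patient_id = .data$patient_id, stratum = .data$stratum,
      bipap_transition = .data$bipap_transition == "Yes",
      modality = "CPAP", r_pco2 = .data$r_pco2_cpap, r_spo2 = .data$r_spo2_cpap)
  bipap <- wide |>
    dplyr::filter(.data$bipap_transition == "Yes") |>
    dplyr::transmute(
      patient_id = .data$patient_id, stratum = .data$stratum,
      bipap_transition = TRUE,
      modality = "BIPAP", r_pco2 = .data$r_pco2_bipap, r_spo2 = .data$r_spo2_bipap)
  out <- dplyr::bind_rows(cpap, bipap)
  out$strength_pco2 <- classify_strength(out$r_pco2, threshold)
  out$strength_spo2 <- classify_strength(out$r_spo2, threshold)
  out
}

#' Stratified strong-correlation counts for a cohort
#'
#' Summarizes a long correlation-record table into the counts a titration
#' cohort report is built from: how many patients transitioned to BiPAP, how
#' many show strong positive pCO2-pressure coupling under CPAP among those
#' starting below 55 mmHg, how many severe hypercapnics lack a strong CPAP
#' pCO2 correlation, strong SpO2 correlations per modality, and the severe
#' stratum's BiPAP SpO2 response. Percentages use the cohort size for CPAP
#' figures and the BiPAP-transitioned count for BiPAP figures.
#'
#' @param records Long record tibble as from [load_table2_fixture()] or
#'   [session_correlations()] rows bound together.
#' @return Named list of counts and percentages (class `cohort_counts`).
#' @export
cohort_counts <- function(records) {
  if (!nrow(records)) abort("records must be nonempty")
  pat <- records |>
    dplyr::distinct(.data$patient_id, .data$stratum)
  n_patients <- nrow(pat)
  bipap_ids <- unique(records$patient_id[records$modality == "BIPAP"])
  cpap <- records[records$modality == "CPAP", ]
  bipap <- records[records$modality == "BIPAP", ]
  n_bipap <- length(bipap_ids)

  count_ids <- function(d, cond) length(unique(d$patient_id[cond & !is.na(cond)]))
  n_strong_pos_pco2_cpap_lt55 <- count_ids(
    cpap, cpap$stratum %in% c("NO", "LT55") & cpap$strength_pco2 == "STRONG_POS")
  n_gt55_cpap <- count_ids(cpap, cpap$stratum == "GT55")
  n_gt55_no_strong_pco2_cpap <- count_ids(
    cpap, cpap$stratum == "GT55" & cpap$strength_pco2 == "WEAK")
  n_strong_neg_pco2_bipap <- count_ids(bipap, bipap$strength_pco2 == "STRONG_NEG")
  n_strong_pos_spo2_cpap <- count_ids(cpap, cpap$strength_spo2 == "STRONG_POS")
  n_strong_neg_spo2_cpap <- count_ids(cpap, cpap$strength_spo2 == "STRONG_NEG")
  n_strong_pos_spo2_bipap <- count_ids(bipap, bipap$strength_spo2 == "STRONG_POS")
  n_strong_pos_spo2_bipap_gt55 <- count_ids(
    bipap, bipap$stratum == "GT55" & bipap$strength_spo2 == "STRONG_POS")
  n_lt55_or_normo <- sum(pat$stratum %in% c("NO", "LT55"))

  structure(list(
    n_patients = n_patients,
    n_normocapnic = sum(pat$stratum == "NO"),
    n_bipap_transition = n_bipap,
    n_strong_pos_pco2_cpap_lt55 = n_strong_pos_pco2_cpap_lt55,
    pct_strong_pos_pco2_cpap_lt55 =
      if (n_lt55_or_normo) 100 * n_strong_pos_pco2_cpap_lt55 / n_lt55_or_normo else NA_real_,
    n_gt55_no_strong_pco2_cpap = n_gt55_no_strong_pco2_cpap,
    n_gt55_cpap = n_gt55_cpap,
    n_strong_neg_pco2_bipap = n_strong_neg_pco2_bipap,
    n_strong_pos_spo2_cpap = n_strong_pos_spo2_cpap,
    pct_strong_pos_spo2_cpap = 100 * n_strong_pos_spo2_cpap / n_patients,
    n_strong_neg_spo2_cpap = n_strong_neg_spo2_cpap,
    n_strong_pos_spo2_bipap = n_strong_pos_spo2_bipap,
    pct_strong_pos_spo2_bipap =
      if (n_bipap) 100 * n_strong_pos_spo2_bipap / n_bipap else NA_real_,
    n_strong_pos_spo2_bipap_gt55 = n_strong_pos_spo2_bipap_gt55
  ), class = "cohort_counts")
}

#' @export
print.cohort_counts <- function(x, ...) {
  cat("<cohort_counts>\n")
  for (nm in names(x)) cat(sprintf("  %-34s %s\n", nm, format(x[[nm]], digits = 4)))
  invisible(x)
}

#' Before/after cohort summary with deltas and t test
#'
#' Means, SDs (n-1 denominator), ranges for both series, per-subject deltas
#' (`after - before`) with median and IQR (linear-interpolation quartiles),
#' and a two-sided t test: paired when `paired = TRUE` (default), otherwise
#' Welch.
#'
#' @param before,after Numeric vectors; equal length when paired, each n >= 2.
#' @param paired Paired test (default) or Welch two-sample.
#' @return One-row tibble (`n`, `mean_before`, `sd_before`, `min_before`,
#'   `max_before`, same for after, `delta_mean`, `delta_sd`, `delta_median`,
#'   `delta_iqr`, `t`, `df`, `p`).
#' @export
summary_stats <- function(before, after, paired = TRUE) {
  if (paired && length(before) != length(after)) {
    abort("paired series must have equal length")
  }
  if (length(before) < 2 || length(after) < 2) abort("need n >= 2 per series")
  delta <- if (paired) after - before else NULL
  if (paired && sd(delta) == 0 && !all(delta == 0)) {
    abort("degenerate delta variance: paired t statistic undefined",
          class = "paptitrate_degenerate_variance_error")
  }
  tt <- if (paired) {
    if (all(delta == 0)) list(statistic = 0, parameter = length(delta) - 1, p.value = 1)
    else t.test(after, before, paired = TRUE)
  } else {
    t.test(after, before, var.equal = FALSE)
  }
  q <- if (paired) quantile(delta, c(0.25, 0.5, 0.75), type = 7) else rep(NA_real_, 3)
  tibble(
    n = length(before),
    mean_before = mean(before), sd_before = sd(before),
    min_before = min(before), max_before = max(before),
    mean_after = mean(after), sd_after = sd(after),
    min_after = min(after), max_after = max(after),
    delta_mean = if (paired) mean(delta) else mean(after) - mean(before),
    delta_sd = if (paired) sd(delta) else NA_real_,
    delta_median = unname(q[2]), delta_iqr = unname(q[3] - q[1]),
    t = unname(tt$statistic), df = unname(tt$parameter),
    p = unname(tt$p.value)
  )
}

#' Welch t test from printed summary statistics
#'
#' Computes the Welch statistic and Welch-Satterthwaite degrees of freedom
#' directly from group means, SDs and sizes — the form needed when only the
#' summary table of a cohort is available.
#'
#' @param m1,sd1,n1 First group mean, SD (> 0), size (>= 2).
#' @param m2,sd2,n2 Second group.
#' @return One-row tibble: `t`, `df`, `p` (two-sided).
#' @export
t_from_summary <- function(m1, sd1, n1, m2, sd2, n2) {
  if (n1 < 2 || n2 < 2) abort("need n >= 2 per group")
  if (sd1 <= 0 || sd2 <= 0) abort("SDs must be > 0")
  v1 <- sd1^2 / n1
  v2 <- sd2^2 / n2
  t <- (m1 - m2) / sqrt(v1 + v2)
  df <- (v1 + v2)^2 / (v1^2 / (n1 - 1) + v2^2 / (n2 - 1))
  tibble(t = t, df = df, p = 2 * pt(-abs(t), df))
}

#' Correlation-record dot plot
#'
#' Coefficients per patient, faceted by response variable and colored by
#' modality, with the strength boundaries drawn.
#'
#' @param records Long correlation-record tibble.
#' @param threshold Strength boundary to draw.
#' @return A ggplot object.
#' @export
plot_correlation_records <- function(records, threshold = 0.5) {
  d <- records |>
    tidyr::pivot_longer(c("r_pco2", "r_spo2"), names_to = "response",
                        values_to = "r", names_prefix = "r_") |>
    dplyr::filter(!is.na(.data$r))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$r, y = .data$patient_id,
                                  colour = .data$modality)) +
    ggplot2::geom_vline(xintercept = c(-threshold, threshold), linetype = 2) +
    ggplot2::geom_point() +
    ggplot2::facet_wrap(ggplot2::vars(.data$response)) +
    ggplot2::xlim(-1, 1) +
    ggplot2::labs(x = "Pearson r vs pressure", y = "patient")
}
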