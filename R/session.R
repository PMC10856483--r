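#' Titration session container
#'
#' A `titration_session` bundles one overnight attended titration recording:
#' a vitals time series sampled at integer seconds, the device-setting
#' schedule (piecewise-constant, half-open intervals), the scored (or
#' ground-truth) respiratory events, and patient metadata. All user-facing
#' components are tibbles so they compose directly with dplyr pipelines.
#'
#' @param patient_id Character scalar identifying the patient.
#' @param samples Tibble with columns `t` (integer seconds from session start,
#'   strictly increasing), `airflow` (dimensionless amplitude, 0-1.5),
#'   `spo2` (percent), `pco2` (mmHg); optional `rr` (breaths/min) and `hr`
#'   (beats/min) pass-through columns.
#' @param settings Tibble with columns `t_start`, `mode` (`"CPAP"` or
#'   `"BIPAP"`), `cpap_pressure`, `ipap`, `epap` (cmH2O; `NA` for the
#'   inapplicable mode) and `o2_flow` (integer L/min, 0-5). The first row must
#'   start at `t_start = 0`; rows are half-open intervals `[t_start, next)`.
#' @param events Tibble with columns `kind` (`"APNEA"`/`"HYPOPNEA"`),
#'   `t_start`, `duration` (seconds, >= 10). Overlapping events are merged on
#'   ingest with a warning.
#' @param duration Session length in seconds; defaults to `max(t) + 1`.
#' @param phenotype Optional [patient_phenotype] ground truth (synthetic
#'   sessions only).
#' @param decisions Optional decision-log tibble as produced by
#'   [run_titration()].
#' @param intolerance Optional tibble (`epoch_start`, `flag`) of per-epoch
#'   pressure-intolerance annotations.
#'
#' @return An object of class `titration_session`.
#' @seealso [read_session()], [write_session()], [setting_at()]
#' @export
titration_session <- function(patient_id, samples, settings,
                              events = empty_events(), duration = NULL,
                              phenotype = NULL, decisions = NULL,
                              intolerance = NULL) {
  samples <- as_tibble(samples)
  settings <- as_tibble(settings)
  events <- as_tibble(events)
  settings <- normalize_settings(settings)
  if (is.null(duration)) {
    duration <- max(samples$t) + 1L
  }
  events <- merge_overlapping_events(events)
  x <- structure(
    list(
      patient_id = as.character(patient_id),
      duration = as.integer(duration),
      samples = samples,
      settings = settings,
      events = events,
      phenotype = phenotype,
      decisions = decisions,
      intolerance = intolerance
    ),
    class = "titration_session"
  )
  validate_session(x)
}

#' @export
print.titration_session <- function(x, ...) {
  cat(sprintf(
    "<titration_session> patient %s: %d s, %d samples, %d setting intervals, %d events\n",
    x$patient_id, x$duration, nrow(x$samples), nrow(x$settings), nrow(x$events)
  ))
  invisible(x)
}

empty_events <- function() {
  tibble(kind = character(), t_start = double(), duration = double())
}

normalize_settings <- function(settings) {
  for (col in c("cpap_pressure", "ipap", "epap", "o2_flow")) {
    if (!col %in% names(settings)) settings[[col]] <- NA_real_
  }
  settings[c("t_start", "mode", "cpap_pressure", "ipap", "epap", "o2_flow")]
}

merge_overlapping_events <- function(events) {
  if (nrow(events) < 2) return(events)
  events <- dplyr::arrange(events, .data$t_start)
  ends <- events$t_start + events$duration
  merged <- events[1, ]
  for (i in seq_len(nrow(events))[-1]) {
    last <- nrow(merged)
    if (events$t_start[i] < merged$t_start[last] + merged$duration[last]) {
      warn(sprintf(
        "events at t=%g and t=%g overlap; merged",
        merged$t_start[last], events$t_start[i]
      ))
      new_end <- max(merged$t_start[last] + merged$duration[last], ends[i])
      merged$duration[last] <- new_end - merged$t_start[last]
      # an overlap involving an apnea is scored as apnea
      if (events$kind[i] == "APNEA") merged$kind[last] <- "APNEA"
    } else {
      merged <- dplyr::bind_rows(merged, events[i, ])
    }
  }
  merged
}

fail_row <- function(rule, row, detail) {
  abort(sprintf("validation error [%s] at row %d: %s", rule, row, detail),
        class = "paptitrate_validation_error")
}

#' Validate a titration session
#'
#' Checks every container invariant: monotone integer time, vitals ranges,
#' device-setting bounds per mode, schedule coverage from t = 0, event
#' non-overlap and containment in `[0, duration)`. Errors name the offending
#' row and rule.
#'
#' @param session A [titration_session].
#' @return The session, invisibly, if valid; otherwise an error of class
#'   `paptitrate_validation_error`.
#' @export
validate_session <- function(session) {
  s <- session$samples
  need <- c("t", "airflow", "spo2", "pco2")
  miss <- setdiff(need, names(s))
  if (length(miss)) abort(paste0("samples missing column(s): ", paste(miss, collapse = ", ")))
  if (nrow(s) == 0) abort("session has no samples")
  if (any(s$t < 0)) fail_row("t >= 0", which(s$t < 0)[1], "negative time")
  bad <- which(diff(s$t) <= 0)
  if (length(bad)) fail_row("t strictly increasing", bad[1] + 1L, sprintf("t=%g", s$t[bad[1] + 1L]))
  bad <- which(s$spo2 < 0 | s$spo2 > 100)
  if (length(bad)) fail_row("spo2 in [0,100]", bad[1], sprintf("spo2=%g", s$spo2[bad[1]]))
  bad <- which(s$pco2 <= 0 | s$pco2 >= 150)
  if (length(bad)) fail_row("pco2 in (0,150)", bad[1], sprintf("pco2=%g", s$pco2[bad[1]]))
  bad <- which(s$airflow < 0 | s$airflow > 1.5)
  if (length(bad)) fail_row("airflow in [0,1.5]", bad[1], sprintf("airflow=%g", s$airflow[bad[1]]))

  st <- session$settings
  if (nrow(st) == 0) abort("session has no device settings")
  if (st$t_start[1] != 0) fail_row("first setting at t_start=0", 1L, sprintf("t_start=%g", st$t_start[1]))
  bad <- which(diff(st$t_start) <= 0)
  if (length(bad)) fail_row("settings strictly increasing", bad[1] + 1L, "non-increasing t_start")
  for (i in seq_len(nrow(st))) {
    row <- st[i, ]
    if (!row$mode %in% c("CPAP", "BIPAP")) fail_row("mode in {CPAP,BIPAP}", i, row$mode)
    if (row$mode == "CPAP") {
      if (is.na(row$cpap_pressure) || row$cpap_pressure < 4 || row$cpap_pressure > 20)
        fail_row("CPAP pressure in [4,20]", i, sprintf("cpap_pressure=%s", row$cpap_pressure))
    } else {
      if (is.na(row$epap) || is.na(row$ipap))
        fail_row("BIPAP requires ipap and epap", i, "missing pressure")
      if (row$epap < 4) fail_row("epap >= 4", i, sprintf("epap=%g", row$epap))
      d <- row$ipap - row$epap
      if (d < 4 || d > 10)
        fail_row("ipap-epap differential in [4,10]", i, sprintf("differential=%g", d))
    }
    if (is.na(row$o2_flow) || !row$o2_flow %in% 0:5)
      fail_row("o2_flow integer in 0..5", i, sprintf("o2_flow=%s", row$o2_flow))
  }

  ev <- session$events
  if (nrow(ev)) {
    bad <- which(!ev$kind %in% c("APNEA", "HYPOPNEA"))
    if (length(bad)) fail_row("event kind", bad[1], ev$kind[bad[1]])
    bad <- which(ev$duration < 10)
    if (length(bad)) fail_row("event duration >= 10 s", bad[1], sprintf("duration=%g", ev$duration[bad[1]]))
    bad <- which(ev$t_start < 0 | ev$t_start + ev$duration > session$duration)
    if (length(bad)) fail_row("event within [0,duration)", bad[1], sprintf("t_start=%g", ev$t_start[bad[1]]))
    if (nrow(ev) > 1) {
      o <- order(ev$t_start)
      ends <- ev$t_start[o] + ev$duration[o]
      bad <- which(ev$t_start[o][-1] < ends[-length(ends)])
      if (length(bad)) fail_row("events non-overlapping", o[bad[1] + 1L], "overlap")
    }
  }
  invisible(session)
}

#' Device setting in force at a time point
#'
#' Settings are piecewise constant over half-open intervals
#' `[t_start, next_t_start)`.
#'
#' @param session A [titration_session].
#' @param t Time in seconds, `0 <= t < duration`.
#' @return One-row tibble: the setting whose interval contains `t`.
#' @export
setting_at <- function(session, t) {
  if (t < 0 || t >= session$duration) {
    abort(sprintf("t=%g outside session [0,%d)", t, session$duration))
  }
  i <- findInterval(t, session$settings$t_start)
  session$settings[i, ]
}

#' Read a titration session bundle
#'
#' A bundle is a directory holding `vitals.csv` (t,airflow,spo2,pco2,rr,hr),
#' `settings.csv` (t_start,mode,cpap_pressure,ipap,epap,o2_flow),
#' `events.csv` (kind,t_start,duration) and `meta.json` (patient_id,
#' duration, optional phenotype_truth). UTF-8, '.' decimal separator.
#'
#' @param path Directory containing the bundle.
#' @return A validated [titration_session].
#' @export
read_session <- function(path) {
  for (f in c("vitals.csv", "settings.csv", "events.csv", "meta.json")) {
    if (!file.exists(file.path(path, f))) {
      abort(sprintf("session bundle %s is missing %s", path, f), class = "paptitrate_io_error")
    }
  }
  vit <- readr::read_csv(file.path(path, "vitals.csv"), show_col_types = FALSE,
                         col_types = readr::cols(t = "i", .default = "d"))
  st <- readr::read_csv(file.path(path, "settings.csv"), show_col_types = FALSE,
                        col_types = readr::cols(mode = "c", .default = "d"))
  ev <- readr::read_csv(file.path(path, "events.csv"), show_col_types = FALSE,
                        col_types = readr::cols(kind = "c", .default = "d"))
  meta <- jsonlite::read_json(file.path(path, "meta.json"), simplifyVector = TRUE)
  phen <- NULL
  if (!is.null(meta$phenotype_truth)) {
    phen <- as_phenotype(meta$phenotype_truth)
  }
  dec <- NULL
  if (file.exists(file.path(path, "decisions.csv"))) {
    dec <- readr::read_csv(file.path(path, "decisions.csv"), show_col_types = FALSE,
                           col_types = readr::cols(.default = "c")) |>
      dplyr::mutate(dplyr::across(dplyr::any_of(c("epoch_start", "magnitude")), as.numeric))
  }
  titration_session(
    patient_id = meta$patient_id, samples = vit, settings = st, events = ev,
    duration = meta$duration, phenotype = phen, decisions = dec
  )
}

#' Write a titration session bundle
#'
#' Inverse of [read_session()]: writes `vitals.csv`, `settings.csv`,
#' `events.csv` and `meta.json` (plus `decisions.csv` when a decision log is
#' attached) into `path`. Numeric round trip is exact for integers and within
#' 1e-9 for reals; rewriting an unchanged session is byte-identical.
#'
#' @param session A valid [titration_session].
#' @param path Target directory (created if needed).
#' @return `path`, invisibly.
#' @export
write_session <- function(session, path) {
  validate_session(session)
  dir.create(path, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(path)) abort(sprintf("cannot create %s", path), class = "paptitrate_io_error")
  # fixed decimal precision keeps rewrites byte-identical and reals within 1e-9
  round9 <- function(df) {
    dplyr::mutate(df, dplyr::across(dplyr::where(is.double), ~ round(.x, 9)))
  }
  readr::write_csv(round9(session$samples), file.path(path, "vitals.csv"))
  readr::write_csv(round9(session$settings), file.path(path, "settings.csv"))
  readr::write_csv(round9(session$events), file.path(path, "events.csv"))
  meta <- list(patient_id = session$patient_id, duration = session$duration)
  if (!is.null(session$phenotype)) meta$phenotype_truth <- unclass(session$phenotype)
  jsonlite::write_json(meta, file.path(path, "meta.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  if (!is.null(session$decisions)) {
    readr::write_csv(session$decisions, file.path(path, "decisions.csv"))
  }
  invisible(path)
}

#' @rdname titration_session
#' @param x Object to coerce / test.
#' @export
is_titration_session <- function(x) inherits(x, "titration_session")

#' Vitals of a session as a tibble
#'
#' Accessor used throughout analysis pipelines.
#' @param session A [titration_session].
#' @return The `samples` tibble.
#' @export
session_samples <- function(session) session$samples

#' Plot a titration session
#'
#' Stacked panels of SpO2, pCO2 and airflow over the night, with the applied
#' pressure (CPAP pressure, or IPAP/EPAP) and O2 flow as step traces; scored
#' events are shaded.
#'
#' @param object A [titration_session].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot titration_session
#' @export
autoplot.titration_session <- function(object, ...) {
  vit <- object$samples |>
    dplyr::select(dplyr::any_of(c("t", "airflow", "spo2", "pco2"))) |>
    tidyr::pivot_longer(-"t", names_to = "channel", values_to = "value")
  st <- object$settings |>
    dplyr::mutate(pressure = ifelse(.data$mode == "CPAP", .data$cpap_pressure, .data$ipap)) |>
    dplyr::select("t_start", "pressure", "o2_flow") |>
    tidyr::pivot_longer(-"t_start", names_to = "channel", values_to = "value") |>
    dplyr::rename(t = "t_start")
  dat <- dplyr::bind_rows(vit, st) |>
    dplyr::mutate(channel = factor(.data$channel,
                                   levels = c("spo2", "pco2", "airflow", "pressure", "o2_flow")))
  p <- ggplot2::ggplot(dat, ggplot2::aes(x = .data$t, y = .data$value))
  if (nrow(object$events)) {
    ev <- object$events
    p <- p + ggplot2::geom_rect(
      data = ev,
      ggplot2::aes(xmin = .data$t_start, xmax = .data$t_start + .data$duration,
                   ymin = -Inf, ymax = Inf),
      inherit.aes = FALSE, fill = "pink", alpha = 0.4
    )
  }
  p +
    ggplot2::geom_step(data = dplyr::filter(dat, .data$channel %in% c("pressure", "o2_flow"))) +
    ggplot2::geom_line(data = dplyr::filter(dat, !.data$channel %in% c("pressure", "o2_flow"))) +
    ggplot2::facet_grid(rows = ggplot2::vars(.data$channel), scales = "free_y") +
    ggplot2::labs(x = "time from session start [s]", y = NULL,
                  title = sprintf("Titration session %s", object$patient_id))
}
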