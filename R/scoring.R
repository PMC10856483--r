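#' Apnea/hypopnea scoring configuration
#'
#' Thresholds follow the usual sleep-laboratory convention: an apnea is a
#' >= 90% drop of airflow amplitude from the rolling baseline lasting at least
#' 10 s; a hypopnea is a >= 30% (but < 90%) drop of at least 10 s accompanied
#' by an oxygen desaturation of >= 3% within 30 s of the event end. The
#' rolling baseline is the median airflow over the preceding
#' `baseline_window_s` seconds, excluding samples already inside a candidate
#' event.
#'
#' @param apnea_drop_frac Fractional airflow drop defining apnea (default 0.90).
#' @param hypopnea_drop_frac Fractional drop defining hypopnea (default 0.30).
#' @param min_event_s Minimum event duration in seconds (>= 10).
#' @param baseline_window_s Rolling-baseline window in seconds.
#' @param hypopnea_desat_pct Desaturation (percentage points of SpO2) required
#'   to score a hypopnea.
#' @return A `scoring_config` list.
#' @export
scoring_config <- function(apnea_drop_frac = 0.90, hypopnea_drop_frac = 0.30,
                           min_event_s = 10, baseline_window_s = 120,
                           hypopnea_desat_pct = 3) {
  if (!(hypopnea_drop_frac > 0 && hypopnea_drop_frac < apnea_drop_frac &&
        apnea_drop_frac <= 1)) {
    abort("need 0 < hypopnea_drop_frac < apnea_drop_frac <= 1")
  }
  if (min_event_s < 10) abort("min_event_s must be >= 10")
  structure(
    list(apnea_drop_frac = apnea_drop_frac,
         hypopnea_drop_frac = hypopnea_drop_frac,
         min_event_s = min_event_s,
         baseline_window_s = baseline_window_s,
         hypopnea_desat_pct = hypopnea_desat_pct),
    class = "scoring_config"
  )
}

#' Score respiratory events from the airflow channel
#'
#' Walks the vitals series once, maintaining a rolling median baseline of
#' airflow over the preceding `baseline_window_s` seconds (in-event samples
#' excluded; the baseline is frozen for the duration of a candidate event).
#' Maximal runs below the hypopnea threshold become events: APNEA when the
#' airflow stays below the apnea threshold for at least `min_event_s`
#' contiguous seconds within the run, otherwise HYPOPNEA when the run is long
#' enough and SpO2 falls by at least `hypopnea_desat_pct` between the 30 s
#' before the run and 30 s after its end.
#'
#' @param samples Vitals tibble with columns `t`, `airflow`, `spo2`.
#' @param config A [scoring_config()].
#' @return Tibble of events (`kind`, `t_start`, `duration`), disjoint and in
#'   time order.
#' @export
detect_events <- function(samples, config = scoring_config()) {
  samples <- as_tibble(samples)
  n <- nrow(samples)
  if (n == 0 || (samples$t[n] - samples$t[1]) < config$baseline_window_s) {
    abort(sprintf("need at least %d s of samples to establish a baseline",
                  config$baseline_window_s))
  }
  t <- samples$t
  flow <- samples$airflow
  spo2 <- samples$spo2
  win <- config$baseline_window_s

  # seed baseline from the opening window
  seed_idx <- which(t < t[1] + win)
  baseline <- median(flow[seed_idx])

  buf_t <- numeric(0)
  buf_f <- numeric(0)
  hypo_thr <- function(b) (1 - config$hypopnea_drop_frac) * b
  apnea_thr <- function(b) (1 - config$apnea_drop_frac) * b

  events <- list()
  in_run <- FALSE
  run_start_i <- NA_integer_
  run_baseline <- NA_real_

  close_run <- function(start_i, end_i, b) {
    # end_i = last in-run sample index
    dur <- if (end_i < n) t[end_i + 1L] - t[start_i] else (t[end_i] - t[start_i] + 1)
    if (dur < config$min_event_s) return(NULL)
    # longest contiguous stretch at apnea depth
    idx <- start_i:end_i
    deep <- flow[idx] <= apnea_thr(b)
    best <- 0
    if (any(deep)) {
      r <- rle(deep)
      ends <- cumsum(r$lengths)
      starts <- ends - r$lengths + 1L
      for (k in which(r$values)) {
        a <- idx[starts[k]]; z <- idx[ends[k]]
        span <- if (z < n) t[z + 1L] - t[a] else t[z] - t[a] + 1
        best <- max(best, span)
      }
    }
    if (best >= config$min_event_s) {
      return(tibble(kind = "APNEA", t_start = t[start_i], duration = dur))
    }
    # hypopnea: require qualifying desaturation near the event
    pre <- spo2[t >= t[start_i] - 30 & t < t[start_i]]
    post <- spo2[t >= t[start_i] & t <= t[end_i] + 30]
    if (length(pre) && length(post) &&
        max(pre) - min(post) >= config$hypopnea_desat_pct) {
      return(tibble(kind = "HYPOPNEA", t_start = t[start_i], duration = dur))
    }
    NULL
  }

  for (i in seq_len(n)) {
    if (!in_run) {
      if (length(buf_f) >= 10) baseline <- median(buf_f)
      if (flow[i] <= hypo_thr(baseline)) {
        in_run <- TRUE
        run_start_i <- i
        run_baseline <- baseline
      } else {
        buf_t <- c(buf_t, t[i]); buf_f <- c(buf_f, flow[i])
        keep <- buf_t > t[i] - win
        buf_t <- buf_t[keep]; buf_f <- buf_f[keep]
      }
    } else {
      if (flow[i] > hypo_thr(run_baseline)) {
        ev <- close_run(run_start_i, i - 1L, run_baseline)
        if (!is.null(ev)) events[[length(events) + 1L]] <- ev
        in_run <- FALSE
        buf_t <- c(buf_t, t[i]); buf_f <- c(buf_f, flow[i])
        keep <- buf_t > t[i] - win
        buf_t <- buf_t[keep]; buf_f <- buf_f[keep]
      }
    }
  }
  if (in_run) {
    ev <- close_run(run_start_i, n, run_baseline)
    if (!is.null(ev)) events[[length(events) + 1L]] <- ev
  }
  if (!length(events)) return(empty_events())
  dplyr::bind_rows(events)
}

#' Apnea-hypopnea index
#'
#' Scored events per hour: `count / (duration / 3600)`.
#'
#' @param events Event tibble (`kind`, `t_start`, `duration`).
#' @param duration Recording duration in seconds (> 0).
#' @param include_hypopneas Count hypopneas alongside apneas (default TRUE).
#' @return Events per hour (numeric scalar >= 0).
#' @export
compute_ahi <- function(events, duration, include_hypopneas = TRUE) {
  if (duration <= 0) abort("duration must be > 0")
  n <- if (include_hypopneas) nrow(events) else sum(events$kind == "APNEA")
  n / (duration / 3600)
}
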