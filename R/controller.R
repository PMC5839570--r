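#' Controller configuration
#'
#' Parameters of the adaptive pH-stat: the controller doses `unit_volume` of
#' titrant whenever a valid reading falls strictly below `setpoint` and at
#' least `min_interval` seconds have passed since the previous dose. When
#' the process quiets down, the dose is halved and the interval doubled
#' (down to `unit_volume_floor`, up to `interval_cap`); a dose triggered by
#' a deep excursion below the setpoint reverses one adaptation step. The
#' defaults mirror a reactor that needs 2 ml of 0.5 M base every 5 s at the
#' start and ~0.5 ml every few minutes later, holding pH at 10.55.
#'
#' @param setpoint target pH in `(0, 14)`.
#' @param initial_unit_volume starting dose, ml.
#' @param min_interval starting minimum spacing between doses, s.
#' @param unit_volume_floor smallest dose adaptation may reach, ml.
#' @param interval_cap largest interval adaptation may reach, s.
#' @param stale_timeout s without a valid reading before the controller
#'   raises an alarm (a safety addition: an unreadable display must never
#'   silently stall the loop).
#' @param log_period s between log records.
#' @param adaptation enable the adaptive rule.
#' @param quiet_windows consecutive dose-free windows (each `min_interval`
#'   long) before one adaptation step.
#' @param reversal_drop pH below `setpoint - reversal_drop` at dose time
#'   triggers one reverse adaptation step.
#' @return An object of class `control_config`.
#' @export
control_config <- function(setpoint = 10.55, initial_unit_volume = 2,
                           min_interval = 5, unit_volume_floor = 0.5,
                           interval_cap = 60, stale_timeout = 10,
                           log_period = 1, adaptation = TRUE,
                           quiet_windows = 4, reversal_drop = 0.05) {
  stopifnot(setpoint > 0, setpoint < 14,
            initial_unit_volume > 0, unit_volume_floor > 0,
            unit_volume_floor <= initial_unit_volume,
            min_interval > 0, interval_cap >= min_interval,
            stale_timeout > 0, log_period > 0, quiet_windows >= 1,
            reversal_drop > 0)
  structure(list(setpoint = setpoint,
                 initial_unit_volume = initial_unit_volume,
                 min_interval = min_interval,
                 unit_volume_floor = unit_volume_floor,
                 interval_cap = interval_cap,
                 stale_timeout = stale_timeout,
                 log_period = log_period,
                 adaptation = isTRUE(adaptation),
                 quiet_windows = quiet_windows,
                 reversal_drop = reversal_drop),
            class = "control_config")
}

#' Controller state
#'
#' @param config a [control_config()].
#' @param now clock at initialization, s.
#' @return An object of class `control_state`.
#' @export
control_state <- function(config, now = 0) {
  structure(list(last_dose_time = -Inf,
                 unit_volume = config$initial_unit_volume,
                 min_interval = config$min_interval,
                 cumulative_volume = 0,
                 last_valid_reading = NULL,
                 last_valid_time = now,
                 quiet_streak = 0L,
                 window_start = now,
                 window_dosed = FALSE),
            class = "control_state")
}

#' Dosing decision
#'
#' Pure decision function of the pH-stat: given the newest reading, the
#' controller state and the clock, returns one of
#' \itemize{
#'   \item `DOSE` — the reading is valid, strictly below the setpoint, and
#'     the minimum interval since the last dose has elapsed;
#'   \item `NONE` — otherwise (invalid readings never dose; a reading equal
#'     to the setpoint does not dose);
#'   \item `ALARM` — no valid reading for at least `stale_timeout` seconds.
#' }
#'
#' @param reading a [ph_reading()].
#' @param state a [control_state()].
#' @param config a [control_config()].
#' @param now monotonic clock, s.
#' @return `list(action = "DOSE"|"NONE"|"ALARM", volume = ml or NA)`.
#' @export
decide <- function(reading, state, config, now) {
  valid <- inherits(reading, "ph_reading") && reading$valid
  last_valid <- if (valid) now else state$last_valid_time
  if (now - last_valid >= config$stale_timeout)
    return(list(action = "ALARM", volume = NA_real_))
  if (valid && reading$value < config$setpoint &&
      (now - state$last_dose_time) >= state$min_interval)
    return(list(action = "DOSE", volume = state$unit_volume))
  list(action = "NONE", volume = NA_real_)
}

#' Adaptation step
#'
#' Called once per decision tick. Time is divided into consecutive windows
#' of the current `min_interval`; after `quiet_windows` windows in a row
#' with no dose, the controller concludes the process has slowed and halves
#' the unit volume (not below the floor) while doubling the interval (not
#' above the cap). Any dose resets the streak, and
#' [register_dose()] reverses one step when the dose was triggered by a deep
#' excursion — so the controller speeds back up if the process accelerates
#' again.
#'
#' @inheritParams decide
#' @return The updated [control_state()].
#' @export
adapt <- function(state, config, now) {
  if (!config$adaptation) return(state)
  if (now - state$window_start >= state$min_interval) {
    state$quiet_streak <- if (state$window_dosed) 0L else state$quiet_streak + 1L
    state$window_dosed <- FALSE
    state$window_start <- now
    if (state$quiet_streak >= config$quiet_windows) {
      state$unit_volume <- max(config$unit_volume_floor, state$unit_volume / 2)
      state$min_interval <- min(config$interval_cap, 2 * state$min_interval)
      state$quiet_streak <- 0L
    }
  }
  state
}

#' Book a reading / an executed dose into the controller state
#'
#' `register_reading` refreshes the staleness clock; `register_dose` records
#' the dose time and volume, resets the quiet streak and applies the
#' deep-excursion reversal of [adapt()].
#'
#' @inheritParams decide
#' @param volume ml actually booked by the pump.
#' @return The updated [control_state()].
#' @export
register_reading <- function(state, reading, now) {
  if (inherits(reading, "ph_reading") && reading$valid) {
    state$last_valid_reading <- reading
    state$last_valid_time <- now
  }
  state
}

#' @rdname register_reading
#' @export
register_dose <- function(state, volume, reading, config, now) {
  state$last_dose_time <- now
  state$cumulative_volume <- state$cumulative_volume + volume
  state$quiet_streak <- 0L
  state$window_dosed <- TRUE
  if (config$adaptation && inherits(reading, "ph_reading") && reading$valid &&
      reading$value < config$setpoint - config$reversal_drop) {
    state$unit_volume <- min(config$initial_unit_volume, 2 * state$unit_volume)
    state$min_interval <- max(config$min_interval, state$min_interval / 2)
  }
  state
}

#' Manual dosing mode
#'
#' Emulates press-and-hold dosing: the pump runs for as long as a press
#' lasts, delivering `coefficient * elapsed_ms` of reagent. Presses are
#' given as start/stop event pairs; a stop without a preceding start is a
#' no-op, an unclosed start is ignored.
#'
#' @param spec a [peristaltic_pump_spec()].
#' @param events data frame with columns `time_s` and `action`
#'   (`"start"`/`"stop"`), in chronological order.
#' @return Data frame of doses (`start_s`, `stop_s`, `volume_ml`) with
#'   attribute `total_ml`.
#' @export
manual_mode <- function(spec, events) {
  stopifnot(inherits(spec, "peristaltic_pump_spec"))
  ev <- as.data.frame(events)
  stopifnot(all(c("time_s", "action") %in% names(ev)))
  open <- NA_real_
  doses <- list()
  for (i in seq_len(nrow(ev))) {
    if (ev$action[i] == "start" && is.na(open)) open <- ev$time_s[i]
    else if (ev$action[i] == "stop" && !is.na(open)) {
      elapsed_ms <- (ev$time_s[i] - open) * 1000
      doses[[length(doses) + 1L]] <-
        data.frame(start_s = open, stop_s = ev$time_s[i],
                   volume_ml = spec$coefficient * elapsed_ms)
      open <- NA_real_
    }
  }
  out <- if (length(doses)) do.call(rbind, doses)
  else data.frame(start_s = numeric(0), stop_s = numeric(0),
                  volume_ml = numeric(0))
  attr(out, "total_ml") <- sum(out$volume_ml)
  out
}

#' One step of a positional PID regulator
#'
#' Standard discrete PID on the pH error, returning a dose rate clamped to
#' `[0, max_rate]` with integral anti-windup (the integral is frozen while
#' the output is clamped). Shipped as a secondary mode: for processes with a
#' strong fast initial phase and a slow electrode, the threshold-dosing
#' controller above is the robust choice, and PID typically cannot stabilize
#' that first phase.
#'
#' @param error `setpoint - pH`.
#' @param integral accumulated integral term.
#' @param previous_error error at the previous step.
#' @param Kp,Ki,Kd gains.
#' @param dt step, s (`> 0`).
#' @param max_rate upper clamp, ml/s.
#' @return `list(rate, integral, previous_error)` to feed into the next step.
#' @export
pid_step <- function(error, integral, previous_error, Kp, Ki, Kd, dt,
                     max_rate = Inf) {
  stopifnot(dt > 0)
  candidate_integral <- integral + error * dt
  raw <- Kp * error + Ki * candidate_integral +
    Kd * (error - previous_error) / dt
  rate <- min(max(raw, 0), max_rate)
  list(rate = rate,
       integral = if (raw < 0 || raw > max_rate) integral
                  else candidate_integral,
       previous_error = error)
}

#' Run the closed pH-stat loop
#'
#' The full instrument cycle at 1 s ticks: the plant's display is rendered
#' into a frame, decoded optically, the decision logic fires (or not), the
#' pump actuates with its noise model, the vessel chemistry advances, the
#' adaptive rule updates, and a log record is written every `log_period`
#' seconds. An alarm (no valid reading for `stale_timeout`) terminates the
#' loop with the log flagged.
#'
#' The logged `cumulative_volume_ml` is the pump's own dispensed total — the
#' instrument's accounting, which is what a real log contains; actuation
#' noise affects the vessel, not the ledger.
#'
#' @param plant a [plant_state()].
#' @param pump a pump specification.
#' @param cal an [ocr_calibration()] matching the scenario geometry.
#' @param config a [control_config()].
#' @param duration simulated seconds.
#' @param style a [display_style()] for the rendered frames.
#' @param pump_noise logical; disable for deterministic actuation.
#' @param resume_log optional previous log data frame: the clock and the
#'   cumulative volume continue from its last record.
#' @return Data frame (`time_s`, `pH`, `cumulative_volume_ml`) with
#'   attributes `alarm` (logical), `doses` (data frame `time_s`,
#'   `volume_ml`), `state`, `pump`, `plant`.
#' @export
run_loop <- function(plant, pump, cal, config, duration,
                     style = display_style(), pump_noise = TRUE,
                     resume_log = NULL) {
  stopifnot(inherits(plant, "plant_state"), inherits(config, "control_config"),
            duration >= 1)
  t0 <- 0
  state <- control_state(config, now = 0)
  if (!is.null(resume_log) && nrow(resume_log)) {
    t0 <- resume_log$time_s[nrow(resume_log)]
    state$last_valid_time <- t0
    state$window_start <- t0
    pump$dispensed_ml <- resume_log$cumulative_volume_ml[nrow(resume_log)]
  }

  n <- as.integer(duration)
  log_t <- numeric(n); log_ph <- numeric(n); log_v <- numeric(n)
  dose_t <- numeric(0); dose_v <- numeric(0)
  n_log <- 0L
  alarm <- FALSE
  last_ph <- NA_real_

  for (i in seq_len(n)) {
    now <- t0 + i
    frame <- emit_frame(plant, cal$geometry, style)
    reading <- decode_display(frame, cal, timestamp = now)
    action <- decide(reading, state, config, now)
    state <- register_reading(state, reading, now)
    if (reading$valid) last_ph <- reading$value

    delivered <- 0
    if (action$action == "ALARM") {
      alarm <- TRUE
    } else if (action$action == "DOSE") {
      planned <- plan_dose(pump, action$volume)
      pump <- planned$pump
      actuation <- planned$runtime_ms %||% planned$steps
      delivered <- virtual_deliver(pump, actuation, noise = pump_noise)
      state <- register_dose(state, action$volume, reading, config, now)
      dose_t <- c(dose_t, now); dose_v <- c(dose_v, action$volume)
    }

    plant <- plant_step(plant, 1, added_ml = delivered)
    state <- adapt(state, config, now)

    if ((i %% config$log_period) == 0 || alarm) {
      n_log <- n_log + 1L
      log_t[n_log] <- now
      log_ph[n_log] <- last_ph
      log_v[n_log] <- round(pump$dispensed_ml, 3)
    }
    if (alarm) break
  }

  log <- data.frame(time_s = log_t[seq_len(n_log)],
                    pH = round(log_ph[seq_len(n_log)], 3),
                    cumulative_volume_ml = log_v[seq_len(n_log)])
  attr(log, "alarm") <- alarm
  attr(log, "doses") <- data.frame(time_s = dose_t, volume_ml = dose_v)
  attr(log, "state") <- state
  attr(log, "pump") <- pump
  attr(log, "plant") <- plant
  log
}

#' Summarize a run log
#'
#' Totals and band statistics of a pH-stat log: total dosed volume, final
#' pH, and — excluding the initial transient (`skip_fraction` of the run) —
#' the min/max/mean of the logged pH.
#'
#' @param log data frame from [run_loop()] or [read_log()].
#' @param setpoint optional; adds the fraction of post-transient records
#'   within `[setpoint, setpoint + 0.1]`.
#' @param skip_fraction leading fraction of records treated as transient.
#' @return A list of class `run_summary`.
#' @export
run_summary <- function(log, setpoint = NULL, skip_fraction = 0.25) {
  stopifnot(nrow(log) >= 1)
  total <- log$cumulative_volume_ml[nrow(log)]
  final_ph <- log$pH[nrow(log)]
  tail_idx <- log$time_s > (log$time_s[1] +
    skip_fraction * (log$time_s[nrow(log)] - log$time_s[1]))
  tail_ph <- log$pH[tail_idx & !is.na(log$pH)]
  out <- list(n_records = nrow(log),
              total_volume_ml = total,
              final_ph = final_ph,
              band_min = if (length(tail_ph)) min(tail_ph) else NA_real_,
              band_max = if (length(tail_ph)) max(tail_ph) else NA_real_,
              band_mean = if (length(tail_ph)) mean(tail_ph) else NA_real_)
  if (!is.null(setpoint) && length(tail_ph))
    out$in_band_fraction <- mean(tail_ph >= setpoint & tail_ph <= setpoint + 0.1)
  structure(out, class = "run_summary")
}

#' @export
print.run_summary <- function(x, ...) {
  cat(sprintf("records: %d\ntotal volume: %.3f ml\nfinal pH: %.3f\n",
              x$n_records, x$total_volume_ml, x$final_ph))
  cat(sprintf("post-transient pH: min %.3f, max %.3f, mean %.3f\n",
              x$band_min, x$band_max, x$band_mean))
  if (!is.null(x$in_band_fraction))
    cat(sprintf("in-band fraction: %.3f\n", x$in_band_fraction))
  invisible(x)
}
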