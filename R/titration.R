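#' Titration configuration
#'
#' Stability-gated incremental titration: the next increment is only added
#' once the reading has stopped moving — the change of pH across a window of
#' `stability_window` seconds is at most `stability_epsilon`. Increments may
#' follow a schedule (list of `(volume, count)` stages), mirroring the bench
#' practice of switching to finer additions near the expected equivalence
#' point.
#'
#' @param increment_ml single increment volume, ml (ignored when `schedule`
#'   is given).
#' @param schedule optional list of `c(volume, count)` pairs, applied in
#'   order.
#' @param stability_window s between the two compared readings.
#' @param stability_epsilon max allowed pH change over the window; must be
#'   at least the display resolution (0.001). Default 0.005.
#' @param max_volume stop after this much titrant, ml.
#' @param timeout_s max seconds to wait for stability at any one point.
#' @return An object of class `titration_config`.
#' @export
titration_config <- function(increment_ml = 0.2, schedule = NULL,
                             stability_window = 5, stability_epsilon = 0.005,
                             max_volume = Inf, timeout_s = 600) {
  stopifnot(stability_window > 0, stability_epsilon >= 0.001,
            max_volume > 0, timeout_s > stability_window)
  if (is.null(schedule)) {
    stopifnot(increment_ml >= 0)
  } else {
    stopifnot(all(vapply(schedule, function(s)
      length(s) == 2 && s[1] > 0 && s[2] >= 1, logical(1))))
  }
  structure(list(increment_ml = increment_ml, schedule = schedule,
                 stability_window = stability_window,
                 stability_epsilon = stability_epsilon,
                 max_volume = max_volume, timeout_s = timeout_s),
            class = "titration_config")
}

.expand_schedule <- function(config) {
  if (!is.null(config$schedule))
    unlist(lapply(config$schedule, function(s) rep(s[1], s[2])))
  else if (config$increment_ml > 0 && is.finite(config$max_volume))
    rep(config$increment_ml, ceiling(config$max_volume / config$increment_ml))
  else if (config$increment_ml > 0)
    stop("need a finite 'max_volume' or an explicit schedule", call. = FALSE)
  else numeric(0)
}

# Step the plant until the reading is stable per the config; returns the
# plant and the stable pH, or signals a timeout condition carrying the
# partial curve built so far.
.wait_stable <- function(plant, config, reader, partial) {
  history <- reader(plant)
  w <- config$stability_window
  for (s in seq_len(config$timeout_s)) {
    plant <- plant_step(plant, 1)
    history <- c(history, reader(plant))
    if (length(history) > w &&
        abs(history[length(history)] - history[length(history) - w]) <=
          config$stability_epsilon)
      return(list(plant = plant, ph = history[length(history)]))
  }
  cond <- structure(class = c("phstat_titration_timeout", "error", "condition"),
                    list(message = "pH never stabilized within timeout",
                         call = NULL, partial_curve = partial))
  stop(cond)
}

#' Run a stability-gated titration
#'
#' Adds titrant in predefined increments, waiting before each addition until
#' the pH reading has been stable for the configured window, and records one
#' `(cumulative volume, pH)` point per addition (plus the initial point).
#' Stops at the end of the schedule or at `max_volume`. If the pH never
#' stabilizes, a timeout error of class `phstat_titration_timeout` is
#' signalled carrying the partial curve in `$partial_curve`.
#'
#' @param plant a [plant_state()] holding the analyte.
#' @param pump pump specification for the titrant.
#' @param config a [titration_config()].
#' @param reader function of the plant returning the observed pH; the
#'   default reads the (lagged, noisy) electrode. Use
#'   `function(p) plant_true_ph(p)` for an ideal probe.
#' @param molarity titrant molarity (defaults to the plant's).
#' @param pump_noise logical; `TRUE` adds actuation noise to deliveries.
#' @return A data frame of class `titration_curve` with columns
#'   `cumulative_volume_ml`, `pH`; attribute `pump` holds the final pump
#'   state.
#' @export
titrate <- function(plant, pump, config = titration_config(),
                    reader = function(p) p$measured_ph,
                    molarity = plant$titrant_molarity, pump_noise = FALSE) {
  stopifnot(inherits(plant, "plant_state"),
            inherits(config, "titration_config"))
  increments <- .expand_schedule(config)
  vols <- numeric(0); phs <- numeric(0)
  curve <- function() {
    structure(data.frame(cumulative_volume_ml = vols, pH = phs),
              class = c("titration_curve", "data.frame"))
  }

  st <- .wait_stable(plant, config, reader, curve())
  plant <- st$plant
  vols <- 0; phs <- st$ph
  cum <- 0
  for (inc in increments) {
    if (cum + inc > config$max_volume + 1e-9) break
    planned <- plan_dose(pump, inc)
    pump <- planned$pump
    actuation <- planned$runtime_ms %||% planned$steps
    delivered <- virtual_deliver(pump, actuation, noise = pump_noise)
    plant <- plant_step(plant, 1, added_ml = delivered, molarity = molarity)
    cum <- cum + inc
    st <- .wait_stable(plant, config, reader, curve())
    plant <- st$plant
    # x-axis is the pump's own dispensed total (step-quantized for a
    # syringe): with actuation noise off this is exactly what entered the
    # vessel, so the recorded curve is self-consistent near equivalence.
    vols <- c(vols, pump$dispensed_ml); phs <- c(phs, st$ph)
  }
  out <- curve()
  attr(out, "pump") <- pump
  attr(out, "plant") <- plant
  out
}

#' Equivalence point from a titration curve
#'
#' First-derivative method: `dpH/dV` by central finite differences on the
#' (possibly uneven) volume grid; the equivalence volume is where the
#' derivative peaks, refined by fitting a parabola through the peak and its
#' two neighbours and taking its vertex. A curve whose maximum slope is
#' below `min_slope` is reported as having no equivalence point (e.g. water
#' titrated with water).
#'
#' @param curve a `titration_curve` (or data frame with columns
#'   `cumulative_volume_ml`, `pH`) with at least 5 points and strictly
#'   increasing volumes.
#' @param min_slope pH/ml below which the curve counts as flat.
#' @return `list(volume_ml, found, method)` of class `equivalence_point`;
#'   `volume_ml` is `NA` when no equivalence point is found.
#' @export
equivalence_point <- function(curve, min_slope = 0.5) {
  v <- curve$cumulative_volume_ml
  ph <- curve$pH
  if (length(v) < 5)
    stop("need at least 5 titration points", call. = FALSE)
  if (any(diff(v) <= 0))
    stop("volumes must be strictly increasing", call. = FALSE)
  n <- length(v)
  i <- 2:(n - 1)
  d <- (ph[i + 1] - ph[i - 1]) / (v[i + 1] - v[i - 1])
  method <- "first_derivative_parabolic"
  if (max(d) < min_slope)
    return(structure(list(volume_ml = NA_real_, found = FALSE,
                          method = method), class = "equivalence_point"))
  p <- which.max(d)
  est <- v[i[p]]
  if (p > 1 && p < length(d)) {
    x <- v[i[(p - 1):(p + 1)]]
    y <- d[(p - 1):(p + 1)]
    co <- tryCatch(solve(cbind(1, x, x^2), y), error = function(e) NULL)
    if (!is.null(co) && co[3] < 0) {
      vertex <- unname(-co[2] / (2 * co[3]))
      if (vertex >= x[1] && vertex <= x[3]) est <- vertex
    }
  }
  structure(list(volume_ml = est, found = TRUE, method = method),
            class = "equivalence_point")
}

#' @export
print.equivalence_point <- function(x, ...) {
  if (x$found)
    cat(sprintf("<equivalence_point> %.4f ml (%s)\n", x$volume_ml, x$method))
  else cat("<equivalence_point> none found (flat curve)\n")
  invisible(x)
}

#' Analyte plant for a classic strong-acid titration
#'
#' Convenience constructor for the bench demonstration: `analyte_ml` of
#' `analyte_molar` strong acid in the vessel, titrated with
#' `titrant_molar` strong base. Electrode lag and noise are off by default
#' so the recorded curve equals the charge-balance chemistry.
#'
#' @param analyte_ml,analyte_molar analyte volume (ml) and molarity.
#' @param titrant_molar titrant molarity.
#' @param electrode_tau,noise_sd electrode model, see [plant_state()].
#' @return A [plant_state()].
#' @export
titration_plant <- function(analyte_ml = 10, analyte_molar = 0.1,
                            titrant_molar = 0.1, electrode_tau = 0,
                            noise_sd = 0) {
  plant_state(volume_l = analyte_ml / 1000,
              acid_mol = analyte_ml / 1000 * analyte_molar, base_mol = 0,
              kinetics = NULL, electrode_tau = electrode_tau,
              noise_sd = noise_sd, titrant_molarity = titrant_molar,
              transition_prob = 0)
}
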