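#' Syringe pump specification
#'
#' Leadscrew-driven syringe pump: a stepper motor (NEMA 17 class, 200
#' steps/revolution) turns a leadscrew of given pitch, pushing the plunger a
#' fixed distance per step, so dispensed volume is controlled by step count.
#' With the defaults (200 steps, 0.8 mm pitch) the linear resolution is
#' 0.004 mm/step; the volumetric resolution then follows from the syringe
#' bore via [ml_per_step()].
#'
#' The object also carries the pump's dispensing state: `plunger_position`
#' (steps from fully drawn), `dispensed_ml`, and a sub-step residual
#' accumulator so long dosing sequences do not drift from rounding.
#'
#' @param syringe_inner_diameter syringe bore in mm (no universal default:
#'   the bore of a nominal "20 ml" or "50 ml" syringe varies by brand;
#'   20.0 mm and 28.8 mm reproduce the usual 0.0013 / 0.0026 ml per step
#'   figures).
#' @param syringe_capacity syringe volume in ml.
#' @param steps_per_rev motor steps per revolution.
#' @param lead leadscrew pitch, mm per revolution.
#' @param plunger_position initial plunger position in steps from fully
#'   drawn (0 = full syringe).
#' @return An object of class `syringe_pump_spec`.
#' @export
syringe_pump_spec <- function(syringe_inner_diameter, syringe_capacity,
                              steps_per_rev = 200, lead = 0.8,
                              plunger_position = 0) {
  stopifnot(steps_per_rev > 0, lead > 0)
  if (!is.numeric(syringe_inner_diameter) || syringe_inner_diameter <= 0)
    stop("'syringe_inner_diameter' must be positive", call. = FALSE)
  stopifnot(syringe_capacity > 0, plunger_position >= 0)
  structure(list(steps_per_rev = as.numeric(steps_per_rev),
                 lead = as.numeric(lead),
                 syringe_inner_diameter = as.numeric(syringe_inner_diameter),
                 syringe_capacity = as.numeric(syringe_capacity),
                 plunger_position = as.numeric(plunger_position),
                 residual_ml = 0,
                 dispensed_ml = 0),
            class = "syringe_pump_spec")
}

#' Peristaltic pump specification
#'
#' Time-calibrated pump: delivered volume is proportional to motor run time
#' (1 ms resolution), via a calibration coefficient in ml/ms. The cheap
#' permanent-magnet motors these pumps use start unreliably, so short doses
#' are imprecise; `dead_time` models the unproductive start-up and
#' `min_reliable_dose` the volume below which dosing accuracy degrades.
#' Defaults depend on the supply voltage: a 9 V supply starts the motor less
#' cleanly than 12 V.
#'
#' @param coefficient ml delivered per ms of run time.
#' @param supply_voltage_tag `"12V"` or `"9V"`; selects defaults for
#'   `dead_time` (0 / 40 ms) and `min_reliable_dose` (0.5 / 1.5 ml).
#' @param dead_time unproductive start-up, ms.
#' @param min_reliable_dose volume below which a below-reliable-dose flag is
#'   raised (never blocks dosing).
#' @return An object of class `peristaltic_pump_spec`.
#' @export
peristaltic_pump_spec <- function(coefficient, supply_voltage_tag = "12V",
                                  dead_time = NULL, min_reliable_dose = NULL) {
  stopifnot(coefficient > 0)
  supply_voltage_tag <- match.arg(supply_voltage_tag, c("12V", "9V"))
  if (is.null(dead_time))
    dead_time <- if (supply_voltage_tag == "9V") 40 else 0
  if (is.null(min_reliable_dose))
    min_reliable_dose <- if (supply_voltage_tag == "9V") 1.5 else 0.5
  stopifnot(dead_time >= 0, min_reliable_dose >= 0)
  structure(list(coefficient = as.numeric(coefficient),
                 dead_time = as.numeric(dead_time),
                 min_reliable_dose = as.numeric(min_reliable_dose),
                 supply_voltage_tag = supply_voltage_tag,
                 dispensed_ml = 0),
            class = "peristaltic_pump_spec")
}

#' Syringe pump resolution
#'
#' `mm_per_step` is the plunger travel per motor step (`lead /
#' steps_per_rev`); `ml_per_step` converts it to volume through the syringe
#' cross-section, `pi * (d/2)^2 * mm_per_step / 1000` (mm^3 to ml).
#'
#' @param spec a [syringe_pump_spec()].
#' @return Scalar resolution (mm/step or ml/step).
#' @export
mm_per_step <- function(spec) {
  stopifnot(inherits(spec, "syringe_pump_spec"))
  spec$lead / spec$steps_per_rev
}

#' @rdname mm_per_step
#' @export
ml_per_step <- function(spec) {
  pi * (spec$syringe_inner_diameter / 2)^2 * mm_per_step(spec) / 1000
}

syringe_remaining_ml <- function(spec)
  spec$syringe_capacity - spec$plunger_position * ml_per_step(spec)

#' Convert a requested volume to pump actuation
#'
#' `volume_to_steps` rounds the volume to the nearest whole motor step;
#' `volume_to_runtime` returns `dead_time + volume / coefficient` in ms. The
#' runtime result carries a logical attribute `below_min_reliable` flagging
#' doses smaller than the pump's reliable minimum (a warning, never a
#' refusal).
#'
#' @param spec pump specification.
#' @param volume requested volume in ml (`> 0`).
#' @return Steps (integer) or run time in ms (numeric).
#' @export
volume_to_steps <- function(spec, volume) {
  stopifnot(inherits(spec, "syringe_pump_spec"))
  if (!is.numeric(volume) || volume <= 0)
    stop("requested volume must be positive", call. = FALSE)
  if (volume > syringe_remaining_ml(spec) + 1e-12)
    stop(sprintf(
      "capacity exceeded: requested %.3f ml but only %.3f ml left in syringe",
      volume, syringe_remaining_ml(spec)), call. = FALSE)
  as.integer(round(volume / ml_per_step(spec)))
}

#' @rdname volume_to_steps
#' @export
volume_to_runtime <- function(spec, volume) {
  stopifnot(inherits(spec, "peristaltic_pump_spec"))
  if (!is.numeric(volume) || volume <= 0)
    stop("requested volume must be positive", call. = FALSE)
  rt <- spec$dead_time + volume / spec$coefficient
  attr(rt, "below_min_reliable") <- volume < spec$min_reliable_dose
  rt
}

#' Plan and book a dose on a pump
#'
#' Converts a requested volume to actuation and advances the pump's state
#' (plunger position / dispensed total). For the syringe pump the sub-step
#' rounding error is carried forward in an accumulator so that cumulative
#' dispensed volume tracks cumulative requested volume to within one step.
#'
#' @param spec pump specification (state included).
#' @param volume requested ml.
#' @return `list(pump = updated spec, steps = ...)` or
#'   `list(pump = updated spec, runtime_ms = ...)`.
#' @export
plan_dose <- function(spec, volume) {
  if (inherits(spec, "syringe_pump_spec")) {
    if (!is.numeric(volume) || volume <= 0)
      stop("requested volume must be positive", call. = FALSE)
    if (volume > syringe_remaining_ml(spec) + 1e-12)
      stop("capacity exceeded", call. = FALSE)
    mlps <- ml_per_step(spec)
    steps <- as.integer(round((volume + spec$residual_ml) / mlps))
    spec$residual_ml <- volume + spec$residual_ml - steps * mlps
    spec$plunger_position <- spec$plunger_position + steps
    spec$dispensed_ml <- spec$dispensed_ml + steps * mlps
    list(pump = spec, steps = steps)
  } else if (inherits(spec, "peristaltic_pump_spec")) {
    rt <- volume_to_runtime(spec, volume)
    spec$dispensed_ml <- spec$dispensed_ml + volume
    list(pump = spec, runtime_ms = as.numeric(rt),
         below_min_reliable = attr(rt, "below_min_reliable"))
  } else stop("not a pump specification", call. = FALSE)
}

#' Fit a pump calibration from repeated-dose measurements
#'
#' The standard bench procedure: run the pump for a fixed actuation (e.g.
#' 500 ms, or a fixed step count) many times into a vessel, weigh/measure
#' the total, and divide. The fitted coefficient is the ratio of sums
#' `sum(measured_volume) / sum(run_time)` — the pooled-total estimator, which
#' is what dosing the whole series into one beaker physically measures and
#' is robust to per-dose noise.
#'
#' @param measurements data frame with columns `run_time` (ms for a
#'   peristaltic pump, steps for a syringe pump) and `measured_volume` (ml).
#' @return An object of class `pump_calibration`: `coefficient` (ml per ms
#'   or per step), `n`, and `per_dose_cv` (coefficient of variation of the
#'   per-dose ratios; `NA` for a single measurement).
#' @export
fit_calibration <- function(measurements) {
  if (is.null(measurements) || nrow(as.data.frame(measurements)) < 1L)
    stop("need at least one calibration measurement", call. = FALSE)
  m <- as.data.frame(measurements)
  if (!all(c("run_time", "measured_volume") %in% names(m)))
    stop("measurements need columns 'run_time' and 'measured_volume'",
         call. = FALSE)
  if (any(m$run_time <= 0) || any(m$measured_volume <= 0))
    stop("run times and measured volumes must be positive", call. = FALSE)
  per_dose <- m$measured_volume / m$run_time
  coef <- sum(m$measured_volume) / sum(m$run_time)
  structure(list(coefficient = coef,
                 n = nrow(m),
                 per_dose_cv = if (nrow(m) > 1L)
                   stats::sd(per_dose) / mean(per_dose) else NA_real_),
            class = "pump_calibration")
}

#' @export
print.pump_calibration <- function(x, ...) {
  cat(sprintf("<pump_calibration> coefficient %.6g (n = %d, per-dose CV %s)\n",
              x$coefficient, x$n,
              if (is.na(x$per_dose_cv)) "NA"
              else sprintf("%.2f%%", 100 * x$per_dose_cv)))
  invisible(x)
}

#' Module identity
#'
#' What a pump module announces when it is plugged in: its name, the reagent
#' it carries, its pump type and its stored calibration — enough for the
#' controller to use it without manual configuration.
#'
#' @param name,description,reagent free text.
#' @param calibration a [syringe_pump_spec()] or [peristaltic_pump_spec()].
#' @return An object of class `module_identity`.
#' @export
module_identity <- function(name, description, reagent, calibration) {
  pump_type <- if (inherits(calibration, "syringe_pump_spec")) "syringe"
  else if (inherits(calibration, "peristaltic_pump_spec")) "peristaltic"
  else stop("'calibration' must be a pump specification", call. = FALSE)
  structure(list(name = name, description = description, reagent = reagent,
                 pump_type = pump_type, calibration = calibration),
            class = "module_identity")
}
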