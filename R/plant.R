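#' pH of a strong acid / strong base mixture
#'
#' Charge balance for fully dissociated electrolytes:
#' `[H+] + C_b = [OH-] + C_a` with `[OH-] = Kw/[H+]` gives
#' `[H+]^2 + (C_b - C_a)[H+] - Kw = 0`, whose positive root is taken. This
#' closed form is the ground truth behind the simulated reactor: it is exact,
#' strictly decreasing in `C_a`, increasing in `C_b`, and continuous through
#' the equivalence point.
#'
#' @param C_a,C_b net strong acid / strong base concentrations, mol/L
#'   (vectorized).
#' @param Kw water ion product (default `1e-14`, 25 degrees C).
#' @return pH value(s).
#' @export
ph_strong <- function(C_a, C_b, Kw = 1e-14) {
  stopifnot(all(C_a >= 0), all(C_b >= 0), Kw > 0)
  net <- C_b - C_a                       # net base
  s <- sqrt(net^2 + 4 * Kw)
  # rationalized form on the basic side avoids catastrophic cancellation
  H <- ifelse(net > 0, 2 * Kw / (net + s), (s - net) / 2)
  -log10(H)
}

#' Acid-generation kinetics
#'
#' Two-regime generation rate emulating a catalytic oxidation that releases
#' acid quickly at first and then settles into a slow tail:
#' `r(t) = r_fast * exp(-t / tau_fast) + r_slow` for `t < duration`, zero
#' afterwards. The defaults size the fast phase so that early neutralization
#' demand is about 2 ml of 0.5 M base per 5 s in a 2.5 L reactor, decaying
#' with a 600 s time constant to a tail needing roughly 0.5 ml every couple
#' of minutes.
#'
#' @param r_fast initial fast-phase rate, mol acid / s.
#' @param tau_fast fast-phase decay constant, s.
#' @param r_slow persistent slow rate, mol acid / s.
#' @param duration s after which generation stops.
#' @return An object of class `tempo_kinetics`.
#' @export
tempo_kinetics <- function(r_fast = 2e-4, tau_fast = 600, r_slow = 1.5e-6,
                           duration = 10800) {
  stopifnot(r_fast >= 0, tau_fast > 0, r_slow >= 0, duration >= 0)
  structure(list(r_fast = r_fast, tau_fast = tau_fast, r_slow = r_slow,
                 duration = duration),
            class = "tempo_kinetics")
}

# Exact integral of the generation rate over [t0, t1] (mol).
generated_acid <- function(kin, t0, t1) {
  if (is.null(kin)) return(0)
  t0 <- min(t0, kin$duration)
  t1 <- min(t1, kin$duration)
  if (t1 <= t0) return(0)
  kin$r_fast * kin$tau_fast *
    (exp(-t0 / kin$tau_fast) - exp(-t1 / kin$tau_fast)) +
    kin$r_slow * (t1 - t0)
}

#' Simulated reactor state
#'
#' A stirred vessel of strong electrolytes with an optional acid-generating
#' process, read through a pH electrode with first-order lag and Gaussian
#' measurement noise. Any buffering of the real mixture is folded into the
#' effective generation rate so that the true pH stays closed-form
#' ([ph_strong()]). All stochastic draws (noise, frame corruption, pump
#' actuation) come from R's global RNG: seed once per simulation with
#' `set.seed()` for bit-reproducible runs.
#'
#' @param volume_l vessel volume in litres.
#' @param init_ph starting pH; converted into an initial strong acid or base
#'   load (ignored when `acid_mol`/`base_mol` are given).
#' @param acid_mol,base_mol explicit initial moles of strong acid/base.
#' @param Kw water ion product.
#' @param kinetics a [tempo_kinetics()] or `NULL` for an inert vessel.
#' @param electrode_tau first-order electrode time constant, s (0 disables
#'   lag).
#' @param noise_sd Gaussian sd of the measured pH, in pH units (0 disables).
#' @param titrant_molarity mol/L of the dosed reagent (base for a pH-stat
#'   holding an acid-generating process).
#' @param transition_prob probability that an emitted display frame is a
#'   corrupted mid-transition frame.
#' @return An object of class `plant_state`.
#' @export
plant_state <- function(volume_l = 2.5, init_ph = 10.55,
                        acid_mol = NULL, base_mol = NULL, Kw = 1e-14,
                        kinetics = tempo_kinetics(), electrode_tau = 20,
                        noise_sd = 0.001, titrant_molarity = 0.5,
                        transition_prob = 0.02) {
  stopifnot(volume_l > 0, Kw > 0, electrode_tau >= 0, noise_sd >= 0,
            titrant_molarity > 0, transition_prob >= 0, transition_prob <= 1)
  if (is.null(acid_mol) && is.null(base_mol)) {
    if (init_ph >= -log10(sqrt(Kw))) {        # basic side
      base_mol <- (Kw / 10^(-init_ph) - 10^(-init_ph)) * volume_l
      acid_mol <- 0
    } else {
      acid_mol <- (10^(-init_ph) - Kw / 10^(-init_ph)) * volume_l
      base_mol <- 0
    }
  }
  acid_mol <- acid_mol %||% 0
  base_mol <- base_mol %||% 0
  stopifnot(acid_mol >= 0, base_mol >= 0)
  st <- structure(list(volume_l = volume_l, acid_mol = acid_mol,
                       base_mol = base_mol, Kw = Kw, kinetics = kinetics,
                       electrode_tau = electrode_tau, noise_sd = noise_sd,
                       titrant_molarity = titrant_molarity,
                       transition_prob = transition_prob,
                       t = 0, ph_lagged = NA_real_, measured_ph = NA_real_),
                  class = "plant_state")
  st$ph_lagged <- plant_true_ph(st)            # electrode starts settled
  st$measured_ph <- st$ph_lagged
  st
}

#' @rdname plant_state
#' @param state a `plant_state`.
#' @export
plant_true_ph <- function(state)
  ph_strong(state$acid_mol / state$volume_l, state$base_mol / state$volume_l,
            state$Kw)

#' @export
print.plant_state <- function(x, ...) {
  cat(sprintf(
    "<plant_state> t=%.0f s, V=%.4f L, true pH %.4f, measured %.4f\n",
    x$t, x$volume_l, plant_true_ph(x), x$measured_ph))
  invisible(x)
}

#' Advance the simulated reactor
#'
#' Applies a titrant addition, integrates the acid-generation kinetics
#' exactly over the step (the exponential form has a closed-form integral),
#' recomputes the true pH, relaxes the electrode reading toward it with the
#' first-order lag, and draws fresh measurement noise.
#'
#' @param state a [plant_state()].
#' @param dt step length, s (`> 0`).
#' @param added_ml ml of titrant added during the step.
#' @param molarity titrant molarity; defaults to the plant's configured one.
#' @return The advanced `plant_state`.
#' @export
plant_step <- function(state, dt, added_ml = 0,
                       molarity = state$titrant_molarity) {
  stopifnot(dt > 0, added_ml >= 0)
  state$base_mol <- state$base_mol + added_ml / 1000 * molarity
  state$volume_l <- state$volume_l + added_ml / 1000
  state$acid_mol <- state$acid_mol +
    generated_acid(state$kinetics, state$t, state$t + dt)
  true_ph <- plant_true_ph(state)
  state$ph_lagged <- if (state$electrode_tau > 0)
    state$ph_lagged + (1 - exp(-dt / state$electrode_tau)) *
      (true_ph - state$ph_lagged)
  else true_ph
  state$measured_ph <- state$ph_lagged +
    if (state$noise_sd > 0) stats::rnorm(1, 0, state$noise_sd) else 0
  state$t <- state$t + dt
  state
}

#' Virtual pump actuation
#'
#' Converts an actuation command into the volume that physically reaches the
#' vessel, including actuation noise. The peristaltic model delivers
#' `max(0, coefficient * (runtime - dead_time))` scaled by a multiplicative
#' Gaussian error whose sd grows for small doses
#' (`sigma = sigma0 * (1 + v_ref / volume)`): short runs are dominated by
#' the motor's erratic start, so small unit volumes are relatively noisier,
#' and more so on a 9 V supply than on 12 V. The syringe model delivers
#' `steps * ml_per_step` with a ~1 % coefficient of variation.
#'
#' @param spec pump specification.
#' @param runtime_ms peristaltic run time, ms.
#' @param noise logical; `FALSE` gives the deterministic nominal volume.
#' @return Delivered volume in ml (never negative).
#' @export
virtual_peristaltic_deliver <- function(spec, runtime_ms, noise = TRUE) {
  stopifnot(inherits(spec, "peristaltic_pump_spec"), runtime_ms >= 0)
  v <- max(0, spec$coefficient * (runtime_ms - spec$dead_time))
  if (v == 0 || !noise) return(v)
  p <- .peristaltic_noise_profile(spec$supply_voltage_tag)
  sigma <- p$sigma0 * (1 + p$v_ref / v)
  max(0, v * (1 + stats::rnorm(1, 0, sigma)))
}

.peristaltic_noise_profile <- function(voltage_tag) {
  # v_ref is the start-up-equivalent volume: doses comparable to it are
  # dominated by the motor's erratic spin-up, so their relative error —
  # and, summed over the many doses needed for a given total, the spread
  # of the delivered total — grows as unit volume shrinks.
  if (voltage_tag == "9V") list(sigma0 = 0.03, v_ref = 1.0)
  else list(sigma0 = 0.01, v_ref = 0.05)
}

#' @rdname virtual_peristaltic_deliver
#' @param steps syringe motor steps.
#' @param cv coefficient of variation of syringe delivery.
#' @export
virtual_syringe_deliver <- function(spec, steps, noise = TRUE, cv = 0.01) {
  stopifnot(inherits(spec, "syringe_pump_spec"), steps >= 0)
  v <- steps * ml_per_step(spec)
  if (v == 0 || !noise) return(v)
  max(0, v * (1 + stats::rnorm(1, 0, cv)))
}

# Dispatch: actuate whichever pump type, returning delivered ml.
virtual_deliver <- function(spec, actuation, noise = TRUE) {
  if (inherits(spec, "peristaltic_pump_spec"))
    virtual_peristaltic_deliver(spec, actuation, noise)
  else virtual_syringe_deliver(spec, actuation, noise)
}

#' Emit a display frame for the current measured pH
#'
#' Renders the electrode reading (rounded to the display's 0.001 resolution)
#' as a seven-segment frame; with probability `transition_prob` one digit is
#' replaced by a half-lit transition pattern (`{a, d, g}`), which the decoder
#' rejects as invalid — emulating frames captured while the meter's display
#' is changing.
#'
#' @param state a [plant_state()].
#' @param geometry a [segment_geometry()].
#' @param style a [display_style()].
#' @param transition_prob overrides the plant's configured probability.
#' @return A [frame_image()].
#' @export
emit_frame <- function(state, geometry, style = display_style(),
                       transition_prob = state$transition_prob) {
  k <- geometry$n_digits - geometry$decimal_index
  vmax <- (10^geometry$n_digits - 1) / 10^k
  value <- min(max(round(state$measured_ph, k), 0), vmax)
  corrupt <- transition_prob > 0 && stats::runif(1) < transition_prob
  if (!corrupt) return(render_display(value, geometry, style))
  ov <- vector("list", geometry$n_digits)
  ov[[sample.int(geometry$n_digits, 1)]] <- c("a", "d", "g")
  render_display(value, geometry, style, lit_override = ov)
}

#' Reference simulation scenarios
#'
#' `scenario("tempo_default")` assembles the canonical acid-generating run:
#' a 2.5 L reactor holding pH 10.55 with 0.5 M NaOH dosed by a calibrated
#' 12 V peristaltic pump (8.167e-4 ml/ms, i.e. 49 ml/min), two-phase
#' generation kinetics, 20 s electrode lag, 0.001 pH measurement noise, and
#' a small seven-segment display read optically each second.
#' `scenario("inert")` is the same vessel with generation switched off.
#'
#' @param name scenario name.
#' @return A list with components `plant`, `pump`, `config` (a
#'   [control_config()]), `geometry`, `style`, and `cal` (an
#'   [ocr_calibration()]).
#' @export
scenario <- function(name = c("tempo_default", "inert")) {
  name <- match.arg(name)
  geometry <- segment_geometry(anchor_row = 2, anchor_col = 2,
                               digit_width = 6, digit_height = 9,
                               digit_pitch = 8, n_digits = 5,
                               decimal_index = 2)
  style <- display_style(on_intensity = 230, off_intensity = 30,
                         background = 15, noise_sd = 0)
  cal <- ocr_calibration(threshold = 128, geometry = geometry)
  kin <- if (name == "tempo_default") tempo_kinetics() else NULL
  plant <- plant_state(volume_l = 2.5, init_ph = 10.55, kinetics = kin,
                       electrode_tau = 20, noise_sd = 0.001,
                       titrant_molarity = 0.5, transition_prob = 0.02)
  pump <- peristaltic_pump_spec(coefficient = 8.167e-4,
                                supply_voltage_tag = "12V")
  config <- control_config()
  list(plant = plant, pump = pump, config = config,
       geometry = geometry, style = style, cal = cal)
}
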