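#' Ventilator settings for a simulated volume-controlled breath
#'
#' Bundles the ventilator-side parameters of a volume-controlled,
#' constant-flow mechanical breath. The defaults reproduce a common
#' experimental configuration for a medium-sized anaesthetised pig:
#' tidal volume 0.4 L, respiratory rate 20 breaths/min, I:E ratio 1:2,
#' extrinsic PEEP 5 cmH2O, sampled at 200 Hz.
#'
#' @param tidal_volume Tidal volume V_T in litres (> 0).
#' @param respiratory_rate Respiratory rate in breaths per minute (> 0).
#' @param ie_ratio Inspiratory:expiratory ratio as a length-2 positive
#'   numeric vector, e.g. `c(1, 2)` for 1:2.
#' @param peep_e Extrinsic (ventilator-set) PEEP in cmH2O (>= 0).
#' @param sample_rate Sampling frequency in Hz (> 0).
#' @param hold_duration End-inspiratory pause length in seconds; 0 for a
#'   regular breath. A sustained hold lets airway pressure relax to its
#'   static plateau, which the interrupter technique needs.
#'
#' @return An object of class `ventilator_settings`.
#' @seealso [simulate_breath()], [interrupter_crs()]
#' @export
ventilator_settings <- function(tidal_volume = 0.4,
                                respiratory_rate = 20,
                                ie_ratio = c(1, 2),
                                peep_e = 5,
                                sample_rate = 200,
                                hold_duration = 0) {
  vr_check(is.numeric(tidal_volume) && length(tidal_volume) == 1 &&
             is.finite(tidal_volume) && tidal_volume > 0,
           "tidal_volume must be a single positive finite number [L]",
           "invalid_parameter")
  vr_check(is.numeric(respiratory_rate) && length(respiratory_rate) == 1 &&
             is.finite(respiratory_rate) && respiratory_rate > 0,
           "respiratory_rate must be a single positive finite number [bpm]",
           "invalid_parameter")
  vr_check(is.numeric(ie_ratio) && length(ie_ratio) == 2 &&
             all(is.finite(ie_ratio)) && all(ie_ratio > 0),
           "ie_ratio must be two positive numbers (insp, exp)",
           "invalid_parameter")
  vr_check(is.numeric(peep_e) && length(peep_e) == 1 &&
             is.finite(peep_e) && peep_e >= 0,
           "peep_e must be a single non-negative finite number [cmH2O]",
           "invalid_parameter")
  vr_check(is.numeric(sample_rate) && length(sample_rate) == 1 &&
             is.finite(sample_rate) && sample_rate > 0,
           "sample_rate must be a single positive finite number [Hz]",
           "invalid_parameter")
  vr_check(is.numeric(hold_duration) && length(hold_duration) == 1 &&
             is.finite(hold_duration) && hold_duration >= 0,
           "hold_duration must be a single non-negative finite number [s]",
           "invalid_parameter")
  structure(
    list(tidal_volume = as.numeric(tidal_volume),
         respiratory_rate = as.numeric(respiratory_rate),
         ie_ratio = as.numeric(ie_ratio),
         peep_e = as.numeric(peep_e),
         sample_rate = as.numeric(sample_rate),
         hold_duration = as.numeric(hold_duration)),
    class = "ventilator_settings")
}

#' Inspiratory time implied by a set of ventilator settings
#'
#' T_I = 60 / respiratory_rate * i / (i + e).
#'
#' @param settings A [ventilator_settings()] object.
#' @return Inspiratory time in seconds.
#' @export
inspiratory_time <- function(settings) {
  stopifnot(inherits(settings, "ventilator_settings"))
  60 / settings$respiratory_rate *
    settings$ie_ratio[1] / sum(settings$ie_ratio)
}

#' Respiratory mechanics of the one-compartment model
#'
#' Ground-truth (or estimated) parameters of the first-order linear model of
#' the respiratory system, Paw = V / C_RS + V' * R_RS + PEEP. An optional
#' viscoelastic (Kelvin-body) second compartment superposes a slowly
#' relaxing pressure component on top of the first-order pressure: this makes
#' the dynamic end-inspiratory pressure exceed the static plateau, as stress
#' relaxation and gas redistribution do in real lungs, and is the documented
#' way to give the least-squares estimator its characteristic negative bias
#' relative to the interrupter reference.
#'
#' @param c_rs Respiratory system compliance in ml/cmH2O (> 0).
#' @param r_rs Respiratory system resistance in cmH2O/(L/s) (>= 0).
#' @param peep_total Total PEEP in cmH2O (>= 0).
#' @param viscoelastic_fraction Extra relaxing elastance as a fraction of the
#'   static elastance, in 0 (inclusive) to 1 (exclusive). Default 0 (pure first-order model).
#' @param viscoelastic_tau Relaxation time constant of the viscoelastic
#'   compartment in seconds (> 0). Default 1.
#' @param validate Internal; skip range checks (used to carry non-physical
#'   least-squares estimates without rejecting them).
#'
#' @return An object of class `mechanics_params`.
#' @export
mechanics_params <- function(c_rs, r_rs, peep_total,
                             viscoelastic_fraction = 0,
                             viscoelastic_tau = 1,
                             validate = TRUE) {
  if (validate) {
    vr_check(is.numeric(c_rs) && length(c_rs) == 1 && is.finite(c_rs) && c_rs > 0,
             "c_rs must be a single positive finite number [ml/cmH2O]",
             "invalid_parameter")
    vr_check(is.numeric(r_rs) && length(r_rs) == 1 && is.finite(r_rs) && r_rs >= 0,
             "r_rs must be a single non-negative finite number [cmH2O/(L/s)]",
             "invalid_parameter")
    vr_check(is.numeric(peep_total) && length(peep_total) == 1 &&
               is.finite(peep_total) && peep_total >= 0,
             "peep_total must be a single non-negative finite number [cmH2O]",
             "invalid_parameter")
    vr_check(is.numeric(viscoelastic_fraction) && length(viscoelastic_fraction) == 1 &&
               is.finite(viscoelastic_fraction) &&
               viscoelastic_fraction >= 0 && viscoelastic_fraction < 1,
             "viscoelastic_fraction must lie in [0, 1)", "invalid_parameter")
    vr_check(is.numeric(viscoelastic_tau) && length(viscoelastic_tau) == 1 &&
               is.finite(viscoelastic_tau) && viscoelastic_tau > 0,
             "viscoelastic_tau must be a single positive finite number [s]",
             "invalid_parameter")
  }
  structure(
    list(c_rs = as.numeric(c_rs),
         r_rs = as.numeric(r_rs),
         peep_total = as.numeric(peep_total),
         viscoelastic_fraction = as.numeric(viscoelastic_fraction),
         viscoelastic_tau = as.numeric(viscoelastic_tau)),
    class = "mechanics_params")
}

# Internal constructor for a sampled breath. Arrays are in canonical units:
# time s, paw cmH2O, flow L/s, volume L. Window indices are 1-based and
# half-open: inspiratory samples are insp_start:(insp_end - 1).
new_breath_tracing <- function(time, paw, flow, volume,
                               insp_start, insp_end, sample_rate,
                               has_hold = FALSE, hold_start = NA_integer_,
                               hold_end = NA_integer_, meta = list()) {
  n <- length(time)
  stopifnot(length(paw) == n, length(flow) == n, length(volume) == n,
            insp_start >= 1, insp_start < insp_end, insp_end <= n + 1)
  structure(
    list(time = time, paw = paw, flow = flow, volume = volume,
         insp_start = as.integer(insp_start), insp_end = as.integer(insp_end),
         sample_rate = sample_rate, has_hold = isTRUE(has_hold),
         hold_start = as.integer(hold_start), hold_end = as.integer(hold_end),
         meta = meta),
    class = "breath_tracing")
}

#' @export
print.breath_tracing <- function(x, ...) {
  cat("<breath_tracing> ", length(x$time), " samples @ ", x$sample_rate,
      " Hz (", format(length(x$time) / x$sample_rate, digits = 4), " s)\n",
      sep = "")
  cat("  inspiration: samples ", x$insp_start, "-", x$insp_end - 1,
      if (x$has_hold) sprintf(", hold: %d-%d", x$hold_start, x$hold_end) else "",
      "\n", sep = "")
  cat("  paw [cmH2O]: ", format(min(x$paw), digits = 4), " .. ",
      format(max(x$paw), digits = 4),
      "; end-insp volume [L]: ",
      format(x$volume[min(x$insp_end, length(x$volume))], digits = 6),
      "\n", sep = "")
  invisible(x)
}

#' @export
print.mechanics_params <- function(x, ...) {
  cat(sprintf("<mechanics_params> C_RS = %.3g ml/cmH2O, R_RS = %.3g cmH2O/(L/s), PEEP = %.3g cmH2O\n",
              x$c_rs, x$r_rs, x$peep_total))
  if (x$viscoelastic_fraction > 0)
    cat(sprintf("  viscoelastic: fraction %.3g, tau %.3g s\n",
                x$viscoelastic_fraction, x$viscoelastic_tau))
  invisible(x)
}

#' @export
print.ventilator_settings <- function(x, ...) {
  cat(sprintf("<ventilator_settings> V_T = %.3g L, RR = %.3g bpm, I:E = %g:%g, PEEPe = %.3g cmH2O, %g Hz",
              x$tidal_volume, x$respiratory_rate, x$ie_ratio[1], x$ie_ratio[2],
              x$peep_e, x$sample_rate))
  if (x$hold_duration > 0) cat(sprintf(", hold %.3g s", x$hold_duration))
  cat("\n")
  invisible(x)
}

#' Simulate one volume-controlled constant-flow mechanical breath
#'
#' Generates the sampled airway pressure, flow and volume of a single breath
#' from the one-compartment equation of motion
#' \deqn{P_{aw} = V / C_{RS} + V' R_{RS} + PEEP}
#' under volume-controlled constant-flow ventilation. Inspiratory flow is
#' constant at V_T / T_I; a one-sample half-amplitude valve-closure ramp ends
#' inspiration so that the trapezoidally integrated volume lands exactly on
#' V_T. An optional end-inspiratory hold (zero flow) follows, then passive
#' exponential expiration with time constant R_RS * C_RS. Pressure is
#' computed from the integrated volume array, so the equation of motion holds
#' sample-exactly and a least-squares fit of the model to a noiseless breath
#' recovers the generating parameters to machine precision.
#'
#' When `viscoelastic_fraction > 0`, a Kelvin-body pressure with elastance
#' `viscoelastic_fraction / c_rs` (per litre) and relaxation time
#' `viscoelastic_tau` is superposed; it builds up during inspiration and
#' relaxes during the hold, so the dynamic pressure exceeds the static
#' plateau.
#'
#' @param params A [mechanics_params()] object (ground truth).
#' @param settings A [ventilator_settings()] object.
#' @param seed Optional integer recorded in the tracing metadata for
#'   provenance; the forward model itself is deterministic.
#'
#' @return A `breath_tracing` object.
#' @examples
#' br <- simulate_breath(mechanics_params(30, 10, 5), ventilator_settings())
#' max(br$paw)  # ~ 5 + 400/30 + 0.4*10 cmH2O at end-inspiration
#' @export
simulate_breath <- function(params, settings, seed = NULL) {
  stopifnot(inherits(params, "mechanics_params"),
            inherits(settings, "ventilator_settings"))
  fs <- settings$sample_rate
  dt <- 1 / fs
  ti <- inspiratory_time(settings)
  n_i <- round(ti * fs)
  vr_check(n_i >= 50,
           sprintf("inspiration spans only %d samples; at least 50 are required", n_i),
           "resolution_error")
  vt <- settings$tidal_volume
  flow_i <- vt / ti
  n_hold <- round(settings$hold_duration * fs)
  n_total <- round((60 / settings$respiratory_rate + settings$hold_duration) * fs)
  # layout: [1..n_i] constant flow | [n_i+1] ramp | [n_i+2 .. n_i+2+n_hold] zero
  # flow (valve switch + hold) | remainder passive expiration
  exp_start <- n_i + 3 + n_hold
  vr_check(exp_start <= n_total + 1,
           "cycle too short for inspiration plus hold", "invalid_parameter")

  flow <- numeric(n_total)
  flow[seq_len(n_i)] <- flow_i
  flow[n_i + 1] <- flow_i / 2
  c_l <- params$c_rs / 1000              # compliance in L/cmH2O
  tau_e <- max(params$r_rs * c_l, 0.02)  # floor keeps R_RS = 0 representable
  if (exp_start <= n_total) {
    t_e <- (seq(exp_start, n_total) - exp_start) * dt
    flow[exp_start:n_total] <- -(vt / tau_e) * exp(-t_e / tau_e)
  }

  volume <- cumtrapz_flow(flow, dt)
  elastance <- 1 / c_l                   # cmH2O/L
  paw <- params$peep_total + elastance * volume + params$r_rs * flow

  if (params$viscoelastic_fraction > 0) {
    paw <- paw + viscoelastic_pressure(flow, dt,
                                       e2 = params$viscoelastic_fraction * elastance,
                                       tau = params$viscoelastic_tau)
  }

  new_breath_tracing(
    time = (seq_len(n_total) - 1) * dt,
    paw = paw, flow = flow, volume = volume,
    insp_start = 1L, insp_end = n_i + 1L, sample_rate = fs,
    has_hold = n_hold > 0,
    hold_start = if (n_hold > 0) n_i + 2L else NA_integer_,
    hold_end = if (n_hold > 0) n_i + 2L + n_hold else NA_integer_,
    meta = list(truth = params, settings = settings, seed = seed))
}

# Cumulative trapezoidal integral of a sampled flow, volume[1] = 0.
cumtrapz_flow <- function(flow, dt) {
  n <- length(flow)
  if (n < 2) return(numeric(n))
  c(0, cumsum((flow[-n] + flow[-1]) * dt / 2))
}

# Kelvin-body pressure: dPve/dt = e2 * flow - Pve / tau, integrated with the
# exact exponential update per sample step (flow taken at the step midpoint).
viscoelastic_pressure <- function(flow, dt, e2, tau) {
  n <- length(flow)
  decay <- exp(-dt / tau)
  gain <- e2 * tau * (1 - decay)
  p <- numeric(n)
  mid <- (flow[-n] + flow[-1]) / 2
  for (k in 2:n) p[k] <- p[k - 1] * decay + gain * mid[k - 1]
  p
}

#' Configuration of the synthetic-pool parameter sampler
#'
#' Uniform sampling ranges for the per-recording mechanics and tidal volume
#' of a synthetic breath pool. The defaults bracket healthy to mildly
#' injured (oleic-acid ARDS model) lungs of a 25-35 kg pig: compliance
#' 10-40 ml/cmH2O, resistance 5-25 cmH2O/(L/s), PEEP 4-8 cmH2O, tidal
#' volume 0.25-0.45 L. A degenerate range (`c(x, x)`) pins a parameter.
#'
#' @param c_rs Range of compliance (ml/cmH2O).
#' @param r_rs Range of resistance (cmH2O/(L/s)).
#' @param peep Range of total PEEP (cmH2O).
#' @param v_t Range of tidal volume (L).
#' @param viscoelastic_fraction Range of the viscoelastic elastance fraction
#'   (default pinned at 0, which keeps the pure first-order model and the
#'   exact-recovery property of the least-squares fit).
#' @param viscoelastic_tau Range of the viscoelastic time constant (s).
#' @return An object of class `pool_sampler_config`.
#' @export
pool_sampler_config <- function(c_rs = c(10, 40),
                                r_rs = c(5, 25),
                                peep = c(4, 8),
                                v_t = c(0.25, 0.45),
                                viscoelastic_fraction = c(0, 0),
                                viscoelastic_tau = c(1, 1)) {
  chk_range <- function(x, name, lo_ok = 0, strict = TRUE) {
    vr_check(is.numeric(x) && length(x) == 2 && all(is.finite(x)) &&
               x[2] >= x[1] && (if (strict) x[1] > lo_ok else x[1] >= lo_ok),
             sprintf("%s must be a finite non-decreasing range with admissible bounds", name),
             "invalid_configuration")
  }
  chk_range(c_rs, "c_rs")
  chk_range(r_rs, "r_rs", strict = FALSE)
  chk_range(peep, "peep", strict = FALSE)
  chk_range(v_t, "v_t")
  chk_range(viscoelastic_fraction, "viscoelastic_fraction", strict = FALSE)
  vr_check(viscoelastic_fraction[2] < 1,
           "viscoelastic_fraction upper bound must be < 1", "invalid_configuration")
  chk_range(viscoelastic_tau, "viscoelastic_tau")
  structure(list(c_rs = c_rs, r_rs = r_rs, peep = peep, v_t = v_t,
                 viscoelastic_fraction = viscoelastic_fraction,
                 viscoelastic_tau = viscoelastic_tau),
            class = "pool_sampler_config")
}

#' Generate a pool of synthetic breath recordings
#'
#' Emulates a pool of experimental recordings: each record pairs a regular
#' breath with an end-inspiratory-hold breath generated from identical,
#' randomly drawn mechanics, so that the hold breath provides the
#' interrupter-technique reference compliance for its regular sibling.
#' Sampling is uniform within the configured ranges and fully determined by
#' the seed.
#'
#' @param n_recordings Number of records (>= 1).
#' @param sampler A [pool_sampler_config()].
#' @param settings Base [ventilator_settings()]; the sampled tidal volume
#'   overrides `settings$tidal_volume` per record.
#' @param seed Integer seed; the same seed reproduces the pool bit-exactly.
#' @param hold_duration Hold length of the reference breath in seconds
#'   (default 2, long enough for the plateau to stabilise).
#'
#' @return A list of class `breath_pool`; each element is a list with
#'   components `regular` (breath_tracing), `hold` (breath_tracing) and
#'   `truth` (mechanics_params).
#' @export
generate_pool <- function(n_recordings,
                          sampler = pool_sampler_config(),
                          settings = ventilator_settings(),
                          seed = 1,
                          hold_duration = 2) {
  vr_check(is.numeric(n_recordings) && length(n_recordings) == 1 &&
             n_recordings >= 1, "n_recordings must be >= 1",
           "invalid_configuration")
  stopifnot(inherits(sampler, "pool_sampler_config"),
            inherits(settings, "ventilator_settings"))
  n <- as.integer(n_recordings)
  draws <- withr::with_seed(as.integer(seed), {
    matrix(stats::runif(n * 6), nrow = n)
  })
  span <- function(u, r) r[1] + u * (r[2] - r[1])
  pool <- vector("list", n)
  for (i in seq_len(n)) {
    truth <- mechanics_params(
      c_rs = span(draws[i, 1], sampler$c_rs),
      r_rs = span(draws[i, 2], sampler$r_rs),
      peep_total = span(draws[i, 3], sampler$peep),
      viscoelastic_fraction = span(draws[i, 5], sampler$viscoelastic_fraction),
      viscoelastic_tau = span(draws[i, 6], sampler$viscoelastic_tau))
    vt_i <- span(draws[i, 4], sampler$v_t)
    set_reg <- settings
    set_reg$tidal_volume <- vt_i
    # the ventilator-set PEEPe is the sampled total PEEP (no intrinsic PEEP
    # in the one-compartment model), and the interrupter reads it from here
    set_reg$peep_e <- truth$peep_total
    set_reg$hold_duration <- 0
    set_hold <- set_reg
    set_hold$hold_duration <- hold_duration
    pool[[i]] <- list(regular = simulate_breath(truth, set_reg),
                      hold = simulate_breath(truth, set_hold),
                      truth = truth)
  }
  structure(pool, class = "breath_pool",
            seed = as.integer(seed), settings = settings, sampler = sampler)
}

#' @export
print.breath_pool <- function(x, ...) {
  crs <- vapply(x, function(r) r$truth$c_rs, numeric(1))
  cat("<breath_pool> ", length(x), " records (regular + hold breath each)\n",
      "  C_RS truth [ml/cmH2O]: ", format(min(crs), digits = 4), " .. ",
      format(max(crs), digits = 4), ", seed ", attr(x, "seed"), "\n", sep = "")
  invisible(x)
}
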