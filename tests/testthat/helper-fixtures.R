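# Shared fixtures, built in code at test time.

default_params <- function(...) {
  args <- utils::modifyList(
    list(c_rs = 30, r_rs = 10, peep_total = 5), list(...))
  do.call(mechanics_params, args)
}

# The worked example used across modules: C_RS 30 ml/cmH2O, R_RS 10,
# PEEP 5, V_T 0.4 L at RR 20, I:E 1:2, 200 Hz.
example_breath <- function(hold = 0, ...) {
  simulate_breath(default_params(...),
                  ventilator_settings(hold_duration = hold))
}

# A minimal hand-built tracing with a perfectly flat plateau, for
# closed-form interrupter arithmetic independent of the simulator.
flat_plateau_breath <- function(p_plat = 25, v_t = 0.4, peep = 5,
                                n_insp = 60, n_hold = 40, fs = 200) {
  n <- n_insp + n_hold
  flow <- c(rep(v_t / (n_insp / fs), n_insp), rep(0, n_hold))
  volume <- ventrobust:::cumtrapz_flow(flow, 1 / fs)
  volume[(n_insp + 1):n] <- v_t
  paw <- c(seq(peep, p_plat + 2, length.out = n_insp), rep(p_plat, n_hold))
  ventrobust:::new_breath_tracing(
    time = (seq_len(n) - 1) / fs, paw = paw, flow = flow, volume = volume,
    insp_start = 1L, insp_end = n_insp + 1L, sample_rate = fs,
    has_hold = TRUE, hold_start = n_insp + 1L, hold_end = n,
    meta = list(settings = ventilator_settings(peep_e = peep)))
}

# Small heterogeneous pool with the viscoelastic study configuration.
study_pool <- function(n = 50, seed = 11) {
  generate_pool(n,
                pool_sampler_config(viscoelastic_fraction = c(0.10, 0.20),
                                    viscoelastic_tau = c(0.8, 1.2)),
                seed = seed)
}

pool_patterns <- function(pool, ...) {
  lapply(pool, function(r) build_input_pattern(r$regular, ...))
}

pool_references <- function(pool) {
  vapply(pool, function(r) interrupter_crs(r$hold)$c_rs_ref, numeric(1))
}
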