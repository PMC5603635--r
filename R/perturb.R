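#' Perturbation specification
#'
#' Describes one sensor-fault condition: random noise (`"RN"`) of a given
#' amplitude, or transient disconnection (`"TD"`) of a given duration, both
#' expressed as a percentage (of the inspiratory maximum airway pressure for
#' RN; of the inspiratory time for TD). The canonical sweep grid is
#' 0, 2, 4, ..., 50 percent — level 0 is the unperturbed baseline and the 25
#' nonzero levels match the graded-severity protocol; arbitrary levels in
#' 0 to 50 are accepted for ad-hoc use.
#'
#' @param kind `"RN"` (random noise) or `"TD"` (transient disconnection).
#' @param level_percent Severity in percent, in 0 to 50.
#' @param seed Integer seed for the noise draw (RN only).
#' @return An object of class `perturbation_spec`.
#' @export
perturbation_spec <- function(kind, level_percent, seed = NULL) {
  kind <- match.arg(kind, c("RN", "TD"))
  vr_check(is.numeric(level_percent) && length(level_percent) == 1 &&
             is.finite(level_percent) && level_percent >= 0 && level_percent <= 50,
           "level_percent must lie in [0, 50]", "invalid_parameter")
  structure(list(kind = kind, level_percent = as.numeric(level_percent),
                 seed = seed),
            class = "perturbation_spec")
}

#' Add bounded white noise to the pressure channel
#'
#' Corrupts the airway-pressure tracing with i.i.d. uniform noise on
#' \eqn{[-a, +a]}, where \eqn{a} is `level_percent` percent of the maximum
#' airway pressure over the inspiratory limb of the clean tracing. Uniform
#' noise has zero mean, the "defined extrema" of bounded sensor interference,
#' and — being i.i.d. per sample — a flat (white) spectrum. Flow, volume,
#' time and window indices are untouched: only the pressure sensor is
#' assumed faulty.
#'
#' @param breath A `breath_tracing`.
#' @param level_percent Noise amplitude as percent of inspiratory P_aw,max
#'   (>= 0). Level 0 returns the input unchanged.
#' @param seed Optional integer seed; a fixed seed makes the draw
#'   deterministic. The global RNG state is left untouched.
#' @return A perturbed copy of `breath`.
#' @export
add_random_noise <- function(breath, level_percent, seed = NULL) {
  stopifnot(inherits(breath, "breath_tracing"))
  vr_check(is.numeric(level_percent) && length(level_percent) == 1 &&
             is.finite(level_percent) && level_percent >= 0,
           "level_percent must be a single non-negative number",
           "invalid_parameter")
  if (level_percent == 0) return(breath)
  insp <- breath$insp_start:(breath$insp_end - 1L)
  a <- (level_percent / 100) * max(breath$paw[insp])
  n <- length(breath$paw)
  noise <- if (is.null(seed)) stats::runif(n, -a, a)
           else withr::with_seed(as.integer(seed), stats::runif(n, -a, a))
  out <- breath
  out$paw <- breath$paw + noise
  out$meta$perturbation <- perturbation_spec("RN", level_percent, seed)
  out
}

#' Zero the pressure channel over the centre of inspiration
#'
#' Simulates a transient disconnection of the pressure sensor: the airway
#' pressure is switched to 0 cmH2O (absolute zero, not PEEP) over a
#' contiguous window of `round(level_percent / 100 * nI)` samples centred on
#' the midpoint of the inspiratory phase, where `nI` is the inspiratory
#' sample count. When perfect centring is impossible (odd/even mismatch) the
#' window starts one sample earlier. Flow, volume, time and window indices
#' are untouched. The operation is deterministic.
#'
#' @param breath A `breath_tracing`.
#' @param level_percent Disconnection duration as percent of inspiratory
#'   time, in 0 to 50. Level 0 returns the input unchanged.
#' @return A perturbed copy of `breath`.
#' @export
apply_disconnection <- function(breath, level_percent) {
  stopifnot(inherits(breath, "breath_tracing"))
  vr_check(is.numeric(level_percent) && length(level_percent) == 1 &&
             is.finite(level_percent) && level_percent >= 0 && level_percent <= 50,
           "level_percent must lie in [0, 50]", "invalid_parameter")
  n_i <- breath$insp_end - breath$insp_start
  n_zero <- round(level_percent / 100 * n_i)
  if (n_zero == 0) return(breath)
  start <- breath$insp_start + floor((n_i - n_zero) / 2)
  out <- breath
  out$paw[seq.int(start, start + n_zero - 1L)] <- 0
  out$meta$perturbation <- perturbation_spec("TD", level_percent)
  out
}

#' Apply a perturbation described by a spec
#'
#' Dispatch helper: applies [add_random_noise()] or [apply_disconnection()]
#' according to `spec$kind`.
#'
#' @param breath A `breath_tracing`.
#' @param spec A [perturbation_spec()].
#' @return A perturbed copy of `breath`.
#' @export
apply_perturbation <- function(breath, spec) {
  stopifnot(inherits(spec, "perturbation_spec"))
  switch(spec$kind,
         RN = add_random_noise(breath, spec$level_percent, spec$seed),
         TD = apply_disconnection(breath, spec$level_percent))
}
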