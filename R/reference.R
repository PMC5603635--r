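#' Interrupter-technique reference compliance
#'
#' Computes the gold-standard ("true") respiratory system compliance from a
#' breath with an end-inspiratory hold: occluding flow lets airway pressure
#' relax to its static plateau P_plat, and
#' \deqn{C_{RS} = V_T / (P_{plat} - PEEP_e)}
#' in ml/cmH2O. Because flow is zero at the plateau, the estimate is
#' independent of airway resistance and of stress-relaxation transients that
#' have died out by the end of the hold.
#'
#' The plateau is measured as the mean airway pressure over a trailing window
#' of the hold (default 0.2 s) rather than a single sample, for robustness to
#' residual ringing. PEEPe is the known ventilator-set value, taken from the
#' tracing metadata when not supplied.
#'
#' @param breath A `breath_tracing` with `has_hold = TRUE`.
#' @param peep_e Extrinsic PEEP in cmH2O; defaults to the value recorded in
#'   the tracing's ventilator settings.
#' @param plateau_window Averaging window at the end of the hold, seconds.
#'
#' @return An object of class `reference_compliance` with fields `c_rs_ref`
#'   (ml/cmH2O), `p_plat` (cmH2O), `v_t` (L) and `peep_e` (cmH2O).
#' @examples
#' br <- simulate_breath(mechanics_params(30, 10, 5),
#'                       ventilator_settings(hold_duration = 2))
#' interrupter_crs(br)$c_rs_ref  # ~ 30
#' @export
interrupter_crs <- function(breath, peep_e = NULL, plateau_window = 0.2) {
  stopifnot(inherits(breath, "breath_tracing"))
  vr_check(isTRUE(breath$has_hold) && !is.na(breath$hold_start),
           "breath has no end-inspiratory hold", "missing_hold")
  if (is.null(peep_e)) {
    peep_e <- breath$meta$settings$peep_e
    vr_check(!is.null(peep_e),
             "peep_e not supplied and absent from tracing metadata",
             "invalid_parameter")
  }
  fs <- breath$sample_rate
  n_w <- max(1L, round(plateau_window * fs))
  hold_idx <- breath$hold_start:breath$hold_end
  vr_check(length(hold_idx) >= n_w,
           sprintf("hold (%d samples) shorter than plateau window (%d samples)",
                   length(hold_idx), n_w),
           "missing_hold")
  win <- hold_idx[(length(hold_idx) - n_w + 1):length(hold_idx)]
  p_plat <- mean(breath$paw[win])
  v_t <- breath$volume[breath$hold_end]
  vr_check(p_plat > peep_e,
           sprintf("non-physical plateau: P_plat = %.3g <= PEEPe = %.3g cmH2O",
                   p_plat, peep_e),
           "non_physical_plateau")
  structure(list(c_rs_ref = 1000 * v_t / (p_plat - peep_e),
                 p_plat = p_plat, v_t = v_t, peep_e = peep_e),
            class = "reference_compliance")
}

#' @export
print.reference_compliance <- function(x, ...) {
  cat(sprintf("<reference_compliance> C_RS = %.4g ml/cmH2O (P_plat %.4g, V_T %.4g L, PEEPe %.4g)\n",
              x$c_rs_ref, x$p_plat, x$v_t, x$peep_e))
  invisible(x)
}
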