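#' Multilinear fit of the equation of motion
#'
#' Ordinary least-squares estimation of compliance, resistance and PEEP from
#' a breath's sampled pressure, volume and flow, under the first-order model
#' \deqn{P_{aw} = (1 / C_{RS}) V + R_{RS} V' + PEEP.}
#' The regression is plain unweighted OLS with no outlier rejection: the fit
#' uses whatever pressure values are present, including zeroed (disconnected)
#' or noise-corrupted samples. That fidelity to the unmodified method is
#' deliberate — it is exactly what makes the estimator fragile under sensor
#' disconnection, which the robustness sweep quantifies.
#'
#' A fitted elastance that is zero or negative yields a non-physical
#' (negative or enormous) compliance; such fits are returned flagged, not
#' rejected, so that wild estimates propagate into the error statistics the
#' way a naive monitor would report them.
#'
#' @param breath A `breath_tracing`.
#' @param window Sample range to fit, as an inclusive `c(first, last)` pair
#'   of 1-based indices. Default `NULL` fits the whole breath (inspiration
#'   plus expiration), which averages compliance over the breath; pass
#'   `c(breath$insp_start, breath$insp_end - 1)` for inspiratory-only fitting.
#'
#' @return An object of class `mlf_fit` with fields `c_rs` (ml/cmH2O),
#'   `r_rs` (cmH2O/(L/s)), `peep` (cmH2O), `params_hat` (a
#'   `mechanics_params`, unvalidated when non-physical), `non_physical`
#'   (logical), `residual_rms` (cmH2O), `n_samples` and `window`.
#' @examples
#' br <- simulate_breath(mechanics_params(30, 10, 5), ventilator_settings())
#' mlf_fit(br)$c_rs  # 30 to machine precision
#' @export
mlf_fit <- function(breath, window = NULL) {
  stopifnot(inherits(breath, "breath_tracing"))
  n <- length(breath$paw)
  if (is.null(window)) window <- c(1L, n)
  vr_check(is.numeric(window) && length(window) == 2 &&
             window[1] >= 1 && window[2] <= n && window[2] >= window[1],
           "window must be an inclusive c(first, last) range inside the breath",
           "invalid_parameter")
  idx <- seq.int(window[1], window[2])
  vr_check(length(idx) >= 3, "at least 3 samples are needed (three unknowns)",
           "singular_fit")
  x <- cbind(intercept = 1, volume = breath$volume[idx], flow = breath$flow[idx])
  fit <- stats::lm.fit(x, breath$paw[idx])
  if (fit$rank < 3L)
    vr_stop("design matrix (volume, flow, intercept) is rank-deficient",
            "singular_fit")
  coefs <- fit$coefficients
  elastance <- coefs[["volume"]]          # cmH2O/L
  c_rs <- 1000 / elastance                # ml/cmH2O; sign propagates
  non_physical <- !is.finite(c_rs) || elastance <= 0
  structure(
    list(c_rs = c_rs,
         r_rs = coefs[["flow"]],
         peep = coefs[["intercept"]],
         params_hat = mechanics_params(c_rs, coefs[["flow"]], coefs[["intercept"]],
                                       validate = FALSE),
         non_physical = non_physical,
         residual_rms = sqrt(mean(fit$residuals^2)),
         n_samples = length(idx),
         window = as.integer(window)),
    class = "mlf_fit")
}

#' @export
print.mlf_fit <- function(x, ...) {
  cat(sprintf("<mlf_fit> C_RS = %.4g ml/cmH2O, R_RS = %.4g cmH2O/(L/s), PEEP = %.4g cmH2O\n",
              x$c_rs, x$r_rs, x$peep))
  cat(sprintf("  %d samples (window %d-%d), residual RMS %.3g cmH2O%s\n",
              x$n_samples, x$window[1], x$window[2], x$residual_rms,
              if (x$non_physical) "  [non-physical elastance]" else ""))
  invisible(x)
}

#' Compliance estimate from the multilinear fit
#'
#' Estimator facade used by the robustness sweep: fits [mlf_fit()] over its
#' default window (the whole breath) and returns the compliance estimate,
#' including non-physical values, which the sweep must propagate.
#'
#' @param breath A `breath_tracing`.
#' @param window Optional fitting window, as in [mlf_fit()].
#' @return Compliance estimate in ml/cmH2O (possibly negative or huge when
#'   the fitted elastance is non-physical).
#' @export
mlf_estimate_crs <- function(breath, window = NULL) {
  mlf_fit(breath, window = window)$c_rs
}
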