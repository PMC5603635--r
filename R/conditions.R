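# Classed conditions so callers can distinguish failure modes programmatically.

vr_stop <- function(msg, class, call = sys.call(-1)) {
  stop(errorCondition(msg, class = c(paste0("ventrobust_", class), "ventrobust_error"),
                      call = call))
}

vr_check <- function(cond, msg, class) {
  if (!isTRUE(cond)) vr_stop(msg, class, call = sys.call(-2))
  invisible(TRUE)
}
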