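# Classed conditions so callers can distinguish assay-definition problems,
# amplification failures, uncallable band patterns, parameter errors, ...
cg_abort <- function(message, class, call = sys.call(-1)) {
  stop(errorCondition(
    message,
    class = c(paste0("cgassoc_", class), "cgassoc_error"),
    call = call
  ))
}

cg_warn <- function(message, class) {
  warning(warningCondition(
    message,
    class = c(paste0("cgassoc_", class), "cgassoc_warning")
  ))
}
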