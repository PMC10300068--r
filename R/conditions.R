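# Classed conditions so callers can handle specific failure modes
# (tryCatch(..., signcite_not_found = ...)) instead of matching messages.

sc_abort <- function(message, class, ..., call = NULL) {
  stop(errorCondition(message, ..., class = c(class, "signcite_error"),
                      call = call))
}

sc_warn <- function(message, class) {
  warning(warningCondition(message, class = c(class, "signcite_warning")))
}
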