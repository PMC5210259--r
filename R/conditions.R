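# Structured error conditions. Every user-facing failure carries a
# freebed_* class so callers (and the CLI) can react without parsing messages.

fb_stop <- function(class, msg, ...) {
  stop(errorCondition(msg, ..., class = c(class, "freebed_error")))
}

fb_warn <- function(class, msg, ...) {
  warning(warningCondition(msg, ..., class = c(class, "freebed_warning")))
}
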