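# Internal condition helpers: every validation failure gets a distinct class so
# callers (and tests) can distinguish e.g. an unknown decision label from an
# orphan reference without parsing messages.

refersdt_abort <- function(message, class, call = sys.call(-1)) {
  stop(structure(
    class = c(class, "refersdt_error", "error", "condition"),
    list(message = message, call = call)
  ))
}

`%||%` <- function(x, y) if (is.null(x)) y else x
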