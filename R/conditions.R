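# Classed conditions so callers can distinguish bad input from a
# mathematically undefined index value.

nf_stop <- function(class, message) {
  cond <- structure(
    class = c(class, "nemafauna_error", "error", "condition"),
    list(message = message, call = NULL)
  )
  stop(cond)
}

# Undefined index values (zero denominators and the like) are signalled as a
# distinct condition class; `index_table()` catches these and records the
# reason instead of aborting.
nf_undefined <- function(subclass, message) {
  cond <- structure(
    class = c(subclass, "nema_undefined", "nemafauna_error", "error", "condition"),
    list(message = message, call = NULL)
  )
  stop(cond)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
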