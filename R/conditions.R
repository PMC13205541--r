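# Structured error conditions. Every user-facing failure is one of four
# classes so callers (and the command-line wrapper) can map them to exit codes:
# validation (bad data), input (unreadable file), config (bad settings),
# generation (synthetic generator could not satisfy its spec).

stop_fviq <- function(msg, class) {
  stop(errorCondition(msg, class = c(class, "fviq_error")))
}

stop_validation <- function(msg) stop_fviq(msg, "fviq_validation_error")
stop_input      <- function(msg) stop_fviq(msg, "fviq_input_error")
stop_config     <- function(msg) stop_fviq(msg, "fviq_config_error")
stop_generation <- function(msg) stop_fviq(msg, "fviq_generation_error")

# Degenerate-ROI errors are a flavour of validation error: the data are not
# wrong, but an automatic threshold cannot be computed and a manual override
# is required.
stop_degenerate_roi <- function(msg) {
  stop(errorCondition(
    msg,
    class = c("fviq_degenerate_roi", "fviq_validation_error", "fviq_error")
  ))
}
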