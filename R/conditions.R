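# Classed conditions so callers (and tests) can distinguish failure modes.

raman_abort <- function(msg, class, call = sys.call(-1)) {
  stop(structure(
    class = c(class, "raman_error", "error", "condition"),
    list(message = msg, call = call)
  ))
}

abort_schema     <- function(msg) raman_abort(msg, "raman_schema_error")
abort_structural <- function(msg) raman_abort(msg, "raman_structural_error")
abort_vocab      <- function(msg) raman_abort(msg, "raman_vocab_error")
abort_param      <- function(msg) raman_abort(msg, "raman_param_error")
abort_config     <- function(msg) raman_abort(msg, "raman_config_error")
abort_calibration <- function(msg) raman_abort(msg, "raman_calibration_error")
abort_degenerate <- function(msg) raman_abort(msg, "raman_degenerate_error")
abort_range      <- function(msg) raman_abort(msg, "raman_range_error")
abort_contract   <- function(msg) raman_abort(msg, "raman_contract_error")
abort_insufficient <- function(msg) raman_abort(msg, "raman_insufficient_data_error")
abort_leakage    <- function(msg) raman_abort(msg, "raman_leakage_error")
abort_task       <- function(msg) raman_abort(msg, "raman_task_error")
abort_io         <- function(msg) raman_abort(msg, "raman_io_error")
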