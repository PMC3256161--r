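# Classed conditions so callers (and the CLI) can map failures to error
# classes without parsing messages.
fc_error <- function(class, msg, ...) {
  stop(errorCondition(msg, ..., class = c(class, "fretcssr_error")))
}

fc_usage_error     <- function(msg, ...) fc_error("fretcssr_usage_error", msg, ...)
fc_config_error    <- function(msg, ...) fc_error("fretcssr_config_error", msg, ...)
fc_data_error      <- function(msg, ...) fc_error("fretcssr_data_error", msg, ...)
fc_partition_error <- function(msg, ...) fc_error("fretcssr_partition_error", msg, ...)
fc_inference_error <- function(msg, ...) fc_error("fretcssr_inference_error", msg, ...)
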