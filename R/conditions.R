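# Classed error conditions so callers (and the CLI) can distinguish user input
# problems from data-integrity problems without parsing messages.

cm_abort <- function(message, class) {
  stop(errorCondition(message, class = c(class, "cohortmapr_error")))
}

abort_format    <- function(message) cm_abort(message, "cohortmapr_format_error")
abort_integrity <- function(message) cm_abort(message, "cohortmapr_integrity_error")
abort_lookup    <- function(message) cm_abort(message, "cohortmapr_lookup_error")
abort_argument  <- function(message) cm_abort(message, "cohortmapr_argument_error")
abort_capacity  <- function(message) cm_abort(message, "cohortmapr_capacity_error")
abort_state     <- function(message) cm_abort(message, "cohortmapr_state_error")
abort_training  <- function(message) cm_abort(message, "cohortmapr_training_error")
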