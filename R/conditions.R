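# Internal condition constructors. All user-facing failures are classed so
# callers (and the CLI) can distinguish malformed input from contract misuse.

stop_parse <- function(msg, call = sys.call(-1)) {
  stop(structure(class = c("lincr_parse_error", "lincr_error", "error", "condition"),
                 list(message = msg, call = call)))
}

stop_input <- function(msg, call = sys.call(-1)) {
  stop(structure(class = c("lincr_input_error", "lincr_error", "error", "condition"),
                 list(message = msg, call = call)))
}

stop_contract <- function(msg, call = sys.call(-1)) {
  stop(structure(class = c("lincr_contract_error", "lincr_error", "error", "condition"),
                 list(message = msg, call = call)))
}
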