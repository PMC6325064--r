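# Condition helpers.  Invalid geometry / configuration raises a
# "memtopo_invalid_spec" condition; violated call contracts (mismatched
# provenance, degenerate windows) raise "memtopo_contract_error".

stop_invalid_spec <- function(...) {
  stop(errorCondition(paste0(...),
                      class = c("memtopo_invalid_spec", "memtopo_error")))
}

stop_contract <- function(...) {
  stop(errorCondition(paste0(...),
                      class = c("memtopo_contract_error", "memtopo_error")))
}

check_count <- function(x, name, min = 1L) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x != as.integer(x) ||
      x < min) {
    stop_invalid_spec(name, " must be a single integer >= ", min,
                      " (got ", deparse(x), ")")
  }
  as.integer(x)
}
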