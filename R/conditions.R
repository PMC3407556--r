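# Classed conditions so callers can distinguish failure modes programmatically.
# Every pseudophy error inherits from "pseudophy_error" plus a specific class,
# e.g. "pseudophy_alignment_error".

stop_pseudophy <- function(class, message, ...) {
  extra <- list(...)
  cond <- structure(
    class = c(paste0("pseudophy_", class), "pseudophy_error",
              "error", "condition"),
    c(list(message = message, call = sys.call(-1)), extra)
  )
  stop(cond)
}

`%||%` <- function(x, y) if (is.null(x)) y else x
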