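# internal helpers

`%||%` <- function(a, b) if (is.null(a)) b else a

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

# recursive modifyList that keeps defaults for keys the user omits
deep_merge <- function(base, override) {
  if (is.null(override)) return(base)
  stopifnot(is.list(base), is.list(override))
  for (nm in names(override)) {
    if (is.list(base[[nm]]) && is.list(override[[nm]]) &&
        !is.null(names(base[[nm]]))) {
      base[[nm]] <- deep_merge(base[[nm]], override[[nm]])
    } else {
      base[[nm]] <- override[[nm]]
    }
  }
  base
}

stop_wgdt <- function(..., class = "wgdt_error") {
  stop(structure(
    class = c(class, "error", "condition"),
    list(message = paste0(...), call = sys.call(-1))
  ))
}

# g C per umol CO2
C_PER_UMOL <- 12e-6
# g C per g glucose
GLUCOSE_C_FRAC <- 0.4
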