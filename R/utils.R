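#' @keywords internal
"_PACKAGE"

# Error helper: classed conditions so callers can catch specific failures.
fb_stop <- function(msg, class) {
  stop(errorCondition(msg, class = c(class, "fragbam_error", "error")))
}

fb_warn <- function(msg, class = "fragbam_warning") {
  warning(warningCondition(msg, class = c(class, "warning")))
}

is_count <- function(x) {
  length(x) == 1L && is.numeric(x) && !is.na(x) && x == as.integer(x)
}

# Derive an independent 31-bit RNG seed for (seed, stream label) so each
# sample of a cohort gets its own reproducible stream.
derive_seed <- function(seed, label) {
  h <- as.double(seed %% 2147483647L)
  for (code in utf8ToInt(as.character(label))) {
    h <- (h * 31 + code) %% 2147483647
  }
  as.integer(h)
}
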