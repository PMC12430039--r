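# internal helpers shared across modules

`%||%` <- function(a, b) if (is.null(a)) b else a

abort_sleepdmpm <- function(msg, class, ...) {
  rlang::abort(msg, class = c(class, "sleepdmpm_error"), ...)
}

assert_scalar_count <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x <= 0 || x != round(x)) {
    abort_sleepdmpm(sprintf("`%s` must be a single positive integer.", name),
                    "sleepdmpm_domain_error")
  }
  as.integer(x)
}

# stable log1p(exp(x))
log1pexp <- function(x) {
  out <- numeric(length(x))
  big <- x > 35
  out[big] <- x[big]
  out[!big] <- log1p(exp(x[!big]))
  out
}

# equal-tailed 90% interval bounds used throughout
ci_probs <- c(0.05, 0.95)
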