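# Internal helpers: error classes, deterministic seed derivation, hashing.

abort_agemark <- function(message, class, ...) {
  rlang::abort(message, class = c(class, "agemark_error"), ...)
}

stop_validation <- function(message, ...) abort_agemark(message, "agemark_validation_error", ...)
stop_format <- function(message, ...) abort_agemark(message, "agemark_format_error", ...)
stop_parameter <- function(message, ...) abort_agemark(message, "agemark_parameter_error", ...)

# Deterministic 31-bit child seed from a master seed and an arbitrary key
# path.  Hash-based so that per-run and per-cutoff streams never collide and
# never depend on evaluation order.
derive_seed <- function(seed, ...) {
  key <- paste(c(format(seed), vapply(list(...), format, character(1))), collapse = "/")
  hex <- substr(rlang::hash(key), 1, 7)
  strtoi(hex, base = 16L) %% .Machine$integer.max
}

# Semantic hash of a configuration list: order-independent in names, stable
# across sessions (used in reproducibility headers).
config_hash <- function(config) {
  config <- config[order(names(config))]
  rlang::hash(lapply(config, function(x) if (is.numeric(x)) format(x, digits = 15) else x))
}

`%theninform%` <- function(cond, msg) if (isTRUE(cond)) rlang::inform(msg) else invisible(NULL)
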