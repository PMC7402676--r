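# Internal helpers shared across modules.

#' Stop with a schema error that names the offending file, row and field
#' @noRd
schema_abort <- function(msg, file = NULL, row = NULL, field = NULL) {
  loc <- c(
    if (!is.null(file)) paste0("file: ", file),
    if (!is.null(row)) paste0("row: ", paste(row, collapse = ", ")),
    if (!is.null(field)) paste0("field: ", field)
  )
  abort(c(msg, loc), class = "littermix_schema_error")
}

#' @noRd
check_number <- function(x, name, lower = -Inf, upper = Inf,
                         allow_na = FALSE, strict_lower = FALSE) {
  if (!is.numeric(x)) abort(sprintf("`%s` must be numeric.", name))
  bad <- if (allow_na) x[!is.na(x)] else x
  if (!allow_na && anyNA(x)) abort(sprintf("`%s` must not contain NA.", name))
  low_ok <- if (strict_lower) all(bad > lower) else all(bad >= lower)
  if (!low_ok || !all(bad <= upper)) {
    abort(sprintf(
      "`%s` must lie in %s%s, %s]: got %s.",
      name, if (strict_lower) "(" else "[", format(lower), format(upper),
      paste(format(utils::head(bad[bad < lower | bad > upper |
        (strict_lower & bad <= lower)], 3)), collapse = ", ")
    ))
  }
  invisible(x)
}

# Structured one-line log records on stderr; silenced via
# options(littermix.quiet = TRUE).
log_note <- function(stage, msg) {
  if (isTRUE(getOption("littermix.quiet", FALSE))) return(invisible(NULL))
  message(sprintf("[littermix:%s] %s", stage, msg))
  invisible(NULL)
}

# sample() that never interprets a length-1 x as 1:x
resample <- function(x, size, replace = FALSE, prob = NULL) {
  x[sample.int(length(x), size, replace = replace, prob = prob)]
}

# deterministic sub-seed derivation, kept below .Machine$integer.max
derive_seed <- function(seed, offset) {
  as.integer((as.numeric(seed) * 48271 + offset) %% 2147483647L)
}
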