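# Structured condition classes. Every package error inherits from
# "primerwalk_error" plus one specific subclass, so callers (and the batch
# runner) can branch on expect_error(class = ...) / tryCatch without string
# matching on messages.

pw_stop <- function(class, msg, call. = FALSE, ...) {
  cnd <- errorCondition(msg, ..., class = c(class, "primerwalk_error"))
  stop(cnd)
}

#' @keywords internal
pw_check_dna <- function(sequence, what = "sequence", min_len = 1L,
                         allow_empty = FALSE) {
  if (!is.character(sequence) || length(sequence) != 1L || is.na(sequence))
    pw_stop("pw_alphabet_error",
            sprintf("%s must be a single character string", what))
  if (!nzchar(sequence)) {
    if (allow_empty) return(invisible(sequence))
    pw_stop("pw_length_error", sprintf("%s must be non-empty", what))
  }
  bad <- unique(strsplit(gsub("[ACGT]", "", sequence), "")[[1]])
  if (length(bad))
    pw_stop("pw_alphabet_error",
            sprintf("%s contains non-ACGT characters: %s", what,
                    paste(sQuote(bad), collapse = ", ")),
            offending = bad)
  if (nchar(sequence) < min_len)
    pw_stop("pw_length_error",
            sprintf("%s must be at least %d nt long (got %d)", what,
                    min_len, nchar(sequence)))
  invisible(sequence)
}

pw_check_number <- function(x, what, min = -Inf, strict_min = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    pw_stop("pw_parameter_error", sprintf("%s must be a finite number", what))
  ok <- if (strict_min) x > min else x >= min
  if (!ok)
    pw_stop("pw_parameter_error",
            sprintf("%s must be %s %g (got %g)", what,
                    if (strict_min) ">" else ">=", min, x))
  invisible(x)
}
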