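# FASTA input, primer FASTA/CSV output.

#' Read a multi-FASTA file of templates
#'
#' Records are normalized: lowercase is uppercased and line breaks and
#' whitespace inside the body are removed. The alphabet is strictly
#' A/C/G/T — ambiguity codes (N, R, Y, ...) would make the melting
#' temperature undefined, so they are rejected loudly with the offending
#' record ids rather than silently skipped.
#'
#' @param path path to a FASTA file.
#' @return data.frame with columns `id` (first whitespace-delimited header
#'   token), `description` (header remainder, possibly empty), `sequence`.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path))
    pw_stop("pw_fasta_format_error", sprintf("file not found: %s", path))
  first <- Filter(nzchar, trimws(readLines(path, n = 50L, warn = FALSE)))
  if (!length(first) || !startsWith(first[1L], ">"))
    pw_stop("pw_fasta_format_error",
            sprintf("%s does not start with a '>' header line", path))
  # BStringSet (not DNAStringSet) so alphabet violations are reported per
  # record below instead of as a parser error
  set <- tryCatch(Biostrings::readBStringSet(path),
                  error = function(e)
                    pw_stop("pw_fasta_format_error",
                            sprintf("cannot parse %s: %s", path,
                                    conditionMessage(e))))
  headers <- names(set)
  ids <- sub("\\s.*$", "", headers)
  desc <- trimws(sub("^\\S*\\s*", "", headers))
  seqs <- toupper(gsub("[[:space:]]", "", as.character(set)))
  if (any(!nzchar(ids)))
    pw_stop("pw_fasta_format_error",
            sprintf("%s has a record with an empty id", path))
  if (any(!nzchar(seqs)))
    pw_stop("pw_fasta_format_error",
            sprintf("empty sequence body for record(s): %s",
                    paste(ids[!nzchar(seqs)], collapse = ", ")))
  bad <- vapply(seqs, function(s) grepl("[^ACGT]", s), TRUE,
                USE.NAMES = FALSE)
  if (any(bad)) {
    chars <- unique(unlist(strsplit(gsub("[ACGT]", "", seqs[bad]), "")))
    pw_stop("pw_alphabet_error",
            sprintf("non-ACGT characters (%s) in record(s): %s",
                    paste(sQuote(chars), collapse = ", "),
                    paste(ids[bad], collapse = ", ")),
            records = ids[bad], offending = chars)
  }
  data.frame(id = ids, description = desc, sequence = unname(seqs),
             stringsAsFactors = FALSE)
}

as_pair_list <- function(x) {
  if (inherits(x, "primer_design")) x$pairs
  else if (inherits(x, "primer_pair")) list(x)
  else if (is.list(x) && all(vapply(x, inherits, TRUE, "primer_pair"))) x
  else pw_stop("pw_parameter_error",
               "expected a primer_design, a primer_pair, or a list of primer_pair")
}

#' Write designed primers as FASTA
#'
#' Each pair becomes two records named `<record_id>_F` and `<record_id>_R`
#' containing the full primer sequences (extension + annealing region).
#'
#' @param x a `primer_design`, a `primer_pair`, or a list of `primer_pair`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_primers_fasta <- function(x, path) {
  pairs <- as_pair_list(x)
  seqs <- unlist(lapply(pairs, function(p)
    stats::setNames(c(p$forward_full, p$reverse_full),
                    paste0(p$record_id, c("_F", "_R")))))
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(seqs), path)
  invisible(path)
}

#' Tabulate a design as a report data.frame
#'
#' One row per primer plus one row per failed record. Fixed column order:
#' `record_id`, `status`, `orientation`, `full_sequence`,
#' `annealing_sequence`, `extension`, `annealing_length`, `tm_celsius`
#' (2 decimals), `ends_gc`, `warnings`, `diagnostic`.
#'
#' @param x a `primer_design` (or pairs as in [write_primers_fasta()]).
#' @return data.frame in the column order above.
#' @export
primers_table <- function(x) {
  pairs <- as_pair_list(x)
  failures <- if (inherits(x, "primer_design")) x$failures else list()
  row1 <- function(p, orient) {
    cand <- p[[orient]]
    ext <- if (orient == "forward") p$ext_forward else p$ext_reverse
    full <- if (orient == "forward") p$forward_full else p$reverse_full
    data.frame(record_id = p$record_id, status = "ok",
               orientation = orient, full_sequence = full,
               annealing_sequence = cand$annealing_seq, extension = ext,
               annealing_length = cand$length,
               tm_celsius = round(cand$tm, 2), ends_gc = cand$ends_gc,
               warnings = paste(p$warnings, collapse = "; "),
               diagnostic = "", stringsAsFactors = FALSE)
  }
  rows <- lapply(pairs, function(p) rbind(row1(p, "forward"),
                                          row1(p, "reverse")))
  frows <- lapply(failures, function(f)
    data.frame(record_id = f$record_id, status = "failed",
               orientation = NA_character_, full_sequence = NA_character_,
               annealing_sequence = NA_character_, extension = NA_character_,
               annealing_length = NA_integer_, tm_celsius = NA_real_,
               ends_gc = NA, warnings = "", diagnostic = f$message,
               stringsAsFactors = FALSE))
  out <- do.call(rbind, c(rows, frows))
  if (is.null(out)) out <- row1(pairs[[1]], "forward")[0, ]
  rownames(out) <- NULL
  out
}

#' Write the primer report as CSV
#'
#' UTF-8, '.' decimal separator, '\n' newlines; columns as documented in
#' [primers_table()]. Failed records appear with `status = "failed"` and a
#' diagnostic (including the nearest achievable Tm).
#'
#' @inheritParams primers_table
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_primers_csv <- function(x, path) {
  utils::write.csv(primers_table(x), path, row.names = FALSE,
                   fileEncoding = "UTF-8", na = "")
  invisible(path)
}

#' Write a data.frame of records as FASTA
#'
#' @param records data.frame with `id`, `sequence` (and optional
#'   `description`).
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(records, path) {
  stopifnot(is.data.frame(records),
            all(c("id", "sequence") %in% names(records)))
  nm <- records$id
  if (!is.null(records$description)) {
    has <- nzchar(records$description)
    nm[has] <- paste(records$id[has], records$description[has])
  }
  Biostrings::writeXStringSet(
    Biostrings::DNAStringSet(stats::setNames(records$sequence, nm)), path)
  invisible(path)
}
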