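# Boundary-anchored primer design.
#
# Amplicon boundaries are fixed at the template ends (single-nucleotide
# precision), so the only freedom is how far each primer walks into the
# template. The walker evaluates every allowed length at each end, keeps the
# candidates whose Tm falls inside the tolerance window, and ranks them
# under the user's constraints.

#' Design constraints for a primer pair
#'
#' @param tm_optimal target melting temperature (Celsius).
#' @param tm_tolerance half-width of the acceptance window (Celsius);
#'   candidates with |Tm - tm_optimal| <= tm_tolerance are valid. The
#'   default 5 matches the common practice of annealing 5 C below the
#'   target.
#' @param force_gc_clamp prefer candidates whose 3' end is G or C; if no
#'   in-window candidate has a G/C clamp the best unclamped one is returned
#'   with a warning, never a refusal.
#' @param ext_forward,ext_reverse 5' extension sequences (may be empty)
#'   prepended verbatim to the forward/reverse primers; they carry cloning
#'   features and never enter the Tm calculation.
#' @param min_len,max_len bounds (nt) on the annealing-region length the
#'   walker explores.
#' @return object of class `design_spec`.
#' @examples
#' design_spec(tm_optimal = 60)
#' @export
design_spec <- function(tm_optimal = 60, tm_tolerance = 5,
                        force_gc_clamp = TRUE,
                        ext_forward = "", ext_reverse = "",
                        min_len = 15L, max_len = 40L) {
  pw_check_number(tm_optimal, "tm_optimal")
  pw_check_number(tm_tolerance, "tm_tolerance", min = 0, strict_min = TRUE)
  pw_check_number(min_len, "min_len", min = 2)
  pw_check_number(max_len, "max_len", min = min_len)
  stopifnot(is.logical(force_gc_clamp), length(force_gc_clamp) == 1L)
  pw_check_dna(ext_forward, "ext_forward", allow_empty = TRUE)
  pw_check_dna(ext_reverse, "ext_reverse", allow_empty = TRUE)
  structure(list(tm_optimal = tm_optimal, tm_tolerance = tm_tolerance,
                 force_gc_clamp = force_gc_clamp,
                 ext_forward = ext_forward, ext_reverse = ext_reverse,
                 min_len = as.integer(min_len),
                 max_len = as.integer(max_len)),
            class = "design_spec")
}

#' Reverse complement of a DNA string
#'
#' @param sequence DNA string over A/C/G/T (empty allowed).
#' @return the Watson-Crick complement, reversed.
#' @examples
#' reverse_complement("ACGT")
#' @export
reverse_complement <- function(sequence) {
  pw_check_dna(sequence, allow_empty = TRUE)
  if (!nzchar(sequence)) return(sequence)
  paste(rev(strsplit(chartr("ACGT", "TGCA", sequence), "",
                     fixed = TRUE)[[1]]), collapse = "")
}

ends_gc <- function(sequence) {
  substring(sequence, nchar(sequence), nchar(sequence)) %in% c("G", "C")
}

#' Enumerate boundary-anchored primer candidates
#'
#' Walks one end of the template: for each length L from `min_len` to
#' `min(max_len, template length)` the boundary-anchored candidate (template
#' prefix for the forward orientation; reverse complement of the template
#' suffix for the reverse orientation) is evaluated, and those whose Tm lies
#' within the tolerance window are returned in order of increasing length.
#'
#' @param template DNA string (A/C/G/T), at least `min_len` long.
#' @param orientation `"forward"` or `"reverse"`.
#' @param spec a [design_spec()].
#' @param params an [nn_params()] set.
#' @param buffer a [buffer_conditions()] object.
#' @param salt_coef,mg_coef passed to [melting_temperature()].
#' @return data.frame with columns `annealing_seq`, `length`, `tm`,
#'   `ends_gc`, `orientation` (in-window candidates only). The attribute
#'   `"evaluated"` holds the (length, tm) of every candidate examined, so a
#'   caller can report the nearest achievable Tm when the window is
#'   unreachable.
#' @export
enumerate_candidates <- function(template,
                                 orientation = c("forward", "reverse"),
                                 spec = design_spec(),
                                 params = nn_params(),
                                 buffer = buffer_conditions(),
                                 salt_coef = 0.368, mg_coef = 120) {
  orientation <- match.arg(orientation)
  pw_check_dna(template, "template")
  n <- nchar(template)
  if (n < spec$min_len)
    pw_stop("pw_template_too_short_error",
            sprintf("template (%d nt) is shorter than min_len = %d", n,
                    spec$min_len))
  lens <- spec$min_len:min(spec$max_len, n)
  seqs <- if (orientation == "forward") {
    substring(template, 1L, lens)
  } else {
    vapply(substring(template, n - lens + 1L, n), reverse_complement, "",
           USE.NAMES = FALSE)
  }
  tms <- vapply(seqs, tm_celsius, 0, params = params, buffer = buffer,
                salt_coef = salt_coef, mg_coef = mg_coef, USE.NAMES = FALSE)
  keep <- abs(tms - spec$tm_optimal) <= spec$tm_tolerance
  out <- data.frame(annealing_seq = seqs[keep], length = lens[keep],
                    tm = tms[keep], ends_gc = ends_gc(seqs[keep]),
                    orientation = rep(orientation, sum(keep)),
                    stringsAsFactors = FALSE, row.names = NULL)
  attr(out, "evaluated") <- data.frame(length = lens, tm = tms)
  out
}

#' Rank candidates and pick the best primer
#'
#' Candidates are scored by closeness of Tm to the optimum. With the G/C
#' clamp forced, clamped candidates are preferred whenever at least one is
#' in the window; if none is, the closest-Tm candidate is returned with an
#' advisory warning rather than a refusal. Ties on |Tm - optimum| break to
#' the shorter candidate (cheaper synthesis), then to the G/C-clamped one.
#'
#' @param candidates data.frame from [enumerate_candidates()].
#' @param spec a [design_spec()].
#' @return list with `candidate` (a one-row data.frame) and `warnings`
#'   (character vector, possibly empty).
#' @export
rank_and_pick <- function(candidates, spec = design_spec()) {
  if (is.null(candidates) || nrow(candidates) == 0L)
    pw_stop("pw_no_candidate_error",
            "no candidate within the melting-temperature window")
  warnings <- character()
  pool <- candidates
  if (spec$force_gc_clamp) {
    if (any(candidates$ends_gc)) {
      pool <- candidates[candidates$ends_gc, , drop = FALSE]
    } else {
      warnings <- "no G/C clamp available in the tolerance window"
    }
  }
  dtm <- abs(pool$tm - spec$tm_optimal)
  ord <- order(dtm, pool$length, !pool$ends_gc)
  list(candidate = pool[ord[1L], , drop = FALSE], warnings = warnings)
}

pick_orientation <- function(template, orientation, spec, params, buffer,
                             salt_coef, mg_coef, auto_widen = NULL) {
  cands <- enumerate_candidates(template, orientation, spec, params, buffer,
                                salt_coef, mg_coef)
  widened <- NULL
  if (nrow(cands) == 0L && !is.null(auto_widen) && auto_widen > 0) {
    tol <- spec$tm_tolerance
    while (nrow(cands) == 0L && tol < 50) {
      tol <- tol + auto_widen
      wspec <- spec
      wspec$tm_tolerance <- tol
      cands <- enumerate_candidates(template, orientation, wspec, params,
                                    buffer, salt_coef, mg_coef)
    }
    if (nrow(cands) > 0L) widened <- tol
  }
  if (nrow(cands) == 0L) {
    ev <- attr(cands, "evaluated")
    nearest <- ev$tm[which.min(abs(ev$tm - spec$tm_optimal))]
    pw_stop("pw_no_candidate_error",
            sprintf("%s: no candidate within %.1f +/- %.1f C; nearest achievable Tm is %.2f C",
                    orientation, spec$tm_optimal, spec$tm_tolerance, nearest),
            nearest_tm = nearest, orientation = orientation)
  }
  pick <- rank_and_pick(cands, spec)
  if (!is.null(widened))
    pick$warnings <- c(pick$warnings,
                       sprintf("%s: tolerance widened to %.1f C to reach a candidate",
                               orientation, widened))
  pick
}

#' Design the primer pair for one template
#'
#' Runs the candidate walk and ranking for both ends of the template, then
#' prepends the 5' extensions. By construction the amplicon implied by the
#' pair is exactly the input template.
#'
#' @param id record identifier.
#' @param template DNA string.
#' @inheritParams enumerate_candidates
#' @param auto_widen optional step (Celsius): when no candidate falls in the
#'   window, widen the tolerance iteratively by this step (progressive
#'   constraint release) instead of failing; a warning records the final
#'   tolerance. `NULL` (default) fails with a diagnostic that reports the
#'   nearest achievable Tm.
#' @return object of class `primer_pair`: `record_id`, `forward_full`,
#'   `reverse_full`, `forward`/`reverse` (the chosen candidates), and
#'   `warnings`.
#' @export
design_pair <- function(id, template, spec = design_spec(),
                        params = nn_params(), buffer = buffer_conditions(),
                        salt_coef = 0.368, mg_coef = 120,
                        auto_widen = NULL) {
  picks <- tryCatch(
    list(forward = pick_orientation(template, "forward", spec, params,
                                    buffer, salt_coef, mg_coef, auto_widen),
         reverse = pick_orientation(template, "reverse", spec, params,
                                    buffer, salt_coef, mg_coef, auto_widen)),
    primerwalk_error = function(e) {
      pw_stop("pw_design_failure",
              sprintf("record '%s': %s", id, conditionMessage(e)),
              record_id = id, parent = e,
              nearest_tm = if (!is.null(e$nearest_tm)) e$nearest_tm else NA_real_)
    })
  fwd <- picks$forward$candidate
  rev <- picks$reverse$candidate
  structure(list(
    record_id = id,
    forward_full = paste0(spec$ext_forward, fwd$annealing_seq),
    reverse_full = paste0(spec$ext_reverse, rev$annealing_seq),
    forward = fwd,
    reverse = rev,
    ext_forward = spec$ext_forward,
    ext_reverse = spec$ext_reverse,
    warnings = c(picks$forward$warnings, picks$reverse$warnings)
  ), class = "primer_pair")
}

#' @export
print.primer_pair <- function(x, ...) {
  cat(sprintf("Primer pair for '%s'\n", x$record_id))
  cat(sprintf("  F: %s  (anneal %d nt, Tm %.2f C%s)\n", x$forward_full,
              x$forward$length, x$forward$tm,
              if (x$forward$ends_gc) ", G/C clamp" else ""))
  cat(sprintf("  R: %s  (anneal %d nt, Tm %.2f C%s)\n", x$reverse_full,
              x$reverse$length, x$reverse$tm,
              if (x$reverse$ends_gc) ", G/C clamp" else ""))
  for (w in x$warnings) cat("  warning:", w, "\n")
  invisible(x)
}

#' Design primers for a batch of templates
#'
#' Order-preserving map of [design_pair()] over the records; per-record
#' design failures are collected, never raised, so one undesignable record
#' does not abort a library run.
#'
#' @param records data.frame with columns `id` and `sequence` (as returned
#'   by [read_fasta()]), or a named character vector of sequences.
#' @inheritParams design_pair
#' @return object of class `primer_design`: list with `pairs` (list of
#'   `primer_pair`) and `failures` (list of `record_id`/`message`/
#'   `nearest_tm`).
#' @examples
#' recs <- data.frame(id = "demo",
#'                    sequence = paste(rep("ATGACCATGATTACGGATTCACT", 10),
#'                                     collapse = ""))
#' design_batch(recs, design_spec(tm_optimal = 60))
#' @export
design_batch <- function(records, spec = design_spec(),
                         params = nn_params(), buffer = buffer_conditions(),
                         salt_coef = 0.368, mg_coef = 120,
                         auto_widen = NULL) {
  if (is.character(records))
    records <- data.frame(id = names(records), sequence = unname(records),
                          stringsAsFactors = FALSE)
  stopifnot(is.data.frame(records), all(c("id", "sequence") %in%
                                          names(records)))
  if (nrow(records) < 1L)
    pw_stop("pw_parameter_error", "batch needs at least one record")
  dup <- unique(records$id[duplicated(records$id)])
  if (length(dup))
    pw_stop("pw_duplicate_id_error",
            sprintf("duplicate record ids: %s", paste(dup, collapse = ", ")))
  pairs <- list()
  failures <- list()
  for (i in seq_len(nrow(records))) {
    res <- tryCatch(
      design_pair(records$id[i], records$sequence[i], spec, params, buffer,
                  salt_coef, mg_coef, auto_widen),
      pw_design_failure = function(e) e)
    if (inherits(res, "primer_pair")) {
      pairs[[length(pairs) + 1L]] <- res
    } else {
      failures[[length(failures) + 1L]] <-
        list(record_id = records$id[i], message = conditionMessage(res),
             nearest_tm = if (!is.null(res$nearest_tm)) res$nearest_tm
                          else NA_real_)
    }
  }
  structure(list(pairs = pairs, failures = failures, spec = spec),
            class = "primer_design")
}

#' @export
print.primer_design <- function(x, ...) {
  cat(sprintf("Primer design: %d pair(s), %d failure(s)\n",
              length(x$pairs), length(x$failures)))
  for (p in x$pairs) print(p)
  for (f in x$failures) cat(sprintf("  FAILED %s: %s\n", f$record_id,
                                    f$message))
  invisible(x)
}

#' Summarise a batch design
#'
#' @param object a `primer_design`.
#' @param ... unused.
#' @return the [primers_table()] data.frame, invisibly.
#' @method summary primer_design
#' @export
summary.primer_design <- function(object, ...) {
  tab <- primers_table(object)
  cat(sprintf("Designed %d/%d records (Tm target %.1f +/- %.1f C)\n",
              length(object$pairs),
              length(object$pairs) + length(object$failures),
              object$spec$tm_optimal, object$spec$tm_tolerance))
  ok <- tab[tab$status == "ok", ]
  if (nrow(ok))
    cat(sprintf("Annealing length %d-%d nt, Tm %.2f-%.2f C, %d/%d with G/C clamp\n",
                min(ok$annealing_length), max(ok$annealing_length),
                min(ok$tm_celsius), max(ok$tm_celsius),
                sum(ok$ends_gc), nrow(ok)))
  invisible(tab)
}
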