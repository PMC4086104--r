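#' Nearest-neighbour thermodynamic parameter sets
#'
#' Loads a table of dinucleotide-stack enthalpies and entropies plus duplex
#' initiation terms. Two tables ship with the package, transcribed from the
#' primary literature: the SantaLucia (1998) "unified" parameters (with
#' per-terminal A/T and G/C initiation corrections) and the Breslauer et al.
#' (1986) parameters (single entropic initiation term). Users may point
#' `path` at their own table in the same TSV layout, e.g. to substitute a
#' recalibrated set.
#'
#' All energies are in calorie units: enthalpies in cal/mol, entropies in
#' cal/(mol K). Stacks are keyed by the 5'-to-3' top-strand dinucleotide;
#' the duplex partner is the perfect Watson-Crick complement.
#'
#' @param name `"santalucia"` (default) or `"breslauer"`; ignored when
#'   `path` is given except as the label of the returned set.
#' @param path optional path to a user-supplied parameter TSV with columns
#'   `type` (`stack`, `init`, `term_AT`, `term_GC`), `key`, `dH_cal_mol`,
#'   `dS_cal_molK`.
#' @return An object of class `nn_params`: a list with elements `name`,
#'   `stack_dH`, `stack_dS` (named numeric vectors over the 16 stacks),
#'   `init_dH`, `init_dS`, and `terminal` (a list with `AT` and `GC`
#'   two-element `c(dH, dS)` vectors, possibly zero).
#' @examples
#' p <- nn_params("santalucia")
#' p$stack_dH[["CG"]]
#' @export
nn_params <- function(name = c("santalucia", "breslauer"), path = NULL) {
  if (is.null(path)) {
    name <- match.arg(name)
    file <- switch(name,
                   santalucia = "nn_santalucia1998.tsv",
                   breslauer  = "nn_breslauer1986.tsv")
    path <- system.file("extdata", file, package = "primerwalk",
                        mustWork = TRUE)
  } else {
    if (!file.exists(path))
      pw_stop("pw_parameter_error",
              sprintf("parameter table not found: %s", path))
    name <- if (length(name) == 1L) name else
      sub("\\.[^.]*$", "", basename(path))
  }
  tab <- utils::read.delim(path, comment.char = "#",
                           stringsAsFactors = FALSE)
  need <- c("type", "key", "dH_cal_mol", "dS_cal_molK")
  if (!all(need %in% names(tab)))
    pw_stop("pw_parameter_error",
            sprintf("parameter table %s lacks columns: %s", path,
                    paste(setdiff(need, names(tab)), collapse = ", ")))
  st <- tab[tab$type == "stack", ]
  stack_dH <- stats::setNames(st$dH_cal_mol, st$key)
  stack_dS <- stats::setNames(st$dS_cal_molK, st$key)
  pick <- function(type, col) {
    row <- tab[tab$type == type, ]
    if (nrow(row)) row[[col]][1] else 0
  }
  obj <- structure(list(
    name     = name,
    stack_dH = stack_dH,
    stack_dS = stack_dS,
    init_dH  = pick("init", "dH_cal_mol"),
    init_dS  = pick("init", "dS_cal_molK"),
    terminal = list(
      AT = c(dH = pick("term_AT", "dH_cal_mol"),
             dS = pick("term_AT", "dS_cal_molK")),
      GC = c(dH = pick("term_GC", "dH_cal_mol"),
             dS = pick("term_GC", "dS_cal_molK")))
  ), class = "nn_params")
  validate_nn_params(obj)
}

ALL_STACKS <- as.vector(outer(c("A", "C", "G", "T"), c("A", "C", "G", "T"),
                              paste0))

validate_nn_params <- function(p) {
  missing <- setdiff(ALL_STACKS, names(p$stack_dH))
  if (length(missing))
    pw_stop("pw_parameter_error",
            sprintf("parameter set '%s' is missing stacks: %s", p$name,
                    paste(missing, collapse = ", ")))
  if (any(p$stack_dH >= 0))
    pw_stop("pw_parameter_error",
            sprintf("parameter set '%s' has non-negative stack enthalpies (duplex formation must be exothermic)",
                    p$name))
  p
}

#' @export
print.nn_params <- function(x, ...) {
  cat(sprintf("Nearest-neighbour parameter set '%s'\n", x$name))
  cat(sprintf("  16 stacks; init dH = %g cal/mol, dS = %g cal/(mol K)\n",
              x$init_dH, x$init_dS))
  if (any(unlist(x$terminal) != 0))
    cat(sprintf("  terminal corrections: A/T (%g, %g), G/C (%g, %g)\n",
                x$terminal$AT[["dH"]], x$terminal$AT[["dS"]],
                x$terminal$GC[["dH"]], x$terminal$GC[["dS"]]))
  invisible(x)
}
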