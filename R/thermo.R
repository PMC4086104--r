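# Nearest-neighbour melting-temperature engine.
#
# Tm (in Kelvin) = dH / (dS_salt_corrected - R * ln K), where dH and dS are
# the nearest-neighbour sums for the perfect-match duplex, the entropy is
# corrected for the monovalent-equivalent cation concentration, and K is the
# duplex equilibrium constant at the melting midpoint (its form depends on
# the strand-concentration regime; see buffer_conditions()).

#' Gas constant in cal/(mol K)
#' @export
R_GAS <- 1.9872

#' Nearest-neighbour enthalpy/entropy sum
#'
#' Sums duplex-initiation terms plus one stack term per adjacent
#' dinucleotide of the sequence, for the duplex the sequence forms with its
#' perfect Watson-Crick complement. Terminal corrections (if the parameter
#' set defines them) are applied once per end according to the closing base
#' pair.
#'
#' @param sequence DNA string, strictly A/C/G/T, length >= 2.
#' @param params an [nn_params()] parameter set.
#' @return list with `dH` (cal/mol) and `dS` (cal/(mol K)).
#' @examples
#' nn_sum("ACGTG", nn_params("santalucia"))
#' @export
nn_sum <- function(sequence, params = nn_params()) {
  pw_check_dna(sequence, min_len = 2L)
  bases <- strsplit(sequence, "", fixed = TRUE)[[1]]
  n <- length(bases)
  stacks <- paste0(bases[-n], bases[-1L])
  dH <- params$init_dH + sum(params$stack_dH[stacks])
  dS <- params$init_dS + sum(params$stack_dS[stacks])
  for (end in bases[c(1L, n)]) {
    term <- if (end %in% c("A", "T")) params$terminal$AT else params$terminal$GC
    dH <- dH + term[["dH"]]
    dS <- dS + term[["dS"]]
  }
  list(dH = unname(dH), dS = unname(dS))
}

#' Entropic salt correction
#'
#' Adjusts the nearest-neighbour entropy for the ionic strength of the
#' buffer: `dS + coef * n_stacks * ln(monovalent_eq in mol/L)`. At 1 M
#' monovalent equivalent the correction vanishes; below 1 M the entropy
#' becomes more negative (duplexes are less stable at low salt). The default
#' coefficient 0.368 cal/(mol K) is the SantaLucia entropic form; it is
#' exposed so recalibrated coefficient sets can be substituted.
#'
#' @param dS_raw uncorrected entropy, cal/(mol K).
#' @param n_stacks number of phosphate/stack units the correction scales
#'   with; [melting_temperature()] passes `length - 1` for an N-mer.
#' @param monovalent_eq_mM monovalent-equivalent cation concentration (mM),
#'   must be positive.
#' @param coef correction coefficient, cal/(mol K) per stack.
#' @return corrected entropy, cal/(mol K).
#' @export
salt_correct <- function(dS_raw, n_stacks, monovalent_eq_mM, coef = 0.368) {
  if (!is.numeric(monovalent_eq_mM) || length(monovalent_eq_mM) != 1L ||
      !is.finite(monovalent_eq_mM) || monovalent_eq_mM <= 0)
    pw_stop("pw_salt_error",
            "monovalent-equivalent concentration must be > 0 mM")
  dS_raw + coef * n_stacks * log(monovalent_eq_mM / 1000)
}

#' Melting temperature of a primer/template duplex
#'
#' Composes the nearest-neighbour sum, the monovalent-equivalent
#' conversion, the entropic salt correction and the equilibrium constant
#' into the two-state melting temperature. The calculation concerns the
#' annealing region only: 5' extensions never enter it, because candidate
#' selection targets the first PCR cycles in which only the annealing
#' region pairs with the template.
#'
#' @inheritParams nn_sum
#' @param buffer a [buffer_conditions()] object.
#' @param salt_coef coefficient for [salt_correct()].
#' @param mg_coef coefficient for [monovalent_equivalent()].
#' @return An object of class `thermo_result`: list with `tm_celsius`,
#'   `dH_total` (cal/mol), `dS_raw`, `dS_total` (salt-corrected,
#'   cal/(mol K)), `K` (1/M), `monovalent_eq_mM`, `k_mode`, and `sequence` —
#'   all intermediates recorded for audit.
#' @examples
#' melting_temperature("ATGACCATGATTACGGATTC",
#'                     buffer = buffer_conditions(monovalent_mM = 50))
#' @export
melting_temperature <- function(sequence, params = nn_params(),
                                buffer = buffer_conditions(),
                                salt_coef = 0.368, mg_coef = 120) {
  ns <- nn_sum(sequence, params)
  mon <- monovalent_equivalent(buffer, mg_coef = mg_coef)
  dS_corr <- salt_correct(ns$dS, nchar(sequence) - 1L, mon, coef = salt_coef)
  K <- equilibrium_constant(buffer)
  denom <- dS_corr - R_GAS * log(K)
  if (denom >= 0)
    pw_stop("pw_numerical_error",
            sprintf("non-melting duplex: dS - R ln K = %.3f >= 0 for '%s'",
                    denom, sequence))
  tm_K <- ns$dH / denom
  structure(list(
    sequence = sequence,
    dH_total = ns$dH,
    dS_raw = ns$dS,
    dS_total = dS_corr,
    K = K,
    monovalent_eq_mM = mon,
    k_mode = buffer$k_mode,
    tm_celsius = tm_K - 273.15
  ), class = "thermo_result")
}

#' @export
print.thermo_result <- function(x, ...) {
  cat(sprintf("Tm = %.2f C  (%d-mer, K mode '%s')\n", x$tm_celsius,
              nchar(x$sequence), x$k_mode))
  cat(sprintf("  dH = %g cal/mol, dS = %.2f cal/(mol K) after salt correction (%.1f mM mono-eq)\n",
              x$dH_total, x$dS_total, x$monovalent_eq_mM))
  cat(sprintf("  K = %.3g 1/M\n", x$K))
  invisible(x)
}

# scalar convenience used throughout design/validation
tm_celsius <- function(sequence, params, buffer, salt_coef = 0.368,
                       mg_coef = 120) {
  melting_temperature(sequence, params, buffer, salt_coef, mg_coef)$tm_celsius
}

#' Empirical melting-temperature formula
#'
#' Length/GC/salt closed form, provided as an alternative to the
#' nearest-neighbour engine:
#' `Tm = 81.5 + 16.6 log10(mono_eq M) + 0.41 GC% - 675/N`.
#' Useful as a fast cross-check; less accurate than the thermodynamic model
#' for short oligos.
#'
#' @inheritParams melting_temperature
#' @return Tm in degrees Celsius.
#' @export
empirical_tm <- function(sequence, buffer = buffer_conditions(),
                         mg_coef = 120) {
  pw_check_dna(sequence, min_len = 2L)
  mon_M <- monovalent_equivalent(buffer, mg_coef = mg_coef) / 1000
  if (mon_M <= 0)
    pw_stop("pw_salt_error",
            "monovalent-equivalent concentration must be > 0 mM")
  n <- nchar(sequence)
  gc_pct <- 100 * lengths(regmatches(sequence,
                                     gregexpr("[GC]", sequence))) / n
  81.5 + 16.6 * log10(mon_M) + 0.41 * gc_pct - 675 / n
}
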