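#' Buffer conditions for melting-temperature calculation
#'
#' Bundles the ionic content of the PCR buffer and the strand concentrations
#' that parameterize the salt correction and the duplex equilibrium constant.
#'
#' `k_mode` selects how the equilibrium constant K at the melting midpoint
#' is formed from the strand concentrations:
#' \describe{
#'   \item{`symmetric`}{K = 4/\[Primer\] — the equal-strand-concentration
#'     regime in which most nearest-neighbour parameters were measured, and
#'     the formula used by most online calculators.}
#'   \item{`excess_exact`}{1/K = \[Primer\] − \[Template\]/2 — the
#'     excess-primer regime of the first PCR cycles, where primer vastly
#'     outnumbers template.}
#'   \item{`excess_simplified`}{K = 1/\[Primer\] — the limit of
#'     `excess_exact` when template is negligible (typically three orders of
#'     magnitude below primer at the start of a PCR). Default here, because
#'     custom-buffer melting temperatures are most often wanted for the
#'     early, template-limited cycles.}
#' }
#'
#' @param monovalent_mM Na+/K+-class monovalent cation concentration (mM).
#' @param tris_mM Tris buffer concentration (mM); roughly half of it counts
#'   as monovalent cation in the equivalent-concentration conversion.
#' @param divalent_mM Mg2+ concentration (mM).
#' @param dntp_mM total dNTP concentration (mM, summed over the four
#'   nucleotides); Mg2+ chelated by dNTPs is subtracted before the divalent
#'   term contributes.
#' @param primer_M primer concentration (mol/L), must be positive.
#' @param template_M template concentration (mol/L).
#' @param k_mode one of `"excess_simplified"`, `"symmetric"`,
#'   `"excess_exact"`.
#' @return An object of class `buffer_conditions`.
#' @examples
#' buffer_conditions(monovalent_mM = 50, primer_M = 5e-7)
#' @export
buffer_conditions <- function(monovalent_mM = 50, tris_mM = 0,
                              divalent_mM = 0, dntp_mM = 0,
                              primer_M = 5e-7, template_M = 5e-10,
                              k_mode = c("excess_simplified", "symmetric",
                                         "excess_exact")) {
  k_mode <- match.arg(k_mode)
  pw_check_number(monovalent_mM, "monovalent_mM", min = 0)
  pw_check_number(tris_mM, "tris_mM", min = 0)
  pw_check_number(divalent_mM, "divalent_mM", min = 0)
  pw_check_number(dntp_mM, "dntp_mM", min = 0)
  pw_check_number(primer_M, "primer_M", min = 0, strict_min = TRUE)
  pw_check_number(template_M, "template_M", min = 0)
  structure(list(monovalent_mM = monovalent_mM, tris_mM = tris_mM,
                 divalent_mM = divalent_mM, dntp_mM = dntp_mM,
                 primer_M = primer_M, template_M = template_M,
                 k_mode = k_mode),
            class = "buffer_conditions")
}

#' @export
print.buffer_conditions <- function(x, ...) {
  cat(sprintf(
    "Buffer: %g mM monovalent, %g mM Tris, %g mM Mg2+, %g mM dNTP\n",
    x$monovalent_mM, x$tris_mM, x$divalent_mM, x$dntp_mM))
  cat(sprintf("  primer %.3g M, template %.3g M, K mode '%s'\n",
              x$primer_M, x$template_M, x$k_mode))
  cat(sprintf("  monovalent equivalent: %.1f mM\n", monovalent_equivalent(x)))
  invisible(x)
}

#' Monovalent-equivalent cation concentration
#'
#' Folds monovalent ions, the Tris cation contribution, and free Mg2+ into
#' one effective monovalent concentration for the salt correction:
#' `monovalent + tris/2 + mg_coef * sqrt(max(0, divalent - dNTP))` (all mM).
#' Mg2+ chelated by dNTPs does not stabilize the duplex, so total dNTP is
#' subtracted from Mg2+ first and the difference clamps at zero.
#'
#' @param buffer a [buffer_conditions()] object.
#' @param mg_coef coefficient of the square-root divalent term
#'   (default 120, the standard conversion).
#' @return concentration in mM.
#' @examples
#' monovalent_equivalent(buffer_conditions(monovalent_mM = 50,
#'                                         divalent_mM = 2, dntp_mM = 0.8))
#' @export
monovalent_equivalent <- function(buffer, mg_coef = 120) {
  stopifnot(inherits(buffer, "buffer_conditions"))
  free_mg <- max(0, buffer$divalent_mM - buffer$dntp_mM)
  buffer$monovalent_mM + buffer$tris_mM / 2 + mg_coef * sqrt(free_mg)
}

#' Duplex equilibrium constant at the melting midpoint
#'
#' @param buffer a [buffer_conditions()] object; `buffer$k_mode` selects the
#'   formulation (see [buffer_conditions()]).
#' @return K in 1/M.
#' @examples
#' equilibrium_constant(buffer_conditions(primer_M = 2.5e-7,
#'                                        k_mode = "symmetric"))
#' @export
equilibrium_constant <- function(buffer) {
  stopifnot(inherits(buffer, "buffer_conditions"))
  switch(buffer$k_mode,
    symmetric = 4 / buffer$primer_M,
    excess_simplified = 1 / buffer$primer_M,
    excess_exact = {
      denom <- buffer$primer_M - buffer$template_M / 2
      if (denom <= 0)
        pw_stop("pw_kmode_error",
                sprintf("excess_exact K undefined: primer %.3g M must exceed template/2 = %.3g M",
                        buffer$primer_M, buffer$template_M / 2))
      1 / denom
    })
}

#' Buffer preset registry
#'
#' Loads the bundled polymerase-buffer presets and optionally merges a
#' user-supplied YAML file on top (user presets override bundled ones of the
#' same name). Every preset carries a `provenance_note` documenting how its
#' ionic values were derived; values for proprietary commercial buffers are
#' estimates.
#'
#' @param user_file optional path to a YAML file with the same `presets:`
#'   layout as the bundled `inst/extdata/buffer_presets.yaml`.
#' @return A named list of presets; each has `name`, `conditions`
#'   (a [buffer_conditions()] object) and `provenance_note`.
#' @examples
#' names(buffer_presets())
#' @export
buffer_presets <- function(user_file = NULL) {
  bundled <- system.file("extdata", "buffer_presets.yaml",
                         package = "primerwalk", mustWork = TRUE)
  reg <- parse_preset_file(bundled)
  if (!is.null(user_file)) {
    if (!file.exists(user_file))
      pw_stop("pw_parameter_error",
              sprintf("preset file not found: %s", user_file))
    for (p in parse_preset_file(user_file)) reg[[p$name]] <- p
  }
  reg
}

parse_preset_file <- function(path) {
  raw <- yaml::read_yaml(path)
  if (is.null(raw$presets))
    pw_stop("pw_parameter_error",
            sprintf("%s has no top-level 'presets' list", path))
  out <- list()
  for (p in raw$presets) {
    if (is.null(p$name) || !nzchar(p$name))
      pw_stop("pw_parameter_error",
              sprintf("a preset in %s has no name", path))
    cond <- buffer_conditions(
      monovalent_mM = p$monovalent_mM %||% 0,
      tris_mM = p$tris_mM %||% 0,
      divalent_mM = p$divalent_mM %||% 0,
      dntp_mM = p$dntp_mM %||% 0,
      primer_M = p$primer_M %||% 5e-7,
      template_M = p$template_M %||% 5e-10,
      k_mode = p$k_mode %||% "symmetric")
    out[[p$name]] <- list(name = p$name, conditions = cond,
                          provenance_note = trimws(p$provenance_note %||% ""))
  }
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Resolve a buffer by preset name
#'
#' @param name preset name (see [buffer_presets()]).
#' @param registry a preset registry; defaults to the bundled one.
#' @return the preset's [buffer_conditions()].
#' @export
resolve_buffer <- function(name, registry = buffer_presets()) {
  if (!name %in% names(registry))
    pw_stop("pw_preset_not_found_error",
            sprintf("unknown buffer preset '%s'; available: %s", name,
                    paste(names(registry), collapse = ", ")))
  registry[[name]]$conditions
}
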