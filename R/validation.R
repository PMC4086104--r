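# Validation harness: regress experimental melting temperatures on
# predicted ones, and generate the synthetic fixtures the test surface uses.

default_benchmark_columns <- c("monovalent_mM", "tris_mM", "divalent_mM",
                               "dntp_mM", "primer_M", "template_M", "k_mode")

benchmark_buffer <- function(row) {
  buffer_conditions(
    monovalent_mM = row$monovalent_mM %||% 50,
    tris_mM = row$tris_mM %||% 0,
    divalent_mM = row$divalent_mM %||% 0,
    dntp_mM = row$dntp_mM %||% 0,
    primer_M = row$primer_M %||% 5e-7,
    template_M = row$template_M %||% 5e-10,
    k_mode = row$k_mode %||% "excess_simplified")
}

#' Benchmark predicted against experimental melting temperatures
#'
#' Predicts the Tm of each benchmark oligo under its own buffer conditions
#' and fits the ordinary least-squares regression of experimental on
#' predicted values. A slope near 1, intercept near 0 and r-squared near 1
#' indicate a well-calibrated engine. Records whose prediction fails (e.g.
#' invalid alphabet) are excluded with a warning.
#'
#' @param records data.frame with columns `sequence` and `tm_experimental`;
#'   optional per-record buffer columns `monovalent_mM`, `tris_mM`,
#'   `divalent_mM`, `dntp_mM`, `primer_M`, `template_M`, `k_mode` (defaults
#'   used where absent). Such a table of experimental oligo meltings can be
#'   supplied by the user as a CSV; it is never required.
#' @param params an [nn_params()] set.
#' @param method `"nn"` (nearest-neighbour engine) or `"empirical"` (the
#'   closed-form [empirical_tm()]).
#' @param salt_coef,mg_coef engine coefficients.
#' @return object of class `tm_benchmark`: `n`, `slope`, `intercept`,
#'   `r_squared`, `rmse`, and a `data` frame with per-record `predicted`,
#'   `tm_experimental` and `residual`.
#' @export
tm_benchmark <- function(records, params = nn_params(),
                         method = c("nn", "empirical"),
                         salt_coef = 0.368, mg_coef = 120) {
  method <- match.arg(method)
  stopifnot(is.data.frame(records),
            all(c("sequence", "tm_experimental") %in% names(records)))
  if (nrow(records) < 2L)
    pw_stop("pw_insufficient_data_error",
            "benchmark needs at least 2 records")
  pred <- rep(NA_real_, nrow(records))
  for (i in seq_len(nrow(records))) {
    row <- as.list(records[i, , drop = FALSE])
    pred[i] <- tryCatch({
      buf <- benchmark_buffer(row)
      if (method == "nn")
        tm_celsius(row$sequence, params, buf, salt_coef, mg_coef)
      else
        empirical_tm(row$sequence, buf, mg_coef)
    }, primerwalk_error = function(e) {
      warning(sprintf("benchmark record %d excluded: %s", i,
                      conditionMessage(e)), call. = FALSE)
      NA_real_
    })
  }
  ok <- is.finite(pred) & is.finite(records$tm_experimental)
  if (sum(ok) < 2L)
    pw_stop("pw_insufficient_data_error",
            sprintf("only %d usable record(s) after prediction", sum(ok)))
  x <- pred[ok]
  y <- records$tm_experimental[ok]
  if (stats::var(x) == 0)
    pw_stop("pw_insufficient_data_error",
            "degenerate fit: zero variance in predicted Tm")
  fit <- stats::lm(y ~ x)
  res <- stats::residuals(fit)
  structure(list(
    n = sum(ok),
    slope = unname(stats::coef(fit)[2L]),
    intercept = unname(stats::coef(fit)[1L]),
    # a noise-free self-benchmark is a legitimate input; silence lm's
    # perfect-fit advisory
    r_squared = suppressWarnings(summary(fit)$r.squared),
    rmse = sqrt(mean(res^2)),
    method = method,
    params_name = params$name,
    data = data.frame(predicted = x, tm_experimental = y, residual = res)
  ), class = "tm_benchmark")
}

#' @export
print.tm_benchmark <- function(x, ...) {
  cat(sprintf("Tm benchmark (%s, %s table): n = %d\n", x$method,
              x$params_name, x$n))
  cat(sprintf("  slope %.4f, intercept %.3f C, r^2 %.4f, RMSE %.3f C\n",
              x$slope, x$intercept, x$r_squared, x$rmse))
  invisible(x)
}

#' Scatter plot of a Tm benchmark
#'
#' Experimental vs predicted Tm with the identity line (dashed) and the
#' fitted regression (solid).
#'
#' @param x a [tm_benchmark()] result.
#' @param ... passed to [plot()].
#' @return `x`, invisibly.
#' @method plot tm_benchmark
#' @export
plot.tm_benchmark <- function(x, ...) {
  plot(x$data$predicted, x$data$tm_experimental,
       xlab = "Predicted Tm (C)", ylab = "Experimental Tm (C)",
       main = sprintf("slope %.3f, r^2 %.3f", x$slope, x$r_squared), ...)
  graphics::abline(0, 1, lty = 2)
  graphics::abline(x$intercept, x$slope)
  invisible(x)
}

#' Benchmark every algorithm combination
#'
#' Systematically assays each (parameter table x K mode) combination on the
#' same benchmark records and tabulates the regression statistics, so the
#' best-calibrated combination can be chosen.
#'
#' @inheritParams tm_benchmark
#' @param tables character vector of [nn_params()] names.
#' @param k_modes character vector of K modes (overrides the per-record
#'   `k_mode`).
#' @return data.frame with one row per combination: `table`, `k_mode`,
#'   `n`, `slope`, `intercept`, `r_squared`, `rmse`.
#' @export
tm_benchmark_grid <- function(records,
                              tables = c("santalucia", "breslauer"),
                              k_modes = c("symmetric", "excess_exact",
                                          "excess_simplified"),
                              salt_coef = 0.368, mg_coef = 120) {
  grid <- expand.grid(table = tables, k_mode = k_modes,
                      stringsAsFactors = FALSE)
  rows <- lapply(seq_len(nrow(grid)), function(i) {
    recs <- records
    recs$k_mode <- grid$k_mode[i]
    b <- tm_benchmark(recs, nn_params(grid$table[i]),
                      salt_coef = salt_coef, mg_coef = mg_coef)
    data.frame(table = grid$table[i], k_mode = grid$k_mode[i], n = b$n,
               slope = b$slope, intercept = b$intercept,
               r_squared = b$r_squared, rmse = b$rmse,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

random_template <- function(length, gc_fraction) {
  n_gc <- round(gc_fraction * length)
  bases <- character(length)
  gc_pos <- sample.int(length, n_gc)
  bases[gc_pos] <- sample(c("G", "C"), n_gc, replace = TRUE)
  bases[-gc_pos] <- sample(c("A", "T"), length - n_gc, replace = TRUE)
  if (n_gc == length) bases <- sample(c("G", "C"), length, replace = TRUE)
  paste(bases, collapse = "")
}

#' Generate synthetic templates and benchmark fixtures
#'
#' Emits reproducible random ACGT templates with controlled GC content,
#' plus a benchmark table whose experimental Tm is the engine's own
#' prediction on a random subsequence perturbed by Gaussian noise — the
#' synthetic stand-in for an experimental melting dataset.
#'
#' @param n number of templates.
#' @param length_range two-element integer vector, template length bounds
#'   (nt), inclusive.
#' @param gc_range two-element numeric vector in `[0, 1]`, GC-fraction
#'   bounds; each template draws a fraction uniformly from this range and
#'   carries exactly `round(fraction * length)` G+C bases.
#' @param seed RNG seed; identical seeds give bitwise-identical output.
#' @param noise_sd standard deviation (Celsius) of the Gaussian noise added
#'   to the benchmark's "experimental" Tm.
#' @param oligo_length_range length bounds for the benchmark oligos.
#' @param params,buffer,salt_coef,mg_coef engine settings used for the
#'   benchmark predictions.
#' @param dir if non-NULL, also write `templates.fasta` and `benchmark.csv`
#'   into this directory.
#' @return list with `templates` (data.frame `id`, `sequence`) and
#'   `benchmark` (data.frame `sequence`, buffer columns,
#'   `tm_experimental`).
#' @examples
#' fx <- generate_fixtures(3, c(100, 200), c(0.4, 0.6), seed = 1)
#' nchar(fx$templates$sequence)
#' @export
generate_fixtures <- function(n, length_range = c(300L, 2000L),
                              gc_range = c(0.35, 0.55), seed = 1L,
                              noise_sd = 0.5,
                              oligo_length_range = c(18L, 25L),
                              params = nn_params(),
                              buffer = buffer_conditions(),
                              salt_coef = 0.368, mg_coef = 120,
                              dir = NULL) {
  if (!is.numeric(n) || n < 1)
    pw_stop("pw_parameter_error", "n must be >= 1")
  if (length(length_range) != 2L || any(length_range < 2) ||
      length_range[1] > length_range[2])
    pw_stop("pw_parameter_error", "invalid length_range")
  if (length(gc_range) != 2L || any(gc_range < 0) || any(gc_range > 1) ||
      gc_range[1] > gc_range[2])
    pw_stop("pw_parameter_error", "invalid gc_range")
  set.seed(seed)
  sample_range <- function(rng, n)
    rng[1] + sample.int(rng[2] - rng[1] + 1L, n, replace = TRUE) - 1L
  lens <- sample_range(length_range, n)
  gcs <- stats::runif(n, gc_range[1], gc_range[2])
  templates <- data.frame(
    id = sprintf("tpl_%03d", seq_len(n)),
    sequence = mapply(random_template, lens, gcs),
    stringsAsFactors = FALSE, row.names = NULL)
  oligo_lens <- pmin(sample_range(oligo_length_range, n), lens)
  oligos <- vapply(seq_len(n), function(i) {
    tpl <- templates$sequence[i]
    start <- sample.int(nchar(tpl) - oligo_lens[i] + 1L, 1L)
    substring(tpl, start, start + oligo_lens[i] - 1L)
  }, "")
  pred <- vapply(oligos, tm_celsius, 0, params = params, buffer = buffer,
                 salt_coef = salt_coef, mg_coef = mg_coef,
                 USE.NAMES = FALSE)
  benchmark <- data.frame(
    sequence = oligos,
    monovalent_mM = buffer$monovalent_mM, tris_mM = buffer$tris_mM,
    divalent_mM = buffer$divalent_mM, dntp_mM = buffer$dntp_mM,
    primer_M = buffer$primer_M, template_M = buffer$template_M,
    k_mode = buffer$k_mode,
    tm_experimental = pred + stats::rnorm(n, 0, noise_sd),
    stringsAsFactors = FALSE, row.names = NULL)
  if (!is.null(dir)) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    write_fasta(templates, file.path(dir, "templates.fasta"))
    utils::write.csv(benchmark, file.path(dir, "benchmark.csv"),
                     row.names = FALSE, fileEncoding = "UTF-8")
  }
  list(templates = templates, benchmark = benchmark)
}
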