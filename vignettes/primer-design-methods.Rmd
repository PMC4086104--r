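---
title: "Methods: boundary-anchored primer design and melting-temperature thermodynamics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: boundary-anchored primer design and melting-temperature thermodynamics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(primerwalk)
```

## The design problem

Single-nucleotide-precision cloning fixes both amplicon boundaries
exactly: the forward primer must begin at template position 1 and the
reverse primer must end at position N. The classical primer-design degrees
of freedom (sliding the primer, trimming the amplicon) are gone; the only
knob left is how far each primer reaches into the template. `primerwalk`
treats that knob exhaustively. For each end it evaluates the
boundary-anchored candidate of every length from `min_len` to `max_len`
(the template prefix for the forward primer; the reverse complement of the
template suffix for the reverse primer), keeps those whose melting
temperature falls inside `tm_optimal ± tm_tolerance`, and ranks the rest.
Because candidates are anchored by construction, every successful pair
implies exactly the input amplicon — the suite asserts this by stripping
the extensions and matching the template prefix/suffix literally.

When a library is amplified in one plate it is the *shared* annealing
temperature that matters, so the tolerance window is the central
constraint and the optimum is only a tie-breaker. Ranking is
lexicographic: (1) if `force_gc_clamp` is on and any in-window candidate
ends in G or C, restrict to those; (2) minimise |Tm − optimum|; (3) prefer
the shorter candidate (cheaper synthesis, fewer side reactions); (4)
prefer a clamped candidate. Steps 3–4 are this package's own tie-break
choices — nothing in the underlying method dictates an order among
near-equivalent candidates — and step 1 deliberately degrades to a warning
rather than a refusal when no clamped candidate exists: for batch work an
explicit advisory beats a silent hole in the plate. For the same reason a
record whose window is unreachable *fails loudly* with the nearest
achievable Tm in the diagnostic; the optional `auto_widen` step (off by
default) instead releases the tolerance iteratively, in the spirit of
progressive constraint release, and records the final tolerance as a
warning on the pair.

We enumerate the full `min_len:max_len` range rather than stopping at the
first exit from the window, because Tm is not strictly monotone in length
(an AT-rich extension can lower it), and the walk is cheap. Defaults
`min_len = 15`, `max_len = 40` bracket practical PCR primers; both are
exposed as arguments and CLI flags.

## Thermodynamic model

For a primer of length N forming a perfect-match duplex, enthalpy and
entropy are nearest-neighbour sums over the N−1 dinucleotide stacks plus
initiation terms. Two parameter tables ship as TSV data files (user
tables can be dropped in via `nn_params(path=)`):

* **SantaLucia 1998 "unified"** (default): strand-symmetric stack terms
  with per-terminal initiation — +2.3 kcal/mol, +4.1 cal/(mol K) for an
  A·T-closing end; +0.1 kcal/mol, −2.8 cal/(mol K) for a G·C end.
* **Breslauer 1986**: stack terms with a single entropic initiation of
  −10.8 cal/(mol K), the convention most implementations of that table
  use.

All units are calorie-based; the gas constant is R = 1.9872 cal/(mol K).
The melting temperature is the two-state midpoint

$$T_m = \frac{\Delta H^\circ}{\Delta S^\circ_{salt} - R \ln K} - 273.15.$$

**Salt correction.** The entropy is adjusted as
$\Delta S^\circ_{salt} = \Delta S^\circ + c\,(N-1)\ln[\mathrm{Mon^+}]$
with the monovalent-equivalent concentration in mol/L and the SantaLucia
entropic coefficient c = 0.368 cal/(mol K) per stack as default. The
coefficient is an explicit argument (`salt_coef`) so a recalibrated value
can be substituted without touching the engine; at 1 M the correction
vanishes identically (asserted to 1e-12 in the suite). The
monovalent-equivalent conversion is
`mono + tris/2 + 120·sqrt(max(0, Mg − dNTP))` (mM): half the Tris is
assumed protonated, and Mg²⁺ chelated by dNTPs is excluded before the
square-root term, clamping at zero. The 120 coefficient (`mg_coef`) is
likewise an argument.

**The equilibrium constant.** Most calculators assume equal strand
concentrations, K = 4/[Primer]; that is the regime in which the
nearest-neighbour parameters were measured. In the first PCR cycles,
though, primer is in vast excess over template and
1/K = [Primer] − [Template]/2; with template three orders of magnitude
below primer this simplifies to K = 1/[Primer] (relative error 5e-4 at
1000× excess, asserted analytically). At 0.5 µM primer the symmetric and
excess forms differ by ≈1.8 °C on random 18–25-mers — the acceptance
suite measures this mean gap and requires it in 1.5–2.5 °C. Custom
buffers default to `excess_simplified`; named presets default to
`symmetric` so their numbers stay comparable with the vendor calculators
users cross-check by hand. 5′ extensions are excluded from the Tm on
purpose: in the early cycles only the annealing region pairs with
genomic template, and in later cycles the full-length duplex melts higher
anyway, so the annealing region is the binding constraint.

**Degenerate inputs.** The engine is strict: length ≥ 2, alphabet exactly
{A,C,G,T} (lowercase is uppercased at the I/O boundary only), errors as
typed conditions (`pw_alphabet_error`, `pw_length_error`,
`pw_salt_error`, `pw_kmode_error`). A non-melting denominator
(ΔS − R ln K ≥ 0, reachable only with unphysical concentrations) raises
`pw_numerical_error` instead of returning a negative absolute
temperature. Mismatch and dangling-end corrections are not implemented: a
perfect-match duplex is assumed, which is exactly the situation of a
designed annealing region.

**An empirical alternative.** `empirical_tm()` provides the closed-form
`81.5 + 16.6·log10([Mon+]_eq) + 0.41·GC% − 675/N`. The precise empirical
formula and salt-coefficient recalibration used by the melting-curve
literature exist in several variants; this package fixes the variant
above and keeps both coefficients pluggable, which is the design decision
recorded here.

## Buffer presets

Exact ionic compositions of commercial high-fidelity buffers are
proprietary. The bundled presets therefore carry *estimated* values
assembled from typical protocol sheets, each with a `provenance_note`
saying so, and the registry merges a user YAML over the bundled file so a
lab that has measured its buffer can override any preset. Treat preset
Tms as comparable-within-preset rather than absolute.

## What the synthetic generator emulates — and what it does not

`generate_fixtures()` produces (a) random ACGT templates with length
drawn uniformly from `length_range` and an exact GC count of
`round(f·L)` with f uniform in `gc_range`, and (b) a benchmark table
whose "experimental" Tm is the engine's own prediction on a random
subsequence plus Gaussian noise of `noise_sd` (default 0.5 °C, a typical
inter-laboratory melting reproducibility). Everything is seeded and
bitwise reproducible.

The default template conditions — 61 records of 300–2000 nt at 35–55%
GC — mirror a realistic gene-library extraction batch: gene-sized
amplicons at typical genomic GC. Test problem sizes elsewhere in the
suite (100 templates of 40–500 nt for the walker oracle, 100 pairs for
the precision check, 200 records for the regression, 150 oligos for the
K-mode gap) were chosen as the package's own balance between statistical
stability and a fast default test run.

What passing on these fixtures does **not** show: real genomes have
repeats, homopolymers, extreme-GC islands and secondary structure that
uniform random sequence underrepresents, and the benchmark's noise model
is exchangeable Gaussian around the engine's *own* predictions — it
validates the regression harness and the pipeline plumbing, not the
thermodynamic tables themselves. Validating the tables requires a real
experimental melting dataset, which `tm_benchmark()` accepts as a plain
CSV (`sequence`, per-record buffer columns, `tm_experimental`) but which
is never required.

## Validation harness

`tm_benchmark()` regresses experimental on predicted Tm by ordinary least
squares (the natural choice when the experimental axis carries the
noise), reporting slope, intercept, r², RMSE and residuals;
`tm_benchmark_grid()` assays every parameter-table × K-mode combination
on the same records so the best-calibrated combination can be picked for
a given buffer. Records whose prediction fails are excluded with a
warning; fewer than two usable records, or zero variance in the
predictions, is an error rather than a silent NA fit. On noise-free
self-predictions the fit is exactly (slope 1, intercept 0, r² 1) to
1e-9, which the suite asserts.

## Known limitations

* No hairpin, self-dimer or cross-dimer screening, no genome-wide
  specificity check, and no multiplex compatibility scoring — the scope
  is boundary-anchored Tm-window design.
* Extensions are used verbatim; they are not validated against
  restriction sites or assembly grammars.
* Preset ionic values are estimates (above).
* Perfect-match, DNA-only duplexes; no RNA or mixed backbones.
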