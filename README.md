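# primerwalk

Batch design of PCR primers for **single-nucleotide-precision cloning**:
amplifying a segment whose boundaries are fixed exactly — a gene from start
to stop codon, a promoter, a shuffling fragment — so the only freedom left
to the designer is how far each primer extends into the template. That is
the situation of Gibson/GoldenGate assembly, DNA library construction and
DNA shuffling, where dozens of boundary-precise primer pairs carrying 5′
cloning extensions must be designed at once and amplified side by side in
one plate at one annealing temperature.

`primerwalk` is for experimentalists and pipeline authors doing that kind
of repetitive design. For each FASTA record it:

1. **walks** from both ends of the template, evaluating every
   boundary-anchored candidate from `min_len` to `max_len` nt;
2. **filters** candidates to the melting-temperature window
   `tm_optimal ± tm_tolerance`;
3. **ranks** the survivors — preferring a G/C 3′ clamp when requested, then
   closeness to the optimal Tm, then shorter length;
4. **attaches** the user's forward/reverse 5′ extensions verbatim (any
   assembly chemistry; extensions never enter the Tm).

## The melting-temperature model

Duplex formation is scored with the nearest-neighbour model: the enthalpy
and entropy of the perfect-match duplex are sums of dinucleotide stack
terms plus initiation terms,

    ΔH° = ΔH°_init + Σ_stacks ΔH°_stack,   ΔS° = ΔS°_init + Σ_stacks ΔS°_stack,

using either the SantaLucia (1998) unified table (default) or the
Breslauer (1986) table, both shipped as editable TSV data files. The
entropy is salt-corrected on a **monovalent-equivalent** cation
concentration that folds Na⁺/K⁺, Tris and dNTP-corrected free Mg²⁺ into
one number:

    [Mon⁺]_eq = [Mon⁺] + [Tris]/2 + 120·√max(0, [Mg²⁺] − [dNTP])   (mM)
    ΔS°_salt = ΔS° + 0.368·(N−1)·ln([Mon⁺]_eq in M)

and the melting temperature of an N-mer is

    Tm = ΔH° / (ΔS°_salt − R·ln K) − 273.15,   R = 1.9872 cal/(mol·K).

The equilibrium constant `K` depends on the strand-concentration regime —
the package's headline thermodynamic point:

| `k_mode` | K | regime |
|---|---|---|
| `symmetric` | 4/[Primer] | equal strand concentrations; what most online calculators assume |
| `excess_exact` | 1/([Primer] − [Template]/2) | primer in large excess over template — the first PCR cycles |
| `excess_simplified` | 1/[Primer] | the limit when template is ~1000× below primer (default for custom buffers) |

At typical PCR concentrations the symmetric and excess-primer forms differ
by about 2 °C, which matters when a whole library must anneal together.
Named polymerase-buffer presets (`q5`, `phusion_hf`, `taq_standard`) use
the symmetric form for compatibility with vendor calculators; their ionic
values are documented estimates (see each preset's `provenance_note`).

## Worked example

```r
library(primerwalk)

fx   <- generate_fixtures(3, c(300, 800), c(0.35, 0.55), seed = 11)
spec <- design_spec(tm_optimal = 60, tm_tolerance = 5,
                    ext_forward = "GGTCTCAGGAG",  # BsaI GoldenGate tail
                    ext_reverse = "GAATTCA")      # EcoRI tail
design_batch(fx$templates, spec)
#> Primer design: 3 pair(s), 0 failure(s)
#> Primer pair for 'tpl_001'
#>   F: GGTCTCAGGAGATTATGTGTTAGATGTGCATGTTTACACAAGATC  (anneal 34 nt, Tm 59.97 C, G/C clamp)
#>   R: GAATTCAGTATAGTCGAACGAAGTGCCCC  (anneal 22 nt, Tm 59.62 C, G/C clamp)
#> ...
```

Each line is one primer: the printed sequence is extension + annealing
region; the Tm (here all within 60 ± 5 °C) and length refer to the
annealing region only, and "G/C clamp" flags a G or C at the 3′ end. The
engine itself is one call:

```r
melting_temperature("ATGACCATGATTACGGATTC")
#> Tm = 52.16 C  (20-mer, K mode 'excess_simplified')
#>   dH = -151100 cal/mol, dS = -435.65 cal/(mol K) after salt correction (50.0 mM mono-eq)
#>   K = 2e+06 1/M
```

File-to-file runs (`run_design()`) write `<prefix>_primers.fasta`,
`<prefix>_report.csv` and a parameter log; a shell front end with
`design` / `benchmark` / `fixtures` subcommands ships at
`system.file("cli", "primerwalk.R", package = "primerwalk")`:

```sh
Rscript "$(Rscript -e 'cat(system.file("cli","primerwalk.R",package="primerwalk"))')" \
  design --in templates.fasta --out run1 --tm 60 --tol 5 --preset q5
```

Exit codes: 0 all records designed, 2 some failed (failures appear in the
CSV with the nearest achievable Tm), 1 fatal error.

Calibration can be checked against any experimental melting table with
`tm_benchmark()` (ordinary least squares of experimental on predicted Tm,
reporting slope/intercept/r²/RMSE) and `tm_benchmark_grid()`, which assays
every parameter-table × K-mode combination.

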