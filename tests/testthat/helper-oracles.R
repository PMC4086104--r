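# Independent brute-force oracles and random-sequence helpers shared by the
# suite. Each oracle re-derives its quantity by a deliberately different
# code path from the implementation it checks.

`%||%` <- function(a, b) if (is.null(a)) b else a

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# per-position loop over the printed table (vs the vectorized lookup)
naive_nn_sum <- function(sequence, params) {
  dH <- params$init_dH
  dS <- params$init_dS
  n <- nchar(sequence)
  for (i in seq_len(n - 1L)) {
    st <- substr(sequence, i, i + 1L)
    dH <- dH + params$stack_dH[[st]]
    dS <- dS + params$stack_dS[[st]]
  }
  for (i in c(1L, n)) {
    term <- if (substr(sequence, i, i) %in% c("A", "T"))
      params$terminal$AT else params$terminal$GC
    dH <- dH + term[["dH"]]
    dS <- dS + term[["dS"]]
  }
  list(dH = dH, dS = dS)
}

# all-lengths loop + filter (vs the walker)
naive_enumerate <- function(template, orientation, spec, params, buffer) {
  n <- nchar(template)
  rows <- list()
  for (L in spec$min_len:min(spec$max_len, n)) {
    s <- if (orientation == "forward") substr(template, 1L, L)
         else reverse_complement(substr(template, n - L + 1L, n))
    tm <- melting_temperature(s, params, buffer)$tm_celsius
    if (abs(tm - spec$tm_optimal) <= spec$tm_tolerance)
      rows[[length(rows) + 1L]] <- data.frame(
        annealing_seq = s, length = L, tm = tm,
        ends_gc = substr(s, L, L) %in% c("G", "C"),
        orientation = orientation, stringsAsFactors = FALSE)
  }
  if (length(rows)) {
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    out
  } else {
    data.frame(annealing_seq = character(), length = integer(),
               tm = numeric(), ends_gc = logical(),
               orientation = character(), stringsAsFactors = FALSE)
  }
}

strip_attrs <- function(df) {
  attr(df, "evaluated") <- NULL
  rownames(df) <- NULL
  df
}

# exhaustive pairwise comparison on the lexicographic key
# (|tm - optimal|, length, clamp-last), vs the single order() call
naive_pick <- function(candidates, spec) {
  pool <- candidates
  if (spec$force_gc_clamp && any(candidates$ends_gc))
    pool <- candidates[candidates$ends_gc, , drop = FALSE]
  key <- function(row) c(abs(row$tm - spec$tm_optimal), row$length,
                         as.numeric(!row$ends_gc))
  best <- pool[1L, , drop = FALSE]
  for (i in seq_len(nrow(pool))[-1L]) {
    a <- key(pool[i, , drop = FALSE])
    b <- key(best)
    for (k in 1:3) {
      if (a[k] < b[k]) {
        best <- pool[i, , drop = FALSE]
        break
      }
      if (a[k] > b[k]) break
    }
  }
  best
}

# random candidate table for ranking tests (not necessarily realizable
# sequences; rank_and_pick only reads tm / length / ends_gc)
random_candidates <- function(n, spec) {
  lens <- sample(spec$min_len:spec$max_len, n, replace = TRUE)
  seqs <- vapply(lens, random_dna, "")
  tms <- runif(n, spec$tm_optimal - spec$tm_tolerance,
               spec$tm_optimal + spec$tm_tolerance)
  data.frame(annealing_seq = seqs, length = lens, tm = tms,
             ends_gc = substr(seqs, lens, lens) %in% c("G", "C"),
             orientation = "forward", stringsAsFactors = FALSE)
}

std_buffer <- function(k_mode = "excess_simplified") {
  buffer_conditions(monovalent_mM = 50, primer_M = 5e-7,
                    template_M = 5e-10, k_mode = k_mode)
}
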