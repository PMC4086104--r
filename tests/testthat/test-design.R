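sl <- nn_params("santalucia")
buf <- std_buffer()
spec60 <- design_spec(tm_optimal = 60, tm_tolerance = 5)

test_that("reverse complement is correct and involutive", {
  expect_identical(reverse_complement("ACGT"), "ACGT")
  expect_identical(reverse_complement("AAAA"), "TTTT")
  expect_identical(reverse_complement(""), "")
  expect_error(reverse_complement("ACGN"), class = "pw_alphabet_error")
  set.seed(23)
  for (i in 1:25) {
    s <- random_dna(sample(1:80, 1))
    expect_identical(reverse_complement(reverse_complement(s)), s)
    # cross-check against the Biostrings implementation
    expect_identical(
      reverse_complement(s),
      as.character(Biostrings::reverseComplement(Biostrings::DNAString(s))))
  }
})

test_that("walker rejects templates shorter than min_len", {
  short <- random_dna(spec60$min_len - 1L)
  expect_error(enumerate_candidates(short, "forward", spec60, sl, buf),
               class = "pw_template_too_short_error")
})

test_that("poly-A template cannot reach a 95 C window", {
  spec95 <- design_spec(tm_optimal = 95, tm_tolerance = 1)
  cands <- enumerate_candidates(strrep("A", 100), "forward", spec95, sl, buf)
  expect_equal(nrow(cands), 0)
  # confirm the window is genuinely unreachable, not a filtering accident
  expect_true(all(attr(cands, "evaluated")$tm < 94))
})

test_that("walker candidates are boundary-anchored, in-window, and length-ordered", {
  set.seed(29)
  for (i in 1:20) {
    tpl <- random_dna(sample(60:300, 1))
    for (orient in c("forward", "reverse")) {
      cands <- enumerate_candidates(tpl, orient, spec60, sl, buf)
      if (!nrow(cands)) next
      expect_true(all(diff(cands$length) > 0))
      expect_true(all(abs(cands$tm - 60) <= 5))
      for (j in seq_len(nrow(cands))) {
        anchor <- if (orient == "forward")
          substr(tpl, 1, cands$length[j])
        else
          reverse_complement(substring(tpl, nchar(tpl) - cands$length[j] + 1))
        expect_identical(cands$annealing_seq[j], anchor)
      }
    }
  }
})

test_that("walker output is identical to naive all-lengths enumeration", {
  set.seed(31)
  for (i in 1:30) {
    tpl <- random_dna(sample(40:500, 1))
    orient <- if (i %% 2) "forward" else "reverse"
    expect_identical(
      strip_attrs(enumerate_candidates(tpl, orient, spec60, sl, buf)),
      strip_attrs(naive_enumerate(tpl, orient, spec60, sl, buf)))
  }
})

test_that("ranking picks the clamped candidate when the clamp is forced", {
  cands <- data.frame(
    annealing_seq = c("ACGTA", "ACGTG"), length = c(5L, 5L),
    tm = c(60.3, 60.9), ends_gc = c(FALSE, TRUE),
    orientation = "forward", stringsAsFactors = FALSE)
  spec <- design_spec(tm_optimal = 60, force_gc_clamp = TRUE,
                      min_len = 5, max_len = 10)
  pick <- rank_and_pick(cands, spec)
  expect_identical(pick$candidate$annealing_seq, "ACGTG")
  expect_length(pick$warnings, 0)
  # clamp off: the global Tm minimizer wins
  spec_off <- design_spec(tm_optimal = 60, force_gc_clamp = FALSE,
                          min_len = 5, max_len = 10)
  expect_identical(rank_and_pick(cands, spec_off)$candidate$annealing_seq,
                   "ACGTA")
})

test_that("ranking warns instead of refusing when no clamp is available", {
  cands <- data.frame(annealing_seq = "ACGTA", length = 5L, tm = 59.0,
                      ends_gc = FALSE, orientation = "forward",
                      stringsAsFactors = FALSE)
  spec <- design_spec(tm_optimal = 60, force_gc_clamp = TRUE,
                      min_len = 5, max_len = 10)
  pick <- rank_and_pick(cands, spec)
  expect_identical(pick$candidate$annealing_seq, "ACGTA")
  expect_match(pick$warnings, "no G/C clamp")
  expect_error(rank_and_pick(cands[0, ], spec),
               class = "pw_no_candidate_error")
})

test_that("ranking equals exhaustive scoring by the lexicographic key", {
  set.seed(37)
  for (i in 1:50) {
    spec <- design_spec(tm_optimal = 60, tm_tolerance = 5,
                        force_gc_clamp = i %% 2 == 0)
    cands <- random_candidates(sample(1:12, 1), spec)
    expect_identical(strip_attrs(rank_and_pick(cands, spec)$candidate),
                     strip_attrs(naive_pick(cands, spec)))
  }
})

test_that("designed pairs reconstruct the template exactly (single-nucleotide precision)", {
  set.seed(41)
  spec <- design_spec(tm_optimal = 60, tm_tolerance = 5,
                      ext_forward = "GGTCTCAGGAG", ext_reverse = "GAATTCA")
  for (i in 1:15) {
    tpl <- random_dna(sample(100:400, 1))
    pair <- design_pair(sprintf("t%02d", i), tpl, spec, sl, buf)
    fwd_anneal <- sub(paste0("^", spec$ext_forward), "", pair$forward_full)
    rev_anneal <- sub(paste0("^", spec$ext_reverse), "", pair$reverse_full)
    expect_identical(fwd_anneal,
                     substr(tpl, 1, nchar(fwd_anneal)))
    expect_identical(reverse_complement(rev_anneal),
                     substring(tpl, nchar(tpl) - nchar(rev_anneal) + 1))
    expect_identical(pair$forward_full,
                     paste0(spec$ext_forward, pair$forward$annealing_seq))
  }
})

test_that("empty extensions leave the full primer equal to the annealing region", {
  set.seed(43)
  tpl <- random_dna(200)
  pair <- design_pair("t", tpl, spec60, sl, buf)
  expect_identical(pair$forward_full, pair$forward$annealing_seq)
  expect_identical(pair$reverse_full, pair$reverse$annealing_seq)
})

test_that("design failure carries a nearest-achievable-Tm diagnostic", {
  err <- tryCatch(
    design_pair("polyA", strrep("A", 100),
                design_spec(tm_optimal = 95, tm_tolerance = 1), sl, buf),
    pw_design_failure = function(e) e)
  expect_s3_class(err, "pw_design_failure")
  expect_match(conditionMessage(err), "nearest achievable Tm")
  expect_true(is.finite(err$nearest_tm))
})

test_that("auto-widen releases the window instead of failing, with a warning", {
  pair <- design_pair("polyA", strrep("A", 100),
                      design_spec(tm_optimal = 95, tm_tolerance = 1),
                      sl, buf, auto_widen = 2)
  expect_s3_class(pair, "primer_pair")
  expect_match(paste(pair$warnings, collapse = " "), "tolerance widened")
  # widened tolerance is minimal: the pick is the closest achievable Tm
  expect_lt(abs(pair$forward$tm - 95), 50)
})

test_that("batch design collects failures and preserves record order", {
  set.seed(47)
  records <- data.frame(
    id = c("a", "short", "b"),
    sequence = c(random_dna(250), random_dna(10), random_dna(250)),
    stringsAsFactors = FALSE)
  des <- design_batch(records, spec60, sl, buf)
  expect_length(des$pairs, 2)
  expect_length(des$failures, 1)
  expect_identical(des$failures[[1]]$record_id, "short")
  expect_identical(vapply(des$pairs, `[[`, "", "record_id"), c("a", "b"))
})

test_that("batch design is permutation-invariant and rejects duplicate ids", {
  set.seed(53)
  records <- data.frame(id = sprintf("r%d", 1:6),
                        sequence = replicate(6, random_dna(250)),
                        stringsAsFactors = FALSE)
  des1 <- design_batch(records, spec60, sl, buf)
  perm <- c(4, 1, 6, 2, 5, 3)
  des2 <- design_batch(records[perm, ], spec60, sl, buf)
  ids1 <- vapply(des1$pairs, `[[`, "", "record_id")
  ids2 <- vapply(des2$pairs, `[[`, "", "record_id")
  expect_setequal(ids1, ids2)
  for (id in ids1) {
    p1 <- des1$pairs[[which(ids1 == id)]]
    p2 <- des2$pairs[[which(ids2 == id)]]
    expect_identical(p1$forward_full, p2$forward_full)
    expect_identical(p1$reverse_full, p2$reverse_full)
  }
  expect_error(design_batch(records[c(1, 1, 2), ], spec60, sl, buf),
               class = "pw_duplicate_id_error")
})

test_that("design is deterministic: identical inputs, identical pairs", {
  set.seed(59)
  tpl <- random_dna(300)
  p1 <- design_pair("t", tpl, spec60, sl, buf)
  p2 <- design_pair("t", tpl, spec60, sl, buf)
  expect_identical(p1, p2)
})
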