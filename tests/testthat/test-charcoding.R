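test_that("RY coding maps bases to purine/pyrimidine classes", {
  aln <- multiple_alignment("t1", "ACGT")
  expect_equal(ry_encode(aln)$rows, "RYRY")
  # gaps/missing pass through, mixed ambiguity collapses to N,
  # class-pure ambiguity codes keep their class
  aln2 <- multiple_alignment("t1", "A-N?RYSWU")
  expect_equal(ry_encode(aln2)$rows, "R-N?RYNNY")
})

test_that("RY coding restricted to third positions leaves other columns alone", {
  aln <- multiple_alignment("t1", "ATGCATGAT")
  expect_equal(ry_encode(aln, positions = "third", frame = 1L)$rows,
               "ATRCAYGAY")
  # frame 2: positions cycle from column 2, so columns 1, 4, 7 are third
  # positions (column 1 closes the codon preceding the frame start)
  expect_equal(ry_encode(aln, positions = "third", frame = 2L)$rows,
               "RTGYATRAT")
  expect_error(ry_encode(aln, frame = 4L), "frame")
})

test_that("RY coding is idempotent and stays in its output alphabet", {
  set.seed(7)
  for (i in 1:20) {
    row <- paste(sample(c("A", "C", "G", "T", "N", "-", "?", "R", "Y", "S",
                          "K", "M", "W", "B", "D", "H", "V", "U"),
                        60L, replace = TRUE), collapse = "")
    aln <- multiple_alignment("t1", row)
    once <- ry_encode(aln)
    expect_equal(nchar(once$rows), 60L)
    expect_true(all(strsplit(once$rows, "")[[1L]] %in%
                      c("R", "Y", "N", "-", "?")))
    expect_equal(ry_encode(once), once)
  }
})

test_that("degeneracy table matches the brute-force synonym-component oracle", {
  code <- genetic_code(1)
  dt <- build_degen_table(code)
  oracle <- oracle_degen_table(code)
  expect_equal(dt$codon_to_degen[names(oracle)], oracle)
  expect_equal(dt$codon_to_degen[["ATG"]], "ATG")
  expect_equal(dt$codon_to_degen[["TGG"]], "TGG")
  expect_equal(dt$codon_to_degen[["CTA"]], "YTN")
  expect_equal(dt$codon_to_degen[["AGT"]], "AGY")
})

test_that("degeneracy table adapts to non-standard genetic codes", {
  # vertebrate mitochondrial code: AGA/AGG are stops, not arginine
  dt2 <- build_degen_table(genetic_code(2))
  oracle2 <- oracle_degen_table(genetic_code(2))
  expect_equal(dt2$codon_to_degen[names(oracle2)], oracle2)
  expect_false(identical(dt2$codon_to_degen[["AGA"]],
                         build_degen_table(genetic_code(1))$codon_to_degen[["AGA"]]))
})

test_that("degen_encode recodes clean in-frame codons and passes others through", {
  dt <- build_degen_table(genetic_code(1))
  expect_equal(degen_encode(multiple_alignment("x", "ATGCTA"), dt)$rows,
               "ATGYTN")
  expect_equal(degen_encode(multiple_alignment("x", "AT-CTA"), dt)$rows,
               "AT-YTN")
  # U treated as T for lookup; trailing partial codon untouched
  expect_equal(degen_encode(multiple_alignment("x", "CUAAT"), dt)$rows,
               "YTNAT")
  # idempotent on rows whose image contains only fixed points / non-ACGT
  out <- degen_encode(multiple_alignment("x", "ATGCTATGG"), dt)
  expect_equal(degen_encode(out, dt), out)
})

test_that("codon-position extraction slices columns cyclically from the frame", {
  aln <- multiple_alignment(c("a", "b"), c("ACGTCA", "GGGGGG"))
  expect_equal(extract_codon_positions(aln, 3L)$rows[1L], "GA")
  expect_equal(extract_codon_positions(aln, c(1L, 2L))$rows[1L], "ACTC")
  expect_equal(extract_codon_positions(aln, 1:3), aln)
  expect_error(extract_codon_positions(aln, integer(0L)), "non-empty")
})

test_that("positions {1,2} and {3} partition the alignment columns", {
  set.seed(11)
  for (frame in 1:3) {
    row <- random_coding_row(10L)
    aln <- multiple_alignment("t1", row)
    p12 <- extract_codon_positions(aln, c(1L, 2L), frame = frame)
    p3 <- extract_codon_positions(aln, 3L, frame = frame)
    expect_equal(n_sites(p12) + n_sites(p3), n_sites(aln))
    # interleave back: positions of each column are recoverable
    pos <- ((seq_len(n_sites(aln)) - frame) %% 3L) + 1L
    chars <- strsplit(row, "")[[1L]]
    expect_equal(p12$rows[1L], paste(chars[pos %in% c(1L, 2L)],
                                     collapse = ""))
    expect_equal(p3$rows[1L], paste(chars[pos == 3L], collapse = ""))
  }
})

test_that("translation follows the gap, ambiguity and stop rules", {
  code <- genetic_code(1)
  expect_equal(translate_alignment(multiple_alignment("x", "ATGTGG"),
                                   code)$rows, "MW")
  expect_equal(translate_alignment(multiple_alignment("x", "ATG---"),
                                   code)$rows, "M-")
  expect_equal(translate_alignment(multiple_alignment("x", "ATGT-G"),
                                   code)$rows, "MX")
  expect_equal(translate_alignment(multiple_alignment("x", "ATGTAA"),
                                   code)$rows, "M*")
  expect_equal(translate_alignment(multiple_alignment("x", "ATGTAA"), code,
                                   strip_final_stop = TRUE)$rows, "M")
})

test_that("degeneracy never changes the encoded amino acid", {
  code <- genetic_code(1)
  dt <- build_degen_table(code)
  # every synonym component carries exactly one amino acid
  same_component_aa <- tapply(code$codon_to_aa, dt$codon_to_degen,
                              function(x) length(unique(x)))
  expect_true(all(same_component_aa == 1L))
  # translate(degen(x)) == translate(x) on random sense coding rows
  sense <- names(code$codon_to_aa)[code$codon_to_aa != "*"]
  set.seed(3)
  for (i in 1:25) {
    row <- paste(sample(sense, 20L, replace = TRUE), collapse = "")
    aln <- multiple_alignment("t1", row)
    expect_equal(translate_alignment(degen_encode(aln, dt), code),
                 translate_alignment(aln, code))
  }
})

test_that("stop-codon stripping removes shared final stops and masks internal ones", {
  code <- genetic_code(1)
  aln <- multiple_alignment(c("a", "b", "c"),
                            c("ATGAAATAA", "ATGCCCTAG", "ATGGGG---"))
  out <- strip_stop_codons(aln, code, mode = "final-only")
  expect_equal(n_sites(out), 6L)
  expect_equal(out$rows, c("ATGAAA", "ATGCCC", "ATGGGG"))
  # disagreement between stop and sense final codons is an error
  bad <- multiple_alignment(c("a", "b"), c("ATGTAA", "ATGAAA"))
  expect_error(strip_stop_codons(bad, code, mode = "final-only"), "ragged")
  # no stops anywhere: identity
  clean <- multiple_alignment("a", "ATGAAA")
  expect_equal(strip_stop_codons(clean, code, mode = "final-only"), clean)
  # internal stops are masked, the final codon is left alone
  internal <- multiple_alignment("a", "ATGTAAGGGTGA")
  expect_equal(strip_stop_codons(internal, code, mode = "mask-internal")$rows,
               "ATGNNNGGGTGA")
})
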