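test_that("self-alignment scores the matrix diagonal at 100% identity", {
  a <- "WKTLDNAEW"
  al <- global_align(a, a)
  expect_equal(al$identity_pct, 100)
  expect_equal(al$aligned_a, a)
  mat <- blosum62()
  expect_equal(al$score,
               sum(diag(mat[strsplit(a, "")[[1]], strsplit(a, "")[[1]]])))
})

test_that("alignment against an empty sequence is all gaps at the gap cost", {
  al <- global_align("ACDE", "", gap_open = 10, gap_extend = 0.5)
  expect_equal(al$aligned_b, "----")
  expect_equal(al$score, -(10 + 4 * 0.5))
  al0 <- global_align("", "")
  expect_equal(al0$score, 0)
  expect_error(global_align("AC1E", "ACDE"), "illegal character")
  expect_error(global_align("AC", "DE", gap_open = 0.2, gap_extend = 0.5),
               "gap_open >= gap_extend")
})

test_that("the aligner equals brute-force enumeration on short sequences", {
  mat <- blosum62()
  alphabet <- c("A", "C", "D", "W")
  seqs <- unlist(lapply(1:2, function(L) {
    apply(expand.grid(rep(list(alphabet), L)), 1, paste, collapse = "")
  }))
  pairs <- expand.grid(a = seqs, b = seqs, stringsAsFactors = FALSE)
  set.seed(5)
  pairs <- pairs[sample(nrow(pairs), 60), ]
  for (k in seq_len(nrow(pairs))) {
    got <- global_align(pairs$a[k], pairs$b[k], mat)$score
    want <- enum_best_score(pairs$a[k], pairs$b[k], mat, 10, 0.5)
    expect_equal(got, want,
                 label = paste(pairs$a[k], pairs$b[k], "score"))
  }
  # degapping invariant on a longer random pair
  set.seed(6)
  a <- paste(sample(alphabet, 30, TRUE), collapse = "")
  b <- paste(sample(alphabet, 24, TRUE), collapse = "")
  al <- global_align(a, b)
  expect_equal(gsub("-", "", al$aligned_a), a)
  expect_equal(gsub("-", "", al$aligned_b), b)
  expect_equal(nchar(al$aligned_a), nchar(al$aligned_b))
})

test_that("alignment scores agree with an independent aligner and are symmetric", {
  mat <- blosum62()
  set.seed(8)
  aa <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  for (k in 1:8) {
    a <- paste(sample(aa, sample(8:25, 1), TRUE), collapse = "")
    b <- paste(sample(aa, sample(8:25, 1), TRUE), collapse = "")
    got <- global_align(a, b, mat, gap_open = 10, gap_extend = 0.5)
    ref <- Biostrings::pairwiseAlignment(
      Biostrings::AAString(a), Biostrings::AAString(b),
      substitutionMatrix = mat, gapOpening = 10, gapExtension = 0.5,
      type = "global")
    expect_equal(got$score, Biostrings::score(ref), label = paste(a, b))
    expect_equal(global_align(b, a, mat)$score, got$score)
  }
})

test_that("loop mapping recovers reference spans, insertions and truncations", {
  fam <- generate_family(seed = 3)   # defaults mirror the study loop lengths
  ref <- fam$seqs[["REF"]]
  rows <- map_loops(ref, fam$loops, ref, species_tag = "REF")
  expect_equal(rows$length[rows$loop == "L2"], 9L)
  expect_equal(rows$length[rows$loop == "L4"], 19L)
  expect_equal(rows$length,
               vapply(fam$loops, function(r) r$end - r$start + 1L, 0L),
               ignore_attr = TRUE)
  # a planted 4-residue insertion inside L1 maps to reference + 4
  fam2 <- generate_family(loop_offsets = list(SP1 = c(L1 = 4)), seed = 9)
  rows2 <- map_loops(fam2$seqs[["REF"]], fam2$loops, fam2$seqs[["SP1"]],
                     species_tag = "SP1")
  expect_equal(rows2$length[rows2$loop == "L1"],
               fam2$truth$expected_length[fam2$truth$species == "SP1" &
                                          fam2$truth$loop == "L1"])
  # target truncated before L4: row flagged unmappable
  trunc <- substr(ref, 1, 130)
  rows3 <- map_loops(ref, fam$loops, trunc, species_tag = "trunc")
  expect_false(rows3$mappable[rows3$loop == "L4"])
  expect_equal(rows3$length[rows3$loop == "L4"], 0L)
  # conservation: mapped loop lengths can never exceed the target length
  expect_lte(sum(rows3$length), nchar(trunc))
})

test_that("motif scanning enforces the fixed positions of the L4 signature", {
  pattern <- "WxxxDNxEWxxGxxxxFG"
  # 8 fixed anchors over an 18-column window
  expect_equal(sum(strsplit(pattern, "")[[1]] != "x"), 8L)
  # synthetic L4-like subsequence built to carry the signature, with the
  # wildcard positions filled arbitrarily
  l4 <- "WGLMDNFEWAEGYSKRFGI"
  hits <- motif_scan(c(tsa_like = l4), pattern)
  expect_true(hits$match)
  expect_equal(hits$offset, 1L)
  # substituting the W anchor kills the match and reports the position
  bad <- sub("^W", "A", l4)
  miss <- motif_scan(c(bad = bad), pattern)
  expect_false(miss$match)
  expect_equal(miss$mismatch_positions, "1")
  short <- motif_scan(c(s = "WDN"), pattern)
  expect_false(short$match)
  expect_match(short$reason, "longer than sequence")
  # a shifted occurrence is still found
  shifted <- motif_scan(c(sh = paste0("MKT", l4)), pattern)
  expect_true(shifted$match)
  expect_equal(shifted$offset, 4L)
})

test_that("conservation profiles flag exactly the planted invariant columns", {
  expect_equal(conservation_profile(c("ACDE", "ACDE", "ACDE")), rep(1, 4))
  expect_equal(conservation_profile(c("ACDE", "WYKR")), rep(0.5, 4))
  expect_error(conservation_profile(character(0)), "empty")
  expect_error(conservation_profile(c("ACD", "AC")), "equal length")
  inv <- c(10, 55, 111)
  fam <- generate_family(n_species = 6, invariant_columns = inv,
                         mutation_rate = 0.8, seed = 21)
  cons <- conservation_profile(fam$seqs)  # no indels: already columnar
  expect_equal(which(cons == 1), inv)
})

test_that("FASTA round trip preserves names and sequences", {
  seqs <- c(REF = "MKWVTFISLLLLFSSAYS", SP1 = "MKWVTCISLLLFSSAYS")
  p <- withr::local_tempfile(fileext = ".fasta")
  write_fasta(seqs, p)
  expect_equal(read_fasta(p), seqs)
})
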