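test_that("self-alignment is the identity map with no gaps", {
  set.seed(31)
  for (i in 1:5) {
    s <- random_protein(sample(20:60, 1))
    aln <- global_align(s, s)
    expect_equal(aln$map$query_pos, aln$map$ref_pos)
    expect_equal(aln$map$query_res, aln$map$ref_res)
    expect_false(grepl("-", aln$aligned_query, fixed = TRUE))
  }
})

test_that("a deleted residue still leaves the tyrosine aligned", {
  aln <- global_align("ACY", "ACDY")
  y_row <- aln$map[aln$map$ref_res == "Y", ]
  expect_equal(y_row$query_res, "Y")
  expect_equal(y_row$query_pos, 3L)
})

test_that("alignment scores equal the exhaustive affine-gap DP optimum", {
  data(BLOSUM62, package = "Biostrings", envir = environment())
  set.seed(17)
  for (i in 1:25) {
    q <- random_protein(sample(3:8, 1))
    r <- random_protein(sample(3:8, 1))
    expect_equal(global_align(q, r)$score,
                 oracle_global_score(q, r, BLOSUM62),
                 tolerance = 1e-9, info = paste(q, r))
  }
})

test_that("appending identical flanks shifts the score by the flank self-score", {
  data(BLOSUM62, package = "Biostrings", envir = environment())
  q <- "ACDY"; r <- "ACY"; flank <- "WWMH"
  base <- global_align(q, r)$score
  ext <- global_align(paste0(q, flank), paste0(r, flank))$score
  self <- sum(vapply(strsplit(flank, "")[[1]],
                     function(a) BLOSUM62[a, a], numeric(1)))
  expect_equal(ext, base + self, tolerance = 1e-9)
})

test_that("reference annotations are validated", {
  expect_error(reference_annotation("ACDY", c(2L)), "tyrosine")
  ref <- reference_annotation("ACDY", 4L)
  expect_equal(ref$catalytic_tyr_positions, 4L)
  expect_error(reference_annotation("YAY", c(3L, 1L)))
})

test_that("conserved-tyrosine counting reproduces the capacity rule", {
  ref <- synthetic_reference()
  # a reference profiled against itself conserves all annotated tyrosines
  self <- profile_query(ref$sequence, ref, "self")
  expect_equal(self$n_conserved_tyr, 3L)
  expect_equal(self$predicted_capacity, 3L)
  expect_equal(self$capacity_hypotheses,
               list(c("me0->me1", "me1->me2", "me2->me3")))

  # all three catalytic tyrosines mutated: no capacity
  none <- profile_query(mutate_at(ref$sequence,
                                  ref$catalytic_tyr_positions, "F"),
                        ref, "noY")
  expect_equal(none$n_conserved_tyr, 0L)
  expect_equal(none$capacity_hypotheses, list())

  # exactly one conserved tyrosine: three alternative single-step
  # hypotheses (mono-methylation only, me1->me2, or me2->me3)
  one <- profile_query(mutate_at(ref$sequence,
                                 ref$catalytic_tyr_positions[1:2], "A"),
                       ref, "oneY")
  expect_equal(one$n_conserved_tyr, 1L)
  expect_equal(one$capacity_hypotheses,
               list("me0->me1", "me1->me2", "me2->me3"))

  # two conserved: either pair of consecutive steps
  two <- profile_query(mutate_at(ref$sequence,
                                 ref$catalytic_tyr_positions[1], "A"),
                       ref, "twoY")
  expect_equal(two$n_conserved_tyr, 2L)
  expect_equal(two$capacity_hypotheses,
               list(c("me0->me1", "me1->me2"), c("me1->me2", "me2->me3")))
})

test_that("mutating one more catalytic tyrosine never raises the count", {
  ref <- synthetic_reference()
  seqs <- Reduce(function(s, p) mutate_at(s, p, "A"),
                 ref$catalytic_tyr_positions, accumulate = TRUE,
                 init = ref$sequence)
  counts <- vapply(seqs, function(s)
    profile_query(s, ref)$n_conserved_tyr, integer(1))
  expect_equal(unname(counts), c(3L, 2L, 1L, 0L))
  expect_true(all(diff(counts) <= 0))
})

test_that("signature motifs are found with the documented alternatives", {
  hits <- scan_motifs("AAELAFDYAA")
  expect_equal(hits$motif_id, "ELxF/YDY")
  expect_equal(hits$start, 3L)
  expect_equal(hits$matched_text, "ELAFDY")

  hits2 <- scan_motifs("NHSAAPN")
  expect_equal(hits2$motif_id, "NHS/CxxPN")
  expect_equal(hits2$start, 1L)

  # the slash alternatives: Y at the fourth symbol, C at the third
  expect_equal(nrow(scan_motifs("ELAYDY")), 1L)
  expect_equal(nrow(scan_motifs("NHCAAPN")), 1L)
  expect_equal(nrow(scan_motifs("ELAADY")), 0L)

  # overlapping occurrences are all reported (shared boundary N)
  ov <- scan_motifs("NHSAAPNHSAAPN")
  expect_equal(ov$start[ov$motif_id == "NHS/CxxPN"], c(1L, 7L))
})

test_that("motif hits match a brute-force sliding-window scan", {
  set.seed(23)
  for (i in 1:5) {
    s <- random_protein(200)
    # salt the sequence with instances so hits actually occur
    s <- paste0(s, "ELQFDY", random_protein(20), "NHSKLPN")
    hits <- scan_motifs(s)
    for (id in c("ELxF/YDY", "NHS/CxxPN")) {
      expect_equal(hits$start[hits$motif_id == id],
                   oracle_motif_hits(s, id), info = id)
    }
  }
})
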