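test_that("reference annotations normalize and validate", {
  ref <- read_reference_annotation("EEEE", seq = "LVLV")
  expect_identical(ref$states, "EEEE")
  # 3-10 (G) and pi (I) helices fold into H, bridges (B) into E, other
  # letters into C
  expect_identical(read_reference_annotation("GHIBEbCx")$states,
                   "HHHEEECC")
  # two-column form
  txt <- c("1 E", "2 E", "3 T", "4 C")
  expect_identical(read_reference_annotation(txt)$states, "EETC")
  expect_error(read_reference_annotation("EEEEE", seq = "LVLV"),
               "length 5 does not match sequence length 4")
  expect_error(read_reference_annotation(c("1 E", "3 E")), "gaps")
  expect_error(read_reference_annotation("EE4E"), "position 3")
})

test_that("segment matching implements the overlap criterion", {
  # identical annotations: recall = precision = 1 for present classes
  m <- segment_match("EEEETTHHHH", "EEEETTHHHH")
  expect_identical(m$recall[m$class %in% c("E", "H", "T")], c(1, 1, 1))
  expect_identical(m$precision[m$class %in% c("E", "H", "T")], c(1, 1, 1))
  # all-coil prediction: zero recall, undefined precision (NA, not 0)
  m2 <- segment_match("CCCCCCCCCC", "EECEECEECC")
  e2 <- m2[m2$class == "E", ]
  expect_identical(e2$n_pred, 0L)
  expect_identical(e2$recall, 0)
  expect_true(is.na(e2$precision))
  # hand case: pred E [0,4), ref E [2,6) on length 8; overlap 2 >= 0.5*4
  m3 <- segment_match("EEEECCCC", "CCEEEECC")
  e3 <- m3[m3$class == "E", ]
  expect_identical(e3$n_matched, 1L)
  expect_identical(e3$recall, 1)
  expect_identical(e3$precision, 1)
  # the same pair fails a stricter overlap criterion
  m4 <- segment_match("EEEECCCC", "CCEEEECC", min_overlap_frac = 0.75)
  expect_identical(m4[m4$class == "E", "n_matched"], 0L)
  expect_error(segment_match("EE", "EEE"), "length")
})

test_that("swapping pred and ref swaps recall and precision", {
  a <- "EEEECCHHHHCCEEEC"
  b <- "EEECCCHHHCCCEEEE"
  m_ab <- segment_match(a, b)
  m_ba <- segment_match(b, a)
  expect_equal(m_ab$recall, m_ba$precision)
  expect_equal(m_ab$precision, m_ba$recall)
})

test_that("self-evaluation is perfect wherever defined", {
  for (rec in generate_corpus(10, seed = 3)) {
    m <- segment_match(rec$labels, rec$labels)
    ok <- !is.na(m$recall)
    expect_true(all(m$recall[ok] == 1))
    expect_true(all(m$precision[!is.na(m$precision)] == 1))
  }
})

test_that("turn composition counts RB content and hairpins", {
  # three turns, two containing an RB residue
  corpus <- list(
    list(seq = "VVVGGVVV", states = "EEETTEEE"),   # RB turn, hairpin
    list(seq = "VVVAAVVV", states = "EEETTEEE"),   # non-RB turn, hairpin
    list(seq = "LAEELAEEGP", states = "HHHHHHHHTT")  # RB turn, no hairpin
  )
  st <- turn_composition_stats(corpus)
  expect_equal(st$turn_rb_fraction, 2 / 3)
  expect_identical(st$n_turns, 3L)
  expect_identical(st$n_hairpins, 2L)
  expect_equal(st$hairpin_rb_fraction, 1 / 2)
  # a single RB turn flanked by strands on both sides
  one <- list(list(seq = "VVVGPGVVV", states = "EEETTTEEE"))
  expect_equal(turn_composition_stats(one)$hairpin_rb_fraction, 1)
  # no turns: NA, never 0
  none <- turn_composition_stats(list(list(seq = "VVVV", states = "EEEE")))
  expect_true(is.na(none$turn_rb_fraction))
  expect_true(is.na(none$hairpin_rb_fraction))
})

test_that("composition and involvement fractions are as hand-computed", {
  # strand LVLV: all four residues hydrophobic, all carry interval-1 edges
  one <- list(list(seq = "LVLV", states = "EEEE"))
  st <- composition_stats(one)
  expect_equal(st$strand_hydrophobic_fraction, 1)
  expect_equal(st$strand_involvement, 1)
  expect_true(is.na(st$helix_hydrophobic_fraction))
  # TSTS: no fully hydrophobic residues at all
  st2 <- composition_stats(list(list(seq = "TSTS", states = "EEEE")))
  expect_equal(st2$strand_hydrophobic_fraction, 0)
  expect_true(is.na(st2$strand_involvement))
  # empty corpus: everything undefined
  st3 <- composition_stats(list())
  expect_true(all(is.na(unlist(st3[1:4]))))
})

test_that("all defined fractions stay inside [0, 1] on random corpora", {
  for (seed in c(5, 17, 29)) {
    corpus <- lapply(generate_corpus(15, seed = seed, mutation_rate = 0.1),
                     function(r) list(seq = r$seq, states = r$labels))
    vals <- c(unlist(turn_composition_stats(corpus)[1:2]),
              unlist(composition_stats(corpus)[1:4]))
    vals <- vals[!is.na(vals)]
    expect_true(all(vals >= 0 & vals <= 1))
  }
})

test_that("manifest evaluation runs end to end", {
  dir <- withr::local_tempdir()
  recs <- generate_corpus(3, seed = 9)
  fa <- file.path(dir, "seqs.fa")
  write_fasta(lapply(seq_along(recs), function(k)
    list(id = paste0("s", k), seq = recs[[k]]$seq)), fa)
  # one annotation file per record is the manifest contract; use the
  # first record only for a single-line manifest
  ann <- file.path(dir, "ann1.txt")
  writeLines(recs[[1]]$labels, ann)
  fa1 <- file.path(dir, "one.fa")
  write_fasta(list(list(id = "s1", seq = recs[[1]]$seq)), fa1)
  manifest <- file.path(dir, "manifest.txt")
  writeLines(paste(fa1, ann), manifest)
  rep <- evaluate_manifest(manifest)
  expect_true(all(rep$n_matched <= pmin(rep$n_pred, rep$n_ref)))
  expect_gte(attr(rep, "residue_accuracy"), 0.95)
})
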