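test_that("FASTA round-trips and validates", {
  dir <- withr::local_tempdir()
  path <- file.path(dir, "x.fa")
  recs <- list(list(id = "a1", seq = "LVLVGG"),
               list(id = "a2", seq = paste(rep("LAEE", 30), collapse = "")))
  write_fasta(recs, path)
  back <- read_fasta(path)
  expect_identical(back, recs)
  # lower-case letters are upper-cased with a notice
  writeLines(c(">r1", "lvlv"), path)
  expect_message(r <- read_fasta(path), "upper-casing")
  expect_identical(r[[1]]$seq, "LVLV")
  # illegal character errors carry record and position
  writeLines(c(">r1", "LVX1"), path)
  expect_error(read_fasta(path), "'X' at position 3")
  # duplicate ids and empty files are flagged
  writeLines(c(">r1", "LVLV", ">r1", "AAAA"), path)
  expect_error(read_fasta(path), "duplicate")
  writeLines(character(0), path)
  expect_error(read_fasta(path), "empty")
})

test_that("PDB ATOM parsing applies radii, classes, and altLoc rules", {
  dir <- withr::local_tempdir()
  path <- file.path(dir, "toy.pdb")
  writeLines(c(
    "ATOM      1  N   LEU A   1      11.104   6.134  -6.504  1.00  0.00           N",
    "ATOM      2  CA  LEU A   1      11.639   6.071  -5.147  1.00  0.00           C",
    "ATOM      3  O   LEU A   1      12.620   7.881  -4.212  1.00  0.00           O",
    "ATOM      4  CB ASER A   2      13.000   2.000  -1.000  0.60  0.00           C",
    "ATOM      5  CB BSER A   2      14.000   2.000  -1.000  0.40  0.00           C"
  ), path)
  res <- read_pdb_atoms(path)
  expect_identical(nrow(res$model$atoms), 4L)
  # Bondi radii: N 1.55, C 1.70, O 1.52
  expect_equal(res$model$atoms$r[1:3], c(1.55, 1.70, 1.52))
  # leucine atoms are class 1 (hydrophobic residue), serine class 2
  expect_identical(res$model$atoms$hclass, c(1L, 1L, 1L, 2L))
  # highest-occupancy altLoc kept
  expect_identical(res$model$atoms$x[4], 13.0)
  expect_identical(res$sequence, "LS")
  # HETATM-only input is a no-atoms error
  writeLines("HETATM    1  O   HOH A   1       0.0     0.0     0.0  1.00",
             path)
  expect_error(read_pdb_atoms(path), "no ATOM records")
})

test_that("config files parse into typed key-value pairs", {
  path <- withr::local_tempfile()
  writeLines(c("# comment", "min_strand_len = 4", "flag = true",
               "name = demo"), path)
  cfg <- read_config(path)
  expect_identical(cfg$min_strand_len, 4)
  expect_identical(cfg$flag, TRUE)
  expect_identical(cfg$name, "demo")
  writeLines("oops", path)
  expect_error(read_config(path), "key = value")
})

test_that("sequence generation is label-consistent and deterministic", {
  spec <- fixture_spec(list(list("strand", 6), list("turn_linker", 2),
                            list("strand", 6)), seed = 7)
  g1 <- generate_sequence(spec)
  expect_identical(nchar(g1$seq), 14L)
  expect_identical(g1$labels, "EEEEEETTEEEEEE")
  expect_identical(generate_sequence(spec), g1)
  expect_error(fixture_spec(list(list("loop", 3))), "unknown motif")
  expect_error(fixture_spec(list(list("strand", 0))), ">= 1")
})

test_that("mutation counts follow the binomial rate", {
  n_tot <- 0L; n_mut <- 0L
  for (s in 1:30) {
    spec <- fixture_spec(list(list("strand", 10), list("helix", 12),
                              list("coil", 8)), seed = 100 + s,
                         mutation_rate = 0.1)
    g <- generate_sequence(spec)
    n_tot <- n_tot + nchar(g$seq)
    n_mut <- n_mut + g$n_mutations
    expect_identical(nchar(g$seq), nchar(g$clean_seq))
  }
  # within 3 sigma of Binomial(n_tot, 0.1)
  expect_lt(abs(n_mut - 0.1 * n_tot), 3 * sqrt(n_tot * 0.1 * 0.9))
})

test_that("ball-cluster and patch-pair generators are seeded", {
  expect_identical(nrow(generate_ball_cluster(1, seed = 5)$atoms), 1L)
  c1 <- generate_ball_cluster(4, seed = 5)
  expect_identical(generate_ball_cluster(4, seed = 5), c1)
  expect_false(identical(generate_ball_cluster(4, seed = 6)$atoms, c1$atoms))
  p1 <- generate_patch_pair(seed = 5)
  expect_identical(generate_patch_pair(seed = 5), p1)
  expect_false(identical(unclass(generate_patch_pair(seed = 6)$a)[, ],
                         unclass(p1$a)[, ]))
  # generators leave the global RNG state alone
  set.seed(99); before <- .Random.seed
  invisible(generate_patch_pair(seed = 1))
  expect_identical(.Random.seed, before)
})

test_that("the CLI subcommands run end to end", {
  dir <- withr::local_tempdir()
  out <- capture.output(eec_cli(c("classify", "LKG")))
  expect_length(out, 3L)
  expect_match(out[1], "FULL_HYDROPHOBIC")
  # thermo ledger
  out2 <- capture.output(eec_cli(c("thermo")))
  expect_match(out2[1], "2.7000")
  expect_match(out2[5], "TRUE")
  # predict-ss on a generated FASTA
  fa <- file.path(dir, "in.fa")
  write_fasta(list(list(id = "s1", seq = "VTVTVTVT")), fa)
  outfile <- file.path(dir, "pred.txt")
  eec_cli(c("predict-ss", "--fasta", fa, "--out", outfile))
  expect_identical(readLines(outfile)[3], "EEEEEEEE")
  # dock2d via patch files
  pp <- generate_patch_pair(seed = 1)
  write_patch(pp$a, file.path(dir, "a.pgm"))
  write_patch(pp$b, file.path(dir, "b.pgm"))
  out3 <- capture.output(eec_cli(c("dock2d",
                                   "--patch-a", file.path(dir, "a.pgm"),
                                   "--patch-b", file.path(dir, "b.pgm"),
                                   "--rot-step", "90")))
  expect_match(out3[1], "hydrophobic_overlap")
  expect_gt(length(out3), 1L)
  expect_error(eec_cli(character(0)), "usage")
  expect_error(eec_cli("frobnicate"), "unknown subcommand")
})
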