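test_that("patch images validate labels and round-trip through PGM/CSV", {
  g <- matrix(0L, 4, 5)
  g[2, 2:3] <- 1L; g[3, 4] <- 2L; g[1, 5] <- 3L; g[4, 1] <- 4L
  img <- patch_image(g, spacing = 1.5)
  expect_error(patch_image(matrix(5L, 2, 2)), "0-4")
  expect_error(patch_image(g, spacing = 0), "positive")
  pgm <- withr::local_tempfile(fileext = ".pgm")
  write_patch(img, pgm)
  back <- read_patch(pgm)
  expect_identical(unclass(back)[, ], unclass(img)[, ])
  expect_equal(attr(back, "spacing"), 1.5)
  csv <- withr::local_tempfile(fileext = ".csv")
  write_patch(img, csv)
  expect_identical(unclass(read_patch(csv))[, ], unclass(img)[, ])
})

test_that("projection z-buffers the frontmost exposed atom", {
  # single hydrophobic ball: a filled disc of radius about r/spacing
  m <- ball_model(0, 0, 0, 3, hclass = 1L, class_count = 2L)
  img <- project_patch(m, axis = c(0, 0, 1), spacing = 1)
  n_px <- sum(unclass(img) == 1L)
  expect_gt(n_px, 0.8 * pi * 9)
  expect_lt(n_px, 1.2 * pi * 9)
  expect_true(all(unclass(img) %in% c(0L, 1L)))
  # two stacked balls along z: only the front (hydrophobic) one is seen
  m2 <- ball_model(c(0, 0), c(0, 0), c(5, 0), 3, hclass = c(1L, 2L),
                   class_count = 2L)
  img2 <- project_patch(m2, axis = c(0, 0, 1), spacing = 1)
  # both balls cover the same pixels; the front one is hydrophobic, so
  # the hydrophilic back ball must be invisible
  expect_false(any(unclass(img2) == 4L))
  expect_true(any(unclass(img2) == 1L))
  expect_error(project_patch(m, axis = c(0, 0, 0)), "zero")
  # donor/acceptor flags take precedence over the hydrophobic class
  img3 <- project_patch(ball_model(0, 0, 0, 2, hclass = 1L),
                        donor = TRUE, spacing = 1)
  expect_true(all(unclass(img3) %in% c(0L, 2L)))
})

test_that("a T-shaped fixture projects to the pinned image", {
  m <- ball_model(c(-2, 0, 2, 0, 0), c(2, 2, 2, 0, -2), rep(0, 5),
                  1.2, hclass = c(1L, 1L, 1L, 2L, 2L), class_count = 2L)
  expect_snapshot(print(project_patch(m, axis = c(0, 0, 1), spacing = 1)))
})

test_that("identical hydrophobic squares dock at full overlap", {
  sq <- patch_image(matrix(1L, 2, 2))
  res <- dock_images(sq, sq, rotations = c(0, 90, 180, 270), min_hb = 0)
  expect_identical(res$hydrophobic_overlap[1], 4L)
  # deterministic tie-break: first row is the lexicographically smallest
  # placement among the full-overlap ties
  expect_identical(res$rotation[1], 0)
  expect_identical(res$dx[1], 0L)
  expect_identical(res$dy[1], 0L)
})

test_that("rule-2 infeasibility is distinct from zero overlap", {
  sq <- patch_image(matrix(1L, 2, 2))
  res <- dock_images(sq, sq, rotations = 0, min_hb = 3)
  expect_identical(nrow(res), 0L)
  expect_identical(attr(res, "reason"), "no feasible placement")
  # spacing mismatch and empty patches are errors
  expect_error(dock_images(sq, patch_image(matrix(1L, 2, 2), spacing = 2)),
               "spacing")
  expect_error(dock_images(sq, patch_image(matrix(0L, 2, 2))), "empty")
})

test_that("dock_images agrees with the brute-force oracle", {
  for (seed in 1:6) {
    pp <- generate_patch_pair(seed = seed)
    res <- dock_images(pp$a, pp$b, rotations = c(0, 90, 180, 270),
                       min_hb = 3, top_n = 1e6)
    oracle_best <- brute_force_dock(pp$a, pp$b, min_hb = 3L)
    expect_identical(res$hydrophobic_overlap[1], as.integer(oracle_best))
  }
})

test_that("planted placements are recovered", {
  for (seed in 7:12) {
    pp <- generate_patch_pair(seed = seed)
    res <- dock_images(pp$a, pp$b, rotations = c(0, 90, 180, 270),
                       min_hb = 3, top_n = 1e6)
    best <- res$hydrophobic_overlap[1]
    expect_identical(best, pp$n_hydrophobic)
    tr <- pp$transform
    planted <- res[res$rotation == tr$rotation & res$flipped == tr$flipped &
                     res$dx == tr$dx & res$dy == tr$dy, ]
    expect_identical(nrow(planted), 1L)
    expect_identical(planted$hydrophobic_overlap, best)
  }
})

test_that("docking score is symmetric in its arguments", {
  for (seed in c(3, 14)) {
    pp <- generate_patch_pair(seed = seed)
    r_ab <- dock_images(pp$a, pp$b, rotations = c(0, 90, 180, 270),
                        min_hb = 0)
    r_ba <- dock_images(pp$b, pp$a, rotations = c(0, 90, 180, 270),
                        min_hb = 0)
    expect_identical(r_ab$hydrophobic_overlap[1],
                     r_ba$hydrophobic_overlap[1])
  }
})

test_that("raising min_hb never improves the best feasible score", {
  pp <- generate_patch_pair(seed = 20)
  scores <- vapply(c(0L, 1L, 3L, 4L), function(mh) {
    res <- dock_images(pp$a, pp$b, rotations = c(0, 90, 180, 270),
                       min_hb = mh)
    if (nrow(res)) res$hydrophobic_overlap[1] else -1L
  }, integer(1))
  expect_true(all(diff(scores) <= 0))
})
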