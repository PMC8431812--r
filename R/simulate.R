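# Synthetic fixture generation: sequences with planted secondary-
# structure motifs, random ball clusters, and planted complementary
# patch pairs.  All generators are pure functions of (spec, seed).

#' Specify a synthetic sequence fixture
#'
#' @param plan List of \code{c(kind, length)} pairs (or a two-column
#'   data.frame) with kind in strand, helix, turn_linker, coil and
#'   length >= 1.
#' @param seed Integer RNG seed.
#' @param mutation_rate Per-position probability of substituting a
#'   uniform random different residue in the noisy variant, in [0, 1].
#' @return List of class \code{fixture_spec}.
#' @export
fixture_spec <- function(plan, seed = 1L, mutation_rate = 0) {
  if (is.data.frame(plan)) {
    plan <- lapply(seq_len(nrow(plan)),
                   function(i) list(kind = plan[[1]][i],
                                    length = plan[[2]][i]))
  }
  plan <- lapply(plan, function(p) {
    kind <- as.character(p[[1]]); len <- as.integer(p[[2]])
    if (!kind %in% c("strand", "helix", "turn_linker", "coil")) {
      stop("unknown motif kind '", kind, "'", call. = FALSE)
    }
    if (len < 1L) stop("motif lengths must be >= 1", call. = FALSE)
    list(kind = kind, length = len)
  })
  if (mutation_rate < 0 || mutation_rate > 1) {
    stop("mutation_rate must be in [0, 1]", call. = FALSE)
  }
  structure(list(plan = plan, seed = as.integer(seed),
                 mutation_rate = mutation_rate),
            class = "fixture_spec")
}

# Motif emitters.  Strand: alternating fully hydrophobic residue and
# threonine (the two-face strand pattern).  Helix: L-A-E-E repeats, a
# period-4 pattern with dense i+3/i+4 attraction.  Turn linker: RB
# residues, glycine-rich.  Coil: threonine interleaved with D/N/S so the
# stretch is RB-rich but never accumulates a blocking run of two.
.emit_motif <- function(kind, len) {
  switch(kind,
    strand = {
      hyd <- sample(c("V", "I", "L", "F", "Y"), ceiling(len / 2),
                    replace = TRUE)
      out <- character(len)
      out[seq(1, len, by = 2)] <- hyd[seq_len(length(seq(1, len, by = 2)))]
      if (len >= 2) out[seq(2, len, by = 2)] <- "T"
      out
    },
    helix = rep(c("L", "A", "E", "E"), length.out = len),
    turn_linker = sample(c("G", "G", "P", "N"), len, replace = TRUE),
    coil = {
      out <- rep("T", len)
      if (len >= 2) {
        rb <- sample(c("D", "N", "S"), floor(len / 2), replace = TRUE)
        idx <- seq(2, len, by = 2)
        out[idx] <- rb[seq_along(idx)]
        out[len] <- "T"   # keep RB runs from forming across boundaries
      }
      out
    })
}

.motif_state <- c(strand = "E", helix = "H", turn_linker = "T", coil = "C")

#' Generate a synthetic sequence with known per-residue labels
#'
#' Deterministic under the spec's seed.  Returns both the clean sequence
#' and, when \code{mutation_rate > 0}, a mutated variant whose labels
#' are inherited from the clean one.
#'
#' @param spec \code{\link{fixture_spec}}.
#' @return List: \code{seq}, \code{labels} (E/H/T/C string),
#'   \code{clean_seq} (equal to \code{seq} when no mutation),
#'   \code{n_mutations}.
#' @export
generate_sequence <- function(spec) {
  stopifnot(inherits(spec, "fixture_spec"))
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(spec$seed)
  chars <- character(0); labels <- character(0)
  for (p in spec$plan) {
    chars <- c(chars, .emit_motif(p$kind, p$length))
    labels <- c(labels, rep(.motif_state[[p$kind]], p$length))
  }
  clean <- paste(chars, collapse = "")
  n_mut <- 0L
  if (spec$mutation_rate > 0) {
    hit <- stats::runif(length(chars)) < spec$mutation_rate
    for (i in which(hit)) {
      chars[i] <- sample(setdiff(amino_acids(), chars[i]), 1L)
    }
    n_mut <- sum(hit)
  }
  list(seq = paste(chars, collapse = ""),
       labels = paste(labels, collapse = ""),
       clean_seq = clean, n_mutations = n_mut)
}

# Save/restore the global RNG state so generators are pure.
.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}
.Random.seed_restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}

#' Generate a random synthetic sequence corpus
#'
#' Draws \code{n} plans of alternating structured motifs (strand or
#' helix) and turn linkers, with occasional coil stretches, and emits
#' each through \code{\link{generate_sequence}}.  Used by the evaluation
#' tests; linkers always separate structured motifs, mirroring how turns
#' separate secondary-structure elements.
#'
#' @param n Number of sequences.
#' @param seed Base seed; sequence k uses \code{seed + k}.
#' @param mutation_rate Passed to each spec.
#' @return List of \code{generate_sequence} results.
#' @export
generate_corpus <- function(n, seed = 1L, mutation_rate = 0) {
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  lapply(seq_len(n), function(k) {
    set.seed(seed + k)
    n_motifs <- sample(2:5, 1L)
    plan <- list()
    for (i in seq_len(n_motifs)) {
      kind <- sample(c("strand", "helix", "coil"), 1L,
                     prob = c(0.45, 0.35, 0.2))
      len <- switch(kind,
                    strand = sample(5:11, 1L),
                    helix = sample(8:16, 1L),
                    coil = sample(5:9, 1L))
      plan[[length(plan) + 1L]] <- list(kind = kind, length = len)
      if (i < n_motifs) {
        plan[[length(plan) + 1L]] <- list(kind = "turn_linker",
                                          length = sample(2:3, 1L))
      }
    }
    generate_sequence(fixture_spec(plan, seed = seed + k,
                                   mutation_rate = mutation_rate))
  })
}

#' Generate a random ball cluster
#'
#' \code{n} balls with centers uniform in a cube sized so that balls
#' typically overlap, radii uniform in [1.2, 2], hydrophobicity class
#' sampled from {1, 2}, no charges.
#'
#' @param n Ball count.
#' @param seed RNG seed.
#' @param box_edge Cube edge, Angstrom; default scales with n.
#' @return \code{\link{ball_model}} with \code{class_count} 2.
#' @export
generate_ball_cluster <- function(n, seed = 1L,
                                  box_edge = 2.5 * n^(1 / 3)) {
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  ball_model(stats::runif(n, 0, box_edge), stats::runif(n, 0, box_edge),
             stats::runif(n, 0, box_edge), stats::runif(n, 1.2, 2),
             hclass = sample(1:2, n, replace = TRUE), z_protons = 0,
             class_count = 2L)
}

#' Generate a planted complementary patch pair
#'
#' Builds a random connected hydrophobic blob on a square grid, stamps
#' \code{n_hb} donor pixels next to it, constructs the perfectly
#' complementary facing patch (hydrophobic where the blob is, acceptors
#' facing the donors), and hides it behind a recorded transform drawn
#' from the 90-degree rotation set, the mirror flip, and a small
#' translation.  \code{\link{dock_images}} run with rotations
#' {0, 90, 180, 270} recovers the recorded placement as the overlap
#' maximizer (up to blob symmetry, which the random blobs essentially
#' never have).
#'
#' @param seed RNG seed.
#' @param size Grid edge, pixels (default 12).
#' @param n_blob Blob size, pixels (default 24).
#' @param n_hb Planted donor/acceptor pairs (default 3).
#' @param max_shift Maximum |dx|, |dy| of the planted translation
#'   (default 2).
#' @return List: \code{a}, \code{b} (\code{\link{patch_image}}s),
#'   \code{transform} (list rotation/flipped/dx/dy),
#'   \code{n_hydrophobic} (the achievable maximal overlap).
#' @export
generate_patch_pair <- function(seed = 1L, size = 12L, n_blob = 24L,
                                n_hb = 3L, max_shift = 2L) {
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  g <- matrix(0L, size, size)
  # connected blob by random growth, kept away from the border so the
  # planted translation cannot push it off-canvas
  lo <- 1L + max_shift + 1L; hi <- size - max_shift - 1L
  pos <- c(sample(lo:hi, 1L), sample(lo:hi, 1L))
  g[pos[1], pos[2]] <- 1L
  cells <- list(pos)
  while (sum(g == 1L) < n_blob) {
    from <- cells[[sample(length(cells), 1L)]]
    step <- sample(list(c(1, 0), c(-1, 0), c(0, 1), c(0, -1)), 1L)[[1]]
    nxt <- from + step
    if (any(nxt < lo) || any(nxt > hi)) next
    if (g[nxt[1], nxt[2]] == 0L) {
      g[nxt[1], nxt[2]] <- 1L
      cells[[length(cells) + 1L]] <- nxt
    }
  }
  # donors on empty cells bordering the blob, pairwise non-adjacent so
  # each faces exactly one acceptor
  border <- which(g == 0L, arr.ind = TRUE)
  near_blob <- apply(border, 1L, function(rc) {
    any(g[max(1, rc[1] - 1):min(size, rc[1] + 1),
          max(1, rc[2] - 1):min(size, rc[2] + 1)] == 1L)
  })
  cand <- border[near_blob, , drop = FALSE]
  cand <- cand[sample(nrow(cand)), , drop = FALSE]
  placed <- matrix(integer(0), 0, 2)
  for (k in seq_len(nrow(cand))) {
    if (nrow(placed) >= n_hb) break
    if (nrow(placed) == 0L ||
        all(pmax(abs(placed[, 1] - cand[k, 1]),
                 abs(placed[, 2] - cand[k, 2])) > 2L)) {
      placed <- rbind(placed, cand[k, , drop = FALSE])
    }
  }
  for (k in seq_len(nrow(placed))) g[placed[k, 1], placed[k, 2]] <- 2L
  a <- patch_image(g, spacing = 1)
  # planted transform
  rot <- sample(c(0, 90, 180, 270), 1L)
  flip <- sample(c(FALSE, TRUE), 1L)
  dx <- sample(seq(-max_shift, max_shift), 1L)
  dy <- sample(seq(-max_shift, max_shift), 1L)
  # bt_target: what the transformed b must look like so that placing it
  # at (dx, dy) makes it complementary to a
  bt <- matrix(0L, size, size)
  for (i in seq_len(size)) for (j in seq_len(size)) {
    ia <- i + dy; ja <- j + dx
    if (ia < 1 || ia > size || ja < 1 || ja > size) next
    bt[i, j] <- switch(as.character(g[ia, ja]),
                       "1" = 1L, "2" = 3L, 0L)
  }
  # invert the docking transform chain: bt = R_rot(F_flip(F_mirror(b)))
  inv <- transform_patch(patch_image(bt, 1), rot = (360 - rot) %% 360)
  inv <- transform_patch(inv, rot = 0, flip = flip)
  b <- transform_patch(inv, rot = 0, flip = TRUE)
  list(a = a, b = b,
       transform = list(rotation = rot, flipped = flip, dx = dx, dy = dy),
       n_hydrophobic = sum(unclass(a) == 1L))
}
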