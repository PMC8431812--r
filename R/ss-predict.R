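# Interval-attraction graph and the strand/helix/turn decision rules.
#
# Convention used throughout: "interval" = number of residues strictly
# between two positions.  Interval 1 (sequence separation 2) is the
# same-face strand contact; intervals 2 and 3 (separations 3 and 4) are
# the i+/-3 and i+/-4 helix contacts.  Positions are 0-based half-open
# internally and 1-based inclusive in every user-facing report.

#' Predictor tuning parameters
#'
#' @param min_strand_len Minimum strand segment length (residues).
#' @param min_helix_len Minimum helix segment length.
#' @param strand_density_min Minimum fraction of possible interval-1
#'   attraction edges inside a stretch for a strand call.
#' @param helix_density_min Attraction-density threshold that both the
#'   interval-2 and interval-3 edge sets must strictly exceed for a helix
#'   call.  The default 0.7 is the smallest round value above 2/3, the
#'   analytic ceiling of the interval-3 density of a perfectly
#'   alternating hydrophobic/polar strand-face pattern (hydrophobic at
#'   both termini); any lower threshold misreads alternating strands as
#'   helices, any strict threshold in (2/3, 1) behaves identically on
#'   the motif families this rule set describes.
#' @param turn_block_len Minimum run of adjacent RB residues that blocks
#'   attraction and nucleates a turn.
#' @return List of class \code{predictor_params}.
#' @export
predictor_params <- function(min_strand_len = 3L, min_helix_len = 4L,
                             strand_density_min = 0.5,
                             helix_density_min = 0.7,
                             turn_block_len = 2L) {
  stopifnot(min_strand_len >= 1L, min_helix_len >= 1L, turn_block_len >= 1L,
            strand_density_min >= 0, strand_density_min <= 1,
            helix_density_min >= 0, helix_density_min <= 1)
  structure(list(min_strand_len = as.integer(min_strand_len),
                 min_helix_len = as.integer(min_helix_len),
                 strand_density_min = strand_density_min,
                 helix_density_min = helix_density_min,
                 turn_block_len = as.integer(turn_block_len)),
            class = "predictor_params")
}

#' Build the lateral-attraction graph of a sequence
#'
#' Enumerates candidate pairs at sequence separations 2-4 (intervals
#' 1-3), keeps those whose side-chains attract per
#' \code{\link{lateral_attraction}}, and removes edges whose span crosses
#' a proline or a run of two or more consecutive RB residues: both
#' interpose geometry that blocks the lateral collapse.
#'
#' @param seq Amino-acid string.
#' @param matrix Optional attraction-matrix override.
#' @param turn_block_len RB-run length that blocks a spanning edge.
#' @return List of class \code{attraction_graph}: \code{n}, and
#'   \code{edges}, a data.frame with 0-based columns \code{i}, \code{j},
#'   \code{interval}.
#' @examples
#' build_attraction_graph("LVLV")$edges
#' @export
build_attraction_graph <- function(seq, matrix = NULL, turn_block_len = 2L) {
  letters <- .check_seq(seq)
  n <- length(letters)
  rb <- vapply(letters, function(a) a %in% .rb_set, logical(1))
  tab <- attraction_table(matrix)
  is <- integer(0); js <- integer(0); ks <- integer(0)
  if (n >= 3L) {
    for (sep in 2:4) {
      if (n <= sep) next
      for (i0 in seq_len(n - sep)) {
        i <- i0            # 1-based left endpoint
        j <- i0 + sep
        if (tab[letters[i], letters[j]] == 0L) next
        between <- (i + 1L):(j - 1L)
        if (any(letters[between] == "P")) next
        # a block of >= turn_block_len consecutive RB residues inside the
        # span kills the edge (for interval 1 a single residue cannot
        # form such a block)
        if (length(between) >= turn_block_len) {
          r <- rle(rb[between])
          if (any(r$values & r$lengths >= turn_block_len)) next
        }
        is <- c(is, i - 1L); js <- c(js, j - 1L); ks <- c(ks, sep - 1L)
      }
    }
  }
  edges <- data.frame(i = is, j = js, interval = ks)
  edges <- edges[order(edges$i, edges$j), , drop = FALSE]
  rownames(edges) <- NULL
  structure(list(n = n, edges = edges), class = "attraction_graph")
}

#' Locate turn-nucleating RB runs
#'
#' Maximal runs of consecutive hydrophobic-blocking residues (D, N, S, P,
#' G) of length at least \code{turn_block_len}.
#'
#' @param seq Amino-acid string.
#' @param params \code{\link{predictor_params}}.
#' @return Data frame with 0-based half-open columns \code{start},
#'   \code{end}.
#' @examples
#' find_turn_sites("VVVGGVVV")
#' @export
find_turn_sites <- function(seq, params = predictor_params()) {
  letters <- .check_seq(seq)
  rb <- vapply(letters, function(a) a %in% .rb_set, logical(1))
  r <- rle(rb)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values & r$lengths >= params$turn_block_len
  data.frame(start = unname(starts[keep]) - 1L, end = unname(ends[keep]),
             row.names = NULL)
}

# Attraction-edge density of one stretch [lo, hi) (0-based half-open) at
# the given intervals; NA when fewer than min_possible pairs fit (a
# density over a single pair carries no periodicity evidence).
.stretch_density <- function(edges, lo, hi, intervals, min_possible = 1L) {
  len <- hi - lo
  possible <- sum(pmax(0L, len - (intervals + 1L)))
  if (possible < min_possible) return(NA_real_)
  inside <- edges$i >= lo & edges$j < hi & edges$interval %in% intervals
  sum(inside) / possible
}

#' Predict secondary structure from sequence
#'
#' Four steps, applied deterministically:
#' \enumerate{
#'   \item mark every residue inside an RB run of length
#'     \code{turn_block_len} or more as turn (T);
#'   \item split the remaining sequence into stretches at those runs and
#'     at every proline;
#'   \item for each stretch compute the attraction-edge density at
#'     interval 1 (strand face) and at intervals 2 and 3 separately
#'     (helix contacts), counting only edges wholly inside the stretch;
#'   \item call the stretch H when both helix densities strictly exceed
#'     \code{helix_density_min} and the stretch is at least
#'     \code{min_helix_len} long; each helix density needs at least two
#'     geometrically possible pairs to count as evidence (so stretches
#'     shorter than 6 are never called H: one i,i+4 contact is a single
#'     helical turn, indistinguishable from a strand end);
#'     otherwise E when the interval-1 density reaches
#'     \code{strand_density_min} and the stretch is at least
#'     \code{min_strand_len}; otherwise C.  Helix is tested first, so a
#'     fragment satisfying both folds helix.
#' }
#'
#' @param seq Amino-acid string.
#' @param params \code{\link{predictor_params}}.
#' @param matrix Optional attraction-matrix override.
#' @return List of class \code{ss_prediction}: \code{seq}, \code{states}
#'   (string over E/H/T/C), \code{segments} (data.frame, 0-based
#'   half-open \code{start}, \code{end}, \code{state}), and
#'   \code{params_used}.
#' @examples
#' predict_secondary_structure("VTVTVTVT")$states
#' predict_secondary_structure("LAEELAEELAEEL")$states
#' @export
predict_secondary_structure <- function(seq, params = predictor_params(),
                                        matrix = NULL) {
  letters <- .check_seq(seq)
  n <- length(letters)
  g <- build_attraction_graph(seq, matrix = matrix,
                              turn_block_len = params$turn_block_len)
  states <- rep("C", n)
  turns <- find_turn_sites(seq, params)
  for (t in seq_len(nrow(turns))) {
    states[(turns$start[t] + 1L):turns$end[t]] <- "T"
  }
  # stretches: maximal runs not in a turn and not a proline
  free <- states != "T" & letters != "P"
  r <- rle(free)
  hi <- cumsum(r$lengths); lo <- hi - r$lengths  # 0-based half-open
  for (k in which(r$values)) {
    len <- hi[k] - lo[k]
    d1 <- .stretch_density(g$edges, lo[k], hi[k], 1L)
    d2 <- .stretch_density(g$edges, lo[k], hi[k], 2L, min_possible = 2L)
    d3 <- .stretch_density(g$edges, lo[k], hi[k], 3L, min_possible = 2L)
    helix <- len >= params$min_helix_len &&
      !is.na(d2) && d2 > params$helix_density_min &&
      !is.na(d3) && d3 > params$helix_density_min
    strand <- !is.na(d1) && d1 >= params$strand_density_min &&
      len >= params$min_strand_len
    if (helix) {
      states[(lo[k] + 1L):hi[k]] <- "H"
    } else if (strand) {
      states[(lo[k] + 1L):hi[k]] <- "E"
    }
  }
  structure(list(seq = seq, states = paste(states, collapse = ""),
                 segments = states_to_segments(paste(states, collapse = "")),
                 params_used = params),
            class = "ss_prediction")
}

#' Segment a state string
#'
#' Maximal runs of an identical state letter as 0-based half-open
#' intervals.
#'
#' @param states String over E/H/T/C.
#' @return Data frame with columns \code{start}, \code{end}, \code{state}.
#' @export
states_to_segments <- function(states) {
  s <- strsplit(states, "", fixed = TRUE)[[1]]
  if (!length(s)) return(data.frame(start = integer(0), end = integer(0),
                                    state = character(0)))
  r <- rle(s)
  end <- cumsum(r$lengths)
  data.frame(start = end - r$lengths, end = end, state = r$values,
             stringsAsFactors = FALSE)
}

#' @export
print.ss_prediction <- function(x, ...) {
  cat("<ss_prediction>", nchar(x$seq), "residues\n")
  cat(" seq:    ", x$seq, "\n states: ", x$states, "\n", sep = "")
  invisible(x)
}

#' Human-readable prediction report
#'
#' Runs \code{\link{predict_secondary_structure}} and formats one block
#' per segment with its 1-based inclusive range, the attraction edges it
#' contains, and, for strand segments, the split of interval-1 edges
#' between the two faces (even and odd left endpoints).
#'
#' @inheritParams predict_secondary_structure
#' @return Character vector of report lines (also of class
#'   \code{ss_report}); print it with \code{cat(..., sep = "\n")}.
#' @export
explain_prediction <- function(seq, params = predictor_params(),
                               matrix = NULL) {
  pred <- predict_secondary_structure(seq, params, matrix)
  g <- build_attraction_graph(seq, matrix = matrix,
                              turn_block_len = params$turn_block_len)
  segs <- pred$segments
  lines <- sprintf("prediction for %d residues: %s", nchar(seq), pred$states)
  for (k in seq_len(nrow(segs))) {
    lo <- segs$start[k]; hi <- segs$end[k]
    inside <- g$edges[g$edges$i >= lo & g$edges$j < hi, , drop = FALSE]
    lines <- c(lines, sprintf(
      "segment %d-%d %s (%d residues, %d attraction edges)",
      lo + 1L, hi, segs$state[k], hi - lo, nrow(inside)))
    if (nrow(inside)) {
      lines <- c(lines, sprintf("  edge %d-%d (interval %d)",
                                inside$i + 1L, inside$j + 1L,
                                inside$interval))
    }
    if (segs$state[k] == "E") {
      e1 <- inside[inside$interval == 1L, , drop = FALSE]
      lines <- c(lines, sprintf(
        "  face split: %d edges on the even face, %d on the odd face",
        sum(e1$i %% 2L == 0L), sum(e1$i %% 2L == 1L)))
    }
  }
  structure(lines, class = c("ss_report", "character"))
}

#' @export
print.ss_report <- function(x, ...) {
  cat(x, sep = "\n")
  invisible(x)
}
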