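# Survey statistics: segment-level coverage ("recall") and success rate
# ("precision") against reference annotations, turn composition, and
# hydrophobic-involvement fractions.

# Fold the common annotation alphabets onto E/H/T/C: 3-10 (G) and pi (I)
# helices count as helix, bridges (B/b) as strand, anything else coil.
.normalize_state <- function(ch) {
  ch <- toupper(ch)
  out <- rep("C", length(ch))
  out[ch %in% c("H", "G", "I")] <- "H"
  out[ch %in% c("E", "B")] <- "E"
  out[ch == "T"] <- "T"
  out
}

#' Read a per-residue secondary-structure reference annotation
#'
#' Accepts either a bare state string or two-column text (1-based index,
#' state letter; blank lines and \code{#} comments ignored).  Letters are
#' normalized: G and I fold into H, B into E, anything other than
#' E/H/T into C.
#'
#' @param text Character scalar (bare string or whole file contents) or a
#'   character vector of lines.
#' @param seq Optional sequence the annotation must align to; a length
#'   mismatch is an error.
#' @return List of class \code{reference_annotation} with \code{states}
#'   (normalized string) and \code{seq} (may be NULL).
#' @export
read_reference_annotation <- function(text, seq = NULL) {
  stopifnot(is.character(text), length(text) >= 1L)
  lines <- unlist(strsplit(text, "\n", fixed = TRUE))
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (!length(lines)) stop("empty annotation", call. = FALSE)
  if (length(lines) == 1L && !grepl("[[:space:]]", lines)) {
    raw <- strsplit(lines, "", fixed = TRUE)[[1]]
  } else {
    parts <- strsplit(lines, "[[:space:]]+")
    idx <- suppressWarnings(as.integer(vapply(parts, `[`, "", 1L)))
    st <- vapply(parts, `[`, "", 2L)
    if (anyNA(idx) || anyNA(st)) {
      stop("annotation lines must be '<index> <state letter>'",
           call. = FALSE)
    }
    raw <- rep(NA_character_, max(idx))
    raw[idx] <- st
    if (anyNA(raw)) {
      stop("annotation has gaps at positions ",
           paste(which(is.na(raw)), collapse = ", "), call. = FALSE)
    }
  }
  bad <- which(!toupper(raw) %in% c(LETTERS, letters))
  if (length(bad)) {
    stop(sprintf("unknown annotation letter '%s' at position %d",
                 raw[bad[1]], bad[1]), call. = FALSE)
  }
  states <- paste(.normalize_state(raw), collapse = "")
  if (!is.null(seq) && nchar(states) != nchar(seq)) {
    stop(sprintf("annotation length %d does not match sequence length %d",
                 nchar(states), nchar(seq)), call. = FALSE)
  }
  structure(list(states = states, seq = seq),
            class = "reference_annotation")
}

.states_of <- function(x) {
  if (inherits(x, "ss_prediction") || inherits(x, "reference_annotation")) {
    x$states
  } else if (is.character(x) && length(x) == 1L) {
    x
  } else {
    stop("expected an ss_prediction, reference_annotation, or state string",
         call. = FALSE)
  }
}

# Greedy left-to-right one-to-one matching of same-class segments.
# A pair matches when overlap >= min_overlap_frac * min(len_a, len_b).
.match_segments <- function(a, b, frac) {
  na <- nrow(a); nb <- nrow(b)
  matched <- 0L
  i <- 1L; j <- 1L
  while (i <= na && j <= nb) {
    ov <- min(a$end[i], b$end[j]) - max(a$start[i], b$start[j])
    need <- frac * min(a$end[i] - a$start[i], b$end[j] - b$start[j])
    if (ov >= need && ov > 0) {
      matched <- matched + 1L
      i <- i + 1L; j <- j + 1L
    } else if (a$end[i] <= b$end[j]) {
      i <- i + 1L
    } else {
      j <- j + 1L
    }
  }
  matched
}

#' Segment-level match report
#'
#' Compares a prediction against a reference annotation at the segment
#' level, per class.  A predicted segment matches a reference segment of
#' the same class when their overlap is at least \code{min_overlap_frac}
#' of the shorter of the two; matching is greedy one-to-one in
#' left-to-right order.  Coverage (recall) is the fraction of reference
#' segments matched; success rate (precision) is the fraction of
#' predicted segments matched.  Ratios with a zero denominator are NA,
#' never 0 or 1.
#'
#' @param pred \code{ss_prediction} (or state string).
#' @param ref \code{reference_annotation} (or state string).
#' @param min_overlap_frac Overlap threshold, default 0.5.
#' @param classes States to report, default \code{c("E","H","T")}.
#' @return Data frame of class \code{match_report}: one row per class
#'   with \code{n_pred}, \code{n_ref}, \code{n_matched}, \code{recall},
#'   \code{precision}.
#' @export
segment_match <- function(pred, ref, min_overlap_frac = 0.5,
                          classes = c("E", "H", "T")) {
  ps <- .states_of(pred); rs <- .states_of(ref)
  if (nchar(ps) != nchar(rs)) {
    stop(sprintf("prediction length %d does not match reference length %d",
                 nchar(ps), nchar(rs)), call. = FALSE)
  }
  pseg <- states_to_segments(ps)
  rseg <- states_to_segments(rs)
  rows <- lapply(classes, function(cl) {
    a <- pseg[pseg$state == cl, , drop = FALSE]
    b <- rseg[rseg$state == cl, , drop = FALSE]
    m <- .match_segments(a, b, min_overlap_frac)
    data.frame(class = cl, n_pred = nrow(a), n_ref = nrow(b),
               n_matched = m,
               recall = if (nrow(b)) m / nrow(b) else NA_real_,
               precision = if (nrow(a)) m / nrow(a) else NA_real_,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  attr(out, "min_overlap_frac") <- min_overlap_frac
  class(out) <- c("match_report", class(out))
  out
}

# Normalize corpus input: list of list(seq=, states=) pairs.
.as_corpus <- function(x) {
  stopifnot(is.list(x), length(x) >= 0L)
  lapply(x, function(rec) {
    stopifnot(!is.null(rec$seq), !is.null(rec$states))
    states <- .states_of(rec$states)
    if (nchar(states) != nchar(rec$seq)) {
      stop("corpus record: annotation and sequence lengths differ",
           call. = FALSE)
    }
    list(seq = rec$seq, states = states)
  })
}

#' Turn composition statistics
#'
#' Over a corpus of (sequence, annotation) records: the fraction of turn
#' (T) segments containing at least one RB residue (D, N, S, P, G), and
#' the same fraction restricted to hairpin turns (T segments with strand
#' segments immediately adjacent on both sides).  NA when there are no
#' qualifying segments.
#'
#' @param corpus List of records, each \code{list(seq =, states =)};
#'   \code{states} may be a string, prediction, or annotation object.
#' @return List: \code{turn_rb_fraction}, \code{hairpin_rb_fraction},
#'   \code{n_turns}, \code{n_hairpins}.
#' @export
turn_composition_stats <- function(corpus) {
  corpus <- .as_corpus(corpus)
  n_turn <- 0L; n_turn_rb <- 0L; n_hp <- 0L; n_hp_rb <- 0L
  for (rec in corpus) {
    segs <- states_to_segments(rec$states)
    letters <- strsplit(rec$seq, "", fixed = TRUE)[[1]]
    tidx <- which(segs$state == "T")
    for (k in tidx) {
      res <- letters[(segs$start[k] + 1L):segs$end[k]]
      has_rb <- any(res %in% .rb_set)
      n_turn <- n_turn + 1L
      n_turn_rb <- n_turn_rb + has_rb
      hairpin <- k > 1L && k < nrow(segs) &&
        segs$state[k - 1L] == "E" && segs$state[k + 1L] == "E"
      if (hairpin) {
        n_hp <- n_hp + 1L
        n_hp_rb <- n_hp_rb + has_rb
      }
    }
  }
  list(turn_rb_fraction = if (n_turn) n_turn_rb / n_turn else NA_real_,
       hairpin_rb_fraction = if (n_hp) n_hp_rb / n_hp else NA_real_,
       n_turns = n_turn, n_hairpins = n_hp)
}

#' Hydrophobic composition and involvement statistics
#'
#' Over a corpus of (sequence, annotation) records: the fraction of fully
#' hydrophobic residues (C, I, L, M, W, F, Y, V) among residues inside
#' strand segments and inside helix segments, and the fraction of those
#' hydrophobic residues "involved" in hydrophobic interaction, i.e.
#' carrying at least one attraction edge to another residue of the same
#' segment -- at interval 1 for strands, intervals 2-3 for helices.
#' Undefined ratios are NA.
#'
#' @inheritParams turn_composition_stats
#' @param matrix Optional attraction-matrix override.
#' @return List: \code{strand_hydrophobic_fraction},
#'   \code{helix_hydrophobic_fraction}, \code{strand_involvement},
#'   \code{helix_involvement}, plus the underlying counts.
#' @export
composition_stats <- function(corpus, matrix = NULL) {
  corpus <- .as_corpus(corpus)
  cnt <- c(E_res = 0L, E_hyd = 0L, E_inv = 0L,
           H_res = 0L, H_hyd = 0L, H_inv = 0L)
  for (rec in corpus) {
    segs <- states_to_segments(rec$states)
    letters <- strsplit(rec$seq, "", fixed = TRUE)[[1]]
    for (k in which(segs$state %in% c("E", "H"))) {
      st <- segs$state[k]
      res <- letters[(segs$start[k] + 1L):segs$end[k]]
      sub <- paste(res, collapse = "")
      g <- build_attraction_graph(sub, matrix = matrix)
      want <- if (st == "E") 1L else c(2L, 3L)
      e <- g$edges[g$edges$interval %in% want, , drop = FALSE]
      touched <- unique(c(e$i, e$j)) + 1L
      hyd <- which(vapply(res, function(a)
        .residue_class_table[[a]] == "FULL_HYDROPHOBIC", logical(1)))
      cnt[paste0(st, "_res")] <- cnt[paste0(st, "_res")] + length(res)
      cnt[paste0(st, "_hyd")] <- cnt[paste0(st, "_hyd")] + length(hyd)
      cnt[paste0(st, "_inv")] <- cnt[paste0(st, "_inv")] +
        sum(hyd %in% touched)
    }
  }
  frac <- function(num, den) if (den > 0) num / den else NA_real_
  list(strand_hydrophobic_fraction = frac(cnt[["E_hyd"]], cnt[["E_res"]]),
       helix_hydrophobic_fraction  = frac(cnt[["H_hyd"]], cnt[["H_res"]]),
       strand_involvement = frac(cnt[["E_inv"]], cnt[["E_hyd"]]),
       helix_involvement  = frac(cnt[["H_inv"]], cnt[["H_hyd"]]),
       counts = as.list(cnt))
}

#' Batch evaluation over a manifest
#'
#' Each manifest line names a FASTA file and an annotation file separated
#' by whitespace or a tab.  Every record is predicted with the supplied
#' parameters and compared to its reference; the per-class match report
#' is aggregated over the whole corpus by summing segment counts.
#'
#' @param manifest_path Path to the manifest.
#' @param params \code{\link{predictor_params}}.
#' @param min_overlap_frac Segment-match threshold.
#' @return Data frame: aggregated match report plus per-residue accuracy.
#' @export
evaluate_manifest <- function(manifest_path, params = predictor_params(),
                              min_overlap_frac = 0.5) {
  lines <- readLines(manifest_path)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  base <- dirname(manifest_path)
  agg <- NULL
  n_res <- 0L; n_correct <- 0L
  for (ln in lines) {
    parts <- strsplit(ln, "[[:space:]]+")[[1]]
    if (length(parts) != 2L) stop("manifest line must be '<fasta> <annot>'",
                                  call. = FALSE)
    resolve <- function(p) if (file.exists(p)) p else file.path(base, p)
    recs <- read_fasta(resolve(parts[1]))
    ann_text <- readLines(resolve(parts[2]))
    for (rec in recs) {
      ref <- read_reference_annotation(ann_text, seq = rec$seq)
      pred <- predict_secondary_structure(rec$seq, params)
      rep1 <- segment_match(pred, ref, min_overlap_frac)
      n_res <- n_res + nchar(rec$seq)
      n_correct <- n_correct + sum(strsplit(pred$states, "")[[1]] ==
                                     strsplit(ref$states, "")[[1]])
      if (is.null(agg)) {
        agg <- rep1
      } else {
        for (col in c("n_pred", "n_ref", "n_matched")) {
          agg[[col]] <- agg[[col]] + rep1[[col]]
        }
      }
    }
  }
  if (is.null(agg)) stop("empty manifest", call. = FALSE)
  agg$recall <- ifelse(agg$n_ref > 0, agg$n_matched / agg$n_ref, NA_real_)
  agg$precision <- ifelse(agg$n_pred > 0, agg$n_matched / agg$n_pred,
                          NA_real_)
  attr(agg, "residue_accuracy") <- if (n_res) n_correct / n_res else NA_real_
  agg
}
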