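# Side-chain hydrophobic-portion classification and the pairwise lateral
# hydrophobic-attraction rules derived from it.

# Class labels, one per amino acid.  The grouping reflects how much of the
# side-chain is exposed nonpolar surface and whether a hydrophilic terminus
# gets in the way of lateral packing.
.residue_class_table <- local({
  tab <- c(
    C = "FULL_HYDROPHOBIC", I = "FULL_HYDROPHOBIC", L = "FULL_HYDROPHOBIC",
    M = "FULL_HYDROPHOBIC", W = "FULL_HYDROPHOBIC", F = "FULL_HYDROPHOBIC",
    Y = "FULL_HYDROPHOBIC", V = "FULL_HYDROPHOBIC",
    R = "LONG_AMPHIPATHIC", H = "LONG_AMPHIPATHIC", K = "LONG_AMPHIPATHIC",
    E = "LONG_AMPHIPATHIC", Q = "LONG_AMPHIPATHIC",
    D = "LIMITED_POLAR", N = "LIMITED_POLAR",
    A = "ALANINE",
    G = "NEGLIGIBLE",
    P = "PROLINE",
    S = "SHORT_POLAR", T = "SHORT_POLAR"
  )
  tab[order(names(tab))]
})

#' Standard amino-acid alphabet
#'
#' The 20 one-letter codes the package accepts, in alphabetical order.
#'
#' @return Character vector of length 20.
#' @export
amino_acids <- function() names(.residue_class_table)

# RB ("hydrophobic blocking") residues: side-chains that cannot sustain
# lateral hydrophobic attraction; runs of two or more nucleate turns.
.rb_set <- c("D", "N", "S", "P", "G")

.check_aa <- function(aa, arg = "aa") {
  if (!is.character(aa) || length(aa) != 1L || nchar(aa) != 1L) {
    stop(sprintf("'%s' must be a single one-letter amino-acid code", arg),
         call. = FALSE)
  }
  if (!aa %in% amino_acids()) {
    stop(sprintf("unknown residue '%s': not one of the 20 standard amino acids",
                 aa), call. = FALSE)
  }
  aa
}

# Vectorised validation for whole sequences; reports the first bad position.
.check_seq <- function(seq) {
  if (!is.character(seq) || length(seq) != 1L || nchar(seq) < 1L) {
    stop("'seq' must be a non-empty character scalar", call. = FALSE)
  }
  letters <- strsplit(seq, "", fixed = TRUE)[[1]]
  bad <- which(!letters %in% amino_acids())
  if (length(bad)) {
    stop(sprintf("unknown residue '%s' at position %d", letters[bad[1]],
                 bad[1]), call. = FALSE)
  }
  letters
}

#' Classify a residue's hydrophobic portion
#'
#' Assigns each standard amino acid to one of seven side-chain classes by
#' the extent and accessibility of its nonpolar surface:
#' \describe{
#'   \item{FULL_HYDROPHOBIC}{C, I, L, M, W, F, Y, V: the whole side-chain
#'     can engage in hydrophobic contact.}
#'   \item{LONG_AMPHIPATHIC}{R, H, K, E, Q: a long nonpolar stalk capped
#'     by a hydrophilic head; the stalk packs laterally.}
#'   \item{LIMITED_POLAR}{D, N: short side-chains whose exposed nonpolar
#'     portion is too small for effective attraction.}
#'   \item{ALANINE}{A: a methyl short enough to reach the stalk of long
#'     side-chains without clashing with their polar heads.}
#'   \item{NEGLIGIBLE}{G: essentially no side-chain.}
#'   \item{PROLINE}{P: cyclic; lacks the backbone N-H and terminates
#'     strands.}
#'   \item{SHORT_POLAR}{S, T: hydroxyl-bearing; only T carries an extra
#'     methyl that weakly attracts strongly hydrophobic partners.}
#' }
#'
#' @param aa Single upper-case one-letter code.
#' @return A list of class \code{residue_class} with fields \code{aa},
#'   \code{label}, \code{has_backbone_nh}, \code{is_rb}, and
#'   \code{hydrophobic_reach} (0 = none, 1 = short, 2 = long).
#' @examples
#' classify_residue("L")$label
#' classify_residue("K")$hydrophobic_reach
#' @export
classify_residue <- function(aa) {
  .check_aa(aa)
  label <- unname(.residue_class_table[[aa]])
  reach <- switch(label,
    FULL_HYDROPHOBIC = 2L,
    LONG_AMPHIPATHIC = 2L,
    LIMITED_POLAR    = 0L,
    ALANINE          = 1L,
    NEGLIGIBLE       = 0L,
    PROLINE          = 1L,
    SHORT_POLAR      = if (aa == "T") 1L else 0L
  )
  structure(
    list(aa = aa, label = label,
         has_backbone_nh = aa != "P",
         is_rb = aa %in% .rb_set,
         hydrophobic_reach = reach),
    class = "residue_class"
  )
}

#' @export
print.residue_class <- function(x, ...) {
  cat(sprintf("<residue %s> class %s, reach %d, backbone N-H %s, RB %s\n",
              x$aa, x$label, x$hydrophobic_reach,
              if (x$has_backbone_nh) "yes" else "no",
              if (x$is_rb) "yes" else "no"))
  invisible(x)
}

#' Is a residue in the hydrophobic-blocking (RB) group?
#'
#' D, N, S, P and G cannot sustain lateral hydrophobic attraction with
#' their sequence neighbours; runs of two or more of them block attraction
#' on both sides and nucleate turns.
#'
#' @param aa Single one-letter code.
#' @return Logical scalar.
#' @examples
#' is_rb("D")  # TRUE
#' is_rb("T")  # FALSE: the threonine methyl is not blocking
#' @export
is_rb <- function(aa) {
  .check_aa(aa)
  aa %in% .rb_set
}

# The pairwise verdict, derived deterministically from the class table:
#  - any pair touching NEGLIGIBLE (G), LIMITED_POLAR (D/N) or PROLINE: NONE
#  - S never attracts (RB); T attracts only FULL_HYDROPHOBIC or ALANINE
#  - ALANINE attracts FULL_HYDROPHOBIC, LONG_AMPHIPATHIC, ALANINE and T
#  - remaining pairs (FULL x FULL, FULL x LONG, LONG x LONG) attract
.pair_attracts <- function(a1, a2) {
  c1 <- .residue_class_table[[a1]]
  c2 <- .residue_class_table[[a2]]
  blocked <- c("NEGLIGIBLE", "LIMITED_POLAR", "PROLINE")
  if (c1 %in% blocked || c2 %in% blocked) return(FALSE)
  if (a1 == "S" || a2 == "S") return(FALSE)
  if (a1 == "T" || a2 == "T") {
    other <- if (a1 == "T") c2 else c1
    if (a1 == "T" && a2 == "T") return(FALSE)
    return(other %in% c("FULL_HYDROPHOBIC", "ALANINE"))
  }
  if (c1 == "ALANINE" || c2 == "ALANINE") {
    other <- if (c1 == "ALANINE") c2 else c1
    return(other %in% c("FULL_HYDROPHOBIC", "LONG_AMPHIPATHIC", "ALANINE"))
  }
  # both reach >= 2 here: FULL or LONG
  TRUE
}

#' Lateral hydrophobic-attraction verdict for a residue pair
#'
#' Binary verdict on whether the side-chains of two sequence-adjacent
#' residues (at small sequence separation) can laterally collapse their
#' hydrophobic portions together.  A hydrophobic side-chain attracts a
#' hydrophilic one only when it can reach the nonpolar stalk without
#' clashing with the polar head, which rules out the short polar classes.
#'
#' @param aa1,aa2 One-letter codes.
#' @param matrix Optional 20x20 0/1 override matrix as returned by
#'   \code{\link{read_attraction_matrix}}; when supplied the verdict is
#'   looked up instead of derived.
#' @return \code{"ATTRACT"} or \code{"NONE"}; always symmetric.
#' @examples
#' lateral_attraction("L", "L")  # ATTRACT
#' lateral_attraction("G", "V")  # NONE
#' @export
lateral_attraction <- function(aa1, aa2, matrix = NULL) {
  .check_aa(aa1, "aa1")
  .check_aa(aa2, "aa2")
  if (!is.null(matrix)) {
    stopifnot(is.matrix(matrix), all(dim(matrix) == 20L))
    hit <- matrix[aa1, aa2] != 0
  } else {
    hit <- .pair_attracts(aa1, aa2)
  }
  if (hit) "ATTRACT" else "NONE"
}

#' Full 20x20 attraction verdict table
#'
#' Emits the complete pairwise table so that any change to the underlying
#' class rules is visible and deliberate.  Rows and columns are the one-
#' letter codes in alphabetical order; cells are 1 (attract) or 0.
#'
#' @param matrix Optional override matrix, passed through unchanged after
#'   validation.
#' @return Integer matrix with dimnames.
#' @export
attraction_table <- function(matrix = NULL) {
  aas <- amino_acids()
  if (!is.null(matrix)) {
    stopifnot(is.matrix(matrix), all(dim(matrix) == 20L))
    m <- matrix
  } else {
    m <- outer(aas, aas,
               Vectorize(function(a, b) as.integer(.pair_attracts(a, b))))
  }
  dimnames(m) <- list(aas, aas)
  storage.mode(m) <- "integer"
  m
}

#' Read a replacement attraction matrix
#'
#' Plain-text, comma-separated 20x20 table of 0/1 cells, rows and columns
#' in alphabetical one-letter order (no header).  Lets a user swap in
#' their own pairwise rules without touching the class table.
#'
#' @param path File path.
#' @return Integer 20x20 matrix with amino-acid dimnames.
#' @export
read_attraction_matrix <- function(path) {
  m <- as.matrix(utils::read.csv(path, header = FALSE))
  if (!all(dim(m) == 20L)) {
    stop("attraction matrix must be 20x20, got ",
         paste(dim(m), collapse = "x"), call. = FALSE)
  }
  if (!all(m %in% c(0L, 1L))) stop("attraction matrix cells must be 0 or 1",
                                   call. = FALSE)
  if (!isTRUE(all.equal(m, t(m), check.attributes = FALSE))) {
    stop("attraction matrix must be symmetric", call. = FALSE)
  }
  dimnames(m) <- list(amino_acids(), amino_acids())
  storage.mode(m) <- "integer"
  m
}
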