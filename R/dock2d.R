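# Two-rule quaternary-structure predictor on 2D labeled surface patches:
# rule 1 maximizes hydrophobic overlap of the facing projections, rule 2
# requires several donor-acceptor contacts at the placement.

# Pixel labels (also the PGM grey values)
PATCH_LABELS <- c(EMPTY = 0L, HYDROPHOBIC = 1L, DONOR = 2L,
                  ACCEPTOR = 3L, HYDROPHILIC = 4L)

#' Construct a labeled surface-patch image
#'
#' @param grid Integer matrix of labels 0-4 (EMPTY, HYDROPHOBIC, DONOR,
#'   ACCEPTOR, HYDROPHILIC); rows index y, columns x.
#' @param spacing Angstrom per pixel, > 0.
#' @return Matrix of class \code{patch_image} with a \code{spacing}
#'   attribute.
#' @export
patch_image <- function(grid, spacing = 1) {
  grid <- as.matrix(grid)
  dimnames(grid) <- NULL
  storage.mode(grid) <- "integer"
  if (spacing <= 0) stop("spacing must be positive", call. = FALSE)
  if (!all(grid %in% PATCH_LABELS)) {
    stop("patch labels must be integers 0-4", call. = FALSE)
  }
  structure(grid, spacing = spacing, class = c("patch_image", "matrix"))
}

#' @export
print.patch_image <- function(x, ...) {
  cat(sprintf("<patch_image> %dx%d pixels at %g A/px\n",
              nrow(x), ncol(x), attr(x, "spacing")))
  glyph <- c(".", "#", "D", "A", "o")
  for (i in seq_len(nrow(x))) {
    cat(paste(glyph[x[i, ] + 1L], collapse = ""), "\n", sep = "")
  }
  invisible(x)
}

# 90-degree-exact grid transforms.  flip reverses columns (mirror about
# the vertical axis); rotation is counter-clockwise in grid terms.
.rot90 <- function(g) t(g)[rev(seq_len(ncol(g))), , drop = FALSE]

transform_patch <- function(img, rot = 0, flip = FALSE) {
  g <- unclass(img)
  attr(g, "spacing") <- NULL
  if (flip) g <- g[, rev(seq_len(ncol(g))), drop = FALSE]
  rot <- rot %% 360
  if (rot %% 90 == 0) {
    for (k in seq_len((rot %/% 90) %% 4)) g <- .rot90(g)
  } else {
    # nearest-neighbour resample about the grid center; exactness is
    # only claimed for multiples of 90 degrees
    th <- rot * pi / 180
    h <- nrow(g); w <- ncol(g)
    cy <- (h + 1) / 2; cx <- (w + 1) / 2
    hh <- ceiling(abs(h * cos(th)) + abs(w * sin(th)))
    ww <- ceiling(abs(w * cos(th)) + abs(h * sin(th)))
    oy <- (hh + 1) / 2; ox <- (ww + 1) / 2
    out <- matrix(0L, hh, ww)
    for (i in seq_len(hh)) for (j in seq_len(ww)) {
      # inverse-rotate the target pixel into source coordinates
      dy <- i - oy; dx <- j - ox
      sj <- round(cx + dx * cos(th) + dy * sin(th))
      si <- round(cy - dx * sin(th) + dy * cos(th))
      if (si >= 1 && si <= h && sj >= 1 && sj <= w) out[i, j] <- g[si, sj]
    }
    g <- out
  }
  patch_image(g, spacing = if (!is.null(attr(img, "spacing")))
    attr(img, "spacing") else 1)
}

# Score one placement: b_t slid by (dx, dy) relative to a.  Cell (i, j)
# of a faces cell (i - dy, j - dx) of b_t.
.placement_score <- function(a, bt, dx, dy, hb_radius_px) {
  ha <- nrow(a); wa <- ncol(a); hb <- nrow(bt); wb <- ncol(bt)
  i_lo <- max(1L, 1L + dy); i_hi <- min(ha, hb + dy)
  j_lo <- max(1L, 1L + dx); j_hi <- min(wa, wb + dx)
  if (i_lo > i_hi || j_lo > j_hi) return(NULL)
  sub_a <- a[i_lo:i_hi, j_lo:j_hi, drop = FALSE]
  sub_b <- bt[(i_lo - dy):(i_hi - dy), (j_lo - dx):(j_hi - dx),
              drop = FALSE]
  overlap <- sum(sub_a == 1L & sub_b == 1L)
  # donor/acceptor contacts within Chebyshev distance hb_radius_px,
  # counted as pairs in the placed frame
  contacts <- 0L
  da <- which(a == 2L, arr.ind = TRUE); aa <- which(a == 3L, arr.ind = TRUE)
  db <- which(bt == 2L, arr.ind = TRUE); ab <- which(bt == 3L, arr.ind = TRUE)
  count_pairs <- function(pa, pb) {
    if (!nrow(pa) || !nrow(pb)) return(0L)
    tot <- 0L
    for (k in seq_len(nrow(pa))) {
      ddy <- abs((pb[, 1] + dy) - pa[k, 1])
      ddx <- abs((pb[, 2] + dx) - pa[k, 2])
      tot <- tot + sum(pmax(ddy, ddx) <= hb_radius_px)
    }
    tot
  }
  contacts <- count_pairs(da, ab) + count_pairs(aa, db)
  list(overlap = overlap, contacts = contacts)
}

#' Dock two labeled surface patches in 2D
#'
#' Mirrors \code{b} internally (the two projections face each other),
#' then searches exhaustively over rotations, the extra mirror flip, and
#' every integer translation with bounding-box overlap.  The score of a
#' placement is the count of pixels hydrophobic in both images (rule 1);
#' a placement is feasible when at least \code{min_hb} donor-acceptor
#' pairs lie within Chebyshev distance \code{hb_radius_px} of each other
#' (rule 2).  Feasible placements are returned sorted by score
#' descending, ties broken by (flipped, rotation, dx, dy); the search is
#' deterministic.
#'
#' @param a,b \code{\link{patch_image}}s with equal spacing.
#' @param rot_step Rotation step in degrees (default 5); rotations not a
#'   multiple of 90 use nearest-neighbour resampling.
#' @param rotations Optional explicit rotation set overriding
#'   \code{rot_step}.
#' @param min_hb Minimum donor-acceptor contacts for feasibility
#'   (default 3).
#' @param hb_radius_px Chebyshev contact radius in pixels (default 1).
#' @param top_n Maximum number of placements returned (default 50).
#' @return Data frame of class \code{docking_placements}: columns
#'   \code{rotation}, \code{flipped}, \code{dx}, \code{dy},
#'   \code{hydrophobic_overlap}, \code{hb_contacts}, \code{feasible}.
#'   Zero rows with attribute \code{reason = "no feasible placement"}
#'   when rule 2 can never be met (distinct from a feasible placement
#'   with zero overlap).
#' @export
dock_images <- function(a, b, rot_step = 5, rotations = NULL, min_hb = 3L,
                        hb_radius_px = 1L, top_n = 50L) {
  stopifnot(inherits(a, "patch_image"), inherits(b, "patch_image"))
  if (!isTRUE(all.equal(attr(a, "spacing"), attr(b, "spacing")))) {
    stop("patch spacings differ", call. = FALSE)
  }
  if (!any(a != 0L) || !any(b != 0L)) {
    stop("cannot dock an empty patch", call. = FALSE)
  }
  if (is.null(rotations)) rotations <- seq(0, 360 - rot_step, by = rot_step)
  b_face <- transform_patch(b, rot = 0, flip = TRUE)  # facing mirror
  rows <- list()
  for (flip in c(FALSE, TRUE)) {
    for (rot in rotations) {
      bt <- unclass(transform_patch(b_face, rot = rot, flip = flip))
      for (dy in (-(nrow(bt) - 1L)):(nrow(a) - 1L)) {
        for (dx in (-(ncol(bt) - 1L)):(ncol(a) - 1L)) {
          sc <- .placement_score(unclass(a), bt, dx, dy, hb_radius_px)
          if (is.null(sc)) next
          if (sc$contacts < min_hb) next
          rows[[length(rows) + 1L]] <- data.frame(
            rotation = rot, flipped = flip, dx = dx, dy = dy,
            hydrophobic_overlap = sc$overlap, hb_contacts = sc$contacts,
            feasible = TRUE)
        }
      }
    }
  }
  if (!length(rows)) {
    out <- data.frame(rotation = numeric(0), flipped = logical(0),
                      dx = integer(0), dy = integer(0),
                      hydrophobic_overlap = integer(0),
                      hb_contacts = integer(0), feasible = logical(0))
    attr(out, "reason") <- "no feasible placement"
    class(out) <- c("docking_placements", class(out))
    return(out)
  }
  out <- do.call(rbind, rows)
  ord <- order(-out$hydrophobic_overlap, out$flipped, out$rotation,
               out$dx, out$dy)
  out <- out[ord, , drop = FALSE]
  rownames(out) <- NULL
  out <- utils::head(out, top_n)
  class(out) <- c("docking_placements", class(out))
  out
}

#' Project a ball model to a labeled 2D patch
#'
#' Orthographic projection along \code{axis} with a z-buffer: every
#' pixel takes the label of the frontmost atom covering it.  Donor and
#' acceptor flags take precedence (they carry the hydrogen-bond rule),
#' then the hydrophobic class, else hydrophilic.
#'
#' @param m \code{\link{ball_model}}.
#' @param axis Projection direction, nonzero 3-vector.
#' @param spacing Angstrom per pixel.
#' @param donor,acceptor Logical per-atom flags (default all FALSE).
#' @param hydrophobic_class Class index treated as hydrophobic (default
#'   1).
#' @return \code{\link{patch_image}}.
#' @export
project_patch <- function(m, axis = c(0, 0, 1), spacing = 1,
                          donor = NULL, acceptor = NULL,
                          hydrophobic_class = 1L) {
  stopifnot(inherits(m, "ball_model"))
  if (sqrt(sum(axis^2)) == 0) stop("zero projection axis", call. = FALSE)
  at <- m$atoms
  n <- nrow(at)
  if (is.null(donor)) donor <- rep(FALSE, n)
  if (is.null(acceptor)) acceptor <- rep(FALSE, n)
  w <- axis / sqrt(sum(axis^2))
  # any unit vector not parallel to w
  seed <- if (abs(w[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  u <- seed - sum(seed * w) * w
  u <- u / sqrt(sum(u^2))
  v <- c(w[2] * u[3] - w[3] * u[2],
         w[3] * u[1] - w[1] * u[3],
         w[1] * u[2] - w[2] * u[1])
  centers <- as.matrix(at[, c("x", "y", "z")])
  cu <- centers %*% u; cv <- centers %*% v; cw <- centers %*% w
  u_lo <- min(cu - at$r); u_hi <- max(cu + at$r)
  v_lo <- min(cv - at$r); v_hi <- max(cv + at$r)
  gu <- seq(u_lo + spacing / 2, u_hi, by = spacing)
  gv <- seq(v_lo + spacing / 2, v_hi, by = spacing)
  grid <- matrix(0L, length(gv), length(gu))
  zbuf <- matrix(-Inf, length(gv), length(gu))
  for (a in seq_len(n)) {
    label <- if (donor[a]) 2L else if (acceptor[a]) 3L
      else if (at$hclass[a] == hydrophobic_class) 1L else 4L
    for (i in seq_along(gv)) {
      dv2 <- (gv[i] - cv[a])^2
      if (dv2 > at$r[a]^2) next
      du2 <- (gu - cu[a])^2
      hit <- which(du2 + dv2 <= at$r[a]^2)
      if (!length(hit)) next
      height <- cw[a] + sqrt(at$r[a]^2 - du2[hit] - dv2)
      front <- height > zbuf[i, hit]
      zbuf[i, hit[front]] <- height[front]
      grid[i, hit[front]] <- label
    }
  }
  patch_image(grid, spacing = spacing)
}

#' Read and write patches as PGM (P2) or CSV
#'
#' PGM files use grey values 0-4 with the label mapping 0 EMPTY,
#' 1 HYDROPHOBIC, 2 DONOR, 3 ACCEPTOR, 4 HYDROPHILIC; CSV files are
#' headerless label grids.  Spacing is stored in a PGM comment line and
#' defaults to 1 for CSV.
#'
#' @param img \code{\link{patch_image}}.
#' @param path File path; extension \code{.pgm} or \code{.csv} selects
#'   the format.
#' @return \code{read_patch} returns a \code{patch_image};
#'   \code{write_patch} returns \code{path} invisibly.
#' @export
write_patch <- function(img, path) {
  stopifnot(inherits(img, "patch_image"))
  g <- unclass(img)
  if (grepl("\\.pgm$", path, ignore.case = TRUE)) {
    lines <- c("P2",
               sprintf("# spacing %.17g A/px; labels 0=EMPTY 1=HYDROPHOBIC 2=DONOR 3=ACCEPTOR 4=HYDROPHILIC",
                       attr(img, "spacing")),
               sprintf("%d %d", ncol(g), nrow(g)), "4",
               apply(g, 1L, paste, collapse = " "))
    writeLines(lines, path)
  } else {
    utils::write.table(g, path, sep = ",", row.names = FALSE,
                       col.names = FALSE)
  }
  invisible(path)
}

#' @rdname write_patch
#' @export
read_patch <- function(path) {
  if (grepl("\\.pgm$", path, ignore.case = TRUE)) {
    lines <- readLines(path)
    if (lines[1] != "P2") stop("only plain (P2) PGM is supported",
                               call. = FALSE)
    spacing <- 1
    comments <- grep("^#", lines)
    for (cm in comments) {
      hit <- regmatches(lines[cm],
                        regexec("spacing ([0-9.eE+-]+)", lines[cm]))[[1]]
      if (length(hit) == 2L) spacing <- as.numeric(hit[2])
    }
    body <- lines[-c(1L, comments)]
    nums <- as.integer(unlist(strsplit(trimws(body), "[[:space:]]+")))
    wd <- nums[1]; ht <- nums[2]
    vals <- nums[-(1:3)]  # drop width, height, maxval
    if (length(vals) != wd * ht) stop("corrupt PGM pixel count",
                                      call. = FALSE)
    patch_image(matrix(vals, nrow = ht, ncol = wd, byrow = TRUE),
                spacing = spacing)
  } else {
    patch_image(as.matrix(utils::read.csv(path, header = FALSE)),
                spacing = 1)
  }
}
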