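# Independent oracles used by the geometry and docking tests.  These are
# deliberately written against the mathematics, not the package code.

# Closed-form area/volume of the union of two equal spheres of radius r
# with center distance d < 2r (spherical-cap formulas).
two_sphere_union <- function(r, d) {
  stopifnot(d > 0, d < 2 * r)
  h <- r - d / 2                      # cap height cut off each sphere
  area <- 2 * (4 * pi * r^2) - 2 * (2 * pi * r * h)
  volume <- 2 * (4 / 3) * pi * r^3 - 2 * (pi * h^2 * (3 * r - h) / 3)
  list(area = area, volume = volume)
}

# Brute-force docking re-scorer, independent of dock_images: works on
# coordinate lists, rotates by explicit coordinate maps, and returns the
# best feasible score over the full discrete search space.
brute_force_dock <- function(a, b, min_hb = 3L, hb_radius_px = 1L) {
  cells <- function(g) {
    idx <- which(g != 0L, arr.ind = TRUE)
    data.frame(i = idx[, 1], j = idx[, 2], lab = g[idx])
  }
  rot_cells <- function(cs, h, w, rot) {
    # counter-clockwise grid rotation: same convention as t() + row rev
    switch(as.character(rot),
      "0"   = list(cs = cs, h = h, w = w),
      "90"  = list(cs = data.frame(i = w - cs$j + 1L, j = cs$i,
                                   lab = cs$lab), h = w, w = h),
      "180" = list(cs = data.frame(i = h - cs$i + 1L, j = w - cs$j + 1L,
                                   lab = cs$lab), h = h, w = w),
      "270" = list(cs = data.frame(i = cs$j, j = h - cs$i + 1L,
                                   lab = cs$lab), h = w, w = h))
  }
  mirror_cells <- function(cs, w) {
    data.frame(i = cs$i, j = w - cs$j + 1L, lab = cs$lab)
  }
  ga <- unclass(a); gb <- unclass(b)
  ca <- cells(ga)
  best <- -Inf
  for (flip in c(FALSE, TRUE)) {
    base <- mirror_cells(cells(gb), ncol(gb))          # facing mirror
    if (flip) base <- mirror_cells(base, ncol(gb))     # extra mirror
    for (rot in c(0, 90, 180, 270)) {
      rc <- rot_cells(base, nrow(gb), ncol(gb), rot)
      cs <- rc$cs
      for (dy in (-(rc$h - 1L)):(nrow(ga) - 1L)) {
        for (dx in (-(rc$w - 1L)):(ncol(ga) - 1L)) {
          # b cell (i, j) lands on a cell (i + dy, j + dx)
          bi <- cs$i + dy; bj <- cs$j + dx
          keep <- bi >= 1L & bi <= nrow(ga) & bj >= 1L & bj <= ncol(ga)
          if (!any(keep)) next
          placed <- data.frame(i = bi[keep], j = bj[keep],
                               lab = cs$lab[keep])
          key_a <- paste(ca$i, ca$j)
          key_b <- paste(placed$i, placed$j)
          overlap <- sum(ca$lab[match(key_b, key_a)] == 1L &
                           placed$lab == 1L, na.rm = TRUE)
          contacts <- 0L
          for (pa in which(ca$lab %in% c(2L, 3L))) {
            want <- if (ca$lab[pa] == 2L) 3L else 2L
            hits <- placed$lab == want &
              pmax(abs(placed$i - ca$i[pa]),
                   abs(placed$j - ca$j[pa])) <= hb_radius_px
            contacts <- contacts + sum(hits)
          }
          if (contacts >= min_hb && overlap > best) best <- overlap
        }
      }
    }
  }
  best
}

# Micro corpus with hand-checkable survey statistics.
micro_corpus <- function() {
  list(
    list(seq = "LVLVGGLVLV", states = "EEEETTEEEE"),  # hairpin, RB turn
    list(seq = "LVLVAALVLV", states = "EEEETTEEEE"),  # hairpin, no RB
    list(seq = "LAEELAEEGG", states = "HHHHHHHHTT"),  # trailing RB turn
    list(seq = "TSTSTSTSTS", states = "CCCCCCCCCC"),  # pure coil
    list(seq = "LVLVLVLVLV", states = "EEEEEEEEEE")   # pure strand
  )
}
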