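# Union-of-balls (CPK) molecular models and the numerical surface/volume
# estimator behind the conformational Gibbs functional.

#' Construct a union-of-balls model
#'
#' @param x,y,z Atom centers, Angstrom.
#' @param r Van der Waals radii, Angstrom, all positive.
#' @param hclass Hydrophobicity class index per atom, in 1..class_count.
#' @param z_protons Proton count per atom (drives the Coulomb term);
#'   default 0.
#' @param class_count Number of hydrophobicity classes l; defaults to
#'   \code{max(hclass)}.
#' @return List of class \code{ball_model} with a data.frame
#'   \code{atoms} and \code{class_count}.
#' @export
ball_model <- function(x, y, z, r, hclass = 1L, z_protons = 0,
                       class_count = NULL) {
  n <- length(x)
  stopifnot(length(y) == n, length(z) == n, n >= 1L)
  r <- rep_len(r, n); hclass <- rep_len(as.integer(hclass), n)
  z_protons <- rep_len(z_protons, n)
  if (any(r <= 0)) stop("all radii must be positive", call. = FALSE)
  if (any(z_protons < 0)) stop("proton counts must be >= 0", call. = FALSE)
  if (is.null(class_count)) class_count <- max(hclass)
  if (any(hclass < 1L | hclass > class_count)) {
    stop("hclass indices must lie in 1..class_count", call. = FALSE)
  }
  structure(list(atoms = data.frame(x = x, y = y, z = z, r = r,
                                    hclass = hclass,
                                    z_protons = z_protons),
                 class_count = as.integer(class_count)),
            class = "ball_model")
}

#' @export
print.ball_model <- function(x, ...) {
  cat(sprintf("<ball_model> %d atoms, %d hydrophobicity class(es)\n",
              nrow(x$atoms), x$class_count))
  invisible(x)
}

#' Gibbs-functional parameters
#'
#' None of these constants is tabulated anywhere authoritative; the
#' defaults are documented toy values that respect the required sign
#' structure (see \code{\link{validate_omega_order}}).
#'
#' @param omega_e Per-volume chemical potential of an electron,
#'   energy/A^3, must be > 0 (default 0.01).
#' @param d_w Water-molecule diameter, Angstrom (default 2.8).
#' @param omega Per-class surface chemical potentials, energy/A^2, one
#'   per hydrophobicity class; positive = hydrophobic (repels water),
#'   negative = hydrophilic.  Default \code{c(0.05, -0.05)}.
#' @param coulomb_k The constant e^2/(4 pi eps) folded into one scalar,
#'   energy * Angstrom (default 0: geometry-only).
#' @param n_sphere_points Quasi-uniform sample points per atom sphere for
#'   area estimation (default 960).
#' @param voxel_edge Voxel edge for volume counting, Angstrom (default
#'   0.2).
#' @return List of class \code{gibbs_params}.
#' @export
gibbs_params <- function(omega_e = 0.01, d_w = 2.8,
                         omega = c(0.05, -0.05), coulomb_k = 0,
                         n_sphere_points = 960L, voxel_edge = 0.2) {
  stopifnot(omega_e > 0, d_w >= 0, length(omega) >= 1L,
            n_sphere_points >= 8L, voxel_edge > 0)
  structure(list(omega_e = omega_e, d_w = d_w, omega = omega,
                 coulomb_k = coulomb_k,
                 n_sphere_points = as.integer(n_sphere_points),
                 voxel_edge = voxel_edge),
            class = "gibbs_params")
}

#' Check the required ordering of surface chemical potentials
#'
#' The class potentials must admit an ordering
#' \eqn{\omega_1 > \dots > \omega_k > 0 > \dots > \omega_l}: strictly
#' decreasing, with no class exactly at zero.  The check is available
#' rather than assumed; geometry estimation does not need it, the energy
#' interpretation does.
#'
#' @param omega Numeric vector of class potentials.
#' @return TRUE invisibly, or an error describing the violation.
#' @export
validate_omega_order <- function(omega) {
  if (any(omega == 0)) {
    stop("no surface chemical potential may be exactly zero",
         call. = FALSE)
  }
  if (is.unsorted(rev(sort(omega, decreasing = TRUE))) ||
      any(diff(sort(omega, decreasing = TRUE)) == 0)) {
    stop("surface chemical potentials must be strictly ordered",
         call. = FALSE)
  }
  invisible(TRUE)
}

# Deterministic quasi-uniform unit-sphere directions (Fibonacci lattice).
.fibonacci_sphere <- function(n) {
  i <- seq_len(n) - 0.5
  phi <- (1 + sqrt(5)) / 2
  theta <- 2 * pi * i / phi
  zc <- 1 - 2 * i / n
  rho <- sqrt(pmax(0, 1 - zc^2))
  cbind(rho * cos(theta), rho * sin(theta), zc)
}

#' Estimate union volume, boundary area, and per-class areas
#'
#' Area by quasi-uniform sphere-point sampling: a sample point on atom
#' a's sphere belongs to the boundary iff it lies outside every other
#' ball; the atom contributes its exposed fraction times 4 pi r^2.  Each
#' boundary point is assigned to exactly one hydrophobicity class -- the
#' class whose ball set is nearest (its own atom's class except on
#' measure-zero ties), so the class areas partition the total exactly.
#' Volume by voxel-center counting over the bounding box.
#'
#' @param m \code{\link{ball_model}}.
#' @param p \code{\link{gibbs_params}}.
#' @return List of class \code{surface_estimate}: \code{volume},
#'   \code{area_total}, \code{area_by_class} (length l),
#'   \code{n_components} (connected components of the ball overlap
#'   graph), and method metadata.
#' @export
estimate_geometry <- function(m, p = gibbs_params()) {
  stopifnot(inherits(m, "ball_model"), inherits(p, "gibbs_params"))
  at <- m$atoms
  n <- nrow(at)
  if (any(at$r <= 0)) stop("degenerate zero-radius atom", call. = FALSE)
  dirs <- .fibonacci_sphere(p$n_sphere_points)
  centers <- as.matrix(at[, c("x", "y", "z")])
  area_class <- numeric(m$class_count)
  area_total <- 0
  for (a in seq_len(n)) {
    pts <- sweep(dirs * at$r[a], 2L, centers[a, ], `+`)
    exposed <- rep(TRUE, nrow(pts))
    for (b in seq_len(n)) {
      if (b == a) next
      d2 <- (pts[, 1] - centers[b, 1])^2 + (pts[, 2] - centers[b, 2])^2 +
        (pts[, 3] - centers[b, 3])^2
      exposed <- exposed & d2 > at$r[b]^2
      if (!any(exposed)) break
    }
    n_exp <- sum(exposed)
    if (n_exp == 0L) next
    w <- 4 * pi * at$r[a]^2 / p$n_sphere_points
    if (m$class_count == 1L) {
      area_class[1L] <- area_class[1L] + n_exp * w
    } else {
      # nearest-class rule: signed distance |y - x_b| - r_b minimized per
      # class; the owning atom gives 0 for its own class
      epts <- pts[exposed, , drop = FALSE]
      best <- matrix(Inf, nrow(epts), m$class_count)
      for (b in seq_len(n)) {
        db <- sqrt((epts[, 1] - centers[b, 1])^2 +
                   (epts[, 2] - centers[b, 2])^2 +
                   (epts[, 3] - centers[b, 3])^2) - at$r[b]
        cb <- at$hclass[b]
        best[, cb] <- pmin(best[, cb], db)
      }
      cls <- max.col(-best, ties.method = "first")
      tab <- tabulate(cls, nbins = m$class_count)
      area_class <- area_class + tab * w
    }
    area_total <- area_total + n_exp * w
  }
  # volume by voxel-center counting
  h <- p$voxel_edge
  # irrational grid offset de-aligns voxel centers from atom centers,
  # avoiding the lattice-count bias of a sphere sitting on a grid node
  off <- h * (sqrt(2) - 1)
  lo <- apply(centers - at$r, 2, min) - h + off
  hi <- apply(centers + at$r, 2, max) + h
  gx <- seq(lo[1], hi[1], by = h)
  gy <- seq(lo[2], hi[2], by = h)
  gz <- seq(lo[3], hi[3], by = h)
  inside_cols <- 0
  # slice along z to bound memory
  for (zc in gz) {
    gxy <- expand.grid(x = gx, y = gy)
    inside <- rep(FALSE, nrow(gxy))
    for (b in seq_len(n)) {
      dz2 <- (zc - centers[b, 3])^2
      if (dz2 > at$r[b]^2) next
      d2 <- (gxy$x - centers[b, 1])^2 + (gxy$y - centers[b, 2])^2 + dz2
      inside <- inside | d2 <= at$r[b]^2
    }
    inside_cols <- inside_cols + sum(inside)
  }
  volume <- inside_cols * h^3
  # connected components of the overlap graph (balls touching/overlapping)
  comp <- seq_len(n)
  find <- function(i) { while (comp[i] != i) i <- comp[i]; i }
  if (n > 1L) {
    for (a in seq_len(n - 1L)) for (b in (a + 1L):n) {
      if (sum((centers[a, ] - centers[b, ])^2) <=
          (at$r[a] + at$r[b])^2) {
        comp[find(b)] <- find(a)
      }
    }
  }
  n_components <- length(unique(vapply(seq_len(n), find, integer(1))))
  structure(list(volume = volume, area_total = area_total,
                 area_by_class = area_class,
                 n_components = n_components,
                 n_sphere_points = p$n_sphere_points,
                 voxel_edge = h),
            class = "surface_estimate")
}

#' @export
print.surface_estimate <- function(x, ...) {
  cat(sprintf("<surface_estimate> V = %.3f A^3, A = %.3f A^2 (%d pts/atom, voxel %.2f A)\n",
              x$volume, x$area_total, x$n_sphere_points, x$voxel_edge))
  cat("  area by class:", paste(sprintf("%.3f", x$area_by_class),
                                collapse = ", "), "\n")
  invisible(x)
}

#' Dump / load a ball model as tabular text
#'
#' Whitespace-separated columns x, y, z, r, hclass, z_protons with a
#' header; round-trips losslessly at full double precision.
#'
#' @param m \code{\link{ball_model}}.
#' @param path File path.
#' @return \code{read_ball_model} returns a \code{ball_model};
#'   \code{write_ball_model} returns \code{path} invisibly.
#' @export
write_ball_model <- function(m, path) {
  stopifnot(inherits(m, "ball_model"))
  df <- m$atoms
  utils::write.table(format(df, digits = 17, trim = TRUE), path,
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_ball_model
#' @export
read_ball_model <- function(path) {
  df <- utils::read.table(path, header = TRUE)
  ball_model(df$x, df$y, df$z, df$r, df$hclass, df$z_protons)
}
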