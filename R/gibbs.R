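# The conformational Gibbs free-energy functional, its force
# decomposition, and a toy gradient-descent relaxer.
#
# G(X) = omega_e V(Omega_X) + omega_e d_w A(Sigma_X)
#        + sum_i omega_i A(Sigma_X,i)
#        + coulomb_k sum_{a<b} Z_a Z_b / |x_a - x_b|
#
# The first two terms (volume plus a water-diameter-thick boundary
# layer) give the packing force, the class-weighted area term the
# aqueous force, and the Coulomb term the expansion force; each force is
# minus the finite-difference gradient of its term group.

.coulomb_sum <- function(centers, zp, k) {
  n <- nrow(centers)
  if (k == 0 || n < 2L || all(zp == 0)) return(0)
  s <- 0
  for (a in seq_len(n - 1L)) for (b in (a + 1L):n) {
    if (zp[a] == 0 || zp[b] == 0) next
    d <- sqrt(sum((centers[a, ] - centers[b, ])^2))
    if (d == 0) {
      stop("coincident charged atom centers: Coulomb term is singular",
           call. = FALSE)
    }
    s <- s + zp[a] * zp[b] / d
  }
  k * s
}

# The three term groups evaluated at the model's current coordinates.
.gibbs_terms <- function(m, p) {
  if (length(p$omega) < m$class_count) {
    stop(sprintf("gibbs_params supplies %d omega value(s) but the model has %d classes",
                 length(p$omega), m$class_count), call. = FALSE)
  }
  est <- estimate_geometry(m, p)
  packing <- p$omega_e * est$volume + p$omega_e * p$d_w * est$area_total
  aqueous <- sum(p$omega[seq_len(m$class_count)] * est$area_by_class)
  expansion <- .coulomb_sum(as.matrix(m$atoms[, c("x", "y", "z")]),
                            m$atoms$z_protons, p$coulomb_k)
  c(packing = packing, aqueous = aqueous, expansion = expansion)
}

#' Conformational Gibbs free energy of a ball model
#'
#' Evaluates the four-term functional: electron-volume term, thin
#' water-layer area term, hydrophobicity-class-weighted area term, and
#' the pairwise Coulomb sum over unordered distinct atom pairs.
#'
#' @param m \code{\link{ball_model}}.
#' @param p \code{\link{gibbs_params}}.
#' @return Energy scalar with attribute \code{"terms"} giving the
#'   packing/aqueous/expansion split.
#' @export
gibbs_free_energy <- function(m, p = gibbs_params()) {
  stopifnot(inherits(m, "ball_model"), inherits(p, "gibbs_params"))
  terms <- .gibbs_terms(m, p)
  structure(sum(terms), terms = terms)
}

.shift_atom <- function(m, a, dim, h) {
  m$atoms[[dim]][a] <- m$atoms[[dim]][a] + h
  m
}

#' Intrinsic folding forces by central finite differences
#'
#' For every atom and coordinate, each term group of the functional is
#' re-evaluated at +/- h and differenced, yielding the packing, aqueous,
#' and expansion force; the total is their sum, hence exactly equal to
#' the central difference of the full functional (the decomposition is
#' exact by linearity).  The area estimator is piecewise constant in the
#' coordinates, so forces on small models are quantized at the sample
#' resolution; the relaxer copes via a backtracking line search.
#'
#' @param m \code{\link{ball_model}}.
#' @param p \code{\link{gibbs_params}}.
#' @param h Finite-difference step, Angstrom (default 0.01).
#' @return List of class \code{force_decomposition} with n x 3 matrices
#'   \code{total}, \code{packing}, \code{aqueous}, \code{expansion}.
#' @export
intrinsic_forces <- function(m, p = gibbs_params(), h = 0.01) {
  stopifnot(inherits(m, "ball_model"), inherits(p, "gibbs_params"))
  if (h <= 0) stop("finite-difference step h must be positive",
                   call. = FALSE)
  n <- nrow(m$atoms)
  packing <- aqueous <- expansion <- matrix(0, n, 3,
                                            dimnames = list(NULL,
                                                            c("x", "y", "z")))
  for (a in seq_len(n)) {
    for (d in 1:3) {
      dim <- c("x", "y", "z")[d]
      tp <- .gibbs_terms(.shift_atom(m, a, dim, +h), p)
      tm <- .gibbs_terms(.shift_atom(m, a, dim, -h), p)
      g <- (tp - tm) / (2 * h)   # gradient of each term group
      packing[a, d] <- -g[["packing"]]
      aqueous[a, d] <- -g[["aqueous"]]
      expansion[a, d] <- -g[["expansion"]]
    }
  }
  structure(list(total = packing + aqueous + expansion,
                 packing = packing, aqueous = aqueous,
                 expansion = expansion, h = h),
            class = "force_decomposition")
}

#' @export
print.force_decomposition <- function(x, ...) {
  cat(sprintf("<force_decomposition> %d atoms (h = %g A)\n",
              nrow(x$total), x$h))
  cat("  max |total force| =", max(sqrt(rowSums(x$total^2))), "\n")
  invisible(x)
}

#' Relax a ball model by gradient descent on the Gibbs functional
#'
#' Moves atom centers along the total intrinsic force with a
#' backtracking line search: a step is accepted only if it lowers G,
#' otherwise it is halved up to \code{max_backtracks} times.  Stops when
#' the largest per-atom force norm falls below \code{force_tol}, when no
#' acceptable step exists, or at the iteration cap.  With backtracking
#' the recorded G sequence is nonincreasing by construction.
#'
#' @param m \code{\link{ball_model}}.
#' @param p \code{\link{gibbs_params}}.
#' @param step Initial step length, Angstrom.
#' @param max_iters Iteration cap.
#' @param force_tol Convergence threshold on the max per-atom force norm.
#' @param h Finite-difference step for the forces.
#' @param max_backtracks Step halvings allowed per iteration.
#' @return List of class \code{relax_result}: final \code{model},
#'   \code{g_values} (G at start and after every accepted step),
#'   \code{trajectory} (list of models), \code{converged},
#'   \code{iterations}.
#' @export
relax <- function(m, p = gibbs_params(), step = 0.1, max_iters = 50L,
                  force_tol = 1e-4, h = 0.01, max_backtracks = 8L) {
  stopifnot(inherits(m, "ball_model"), inherits(p, "gibbs_params"))
  if (step <= 0) stop("step must be positive", call. = FALSE)
  g0 <- as.numeric(gibbs_free_energy(m, p))
  g_values <- g0
  trajectory <- list(m)
  converged <- FALSE
  iter <- 0L
  while (iter < max_iters) {
    f <- intrinsic_forces(m, p, h)
    fmax <- max(sqrt(rowSums(f$total^2)))
    if (fmax < force_tol) { converged <- TRUE; break }
    dir <- f$total / fmax          # normalized by the largest atom force
    s <- step
    accepted <- FALSE
    for (bt in seq_len(max_backtracks + 1L)) {
      trial <- m
      trial$atoms$x <- m$atoms$x + s * dir[, 1]
      trial$atoms$y <- m$atoms$y + s * dir[, 2]
      trial$atoms$z <- m$atoms$z + s * dir[, 3]
      g_trial <- as.numeric(gibbs_free_energy(trial, p))
      if (g_trial < g_values[length(g_values)]) {
        m <- trial
        g_values <- c(g_values, g_trial)
        trajectory <- c(trajectory, list(m))
        accepted <- TRUE
        break
      }
      s <- s / 2
    }
    iter <- iter + 1L
    if (!accepted) { converged <- TRUE; break }  # no descent step found
  }
  structure(list(model = m, g_values = g_values, trajectory = trajectory,
                 converged = converged, iterations = iter),
            class = "relax_result")
}

#' @export
print.relax_result <- function(x, ...) {
  cat(sprintf("<relax_result> %d iterations, G %.4f -> %.4f, %s\n",
              x$iterations, x$g_values[1], x$g_values[length(x$g_values)],
              if (x$converged) "converged" else "hit iteration cap"))
  invisible(x)
}
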