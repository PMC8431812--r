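# Smaller sampling than the defaults keeps these tests fast; the
# geometry accuracy itself is covered in test-geometry.R.
fast_params <- function(...) {
  gibbs_params(n_sphere_points = 480L, voxel_edge = 0.25, ...)
}

test_that("the functional sums its four terms", {
  # single ball, no charge, omega_1 = 1, omega_e = 1, d_w = 0: G = V + A
  p <- gibbs_params(omega_e = 1, d_w = 0, omega = 1, coulomb_k = 0)
  m <- ball_model(0, 0, 0, 1.4, hclass = 1L, class_count = 1L)
  est <- estimate_geometry(m, p)
  g <- gibbs_free_energy(m, p)
  expect_equal(as.numeric(g), est$volume + est$area_total)
  # two distant unit charges at distance 2 with k = 1: Coulomb term 1/2
  pc <- gibbs_params(omega = c(0.05, -0.05), coulomb_k = 1)
  mc <- ball_model(c(0, 2), c(0, 0), c(0, 0), 0.4, hclass = c(1L, 2L),
                   z_protons = 1, class_count = 2L)
  terms <- attr(gibbs_free_energy(mc, pc), "terms")
  expect_identical(terms[["expansion"]], 0.5)
  # coincident charged centers are singular
  bad <- ball_model(c(0, 0), c(0, 0), c(0, 0), 0.4, z_protons = 1)
  expect_error(gibbs_free_energy(bad, pc), "singular")
  # model with more classes than omega values is refused
  expect_error(gibbs_free_energy(mc, gibbs_params(omega = 0.05)), "classes")
})

test_that("hydrophobic overlap lowers the energy", {
  p <- fast_params(omega = 0.05)
  near <- ball_model(c(0, 1.4), c(0, 0), c(0, 0), 1.4, hclass = 1L,
                     class_count = 1L)
  far <- ball_model(c(0, 10), c(0, 0), c(0, 0), 1.4, hclass = 1L,
                    class_count = 1L)
  expect_lt(as.numeric(gibbs_free_energy(near, p)),
            as.numeric(gibbs_free_energy(far, p)))
})

test_that("forces decompose exactly and behave at symmetry", {
  p <- fast_params(omega = 0.05)
  m <- ball_model(c(0, 6), c(0, 0), c(0, 0), 3.5, hclass = 1L,
                  class_count = 1L)
  f <- intrinsic_forces(m, p)
  # decomposition identity holds to machine precision by construction
  expect_identical(f$total, f$packing + f$aqueous + f$expansion)
  # equal magnitude, opposite direction, pointing inward (attraction)
  expect_gt(f$total[1, "x"], 0)
  expect_lt(f$total[2, "x"], 0)
  expect_equal(f$total[1, "x"], -f$total[2, "x"], tolerance = 1e-9)
  # total equals the central difference of the full functional
  h <- 0.01
  m_up <- m; m_up$atoms$x[1] <- m_up$atoms$x[1] + h
  m_dn <- m; m_dn$atoms$x[1] <- m_dn$atoms$x[1] - h
  g_up <- as.numeric(gibbs_free_energy(m_up, p))
  g_dn <- as.numeric(gibbs_free_energy(m_dn, p))
  fd <- -(g_up - g_dn) / (2 * h)
  expect_equal(as.numeric(f$total[1, "x"]), fd, tolerance = 1e-6)
  expect_error(intrinsic_forces(m, p, h = 0), "positive")
})

test_that("an isolated ball feels no net force", {
  p <- fast_params(omega = 0.05)
  f <- intrinsic_forces(ball_model(0, 0, 0, 1.4, class_count = 1L), p)
  expect_true(all(abs(f$total) < 1e-9))
})

test_that("the expansion force matches the analytic Coulomb derivative", {
  # point-like balls, surface terms switched off by tiny omegas
  p <- gibbs_params(omega_e = 1e-12, omega = c(1e-12, -1e-12),
                    coulomb_k = 1, n_sphere_points = 128L, voxel_edge = 0.5)
  m <- ball_model(c(0, 2), c(0, 0), c(0, 0), 0.3, hclass = c(1L, 2L),
                  z_protons = 1, class_count = 2L)
  f <- intrinsic_forces(m, p)
  # force magnitude Z^2 k / d^2 = 1/4, repulsive along x
  expect_equal(as.numeric(abs(f$expansion[1, "x"])), 0.25,
               tolerance = 0.01)
  expect_lt(f$expansion[1, "x"], 0)
  expect_gt(f$expansion[2, "x"], 0)
})

test_that("relaxation descends the functional", {
  p <- fast_params(omega = 0.05)
  # already stationary: a single ball stops immediately, center unchanged
  single <- ball_model(0, 0, 0, 1.4, class_count = 1L)
  r0 <- relax(single, p, step = 0.1, max_iters = 5)
  expect_true(r0$converged)
  expect_lte(r0$iterations, 1L)
  expect_identical(r0$model$atoms$x, single$atoms$x)
  # overlapping hydrophobic pair: distance shrinks, G drops monotonically
  m <- ball_model(c(0, 6), c(0, 0), c(0, 0), 3.5, hclass = 1L,
                  class_count = 1L)
  res <- relax(m, p, step = 0.2, max_iters = 6)
  expect_true(all(diff(res$g_values) < 0))
  d_final <- abs(diff(res$model$atoms$x))
  expect_lt(d_final, 6)
  expect_lt(res$g_values[length(res$g_values)], res$g_values[1])
  # the first accepted step shrinks the hydrophobic surface
  a0 <- estimate_geometry(m, p)$area_by_class[1]
  a1 <- estimate_geometry(res$trajectory[[2]], p)$area_by_class[1]
  expect_lt(a1, a0)
  expect_error(relax(m, p, step = 0), "positive")
})
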