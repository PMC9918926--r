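test_that("single right-triangle stiffness matches the hand cotangent formula", {
  nodes <- rbind(c(0, 0), c(1, 0), c(0, 1))
  elements <- matrix(c(1L, 2L, 3L), 1L)
  boundary <- rbind(c(1L, 2L), c(2L, 3L), c(3L, 1L))
  m <- eitclass:::new_torso_mesh(nodes, elements, boundary,
                                 electrodes = list(1L, 2L))
  K <- as.matrix(assemble_system(m, 1.0))
  # For the unit right triangle: K = [[1, -1/2, -1/2], [-1/2, 1/2, 0],
  # [-1/2, 0, 1/2]] (cotangent weights).
  expect_equal(K, rbind(c(1, -0.5, -0.5), c(-0.5, 0.5, 0), c(-0.5, 0, 0.5)),
               tolerance = 1e-14)
})

test_that("stiffness has the constant null space and is linear in sigma", {
  m <- coarse_torso_mesh()
  K <- assemble_system(m, 1.0)
  expect_lt(max(abs(K %*% rep(1, nrow(m$nodes)))), 1e-12 * max(abs(K)))
  K3 <- assemble_system(m, 3.0)
  expect_equal(as.matrix(K3), 3 * as.matrix(K), tolerance = 1e-15)
  expect_error(assemble_system(m, -1), "positive")
})

test_that("solutions scale exactly with current and inversely with sigma", {
  m <- coarse_torso_mesh()
  sig <- rep(0.2, nrow(m$elements))
  u1 <- solve_injection(m, sig, 1L, 5L, 1e-3)
  u2 <- solve_injection(m, sig, 1L, 5L, 2e-3)
  expect_equal(u2, 2 * u1, tolerance = 1e-12)
  u3 <- solve_injection(m, 3 * sig, 1L, 5L, 1e-3)
  expect_equal(u3, u1 / 3, tolerance = 1e-12)
})

test_that("frames are deterministic and inherit protocol length", {
  m <- coarse_torso_mesh()
  p <- default_protocol(8L)
  sig <- rep(0.2, nrow(m$elements))
  f1 <- simulate_frame(m, sig, p)
  f2 <- simulate_frame(m, sig, p)
  expect_equal(f1$m, 32L)
  expect_identical(f1$values, f2$values)
})

test_that("a zero-contrast inclusion leaves the frame unchanged", {
  m <- coarse_torso_mesh()
  p <- default_protocol(8L)
  sig <- rep(0.2, nrow(m$elements))
  f_hom <- simulate_frame(m, sig, p)
  set.seed(3)
  shape <- sample_inclusion(outline = m$outline)
  y <- labels_from_shape(m, shape)
  f_inc <- simulate_frame(m, conductivity_from_labels(y, 0.2, 0.2), p)
  expect_identical(f_inc$values, f_hom$values)
})

test_that("discrete reciprocity holds on random conductivity fields", {
  m <- coarse_torso_mesh()
  set.seed(11)
  for (trial in 1:20) {
    sig <- exp(stats::rnorm(nrow(m$elements), log(0.3), 0.5))
    pair1 <- sample(1:8, 2L)
    pair2 <- sample(setdiff(1:8, pair1), 2L)
    u12 <- solve_injection(m, sig, pair1[1L], pair1[2L], 1e-3)
    u34 <- solve_injection(m, sig, pair2[1L], pair2[2L], 1e-3)
    v1 <- electrode_potential(m, u12, pair2[1L]) -
      electrode_potential(m, u12, pair2[2L])
    v2 <- electrode_potential(m, u34, pair1[1L]) -
      electrode_potential(m, u34, pair1[2L])
    expect_lt(abs(v1 - v2) / max(abs(v1), 1e-30), 1e-8)
  }
})

test_that("frames are invariant under node reordering", {
  m <- coarse_torso_mesh()
  p <- default_protocol(8L)
  set.seed(5)
  sig <- exp(stats::rnorm(nrow(m$elements), log(0.3), 0.4))
  f1 <- simulate_frame(m, sig, p)
  perm <- sample(nrow(m$nodes))
  inv <- integer(length(perm)); inv[perm] <- seq_along(perm)
  m2 <- m
  m2$nodes <- m$nodes[perm, ]
  m2$elements <- matrix(inv[m$elements], ncol = 3L)
  m2$boundary_edges <- matrix(inv[m$boundary_edges], ncol = 2L)
  f2 <- simulate_frame(m2, sig, p)
  expect_equal(f2$values, f1$values, tolerance = 1e-10)
})

test_that("noise is disabled at infinite SNR, reproducible, and calibrated", {
  m <- coarse_torso_mesh()
  p <- default_protocol(8L)
  f <- simulate_frame(m, rep(0.2, nrow(m$elements)), p)
  expect_identical(add_noise(f, Inf, 1L)$values, f$values)
  n1 <- add_noise(f, 20, 99L)
  n2 <- add_noise(f, 20, 99L)
  expect_identical(n1$values, n2$values)
  expect_false(identical(n1$values, add_noise(f, 20, 100L)$values))
  # Monte-Carlo calibration: empirical SNR within 0.5 dB of nominal
  set.seed(1)
  sig_pow <- mean(f$values^2)
  noise_pow <- mean(vapply(1:10000, function(i) {
    mean((add_noise(f, 20, i)$values - f$values)^2)
  }, numeric(1L)))
  snr_emp <- 10 * log10(sig_pow / noise_pow)
  expect_lt(abs(snr_emp - 20), 0.5)
})

test_that("boundary potentials converge to the closed-form disk solution", {
  errs <- vapply(c(10, 20, 40), function(den) {
    h <- 1 / den
    m <- build_torso_mesh(list(a = 1, b = 1, exponent = 2),
                          electrode_count = 8L,
                          electrode_arc_fraction = 8 * h / pi,
                          target_edge_length = h, min_angle = 15)
    sig <- 1; cur <- 1e-3
    u <- solve_injection(m, rep(sig, nrow(m$elements)), 1L, 5L, cur)
    pos <- t(vapply(seq_along(m$electrodes), function(k) {
      ed <- m$boundary_edges[m$electrodes[[k]], , drop = FALSE]
      colMeans((m$nodes[ed[, 1L], , drop = FALSE] +
                m$nodes[ed[, 2L], , drop = FALSE]) / 2)
    }, numeric(2L)))
    uex <- disk_two_point_potential(m$nodes, pos[1L, ], pos[5L, ], cur, sig)
    others <- setdiff(1:8, c(1L, 5L))
    vnum <- vapply(others, function(k) electrode_potential(m, u, k), 1)
    vex <- vapply(others, function(k) electrode_potential(m, uex, k), 1)
    dn <- outer(vnum, vnum, `-`); de <- outer(vex, vex, `-`)
    sel <- abs(de) > 1e-12
    max(abs(dn[sel] - de[sel]) / abs(de[sel]))
  }, numeric(1L))
  expect_lt(errs[2L], 0.02)           # within 2% at h = radius / 20
  expect_true(all(diff(errs) < 0))    # monotone decrease under refinement
})
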