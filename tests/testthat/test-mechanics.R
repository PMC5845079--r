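p <- model_params()

test_that("pairwise decay law evaluates the closed form", {
  expect_equal(pairwise_energy(p$M0, 10, 0, 2.5), p$M0)
  expect_equal(pairwise_energy(p$M0, 10, 2.5, 2.5), p$M0 * exp(-10))
  expect_equal(pairwise_energy(2.596e-2, 10, 30, 2.5), 1.99e-54,
               tolerance = 0.01)
  expect_error(pairwise_energy(1, 10, 1, 0), "positive")
  expect_error(pairwise_energy(1, 10, -1, 1), "non-negative")
  # runtime cutoff clamps small signals to zero
  expect_equal(pairwise_energy(1, 10, 30, 2.5, eps = 1e-10), 0)
})

test_that("detection threshold matches the printed worked value", {
  expect_equal(detection_threshold(2.596e-2, 10, 30, 2.5), 1.99e-54,
               tolerance = 0.01)
  expect_equal(detection_threshold(p$M0, 10, 0, 2.5), p$M0)
  expect_equal(detection_threshold(p$M0, 0, 17, 2.5), p$M0)
})

test_that("sensed stimulus handles isolated, paired and symmetric cells", {
  iso <- cell_population(0, 0, "epithelial", p)
  s <- sensed_stimulus(1, iso, p)
  expect_equal(s$M_remote, 0)
  expect_equal(s$M_total, p$M0)
  expect_null(s$z_hat)
  expect_equal(s$alpha, p$beta * p$R^3 / (p$mu * p$F_traction))

  two <- two_cell_fixture(6, p)
  s1 <- sensed_stimulus(1, two, p)
  s2 <- sensed_stimulus(2, two, p)
  expect_equal(s1$M_remote, s2$M_remote)
  expect_equal(s1$z_hat, c(1, 0))
  expect_equal(s2$z_hat, c(-1, 0))

  hex <- hexagon_fixture(5, p)
  expect_equal(sqrt(sum((sensed_stimulus(1, hex, p)$z_hat %||% c(0, 0))^2)),
               0, tolerance = 1e-10)
})

test_that("stimulus rejects T cells and duplicated ids", {
  bad <- cell_population(c(0, 5), c(0, 0), c("epithelial", "tcell"), p)
  expect_error(sensed_stimulus(1, bad, p), "epithelial/cancer")
  dup <- two_cell_fixture(5, p)
  dup$id[2] <- dup$id[1]
  expect_error(sensed_stimulus(1, dup, p), "duplicated")
})

test_that("remote stimulus superposes: vectorised path equals double loop", {
  for (seed in 1:5) {
    cells <- random_population(20, p, seed = seed)
    st <- mechanics_state(cells, p)
    for (i in c(1, 7, 20)) {
      expect_equal(st$M_remote[i], brute_remote(i, cells, p),
                   tolerance = 1e-12)
      expect_equal(st$M_remote[i], sensed_stimulus(i, cells, p)$M_remote,
                   tolerance = 1e-12)
    }
    expect_equal(st$contact_sum, brute_contact_sum(cells, p),
                 tolerance = 1e-12)
  }
})

test_that("stimulus is equivariant under rigid motions", {
  cells <- random_population(12, p, seed = 42)
  s_ref <- sensed_stimulus(3, cells, p)
  th <- 0.7
  rot <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2L)
  moved <- cells
  xy <- as.matrix(cells[, c("x", "y")]) %*% t(rot)
  moved$x <- xy[, 1L] + 11
  moved$y <- xy[, 2L] - 4
  s_rot <- sensed_stimulus(3, moved, p)
  expect_equal(s_rot$M_remote, s_ref$M_remote, tolerance = 1e-12)
  expect_equal(s_rot$z_hat, as.numeric(rot %*% s_ref$z_hat),
               tolerance = 1e-9)
})

test_that("remote stimulus decreases when a neighbour moves away", {
  cells <- cell_population(c(0, 5, -4), c(0, 0, 3), "epithelial", p)
  before <- sensed_stimulus(1, cells, p)$M_remote
  cells$x[2] <- 9
  expect_lt(sensed_stimulus(1, cells, p)$M_remote, before)
})

test_that("migration drift follows alpha * max(net, 0) * z_hat", {
  stim <- list(z_hat = c(1, 0), alpha = 1)
  expect_equal(migration_drift(stim, 0.01), c(0.01, 0))
  expect_equal(migration_drift(stim, 0), c(0, 0))
  expect_equal(migration_drift(stim, -1), c(0, 0))
  expect_equal(migration_drift(list(z_hat = NULL, alpha = 1), 5), c(0, 0))
})
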