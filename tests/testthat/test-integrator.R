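p <- model_params()

test_that("adaptive step respects the half-radius displacement bound", {
  expect_equal(choose_dt(0, 2.5), 0.1)
  expect_equal(choose_dt(25, 2.5), 0.05)
  expect_equal(choose_dt(1, 2.5), 0.1)  # the default cap binds
  expect_error(choose_dt(-1, 2.5), "non-negative")
})

test_that("an isolated cell with D = 0 does not move", {
  cells <- cell_population(3, -4, "epithelial", p)
  out <- step_epithelial_cancer(cells, p, dt = 0.1, noise = FALSE)
  expect_equal(out$x, cells$x)
  expect_equal(out$y, cells$y)
})

test_that("two cells at the solved equilibrium overlap are stationary", {
  h <- equilibrium_overlap(p)
  cells <- two_cell_fixture(2 * p$R - h, p)
  out <- step_epithelial_cancer(cells, p, dt = 0.1, noise = FALSE)
  expect_equal(out$x, cells$x, tolerance = 1e-6)
  expect_equal(out$y, cells$y, tolerance = 1e-6)
})

test_that("off-equilibrium pairs drift in the direction the balance dictates", {
  h_star <- equilibrium_overlap(p)
  # below the equilibrium overlap the contact term dominates: cells separate
  below <- two_cell_fixture(2 * p$R - (h_star - 0.3), p)
  st <- mechanics_state(below, p)
  expect_lt(st$M_remote[1] - st$contact_sum[1], 0)
  out <- step_epithelial_cancer(below, p, dt = 0.1, state = st,
                                noise = FALSE)
  expect_gt(abs(diff(out$x)), abs(diff(below$x)))
  # above it the remote attraction dominates: cells close in
  above <- two_cell_fixture(2 * p$R - (h_star + 0.3), p)
  st <- mechanics_state(above, p)
  expect_gt(st$M_remote[1] - st$contact_sum[1], 0)
  out <- step_epithelial_cancer(above, p, dt = 0.1, state = st,
                                noise = FALSE)
  expect_lt(abs(diff(out$x)), abs(diff(above$x)))
})

test_that("Wiener increments carry variance 2 D dt per component", {
  # a wide grid of isolated cells: drift is zero, every increment is noise
  g <- expand.grid(x = seq_len(45) * 61, y = seq_len(45) * 61)
  cells <- cell_population(g$x, g$y, "epithelial", p)
  incs <- numeric()
  withr::with_seed(7, {
    cur <- cells
    for (i in 1:25) {
      out <- step_epithelial_cancer(cur, p, dt = 0.1)
      incs <- c(incs, out$x - cur$x, out$y - cur$y)
      cur <- out
    }
  })
  expected <- 2 * p$D * 0.1
  v <- var(incs)
  se <- expected * sqrt(2 / (length(incs) - 1))
  expect_lt(abs(v - expected), 3 * se)
  expect_equal(mean(incs), 0, tolerance = 3 * sqrt(expected / length(incs)))
})

test_that("no step moves a cell farther than half its radius", {
  # an artificially violent attraction field must still respect the cap
  cells <- random_population(15, p, span = 4, seed = 3)
  strong <- model_params(F_traction = 100)  # M0 ~ 2.6e5
  for (rep in 1:5) {
    st <- mechanics_state(cells, strong)
    expect_gt(st$max_speed * 0.1, strong$R / 2)  # cap genuinely active
    out <- step_epithelial_cancer(cells, strong, dt = 0.1, state = st)
    disp <- sqrt((out$x - cells$x)^2 + (out$y - cells$y)^2)
    expect_true(all(disp <= strong$R / 2 + 1e-12))
    cells <- out
  }
})

test_that("T cells ride the gradient straight toward a single source", {
  geom <- stroma_geometry(k = 0)
  cells <- cell_population(40, 0, "tcell", p)
  src <- chemokine_sources(matrix(c(0, 0), 1L), gamma = p$gamma,
                           D_c = p$D_c, r_min = p$R_t)
  out <- step_tcells(cells, src, geom, p, dt = 0.1, noise = FALSE)
  expect_lt(out$x, 40)             # moved toward the origin
  expect_equal(out$y, 0)           # exactly along the line
  disp <- 40 - out$x
  expect_lte(disp, p$R_t / 2 + 1e-12)  # clamped at R_t / 2
})

test_that("stationary T cells without cancer cells present", {
  geom <- stroma_geometry(k = 0)
  cells <- cell_population(40, 0, "tcell", p)
  src <- chemokine_sources(matrix(numeric(), 0L, 2L))
  out <- step_tcells(cells, src, geom, p, dt = 0.1, noise = FALSE)
  expect_equal(out$x, 40)
  expect_equal(out$y, 0)
})

test_that("stromal anisotropy rescales a radial T-cell step by e^{-ks}", {
  src <- chemokine_sources(matrix(c(0, 0), 1L), gamma = p$gamma,
                           D_c = p$D_c, r_min = p$R_t)
  cells <- cell_population(42.5, 0, "tcell", p)  # mid-stroma, s = 7.5
  iso <- step_tcells(cells, src, stroma_geometry(k = 0), p,
                     dt = 1e-4, noise = FALSE)
  ani <- step_tcells(cells, src, stroma_geometry(k = 0.3), p,
                     dt = 1e-4, noise = FALSE)
  step_iso <- 42.5 - iso$x
  step_ani <- 42.5 - ani$x
  expect_gt(step_iso, 0)
  expect_equal(step_ani / step_iso, exp(-0.3 * 7.5), tolerance = 1e-9)
})

test_that("trajectories are bit-reproducible under a fixed seed", {
  cells <- random_population(10, p, span = 8, seed = 5)
  run_once <- function() {
    set.seed(11)
    cur <- cells
    for (i in 1:20) cur <- step_epithelial_cancer(cur, p, dt = 0.1)
    cur
  }
  expect_identical(run_once(), run_once())
})

test_that("positions beyond the boundary are reflected back inside", {
  cells <- cell_population(59.9, 0, "tcell", p)
  src <- chemokine_sources(matrix(c(100, 0), 1L), gamma = p$gamma,
                           D_c = p$D_c, r_min = p$R_t)
  out <- step_tcells(cells, src, stroma_geometry(k = 0), p, dt = 0.1,
                     noise = FALSE, boundary_radius = 60)
  expect_lte(sqrt(out$x^2 + out$y^2), 60)
})
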