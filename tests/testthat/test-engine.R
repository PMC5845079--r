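p <- model_params()

test_that("hexagonal initialization fills the islet deterministically", {
  sc <- scenario_config(packing_factor = 1)
  cells <- initialize_islet(sc, p)
  expect_true(all(cells$phenotype == "epithelial"))
  expect_true(all(sqrt(cells$x^2 + cells$y^2) <= sc$islet_radius - p$R))
  d <- as.matrix(dist(cbind(cells$x, cells$y)))
  diag(d) <- Inf
  nn <- apply(d, 1, min)
  expect_equal(unname(nn), rep(2 * p$R, nrow(cells)), tolerance = 1e-9)
  # placement does not consume randomness
  expect_identical(initialize_islet(sc, p), cells)
})

test_that("compressed packing puts interior cells in six-fold contact", {
  sc <- scenario_config(packing_factor = 0.9)
  cells <- initialize_islet(sc, p)
  pr <- contact_pairs(cells, p)
  expect_true(all(pr$h > 0))
  counts <- table(c(pr$a, pr$b))
  interior <- which(sqrt(cells$x^2 + cells$y^2) < sc$islet_radius - 4 * p$R)
  expect_true(all(counts[as.character(interior)] == 6))
})

test_that("T cells spawn in the prescribed number outside the stroma", {
  sc <- scenario_config(immunity = "strong", n_tcells_weak = 10)
  cells <- initialize_islet(sc, p)
  set.seed(1)
  out <- spawn_tcells(cells, sc, p)
  tc <- out[out$phenotype == "tcell", ]
  expect_equal(nrow(tc), 20L)  # N_s = 2 N_w
  expect_equal(unname(sqrt(tc$x^2 + tc$y^2)),
               rep(35 + 15 + 5, 20L))
  sc$immunity <- "none"
  expect_equal(sum(spawn_tcells(cells, sc, p)$phenotype == "tcell"), 0L)
})

test_that("a zero-horizon run reports exactly the initial counts", {
  sc <- scenario_config(t_end = 0, seed = 2)
  rs <- run_simulation(sc)
  expect_equal(nrow(rs$series), 1L)
  expect_equal(rs$series$n_cancer, 0)
  expect_equal(rs$series$n_tcell, 0)
  expect_equal(rs$series$n_epithelial, nrow(initialize_islet(sc, p)))
})

test_that("replicates are reproducible: same seed, identical output", {
  sc <- scenario_config(t_end = 15, seed = 9, immunity = "strong")
  r1 <- run_simulation(sc)
  r2 <- run_simulation(sc)
  expect_identical(r1$series, r2$series)
  expect_identical(r1$events, r2$events)
  expect_identical(r1$final_cells, r2$final_cells)
})

test_that("population bookkeeping reconciles with the event log", {
  sc <- scenario_config(t_end = 25, seed = 4, immunity = "strong")
  rs <- run_simulation(sc)
  ev <- rs$events
  n0 <- rs$series$n_epithelial[1L]
  last <- rs$series[nrow(rs$series), ]
  n_mut <- sum(ev$kind == "mutation")
  n_apop <- sum(ev$kind == "apoptosis")
  n_div <- sum(ev$kind == "division")
  n_kill <- sum(ev$kind == "engulfment")
  n_spawn <- sum(ev$kind == "tcell_spawn")
  n_tdeath <- sum(ev$kind == "tcell_death")
  expect_equal(last$n_epithelial, n0 + n_div - n_mut - n_apop)
  expect_equal(last$n_cancer, n_mut - n_kill)
  expect_equal(last$n_tcell, n_spawn - n_tdeath)
  # counts also reconcile step by step against cumulative events
  mid <- nrow(rs$series) %/% 2L
  t_mid <- rs$series$time[mid]
  upto <- ev[ev$time <= t_mid, ]
  expect_equal(rs$series$n_cancer[mid],
               sum(upto$kind == "mutation") - sum(upto$kind == "engulfment"))
})

test_that("without immunity the cancer count never decreases", {
  sc <- scenario_config(t_end = 25, seed = 6, immunity = "none")
  rs <- run_simulation(sc)
  expect_equal(sum(rs$events$kind == "tcell_spawn"), 0L)
  expect_true(all(diff(rs$series$n_cancer) >= 0))
  expect_gt(rs$series$n_cancer[nrow(rs$series)], 0)
})

test_that("the deterministic seeding switch starts one central tumor cell", {
  sc <- scenario_config(t_end = 11, seed = 5, immunity = "none",
                        seed_cancer_at = 5)
  rs <- run_simulation(sc)
  ev <- rs$events
  first <- ev[ev$kind == "mutation", ][1L, ]
  expect_lt(abs(first$time - 5), 0.2)
  # the seeded cell was the innermost epithelial cell
  cells0 <- initialize_islet(sc, p)
  expect_equal(first$id,
               cells0$id[which.min(cells0$x^2 + cells0$y^2)])
})

test_that("hard overlap constraint is honoured at every recorded state", {
  sc <- scenario_config(t_end = 20, seed = 8, immunity = "strong")
  rs <- run_simulation(sc)
  cells <- rs$final_cells
  d <- as.matrix(dist(cbind(cells$x, cells$y)))
  rsum <- outer(cells$radius, cells$radius, "+")
  hmax <- outer(cells$radius, cells$radius, pmin) / 2
  h <- rsum - d
  diag(h) <- 0
  # the projection is iterative; residuals sit far below the model scale
  expect_true(all(h <= hmax + 1e-2))
})

test_that("k sweep aggregates replicates per anisotropy value", {
  sc <- scenario_config(t_end = 5, seed = 1, immunity = "strong")
  sw <- k_sweep(sc, k_values = c(0, 0.5), replicates = 2)
  expect_equal(nrow(sw), 4L)
  expect_equal(sort(unique(sw$k)), c(0, 0.5))
  expect_identical(sw, k_sweep(sc, k_values = c(0, 0.5), replicates = 2))
  agg <- summarize_sweep(sw)
  expect_equal(agg$n, c(2L, 2L))
})
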