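# Cycle closure, WLS node reconstruction, offsets, and benchmark metrics.

test_that("two nodes split a single edge ddG around the zero-mean gauge", {
  m <- perturbation_map(c("A", "B"),
                        data.frame(source = "A", target = "B",
                                   similarity = 1))
  sol <- solve_node_dgs(m, data.frame(edge = "A->B", ddg = 1, se = 0))
  expect_equal(sol$dg_calc, c(-0.5, 0.5), tolerance = 1e-12)
})

test_that("consistent graphs are reproduced exactly; inconsistent triangles project", {
  cons <- triangle_edges(ddg = c(1, 1, 2))
  sol <- solve_node_dgs(triangle_map(), cons)
  expect_lt(max(abs(attr(sol, "residuals"))), 1e-9)

  incons <- triangle_edges(ddg = c(1, 1, 3))
  sol2 <- solve_node_dgs(triangle_map(), incons)
  pinned <- sol2$dg_calc - sol2$dg_calc[1]
  expect_equal(pinned, c(0, 4 / 3, 8 / 3), tolerance = 1e-9)
  fitted <- attr(sol2, "fitted")
  expect_equal(unname(fitted), c(4 / 3, 4 / 3, 8 / 3), tolerance = 1e-9)
  # corrected edges close every cycle at machine precision
  expect_lt(abs(fitted["A->B"] + fitted["B->C"] - fitted["A->C"]), 1e-12)
})

test_that("WLS node solve matches a direct numerical minimiser on small graphs", {
  set.seed(23)
  for (trial in 1:5) {
    n <- sample(4:8, 1)
    ids <- letters[1:n]
    sim <- matrix(0, n, n)
    sim[upper.tri(sim)] <- runif(n * (n - 1) / 2, 0.3, 0.95)
    sim <- sim + t(sim)
    map <- nesfe:::build_map_from_similarity(sim, ids, 2)
    m <- nrow(map$edges)
    edges <- data.frame(edge = map$edges$id, ddg = rnorm(m, 0, 1.5),
                        se = runif(m, 0, 0.5))
    sol <- solve_node_dgs(map, edges, se_floor = 0.1)
    w <- 1 / pmax(edges$se, 0.1)^2
    oracle <- brute_force_wls_nodes(map$edges$source, map$edges$target,
                                    edges$ddg, w, map$nodes)
    expect_equal(sol$dg_calc, unname(oracle), tolerance = 1e-5)
  }
})

test_that("solver rejects disconnected graphs and missing edge results", {
  m <- triangle_map()
  expect_error(solve_node_dgs(m, triangle_edges()[1:2, ]), "missing edge")
  disc <- structure(list(
    nodes = c("A", "B", "C", "D"),
    edges = data.frame(source = c("A", "C"), target = c("B", "D"),
                       similarity = 1,
                       id = c("A->B", "C->D"))
  ), class = "perturbation_map")
  expect_error(
    solve_node_dgs(disc, data.frame(edge = c("A->B", "C->D"),
                                    ddg = c(1, 1), se = 0)),
    "disconnected"
  )
})

test_that("cycle closure errors are signed sums; trees yield none", {
  expect_equal(unname(cycle_closure_errors(triangle_map(),
                                           triangle_edges(c(1, 1, 2)))), 0,
               tolerance = 1e-12)
  expect_equal(unname(cycle_closure_errors(triangle_map(),
                                           triangle_edges(c(1, 1, 3)))), -1,
               tolerance = 1e-12)
  tree <- perturbation_map(c("A", "B", "C"),
                           data.frame(source = c("A", "B"),
                                      target = c("B", "C"), similarity = 1))
  expect_length(cycle_closure_errors(tree, triangle_edges()[1:2, ]), 0)
})

test_that("experimental offset matches means, is idempotent, keeps differences", {
  nodes <- data.frame(id = c("A", "B"), dg_calc = c(0, 1), se = 0)
  exp <- data.frame(id = c("A", "B"), dg_exp = c(-10, -9), sigma_exp = 0.3)
  off <- offset_to_experiment(nodes, exp)
  expect_equal(off$dg_calc, c(-10, -9), tolerance = 1e-12)
  expect_equal(offset_to_experiment(off, exp)$dg_calc, off$dg_calc,
               tolerance = 1e-12)

  nodes3 <- data.frame(id = c("A", "B", "C"), dg_calc = c(0, 2, 4), se = 0)
  exp2 <- data.frame(id = c("A", "B"), dg_exp = c(-8, -6), sigma_exp = 0.3)
  off3 <- offset_to_experiment(nodes3, exp2)
  expect_equal(off3$dg_calc, c(-8, -6, -4), tolerance = 1e-12)
  expect_equal(diff(off3$dg_calc), diff(nodes3$dg_calc), tolerance = 1e-12)

  expect_error(offset_to_experiment(
    nodes, data.frame(id = "Z", dg_exp = 1, sigma_exp = 0)
  ), "no ligand overlaps")
})

test_that("metrics reproduce exact cases and flag degenerate input", {
  m <- compute_metrics(c(1, 2, 3), c(1, 2, 3))
  expect_identical(m$aue, 0)
  expect_identical(m$rmse, 0)
  expect_identical(m$pearson_rho, 1)
  expect_identical(m$kendall_tau, 1)

  expect_identical(compute_metrics(c(3, 2, 1), c(1, 2, 3))$kendall_tau, -1)

  deg <- compute_metrics(c(1, 1, 1), c(1, 2, 3))
  expect_true(deg$degenerate)
  expect_true(is.na(deg$kendall_tau))
  expect_equal(deg$rmse, sqrt(mean(c(0, 1, 2)^2)), tolerance = 1e-12)

  # invariance to common shifts (errors) and monotone transforms (tau)
  set.seed(2)
  a <- rnorm(10); b <- rnorm(10)
  m1 <- compute_metrics(a, b)
  m2 <- compute_metrics(a + 3.2, b + 3.2)
  expect_equal(m1$aue, m2$aue, tolerance = 1e-12)
  expect_equal(m1$rmse, m2$rmse, tolerance = 1e-12)
  expect_equal(compute_metrics(exp(a), exp(b))$kendall_tau, m1$kendall_tau,
               tolerance = 1e-12)
})

test_that("Kendall tau equals the brute-force pair count, ties included", {
  set.seed(41)
  for (trial in 1:20) {
    n <- sample(5:12, 1)
    x <- sample(1:6, n, replace = TRUE) + rnorm(n, 0, 0.01 * (trial %% 2))
    y <- sample(1:6, n, replace = TRUE)
    if (sd(x) == 0 || sd(y) == 0) next
    expect_equal(compute_metrics(x, y)$kendall_tau, brute_force_tau_b(x, y),
                 tolerance = 1e-12)
  }
})

test_that("bootstrap metric CIs are deterministic and collapse for exact data", {
  x <- c(1, 2, 3, 4, 5)
  ci1 <- bootstrap_metric_ci(x, x, n_boot = 200, seed = 3)
  ci2 <- bootstrap_metric_ci(x, x, n_boot = 200, seed = 3)
  expect_identical(ci1, ci2)
  expect_identical(ci1$rmse$lower, 0)
  expect_identical(ci1$rmse$upper, 0)
  expect_true(ci1$aue$lower <= ci1$aue$value &&
                ci1$aue$value <= ci1$aue$upper)
})

test_that("null bands are deterministic, trivial without noise, centred by the floor", {
  set.seed(6)
  expv <- runif(30, -12, -8)
  nb1 <- experimental_null_band(expv, 0, n_samples = 300, seed = 5)
  nb2 <- experimental_null_band(expv, 0, n_samples = 300, seed = 5)
  expect_identical(nb1, nb2)

  nb0 <- experimental_null_band(expv, 0, n_samples = 100, seed = 5,
                                sigma_floor = 0)
  expect_identical(nb0$rmse$lower, 0)
  expect_identical(nb0$rmse$upper, 0)
  expect_identical(nb0$kendall_tau$lower, 1)

  # two independent replicates at the floor: RMSE centred near 0.43 sqrt(2)
  centre <- (nb1$rmse$lower + nb1$rmse$upper) / 2
  expect_lt(abs(centre - 0.43 * sqrt(2)), 0.12)
})
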