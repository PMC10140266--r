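# Synthetic generators: CFT-consistent works, map studies, poses, mock NES.

KT298 <- nesfe::kbt_kcal(298)

test_that("CFT Gaussian works have the closed-form means and delta limit", {
  ws0 <- gen_cft_gaussian_works(1.5, 0, 5, 5, seed = 1)
  expect_true(all(ws0$w_f == 1.5))
  expect_true(all(ws0$w_r == -1.5))

  ws <- gen_cft_gaussian_works(2, 1, 4000, 4000, 298, seed = 2)
  mu_f <- 2 + 1 / (2 * KT298) # 2.8443 kcal/mol at 298 K
  expect_equal(mu_f, 2.8443, tolerance = 1e-4)
  expect_lt(abs(mean(ws$w_f) - mu_f), 3 / sqrt(4000))
  expect_lt(abs(mean(ws$w_r) - (-2 + 1 / (2 * KT298))), 3 / sqrt(4000))
  expect_lt(abs(sd(ws$w_f) - 1), 0.05)

  again <- gen_cft_gaussian_works(2, 1, 4000, 4000, 298, seed = 2)
  expect_identical(ws$w_f, again$w_f)
  expect_identical(ws$w_r, again$w_r)
})

test_that("the empirical Crooks crossing converges to the true free energy", {
  ws <- gen_cft_gaussian_works(1.2, 1, 1e5, 1e5, 298, seed = 3)
  # Gaussian fits to P_f(W) and P_r(-W); their crossing estimates dG
  crossing <- gaussian_crossing(mean(ws$w_f), sd(ws$w_f),
                                mean(-ws$w_r), sd(ws$w_r))
  expect_lt(abs(crossing - 1.2), 0.02)
})

test_that("map studies regenerate bit-identically and recover truth without noise", {
  s1 <- gen_map_study(10, edge_noise_sd = 0.25, seed = 7)
  s2 <- gen_map_study(10, edge_noise_sd = 0.25, seed = 7)
  expect_identical(s1$dg_true, s2$dg_true)
  expect_identical(s1$edges$ddg, s2$edges$ddg)
  expect_identical(s1$affinities$dg_exp, s2$affinities$dg_exp)

  # edge truth equals node-difference truth exactly
  expect_equal(unname(s1$ddg_true),
               unname(s1$dg_true[s1$map$edges$target] -
                        s1$dg_true[s1$map$edges$source]),
               tolerance = 1e-15)

  s0 <- gen_map_study(8, edge_noise_sd = 0, exp_noise_sd = 0, seed = 9)
  sol <- solve_node_dgs(s0$map, s0$edges)
  truth_centred <- s0$dg_true - mean(s0$dg_true)
  expect_equal(sol$dg_calc, unname(truth_centred), tolerance = 1e-9)
})

test_that("graph averaging keeps node recovery below the edge noise", {
  hits <- 0
  n_seeds <- 40
  for (k in seq_len(n_seeds)) {
    st <- gen_map_study(20, edge_noise_sd = 0.3, seed = 300 + k)
    sol <- solve_node_dgs(st$map, st$edges)
    err <- sol$dg_calc - (st$dg_true - mean(st$dg_true))
    if (sqrt(mean(err^2)) < 0.3) hits <- hits + 1
  }
  expect_gte(hits / n_seeds, 0.9)
})

test_that("pose perturbations have exact translation RMSD and known ranking", {
  b <- benzene()
  ref <- hexagon_coords()
  ps <- perturb_poses(b, ref, c(0, 2), seed = 4, rot_per_ang = 0)
  expect_equal(ps$coords[[1]], ref, tolerance = 1e-12)
  expect_equal(mapped_rmsd(ps$coords[[2]], ref, cbind(1:6, 1:6)), 2,
               tolerance = 1e-12)

  ps2 <- perturb_poses(b, ref, c(3, 0.5, 2), seed = 8)
  mm <- compute_mcs(b, b)
  expect_identical(select_best_pose(ps2, ref, mm)$index, 2L)
  expect_identical(attr(ps2, "ranking"), c(2L, 3L, 1L))

  ps3 <- perturb_poses(b, ref, c(3, 0.5, 2), seed = 8)
  expect_identical(ps2$coords, ps3$coords)
})

test_that("the mock NES backend is exact at zero dissipation and reproducible", {
  d1 <- file.path(tempdir(), "mocknes1")
  man <- mock_nes_backend("A->B", -1.5, dissipation_sigma = 0,
                          n_transitions = 10, n_replicas = 1, seed = 5,
                          dir = d1)
  er <- estimate_edge_from_files(man, n_boot = 20, seed = 6)
  expect_equal(er$ddg, -1.5, tolerance = 1e-8)

  d2 <- file.path(tempdir(), "mocknes2")
  d3 <- file.path(tempdir(), "mocknes3")
  m2 <- mock_nes_backend("A->B", 0.7, dissipation_sigma = 1,
                         n_transitions = 20, n_replicas = 2, seed = 9,
                         dir = d2)
  m3 <- mock_nes_backend("A->B", 0.7, dissipation_sigma = 1,
                         n_transitions = 20, n_replicas = 2, seed = 9,
                         dir = d3)
  expect_identical(readLines(m2$forward[1]), readLines(m3$forward[1]))
  expect_identical(readLines(m2$reverse[3]), readLines(m3$reverse[3]))

  er2 <- estimate_edge_from_files(m2, n_boot = 20, seed = 10)
  er3 <- estimate_edge_from_files(m3, n_boot = 20, seed = 10)
  expect_identical(er2$ddg, er3$ddg)
  expect_identical(er2$se, er3$se)
})

test_that("mock NES pipeline recovers the true edge ddG within its error bar", {
  hits <- 0
  n_seeds <- 25
  for (k in seq_len(n_seeds)) {
    d <- file.path(tempdir(), sprintf("mockrec%d", k))
    man <- mock_nes_backend("A->B", -1.5, dissipation_sigma = 1,
                            n_transitions = 80, n_replicas = 3,
                            seed = 9000 + 31 * k, dir = d)
    er <- estimate_edge_from_files(man, n_boot = 50, seed = 40 + k)
    if (abs(er$ddg - (-1.5)) < 3 * er$se) hits <- hits + 1
    unlink(d, recursive = TRUE)
  }
  expect_gte(hits / n_seeds, 0.9)
})
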