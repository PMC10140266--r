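# Work integration, BAR/Jarzynski estimation, bootstrap, replica handling.

KT298 <- nesfe::kbt_kcal(298)

test_that("frame schedule matches the stated extraction protocol", {
  fs <- frame_schedule(6000, 2000, 80)
  expect_length(fs, 80)
  expect_equal(unique(diff(fs)), 50)
  expect_identical(fs[80], 6000)
  expect_gt(fs[1], 2000) # the discarded prefix is excluded entirely
  expect_identical(frame_schedule(4, 0, 4), c(1, 2, 3, 4))
  expect_identical(frame_schedule(100, 50, 1), 100)
  expect_error(frame_schedule(100, 50, 100, output_interval = 10),
               "exceeds")
  expect_error(frame_schedule(100, 100, 1))
})

test_that("trapezoidal work integration is exact on constants and linear traces", {
  lam <- seq(0, 1, 0.05)
  expect_equal(integrate_work(dhdl_trace(lam, rep(3.7, length(lam)))), 3.7,
               tolerance = 1e-12)
  expect_identical(integrate_work(dhdl_trace(lam, rep(0, length(lam)))), 0)
  expect_equal(integrate_work(dhdl_trace(lam, 2 * lam)), 1, tolerance = 1e-12)
  # reverse traversal yields the negated integral for the same path
  expect_equal(integrate_work(dhdl_trace(rev(lam), 2 * rev(lam))), -1,
               tolerance = 1e-12)
  expect_error(dhdl_trace(c(0, 0.5, 0.4, 1), 1:4), "monotone")
})

test_that("BAR solves the delta-function and symmetric cases exactly", {
  expect_equal(bar_estimate(work_set(rep(5, 3), rep(-5, 3)))$value, 5,
               tolerance = 1e-9)
  expect_equal(bar_estimate(work_set(rep(0, 3), rep(0, 3)))$value, 0,
               tolerance = 1e-9)
})

test_that("BAR agrees with the grid-scan root oracle", {
  set.seed(31)
  for (trial in 1:5) {
    dg <- runif(1, -4, 4)
    sigma <- runif(1, 0.4, 2)
    ws <- gen_cft_gaussian_works(dg, sigma, 150, 150, 298, seed = 100 + trial)
    est <- bar_estimate(ws)$value
    oracle <- grid_scan_bar(ws$w_f, ws$w_r)
    expect_equal(est, oracle, tolerance = 2e-4) # oracle grid resolution
  }
  # high-precision check on one set with a very fine final grid
  ws <- gen_cft_gaussian_works(2, 1, 200, 200, 298, seed = 1)
  est <- bar_estimate(ws)$value
  beta <- 1 / KT298
  score <- function(dg) nesfe:::bar_score(dg, ws$w_f, -ws$w_r, beta, 1)
  expect_lt(abs(score(est)), abs(score(est + 1e-6)))
  expect_lt(abs(score(est)), abs(score(est - 1e-6)))
})

test_that("BAR recovers the Gaussian CFT truth and transforms correctly", {
  ws <- gen_cft_gaussian_works(2, 1, 1000, 1000, 298, seed = 5)
  est <- bar_estimate(ws)
  se <- bootstrap_se(ws, n_boot = 100, seed = 6)
  expect_lt(abs(est$value - 2), 3 * se)

  # antisymmetry: estimating the reversed process (the B to A works as
  # forward, the A to B works as the stored reverse) negates dG
  flipped <- bar_estimate(work_set(ws$w_r, ws$w_f))
  expect_equal(flipped$value, -est$value, tolerance = 1e-9)

  # shift covariance
  shifted <- bar_estimate(work_set(ws$w_f + 1.25, ws$w_r - 1.25))
  expect_equal(shifted$value - est$value, 1.25, tolerance = 1e-9)
})

test_that("BAR reports insufficient overlap for disjoint work distributions", {
  ws <- work_set(rep(1000, 5), rep(500, 5))
  expect_error(bar_estimate(ws), "insufficient overlap")
  # moderately separated deltas hit the CFT midpoint (W_f - W_r) / 2
  expect_equal(bar_estimate(work_set(rep(3, 5), rep(-1, 5)))$value, 2,
               tolerance = 1e-6)
})

test_that("Jarzynski matches delta and Gaussian closed forms", {
  expect_equal(jarzynski_estimate(rep(2.5, 4), 298, "f"), 2.5,
               tolerance = 1e-12)
  expect_identical(jarzynski_estimate(rep(0, 4), 298, "f"), 0)
  # Gaussian: dG = mu - beta sigma^2 / 2 in the traversal direction
  set.seed(17)
  mu <- 2 + 0.5^2 / (2 * KT298)
  w <- rnorm(10000, mu, 0.5)
  expect_equal(jarzynski_estimate(w, 298, "f"), 2, tolerance = 0.05)
  wr <- rnorm(10000, -2 + 0.5^2 / (2 * KT298), 0.5)
  expect_equal(jarzynski_estimate(wr, 298, "r"), 2, tolerance = 0.05)
  # overflow guard: large magnitudes do not produce NaN
  expect_true(is.finite(jarzynski_estimate(c(-4000, -4010), 298, "f")))
})

test_that("bootstrap SE is seed-deterministic and zero for zero variance", {
  ws <- gen_cft_gaussian_works(1, 0.8, 100, 100, 298, seed = 9)
  s1 <- bootstrap_se(ws, n_boot = 50, seed = 4)
  s2 <- bootstrap_se(ws, n_boot = 50, seed = 4)
  expect_identical(s1, s2)
  expect_gt(s1, 0)
  s0 <- bootstrap_se(work_set(rep(2, 10), rep(-2, 10)), n_boot = 50, seed = 4)
  expect_identical(s0, 0)
})

test_that("bootstrap SE tracks the true sampling spread of the estimator", {
  # Monte-Carlo oracle: empirical SD of BAR over independent regenerations
  ests <- vapply(1:200, function(k) {
    bar_estimate(gen_cft_gaussian_works(1.5, 1, 200, 200, 298,
                                        seed = 5000 + k))$value
  }, numeric(1))
  empirical <- sd(ests)
  ws <- gen_cft_gaussian_works(1.5, 1, 200, 200, 298, seed = 5001)
  boot <- bootstrap_se(ws, n_boot = 500, seed = 77)
  expect_lt(abs(boot - empirical) / empirical, 0.3)
})

test_that("replica combination follows the stated error model", {
  r <- combine_replicas(c(2, 2, 2), c(0, 0, 0))
  expect_equal(r$value, 2)
  expect_identical(r$se, 0)

  r <- combine_replicas(c(1, 2, 3), c(0, 0, 0))
  expect_equal(r$value, 2)
  expect_equal(r$se, 1 / sqrt(3), tolerance = 1e-12)

  r <- combine_replicas(c(1, 2, 3), c(0.3, 0.3, 0.3))
  expect_equal(r$se, sqrt(1 / 3 + 0.27 / 9), tolerance = 1e-12)

  single <- combine_replicas(2.5, 0.4)
  expect_identical(single$se, 0.4)
  expect_error(combine_replicas(numeric(0)), "no replica")
})

test_that("edge ddG assembles legs with quadrature uncertainties", {
  e <- edge_ddg(list(value = 5, se = 0), list(value = 3, se = 0), edge = "x")
  expect_identical(e$ddg, 2)
  expect_identical(e$se, 0)
  e2 <- edge_ddg(list(value = 1.1, se = 0.2), list(value = 1.1, se = 0.2))
  expect_equal(e2$ddg, 0)
  expect_equal(e2$se, 0.2 * sqrt(2), tolerance = 1e-12)
  e3 <- edge_ddg(list(value = -1.2, se = 0.3), list(value = 0.8, se = 0.4))
  expect_equal(e3$ddg, -2)
  expect_equal(e3$se, 0.5, tolerance = 1e-12)
})

test_that("work files convert kJ/mol to kcal/mol and report bad rows", {
  p <- tempfile()
  writeLines(c("# comment", "1 4.184", "2 -8.368"), p)
  expect_equal(read_work_file(p), c(1, -2), tolerance = 1e-12)

  p80 <- tempfile()
  writeLines(sprintf("%d %.3f", 1:80, rnorm(80)), p80)
  expect_length(read_work_file(p80), 80)

  empty <- tempfile()
  writeLines("# only a comment", empty)
  expect_error(read_work_file(empty), "no work values")

  bad <- tempfile()
  writeLines(c("1 4.184", "2 oops"), bad)
  expect_error(read_work_file(bad), "line 2")

  # round trip through the writer
  rt <- tempfile()
  write_work_file(c(0.25, -1.75), rt)
  expect_equal(read_work_file(rt), c(0.25, -1.75), tolerance = 1e-12)
})

test_that("dhdl files parse 2- and 3-column layouts in kJ/mol", {
  p2 <- tempfile()
  writeLines(c("# lambda dhdl", sprintf("%.3f %.4f", seq(0, 1, 0.25),
                                        4.184 * 2 * seq(0, 1, 0.25))), p2)
  tr <- read_dhdl(p2)
  expect_equal(integrate_work(tr), 1, tolerance = 1e-9)

  p3 <- tempfile()
  writeLines(sprintf("%.1f %.3f %.4f", 0:4 * 10, seq(0, 1, 0.25),
                     4.184 * rep(1, 5)), p3)
  expect_equal(integrate_work(read_dhdl(p3)), 1, tolerance = 1e-9)
})
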