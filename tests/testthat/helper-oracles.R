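# Independent oracles used to cross-check the package implementations.
# These deliberately use brute force or closed forms, never the code paths
# they validate.

# Dense grid scan for the BAR self-consistency root: scan dG over a wide
# grid and locate the sign change of the MLE score, then refine once on a
# finer grid. Independent of the package's bisection.
grid_scan_bar <- function(w_f, w_r, temperature = 298,
                          kb = 0.0019872041) {
  beta <- 1 / (kb * temperature)
  u_r <- -w_r
  m_ratio <- length(w_f) / length(u_r)
  score <- function(dg) {
    sum(1 / (1 + m_ratio * exp(beta * (w_f - dg)))) -
      sum(1 / (1 + exp(-beta * (u_r - dg)) / m_ratio))
  }
  refine <- function(lo, hi, n) {
    grid <- seq(lo, hi, length.out = n)
    vals <- vapply(grid, score, numeric(1))
    flip <- which(diff(sign(vals)) != 0)[1]
    c(grid[flip], grid[flip + 1])
  }
  span <- range(c(w_f, u_r))
  b <- refine(span[1] - 30, span[2] + 30, 20001)
  for (k in 1:4) b <- refine(b[1], b[2], 2001)
  mean(b)
}

# O(n^2) Kendall tau-b: explicit concordant/discordant pair count with tie
# correction.
brute_force_tau_b <- function(x, y) {
  n <- length(x)
  conc <- disc <- tx <- ty <- 0
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      dx <- sign(x[j] - x[i])
      dy <- sign(y[j] - y[i])
      if (dx == 0 && dy == 0) {
        # tied in both: contributes to neither correction term
      } else if (dx == 0) {
        tx <- tx + 1
      } else if (dy == 0) {
        ty <- ty + 1
      } else if (dx == dy) {
        conc <- conc + 1
      } else {
        disc <- disc + 1
      }
    }
  }
  (conc - disc) / sqrt((conc + disc + tx) * (conc + disc + ty))
}

# Enumerate all spanning trees of a small complete graph (by edge-subset
# enumeration) and return the minimum total distance.
brute_force_min_spanning_tree <- function(dist_mat) {
  n <- nrow(dist_mat)
  pairs <- t(combn(n, 2))
  m <- nrow(pairs)
  best <- Inf
  for (subset in combn(m, n - 1, simplify = FALSE)) {
    g <- igraph::graph_from_edgelist(pairs[subset, , drop = FALSE],
                                     directed = FALSE)
    if (igraph::vcount(g) < n) next
    if (igraph::components(g)$no != 1) next
    w <- sum(dist_mat[pairs[subset, , drop = FALSE]])
    best <- min(best, w)
  }
  best
}

# Numeric WLS minimiser for the node-potential objective, independent of
# the package's Laplacian solve: direct optimisation from several starts.
brute_force_wls_nodes <- function(sources, targets, ddg, w, nodes) {
  obj <- function(g) {
    names(g) <- nodes
    sum(w * (g[targets] - g[sources] - ddg)^2)
  }
  best <- NULL
  for (start in 1:3) {
    set.seed(start)
    fit <- optim(rnorm(length(nodes)), obj, method = "BFGS",
                 control = list(maxit = 2000, reltol = 1e-14))
    if (is.null(best) || fit$value < best$value) best <- fit
  }
  g <- best$par
  g - mean(g)
}

# Gaussian density crossing of P_f(W) and P_r(-W): solve the quadratic for
# equal log densities of N(m1, s1) and N(m2, s2).
gaussian_crossing <- function(m1, s1, m2, s2) {
  a <- 1 / (2 * s2^2) - 1 / (2 * s1^2)
  b <- m1 / s1^2 - m2 / s2^2
  cc <- m2^2 / (2 * s2^2) - m1^2 / (2 * s1^2) + log(s2 / s1)
  if (abs(a) < 1e-12) return(-cc / b)
  roots <- (-b + c(-1, 1) * sqrt(b^2 - 4 * a * cc)) / (2 * a)
  # the relevant crossing lies between the two means
  roots[which.min(abs(roots - (m1 + m2) / 2))]
}
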