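# Cycle closure, absolute dG reconstruction, and benchmark metrics.
#
# Edge ddG estimates around graph cycles do not generally sum to zero; the
# thermodynamically consistent set closest to the measurements is the
# weighted least squares projection onto node potentials: minimise
# sum_e w_e (g_b - g_a - ddG_e)^2 with w_e = 1 / max(se_e, se_floor)^2.
# The solution is defined up to an additive constant; the gauge is fixed to
# mean(g) = 0 and later anchored to the mean experimental affinity of the
# series. Node uncertainties come from the diagonal of the pseudo-inverse
# of the weighted graph Laplacian.

#' Solve for absolute node free energies from edge ddG values
#'
#' Weighted least squares over the perturbation graph (the cycle-closure
#' projection): node values minimise the weighted squared edge residuals,
#' gauge-fixed to `mean(g) = 0`. Edge weights are `1 / max(se, se_floor)^2`;
#' the floor keeps zero-uncertainty edges from acquiring infinite weight.
#'
#' @param map a [perturbation_map()].
#' @param edges list of `edge_result` objects (or a data.frame with columns
#'   `edge`, `ddg`, `se`) covering every map edge.
#' @param se_floor smallest SE used in weighting (kcal/mol).
#' @return data.frame with columns `id`, `dg_calc`, `se` (kcal/mol); the
#'   attribute `residuals` holds per-edge fitted-minus-input values and
#'   `fitted` the node-consistent (cycle-closed) edge values.
#' @export
solve_node_dgs <- function(map, edges, se_floor = 0.1) {
  et <- edge_table(edges)
  missing_edges <- setdiff(map$edges$id, et$edge)
  if (length(missing_edges) > 0) {
    stop(sprintf("missing edge result(s): %s",
                 paste(missing_edges, collapse = ", ")), call. = FALSE)
  }
  g <- map_graph(map)
  comp <- igraph::components(g)
  if (comp$no > 1) {
    parts <- split(names(comp$membership), comp$membership)
    stop(sprintf("graph is disconnected: components {%s}",
                 paste(vapply(parts, paste, "", collapse = ","),
                       collapse = "} {")), call. = FALSE)
  }
  nodes <- map$nodes
  n <- length(nodes)
  m <- nrow(map$edges)
  et <- et[match(map$edges$id, et$edge), ]
  w <- 1 / pmax(et$se, se_floor)^2

  # incidence matrix B: edge e = (a -> b) has -1 at a, +1 at b
  b_mat <- matrix(0, m, n, dimnames = list(map$edges$id, nodes))
  for (e in seq_len(m)) {
    b_mat[e, map$edges$source[e]] <- -1
    b_mat[e, map$edges$target[e]] <- 1
  }
  lap <- t(b_mat) %*% (w * b_mat)
  rhs <- as.vector(t(b_mat) %*% (w * et$ddg))
  # gauge mean(g) = 0: (L + 11^T/n) is nonsingular and its solution has
  # zero mean because rhs is orthogonal to 1
  g_vals <- solve(lap + matrix(1 / n, n, n), rhs)
  g_vals <- as.vector(g_vals) - mean(g_vals)

  lap_pinv <- MASS::ginv(lap)
  node_se <- sqrt(pmax(diag(lap_pinv), 0))

  fitted <- as.vector(b_mat %*% g_vals)
  out <- data.frame(id = nodes, dg_calc = g_vals, se = node_se,
                    stringsAsFactors = FALSE)
  attr(out, "fitted") <- stats::setNames(fitted, map$edges$id)
  attr(out, "residuals") <- stats::setNames(fitted - et$ddg, map$edges$id)
  out
}

edge_table <- function(edges) {
  if (is.data.frame(edges)) {
    stopifnot(all(c("edge", "ddg", "se") %in% names(edges)))
    return(edges[, c("edge", "ddg", "se")])
  }
  do.call(rbind, lapply(edges, function(e) {
    data.frame(edge = e$edge, ddg = e$ddg, se = e$se,
               stringsAsFactors = FALSE)
  }))
}

#' Signed ddG sums around fundamental cycles
#'
#' For a spanning tree of the map, each non-tree edge closes one fundamental
#' cycle; the signed sum of edge ddG values around that cycle is zero for a
#' thermodynamically consistent data set. A tree map returns an empty
#' vector.
#'
#' @param map a [perturbation_map()].
#' @param edges edge results as in [solve_node_dgs()].
#' @return named numeric vector of cycle closure errors (kcal/mol), one per
#'   non-tree edge.
#' @export
cycle_closure_errors <- function(map, edges) {
  et <- edge_table(edges)
  et <- et[match(map$edges$id, et$edge), ]
  g <- map_graph(map)
  comp <- igraph::components(g)
  if (comp$no > 1) stop("graph is disconnected", call. = FALSE)
  ddg <- stats::setNames(et$ddg, map$edges$id)

  igraph::E(g)$idx <- seq_len(nrow(map$edges))
  tree <- igraph::mst(g)
  tree_eids <- igraph::E(tree)$idx
  non_tree <- setdiff(seq_len(nrow(map$edges)), tree_eids)
  if (length(non_tree) == 0) return(stats::setNames(numeric(0), character(0)))

  signed_step <- function(a, b) {
    hit <- which(map$edges$source == a & map$edges$target == b)
    if (length(hit) > 0) return(ddg[hit[1]])
    hit <- which(map$edges$source == b & map$edges$target == a)
    -ddg[hit[1]]
  }
  out <- numeric(0)
  for (k in non_tree) {
    a <- map$edges$source[k]
    b <- map$edges$target[k]
    path <- igraph::as_ids(igraph::shortest_paths(tree, from = a,
                                                  to = b)$vpath[[1]])
    s <- ddg[map$edges$id[k]] # the chord a -> b
    # close the cycle back along the tree path b -> a
    for (i in seq_len(length(path) - 1)) {
      s <- s - signed_step(path[i], path[i + 1])
    }
    out[map$edges$id[k]] <- unname(s)
  }
  out
}

#' Offset calculated node free energies to the experimental mean
#'
#' Relative free energies fix only differences; the absolute scale is set by
#' shifting all calculated values by one constant so that their mean over
#' ligands with experimental data equals the mean experimental affinity of
#' the same ligands. Idempotent; preserves all pairwise differences; node
#' uncertainties are unchanged.
#'
#' @param nodes data.frame from [solve_node_dgs()] (columns `id`,
#'   `dg_calc`, `se`).
#' @param exp affinity data.frame (columns `id`, `dg_exp`, `sigma_exp`), as
#'   from [read_affinities()].
#' @return `nodes` with shifted `dg_calc`.
#' @export
offset_to_experiment <- function(nodes, exp) {
  shared <- intersect(nodes$id, exp$id)
  if (length(shared) == 0) {
    stop("no ligand overlaps with the experimental table", call. = FALSE)
  }
  calc_mean <- mean(nodes$dg_calc[match(shared, nodes$id)])
  exp_mean <- mean(exp$dg_exp[match(shared, exp$id)])
  nodes$dg_calc <- nodes$dg_calc + (exp_mean - calc_mean)
  nodes
}

#' Benchmark metrics against experiment
#'
#' Average unsigned error, root-mean-square error, Pearson correlation and
#' Kendall rank correlation (tau-b, tie-corrected) of calculated vs
#' experimental values. With zero variance in either vector the
#' correlations are undefined and returned as NA with `degenerate = TRUE`;
#' the error metrics are still computed.
#'
#' @param calc,exp numeric vectors of equal length >= 2 (kcal/mol).
#' @return list with `aue`, `rmse`, `pearson_rho`, `kendall_tau`,
#'   `n`, `degenerate`.
#' @export
compute_metrics <- function(calc, exp) {
  calc <- as.numeric(calc)
  exp <- as.numeric(exp)
  stopifnot(length(calc) == length(exp), length(calc) >= 2)
  degenerate <- stats::sd(calc) == 0 || stats::sd(exp) == 0
  list(
    aue = mean(abs(calc - exp)),
    rmse = sqrt(mean((calc - exp)^2)),
    pearson_rho = if (degenerate) NA_real_ else stats::cor(calc, exp),
    kendall_tau = if (degenerate) NA_real_ else
      stats::cor(calc, exp, method = "kendall"),
    n = length(calc),
    degenerate = degenerate
  )
}

metric_names <- c("aue", "rmse", "pearson_rho", "kendall_tau")

#' Bootstrap confidence intervals for benchmark metrics
#'
#' Percentile 95% CIs from resampling (calc, exp) pairs with replacement.
#' Degenerate resamples (a single repeated pair, where correlations are
#' undefined) are rejected and redrawn. Deterministic per seed.
#'
#' @param calc,exp paired vectors (n >= 3).
#' @param n_boot number of resamples (>= 100).
#' @param seed RNG seed.
#' @param level confidence level.
#' @return named list per metric with `lower`, `upper` and point `value`.
#' @export
bootstrap_metric_ci <- function(calc, exp, n_boot = 1000, seed,
                                level = 0.95) {
  stopifnot(length(calc) == length(exp), length(calc) >= 3, n_boot >= 100)
  if (missing(seed)) stop("bootstrap_metric_ci requires a seed", call. = FALSE)
  n <- length(calc)
  alpha <- (1 - level) / 2
  samples <- with_seed(seed, {
    out <- matrix(NA_real_, n_boot, length(metric_names),
                  dimnames = list(NULL, metric_names))
    for (b in seq_len(n_boot)) {
      for (try in 1:100) {
        idx <- sample.int(n, n, replace = TRUE)
        if (length(unique(idx)) > 1) break
      }
      m <- compute_metrics(calc[idx], exp[idx])
      out[b, ] <- c(m$aue, m$rmse, m$pearson_rho, m$kendall_tau)
    }
    out
  })
  point <- compute_metrics(calc, exp)
  res <- list()
  for (nm in metric_names) {
    qs <- stats::quantile(samples[, nm], c(alpha, 1 - alpha), na.rm = TRUE,
                          names = FALSE)
    res[[nm]] <- list(value = point[[nm]], lower = qs[1], upper = qs[2])
  }
  res
}

#' Experimental-uncertainty null bands for benchmark metrics
#'
#' The performance ceiling set by experimental noise: two hypothetical
#' replicate measurements of the same series are simulated by perturbing
#' the experimental values twice with independent Gaussian noise of SD
#' `max(sigma_exp, sigma_floor)` per ligand, and each metric is computed
#' between the two replicates. The percentile band over `n_samples` draws
#' is the region a perfect predictor could plausibly occupy; for RMSE its
#' centre sits near `sigma_floor * sqrt(2)` when the floor dominates. The
#' default floor of 0.43 kcal/mol is the best-practices lower bound on
#' experimental binding free energy uncertainty.
#'
#' @param exp experimental values (n >= 3).
#' @param sigma_exp per-value uncertainties (recycled if scalar).
#' @param n_samples number of Monte Carlo draws.
#' @param seed RNG seed.
#' @param sigma_floor lower bound applied to `sigma_exp` (set 0 to disable).
#' @param level band level.
#' @return named list per metric with `lower` and `upper`.
#' @export
experimental_null_band <- function(exp, sigma_exp, n_samples = 1000, seed,
                                   sigma_floor = 0.43, level = 0.95) {
  exp <- as.numeric(exp)
  stopifnot(length(exp) >= 3)
  if (missing(seed)) stop("experimental_null_band requires a seed", call. = FALSE)
  sigma <- pmax(rep_len(as.numeric(sigma_exp), length(exp)), sigma_floor)
  alpha <- (1 - level) / 2
  samples <- with_seed(seed, {
    out <- matrix(NA_real_, n_samples, length(metric_names),
                  dimnames = list(NULL, metric_names))
    for (b in seq_len(n_samples)) {
      y1 <- exp + stats::rnorm(length(exp), 0, sigma)
      y2 <- exp + stats::rnorm(length(exp), 0, sigma)
      m <- compute_metrics(y1, y2)
      out[b, ] <- c(m$aue, m$rmse, m$pearson_rho, m$kendall_tau)
    }
    out
  })
  res <- list()
  for (nm in metric_names) {
    qs <- stats::quantile(samples[, nm], c(alpha, 1 - alpha), na.rm = TRUE,
                          names = FALSE)
    res[[nm]] <- list(lower = qs[1], upper = qs[2])
  }
  res
}
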