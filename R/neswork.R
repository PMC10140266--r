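# Non-equilibrium work computation and free energy estimation.
#
# Free energies are estimated from bidirectional non-equilibrium work
# samples with the Bennett/Shirts maximum-likelihood estimator, which is the
# estimator consistent with the Crooks fluctuation theorem
# P_f(W) / P_r(-W) = exp(beta (W - dG)). Reverse works are stored as the
# work done along the B -> A switch (pmx convention); the estimator negates
# them internally. The internal unit is kcal/mol throughout; file readers
# convert from kJ/mol at the boundary.

#' Bidirectional work set
#'
#' @param w_f forward (A to B) work samples, kcal/mol.
#' @param w_r reverse work samples recorded as the work done along the
#'   B to A switch, kcal/mol.
#' @param edge edge identifier (informational).
#' @param leg `"complex"` or `"water"` (informational).
#' @param replica replica index (informational).
#' @return object of class `work_set`.
#' @export
work_set <- function(w_f, w_r, edge = "", leg = "", replica = 1L) {
  w_f <- as.numeric(w_f)
  w_r <- as.numeric(w_r)
  stopifnot(length(w_f) >= 1, length(w_r) >= 1)
  if (!all(is.finite(w_f)) || !all(is.finite(w_r))) {
    stop("work values must be finite", call. = FALSE)
  }
  structure(list(w_f = w_f, w_r = w_r, edge = edge, leg = leg,
                 replica = as.integer(replica)),
            class = "work_set")
}

#' @export
print.work_set <- function(x, ...) {
  cat(sprintf("<work_set %s/%s rep %d: %d forward, %d reverse works>\n",
              x$edge, x$leg, x$replica, length(x$w_f), length(x$w_r)))
  invisible(x)
}

#' Snapshot extraction schedule for transition starts
#'
#' Times (ps) at which frames are pulled from an equilibrium trajectory to
#' seed non-equilibrium transitions: the equilibration prefix `t_discard` is
#' excluded and `n_frames` equally spaced frames are taken from what
#' remains, ending exactly at `t_total`. The default protocol (6 ns
#' production, first 2 ns discarded, 80 frames) gives 80 starts at 50 ps
#' spacing.
#'
#' @param t_total total trajectory length (ps).
#' @param t_discard initial time to discard (ps).
#' @param n_frames number of snapshots.
#' @param output_interval trajectory output interval (ps); when given, an
#'   error is raised if the schedule asks for more frames than the
#'   trajectory holds after discard.
#' @return numeric vector of `n_frames` times (ps).
#' @export
frame_schedule <- function(t_total = 6000, t_discard = 2000, n_frames = 80,
                           output_interval = NULL) {
  stopifnot(t_discard >= 0, t_discard < t_total, n_frames >= 1)
  if (!is.null(output_interval)) {
    available <- floor((t_total - t_discard) / output_interval)
    if (n_frames > available) {
      stop(sprintf(
        "n_frames = %d exceeds the %d frames available at a %g ps output interval",
        n_frames, available, output_interval
      ), call. = FALSE)
    }
  }
  delta <- (t_total - t_discard) / n_frames
  t_discard + seq_len(n_frames) * delta
}

#' dH/dlambda switching trace
#'
#' @param lam lambda values in `[0, 1]`, strictly monotone (increasing for a
#'   forward A to B switch, decreasing for reverse).
#' @param dhdl dH/dlambda samples, kcal/mol.
#' @return object of class `dhdl_trace`.
#' @export
dhdl_trace <- function(lam, dhdl) {
  lam <- as.numeric(lam)
  dhdl <- as.numeric(dhdl)
  stopifnot(length(lam) == length(dhdl), length(lam) >= 2)
  d <- diff(lam)
  if (!(all(d > 0) || all(d < 0))) {
    stop("lambda must be strictly monotone", call. = FALSE)
  }
  if (min(lam) < 0 || max(lam) > 1) {
    stop("lambda values must lie in [0, 1]", call. = FALSE)
  }
  structure(list(lam = lam, dhdl = dhdl), class = "dhdl_trace")
}

#' Work by thermodynamic integration of a switching trace
#'
#' Trapezoidal integral of dH/dlambda over lambda along the traversal
#' direction; a reverse trace (lambda from 1 to 0) yields the B to A work as
#' integrated, typically the negative of the forward integral for the same
#' path. Exact for integrands linear in lambda.
#'
#' @param trace a [dhdl_trace()].
#' @return work in kcal/mol.
#' @export
integrate_work <- function(trace) {
  if (!inherits(trace, "dhdl_trace")) trace <- dhdl_trace(trace$lam, trace$dhdl)
  sum(diff(trace$lam) * (head(trace$dhdl, -1) + tail(trace$dhdl, -1)) / 2)
}

# BAR maximum-likelihood self-consistency score; monotone increasing in dG.
# m_ratio = n_f / n_r; u_r = -W_r (reverse works on the forward scale).
bar_score_parts <- function(dg, w_f, u_r, beta, m_ratio) {
  lhs <- sum(1 / (1 + m_ratio * exp(beta * (w_f - dg))))
  rhs <- sum(1 / (1 + exp(-beta * (u_r - dg)) / m_ratio))
  c(lhs = lhs, rhs = rhs)
}

bar_score <- function(dg, w_f, u_r, beta, m_ratio) {
  p <- bar_score_parts(dg, w_f, u_r, beta, m_ratio)
  p[["lhs"]] - p[["rhs"]]
}

#' Crooks/Bennett maximum-likelihood free energy estimate
#'
#' Solves the Bennett acceptance ratio self-consistency equation, the
#' maximum-likelihood estimator for bidirectional work samples under the
#' Crooks fluctuation theorem. The score is monotone in dG, so the root is
#' bracketed and found by bisection to 1e-10 kcal/mol.
#'
#' @param works a [work_set()] (reverse works stored as B to A work).
#' @param temperature temperature in K.
#' @return object of class `fe_estimate`: fields `value` (kcal/mol),
#'   `se_boot` (NA until [bootstrap_se()] fills it), `estimator`, `n_f`,
#'   `n_r`, `temperature`.
#' @export
bar_estimate <- function(works, temperature = DEFAULT_TEMPERATURE) {
  stopifnot(inherits(works, "work_set"), temperature > 0)
  beta <- 1 / kbt_kcal(temperature)
  w_f <- works$w_f
  u_r <- -works$w_r
  m_ratio <- length(w_f) / length(u_r)
  pool <- c(w_f, u_r)
  lo <- min(pool) - 50 / beta
  hi <- max(pool) + 50 / beta
  f_lo <- bar_score(lo, w_f, u_r, beta, m_ratio)
  f_hi <- bar_score(hi, w_f, u_r, beta, m_ratio)
  if (is.na(f_lo) || is.na(f_hi) || f_lo * f_hi > 0) {
    stop(sprintf(
      "insufficient overlap: no root in bracket [%.3f, %.3f]", lo, hi
    ), call. = FALSE)
  }
  # bisection: the score is monotone increasing in dG
  for (iter in 1:200) {
    mid <- (lo + hi) / 2
    f_mid <- bar_score(mid, w_f, u_r, beta, m_ratio)
    if (f_mid < 0) lo <- mid else hi <- mid
    if (hi - lo < 1e-10) break
  }
  root <- (lo + hi) / 2
  # with disjoint work distributions both Fermi sums underflow to a flat
  # zero plateau and the "root" is meaningless: flag it instead
  parts <- bar_score_parts(root, w_f, u_r, beta, m_ratio)
  if (sum(parts) < 1e-8) {
    stop(sprintf(
      "insufficient overlap between forward and reverse works in bracket [%.3f, %.3f]",
      lo - 50 / beta, hi + 50 / beta
    ), call. = FALSE)
  }
  structure(
    list(value = root, se_boot = NA_real_, estimator = "bar_mle",
         n_f = length(w_f), n_r = length(u_r), temperature = temperature),
    class = "fe_estimate"
  )
}

#' @export
print.fe_estimate <- function(x, ...) {
  se <- if (is.na(x$se_boot)) "" else sprintf(" +/- %.3f", x$se_boot)
  cat(sprintf("<fe_estimate [%s]: %.4f%s kcal/mol (n_f=%d, n_r=%d, T=%gK)>\n",
              x$estimator, x$value, se, x$n_f, x$n_r, x$temperature))
  invisible(x)
}

#' Jarzynski exponential-average estimate
#'
#' One-directional free energy estimate from the Jarzynski equality,
#' dG = -kT ln <exp(-beta W)>, computed with log-sum-exp stabilisation.
#' Used as an independent validation oracle for [bar_estimate()]; biased at
#' finite sample size when dissipation is large.
#'
#' @param w work samples, kcal/mol (for `direction = "r"`, the B to A
#'   works; the returned value is the A to B free energy).
#' @param temperature temperature in K.
#' @param direction `"f"` (forward) or `"r"` (reverse).
#' @return free energy in kcal/mol (A to B).
#' @export
jarzynski_estimate <- function(w, temperature = DEFAULT_TEMPERATURE,
                               direction = c("f", "r")) {
  direction <- match.arg(direction)
  w <- as.numeric(w)
  stopifnot(length(w) >= 1, all(is.finite(w)))
  beta <- 1 / kbt_kcal(temperature)
  x <- -beta * w
  m <- max(x)
  lse <- m + log(mean(exp(x - m)))
  dg_dir <- -lse / beta # free energy along the traversal direction
  if (direction == "f") dg_dir else -dg_dir
}

#' Bootstrap standard error of the BAR estimate
#'
#' Standard deviation of [bar_estimate()] over `n_boot` resamples of the
#' forward and reverse work sets (independently, with replacement).
#' Deterministic for a fixed seed; estimation failures (insufficient
#' overlap in a resample) are tolerated up to 10% of resamples.
#'
#' @param works a [work_set()].
#' @param temperature temperature in K.
#' @param n_boot number of bootstrap resamples (>= 2).
#' @param seed RNG seed (required for reproducibility).
#' @return bootstrap SE in kcal/mol.
#' @export
bootstrap_se <- function(works, temperature = DEFAULT_TEMPERATURE,
                         n_boot = 100, seed) {
  stopifnot(inherits(works, "work_set"), n_boot >= 2)
  if (missing(seed)) stop("bootstrap_se requires a seed", call. = FALSE)
  n_f <- length(works$w_f)
  n_r <- length(works$w_r)
  vals <- with_seed(seed, {
    vapply(seq_len(n_boot), function(b) {
      ws <- work_set(
        works$w_f[sample.int(n_f, n_f, replace = TRUE)],
        works$w_r[sample.int(n_r, n_r, replace = TRUE)]
      )
      tryCatch(bar_estimate(ws, temperature)$value, error = function(e) NA_real_)
    }, numeric(1))
  })
  n_fail <- sum(is.na(vals))
  if (n_fail > 0.1 * n_boot) {
    stop(sprintf("bootstrap failed in %d/%d resamples (insufficient overlap)",
                 n_fail, n_boot), call. = FALSE)
  }
  stats::sd(vals[!is.na(vals)])
}

#' Combine replica free energy estimates
#'
#' Mean over replicas; the uncertainty combines the standard error over
#' replicas with the propagated per-replica bootstrap uncertainties:
#' se^2 = s^2 / R + (sum_i se_boot_i^2) / R^2, where s is the sample SD over
#' the R replica values. For a single replica the bootstrap SE is returned
#' unchanged.
#'
#' @param values replica free energy values (kcal/mol), or a list of
#'   `fe_estimate` objects.
#' @param se_boot per-replica bootstrap SEs (ignored when `values` is a list
#'   of estimates).
#' @return list with `value` and `se` (kcal/mol) and `replicas`.
#' @export
combine_replicas <- function(values, se_boot = NULL) {
  if (is.list(values) && length(values) > 0 &&
      inherits(values[[1]], "fe_estimate")) {
    se_boot <- vapply(values, function(e) e$se_boot, numeric(1))
    values <- vapply(values, function(e) e$value, numeric(1))
  }
  values <- as.numeric(values)
  if (length(values) == 0) stop("no replica estimates", call. = FALSE)
  r <- length(values)
  se_boot <- as.numeric(se_boot %||% rep(0, r))
  se_boot[is.na(se_boot)] <- 0
  stopifnot(length(se_boot) == r)
  if (r == 1) {
    return(list(value = values, se = se_boot, replicas = 1L))
  }
  s2 <- stats::var(values)
  se <- sqrt(s2 / r + sum(se_boot^2) / r^2)
  list(value = mean(values), se = se, replicas = as.integer(r))
}

#' Assemble an edge ddG from its two legs
#'
#' ddG = dG_complex - dG_water with uncertainties added in quadrature.
#'
#' @param complex,water lists with `value` and `se` (kcal/mol), as returned
#'   by [combine_replicas()].
#' @param edge edge id.
#' @param replicas replica count (informational).
#' @return object of class `edge_result` with fields `edge`, `dg_complex`,
#'   `dg_water`, `ddg`, `se`, `replicas`.
#' @export
edge_ddg <- function(complex, water, edge = "", replicas = 1L) {
  res <- structure(
    list(
      edge = edge,
      dg_complex = complex$value,
      dg_water = water$value,
      ddg = complex$value - water$value,
      se = sqrt(complex$se^2 + water$se^2),
      replicas = as.integer(replicas)
    ),
    class = "edge_result"
  )
  stopifnot(abs(res$ddg - (res$dg_complex - res$dg_water)) < 1e-9,
            res$se >= 0)
  res
}

#' @export
print.edge_result <- function(x, ...) {
  cat(sprintf("<edge %s: ddG = %.3f +/- %.3f kcal/mol (%d replicas)>\n",
              x$edge, x$ddg, x$se, x$replicas))
  invisible(x)
}

# ---- file I/O ------------------------------------------------------------

#' Read a two-column work file
#'
#' pmx-style work files: two whitespace-separated columns (snapshot index,
#' work in kJ/mol), `#` comment lines ignored. Values are converted to
#' kcal/mol; order is preserved.
#'
#' @param path file path.
#' @return numeric vector of works in kcal/mol.
#' @export
read_work_file <- function(path) {
  stopifnot(file.exists(path))
  lines <- readLines(path, warn = FALSE)
  keep <- which(nzchar(trimws(lines)) & !startsWith(trimws(lines), "#"))
  if (length(keep) == 0) {
    stop(sprintf("'%s': no work values", path), call. = FALSE)
  }
  vals <- numeric(length(keep))
  for (k in seq_along(keep)) {
    toks <- strsplit(trimws(lines[keep[k]]), "\\s+")[[1]]
    if (length(toks) < 2) {
      stop(sprintf("'%s' line %d: expected two columns", path, keep[k]),
           call. = FALSE)
    }
    v <- suppressWarnings(as.numeric(toks[2]))
    if (is.na(v)) {
      stop(sprintf("'%s' line %d: non-numeric work value '%s'",
                   path, keep[k], toks[2]), call. = FALSE)
    }
    vals[k] <- v
  }
  vals / KJ_PER_KCAL
}

#' Write a two-column work file
#'
#' Inverse of [read_work_file()]: works given in kcal/mol are written in
#' kJ/mol with a snapshot index column.
#'
#' @param works numeric vector, kcal/mol.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_work_file <- function(works, path) {
  lines <- c("# snapshot  work_kJ_per_mol",
             sprintf("%d %.10g", seq_along(works), works * KJ_PER_KCAL))
  writeLines(lines, path)
  invisible(path)
}

#' Read a dH/dlambda trace file
#'
#' Two whitespace-separated columns (lambda, dH/dlambda in kJ/mol) or three
#' (time, lambda, dH/dlambda in kJ/mol); `#` and `@` lines (xvg headers)
#' ignored. dH/dlambda is converted to kcal/mol.
#'
#' @param path file path.
#' @return a [dhdl_trace()].
#' @export
read_dhdl <- function(path) {
  stopifnot(file.exists(path))
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#") &
                   !startsWith(lines, "@")]
  if (length(lines) < 2) stop(sprintf("'%s': too few rows", path), call. = FALSE)
  mat <- do.call(rbind, lapply(lines, function(l) {
    as.numeric(strsplit(l, "\\s+")[[1]])
  }))
  if (ncol(mat) == 2) {
    dhdl_trace(mat[, 1], mat[, 2] / KJ_PER_KCAL)
  } else if (ncol(mat) >= 3) {
    dhdl_trace(mat[, 2], mat[, 3] / KJ_PER_KCAL)
  } else {
    stop(sprintf("'%s': expected 2 or 3 columns", path), call. = FALSE)
  }
}
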