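# Synthetic data generators and mock backends.
#
# These replace the docking and MD engines with exactly solvable stand-ins:
# Gaussian work distributions that satisfy the Crooks fluctuation theorem by
# construction, noisy edge graphs with known node truth, and rigid-body pose
# perturbations with known displacement ranking. They write the same file
# formats the real pipeline reads, so mock and real inputs are
# interchangeable. Every generator is bit-reproducible under a fixed seed.

#' Gaussian work samples consistent with the Crooks fluctuation theorem
#'
#' For equal-variance Gaussian forward/reverse work distributions the
#' Crooks relation fixes both means given the free energy and the width:
#' `W_f ~ N(dg_true + beta sigma^2 / 2, sigma^2)` and the reverse (B to A)
#' works `W_r ~ N(-dg_true + beta sigma^2 / 2, sigma^2)`. The mean
#' dissipated work is `beta sigma^2 / 2` in each direction.
#'
#' @param dg_true true free energy difference (kcal/mol).
#' @param sigma work distribution SD (kcal/mol); 0 gives delta functions.
#' @param n_f,n_r sample counts.
#' @param temperature temperature (K).
#' @param seed RNG seed.
#' @return a [work_set()].
#' @export
gen_cft_gaussian_works <- function(dg_true, sigma, n_f = 80, n_r = 80,
                                   temperature = DEFAULT_TEMPERATURE, seed) {
  stopifnot(sigma >= 0, n_f >= 1, n_r >= 1)
  if (missing(seed)) stop("gen_cft_gaussian_works requires a seed", call. = FALSE)
  beta <- 1 / kbt_kcal(temperature)
  dissip <- beta * sigma^2 / 2
  with_seed(seed, {
    w_f <- stats::rnorm(n_f, dg_true + dissip, sigma)
    w_r <- stats::rnorm(n_r, -dg_true + dissip, sigma)
    work_set(w_f, w_r)
  })
}

#' Synthetic perturbation-map study with known truth
#'
#' Generates a congeneric-series stand-in: true absolute binding free
#' energies uniform over `dg_range`, a connected perturbation map with
#' cycles built by the package's MST + augmentation scheme over a random
#' similarity matrix, per-edge ddG measurements (truth + Gaussian noise),
#' and an experimental affinity table (truth + Gaussian noise). Defaults
#' emulate a mid-sized congeneric series: 27 ligands spanning 4.3 kcal/mol,
#' target node degree 3, experimental noise at the 0.43 kcal/mol
#' best-practices floor.
#'
#' @param n_ligands number of ligands (>= 3).
#' @param dg_range range (kcal/mol) the true affinities are drawn from.
#' @param edge_noise_sd SD of the edge ddG noise (kcal/mol).
#' @param exp_noise_sd SD of the experimental noise (kcal/mol).
#' @param target_degree minimum node degree of the map.
#' @param seed RNG seed.
#' @return object of class `synthetic_study`: `map`, `dg_true` (named),
#'   `edges` (data.frame edge, ddg, se with noisy values), `ddg_true`
#'   (named by edge id), `affinities` (data.frame id, dg_exp, sigma_exp),
#'   `seed`.
#' @export
gen_map_study <- function(n_ligands = 27, dg_range = c(-11.5, -7.2),
                          edge_noise_sd = 0.3, exp_noise_sd = 0.43,
                          target_degree = 3, seed) {
  stopifnot(n_ligands >= 3)
  if (missing(seed)) stop("gen_map_study requires a seed", call. = FALSE)
  ids <- sprintf("lig%02d", seq_len(n_ligands))
  with_seed(seed, {
    sim <- matrix(0, n_ligands, n_ligands)
    sim[upper.tri(sim)] <- stats::runif(n_ligands * (n_ligands - 1) / 2,
                                        0.3, 0.95)
    sim <- sim + t(sim)
    map <- build_map_from_similarity(sim, ids, target_degree)
    dg_true <- stats::setNames(
      stats::runif(n_ligands, min(dg_range), max(dg_range)), ids
    )
    ddg_true <- dg_true[map$edges$target] - dg_true[map$edges$source]
    names(ddg_true) <- map$edges$id
    edges <- data.frame(
      edge = map$edges$id,
      ddg = ddg_true + stats::rnorm(nrow(map$edges), 0, edge_noise_sd),
      se = edge_noise_sd,
      stringsAsFactors = FALSE
    )
    affinities <- data.frame(
      id = ids,
      dg_exp = dg_true + stats::rnorm(n_ligands, 0, exp_noise_sd),
      sigma_exp = exp_noise_sd,
      stringsAsFactors = FALSE
    )
    structure(
      list(map = map, dg_true = dg_true, ddg_true = ddg_true, edges = edges,
           affinities = affinities, seed = seed),
      class = "synthetic_study"
    )
  })
}

#' @export
print.synthetic_study <- function(x, ...) {
  cat(sprintf("<synthetic_study: %d ligands, %d edges, seed %s>\n",
              length(x$dg_true), nrow(x$edges), format(x$seed)))
  invisible(x)
}

# Uniform random rotation matrix (Arvo's method via QR of a Gaussian
# matrix, sign-fixed to det +1).
random_rotation <- function() {
  qr_dec <- qr(matrix(stats::rnorm(9), 3, 3))
  q <- qr.Q(qr_dec)
  d <- sign(diag(qr.R(qr_dec)))
  q <- q %*% diag(d)
  if (det(q) < 0) q[, 1] <- -q[, 1]
  q
}

# Rotation by `angle` radians about a random axis.
random_axis_rotation <- function(angle) {
  ax <- stats::rnorm(3)
  ax <- ax / sqrt(sum(ax^2))
  k <- matrix(c(0, -ax[3], ax[2], ax[3], 0, -ax[1], -ax[2], ax[1], 0), 3, 3,
              byrow = TRUE)
  diag(3) + sin(angle) * k + (1 - cos(angle)) * (k %*% k)
}

#' Rigid-body pose perturbations with known displacement ranking
#'
#' Pose k is the reference rotated about its centroid by a small angle
#' proportional to `displacement_scales[k]` and translated along a random
#' direction by exactly `displacement_scales[k]` Angstrom. Because the
#' rotation is about the centroid, the unmapped RMSD decomposes as
#' `sqrt(d^2 + r(angle)^2)` and is strictly monotone in the scale, so the
#' scale ordering is the RMSD ordering; with `rot_per_ang = 0` the RMSD of
#' a pose equals its translation norm exactly.
#'
#' @param mol `nes_mol` providing the topology.
#' @param ref_coords reference coordinates (n x 3, Angstrom).
#' @param displacement_scales translation norms (Angstrom), one per pose.
#' @param seed RNG seed.
#' @param rot_per_ang rotation angle per Angstrom of displacement
#'   (radians; default 0.05).
#' @return a [pose_set()] with attribute `ranking` = order of poses by
#'   scale (least-displaced first).
#' @export
perturb_poses <- function(mol, ref_coords, displacement_scales, seed,
                          rot_per_ang = 0.05) {
  if (missing(seed)) stop("perturb_poses requires a seed", call. = FALSE)
  ref_coords <- as.matrix(ref_coords)
  scales <- as.numeric(displacement_scales)
  with_seed(seed, {
    centroid <- colMeans(ref_coords)
    centered <- sweep(ref_coords, 2, centroid)
    coords <- lapply(scales, function(s) {
      rot <- if (s > 0 && rot_per_ang > 0) {
        random_axis_rotation(s * rot_per_ang)
      } else {
        diag(3)
      }
      dir <- stats::rnorm(3)
      dir <- if (s > 0) dir / sqrt(sum(dir^2)) else c(0, 0, 0)
      sweep(centered %*% t(rot), 2, centroid + s * dir, "+")
    })
    ps <- pose_set(mol$title, mol, coords)
    attr(ps, "ranking") <- order(scales)
    ps
  })
}

#' Mock non-equilibrium switching backend
#'
#' Stand-in for the equilibrium + transition MD stages of one edge: writes
#' pmx-style work files (kJ/mol, two columns) for both legs and all
#' replicas. The water leg is generated with leg dG = 0 and the complex leg
#' with leg dG = `true_ddg`, so the edge ddG equals `true_ddg` by
#' construction; the estimator only ever sees work values, never leg
#' labels.
#'
#' @param edge edge id (used in file names; `->` is written as `_`).
#' @param true_ddg true edge ddG (kcal/mol).
#' @param dissipation_sigma work distribution SD (kcal/mol).
#' @param n_transitions transitions per direction (>= 2).
#' @param n_replicas replica count.
#' @param seed RNG seed.
#' @param dir output directory (created if needed).
#' @param temperature temperature (K).
#' @return data.frame manifest: `edge`, `leg`, `replica`, `direction`,
#'   `path`.
#' @export
mock_nes_backend <- function(edge, true_ddg, dissipation_sigma = 1,
                             n_transitions = 80, n_replicas = 3, seed,
                             dir = ".", temperature = DEFAULT_TEMPERATURE) {
  stopifnot(n_transitions >= 2, n_replicas >= 1)
  if (missing(seed)) stop("mock_nes_backend requires a seed", call. = FALSE)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  safe_edge <- gsub("->", "_", edge, fixed = TRUE)
  leg_dg <- c(water = 0, complex = true_ddg)
  manifest <- list()
  k <- 0
  for (leg in names(leg_dg)) {
    for (rep in seq_len(n_replicas)) {
      k <- k + 1
      ws <- gen_cft_gaussian_works(
        leg_dg[[leg]], dissipation_sigma, n_transitions, n_transitions,
        temperature, seed = seed + 1000 * match(leg, names(leg_dg)) + rep
      )
      path_f <- file.path(dir, sprintf("%s_%s_rep%d_forward.dat",
                                       safe_edge, leg, rep))
      path_r <- file.path(dir, sprintf("%s_%s_rep%d_reverse.dat",
                                       safe_edge, leg, rep))
      write_work_file(ws$w_f, path_f)
      write_work_file(ws$w_r, path_r)
      manifest[[k]] <- data.frame(
        edge = edge, leg = leg, replica = rep,
        forward = path_f, reverse = path_r, stringsAsFactors = FALSE
      )
    }
  }
  do.call(rbind, manifest)
}

#' Estimate one edge from mock or ingested work files
#'
#' Runs the full per-edge analysis: per replica and leg, read the work
#' files, BAR-estimate the leg dG with bootstrap SE, combine replicas, and
#' assemble the edge ddG with quadrature SEs.
#'
#' @param manifest data.frame as returned by [mock_nes_backend()] (columns
#'   `edge`, `leg`, `replica`, `forward`, `reverse`) for a single edge.
#' @param temperature temperature (K).
#' @param n_boot bootstrap resamples per leg/replica.
#' @param seed RNG seed for the bootstrap.
#' @return an `edge_result`.
#' @export
estimate_edge_from_files <- function(manifest,
                                     temperature = DEFAULT_TEMPERATURE,
                                     n_boot = 100, seed) {
  stopifnot(nrow(manifest) >= 2, length(unique(manifest$edge)) == 1)
  if (missing(seed)) stop("estimate_edge_from_files requires a seed", call. = FALSE)
  legs <- list()
  for (leg in c("complex", "water")) {
    rows <- manifest[manifest$leg == leg, , drop = FALSE]
    if (nrow(rows) == 0) stop(sprintf("missing %s leg", leg), call. = FALSE)
    ests <- vector("list", nrow(rows))
    for (i in seq_len(nrow(rows))) {
      ws <- work_set(read_work_file(rows$forward[i]),
                     read_work_file(rows$reverse[i]),
                     edge = rows$edge[i], leg = leg,
                     replica = rows$replica[i])
      est <- bar_estimate(ws, temperature)
      est$se_boot <- bootstrap_se(ws, temperature, n_boot,
                                  seed = seed + 17 * i +
                                    1000 * match(leg, c("complex", "water")))
      ests[[i]] <- est
    }
    legs[[leg]] <- combine_replicas(ests)
  }
  edge_ddg(legs$complex, legs$water, edge = manifest$edge[1],
           replicas = length(unique(manifest$replica)))
}
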