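# Maximum common substructure, mapped RMSD, and best-pose selection.
#
# The MCS between a ligand and the reference ligand defines the atom pairs
# over which pose deviation is measured. RMSD is computed WITHOUT
# superposition: docked and reference poses share the receptor frame, and
# aligning them first would hide exactly the binding-mode flips the filter
# is meant to catch. All symmetry-equivalent MCS mappings are evaluated and
# the minimum RMSD taken, so an aromatic ring numbering flip cannot inflate
# the deviation.

#' MCS search options
#'
#' Defaults enforce chemically sensible mappings: heavy atoms only,
#' element-exact matching, ring atoms match only ring atoms and ring bonds
#' only ring bonds, minimum common substructure of 3 heavy atoms, 10 s
#' search budget.
#'
#' @param min_atoms smallest acceptable MCS size (heavy atoms).
#' @param ring_matches_ring require ring/non-ring character to agree for
#'   atoms and bonds.
#' @param timeout search budget in seconds.
#' @param max_mappings cap on the number of symmetry-equivalent mappings
#'   retained for RMSD minimisation.
#' @return options list.
#' @export
mcs_options <- function(min_atoms = 3, ring_matches_ring = TRUE,
                        timeout = 10, max_mappings = 64) {
  list(min_atoms = min_atoms, ring_matches_ring = ring_matches_ring,
       timeout = timeout, max_mappings = max_mappings)
}

# Bond index lookup table keyed "a:b" with a < b.
bond_index_table <- function(mol) {
  if (nrow(mol$bonds) == 0) return(new.env(parent = emptyenv()))
  env <- new.env(parent = emptyenv(), size = nrow(mol$bonds))
  for (j in seq_len(nrow(mol$bonds))) {
    a <- mol$bonds$a[j]; b <- mol$bonds$b[j]
    assign(paste0(min(a, b), ":", max(a, b)), j, envir = env)
  }
  env
}

#' Maximum common substructure between two molecules
#'
#' Finds the largest connected common induced substructure over heavy atoms
#' by a McGregor-style branch-and-bound search: the mapping grows along
#' bonds from every compatible seed atom pair, with element-exact matching,
#' ring atoms matching only ring atoms and ring bonds only ring bonds, and
#' an upper-bound prune on the attainable mapping size. All mappings of
#' maximal size (up to `opts$max_mappings`) are retained so downstream RMSD
#' evaluation can minimise over symmetry-equivalent matches. Deterministic
#' for fixed inputs and options; ties are broken by lexicographically
#' smallest pair list.
#'
#' @param query,reference `nes_mol` objects.
#' @param opts [mcs_options()].
#' @return object of class `atom_mapping`: `pairs` is a k x 2 integer matrix
#'   (query atom index, reference atom index; 1-based), `equivalents` a list
#'   of alternative k x 2 matrices covering symmetry-equivalent mappings
#'   (including `pairs` itself).
#' @export
compute_mcs <- function(query, reference, opts = mcs_options()) {
  stopifnot(inherits(query, "nes_mol"), inherits(reference, "nes_mol"))
  hq <- heavy_atoms(query)
  hr <- heavy_atoms(reference)
  nq <- length(query$elements)
  nr <- length(reference$elements)

  atom_compat <- matrix(FALSE, nq, nr)
  for (i in hq) {
    for (j in hr) {
      atom_compat[i, j] <- query$elements[i] == reference$elements[j] &&
        query$aromatic_atom[i] == reference$aromatic_atom[j] &&
        (!opts$ring_matches_ring ||
           query$ring_atom[i] == reference$ring_atom[j])
    }
  }
  if (sum(atom_compat) < opts$min_atoms) {
    stop("insufficient common substructure", call. = FALSE)
  }

  # bond index matrices (0 = no bond) and adjacency lists
  bq_idx <- matrix(0L, nq, nq)
  adj_q <- vector("list", nq)
  if (nrow(query$bonds) > 0) {
    for (k in seq_len(nrow(query$bonds))) {
      a <- query$bonds$a[k]; b <- query$bonds$b[k]
      bq_idx[a, b] <- k; bq_idx[b, a] <- k
      adj_q[[a]] <- c(adj_q[[a]], b); adj_q[[b]] <- c(adj_q[[b]], a)
    }
  }
  br_idx <- matrix(0L, nr, nr)
  adj_r <- vector("list", nr)
  if (nrow(reference$bonds) > 0) {
    for (k in seq_len(nrow(reference$bonds))) {
      a <- reference$bonds$a[k]; b <- reference$bonds$b[k]
      br_idx[a, b] <- k; br_idx[b, a] <- k
      adj_r[[a]] <- c(adj_r[[a]], b); adj_r[[b]] <- c(adj_r[[b]], a)
    }
  }
  bond_compat <- function(bq, br) {
    if (opts$ring_matches_ring &&
        query$ring_bond[bq] != reference$ring_bond[br]) return(FALSE)
    (query$aromatic_bond[bq] && reference$aromatic_bond[br]) ||
      (!query$aromatic_bond[bq] && !reference$aromatic_bond[br] &&
         query$bonds$order[bq] == reference$bonds$order[br])
  }

  st <- new.env(parent = emptyenv())
  st$best_size <- opts$min_atoms - 1L
  st$best <- list()
  st$deadline <- Sys.time() + opts$timeout
  st$timed_out <- FALSE

  record <- function(qmap) {
    size <- sum(qmap > 0)
    if (size < st$best_size) return()
    pairs <- cbind(which(qmap > 0), qmap[qmap > 0])
    if (size > st$best_size) {
      st$best_size <- size
      st$best <- list(pairs)
    } else if (length(st$best) < opts$max_mappings) {
      st$best <- c(st$best, list(pairs))
    }
  }

  # qmap: per-query-atom reference index (0 = unmapped); rused: reference
  # atoms in use; excluded: query atoms barred from this subtree.
  extend <- function(qmap, rused, excluded) {
    if (st$timed_out || Sys.time() > st$deadline) {
      st$timed_out <- TRUE
      return()
    }
    size <- sum(qmap > 0)
    mapped_q <- which(qmap > 0)
    # frontier: unmapped, unexcluded query atoms adjacent to the mapping
    frontier <- integer(0)
    for (u in mapped_q) {
      for (i in adj_q[[u]]) {
        if (qmap[i] == 0 && !excluded[i] && query$elements[i] != "H") {
          frontier <- c(frontier, i)
        }
      }
    }
    frontier <- sort(unique(frontier))
    if (length(frontier) == 0) {
      record(qmap)
      return()
    }
    # optimistic bound: current size + all growable query atoms, capped by
    # the reference atoms still free
    avail_q <- sum(qmap == 0 & !excluded & query$elements != "H")
    bound <- size + min(avail_q, length(hr) - size)
    if (bound < st$best_size ||
        (bound == st$best_size && length(st$best) >= opts$max_mappings)) {
      return()
    }

    i <- frontier[1]
    # candidate reference atoms: adjacent to the mapped image, compatible,
    # and bond-consistent with every mapped pair (induced semantics)
    cand <- integer(0)
    for (u in mapped_q) {
      if (bq_idx[i, u] == 0) next
      for (j in adj_r[[qmap[u]]]) {
        if (rused[j] || !atom_compat[i, j]) next
        cand <- c(cand, j)
      }
    }
    for (j in sort(unique(cand))) {
      ok <- TRUE
      for (u in mapped_q) {
        bq <- bq_idx[i, u]
        br <- br_idx[j, qmap[u]]
        if (bq == 0 && br == 0) next
        if (bq == 0 || br == 0 || !bond_compat(bq, br)) {
          ok <- FALSE
          break
        }
      }
      if (ok) {
        qmap[i] <- j
        rused[j] <- TRUE
        extend(qmap, rused, excluded)
        qmap[i] <- 0L
        rused[j] <- FALSE
      }
    }
    # subtree where query atom i is never part of the mapping
    excluded[i] <- TRUE
    extend(qmap, rused, excluded)
  }

  seeds <- which(atom_compat, arr.ind = TRUE)
  seeds <- seeds[order(seeds[, 1], seeds[, 2]), , drop = FALSE]
  for (s in seq_len(nrow(seeds))) {
    if (st$timed_out) break
    i <- seeds[s, 1]; j <- seeds[s, 2]
    qmap <- integer(nq)
    qmap[i] <- j
    rused <- logical(nr)
    rused[j] <- TRUE
    # exclude lower-numbered query seeds: any mapping containing (i', j')
    # with i' < i is found from an earlier seed
    excluded <- logical(nq)
    if (i > 1) excluded[seq_len(i - 1)] <- TRUE
    extend(qmap, rused, excluded)
  }
  if (st$timed_out && st$best_size < opts$min_atoms) {
    stop("MCS search timed out", call. = FALSE)
  }
  if (st$best_size < opts$min_atoms) {
    stop("insufficient common substructure", call. = FALSE)
  }

  canon <- lapply(st$best, function(m) m[order(m[, 1]), , drop = FALSE])
  keys <- vapply(canon, function(m) paste(t(m), collapse = ","), character(1))
  canon <- canon[!duplicated(keys)]
  keys <- keys[!duplicated(keys)]
  canon <- canon[order(keys)]
  structure(
    list(pairs = canon[[1]], equivalents = canon, size = st$best_size),
    class = "atom_mapping"
  )
}

#' @export
print.atom_mapping <- function(x, ...) {
  cat(sprintf("<atom_mapping: %d atom pairs, %d symmetry-equivalent mapping(s)>\n",
              x$size, length(x$equivalents)))
  invisible(x)
}

#' RMSD over mapped atom pairs, without superposition
#'
#' Root-mean-square deviation between query and reference coordinates over
#' the mapped atom pairs, computed in the shared receptor frame (no
#' alignment). For a rigid translation by a vector of length d this equals d
#' exactly.
#'
#' @param query_coords,ref_coords n x 3 coordinate matrices (Angstrom).
#' @param mapping an `atom_mapping` or a k x 2 index matrix
#'   (query, reference).
#' @param use_equivalents when `mapping` is an `atom_mapping`, evaluate all
#'   symmetry-equivalent mappings and return the minimum RMSD.
#' @return RMSD in Angstrom.
#' @export
mapped_rmsd <- function(query_coords, ref_coords, mapping,
                        use_equivalents = TRUE) {
  maps <- mapping_list(mapping, use_equivalents)
  rmsds <- vapply(maps, function(m) {
    d <- as.matrix(query_coords)[m[, 1], , drop = FALSE] -
      as.matrix(ref_coords)[m[, 2], , drop = FALSE]
    sqrt(mean(rowSums(d^2)))
  }, numeric(1))
  min(rmsds)
}

mapping_list <- function(mapping, use_equivalents = TRUE) {
  if (inherits(mapping, "atom_mapping")) {
    maps <- if (use_equivalents) mapping$equivalents else list(mapping$pairs)
  } else {
    maps <- list(as.matrix(mapping))
  }
  for (m in maps) {
    if (nrow(m) == 0) stop("empty atom mapping", call. = FALSE)
    if (anyDuplicated(m[, 1]) || anyDuplicated(m[, 2])) {
      stop("atom mapping is not injective", call. = FALSE)
    }
  }
  maps
}

#' Select the docked pose closest to the reference
#'
#' Evaluates the MCS-mapped RMSD (no superposition, minimum over
#' symmetry-equivalent mappings) of every pose against the reference
#' coordinates and returns the minimiser; ties are broken by lowest pose
#' index so engine rank order is preserved.
#'
#' @param poses a [pose_set()].
#' @param ref_coords reference ligand coordinates (n x 3, Angstrom).
#' @param mapping `atom_mapping` from the pose molecule (query) to the
#'   reference molecule.
#' @return list with `index` (1-based pose index), `rmsd` (Angstrom) and
#'   `rmsds` (per-pose vector).
#' @export
select_best_pose <- function(poses, ref_coords, mapping) {
  stopifnot(inherits(poses, "pose_set"), length(poses$coords) >= 1)
  rmsds <- vapply(poses$coords, function(xyz) {
    mapped_rmsd(xyz, ref_coords, mapping)
  }, numeric(1))
  idx <- which.min(rmsds) # which.min returns the first minimum: lowest index
  list(index = idx, rmsd = rmsds[idx], rmsds = rmsds)
}

#' Filter pose sets against a reference ligand
#'
#' Convenience wrapper running [compute_mcs()] + [select_best_pose()] for
#' every ligand of a pose collection against one reference ligand, the
#' post-hoc filter applied to multi-pose docking output.
#'
#' @param pose_sets named list of [pose_set()].
#' @param reference a `nes_mol` with coordinates (the reference pose, same
#'   receptor frame).
#' @param opts [mcs_options()].
#' @return data.frame with columns `id`, `pose_index`, `mcs_rmsd`,
#'   `mcs_size`, plus a `selected` attribute: list of single-pose
#'   [pose_set()]s for the chosen poses.
#' @export
filter_poses_by_mcs <- function(pose_sets, reference, opts = mcs_options()) {
  stopifnot(inherits(reference, "nes_mol"), !is.null(reference$coords))
  rows <- list()
  selected <- list()
  for (id in names(pose_sets)) {
    ps <- pose_sets[[id]]
    mapping <- compute_mcs(ps$mol, reference, opts)
    sel <- select_best_pose(ps, reference$coords, mapping)
    rows[[id]] <- data.frame(
      id = id, pose_index = sel$index, mcs_rmsd = sel$rmsd,
      mcs_size = mapping$size, stringsAsFactors = FALSE
    )
    selected[[id]] <- pose_set(id, ps$mol, ps$coords[sel$index],
                               ps$scores[sel$index])
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "selected") <- selected
  out
}
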