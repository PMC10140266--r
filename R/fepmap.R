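# Perturbation-map construction and the unified map data structure.
#
# Ligands are nodes; alchemical transformations are edges scored by MCS
# similarity. The map is built as a minimum spanning tree on distance
# (1 - similarity), then augmented with the highest-similarity non-tree
# edges until every node reaches the target degree, so that every node lies
# on at least one cycle and cycle-closure analysis is possible. The edge
# direction (stored with endpoints in lexicographic order) is a bookkeeping
# convention, not physics.

edge_id <- function(a, b) paste0(a, "->", b)

#' Construct a perturbation map object
#'
#' @param nodes character vector of ligand ids.
#' @param edges data.frame with columns `source`, `target`, `similarity`.
#' @return object of class `perturbation_map` with fields `nodes` and
#'   `edges` (the edge table gains an `id` column "source->target").
#' @export
perturbation_map <- function(nodes, edges) {
  nodes <- as.character(nodes)
  stopifnot(length(nodes) >= 1, !anyDuplicated(nodes))
  edges <- as.data.frame(edges)
  stopifnot(all(c("source", "target", "similarity") %in% names(edges)))
  edges$source <- as.character(edges$source)
  edges$target <- as.character(edges$target)
  edges$similarity <- as.numeric(edges$similarity)
  edges$id <- edge_id(edges$source, edges$target)
  map <- structure(list(nodes = nodes, edges = edges),
                   class = "perturbation_map")
  validate_map(map)
  map
}

#' Validate perturbation-map invariants
#'
#' Checks: all edge endpoints are known nodes, no self-edges, no duplicate
#' unordered pairs, similarities in `[0, 1]`, graph connected over all
#' nodes, every node of a multi-node map has degree >= 1.
#'
#' @param map a [perturbation_map()].
#' @return `map`, invisibly; errors describe the violated invariant.
#' @export
validate_map <- function(map) {
  e <- map$edges
  unknown <- setdiff(c(e$source, e$target), map$nodes)
  if (length(unknown) > 0) {
    stop(sprintf("edge references unknown node(s): %s",
                 paste(unknown, collapse = ", ")), call. = FALSE)
  }
  if (any(e$source == e$target)) {
    stop("self-edges are not allowed", call. = FALSE)
  }
  key <- ifelse(e$source < e$target, paste(e$source, e$target),
                paste(e$target, e$source))
  if (anyDuplicated(key)) {
    stop("duplicate edges between the same node pair", call. = FALSE)
  }
  if (any(e$similarity < 0 | e$similarity > 1)) {
    stop("similarity scores must lie in [0, 1]", call. = FALSE)
  }
  if (length(map$nodes) > 1) {
    g <- map_graph(map)
    comp <- igraph::components(g)
    if (comp$no > 1) {
      sizes <- table(comp$membership)
      small <- names(comp$membership)[comp$membership != which.max(sizes)]
      stop(sprintf("map is disconnected; separated node(s): %s",
                   paste(small, collapse = ", ")), call. = FALSE)
    }
    deg <- igraph::degree(g)
    if (any(deg < 1)) {
      stop(sprintf("node(s) with no edges: %s",
                   paste(names(deg)[deg < 1], collapse = ", ")), call. = FALSE)
    }
  }
  invisible(map)
}

map_graph <- function(map) {
  igraph::graph_from_data_frame(
    map$edges[, c("source", "target")],
    directed = FALSE,
    vertices = data.frame(name = map$nodes)
  )
}

#' @export
print.perturbation_map <- function(x, ...) {
  cat(sprintf("<perturbation_map: %d nodes, %d edges>\n",
              length(x$nodes), nrow(x$edges)))
  invisible(x)
}

#' MCS similarity between two molecules
#'
#' Similarity score `|MCS| / max(heavy atoms of A, heavy atoms of B)` in
#' `[0, 1]`; pairs whose MCS fails the minimum-size threshold (or times
#' out) score 0.
#'
#' @param mol_a,mol_b `nes_mol` objects.
#' @param opts [mcs_options()].
#' @return similarity in `[0, 1]`.
#' @export
mcs_similarity <- function(mol_a, mol_b, opts = mcs_options()) {
  size <- tryCatch(compute_mcs(mol_a, mol_b, opts)$size,
                   error = function(e) 0)
  size / max(length(heavy_atoms(mol_a)), length(heavy_atoms(mol_b)))
}

# Shared MST + augmentation scheme over a similarity matrix. Kruskal on
# distance (1 - similarity) with ties broken by lexicographic edge id, then
# greedy augmentation by highest similarity among edges touching a node
# below the target degree.
build_map_from_similarity <- function(sim, ids, target_degree = 2) {
  n <- length(ids)
  stopifnot(nrow(sim) == n, ncol(sim) == n, n >= 2, target_degree >= 1)
  cand <- list()
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      a <- ids[i]; b <- ids[j]
      if (a > b) { tmp <- a; a <- b; b <- tmp }
      cand[[length(cand) + 1]] <- data.frame(
        source = a, target = b, similarity = sim[i, j],
        stringsAsFactors = FALSE
      )
    }
  }
  cand <- do.call(rbind, cand)
  cand <- cand[cand$similarity > 0, , drop = FALSE]
  cand <- cand[order(1 - cand$similarity, edge_id(cand$source, cand$target)), ,
               drop = FALSE]

  # Kruskal MST
  comp <- stats::setNames(seq_len(n), ids)
  in_tree <- logical(nrow(cand))
  for (k in seq_len(nrow(cand))) {
    ca <- comp[cand$source[k]]
    cb <- comp[cand$target[k]]
    if (ca != cb) {
      in_tree[k] <- TRUE
      comp[comp == cb] <- ca
    }
  }
  if (length(unique(comp)) > 1) {
    orphans <- names(comp)[comp != comp[which.max(tabulate(comp))]]
    stop(sprintf(
      "cannot build a connected map; ligand(s) with no scoring edge: %s",
      paste(sort(orphans), collapse = ", ")
    ), call. = FALSE)
  }
  edges <- cand[in_tree, , drop = FALSE]

  # augment: highest similarity first, only edges touching a deficient node
  deg <- stats::setNames(integer(n), ids)
  for (k in which(in_tree)) {
    deg[cand$source[k]] <- deg[cand$source[k]] + 1L
    deg[cand$target[k]] <- deg[cand$target[k]] + 1L
  }
  rest <- cand[!in_tree, , drop = FALSE]
  for (k in seq_len(nrow(rest))) {
    if (all(deg >= target_degree)) break
    a <- rest$source[k]; b <- rest$target[k]
    if (deg[a] < target_degree || deg[b] < target_degree) {
      edges <- rbind(edges, rest[k, ])
      deg[a] <- deg[a] + 1L
      deg[b] <- deg[b] + 1L
    }
  }
  rownames(edges) <- NULL
  perturbation_map(ids, edges)
}

#' Build a perturbation map from ligand records
#'
#' Scores all ligand pairs by [mcs_similarity()], builds the minimum
#' spanning tree on distance (1 - similarity), and greedily adds the
#' highest-similarity non-tree edges until every node reaches
#' `target_degree` (default 2, so every ligand lies on a cycle) or no
#' candidates remain. Deterministic given input order; ties are broken by
#' lexicographic edge id.
#'
#' @param ligands list of [ligand_record()] (>= 2).
#' @param target_degree minimum desired node degree.
#' @param opts [mcs_options()] passed to the similarity scoring.
#' @return a [perturbation_map()].
#' @export
build_map <- function(ligands, target_degree = 2, opts = mcs_options()) {
  stopifnot(length(ligands) >= 2)
  ids <- vapply(ligands, function(r) r$id, character(1))
  mols <- lapply(ligands, function(r) r$mol)
  n <- length(ids)
  sim <- matrix(0, n, n)
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      sim[i, j] <- sim[j, i] <- mcs_similarity(mols[[i]], mols[[j]], opts)
    }
  }
  build_map_from_similarity(sim, ids, target_degree)
}

#' Read a perturbation map from CSV
#'
#' CSV columns `source,target,similarity`; the node set is the union of the
#' endpoints unless given explicitly. All map invariants are validated.
#'
#' @param path CSV file.
#' @param nodes optional explicit node set (to detect isolated nodes).
#' @return a [perturbation_map()].
#' @export
read_map <- function(path, nodes = NULL) {
  stopifnot(file.exists(path))
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("source", "target", "similarity")
  if (!all(need %in% names(df))) {
    stop(sprintf("'%s': map CSV needs columns %s", path,
                 paste(need, collapse = ",")), call. = FALSE)
  }
  nodes <- nodes %||% sort(unique(c(df$source, df$target)))
  perturbation_map(nodes, df)
}

#' Write a perturbation map to CSV
#'
#' @param map a [perturbation_map()].
#' @param path output CSV.
#' @return `path`, invisibly.
#' @export
write_map <- function(map, path) {
  utils::write.csv(map$edges[, c("source", "target", "similarity")],
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
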