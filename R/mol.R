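# Internal molecule representation
#
# A `nes_mol` is a light, graph-oriented view of one ligand: element symbols,
# per-atom formal charges, optional 3D coordinates (Angstrom), a bond table,
# and perceived ring/aromaticity flags. Structure parsing is delegated to
# ChemmineR/ChemmineOB (OpenBabel); ring perception and a simplified Hueckel
# aromaticity model are computed here on the molecular graph because the SDF
# V2000 bond block is kekulized.

new_nes_mol <- function(elements, charges, coords, bonds, title = "") {
  n <- length(elements)
  stopifnot(length(charges) == n)
  if (!is.null(coords)) {
    coords <- as.matrix(coords)
    stopifnot(nrow(coords) == n, ncol(coords) == 3)
    dimnames(coords) <- NULL
  }
  bonds <- as.data.frame(bonds)
  names(bonds) <- c("a", "b", "order")[seq_len(ncol(bonds))]
  rownames(bonds) <- NULL
  mol <- structure(
    list(
      elements = as.character(elements),
      charges = as.integer(charges),
      coords = coords,
      bonds = bonds,
      title = as.character(title)
    ),
    class = "nes_mol"
  )
  perceive_rings(mol)
}

#' @export
print.nes_mol <- function(x, ...) {
  cat(sprintf(
    "<nes_mol '%s': %d atoms (%d heavy), %d bonds, net charge %+d>\n",
    x$title, length(x$elements), length(heavy_atoms(x)), nrow(x$bonds),
    mol_net_charge(x)
  ))
  invisible(x)
}

# Indices of non-hydrogen atoms.
heavy_atoms <- function(mol) which(mol$elements != "H")

#' Net formal charge of a molecule
#'
#' Sum of atomic formal charges of the parsed structure. No protonation-state
#' enumeration is performed: the charge is a property of the input structure
#' as written.
#'
#' @param mol a molecule as returned by [parse_smiles()] or [read_sdf_mols()].
#' @return integer net charge in elementary charge units.
#' @export
mol_net_charge <- function(mol) {
  stopifnot(inherits(mol, "nes_mol"))
  sum(mol$charges)
}

mol_graph <- function(mol) {
  igraph::graph_from_data_frame(
    d = mol$bonds[, c("a", "b")],
    directed = FALSE,
    vertices = data.frame(name = seq_along(mol$elements))
  )
}

# Ring perception: a bond is a ring bond iff it is not a bridge of the
# molecular graph; for each ring bond the smallest ring through it is found
# by BFS in the graph with that bond removed. Aromaticity uses a simplified
# Hueckel count on the kekulized structure: within a candidate ring, a C with
# an in-ring double bond contributes 1 pi electron, a heteroatom (N, O, S, P)
# without one contributes its lone pair (2), and a carbon without any double
# bond (or with only an exocyclic one) blocks aromaticity; the ring is
# aromatic when the total is 4n + 2. This covers the common heteroaromatics
# (benzene, pyridine, pyrrole, furan, thiophene, imidazole, ...) without a
# full valence model.
perceive_rings <- function(mol) {
  n <- length(mol$elements)
  nb <- nrow(mol$bonds)
  mol$ring_bond <- logical(nb)
  mol$ring_atom <- logical(n)
  mol$aromatic_atom <- logical(n)
  mol$aromatic_bond <- logical(nb)
  mol$rings <- list()
  if (nb == 0) return(mol)

  g <- mol_graph(mol)
  br <- igraph::bridges(g)
  is_bridge <- rep(FALSE, nb)
  is_bridge[as.integer(br)] <- TRUE
  mol$ring_bond <- !is_bridge
  mol$ring_atom[unique(unlist(mol$bonds[mol$ring_bond, c("a", "b")]))] <- TRUE

  rings <- list()
  for (ei in which(mol$ring_bond)) {
    g2 <- igraph::delete_edges(g, ei)
    sp <- igraph::shortest_paths(
      g2,
      from = mol$bonds$a[ei], to = mol$bonds$b[ei]
    )$vpath[[1]]
    if (length(sp) >= 3) {
      ring <- sort(as.integer(sp))
      key <- paste(ring, collapse = ",")
      if (is.null(rings[[key]])) {
        rings[[key]] <- as.integer(sp) # ordered along the cycle
      }
    }
  }
  mol$rings <- unname(rings)

  bond_order_lookup <- function(i, j) {
    hit <- which((mol$bonds$a == i & mol$bonds$b == j) |
                   (mol$bonds$a == j & mol$bonds$b == i))
    if (length(hit) == 0) return(NA_integer_)
    hit[1]
  }

  for (ring in mol$rings) {
    k <- length(ring)
    if (k < 5 || k > 7) next
    elems <- mol$elements[ring]
    if (!all(elems %in% c("C", "N", "O", "S", "P"))) next
    pi_e <- 0
    ok <- TRUE
    for (a in ring) {
      incident <- which(mol$bonds$a == a | mol$bonds$b == a)
      dbl <- incident[mol$bonds$order[incident] >= 2]
      partners <- ifelse(mol$bonds$a[dbl] == a, mol$bonds$b[dbl],
                         mol$bonds$a[dbl])
      in_ring_dbl <- any(partners %in% ring)
      if (in_ring_dbl) {
        pi_e <- pi_e + 1
      } else if (mol$elements[a] %in% c("N", "O", "S", "P")) {
        pi_e <- pi_e + 2
      } else if (length(dbl) > 0) {
        pi_e <- pi_e + 0 # exocyclic double bond: no ring pi contribution
      } else {
        ok <- FALSE # saturated carbon breaks conjugation
        break
      }
    }
    if (ok && pi_e >= 6 && (pi_e - 2) %% 4 == 0) {
      mol$aromatic_atom[ring] <- TRUE
      for (idx in seq_len(k)) {
        bi <- bond_order_lookup(ring[idx], ring[idx %% k + 1])
        if (!is.na(bi)) mol$aromatic_bond[bi] <- TRUE
      }
    }
  }
  mol
}

# ---- parsing -------------------------------------------------------------

# Scan raw SDF record lines for "M  CHG" entries (atom index, charge pairs).
parse_chg_lines <- function(lines, n_atoms) {
  charges <- integer(n_atoms)
  for (ln in grep("^M  CHG", lines, value = TRUE)) {
    toks <- as.integer(strsplit(trimws(sub("^M  CHG", "", ln)), "\\s+")[[1]])
    k <- toks[1]
    for (i in seq_len(k)) {
      idx <- toks[2 * i]
      charges[idx] <- toks[2 * i + 1]
    }
  }
  charges
}

# Fixed-column V2000 parse of one record's raw lines; used when ChemmineR
# rejects a record (it flags 1-atom/0-bond molecules as invalid).
parse_v2000_block <- function(lines) {
  na <- as.integer(substr(lines[4], 1, 3))
  nb <- as.integer(substr(lines[4], 4, 6))
  if (is.na(na) || na < 1) stop("bad V2000 counts line", call. = FALSE)
  atom_lines <- lines[5:(4 + na)]
  coords <- cbind(
    as.numeric(substr(atom_lines, 1, 10)),
    as.numeric(substr(atom_lines, 11, 20)),
    as.numeric(substr(atom_lines, 21, 30))
  )
  elements <- trimws(substr(atom_lines, 32, 34))
  bonds <- if (nb > 0) {
    bl <- lines[(5 + na):(4 + na + nb)]
    data.frame(
      a = as.integer(substr(bl, 1, 3)),
      b = as.integer(substr(bl, 4, 6)),
      order = as.integer(substr(bl, 7, 9))
    )
  } else {
    data.frame(a = integer(), b = integer(), order = integer())
  }
  list(elements = elements, coords = coords, bonds = bonds)
}

sdfset_record_to_mol <- function(sdf, raw_lines, title) {
  ab <- tryCatch(ChemmineR::atomblock(sdf), error = function(e) NULL)
  bb <- tryCatch(ChemmineR::bondblock(sdf), error = function(e) NULL)
  if (is.null(ab) || ncol(ab) < 3 ||
      !all(grepl("_\\d+$", rownames(ab)))) {
    blk <- parse_v2000_block(raw_lines)
    elements <- blk$elements
    coords <- blk$coords
    bonds <- blk$bonds
  } else {
    elements <- sub("_\\d+$", "", rownames(ab))
    coords <- ab[, 1:3, drop = FALSE]
    bonds <- if (is.null(bb) || nrow(bb) == 0) {
      data.frame(a = integer(), b = integer(), order = integer())
    } else {
      data.frame(
        a = as.integer(bb[, 1]),
        b = as.integer(bb[, 2]),
        order = as.integer(bb[, 3])
      )
    }
  }
  charges <- parse_chg_lines(raw_lines, length(elements))
  new_nes_mol(elements, charges, coords, bonds, title = title)
}

#' Parse a SMILES string into a molecule
#'
#' Delegates SMILES interpretation (valence, formal charges, kekulization) to
#' OpenBabel via ChemmineOB; hydrogens stay implicit, so all atoms are heavy
#' atoms. Ring membership and aromaticity are then perceived on the molecular
#' graph.
#'
#' @param smiles a single SMILES string.
#' @param id molecule title to attach.
#' @return a `nes_mol` object.
#' @export
parse_smiles <- function(smiles, id = "") {
  stopifnot(is.character(smiles), length(smiles) == 1)
  sdf_text <- tryCatch(
    suppressWarnings(ChemmineOB::convertFormat(
      "SMI", "SDF", source = paste0(smiles, "\n")
    )),
    error = function(e) NULL
  )
  if (is.null(sdf_text) || !nzchar(sdf_text)) {
    stop(sprintf("cannot parse SMILES for '%s': \"%s\"", id, smiles),
         call. = FALSE)
  }
  lines <- strsplit(sdf_text, "\n", fixed = TRUE)[[1]]
  counts <- suppressWarnings(as.integer(substr(lines[4], 1, 3)))
  if (is.na(counts) || counts == 0) {
    stop(sprintf("cannot parse SMILES for '%s': \"%s\"", id, smiles),
         call. = FALSE)
  }
  tf <- tempfile(fileext = ".sdf")
  on.exit(unlink(tf))
  writeLines(lines, tf)
  sdfset <- suppressWarnings(ChemmineR::read.SDFset(tf))
  mol <- sdfset_record_to_mol(sdfset[[1]], lines, title = id)
  mol$smiles <- smiles
  mol
}

# Split the raw lines of an SDF file into per-record chunks.
split_sdf_records <- function(lines) {
  ends <- grep("^\\$\\$\\$\\$", lines)
  if (length(ends) == 0 && length(lines) > 0) ends <- length(lines)
  starts <- c(1, head(ends, -1) + 1)
  mapply(function(s, e) lines[s:e], starts, ends, SIMPLIFY = FALSE)
}

#' Read all molecules from an SDF (V2000) file
#'
#' Structure parsing goes through ChemmineR; formal charges are recovered from
#' the records' `M  CHG` lines, and the molecule id is taken from the title
#' line (falling back to an `_Name` data field when the title is empty,
#' matching common docking-engine output).
#'
#' @param path SDF file path.
#' @return list of `nes_mol`; names are record titles (possibly duplicated for
#'   multi-pose files). Each molecule carries its SDF data fields in
#'   `$props` as a named character vector.
#' @export
read_sdf_mols <- function(path) {
  stopifnot(file.exists(path))
  lines <- readLines(path, warn = FALSE)
  if (length(trimws(lines)) == 0 || all(!nzchar(trimws(lines)))) {
    return(list())
  }
  records <- split_sdf_records(lines)
  records <- Filter(function(r) any(nzchar(trimws(r))), records)
  if (length(records) == 0) return(list())
  sdfset <- suppressWarnings(ChemmineR::read.SDFset(path))
  if (length(sdfset) != length(records)) {
    stop(sprintf("SDF parse mismatch in '%s': %d records vs %d parsed",
                 path, length(records), length(sdfset)), call. = FALSE)
  }
  out <- vector("list", length(records))
  for (i in seq_along(records)) {
    raw <- records[[i]]
    title <- trimws(raw[1])
    props <- sdf_record_props(raw)
    if (!nzchar(title) && !is.na(props["_Name"])) title <- props[["_Name"]]
    if (!nzchar(title)) {
      stop(sprintf("SDF record %d in '%s' has no id (empty title, no _Name)",
                   i, path), call. = FALSE)
    }
    mol <- sdfset_record_to_mol(sdfset[[i]], raw, title = title)
    mol$props <- props
    out[[i]] <- mol
  }
  names(out) <- vapply(out, function(m) m$title, character(1))
  out
}

# Extract "> <tag>" data fields from raw SDF record lines as strings.
sdf_record_props <- function(lines) {
  tag_idx <- grep("^>\\s*<.*>", lines)
  props <- character(0)
  for (ti in tag_idx) {
    tag <- sub("^>\\s*<([^>]*)>.*$", "\\1", lines[ti])
    val <- if (ti + 1 <= length(lines)) trimws(lines[ti + 1]) else ""
    props[tag] <- val
  }
  props
}

# ---- writing -------------------------------------------------------------

# Minimal V2000 emitter: coordinates at 4 decimals (SDF convention), bond
# block and M CHG lines from the molecule, optional data fields.
format_v2000 <- function(mol, coords = NULL, title = NULL, props = NULL) {
  coords <- coords %||% mol$coords
  stopifnot(!is.null(coords), nrow(coords) == length(mol$elements))
  n <- length(mol$elements)
  nb <- nrow(mol$bonds)
  out <- c(
    title %||% mol$title,
    "  nesfe",
    "",
    sprintf("%3d%3d  0  0  0  0  0  0  0  0999 V2000", n, nb)
  )
  for (i in seq_len(n)) {
    out <- c(out, sprintf("%10.4f%10.4f%10.4f %-3s 0  0  0  0  0  0  0  0  0  0  0  0",
                          coords[i, 1], coords[i, 2], coords[i, 3],
                          mol$elements[i]))
  }
  for (j in seq_len(nb)) {
    out <- c(out, sprintf("%3d%3d%3d  0  0  0  0",
                          mol$bonds$a[j], mol$bonds$b[j], mol$bonds$order[j]))
  }
  chg <- which(mol$charges != 0)
  if (length(chg) > 0) {
    for (grp in split(chg, ceiling(seq_along(chg) / 8))) {
      out <- c(out, paste0(
        sprintf("M  CHG%3d", length(grp)),
        paste0(sprintf("%4d%4d", grp, mol$charges[grp]), collapse = "")
      ))
    }
  }
  out <- c(out, "M  END")
  if (!is.null(props)) {
    for (tag in names(props)) {
      out <- c(out, sprintf(">  <%s>", tag), as.character(props[[tag]]), "")
    }
  }
  c(out, "$$$$")
}
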