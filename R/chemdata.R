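# Ligand ingestion, identity, and formal-charge consistency filtering.
#
# Alchemical perturbations between ligands of different net charge are not
# supported downstream (charge-change edges need special treatment the
# workflow does not implement), so ingestion computes each ligand's net
# formal charge from the parsed structure and the series is filtered to the
# modal charge before map construction.

#' Create a ligand record
#'
#' @param id unique ligand identifier.
#' @param smiles SMILES string (must parse).
#' @param conformer optional n x 3 coordinate matrix (Angstrom) with one row
#'   per atom of the parsed (heavy-atom) structure.
#' @param props named character vector of free-form properties.
#' @return object of class `ligand_record` with fields `id`, `smiles`,
#'   `net_charge`, `mol`, `conformer`, `props`.
#' @export
ligand_record <- function(id, smiles, conformer = NULL, props = character(0)) {
  stopifnot(is.character(id), length(id) == 1, nzchar(id))
  mol <- parse_smiles(smiles, id = id)
  if (!is.null(conformer)) {
    conformer <- as.matrix(conformer)
    if (nrow(conformer) != length(mol$elements)) {
      stop(sprintf(
        "ligand '%s': conformer has %d rows but molecule has %d atoms",
        id, nrow(conformer), length(mol$elements)
      ), call. = FALSE)
    }
  }
  structure(
    list(
      id = id, smiles = smiles, net_charge = mol_net_charge(mol),
      mol = mol, conformer = conformer, props = props
    ),
    class = "ligand_record"
  )
}

#' @export
print.ligand_record <- function(x, ...) {
  cat(sprintf("<ligand '%s' %s net_charge=%+d%s>\n", x$id, x$smiles,
              x$net_charge,
              if (is.null(x$conformer)) "" else " +conformer"))
  invisible(x)
}

#' Read ligands from a SMILES (.smi) or CSV file
#'
#' `.smi` files hold one `id SMILES` (or `SMILES id`) pair per
#' whitespace-separated line; the token that parses as SMILES is taken as the
#' structure, so both common column orders are accepted. CSV files need
#' header columns `id` and `smiles`. Records are returned in file order with
#' `net_charge` computed from the parsed structure.
#'
#' @param path input file (.smi or .csv; anything non-.csv is treated as
#'   SMILES lines).
#' @return list of [ligand_record()] objects, named by id.
#' @export
read_ligands <- function(path) {
  stopifnot(file.exists(path))
  ext <- tolower(tools::file_ext(path))
  if (ext == "csv") {
    df <- utils::read.csv(path, stringsAsFactors = FALSE)
    lc <- tolower(names(df))
    if (!all(c("id", "smiles") %in% lc)) {
      stop(sprintf("'%s': CSV must have header columns id,smiles", path),
           call. = FALSE)
    }
    ids <- as.character(df[[which(lc == "id")[1]]])
    smis <- as.character(df[[which(lc == "smiles")[1]]])
  } else {
    lines <- readLines(path, warn = FALSE)
    lines <- trimws(lines)
    lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
    toks <- strsplit(lines, "\\s+")
    bad <- which(vapply(toks, length, 0L) < 2)
    if (length(bad) > 0) {
      stop(sprintf("'%s' row %d: expected 'id SMILES'", path, bad[1]),
           call. = FALSE)
    }
    # accept both "id SMILES" and the classic "SMILES id" order: SMILES
    # strings contain structure characters ([, ], (, ), =, #) ids normally
    # lack ("]" first inside the class keeps it literal)
    first <- vapply(toks, `[`, "", 1)
    second <- vapply(toks, `[`, "", 2)
    structure_chars <- "[][()=#]"
    smiles_first <- mean(grepl(structure_chars, first)) >
      mean(grepl(structure_chars, second))
    if (smiles_first) {
      ids <- second
      smis <- first
    } else {
      ids <- first
      smis <- second
    }
  }
  if (length(ids) == 0) stop(sprintf("'%s': no ligand rows", path), call. = FALSE)
  dup <- ids[duplicated(ids)]
  if (length(dup) > 0) {
    stop(sprintf("'%s': duplicate ligand id(s): %s", path,
                 paste(unique(dup), collapse = ", ")), call. = FALSE)
  }
  recs <- vector("list", length(ids))
  for (i in seq_along(ids)) {
    recs[[i]] <- tryCatch(
      ligand_record(ids[i], smis[i]),
      error = function(e) {
        stop(sprintf("row %d (ligand '%s'): %s", i, ids[i],
                     conditionMessage(e)), call. = FALSE)
      }
    )
  }
  names(recs) <- ids
  recs
}

#' Filter a ligand series to a single net charge
#'
#' Keeps the ligands carrying the modal net charge of the series and drops
#' the rest, so that all downstream perturbations conserve charge. A tie for
#' the modal charge is an error (silently mixing charges would invalidate
#' every edge crossing the tie), listing the tied charges for the caller to
#' resolve.
#'
#' @param records list of [ligand_record()].
#' @return list with elements `kept` and `dropped` (both lists of records);
#'   `kept` and `dropped` partition the input.
#' @export
filter_to_single_net_charge <- function(records) {
  stopifnot(is.list(records), length(records) > 0)
  charges <- vapply(records, function(r) r$net_charge, integer(1))
  tab <- table(charges)
  top <- max(tab)
  modal <- names(tab)[tab == top]
  if (length(modal) > 1) {
    stop(sprintf("tie for modal net charge among {%s}: choose explicitly",
                 paste(modal, collapse = ", ")), call. = FALSE)
  }
  keep <- charges == as.integer(modal)
  list(kept = records[keep], dropped = records[!keep])
}

# ---- poses ---------------------------------------------------------------

#' Pose set for one ligand
#'
#' Ordered list of candidate binding poses (coordinate blocks in a shared
#' receptor frame) for one ligand, as produced by a multi-pose docking
#' engine, plus any per-pose engine score kept as an opaque string.
#'
#' @param id ligand id.
#' @param mol `nes_mol` topology shared by all poses.
#' @param coords list of n x 3 coordinate matrices (Angstrom).
#' @param scores optional character vector of per-pose engine scores.
#' @return object of class `pose_set`.
#' @export
pose_set <- function(id, mol, coords, scores = NULL) {
  stopifnot(length(coords) >= 1)
  n <- length(mol$elements)
  for (k in seq_along(coords)) {
    coords[[k]] <- as.matrix(coords[[k]])
    if (nrow(coords[[k]]) != n) {
      stop(sprintf("pose %d of '%s': %d atoms, expected %d",
                   k, id, nrow(coords[[k]]), n), call. = FALSE)
    }
  }
  if (!is.null(scores)) stopifnot(length(scores) == length(coords))
  structure(list(id = id, mol = mol, coords = coords,
                 scores = as.character(scores %||% rep(NA, length(coords)))),
            class = "pose_set")
}

#' @export
print.pose_set <- function(x, ...) {
  cat(sprintf("<pose_set '%s': %d poses x %d atoms>\n",
              x$id, length(x$coords), length(x$mol$elements)))
  invisible(x)
}

#' Read docked poses from a multi-record SDF file
#'
#' Records are grouped by ligand id (SDF title line, falling back to the
#' `_Name` data field); consecutive records with the same id become one
#' ligand's ordered pose list. Any engine score data field (`score`,
#' `minimizedAffinity`, `docking_score`, or the first data field present) is
#' preserved as a string.
#'
#' @param path SDF file.
#' @return named list of [pose_set()] objects (empty list for an empty file).
#' @export
read_poses <- function(path) {
  mols <- read_sdf_mols(path)
  if (length(mols) == 0) return(list())
  ids <- vapply(mols, function(m) m$title, character(1))
  out <- list()
  score_tags <- c("score", "minimizedAffinity", "docking_score", "Score")
  for (id in unique(ids)) {
    grp <- mols[ids == id]
    coords <- lapply(grp, function(m) m$coords)
    scores <- vapply(grp, function(m) {
      p <- m$props %||% character(0)
      hit <- intersect(score_tags, names(p))
      if (length(hit) > 0) p[[hit[1]]] else if (length(p) > 0) p[[1]] else NA_character_
    }, character(1))
    out[[id]] <- pose_set(id, grp[[1]], coords, scores)
  }
  out
}

#' Write pose sets to an SDF file
#'
#' One V2000 record per pose, coordinates at 4 decimals, title = ligand id;
#' extra data fields can be attached per pose via `props`.
#'
#' @param pose_sets named list of [pose_set()] (or a single one).
#' @param path output file.
#' @param props optional list (parallel to poses within each set) of named
#'   property lists to write as data fields.
#' @return `path`, invisibly.
#' @export
write_poses <- function(pose_sets, path, props = NULL) {
  if (inherits(pose_sets, "pose_set")) pose_sets <- list(pose_sets)
  lines <- character(0)
  for (ps in pose_sets) {
    for (k in seq_along(ps$coords)) {
      pp <- if (!is.null(props)) props[[k]] else NULL
      if (!is.null(ps$scores) && !is.na(ps$scores[k])) {
        pp <- c(pp, list(score = ps$scores[k]))
      }
      lines <- c(lines, format_v2000(ps$mol, coords = ps$coords[[k]],
                                     title = ps$id, props = pp))
    }
  }
  writeLines(lines, path)
  invisible(path)
}

# ---- experimental affinities --------------------------------------------

#' Read an experimental affinity table
#'
#' CSV with header `id,dg_exp_kcal,sigma_exp_kcal`. Ids must be unique,
#' uncertainties non-negative; missing uncertainties may be encoded as NA and
#' are replaced by `default_sigma`.
#'
#' @param path CSV file.
#' @param default_sigma value substituted for missing uncertainties
#'   (default 0.43 kcal/mol, the best-practices lower bound for experimental
#'   binding free energy uncertainty).
#' @return data.frame with columns `id`, `dg_exp`, `sigma_exp` (kcal/mol).
#' @export
read_affinities <- function(path, default_sigma = 0.43) {
  stopifnot(file.exists(path))
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("id", "dg_exp_kcal", "sigma_exp_kcal")
  if (!all(need %in% names(df))) {
    stop(sprintf("'%s': affinity CSV must have columns %s", path,
                 paste(need, collapse = ",")), call. = FALSE)
  }
  if (nrow(df) == 0) stop(sprintf("'%s': empty affinity table", path),
                          call. = FALSE)
  if (anyDuplicated(df$id)) {
    stop(sprintf("'%s': duplicate ids in affinity table", path), call. = FALSE)
  }
  sigma <- as.numeric(df$sigma_exp_kcal)
  sigma[is.na(sigma)] <- default_sigma
  if (any(sigma < 0)) stop("sigma_exp must be >= 0", call. = FALSE)
  data.frame(id = as.character(df$id), dg_exp = as.numeric(df$dg_exp_kcal),
             sigma_exp = sigma, stringsAsFactors = FALSE)
}

#' Write an experimental affinity table
#'
#' @param affinities data.frame as returned by [read_affinities()].
#' @param path output CSV.
#' @return `path`, invisibly.
#' @export
write_affinities <- function(affinities, path) {
  out <- data.frame(id = affinities$id, dg_exp_kcal = affinities$dg_exp,
                    sigma_exp_kcal = affinities$sigma_exp)
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
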