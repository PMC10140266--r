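# Restricted SMARTS engine for core matching.
#
# Supports the subset needed for manually specified core patterns:
# organic-subset atoms (B C N O S P F Cl Br I), aromatic lowercase
# (c n o s p), wildcards * / A / a, bracket atoms with element, #n, charge,
# ring membership R / R0, implicit-H count Hn, degree Dn, negation !, and
# the AND combinators & and ;. Bonds: - = # : ~ and the default
# single-or-aromatic. Branches and ring closures (digits, %nn) are
# supported. OR (","), recursive SMARTS ("$(...)"), and other primitives are
# rejected with an error rather than silently mis-matched. Matching is done
# by subgraph isomorphism (igraph LAD) with per-atom candidate domains,
# followed by bond-predicate filtering.

ORGANIC_2CHAR <- c("Cl", "Br")
ORGANIC_1CHAR <- c("B", "C", "N", "O", "S", "P", "F", "I")
AROMATIC_ELEMS <- c(c = "C", n = "N", o = "O", s = "S", p = "P")
ELEMENT_NUMBERS <- c(H = 1, B = 5, C = 6, N = 7, O = 8, F = 9, P = 15,
                     S = 16, Cl = 17, Br = 35, I = 53)

smarts_error <- function(pattern, msg) {
  stop(sprintf("invalid SMARTS \"%s\": %s", pattern, msg), call. = FALSE)
}

# One primitive test, possibly negated. `kind` in: element, anum, aromatic,
# aliphatic, any, ring, charge, hcount, degree.
smarts_prim <- function(kind, value = NULL, neg = FALSE) {
  list(kind = kind, value = value, neg = neg)
}

# Parse the inside of a bracket atom into a list of primitives (implicit AND).
parse_bracket <- function(body, pattern) {
  prims <- list()
  i <- 1
  n <- nchar(body)
  neg <- FALSE
  while (i <= n) {
    ch <- substr(body, i, i)
    if (ch %in% c("&", ";")) { i <- i + 1; next }
    if (ch == ",") smarts_error(pattern, "OR (',') is not supported")
    if (ch == "$") smarts_error(pattern, "recursive SMARTS is not supported")
    if (ch == "!") { neg <- TRUE; i <- i + 1; next }
    consumed <- NULL
    rest <- substr(body, i, n)
    if (ch == "#") {
      m <- regmatches(rest, regexpr("^#[0-9]+", rest))
      if (length(m) == 0) smarts_error(pattern, "expected number after '#'")
      prims <- c(prims, list(smarts_prim("anum", as.integer(substr(m, 2, nchar(m))), neg)))
      consumed <- nchar(m)
    } else if (ch == "*") {
      prims <- c(prims, list(smarts_prim("any", neg = neg)))
      consumed <- 1
    } else if (ch == "A") {
      prims <- c(prims, list(smarts_prim("aliphatic", neg = neg)))
      consumed <- 1
    } else if (ch == "a") {
      prims <- c(prims, list(smarts_prim("aromatic", neg = neg)))
      consumed <- 1
    } else if (ch == "R") {
      m <- regmatches(rest, regexpr("^R[0-9]?", rest))
      val <- if (nchar(m) == 2 && substr(m, 2, 2) == "0") FALSE else TRUE
      prims <- c(prims, list(smarts_prim("ring", val, neg)))
      consumed <- nchar(m)
    } else if (ch == "H") {
      m <- regmatches(rest, regexpr("^H[0-9]?", rest))
      val <- if (nchar(m) == 1) 1L else as.integer(substr(m, 2, 2))
      prims <- c(prims, list(smarts_prim("hcount", val, neg)))
      consumed <- nchar(m)
    } else if (ch == "D") {
      m <- regmatches(rest, regexpr("^D[0-9]?", rest))
      val <- if (nchar(m) == 1) 1L else as.integer(substr(m, 2, 2))
      prims <- c(prims, list(smarts_prim("degree", val, neg)))
      consumed <- nchar(m)
    } else if (ch %in% c("+", "-")) {
      m <- regmatches(rest, regexpr("^\\++$|^-+$|^[+-][0-9]*", rest))
      sgn <- if (substr(m, 1, 1) == "+") 1L else -1L
      digits <- gsub("[+-]", "", m)
      val <- if (nzchar(digits)) sgn * as.integer(digits) else
        sgn * nchar(gsub("[^+-]", "", m))
      prims <- c(prims, list(smarts_prim("charge", val, neg)))
      consumed <- nchar(m)
    } else {
      two <- substr(body, i, min(i + 1, n))
      if (two %in% ORGANIC_2CHAR || two %in% names(ELEMENT_NUMBERS)) {
        prims <- c(prims, list(smarts_prim("element",
                                           list(elem = two, arom = FALSE), neg)))
        consumed <- 2
      } else if (ch %in% names(AROMATIC_ELEMS)) {
        prims <- c(prims, list(smarts_prim("element",
                                           list(elem = AROMATIC_ELEMS[[ch]], arom = TRUE), neg)))
        consumed <- 1
      } else if (ch %in% c(ORGANIC_1CHAR, "H")) {
        prims <- c(prims, list(smarts_prim("element",
                                           list(elem = ch, arom = FALSE), neg)))
        consumed <- 1
      } else {
        smarts_error(pattern, sprintf("unsupported primitive at '%s'",
                                      substr(body, i, n)))
      }
    }
    neg <- FALSE
    i <- i + consumed
  }
  if (length(prims) == 0) smarts_error(pattern, "empty bracket atom")
  prims
}

# Implicit hydrogen count from default valence, kekulized bond orders and
# formal charge; used only by the Hn primitive.
implicit_h_counts <- function(mol) {
  defval <- c(C = 4, N = 3, O = 2, S = 2, P = 3, F = 1, Cl = 1, Br = 1,
              I = 1, B = 3)
  n <- length(mol$elements)
  deg_order <- numeric(n)
  if (nrow(mol$bonds) > 0) {
    for (j in seq_len(nrow(mol$bonds))) {
      o <- mol$bonds$order[j]
      deg_order[mol$bonds$a[j]] <- deg_order[mol$bonds$a[j]] + o
      deg_order[mol$bonds$b[j]] <- deg_order[mol$bonds$b[j]] + o
    }
  }
  expl_h <- numeric(n)
  vapply(seq_len(n), function(i) {
    dv <- defval[mol$elements[i]]
    if (is.na(dv)) return(0)
    # positive charge on N adds a bonding site; negative charge removes one
    max(0, dv + mol$charges[i] - deg_order[i])
  }, numeric(1))
}

smarts_atom_ok <- function(prims, mol, idx, hcounts) {
  for (p in prims) {
    val <- switch(p$kind,
      any = TRUE,
      aromatic = mol$aromatic_atom[idx],
      aliphatic = !mol$aromatic_atom[idx],
      ring = mol$ring_atom[idx] == p$value,
      anum = identical(unname(ELEMENT_NUMBERS[mol$elements[idx]]),
                       as.numeric(p$value)),
      charge = mol$charges[idx] == p$value,
      hcount = hcounts[idx] == p$value,
      degree = sum(mol$bonds$a == idx | mol$bonds$b == idx) == p$value,
      element = {
        mol$elements[idx] == p$value$elem &&
          mol$aromatic_atom[idx] == p$value$arom
      }
    )
    if (p$neg) val <- !val
    if (!val) return(FALSE)
  }
  TRUE
}

smarts_bond_ok <- function(sym, mol, bond_idx) {
  ord <- mol$bonds$order[bond_idx]
  arom <- mol$aromatic_bond[bond_idx]
  if (is.na(sym)) return((ord == 1 && !arom) || arom)
  switch(sym,
    "-" = ord == 1 && !arom,
    "=" = ord == 2 && !arom,
    "#" = ord == 3,
    ":" = arom,
    "~" = TRUE,
    (ord == 1 && !arom) || arom # default: single or aromatic
  )
}

# Parse a SMARTS string into atoms (primitive lists) and bonds.
parse_smarts <- function(pattern) {
  stopifnot(is.character(pattern), length(pattern) == 1)
  atoms <- list()
  bonds <- list() # list(a, b, sym)
  stack <- integer(0)
  prev <- NA_integer_
  pending_bond <- NA_character_
  ring <- list()
  i <- 1
  n <- nchar(pattern)
  add_atom <- function(prims) {
    atoms[[length(atoms) + 1]] <<- prims
    this <- length(atoms)
    if (!is.na(prev)) {
      bonds[[length(bonds) + 1]] <<- list(a = prev, b = this,
                                          sym = pending_bond)
    }
    pending_bond <<- NA_character_
    prev <<- this
  }
  while (i <= n) {
    ch <- substr(pattern, i, i)
    if (ch == "(") {
      if (is.na(prev)) smarts_error(pattern, "branch before any atom")
      stack <- c(stack, prev)
      i <- i + 1
    } else if (ch == ")") {
      if (length(stack) == 0) smarts_error(pattern, "unbalanced ')'")
      prev <- stack[length(stack)]
      stack <- stack[-length(stack)]
      i <- i + 1
    } else if (ch %in% c("-", "=", "#", ":", "~")) {
      pending_bond <- ch
      i <- i + 1
    } else if (grepl("[0-9]", ch) || ch == "%") {
      if (is.na(prev)) smarts_error(pattern, "ring closure before any atom")
      if (ch == "%") {
        num <- substr(pattern, i + 1, i + 2)
        if (!grepl("^[0-9]{2}$", num)) smarts_error(pattern, "bad %nn closure")
        i <- i + 3
      } else {
        num <- ch
        i <- i + 1
      }
      if (is.null(ring[[num]])) {
        ring[[num]] <- list(atom = prev, sym = pending_bond)
      } else {
        sym <- if (!is.na(pending_bond)) pending_bond else ring[[num]]$sym
        bonds[[length(bonds) + 1]] <- list(a = ring[[num]]$atom, b = prev,
                                           sym = sym)
        ring[[num]] <- NULL
      }
      pending_bond <- NA_character_
    } else if (ch == "[") {
      close <- regexpr("]", substr(pattern, i, n), fixed = TRUE)
      if (close < 0) smarts_error(pattern, "unterminated '['")
      body <- substr(pattern, i + 1, i + close - 2)
      add_atom(parse_bracket(body, pattern))
      i <- i + close
    } else {
      two <- substr(pattern, i, min(i + 1, n))
      if (two %in% ORGANIC_2CHAR) {
        add_atom(list(smarts_prim("element", list(elem = two, arom = FALSE))))
        i <- i + 2
      } else if (ch %in% ORGANIC_1CHAR) {
        add_atom(list(smarts_prim("element", list(elem = ch, arom = FALSE))))
        i <- i + 1
      } else if (ch %in% names(AROMATIC_ELEMS)) {
        add_atom(list(smarts_prim("element",
                                  list(elem = AROMATIC_ELEMS[[ch]], arom = TRUE))))
        i <- i + 1
      } else if (ch == "*") {
        add_atom(list(smarts_prim("any")))
        i <- i + 1
      } else if (ch == "A") {
        add_atom(list(smarts_prim("aliphatic")))
        i <- i + 1
      } else if (ch == "a") {
        add_atom(list(smarts_prim("aromatic")))
        i <- i + 1
      } else {
        smarts_error(pattern, sprintf("unexpected character '%s'", ch))
      }
    }
  }
  if (length(stack) > 0) smarts_error(pattern, "unbalanced '('")
  if (length(ring) > 0) smarts_error(pattern, "unclosed ring bond")
  if (length(atoms) == 0) smarts_error(pattern, "no atoms")
  list(atoms = atoms, bonds = bonds)
}

#' Match a core SMARTS pattern against a molecule
#'
#' Substructure search used to verify that a manually specified fixed core is
#' present in a ligand. A restricted SMARTS dialect is supported (see
#' package vignette); unsupported constructs raise an error instead of
#' silently mis-matching.
#'
#' @param mol a `nes_mol`.
#' @param smarts core pattern.
#' @return list with `matched` (logical) and `atoms` (integer indices of the
#'   first match in `mol`, 1-based; empty when unmatched).
#' @export
match_core <- function(mol, smarts) {
  stopifnot(inherits(mol, "nes_mol"))
  pat <- parse_smarts(smarts)
  np <- length(pat$atoms)
  hcounts <- implicit_h_counts(mol)
  nm <- length(mol$elements)
  domains <- lapply(pat$atoms, function(prims) {
    which(vapply(seq_len(nm), function(i) smarts_atom_ok(prims, mol, i, hcounts),
                 logical(1)))
  })
  if (any(vapply(domains, length, 0L) == 0)) {
    return(list(matched = FALSE, atoms = integer(0)))
  }
  if (np == 1) {
    return(list(matched = TRUE, atoms = domains[[1]][1]))
  }
  pat_edges <- do.call(rbind, lapply(pat$bonds, function(b) c(b$a, b$b)))
  pat_g <- igraph::graph_from_edgelist(pat_edges, directed = FALSE)
  if (igraph::vcount(pat_g) < np) {
    pat_g <- igraph::add_vertices(pat_g, np - igraph::vcount(pat_g))
  }
  mol_g <- mol_graph(mol)
  isos <- tryCatch(
    igraph::subgraph_isomorphisms(pat_g, mol_g, method = "lad",
                                  induced = FALSE, domains = domains),
    error = function(e) list()
  )
  bond_lookup <- function(i, j) {
    which((mol$bonds$a == i & mol$bonds$b == j) |
            (mol$bonds$a == j & mol$bonds$b == i))[1]
  }
  for (iso in isos) {
    map <- as.integer(iso)
    ok <- TRUE
    for (b in pat$bonds) {
      bi <- bond_lookup(map[b$a], map[b$b])
      if (is.na(bi) || !smarts_bond_ok(b$sym %||% NA_character_, mol, bi)) {
        ok <- FALSE
        break
      }
    }
    if (ok) return(list(matched = TRUE, atoms = map))
  }
  list(matched = FALSE, atoms = integer(0))
}
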