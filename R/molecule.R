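# Molecule representation and SMILES input/output.
#
# A molecule is a molecular graph: atoms carry element, formal charge, resolved
# hydrogen count and an optional atom-map number (0 = unmapped); bonds carry an
# integer order (1, 2, 3). Stereochemistry is ignored throughout and aromatic
# (lowercase) notation is rejected: structures are expected in Kekulé form.

.ORGANIC_SUBSET <- c("B", "C", "N", "O", "P", "S", "F", "Cl", "Br", "I")

# default valence lists used to resolve implicit hydrogens on bare atoms
.VALENCES <- list(
  B = 3L, C = 4L, N = c(3L, 5L), O = 2L, P = c(3L, 5L), S = c(2L, 4L, 6L),
  F = 1L, Cl = 1L, Br = 1L, I = 1L
)

#' Parse a SMILES string into a molecule
#'
#' Supports the Daylight dialect used throughout the package: the organic
#' subset written bare, bracket atoms with hydrogen counts, charges and
#' atom-map numbers (`[CH3:5]`, `[O-]`, `[H+]`), single/double/triple bonds,
#' branches and ring closures (including `%nn`). Stereo markers (`/`, `\`,
#' `@`) are accepted and dropped. Aromatic lowercase notation is not
#' supported; write rings in Kekulé form. Explicit bracket hydrogens bonded
#' to a heavy atom are folded into that atom's hydrogen count.
#'
#' @param smiles a single non-empty SMILES string (one connected component or
#'   a free-standing atom such as `[H+]`).
#' @return an object of class `rpe_molecule`: a list with `atoms`
#'   (data.frame: element, charge, hcount, map, aromatic), `bonds`
#'   (data.frame: a1, a2, order) and `canonical_smiles`.
#' @examples
#' m <- parse_molecule("CC(C)CC(N)C(=O)O")  # leucine
#' elemental_formula(m)
#' @export
parse_molecule <- function(smiles) {
  if (!is.character(smiles) || length(smiles) != 1L || is.na(smiles) ||
      nchar(smiles) == 0L) {
    stop("parse error: SMILES must be a single non-empty string")
  }
  if (grepl(".", smiles, fixed = TRUE)) {
    stop("parse error: '.' (multi-component) not allowed in a single molecule; ",
         "use parse_reaction_smiles() for reactions")
  }
  mol <- .parse_smiles_single(smiles)
  mol <- .fold_explicit_h(mol, smiles)
  mol$canonical_smiles <- .write_smiles(mol, order = .canonical_order(mol),
                                        include_maps = FALSE)
  class(mol) <- "rpe_molecule"
  mol
}

# core tokenizing state machine; returns atoms/bonds without implicit-H folding
.parse_smiles_single <- function(smiles) {
  chars <- strsplit(smiles, "")[[1]]
  n <- length(chars)
  el <- character(0); chg <- integer(0); hc <- integer(0); mp <- integer(0)
  explicit_h <- logical(0)  # bracket atom (H count fixed by input)
  b1 <- integer(0); b2 <- integer(0); bo <- integer(0)

  prev <- 0L                 # index of previous atom in chain
  stack <- integer(0)        # branch stack
  pend <- NA_integer_        # pending bond order
  rings <- list()            # ring closure id -> list(atom, order)

  add_atom <- function(e, q, h, m, expl) {
    el[length(el) + 1L] <<- e
    chg[length(chg) + 1L] <<- q
    hc[length(hc) + 1L] <<- h
    mp[length(mp) + 1L] <<- m
    explicit_h[length(explicit_h) + 1L] <<- expl
    idx <- length(el)
    if (prev > 0L) {
      b1[length(b1) + 1L] <<- prev
      b2[length(b2) + 1L] <<- idx
      bo[length(bo) + 1L] <<- if (is.na(pend)) 1L else pend
    }
    pend <<- NA_integer_
    prev <<- idx
    invisible(idx)
  }

  close_ring <- function(id) {
    if (prev == 0L) stop("parse error: ring closure '", id, "' before any atom")
    if (is.null(rings[[id]])) {
      rings[[id]] <<- list(atom = prev, order = pend)
    } else {
      op <- rings[[id]]
      ord <- if (!is.na(pend)) pend else if (!is.null(op$order) && !is.na(op$order)) op$order else 1L
      if (!is.na(pend) && !is.null(op$order) && !is.na(op$order) && pend != op$order) {
        stop("parse error: conflicting bond orders on ring closure '", id, "'")
      }
      b1[length(b1) + 1L] <<- op$atom
      b2[length(b2) + 1L] <<- prev
      bo[length(bo) + 1L] <<- ord
      rings[[id]] <<- NULL
    }
    pend <<- NA_integer_
  }

  i <- 1L
  while (i <= n) {
    ch <- chars[i]
    if (ch == "[") {
      j <- i
      while (j <= n && chars[j] != "]") j <- j + 1L
      if (j > n) stop("parse error: unclosed bracket atom starting at '",
                      substr(smiles, i, min(n, i + 6L)), "'")
      body <- substr(smiles, i + 1L, j - 1L)
      a <- .parse_bracket_atom(body)
      add_atom(a$element, a$charge, a$hcount, a$map, TRUE)
      i <- j + 1L
    } else if (ch == "(") {
      if (prev == 0L) stop("parse error: branch open '(' before any atom")
      stack <- c(stack, prev)
      i <- i + 1L
    } else if (ch == ")") {
      if (length(stack) == 0L) stop("parse error: unmatched ')'")
      prev <- stack[length(stack)]
      stack <- stack[-length(stack)]
      i <- i + 1L
    } else if (ch == "=") { pend <- 2L; i <- i + 1L
    } else if (ch == "#") { pend <- 3L; i <- i + 1L
    } else if (ch == "-") { pend <- 1L; i <- i + 1L
    } else if (ch == "/" || ch == "\\") { pend <- 1L; i <- i + 1L
    } else if (ch == "%") {
      if (i + 2L > n || !grepl("^[0-9]{2}$", substr(smiles, i + 1L, i + 2L))) {
        stop("parse error: '%' must be followed by two digits")
      }
      close_ring(substr(smiles, i + 1L, i + 2L))
      i <- i + 3L
    } else if (grepl("[0-9]", ch)) {
      close_ring(ch)
      i <- i + 1L
    } else if (ch %in% c("C", "B") && i < n && chars[i + 1L] %in% c("l", "r") &&
               paste0(ch, chars[i + 1L]) %in% c("Cl", "Br")) {
      add_atom(paste0(ch, chars[i + 1L]), 0L, NA_integer_, 0L, FALSE)
      i <- i + 2L
    } else if (ch %in% .ORGANIC_SUBSET) {
      add_atom(ch, 0L, NA_integer_, 0L, FALSE)
      i <- i + 1L
    } else if (ch %in% c("b", "c", "n", "o", "p", "s")) {
      stop("parse error: aromatic SMILES atom '", ch,
           "' not supported; write the structure in Kekélé form")
    } else {
      stop("parse error: unexpected token '", ch, "' in SMILES")
    }
  }
  if (length(stack) > 0L) stop("parse error: unclosed '(' in SMILES")
  if (length(rings) > 0L) {
    stop("parse error: unclosed ring bond(s): ",
         paste(names(rings), collapse = ", "))
  }
  if (length(el) == 0L) stop("parse error: no atoms in SMILES")

  atoms <- data.frame(element = el, charge = chg, hcount = hc, map = mp,
                      aromatic = FALSE, stringsAsFactors = FALSE)
  bonds <- if (length(b1)) {
    data.frame(a1 = b1, a2 = b2, order = bo)
  } else {
    data.frame(a1 = integer(0), a2 = integer(0), order = integer(0))
  }

  # resolve implicit hydrogens for bare (organic-subset) atoms
  bsum <- integer(nrow(atoms))
  if (nrow(bonds)) {
    for (k in seq_len(nrow(bonds))) {
      bsum[bonds$a1[k]] <- bsum[bonds$a1[k]] + bonds$order[k]
      bsum[bonds$a2[k]] <- bsum[bonds$a2[k]] + bonds$order[k]
    }
  }
  for (a in seq_len(nrow(atoms))) {
    if (!explicit_h[a]) {
      vs <- .VALENCES[[atoms$element[a]]]
      v <- vs[vs >= bsum[a]][1]
      atoms$hcount[a] <- if (is.na(v)) 0L else v - bsum[a]
    }
  }
  list(atoms = atoms, bonds = bonds)
}

.parse_bracket_atom <- function(body) {
  m <- regmatches(body, regexec(
    "^([0-9]*)(\\*|[A-Z][a-z]?|[a-z])(@{0,2})(H[0-9]*)?([+-][0-9]*|\\+\\+|--)?(:([0-9]+))?$",
    body))[[1]]
  if (length(m) == 0L) stop("parse error: bad bracket atom '[", body, "]'")
  elem <- m[3]
  if (elem %in% c("b", "c", "n", "o", "p", "s")) {
    stop("parse error: aromatic SMILES atom '", elem, "' not supported")
  }
  hstr <- m[5]
  h <- if (hstr == "") 0L else if (hstr == "H") 1L else as.integer(substr(hstr, 2L, nchar(hstr)))
  cstr <- m[6]
  q <- 0L
  if (cstr == "++") q <- 2L
  else if (cstr == "--") q <- -2L
  else if (cstr == "+") q <- 1L
  else if (cstr == "-") q <- -1L
  else if (grepl("^[+-][0-9]+$", cstr)) {
    q <- as.integer(substr(cstr, 2L, nchar(cstr)))
    if (substr(cstr, 1L, 1L) == "-") q <- -q
  }
  map <- if (m[8] == "") 0L else as.integer(m[8])
  list(element = elem, charge = q, hcount = h, map = map)
}

# explicit bracket H atoms bonded to one heavy atom become implicit hydrogens
.fold_explicit_h <- function(mol, smiles) {
  hidx <- which(mol$atoms$element == "H")
  if (!length(hidx)) return(mol)
  drop <- integer(0)
  for (a in hidx) {
    nb <- c(mol$bonds$a2[mol$bonds$a1 == a], mol$bonds$a1[mol$bonds$a2 == a])
    if (length(nb) == 1L && mol$atoms$charge[a] == 0L &&
        mol$atoms$element[nb] != "H") {
      mol$atoms$hcount[nb] <- mol$atoms$hcount[nb] + 1L
      drop <- c(drop, a)
    } else if (length(nb) > 1L) {
      stop("parse error: hydrogen atom with multiple bonds in '", smiles, "'")
    }
  }
  if (length(drop)) {
    keep <- setdiff(seq_len(nrow(mol$atoms)), drop)
    remap <- integer(nrow(mol$atoms)); remap[keep] <- seq_along(keep)
    mol$bonds <- mol$bonds[!(mol$bonds$a1 %in% drop | mol$bonds$a2 %in% drop), ,
                           drop = FALSE]
    mol$bonds$a1 <- remap[mol$bonds$a1]
    mol$bonds$a2 <- remap[mol$bonds$a2]
    mol$atoms <- mol$atoms[keep, , drop = FALSE]
    rownames(mol$atoms) <- NULL
    rownames(mol$bonds) <- NULL
  }
  mol
}

# construct a molecule from atom/bond tables (used by the rewriting engine)
new_molecule <- function(atoms, bonds) {
  rownames(atoms) <- NULL
  rownames(bonds) <- NULL
  mol <- list(atoms = atoms, bonds = bonds)
  mol$canonical_smiles <- .write_smiles(mol, order = .canonical_order(mol),
                                        include_maps = FALSE)
  class(mol) <- "rpe_molecule"
  mol
}

# canonical atom ordering via BLISS on the bond-subdivided colored graph;
# invariant under input atom order and atom-map renumbering
.canonical_order <- function(mol) {
  n <- nrow(mol$atoms)
  if (n == 1L) return(1L)
  nb <- nrow(mol$bonds)
  edges <- integer(0)
  if (nb > 0L) {
    bv <- n + seq_len(nb)
    edges <- as.integer(c(rbind(mol$bonds$a1, bv), rbind(bv, mol$bonds$a2)))
  }
  g <- igraph::make_empty_graph(n = n + nb, directed = FALSE)
  if (length(edges)) g <- igraph::add_edges(g, edges)
  akey <- paste(mol$atoms$element, mol$atoms$charge, mol$atoms$hcount,
                mol$atoms$aromatic)
  lv <- sort(unique(akey))
  cols <- c(match(akey, lv), length(lv) + mol$bonds$order)
  lab <- igraph::canonical_permutation(g, colors = as.integer(cols))$labeling
  order(lab[seq_len(n)])
}

# SMILES writer: deterministic DFS over a supplied atom order
.write_smiles <- function(mol, order = seq_len(nrow(mol$atoms)),
                          include_maps = FALSE) {
  n <- nrow(mol$atoms)
  rank <- integer(n); rank[order] <- seq_len(n)
  adj <- vector("list", n)
  bond_order <- list()
  bkey <- function(i, j) paste0(min(i, j), "_", max(i, j))
  if (nrow(mol$bonds)) {
    for (k in seq_len(nrow(mol$bonds))) {
      i <- mol$bonds$a1[k]; j <- mol$bonds$a2[k]
      adj[[i]] <- c(adj[[i]], j); adj[[j]] <- c(adj[[j]], i)
      bond_order[[bkey(i, j)]] <- mol$bonds$order[k]
    }
  }
  for (i in seq_len(n)) {
    if (length(adj[[i]])) adj[[i]] <- adj[[i]][order(rank[adj[[i]]])]
  }

  visited <- logical(n)
  ring_ids <- list()     # bond key -> ring closure number
  ring_ctr <- 0L
  tree_children <- vector("list", n)
  back_open <- vector("list", n)   # atom -> bond keys opened here
  back_close <- vector("list", n)  # atom -> bond keys closed here
  dfs1 <- function(a, from) {
    visited[a] <<- TRUE
    for (b in adj[[a]]) {
      if (b == from) next
      k <- bkey(a, b)
      if (visited[b]) {
        if (is.null(ring_ids[[k]])) {
          ring_ctr <<- ring_ctr + 1L
          ring_ids[[k]] <<- ring_ctr
          back_close[[a]] <<- c(back_close[[a]], k)
          back_open[[b]] <<- c(back_open[[b]], k)
        }
      } else {
        tree_children[[a]] <<- c(tree_children[[a]], b)
        dfs1(b, a)
      }
    }
  }

  bsym <- function(o) c("", "=", "#")[o]
  atom_token <- function(a) {
    e <- mol$atoms$element[a]; q <- mol$atoms$charge[a]
    h <- mol$atoms$hcount[a]; mp <- mol$atoms$map[a]
    need_map <- include_maps && mp > 0L
    bare_ok <- !need_map && q == 0L && e %in% .ORGANIC_SUBSET
    if (bare_ok) {
      bs <- 0L
      for (b in adj[[a]]) bs <- bs + bond_order[[bkey(a, b)]]
      vs <- .VALENCES[[e]]
      v <- vs[vs >= bs][1]
      impl <- if (is.na(v)) 0L else v - bs
      if (impl == h) return(e)
    }
    qs <- if (q == 0L) "" else if (q == 1L) "+" else if (q == -1L) "-" else
      if (q > 0L) paste0("+", q) else paste0("-", abs(q))
    hs <- if (h == 0L) "" else if (h == 1L) "H" else paste0("H", h)
    ms <- if (need_map) paste0(":", mp) else ""
    paste0("[", e, hs, qs, ms, "]")
  }

  emit <- function(a, from) {
    out <- atom_token(a)
    for (k in back_open[[a]]) out <- paste0(out, .ring_digit(ring_ids[[k]]))
    for (k in back_close[[a]]) {
      out <- paste0(out, bsym(bond_order[[k]]), .ring_digit(ring_ids[[k]]))
    }
    kids <- tree_children[[a]]
    if (length(kids)) {
      for (idx in seq_along(kids)) {
        b <- kids[idx]
        part <- paste0(bsym(bond_order[[bkey(a, b)]]), emit(b, a))
        if (idx < length(kids)) part <- paste0("(", part, ")")
        out <- paste0(out, part)
      }
    }
    out
  }

  parts <- character(0)
  for (s in order) {
    if (!visited[s]) {
      dfs1(s, 0L)
      parts <- c(parts, emit(s, 0L))
    }
  }
  paste(parts, collapse = ".")
}

.ring_digit <- function(id) if (id <= 9L) as.character(id) else sprintf("%%%02d", id)

#' Elemental composition of a molecule (or list of molecules)
#'
#' Hydrogens are counted explicitly (implicit hydrogens resolved at parse
#' time). Composition of a molecule list is the sum over members.
#'
#' @param mol an `rpe_molecule` or a list of them.
#' @return list with `counts` (named integer vector, element -> count) and
#'   `net_charge`.
#' @export
elemental_formula <- function(mol) {
  if (is.list(mol) && !inherits(mol, "rpe_molecule")) {
    comps <- lapply(mol, elemental_formula)
    all_el <- sort(unique(unlist(lapply(comps, function(x) names(x$counts)))))
    counts <- stats::setNames(integer(length(all_el)), all_el)
    q <- 0L
    for (cm in comps) {
      counts[names(cm$counts)] <- counts[names(cm$counts)] + cm$counts
      q <- q + cm$net_charge
    }
    return(list(counts = counts, net_charge = q))
  }
  stopifnot(inherits(mol, "rpe_molecule"))
  el <- c(mol$atoms$element, rep("H", sum(mol$atoms$hcount)))
  counts <- table(el)
  counts <- stats::setNames(as.integer(counts), names(counts))
  counts <- counts[order(names(counts))]
  list(counts = counts, net_charge = sum(mol$atoms$charge))
}

# number of non-hydrogen atoms
heavy_atom_count <- function(mol) sum(mol$atoms$element != "H")

# ring membership per atom: incident to at least one non-bridge bond
.ring_atoms <- function(mol) {
  n <- nrow(mol$atoms)
  inring <- logical(n)
  if (nrow(mol$bonds) == 0L) return(inring)
  g <- igraph::make_empty_graph(n = n, directed = FALSE)
  g <- igraph::add_edges(g, as.integer(rbind(mol$bonds$a1, mol$bonds$a2)))
  br <- igraph::bridges(g)
  ring_edges <- setdiff(seq_len(nrow(mol$bonds)), as.integer(br))
  for (k in ring_edges) {
    inring[mol$bonds$a1[k]] <- TRUE
    inring[mol$bonds$a2[k]] <- TRUE
  }
  inring
}

#' @export
print.rpe_molecule <- function(x, ...) {
  f <- elemental_formula(x)
  cat("<rpe_molecule> ", x$canonical_smiles, "\n", sep = "")
  cat("  atoms: ", nrow(x$atoms), " (", heavy_atom_count(x), " heavy), bonds: ",
      nrow(x$bonds), ", charge: ", f$net_charge, "\n", sep = "")
  invisible(x)
}

# SMILES with atom maps retained (TSV round-trips)
write_smiles_mapped <- function(mol) {
  .write_smiles(mol, order = .canonical_order(mol), include_maps = TRUE)
}

# molecule equality by canonical form
same_molecule <- function(a, b) identical(a$canonical_smiles, b$canonical_smiles)
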