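# Biotransformation rule engine.
#
# Rules are extracted from fully atom-mapped reference reactions: the
# reaction center (bonds broken/formed/order-changed plus atoms with changed
# hydrogen count or charge) is detected from the mapping, a product-side
# pattern (center atoms plus an `radius`-bond environment) is cut out, and
# retro application embeds that pattern in a target molecule and rewrites the
# matched region back to the reactant side, reconstructing precursors and
# co-reactants so that balanced source reactions yield balanced candidates.

# ---- mapping tables ----

# one row per mapped heavy atom: map, mol index, atom index, element, charge, hcount
.map_table <- function(mols) {
  rows <- list()
  for (i in seq_along(mols)) {
    a <- mols[[i]]$atoms
    keep <- which(a$map > 0L)
    if (length(keep)) {
      rows[[length(rows) + 1L]] <- data.frame(
        map = a$map[keep], mol = i, atom = keep,
        element = a$element[keep], charge = a$charge[keep],
        hcount = a$hcount[keep], stringsAsFactors = FALSE)
    }
  }
  if (!length(rows)) {
    return(data.frame(map = integer(0), mol = integer(0), atom = integer(0),
                      element = character(0), charge = integer(0),
                      hcount = integer(0)))
  }
  do.call(rbind, rows)
}

# bonds between mapped atoms, keyed by "m1|m2" (m1 < m2) -> order
.mapped_bonds <- function(mols) {
  out <- list()
  for (i in seq_along(mols)) {
    m <- mols[[i]]
    if (!nrow(m$bonds)) next
    for (k in seq_len(nrow(m$bonds))) {
      m1 <- m$atoms$map[m$bonds$a1[k]]
      m2 <- m$atoms$map[m$bonds$a2[k]]
      if (m1 > 0L && m2 > 0L) {
        out[[paste0(min(m1, m2), "|", max(m1, m2))]] <- m$bonds$order[k]
      }
    }
  }
  out
}

#' Detect the reaction center of a fully atom-mapped reaction
#'
#' The center is the symmetric difference of the mapped bond sets (bonds
#' broken, formed, or with changed order) plus every mapped atom whose
#' hydrogen count or formal charge differs between the two sides; atoms
#' incident to a changed bond are included.
#'
#' @param rxn a fully atom-mapped `rpe_reaction`.
#' @return an `rpe_reaction_center`: list with `changed_bonds` (data.frame
#'   m1, m2, change, order_r, order_p) and `changed_atoms` (map numbers).
#' @export
reaction_center <- function(rxn) {
  if (!is_fully_mapped(rxn)) {
    stop("reaction '", rxn$id, "': unmapped atoms present ",
         "(rule extraction requires a fully atom-mapped reaction)")
  }
  rt <- .map_table(rxn$reactants)
  pt <- .map_table(rxn$products)
  rb <- .mapped_bonds(rxn$reactants)
  pb <- .mapped_bonds(rxn$products)

  keys <- union(names(rb), names(pb))
  cb <- list()
  for (k in keys) {
    orr <- rb[[k]]; orp <- pb[[k]]
    change <- NULL
    if (is.null(orp)) change <- "broken"
    else if (is.null(orr)) change <- "formed"
    else if (orr != orp) change <- "order-changed"
    if (!is.null(change)) {
      mm <- as.integer(strsplit(k, "|", fixed = TRUE)[[1]])
      cb[[length(cb) + 1L]] <- data.frame(
        m1 = mm[1], m2 = mm[2], change = change,
        order_r = if (is.null(orr)) 0L else orr,
        order_p = if (is.null(orp)) 0L else orp,
        stringsAsFactors = FALSE)
    }
  }
  changed_bonds <- if (length(cb)) do.call(rbind, cb) else
    data.frame(m1 = integer(0), m2 = integer(0), change = character(0),
               order_r = integer(0), order_p = integer(0))

  rt <- rt[order(rt$map), ]; pt <- pt[order(pt$map), ]
  prop_changed <- rt$map[rt$hcount != pt$hcount | rt$charge != pt$charge]
  changed_atoms <- sort(unique(c(changed_bonds$m1, changed_bonds$m2,
                                 prop_changed)))
  out <- list(changed_bonds = changed_bonds, changed_atoms = changed_atoms)
  class(out) <- "rpe_reaction_center"
  out
}

#' Canonical signature of a reaction center
#'
#' Map-number independent string over changed-bond types (element pair and
#' order transition) and changed-atom property deltas; used to group
#' mechanistically equivalent reference reactions (e.g. all transaminations)
#' for cofactor-frequency ranking and enzyme inference.
#'
#' @param rxn an oriented, fully mapped `rpe_reaction`.
#' @return signature string.
#' @export
center_signature <- function(rxn) {
  ctr <- reaction_center(rxn)
  rt <- .map_table(rxn$reactants); rt <- rt[order(rt$map), ]
  pt <- .map_table(rxn$products); pt <- pt[order(pt$map), ]
  el <- stats::setNames(rt$element, rt$map)
  btok <- character(0)
  cb <- ctr$changed_bonds
  if (nrow(cb)) {
    btok <- vapply(seq_len(nrow(cb)), function(k) {
      es <- sort(c(el[[as.character(cb$m1[k])]], el[[as.character(cb$m2[k])]]))
      paste0(es[1], "~", es[2], ":", cb$order_r[k], ">", cb$order_p[k])
    }, "")
  }
  dh <- stats::setNames(pt$hcount - rt$hcount, rt$map)
  dq <- stats::setNames(pt$charge - rt$charge, rt$map)
  amaps <- rt$map[dh[as.character(rt$map)] != 0 | dq[as.character(rt$map)] != 0]
  atok <- vapply(amaps, function(m) {
    paste0(el[[as.character(m)]], ":dH", dh[[as.character(m)]],
           ":dQ", dq[[as.character(m)]])
  }, "")
  paste(c(sort(btok), sort(atok)), collapse = ";")
}

# ---- rule extraction ----

# orient a reaction for rule purposes: as_written keeps sides, reversed swaps
.orient <- function(rxn, direction) {
  if (direction == "reversed") reverse_reaction(rxn) else rxn
}

#' Extract all retro-applicable rules of a reaction in one direction
#'
#' One rule is produced per product-side molecule that contains at least one
#' reaction-center heavy atom (a pattern spanning several product molecules
#' could never embed in a single target compound). The designated product
#' molecule supplies the match pattern: its center atoms plus all atoms
#' within `radius` bonds.
#'
#' @param rxn a fully mapped `rpe_reaction`.
#' @param direction `"as_written"` or `"reversed"` (the forward direction of
#'   the resulting rule; retro application runs it backwards).
#' @param radius environment radius in bonds (default 1).
#' @return list of `rpe_rule`.
#' @export
extract_rules <- function(rxn, direction = "as_written", radius = 1L) {
  stopifnot(radius >= 0L)
  orxn <- .orient(rxn, direction)
  ctr <- reaction_center(orxn)
  rules <- list()
  for (ps in seq_along(orxn$products)) {
    mol <- orxn$products[[ps]]
    heavy_center <- which(mol$atoms$map %in% ctr$changed_atoms &
                            mol$atoms$element != "H")
    if (!length(heavy_center)) next
    rules[[length(rules) + 1L]] <-
      .build_rule(rxn, orxn, ctr, direction, radius, ps, heavy_center)
  }
  rules
}

#' Extract a single transformation rule
#'
#' As [extract_rules()] but returns the rule for one designated product
#' molecule (`pstar`); by default the first product molecule containing
#' reaction-center atoms, which by database convention is the main product.
#'
#' @inheritParams extract_rules
#' @param pstar index of the designated product molecule, or `NULL` for the
#'   first eligible one.
#' @return an `rpe_rule`.
#' @export
extract_rule <- function(rxn, direction = "as_written", radius = 1L,
                         pstar = NULL) {
  rules <- extract_rules(rxn, direction, radius)
  if (!length(rules)) {
    stop("reaction '", rxn$id, "': no product molecule carries reaction-center ",
         "atoms (identity reaction?)")
  }
  if (is.null(pstar)) return(rules[[1L]])
  for (r in rules) if (r$pstar == pstar) return(r)
  stop("reaction '", rxn$id, "': product molecule ", pstar,
       " carries no reaction-center atoms")
}

.build_rule <- function(rxn, orxn, ctr, direction, radius, ps, heavy_center) {
  mol <- orxn$products[[ps]]
  n <- nrow(mol$atoms)

  # grow environment: atoms within `radius` bonds of any center atom
  adj <- vector("list", n)
  if (nrow(mol$bonds)) {
    for (k in seq_len(nrow(mol$bonds))) {
      i <- mol$bonds$a1[k]; j <- mol$bonds$a2[k]
      adj[[i]] <- c(adj[[i]], j); adj[[j]] <- c(adj[[j]], i)
    }
  }
  dist <- rep(Inf, n); dist[heavy_center] <- 0
  frontier <- heavy_center
  d <- 0
  while (length(frontier) && d < radius) {
    d <- d + 1
    nxt <- integer(0)
    for (a in frontier) for (b in adj[[a]]) {
      if (dist[b] > d) { dist[b] <- d; nxt <- c(nxt, b) }
    }
    frontier <- unique(nxt)
  }
  pat_idx <- sort(which(is.finite(dist)))

  inring <- .ring_atoms(mol)
  pat <- data.frame(
    idx = pat_idx,
    map = mol$atoms$map[pat_idx],
    element = mol$atoms$element[pat_idx],
    charge = mol$atoms$charge[pat_idx],
    hcount = mol$atoms$hcount[pat_idx],
    aromatic = mol$atoms$aromatic[pat_idx],
    inring = inring[pat_idx],
    is_center = pat_idx %in% heavy_center,
    stringsAsFactors = FALSE)

  # induced pattern bonds (positions into pat)
  pos <- stats::setNames(seq_along(pat_idx), pat_idx)
  pb <- mol$bonds[mol$bonds$a1 %in% pat_idx & mol$bonds$a2 %in% pat_idx, ,
                  drop = FALSE]
  pat_bonds <- data.frame(i = unname(pos[as.character(pb$a1)]),
                          j = unname(pos[as.character(pb$a2)]),
                          order = pb$order)

  # reactant-side lookup: map -> (mol, atom)
  rt <- .map_table(orxn$reactants)
  rlook <- stats::setNames(split(rt[, c("mol", "atom")], seq_len(nrow(rt))),
                           rt$map)

  # principal substrate: reactant molecule contributing most pattern atoms,
  # restricted to molecules holding the preimage of >= 1 center pattern atom;
  # anchor = lowest-map center pattern atom with preimage in it
  pre_mol <- vapply(pat$map, function(m) rt$mol[rt$map == m][1], 0L)
  center_mols <- unique(pre_mol[pat$is_center])
  cnt <- table(factor(pre_mol, levels = sort(unique(pre_mol))))
  cand_mols <- intersect(as.integer(names(sort(cnt, decreasing = TRUE))),
                         center_mols)
  best <- cand_mols[which.max(cnt[as.character(cand_mols)])]
  anchor_maps <- sort(pat$map[pat$is_center & pre_mol == best])
  anchor_map <- anchor_maps[1]

  # verbatim co-substrates: reactant molecules with no pattern preimage and
  # product molecules other than the designated one
  co_reactants <- orxn$reactants[setdiff(seq_along(orxn$reactants),
                                         unique(pre_mol))]
  co_products <- orxn$products[setdiff(seq_along(orxn$products), ps)]

  rule <- list(
    rule_id = paste0(rxn$id, ":", direction, ":P", ps, ":r", radius),
    source_reaction = rxn$id,
    direction = direction,
    radius = radius,
    rxn = orxn,
    pstar = ps,
    pattern = pat,
    pattern_bonds = pat_bonds,
    anchor_map = anchor_map,
    principal_reactant = best,
    center = ctr,
    signature = center_signature(orxn),
    co_reactants = co_reactants,
    co_products = co_products)
  class(rule) <- "rpe_rule"
  rule
}

#' @export
print.rpe_rule <- function(x, ...) {
  cat("<rpe_rule> ", x$rule_id, "\n", sep = "")
  cat("  pattern: ", rule_pattern_string(x), "\n", sep = "")
  cat("  signature: ", x$signature, "\n", sep = "")
  invisible(x)
}

# SMARTS-like descriptive encoding of the match pattern (one token per atom,
# bonds as an explicit list); informational, not re-parsed
rule_pattern_string <- function(rule) {
  p <- rule$pattern
  atoks <- vapply(seq_len(nrow(p)), function(i) {
    base <- paste0(p$element[i],
                   if (p$is_center[i]) paste0(";H", p$hcount[i],
                                              ";", sprintf("%+d", p$charge[i])) else "",
                   if (p$inring[i]) ";R" else ";!R")
    paste0("[", base, "]")
  }, "")
  btoks <- if (nrow(rule$pattern_bonds)) {
    apply(rule$pattern_bonds, 1L, function(b) {
      paste0(b[["i"]], c("-", "=", "#")[b[["order"]]], b[["j"]])
    })
  } else character(0)
  paste0(paste(atoks, collapse = ""),
         if (length(btoks)) paste0(" bonds:", paste(btoks, collapse = ",")))
}

# ---- subgraph matching ----

# all embeddings of the rule pattern in the target molecule, deduplicated by
# image atom set (= automorphism classes of the match images); returns a list
# of integer vectors (pattern position -> target atom index)
.match_pattern <- function(rule, target) {
  pat <- rule$pattern
  pb <- rule$pattern_bonds
  np <- nrow(pat)
  nt <- nrow(target$atoms)
  if (np > nt) return(list())
  t_inring <- .ring_atoms(target)

  ok_atom <- function(p, t) {
    if (target$atoms$element[t] != pat$element[p]) return(FALSE)
    if (target$atoms$aromatic[t] != pat$aromatic[p]) return(FALSE)
    if (t_inring[t] != pat$inring[p]) return(FALSE)
    if (pat$is_center[p]) {
      if (target$atoms$charge[t] != pat$charge[p]) return(FALSE)
      if (target$atoms$hcount[t] != pat$hcount[p]) return(FALSE)
    }
    TRUE
  }

  # adjacency with orders in the target
  t_adj <- vector("list", nt)
  t_ord <- list()
  bk <- function(i, j) paste0(min(i, j), "|", max(i, j))
  if (nrow(target$bonds)) {
    for (k in seq_len(nrow(target$bonds))) {
      i <- target$bonds$a1[k]; j <- target$bonds$a2[k]
      t_adj[[i]] <- c(t_adj[[i]], j); t_adj[[j]] <- c(t_adj[[j]], i)
      t_ord[[bk(i, j)]] <- target$bonds$order[k]
    }
  }
  p_adj <- vector("list", np)
  p_ord <- list()
  if (nrow(pb)) {
    for (k in seq_len(nrow(pb))) {
      i <- pb$i[k]; j <- pb$j[k]
      p_adj[[i]] <- c(p_adj[[i]], j); p_adj[[j]] <- c(p_adj[[j]], i)
      p_ord[[bk(i, j)]] <- pb$order[k]
    }
  }

  # search order: per connected pattern component, each atom after the first
  # has an already-placed neighbor
  placed <- logical(np)
  order_seq <- integer(0)
  seed_flag <- logical(0)
  for (s in seq_len(np)) {
    if (placed[s]) next
    comp <- s
    placed[s] <- TRUE
    order_seq <- c(order_seq, s); seed_flag <- c(seed_flag, TRUE)
    repeat {
      nxt <- NA_integer_
      for (a in order_seq[placed[order_seq] & order_seq %in% comp]) {
        for (b in p_adj[[a]]) if (!placed[b]) { nxt <- b; break }
        if (!is.na(nxt)) break
      }
      if (is.na(nxt)) break
      placed[nxt] <- TRUE
      comp <- c(comp, nxt)
      order_seq <- c(order_seq, nxt); seed_flag <- c(seed_flag, FALSE)
    }
  }

  res <- list()
  assign_vec <- integer(np)
  used <- logical(nt)
  bt <- function(step) {
    if (step > np) {
      res[[length(res) + 1L]] <<- assign_vec
      return(invisible(NULL))
    }
    p <- order_seq[step]
    cands <- if (seed_flag[step]) seq_len(nt) else {
      prev <- p_adj[[p]][assign_vec[p_adj[[p]]] != 0L]
      unique(unlist(lapply(prev, function(q) t_adj[[assign_vec[q]]])))
    }
    for (t in cands) {
      if (used[t] || !ok_atom(p, t)) next
      fit <- TRUE
      for (q in p_adj[[p]]) {
        if (assign_vec[q] == 0L) next
        to <- t_ord[[bk(t, assign_vec[q])]]
        if (is.null(to) || to != p_ord[[bk(p, q)]]) { fit <- FALSE; break }
      }
      if (!fit) next
      assign_vec[p] <<- t; used[t] <<- TRUE
      bt(step + 1L)
      assign_vec[p] <<- 0L; used[t] <<- FALSE
    }
    invisible(NULL)
  }
  assign_vec[] <- 0L
  bt(1L)

  if (!length(res)) return(list())
  keys <- vapply(res, function(m) paste(sort(m), collapse = ","), "")
  res[!duplicated(keys)]
}

# ---- retro application ----

#' Apply a rule in the retro direction to a target molecule
#'
#' Each automorphism-distinct embedding of the rule's product pattern in the
#' target yields one complete candidate synthesis reaction
#' (precursor(s) + co-reactants >> target + co-products): the matched region
#' is rewritten to the reactant side of the source reaction, reactant-side
#' atoms without counterparts in the target (e.g. an amino group restored by
#' a retro transamination) are copied from the source structures, and intact
#' co-substrates are copied verbatim.
#'
#' @param rule an `rpe_rule`.
#' @param target an `rpe_molecule`.
#' @return list of candidates; each is a list with `reaction`
#'   (`rpe_reaction`), `main_precursor` (canonical SMILES of the precursor
#'   designated for iterative expansion), `main_idx` (its position among the
#'   reactants), `rule_id`, `source_reaction` and `embedding`.
#' @export
apply_retro <- function(rule, target) {
  embeddings <- .match_pattern(rule, target)
  out <- list()
  for (e in seq_along(embeddings)) {
    cand <- .rewrite(rule, target, embeddings[[e]], e)
    if (!is.null(cand)) out[[length(out) + 1L]] <- cand
  }
  out
}

.rewrite <- function(rule, target, emb, idx) {
  orxn <- rule$rxn
  pat <- rule$pattern
  nt <- nrow(target$atoms)

  # reactant-side global atom table
  rmols <- orxn$reactants
  sizes <- vapply(rmols, function(m) nrow(m$atoms), 0L)
  roff <- cumsum(c(0L, sizes))[seq_along(rmols)]
  gid <- function(mol, atom) roff[mol] + atom
  nr <- sum(sizes)

  rt <- .map_table(rmols)
  map2r <- stats::setNames(gid(rt$mol, rt$atom), rt$map)

  # pattern position -> reactant global id (preimage)
  pre <- map2r[as.character(pat$map)]

  # node universe: target atoms (1..nt) plus template copies of reactant
  # atoms that do NOT correspond to the designated product molecule.
  # Reactant atoms mapped to non-pattern atoms of the designated product are
  # "absorbed": the target's own unmatched environment stands in for them.
  pstar_maps <- orxn$products[[rule$pstar]]$atoms$map
  pstar_maps <- pstar_maps[pstar_maps > 0L]
  absorbed <- setdiff(map2r[as.character(setdiff(pstar_maps, pat$map))], NA)
  node_of_r <- integer(nr)                   # 0 = absorbed
  node_of_r[pre] <- emb
  extra <- setdiff(which(node_of_r == 0L), absorbed)
  node_of_r[extra] <- nt + seq_along(extra)
  nn <- nt + length(extra)

  el <- c(target$atoms$element, character(length(extra)))
  ch <- c(target$atoms$charge, integer(length(extra)))
  hc <- c(target$atoms$hcount, integer(length(extra)))
  ar <- c(target$atoms$aromatic, logical(length(extra)))
  for (z in seq_along(extra)) {
    g <- extra[z]
    mol <- max(which(roff < g))
    atom <- g - roff[mol]
    node <- nt + z
    el[node] <- rmols[[mol]]$atoms$element[atom]
    ch[node] <- rmols[[mol]]$atoms$charge[atom]
    hc[node] <- rmols[[mol]]$atoms$hcount[atom]
    ar[node] <- rmols[[mol]]$atoms$aromatic[atom]
  }
  # center atoms take reactant-side hydrogen count / charge
  for (k in seq_len(nrow(pat))) {
    if (!pat$is_center[k]) next
    g <- pre[k]
    mol <- max(which(roff < g))
    atom <- g - roff[mol]
    t <- emb[k]
    ch[t] <- rmols[[mol]]$atoms$charge[atom]
    hc[t] <- rmols[[mol]]$atoms$hcount[atom]
  }

  bk <- function(i, j) paste0(min(i, j), "|", max(i, j))
  # pattern bond lookup (by pattern positions)
  patb <- list()
  if (nrow(rule$pattern_bonds)) {
    for (k in seq_len(nrow(rule$pattern_bonds))) {
      patb[[bk(rule$pattern_bonds$i[k], rule$pattern_bonds$j[k])]] <-
        rule$pattern_bonds$order[k]
    }
  }
  pat_pos_of_t <- integer(nt)     # target atom -> pattern position (0 none)
  pat_pos_of_t[emb] <- seq_len(nrow(pat))

  # reactant bond lookup between global ids
  rbond <- list()
  for (i in seq_along(rmols)) {
    b <- rmols[[i]]$bonds
    if (!nrow(b)) next
    for (k in seq_len(nrow(b))) {
      rbond[[bk(gid(i, b$a1[k]), gid(i, b$a2[k]))]] <- b$order[k]
    }
  }

  eb <- list()  # node bond key -> order
  # 1. target bonds, rewritten where both ends are matched pattern atoms
  if (nrow(target$bonds)) {
    for (k in seq_len(nrow(target$bonds))) {
      t1 <- target$bonds$a1[k]; t2 <- target$bonds$a2[k]
      p1 <- pat_pos_of_t[t1]; p2 <- pat_pos_of_t[t2]
      if (p1 > 0L && p2 > 0L && !is.null(patb[[bk(p1, p2)]])) {
        ro <- rbond[[bk(pre[p1], pre[p2])]]
        if (!is.null(ro)) eb[[bk(t1, t2)]] <- ro        # kept (maybe new order)
        # else: bond formed in the forward direction -> removed in retro
      } else {
        eb[[bk(t1, t2)]] <- target$bonds$order[k]        # environment bond
      }
    }
  }
  # 2. reactant-side bonds involving at least one template atom, plus
  #    pattern-pattern bonds absent from the target (retro ring closures);
  #    bonds inside the absorbed region are represented by the target itself
  for (key in names(rbond)) {
    gg <- as.integer(strsplit(key, "|", fixed = TRUE)[[1]])
    n1 <- node_of_r[gg[1]]; n2 <- node_of_r[gg[2]]
    if (n1 == 0L && n2 == 0L) next                      # absorbed-absorbed
    if (n1 == 0L || n2 == 0L) {
      other <- if (n1 == 0L) n2 else n1
      if (other > nt) return(NULL)  # template attachment outside the pattern:
      next                          # radius too small to rebuild -> no candidate
    }
    k2 <- bk(n1, n2)
    if (is.null(eb[[k2]])) eb[[k2]] <- rbond[[key]]
  }

  bonds <- if (length(eb)) {
    pairs <- do.call(rbind, lapply(names(eb), function(k) {
      as.integer(strsplit(k, "|", fixed = TRUE)[[1]])
    }))
    data.frame(a1 = pairs[, 1], a2 = pairs[, 2],
               order = unlist(eb, use.names = FALSE))
  } else data.frame(a1 = integer(0), a2 = integer(0), order = integer(0))

  # connected components -> reactant-side molecules
  comp <- seq_len(nn)
  find <- function(x) { while (comp[x] != x) { comp[x] <<- comp[comp[x]]; x <- comp[x] }; x }
  if (nrow(bonds)) {
    for (k in seq_len(nrow(bonds))) {
      r1 <- find(bonds$a1[k]); r2 <- find(bonds$a2[k])
      if (r1 != r2) comp[r1] <- r2
    }
  }
  roots <- vapply(seq_len(nn), find, 0L)
  comp_ids <- unique(roots)

  anchor_pos <- which(pat$map == rule$anchor_map)[1]
  anchor_node <- emb[anchor_pos]
  main_root <- roots[anchor_node]

  mols_out <- list()
  main_idx <- NA_integer_
  for (ci in seq_along(comp_ids)) {
    nodes <- which(roots == comp_ids[ci])
    sub_atoms <- data.frame(element = el[nodes], charge = ch[nodes],
                            hcount = hc[nodes], map = 0L, aromatic = ar[nodes],
                            stringsAsFactors = FALSE)
    remap <- integer(nn); remap[nodes] <- seq_along(nodes)
    sb <- bonds[bonds$a1 %in% nodes & bonds$a2 %in% nodes, , drop = FALSE]
    sub_bonds <- data.frame(a1 = remap[sb$a1], a2 = remap[sb$a2],
                            order = sb$order)
    mols_out[[ci]] <- new_molecule(sub_atoms, sub_bonds)
    if (comp_ids[ci] == main_root) main_idx <- ci
  }
  # main precursor first, remaining components in canonical order
  ord <- c(main_idx, setdiff(order(vapply(mols_out, function(m) m$canonical_smiles, "")),
                             main_idx))
  mols_out <- mols_out[ord]

  co_products <- lapply(rule$co_products, .strip_maps)
  products <- c(list(.strip_maps(target)), co_products)

  rxn <- new_reaction(
    id = paste0(rule$rule_id, ":cand", idx),
    reactants = mols_out, products = products,
    reversibility = "unknown",
    ec_numbers = orxn$ec_numbers, enzyme_names = orxn$enzyme_names,
    source = paste0("rule:", rule$rule_id))

  list(reaction = rxn,
       main_precursor = mols_out[[1L]]$canonical_smiles,
       main_idx = 1L,
       rule_id = rule$rule_id,
       source_reaction = rule$source_reaction,
       signature = rule$signature,
       embedding = emb)
}

.strip_maps <- function(mol) {
  if (all(mol$atoms$map == 0L)) return(mol)
  a <- mol$atoms; a$map <- 0L
  new_molecule(a, mol$bonds)
}

# ---- rule serialization ----

#' Write rules to JSON
#'
#' Rules are serialized with their full provenance (mapped source reaction,
#' direction, radius, designated product) so that [read_rules()] can
#' reconstruct them exactly.
#'
#' @param rules list of `rpe_rule`.
#' @param path output JSON path.
#' @export
write_rules <- function(rules, path) {
  doc <- lapply(rules, function(r) {
    list(rule_id = r$rule_id,
         source_reaction = r$source_reaction,
         direction = r$direction,
         radius = r$radius,
         pstar = r$pstar,
         reaction_smiles = reaction_smiles_of(r$rxn, mapped = TRUE),
         ec = r$rxn$ec_numbers,
         enzyme_name = r$rxn$enzyme_names,
         reversibility = r$rxn$reversibility,
         pattern = rule_pattern_string(r),
         signature = r$signature,
         co_reactants = vapply(r$co_reactants, function(m) m$canonical_smiles, ""),
         co_products = vapply(r$co_products, function(m) m$canonical_smiles, ""))
  })
  jsonlite::write_json(doc, path, auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(path)
}

#' Read rules back from JSON
#'
#' @param path JSON file written by [write_rules()].
#' @return list of `rpe_rule`.
#' @export
read_rules <- function(path) {
  doc <- jsonlite::read_json(path)
  lapply(doc, function(d) {
    rxn <- parse_reaction_smiles(d$reaction_smiles, id = d$source_reaction,
                                 reversibility = d$reversibility,
                                 ec_numbers = unlist(d$ec),
                                 enzyme_names = unlist(d$enzyme_name))
    rule <- extract_rule(rxn, direction = "as_written", radius = d$radius,
                         pstar = d$pstar)
    # restore identity fields tied to the original direction
    rule$rule_id <- d$rule_id
    rule$direction <- d$direction
    rule
  })
}
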