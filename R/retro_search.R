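# Iterative retrosynthesis: apply every rule to the current target, rank the
# candidate precursor reactions, recurse on the designated main precursor of
# each of the top-`beam` candidates until a known metabolic precursor is
# reached, then extract and replay linear routes.

#' Default ranking weights
#'
#' `reaction_in_db` dominates (a candidate identical to a reference reaction
#' outranks any novel one), followed by the fraction of candidate reactants
#' present in the database, followed by structural simplicity of the proposed
#' precursor; co-reactant frequency among mechanistically equivalent
#' reference reactions breaks remaining ties.
#'
#' @export
default_rank_weights <- function() {
  c(reaction_in_db = 4, reactant_in_db = 2, simplicity = 1)
}

# build all retro-applicable rule variants from a database
#' Extract the full rule pool of a database
#'
#' One primary rule per reaction and permitted direction (see
#' [rule_directions()]); each primary rule contributes one applicable pattern
#' variant per product-side molecule carrying reaction-center atoms. The
#' returned list holds all variants; `attr(, "n_rules")` is the primary rule
#' count (sum over reactions of permitted directions).
#'
#' @param db an `rpe_reaction_db`.
#' @param radius environment radius in bonds.
#' @param exclude_ids reaction ids to skip. The default excludes the
#'   database manifest's `default_retro_exclude` plus any reaction whose
#'   source field carries a `profile:ester` tag (esterifications are outside
#'   the default retro profile); pass `character(0)` to use every reaction.
#' @return list of `rpe_rule` with attribute `n_rules`.
#' @export
build_ruleset <- function(db, radius = 1L, exclude_ids = NULL) {
  if (is.null(exclude_ids)) {
    man <- attr(db, "manifest")
    exclude_ids <- if (!is.null(man)) man$default_retro_exclude else character(0)
    tagged <- vapply(db$reactions, function(r) {
      grepl("profile:ester", r$source, fixed = TRUE)
    }, TRUE)
    exclude_ids <- union(exclude_ids, names(db$reactions)[tagged])
  }
  rules <- list()
  n_primary <- 0L
  for (r in db$reactions) {
    if (r$id %in% exclude_ids) next
    for (dir in rule_directions(r)) {
      n_primary <- n_primary + 1L
      rules <- c(rules, extract_rules(r, dir, radius))
    }
  }
  attr(rules, "n_rules") <- n_primary
  rules
}

# score one candidate; returns the component breakdown
.score_candidate <- function(cand, db, precursors, weights, sigtab) {
  known_ids <- find_exact(cand$reaction, db)
  rin <- as.numeric(length(known_ids) > 0L)
  rs <- vapply(cand$reaction$reactants, function(m) m$canonical_smiles, "")
  frac <- mean(rs %in% c(db$compound_index, precursors))
  ht <- heavy_atom_count(cand$reaction$products[[1L]])
  hm <- heavy_atom_count(cand$reaction$reactants[[cand$main_idx]])
  simp <- ht / max(ht, hm)
  cof <- .cofactor_frequency(cand, db, sigtab)
  total <- weights[["reaction_in_db"]] * rin +
    weights[["reactant_in_db"]] * frac +
    weights[["simplicity"]] * simp
  list(reaction_in_db = rin, known_ids = known_ids, reactant_in_db = frac,
       simplicity = simp, cofactor_freq = cof, total = total,
       key = canonical_reaction_key(cand$reaction, "as_written"))
}

.rpe_cache <- new.env(parent = emptyenv())

# reference reactions grouped by center signature, per permitted direction;
# memoised on the set of reaction ids
.db_signature_table <- function(db) {
  key <- paste(names(db$reactions), collapse = "\r")
  cached <- .rpe_cache[[key]]
  if (!is.null(cached)) return(cached)
  rows <- list()
  for (r in db$reactions) {
    for (dir in rule_directions(r)) {
      orxn <- .orient(r, dir)
      sig <- tryCatch(center_signature(orxn), error = function(e) NA_character_)
      if (is.na(sig)) next
      rows[[length(rows) + 1L]] <- list(
        id = r$id, direction = dir, signature = sig,
        reactants = vapply(orxn$reactants, function(m) m$canonical_smiles, ""),
        ec = r$ec_numbers, enzyme = r$enzyme_names)
    }
  }
  .rpe_cache[[key]] <- rows
  rows
}

# occurrences of the candidate's co-reactant set among same-signature
# reference reactions
.cofactor_frequency <- function(cand, db, sigtab) {
  co <- vapply(cand$reaction$reactants[-cand$main_idx],
               function(m) m$canonical_smiles, "")
  if (!length(co)) co <- character(0)
  n <- 0L
  for (row in sigtab) {
    if (row$signature != cand$signature) next
    if (all(co %in% row$reactants)) n <- n + 1L
  }
  n
}

#' Rank candidate reactions
#'
#' Descending by the weighted total of: presence of the full candidate in
#' the database, fraction of reactants present in the database (or the
#' precursor set), and simplicity of the proposed main precursor
#' (heavy-atom ratio, 1 when the precursor is no larger than the target).
#' Ties break by co-reactant frequency (descending), then by canonical
#' reaction key — deterministic and stable across runs.
#'
#' @param cands list of candidates from [apply_retro()].
#' @param db an `rpe_reaction_db`.
#' @param precursors character vector of canonical precursor SMILES counted
#'   as "present" for the reactant score.
#' @param weights named numeric, see [default_rank_weights()].
#' @return the candidates, ordered, each with a `score` element attached.
#' @export
rank_candidates <- function(cands, db, precursors = character(0),
                            weights = default_rank_weights()) {
  if (!length(cands)) return(cands)
  sigtab <- .db_signature_table(db)
  scored <- lapply(cands, function(cd) {
    cd$score <- .score_candidate(cd, db, precursors, weights, sigtab)
    cd
  })
  keys <- vapply(scored, function(cd) cd$score$key, "")
  tot <- vapply(scored, function(cd) cd$score$total, 0)
  cof <- vapply(scored, function(cd) cd$score$cofactor_freq, 0L)
  scored[order(-tot, -cof, keys)]
}

#' Order cofactor variants by reference-reaction frequency
#'
#' For candidates that differ only in the co-reactant/co-product choice
#' (e.g. oxoglutarate- versus pyruvate-accepting transaminations), orders by
#' descending frequency of the co-reactant set among database reactions with
#' the same reaction-center signature; equal frequencies break by canonical
#' reaction key.
#'
#' @inheritParams rank_candidates
#' @return reordered candidate list with `cofactor_freq` attached.
#' @export
cofactor_preference <- function(cands, db) {
  if (length(cands) <= 1L) {
    if (length(cands) == 1L) {
      sigtab <- .db_signature_table(db)
      cands[[1L]]$cofactor_freq <- .cofactor_frequency(cands[[1L]], db, sigtab)
    }
    return(cands)
  }
  sigtab <- .db_signature_table(db)
  freq <- vapply(cands, .cofactor_frequency, 0L, db = db, sigtab = sigtab)
  keys <- vapply(cands, function(cd) {
    canonical_reaction_key(cd$reaction, "as_written")
  }, "")
  out <- cands[order(-freq, keys)]
  for (i in seq_along(out)) {
    out[[i]]$cofactor_freq <- sort(freq, decreasing = TRUE)[i]
  }
  out
}

#' Build a retrosynthesis tree
#'
#' Breadth-limited iterative retrosynthesis: at every node all rules are
#' applied retro to the node compound, candidates are deduplicated by
#' canonical reaction key and ranked, and the main precursor of each of the
#' top-`beam` candidates is recursed on. A compound already on the current
#' root path is never re-expanded; nodes at `max_depth` are marked
#' `depth_limited`.
#'
#' @param target an `rpe_molecule` (or SMILES string).
#' @param rules rule pool from [build_ruleset()].
#' @param db an `rpe_reaction_db`.
#' @param precursors character vector of known-precursor SMILES.
#' @param max_depth maximum number of retro steps (>= 0).
#' @param beam candidates expanded per node (>= 1).
#' @param weights ranking weights.
#' @return an `rpe_retro_node` tree. Node fields: `compound` (canonical
#'   SMILES), `status` (`precursor`, `expanded`, `dead_end`,
#'   `depth_limited`), `depth`, `candidates` (ranked; each with `score`,
#'   `novel`, `known_ids` and, for expanded entries, `child`).
#' @export
build_tree <- function(target, rules, db, precursors, max_depth = 6L,
                       beam = 5L, weights = default_rank_weights()) {
  stopifnot(max_depth >= 0L, beam >= 1L)
  if (is.character(target)) target <- parse_molecule(target)
  prec <- vapply(precursors, function(s) parse_molecule(s)$canonical_smiles, "")
  node <- .expand_node(target, rules, db, prec, depth = 0L,
                       path = character(0), max_depth = max_depth,
                       beam = beam, weights = weights)
  class(node) <- "rpe_retro_node"
  node
}

.expand_node <- function(mol, rules, db, prec, depth, path, max_depth, beam,
                         weights) {
  canon <- mol$canonical_smiles
  node <- list(compound = canon, depth = depth, candidates = list())
  if (canon %in% prec) {
    node$status <- "precursor"
    return(node)
  }
  if (depth >= max_depth) {
    node$status <- "depth_limited"
    return(node)
  }
  cands <- list()
  for (rule in rules) {
    cands <- c(cands, apply_retro(rule, mol))
  }
  if (length(cands)) {
    keys <- vapply(cands, function(cd) {
      canonical_reaction_key(cd$reaction, "as_written")
    }, "")
    cands <- cands[!duplicated(keys)]
  }
  if (!length(cands)) {
    node$status <- "dead_end"
    return(node)
  }
  ranked <- rank_candidates(cands, db, prec, weights)
  keep <- ranked[seq_len(min(beam, length(ranked)))]
  node$status <- "expanded"
  node$candidates <- lapply(keep, function(cd) {
    cd$novel <- cd$score$reaction_in_db == 0
    cd$known_ids <- cd$score$known_ids
    child_canon <- cd$main_precursor
    # stand-in for the manual selection step of the original procedure: a
    # novel (not-in-database) candidate is kept and ranked, but iterated on
    # only when all of its proposed reactants are known compounds -- a
    # predicted reaction that introduces a second unknown is never pursued
    pursue <- cd$score$reaction_in_db > 0 ||
      cd$score$reactant_in_db == 1 ||
      child_canon %in% prec
    if (child_canon %in% path) {
      cd$child <- list(compound = child_canon, depth = depth + 1L,
                       status = "dead_end", candidates = list(),
                       cycle = TRUE)
    } else if (!pursue) {
      cd$child <- list(compound = child_canon, depth = depth + 1L,
                       status = "dead_end", candidates = list(),
                       pruned = "unsupported_precursor")
    } else {
      child_mol <- cd$reaction$reactants[[cd$main_idx]]
      cd$child <- .expand_node(child_mol, rules, db, prec, depth + 1L,
                               c(path, canon), max_depth, beam, weights)
    }
    cd
  })
  node
}

#' @export
print.rpe_retro_node <- function(x, ...) {
  rec <- function(node, indent) {
    cat(indent, node$compound, " [", node$status, "]\n", sep = "")
    for (cd in node$candidates) {
      cat(indent, "  <- ", cd$main_precursor,
          " (", cd$rule_id,
          if (isTRUE(cd$novel)) ", novel" else ", known", ")\n", sep = "")
      if (!is.null(cd$child)) rec(cd$child, paste0(indent, "    "))
    }
  }
  rec(x, "")
  invisible(x)
}

#' Extract linear routes from a retrosynthesis tree
#'
#' All distinct root paths terminating at a precursor node, each reported
#' precursor-to-target, deduplicated by the ordered sequence of canonical
#' reaction keys and sorted by (length, aggregate rank score descending,
#' key sequence).
#'
#' @param tree an `rpe_retro_node`.
#' @return list of `rpe_route`: `steps` (candidate entries, precursor side
#'   first), `length`, `precursor`, `target`.
#' @export
extract_routes <- function(tree) {
  routes <- list()
  walk <- function(node, steps) {
    if (node$status == "precursor" && length(steps)) {
      r <- list(steps = rev(steps), length = length(steps),
                precursor = node$compound,
                target = steps[[1L]]$reaction$products[[1L]]$canonical_smiles)
      class(r) <- "rpe_route"
      routes[[length(routes) + 1L]] <<- r
      return(invisible(NULL))
    }
    for (cd in node$candidates) {
      if (!is.null(cd$child)) walk(cd$child, c(steps, list(cd)))
    }
    invisible(NULL)
  }
  walk(tree, list())
  if (!length(routes)) return(routes)
  keyseq <- vapply(routes, function(r) {
    paste(vapply(r$steps, function(s) s$score$key, ""), collapse = " | ")
  }, "")
  routes <- routes[!duplicated(keyseq)]
  keyseq <- keyseq[!duplicated(keyseq)]
  lens <- vapply(routes, function(r) r$length, 0L)
  agg <- vapply(routes, function(r) {
    sum(vapply(r$steps, function(s) s$score$total, 0))
  }, 0)
  routes[order(lens, -agg, keyseq)]
}

#' Replay a route in the forward direction
#'
#' Verifies route integrity: starting from the precursor, the main product
#' of every step must equal the main reactant of the following step, every
#' step must balance, and the last step must regenerate the route target.
#'
#' @param route an `rpe_route`.
#' @return the target `rpe_molecule`.
#' @export
replay_forward <- function(route) {
  if (!inherits(route, "rpe_route") || !length(route$steps)) {
    stop("route integrity error: empty route")
  }
  current <- route$steps[[1L]]$reaction$reactants[[route$steps[[1L]]$main_idx]]
  if (current$canonical_smiles != route$precursor) {
    stop("route integrity error: first step does not start at the precursor")
  }
  for (i in seq_along(route$steps)) {
    step <- route$steps[[i]]$reaction
    main_in <- step$reactants[[route$steps[[i]]$main_idx]]
    if (main_in$canonical_smiles != current$canonical_smiles) {
      stop("route integrity error: step ", i,
           " reactant does not match the previous product")
    }
    if (!check_balance(step, 0L)$balanced &&
        !check_balance(step, 2L)$balanced) {
      stop("route integrity error: step ", i, " is unbalanced")
    }
    current <- step$products[[1L]]
  }
  if (current$canonical_smiles != route$target) {
    stop("route integrity error: forward replay does not reach the target")
  }
  current
}

#' @export
print.rpe_route <- function(x, ...) {
  cat("<rpe_route> ", x$length, " step(s): ", x$precursor, " -> ... -> ",
      x$target, "\n", sep = "")
  for (i in seq_along(x$steps)) {
    s <- x$steps[[i]]
    cat("  ", i, ". ", canonical_reaction_key(s$reaction), "  [",
        if (isTRUE(s$novel)) "novel" else paste("ref:", paste(s$known_ids, collapse = ",")),
        "]\n", sep = "")
  }
  invisible(x)
}
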