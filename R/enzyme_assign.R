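# Enzyme assignment for predicted reactions: candidate enzymes from
# reference-reaction annotations and center-signature inference, then
# phylogenetic assessment — p-distances, neighbor-joining, bootstrap
# supports, species-overlap duplication/speciation labeling, and ortholog
# verdicts for a target organism.

#' Candidate enzymes for a selected candidate reaction
#'
#' Enzymes annotated on the rule's source reaction (evidence
#' `reference_reaction`) plus enzymes of every other database reaction whose
#' reaction-center signature matches the rule (evidence `rule_inference`),
#' deduplicated by (EC, name).
#'
#' @param selected a candidate from [apply_retro()] (or a tree/route step).
#' @param db an `rpe_reaction_db`.
#' @return data.frame with columns ec, name, source_reaction, evidence.
#' @export
candidate_enzymes <- function(selected, db) {
  src_id <- selected$source_reaction
  if (is.null(db$reactions[[src_id]])) {
    stop("rule source reaction '", src_id, "' not present in the database")
  }
  rows <- list()
  add <- function(ec, name, src, ev) {
    n <- max(length(ec), length(name))
    if (n == 0L) return(invisible(NULL))
    ec <- c(ec, rep("", n - length(ec)))
    name <- c(name, rep("", n - length(name)))
    for (i in seq_len(n)) {
      rows[[length(rows) + 1L]] <<- data.frame(
        ec = ec[i], name = name[i], source_reaction = src, evidence = ev,
        stringsAsFactors = FALSE)
    }
  }
  src <- db$reactions[[src_id]]
  add(src$ec_numbers, src$enzyme_names, src_id, "reference_reaction")
  for (row in .db_signature_table(db)) {
    if (row$id == src_id) next
    if (row$signature != selected$signature) next
    add(row$ec, row$enzyme, row$id, "rule_inference")
  }
  if (!length(rows)) {
    return(data.frame(ec = character(0), name = character(0),
                      source_reaction = character(0), evidence = character(0),
                      stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, rows)
  out[!duplicated(paste(out$ec, out$name, sep = "\r")), , drop = FALSE]
}

# ---- distances ----

#' Pairwise p-distances from an alignment
#'
#' Distance = mismatches / shared non-gap columns, over the columns where
#' both sequences have a residue. Taxa are ordered lexicographically by
#' label, which makes downstream tree construction invariant to input order.
#'
#' @param aligned named character vector of equal-length aligned sequences
#'   (gaps as `-`), length >= 2.
#' @return symmetric distance matrix with zero diagonal.
#' @export
p_distances <- function(aligned) {
  if (length(aligned) < 2L) stop("need at least 2 sequences")
  if (is.null(names(aligned)) || anyDuplicated(names(aligned))) {
    stop("sequences must carry unique names")
  }
  lens <- nchar(aligned)
  if (length(unique(lens)) != 1L) {
    stop("ragged alignment: sequence lengths differ (",
         paste(unique(lens), collapse = ", "), ")")
  }
  aligned <- aligned[order(names(aligned))]
  n <- length(aligned)
  chars <- lapply(aligned, function(s) strsplit(s, "")[[1]])
  d <- matrix(0, n, n, dimnames = list(names(aligned), names(aligned)))
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      a <- chars[[i]]; b <- chars[[j]]
      shared <- a != "-" & b != "-"
      ns <- sum(shared)
      if (ns == 0L) {
        stop("sequences '", names(aligned)[i], "' and '", names(aligned)[j],
             "' share no ungapped columns")
      }
      d[i, j] <- d[j, i] <- sum(a[shared] != b[shared]) / ns
    }
  }
  d
}

# ---- neighbor joining ----

#' Neighbor-joining tree
#'
#' Standard Saitou-Nei agglomeration on the Q-criterion with the
#' deterministic tie-break "smallest (i, j) pair" in the current matrix
#' order (taxa sorted by label). Negative branch lengths are clamped to
#' zero. Two taxa yield a two-tip tree whose path length equals their
#' distance.
#'
#' @param d square symmetric distance matrix with taxon labels.
#' @return an `rpe_gene_tree`: list with `phylo` (ape tree, rooted along the
#'   final join edge), plus empty `supports`/`events` slots.
#' @export
nj_tree <- function(d) {
  if (!is.matrix(d) || nrow(d) != ncol(d)) stop("distance matrix must be square")
  if (!isTRUE(all.equal(d, t(d), tolerance = 1e-12))) {
    stop("distance matrix must be symmetric")
  }
  n0 <- nrow(d)
  if (n0 < 2L) stop("need at least 2 taxa")
  labels <- rownames(d)
  if (is.null(labels)) labels <- paste0("t", seq_len(n0))

  # active working set: each entry is a temporary node id
  # tips get ids 1..n0; internal nodes get negative temporary ids
  active <- seq_len(n0)
  edges <- list()     # list of c(parent_tmp, child_tmp, length)
  next_int <- -1L
  D <- d

  while (length(active) > 2L) {
    n <- length(active)
    r <- rowSums(D)
    best <- NULL
    bestq <- Inf
    for (i in seq_len(n - 1L)) {
      for (j in (i + 1L):n) {
        q <- (n - 2) * D[i, j] - r[i] - r[j]
        if (q < bestq - 1e-12) { bestq <- q; best <- c(i, j) }
      }
    }
    i <- best[1]; j <- best[2]
    li <- D[i, j] / 2 + (r[i] - r[j]) / (2 * (n - 2))
    lj <- D[i, j] - li
    li <- max(0, li); lj <- max(0, lj)
    u <- next_int; next_int <- next_int - 1L
    edges[[length(edges) + 1L]] <- c(u, active[i], li)
    edges[[length(edges) + 1L]] <- c(u, active[j], lj)
    newd <- (D[i, ] + D[j, ] - D[i, j]) / 2
    keep <- setdiff(seq_len(n), c(i, j))
    D2 <- matrix(0, n - 1L, n - 1L)
    if (length(keep)) {
      D2[seq_along(keep), seq_along(keep)] <- D[keep, keep, drop = FALSE]
      D2[seq_along(keep), n - 1L] <- newd[keep]
      D2[n - 1L, seq_along(keep)] <- newd[keep]
    }
    D <- D2
    active <- c(active[keep], u)
  }
  # join the last two subtrees: root in the middle of the final edge
  lfin <- D[1, 2]
  root <- next_int
  edges[[length(edges) + 1L]] <- c(root, active[1], lfin / 2)
  edges[[length(edges) + 1L]] <- c(root, active[2], lfin / 2)

  # renumber: tips 1..n0 keep ids; internal tmp ids -> n0+1.. with the root
  # first (ape convention)
  tmp_ids <- unique(vapply(edges, function(e) e[1], 0))
  tmp_ids <- c(root, setdiff(tmp_ids, root))
  int_map <- stats::setNames(n0 + seq_along(tmp_ids), tmp_ids)
  conv <- function(x) if (x > 0) x else unname(int_map[as.character(x)])
  em <- t(vapply(edges, function(e) c(conv(e[1]), conv(e[2])), c(0, 0)))
  el <- vapply(edges, function(e) e[3], 0)
  phy <- list(edge = em, edge.length = el, tip.label = labels,
              Nnode = length(tmp_ids))
  class(phy) <- "phylo"
  phy <- ape::reorder.phylo(phy, "cladewise")
  gt <- list(phylo = phy, supports = NULL, events = NULL, species = NULL)
  class(gt) <- "rpe_gene_tree"
  gt
}

# ---- bipartitions ----

# canonical split keys for the internal edges of a tree (unrooted
# interpretation): each split is encoded by the sorted labels of the side
# NOT containing the alphabetically first taxon
tree_splits <- function(phy) {
  ntip <- length(phy$tip.label)
  ref <- sort(phy$tip.label)[1]
  desc <- .descendant_tips(phy)
  keys <- character(0)
  for (node in (ntip + 1L):(ntip + phy$Nnode)) {
    tips <- phy$tip.label[desc[[node]]]
    if (length(tips) <= 1L || length(tips) >= ntip - 1L) next  # trivial
    side <- if (ref %in% tips) setdiff(phy$tip.label, tips) else tips
    keys <- c(keys, paste(sort(side), collapse = "|"))
  }
  unique(keys)
}

# tip indices below each node (index = node id)
.descendant_tips <- function(phy) {
  ntip <- length(phy$tip.label)
  nnode <- ntip + phy$Nnode
  out <- vector("list", nnode)
  for (i in seq_len(ntip)) out[[i]] <- i
  po <- ape::reorder.phylo(phy, "postorder")
  for (k in seq_len(nrow(po$edge))) {
    par <- po$edge[k, 1]; child <- po$edge[k, 2]
    out[[par]] <- c(out[[par]], out[[child]])
  }
  out
}

#' Neighbor-joining tree with bootstrap supports
#'
#' `n` column resamples (with replacement) of the alignment; each replicate
#' is run through [p_distances()] and [nj_tree()], and the support of every
#' internal bipartition of the full-data tree is the percentage of
#' replicates containing it. Reproducible for a fixed seed; invariant to the
#' input order of sequences.
#'
#' @param aligned named character vector of aligned sequences.
#' @param n number of bootstrap replicates (>= 1).
#' @param seed integer RNG seed.
#' @return an `rpe_gene_tree` with `supports` (named by split key, percent)
#'   filled in.
#' @export
bootstrap_supports <- function(aligned, n = 1000L, seed = 1L) {
  stopifnot(n >= 1L)
  full <- nj_tree(p_distances(aligned))
  splits <- tree_splits(full$phylo)
  counts <- stats::setNames(rep(0L, length(splits)), splits)
  aligned <- aligned[order(names(aligned))]
  len <- unique(nchar(aligned))
  chars <- do.call(rbind, lapply(aligned, function(s) strsplit(s, "")[[1]]))
  old <- .Random.seed_get()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  used <- 0L
  for (b in seq_len(n)) {
    cols <- sample.int(len, len, replace = TRUE)
    rep_aln <- apply(chars[, cols, drop = FALSE], 1L, paste, collapse = "")
    names(rep_aln) <- names(aligned)
    rep_tree <- tryCatch(nj_tree(p_distances(rep_aln)),
                         error = function(e) NULL)
    if (is.null(rep_tree)) next
    used <- used + 1L
    rs <- tree_splits(rep_tree$phylo)
    hit <- splits %in% rs
    counts[hit] <- counts[hit] + 1L
  }
  full$supports <- if (used > 0L) round(100 * counts / used, 1) else counts
  full$n_bootstrap <- n
  full
}

# ---- event labeling and orthologs ----

# species-overlap labeling of a rooted tree; returns per-internal-node event
# vector and the leaf-set keys of duplication clades
.species_overlap_events <- function(phy, species_of_tip) {
  ntip <- length(phy$tip.label)
  desc <- .descendant_tips(phy)
  events <- stats::setNames(rep("none", phy$Nnode),
                            as.character((ntip + 1L):(ntip + phy$Nnode)))
  dup_keys <- character(0)
  for (node in (ntip + 1L):(ntip + phy$Nnode)) {
    kids <- phy$edge[phy$edge[, 1] == node, 2]
    sets <- lapply(kids, function(k) {
      unique(unname(species_of_tip[phy$tip.label[desc[[k]]]]))
    })
    dup <- FALSE
    if (length(sets) >= 2L) {
      for (a in seq_len(length(sets) - 1L)) {
        for (b in (a + 1L):length(sets)) {
          if (length(intersect(sets[[a]], sets[[b]]))) dup <- TRUE
        }
      }
    }
    events[as.character(node)] <- if (dup) "duplication" else "speciation"
    if (dup) {
      dup_keys <- c(dup_keys,
                    paste(sort(phy$tip.label[desc[[node]]]), collapse = "|"))
    }
  }
  list(events = events, dup_keys = dup_keys)
}

#' Label duplication and speciation events
#'
#' Roots the tree (midpoint by default, or at an outgroup tip) and applies
#' the species-overlap rule: an internal node is a duplication iff the
#' species sets of its child clades intersect, otherwise a speciation.
#'
#' @param gt an `rpe_gene_tree` (from [nj_tree()] / [bootstrap_supports()]).
#' @param species_map named character vector (tip label -> species id) or a
#'   data.frame with columns seq_id, species_id.
#' @param outgroup optional tip label to root on instead of midpoint.
#' @return the gene tree with `phylo` rooted and `events`/`species` filled.
#' @export
label_events <- function(gt, species_map, outgroup = NULL) {
  stopifnot(inherits(gt, "rpe_gene_tree"))
  if (is.data.frame(species_map)) {
    species_map <- stats::setNames(species_map$species_id, species_map$seq_id)
  }
  missing <- setdiff(gt$phylo$tip.label, names(species_map))
  if (length(missing)) {
    stop("no species mapping for sequence(s): ", paste(missing, collapse = ", "))
  }
  phy <- gt$phylo
  phy <- if (!is.null(outgroup)) {
    ape::root(phy, outgroup = outgroup, resolve.root = TRUE)
  } else {
    phangorn::midpoint(phy)
  }
  ev <- .species_overlap_events(phy, species_map)
  gt$phylo <- phy
  gt$events <- ev$events
  gt$duplication_clades <- ev$dup_keys
  gt$species <- species_map[phy$tip.label]
  gt
}

#' Ortholog verdict for a seed sequence in a target species
#'
#' Orthologs of the seed are the leaves connected to it through
#' speciation-only internal nodes of the labeled tree. When none of them
#' belongs to the target species the verdict is `none_found`, which
#' downgrades confidence in the associated predicted reaction.
#'
#' @param gt a labeled `rpe_gene_tree` (see [label_events()]).
#' @param seed_leaf tip label of the experimentally characterized enzyme.
#' @param target_species species id to search.
#' @param min_support optional minimum bootstrap support (percent) required
#'   on the internal nodes of the connecting path.
#' @return list with `verdict` (`"ortholog_found"` or `"none_found"`),
#'   `orthologs` (all speciation-connected leaves) and `in_target` (those of
#'   the target species).
#' @export
ortholog_verdict <- function(gt, seed_leaf, target_species,
                             min_support = NULL) {
  stopifnot(inherits(gt, "rpe_gene_tree"))
  if (is.null(gt$events)) stop("tree is not event-labeled; run label_events()")
  phy <- gt$phylo
  tips <- phy$tip.label
  if (!seed_leaf %in% tips) stop("seed leaf '", seed_leaf, "' not in tree")
  ntip <- length(tips)
  parent <- integer(ntip + phy$Nnode)
  for (k in seq_len(nrow(phy$edge))) parent[phy$edge[k, 2]] <- phy$edge[k, 1]

  path_to_root <- function(node) {
    p <- integer(0)
    while (parent[node] != 0L) { node <- parent[node]; p <- c(p, node) }
    p
  }
  seed_idx <- match(seed_leaf, tips)
  seed_anc <- path_to_root(seed_idx)
  ok_node <- function(node) {
    if (gt$events[[as.character(node)]] != "speciation") return(FALSE)
    if (!is.null(min_support) && !is.null(gt$supports)) {
      desc <- .descendant_tips(phy)
      tipset <- tips[desc[[node]]]
      if (length(tipset) > 1L && length(tipset) < ntip - 1L) {
        ref <- sort(tips)[1]
        side <- if (ref %in% tipset) setdiff(tips, tipset) else tipset
        key <- paste(sort(side), collapse = "|")
        s <- gt$supports[key]
        if (!is.na(s) && s < min_support) return(FALSE)
      }
    }
    TRUE
  }
  orth <- character(0)
  for (t in seq_len(ntip)) {
    if (t == seed_idx) next
    anc <- path_to_root(t)
    mrca <- intersect(seed_anc, anc)[1]
    onpath <- c(seed_anc[seq_len(match(mrca, seed_anc))],
                anc[seq_len(match(mrca, anc) - 1L)])
    onpath <- unique(onpath)
    if (all(vapply(onpath, ok_node, TRUE))) orth <- c(orth, tips[t])
  }
  in_target <- orth[unname(gt$species[orth]) == target_species]
  list(verdict = if (length(in_target)) "ortholog_found" else "none_found",
       orthologs = orth, in_target = in_target)
}

# ---- input/output ----

#' Read an (aligned) FASTA file
#'
#' @param path FASTA file.
#' @return named character vector of sequences.
#' @export
read_fasta <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  hdr <- grepl("^>", lines)
  if (!any(hdr)) stop("not a FASTA file: ", path)
  idx <- cumsum(hdr)
  nms <- sub("^>\\s*", "", lines[hdr])
  nms <- sub("\\s.*$", "", nms)
  seqs <- vapply(split(lines[!hdr], idx[!hdr]), paste, "", collapse = "")
  stats::setNames(toupper(unname(seqs)), nms)
}

#' Read a sequence-to-species map TSV
#'
#' Two columns (seq_id, species_id), with or without a header line.
#'
#' @param path TSV file.
#' @return named character vector (seq_id -> species_id).
#' @export
read_species_map <- function(path) {
  tab <- utils::read.delim(path, header = FALSE, colClasses = "character")
  if (ncol(tab) < 2L) stop("species map must have two columns: ", path)
  if (identical(tolower(tab[1, 1]), "seq_id")) tab <- tab[-1, , drop = FALSE]
  stats::setNames(tab[[2]], tab[[1]])
}

#' Write a labeled gene tree as newick with NHX event tags
#'
#' Bootstrap supports become internal node labels; duplication/speciation
#' labels are emitted as `[&&NHX:Ev=D]` / `[&&NHX:Ev=S]` comments.
#'
#' @param gt an `rpe_gene_tree`.
#' @param path output file.
#' @export
write_gene_tree <- function(gt, path) {
  phy <- gt$phylo
  ntip <- length(phy$tip.label)
  desc <- .descendant_tips(phy)
  kids_of <- function(node) phy$edge[phy$edge[, 1] == node, 2]
  len_of <- stats::setNames(phy$edge.length, phy$edge[, 2])
  ref <- sort(phy$tip.label)[1]
  sup_of <- function(node) {
    if (is.null(gt$supports)) return("")
    tipset <- phy$tip.label[desc[[node]]]
    if (length(tipset) <= 1L || length(tipset) >= ntip - 1L) return("")
    side <- if (ref %in% tipset) setdiff(phy$tip.label, tipset) else tipset
    s <- gt$supports[paste(sort(side), collapse = "|")]
    if (is.na(s)) "" else format(unname(s))
  }
  ev_of <- function(node) {
    if (is.null(gt$events)) return("")
    e <- gt$events[[as.character(node)]]
    if (is.null(e) || e == "none") return("")
    paste0("[&&NHX:Ev=", if (e == "duplication") "D" else "S", "]")
  }
  rec <- function(node) {
    if (node <= ntip) {
      lab <- phy$tip.label[node]
    } else {
      lab <- paste0("(", paste(vapply(kids_of(node), rec, ""), collapse = ","),
                    ")", sup_of(node))
    }
    br <- len_of[as.character(node)]
    paste0(lab,
           if (!is.na(br)) paste0(":", format(unname(br), digits = 10)),
           if (node > ntip) ev_of(node))
  }
  root <- setdiff(phy$edge[, 1], phy$edge[, 2])[1]
  writeLines(paste0(rec(root), ";"), path)
  invisible(path)
}

#' Global pairwise alignment (Needleman-Wunsch)
#'
#' Convenience aligner for distance estimation on unaligned pairs: match 1,
#' mismatch 0, linear gap -1. Not a substitute for a proper multiple
#' aligner; acceptance-grade analyses use pre-aligned input.
#'
#' @param a,b sequences (strings).
#' @return list with `a`, `b` (gapped strings) and `score`.
#' @export
align_pair <- function(a, b) {
  x <- strsplit(a, "")[[1]]; y <- strsplit(b, "")[[1]]
  n <- length(x); m <- length(y)
  S <- matrix(0, n + 1L, m + 1L)
  S[, 1] <- -(0:n); S[1, ] <- -(0:m)
  for (i in seq_len(n)) {
    for (j in seq_len(m)) {
      S[i + 1L, j + 1L] <- max(S[i, j] + (x[i] == y[j]),
                               S[i, j + 1L] - 1, S[i + 1L, j] - 1)
    }
  }
  ga <- character(0); gb <- character(0)
  i <- n; j <- m
  while (i > 0L || j > 0L) {
    if (i > 0L && j > 0L && S[i + 1L, j + 1L] == S[i, j] + (x[i] == y[j])) {
      ga <- c(x[i], ga); gb <- c(y[j], gb); i <- i - 1L; j <- j - 1L
    } else if (i > 0L && S[i + 1L, j + 1L] == S[i, j + 1L] - 1) {
      ga <- c(x[i], ga); gb <- c("-", gb); i <- i - 1L
    } else {
      ga <- c("-", ga); gb <- c(y[j], gb); j <- j - 1L
    }
  }
  list(a = paste(ga, collapse = ""), b = paste(gb, collapse = ""),
       score = S[n + 1L, m + 1L])
}

#' @export
print.rpe_gene_tree <- function(x, ...) {
  cat("<rpe_gene_tree> ", length(x$phylo$tip.label), " leaves",
      if (!is.null(x$supports)) paste0(", ", length(x$supports),
                                       " supported splits"),
      if (!is.null(x$events)) paste0(", ",
                                     sum(x$events == "duplication"),
                                     " duplication node(s)"), "\n", sep = "")
  invisible(x)
}
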