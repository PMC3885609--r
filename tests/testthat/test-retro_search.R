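# Candidate ranking, cofactor preference, tree building, route extraction
# and forward replay.

.kica_candidates <- function() {
  db <- fixture_db()
  mol <- parse_molecule(flavor_compound("kica"))
  cands <- list()
  for (rule in fixture_rules()) cands <- c(cands, apply_retro(rule, mol))
  keys <- vapply(cands, function(cd) canonical_reaction_key(cd$reaction), "")
  cands[!duplicated(keys)]
}

test_that("database-backed candidates outrank novel ones", {
  db <- fixture_db()
  ranked <- rank_candidates(.kica_candidates(), db)
  tot <- vapply(ranked, function(cd) cd$score$total, 0)
  expect_true(all(diff(tot) <= 1e-12))
  novel <- vapply(ranked, function(cd) cd$score$reaction_in_db == 0, TRUE)
  # every database-exact candidate precedes every novel candidate
  expect_true(max(which(!novel)) < min(which(novel)))
  # the top candidate is an exact reference reaction
  expect_identical(ranked[[1]]$score$reaction_in_db, 1)
  # all-else-equal, a candidate whose precursor is a known compound outranks
  # one whose precursor is unknown: compare the known-reactant fractions of
  # the best and worst novel candidates
  frac_novel <- vapply(ranked[novel], function(cd) cd$score$reactant_in_db, 0)
  if (length(frac_novel) > 1L) {
    expect_gte(frac_novel[1], frac_novel[length(frac_novel)])
  }
})

test_that("ranking is deterministic with key tie-breaks", {
  db <- fixture_db()
  cands <- .kica_candidates()
  k1 <- vapply(rank_candidates(cands, db), function(cd) cd$score$key, "")
  k2 <- vapply(rank_candidates(rev(cands), db), function(cd) cd$score$key, "")
  expect_identical(k1, k2)
})

test_that("cofactor_preference prefers oxoglutarate over pyruvate 3:1", {
  db <- fixture_db()
  cands <- .kica_candidates()
  # keep the two amino-acceptor variants: leucine + oxoglutarate / pyruvate
  is_tx <- vapply(cands, function(cd) {
    cd$main_precursor == flavor_compound("leucine") &&
      length(cd$reaction$reactants) == 2L &&
      cd$reaction$reactants[[2]]$canonical_smiles %in%
        c(flavor_compound("oxoglutarate"), flavor_compound("pyruvate"))
  }, TRUE)
  tx <- cands[is_tx]
  co <- vapply(tx, function(cd) cd$reaction$reactants[[2]]$canonical_smiles, "")
  expect_setequal(co, c(flavor_compound("oxoglutarate"),
                        flavor_compound("pyruvate")))
  ordered <- cofactor_preference(tx, db)
  expect_identical(ordered[[1]]$reaction$reactants[[2]]$canonical_smiles,
                   flavor_compound("oxoglutarate"))
  expect_identical(ordered[[1]]$cofactor_freq, 3L)
  expect_identical(ordered[[2]]$cofactor_freq, 1L)
  # single candidate passes through unchanged
  one <- cofactor_preference(tx[1], db)
  expect_length(one, 1L)
})

test_that("a target that is already a precursor yields a single precursor node", {
  db <- fixture_db()
  tree <- build_tree(flavor_compound("leucine"), fixture_rules(), db,
                     flavor_compound("leucine"), max_depth = 4L)
  expect_identical(tree$status, "precursor")
  expect_length(tree$candidates, 0L)
  expect_length(extract_routes(tree), 0L)
})

test_that("the leucine -> 3-methylbutanol route is recovered and replays", {
  db <- fixture_db()
  tree <- build_tree(flavor_compound("methylbutanol"), fixture_rules(), db,
                     flavor_compound("leucine"), max_depth = 4L, beam = 5L)
  routes <- extract_routes(tree)
  expect_gt(length(routes), 0L)
  best <- routes[[1]]
  expect_identical(best$length, 3L)
  expect_identical(vapply(best$steps, function(s) s$source_reaction, ""),
                   c("R_BCAT_LEU", "R_KDCA_KICA", "R_ALCDH"))
  inter <- vapply(best$steps, function(s)
    s$reaction$products[[1]]$canonical_smiles, "")
  expect_identical(inter, c(flavor_compound("kica"),
                            flavor_compound("methylbutanal"),
                            flavor_compound("methylbutanol")))
  out <- replay_forward(best)
  expect_identical(out$canonical_smiles, flavor_compound("methylbutanol"))
})

test_that("3-methylbutanoic acid yields exactly the three reference routes", {
  db <- fixture_db()
  tree <- build_tree(flavor_compound("methylbutanoate"), fixture_rules(), db,
                     flavor_compound("kica"), max_depth = 4L, beam = 5L)
  routes <- extract_routes(tree)
  expect_length(routes, 3L)
  via <- vapply(routes, function(r) {
    paste(vapply(r$steps, function(s) s$source_reaction, ""), collapse = ">")
  }, "")
  expect_setequal(via, c("R_KDCA_KICA>R_ALDDH",
                         "R_HYCDH>R_LMO",
                         "R_KADH>R_PTA>R_ACK"))
  for (r in routes) {
    expect_identical(r$precursor, flavor_compound("kica"))
    expect_identical(replay_forward(r)$canonical_smiles,
                     flavor_compound("methylbutanoate"))
  }
  # the HICA route's acid-forming step is the novel monooxygenase analogy
  hica_route <- routes[[which(via == "R_HYCDH>R_LMO")]]
  expect_true(hica_route$steps[[2]]$novel)
  expect_false(hica_route$steps[[1]]$novel)
})

test_that("the novel KICA + O2 reaction is proposed for 2-methylpropanal", {
  db <- fixture_db()
  tree <- build_tree(flavor_compound("methylpropanal"), fixture_rules(), db,
                     c(flavor_compound("valine"), flavor_compound("leucine")),
                     max_depth = 2L, beam = 5L)
  mains <- vapply(tree$candidates, function(cd) cd$main_precursor, "")
  novel <- vapply(tree$candidates, function(cd) isTRUE(cd$novel), TRUE)
  i_kiv <- which(mains == flavor_compound("kiv"))
  i_kica <- which(mains == flavor_compound("kica"))
  expect_length(i_kiv, 1L)
  expect_length(i_kica, 1L)
  expect_false(novel[i_kiv])                       # exact database match
  expect_identical(tree$candidates[[i_kiv]]$known_ids, "R_KDCA_KIV")
  expect_true(novel[i_kica])                       # unrevealed chemistry
  expect_identical(tree$candidates[[i_kica]]$source_reaction, "R_KMBA_OX")
  expect_setequal(reactant_smiles(tree$candidates[[i_kica]]$reaction),
                  c(flavor_compound("kica"), csmiles("O=O")))
  expect_setequal(product_smiles(tree$candidates[[i_kica]]$reaction),
                  c(flavor_compound("methylpropanal"),
                    flavor_compound("oxalate")))
})

test_that("DMS retro proposes methanethiol + S-AdoMet at top rank", {
  db <- fixture_db()
  tree <- build_tree(flavor_compound("dms"), fixture_rules(), db,
                     flavor_compound("methionine"), max_depth = 3L, beam = 5L)
  top <- tree$candidates[[1]]
  expect_identical(top$main_precursor, flavor_compound("methanethiol"))
  expect_true(csmiles(rpe:::.SAM) %in% reactant_smiles(top$reaction))
  expect_true(top$novel)
})

test_that("search is deterministic and depth/beam behave monotonically", {
  db <- fixture_db()
  run <- function(depth, beam) {
    tree <- build_tree(flavor_compound("methylbutanoate"), fixture_rules(),
                       db, flavor_compound("kica"), max_depth = depth,
                       beam = beam)
    vapply(extract_routes(tree), function(r) {
      paste(vapply(r$steps, function(s) s$score$key, ""), collapse = "|")
    }, "")
  }
  expect_identical(run(4L, 5L), run(4L, 5L))
  # deeper search never loses routes
  expect_true(all(run(3L, 5L) %in% run(4L, 5L)))
  expect_true(all(run(4L, 5L) %in% run(5L, 5L)))
  # a wide beam agrees with the default beam on the top candidates
  t_wide <- build_tree(flavor_compound("methylbutanoate"), fixture_rules(),
                       db, flavor_compound("kica"), max_depth = 2L, beam = 50L)
  t_k <- build_tree(flavor_compound("methylbutanoate"), fixture_rules(),
                    db, flavor_compound("kica"), max_depth = 2L, beam = 2L)
  keys_wide <- vapply(t_wide$candidates, function(cd) cd$score$key, "")
  keys_k <- vapply(t_k$candidates, function(cd) cd$score$key, "")
  expect_identical(keys_wide[1:2], keys_k)
})

test_that("routes never revisit compounds and replay catches corruption", {
  db <- fixture_db()
  tree <- build_tree(flavor_compound("methylbutanol"), fixture_rules(), db,
                     flavor_compound("leucine"), max_depth = 4L, beam = 5L)
  for (r in extract_routes(tree)) {
    comps <- c(r$precursor, vapply(r$steps, function(s)
      s$reaction$products[[1]]$canonical_smiles, ""))
    expect_identical(anyDuplicated(comps), 0L)
    expect_identical(replay_forward(r)$canonical_smiles, r$target)
  }
  # empty / corrupted routes error
  expect_error(replay_forward(structure(list(steps = list()),
                                        class = "rpe_route")),
               "empty route")
  good <- extract_routes(tree)[[1]]
  bad <- good
  bad$steps <- bad$steps[c(1, 3)]   # drop the middle step
  expect_error(replay_forward(bad), "route integrity")
})
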