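# Candidate enzymes, p-distances, neighbor joining (with brute-force
# topology oracle), bootstrap supports, event labeling, ortholog verdicts.

test_that("candidate_enzymes pulls reference and rule-inference evidence", {
  db <- fixture_db()
  # HICA -> 3-methylbutanoic acid candidate from the lactate monooxygenase rule
  lmo_rule <- extract_rule(db$reactions[["R_LMO"]], "as_written", 1L)
  cand <- apply_retro(lmo_rule, parse_molecule(flavor_compound("methylbutanoate")))[[1]]
  enz <- candidate_enzymes(cand, db)
  expect_true("lactate 2-monooxygenase" %in% enz$name)
  expect_true("1.13.12.4" %in% enz$ec)
  expect_identical(enz$evidence[enz$name == "lactate 2-monooxygenase"],
                   "reference_reaction")

  # DMS candidate: methylation references plus same-signature TMT inference
  meth_rule <- extract_rule(db$reactions[["R_METH"]], "as_written", 1L)
  dms_cand <- apply_retro(meth_rule, parse_molecule("CSC"))[[1]]
  enz2 <- candidate_enzymes(dms_cand, db)
  expect_true(all(c("2.1.1.10", "2.1.1.13", "2.1.1.9") %in% enz2$ec))
  expect_identical(unique(enz2$evidence[enz2$ec == "2.1.1.9"]),
                   "rule_inference")

  # purely chemical reference: no enzymes anywhere with that signature
  kmba_rule <- extract_rule(db$reactions[["R_KMBA_OX"]], "as_written", 1L)
  chem_cand <- apply_retro(kmba_rule,
                           parse_molecule(flavor_compound("methylpropanal")))[[1]]
  expect_identical(nrow(candidate_enzymes(chem_cand, db)), 0L)
})

test_that("p_distances implements mismatches over shared columns", {
  expect_equal(p_distances(c(a = "ACDEFG", b = "ACDEFG"))["a", "b"], 0)
  expect_equal(p_distances(c(a = "ACDEFG", b = "ACDEFY"))["a", "b"], 1 / 6)
  # gaps shrink the shared denominator
  d <- p_distances(c(a = "AC-EFG", b = "ACDEFY"))
  expect_equal(d["a", "b"], 1 / 5)
  expect_error(p_distances(c(a = "ACGT", b = "ACG")), "ragged")
  expect_error(p_distances(c(a = "AC--", b = "--GT")), "no ungapped")
  expect_error(p_distances(c(a = "ACGT")), "at least 2")
  # taxa are returned in label order regardless of input order
  d2 <- p_distances(c(z = "AAAA", a = "AATA", m = "AAAA"))
  expect_identical(rownames(d2), c("a", "m", "z"))
})

test_that("NJ recovers 4-taxon additive topologies (vs exhaustive LS oracle)", {
  tr <- ape::read.tree(text = "((a:1,b:2):1,(c:3,d:1):2);")
  d <- ape::cophenetic.phylo(tr)
  d <- d[order(rownames(d)), order(colnames(d))]
  gt <- nj_tree(d)
  # oracle: enumerate all 3 unrooted topologies, the additive one fits with
  # zero residual and must be unique
  topos <- oracle_all_topologies(4L)
  expect_length(topos, 3L)
  res <- vapply(topos, oracle_ls_residual, 0, d = d)
  expect_identical(sum(res < 1e-9), 1L)
  best <- topos[[which.min(res)]]
  expect_identical(oracle_phylo_splits(gt$phylo),
                   oracle_topology_splits(best, rownames(d)))
})

test_that("NJ recovers generating topologies on additive matrices up to n = 8", {
  # exhaustive topology enumeration up to n = 7 (945 topologies); for n = 8
  # the generating tree itself is the oracle (an exactly additive matrix
  # fits its generating topology with zero residual, uniquely; enumerating
  # the 10,395 eight-taxon topologies buys no extra discrimination)
  for (n in 4:7) {
    for (seed in if (n < 7) 1:3 else 1L) {
      oa <- oracle_random_additive(n, seed = 100 * n + seed)
      gt <- nj_tree(oa$d)
      topos <- oracle_all_topologies(n)
      res <- vapply(topos, oracle_ls_residual, 0, d = oa$d)
      best <- topos[[which.min(res)]]
      expect_lt(min(res), 1e-9)
      expect_identical(oracle_phylo_splits(gt$phylo),
                       oracle_topology_splits(best, rownames(oa$d)),
                       info = paste("n", n, "seed", seed))
    }
  }
  for (n in 7:8) {
    for (seed in 2:4) {
      oa <- oracle_random_additive(n, seed = 100 * n + seed)
      gt <- nj_tree(oa$d)
      expect_identical(oracle_phylo_splits(gt$phylo),
                       oracle_phylo_splits(oa$phy),
                       info = paste("n", n, "seed", seed))
    }
  }
})

test_that("NJ handles the degenerate and tie cases deterministically", {
  d2 <- matrix(c(0, 3, 3, 0), 2, 2, dimnames = list(c("a", "b"), c("a", "b")))
  g2 <- nj_tree(d2)
  expect_equal(sum(g2$phylo$edge.length), 3)   # single edge of length d12
  # ultrametric 3-taxon: the close pair joins first (smallest-pair tie-break)
  d3 <- matrix(c(0, 2, 6, 2, 0, 6, 6, 6, 0), 3, 3,
               dimnames = list(c("a", "b", "c"), c("a", "b", "c")))
  g3 <- nj_tree(d3)
  desc <- rpe:::.descendant_tips(g3$phylo)
  sibs <- Filter(function(s) length(s) == 2L, desc[-(1:3)])
  expect_true(any(vapply(sibs, function(s) {
    setequal(g3$phylo$tip.label[s], c("a", "b"))
  }, TRUE)))
  # asymmetric matrices are rejected
  bad <- d3; bad[1, 2] <- 5
  expect_error(nj_tree(bad), "symmetric")
  expect_error(nj_tree(matrix(0, 1, 1)), "at least 2")
})

test_that("bootstrap supports are deterministic, bounded and order-invariant", {
  fam <- simulate_protein_family(
    "((a_s1:1,b_s2:1):2,(c_s3:1,d_s4:1):2);", 120, 0.08, seed = 5)
  gt1 <- bootstrap_supports(fam$alignment, n = 50, seed = 9)
  gt2 <- bootstrap_supports(fam$alignment, n = 50, seed = 9)
  expect_identical(gt1$supports, gt2$supports)
  gt3 <- bootstrap_supports(rev(fam$alignment), n = 50, seed = 9)
  expect_identical(gt1$supports, gt3$supports)
  expect_true(all(gt1$supports >= 0 & gt1$supports <= 100))
  # n = 1 can only produce 0 or 100
  g1 <- bootstrap_supports(fam$alignment, n = 1, seed = 3)
  expect_true(all(g1$supports %in% c(0, 100)))
  # an alignment whose every column supports the same split: support 100
  aln <- c(a = strrep("A", 50), b = strrep("A", 50),
           c = strrep("W", 50), d = strrep("W", 50))
  gperf <- bootstrap_supports(aln, n = 25, seed = 1)
  expect_identical(unname(gperf$supports[["c|d"]]), 100)
})

test_that("species-overlap labeling matches hand-evaluated cases", {
  # two gene copies in two species: duplication at the root, speciations below
  gt <- nj_tree(p_distances(c(a_sp1 = "AAAAAAAAAA", a_sp2 = "AAAAAAAATT",
                              b_sp1 = "WWWWWWWWGG", b_sp2 = "WWWWWWWWCC")))
  lab <- label_events(gt, c(a_sp1 = "sp1", a_sp2 = "sp2",
                            b_sp1 = "sp1", b_sp2 = "sp2"))
  ev <- unname(lab$events)
  expect_identical(sum(ev == "duplication"), 1L)
  root <- setdiff(lab$phylo$edge[, 1], lab$phylo$edge[, 2])[1]
  expect_identical(lab$events[[as.character(root)]], "duplication")

  # one copy per species, congruent with the species tree: all speciation
  gt2 <- nj_tree(p_distances(c(g_sp1 = "AAAAAAAAAA", g_sp2 = "AAAAAAAATT",
                               g_sp3 = "AAAAWWWWWW", g_sp4 = "TTAAWWWWWW")))
  lab2 <- label_events(gt2, c(g_sp1 = "sp1", g_sp2 = "sp2",
                              g_sp3 = "sp3", g_sp4 = "sp4"))
  expect_true(all(lab2$events == "speciation"))

  # ((a_sp1, b_sp1), c_sp2): overlap at the cherry, speciation at the root
  phy <- ape::read.tree(text = "((a_sp1:1,b_sp1:1):1,c_sp2:2);")
  ev3 <- rpe:::.species_overlap_events(
    phy, c(a_sp1 = "sp1", b_sp1 = "sp1", c_sp2 = "sp2"))
  cherry <- ape::getMRCA(phy, c("a_sp1", "b_sp1"))
  root3 <- ape::getMRCA(phy, c("a_sp1", "c_sp2"))
  expect_identical(ev3$events[[as.character(cherry)]], "duplication")
  expect_identical(ev3$events[[as.character(root3)]], "speciation")

  expect_error(label_events(gt2, c(g_sp1 = "sp1")), "no species mapping")
})

test_that("ortholog verdicts follow speciation-only connectivity", {
  fam <- simulate_protein_family(
    "((a_s1:1,(a_s2:1,a_s3:1):1):4,(b_s1:1,(b_s2:1,b_s3:1):1):4);",
    300, 0.05, seed = 21)
  gt <- label_events(nj_tree(p_distances(fam$alignment)), fam$species_map)
  v <- ortholog_verdict(gt, "a_s1", "s3")
  expect_identical(v$verdict, "ortholog_found")
  expect_setequal(v$orthologs, c("a_s2", "a_s3"))  # b copies sit across the dup
  # the b-copy of s3 is only reachable through the duplication node
  expect_false("b_s3" %in% v$orthologs)
  v2 <- ortholog_verdict(gt, "a_s1", "s99")
  expect_identical(v2$verdict, "none_found")
  expect_error(ortholog_verdict(gt, "nope", "s1"), "not in tree")
  # single-species tree, different target species
  gt1 <- label_events(nj_tree(p_distances(c(x_s1 = "AAAA", y_s1 = "AATT"))),
                      c(x_s1 = "s1", y_s1 = "s1"))
  expect_identical(ortholog_verdict(gt1, "x_s1", "s2")$verdict, "none_found")
})

test_that("duplication count respects the per-species copy-number bound", {
  # pigeonhole: a species with k copies forces >= k-1 duplications
  set.seed(33)
  for (rep in 1:10) {
    ncop <- sample(2:3, 1)
    tips <- character(0)
    for (sp in paste0("s", 1:3)) {
      for (k in seq_len(ncop)) tips <- c(tips, paste0("g", k, "_", sp))
    }
    tree <- ape::rtree(length(tips), tip.label = sample(tips))
    fam <- simulate_protein_family(tree, 200, 0.05, seed = rep)
    gt <- label_events(nj_tree(p_distances(fam$alignment)), fam$species_map)
    ndup <- sum(gt$events == "duplication")
    expect_gte(ndup, ncop - 1L)
  }
})

test_that("duplication labeling recovers the truth on simulated families", {
  # known gene tree: one ancient duplication (long stem), three species per
  # copy; >= 95 of 100 seeded replicates must label exactly the true set
  newick <- "((g1_s1:1,(g1_s2:1,g1_s3:1):1):4,(g2_s1:1,(g2_s2:1,g2_s3:1):1):4);"
  ok <- 0L
  for (seed in 1:100) {
    fam <- simulate_protein_family(newick, 300, 0.05, seed = seed)
    gt <- label_events(nj_tree(p_distances(fam$alignment)), fam$species_map)
    got <- sort(gt$duplication_clades)
    if (identical(got, sort(fam$true_duplications))) ok <- ok + 1L
  }
  expect_gte(ok, 95L)
})

test_that("simulated families behave as stated", {
  nwk <- "((a_s1:1,b_s2:1):1,(c_s3:1,d_s4:1):1);"
  f0 <- simulate_protein_family(nwk, 100, 0, seed = 1)
  expect_length(unique(f0$alignment), 1L)         # rate 0: identical leaves
  d0 <- p_distances(f0$alignment)
  expect_true(all(d0 == 0))
  f1 <- simulate_protein_family(nwk, 100, 0.05, seed = 7)
  f2 <- simulate_protein_family(nwk, 100, 0.05, seed = 7)
  expect_identical(f1$alignment, f2$alignment)    # seed-stable
  # NJ on p-distances recovers the generating topology >= 19/20 seeds
  hits <- 0L
  for (seed in 1:20) {
    fam <- simulate_protein_family(nwk, 500, 0.05, seed = seed)
    gt <- nj_tree(p_distances(fam$alignment))
    truth <- ape::read.tree(text = nwk)
    if (identical(oracle_phylo_splits(gt$phylo), oracle_phylo_splits(truth))) {
      hits <- hits + 1L
    }
  }
  expect_gte(hits, 19L)
})

test_that("gene trees are written as newick with NHX event tags", {
  fam <- simulate_protein_family(
    "((g1_s1:1,(g1_s2:1,g1_s3:1):1):4,(g2_s1:1,(g2_s2:1,g2_s3:1):1):4);",
    200, 0.05, seed = 2)
  gt <- label_events(bootstrap_supports(fam$alignment, n = 20, seed = 4),
                     fam$species_map)
  path <- withr::local_tempfile(fileext = ".nwk")
  write_gene_tree(gt, path)
  txt <- readLines(path)
  expect_match(txt, "\\[&&NHX:Ev=D\\]")
  expect_match(txt, "\\[&&NHX:Ev=S\\]")
  # strip NHX tags: ape must be able to read the remainder
  plain <- gsub("\\[&&NHX:Ev=[DS]\\]", "", txt)
  phy <- ape::read.tree(text = plain)
  expect_setequal(phy$tip.label, names(fam$alignment))
})

test_that("pairwise global alignment scores and gaps behave", {
  al <- align_pair("ACGT", "ACGT")
  expect_identical(al$score, 4)
  expect_identical(al$a, "ACGT")
  al2 <- align_pair("ACGT", "AGT")
  expect_identical(nchar(al2$a), nchar(al2$b))
  expect_identical(gsub("-", "", al2$b), "AGT")
  expect_identical(al2$score, 2)  # 3 matches - 1 gap
})
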