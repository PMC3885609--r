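# Deterministic fixtures: the flavor-forming reaction network of
# branched-chain and sulfur amino acid catabolism in lactic acid bacteria
# (transaminations, keto-acid decarboxylation / oxidative decarboxylation,
# aldehyde/alcohol/hydroxyacid dehydrogenases, acyl transfer and kinase
# steps, the lactate 2-monooxygenase reference reaction, the chemical
# keto-acid oxidation, C-S lyase elimination and S-methylations), fully
# atom-mapped and stoichiometrically balanced with protons written
# explicitly; plus simulated protein families with known gene trees for the
# ortholog-inference machinery.
#
# Structures are PubChem-derived SMILES embedded as literals (stereo
# dropped, Kekulé rings, neutral protonated acids/phosphates). Atom-map
# conventions: main-compound skeletons use maps < 100 (hand-assigned so that
# mechanistically corresponding atoms share numbers across reactions);
# cofactors are auto-numbered from fixed offsets (ADP/ATP 600+, transferred
# phosphoryl 651+, S-adenosyl compounds 700+, CoA 800+, NAD 900+).

# ---- compound SMILES (unmapped reference forms) ----

.FLAVOR_COMPOUNDS <- c(
  leucine                 = "CC(C)CC(N)C(=O)O",
  valine                  = "CC(C)C(N)C(=O)O",
  isoleucine              = "CCC(C)C(N)C(=O)O",
  methionine              = "CSCCC(N)C(=O)O",
  homocysteine            = "SCCC(N)C(=O)O",
  alanine                 = "CC(N)C(=O)O",
  glutamate               = "OC(=O)CCC(N)C(=O)O",
  oxoglutarate            = "OC(=O)CCC(=O)C(=O)O",
  pyruvate                = "CC(=O)C(=O)O",
  kica                    = "CC(C)CC(=O)C(=O)O",
  kiv                     = "CC(C)C(=O)C(=O)O",
  kmva                    = "CCC(C)C(=O)C(=O)O",
  kmba                    = "CSCCC(=O)C(=O)O",
  hica                    = "CC(C)CC(O)C(=O)O",
  oxobutanoate            = "CCC(=O)C(=O)O",
  lactate                 = "CC(O)C(=O)O",
  acetate                 = "CC(=O)O",
  methylbutanal           = "CC(C)CC=O",
  methylbutanol           = "CC(C)CCO",
  methylbutanoate         = "CC(C)CC(=O)O",
  methylpropanal          = "CC(C)C=O",
  oxalate                 = "OC(=O)C(=O)O",
  mtac                    = "CSCC=O",
  methanethiol            = "CS",
  dms                     = "CSC",
  ethanethiol             = "CCS",
  ethylmethylsulfide      = "CCSC",
  isovaleryl_coa          = NA,  # built from the CoA template below
  isovaleryl_phosphate    = "CC(C)CC(=O)OP(=O)(O)O",
  methylbutyl_acetate     = "CC(=O)OCCC(C)C",
  co2                     = "O=C=O",
  o2                      = "O=O",
  water                   = "O",
  ammonia                 = "N",
  proton                  = "[H+]",
  phosphate               = "OP(=O)(O)O"
)

# cofactor templates; NAD+/NADH (and SAM/SAH, ADP/ATP, CoA/acyl-CoA) are
# written with identical atom text order so that positional auto-mapping
# pairs corresponding atoms
.NAD_RIBO <- "C2OC(COP(=O)(O)OP(=O)(O)OCC3OC(N4C=NC5=C4N=CN=C5N)C(O)C3O)C(O)C2O"
.NAD_PLUS <- paste0("NC(=O)C1=CC=C[N+](=C1)", .NAD_RIBO)
.NADH     <- paste0("NC(=O)C1CC=CN(C=1)", .NAD_RIBO)
.COA      <- paste0("CC(C)(COP(=O)(O)OP(=O)(O)OCC1OC(N2C=NC3=C2N=CN=C3N)",
                    "C(OP(=O)(O)O)C1O)C(O)C(=O)NCCC(=O)NCCS")
.SAM      <- "C[S+](CCC(N)C(=O)O)CC1OC(N2C=NC3=C2N=CN=C3N)C(O)C1O"
.SAH      <- "S(CCC(N)C(=O)O)CC1OC(N2C=NC3=C2N=CN=C3N)C(O)C1O"
.ADP      <- "C(OP(=O)(O)OP(=O)(O)O)C1OC(N2C=NC3=C2N=CN=C3N)C(O)C1O"
.ATP      <- "C(OP(=O)(O)OP(=O)(O)OP(=O)(O)O)C1OC(N2C=NC3=C2N=CN=C3N)C(O)C1O"

# heavy-atom position (parse order) of the terminal phosphate hydroxyl of
# ADP that becomes the new bridging oxygen in ATP: C,O,P,O,O,O,P,O,O -> 10th
.ADP_ATTACK_POS <- 10L

# assign atom maps to heavy atoms in parse order
.map_auto <- function(smiles, offset) {
  m <- parse_molecule(smiles)
  heavy <- which(m$atoms$element != "H")
  m$atoms$map[heavy] <- offset + seq_along(heavy)
  m
}

# assign an explicit map vector to heavy atoms in parse order
.map_custom <- function(smiles, maps) {
  m <- parse_molecule(smiles)
  heavy <- which(m$atoms$element != "H")
  stopifnot(length(maps) == length(heavy))
  m$atoms$map[heavy] <- as.integer(maps)
  m
}

.n_heavy <- function(smiles) {
  m <- parse_molecule(smiles)
  sum(m$atoms$element != "H")
}

#' Build the flavor-forming fixture reaction network
#'
#' Deterministically regenerates the atom-mapped reaction database used by
#' the examples and tests: leucine/valine/isoleucine/methionine catabolism
#' with the enzyme annotations of the source network (BcAT, GDH, HycDH,
#' KdcA, AlcDH, AldDH, EstA, KaDH, PTA, ACK, C-S lyase, lactate
#' 2-monooxygenase, S-methyltransferases) plus the chemical keto-acid
#' oxidation. All reactions balance at `h_slack = 0` and are fully
#' atom-mapped; regeneration is byte-stable.
#'
#' @param path optional TSV output path (written with [write_db()]).
#' @return an `rpe_reaction_db` with a `manifest` attribute.
#' @export
build_flavor_network <- function(path = NULL) {
  cp <- .FLAVOR_COMPOUNDS
  P <- parse_molecule

  nad  <- .map_auto(.NAD_PLUS, 900L)
  nadh <- .map_auto(.NADH, 900L)
  coa  <- .map_auto(.COA, 800L)
  n_coa <- .n_heavy(.COA)
  sam  <- .map_auto(.SAM, 700L)
  n_sam <- .n_heavy(.SAM)
  sah  <- .map_custom(.SAH, 702L:(700L + n_sam))
  adp  <- .map_auto(.ADP, 600L)
  n_adp <- .n_heavy(.ADP)
  k <- .ADP_ATTACK_POS
  atp  <- .map_custom(.ATP, c(600L + seq_len(k), 651L, 653L, 654L, 655L,
                              (600L + k + 1L):(600L + n_adp)))
  hplus <- P("[H+]")
  phosphate <- P("[OH:652][P:651](=[O:653])([OH:654])[OH:655]")

  # branched-chain skeleton map scheme: 1-3 isopropyl (or 27/28 ethyl for
  # the isoleucine series), 4 beta CH2, 5 alpha C, 6 keto/hydroxy O,
  # 7-9 carboxyl, 10 amino N; oxoglutarate/glutamate 11-19, pyruvate/alanine
  # 21-25
  leu  <- P("[CH3:1][CH:2]([CH3:3])[CH2:4][CH:5]([NH2:10])[C:7](=[O:8])[OH:9]")
  kica <- P("[CH3:1][CH:2]([CH3:3])[CH2:4][C:5](=[O:6])[C:7](=[O:8])[OH:9]")
  hica <- P("[CH3:1][CH:2]([CH3:3])[CH2:4][CH:5]([OH:6])[C:7](=[O:8])[OH:9]")
  val  <- P("[CH3:1][CH:2]([CH3:3])[CH:5]([NH2:10])[C:7](=[O:8])[OH:9]")
  kiv  <- P("[CH3:1][CH:2]([CH3:3])[C:5](=[O:6])[C:7](=[O:8])[OH:9]")
  ile  <- P("[CH3:27][CH2:28][CH:2]([CH3:3])[CH:5]([NH2:10])[C:7](=[O:8])[OH:9]")
  kmva <- P("[CH3:27][CH2:28][CH:2]([CH3:3])[C:5](=[O:6])[C:7](=[O:8])[OH:9]")
  og   <- P("[OH:11][C:12](=[O:13])[CH2:14][CH2:15][C:16](=[O:6])[C:17](=[O:18])[OH:19]")
  glu  <- P("[OH:11][C:12](=[O:13])[CH2:14][CH2:15][CH:16]([NH2:10])[C:17](=[O:18])[OH:19]")
  pyr  <- P("[CH3:21][C:22](=[O:6])[C:23](=[O:24])[OH:25]")
  ala  <- P("[CH3:21][CH:22]([NH2:10])[C:23](=[O:24])[OH:25]")
  met  <- P("[CH3:1][S:2][CH2:3][CH2:4][CH:5]([NH2:10])[C:7](=[O:8])[OH:9]")
  kmba <- P("[CH3:1][S:2][CH2:3][CH2:4][C:5](=[O:6])[C:7](=[O:8])[OH:9]")

  mbal <- P("[CH3:1][CH:2]([CH3:3])[CH2:4][CH:5]=[O:6]")
  mbol <- P("[CH3:1][CH:2]([CH3:3])[CH2:4][CH2:5][OH:6]")
  mpal <- P("[CH3:1][CH:2]([CH3:3])[CH:5]=[O:6]")
  co2  <- P("[O:8]=[C:7]=[O:9]")

  ivcoa <- .map_custom(paste0(.COA, "C(=O)CC(C)C"),
                       c(800L + seq_len(n_coa), 5L, 6L, 4L, 2L, 1L, 3L))
  accoa <- .map_custom(paste0(.COA, "C(=O)C"),
                       c(800L + seq_len(n_coa), 31L, 32L, 33L))
  ivp   <- P(paste0("[CH3:1][CH:2]([CH3:3])[CH2:4][C:5](=[O:6])",
                    "[O:652][P:651](=[O:653])([OH:654])[OH:655]"))
  mba   <- P("[CH3:1][CH:2]([CH3:3])[CH2:4][C:5](=[O:6])[OH:20]")
  mba_p <- P("[CH3:1][CH:2]([CH3:3])[CH2:4][C:5](=[O:6])[OH:652]")
  ester <- P("[CH3:33][C:31](=[O:32])[O:6][CH2:5][CH2:4][CH:2]([CH3:1])[CH3:3]")

  R <- function(id, reactants, products, rev, ec, name, src = "flavor-network") {
    new_reaction(id, reactants, products, rev, ec, name, src)
  }
  reactions <- list(
    R("R_BCAT_LEU", list(leu, og), list(kica, glu), "reversible",
      "2.6.1.42", "BcAT"),
    R("R_BCAT_VAL", list(val, og), list(kiv, glu), "reversible",
      "2.6.1.42", "BcAT"),
    R("R_BCAT_ILE", list(ile, og), list(kmva, glu), "reversible",
      "2.6.1.42", "BcAT"),
    R("R_ARAT_MET", list(met, pyr), list(kmba, ala), "irreversible",
      "2.6.1.88", "AraT"),
    R("R_GDH", list(glu, P("[OH2:26]"), nad),
      list(P(paste0("[OH:11][C:12](=[O:13])[CH2:14][CH2:15][C:16](=[O:26])",
                    "[C:17](=[O:18])[OH:19]")), P("[NH3:10]"), nadh, hplus),
      "irreversible", "1.4.1.2", "GDH"),
    R("R_KDCA_KICA", list(kica), list(mbal, co2), "irreversible",
      "4.1.1.72", "KdcA"),
    R("R_KDCA_KIV", list(kiv), list(mpal, co2), "irreversible",
      "4.1.1.72", "KdcA"),
    R("R_ALCDH", list(mbal, nadh, hplus), list(mbol, nad), "reversible",
      "1.1.1.1", "AlcDH"),
    R("R_ALDDH", list(mbal, nad, P("[OH2:20]")), list(mba, nadh, hplus),
      "irreversible", "1.2.1.5", "AldDH"),
    R("R_KADH", list(kica, coa, nad), list(ivcoa, co2, nadh, hplus),
      "irreversible", "1.2.4.4", "KaDH"),
    R("R_PTA", list(ivcoa, phosphate), list(ivp, coa), "reversible",
      "2.3.1.8", "PTA"),
    R("R_ACK", list(ivp, adp), list(mba_p, atp), "irreversible",
      "2.7.2.14", "ACK"),
    R("R_HYCDH", list(kica, nadh, hplus), list(hica, nad), "reversible",
      "1.1.1.337", "HycDH"),
    R("R_LMO",
      list(P("[CH3:1][CH:2]([OH:3])[C:4](=[O:5])[OH:6]"), P("[O:7]=[O:8]")),
      list(P("[CH3:1][C:2](=[O:7])[OH:3]"), P("[O:5]=[C:4]=[O:6]"),
           P("[OH2:8]")),
      "irreversible", "1.13.12.4", "lactate 2-monooxygenase"),
    R("R_KMBA_OX",
      list(P("[CH3:1][S:2][CH2:3][CH2:4][C:5](=[O:6])[C:7](=[O:8])[OH:9]"),
           P("[O:10]=[O:11]")),
      list(P("[CH3:1][S:2][CH2:3][CH:4]=[O:10]"),
           P("[OH:9][C:7](=[O:8])[C:5](=[O:6])[OH:11]")),
      "irreversible", character(0), character(0), src = "sulfur-chemical"),
    R("R_CSL", list(met, P("[OH2:26]")),
      list(P("[CH3:1][SH:2]"),
           P("[CH3:3][CH2:4][C:5](=[O:26])[C:7](=[O:8])[OH:9]"),
           P("[NH3:10]")),
      "irreversible", "4.4.1.8", "C-S lyase"),
    R("R_METH",
      list(P("[SH:30][CH2:31][CH2:32][CH:33]([NH2:34])[C:35](=[O:36])[OH:37]"),
           sam),
      list(P("[CH3:701][S:30][CH2:31][CH2:32][CH:33]([NH2:34])[C:35](=[O:36])[OH:37]"),
           sah, hplus),
      "irreversible", c("2.1.1.10", "2.1.1.13"),
      c("homocysteine S-methyltransferase", "methionine synthase")),
    R("R_TMT", list(P("[CH3:40][CH2:41][SH:42]"), sam),
      list(P("[CH3:40][CH2:41][S:42][CH3:701]"), sah, hplus),
      "irreversible", "2.1.1.9", "thiol S-methyltransferase"),
    R("R_ESTA", list(mbol, accoa), list(ester, coa), "irreversible",
      "3.1.1.-", "EstA", src = "flavor-network profile:ester"),
    # chemical DMS oxidation to DMSO (two-fold stoichiometry written as
    # repeated molecules); keeps DMS in the compound index while the
    # methanethiol methylation itself stays novel
    R("R_DMS_OX",
      list(P("[CH3:50][S:51][CH3:52]"), P("[CH3:53][S:54][CH3:55]"),
           P("[O:56]=[O:57]")),
      list(P("[CH3:50][S:51](=[O:56])[CH3:52]"),
           P("[CH3:53][S:54](=[O:57])[CH3:55]")),
      "irreversible", character(0), character(0), src = "sulfur-chemical")
  )

  db <- reaction_db(reactions)
  attr(db, "manifest") <- list(
    name = "flavor-network",
    version = "1",
    reaction_count = length(reactions),
    reversible = vapply(reactions, function(r) r$reversibility, "") == "reversible",
    reaction_ids = vapply(reactions, function(r) r$id, ""),
    enzymes = sort(unique(unlist(lapply(reactions, function(r) r$enzyme_names)))),
    compounds = sort(unique(vapply(
      unlist(lapply(reactions, function(r) c(r$reactants, r$products)),
             recursive = FALSE),
      function(m) m$canonical_smiles, ""))),
    # esterification is part of the network but not of the default retro
    # profile (ester targets are outside the worked examples)
    default_retro_exclude = "R_ESTA",
    cofactor_notes = paste(
      "KaDH/PTA/ACK cofactors follow standard biochemistry (CoA + NAD+,",
      "inorganic phosphate, ADP/ATP); acids and phosphates are written",
      "protonated so that all reactions balance with h_slack = 0."))
  if (!is.null(path)) write_db(db, path)
  db
}

#' Canonical SMILES of a named fixture compound
#'
#' @param name compound key, e.g. `"kica"`, `"leucine"`, `"dms"`;
#'   see `names(flavor_compounds())`.
#' @return canonical SMILES string.
#' @export
flavor_compound <- function(name) {
  s <- if (name %in% names(.FLAVOR_COMPOUNDS)) .FLAVOR_COMPOUNDS[[name]] else NULL
  if (is.null(s) || is.na(s)) stop("unknown fixture compound: ", name)
  parse_molecule(s)$canonical_smiles
}

#' @rdname flavor_compound
#' @export
flavor_compounds <- function() .FLAVOR_COMPOUNDS[!is.na(.FLAVOR_COMPOUNDS)]

# ---- simulated protein families ----

.AA_ALPHABET <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L", "M", "N",
                  "P", "Q", "R", "S", "T", "V", "W", "Y")

#' Simulate a protein family along a known gene tree
#'
#' The root sequence is uniform over the 20 amino acids; along each branch
#' every site independently substitutes (to a uniformly chosen different
#' residue) with probability `sub_rate * branch length` (branch lengths
#' default to 1 when the tree has none), capped at 0.95. No indels are
#' introduced, so the leaf sequences are trivially aligned. Leaf labels must
#' follow the `gene_species` convention (species = text after the last
#' underscore). Deterministic for a fixed seed.
#'
#' @param tree a newick string or `ape::phylo` object (rooted).
#' @param seq_length number of sites (>= 1).
#' @param sub_rate per-branch, per-site substitution probability in `[0, 1)`.
#' @param seed integer RNG seed.
#' @return list with `alignment` (named character vector), `species_map`
#'   (data.frame seq_id, species_id), `true_events` (event label per internal
#'   node of the true rooted tree, from the species-overlap rule),
#'   `true_duplications` (leaf-set keys of true duplication clades) and
#'   `tree` (the rooted `phylo`).
#' @export
simulate_protein_family <- function(tree, seq_length, sub_rate, seed) {
  stopifnot(seq_length >= 1L, sub_rate >= 0, sub_rate < 1)
  phy <- if (inherits(tree, "phylo")) tree else ape::read.tree(text = tree)
  if (is.null(phy)) stop("could not parse tree")
  old <- .Random.seed_get()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)

  ntip <- length(phy$tip.label)
  nnode <- ntip + phy$Nnode
  root <- ntip + 1L
  seqs <- vector("list", nnode)
  seqs[[root]] <- sample(.AA_ALPHABET, seq_length, replace = TRUE)
  # preorder traversal over the edge matrix
  eo <- ape::reorder.phylo(phy, "cladewise")
  for (k in seq_len(nrow(eo$edge))) {
    par <- eo$edge[k, 1]; child <- eo$edge[k, 2]
    len <- if (is.null(eo$edge.length)) 1 else eo$edge.length[k]
    p <- min(0.95, sub_rate * len)
    s <- seqs[[par]]
    hit <- which(stats::runif(seq_length) < p)
    if (length(hit)) {
      s[hit] <- vapply(s[hit], function(a) {
        sample(setdiff(.AA_ALPHABET, a), 1L)
      }, "")
    }
    seqs[[child]] <- s
  }
  aln <- vapply(seq_len(ntip), function(i) paste(seqs[[i]], collapse = ""), "")
  names(aln) <- phy$tip.label
  species <- sub("^.*_", "", phy$tip.label)
  smap <- data.frame(seq_id = phy$tip.label, species_id = species,
                     stringsAsFactors = FALSE)
  ev <- .species_overlap_events(phy, stats::setNames(species, phy$tip.label))
  list(alignment = aln, species_map = smap,
       true_events = ev$events,
       true_duplications = ev$dup_keys,
       tree = phy)
}

# save/restore .Random.seed so fixture generation does not disturb the
# caller's RNG stream
.Random.seed_get <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv())
  else NULL
}
.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}

#' Write an alignment to FASTA and its species map to TSV
#'
#' @param fam result of [simulate_protein_family()].
#' @param fasta,species_tsv output paths (NULL to skip either).
#' @export
write_family <- function(fam, fasta = NULL, species_tsv = NULL) {
  if (!is.null(fasta)) {
    con <- file(fasta, "w")
    on.exit(close(con), add = TRUE)
    for (nm in names(fam$alignment)) {
      writeLines(c(paste0(">", nm), fam$alignment[[nm]]), con)
    }
  }
  if (!is.null(species_tsv)) {
    utils::write.table(fam$species_map, species_tsv, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = c("seq_id", "species_id"))
  }
  invisible(fam)
}
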