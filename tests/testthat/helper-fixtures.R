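# Shared fixture objects, built once per test run.

fixture_db <- local({
  db <- NULL
  function() {
    if (is.null(db)) db <<- build_flavor_network()
    db
  }
})

fixture_rules <- local({
  rules <- NULL
  function() {
    if (is.null(rules)) rules <<- build_ruleset(fixture_db(), radius = 1L)
    rules
  }
})

csmiles <- function(s) parse_molecule(s)$canonical_smiles

reactant_smiles <- function(rxn) {
  sort(vapply(rxn$reactants, function(m) m$canonical_smiles, ""))
}
product_smiles <- function(rxn) {
  sort(vapply(rxn$products, function(m) m$canonical_smiles, ""))
}

# a tiny toy reaction: mapped hydration of ethene (used where the flavor
# network would be overkill)
toy_hydration <- function(rev = "irreversible") {
  parse_reaction_smiles("[CH2:1]=[CH2:2].[OH2:3]>>[CH3:1][CH2:2][OH:3]",
                        id = "TOY_HYD", reversibility = rev)
}
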