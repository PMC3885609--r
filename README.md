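# rpe — Reverse Pathway Engineering for metabolic gap filling

Genome-scale metabolic models are chronically incomplete: many measured
metabolites — flavor compounds of fermented foods are a classic case — have
no annotated synthesis route. `rpe` closes such gaps by **reverse pathway
engineering**: it learns *biotransformation rules* from a curated,
atom-mapped reference reaction database, applies them **backwards** from a
target compound (retrosynthesis), ranks the resulting candidate precursor
reactions, and iterates until a known metabolic precursor (e.g. an amino
acid) is reached. A comparative-genomics layer then proposes **candidate
enzymes** for each predicted step and assesses them by neighbor-joining
phylogenetics with bootstrap supports and species-overlap ortholog
inference.

## The method in brief

**Rule extraction.** Every reference reaction is fully atom-mapped. Its
*reaction center* is the symmetric difference of the mapped bond sets —
bonds broken, formed, or changed in order — plus atoms whose hydrogen count
or formal charge changes. A rule's match pattern is the center restricted to
one product molecule plus all atoms within an environment radius *r*
(default 1 bond). Reversible reactions give two rules (one per direction);
irreversible or unknown reversibility gives one.

**Retro application.** The pattern is embedded in the target by subgraph
matching (element, aromaticity and ring membership must agree everywhere;
hydrogen count and charge additionally on center atoms). Each
automorphism-distinct embedding is rewritten back to the reactant side:
center bonds and atom properties revert, reactant-side atoms with no target
counterpart (e.g. the amino group restored by a retro transamination) are
copied from the reference structures, and intact co-substrates (NAD(H),
CoA, S-adenosyl-L-methionine, ATP/ADP — carried in full structure) are
copied whole. Balanced reference reactions therefore yield balanced
candidates, checked at zero hydrogen slack.

**Ranking and search.** Candidates are ordered by
`4·(reaction in DB) + 2·(fraction of reactants in DB) + 1·simplicity`,
with co-reactant frequency among mechanistically equivalent reference
reactions (same center signature) as the tie layer — this is what makes
oxoglutarate, seen in three reference transaminations, beat pyruvate, seen
in one. Beam search (default width 5) expands the main precursor of the top
candidates; a novel candidate whose proposed precursor is itself unknown to
the database is kept and flagged but not pursued further. Routes are linear
precursor→target chains, verified by forward replay.

**Enzyme assignment.** Candidates inherit the enzymes of their reference
reaction, plus enzymes of all reactions sharing the rule's center signature.
For a candidate enzyme family, `rpe` computes p-distances on an alignment,
builds a Saitou–Nei neighbor-joining tree, bootstraps column resamples,
midpoint-roots, labels each internal node *duplication* (child clades share
a species) or *speciation*, and reports whether the target organism holds
an ortholog of the characterized seed enzyme — if not, confidence in the
predicted reaction is downgraded.

## Worked example

Three routes from alpha-keto isocaproate (KICA) to the cheese flavor
compound 3-methylbutanoic acid:

```r
library(rpe)
db    <- build_flavor_network()
rules <- build_ruleset(db, radius = 1)
tree  <- build_tree(flavor_compound("methylbutanoate"), rules, db,
                    precursors = flavor_compound("kica"),
                    max_depth = 4, beam = 5)
routes <- extract_routes(tree)
length(routes)
#> [1] 3
```

The three routes (as printed, cofactor SMILES abbreviated here): oxidation
via 3-methylbutanal, the novel hydroxyacid route via HICA, and the
oxidative-decarboxylation route via isovaleryl-CoA / isovaleryl-phosphate:

```
<rpe_route> 2 step(s): KICA -> ... -> 3-methylbutanoic acid
  1. KICA >> CO2 + 3-methylbutanal                      [ref: R_KDCA_KICA]
  2. 3-methylbutanal + NAD+ + H2O >> acid + NADH + H+   [ref: R_ALDDH]
<rpe_route> 2 step(s): KICA -> ... -> 3-methylbutanoic acid
  1. KICA + NADH + H+ >> HICA + NAD+                    [ref: R_HYCDH]
  2. HICA + O2 >> acid + CO2 + H2O                      [novel]
<rpe_route> 3 step(s): KICA -> ... -> 3-methylbutanoic acid
  1. KICA + CoA + NAD+ >> isovaleryl-CoA + CO2 + NADH + H+  [ref: R_KADH]
  2. isovaleryl-CoA + Pi >> isovaleryl-P + CoA              [ref: R_PTA]
  3. isovaleryl-P + ADP >> acid + ATP                       [ref: R_ACK]
```

The `[novel]` step is not present in the reference database; its enzyme
evidence comes from the analogous reference reaction:

```r
candidate_enzymes(routes[[2]]$steps[[2]], db)
#>          ec                    name source_reaction           evidence
#> 1 1.13.12.4 lactate 2-monooxygenase           R_LMO reference_reaction
```

The same machinery predicts the chemical conversion of KICA + O2 to
2-methylpropanal + oxalic acid (by analogy to the keto-methylthiobutyrate
oxidation) and the methylation of methanethiol by S-adenosyl-L-methionine
to dimethyl sulfide, with EC 2.1.1.10 / 2.1.1.13 / 2.1.1.9 as candidate
enzymes.

## Command line

```sh
Rscript inst/cli/rpe.R fixture --name flavor-network --out db.tsv
Rscript inst/cli/rpe.R build-rules --db db.tsv --radius 1 --out rules.json
Rscript inst/cli/rpe.R retro --target 'CC(C)CC(=O)O' --db db.tsv \
    --precursors prec.txt --max-depth 4 --beam 5 --out tree.json
Rscript inst/cli/rpe.R orthologs --fasta fam.faa --species-map map.tsv \
    --bootstrap 1000 --seed 42 --seed-leaf g1_s1 --target-species s3 \
    --out fam.nwk
```

Exit codes: 0 success, 2 validation error, 3 I/O error. A JSON config file
(`--config`) may preset any flag; explicit flags win.

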