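---
title: "Reverse pathway engineering: model, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Reverse pathway engineering: model, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rpe)
```

## The problem and the model

Many metabolites measured in fermentations — flavor aldehydes, alcohols,
acids and volatile sulfur compounds among them — have no annotated
biosynthetic route. `rpe` treats this as a retrosynthesis problem over a
knowledge base of *reference reactions*: known enzymatic and chemical
reactions, stoichiometrically balanced and fully atom-mapped. The atom map
is the load-bearing annotation. From it we compute the **reaction center**:
the set of bonds broken, formed, or changed in order between the two sides,
plus every atom whose hydrogen count or formal charge changes. Everything
else in the molecule is context.

A **biotransformation rule** is a directed rewrite derived from one
reference reaction: its match pattern is the center restricted to one
product-side molecule, grown by an environment radius $r$ (graph distance in
bonds), and its rewrite instructions are the reactant-side bonds and atom
states of the mapped counterparts. Applying a rule *retro* to a target
molecule means embedding the pattern in the target and rewriting the
matched region back to the reactant side. Atoms of the reactant side that
have no counterpart inside the target (the amino group removed by a forward
transamination, the CO2 carbon removed by a decarboxylation) are copied
from the reference structures; product-side molecules other than the
matched one, and reactant molecules untouched by the pattern, are copied
whole. Because the reference reaction balances and the rewrite is an exact
graph surgery, every candidate reaction balances too — the test suite
asserts this at zero hydrogen slack for every fixture rule on every worked
target.

Iterating — apply all rules, rank, recurse on the proposed precursor —
yields a retrosynthesis tree whose precursor-terminated root paths are the
predicted **routes**, each verified by forward replay.

### Why the pattern lives on one product molecule

A reaction center usually spans several molecules (a transamination changes
atoms in both the amino donor and the keto acceptor). A pattern spanning
two product molecules can never embed in a single target compound, so rules
are generated per product molecule that carries center atoms. The
first-listed product (by database convention, the main product) is the
designated one for the spec-level single-rule view; the search uses every
variant, which is what lets the engine discover, e.g., that a carboxylic
acid target can be produced as either the aldehyde-oxidation product or the
acyl-phosphate hydrolysis product of the same reference chemistry.

### Match semantics

Pattern atoms must agree with the target on element, aromaticity flag and
ring membership. Center atoms additionally pin hydrogen count and formal
charge — the rewrite sets these to reactant-side values, so matching them
exactly is what keeps hydrogen bookkeeping closed. Environment atoms
deliberately do **not** constrain degree or hydrogen count: that freedom is
precisely what permits analogical transfer — the rule learned on
alpha-keto-methylthiobutyrate (a thioether chain beyond radius 1) fires on
alpha-keto isocaproate (an isobutyl chain), predicting the chemical
KICA + O2 conversion; the lactate 2-monooxygenase rule fires on
alpha-hydroxy-isocaproate; the homocysteine S-methylation rule fires on
methanethiol, predicting dimethyl sulfide formation. Embeddings are
de-duplicated by their image atom set, which coincides with de-duplication
by pattern automorphism classes (two embeddings share an image set exactly
when they differ by a pattern automorphism), so a symmetric substrate such
as glycerol yields two primary-alcohol candidates, not four.

## Tunable parameters

| parameter | default | units | rationale |
|---|---|---|---|
| `radius` | 1 | bonds | radius 0 over-generalizes (a bare carboxyl pattern fires in chemically absurd contexts); radius 2 or more makes patterns so specific that the cross-substrate analogies above stop firing. 1 reproduces all worked predictions. |
| `beam` | 5 | candidates/node | the fixture networks produce 3–6 plausible candidates per node; 5 keeps every database-supported candidate while bounding the tree. |
| `max_depth` | 6 | retro steps | worked routes are at most 3–4 steps; 6 leaves headroom. The worked examples in tests use 4, the depth of the deepest published tree. |
| `h_slack` | 0 | H atoms | fixtures write acids and phosphates protonated and protons explicitly, so exact balance is attainable; the slack (requiring a matching charge difference) exists for external databases with mixed protonation conventions. |
| rank weights | 4 / 2 / 1 | — | database-exact candidates must dominate (4 exceeds the maximum attainable 2 + 1 of a novel candidate); reactant presence outweighs simplicity. The source procedure ranks qualitatively; the weights are configuration, not dogma. |
| `bootstrap_n` | 1000 | replicates | the customary figure for published NJ trees; tests use 20–100 for speed. |

**Simplicity** is defined as `heavy(target) / max(heavy(target),
heavy(main precursor))`: 1 when the proposed precursor is no larger than
the target, shrinking as the precursor grows. Heavy-atom count was chosen
over ring counts or topological indices because the reference procedure's
own description of ranking mentions only "simplicity of structures", and
atom count is the least-surprising reading; all four score components are
logged per candidate so alternates can be swapped in.

**Co-reactant frequency** breaks ties: among reference reactions sharing
the candidate rule's center signature (a canonical string over changed-bond
element pairs, order transitions and hydrogen/charge deltas), we count
those whose reactant side contains the candidate's co-reactant set. In the
fixture network three transaminations use oxoglutarate and one uses
pyruvate, so the oxoglutarate variant ranks first — reproducing the
correction of the simplicity-based preference for pyruvate.

### The expansion policy (a design decision)

The original procedure interposes a human: predicted reactions were
inspected and one was *selected*, guided by the reference reactions found
in the database. A beam search alone is a poor substitute, because analogy
rules happily fire inside cofactor moieties (the pantoyl hydroxyl of
coenzyme A matches a hydroxyacid-dehydrogenase pattern) and generate
precursors that are themselves unknown compounds, spawning unbounded
chains of speculation. The package therefore pursues a candidate's
precursor only when the candidate is a database reaction, or all of its
proposed reactants are known compounds, or the precursor is itself a stated
terminal precursor. Novel candidates failing this are still produced,
ranked and flagged (`pruned = "unsupported_precursor"`) — they are visible
predictions, just not recursion points. With this policy the
3-methylbutanoic acid run yields exactly the three published routes;
without it, two extra four-step routes appear whose intermediates are
phospho-diesters and oxidized CoA species no curator would accept.

## Chemistry representation and numerical conventions

* **SMILES dialect.** Organic-subset and bracket atoms, charges, atom maps,
  ring closures; stereochemistry is parsed and dropped (the flavor-network
  chemistry is stereo-agnostic at this resolution). Aromatic lowercase
  notation is rejected — all rings, including the adenine of NAD/CoA/SAM,
  are written in Kekulé form, so bond orders are always integers and the
  aromatic flag is uniformly false. Free-standing `[H+]` is a molecule;
  bracket hydrogens bonded to a heavy atom fold into its hydrogen count.
* **Canonical forms.** Atom ordering comes from a BLISS canonical labeling
  of the bond-subdivided colored graph (colors encode element, charge,
  hydrogen count; bond vertices encode order), followed by a deterministic
  DFS SMILES writer. Canonical forms exclude atom maps, making them
  invariant under map renumbering; `parse(canonical(x))` is idempotent.
  Molecule equality, reaction keys, deduplication and exact-match lookup
  all reduce to string comparison on these forms.
* **Determinism.** Candidate order is a total order (score, then
  co-reactant frequency, then canonical reaction key); NJ breaks equal
  Q-criteria by the smallest index pair with taxa pre-sorted by label;
  bootstrap resampling is seeded. Reruns are bit-identical.
* **Degenerate inputs.** Identity reactions have an empty center and yield
  no rules; partially mapped reactions are rejected (automatic atom mapping
  is out of scope); a rule whose radius is too small to anchor a
  reactant-side attachment simply produces no candidate for that embedding;
  negative NJ branch lengths clamp to zero; two-taxon trees are a single
  edge split at its midpoint.

## The fixture generator: what it emulates, what it does not

`build_flavor_network()` regenerates, deterministically and byte-stably,
a 20-reaction atom-mapped network of leucine/valine/isoleucine/methionine
catabolism: the transaminase entry reactions (three oxoglutarate-accepting,
one pyruvate-accepting, matching the frequency argument above), glutamate
dehydrogenase, keto-acid decarboxylation, alcohol/aldehyde/hydroxyacid
dehydrogenases, the oxidative-decarboxylation branch through
isovaleryl-CoA and isovaleryl-phosphate, the lactate 2-monooxygenase
reference, the chemical keto-acid oxidation, C-S lyase elimination, two
S-methylations, an esterification (tagged out of the default retro
profile) and a chemical DMS oxidation (which keeps DMS in the compound
index while leaving the methanethiol methylation novel). Cofactors are
carried in full structure; acids and phosphates are protonated and protons
explicit, so every reaction balances at `h_slack = 0`. Reversibility flags
(only the aminotransferases, alcohol and hydroxyacid dehydrogenases and
phosphotransacylase are reversible) follow the catabolic direction of the
source network; this is what holds the acid run at exactly three routes.

`simulate_protein_family()` evolves a root sequence (uniform over 20 amino
acids) down a given gene tree with per-branch, per-site substitution
probability `sub_rate × branch length` (capped at 0.95), substituting to a
uniformly chosen different residue. No indels, no rate heterogeneity, no
substitution-matrix structure: alignments are trivially exact and
p-distances are unbiased at low divergence. A green
duplication-recovery test therefore establishes that the NJ →
midpoint-rooting → species-overlap pipeline recovers known events under
clean, low-noise evolution — not that it is robust to alignment error,
long-branch attraction or rate variation, which real enzyme families
exhibit. The 300-column, 0.05-rate defaults are typical of a conserved
enzyme domain at genus-level divergence.

## Phylogenetic conventions

Distances are p-distances (mismatches over shared ungapped columns); pairs
sharing no columns are an error, and replicates hitting that error during
bootstrap are skipped (with the support denominator adjusted). Trees are
built by standard Saitou–Nei neighbor joining. Rooting for event labeling
is midpoint by default with an `--outgroup` override — the species-overlap
rule needs a root, and the source material is silent on rooting; midpoint
is the usual surrogate when no outgroup is designated. An internal node is
a *duplication* iff the species sets of its child clades intersect.
Orthologs of a seed leaf are the leaves reachable through speciation-only
internal nodes; presence of any ortholog in the target species suffices for
a positive verdict (no support threshold by default, matching the
qualitative use in the source analysis; `--min-support` exists).

## Serialization choices

Reaction databases travel as TSV (`id`, `reaction_smiles` with atom maps,
`reversibility`, semicolon-joined `ec`/`enzyme_name`, `source`); rules,
trees, routes and verdicts as JSON with the full run configuration
embedded. The command line accepts a JSON — not YAML — config file: the
target R environment carries no YAML parser, and JSON loses nothing here.

## Known limitations

* No automatic atom-atom mapping: reference reactions must arrive mapped.
* No aromatic perception: Kekulé input only; two Kekulé forms of the same
  aromatic ring are distinct molecules to the engine (tautomers likewise).
* Linear routes only: each candidate designates one main precursor (the
  component holding the anchor center atom of the principal substrate);
  branched AND-trees over multiple unknown precursors are not enumerated.
* Stereochemistry is ignored throughout; stereo-specific enzymes cannot be
  distinguished.
* The pairwise Needleman–Wunsch aligner is a convenience for distance
  estimates; multiple alignment quality is the caller's responsibility.
* Thermodynamics, kinetics and flux are out of scope: a route is a
  structural proposal, not a feasibility claim.
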