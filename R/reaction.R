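# Reactions: reactant/product molecule lists with reversibility and enzyme
# annotations, stoichiometric balance checking, and direction-sensitive
# canonical keys used for deduplication and exact-match lookups.

.REVERSIBILITY_TOKENS <- c("reversible", "irreversible", "unknown")

#' Construct a reaction
#'
#' @param id reaction identifier (unique within a database).
#' @param reactants,products non-empty lists of `rpe_molecule`.
#' @param reversibility one of `"reversible"`, `"irreversible"`, `"unknown"`.
#' @param ec_numbers,enzyme_names character vectors of enzyme annotations
#'   (may be empty, e.g. for purely chemical reactions).
#' @param source free-text provenance.
#' @return an `rpe_reaction` object.
#' @export
new_reaction <- function(id, reactants, products,
                         reversibility = "unknown",
                         ec_numbers = character(0),
                         enzyme_names = character(0),
                         source = "") {
  if (!length(reactants) || !length(products)) {
    stop("reaction '", id, "': reactant and product lists must be non-empty")
  }
  if (!reversibility %in% .REVERSIBILITY_TOKENS) {
    stop("reaction '", id, "': unknown reversibility token '", reversibility,
         "' (expected one of: ", paste(.REVERSIBILITY_TOKENS, collapse = ", "), ")")
  }
  rxn <- list(id = as.character(id), reactants = reactants, products = products,
              reversibility = reversibility,
              ec_numbers = ec_numbers[nzchar(ec_numbers)],
              enzyme_names = enzyme_names[nzchar(enzyme_names)],
              source = source)
  class(rxn) <- "rpe_reaction"
  rxn
}

#' Parse a reaction SMILES string
#'
#' `"A.B>>C.D"` with optional atom maps (`:n`). The two sides are split on
#' `">>"` and components on `"."`.
#'
#' @inheritParams new_reaction
#' @param reaction_smiles the reaction SMILES.
#' @export
parse_reaction_smiles <- function(reaction_smiles, id = "rxn",
                                  reversibility = "unknown",
                                  ec_numbers = character(0),
                                  enzyme_names = character(0),
                                  source = "") {
  sides <- strsplit(reaction_smiles, ">>", fixed = TRUE)[[1]]
  if (length(sides) != 2L || !nzchar(sides[1]) || !nzchar(sides[2])) {
    stop("reaction '", id, "': expected 'reactants>>products', got '",
         reaction_smiles, "'")
  }
  parse_side <- function(s) {
    lapply(strsplit(s, ".", fixed = TRUE)[[1]], parse_molecule)
  }
  new_reaction(id, parse_side(sides[1]), parse_side(sides[2]),
               reversibility, ec_numbers, enzyme_names, source)
}

# reaction SMILES with atom maps, molecules in input order
reaction_smiles_of <- function(rxn, mapped = TRUE) {
  wr <- if (mapped) write_smiles_mapped else function(m) m$canonical_smiles
  paste0(paste(vapply(rxn$reactants, wr, ""), collapse = "."), ">>",
         paste(vapply(rxn$products, wr, ""), collapse = "."))
}

# ---- atom mapping helpers ----

# per-side map multisets over heavy atoms; H-only molecules are exempt
.side_maps <- function(mols) {
  unlist(lapply(mols, function(m) {
    heavy <- m$atoms$element != "H"
    if (!any(heavy)) return(integer(0))
    m$atoms$map[heavy]
  }))
}

# TRUE iff every heavy atom on both sides carries a positive atom map and the
# two multisets agree
is_fully_mapped <- function(rxn) {
  rm <- .side_maps(rxn$reactants)
  pm <- .side_maps(rxn$products)
  all(rm > 0L) && all(pm > 0L) &&
    !anyDuplicated(rm) && !anyDuplicated(pm) &&
    identical(sort(rm), sort(pm))
}

#' Check stoichiometric balance of a reaction
#'
#' Balanced iff per-element reactant and product sums agree. Hydrogen may
#' differ by up to `h_slack` provided the charge difference matches the
#' hydrogen difference (proton bookkeeping); with `h_slack = 0` both hydrogen
#' and charge must agree exactly.
#'
#' @param rxn an `rpe_reaction`.
#' @param h_slack non-negative integer hydrogen tolerance.
#' @return list with `balanced` (logical) and `diff` (named numeric vector of
#'   product-minus-reactant per-element imbalances plus `charge`), empty when
#'   balanced.
#' @export
check_balance <- function(rxn, h_slack = 0L) {
  stopifnot(h_slack >= 0L)
  fr <- elemental_formula(rxn$reactants)
  fp <- elemental_formula(rxn$products)
  els <- sort(union(names(fr$counts), names(fp$counts)))
  get <- function(f, e) if (e %in% names(f$counts)) f$counts[[e]] else 0L
  d <- vapply(els, function(e) get(fp, e) - get(fr, e), numeric(1))
  dq <- fp$net_charge - fr$net_charge
  dh <- if ("H" %in% els) d[["H"]] else 0
  heavy_ok <- all(d[setdiff(els, "H")] == 0)
  h_ok <- (dh == 0 && dq == 0) || (abs(dh) <= h_slack && dh == dq)
  if (heavy_ok && h_ok) {
    list(balanced = TRUE, diff = numeric(0))
  } else {
    diff <- c(d[d != 0], if (dq != 0) c(charge = dq))
    list(balanced = FALSE, diff = diff)
  }
}

#' Direction-sensitive canonical reaction key
#'
#' Invariant under molecule ordering within each side and under atom-map
#' renumbering (maps are excluded from canonical forms).
#'
#' @param rxn an `rpe_reaction`.
#' @param direction `"as_written"` or `"reversed"`.
#' @return a string key.
#' @export
canonical_reaction_key <- function(rxn, direction = c("as_written", "reversed")) {
  direction <- match.arg(direction)
  r <- sort(vapply(rxn$reactants, function(m) m$canonical_smiles, ""))
  p <- sort(vapply(rxn$products, function(m) m$canonical_smiles, ""))
  if (direction == "reversed") { tmp <- r; r <- p; p <- tmp }
  paste0(paste(r, collapse = "."), ">>", paste(p, collapse = "."))
}

#' Reaction with reactant and product sides swapped
#'
#' Used for reversed-direction rules of reversible reactions.
#'
#' @param rxn an `rpe_reaction`.
#' @return the reversed `rpe_reaction`.
#' @export
reverse_reaction <- function(rxn) {
  new_reaction(rxn$id, rxn$products, rxn$reactants, rxn$reversibility,
               rxn$ec_numbers, rxn$enzyme_names, rxn$source)
}

#' @export
print.rpe_reaction <- function(x, ...) {
  cat("<rpe_reaction> ", x$id, " [", x$reversibility, "]\n", sep = "")
  cat("  ", paste(vapply(x$reactants, function(m) m$canonical_smiles, ""),
                  collapse = " + "),
      " >> ",
      paste(vapply(x$products, function(m) m$canonical_smiles, ""),
            collapse = " + "), "\n", sep = "")
  if (length(x$enzyme_names) || length(x$ec_numbers)) {
    cat("  enzymes: ", paste(x$enzyme_names, collapse = "; "),
        if (length(x$ec_numbers)) paste0(" (EC ", paste(x$ec_numbers, collapse = ", "), ")"),
        "\n", sep = "")
  }
  invisible(x)
}
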