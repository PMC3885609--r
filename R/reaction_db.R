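# Reaction database: TSV input/output, validation, deduplication, and
# direction-aware exact-match queries.
#
# TSV dialect (tab-delimited, UTF-8, header required):
#   id  reaction_smiles  reversibility  ec  enzyme_name  source
# `ec` and `enzyme_name` are semicolon-separated lists.

.DB_COLUMNS <- c("id", "reaction_smiles", "reversibility", "ec",
                 "enzyme_name", "source")

#' Build a reaction database from a list of reactions
#'
#' Computes the compound index (canonical forms of every reactant/product)
#' and the direction-aware key index used by [find_exact()].
#'
#' @param reactions list of `rpe_reaction`.
#' @return an `rpe_reaction_db`.
#' @export
reaction_db <- function(reactions) {
  ids <- vapply(reactions, function(r) r$id, "")
  if (anyDuplicated(ids)) {
    stop("duplicate reaction id(s): ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  names(reactions) <- ids
  db <- list(reactions = reactions)
  class(db) <- "rpe_reaction_db"
  .reindex_db(db)
}

.reindex_db <- function(db) {
  keys <- character(0)
  comp <- character(0)
  for (r in db$reactions) {
    k <- canonical_reaction_key(r, "as_written")
    keys[k] <- r$id
    if (r$reversibility == "reversible") {
      kr <- canonical_reaction_key(r, "reversed")
      keys[kr] <- r$id
    }
    comp <- c(comp, vapply(c(r$reactants, r$products),
                           function(m) m$canonical_smiles, ""))
  }
  db$key_index <- keys
  db$compound_index <- sort(unique(comp))
  db
}

#' Load a reaction database from TSV
#'
#' Every row is parsed, validated (unique ids, known reversibility tokens)
#' and its balance verdict at `h_slack` is recorded in the `balance` column
#' of the returned database's `log` attribute (also emitted as messages when
#' `quiet = FALSE`).
#'
#' @param path TSV file path.
#' @param h_slack hydrogen slack used for the per-row balance log.
#' @param quiet suppress per-row balance messages.
#' @return an `rpe_reaction_db`.
#' @export
load_db <- function(path, h_slack = 0L, quiet = TRUE) {
  if (!file.exists(path)) stop("I/O error: no such file: ", path)
  tab <- utils::read.delim(path, sep = "\t", header = TRUE,
                           colClasses = "character", quote = "",
                           check.names = FALSE)
  if (!identical(colnames(tab), .DB_COLUMNS)) {
    stop("validation error: expected header ",
         paste(.DB_COLUMNS, collapse = ", "), " in ", path)
  }
  reactions <- vector("list", nrow(tab))
  balance_log <- character(nrow(tab))
  for (i in seq_len(nrow(tab))) {
    row <- tab[i, ]
    if (!row$reversibility %in% .REVERSIBILITY_TOKENS) {
      stop("validation error: row ", i, " (id '", row$id,
           "'): unknown reversibility token '", row$reversibility, "'")
    }
    split_semi <- function(s) {
      if (is.na(s) || !nzchar(s)) character(0) else strsplit(s, ";", fixed = TRUE)[[1]]
    }
    rxn <- parse_reaction_smiles(row$reaction_smiles, id = row$id,
                                 reversibility = row$reversibility,
                                 ec_numbers = split_semi(row$ec),
                                 enzyme_names = split_semi(row$enzyme_name),
                                 source = row$source)
    bal <- check_balance(rxn, h_slack = h_slack)
    balance_log[i] <- if (bal$balanced) "balanced" else {
      paste0("unbalanced(", paste(names(bal$diff), bal$diff, sep = ":",
                                  collapse = ","), ")")
    }
    if (!quiet) message("row ", i, " [", row$id, "]: ", balance_log[i])
    reactions[[i]] <- rxn
  }
  db <- reaction_db(reactions)
  attr(db, "log") <- data.frame(id = tab$id, balance = balance_log,
                                stringsAsFactors = FALSE)
  db
}

#' Write a reaction database to TSV
#'
#' Emits columns in the canonical order; atom maps are retained in
#' `reaction_smiles`. `load_db(write_db(db))` reproduces an equal database.
#'
#' @param db an `rpe_reaction_db`.
#' @param path output file path.
#' @export
write_db <- function(db, path) {
  rows <- lapply(db$reactions, function(r) {
    data.frame(id = r$id,
               reaction_smiles = reaction_smiles_of(r, mapped = TRUE),
               reversibility = r$reversibility,
               ec = paste(r$ec_numbers, collapse = ";"),
               enzyme_name = paste(r$enzyme_names, collapse = ";"),
               source = r$source,
               stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  if (is.null(tab)) {
    tab <- as.data.frame(stats::setNames(rep(list(character(0)), 6), .DB_COLUMNS))
  }
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     fileEncoding = "UTF-8")
  invisible(path)
}

#' Remove redundant reactions
#'
#' Keeps the first occurrence per direction-sensitive canonical key. A
#' reaction is also redundant when its as-written key equals the reversed key
#' of an already-kept reversible reaction (the kept reaction's reverse
#' direction covers it). Enzyme annotations of discarded duplicates are
#' merged into the kept record. Idempotent.
#'
#' @param db an `rpe_reaction_db`.
#' @param quiet suppress the removal-count message.
#' @return deduplicated `rpe_reaction_db`.
#' @export
deduplicate <- function(db, quiet = TRUE) {
  kept <- list()
  covered <- character(0)           # direction keys already covered
  key_of_kept <- character(0)       # as-written key -> kept id
  removed <- 0L
  for (r in db$reactions) {
    k <- canonical_reaction_key(r, "as_written")
    if (k %in% covered) {
      removed <- removed + 1L
      # merge annotations into the kept record with the same coverage
      tgt <- key_of_kept[[k]]
      if (!is.null(tgt) && !is.na(tgt)) {
        kept[[tgt]]$ec_numbers <- unique(c(kept[[tgt]]$ec_numbers, r$ec_numbers))
        kept[[tgt]]$enzyme_names <- unique(c(kept[[tgt]]$enzyme_names,
                                             r$enzyme_names))
      }
      next
    }
    kept[[r$id]] <- r
    covered <- c(covered, k)
    key_of_kept[k] <- r$id
    if (r$reversibility == "reversible") {
      kr <- canonical_reaction_key(r, "reversed")
      covered <- c(covered, kr)
      key_of_kept[kr] <- r$id
    }
  }
  if (!quiet) message("deduplicate: removed ", removed, " redundant reaction(s)")
  out <- reaction_db(unname(kept))
  attr(out, "removed") <- removed
  out
}

#' Directions in which biotransformation rules are generated
#'
#' Reversible reactions yield two rules (one per direction); irreversible or
#' unknown reversibility yields a single as-written rule.
#'
#' @param rxn an `rpe_reaction`.
#' @return character vector of directions.
#' @export
rule_directions <- function(rxn) {
  if (rxn$reversibility == "reversible") c("as_written", "reversed")
  else "as_written"
}

#' Exact-match lookup of a candidate reaction
#'
#' Returns ids of database reactions whose direction-equivalent canonical key
#' matches the candidate as written. An empty result means the candidate is a
#' novel reaction.
#'
#' @param rxn_candidate an `rpe_reaction`.
#' @param db an `rpe_reaction_db`.
#' @return character vector of matching reaction ids (possibly empty).
#' @export
find_exact <- function(rxn_candidate, db) {
  k <- canonical_reaction_key(rxn_candidate, "as_written")
  hits <- db$key_index[names(db$key_index) == k]
  unique(unname(hits))
}

#' @export
print.rpe_reaction_db <- function(x, ...) {
  cat("<rpe_reaction_db> ", length(x$reactions), " reactions, ",
      length(x$compound_index), " distinct compounds\n", sep = "")
  invisible(x)
}
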