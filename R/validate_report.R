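#' Scan selected peptides against the nonredundant database
#'
#' Finds every exact substring occurrence of every selected peptide in every
#' database representative and checks whether each occurrence could actually
#' be produced by the digestion rule at that locus: the occurrence must
#' start at the protein N-terminus or be preceded by a cleavable residue
#' whose cut is not blocked by the peptide's first residue, and must end at
#' the C-terminus or terminate in a cleavable residue whose cut is not
#' blocked by the following residue. Exact search is the strictest reading
#' of a short-peptide alignment filtered to zero mismatches and zero gaps.
#' An optional near-match mode additionally reports single-substitution
#' occurrences for diagnostics; these are never context-valid.
#'
#' @param peptides Character vector of selected peptide sequences.
#' @param db An `nr_db`.
#' @param rule The [cleavage_rule()] used for digestion.
#' @param max_mismatch 0 (default, exact only) or 1 to also report
#'   single-substitution near-matches (`exact = FALSE`).
#' @return Tibble `peptide`, `protein_id`, `position` (0-based start,
#'   half-open), `exact`, `context_valid`. Errors if a selected peptide has
#'   no exact occurrence anywhere in the database (selected peptides must
#'   exist in their source variants).
#' @export
specificity_scan <- function(peptides, db, rule = cleavage_rule(),
                             max_mismatch = 0L) {
  stopifnot(inherits(db, "nr_db"), max_mismatch %in% c(0L, 1L))
  peptides <- unique(as.character(peptides))
  if (length(peptides) == 0L) {
    return(tibble(peptide = character(), protein_id = character(),
                  position = integer(), exact = logical(),
                  context_valid = logical()))
  }
  subjects <- Biostrings::AAStringSet(db$representatives$sequence)
  names(subjects) <- db$representatives$id
  rows <- purrr::map(peptides, function(pep) {
    m <- Biostrings::vmatchPattern(pep, subjects,
                                   max.mismatch = max_mismatch)
    starts <- Biostrings::startIndex(m)
    hit_idx <- which(lengths(starts) > 0L)
    if (length(hit_idx) == 0L) {
      return(tibble(peptide = character(), protein_id = character(),
                    position = integer(), exact = logical(),
                    context_valid = logical()))
    }
    purrr::map(hit_idx, function(i) {
      s <- db$representatives$sequence[[i]]
      st <- starts[[i]]                      # 1-based starts
      en <- st + nchar(pep) - 1L
      exact <- substring(s, st, en) == pep
      prev <- ifelse(st > 1L, substring(s, st - 1L, st - 1L), "")
      nxt <- ifelse(en < nchar(s), substring(s, en + 1L, en + 1L), "")
      first <- substring(pep, 1L, 1L)
      last <- substring(pep, nchar(pep), nchar(pep))
      left_ok <- st == 1L |
        (prev %in% rule$cleave_after & !(first %in% rule$blocked_by_next))
      right_ok <- en == nchar(s) |
        (last %in% rule$cleave_after & !(nxt %in% rule$blocked_by_next))
      tibble(peptide = pep,
             protein_id = db$representatives$id[[i]],
             position = st - 1L,
             exact = exact,
             context_valid = exact & left_ok & right_ok)
    }) |> bind_rows()
  })
  hits <- bind_rows(rows)
  no_exact <- if (max_mismatch == 0L) {
    setdiff(peptides, hits$peptide[hits$exact])
  } else {
    character()  # diagnostic mode: absence is reportable, not fatal
  }
  if (length(no_exact) > 0L) {
    abort(paste0("selected peptide(s) without any exact occurrence in the ",
                 "database: ", paste(no_exact, collapse = ", ")))
  }
  hits |> arrange(.data$peptide, .data$protein_id, .data$position)
}

#' Per-protein validation report
#'
#' For every database protein carrying at least one context-valid peptide
#' occurrence: the number of distinct selected peptides it contains, its
#' global percent identity to the reference, and whether it belongs to the
#' retained variant set. Proteins outside the variant set (off-target) are
#' what the peptide-count threshold reasoning is about: a protein sharing
#' only one of several selected peptides is likely an accessory protein
#' rather than an allelic variant.
#'
#' @param hits Hit table from [specificity_scan()].
#' @param db An `nr_db`.
#' @param reference Reference protein.
#' @param variant_set A `variant_set` (or character vector of variant ids).
#' @return An object of class `validation_report`: list with `proteins`
#'   (tibble `protein_id`, `n_peptides`, `pct_identity`, `in_variant_set`)
#'   and `hits` (the context-valid hit table).
#' @export
validation_report <- function(hits, db, reference, variant_set) {
  ref <- as_reference(reference)
  variant_ids <- if (inherits(variant_set, "variant_set")) {
    variant_set$variants$id
  } else {
    as.character(variant_set)
  }
  valid <- hits |> filter(.data$context_valid)
  per_protein <- valid |>
    group_by(protein_id = .data$protein_id) |>
    summarise(n_peptides = dplyr::n_distinct(.data$peptide), .groups = "drop")
  seqs <- db$representatives$sequence[match(per_protein$protein_id,
                                            db$representatives$id)]
  gs <- global_stats(seqs, ref$sequence)
  proteins <- per_protein |>
    mutate(pct_identity = gs$pct_identity,
           in_variant_set = .data$protein_id %in% variant_ids) |>
    arrange(.data$protein_id)
  structure(list(proteins = proteins, hits = valid),
            class = "validation_report")
}

#' @export
print.validation_report <- function(x, ...) {
  off <- sum(!x$proteins$in_variant_set)
  cat("<validation_report> ", nrow(x$proteins),
      " protein(s) with context-valid peptide hits; ", off,
      " off-target\n", sep = "")
  invisible(x)
}
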