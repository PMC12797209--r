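#' Build the peptide x variant presence/absence matrix
#'
#' Digests every retained allelic variant and records which peptides are
#' digestion products of which variants. Peptides flagged as multi-copy
#' during database preparation, and any user-excluded peptides, are removed
#' from the matrix before selection. A variant left with no remaining
#' peptide keeps its (all-false) column and is flagged; it will end up
#' uncoverable.
#'
#' @param variant_set A `variant_set` from [select_variants()] /
#'   [frequency_filter()], or a tibble with `id` and `sequence` columns.
#' @param rule A [cleavage_rule()].
#' @param multicopy Optional `multicopy_set` (or character vector of
#'   peptides) to exclude.
#' @param user_exclude Optional character vector of peptides to exclude.
#' @param min_length,max_length Optional peptide length bounds (residues);
#'   peptides outside the bounds are dropped from the matrix. Off by
#'   default; useful to restrict the pool to mass-spectrometry-friendly
#'   lengths.
#' @return An object of class `presence_matrix`: list with `mat` (logical
#'   matrix, peptide rows in first-occurrence order, variant columns in
#'   variant order), `dropped_multicopy`, `dropped_user`, `empty_variants`.
#' @export
build_matrix <- function(variant_set, rule = cleavage_rule(),
                         multicopy = NULL, user_exclude = NULL,
                         min_length = NULL, max_length = NULL) {
  variants <- if (inherits(variant_set, "variant_set")) {
    variant_set$variants
  } else {
    variant_set
  }
  stopifnot(is.data.frame(variants), nrow(variants) > 0L,
            all(c("id", "sequence") %in% names(variants)))
  mc <- if (inherits(multicopy, "multicopy_set")) multicopy$peptides else
    as.character(multicopy %||% character())
  excl <- as.character(user_exclude %||% character())

  digests <- lapply(variants$sequence, function(s) unique(digest(s, rule)))
  all_pep <- unique(unlist(digests, use.names = FALSE))  # first-occurrence order
  if (!is.null(min_length)) all_pep <- all_pep[nchar(all_pep) >= min_length]
  if (!is.null(max_length)) all_pep <- all_pep[nchar(all_pep) <= max_length]
  drop_mc <- all_pep[all_pep %in% mc]
  drop_user <- all_pep[all_pep %in% excl & !(all_pep %in% mc)]
  keep <- setdiff(all_pep, c(drop_mc, drop_user))

  mat <- matrix(FALSE, nrow = length(keep), ncol = nrow(variants),
                dimnames = list(keep, variants$id))
  for (j in seq_along(digests)) {
    mat[intersect(keep, digests[[j]]), j] <- TRUE
  }
  empty <- colnames(mat)[colSums(mat) == 0L]
  if (length(empty) > 0L) {
    warn(paste0("variant(s) with no remaining peptide after exclusions: ",
                paste(empty, collapse = ", ")))
  }
  structure(list(mat = mat,
                 dropped_multicopy = drop_mc,
                 dropped_user = drop_user,
                 empty_variants = empty),
            class = "presence_matrix")
}

#' @export
print.presence_matrix <- function(x, ...) {
  cat("<presence_matrix> ", nrow(x$mat), " peptide(s) x ", ncol(x$mat),
      " variant(s); ", length(x$dropped_multicopy),
      " multi-copy and ", length(x$dropped_user),
      " user-excluded peptide(s) removed\n", sep = "")
  invisible(x)
}

#' Initialize a peptide selection state
#'
#' @param matrix A `presence_matrix`.
#' @param target Number of covering peptides required per variant
#'   (default 3).
#' @return An object of class `selection_state` tracking the minimum list,
#'   per-variant coverage, remaining candidate peptides, and uncoverable
#'   variants.
#' @export
selection_state <- function(matrix, target = 3L) {
  stopifnot(inherits(matrix, "presence_matrix"), target >= 1)
  structure(list(
    mat = matrix$mat,
    target = as.integer(target),
    minimum_list = character(),
    selected_from = character(),   # "user" or "greedy", parallel to minimum_list
    coverage = stats::setNames(integer(ncol(matrix$mat)), colnames(matrix$mat)),
    remaining = rownames(matrix$mat),
    uncoverable = character()),
    class = "selection_state")
}

select_peptide <- function(state, peptide, from) {
  state$minimum_list <- c(state$minimum_list, peptide)
  state$selected_from <- c(state$selected_from, from)
  state$coverage <- state$coverage + as.integer(state$mat[peptide, ])
  state$remaining <- setdiff(state$remaining, peptide)
  state
}

#' Seed the minimum list with user-supplied peptides
#'
#' Each user peptide that is present as a matrix row (hence neither
#' multi-copy nor excluded) is moved to the minimum list and removed from
#' the candidate pool; coverage is updated. Absent peptides are reported
#' with a warning, never added.
#'
#' @param state A freshly initialized [selection_state()].
#' @param include Character vector of peptide sequences to force-include.
#' @return The updated `selection_state`.
#' @export
seed_with_user_list <- function(state, include) {
  stopifnot(inherits(state, "selection_state"))
  include <- unique(as.character(include %||% character()))
  missing <- include[!(include %in% state$remaining)]
  if (length(missing) > 0L) {
    warn(paste0("user peptide(s) not in the presence matrix ",
                "(absent, multi-copy, or excluded), ignored: ",
                paste(missing, collapse = ", ")))
  }
  for (p in include[include %in% state$remaining]) {
    state <- select_peptide(state, p, "user")
  }
  state
}

#' Greedy minimal peptide selection
#'
#' Selects peptides until every allelic variant is covered by at least
#' `target` peptides of the minimum list, where possible. Each round:
#' (a) take the under-covered variants with the lowest current coverage;
#' (b) list the remaining peptides contained in those variants;
#' (c) keep the peptides of (b) covering the highest number of
#' under-covered variants overall; (d) for each such peptide, list its
#' under-covered variants; (e) score the peptide by the smallest number of
#' remaining potential peptides among those variants, and select the
#' peptide with the smallest score — the one rescuing the peptide-poorest
#' variant — breaking ties by byte order of the peptide sequence. The
#' selected peptide moves to the minimum list and its row leaves the
#' candidate pool. Variants that can no longer reach the target are set
#' aside as uncoverable. The loop always terminates: every round removes
#' one row.
#'
#' @param x A `presence_matrix` or a (possibly seeded) `selection_state`.
#' @param target Required covering peptides per variant (used when `x` is a
#'   matrix; default 3).
#' @return The final `selection_state`, with `minimum_list`, `coverage`,
#'   and `uncoverable` filled in.
#' @examples
#' m <- matrix(FALSE, 4, 4, dimnames = list(paste0("p", 1:4), paste0("V", 1:4)))
#' m["p1", c("V1", "V2")] <- TRUE; m["p2", c("V2", "V3")] <- TRUE
#' m["p3", c("V1", "V4")] <- TRUE; m["p4", "V3"] <- TRUE
#' pm <- structure(list(mat = m, dropped_multicopy = character(),
#'                      dropped_user = character(), empty_variants = character()),
#'                 class = "presence_matrix")
#' greedy_select(pm, target = 1)$minimum_list  # "p3" then "p2"
#' @export
greedy_select <- function(x, target = 3L) {
  state <- if (inherits(x, "presence_matrix")) selection_state(x, target) else x
  stopifnot(inherits(state, "selection_state"))
  mat <- state$mat
  repeat {
    remaining <- state$remaining
    potential <- if (length(remaining) > 0L) {
      colSums(mat[remaining, , drop = FALSE])
    } else {
      stats::setNames(integer(ncol(mat)), colnames(mat))
    }
    under <- names(state$coverage)[state$coverage < state$target]
    newly_lost <- under[potential[under] == 0L & !(under %in% state$uncoverable)]
    state$uncoverable <- sort_c(c(state$uncoverable, newly_lost))
    under <- setdiff(under, state$uncoverable)
    if (length(under) == 0L) break
    # (a) under-covered variants at minimal coverage
    a <- under[state$coverage[under] == min(state$coverage[under])]
    # (b) remaining peptides present in at least one of (a)
    in_a <- rowSums(mat[remaining, a, drop = FALSE]) > 0L
    b <- remaining[in_a]
    # (c) peptides of (b) covering the most under-covered variants
    n_under <- rowSums(mat[b, under, drop = FALSE])
    cands <- b[n_under == max(n_under)]
    # (d)/(e) score = min remaining-peptide count among the candidate's
    # under-covered variants; pick the smallest, ties by byte order
    score <- vapply(cands, function(p) {
      d <- under[mat[p, under]]
      min(potential[d])
    }, numeric(1))
    pick <- sort_c(cands[score == min(score)])[[1L]]
    state <- select_peptide(state, pick, "greedy")
  }
  state
}

#' @export
print.selection_state <- function(x, ...) {
  covered <- sum(x$coverage >= x$target)
  cat("<selection_state> ", length(x$minimum_list), " peptide(s) selected; ",
      covered, "/", length(x$coverage), " variant(s) at coverage >= ",
      x$target,
      if (length(x$uncoverable) > 0L)
        paste0("; ", length(x$uncoverable), " uncoverable"),
      "\n", sep = "")
  invisible(x)
}

#' Write the minimum peptide list as a FAA file
#'
#' Headers carry the selection rank, origin (user seed or greedy), and the
#' number of variants each peptide covers.
#'
#' @param state Final `selection_state`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_minimum_faa <- function(state, path) {
  stopifnot(inherits(state, "selection_state"))
  if (length(state$minimum_list) == 0L) {
    writeLines(character(), path)
    return(invisible(path))
  }
  n_cov <- vapply(state$minimum_list, function(p) sum(state$mat[p, ]),
                  integer(1))
  write_faa(tibble(id = sprintf("pep%03d", seq_along(state$minimum_list)),
                   description = paste0("source=", state$selected_from,
                                        " variants_covered=", n_cov),
                   sequence = state$minimum_list),
            path)
}
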