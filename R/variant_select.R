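as_reference <- function(reference) {
  if (is.data.frame(reference)) {
    stopifnot(nrow(reference) == 1L, all(c("id", "sequence") %in% names(reference)))
    list(id = reference$id[[1L]], sequence = reference$sequence[[1L]])
  } else if (is.list(reference) && all(c("id", "sequence") %in% names(reference))) {
    list(id = reference$id, sequence = reference$sequence)
  } else if (is.character(reference) && length(reference) == 1L) {
    list(id = "reference", sequence = reference)
  } else {
    abort("reference must be a one-row protein tibble, a list(id, sequence), or a sequence string")
  }
}

#' Find allelic-variant candidates of a reference protein
#'
#' Runs the local similarity search of the reference against the
#' nonredundant database, expands each hit to genome level through its
#' cluster membership, and keeps, per genome, only the highest-scoring hit
#' (ties broken by subject id). The candidate set is the distinct
#' representatives that are the best hit in at least one genome, with their
#' full sequences and observation counts from the cluster table.
#'
#' @param reference Reference protein: one-row tibble (`id`, `sequence`),
#'   list, or bare sequence string.
#' @param db An `nr_db`.
#' @param min_identity,min_coverage Local-search thresholds in percent
#'   (defaults 60/60).
#' @param ... Further arguments passed to [local_search()].
#' @return Tibble of candidates: `id`, `description`, `sequence`,
#'   `observations` (cluster size), `score`, `pct_identity`,
#'   `query_coverage`, `best_in` (list-column: genomes where this candidate
#'   is the best hit), `genomes` (list-column: all genomes holding an
#'   identical member).
#' @export
find_candidates <- function(reference, db, min_identity = 60,
                            min_coverage = 60, ...) {
  ref <- as_reference(reference)
  hits <- local_search(ref$sequence, db, min_identity = min_identity,
                       min_coverage = min_coverage, query_id = ref$id, ...)
  if (nrow(hits) == 0L) {
    abort("reference not found in database: no hit above the identity/coverage thresholds")
  }
  cl <- db$clusters
  cl_idx <- match(hits$subject_id, cl$representative_id)
  per_genome <- tibble(
    subject_id = rep(hits$subject_id, lengths(cl$member_ids[cl_idx])),
    score = rep(hits$score, lengths(cl$member_ids[cl_idx])),
    genome_id = member_genomes(unlist(cl$member_ids[cl_idx], use.names = FALSE))
  ) |>
    distinct(.data$subject_id, .data$score, .data$genome_id)
  best <- per_genome[order(per_genome$genome_id, -per_genome$score,
                           per_genome$subject_id, method = "radix"), ] |>
    group_by(.data$genome_id) |>
    slice(1L) |>
    ungroup()
  keep_ids <- sort_c(unique(best$subject_id))
  reps <- db$representatives
  ri <- match(keep_ids, reps$id)
  ci <- match(keep_ids, cl$representative_id)
  hi <- match(keep_ids, hits$subject_id)
  tibble(
    id = keep_ids,
    description = reps$description[ri],
    sequence = reps$sequence[ri],
    observations = cl$n_members[ci],
    score = hits$score[hi],
    pct_identity = hits$pct_identity[hi],
    query_coverage = hits$query_coverage[hi],
    best_in = lapply(keep_ids, function(s) sort_c(best$genome_id[best$subject_id == s])),
    genomes = lapply(ci, function(i) sort_c(unique(member_genomes(cl$member_ids[[i]]))))
  )
}

#' Filter candidates by length/identity divergence to the reference
#'
#' Each candidate is globally aligned to the reference. The divergence
#' metric is the absolute difference, in percentage points, between the
#' length ratio of the two raw sequences (`pct_length`, 100 x shorter /
#' longer) and the global percent identity. A length-conserved variant with
#' identity I has divergence roughly 100 - I, so the threshold bounds how
#' much an allelic variant may diverge from the reference while paralogs and
#' unrelated proteins are removed.
#'
#' @param candidates Candidate tibble from [find_candidates()].
#' @param reference Reference protein (as in [find_candidates()]).
#' @param max_divergence Maximum divergence in percentage points. The
#'   default, 25, keeps length-conserved variants down to roughly 75%
#'   identity; it is deliberately a prominent tuning knob since no single
#'   value suits every protein family.
#' @return The candidate tibble restricted to surviving rows, with added
#'   columns `global_identity`, `pct_length`, `divergence`.
#' @export
divergence_filter <- function(candidates, reference, max_divergence = 25) {
  stopifnot(is.data.frame(candidates))
  if (nrow(candidates) == 0L) {
    abort("divergence_filter: no candidates supplied")
  }
  ref <- as_reference(reference)
  gs <- global_stats(candidates$sequence, ref$sequence)
  candidates |>
    mutate(global_identity = gs$pct_identity,
           pct_length = gs$pct_length,
           divergence = abs(gs$pct_length - gs$pct_identity)) |>
    filter(.data$divergence <= max_divergence)
}

#' Resolve within-genome ambiguity by iterative clustering with the reference
#'
#' When a genome still contributes more than one retained sequence, the
#' retained candidates plus the reference are clustered greedily
#' ([greedy_cluster()]) at an identity threshold starting at `start` percent
#' and increasing by `step` after each round; only the members of the
#' reference's cluster are retained. The loop stops when every genome
#' contributes at most one sequence, or when the threshold exceeds 100 (the
#' degenerate case of true duplicate loci), in which case the affected
#' genomes are reported as a warning.
#'
#' @param candidates Candidate tibble (must carry the `genomes` list-column).
#' @param reference Reference protein.
#' @param start Initial identity threshold in percent (default 70).
#' @param step Threshold increment per round (default 0.5).
#' @return The retained candidate tibble.
#' @export
iterative_cluster_filter <- function(candidates, reference, start = 70,
                                     step = 0.5) {
  stopifnot(is.data.frame(candidates), "genomes" %in% names(candidates))
  ref <- as_reference(reference)
  ref_id <- "..reference.."
  retained <- candidates
  threshold <- start
  repeat {
    if (nrow(retained) <= 1L) break
    genome_tab <- table(unlist(retained$genomes, use.names = FALSE))
    if (all(genome_tab <= 1L)) break
    multi <- sort_c(names(genome_tab)[genome_tab > 1L])
    if (threshold > 100) {
      warn(paste0("iterative clustering reached threshold > 100 with ",
                  "multiple sequences remaining in genome(s): ",
                  paste(multi, collapse = ", ")))
      break
    }
    pool <- tibble(id = c(ref_id, retained$id),
                   sequence = c(ref$sequence, retained$sequence))
    cl <- greedy_cluster(pool, threshold)
    ref_cluster <- cl$cluster[cl$id == ref_id]
    keep <- cl$id[cl$cluster == ref_cluster & cl$id != ref_id]
    if (length(keep) == 0L) {
      # every remaining candidate separated from the reference at once:
      # equidistant duplicate loci that clustering cannot resolve
      warn(paste0("iterative clustering could not resolve duplicate loci ",
                  "in genome(s): ", paste(multi, collapse = ", ")))
      break
    }
    retained <- retained |> filter(.data$id %in% keep)
    threshold <- threshold + step
  }
  retained
}

#' Frequency filter: retain the most-observed variants
#'
#' Candidates are sorted by observation count (cluster size) descending,
#' ties broken by id, and the shortest prefix whose cumulative share of
#' total observations reaches `keep_fraction` is retained. A candidate whose
#' sequence is identical to the reference is always retained regardless of
#' rank.
#'
#' @param candidates Candidate tibble with an `observations` column.
#' @param reference Reference protein.
#' @param keep_fraction Fraction of total observations to retain
#'   (default 0.98).
#' @return An object of class `variant_set`: list with `reference`
#'   (list `id`, `sequence`), `variants` (the retained tibble) and
#'   `retained_fraction` (achieved share of observations).
#' @export
frequency_filter <- function(candidates, reference, keep_fraction = 0.98) {
  stopifnot(is.data.frame(candidates), "observations" %in% names(candidates))
  if (nrow(candidates) == 0L) {
    abort("frequency_filter: no candidates supplied")
  }
  stopifnot(keep_fraction > 0, keep_fraction <= 1)
  ref <- as_reference(reference)
  ord <- order(-candidates$observations, candidates$id, method = "radix")
  s <- candidates[ord, ]
  total <- sum(s$observations)
  cum <- cumsum(s$observations)
  n_keep <- which(cum >= keep_fraction * total)[[1L]]
  keep <- seq_len(nrow(s)) <= n_keep | s$sequence == ref$sequence
  variants <- s[keep, ]
  structure(list(reference = ref,
                 variants = variants,
                 retained_fraction = sum(variants$observations) / total),
            class = "variant_set")
}

#' @export
print.variant_set <- function(x, ...) {
  cat("<variant_set> ", nrow(x$variants), " allelic variant(s) of '",
      x$reference$id, "' (", round(100 * x$retained_fraction, 2),
      "% of observations)\n", sep = "")
  invisible(x)
}

#' Select the allelic variants of a reference protein
#'
#' Convenience wrapper chaining [find_candidates()], [divergence_filter()],
#' [iterative_cluster_filter()] and [frequency_filter()]. Each stage only
#' removes candidates, so the result is a subset of the initial best-hit
#' set.
#'
#' @inheritParams find_candidates
#' @inheritParams divergence_filter
#' @inheritParams iterative_cluster_filter
#' @inheritParams frequency_filter
#' @param cluster_start,cluster_step Identity schedule of the iterative
#'   clustering stage (defaults 70 and 0.5 percent).
#' @return A `variant_set`.
#' @export
select_variants <- function(reference, db, min_identity = 60,
                            min_coverage = 60, max_divergence = 25,
                            cluster_start = 70, cluster_step = 0.5,
                            keep_fraction = 0.98) {
  find_candidates(reference, db, min_identity = min_identity,
                  min_coverage = min_coverage) |>
    divergence_filter(reference, max_divergence = max_divergence) |>
    iterative_cluster_filter(reference, start = cluster_start,
                             step = cluster_step) |>
    frequency_filter(reference, keep_fraction = keep_fraction)
}
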