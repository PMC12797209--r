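#' Global pairwise protein alignment
#'
#' Optimal Needleman-Wunsch alignment (end gaps penalized) under BLOSUM62
#' with affine gap penalties, gap open 10 and gap extension 0.5 — the
#' defaults of classical global protein aligners. Percent identity follows
#' the convention of counting identical residue pairs over **all** alignment
#' columns, gap columns included; `pct_length` is 100 times the ratio of the
#' shorter to the longer raw sequence length, the length-conservation metric
#' used by the divergence filter.
#'
#' @param a,b Protein sequences (character scalars).
#' @param a_id,b_id Optional identifiers carried into the result.
#' @param gap_opening,gap_extension Affine gap penalties; a gap of length L
#'   costs `gap_opening + L * gap_extension`.
#' @param substitution_matrix Name of the substitution matrix (default
#'   `"BLOSUM62"`).
#' @return Object of class `global_alignment`: list with `query_id`,
#'   `subject_id`, `aligned_query`, `aligned_subject`, `score`,
#'   `pct_identity`, `pct_length`.
#' @examples
#' global_align("MKARLT", "MKARLT")$pct_identity  # 100
#' @export
global_align <- function(a, b, a_id = "query", b_id = "subject",
                         gap_opening = 10, gap_extension = 0.5,
                         substitution_matrix = "BLOSUM62") {
  if (!nzchar(a) || !nzchar(b)) {
    abort("global_align: empty sequence")
  }
  aln <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(a), Biostrings::AAString(b),
    type = "global", substitutionMatrix = substitution_matrix,
    gapOpening = gap_opening, gapExtension = gap_extension)
  qa <- as.character(Biostrings::alignedPattern(aln))
  sa <- as.character(Biostrings::alignedSubject(aln))
  structure(list(
    query_id = a_id, subject_id = b_id,
    aligned_query = unname(qa), aligned_subject = unname(sa),
    score = Biostrings::score(aln),
    pct_identity = 100 * Biostrings::nmatch(aln) / nchar(qa),
    pct_length = 100 * min(nchar(a), nchar(b)) / max(nchar(a), nchar(b))),
    class = "global_alignment")
}

#' @export
print.global_alignment <- function(x, ...) {
  cat("<global_alignment> ", x$query_id, " vs ", x$subject_id,
      ": score ", format(x$score), ", identity ",
      format(round(x$pct_identity, 2)), "%, length ratio ",
      format(round(x$pct_length, 2)), "%\n", sep = "")
  invisible(x)
}

# Vectorized global alignment of many sequences against one reference.
# Returns a tibble with score, pct_identity, pct_length per input sequence.
global_stats <- function(sequences, reference,
                         gap_opening = 10, gap_extension = 0.5,
                         substitution_matrix = "BLOSUM62") {
  if (length(sequences) == 0L) {
    return(tibble(score = double(), pct_identity = double(),
                  pct_length = double()))
  }
  aln <- Biostrings::pairwiseAlignment(
    Biostrings::AAStringSet(sequences), Biostrings::AAString(reference),
    type = "global", substitutionMatrix = substitution_matrix,
    gapOpening = gap_opening, gapExtension = gap_extension)
  alen <- nchar(as.character(Biostrings::alignedPattern(aln)))
  len_a <- nchar(sequences)
  len_b <- nchar(reference)
  tibble(score = Biostrings::score(aln),
         pct_identity = 100 * Biostrings::nmatch(aln) / alen,
         pct_length = 100 * pmin(len_a, len_b) / pmax(len_a, len_b))
}

kmer_set <- function(sequence, k) {
  n <- nchar(sequence)
  if (n < k) return(character())
  unique(substring(sequence, 1:(n - k + 1L), k:n))
}

#' Local similarity search of a query against a nonredundant database
#'
#' Smith-Waterman local alignment (BLOSUM62, gap open 11, extension 1) of
#' the query against every database representative, preceded by a shared
#' k-mer prefilter (default k = 4, at least one exact shared k-mer) that
#' prunes clearly unrelated sequences. Hits are reported when percent
#' identity (identical pairs over local alignment columns) and query
#' coverage (aligned query span over query length) both reach their
#' thresholds, sorted by score descending with ties broken by subject id.
#'
#' @param query Query protein sequence (character scalar).
#' @param db An `nr_db` from [compact_proteins()] or [read_nr_db()].
#' @param min_identity,min_coverage Reporting thresholds in percent
#'   (defaults 60/60).
#' @param query_id Identifier carried into the hit table.
#' @param k k-mer size of the prefilter.
#' @param prefilter Set `FALSE` to align against every representative.
#' @param gap_opening,gap_extension,substitution_matrix Local alignment
#'   scoring (defaults 11 / 1 / BLOSUM62).
#' @return Tibble `query_id`, `subject_id`, `pct_identity`,
#'   `query_coverage`, `score`.
#' @export
local_search <- function(query, db, min_identity = 60, min_coverage = 60,
                         query_id = "query", k = 4L, prefilter = TRUE,
                         gap_opening = 11, gap_extension = 1,
                         substitution_matrix = "BLOSUM62") {
  stopifnot(inherits(db, "nr_db"))
  reps <- db$representatives
  if (nrow(reps) == 0L) {
    abort("local_search: empty database")
  }
  cand <- seq_len(nrow(reps))
  if (prefilter && nchar(query) >= k) {
    qk <- kmer_set(query, k)
    hit_kmer <- map_lgl(reps$sequence, function(s) {
      n <- nchar(s)
      if (n < k) return(TRUE)
      any(substring(s, 1:(n - k + 1L), k:n) %in% qk)
    })
    cand <- cand[hit_kmer]
  }
  if (length(cand) == 0L) {
    return(tibble(query_id = character(), subject_id = character(),
                  pct_identity = double(), query_coverage = double(),
                  score = double()))
  }
  aln <- Biostrings::pairwiseAlignment(
    Biostrings::AAStringSet(reps$sequence[cand]),
    Biostrings::AAString(query),
    type = "local", substitutionMatrix = substitution_matrix,
    gapOpening = gap_opening, gapExtension = gap_extension)
  alen <- nchar(as.character(Biostrings::alignedPattern(aln)))
  hits <- tibble(
    query_id = query_id,
    subject_id = reps$id[cand],
    pct_identity = 100 * Biostrings::nmatch(aln) / alen,
    query_coverage = 100 * Biostrings::width(Biostrings::subject(aln)) /
      nchar(query),
    score = Biostrings::score(aln)) |>
    filter(.data$pct_identity >= min_identity,
           .data$query_coverage >= min_coverage)
  hits[order(-hits$score, hits$subject_id, method = "radix"), ]
}

#' Greedy incremental identity clustering
#'
#' CD-HIT-style clustering: sequences are sorted by decreasing length (ties
#' by id), the first seeds a cluster, and each following sequence joins the
#' first existing cluster whose representative it matches at or above the
#' identity threshold, otherwise it seeds a new cluster. Identity uses the
#' short-sequence convention: identical residue pairs in the global
#' alignment divided by the length of the shorter raw sequence.
#'
#' @param seqs Tibble with columns `id` and `sequence` (ids unique).
#' @param identity_threshold Percent identity in `[0, 100]`.
#' @return The input tibble with added columns `cluster` (integer, in
#'   cluster-creation order) and `representative_id`, ordered by cluster then
#'   id.
#' @export
greedy_cluster <- function(seqs, identity_threshold) {
  stopifnot(is.data.frame(seqs), all(c("id", "sequence") %in% names(seqs)))
  if (nrow(seqs) == 0L) {
    abort("greedy_cluster: empty input")
  }
  stopifnot(identity_threshold >= 0, identity_threshold <= 100,
            !anyDuplicated(seqs$id))
  ord <- order(-nchar(seqs$sequence), seqs$id, method = "radix")
  s <- seqs[ord, ]
  assign_cluster <- integer(nrow(s))
  rep_idx <- integer()          # row index (in s) of each cluster rep
  for (i in seq_len(nrow(s))) {
    joined <- NA_integer_
    if (length(rep_idx) > 0L) {
      aln <- Biostrings::pairwiseAlignment(
        Biostrings::AAStringSet(s$sequence[rep_idx]),
        Biostrings::AAString(s$sequence[[i]]),
        type = "global", substitutionMatrix = "BLOSUM62",
        gapOpening = 10, gapExtension = 0.5)
      ident <- 100 * Biostrings::nmatch(aln) /
        pmin(nchar(s$sequence[rep_idx]), nchar(s$sequence[[i]]))
      ok <- which(ident >= identity_threshold)
      if (length(ok) > 0L) joined <- ok[[1L]]
    }
    if (is.na(joined)) {
      rep_idx <- c(rep_idx, i)
      assign_cluster[[i]] <- length(rep_idx)
    } else {
      assign_cluster[[i]] <- joined
    }
  }
  out <- s |>
    mutate(cluster = assign_cluster,
           representative_id = s$id[rep_idx[assign_cluster]])
  out[order(out$cluster, out$id, method = "radix"), ]
}
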