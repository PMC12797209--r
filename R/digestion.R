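#' Define a protease cleavage rule
#'
#' A rule cleaves the peptide bond after any residue in `cleave_after`,
#' except when the immediately following residue is in `blocked_by_next`.
#' The default is the two-rule trypsin model: cut after lysine (K) or
#' arginine (R) unless the next residue is proline (P). No missed cleavages
#' are simulated.
#'
#' @param name Rule name (free text).
#' @param cleave_after Residues after which the backbone is cut.
#' @param blocked_by_next Residues that, when immediately C-terminal to the
#'   cleavage site, block the cut. May be empty.
#' @return An object of class `cleavage_rule`.
#' @examples
#' cleavage_rule()               # trypsin, two rules
#' cleavage_rule("LysC", "K", character())
#' @export
cleavage_rule <- function(name = "Trypsin-2rules",
                          cleave_after = c("K", "R"),
                          blocked_by_next = "P") {
  cleave_after <- toupper(as.character(cleave_after))
  blocked_by_next <- toupper(as.character(blocked_by_next))
  if (length(cleave_after) == 0L) {
    abort("cleavage_rule: cleave_after must name at least one residue")
  }
  if (length(intersect(cleave_after, blocked_by_next)) > 0L) {
    abort("cleavage_rule: cleave_after and blocked_by_next must be disjoint")
  }
  structure(list(name = name,
                 cleave_after = cleave_after,
                 blocked_by_next = blocked_by_next),
            class = "cleavage_rule")
}

#' @export
print.cleavage_rule <- function(x, ...) {
  cat("<cleavage_rule> ", x$name, ": cut after [",
      paste(x$cleave_after, collapse = ""), "]",
      if (length(x$blocked_by_next) > 0L)
        paste0(" unless next is [", paste(x$blocked_by_next, collapse = ""), "]"),
      "\n", sep = "")
  invisible(x)
}

rule_split_regex <- function(rule) {
  cls <- paste(rule$cleave_after, collapse = "")
  if (length(rule$blocked_by_next) > 0L) {
    sprintf("(?<=[%s])(?=[^%s])", cls, paste(rule$blocked_by_next, collapse = ""))
  } else {
    sprintf("(?<=[%s])(?=.)", cls)
  }
}

#' Digest protein sequences in silico
#'
#' Splits each sequence at every position satisfying the cleavage rule and
#' returns the resulting peptides N-terminal to C-terminal. The peptides of a
#' sequence always concatenate back to that sequence (the digest is a
#' partition), and no internal peptide position is a valid cleavage site.
#'
#' @param sequences Character vector of protein sequences.
#' @param rule A [cleavage_rule()]; default trypsin with the proline rule.
#' @return A list (one element per input sequence) of character vectors of
#'   peptides. For convenience, a single unnamed sequence returns the bare
#'   character vector.
#' @examples
#' digest("MARLAKPGR")  # "MAR", "LAKPGR": K before P is not cut
#' digest(c("AAAA", "KRK"))
#' @export
digest <- function(sequences, rule = cleavage_rule()) {
  stopifnot(inherits(rule, "cleavage_rule"))
  if (length(sequences) == 0L) {
    return(list())
  }
  if (any(is.na(sequences) | !nzchar(sequences))) {
    abort("digest: empty sequence")
  }
  out <- strsplit(sequences, rule_split_regex(rule), perl = TRUE)
  if (length(sequences) == 1L && is.null(names(sequences))) {
    return(out[[1L]])
  }
  names(out) <- names(sequences)
  out
}

#' Digest every protein of a panel into a long peptide table
#'
#' @param proteins Protein tibble.
#' @param rule A [cleavage_rule()].
#' @return Tibble `genome_id`, `protein_id`, `peptide`, `pos` (1-based rank
#'   of the peptide within its protein, N to C).
#' @export
digest_proteins <- function(proteins, rule = cleavage_rule()) {
  stopifnot(is.data.frame(proteins))
  peps <- strsplit(proteins$sequence, rule_split_regex(rule), perl = TRUE)
  n <- lengths(peps)
  tibble(genome_id = rep(proteins$genome_id, n),
         protein_id = rep(proteins$id, n),
         peptide = unlist(peps, use.names = FALSE),
         pos = unlist(lapply(n, seq_len), use.names = FALSE))
}

#' Identify multi-copy peptides across a set of genomes
#'
#' Digests every protein of every genome and flags a peptide as multi-copy
#' when its total occurrence count within a single genome — summed over all
#' proteins of that genome and counting repeats inside one protein — is at
#' least two. The returned set is the union over genomes. Multi-copy peptides
#' cannot quantify a single protein and are excluded from peptide selection.
#'
#' @param proteins Protein tibble covering the genomes to screen.
#' @param rule A [cleavage_rule()].
#' @return An object of class `multicopy_set`: list with `peptides`
#'   (character vector, byte-sorted) and `counts` (tibble `genome_id`,
#'   `peptide`, `count` restricted to counts >= 2).
#' @examples
#' prot <- tibble::tibble(id = c("a", "b"), description = "",
#'                        genome_id = "g1",
#'                        sequence = c("AAKCCR", "AAKDDR"))
#' find_multicopy(prot)$peptides   # "AAK" occurs twice in g1
#' @export
find_multicopy <- function(proteins, rule = cleavage_rule()) {
  long <- digest_proteins(proteins, rule)
  counts <- long |>
    count(.data$genome_id, .data$peptide, name = "count") |>
    filter(.data$count >= 2L) |>
    arrange(.data$genome_id, .data$peptide)
  structure(list(peptides = sort_c(unique(counts$peptide)),
                 counts = counts),
            class = "multicopy_set")
}

#' @export
print.multicopy_set <- function(x, ...) {
  cat("<multicopy_set> ", length(x$peptides), " peptide(s) with >=2 copies",
      " in at least one genome\n", sep = "")
  invisible(x)
}

#' Write multi-copy peptides as a FAA file
#'
#' One record per peptide; the header carries a stable index and the maximum
#' per-genome occurrence count.
#'
#' @param multicopy A `multicopy_set` from [find_multicopy()].
#' @param path Output FAA path.
#' @return `path`, invisibly.
#' @export
write_multicopy_faa <- function(multicopy, path) {
  stopifnot(inherits(multicopy, "multicopy_set"))
  if (length(multicopy$peptides) == 0L) {
    writeLines(character(), path)
    return(invisible(path))
  }
  max_counts <- multicopy$counts |>
    group_by(.data$peptide) |>
    summarise(max_count = max(.data$count), .groups = "drop")
  ord <- tibble(peptide = multicopy$peptides) |>
    left_join(max_counts, by = "peptide")
  write_faa(tibble(id = sprintf("mc%05d", seq_along(ord$peptide)),
                   description = paste0("max_per_genome_count=", ord$max_count),
                   sequence = ord$peptide),
            path)
}

#' Read a multi-copy peptide FAA back into a `multicopy_set`
#'
#' Round-trips the file written by [write_multicopy_faa()]. Per-genome counts
#' are not stored in the file; only the peptide set is reconstructed.
#'
#' @param path FAA file of peptides.
#' @return A `multicopy_set` with an empty `counts` table.
#' @export
read_multicopy_faa <- function(path) {
  info <- file.info(path)
  if (!is.na(info$size) && info$size == 0) {
    peps <- character()
  } else {
    peps <- read_faa(path)$sequence
  }
  structure(list(peptides = sort_c(unique(peps)),
                 counts = tibble(genome_id = character(),
                                 peptide = character(),
                                 count = integer())),
            class = "multicopy_set")
}
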