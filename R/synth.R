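# Residue sampling frequencies loosely matching bacterial proteomes;
# K + R ~ 11% so tryptic peptides have realistic lengths (mean ~9).
AA_FREQ <- c(A = 8.9, C = 1.0, D = 5.4, E = 6.2, F = 4.0, G = 7.4, H = 2.2,
             I = 7.3, K = 6.5, L = 10.0, M = 2.3, N = 4.3, P = 4.0, Q = 3.7,
             R = 4.8, S = 6.2, T = 5.6, V = 7.0, W = 1.1, Y = 3.1)

random_protein <- function(length) {
  paste(sample(names(AA_FREQ), length, replace = TRUE, prob = AA_FREQ),
        collapse = "")
}

#' Introduce an exact number of amino-acid substitutions
#'
#' Replaces exactly `n_substitutions` distinct positions with a different
#' residue drawn from the 20-letter alphabet, so the Hamming distance to the
#' input is exactly `n_substitutions`. Positions listed in `protect` are
#' never touched (useful to preserve cleavage sites around peptides of
#' interest).
#'
#' @param sequence Protein sequence.
#' @param n_substitutions Number of positions to change; must be smaller
#'   than the number of mutable positions.
#' @param seed Optional seed for reproducibility; when `NULL` the current
#'   RNG stream is used.
#' @param protect Integer positions exempt from mutation.
#' @return The mutated sequence.
#' @examples
#' mutate_protein("MKAARLT", 2, seed = 1)
#' @export
mutate_protein <- function(sequence, n_substitutions, seed = NULL,
                           protect = integer()) {
  run <- function() {
    chars <- strsplit(sequence, "", fixed = TRUE)[[1L]]
    mutable <- setdiff(seq_along(chars), protect)
    if (n_substitutions >= length(chars) || n_substitutions > length(mutable)) {
      abort("mutate_protein: n_substitutions too large for this sequence")
    }
    if (n_substitutions == 0L) return(sequence)
    pos <- sample(mutable, n_substitutions)
    chars[pos] <- vapply(chars[pos], function(old) {
      sample(setdiff(STANDARD_AA, old), 1L)
    }, character(1))
    paste(chars, collapse = "")
  }
  if (is.null(seed)) run() else withr::with_seed(seed, run())
}

identity_to_nsub <- function(length, identity) {
  n <- as.integer(round(length * (1 - identity)))
  max(0L, min(length - 1L, n))
}

# Destroy every tryptic peptide of `sequence` that also occurs in the
# forbidden set, by substituting one residue inside each shared peptide
# (never to K/R/P, so no new cleavage sites appear). This is what makes the
# generated panel "uniqueness-guaranteed": no non-family protein can yield
# a context-valid occurrence of any family peptide.
scrub_shared_peptides <- function(sequence, forbidden, rule,
                                  max_rounds = 25L) {
  safe <- setdiff(STANDARD_AA, c(rule$cleave_after, rule$blocked_by_next))
  for (round in seq_len(max_rounds)) {
    peps <- digest(sequence, rule)
    shared <- which(peps %in% forbidden)
    if (length(shared) == 0L) return(sequence)
    offsets <- cumsum(c(0L, nchar(peps)))
    for (i in shared) {
      pos <- offsets[i] + sample(nchar(peps[i]), 1L)
      old <- substring(sequence, pos, pos)
      substr(sequence, pos, pos) <- sample(setdiff(safe, old), 1L)
    }
  }
  abort("scrub_shared_peptides: failed to remove shared peptides")
}

#' Generate a synthetic proteome panel with planted ground truth
#'
#' Emulates the inputs of the pipeline: a directory's worth of per-genome
#' protein panels, each holding shared core proteins, genome-specific
#' background proteins, one planted allelic variant of a reference protein
#' (substitutions only, within a stated identity band), and optionally a
#' diverged decoy paralog, a duplicated protein (creating expected
#' multi-copy peptides), and spurious genomes (ambiguous residues or an
#' inflated protein count).
#'
#' Peptide uniqueness is guaranteed by construction: every non-family
#' protein (core, background, decoy, duplicate) is scrubbed of any tryptic
#' peptide shared with the reference or any planted family variant, so a
#' specificity scan of family-derived peptides has a planted truth of zero
#' off-target proteins. Every planted property is returned in `truth`.
#' Generation is fully deterministic given `seed` and the parameters.
#'
#' @param seed Integer seed; the same seed reproduces the panel exactly.
#' @param n_genomes Number of genomes (default 50).
#' @param out_dir Optional directory; when given, one FAA file per genome
#'   plus `reference.faa` and a `truth.json` summary are written there.
#' @param reference Optional reference sequence; generated when `NULL`.
#' @param reference_length Length of the generated reference (default 300).
#' @param n_background_shared Core proteins identical across genomes
#'   (default 15).
#' @param n_background_unique Genome-specific random proteins (default 15).
#' @param background_length Length range of background proteins.
#' @param family_identity Identity band of planted family variants to the
#'   reference (default 0.80–0.95).
#' @param decoy_identity Identity band of decoy paralogs (default
#'   0.40–0.65).
#' @param decoy_fraction Fraction of genomes carrying a decoy (default 0.4).
#' @param duplicated_fraction Fraction of genomes with one duplicated-locus
#'   protein (default 0.2).
#' @param n_spurious_ambiguous Genomes corrupted with an ambiguous residue
#'   (default 1).
#' @param n_spurious_outlier Genomes with an inflated protein count
#'   (default 1).
#' @param outlier_inflation Fractional count inflation of outlier genomes
#'   (default 0.30).
#' @param rule The [cleavage_rule()] used for the uniqueness scrub.
#' @return List with `proteins` (panel tibble over all genomes),
#'   `reference` (one-row tibble), `truth` (planted ground truth: `family`,
#'   `decoys`, `duplicated`, `spurious`, `expected_variants`, `seed`), and
#'   `dir` (when written).
#' @examples
#' pan <- make_panel(seed = 42, n_genomes = 6, reference_length = 120,
#'                   n_background_shared = 4, n_background_unique = 3,
#'                   n_spurious_ambiguous = 0, n_spurious_outlier = 0)
#' dplyr::count(pan$proteins, genome_id)
#' @export
make_panel <- function(seed,
                       n_genomes = 50L,
                       out_dir = NULL,
                       reference = NULL,
                       reference_length = 300L,
                       n_background_shared = 15L,
                       n_background_unique = 15L,
                       background_length = c(120L, 400L),
                       family_identity = c(0.80, 0.95),
                       decoy_identity = c(0.40, 0.65),
                       decoy_fraction = 0.4,
                       duplicated_fraction = 0.2,
                       n_spurious_ambiguous = 1L,
                       n_spurious_outlier = 1L,
                       outlier_inflation = 0.30,
                       rule = cleavage_rule()) {
  stopifnot(n_genomes >= 1L,
            n_spurious_ambiguous + n_spurious_outlier < n_genomes)
  if (identity_to_nsub(reference_length, min(family_identity)) >=
      reference_length) {
    abort("make_panel: identity band infeasible for this reference length")
  }
  withr::with_seed(as.integer(seed), {
    genome_ids <- sprintf("g%03d", seq_len(n_genomes))
    ref_seq <- reference %||% random_protein(reference_length)
    ref_len <- nchar(ref_seq)

    # deterministic assignment of planted roles to genomes
    shuffled <- sample(genome_ids)
    n_spur <- n_spurious_ambiguous + n_spurious_outlier
    spurious_amb <- head(shuffled, n_spurious_ambiguous)
    spurious_out <- head(tail(shuffled, -n_spurious_ambiguous),
                         n_spurious_outlier)
    rest <- tail(shuffled, -n_spur)
    decoy_genomes <- head(rest, round(decoy_fraction * n_genomes))
    dup_genomes <- tail(rest, round(duplicated_fraction * n_genomes))

    # plant the family first so the forbidden peptide set is known
    family_tbl <- bind_rows(lapply(genome_ids, function(g) {
      fam_ident <- stats::runif(1, family_identity[1], family_identity[2])
      tibble(genome_id = g, protein_id = paste0(g, "_fam"),
             sequence = mutate_protein(ref_seq,
                                       identity_to_nsub(ref_len, fam_ident)),
             target_identity = fam_ident)
    }))
    forbidden <- unique(unlist(
      lapply(c(ref_seq, family_tbl$sequence), digest, rule = rule),
      use.names = FALSE))
    clean_protein <- function(length) {
      scrub_shared_peptides(random_protein(length), forbidden, rule)
    }

    shared_bg <- tibble(
      id = sprintf("core%03d", seq_len(n_background_shared)),
      description = sprintf("conserved core protein %d",
                            seq_len(n_background_shared)),
      sequence = vapply(seq_len(n_background_shared), function(i) {
        clean_protein(sample(background_length[1]:background_length[2], 1L))
      }, character(1)))

    decoys <- list(); duplicated <- list()
    panels <- list()
    for (g in genome_ids) {
      uniq <- tibble(
        id = sprintf("%s_u%03d", g, seq_len(n_background_unique)),
        description = "hypothetical protein",
        sequence = vapply(seq_len(n_background_unique), function(i) {
          clean_protein(sample(background_length[1]:background_length[2], 1L))
        }, character(1)))
      fam_row <- family_tbl[family_tbl$genome_id == g, ]
      fam <- tibble(id = fam_row$protein_id,
                    description = "target protein allelic variant",
                    sequence = fam_row$sequence)
      recs <- bind_rows(shared_bg, uniq, fam)
      if (g %in% decoy_genomes) {
        dec_ident <- stats::runif(1, decoy_identity[1], decoy_identity[2])
        dec_seq <- scrub_shared_peptides(
          mutate_protein(ref_seq, identity_to_nsub(ref_len, dec_ident)),
          forbidden, rule)
        recs <- bind_rows(recs, tibble(id = paste0(g, "_decoy"),
                                       description = "paralogous protein",
                                       sequence = dec_seq))
        decoys[[g]] <- tibble(genome_id = g, protein_id = paste0(g, "_decoy"),
                              sequence = dec_seq, target_identity = dec_ident)
      }
      if (g %in% dup_genomes) {
        src <- uniq[sample(nrow(uniq), 1L), ]
        recs <- bind_rows(recs, tibble(id = paste0(src$id, "_dup"),
                                       description = src$description,
                                       sequence = src$sequence))
        duplicated[[g]] <- tibble(genome_id = g,
                                  protein_id = paste0(src$id, "_dup"),
                                  sequence = src$sequence)
      }
      if (g %in% spurious_amb) {
        # corrupt one background protein with an ambiguous residue
        k <- which(recs$id == uniq$id[1L])
        s <- recs$sequence[[k]]
        pos <- sample(nchar(s), 1L)
        substr(s, pos, pos) <- "B"
        recs$sequence[[k]] <- s
      }
      if (g %in% spurious_out) {
        n_extra <- max(1L, as.integer(round(outlier_inflation * nrow(recs))))
        recs <- bind_rows(recs, tibble(
          id = sprintf("%s_x%03d", g, seq_len(n_extra)),
          description = "hypothetical protein",
          sequence = vapply(seq_len(n_extra), function(i) {
            clean_protein(sample(background_length[1]:background_length[2], 1L))
          }, character(1))))
      }
      panels[[g]] <- recs |> mutate(genome_id = g) |>
        select("id", "description", "genome_id", "sequence")
    }

    proteins <- bind_rows(panels)
    spurious_tbl <- bind_rows(
      tibble(genome_id = spurious_amb,
             reason = rep("ambiguous_residue", length(spurious_amb))),
      tibble(genome_id = spurious_out,
             reason = rep("count_outlier", length(spurious_out))))
    clean <- setdiff(genome_ids, spurious_tbl$genome_id)
    truth <- list(
      reference = ref_seq,
      family = family_tbl,
      decoys = bind_rows(decoys),
      duplicated = bind_rows(duplicated),
      spurious = spurious_tbl |> arrange(.data$genome_id),
      expected_variants = family_tbl |>
        filter(.data$genome_id %in% clean) |>
        pull("sequence") |> sort_c(),
      seed = as.integer(seed))

    reference_tbl <- tibble(id = "reference",
                            description = "reference protein",
                            genome_id = "reference",
                            sequence = ref_seq)
    out <- list(proteins = proteins, reference = reference_tbl, truth = truth)
    if (!is.null(out_dir)) {
      dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
      for (g in genome_ids) {
        write_faa(panels[[g]], file.path(out_dir, paste0(g, ".faa")))
      }
      write_faa(reference_tbl, file.path(out_dir, "reference.faa"))
      jsonlite::write_json(
        list(seed = truth$seed,
             n_genomes = n_genomes,
             spurious = truth$spurious,
             family = truth$family |> select("genome_id", "protein_id",
                                             "target_identity")),
        file.path(out_dir, "truth.json"), auto_unbox = TRUE, digits = NA)
      out$dir <- out_dir
    }
    out
  })
}
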