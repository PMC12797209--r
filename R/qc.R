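#' Screen genomes for non-standard residues
#'
#' A genome fails the alphabet screen when any of its proteins contains a
#' character outside the allowed residue alphabet: ambiguous codes (B, Z, J),
#' placeholders (X, -), internal stops and the like. By default only the 20
#' standard one-letter residues are allowed; selenocysteine (U) and
#' pyrrolysine (O) can be whitelisted through `valid_alphabet`.
#'
#' @param proteins Protein tibble (see [read_faa()]).
#' @param valid_alphabet Character vector of allowed residues.
#' @return One row per genome: `genome_id`, `n_proteins`,
#'   `offending_residues` (comma-joined, empty when clean), `alphabet_ok`.
#' @export
screen_alphabet <- function(proteins, valid_alphabet = STANDARD_AA) {
  stopifnot(is.data.frame(proteins), nrow(proteins) > 0L)
  bad_pattern <- paste0("[^", paste(valid_alphabet, collapse = ""), "]")
  proteins |>
    group_by(genome_id = .data$genome_id) |>
    summarise(
      n_proteins = dplyr::n(),
      offending_residues = {
        found <- stringr::str_extract_all(.data$sequence, bad_pattern)
        paste(sort_c(unique(unlist(found))), collapse = ",")
      },
      .groups = "drop"
    ) |>
    mutate(alphabet_ok = !nzchar(.data$offending_residues)) |>
    arrange(.data$genome_id)
}

#' Flag genomes whose protein count deviates from the median
#'
#' A genome fails when `|count - median| / median > max_dev`. With an even
#' number of genomes the median is the mean of the two central values; a
#' single genome trivially passes (deviation 0). The decision is
#' scale-invariant.
#'
#' @param counts Named integer vector of protein counts per genome id.
#' @param max_dev Maximum tolerated fractional deviation (default 0.15,
#'   i.e. >15 percent from the median fails).
#' @return Tibble `genome_id`, `n_proteins`, `deviation_pct`, `count_ok`.
#' @export
screen_outliers <- function(counts, max_dev = 0.15) {
  if (length(counts) == 0L) {
    abort("screen_outliers: no genomes supplied")
  }
  med <- median(counts)
  deviation <- if (med == 0) rep(0, length(counts)) else abs(counts - med) / med
  tibble(genome_id = names(counts),
         n_proteins = as.integer(unname(counts)),
         deviation_pct = 100 * unname(deviation),
         count_ok = unname(deviation <= max_dev)) |>
    arrange(.data$genome_id)
}

#' Run per-genome quality control
#'
#' Step one of database preparation: remove spurious genomes, either because
#' a protein contains residues outside the allowed alphabet or because the
#' genome's protein count deviates from the median by more than `max_dev`.
#' The count median is computed over genomes that passed the alphabet screen,
#' so corrupted genomes do not distort the count distribution. The screen is
#' optional (`enabled = FALSE` keeps every genome but still reports
#' diagnostics).
#'
#' @param proteins Protein tibble covering one or more genomes.
#' @param max_dev Maximum fractional deviation of the protein count from the
#'   median (default 0.15).
#' @param valid_alphabet Allowed residue alphabet (default: 20 standard).
#' @param enabled When `FALSE`, QC is bypassed: all genomes pass and the
#'   report carries the computed diagnostics with status `pass`.
#' @return A list with `proteins` (records of passing genomes) and `report`
#'   (one row per input genome: `genome_id`, `n_proteins`, `status`,
#'   `offending_residues`, `deviation_pct`). `status` is one of `pass`,
#'   `fail_alphabet`, `fail_count`.
#' @examples
#' pan <- make_panel(seed = 1, n_genomes = 4, n_spurious_ambiguous = 1,
#'                   n_spurious_outlier = 0, n_background_shared = 3,
#'                   n_background_unique = 2, reference_length = 60)
#' run_qc(pan$proteins)$report
#' @export
run_qc <- function(proteins, max_dev = 0.15, valid_alphabet = STANDARD_AA,
                   enabled = TRUE) {
  alpha <- screen_alphabet(proteins, valid_alphabet)
  passing_alpha <- alpha$genome_id[alpha$alphabet_ok]
  # median over alphabet-passing genomes only (all genomes if none pass)
  pool <- if (length(passing_alpha) > 0L) {
    alpha |> filter(.data$alphabet_ok)
  } else {
    alpha
  }
  counts <- stats::setNames(pool$n_proteins, pool$genome_id)
  out <- screen_outliers(counts, max_dev = max_dev)
  med <- median(counts)
  report <- alpha |>
    left_join(out |> select("genome_id", "deviation_pct", "count_ok"),
              by = "genome_id") |>
    mutate(
      deviation_pct = dplyr::coalesce(
        .data$deviation_pct,
        if (med == 0) 0 else 100 * abs(.data$n_proteins - med) / med),
      count_ok = dplyr::coalesce(.data$count_ok,
                                 .data$deviation_pct <= 100 * max_dev),
      status = dplyr::case_when(
        !enabled ~ "pass",
        !.data$alphabet_ok ~ "fail_alphabet",
        !.data$count_ok ~ "fail_count",
        TRUE ~ "pass")
    ) |>
    select("genome_id", "n_proteins", "status", "offending_residues",
           "deviation_pct") |>
    arrange(.data$genome_id)
  keep <- report$genome_id[report$status == "pass"]
  if (length(keep) == 0L) {
    cond <- rlang::error_cnd("panpep_qc_all_failed",
                             message = "all genomes failed quality control",
                             report = report)
    rlang::cnd_signal(cond)
  }
  list(proteins = proteins |> filter(.data$genome_id %in% keep),
       report = report)
}
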