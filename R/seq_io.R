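#' Read a FASTA amino-acid (FAA) file into a protein tibble
#'
#' Parses a protein FASTA file into one row per record. The record id is the
#' first whitespace-delimited token of the header, the description is the
#' remainder (possibly empty). Multi-line sequences are concatenated, residues
#' are uppercased and a single terminal stop character (`*`) is stripped;
#' internal `*` characters are left in place for the QC stage to flag.
#'
#' @param path Path to a FASTA amino-acid file (optionally gzip-compressed).
#' @param genome_id Genome label attached to every record; defaults to the
#'   file name without its extension.
#' @return A tibble with columns `id`, `description`, `genome_id`, `sequence`,
#'   in file order.
#' @examples
#' faa <- tempfile(fileext = ".faa")
#' writeLines(c(">p1 alpha toxin", "MKA", "R*", ">p2", "MGGK"), faa)
#' read_faa(faa)
#' @export
read_faa <- function(path, genome_id = NULL) {
  if (!file.exists(path)) {
    abort(paste0("FAA file does not exist: ", path))
  }
  genome_id <- genome_id %||% strip_faa_ext(basename(path))
  set <- tryCatch(
    Biostrings::readBStringSet(path),
    error = function(e) abort(paste0("cannot parse FASTA file '", path, "': ",
                                     conditionMessage(e)))
  )
  if (length(set) == 0L) {
    abort(paste0("FAA file is empty: ", path))
  }
  headers <- names(set)
  ids <- sub("\\s.*$", "", headers)
  descriptions <- ifelse(grepl("\\s", headers),
                         sub("^\\S+\\s+", "", headers), "")
  sequences <- toupper(as.character(set))
  sequences <- sub("\\*$", "", sequences)
  if (any(!nzchar(ids))) {
    abort(paste0("record with empty id in ", path))
  }
  if (any(!nzchar(sequences))) {
    bad <- ids[!nzchar(sequences)]
    abort(paste0("record(s) without sequence in ", path, ": ",
                 paste(bad, collapse = ", ")))
  }
  dup <- unique(ids[duplicated(ids)])
  if (length(dup) > 0L) {
    abort(paste0("duplicate protein id(s) in ", path, ": ",
                 paste(dup, collapse = ", ")))
  }
  tibble(id = ids,
         description = unname(descriptions),
         genome_id = genome_id,
         sequence = unname(sequences))
}

strip_faa_ext <- function(x) sub("\\.(faa|fasta|fa)(\\.gz)?$", "", x,
                                 ignore.case = TRUE)

#' Write a protein tibble to a FAA file
#'
#' Inverse of [read_faa()]: writes `>id description` headers (no trailing
#' space when the description is empty) and wraps sequences at 60 residues
#' per line.
#'
#' @param proteins Tibble with at least `id` and `sequence` columns; an
#'   optional `description` column is appended to headers.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_faa <- function(proteins, path) {
  stopifnot(is.data.frame(proteins))
  if (nrow(proteins) == 0L) {
    abort("cannot write an empty record list")
  }
  desc <- if ("description" %in% names(proteins)) proteins$description else
    character(nrow(proteins))
  desc <- rep_len(desc, nrow(proteins))
  headers <- ifelse(nzchar(desc), paste(proteins$id, desc), proteins$id)
  set <- Biostrings::BStringSet(proteins$sequence)
  names(set) <- headers
  Biostrings::writeXStringSet(set, path, width = 60L)
  invisible(path)
}

#' Scan a directory of per-genome FAA files
#'
#' Reads every FASTA amino-acid file in `dir` into a single protein tibble,
#' one genome per file. The genome id is the file name without its extension;
#' panels are returned sorted by genome id so the result is independent of
#' filesystem enumeration order.
#'
#' @param dir Directory containing one FAA file per genome.
#' @param extensions File extensions treated as FASTA (case-insensitive).
#' @return A tibble of protein records (`id`, `description`, `genome_id`,
#'   `sequence`) covering all genomes, ordered by `genome_id` then file order.
#' @export
scan_genome_dir <- function(dir, extensions = c("faa", "fasta", "fa")) {
  if (!dir.exists(dir)) {
    abort(paste0("genome directory does not exist: ", dir))
  }
  pattern <- paste0("\\.(", paste(extensions, collapse = "|"), ")(\\.gz)?$")
  files <- list.files(dir, pattern = pattern, ignore.case = TRUE,
                      full.names = TRUE)
  if (length(files) == 0L) {
    abort(paste0("no FASTA files (", paste(extensions, collapse = "/"),
                 ") found in ", dir))
  }
  genome_ids <- strip_faa_ext(basename(files))
  dup <- unique(genome_ids[duplicated(genome_ids)])
  if (length(dup) > 0L) {
    abort(paste0("duplicate genome id(s) from file stems in ", dir, ": ",
                 paste(dup, collapse = ", ")))
  }
  ord <- order(genome_ids, method = "radix")
  files <- files[ord]
  genome_ids <- genome_ids[ord]
  purrr::map2(files, genome_ids,
              function(f, g) read_faa(f, genome_id = g)) |>
    bind_rows()
}

#' Split a protein tibble into per-genome panels
#'
#' @param proteins Protein tibble as returned by [scan_genome_dir()].
#' @return Named list of per-genome tibbles, names sorted byte-wise.
#' @keywords internal
split_panels <- function(proteins) {
  split(proteins, proteins$genome_id)[sort_c(unique(proteins$genome_id))]
}
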