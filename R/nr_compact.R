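#' Compact a protein panel into a nonredundant database
#'
#' Builds the panallelome: one representative per distinct amino-acid
#' sequence plus, for each representative, the full list of identical member
#' proteins across all genomes. Clustering at 100% identity and 100% coverage
#' is exact string equality, so deduplication is performed by hashing;
#' proteins are processed in chunks of at most `chunk_size` and, inside each
#' chunk, partitioned by sequence length before deduplication (sequences of
#' different lengths can never be identical), which bounds memory on large
#' inputs. Chunk results are merged incrementally; the final database is
#' independent of `chunk_size` and of genome order.
#'
#' Member ids are genome-qualified (`genome_id|protein_id`) so downstream
#' stages can expand clusters back to genomes. The representative description
#' is the modal description over the full member list (ties broken by byte
#' order of the description), and the representative id is the byte-smallest
#' member id bearing that description.
#'
#' @param proteins Protein tibble (post QC).
#' @param chunk_size Maximum number of proteins deduplicated per chunk
#'   (default 1e7).
#' @return An object of class `nr_db`: list with `representatives` (tibble
#'   `id`, `description`, `sequence`) and `clusters` (tibble
#'   `representative_id`, `length`, `n_members`, `member_ids` list-column),
#'   both ordered by representative id.
#' @examples
#' prot <- tibble::tibble(id = "p1", description = "toxin",
#'                        genome_id = c("g1", "g2", "g3"), sequence = "MKR")
#' compact_proteins(prot)
#' @export
compact_proteins <- function(proteins, chunk_size = 1e7) {
  stopifnot(is.data.frame(proteins), chunk_size >= 1)
  if (nrow(proteins) == 0L) {
    abort("compact_proteins: zero proteins supplied")
  }
  qualified <- paste0(proteins$genome_id, "|", proteins$id)
  dup <- unique(qualified[duplicated(qualified)])
  if (length(dup) > 0L) {
    abort(paste0("duplicate genome-qualified id(s): ",
                 paste(head(dup, 5L), collapse = ", ")))
  }
  seqs <- proteins$sequence
  descs <- if ("description" %in% names(proteins)) proteins$description else ""
  descs <- rep_len(descs, length(seqs))

  index <- new.env(hash = TRUE, parent = emptyenv())  # sequence -> cluster no.
  cl_seq <- character()
  cl_members <- list()
  cl_descs <- list()

  n <- length(seqs)
  starts <- seq(1L, n, by = chunk_size)
  for (s in starts) {
    idx <- s:min(s + chunk_size - 1L, n)
    # partition the chunk by length, then dedup exactly within each partition
    ord <- idx[order(nchar(seqs[idx]), method = "radix")]
    chunk_seqs <- seqs[ord]
    first <- !duplicated(chunk_seqs)
    grp <- match(chunk_seqs, chunk_seqs[first])
    uniq <- chunk_seqs[first]
    members_by_grp <- split(qualified[ord], grp)
    descs_by_grp <- split(descs[ord], grp)
    for (u in seq_along(uniq)) {
      key <- uniq[[u]]
      hit <- index[[key]]
      if (is.null(hit)) {
        k <- length(cl_seq) + 1L
        index[[key]] <- k
        cl_seq[[k]] <- key
        cl_members[[k]] <- members_by_grp[[u]]
        cl_descs[[k]] <- descs_by_grp[[u]]
      } else {
        cl_members[[hit]] <- c(cl_members[[hit]], members_by_grp[[u]])
        cl_descs[[hit]] <- c(cl_descs[[hit]], descs_by_grp[[u]])
      }
    }
  }

  reps <- purrr::map2(cl_members, cl_descs, choose_representative)
  rep_ids <- map_chr(reps, "id")
  rep_descs <- map_chr(reps, "description")
  ord <- order(rep_ids, method = "radix")

  representatives <- tibble(id = rep_ids[ord],
                            description = rep_descs[ord],
                            sequence = cl_seq[ord])
  clusters <- tibble(representative_id = rep_ids[ord],
                     length = nchar(cl_seq[ord]),
                     n_members = lengths(cl_members)[ord],
                     member_ids = lapply(cl_members[ord], sort_c))
  new_nr_db(representatives, clusters)
}

new_nr_db <- function(representatives, clusters) {
  structure(list(representatives = representatives, clusters = clusters),
            class = "nr_db")
}

#' Choose the representative id and description of an identical-sequence cluster
#'
#' The description is the modal description among members (modal ties broken
#' by byte order of the description); the id is the byte-smallest member id
#' bearing that description.
#'
#' @param member_ids Genome-qualified member ids.
#' @param member_descriptions Descriptions parallel to `member_ids`.
#' @return List with elements `id` and `description`.
#' @export
choose_representative <- function(member_ids, member_descriptions) {
  stopifnot(length(member_ids) >= 1L,
            length(member_ids) == length(member_descriptions))
  tab <- table(member_descriptions)
  best <- sort_c(names(tab)[tab == max(tab)])[1L]
  list(id = sort_c(member_ids[member_descriptions == best])[1L],
       description = best)
}

#' @export
print.nr_db <- function(x, ...) {
  cat("<nr_db> ", nrow(x$representatives), " representative(s), ",
      sum(x$clusters$n_members), " member protein(s)\n", sep = "")
  invisible(x)
}

#' Write a nonredundant database to disk
#'
#' Two files mirror the pipeline's database outputs: `representatives.faa`
#' (all representative sequences) and `clusters.tsv` with columns
#' `representative_id`, `length`, `n_members`, `member_ids`
#' (comma-separated).
#'
#' @param db An `nr_db`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_nr_db <- function(db, dir) {
  stopifnot(inherits(db, "nr_db"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_faa(db$representatives, file.path(dir, "representatives.faa"))
  readr::write_tsv(
    db$clusters |>
      mutate(member_ids = map_chr(.data$member_ids, paste, collapse = ",")),
    file.path(dir, "clusters.tsv"))
  invisible(dir)
}

#' Load a nonredundant database written by [write_nr_db()]
#'
#' Validates the database invariants on load: every cluster references a
#' representative present in the FAA (and vice versa), the representative is
#' among its members, member counts match the member lists, and cluster
#' lengths match the representative sequences. Any violation is an error
#' naming the invariant.
#'
#' @param dir Directory holding `representatives.faa` and `clusters.tsv`.
#' @return An `nr_db`.
#' @export
read_nr_db <- function(dir) {
  faa <- file.path(dir, "representatives.faa")
  tsv <- file.path(dir, "clusters.tsv")
  if (!file.exists(faa) || !file.exists(tsv)) {
    abort(paste0("database files missing under ", dir,
                 " (need representatives.faa and clusters.tsv)"))
  }
  reps <- read_faa(faa) |> select("id", "description", "sequence")
  clusters <- readr::read_tsv(tsv, show_col_types = FALSE,
                              col_types = "ciic") |>
    mutate(member_ids = strsplit(.data$member_ids, ",", fixed = TRUE))
  if (!setequal(reps$id, clusters$representative_id)) {
    abort("nr_db invariant violated: representative sets of FAA and cluster table differ")
  }
  clusters <- clusters[match(reps$id, clusters$representative_id), ]
  if (any(clusters$n_members != lengths(clusters$member_ids))) {
    abort("nr_db invariant violated: n_members does not match member_ids")
  }
  if (any(clusters$length != nchar(reps$sequence))) {
    abort("nr_db invariant violated: cluster length does not match representative sequence")
  }
  in_members <- map_lgl(seq_len(nrow(clusters)), function(i) {
    clusters$representative_id[[i]] %in% clusters$member_ids[[i]]
  })
  if (!all(in_members)) {
    abort("nr_db invariant violated: representative_id not among member_ids")
  }
  all_members <- unlist(clusters$member_ids, use.names = FALSE)
  if (anyDuplicated(all_members)) {
    abort("nr_db invariant violated: a member id appears in more than one cluster")
  }
  new_nr_db(reps, clusters |> mutate(member_ids = lapply(.data$member_ids, sort_c)))
}

#' Genomes of origin of a cluster's members
#'
#' @param member_ids Genome-qualified ids (`genome|protein`).
#' @return Character vector of genome ids (with repeats).
#' @keywords internal
member_genomes <- function(member_ids) sub("\\|.*$", "", member_ids)
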