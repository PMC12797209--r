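#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' Tidy a nonredundant database into its cluster table
#'
#' @param x An `nr_db`.
#' @param ... Unused.
#' @return One row per cluster: `representative_id`, `description`,
#'   `length`, `n_members`, `n_genomes`.
#' @method tidy nr_db
#' @export
tidy.nr_db <- function(x, ...) {
  x$clusters |>
    mutate(description = x$representatives$description[
             match(.data$representative_id, x$representatives$id)],
           n_genomes = map_int(.data$member_ids,
                               ~ length(unique(member_genomes(.x))))) |>
    select("representative_id", "description", "length", "n_members",
           "n_genomes")
}

#' @method glance nr_db
#' @export
glance.nr_db <- function(x, ...) {
  tibble(n_representatives = nrow(x$representatives),
         n_proteins = sum(x$clusters$n_members),
         compaction_ratio = sum(x$clusters$n_members) /
           nrow(x$representatives),
         max_cluster_size = max(x$clusters$n_members))
}

#' Tidy a variant set
#'
#' @param x A `variant_set`.
#' @param ... Unused.
#' @return One row per retained allelic variant with observation counts and
#'   alignment statistics against the reference.
#' @method tidy variant_set
#' @export
tidy.variant_set <- function(x, ...) {
  cols <- intersect(c("id", "description", "observations", "global_identity",
                      "pct_length", "divergence", "score"),
                    names(x$variants))
  x$variants |> select(dplyr::all_of(cols))
}

#' @method glance variant_set
#' @export
glance.variant_set <- function(x, ...) {
  tibble(n_variants = nrow(x$variants),
         total_observations = sum(x$variants$observations),
         retained_fraction = x$retained_fraction,
         mean_identity = if ("global_identity" %in% names(x$variants))
           mean(x$variants$global_identity) else NA_real_)
}

#' Tidy a peptide selection
#'
#' @param x A `selection_state` (typically the output of [greedy_select()]).
#' @param ... Unused.
#' @return One row per selected peptide: `rank`, `peptide`, `source`
#'   (`user` or `greedy`), `length`, `n_variants_covered`.
#' @method tidy selection_state
#' @export
tidy.selection_state <- function(x, ...) {
  if (length(x$minimum_list) == 0L) {
    return(tibble(rank = integer(), peptide = character(),
                  source = character(), length = integer(),
                  n_variants_covered = integer()))
  }
  tibble(rank = seq_along(x$minimum_list),
         peptide = x$minimum_list,
         source = x$selected_from,
         length = nchar(x$minimum_list),
         n_variants_covered = vapply(x$minimum_list,
                                     function(p) sum(x$mat[p, ]), integer(1),
                                     USE.NAMES = FALSE))
}

#' @method glance selection_state
#' @export
glance.selection_state <- function(x, ...) {
  tibble(n_peptides = length(x$minimum_list),
         n_variants = length(x$coverage),
         target = x$target,
         n_covered = sum(x$coverage >= x$target),
         n_uncoverable = length(x$uncoverable),
         min_coverage = if (length(x$coverage)) min(x$coverage) else NA_integer_,
         mean_coverage = if (length(x$coverage)) mean(x$coverage) else NA_real_)
}

#' Tidy a presence/absence matrix into long form
#'
#' @param x A `presence_matrix`.
#' @param ... Unused.
#' @return Long tibble `peptide`, `variant_id`, `present`.
#' @method tidy presence_matrix
#' @export
tidy.presence_matrix <- function(x, ...) {
  tibble(peptide = rep(rownames(x$mat), ncol(x$mat)),
         variant_id = rep(colnames(x$mat), each = nrow(x$mat)),
         present = as.vector(x$mat))
}

#' @method tidy validation_report
#' @export
tidy.validation_report <- function(x, ...) x$proteins

#' @method glance validation_report
#' @export
glance.validation_report <- function(x, ...) {
  tibble(n_proteins = nrow(x$proteins),
         n_on_target = sum(x$proteins$in_variant_set),
         n_off_target = sum(!x$proteins$in_variant_set),
         min_peptides_on_target = if (any(x$proteins$in_variant_set))
           min(x$proteins$n_peptides[x$proteins$in_variant_set])
         else NA_integer_)
}

#' @method glance pipeline_run
#' @export
glance.pipeline_run <- function(x, ...) {
  as_tibble(x$counts)
}
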