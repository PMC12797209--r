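#' Pipeline configuration
#'
#' Collects every tuning knob of the pipeline with its default. All
#' thresholds are validated on construction and the object round-trips
#' through the flat key=value config file format ([write_config()] /
#' [read_config()]).
#'
#' @param input_dir Directory of per-genome FAA files.
#' @param reference_faa FAA file holding the reference protein (first
#'   record used).
#' @param out_dir Output directory (optional; no files written when `NULL`).
#' @param qc_enabled Run the per-genome quality screen (default `TRUE`).
#' @param max_dev Maximum fractional deviation of a genome's protein count
#'   from the median (default 0.15).
#' @param rule Cleavage rule name (default `"Trypsin-2rules"`) or a
#'   [cleavage_rule()] object.
#' @param chunk_size Proteins deduplicated per chunk (default 1e7).
#' @param min_identity,min_coverage Local-search thresholds in percent
#'   (defaults 60, 60).
#' @param max_divergence Divergence filter threshold in percentage points
#'   (default 25; see [divergence_filter()]).
#' @param cluster_start,cluster_step Iterative clustering identity schedule
#'   (defaults 70, 0.5).
#' @param keep_fraction Observation share retained by the frequency filter
#'   (default 0.98).
#' @param target_coverage Covering peptides required per variant
#'   (default 3).
#' @param min_pep_length,max_pep_length Optional peptide length bounds for
#'   the presence matrix (default: no bounds).
#' @param include_faa,exclude_faa Optional FAA files of peptides to
#'   force-include or exclude.
#' @param seed Integer seed recorded in the run summary (default 1).
#' @return An object of class `pipeline_config` (a named list).
#' @export
pipeline_config <- function(input_dir = NULL, reference_faa = NULL,
                            out_dir = NULL, qc_enabled = TRUE,
                            max_dev = 0.15, rule = "Trypsin-2rules",
                            chunk_size = 1e7, min_identity = 60,
                            min_coverage = 60, max_divergence = 25,
                            cluster_start = 70, cluster_step = 0.5,
                            keep_fraction = 0.98, target_coverage = 3L,
                            min_pep_length = NULL, max_pep_length = NULL,
                            include_faa = NULL, exclude_faa = NULL,
                            seed = 1L) {
  stopifnot(max_dev >= 0, chunk_size >= 1,
            min_identity >= 0, min_identity <= 100,
            min_coverage >= 0, min_coverage <= 100,
            max_divergence >= 0,
            cluster_start >= 0, cluster_start <= 100, cluster_step > 0,
            keep_fraction > 0, keep_fraction <= 1,
            target_coverage >= 1)
  structure(list(input_dir = input_dir, reference_faa = reference_faa,
                 out_dir = out_dir, qc_enabled = isTRUE(qc_enabled),
                 max_dev = max_dev, rule = rule, chunk_size = chunk_size,
                 min_identity = min_identity, min_coverage = min_coverage,
                 max_divergence = max_divergence,
                 cluster_start = cluster_start, cluster_step = cluster_step,
                 keep_fraction = keep_fraction,
                 target_coverage = as.integer(target_coverage),
                 min_pep_length = min_pep_length,
                 max_pep_length = max_pep_length,
                 include_faa = include_faa, exclude_faa = exclude_faa,
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

resolve_rule <- function(rule) {
  if (inherits(rule, "cleavage_rule")) return(rule)
  if (identical(rule, "Trypsin-2rules")) return(cleavage_rule())
  abort(paste0("unknown cleavage rule name: ", rule,
               " (pass a cleavage_rule() object for custom proteases)"))
}

#' Write / read a flat key=value config file
#'
#' `NULL` fields are omitted; unset paths stay `NULL` on read. The
#' round-trip `read_config(write_config(cfg))` reproduces the config.
#'
#' @param config A [pipeline_config()].
#' @param path File path.
#' @return `write_config()` returns `path` invisibly; `read_config()`
#'   returns a `pipeline_config`.
#' @export
write_config <- function(config, path) {
  stopifnot(inherits(config, "pipeline_config"))
  vals <- config[!vapply(config, is.null, logical(1))]
  vals <- vals[vapply(vals, function(v) !inherits(v, "cleavage_rule"),
                      logical(1)) | names(vals) != "rule"]
  if (inherits(config$rule, "cleavage_rule")) {
    vals$rule <- config$rule$name
  }
  writeLines(sprintf("%s=%s", names(vals),
                     vapply(vals, function(v) format(v, scientific = FALSE),
                            character(1))),
             path)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines)) & !startsWith(trimws(lines), "#")]
  kv <- strsplit(lines, "=", fixed = TRUE)
  keys <- vapply(kv, `[[`, character(1), 1L)
  vals <- vapply(kv, function(x) paste(x[-1L], collapse = "="), character(1))
  args <- stats::setNames(as.list(vals), keys)
  num_fields <- c("max_dev", "chunk_size", "min_identity", "min_coverage",
                  "max_divergence", "cluster_start", "cluster_step",
                  "keep_fraction")
  int_fields <- c("target_coverage", "seed", "min_pep_length",
                  "max_pep_length")
  for (f in intersect(num_fields, names(args))) args[[f]] <- as.numeric(args[[f]])
  for (f in intersect(int_fields, names(args))) args[[f]] <- as.integer(args[[f]])
  if ("qc_enabled" %in% names(args)) {
    args$qc_enabled <- toupper(args$qc_enabled) %in% c("TRUE", "1", "YES")
  }
  do.call(pipeline_config, args)
}

stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    if (inherits(e, "panpep_stage_error")) rlang::cnd_signal(e)
    cond <- rlang::error_cnd("panpep_stage_error",
                             message = paste0("pipeline stage '", name,
                                              "' failed: ",
                                              conditionMessage(e)),
                             parent = e)
    rlang::cnd_signal(cond)
  })
}

#' Run the full peptide-selection pipeline
#'
#' Executes quality control, digestion and multi-copy detection, exact
#' deduplication into the nonredundant database, allelic-variant selection,
#' greedy minimal peptide selection, and specificity validation, in that
#' order. Inputs come either from the config paths (`input_dir`,
#' `reference_faa`) or from in-memory tibbles via `proteins` / `reference`.
#' Given identical inputs and config the run is fully deterministic. Any
#' stage failure aborts with the stage name; outputs written so far are
#' retained.
#'
#' @param config A [pipeline_config()].
#' @param proteins Optional protein tibble (overrides `config$input_dir`).
#' @param reference Optional reference (overrides `config$reference_faa`).
#' @param db Optional pre-built `nr_db`: skips QC, digestion and compaction
#'   (resume mode). Multi-copy peptides must then be supplied via
#'   `multicopy` (or are re-read from disk by [run_resume()]).
#' @param multicopy Optional `multicopy_set` accompanying `db`.
#' @return An object of class `pipeline_run`: list with `config`,
#'   `qc_report`, `multicopy`, `db`, `variants` (a `variant_set`),
#'   `matrix`, `selection`, `validation`, and `counts` (per-stage sizes).
#'   When `config$out_dir` is set all output files are written there.
#' @export
run_pipeline <- function(config = pipeline_config(), proteins = NULL,
                         reference = NULL, db = NULL, multicopy = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  rule <- resolve_rule(config$rule)
  reference <- reference %||% stage("inputs", {
    if (is.null(config$reference_faa)) {
      abort("no reference supplied (reference_faa unset)")
    }
    read_faa(config$reference_faa)[1L, ]
  })
  ref <- as_reference(reference)
  include <- stage("inputs", {
    if (is.null(config$include_faa)) character() else
      read_faa(config$include_faa)$sequence
  })
  exclude <- stage("inputs", {
    if (is.null(config$exclude_faa)) character() else
      read_faa(config$exclude_faa)$sequence
  })

  qc_report <- NULL
  if (is.null(db)) {
    proteins <- proteins %||% stage("inputs", {
      if (is.null(config$input_dir)) {
        abort("no proteome panel supplied (input_dir unset)")
      }
      scan_genome_dir(config$input_dir)
    })
    qc <- stage("qc", run_qc(proteins, max_dev = config$max_dev,
                             enabled = config$qc_enabled))
    qc_report <- qc$report
    multicopy <- stage("digestion", find_multicopy(qc$proteins, rule))
    db <- stage("nr_compact",
                compact_proteins(qc$proteins, chunk_size = config$chunk_size))
  } else {
    stopifnot(inherits(db, "nr_db"))
    multicopy <- multicopy %||% structure(
      list(peptides = character(),
           counts = tibble(genome_id = character(), peptide = character(),
                           count = integer())),
      class = "multicopy_set")
  }

  variants <- stage("variant_select", select_variants(
    ref, db,
    min_identity = config$min_identity, min_coverage = config$min_coverage,
    max_divergence = config$max_divergence,
    cluster_start = config$cluster_start, cluster_step = config$cluster_step,
    keep_fraction = config$keep_fraction))

  matrix <- stage("pep_select", build_matrix(
    variants, rule, multicopy = multicopy, user_exclude = exclude,
    min_length = config$min_pep_length, max_length = config$max_pep_length))
  selection <- stage("pep_select", {
    st <- selection_state(matrix, target = config$target_coverage)
    st <- seed_with_user_list(st, include)
    greedy_select(st)
  })

  validation <- stage("validate", {
    if (length(selection$minimum_list) == 0L) {
      structure(list(proteins = tibble(protein_id = character(),
                                       n_peptides = integer(),
                                       pct_identity = double(),
                                       in_variant_set = logical()),
                     hits = tibble()),
                class = "validation_report")
    } else {
      hits <- specificity_scan(selection$minimum_list, db, rule)
      validation_report(hits, db, ref, variants)
    }
  })

  run <- structure(list(
    config = config,
    qc_report = qc_report,
    multicopy = multicopy,
    db = db,
    variants = variants,
    matrix = matrix,
    selection = selection,
    validation = validation,
    counts = list(
      n_genomes_pass = if (is.null(qc_report)) NA_integer_ else
        sum(qc_report$status == "pass"),
      n_genomes_fail = if (is.null(qc_report)) NA_integer_ else
        sum(qc_report$status != "pass"),
      n_representatives = nrow(db$representatives),
      n_member_proteins = sum(db$clusters$n_members),
      n_multicopy_peptides = length(multicopy$peptides),
      n_variants = nrow(variants$variants),
      n_matrix_peptides = nrow(matrix$mat),
      n_selected_peptides = length(selection$minimum_list),
      n_uncoverable = length(selection$uncoverable),
      n_off_target = sum(!validation$proteins$in_variant_set))),
    class = "pipeline_run")
  if (!is.null(config$out_dir)) {
    write_outputs(run, config$out_dir)
  }
  run
}

#' Resume a run from a previously written database
#'
#' Skips QC, digestion and compaction by loading `representatives.faa`,
#' `clusters.tsv` and `multicopy_peptides.faa` from `db_dir`; downstream
#' stages behave exactly as in [run_pipeline()] on the same database.
#'
#' @param config A [pipeline_config()].
#' @param db_dir Directory written by a previous run (or [write_nr_db()]).
#' @param reference Optional in-memory reference override.
#' @return A `pipeline_run`.
#' @export
run_resume <- function(config, db_dir, reference = NULL) {
  db <- stage("nr_compact", read_nr_db(db_dir))
  mc_path <- file.path(db_dir, "multicopy_peptides.faa")
  multicopy <- if (file.exists(mc_path)) {
    stage("digestion", read_multicopy_faa(mc_path))
  } else {
    NULL
  }
  run_pipeline(config, reference = reference, db = db, multicopy = multicopy)
}

#' @export
print.pipeline_run <- function(x, ...) {
  c <- x$counts
  cat("<pipeline_run>\n",
      "  genomes passing QC : ", c$n_genomes_pass, " (", c$n_genomes_fail,
      " removed)\n",
      "  nonredundant db    : ", c$n_representatives, " representatives / ",
      c$n_member_proteins, " proteins\n",
      "  multi-copy peptides: ", c$n_multicopy_peptides, "\n",
      "  allelic variants   : ", c$n_variants, "\n",
      "  minimum peptides   : ", c$n_selected_peptides,
      " (", c$n_uncoverable, " variant(s) uncoverable)\n",
      "  off-target proteins: ", c$n_off_target, "\n", sep = "")
  invisible(x)
}

#' Write every pipeline output file
#'
#' Writes the machine-readable outputs: per-genome QC report TSV,
#' multi-copy peptide FAA, representative FAA and cluster TSV (the
#' database), variant FAA and TSV, minimum peptide FAA, validation TSV,
#' and a run summary JSON (parameters, package version, seed, per-stage
#' counts).
#'
#' @param run A `pipeline_run`.
#' @param out_dir Output directory, created if needed.
#' @return `out_dir`, invisibly.
#' @export
write_outputs <- function(run, out_dir) {
  stopifnot(inherits(run, "pipeline_run"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(out_dir)) {
    abort(paste0("cannot create output directory: ", out_dir))
  }
  if (!is.null(run$qc_report)) {
    readr::write_tsv(run$qc_report, file.path(out_dir, "qc_report.tsv"))
  }
  write_multicopy_faa(run$multicopy,
                      file.path(out_dir, "multicopy_peptides.faa"))
  write_nr_db(run$db, out_dir)
  write_faa(run$variants$variants |> select("id", "description", "sequence"),
            file.path(out_dir, "variants.faa"))
  readr::write_tsv(
    run$variants$variants |>
      mutate(genomes = map_chr(.data$genomes, paste, collapse = ",")) |>
      select("id", "observations", "divergence", "global_identity",
             "pct_length", "genomes"),
    file.path(out_dir, "variants.tsv"))
  write_minimum_faa(run$selection, file.path(out_dir, "minimum_peptides.faa"))
  readr::write_tsv(run$validation$proteins,
                   file.path(out_dir, "validation.tsv"))
  cfg <- run$config
  cfg_list <- cfg[!vapply(cfg, is.null, logical(1))]
  if (inherits(cfg_list$rule, "cleavage_rule")) {
    cfg_list$rule <- cfg_list$rule$name
  }
  jsonlite::write_json(
    list(package = "panpep",
         version = as.character(utils::packageVersion("panpep")),
         parameters = cfg_list,
         counts = run$counts,
         minimum_list = run$selection$minimum_list,
         uncoverable = run$selection$uncoverable,
         complete = length(run$selection$uncoverable) == 0L &&
           length(run$selection$minimum_list) > 0L),
    file.path(out_dir, "run_summary.json"), auto_unbox = TRUE, digits = NA)
  invisible(out_dir)
}
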