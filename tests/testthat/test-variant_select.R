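# Shared pipeline inputs built once from the memoised panel.
vs_setup <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      pan <- tiny_panel()
      qc <- run_qc(pan$proteins)
      db <- compact_proteins(qc$proteins)
      cache <<- list(pan = pan, db = db, ref = pan$reference)
    }
    cache
  }
})

test_that("find_candidates returns one best hit per genome, expanded to full sequences", {
  s <- vs_setup()
  cands <- find_candidates(s$ref, s$db)
  clean <- setdiff(unique(s$pan$truth$family$genome_id),
                   s$pan$truth$spurious$genome_id)
  # every clean genome contributes its planted variant as its best hit
  expect_setequal(unlist(cands$best_in), clean)
  expect_setequal(cands$sequence,
                  s$pan$truth$family$sequence[
                    s$pan$truth$family$genome_id %in% clean])
  # decoys are outscored by the true variant in their own genome
  expect_false(any(cands$sequence %in% s$pan$truth$decoys$sequence))
  expect_true(all(cands$observations >= 1L))
})

test_that("find_candidates errors when nothing is similar to the reference", {
  s <- vs_setup()
  expect_error(find_candidates(strrep("W", 60), s$db),
               "reference not found")
})

test_that("divergence metric follows the stated arithmetic", {
  s <- vs_setup()
  cands <- find_candidates(s$ref, s$db)
  # identical to reference -> divergence 0
  self <- tibble::tibble(id = "self", description = "", genome_id = "g",
                         sequence = s$ref$sequence, observations = 1L,
                         score = 0, pct_identity = 100, query_coverage = 100,
                         best_in = list("g"), genomes = list("g"))
  kept <- divergence_filter(self, s$ref)
  expect_equal(kept$divergence, 0)
  expect_equal(kept$pct_length, 100)

  # equal length, identity ~70 -> divergence ~30 -> removed at default 25
  far <- self
  far$sequence <- mutate_protein(s$ref$sequence, round(0.3 * nchar(s$ref$sequence)),
                                 seed = 4)
  expect_equal(nrow(divergence_filter(far, s$ref)), 0L)

  # all planted family variants survive the default threshold
  expect_equal(nrow(divergence_filter(cands, s$ref)), nrow(cands))
})

test_that("truncated but conserved candidates have near-zero divergence", {
  s <- vs_setup()
  ref_seq <- s$ref$sequence
  trunc <- substr(ref_seq, 1, round(0.8 * nchar(ref_seq)))
  cand <- tibble::tibble(id = "trunc", description = "", genome_id = "g",
                         sequence = trunc, observations = 1L,
                         score = 0, pct_identity = 100, query_coverage = 80,
                         best_in = list("g"), genomes = list("g"))
  out <- divergence_filter(cand, s$ref)
  expect_equal(nrow(out), 1L)
  expect_lt(out$divergence, 2)   # pct_length == pct_identity =~ 80
})

test_that("iterative clustering removes within-genome paralogs, keeps variants", {
  s <- vs_setup()
  ref_seq <- s$ref$sequence
  len <- nchar(ref_seq)
  variant <- mutate_protein(ref_seq, round(0.08 * len), seed = 5)  # ~92% id
  paralog <- mutate_protein(ref_seq, round(0.28 * len), seed = 6)  # ~72% id
  cands <- tibble::tibble(
    id = c("v", "p"), description = "", sequence = c(variant, paralog),
    observations = 1L, score = 0, pct_identity = 0, query_coverage = 0,
    best_in = list("g1", "g1"), genomes = list("g1", "g1"))
  out <- iterative_cluster_filter(cands, s$ref)
  expect_equal(out$id, "v")

  # one candidate per genome: loop body never runs, everything retained
  solo <- cands[1, ]
  expect_equal(iterative_cluster_filter(solo, s$ref), solo)
})

test_that("true duplicate loci trigger the threshold>100 warning path", {
  s <- vs_setup()
  seqv <- mutate_protein(s$ref$sequence, 10, seed = 7)
  cands <- tibble::tibble(
    id = c("dupA", "dupB"), description = "", sequence = seqv,
    observations = 1L, score = 0, pct_identity = 0, query_coverage = 0,
    best_in = list("g1", "g1"), genomes = list("g1", "g1"))
  expect_warning(out <- iterative_cluster_filter(cands, s$ref),
                 "duplicate loci|threshold > 100")
  expect_equal(nrow(out), 2L)
})

test_that("frequency filter retains the smallest prefix reaching the share", {
  ref <- list(id = "r", sequence = "MKLMKLMKL")
  cands <- tibble::tibble(id = c("A", "B", "C"), description = "",
                          sequence = c("MAAAR", "MCCCR", "MDDDR"),
                          observations = c(90L, 8L, 2L))
  vs <- frequency_filter(cands, ref, keep_fraction = 0.98)
  expect_setequal(vs$variants$id, c("A", "B"))
  expect_equal(vs$retained_fraction, 0.98)

  all_kept <- frequency_filter(cands, ref, keep_fraction = 1)
  expect_equal(nrow(all_kept$variants), 3L)

  single <- frequency_filter(cands[1, ], ref, keep_fraction = 0.01)
  expect_equal(nrow(single$variants), 1L)
})

test_that("frequency filter always protects the reference-identical variant", {
  ref <- list(id = "r", sequence = "MDDDR")
  cands <- tibble::tibble(id = c("A", "B", "C"), description = "",
                          sequence = c("MAAAR", "MCCCR", "MDDDR"),
                          observations = c(90L, 8L, 2L))
  vs <- frequency_filter(cands, ref, keep_fraction = 0.9)
  expect_true("C" %in% vs$variants$id)   # rank 3, protected
  expect_true("A" %in% vs$variants$id)
})

test_that("frequency filter minimality holds on random count vectors", {
  withr::local_seed(41)
  for (i in 1:200) {
    n <- sample(1:12, 1)
    obs <- as.integer(sample(1:100, n, replace = TRUE))
    cands <- tibble::tibble(id = sprintf("c%02d", seq_len(n)),
                            description = "",
                            sequence = sprintf("MK%sR", strrep("A", seq_len(n))),
                            observations = obs)
    frac <- stats::runif(1, 0.5, 1)
    vs <- frequency_filter(cands, list(id = "r", sequence = "MWWWWR"),
                           keep_fraction = frac)
    kept <- vs$variants
    expect_gte(sum(kept$observations) / sum(obs), frac)
    if (nrow(kept) > 1L) {
      # dropping the least-observed retained variant falls below the share
      expect_lt((sum(kept$observations) - min(kept$observations)) / sum(obs),
                frac)
    }
  }
})

test_that("the full variant-selection pipeline is monotone and recovers the planted family", {
  s <- vs_setup()
  cands <- find_candidates(s$ref, s$db)
  vs <- select_variants(s$ref, s$db)
  expect_true(all(vs$variants$id %in% cands$id))
  expect_setequal(vs$variants$sequence, s$pan$truth$expected_variants)
  expect_s3_class(generics::tidy(vs), "tbl_df")
  expect_equal(generics::glance(vs)$n_variants, nrow(vs$variants))
})
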