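random_seq <- function(len) {
  paste(sample(rownames(blosum62_matrix)[1:20], len, TRUE), collapse = "")
}

test_that("global alignment of identical sequences gives 100/100", {
  withr::local_seed(31)
  s <- random_seq(100)
  g <- global_align(s, s)
  expect_equal(g$pct_identity, 100)
  expect_equal(g$pct_length, 100)
  expect_equal(g$aligned_query, s)
  single <- global_align("A", "A")
  expect_equal(single$pct_identity, 100)
  expect_error(global_align("", "A"), "empty")
})

test_that("global alignment score equals the exhaustive DP oracle", {
  withr::local_seed(32)
  for (i in 1:120) {
    a <- random_seq(sample(1:30, 1))
    b <- random_seq(sample(1:30, 1))
    g <- global_align(a, b)
    expect_equal(g$score, nw_score_oracle(a, b), tolerance = 1e-9)
  }
})

test_that("global alignment is symmetric and aligned strings recover inputs", {
  withr::local_seed(33)
  for (i in 1:25) {
    a <- random_seq(sample(5:40, 1))
    b <- random_seq(sample(5:40, 1))
    g1 <- global_align(a, b)
    g2 <- global_align(b, a)
    expect_equal(g1$score, g2$score)
    expect_equal(nchar(g1$aligned_query), nchar(g1$aligned_subject))
    expect_equal(gsub("-", "", g1$aligned_query, fixed = TRUE), a)
    expect_equal(gsub("-", "", g1$aligned_subject, fixed = TRUE), b)
  }
})

test_that("local search finds the query itself at 100/100 and ranks it first", {
  pan <- tiny_panel()
  db <- compact_proteins(run_qc(pan$proteins)$proteins)
  clean <- setdiff(pan$truth$family$genome_id, pan$truth$spurious$genome_id)
  fam <- pan$truth$family$sequence[pan$truth$family$genome_id == clean[1]]
  hits <- local_search(fam, db)
  expect_gt(nrow(hits), 0)
  expect_equal(hits$pct_identity[1], 100)
  expect_equal(hits$query_coverage[1], 100)
  expect_equal(max(hits$score), hits$score[1])
})

test_that("local search returns nothing for unrelated queries and respects thresholds", {
  pan <- tiny_panel()
  db <- compact_proteins(run_qc(pan$proteins)$proteins)
  # a query sharing no 4-mer with the database: homopolymer of rare residue
  hits <- local_search(strrep("W", 50), db)
  expect_equal(nrow(hits), 0L)
  # monotonicity: raising min_identity never adds hits
  ref <- pan$truth$reference
  h60 <- local_search(ref, db, min_identity = 60)
  h80 <- local_search(ref, db, min_identity = 80)
  expect_true(all(h80$subject_id %in% h60$subject_id))
  expect_true(all(h60$pct_identity >= 60 & h60$query_coverage >= 60))
})

test_that("prefilter does not change the reported hit set", {
  pan <- tiny_panel()
  db <- compact_proteins(run_qc(pan$proteins)$proteins)
  ref <- pan$truth$reference
  with_pf <- local_search(ref, db, prefilter = TRUE)
  without_pf <- local_search(ref, db, prefilter = FALSE)
  expect_equal(with_pf, without_pf)
})

test_that("greedy clustering matches hand-simulated rule on toy sequences", {
  # distinct sequences at threshold 100 -> singletons
  seqs <- tibble::tibble(id = c("a", "b", "c"),
                         sequence = c("MKAAAAAA", "MKAAAAAT", "MKTTTTTT"))
  cl <- greedy_cluster(seqs, 100)
  expect_equal(length(unique(cl$cluster)), 3L)

  # identical pair joins regardless of threshold
  two <- tibble::tibble(id = c("x", "y"), sequence = c("MKLMKL", "MKLMKL"))
  expect_equal(length(unique(greedy_cluster(two, 100)$cluster)), 1L)

  # hand-derived: a/b identical at 7/8 = 87.5%, c at 2/8 = 25% to both.
  # threshold 70: longest-first seed a (ties by id), b joins, c seeds new.
  cl70 <- greedy_cluster(seqs, 70)
  expect_equal(cl70$cluster[cl70$id == "a"], cl70$cluster[cl70$id == "b"])
  expect_false(cl70$cluster[cl70$id == "c"] == cl70$cluster[cl70$id == "a"])
  expect_equal(cl70$representative_id[cl70$id == "b"], "a")
  expect_error(greedy_cluster(seqs[0, ], 70), "empty")
})

test_that("greedy clustering at 100 reproduces exact dedup on equal-length input", {
  withr::local_seed(34)
  pool <- c("MKAAAAAA", "MKAAAAAT", "MKTTTTTT")
  seqs <- tibble::tibble(id = paste0("s", 1:9),
                         sequence = rep(pool, each = 3))
  cl <- greedy_cluster(seqs, 100)
  expect_equal(length(unique(cl$cluster)), 3L)
  grp <- split(cl$sequence, cl$cluster)
  expect_true(all(vapply(grp, function(g) length(unique(g)) == 1L,
                         logical(1))))
})
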