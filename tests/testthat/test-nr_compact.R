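random_panel <- function(n_genomes, n_per_genome, n_distinct_pool,
                         len = c(10, 40)) {
  pool <- vapply(seq_len(n_distinct_pool), function(i) {
    paste(sample(c("A", "G", "K", "R", "M", "L", "S", "T"),
                 sample(len[1]:len[2], 1), TRUE), collapse = "")
  }, character(1))
  descs <- sample(c("hla", "alpha-toxin", "hypothetical", ""), n_distinct_pool,
                  TRUE)
  dplyr::bind_rows(lapply(seq_len(n_genomes), function(g) {
    pick <- sample(n_distinct_pool, n_per_genome, replace = TRUE)
    tibble::tibble(id = paste0("p", seq_len(n_per_genome)),
                   description = descs[pick],
                   genome_id = sprintf("g%02d", g),
                   sequence = pool[pick])
  }))
}

expect_db_equals_oracle <- function(db, proteins) {
  oracle <- naive_dedup_oracle(proteins)
  expect_equal(nrow(db$representatives), length(oracle))
  expect_equal(db$representatives$id,
               vapply(oracle, `[[`, character(1), "representative_id"))
  expect_equal(db$representatives$description,
               vapply(oracle, `[[`, character(1), "description"))
  expect_equal(db$representatives$sequence,
               vapply(oracle, `[[`, character(1), "sequence"))
  expect_equal(db$clusters$member_ids, lapply(oracle, `[[`, "members"))
}

test_that("identical sequences collapse to one representative with all members", {
  prot <- tibble::tibble(id = "p1", description = "toxin",
                         genome_id = c("g1", "g2", "g3"), sequence = "MKR")
  db <- compact_proteins(prot)
  expect_equal(nrow(db$representatives), 1L)
  expect_equal(db$clusters$n_members, 3L)
  expect_setequal(db$clusters$member_ids[[1]],
                  c("g1|p1", "g2|p1", "g3|p1"))
  expect_error(compact_proteins(prot[0, ]), "zero proteins")
})

test_that("sequences of different lengths form separate clusters", {
  prot <- tibble::tibble(id = c("p1", "p2"), description = "",
                         genome_id = "g1", sequence = c("AAK", "AAKA"))
  db <- compact_proteins(prot)
  expect_equal(nrow(db$representatives), 2L)
})

test_that("compaction equals the naive dedup oracle for every chunk size", {
  withr::local_seed(21)
  prot <- random_panel(n_genomes = 8, n_per_genome = 30, n_distinct_pool = 90)
  for (cs in c(1, 3, 17, nrow(prot))) {
    db <- compact_proteins(prot, chunk_size = cs)
    expect_db_equals_oracle(db, prot)
  }
})

test_that("compaction conserves members and is genome-order independent", {
  withr::local_seed(22)
  prot <- random_panel(n_genomes = 6, n_per_genome = 25, n_distinct_pool = 60)
  db <- compact_proteins(prot, chunk_size = 7)
  expect_equal(sum(db$clusters$n_members), nrow(prot))
  members <- unlist(db$clusters$member_ids)
  expect_equal(sort(members),
               sort(paste0(prot$genome_id, "|", prot$id)))
  # permuting input rows leaves the database unchanged
  perm <- prot[sample(nrow(prot)), ]
  db2 <- compact_proteins(perm, chunk_size = 11)
  expect_equal(db, db2)
})

test_that("representative choice follows modal description with byte-order ties", {
  expect_equal(
    choose_representative(c("g2|b", "g1|a", "g3|c"),
                          c("hla", "hla", "alpha-toxin")),
    list(id = "g1|a", description = "hla"))
  expect_equal(choose_representative("g1|z", "solo"),
               list(id = "g1|z", description = "solo"))
  # tie on counts: byte-smallest description wins, its bearer's id follows
  expect_equal(choose_representative(c("g1|q", "g1|p"), c("b", "a")),
               list(id = "g1|p", description = "a"))
})

test_that("write/read round-trips the database and checks invariants", {
  withr::local_seed(23)
  prot <- random_panel(n_genomes = 4, n_per_genome = 15, n_distinct_pool = 25)
  db <- compact_proteins(prot)
  dir <- withr::local_tempdir()
  write_nr_db(db, dir)
  back <- read_nr_db(dir)
  expect_equal(back$representatives, db$representatives)
  expect_equal(back$clusters, db$clusters)

  # corrupt: cluster row referencing an unknown representative
  tsv <- file.path(dir, "clusters.tsv")
  lines <- readLines(tsv)
  lines[2] <- sub("^[^\t]+", "ghost|id", lines[2])
  writeLines(lines, tsv)
  expect_error(read_nr_db(dir), "representative sets")

  # corrupt: member count mismatch
  write_nr_db(db, dir)
  lines <- readLines(tsv)
  parts <- strsplit(lines[2], "\t")[[1]]
  parts[3] <- as.character(as.integer(parts[3]) + 1L)
  lines[2] <- paste(parts, collapse = "\t")
  writeLines(lines, tsv)
  expect_error(read_nr_db(dir), "n_members")
})

test_that("tidy and glance summarise the database", {
  pan <- tiny_panel()
  db <- compact_proteins(run_qc(pan$proteins)$proteins)
  td <- generics::tidy(db)
  expect_true(all(c("representative_id", "n_members", "n_genomes") %in%
                    names(td)))
  gl <- generics::glance(db)
  expect_equal(gl$n_proteins, sum(db$clusters$n_members))
  expect_gt(gl$compaction_ratio, 1)  # shared core proteins compress
})
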