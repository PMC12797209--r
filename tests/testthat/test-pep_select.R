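toy_matrix <- function() {
  m <- matrix(FALSE, 4, 4,
              dimnames = list(paste0("p", 1:4), paste0("V", 1:4)))
  m["p1", c("V1", "V2")] <- TRUE
  m["p2", c("V2", "V3")] <- TRUE
  m["p3", c("V1", "V4")] <- TRUE
  m["p4", "V3"] <- TRUE
  as_presence_matrix(m)
}

test_that("build_matrix digests variants and applies exclusions", {
  vs <- tibble::tibble(id = "V1", sequence = "MARLAKPGR")
  pm <- build_matrix(vs)
  expect_setequal(rownames(pm$mat), c("MAR", "LAKPGR"))
  expect_true(all(pm$mat[, "V1"]))

  pm2 <- build_matrix(vs, multicopy = "MAR")
  expect_equal(rownames(pm2$mat), "LAKPGR")
  expect_equal(pm2$dropped_multicopy, "MAR")

  expect_warning(pm3 <- build_matrix(vs, multicopy = c("MAR", "LAKPGR")),
                 "no remaining peptide")
  expect_equal(pm3$empty_variants, "V1")

  # user exclusion reported separately from multicopy
  pm4 <- build_matrix(vs, user_exclude = "LAKPGR")
  expect_equal(pm4$dropped_user, "LAKPGR")
})

test_that("length bounds prune the candidate peptide pool", {
  vs <- tibble::tibble(id = "V1", sequence = "MARLAKPGRKK")
  pm <- build_matrix(vs, min_length = 2, max_length = 5)
  expect_setequal(rownames(pm$mat), "MAR")  # K too short, LAKPGR too long
  pm2 <- build_matrix(vs, min_length = 2)
  expect_setequal(rownames(pm2$mat), c("MAR", "LAKPGR"))
})

test_that("two variants sharing all peptides keep separate columns", {
  vs <- tibble::tibble(id = c("V1", "V2"),
                       sequence = c("AAKCCR", "CCRAAK"))
  pm <- build_matrix(vs)
  expect_equal(ncol(pm$mat), 2L)
  expect_equal(unname(colSums(pm$mat)), c(2, 2))
})

test_that("worked greedy example selects p3 then p2", {
  st <- greedy_select(toy_matrix(), target = 1)
  expect_equal(st$minimum_list, c("p3", "p2"))
  expect_true(all(st$coverage >= 1))
  expect_equal(st$uncoverable, character())
})

test_that("a single variant with many peptides gets exactly `target` peptides", {
  vs <- tibble::tibble(id = "V1",
                       sequence = "MAKCCKDDKEEKFFKGGK")
  pm <- build_matrix(vs)
  st <- greedy_select(pm, target = 3)
  expect_equal(length(st$minimum_list), 3L)
  expect_equal(unname(st$coverage["V1"]), 3L)
})

test_that("variants with too few peptides end up uncoverable at their maximum", {
  m <- matrix(FALSE, 1, 1, dimnames = list("ONLYPEP", "V1"))
  m[1, 1] <- TRUE
  st <- greedy_select(as_presence_matrix(m), target = 3)
  expect_equal(st$minimum_list, "ONLYPEP")
  expect_equal(st$uncoverable, "V1")
  expect_equal(unname(st$coverage["V1"]), 1L)
})

test_that("user seeding moves peptides to the list and recomputes coverage", {
  pm <- toy_matrix()
  st <- selection_state(pm, target = 1)
  st <- seed_with_user_list(st, "p1")
  expect_equal(st$minimum_list, "p1")
  expect_equal(unname(st$coverage[c("V1", "V2")]), c(1L, 1L))
  expect_false("p1" %in% st$remaining)

  expect_warning(st2 <- seed_with_user_list(st, "NOTAPEPTIDE"), "ignored")
  expect_equal(st2$minimum_list, "p1")

  st3 <- seed_with_user_list(selection_state(pm, 1), character())
  expect_equal(st3$minimum_list, character())

  final <- greedy_select(st)
  expect_equal(final$selected_from[1], "user")
  expect_true(all(final$coverage >= 1))
})

test_that("greedy selection is valid, deterministic, and terminates on random instances", {
  withr::local_seed(51)
  for (i in 1:150) {
    mat <- random_presence_matrix(sample(2:12, 1), sample(2:10, 1))
    target <- sample(1:3, 1)
    st <- greedy_select(as_presence_matrix(mat), target = target)
    # termination bound
    expect_lte(length(st$minimum_list), nrow(mat))
    # no duplicates
    expect_equal(anyDuplicated(st$minimum_list), 0L)
    # validity: covered variants reach the target, uncoverable ones cannot
    covered <- setdiff(colnames(mat), st$uncoverable)
    expect_true(all(st$coverage[covered] >= target))
    expect_true(all(colSums(mat[, st$uncoverable, drop = FALSE]) < target))
    # coverage bookkeeping equals direct recount from the matrix
    recount <- colSums(mat[st$minimum_list, , drop = FALSE])
    expect_equal(unname(st$coverage), unname(recount))
    # determinism
    st2 <- greedy_select(as_presence_matrix(mat), target = target)
    expect_identical(st$minimum_list, st2$minimum_list)
  }
})

test_that("greedy cover size stays close to the exhaustive optimum at target 1", {
  withr::local_seed(52)
  ratios <- vapply(1:60, function(i) {
    mat <- random_presence_matrix(sample(3:12, 1), sample(3:10, 1))
    st <- greedy_select(as_presence_matrix(mat), target = 1)
    opt <- optimal_cover_size(mat)
    if (opt == 0L) return(NA_real_)
    length(st$minimum_list) / opt
  }, numeric(1))
  ratios <- ratios[!is.na(ratios)]
  expect_true(all(ratios >= 1))          # never better than optimal
  expect_lt(mean(ratios), 1.5)           # greedy stays near-optimal here
})

test_that("selection tidiers report ranks, sources and coverage summaries", {
  st <- greedy_select(toy_matrix(), target = 1)
  td <- generics::tidy(st)
  expect_equal(td$rank, 1:2)
  expect_equal(td$peptide, c("p3", "p2"))
  expect_equal(td$n_variants_covered, c(2L, 2L))
  gl <- generics::glance(st)
  expect_equal(gl$n_peptides, 2L)
  expect_equal(gl$n_covered, 4L)
})
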