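# Independent oracles used by the property tests. These deliberately do not
# share code with the package implementation.

blosum62_matrix <- local({
  e <- new.env()
  utils::data("BLOSUM62", package = "Biostrings", envir = e)
  e$BLOSUM62
})

# Gotoh affine-gap global alignment score, end gaps penalized; a gap of
# length L costs open + L * ext (the convention of the package's aligner).
nw_score_oracle <- function(a, b, open = 10, ext = 0.5,
                            mat = blosum62_matrix) {
  A <- strsplit(a, "", fixed = TRUE)[[1L]]
  B <- strsplit(b, "", fixed = TRUE)[[1L]]
  n <- length(A); m <- length(B)
  NEG <- -1e9
  M <- matrix(NEG, n + 1L, m + 1L)
  X <- matrix(NEG, n + 1L, m + 1L)  # gap in b (vertical)
  Y <- matrix(NEG, n + 1L, m + 1L)  # gap in a (horizontal)
  M[1L, 1L] <- 0
  for (i in seq_len(n)) X[i + 1L, 1L] <- -(open + i * ext)
  for (j in seq_len(m)) Y[1L, j + 1L] <- -(open + j * ext)
  for (i in seq_len(n)) {
    for (j in seq_len(m)) {
      s <- mat[A[i], B[j]]
      M[i + 1L, j + 1L] <- max(M[i, j], X[i, j], Y[i, j]) + s
      X[i + 1L, j + 1L] <- max(M[i, j + 1L] - open - ext,
                               X[i, j + 1L] - ext,
                               Y[i, j + 1L] - open - ext)
      Y[i + 1L, j + 1L] <- max(M[i + 1L, j] - open - ext,
                               Y[i + 1L, j] - ext,
                               X[i + 1L, j] - open - ext)
    }
  }
  max(M[n + 1L, m + 1L], X[n + 1L, m + 1L], Y[n + 1L, m + 1L])
}

# Naive single-pass exact deduplication: hash map sequence -> member list.
# Representative rule re-derived independently: modal description (ties by
# byte order), then byte-smallest member id bearing it.
naive_dedup_oracle <- function(proteins) {
  qual <- paste0(proteins$genome_id, "|", proteins$id)
  groups <- split(seq_len(nrow(proteins)), proteins$sequence)
  rows <- lapply(names(groups), function(s) {
    idx <- groups[[s]]
    descs <- proteins$description[idx]
    tab <- sort(table(descs), decreasing = TRUE)
    best_desc <- sort(names(tab)[tab == max(tab)], method = "radix")[1L]
    rep_id <- sort(qual[idx][descs == best_desc], method = "radix")[1L]
    list(sequence = s, representative_id = rep_id, description = best_desc,
         members = sort(qual[idx], method = "radix"))
  })
  rows[order(vapply(rows, `[[`, character(1), "representative_id"),
             method = "radix")]
}

# Exhaustive minimum set cover (target 1) over the coverable variants of a
# logical peptide x variant matrix. Returns the optimal cover size.
optimal_cover_size <- function(mat) {
  coverable <- which(colSums(mat) > 0L)
  if (length(coverable) == 0L) return(0L)
  sub <- mat[, coverable, drop = FALSE]
  n <- nrow(sub)
  masks <- vapply(seq_len(n), function(i) {
    sum(2^(which(sub[i, ]) - 1L))
  }, numeric(1))
  full <- sum(2^(seq_along(coverable) - 1L))
  for (k in seq_len(n)) {
    combos <- utils::combn(n, k)
    for (c in seq_len(ncol(combos))) {
      m <- 0
      for (i in combos[, c]) m <- bitwOr(m, masks[i])
      if (m == full) return(k)
    }
  }
  n
}

# Random presence matrix with at least one peptide and one variant.
random_presence_matrix <- function(n_pep, n_var, density = 0.35) {
  mat <- matrix(stats::runif(n_pep * n_var) < density, n_pep, n_var,
                dimnames = list(paste0("P", seq_len(n_pep)),
                                paste0("V", seq_len(n_var))))
  keep <- rowSums(mat) > 0L   # peptides occurring in no variant cannot exist
  mat <- mat[keep, , drop = FALSE]
  if (nrow(mat) == 0L) mat <- matrix(TRUE, 1L, n_var,
                                     dimnames = list("P1", colnames(mat)))
  mat
}

as_presence_matrix <- function(mat) {
  structure(list(mat = mat, dropped_multicopy = character(),
                 dropped_user = character(),
                 empty_variants = colnames(mat)[colSums(mat) == 0L]),
            class = "presence_matrix")
}

# A small memoised study panel shared across test files.
tiny_panel <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cache <<- make_panel(seed = 301, n_genomes = 10, reference_length = 180,
                           n_background_shared = 5, n_background_unique = 5,
                           n_spurious_ambiguous = 1, n_spurious_outlier = 1)
    }
    cache
  }
})
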