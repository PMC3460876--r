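test_that("pair_distance is the symmetric squared difference, 0 on identity", {
  expect_equal(pair_distance("A", "A", pm1_norm), 0)
  expect_equal(pair_distance("A", "C", pm1_norm), 4)  # (1 - (-1))^2
  for (idx in toy_indices) {
    nv <- normalize_index(idx)
    pairs <- matrix(sample(AA20, 20, replace = TRUE), ncol = 2)
    for (r in seq_len(nrow(pairs)))
      expect_equal(pair_distance(pairs[r, 1], pairs[r, 2], nv),
                   pair_distance(pairs[r, 2], pairs[r, 1], nv))
  }
  # non-standard residues take the index mean (normalized 0)
  expect_equal(pair_distance("X", "A", pm1_norm), 1)
})

test_that("pdt_component averages pair distances at one lag", {
  expect_equal(pdt_component("AAAAAA", pm1_norm, 1), 0)
  expect_equal(pdt_component("AAAAAA", pm1_norm, 3), 0)
  # hand-enumerated 5 pairs each: ACACAC all cross, AAACCC one cross
  expect_equal(pdt_component("ACACAC", pm1_norm, 1), 4.0)
  expect_equal(pdt_component("AAACCC", pm1_norm, 1), 0.8)
  expect_error(pdt_component("ACACAC", pm1_norm, 6),
               class = "pdt_distance_error")
  expect_error(pdt_component("ACACAC", pm1_norm, 0),
               class = "pdt_distance_error")
})

test_that("pdt_transform follows the index-major / lambda-minor layout", {
  seq <- "ACDEFGHIKL"
  v <- pdt_transform(seq, toy_set, beta = 2L)
  expect_length(v, 5L * 2L)
  expect_equal(names(v)[1:4], c("TOY00001_lambda1", "TOY00001_lambda2",
                                "TOY00002_lambda1", "TOY00002_lambda2"))
  for (j in 1:5) for (lam in 1:2)
    expect_equal(v[[paste0(toy_set$accessions[j], "_lambda", lam)]],
                 pdt_component(seq, toy_set$values[, j], lam))
  expect_error(pdt_transform("ACD", toy_set, beta = 3L, id = "shorty"),
               "shorty", class = "pdt_distance_error")
})

test_that("pdt_transform equals the brute-force triple-loop oracle", {
  set.seed(7)
  for (rep in 1:20) {
    seq <- random_protein(sample(20:120, 1))
    expect_equal(bare(pdt_transform(seq, toy_set, beta = test_beta)),
                 oracle_pdt(seq, toy_indices, test_beta), tolerance = 1e-12)
  }
})

test_that("feature values are non-negative, zero iff constant property", {
  set.seed(8)
  for (rep in 1:10) {
    v <- pdt_transform(random_protein(50), toy_set, beta = 4L)
    expect_true(all(is.finite(v)) && all(v >= 0))
  }
  expect_equal(bare(pdt_transform(strrep("K", 30), toy_set, beta = 4L)),
               rep(0, 20))
})

test_that("same composition, different order gives different vectors", {
  pm1_set <- normalize_indices(list(pm1_index), filter = FALSE)
  v1 <- pdt_transform("ACACAC", pm1_set, beta = 2L)
  v2 <- pdt_transform("AAACCC", pm1_set, beta = 2L)
  expect_false(isTRUE(all.equal(unname(v1), unname(v2))))
})

test_that("non-standard residues contribute 0 with a warning", {
  expect_warning(v <- pdt_transform("AXA", toy_set, beta = 1L), "X")
  # each pair is (I_j(A) - 0)^2
  expected <- vapply(1:5, function(j) toy_set$values["A", j]^2, numeric(1))
  expect_equal(bare(v), expected)
})

test_that("batch transform preserves order, determinism and skip contract", {
  seqs <- c(s1 = "ACDEFGHIKLMNPQ", s2 = "WYVACDEFGHIKLM", s3 = "ACDEFGHIKLMNPQ")
  X <- pdt_transform_batch(seqs, toy_set, beta = 3L)
  expect_identical(rownames(X), names(seqs))
  expect_equal(X["s1", ], keep_names(pdt_transform(seqs[["s1"]], toy_set, 3L)))
  expect_equal(unname(X["s1", ]), unname(X["s3", ]))  # identical seq, identical row
  withshort <- c(seqs, tiny = "ACD")
  expect_error(pdt_transform_batch(withshort, toy_set, beta = 8L, strict = TRUE),
               "tiny", class = "pdt_distance_error")
  expect_message(Xl <- pdt_transform_batch(withshort, toy_set, beta = 8L,
                                           strict = FALSE), "tiny")
  expect_identical(rownames(Xl), c("s1", "s2", "s3"))
})

test_that("N-terminal deletions move vectors much less than unrelated sequences", {
  set.seed(11)
  n_rep <- 8L
  drift <- matrix(NA_real_, nrow = n_rep, ncol = 3L)  # k = 2, 6, 10
  unrelated <- numeric(n_rep)
  for (r in seq_len(n_rep)) {
    seq <- random_protein(220)
    v0 <- pdt_transform(seq, toy_set, beta = test_beta)
    rel <- function(v) sqrt(sum((v - v0)^2)) / sqrt(sum(v0^2))
    for (ki in seq_along(c(2L, 6L, 10L))) {
      k <- c(2L, 6L, 10L)[ki]
      keep <- setdiff(seq_len(nchar(seq)), sample(1:20, k))
      chopped <- paste(strsplit(seq, "")[[1]][keep], collapse = "")
      drift[r, ki] <- rel(pdt_transform(chopped, toy_set, beta = test_beta))
    }
    unrelated[r] <- rel(pdt_transform(random_protein(220), toy_set, beta = test_beta))
  }
  means <- colMeans(drift)
  expect_true(all(diff(means) >= 0))            # non-decreasing in k
  expect_lt(means[3], mean(unrelated) / 2)      # well below unrelated distance
})

test_that("feature TSV round trip preserves values and layout metadata", {
  seqs <- c(a = "ACDEFGHIKLMNPQRSTVWY", b = "MNPQRSTVWYACDEFGHIKL")
  X <- pdt_transform_batch(seqs, toy_set, beta = 3L)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_feature_tsv(X, path, beta = 3L, accessions = toy_set$accessions, seed = 5)
  Y <- read_feature_tsv(path)
  expect_equal(unclass(Y), unclass(X), ignore_attr = TRUE)
  expect_identical(attr(Y, "beta"), 3L)
  expect_identical(attr(Y, "accessions"), toy_set$accessions)
  expect_error(read_feature_tsv(write_fixture_aaindex()), class = "pdt_io_error")
})
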