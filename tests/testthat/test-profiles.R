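# identity-like pseudo-count model on uniform background: q = I/20 makes
# pseudo-counts reproduce observed frequencies exactly, so Eq-style blends
# can be hand-evaluated.
identity_model <- structure(
  list(mode = "frequency", beta_pc = 10,
       p = stats::setNames(rep(1 / 20, 20), AA20),
       q = diag(20) / 20),
  class = "pseudo_count_model")

test_that("column_frequencies counts residues and ignores gaps", {
  c1 <- column_frequencies(c("A", "A", "A"))
  expect_equal(c1$f[["A"]], 1)
  expect_equal(c1$distinct_count, 1L)
  c2 <- column_frequencies(c("A", "C", "-", "C"))
  expect_equal(c2$f[["A"]], 1 / 3)
  expect_equal(c2$f[["C"]], 2 / 3)
  expect_equal(c2$distinct_count, 2L)
  expect_equal(sum(c2$f), 1)
  expect_error(column_frequencies(c("-", "-")), class = "pdt_empty_column_error")
})

test_that("filter_alignment drops rows at >= 98% identity to the query", {
  q <- strrep("ACDEFGHIKL", 10)  # 100 residues
  dup <- q
  chars <- strsplit(q, "")[[1]]
  chars[c(5, 50, 95)] <- c("W", "W", "W")
  near <- paste(chars, collapse = "")  # 97/100 identical
  msa <- c(q, dup, near)
  out <- filter_alignment(msa)
  expect_identical(out, c(q, near))  # exact duplicate removed, 97% kept
  far <- paste(rev(strsplit(q, "")[[1]]), collapse = "")
  expect_identical(filter_alignment(c(q, far)), c(q, far))
})

test_that("pseudo_counts match an independent 20-term loop oracle", {
  model <- pseudo_count_model()
  expect_equal(sum(model$p), 1)
  expect_true(isSymmetric(unname(model$q)))
  set.seed(21)
  for (rep in 1:5) {
    col <- column_frequencies(sample(AA20, 12, replace = TRUE))
    g <- pseudo_counts(col, model)
    oracle <- numeric(20)
    for (i in 1:20) {
      s <- 0
      for (j in 1:20) s <- s + col$f[j] / model$p[j] * model$q[i, j]
      oracle[i] <- s
    }
    expect_equal(unname(g), oracle, tolerance = 1e-12)
    expect_true(all(is.finite(g)) && all(g >= 0))
  }
  # concentrated column: g varies with the pairing term of that residue
  conc <- column_frequencies(rep("W", 5))
  expect_equal(unname(pseudo_counts(conc, model)),
               unname(model$q[, "W"] / model$p[["W"]]), tolerance = 1e-12)
})

test_that("score mode uses raw BLOSUM62 log-odds (then clamps)", {
  model <- pseudo_count_model("score")
  col <- column_frequencies(c("A", "C"))
  g <- pseudo_counts(col, model)
  expect_equal(unname(g), as.vector(model$q %*% col$f))
  expect_true(any(g < 0))  # raw scores do go negative ...
  tf <- target_frequencies(col, model)
  expect_true(all(tf >= 0))  # ... but target frequencies cannot
  expect_equal(sum(tf), 1)
})

test_that("target frequencies blend f and g and renormalize", {
  model <- pseudo_count_model()
  # alpha = 0: fully pseudo-count-driven, f plays no role
  single <- column_frequencies(rep("H", 7))
  g <- pseudo_counts(single, model)
  expect_equal(target_frequencies(single, model), g / sum(g), tolerance = 1e-12)
  # hand-evaluated blend under the identity-like model: target == observed
  two <- column_frequencies(c("A", "C"))
  expect_equal(target_frequencies(two, identity_model), two$f, tolerance = 1e-12)
  set.seed(22)
  for (rep in 1:5) {
    col <- column_frequencies(sample(AA20, 9, replace = TRUE))
    expect_equal(sum(target_frequencies(col, model)), 1, tolerance = 1e-12)
  }
})

test_that("build_profile yields a row-stochastic L x 20 matrix", {
  msa <- c("ACD-EF",
           "ABD-EF",  # B dropped as non-standard
           "GCD-EF",
           "AC--EF")
  expect_warning(prof <- build_profile(msa), "non-standard")
  expect_identical(dim(prof), c(5L, 20L))  # query has 5 residues
  expect_true(all(abs(rowSums(prof) - 1) < 1e-9))
  expect_true(all(prof >= 0))
  # no-smoothing mode reproduces observed column frequencies
  prof_raw <- suppressWarnings(build_profile(msa, model = NULL))
  expect_equal(unname(prof_raw[5, "F"]), 1)
})

test_that("nth_sequence ranks per-row frequencies with alphabetical ties", {
  M <- matrix(0, nrow = 3, ncol = 20, dimnames = list(NULL, AA20))
  M[1, c("W", "A")] <- c(0.7, 0.3)
  M[2, c("C", "D")] <- c(0.5, 0.5)     # tie -> C before D alphabetically
  M[3, c("V", "K", "Y")] <- c(0.2, 0.5, 0.3)
  prof <- structure(M, class = c("frequency_profile", "matrix"), id = "toy")
  expect_equal(unname(nth_sequence(prof, 1)), "WCK")
  expect_equal(unname(nth_sequence(prof, 2)), "ADY")
  # rank consistency: n=1 frequency >= n=2 frequency at every position
  set.seed(23)
  R <- matrix(rexp(10 * 20), nrow = 10); R <- R / rowSums(R)
  colnames(R) <- AA20
  rp <- structure(R, class = c("frequency_profile", "matrix"), id = "r")
  s1 <- strsplit(unname(nth_sequence(rp, 1)), "")[[1]]
  s2 <- strsplit(unname(nth_sequence(rp, 2)), "")[[1]]
  for (i in 1:10)
    expect_gte(R[i, s1[i]], R[i, s2[i]])
})

test_that("profile_pdt concatenates per-rank transforms", {
  seq <- c(myseq = "ACDEFGHIKLMNPQRSTVWY")
  prof <- make_degenerate_profile(seq)
  v1 <- profile_pdt(prof, toy_set, beta = 4L, n_max = 1L)
  expect_length(v1, 5L * 4L)
  expect_equal(bare(v1), bare(pdt_transform(seq, toy_set, beta = 4L)))
  v2 <- profile_pdt(prof, toy_set, beta = 4L, n_max = 2L)
  expect_length(v2, 5L * 4L * 2L)
  # compositional oracle: manual concatenation of the two rank transforms
  manual <- c(pdt_transform(nth_sequence(prof, 1), toy_set, 4L),
              pdt_transform(nth_sequence(prof, 2), toy_set, 4L))
  expect_equal(bare(v2), bare(manual))
  expect_match(names(v2)[1], "_n1$")
  expect_match(names(v2)[40], "_n2$")
  expect_error(profile_pdt(prof, toy_set, beta = 4L, n_max = 3L))
})

test_that("profile TSV round trip", {
  msa <- c("ACDEF", "ACDEG", "WCDEF")
  prof <- build_profile(msa)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_profile_tsv(prof, path)
  again <- read_profile_tsv(path)
  expect_equal(unclass(again), unclass(prof), ignore_attr = TRUE,
               tolerance = 1e-12)
})

test_that("psiblast_command emits the documented parameters", {
  cmd <- psiblast_command("q.fasta")
  expect_match(cmd, "-num_iterations 10")
  expect_match(cmd, "-evalue 0.001")
})
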