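# Shared fixtures and independent oracles. Oracles are deliberately
# written as naive loops so they stay independent of the vectorized paths
# they check.

AA20 <- pdtransform::AA_CANONICAL

toy_indices <- make_toy_indices(5L, seed = 42L)
toy_set <- normalize_indices(toy_indices, filter = FALSE)

# A +/-1 property scale that is its own z-normalization (ten residues at
# +1, ten at -1) with A = +1 and C = -1.
pm1_index <- aa_index("PM100001", stats::setNames(
  c(A = 1, R = -1, N = 1, D = -1, C = -1, Q = 1, E = -1, G = 1, H = -1,
    I = 1, L = -1, K = 1, M = -1, F = 1, P = -1, S = 1, T = -1, W = 1,
    Y = -1, V = 1)[AA20], AA20), title = "plus/minus one toy scale")
pm1_norm <- normalize_index(pm1_index)

random_protein <- function(L) paste(sample(AA20, L, replace = TRUE), collapse = "")

# Brute-force PDT oracle: z-normalizes each raw index itself (mean /
# population sd over the 20 residues) and loops over every (index, lambda,
# position) triple.
oracle_pdt <- function(seq, raw_indices, beta) {
  chars <- strsplit(seq, "")[[1L]]
  L <- length(chars)
  out <- numeric(0)
  for (idx in raw_indices) {
    v <- idx$values
    mu <- sum(v) / 20
    sigma <- sqrt(sum((v - mu)^2) / 20)
    nv <- (v - mu) / sigma
    lookup <- function(a) if (a %in% AA20) nv[[a]] else 0
    for (lam in seq_len(beta)) {
      acc <- 0
      for (i in 1:(L - lam))
        acc <- acc + (lookup(chars[i]) - lookup(chars[i + lam]))^2
      out <- c(out, acc / (L - lam))
    }
  }
  out
}

# Mann-Whitney oracle: count concordant positive/negative pairs, ties 0.5.
oracle_auc <- function(scores, labels) {
  pos <- scores[labels > 0]
  neg <- scores[labels <= 0]
  total <- 0
  for (p in pos) for (q in neg)
    total <- total + if (p > q) 1 else if (p == q) 0.5 else 0
  total / (length(pos) * length(neg))
}

# Truncated-ROC oracle: walks distinct score thresholds in descending
# order, accumulating trapezoids in (FP, TP) space, interpolating inside
# the threshold block that crosses the FP cutoff.
oracle_roc50 <- function(scores, labels, max_fp = 50) {
  lab <- labels > 0
  P <- sum(lab); N <- sum(!lab)
  cut <- min(max_fp, N)
  thr <- sort(unique(scores), decreasing = TRUE)
  pts <- data.frame(fp = 0, tp = 0)
  for (t in thr)
    pts <- rbind(pts, data.frame(fp = sum(!lab & scores >= t),
                                 tp = sum(lab & scores >= t)))
  area <- 0
  for (r in 2:nrow(pts)) {
    f0 <- pts$fp[r - 1]; f1 <- pts$fp[r]
    t0 <- pts$tp[r - 1]; t1 <- pts$tp[r]
    if (f1 >= cut) {
      frac <- if (f1 > f0) (cut - f0) / (f1 - f0) else 1
      t_cut <- t0 + frac * (t1 - t0)
      area <- area + (cut - f0) * (t0 + t_cut) / 2
      break
    }
    area <- area + (f1 - f0) * (t0 + t1) / 2
  }
  area / (P * cut)
}

# Literal AAIndex1 fixture: three well-formed records typed by hand.
aaindex1_fixture_text <- c(
  "H FIX000001",
  "D hand-typed fixture scale one",
  "R PMID:0000001",
  "I    A/L     R/K     N/M     D/F     C/P     Q/S     E/T     G/W     H/Y     I/V",
  "    0.10    0.20    0.30    0.40    0.50    0.60    0.70    0.80    0.90    1.00",
  "    1.10    1.20    1.30    1.40    1.50    1.60    1.70    1.80    1.90    2.00",
  "//",
  "H FIX000002",
  "D hand-typed fixture scale two,",
  "  with a continued title line",
  "I    A/L     R/K     N/M     D/F     C/P     Q/S     E/T     G/W     H/Y     I/V",
  "   -1.00    2.00   -3.00    4.00   -5.00    6.00   -7.00    8.00   -9.00   10.00",
  "   -0.50    0.25   -0.75    1.25   -1.75    2.25   -2.75    3.25   -3.75    4.25",
  "//",
  "H FIX000003",
  "D fixture scale with missing tryptophan",
  "I    A/L     R/K     N/M     D/F     C/P     Q/S     E/T     G/W     H/Y     I/V",
  "    1.00    2.00    3.00    4.00    5.00    6.00    7.00    8.00    9.00   10.00",
  "   11.00   12.00   13.00   14.00   15.00   16.00   17.00      NA   19.00   20.00",
  "//")

write_fixture_aaindex <- function(lines = aaindex1_fixture_text) {
  path <- withr::local_tempfile(fileext = ".txt", .local_envir = parent.frame())
  writeLines(lines, path)
  path
}

# Shared tiny-benchmark settings used across classifier/evaluation tests.
test_beta <- 5L
make_test_split <- function(seed, effect = 0.9, signal_index = 1L,
                            signal_lambda = 2L, n = 40L) {
  make_family_dataset(
    family_spec(n_pos = n, n_neg = n, signal_index = signal_index,
                signal_lambda = signal_lambda, effect = effect, seed = seed),
    toy_indices)
}

split_features <- function(split, set = toy_set, beta = test_beta) {
  list(train_pos = pdt_transform_batch(split$train_pos, set, beta),
       train_neg = pdt_transform_batch(split$train_neg, set, beta),
       test = rbind(pdt_transform_batch(split$test_pos, set, beta),
                    pdt_transform_batch(split$test_neg, set, beta)),
       test_labels = c(rep(1, length(split$test_pos)),
                       rep(-1, length(split$test_neg))))
}

# strip all attributes (incl. names) / keep only names, for comparisons
# against bare oracle vectors
bare <- function(x) as.vector(x)
keep_names <- function(x) stats::setNames(as.vector(x), names(x))
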