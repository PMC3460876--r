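# ROC / ROC50 scoring and benchmark orchestration over per-family splits.

.check_labels <- function(labels) {
  lab <- if (is.logical(labels)) labels else labels > 0
  if (!any(lab) || all(lab))
    .pdt_error("pdt_score_error", "both classes must be present to score")
  lab
}

#' ROC score (area under the full ROC curve)
#'
#' Normalized area under the curve of true positives vs false positives
#' over the ranked score list; ties are averaged (trapezoid through tied
#' blocks, equivalently the Mann-Whitney statistic). 1 = perfect
#' separation, 0 = perfectly inverted ranking.
#'
#' @param scores Numeric decision values (higher = more positive).
#' @param labels Logical, or numeric with positives `> 0`.
#' @return Scalar in \[0, 1\].
#' @export
roc_score <- function(scores, labels) {
  lab <- .check_labels(labels)
  r <- rank(scores)
  P <- sum(lab); N <- sum(!lab)
  (sum(r[lab]) - P * (P + 1) / 2) / (P * N)
}

#' ROC50 score (ROC area up to the first 50 false positives)
#'
#' Area under the ROC curve truncated at the `max_fp`-th false positive,
#' normalized by `P * min(max_fp, N)` so that perfect early retrieval
#' scores 1. Ties are handled by stepping through tied-score blocks with a
#' trapezoid (and linear interpolation inside the block that crosses the
#' cutoff), so with `N <= max_fp` the value equals [roc_score()] exactly.
#' 0 means no positive precedes the cutoff.
#'
#' @inheritParams roc_score
#' @param max_fp False-positive cutoff (default 50).
#' @return Scalar in \[0, 1\].
#' @export
roc50_score <- function(scores, labels, max_fp = 50L) {
  lab <- .check_labels(labels)
  P <- sum(lab); N <- sum(!lab)
  cut <- min(max_fp, N)
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]; l <- lab[ord]
  blocks <- rle(s)
  ends <- cumsum(blocks$lengths)
  starts <- c(1L, utils::head(ends, -1L) + 1L)
  tp <- 0; fp <- 0; area <- 0
  for (b in seq_along(ends)) {
    btp <- sum(l[starts[b]:ends[b]])
    bfp <- (ends[b] - starts[b] + 1L) - btp
    if (fp + bfp >= cut) {
      frac <- if (bfp > 0) (cut - fp) / bfp else 1
      tp_at_cut <- tp + frac * btp
      area <- area + (cut - fp) * (tp + tp_at_cut) / 2
      fp <- cut; tp <- tp_at_cut
      break
    }
    area <- area + bfp * (tp + (tp + btp)) / 2
    tp <- tp + btp; fp <- fp + bfp
  }
  area / (P * cut)
}

#' Construct a benchmark split
#'
#' @param family Family identifier.
#' @param train_pos,train_neg,test_pos,test_neg Named character vectors of
#'   sequences; no id may appear in both train and test.
#' @return Object of class `benchmark_split`.
#' @export
benchmark_split <- function(family, train_pos, train_neg, test_pos, test_neg) {
  dup <- intersect(c(names(train_pos), names(train_neg)),
                   c(names(test_pos), names(test_neg)))
  if (length(dup) > 0L)
    .pdt_error("pdt_precondition_error",
               sprintf("family %s: id(s) in both train and test: %s",
                       family, paste(utils::head(dup, 3L), collapse = ", ")))
  structure(list(family = family, train_pos = train_pos, train_neg = train_neg,
                 test_pos = test_pos, test_neg = test_neg),
            class = "benchmark_split")
}

#' @export
print.benchmark_split <- function(x, ...) {
  cat(sprintf("<benchmark_split> %s: train %d+/%d-, test %d+/%d-\n", x$family,
              length(x$train_pos), length(x$train_neg),
              length(x$test_pos), length(x$test_neg)))
  invisible(x)
}

.family_model <- function(split, set, beta, kernel, folds, C, seed) {
  Xtr_pos <- pdt_transform_batch(split$train_pos, set, beta)
  Xtr_neg <- pdt_transform_batch(split$train_neg, set, beta)
  k <- if (identical(kernel, "auto")) {
    select_kernel(Xtr_pos, Xtr_neg, folds = folds, C = C, seed = seed)
  } else if (is.list(kernel) && !inherits(kernel, "kernel_spec")) {
    select_kernel(Xtr_pos, Xtr_neg, candidates = kernel, folds = folds,
                  C = C, seed = seed)
  } else kernel
  train_family(Xtr_pos, Xtr_neg, kernel = k, C = C, family = split$family,
               seed = seed)
}

.score_split <- function(model, split, set, beta) {
  Xte <- rbind(pdt_transform_batch(split$test_pos, set, beta),
               pdt_transform_batch(split$test_neg, set, beta))
  labels <- c(rep(1, length(split$test_pos)), rep(-1, length(split$test_neg)))
  sc <- predict(model, Xte)
  list(roc = roc_score(sc, labels), roc50 = roc50_score(sc, labels),
       table = data.frame(id = rownames(Xte), score = unname(sc),
                          label = labels, stringsAsFactors = FALSE))
}

#' Run the PDT benchmark over family splits
#'
#' For each family: transform train/test sequences, pick the kernel
#' (fixed, or per-family by cross-validated ROC when `kernel = "auto"` or a
#' candidate list), train the SVM, and score the test set by ROC and ROC50.
#' Families that fail training are recorded with `NA` scores, excluded from
#' the means, and warned about. Deterministic for a fixed seed (each family
#' uses `seed + its position`).
#'
#' @param splits List of [benchmark_split()] objects.
#' @param set A `norm_index_set`.
#' @param beta Maximum lag (default 8).
#' @param kernel A [kernel_spec()], a list of candidates, or `"auto"`
#'   (quadratic vs RBF by 5-fold CV, the per-family selection protocol).
#' @param folds CV folds for kernel selection.
#' @param C Soft-margin cost.
#' @param seed Base seed.
#' @param return_models Also return the trained models.
#' @return Object of class `pdt_benchmark`: list with `results` (data frame
#'   family/kernel/roc/roc50), `summary` (unweighted `mean_roc`,
#'   `mean_roc50`), `scores` (per-family score tables), optionally `models`.
#' @export
run_benchmark <- function(splits, set, beta = 8L, kernel = "auto",
                          folds = 5L, C = 10, seed = 1L,
                          return_models = FALSE) {
  rows <- list(); tables <- list(); models <- list()
  for (i in seq_along(splits)) {
    sp <- splits[[i]]
    res <- tryCatch({
      m <- .family_model(sp, set, beta, kernel, folds, C, seed + i)
      sc <- .score_split(m, sp, set, beta)
      models[[sp$family]] <- m
      tables[[sp$family]] <- sc$table
      data.frame(family = sp$family, kernel = m$kernel$kind,
                 roc = sc$roc, roc50 = sc$roc50, stringsAsFactors = FALSE)
    }, pdt_error = function(e) {
      warning(sprintf("family %s failed: %s", sp$family, conditionMessage(e)),
              call. = FALSE)
      data.frame(family = sp$family, kernel = NA_character_,
                 roc = NA_real_, roc50 = NA_real_, stringsAsFactors = FALSE)
    })
    rows[[i]] <- res
  }
  results <- do.call(rbind, rows)
  ok <- !is.na(results$roc)
  out <- list(results = results,
              summary = c(mean_roc = mean(results$roc[ok]),
                          mean_roc50 = mean(results$roc50[ok])),
              scores = tables, seed = seed, beta = beta)
  if (return_models) out$models <- models
  structure(out, class = "pdt_benchmark")
}

#' @export
print.pdt_benchmark <- function(x, ...) {
  cat(sprintf("<pdt_benchmark> %d families (beta=%d, seed=%s)\n",
              nrow(x$results), x$beta, x$seed))
  print(x$results, row.names = FALSE)
  cat(sprintf("mean ROC = %.4f, mean ROC50 = %.4f\n",
              x$summary["mean_roc"], x$summary["mean_roc50"]))
  invisible(x)
}

#' Write benchmark results as TSV
#'
#' Per-family rows plus a `MEAN` summary row.
#'
#' @param bench A `pdt_benchmark`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_benchmark_tsv <- function(bench, path) {
  df <- bench$results
  df <- rbind(df, data.frame(family = "MEAN", kernel = "",
                             roc = bench$summary[["mean_roc"]],
                             roc50 = bench$summary[["mean_roc50"]]))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# pdtransform benchmark beta=%d seed=%s",
                     bench$beta, bench$seed), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

.chop_sequence <- function(seq, k, window = 20L) {
  if (k == 0L) return(seq)
  L <- nchar(seq)
  w <- min(window, L)
  drop <- sort(sample(seq_len(w), min(k, w)))
  paste(strsplit(seq, "")[[1L]][-drop], collapse = "")
}

#' N-terminal chopping robustness experiment
#'
#' For each `k`, removes `k` residues chosen uniformly at random (seeded)
#' from the first 20 positions of every *test* sequence, re-scores the
#' benchmark with models trained once on the unmodified training data, and
#' reports the mean ROC. `k = 0` reproduces the unmodified benchmark.
#'
#' @param splits List of [benchmark_split()] objects (test sequences must
#'   be longer than `20 + beta`).
#' @param set A `norm_index_set`.
#' @param k_values Integer vector of chop counts (default `0:20`).
#' @param beta,kernel,folds,C,seed Passed to training (see
#'   [run_benchmark()]); chopping uses `seed` too.
#' @return Data frame with columns `k`, `mean_roc`.
#' @export
chop_experiment <- function(splits, set, k_values = 0:20, beta = 8L,
                            kernel = kernel_spec("quadratic"), folds = 5L,
                            C = 10, seed = 1L) {
  models <- lapply(seq_along(splits), function(i)
    .family_model(splits[[i]], set, beta, kernel, folds, C, seed + i))
  mean_roc <- vapply(k_values, function(k) {
    old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
    set.seed(seed + 1000L * k)
    rocs <- vapply(seq_along(splits), function(i) {
      sp <- splits[[i]]
      sp$test_pos <- vapply(sp$test_pos, .chop_sequence, character(1), k = k)
      sp$test_neg <- vapply(sp$test_neg, .chop_sequence, character(1), k = k)
      .score_split(models[[i]], sp, set, beta)$roc
    }, numeric(1))
    mean(rocs)
  }, numeric(1))
  data.frame(k = as.integer(k_values), mean_roc = mean_roc)
}

#' Write / read a benchmark directory
#'
#' One subdirectory per family holding `train_pos.fasta`,
#' `train_neg.fasta`, `test_pos.fasta`, `test_neg.fasta` (the layout of the
#' Liao-Noble SCOP remote-homology distribution).
#'
#' @param splits List of [benchmark_split()] objects.
#' @param dir Directory path.
#' @return `dir` (writer) / list of splits (reader).
#' @export
write_benchmark_dir <- function(splits, dir) {
  for (sp in splits) {
    fdir <- file.path(dir, sp$family)
    dir.create(fdir, recursive = TRUE, showWarnings = FALSE)
    write_fasta(sp$train_pos, file.path(fdir, "train_pos.fasta"))
    write_fasta(sp$train_neg, file.path(fdir, "train_neg.fasta"))
    write_fasta(sp$test_pos, file.path(fdir, "test_pos.fasta"))
    write_fasta(sp$test_neg, file.path(fdir, "test_neg.fasta"))
  }
  invisible(dir)
}

#' @rdname write_benchmark_dir
#' @export
read_benchmark_dir <- function(dir) {
  if (!dir.exists(dir))
    .pdt_error("pdt_io_error", sprintf("benchmark directory not found: %s", dir))
  fams <- sort(list.dirs(dir, recursive = FALSE, full.names = FALSE))
  if (length(fams) == 0L)
    .pdt_error("pdt_io_error", sprintf("no family subdirectories in %s", dir))
  lapply(fams, function(f) {
    fdir <- file.path(dir, f)
    benchmark_split(f,
                    read_fasta(file.path(fdir, "train_pos.fasta")),
                    read_fasta(file.path(fdir, "train_neg.fasta")),
                    read_fasta(file.path(fdir, "test_pos.fasta")),
                    read_fasta(file.path(fdir, "test_neg.fasta")))
  })
}
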