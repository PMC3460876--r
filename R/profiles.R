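# Frequency profiles: pseudo-count-smoothed target frequencies per query
# position, computed from a query-anchored multiple alignment, and the
# n-th-most-frequent-residue sequences consumed by profile-based PDT.

# Published BLOSUM62 marginal (background) frequencies, canonical residue
# order; sum to 1 exactly at this precision.
.BLOSUM62_BACKGROUND <- c(
  A = 0.074, R = 0.052, N = 0.045, D = 0.054, C = 0.025,
  Q = 0.034, E = 0.054, G = 0.074, H = 0.026, I = 0.068,
  L = 0.099, K = 0.058, M = 0.025, F = 0.047, P = 0.039,
  S = 0.057, T = 0.051, W = 0.013, Y = 0.032, V = 0.073)

.blosum62_scores <- function() {
  e <- new.env()
  utils::data("BLOSUM62", package = "Biostrings", envir = e)
  s <- e$BLOSUM62[AA_CANONICAL, AA_CANONICAL]
  storage.mode(s) <- "double"
  s
}

#' Pseudo-count model for target-frequency smoothing
#'
#' Bundles the constants of the PSI-BLAST-style pseudo-count scheme: the
#' pseudo-count weight (`beta_pc`, the free parameter fixed at 10), the
#' background frequencies `p` (BLOSUM62 marginals), and the residue pairing
#' term `q` (20 x 20, symmetric).
#'
#' Two modes for `q`:
#' \describe{
#'   \item{`"frequency"` (default)}{BLOSUM62-implied joint target
#'     frequencies reconstructed from the half-bit scores,
#'     `q_ij = p_i p_j 2^(s_ij/2)` renormalized to sum 1. Pseudo-counts are
#'     then `g_i = sum_j (f_j / p_j) q_ij` — always non-negative, as a
#'     frequency must be.}
#'   \item{`"score"`}{the raw BLOSUM62 log-odds scores, giving the literal
#'     reading `g_i = sum_j f_j s_ij`; negative pseudo-counts are clamped
#'     to zero before renormalization.}
#' }
#'
#' @param mode `"frequency"` or `"score"`.
#' @param beta_pc Pseudo-count weight (default 10).
#' @return Object of class `pseudo_count_model`.
#' @export
pseudo_count_model <- function(mode = c("frequency", "score"), beta_pc = 10) {
  mode <- match.arg(mode)
  p <- .BLOSUM62_BACKGROUND
  if (any(p <= 0))
    .pdt_error("pdt_model_error", "background frequencies must be positive")
  s <- .blosum62_scores()
  q <- if (mode == "frequency") {
    qm <- outer(p, p) * 2^(s / 2)
    qm / sum(qm)
  } else {
    s
  }
  structure(list(mode = mode, beta_pc = beta_pc, p = p, q = q),
            class = "pseudo_count_model")
}

#' @export
print.pseudo_count_model <- function(x, ...) {
  cat(sprintf("<pseudo_count_model> mode=%s beta_pc=%g\n", x$mode, x$beta_pc))
  invisible(x)
}

#' Observed frequencies of one alignment column
#'
#' Gaps (`-`, `.`) are excluded; frequencies are counts over the remaining
#' residues. Residues outside the 20-letter alphabet are dropped with a
#' warning.
#'
#' @param column Character vector of single letters (residues and gaps).
#' @return Object of class `alignment_column`: list with `f` (named
#'   20-vector summing to 1 over residues present), `distinct_count`, `n`.
#' @export
column_frequencies <- function(column) {
  column <- toupper(unlist(strsplit(column, "")))
  res <- column[!column %in% c("-", ".")]
  odd <- !res %in% AA_CANONICAL
  if (any(odd)) {
    warning(sprintf("dropping non-standard residue(s) %s from column",
                    paste(sort(unique(res[odd])), collapse = ", ")), call. = FALSE)
    res <- res[!odd]
  }
  if (length(res) == 0L)
    .pdt_error("pdt_empty_column_error", "alignment column is all gaps")
  counts <- table(factor(res, levels = AA_CANONICAL))
  f <- as.numeric(counts) / length(res)
  names(f) <- AA_CANONICAL
  structure(list(f = f, distinct_count = sum(counts > 0L), n = length(res)),
            class = "alignment_column")
}

#' Remove near-identical rows from a query-anchored alignment
#'
#' Rows whose identity to the query reaches `max_identity` percent are
#' dropped (identity = matching positions / non-gap query positions); the
#' query row itself is always retained.
#'
#' @param msa Character vector of equal-length aligned rows.
#' @param query_index Row index of the query (default 1).
#' @param max_identity Percent threshold (default 98); rows with identity
#'   `>= max_identity` are removed.
#' @return Filtered alignment, query row first among survivors.
#' @export
filter_alignment <- function(msa, query_index = 1L, max_identity = 98) {
  stopifnot(length(msa) >= 1L, query_index >= 1L, query_index <= length(msa))
  if (length(unique(nchar(msa))) != 1L)
    .pdt_error("pdt_precondition_error", "alignment rows have unequal widths")
  qchars <- strsplit(toupper(msa[query_index]), "")[[1L]]
  anchor <- !qchars %in% c("-", ".")
  ident <- vapply(msa, function(row) {
    rchars <- strsplit(toupper(row), "")[[1L]]
    100 * sum(rchars[anchor] == qchars[anchor]) / sum(anchor)
  }, numeric(1), USE.NAMES = FALSE)
  keep <- ident < max_identity
  keep[query_index] <- TRUE
  msa[keep]
}

#' Pseudo-counts for one column
#'
#' Computes the 20-vector `g` from the column's observed frequencies and
#' the model's background/pairing constants: in `"frequency"` mode
#' `g_i = sum_j (f_j / p_j) q_ij`; in `"score"` mode `g_i = sum_j f_j q_ij`
#' with `q` the raw BLOSUM62 scores.
#'
#' @param col An `alignment_column` from [column_frequencies()].
#' @param model A [pseudo_count_model()].
#' @return Named numeric 20-vector.
#' @export
pseudo_counts <- function(col, model = pseudo_count_model()) {
  stopifnot(inherits(col, "alignment_column"),
            inherits(model, "pseudo_count_model"))
  g <- if (model$mode == "frequency") {
    as.vector(model$q %*% (col$f / model$p))
  } else {
    as.vector(model$q %*% col$f)
  }
  names(g) <- AA_CANONICAL
  g
}

#' Target frequencies for one column
#'
#' Blends observed frequencies `f` (weight `alpha = distinct_count - 1`)
#' with pseudo-counts `g` (weight `beta_pc`), then renormalizes to a proper
#' distribution: `Q_i = (alpha f_i + beta_pc g_i) / (alpha + beta_pc)`,
#' followed by division by `sum(Q)`. A single-residue column has
#' `alpha = 0`, so its target frequencies are entirely pseudo-count-driven.
#' In `"score"` mode negative blended values are clamped to zero before
#' renormalization.
#'
#' @inheritParams pseudo_counts
#' @return Named numeric 20-vector summing to 1.
#' @export
target_frequencies <- function(col, model = pseudo_count_model()) {
  alpha <- col$distinct_count - 1
  g <- pseudo_counts(col, model)
  q <- (alpha * col$f + model$beta_pc * g) / (alpha + model$beta_pc)
  q <- pmax(q, 0)
  if (sum(q) <= 0)
    .pdt_error("pdt_model_error", "degenerate target frequencies (all zero)")
  q / sum(q)
}

#' Build a frequency profile from a query-anchored alignment
#'
#' Applies the identity filter, then computes [target_frequencies()] for
#' every alignment column at which the query has a residue. Columns that
#' are all-gap among the retained rows inherit the background distribution
#' (with a warning); with the query row present this cannot normally occur.
#'
#' @param msa Character vector of equal-length aligned rows (query first by
#'   default).
#' @param query_index Row index of the query.
#' @param model A [pseudo_count_model()]; pass `NULL` to use raw observed
#'   frequencies with no smoothing.
#' @param max_identity Identity threshold for [filter_alignment()].
#' @param id Profile identifier.
#' @return Object of class `frequency_profile`: an L x 20 matrix of target
#'   frequencies, rows ordered by query position, columns in
#'   [AA_CANONICAL] order.
#' @export
build_profile <- function(msa, query_index = 1L, model = pseudo_count_model(),
                          max_identity = 98, id = "query") {
  msa <- c(msa[query_index], msa[-query_index])  # query row first
  msa <- filter_alignment(msa, 1L, max_identity)
  rows <- lapply(msa, function(x) strsplit(toupper(x), "")[[1L]])
  aln <- do.call(rbind, rows)
  qchars <- aln[1L, ]
  qpos <- which(!qchars %in% c("-", "."))
  M <- matrix(NA_real_, nrow = length(qpos), ncol = 20L,
              dimnames = list(NULL, AA_CANONICAL))
  for (r in seq_along(qpos)) {
    colv <- aln[, qpos[r]]
    cf <- tryCatch(column_frequencies(colv), pdt_empty_column_error = function(e) NULL)
    if (is.null(cf)) {
      warning(sprintf("column %d all-gap after filtering; using background", r),
              call. = FALSE)
      M[r, ] <- .BLOSUM62_BACKGROUND
    } else if (is.null(model)) {
      M[r, ] <- cf$f
    } else {
      M[r, ] <- target_frequencies(cf, model)
    }
  }
  structure(M, class = c("frequency_profile", "matrix"), id = id)
}

#' @export
print.frequency_profile <- function(x, ...) {
  cat(sprintf("<frequency_profile> %s: %d positions x 20 residues\n",
              attr(x, "id") %||% "?", nrow(x)))
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Extract the n-th most frequent residue sequence from a profile
#'
#' Per position, residues are ranked by target frequency in descending
#' order (ties broken alphabetically, for determinism); the output sequence
#' takes the `n`-th ranked residue at each position.
#'
#' @param profile A `frequency_profile`.
#' @param n Rank (1 = modal residue; the transform studies n = 1, 2).
#' @return Named character scalar of length-L sequence.
#' @export
nth_sequence <- function(profile, n = 1L) {
  stopifnot(n >= 1L, n <= 20L)
  picks <- apply(unclass(profile), 1L, function(p) {
    ord <- order(-p, AA_CANONICAL)
    AA_CANONICAL[ord[n]]
  })
  out <- paste(picks, collapse = "")
  names(out) <- paste0(attr(profile, "id") %||% "profile", "_n", n)
  out
}

#' Profile-based PDT feature vector
#'
#' Concatenates [pdt_transform()] of [nth_sequence()] for `n = 1..n_max`;
#' output length is `length(set) * beta * n_max`. Feature names carry an
#' `_n<r>` suffix.
#'
#' @param profile A `frequency_profile`.
#' @param set A `norm_index_set`.
#' @param beta Maximum lag.
#' @param n_max 1 or 2 (ranks of profile residues to use).
#' @return Named numeric feature vector.
#' @export
profile_pdt <- function(profile, set, beta = 8L, n_max = 1L) {
  stopifnot(n_max %in% c(1L, 2L))
  parts <- lapply(seq_len(n_max), function(r) {
    s <- nth_sequence(profile, r)
    v <- pdt_transform(s, set, beta, id = names(s))
    names(v) <- paste0(names(v), "_n", r)
    v
  })
  out <- unlist(parts)
  attr(out, "beta") <- as.integer(beta)
  attr(out, "accessions") <- set$accessions
  attr(out, "n_max") <- as.integer(n_max)
  out
}

#' Write / read a frequency profile as TSV
#'
#' L rows by 20 canonical residue columns, with a `pos` column.
#'
#' @param profile A `frequency_profile`.
#' @param path File path.
#' @return `path` (writer) / a `frequency_profile` (reader).
#' @export
write_profile_tsv <- function(profile, path) {
  df <- data.frame(pos = seq_len(nrow(profile)), unclass(profile),
                   check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_profile_tsv
#' @param id Identifier attached to the profile read back.
#' @export
read_profile_tsv <- function(path, id = "query") {
  df <- utils::read.table(path, sep = "\t", header = TRUE, check.names = FALSE)
  M <- as.matrix(df[, AA_CANONICAL, drop = FALSE])
  structure(M, class = c("frequency_profile", "matrix"), id = id)
}

#' PSI-BLAST command line used to generate alignments
#'
#' Convenience only (untested wrapper): emits the command string with the
#' parameters used to produce query-anchored alignments against NR
#' (10 iterations, E-value 0.001). The package never invokes it; all
#' tested profile code starts from an alignment.
#'
#' @param query_fasta Query FASTA path.
#' @param db Database name (default `"nr"`).
#' @param out Output alignment path.
#' @return Character command line.
#' @export
psiblast_command <- function(query_fasta, db = "nr", out = "psiblast.aln") {
  sprintf("psiblast -query %s -db %s -num_iterations 10 -evalue 0.001 -out %s",
          query_fasta, db, out)
}
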