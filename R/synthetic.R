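# Synthetic fixtures: toy index tables, planted-signal protein families and
# degenerate single-sequence profiles. The family generator plants a
# *periodic* arrangement of high/low-property residues at a chosen lag, so
# classes match in composition and only sequence-order-aware features can
# separate them.

.with_seed <- function(seed, expr) {
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  expr
}

#' Generate toy amino-acid indices
#'
#' `k` random property scales over the 20 standard residues, rounded to 3
#' decimals (AAIndex-style precision, so text round trips are exact). None
#' is degenerate or all-zero. Deterministic per seed.
#'
#' @param k Number of indices (>= 1).
#' @param seed Integer seed.
#' @return List of [aa_index] objects with accessions `TOY00001`, ...
#' @export
make_toy_indices <- function(k, seed = 1L) {
  stopifnot(k >= 1L)
  .with_seed(seed, lapply(seq_len(k), function(i) {
    repeat {
      v <- round(stats::runif(20L, -3, 3), 3L)
      if (stats::sd(v) > 0 && any(v != 0)) break
    }
    aa_index(sprintf("TOY%05d", i), stats::setNames(v, AA_CANONICAL),
             title = sprintf("synthetic toy index %d", i))
  }))
}

#' Specification of a planted-signal synthetic family
#'
#' @param n_pos,n_neg Numbers of positive / negative sequences (split half
#'   into train, half into test).
#' @param length_range Min/max sequence length (default 60-120, short
#'   globular-domain scale).
#' @param signal_index Which toy index carries the class signal (position
#'   in the index list passed to [make_family_dataset()]).
#' @param signal_lambda The lag `lambda*` at which classes differ.
#' @param effect Probability that a positive-sequence residue follows the
#'   planted periodic arrangement rather than being uniform (0 = negative
#'   control, no signal).
#' @param family Family identifier.
#' @param seed Integer seed.
#' @return Object of class `family_spec`.
#' @export
family_spec <- function(n_pos = 40L, n_neg = 40L, length_range = c(60L, 120L),
                        signal_index = 1L, signal_lambda = 2L, effect = 0.9,
                        family = "synthetic_family", seed = 1L) {
  stopifnot(n_pos >= 2L, n_neg >= 2L, length_range[1L] >= 2L,
            length_range[2L] >= length_range[1L])
  if (effect < 0)
    .pdt_error("pdt_precondition_error", "effect must be >= 0")
  if (signal_lambda > length_range[1L] - 1L)
    .pdt_error("pdt_precondition_error",
               "signal_lambda must be <= min length - 1")
  structure(list(n_pos = as.integer(n_pos), n_neg = as.integer(n_neg),
                 length_range = as.integer(length_range),
                 signal_index = as.integer(signal_index),
                 signal_lambda = as.integer(signal_lambda),
                 effect = effect, family = family, seed = as.integer(seed)),
            class = "family_spec")
}

.planted_sequence <- function(L, hi, lo, lam, effect) {
  block <- (floor((seq_len(L) - 1L) / lam)) %% 2L
  planted <- stats::runif(L) < effect
  res <- character(L)
  n_hi <- sum(planted & block == 0L)
  n_lo <- sum(planted & block == 1L)
  res[planted & block == 0L] <- sample(hi, n_hi, replace = TRUE)
  res[planted & block == 1L] <- sample(lo, n_lo, replace = TRUE)
  res[!planted] <- sample(AA_CANONICAL, sum(!planted), replace = TRUE)
  paste(res, collapse = "")
}

.shuffle_sequence <- function(seq) {
  paste(sample(strsplit(seq, "")[[1L]]), collapse = "")
}

#' Generate a planted-signal benchmark family
#'
#' Positive sequences alternate blocks of high-property and low-property
#' residues (top/bottom 6 residues of the signal index) with block length
#' `signal_lambda`, so pairs at lag `lambda*` almost always straddle a
#' high/low boundary and the PDT component at `lambda*` is large. Each
#' negative is a within-sequence shuffle of an independently generated
#' positive-style source, so every negative is composition-matched to its
#' source (kept in `attr(, "negative_sources")`). Positives and negatives
#' are split half/half into disjoint train and test sets. Byte-identical
#' output per seed.
#'
#' @param spec A [family_spec()].
#' @param indices List of [aa_index] objects (e.g. [make_toy_indices()]);
#'   `spec$signal_index` selects the signal-carrying one.
#' @return A [benchmark_split()] with attribute `negative_sources`.
#' @export
make_family_dataset <- function(spec, indices) {
  stopifnot(inherits(spec, "family_spec"),
            spec$signal_index <= length(indices))
  nv <- normalize_index(indices[[spec$signal_index]])
  ord <- order(nv, decreasing = TRUE)
  hi <- AA_CANONICAL[ord[1:6]]
  lo <- AA_CANONICAL[ord[15:20]]
  .with_seed(spec$seed, {
    lens <- function(n) sample(spec$length_range[1L]:spec$length_range[2L],
                               n, replace = TRUE)
    pos <- vapply(lens(spec$n_pos), .planted_sequence, character(1),
                  hi = hi, lo = lo, lam = spec$signal_lambda,
                  effect = spec$effect)
    src <- vapply(lens(spec$n_neg), .planted_sequence, character(1),
                  hi = hi, lo = lo, lam = spec$signal_lambda,
                  effect = spec$effect)
    neg <- vapply(src, .shuffle_sequence, character(1), USE.NAMES = FALSE)
    names(pos) <- sprintf("%s_pos%03d", spec$family, seq_along(pos))
    names(neg) <- sprintf("%s_neg%03d", spec$family, seq_along(neg))
    names(src) <- names(neg)
    half_p <- floor(spec$n_pos / 2L)
    half_n <- floor(spec$n_neg / 2L)
    out <- benchmark_split(spec$family,
                           train_pos = pos[seq_len(half_p)],
                           train_neg = neg[seq_len(half_n)],
                           test_pos = pos[(half_p + 1L):spec$n_pos],
                           test_neg = neg[(half_n + 1L):spec$n_neg])
    attr(out, "negative_sources") <- src
    out
  })
}

#' Degenerate single-sequence profile
#'
#' Row `i` puts probability 1 on residue `A_i` (pseudo-counts off): the
#' profile whose n = 1 sequence is the input itself, used to test the
#' profile-to-sequence reduction.
#'
#' @param seq Character scalar over the 20 standard residues.
#' @param id Profile identifier (defaults to the sequence name).
#' @return A `frequency_profile`.
#' @export
make_degenerate_profile <- function(seq, id = names(seq) %||% "seq") {
  codes <- .encode_residues(seq, warn = FALSE)
  if (anyNA(codes))
    .pdt_error("pdt_precondition_error",
               "degenerate profile requires standard residues only")
  M <- matrix(0, nrow = length(codes), ncol = 20L,
              dimnames = list(NULL, AA_CANONICAL))
  M[cbind(seq_along(codes), codes)] <- 1
  structure(M, class = c("frequency_profile", "matrix"), id = id)
}

#' Generate a multi-family synthetic benchmark
#'
#' Convenience wrapper: one [make_family_dataset()] per family with
#' distinct signal indices/lags cycling over the supplied toy indices.
#'
#' @param n_families Number of families.
#' @param indices List of [aa_index] objects.
#' @param lambdas Signal lags, recycled across families.
#' @param seed Base seed (family i uses `seed + i`).
#' @param ... Passed to [family_spec()] (e.g. `n_pos`, `effect`).
#' @return List of [benchmark_split()] objects.
#' @export
make_benchmark <- function(n_families = 4L, indices = make_toy_indices(5L),
                           lambdas = c(1L, 2L, 3L, 4L), seed = 1L, ...) {
  lapply(seq_len(n_families), function(i) {
    sp <- family_spec(signal_index = ((i - 1L) %% length(indices)) + 1L,
                      signal_lambda = lambdas[((i - 1L) %% length(lambdas)) + 1L],
                      family = sprintf("fam%02d", i), seed = seed + i, ...)
    make_family_dataset(sp, indices)
  })
}
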