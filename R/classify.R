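# Per-family SVM classification on PDT vectors.
#
# The soft-margin C-SVM dual
#   max  sum(a) - 1/2 a' (yy' * K) a   s.t.  0 <= a <= C,  sum(a y) = 0
# is solved exactly with quadprog (a tiny ridge keeps the Hessian positive
# definite). Dual weights are stored label-signed (alpha_i * y_i), so the
# discriminant weight vector is w = t(M) %*% alpha_signed (the linear
# projection of the dual solution into feature space).

#' Kernel specification
#'
#' @param kind `"quadratic"` (`(1 + x.y)^2`), `"rbf"`
#'   (`exp(-||x-y||^2 / (2 w^2))`), or `"linear"` (`x.y`; diagnostic kernel
#'   used to check the feature-space weight projection exactly).
#' @param rbf_width RBF width `w`; `NULL` (default) selects the median
#'   pairwise Euclidean distance on the standardized training set at fit
#'   time (deterministic).
#' @param normalize Cosine normalization: standardized feature vectors are
#'   scaled to unit length before the kernel applies, so the base inner
#'   product is a cosine similarity in \[-1, 1\] (for the linear kernel this
#'   equals `K_ij / sqrt(K_ii K_jj)`; for the quadratic it keeps
#'   `(1 + x.y)^2` monotone in similarity). On by default.
#' @return Object of class `kernel_spec`.
#' @export
kernel_spec <- function(kind = c("quadratic", "rbf", "linear"),
                        rbf_width = NULL, normalize = TRUE) {
  kind <- match.arg(kind)
  if (!is.null(rbf_width) && rbf_width <= 0)
    .pdt_error("pdt_precondition_error", "rbf_width must be positive")
  structure(list(kind = kind, rbf_width = rbf_width, normalize = normalize),
            class = "kernel_spec")
}

#' @export
print.kernel_spec <- function(x, ...) {
  cat(sprintf("<kernel_spec> %s%s%s\n", x$kind,
              if (x$kind == "rbf")
                sprintf(" (width=%s)", if (is.null(x$rbf_width)) "median-heuristic"
                        else format(x$rbf_width)) else "",
              if (x$normalize) ", cosine-normalized" else ""))
  invisible(x)
}

.cross_sq_dist <- function(X, Y) {
  d2 <- outer(rowSums(X^2), rowSums(Y^2), "+") - 2 * tcrossprod(X, Y)
  pmax(d2, 0)
}

#' Kernel matrix between two sample sets
#'
#' @param spec A [kernel_spec()]; for an RBF kernel `rbf_width` must be
#'   resolved (non-`NULL`).
#' @param X,Y Row-wise sample matrices (`Y` defaults to `X`).
#' @return `nrow(X)` x `nrow(Y)` kernel matrix (un-normalized; cosine
#'   normalization is applied by the training/prediction code which knows
#'   both diagonals).
#' @export
kernel_matrix <- function(spec, X, Y = X) {
  switch(spec$kind,
    linear    = tcrossprod(X, Y),
    quadratic = (1 + tcrossprod(X, Y))^2,
    rbf = {
      if (is.null(spec$rbf_width))
        .pdt_error("pdt_precondition_error", "rbf_width unresolved")
      exp(-.cross_sq_dist(X, Y) / (2 * spec$rbf_width^2))
    })
}

.unit_rows <- function(X) {
  nrm <- sqrt(rowSums(X^2))
  nrm[nrm == 0] <- 1
  X / nrm
}

.median_width <- function(X) {
  d2 <- .cross_sq_dist(X, X)
  w <- sqrt(stats::median(d2[upper.tri(d2)]))
  if (!is.finite(w) || w <= 0) 1 else w
}

.svm_qp <- function(K, y, C, ridge = 1e-8) {
  n <- length(y)
  Dmat <- (y %o% y) * K + diag(ridge, n)
  sol <- quadprog::solve.QP(
    Dmat = Dmat, dvec = rep(1, n),
    Amat = cbind(y, diag(n), -diag(n)),
    bvec = c(0, rep(0, n), rep(-C, n)), meq = 1)
  a <- pmin(pmax(sol$solution, 0), C)
  a[a < 1e-8 * C] <- 0
  f_no_b <- as.vector(K %*% (a * y))
  margin_sv <- which(a > 1e-6 * C & a < C * (1 - 1e-6))
  sv <- if (length(margin_sv) > 0L) margin_sv else which(a > 0)
  b <- mean(y[sv] - f_no_b[sv])
  list(alpha = a, bias = b)
}

#' Train a one-family SVM on feature vectors
#'
#' Features are standardized (per-feature z-score fitted on the training
#' split), the kernel matrix is built (cosine-normalized if the spec says
#' so), and the C-SVM dual is solved exactly. Fully deterministic for fixed
#' inputs; `seed` is accepted for interface symmetry and recorded.
#'
#' @param pos,neg Matrices of positive / negative training feature vectors
#'   (rows = samples, identical column layout).
#' @param kernel A [kernel_spec()].
#' @param C Soft-margin cost (default 10).
#' @param family Family identifier.
#' @param seed Recorded in the model.
#' @return Object of class `pdt_model`: label-signed dual weights
#'   `alpha_signed`, the standardized training matrix `M`, `center`/`scale`,
#'   resolved `kernel`, `bias`, training `scores`, `feature_names`.
#' @export
train_family <- function(pos, neg, kernel = kernel_spec("quadratic"),
                         C = 10, family = "family", seed = 1L) {
  pos <- as.matrix(pos); neg <- as.matrix(neg)
  if (nrow(pos) < 1L || nrow(neg) < 1L)
    .pdt_error("pdt_training_error",
               sprintf("family %s: need at least one sample of each class", family))
  X <- rbind(pos, neg)
  y <- c(rep(1, nrow(pos)), rep(-1, nrow(neg)))
  ctr <- colMeans(X)
  scl <- apply(X, 2L, stats::sd)
  scl[!is.finite(scl) | scl == 0] <- 1
  Xs <- sweep(sweep(X, 2L, ctr), 2L, scl, "/")
  if (kernel$normalize) Xs <- .unit_rows(Xs)
  if (kernel$kind == "rbf" && is.null(kernel$rbf_width))
    kernel$rbf_width <- .median_width(Xs)
  K <- kernel_matrix(kernel, Xs)
  fit <- .svm_qp(K, y, C)
  scores <- as.vector(K %*% (fit$alpha * y)) + fit$bias
  structure(list(
    alpha_signed = fit$alpha * y, M = Xs, center = ctr, scale = scl,
    kernel = kernel, C = C, bias = fit$bias, family = family, seed = seed,
    scores = stats::setNames(scores, rownames(X)),
    feature_names = colnames(X)), class = "pdt_model")
}

#' @export
print.pdt_model <- function(x, ...) {
  cat(sprintf("<pdt_model> family=%s kernel=%s: %d training vectors (%d SV), %d features\n",
              x$family, x$kernel$kind, nrow(x$M), sum(x$alpha_signed != 0),
              ncol(x$M)))
  invisible(x)
}

#' Decision scores for new feature vectors
#'
#' @param object A `pdt_model`.
#' @param newdata Matrix of feature vectors (same column layout as training).
#' @param ... Unused.
#' @return Numeric decision values (positive = family member side).
#' @export
predict.pdt_model <- function(object, newdata, ...) {
  newdata <- as.matrix(newdata)
  Xs <- sweep(sweep(newdata, 2L, object$center), 2L, object$scale, "/")
  if (object$kernel$normalize) Xs <- .unit_rows(Xs)
  K <- kernel_matrix(object$kernel, Xs, object$M)
  stats::setNames(as.vector(K %*% object$alpha_signed) + object$bias,
                  rownames(newdata))
}

#' Select the kernel by cross-validated ROC
#'
#' Stratified k-fold cross-validation on the training data; the candidate
#' with the highest mean ROC wins, ties (within 1e-12) going to the first
#' candidate in list order (logged).
#'
#' @param pos,neg Training matrices.
#' @param candidates List of [kernel_spec()] objects.
#' @param folds Number of folds (>= 2; also capped by class sizes).
#' @param C Soft-margin cost.
#' @param seed Seed for the fold assignment.
#' @return The winning `kernel_spec`, with attribute `cv_roc` holding the
#'   per-candidate mean ROC.
#' @export
select_kernel <- function(pos, neg,
                          candidates = list(kernel_spec("quadratic"),
                                            kernel_spec("rbf")),
                          folds = 5L, C = 10, seed = 1L) {
  stopifnot(length(candidates) >= 1L)
  if (length(candidates) == 1L) return(candidates[[1L]])
  if (folds < 2L) .pdt_error("pdt_precondition_error", "folds must be >= 2")
  pos <- as.matrix(pos); neg <- as.matrix(neg)
  folds <- min(folds, nrow(pos), nrow(neg))
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  fp <- sample(rep_len(seq_len(folds), nrow(pos)))
  fn <- sample(rep_len(seq_len(folds), nrow(neg)))
  cv_roc <- vapply(candidates, function(k) {
    rocs <- vapply(seq_len(folds), function(f) {
      m <- train_family(pos[fp != f, , drop = FALSE], neg[fn != f, , drop = FALSE],
                        kernel = k, C = C)
      sc <- predict(m, rbind(pos[fp == f, , drop = FALSE],
                             neg[fn == f, , drop = FALSE]))
      roc_score(sc, c(rep(1, sum(fp == f)), rep(-1, sum(fn == f))))
    }, numeric(1))
    mean(rocs)
  }, numeric(1))
  best <- which(cv_roc >= max(cv_roc) - 1e-12)[1L]
  if (sum(cv_roc >= max(cv_roc) - 1e-12) > 1L)
    message(sprintf("select_kernel: tie, keeping candidate %d (%s)",
                    best, candidates[[best]]$kind))
  out <- candidates[[best]]
  attr(out, "cv_roc") <- cv_roc
  out
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
}
.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}

#' Discriminant weight vector of a trained model
#'
#' Projects the dual solution into feature space, `w = sum_n alpha_n M_n`
#' with label-signed `alpha` and `M` the (standardized) training
#' representatives. Exact for a linear kernel; for quadratic/RBF kernels it
#' is the standard linear projection heuristic used to rank feature
#' importance.
#'
#' @param model A `pdt_model`.
#' @return Object of class `pdt_weights`: list with `w` (named vector
#'   aligned to the feature layout), `annotation` (data frame: feature,
#'   accession, lambda, n), `family`.
#' @export
discriminant_weights <- function(model) {
  w <- as.vector(crossprod(model$M, model$alpha_signed))
  names(w) <- model$feature_names
  structure(list(w = w, annotation = .annotate_features(model$feature_names),
                 family = model$family), class = "pdt_weights")
}

.annotate_features <- function(feature_names) {
  m <- regmatches(feature_names,
                  regexec("^(.*)_lambda(\\d+)(_n(\\d+))?$", feature_names))
  data.frame(
    feature = feature_names,
    accession = vapply(m, function(x) if (length(x)) x[2L] else NA_character_,
                       character(1)),
    lambda = vapply(m, function(x) if (length(x)) as.integer(x[3L]) else NA_integer_,
                    integer(1)),
    n = vapply(m, function(x) if (length(x) && nzchar(x[5L])) as.integer(x[5L])
               else 1L, integer(1)),
    stringsAsFactors = FALSE)
}

#' @export
print.pdt_weights <- function(x, ...) {
  cat(sprintf("<pdt_weights> family=%s: %d features\n", x$family, length(x$w)))
  print(utils::head(rank_features(x, 5L)))
  invisible(x)
}

#' Rank features by absolute discriminant weight
#'
#' Mirrors the per-family feature tables: descending `|weight|`, stable
#' tie-break by feature position.
#'
#' @param w A `pdt_weights` (or bare numeric vector).
#' @param top_k Number of features to return (default 10; capped at the
#'   feature count).
#' @return Data frame with columns `rank`, `lambda`, `index` (accession),
#'   `n`, `weight`.
#' @export
rank_features <- function(w, top_k = 10L) {
  if (inherits(w, "pdt_weights")) {
    ann <- w$annotation
    wv <- w$w
  } else {
    wv <- w
    if (is.null(names(wv))) names(wv) <- paste0("f", seq_along(wv))
    ann <- .annotate_features(names(wv))
  }
  ord <- order(-abs(wv), seq_along(wv))
  top <- utils::head(ord, max(0L, min(top_k, length(wv))))
  data.frame(rank = seq_along(top), lambda = ann$lambda[top],
             index = ann$accession[top], n = ann$n[top],
             weight = unname(wv[top]), feature = ann$feature[top],
             stringsAsFactors = FALSE)
}

#' Save / load a trained model archive
#'
#' Single-file serialization of the dual weights, support matrix, kernel
#' spec and feature-layout header (run-time artifact; RDS format).
#'
#' @param model A `pdt_model`.
#' @param path File path.
#' @return `path` (saver) / a `pdt_model` (loader).
#' @export
save_model <- function(model, path) {
  stopifnot(inherits(model, "pdt_model"))
  saveRDS(model, path)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  if (!file.exists(path))
    .pdt_error("pdt_io_error", sprintf("model file not found: %s", path))
  m <- tryCatch(readRDS(path), error = function(e)
    .pdt_error("pdt_io_error", sprintf("malformed model file: %s", path)))
  if (!inherits(m, "pdt_model"))
    .pdt_error("pdt_io_error", sprintf("%s does not contain a pdt_model", path))
  m
}
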