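#' Canonical amino-acid ordering
#'
#' The 20 standard residues in the order used by AAIndex1 `I` blocks
#' (A R N D C Q E G H I / L K M F P S T W Y V). All residue-indexed
#' structures in this package (index tables, profile columns) follow this
#' ordering; feature layout depends on it.
#'
#' @format Character vector of length 20.
#' @export
AA_CANONICAL <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
                  "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")

.pdt_error <- function(class, msg, call = sys.call(-1)) {
  stop(structure(
    class = c(class, "pdt_error", "error", "condition"),
    list(message = msg, call = call)
  ))
}

.is_tag_line <- function(line) grepl("^(//|[A-Z]( |$))", line)

#' Construct an amino-acid index
#'
#' @param accession Character accession (e.g. `"KYTJ820101"`).
#' @param values Named numeric vector over the 20 standard residues;
#'   `NA` marks a missing (incomplete) value. Names are matched against
#'   [AA_CANONICAL]; missing names are filled with `NA`.
#' @param title Free-text description.
#' @return An object of class `aa_index`.
#' @export
aa_index <- function(accession, values, title = "") {
  stopifnot(is.character(accession), length(accession) == 1L)
  if (is.null(names(values))) {
    stopifnot(length(values) == 20L)
    names(values) <- AA_CANONICAL
  }
  bad <- setdiff(names(values), AA_CANONICAL)
  if (length(bad) > 0L)
    .pdt_error("pdt_parse_error",
               sprintf("non-standard residue(s) %s in index %s",
                       paste(bad, collapse = ", "), accession))
  full <- stats::setNames(rep(NA_real_, 20L), AA_CANONICAL)
  full[names(values)] <- as.numeric(values)
  structure(list(accession = accession, title = title, values = full),
            class = "aa_index")
}

#' @export
print.aa_index <- function(x, ...) {
  cat(sprintf("<aa_index> %s: %s\n", x$accession, x$title))
  print(x$values)
  invisible(x)
}

#' Parse an AAIndex1 flat file
#'
#' Reads the `H`/`D`/`I` record format distributed by the AAIndex database:
#' records delimited by `//`, an `H <accession>` line, a `D` title line
#' (continuation lines indented), and an `I` header line followed by two
#' rows of ten values in canonical residue order. `NA` tokens mark missing
#' values and are preserved as `NA` (the record still parses).
#'
#' @param path Path to an AAIndex1-format file.
#' @return List of [aa_index] objects in file order.
#' @seealso [filter_indices()], [normalize_indices()]
#' @export
parse_aaindex1 <- function(path) {
  if (!file.exists(path))
    .pdt_error("pdt_parse_error", sprintf("file not found: %s", path))
  lines <- readLines(path, warn = FALSE)
  out <- list()
  rec_start <- 1L
  i <- 1L
  n <- length(lines)
  while (i <= n) {
    if (grepl("^//", lines[i])) {
      rec <- lines[rec_start:(i - 1L)]
      if (any(nzchar(trimws(rec))))
        out[[length(out) + 1L]] <- .parse_aaindex1_record(rec, rec_start)
      rec_start <- i + 1L
    }
    i <- i + 1L
  }
  if (rec_start <= n && any(nzchar(trimws(lines[rec_start:n]))))
    out[[length(out) + 1L]] <-
      .parse_aaindex1_record(lines[rec_start:n], rec_start)
  out
}

.parse_aaindex1_record <- function(rec, offset) {
  h <- grep("^H ", rec)
  if (length(h) != 1L)
    .pdt_error("pdt_parse_error",
               sprintf("record starting at line %d has no single H line", offset))
  accession <- trimws(sub("^H ", "", rec[h]))

  d <- grep("^D ", rec)
  title <- ""
  if (length(d) >= 1L) {
    j <- d[1L]
    parts <- trimws(sub("^D ", "", rec[j]))
    j <- j + 1L
    while (j <= length(rec) && !.is_tag_line(rec[j])) {
      parts <- c(parts, trimws(rec[j]))
      j <- j + 1L
    }
    title <- paste(parts, collapse = " ")
  }

  iblk <- grep("^I( |$)", rec)
  if (length(iblk) != 1L)
    .pdt_error("pdt_parse_error",
               sprintf("index %s: missing I block (line %d)", accession, offset))
  val_lines <- rec[-(1:iblk)]
  val_lines <- val_lines[nzchar(trimws(val_lines))]
  tokens <- unlist(strsplit(trimws(paste(val_lines, collapse = " ")), "\\s+"))
  if (length(tokens) != 20L)
    .pdt_error("pdt_parse_error",
               sprintf("index %s (line %d): I block has %d values, expected 20",
                       accession, offset + iblk, length(tokens)))
  vals <- suppressWarnings(as.numeric(tokens))
  bad <- which(is.na(vals) & tokens != "NA")
  if (length(bad) > 0L)
    .pdt_error("pdt_parse_error",
               sprintf("index %s (line %d): unparseable value '%s'",
                       accession, offset + iblk, tokens[bad[1L]]))
  aa_index(accession, stats::setNames(vals, AA_CANONICAL), title)
}

#' Write indices back in AAIndex1 format
#'
#' Values are written with 17 significant digits so a parse/write/parse
#' round trip is exact; missing values are written as `NA`.
#'
#' @param indices List of [aa_index] objects.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_aaindex1 <- function(indices, path) {
  fmt1 <- function(v) ifelse(is.na(v), "NA", formatC(v, format = "g", digits = 17))
  con <- file(path, "w")
  on.exit(close(con))
  for (idx in indices) {
    writeLines(c(
      paste("H", idx$accession),
      paste("D", idx$title),
      "I    A/L     R/K     N/M     D/F     C/P     Q/S     E/T     G/W     H/Y     I/V",
      paste0("    ", paste(fmt1(idx$values[1:10]), collapse = "  ")),
      paste0("    ", paste(fmt1(idx$values[11:20]), collapse = "  ")),
      "//"
    ), con)
  }
  invisible(path)
}

#' Drop unusable amino-acid indices
#'
#' Removes every index with any missing value and every index whose 20 raw
#' values are all exactly zero (applied to raw values, before
#' normalization). Survivor order is preserved. Counts dropped by each rule
#' are reported via [message()].
#'
#' @param raw List of [aa_index] objects.
#' @return Filtered list (possibly empty, with a warning).
#' @export
filter_indices <- function(raw) {
  incomplete <- vapply(raw, function(x) anyNA(x$values), logical(1))
  allzero <- vapply(raw, function(x) !anyNA(x$values) && all(x$values == 0),
                    logical(1))
  keep <- !incomplete & !allzero
  message(sprintf("filter_indices: dropped %d incomplete, %d all-zero; %d retained",
                  sum(incomplete), sum(allzero), sum(keep)))
  if (!any(keep)) warning("filter_indices: no indices retained")
  raw[keep]
}

#' Z-normalize one amino-acid index
#'
#' Centers and scales the 20 raw property values to mean 0 and *population*
#' standard deviation 1 (divisor 20, since the average runs over exactly
#' the 20 standard residues).
#'
#' @param idx An [aa_index] with all 20 values present and not all equal.
#' @return Named numeric vector of 20 normalized values.
#' @export
normalize_index <- function(idx) {
  v <- idx$values
  if (anyNA(v))
    .pdt_error("pdt_precondition_error",
               sprintf("index %s has missing values; filter first", idx$accession))
  mu <- mean(v)
  sigma <- sqrt(mean((v - mu)^2))
  if (sigma == 0)
    .pdt_error("pdt_degenerate_index_error",
               sprintf("index %s is constant (zero variance)", idx$accession))
  (v - mu) / sigma
}

#' Build a normalized index set
#'
#' Filters (see [filter_indices()]) and z-normalizes a list of raw indices
#' into the matrix form consumed by the PDT transform. Column order equals
#' surviving file order; the feature-vector layout depends on it.
#'
#' @param raw List of [aa_index] objects (raw values).
#' @param filter Apply [filter_indices()] first (default `TRUE`).
#' @return Object of class `norm_index_set`: list with `values` (20 x k
#'   matrix, rows in [AA_CANONICAL] order) and `accessions`.
#' @export
normalize_indices <- function(raw, filter = TRUE) {
  if (filter) raw <- filter_indices(raw)
  if (length(raw) == 0L)
    .pdt_error("pdt_precondition_error", "no indices to normalize")
  vals <- vapply(raw, normalize_index, numeric(20L))
  rownames(vals) <- AA_CANONICAL
  acc <- vapply(raw, `[[`, character(1), "accession")
  colnames(vals) <- acc
  structure(list(values = vals, accessions = acc,
                 titles = vapply(raw, `[[`, character(1), "title")),
            class = "norm_index_set")
}

#' @export
print.norm_index_set <- function(x, ...) {
  cat(sprintf("<norm_index_set> %d z-normalized indices (%s%s)\n",
              length(x$accessions), paste(utils::head(x$accessions, 3), collapse = ", "),
              if (length(x$accessions) > 3) ", ..." else ""))
  invisible(x)
}

#' @export
length.norm_index_set <- function(x) length(x$accessions)

#' Export a normalized index table as TSV
#'
#' One row per index: accession plus 20 columns in canonical residue order.
#'
#' @param set A `norm_index_set`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_index_tsv <- function(set, path) {
  df <- data.frame(accession = set$accessions,
                   t(set$values), check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
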