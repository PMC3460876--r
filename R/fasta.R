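#' Read protein sequences from FASTA
#'
#' Thin wrapper over [Biostrings::readAAStringSet()] returning a named
#' character vector (names truncated at the first whitespace).
#'
#' @param path FASTA file path.
#' @return Named character vector of sequences.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path))
    .pdt_error("pdt_io_error", sprintf("FASTA file not found: %s", path))
  x <- Biostrings::readAAStringSet(path)
  out <- as.character(x)
  names(out) <- sub("\\s.*$", "", names(x))
  out
}

#' Write protein sequences to FASTA
#'
#' @param seqs Named character vector of sequences.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path) {
  x <- Biostrings::AAStringSet(seqs)
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}
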