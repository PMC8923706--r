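#' Read a FASTA file
#'
#' Wraps [Biostrings::readDNAStringSet()] and returns the sequences as a
#' named uppercase character vector. The name of each element is the record
#' id (first whitespace-delimited token of the header); the full header is
#' kept in the `"description"` attribute. Line wrapping is transparent and
#' lowercase input is uppercased.
#'
#' @param path path to a FASTA file.
#' @return named character vector of uppercase DNA sequences with a
#'   `"description"` attribute (named character vector of full headers).
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("FASTA file not found: ", path)
  lines <- readLines(path, n = 50L, warn = FALSE)
  first <- which(nzchar(trimws(lines)))
  if (length(first) == 0L) {
    out <- character(0)
    attr(out, "description") <- character(0)
    return(out)
  }
  if (!startsWith(trimws(lines[first[1]]), ">")) {
    stop(sprintf("malformed FASTA header at line %d of %s: expected '>'",
                 first[1], path))
  }
  set <- Biostrings::readDNAStringSet(path)
  seqs <- toupper(as.character(set))
  desc <- names(set) %||% character(length(set))
  ids <- vapply(strsplit(desc, "[ \t]+"), `[`, character(1), 1L)
  if (anyNA(ids) || any(!nzchar(ids))) stop("FASTA record with empty id in ", path)
  names(seqs) <- ids
  names(desc) <- ids
  assert_dna(seqs, what = paste0("FASTA sequence in ", path))
  attr(seqs, "description") <- desc
  seqs
}

#' Write sequences to a FASTA file
#'
#' @param seqs named character vector of DNA sequences (names become record
#'   ids; a `"description"` attribute, if present, supplies full headers).
#' @param path output path.
#' @param line_width sequence line width in bp.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path, line_width = 60) {
  if (length(seqs) == 0L) {
    file.create(path)
    return(invisible(path))
  }
  if (is.null(names(seqs)) || any(!nzchar(names(seqs))))
    stop("write_fasta: all sequences must be named")
  desc <- attr(seqs, "description")
  headers <- if (!is.null(desc) && all(names(seqs) %in% names(desc)))
    unname(desc[names(seqs)]) else names(seqs)
  set <- Biostrings::DNAStringSet(unname(seqs))
  names(set) <- headers
  Biostrings::writeXStringSet(set, filepath = path, width = line_width)
  invisible(path)
}
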