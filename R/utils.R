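# Internal helpers shared across modules. All interval arithmetic inside the
# package is 0-based half-open; conversion to the 1-based VCF/FASTA world
# happens only at the I/O boundary.

`%||%` <- function(a, b) if (is.null(a)) b else a

DNA_BASES <- c("A", "C", "G", "T")

.RC_MAP <- local({
  m <- integer(128)
  m[utf8ToInt("A")] <- utf8ToInt("T")
  m[utf8ToInt("T")] <- utf8ToInt("A")
  m[utf8ToInt("C")] <- utf8ToInt("G")
  m[utf8ToInt("G")] <- utf8ToInt("C")
  m[utf8ToInt("N")] <- utf8ToInt("N")
  m
})

#' Reverse complement of DNA strings
#'
#' Vectorised over its input; accepts uppercase A/C/G/T/N.
#'
#' @param x character vector of DNA sequences.
#' @return character vector of the same length.
#' @export
revcomp <- function(x) {
  vapply(x, function(s) {
    if (!nzchar(s)) return(s)
    v <- .RC_MAP[rev(utf8ToInt(s))]
    if (any(v == 0L)) stop("revcomp: sequence contains a non-ACGTN character")
    intToUtf8(v)
  }, character(1), USE.NAMES = FALSE)
}

#' Random DNA sequence
#'
#' @param n sequence length in bp.
#' @return a single uppercase DNA string.
#' @export
random_dna <- function(n) {
  if (n == 0) return("")
  intToUtf8(c(65L, 67L, 71L, 84L)[sample.int(4L, n, replace = TRUE)])
}

# Evaluate `code` under a temporary RNG state seeded with `seed`, restoring
# the caller's RNG state afterwards. Keeps every stage a pure function of
# (inputs, seed).
with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  code
}

# Derive a stage-specific seed from a global one; keeps results < 2^31.
stage_seed <- function(seed, offset) {
  (as.numeric(seed) * 31L + offset) %% 2147483587
}

assert_dna <- function(x, what = "sequence", allow_n = TRUE) {
  pat <- if (allow_n) "^[ACGTN]*$" else "^[ACGT]*$"
  bad <- !grepl(pat, x)
  if (any(bad)) {
    stop(sprintf("%s contains characters outside {A,C,G,T%s}: %s",
                 what, if (allow_n) ",N" else "",
                 paste(utils::head(x[bad], 3), collapse = ", ")), call. = FALSE)
  }
  invisible(x)
}
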