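#' Construct a per-individual tag set
#'
#' A tag set holds the deduplicated, fixed-length, strand-specific sequence
#' tags observed for one individual, together with its phenotypic sex label.
#'
#' @param tags character vector of uppercase DNA tags (duplicates removed).
#' @param individual_id individual identifier.
#' @param sex_label one of `"male"`, `"female"`, `"unknown"`.
#' @return an object of class `tag_set`.
#' @export
tag_set <- function(tags, individual_id = "unknown", sex_label = "unknown") {
  sex_label <- match.arg(sex_label, c("male", "female", "unknown"))
  tags <- unique(as.character(tags))
  if (length(tags)) {
    assert_dna(tags, what = "tag", allow_n = FALSE)
    if (length(unique(nchar(tags))) > 1L)
      stop("tag_set: tags have differing lengths")
  }
  structure(list(individual_id = individual_id, sex_label = sex_label,
                 tags = sort(tags)),
            class = "tag_set")
}

#' @export
print.tag_set <- function(x, ...) {
  cat(sprintf("Tag set '%s' (%s): %d distinct tags%s\n",
              x$individual_id, x$sex_label, length(x$tags),
              if (length(x$tags)) sprintf(" of %d bp", nchar(x$tags[1])) else ""))
  invisible(x)
}

#' Read a tag file
#'
#' One uppercase tag per line; the set is deduplicated on read. The filename
#' convention `<individual>_<sex>.tags` supplies the individual id and sex
#' label when they are not given explicitly.
#'
#' @param path path to the tag file.
#' @param expected_length required tag length in bp; a tag of any other
#'   length is an error naming the offending line.
#' @param individual_id,sex_label overrides for the filename convention.
#' @return a [tag_set()].
#' @export
read_tag_file <- function(path, expected_length = 27,
                          individual_id = NULL, sex_label = NULL) {
  if (!file.exists(path)) stop("tag file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  keep <- nzchar(lines)
  tags <- toupper(lines[keep])
  lineno <- which(keep)
  bad <- !grepl("^[ACGT]+$", tags)
  if (any(bad)) {
    stop(sprintf("non-ACGT tag at line %d of %s", lineno[which(bad)[1]], path))
  }
  wrong <- nchar(tags) != expected_length
  if (any(wrong)) {
    stop(sprintf("tag of length %d (expected %d) at line %d of %s",
                 nchar(tags[which(wrong)[1]]), expected_length,
                 lineno[which(wrong)[1]], path))
  }
  base <- sub("\\.tags$", "", basename(path))
  if (is.null(individual_id) || is.null(sex_label)) {
    m <- regmatches(base, regexec("^(.*)_(male|female|unknown)$", base))[[1]]
    if (length(m) == 3L) {
      individual_id <- individual_id %||% m[2]
      sex_label <- sex_label %||% m[3]
    } else {
      individual_id <- individual_id %||% base
      sex_label <- sex_label %||% "unknown"
    }
  }
  tag_set(tags, individual_id = individual_id, sex_label = sex_label)
}

#' Write a tag set to a file
#'
#' @param x a [tag_set()].
#' @param path output path (convention: `<individual>_<sex>.tags`).
#' @return `path`, invisibly.
#' @export
write_tag_file <- function(x, path) {
  stopifnot(inherits(x, "tag_set"))
  writeLines(x$tags, path)
  invisible(path)
}
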