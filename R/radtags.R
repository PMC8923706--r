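# In-silico type-IIB (BsaXI-style) digestion. The enzyme recognises the
# degenerate motif AC(N5)CTCC and excises a uniform-length, strand-specific
# tag around it; the published library reads are ~27 bp, which we model as
# 8 bp flank + 11 nt motif + 8 bp flank. True BsaXI cut offsets are not
# modelled — only the tag geometry matters for presence/absence analysis.

#' Digestion configuration
#'
#' @param motif degenerate recognition motif over \{A,C,G,T,N\}; `N` matches
#'   any of A/C/G/T (an `N` in the genome matches nothing, so assembly gaps
#'   never yield tags).
#' @param tag_length emitted tag length in bp.
#' @param flank bases kept on each side of the motif; defaults to
#'   `(tag_length - nchar(motif)) / 2` and must satisfy
#'   `2 * flank + nchar(motif) == tag_length`.
#' @param both_strands scan the reverse strand as well?
#' @param canonicalize if `TRUE`, replace each tag by the lexicographic
#'   minimum of itself and its reverse complement. Off by default: the
#'   sequenced tags are strand-specific.
#' @return an object of class `digest_config`.
#' @export
digest_config <- function(motif = "ACNNNNNCTCC", tag_length = 27,
                          flank = NULL, both_strands = TRUE,
                          canonicalize = FALSE) {
  motif <- toupper(motif)
  assert_dna(motif, what = "motif")
  flank <- flank %||% ((tag_length - nchar(motif)) / 2)
  if (flank != as.integer(flank) || 2 * flank + nchar(motif) != tag_length)
    stop("digest_config: need 2 * flank + nchar(motif) == tag_length")
  structure(list(motif = motif, tag_length = as.integer(tag_length),
                 flank = as.integer(flank), both_strands = both_strands,
                 canonicalize = canonicalize),
            class = "digest_config")
}

motif_regex <- function(motif) {
  paste0("(?=", gsub("N", "[ACGT]", motif, fixed = TRUE), ")")
}

scan_starts <- function(seq, regex) {
  m <- gregexpr(regex, seq, perl = TRUE)[[1]]
  if (m[1] == -1L) integer(0) else as.integer(m) - 1L  # 0-based
}

#' Locate recognition-motif sites
#'
#' Finds all (possibly overlapping) matches of the degenerate motif on the
#' forward strand and, when `both_strands`, of its reverse complement —
#' reported with strand `"-"` and `start` still the leftmost 0-based
#' coordinate on the stored sequence.
#'
#' @param seq one uppercase DNA string.
#' @param config a [digest_config()].
#' @return data frame with columns `start` (0-based) and `strand`, sorted by
#'   start then strand.
#' @export
find_motif_sites <- function(seq, config = digest_config()) {
  stopifnot(is.character(seq), length(seq) == 1L)
  fwd <- scan_starts(seq, motif_regex(config$motif))
  hits <- data.frame(start = fwd,
                     strand = rep("+", length(fwd)),
                     stringsAsFactors = FALSE)
  if (config$both_strands) {
    rev <- scan_starts(seq, motif_regex(revcomp(config$motif)))
    hits <- rbind(hits, data.frame(start = rev,
                                   strand = rep("-", length(rev)),
                                   stringsAsFactors = FALSE))
  }
  hits[order(hits$start, hits$strand), , drop = FALSE]
}

#' Extract fixed-length tags at motif sites
#'
#' Emits the `tag_length` window centred on each motif hit; minus-strand
#' hits emit the reverse complement of that window. Hits whose flank falls
#' off either end of the sequence are skipped (counted in the `"n_skipped"`
#' attribute), and the result is deduplicated.
#'
#' @param seq one uppercase DNA string.
#' @param hits data frame from [find_motif_sites()] on the same sequence.
#' @param config a [digest_config()].
#' @return sorted character vector of distinct tags, with attribute
#'   `"n_skipped"`.
#' @export
extract_tags <- function(seq, hits, config = digest_config()) {
  L <- nchar(seq)
  mlen <- nchar(config$motif)
  from <- hits$start - config$flank            # 0-based window start
  to <- hits$start + mlen + config$flank       # 0-based half-open end
  ok <- from >= 0L & to <= L
  tags <- if (any(ok)) substring(seq, from[ok] + 1L, to[ok]) else character(0)
  neg <- hits$strand[ok] == "-"
  if (any(neg)) tags[neg] <- revcomp(tags[neg])
  bad <- grepl("N", tags, fixed = TRUE)        # gap-touching windows
  tags <- tags[!bad]
  if (config$canonicalize && length(tags)) tags <- pmin(tags, revcomp(tags))
  out <- sort(unique(tags))
  attr(out, "n_skipped") <- sum(!ok)
  out
}

#' Digest sequences into a tag set
#'
#' Composition of [find_motif_sites()] and [extract_tags()] over all input
#' sequences, unioned and deduplicated.
#'
#' @param seqs character vector of uppercase DNA sequences (e.g. from
#'   [read_fasta()]).
#' @param config a [digest_config()].
#' @return sorted character vector of distinct tags.
#' @export
digest <- function(seqs, config = digest_config()) {
  if (length(seqs) == 0L) return(character(0))
  out <- lapply(seqs, function(s) {
    extract_tags(s, find_motif_sites(s, config), config)
  })
  sort(unique(unlist(out, use.names = FALSE)))
}

tags_of <- function(x) {
  if (inherits(x, "tag_set")) x$tags else as.character(x)
}

#' Tags exclusive to one group
#'
#' Returns the tags present in \emph{every} set of `group_a` and in
#' \emph{no} set of `group_b` — the intersection of `group_a` minus the
#' union of `group_b`.
#'
#' @param group_a,group_b non-empty lists of [tag_set()] objects (bare
#'   character vectors are also accepted).
#' @return character vector of exclusive tags.
#' @export
exclusive_tags <- function(group_a, group_b) {
  if (inherits(group_a, "tag_set")) group_a <- list(group_a)
  if (inherits(group_b, "tag_set")) group_b <- list(group_b)
  if (length(group_a) == 0L || length(group_b) == 0L)
    stop("exclusive_tags: both groups must be non-empty (an all-of ",
         "intersection over zero sets is undefined)")
  common <- Reduce(intersect, lapply(group_a, tags_of))
  setdiff(common, unique(unlist(lapply(group_b, tags_of), use.names = FALSE)))
}

#' Infer the sex-determination system from tag sets
#'
#' Under male heterogamety (XX/XY) the tags carried by the Y gametolog are
#' present in every male and absent from every female, and symmetrically
#' for the W under ZZ/ZW. Let `M` be the number of tags exclusive to all
#' males and `F` the number exclusive to all females. The call is `XX_XY`
#' when `M >= min_exclusive` and `F <= max_minor_ratio * M`, `ZZ_ZW` under
#' the mirrored condition, and `inconclusive` otherwise. The thresholds
#' guard the all-or-nothing rule against tag dropout and sequencing noise.
#'
#' @param male_sets,female_sets non-empty lists of [tag_set()] objects.
#' @param min_exclusive minimum exclusive-tag count supporting a call.
#' @param max_minor_ratio maximum ratio of the minor to the major exclusive
#'   count compatible with a call.
#' @return an object of class `sex_system_call` with the system, both
#'   exclusive counts, the thresholds, and the exclusive tags themselves.
#' @export
infer_sex_system <- function(male_sets, female_sets,
                             min_exclusive = 10, max_minor_ratio = 0.01) {
  male_excl <- exclusive_tags(male_sets, female_sets)
  female_excl <- exclusive_tags(female_sets, male_sets)
  m <- length(male_excl)
  f <- length(female_excl)
  system <- if (m >= min_exclusive && f <= max_minor_ratio * m) "XX_XY"
            else if (f >= min_exclusive && m <= max_minor_ratio * f) "ZZ_ZW"
            else "inconclusive"
  structure(list(system = system,
                 male_exclusive_count = m,
                 female_exclusive_count = f,
                 male_exclusive_tags = male_excl,
                 female_exclusive_tags = female_excl,
                 min_exclusive = min_exclusive,
                 max_minor_ratio = max_minor_ratio),
            class = "sex_system_call")
}

#' @export
print.sex_system_call <- function(x, ...) {
  cat("Sex-determination system call\n")
  cat(sprintf("  tags in all males, no female:  %d\n", x$male_exclusive_count))
  cat(sprintf("  tags in all females, no male:  %d\n", x$female_exclusive_count))
  cat(sprintf("  call: %s  (min_exclusive = %g, max_minor_ratio = %g)\n",
              x$system, x$min_exclusive, x$max_minor_ratio))
  invisible(x)
}
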