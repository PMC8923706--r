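# Allele-specific InDel PCR markers. The design rule: one primer of the
# pair overlaps the InDel's divergent region on the gametolog haplotype, so
# amplification succeeds only from chromosomes carrying the sex-limited
# allele; the 300-400 bp product is then a dominant presence/absence band
# (band = heterogametic sex). Thermodynamic primer optimisation is out of
# scope — this module checks placement constraints and simulates
# amplification.

#' A primer pair
#'
#' @param name marker name.
#' @param fwd,rev primer sequences, 5' to 3', each at least 15 nt.
#' @param min_product,max_product accepted product-length window in bp.
#' @return an object of class `primer_pair`.
#' @export
primer_pair <- function(name, fwd, rev, min_product = 300, max_product = 400) {
  fwd <- toupper(fwd); rev <- toupper(rev)
  assert_dna(c(fwd, rev), what = "primer", allow_n = FALSE)
  if (nchar(fwd) < 15 || nchar(rev) < 15)
    stop("primer_pair: primers must be at least 15 nt")
  if (!(min_product > 0 && min_product <= max_product))
    stop("primer_pair: need 0 < min_product <= max_product")
  structure(list(name = name, fwd = fwd, rev = rev,
                 min_product = min_product, max_product = max_product),
            class = "primer_pair")
}

#' Select InDel marker candidates from a screen
#'
#' Passed sites of type InDel, ordered by decreasing allele-length
#' difference (larger events give cleaner allele discrimination), ties by
#' coordinate.
#'
#' @param screen_result a `screen_result` from [run_screen()].
#' @return data frame of candidate sites (possibly empty).
#' @export
select_indel_candidates <- function(screen_result) {
  p <- screen_result$passed
  p <- p[p$vtype == "InDel", , drop = FALSE]
  if (nrow(p) == 0L) return(p)
  sz <- abs(nchar(p$ref) - nchar(p$alt))
  p <- p[order(-sz, p$chrom, p$pos), , drop = FALSE]
  rownames(p) <- NULL
  p
}

#' Drop candidates with another variant in primer range
#'
#' A primer or amplicon that overlaps a second segregating site can fail on
#' haplotypes carrying the other allele there (the classic cause of
#' population-specific marker failure), so marker design prefers InDels
#' with no other discovered variant nearby. Uses the screen's own site
#' catalogue — no ground truth required.
#'
#' @param candidates candidate table from [select_indel_candidates()].
#' @param sites full site table (e.g. `screen_result$sites` or the passed
#'   subset) providing the positions to avoid.
#' @param upstream,downstream exclusion distances in bp. The overlap design
#'   anchors the forward primer on the InDel and extends the product
#'   downstream, so the clear zone is asymmetric: a short stretch upstream
#'   (the primer's 5' tail) and the full product window downstream.
#' @return the filtered candidate table.
#' @export
filter_clear_candidates <- function(candidates, sites, upstream = 50,
                                    downstream = 400) {
  if (nrow(candidates) == 0L) return(candidates)
  keep <- vapply(seq_len(nrow(candidates)), function(i) {
    d <- sites$pos - candidates$pos[i]
    same <- sites$chrom == candidates$chrom[i] & d != 0L
    !any(same & d >= -upstream & d <= downstream)
  }, logical(1))
  candidates[keep, , drop = FALSE]
}

#' Build a marker candidate around an InDel site
#'
#' Extracts the reference context (`window` bp each side of the
#' left-anchored site) and constructs the two pool-phase haplotype
#' sequences: `hap_hom` carries the allele the homogametic pool is fixed
#' for, `hap_gametolog` the sex-limited allele. When pooled allele depths
#' are present on `site` the fixed allele is inferred from the homogametic
#' pool's frequency; otherwise the reference is assumed fixed and the
#' gametolog carries ALT. `indel_interval` is the 0-based half-open
#' interval, on `hap_gametolog`, spanning the left-anchored allele — the
#' divergent region a discriminating primer must overlap.
#'
#' @param site one-row data frame (or list) with `chrom`, `pos`, `ref`,
#'   `alt`, and optionally the pooled counts from [run_screen()].
#' @param reference named character vector of scaffolds.
#' @param window reference context on each side of the site, bp.
#' @param model `"XX_XY"` or `"ZZ_ZW"` (which pool is homogametic).
#' @return an object of class `marker_candidate`.
#' @export
build_candidate <- function(site, reference, window = 500,
                            model = c("XX_XY", "ZZ_ZW")) {
  model <- match.arg(model)
  chrom <- site$chrom; pos <- site$pos
  ref_allele <- site$ref; alt_allele <- site$alt
  if (!chrom %in% names(reference))
    stop("build_candidate: unknown scaffold ", chrom)
  scaffold <- reference[[chrom]]
  start0 <- pos - 1L - window                      # 0-based region start
  end0 <- pos - 1L + nchar(ref_allele) + window    # half-open end
  if (start0 < 0 || end0 > nchar(scaffold))
    stop(sprintf("build_candidate: %d bp window around %s:%d truncated by scaffold end",
                 window, chrom, pos))
  region <- substring(scaffold, start0 + 1L, end0)
  if (substring(region, window + 1L, window + nchar(ref_allele)) != ref_allele)
    stop("build_candidate: site REF does not match the reference sequence")
  # which allele is fixed in the homogametic pool?
  gametolog_is_alt <- TRUE
  hom_counts <- if (model == "XX_XY")
    c(site$female_ad_ref, site$female_ad_alt)
  else c(site$male_ad_ref, site$male_ad_alt)
  if (!is.null(hom_counts) && length(hom_counts) == 2 && !anyNA(hom_counts) &&
      sum(hom_counts) > 0) {
    gametolog_is_alt <- (hom_counts[2] / sum(hom_counts)) < 0.5
  }
  apply_allele <- function(allele) {
    paste0(substring(region, 1L, window), allele,
           substring(region, window + nchar(ref_allele) + 1L, nchar(region)))
  }
  g_allele <- if (gametolog_is_alt) alt_allele else ref_allele
  h_allele <- if (gametolog_is_alt) ref_allele else alt_allele
  structure(list(chrom = chrom, pos = pos, ref = ref_allele,
                 alt = alt_allele, region_start0 = start0,
                 region_ref = region, window = window, model = model,
                 gametolog_is_alt = gametolog_is_alt,
                 hap_hom = apply_allele(h_allele),
                 hap_gametolog = apply_allele(g_allele),
                 indel_interval = c(window, window + nchar(g_allele))),
            class = "marker_candidate")
}

#' @export
print.marker_candidate <- function(x, ...) {
  cat(sprintf("InDel marker candidate at %s:%d (%s>%s, gametolog carries %s)\n",
              x$chrom, x$pos, x$ref, x$alt,
              if (x$gametolog_is_alt) "ALT" else "REF"))
  cat(sprintf("  region: %d bp; divergent interval on gametolog haplotype: [%d, %d)\n",
              nchar(x$region_ref), x$indel_interval[1], x$indel_interval[2]))
  invisible(x)
}

# 0-based half-open binding interval of a primer on a template, or NULL.
locate_primer <- function(template, primer, orientation = c("fwd", "rev")) {
  orientation <- match.arg(orientation)
  probe <- if (orientation == "fwd") primer else revcomp(primer)
  m <- regexpr(probe, template, fixed = TRUE)
  if (m[1] == -1L) return(NULL)
  c(m[1] - 1L, m[1] - 1L + nchar(probe))
}

#' Does a primer overlap the InDel's divergent region?
#'
#' Each primer is located on `hap_gametolog` (forward primer on the plus
#' strand, reverse primer as its reverse complement); a primer overlaps iff
#' its binding interval intersects `indel_interval` (half-open
#' intersection). A primer not found on the gametolog haplotype is reported
#' as non-overlapping (`FALSE`), not an error.
#'
#' @param pair a [primer_pair()].
#' @param candidate a `marker_candidate`.
#' @return named logical vector `c(fwd = , rev = )`.
#' @export
primer_overlaps_indel <- function(pair, candidate) {
  iv <- candidate$indel_interval
  check <- function(primer, orientation) {
    b <- locate_primer(candidate$hap_gametolog, primer, orientation)
    if (is.null(b)) return(FALSE)
    max(b[1], iv[1]) < min(b[2], iv[2])
  }
  c(fwd = check(pair$fwd, "fwd"), rev = check(pair$rev, "rev"))
}

# All 0-based start positions where `primer` binds `template` in the given
# orientation with <= max_mismatch mismatches, the 3'-terminal
# `three_prime_exact` bases matching exactly.
primer_sites <- function(template, primer, orientation, max_mismatch,
                         three_prime_exact) {
  probe <- if (orientation == "fwd") primer else revcomp(primer)
  if (nchar(template) < nchar(probe)) return(integer(0))
  hits <- Biostrings::matchPattern(probe, Biostrings::DNAString(template),
                                   max.mismatch = max_mismatch)
  starts <- Biostrings::start(hits) - 1L
  if (max_mismatch > 0 && length(starts) && three_prime_exact > 0) {
    L <- nchar(probe)
    t3 <- min(three_prime_exact, L)
    # primer 3' end maps to the right end of a fwd probe, left end of a rev probe
    exact <- vapply(starts, function(s) {
      w <- substring(template, s + 1L, s + L)
      if (orientation == "fwd")
        substring(w, L - t3 + 1L, L) == substring(probe, L - t3 + 1L, L)
      else substring(w, 1L, t3) == substring(probe, 1L, t3)
    }, logical(1))
    starts <- starts[exact]
  }
  starts
}

#' In-silico PCR
#'
#' Finds every amplicon the pair supports on the template: one primer
#' matching the plus strand and the other matching the minus strand
#' downstream, each with at most `max_mismatch` mismatches except the
#' 3'-terminal `three_prime_exact` bases which must match exactly (the
#' allele-specificity mechanism: a primer whose 3' end sits in the
#' divergent region cannot prime on the other haplotype). Both primer
#' orderings are scanned, so results are invariant to reverse-complementing
#' the template. Amplicons span the forward primer's 5' end through the
#' reverse primer's 5' end and are filtered to the pair's product window.
#'
#' @param template uppercase DNA string.
#' @param pair a [primer_pair()].
#' @param max_mismatch mismatches tolerated outside the 3' clamp.
#' @param three_prime_exact length of the exact-match 3' clamp, bp.
#' @return data frame `(start, end, length, fwd_primer)` with 0-based
#'   half-open template coordinates, sorted by start.
#' @export
in_silico_pcr <- function(template, pair, max_mismatch = 0,
                          three_prime_exact = 5) {
  amps <- list()
  layouts <- list(c(plus = "fwd", minus = "rev"),
                  c(plus = "rev", minus = "fwd"))
  for (lay in layouts) {
    p_plus <- pair[[lay[["plus"]]]]
    p_minus <- pair[[lay[["minus"]]]]
    s_plus <- primer_sites(template, p_plus, "fwd", max_mismatch,
                           three_prime_exact)
    s_minus <- primer_sites(template, p_minus, "rev", max_mismatch,
                            three_prime_exact)
    for (a in s_plus) for (b in s_minus) {
      if (b < a) next
      len <- b + nchar(p_minus) - a
      if (len >= pair$min_product && len <= pair$max_product)
        amps[[length(amps) + 1L]] <- data.frame(
          start = a, end = a + len, length = len,
          fwd_primer = lay[["plus"]], stringsAsFactors = FALSE)
    }
  }
  if (length(amps) == 0L)
    return(data.frame(start = integer(0), end = integer(0),
                      length = integer(0), fwd_primer = character(0)))
  out <- unique(do.call(rbind, amps))
  out <- out[order(out$start, out$end), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Predict the gel band for one individual
#'
#' A dominant marker: the band is present iff [in_silico_pcr()] yields at
#' least one amplicon on either haplotype of the marker region.
#'
#' @param haplotypes character vector of the individual's (one or two)
#'   template sequences for the marker region.
#' @param pair a [primer_pair()].
#' @param ... passed to [in_silico_pcr()].
#' @return logical.
#' @export
predict_band <- function(haplotypes, pair, ...) {
  if (length(haplotypes) == 0L)
    stop("predict_band: no haplotype sequences for the marker region")
  any(vapply(haplotypes,
             function(h) nrow(in_silico_pcr(h, pair, ...)) > 0L,
             logical(1)))
}

#' Band-to-sex assignment
#'
#' @param band_present logical (vector).
#' @param model `"XX_XY"` (band = male) or `"ZZ_ZW"` (band = female).
#' @return `"male"`/`"female"` character vector.
#' @export
assign_sex <- function(band_present, model = c("XX_XY", "ZZ_ZW")) {
  model <- match.arg(model)
  if (model == "XX_XY") ifelse(band_present, "male", "female")
  else ifelse(band_present, "female", "male")
}

#' Sex discrimination rate with exact binomial confidence interval
#'
#' Either pass a per-individual record table (columns `id`,
#' `phenotypic_sex`, `predicted_sex`, optionally `band_present`) or the
#' counts directly. Individuals whose PCR failed outright are counted in
#' the denominator and as non-concordant. The rate is reported as a
#' percentage to two decimals with the exact (Clopper-Pearson) 95% CI.
#'
#' @param records optional per-individual data frame.
#' @param n_correct,n_total direct counts (used when `records` is `NULL`).
#' @return an object of class `validation_result`.
#' @export
discrimination_rate <- function(records = NULL, n_correct = NULL,
                                n_total = NULL) {
  if (!is.null(records)) {
    records$concordant <- records$phenotypic_sex == records$predicted_sex
    n_correct <- sum(records$concordant)
    n_total <- nrow(records)
  }
  if (is.null(n_total) || n_total == 0)
    stop("discrimination_rate: no individuals")
  stopifnot(n_correct >= 0, n_correct <= n_total)
  bt <- stats::binom.test(n_correct, n_total)
  structure(list(records = records, n_correct = n_correct, n_total = n_total,
                 rate = 100 * n_correct / n_total,
                 ci95 = 100 * as.numeric(bt$conf.int)),
            class = "validation_result")
}

#' @export
print.validation_result <- function(x, ...) {
  cat(sprintf("Sex discrimination rate: %.2f%% (%d/%d)\n",
              x$rate, x$n_correct, x$n_total))
  cat(sprintf("  95%% CI (exact binomial): [%.2f%%, %.2f%%]\n",
              x$ci95[1], x$ci95[2]))
  invisible(x)
}

#' Design an overlap primer pair for a candidate
#'
#' Constructs a pair from the gametolog haplotype with the forward primer's
#' 3' end crossing the InDel's divergent region (so its 3' clamp mismatches
#' the other haplotype) and the reverse primer placed to give the requested
#' product length. The construction is verified by [in_silico_pcr()]: the
#' pair must amplify `hap_gametolog` and not `hap_hom`; the 3' end is
#' shifted over a small range until both hold.
#'
#' @param candidate a `marker_candidate`.
#' @param primer_length primer length, nt.
#' @param product_length target product length, bp (inside the window).
#' @param min_product,max_product accepted product window.
#' @param max_mismatch,three_prime_exact stringency passed to
#'   [in_silico_pcr()].
#' @return a [primer_pair()].
#' @export
design_overlap_primers <- function(candidate, primer_length = 24,
                                   product_length = 350,
                                   min_product = 300, max_product = 400,
                                   max_mismatch = 0, three_prime_exact = 5) {
  g <- candidate$hap_gametolog
  iv <- candidate$indel_interval
  name <- sprintf("%s_%d", candidate$chrom, candidate$pos)
  for (shift in c(2L, 1L, 3L, 0L, 4L, 5L)) {
    p3 <- iv[2] + shift                       # 0-based half-open 3' end
    f_start <- p3 - primer_length
    r_end <- f_start + product_length
    if (f_start < 0 || r_end > nchar(g)) next
    fwd <- substring(g, f_start + 1L, p3)
    rev <- revcomp(substring(g, r_end - primer_length + 1L, r_end))
    pair <- primer_pair(name, fwd, rev, min_product, max_product)
    on_g <- in_silico_pcr(g, pair, max_mismatch, three_prime_exact)
    on_h <- in_silico_pcr(candidate$hap_hom, pair, max_mismatch,
                          three_prime_exact)
    if (nrow(on_g) >= 1L && nrow(on_h) == 0L) return(pair)
  }
  stop("design_overlap_primers: no allele-specific placement found for ",
       name)
}

#' Materialise an individual's haplotypes over a marker region
#'
#' Applies all of the individual's planted variants inside the region to
#' the reference window (variants upstream of the region do not change its
#' content, only its coordinates, so they are irrelevant here).
#'
#' @param individual a `diploid_individual`.
#' @param reference,truth output of [simulate_reference()].
#' @param chrom scaffold name.
#' @param start0,end0 0-based half-open region on the reference scaffold.
#' @return character vector of two haplotype sequences.
#' @export
individual_region_haplotypes <- function(individual, reference, truth,
                                         chrom, start0, end0) {
  region <- substring(reference[[chrom]], start0 + 1L, end0)
  sites <- truth$sites
  in_region <- sites$chrom == chrom & sites$pos > start0 &
    (sites$pos + nchar(sites$ref) - 1L) <= end0
  vapply(1:2, function(h) {
    sel <- in_region & individual$alleles[, h] == 1L
    if (!any(sel)) return(region)
    s <- sites[sel, , drop = FALSE]
    s <- s[order(s$pos), , drop = FALSE]
    n <- nrow(s)
    p <- s$pos - start0                      # 1-based within region
    starts <- c(1L, p + nchar(s$ref))
    ends <- c(p - 1L, nchar(region))
    pieces <- substring(region, starts, ends)
    v <- character(2L * n + 1L)
    v[seq(1L, 2L * n + 1L, by = 2L)] <- pieces
    v[seq(2L, 2L * n, by = 2L)] <- s$alt
    paste(v, collapse = "")
  }, character(1))
}

#' Validate a marker across simulated individuals
#'
#' Runs the dominant-band prediction for every individual over the marker
#' region, assigns sex under the model, and scores concordance with the
#' phenotypic sex.
#'
#' @param individuals list from [simulate_individuals()].
#' @param reference,truth output of [simulate_reference()].
#' @param candidate a `marker_candidate`.
#' @param pair a [primer_pair()].
#' @param ... stringency passed to [in_silico_pcr()].
#' @return a `validation_result` whose `records` field holds the
#'   per-individual table.
#' @export
validate_marker <- function(individuals, reference, truth, candidate, pair,
                            ...) {
  start0 <- candidate$region_start0
  end0 <- start0 + nchar(candidate$region_ref)
  rows <- lapply(individuals, function(ind) {
    haps <- individual_region_haplotypes(ind, reference, truth,
                                         candidate$chrom, start0, end0)
    band <- predict_band(haps, pair, ...)
    data.frame(id = ind$id, phenotypic_sex = ind$phenotypic_sex,
               band_present = band,
               predicted_sex = assign_sex(band, candidate$model),
               stringsAsFactors = FALSE)
  })
  discrimination_rate(do.call(rbind, rows))
}
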