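# Two-stage variant screen on a male/female pooled VCF:
#  1. GATK-style hard filters on site-quality annotations (OR semantics,
#     SNPs and InDels use different thresholds; a missing annotation never
#     fails — standard practice for annotations such as the rank sums that
#     are undefined at some sites).
#  2. The sex-bias rule: both pools deeper than `min_depth` (strictly), the
#     homogametic pool homozygous (allele frequency near 0 or 1 — the
#     reference may carry either gametolog allele) and the heterogametic
#     pool heterozygous near 1:1.

SNP_FILTER <- list(QD = c("<", 2), MQ = c("<", 40), FS = c(">", 60),
                   SOR = c(">", 3), MQRankSum = c("<", -12.5),
                   ReadPosRankSum = c("<", -8))
INDEL_FILTER <- list(QD = c("<", 2), FS = c(">", 200), SOR = c(">", 10),
                     MQRankSum = c("<", -12.5), ReadPosRankSum = c("<", -8))

#' Screen configuration
#'
#' @param min_depth per-pool depth must be strictly greater than this.
#' @param hom_tol the homogametic pool counts as homozygous when its ALT
#'   frequency is `<= hom_tol` or `>= 1 - hom_tol`.
#' @param het_tol the heterogametic pool counts as heterozygous near 1:1
#'   when its ALT frequency is within `0.5 +/- het_tol`. The default 0.15
#'   is calibrated to pooled binomial sampling at 30-60x: it retains ~98%
#'   of true 1:1 sites at 60x while a 3:1 site stays more than 3 standard
#'   deviations outside the window.
#' @param model `"XX_XY"` (female homozygous, male heterozygous) or
#'   `"ZZ_ZW"` (mirrored).
#' @return an object of class `screen_config`.
#' @export
screen_config <- function(min_depth = 30, hom_tol = 0.05, het_tol = 0.15,
                          model = c("XX_XY", "ZZ_ZW")) {
  model <- match.arg(model)
  stopifnot(hom_tol >= 0, hom_tol < 0.5, het_tol >= 0, het_tol < 0.5,
            min_depth >= 0)
  structure(list(min_depth = min_depth, hom_tol = hom_tol,
                 het_tol = het_tol, model = model),
            class = "screen_config")
}

#' Classify a biallelic variant
#'
#' @param ref reference allele string.
#' @param alts character vector of alternate alleles (or one comma-joined
#'   string).
#' @return `"SNP"` (single-base ref and alt), `"InDel"` (lengths differ) or
#'   `"multiallelic"` (rejected downstream). Identical ref and alt is an
#'   error.
#' @export
classify_variant <- function(ref, alts) {
  alts <- unlist(strsplit(alts, ",", fixed = TRUE))
  if (length(alts) != 1L) return("multiallelic")
  if (identical(ref, alts)) stop("classify_variant: ref and alt are identical")
  if (nchar(ref) == 1L && nchar(alts) == 1L) "SNP"
  else if (nchar(ref) != nchar(alts)) "InDel"
  else "MNP_reject"  # equal-length multi-base substitution: not screened
}

#' Apply the hard filters
#'
#' OR semantics over the per-type filter expression: a site fails if any
#' applicable inequality holds; a missing (`NA`) metric never fails. The
#' reported reason names the first failing metric in the expression's
#' written order. SNP thresholds: QD < 2, MQ < 40, FS > 60, SOR > 3,
#' MQRankSum < -12.5, ReadPosRankSum < -8. InDel thresholds: QD < 2,
#' FS > 200, SOR > 10, MQRankSum < -12.5, ReadPosRankSum < -8.
#'
#' @param sites data frame with columns `vtype` plus the INFO metrics
#'   (QD, MQ, FS, SOR, MQRankSum, ReadPosRankSum).
#' @return character vector: `"pass"` or `"hard_filter:<metric>"`.
#' @export
hard_filter <- function(sites) {
  n <- nrow(sites)
  out <- rep("pass", n)
  for (i in seq_len(n)) {
    rules <- if (sites$vtype[i] == "SNP") SNP_FILTER else INDEL_FILTER
    for (m in names(rules)) {
      val <- sites[[m]][i]
      if (is.na(val)) next
      thr <- as.numeric(rules[[m]][2])
      hit <- if (rules[[m]][1] == "<") val < thr else val > thr
      if (hit) { out[i] <- paste0("hard_filter:", m); break }
    }
  }
  out
}

#' Pooled allele frequency
#'
#' @param ad_ref,ad_alt reference and alternate allele depths.
#' @return `ad_alt / (ad_ref + ad_alt)`; zero informative reads is an error
#'   (distinct from a depth failure).
#' @export
allele_frequency <- function(ad_ref, ad_alt) {
  tot <- ad_ref + ad_alt
  if (any(tot == 0)) stop("allele_frequency: no informative reads at a site")
  ad_alt / tot
}

split_ad <- function(ad) {
  parts <- strsplit(ad, ",", fixed = TRUE)
  list(ref = vapply(parts, function(x) as.integer(x[1]), integer(1)),
       alt = vapply(parts, function(x) sum(as.integer(x[-1])), integer(1)))
}

# Build the flat site table the screen operates on from VCF records.
pool_sites <- function(records, male_sample = "MALES",
                       female_sample = "FEMALES") {
  n <- nrow(records)
  vtype <- character(n)
  for (i in seq_len(n)) {
    vtype[i] <- if (records$multiallelic[i]) "multiallelic"
                else classify_variant(records$ref[i], records$alt[i])
  }
  df <- data.frame(chrom = records$chrom, pos = records$pos,
                   ref = records$ref, alt = records$alt, vtype = vtype,
                   stringsAsFactors = FALSE)
  for (m in INFO_METRICS) df[[m]] <- records[[m]]
  get_counts <- function(sample) {
    ad <- records[[paste0(sample, "_AD")]]
    dp <- records[[paste0(sample, "_DP")]]
    ok <- !is.na(ad)
    ref_d <- alt_d <- rep(NA_integer_, n)
    if (any(ok)) {
      sp <- split_ad(ad[ok])
      ref_d[ok] <- sp$ref
      alt_d[ok] <- sp$alt
    }
    list(ref = ref_d, alt = alt_d, dp = ifelse(is.na(dp), ref_d + alt_d, dp))
  }
  m <- get_counts(male_sample)
  f <- get_counts(female_sample)
  df$male_ad_ref <- m$ref; df$male_ad_alt <- m$alt; df$male_dp <- m$dp
  df$female_ad_ref <- f$ref; df$female_ad_alt <- f$alt; df$female_dp <- f$dp
  df$usable <- records$usable
  df
}

#' Sex-bias screen on one or more sites
#'
#' Applies the pooled-frequency rule under the given model: both pools
#' strictly deeper than `min_depth`; the homogametic pool's ALT frequency
#' within `hom_tol` of 0 or 1; the heterogametic pool's ALT frequency
#' within `het_tol` of 0.5; and the fixed and segregating alleles
#' consistent (the heterogametic pool must segregate for the allele the
#' homogametic pool lacks). Sites are assumed to have passed
#' [hard_filter()].
#'
#' @param sites site table (see [run_screen()]).
#' @param config a [screen_config()].
#' @return character vector: `"pass"`, `"depth_male"`, `"depth_female"`,
#'   `"hom_fail"`, `"het_fail"` or `"allele_inconsistency"`.
#' @export
sex_bias_screen <- function(sites, config = screen_config()) {
  n <- nrow(sites)
  out <- character(n)
  xx_xy <- config$model == "XX_XY"
  for (i in seq_len(n)) {
    if (is.na(sites$male_dp[i]) || sites$male_dp[i] <= config$min_depth) {
      out[i] <- "depth_male"; next
    }
    if (is.na(sites$female_dp[i]) || sites$female_dp[i] <= config$min_depth) {
      out[i] <- "depth_female"; next
    }
    if (xx_xy) {
      hom <- c(sites$female_ad_ref[i], sites$female_ad_alt[i])
      het <- c(sites$male_ad_ref[i], sites$male_ad_alt[i])
    } else {
      hom <- c(sites$male_ad_ref[i], sites$male_ad_alt[i])
      het <- c(sites$female_ad_ref[i], sites$female_ad_alt[i])
    }
    if (sum(hom) == 0 || sum(het) == 0) { out[i] <- "allele_inconsistency"; next }
    hom_af <- hom[2] / sum(hom)
    het_af <- het[2] / sum(het)
    if (hom_af > config$hom_tol && hom_af < 1 - config$hom_tol) {
      out[i] <- "hom_fail"; next
    }
    if (abs(het_af - 0.5) > config$het_tol) { out[i] <- "het_fail"; next }
    # the allele absent from the homogametic pool must be the one the
    # heterogametic pool segregates for (always holds for biallelic sites
    # with het_af near 0.5; kept as a guard)
    fixed_allele <- if (hom_af <= config$hom_tol) 1L else 2L
    if (het[-fixed_allele][1] == 0) { out[i] <- "allele_inconsistency"; next }
    out[i] <- "pass"
  }
  out
}

#' Run the full screen on pooled VCF records
#'
#' Applies, in order: multiallelic/usability triage, the per-type hard
#' filters, and the sex-bias screen. Every input record is assigned exactly
#' one outcome (`"pass"` or a failure reason), so the outcome tallies
#' partition the input.
#'
#' @param records a `vcf_records` data frame (from [read_vcf()] or
#'   [simulate_pools()]).
#' @param config a [screen_config()].
#' @param male_sample,female_sample sample names of the two pools.
#' @return an object of class `screen_result`: `sites` (site table with a
#'   `reason` column), `passed` (subset with `reason == "pass"`), `tally`,
#'   and the `config`.
#' @export
run_screen <- function(records, config = screen_config(),
                       male_sample = "MALES", female_sample = "FEMALES") {
  sites <- pool_sites(records, male_sample, female_sample)
  n <- nrow(sites)
  reason <- rep(NA_character_, n)
  reason[!sites$usable] <- "unusable"
  reason[is.na(reason) & sites$vtype == "multiallelic"] <- "multiallelic"
  reason[is.na(reason) & sites$vtype == "MNP_reject"] <- "multiallelic"
  todo <- is.na(reason)
  if (any(todo)) reason[todo] <- hard_filter(sites[todo, , drop = FALSE])
  todo <- reason == "pass"
  if (any(todo)) reason[todo] <- sex_bias_screen(sites[todo, , drop = FALSE],
                                                 config)
  sites$reason <- reason
  structure(list(sites = sites,
                 passed = sites[reason == "pass", , drop = FALSE],
                 tally = sort(table(reason), decreasing = TRUE),
                 config = config),
            class = "screen_result")
}

#' @export
print.screen_result <- function(x, ...) {
  cat(sprintf("Sex-bias screen (%s model): %d of %d sites passed\n",
              x$config$model, nrow(x$passed), nrow(x$sites)))
  if (nrow(x$sites)) {
    t <- x$tally
    cat("  outcomes:", paste(sprintf("%s=%d", names(t), as.integer(t)),
                             collapse = ", "), "\n")
  }
  invisible(x)
}

#' @export
summary.screen_result <- function(object, ...) {
  print(object)
  s <- scaffold_summary(object)
  if (nrow(s)) {
    cat("  passed sites by scaffold:\n")
    for (i in seq_len(min(nrow(s), 10L)))
      cat(sprintf("    %-16s %6d  (%.1f%%)\n", s$chrom[i], s$count[i],
                  100 * s$fraction[i]))
  }
  invisible(s)
}

#' Passed-site concentration by scaffold
#'
#' Counts the screen's passed sites per scaffold — a strong concentration
#' on one scaffold marks it as the sex-linked candidate region.
#'
#' @param result a `screen_result`.
#' @return data frame `(chrom, count, fraction)` sorted by descending count,
#'   ties broken by scaffold name; fractions sum to 1 when non-empty.
#' @export
scaffold_summary <- function(result) {
  p <- result$passed
  if (nrow(p) == 0L)
    return(data.frame(chrom = character(0), count = integer(0),
                      fraction = numeric(0)))
  t <- table(p$chrom)
  df <- data.frame(chrom = names(t), count = as.integer(t),
                   stringsAsFactors = FALSE)
  df <- df[order(-df$count, df$chrom), , drop = FALSE]
  df$fraction <- df$count / sum(df$count)
  rownames(df) <- NULL
  df
}

#' Score a screen against the planted truth
#'
#' Recall is computed over planted sex-linked sites that were not assigned
#' an injected failing INFO metric (those are built to be removed by the
#' hard filter, so removing them is correct, not a miss). The false-positive
#' rate is the fraction of all autosomal sites that passed.
#'
#' @param result a `screen_result`.
#' @param truth a `sim_truth`, ideally the `"truth"` attribute of the
#'   [simulate_pools()] output (which carries `fail_metric`).
#' @return list with `recall`, `fpr`, and the underlying counts.
#' @export
score_screen <- function(result, truth) {
  sites <- truth$sites
  key <- function(chrom, pos) paste(chrom, pos)
  passed <- key(result$passed$chrom, result$passed$pos)
  fail <- if ("fail_metric" %in% names(sites)) !is.na(sites$fail_metric)
          else rep(FALSE, nrow(sites))
  sex_ok <- sites$is_sex_linked & !fail
  auto <- !sites$is_sex_linked
  n_recalled <- sum(key(sites$chrom, sites$pos)[sex_ok] %in% passed)
  n_fp <- sum(key(sites$chrom, sites$pos)[auto] %in% passed)
  list(recall = if (sum(sex_ok)) n_recalled / sum(sex_ok) else NA_real_,
       fpr = if (sum(auto)) n_fp / sum(auto) else NA_real_,
       n_sex_linked_eligible = sum(sex_ok), n_recalled = n_recalled,
       n_autosomal = sum(auto), n_false_positive = n_fp)
}
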