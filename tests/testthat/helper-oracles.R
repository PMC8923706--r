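# Independent oracles and small fixture builders used across the suite.
# Oracles are deliberately naive (enumeration, direct expression evaluation,
# tail-probability inversion) and never share code with the implementation
# paths they check.

# per-tag membership scan: tag kept iff present in every set of a and no set of b
brute_exclusive <- function(group_a, group_b) {
  ta <- lapply(group_a, function(s) if (inherits(s, "tag_set")) s$tags else s)
  tb <- lapply(group_b, function(s) if (inherits(s, "tag_set")) s$tags else s)
  universe <- unique(unlist(c(ta, tb)))
  keep <- vapply(universe, function(tag) {
    all(vapply(ta, function(s) tag %in% s, logical(1))) &&
      !any(vapply(tb, function(s) tag %in% s, logical(1)))
  }, logical(1))
  universe[keep]
}

# direct evaluation of the published filter expressions; NA clauses are false
brute_hard_filter_fails <- function(vtype, QD, MQ, FS, SOR, MQRankSum,
                                    ReadPosRankSum) {
  if (vtype == "SNP") {
    isTRUE(QD < 2.0) || isTRUE(MQ < 40.0) || isTRUE(FS > 60.0) ||
      isTRUE(SOR > 3.0) || isTRUE(MQRankSum < -12.5) ||
      isTRUE(ReadPosRankSum < -8.0)
  } else {
    isTRUE(QD < 2.0) || isTRUE(FS > 200.0) || isTRUE(SOR > 10.0) ||
      isTRUE(MQRankSum < -12.5) || isTRUE(ReadPosRankSum < -8.0)
  }
}

# Clopper-Pearson 95% CI by direct inversion of the binomial tails
brute_cp_ci <- function(k, n, alpha = 0.05) {
  lo <- if (k == 0) 0 else
    stats::uniroot(function(p) stats::pbinom(k - 1, n, p) - (1 - alpha / 2),
                   c(1e-12, 1 - 1e-12), tol = 1e-10)$root
  hi <- if (k == n) 1 else
    stats::uniroot(function(p) stats::pbinom(k, n, p) - alpha / 2,
                   c(1e-12, 1 - 1e-12), tol = 1e-10)$root
  c(lo, hi)
}

# Biostrings-based degenerate-motif scan (independent of the regex path)
bs_motif_starts <- function(seq, motif) {
  hits <- Biostrings::matchPattern(motif, Biostrings::DNAString(seq),
                                   fixed = "subject")
  Biostrings::start(hits) - 1L
}

# n distinct fixed-length DNA strings, enumerated (not sampled)
enumerate_tags <- function(n, width = 9) {
  stopifnot(n <= 4^width)
  idx <- seq_len(n) - 1L
  cols <- lapply(rev(seq_len(width) - 1L), function(p) {
    c("A", "C", "G", "T")[(idx %/% 4^p) %% 4 + 1L]
  })
  do.call(paste0, cols)
}

# random two-pool VCF records with multiallelic/unusable/missing-metric cases
make_random_vcf <- function(n, seed) {
  set.seed(seed)
  if (n == 0L) return(sexmarker:::empty_vcf_records(c("MALES", "FEMALES")))
  chrom <- paste0("scaffold_", sample(1:4, n, replace = TRUE))
  pos <- sample.int(1e6, n)
  ref <- sample(c("A", "C", "G", "T"), n, replace = TRUE)
  alt <- vapply(seq_len(n), function(i) {
    r <- stats::runif(1)
    if (r < 0.10) paste(sample(setdiff(c("A", "C", "G", "T"), ref[i]), 2),
                        collapse = ",")
    else if (r < 0.45) paste0(ref[i],
                              paste(sample(c("A", "C", "G", "T"),
                                           sample(2:6, 1), replace = TRUE),
                                    collapse = ""))
    else sample(setdiff(c("A", "C", "G", "T"), ref[i]), 1)
  }, character(1))
  rmet <- function(lo, hi, p_na = 0.15)
    ifelse(stats::runif(n) < p_na, NA_real_, stats::runif(n, lo, hi))
  df <- data.frame(chrom = chrom, pos = pos, id = rep(".", n), ref = ref,
                   alt = alt,
                   qual = round(stats::runif(n, 30, 3000), 2),
                   filter = rep(".", n),
                   QD = rmet(0, 40), MQ = rmet(20, 60), FS = rmet(0, 250),
                   SOR = rmet(0, 12), MQRankSum = rmet(-20, 5),
                   ReadPosRankSum = rmet(-12, 5),
                   stringsAsFactors = FALSE)
  df$multiallelic <- grepl(",", df$alt)
  df$usable <- stats::runif(n) > 0.05
  for (s in c("MALES", "FEMALES")) {
    dp <- stats::rpois(n, 45)
    a <- stats::rbinom(n, dp, stats::runif(n))
    df[[paste0(s, "_AD")]] <- paste0(dp - a, ",", a)
    df[[paste0(s, "_DP")]] <- dp
  }
  attr(df, "samples") <- c("MALES", "FEMALES")
  class(df) <- c("vcf_records", "data.frame")
  df
}

# swap the two pools' columns in a records table
swap_pools <- function(records) {
  out <- records
  for (suf in c("_AD", "_DP")) {
    m <- records[[paste0("MALES", suf)]]
    out[[paste0("MALES", suf)]] <- records[[paste0("FEMALES", suf)]]
    out[[paste0("FEMALES", suf)]] <- m
  }
  out
}

site_key <- function(df) paste(df$chrom, df$pos)
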