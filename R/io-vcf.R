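# Constrained two-pool VCF dialect: CHROM POS ID REF ALT QUAL FILTER INFO
# FORMAT + named samples, FORMAT carrying at least AD and DP. Parsing is
# delegated to vcfR; the writer is ours because the dialect is tiny and must
# stay plain text.

INFO_METRICS <- c("QD", "MQ", "FS", "SOR", "MQRankSum", "ReadPosRankSum")

vcf_columns <- function(samples) {
  c("chrom", "pos", "id", "ref", "alt", "qual", "filter", INFO_METRICS,
    "multiallelic", "usable",
    as.vector(rbind(paste0(samples, "_AD"), paste0(samples, "_DP"))))
}

empty_vcf_records <- function(samples) {
  cols <- vcf_columns(samples)
  df <- as.data.frame(setNames(rep(list(logical(0)), length(cols)), cols))
  new_vcf_records(df, samples)
}

new_vcf_records <- function(df, samples) {
  attr(df, "samples") <- samples
  class(df) <- c("vcf_records", "data.frame")
  df
}

#' Read a two-pool VCF
#'
#' Reads a VCF (plain text, v4.2 subset) into a flat data frame, one row per
#' record, with the site-quality INFO metrics (QD, MQ, FS, SOR, MQRankSum,
#' ReadPosRankSum) parsed as numerics — `NA` meaning the annotation is
#' absent at that site, which downstream filtering treats as "missing", not
#' as failing. Per-sample allele depths (`<sample>_AD`, comma-joined,
#' reference allele first) and total depth (`<sample>_DP`) are extracted for
#' every required sample. Records where AD or DP is absent for a required
#' sample are retained but flagged `usable = FALSE`; multi-allelic records
#' are retained and flagged `multiallelic = TRUE`.
#'
#' @param path path to a VCF file.
#' @param required_samples sample names that must be present.
#' @return a `vcf_records` data frame (attribute `"samples"` holds the
#'   sample names).
#' @export
read_vcf <- function(path, required_samples = c("MALES", "FEMALES")) {
  if (!file.exists(path)) stop("VCF file not found: ", path)
  v <- suppressWarnings(vcfR::read.vcfR(path, verbose = FALSE))
  have <- setdiff(colnames(v@gt), "FORMAT")
  missing <- setdiff(required_samples, have)
  if (length(missing)) {
    stop(sprintf("VCF %s lacks required sample(s) %s; available samples: %s",
                 path, paste(missing, collapse = ", "),
                 if (length(have)) paste(have, collapse = ", ") else "(none)"))
  }
  n <- nrow(v@fix)
  if (n == 0L) return(empty_vcf_records(required_samples))
  fix <- v@fix
  df <- data.frame(
    chrom = fix[, "CHROM"],
    pos = as.integer(fix[, "POS"]),
    id = ifelse(is.na(fix[, "ID"]), ".", fix[, "ID"]),
    ref = toupper(fix[, "REF"]),
    alt = toupper(fix[, "ALT"]),
    qual = suppressWarnings(as.numeric(fix[, "QUAL"])),
    filter = ifelse(is.na(fix[, "FILTER"]), ".", fix[, "FILTER"]),
    stringsAsFactors = FALSE
  )
  for (m in INFO_METRICS) {
    df[[m]] <- suppressWarnings(as.numeric(vcfR::extract.info(v, m, as.numeric = TRUE)))
  }
  df$multiallelic <- grepl(",", df$alt)
  usable <- rep(TRUE, n)
  ad <- vcfR::extract.gt(v, "AD")
  dp <- vcfR::extract.gt(v, "DP")
  for (s in required_samples) {
    ad_s <- if (s %in% colnames(ad)) ad[, s] else rep(NA_character_, n)
    dp_s <- if (s %in% colnames(dp)) suppressWarnings(as.integer(dp[, s])) else rep(NA_integer_, n)
    # DP reconstructed from AD when only DP is missing
    dp_s <- ifelse(is.na(dp_s) & !is.na(ad_s),
                   vapply(strsplit(ad_s, ","), function(x) sum(as.integer(x)), integer(1)),
                   dp_s)
    usable <- usable & !is.na(ad_s) & !is.na(dp_s)
    df[[paste0(s, "_AD")]] <- ad_s
    df[[paste0(s, "_DP")]] <- dp_s
  }
  df$usable <- usable
  df <- df[, vcf_columns(required_samples)]
  new_vcf_records(df, required_samples)
}

#' Write a two-pool VCF
#'
#' Emits the constrained dialect read by [read_vcf()]; the pair round-trips
#' losslessly for every field the pipeline uses.
#'
#' @param records a `vcf_records` data frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_vcf <- function(records, path) {
  samples <- attr(records, "samples")
  if (is.null(samples)) stop("write_vcf: records carry no 'samples' attribute")
  hdr <- c(
    "##fileformat=VCFv4.2",
    sprintf("##INFO=<ID=%s,Number=1,Type=Float,Description=\"%s\">",
            INFO_METRICS,
            c("Variant quality by depth", "RMS mapping quality",
              "Fisher strand bias (phred)", "Symmetric odds ratio strand bias",
              "Mapping-quality rank-sum", "Read-position rank-sum")),
    "##FORMAT=<ID=AD,Number=R,Type=Integer,Description=\"Allele depths (ref,alt)\">",
    "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Total read depth\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", samples), collapse = "\t")
  )
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(hdr, con)
  n <- nrow(records)
  if (n == 0L) return(invisible(path))
  info <- vapply(seq_len(n), function(i) {
    vals <- unlist(records[i, INFO_METRICS])
    keep <- !is.na(vals)
    if (!any(keep)) return(".")
    paste(sprintf("%s=%s", INFO_METRICS[keep],
                  formatC(vals[keep], format = "g", digits = 6)),
          collapse = ";")
  }, character(1))
  qual <- ifelse(is.na(records$qual), ".",
                 formatC(records$qual, format = "g", digits = 6))
  body <- cbind(records$chrom, records$pos, records$id, records$ref,
                records$alt, qual, records$filter, info, "AD:DP")
  for (s in samples) {
    ad <- records[[paste0(s, "_AD")]]
    dp <- records[[paste0(s, "_DP")]]
    body <- cbind(body, ifelse(is.na(ad) | is.na(dp), ".",
                               paste0(ad, ":", dp)))
  }
  writeLines(apply(body, 1L, paste, collapse = "\t"), con)
  invisible(path)
}
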