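# Diploid population simulator. One scaffold is sex-linked: a "gametolog"
# haplotype (Y-like under XX/XY, W-like under ZZ/ZW) carries the alternate
# allele at every planted sex-linked site and is present in exactly one copy
# in the heterogametic sex. Autosomal sites segregate at per-site pool
# frequencies identical in both sexes, so any sex bias observed there is
# sampling noise. All randomness flows from a single config seed through
# fixed per-stage offsets, so each stage is a pure function of its inputs.

#' Simulation configuration
#'
#' Defaults emulate the study design this package targets: a family-scale
#' comparison of a few males and females, a multi-megabase assembly whose
#' sex scaffold carries a young, moderately diverged gametolog (here ~0.3%
#' fixed divergence: 3000 SNPs + 150 InDels per Mb), and two pooled
#' resequencing libraries at ~40x each.
#'
#' @param seed integer; single source of randomness for every stage.
#' @param system `"XX_XY"` (male heterogametic) or `"ZZ_ZW"`.
#' @param n_males,n_females individuals per sex.
#' @param n_scaffolds,scaffold_length assembly shape (bp per scaffold).
#' @param sex_scaffold_index 1-based index of the sex-linked scaffold.
#' @param n_sex_linked_snps,n_sex_linked_indels fixed gametolog differences
#'   planted on the sex scaffold.
#' @param n_autosomal_sites segregating sites spread over the remaining
#'   scaffolds.
#' @param indel_size_range inserted/deleted length range in bp.
#' @param depth_mean mean pooled depth per pool (Poisson).
#' @param seq_error_rate probability a read reports the other allele.
#' @param frac_filter_fail_sites fraction of sites assigned one
#'   hard-filter-failing INFO metric.
#' @param tag_dropout_rate per-tag probability of being missed in an
#'   individual's tag set.
#' @return an object of class `sim_config`.
#' @export
sim_config <- function(seed = 1, system = c("XX_XY", "ZZ_ZW"),
                       n_males = 5, n_females = 5,
                       n_scaffolds = 5, scaffold_length = 1e6,
                       sex_scaffold_index = 1,
                       n_sex_linked_snps = 3000, n_sex_linked_indels = 150,
                       n_autosomal_sites = 2000,
                       indel_size_range = c(2, 10),
                       depth_mean = 40, seq_error_rate = 0.002,
                       frac_filter_fail_sites = 0.05,
                       tag_dropout_rate = 0) {
  system <- match.arg(system)
  stopifnot(n_males >= 0, n_females >= 0, n_scaffolds >= 1,
            scaffold_length > 0, depth_mean > 0,
            n_sex_linked_snps >= 0, n_sex_linked_indels >= 0,
            n_autosomal_sites >= 0,
            length(indel_size_range) == 2, indel_size_range[1] >= 1,
            indel_size_range[1] <= indel_size_range[2],
            seq_error_rate >= 0, seq_error_rate < 1,
            frac_filter_fail_sites >= 0, frac_filter_fail_sites < 1,
            tag_dropout_rate >= 0, tag_dropout_rate <= 1)
  if (sex_scaffold_index < 1 || sex_scaffold_index > n_scaffolds)
    stop("sim_config: sex_scaffold_index out of range")
  if (n_autosomal_sites > 0 && n_scaffolds < 2)
    stop("sim_config: autosomal sites require at least 2 scaffolds")
  structure(as.list(environment()), class = "sim_config")
}

END_MARGIN <- 500L  # bp kept free at scaffold ends (room for amplicons)

# Evenly-binned positions with one site per bin: guarantees every pairwise
# distance exceeds `gap` without rejection sampling.
plant_positions <- function(scaffold_length, k, gap) {
  if (k == 0L) return(integer(0))
  usable <- scaffold_length - 2L * END_MARGIN
  w <- floor(usable / k)
  if (w < gap + 2L)
    stop(sprintf(paste0("scaffold of %d bp too short for %d sites; ",
                        "need at least %d bp"),
                 scaffold_length, k, 2L * END_MARGIN + k * (gap + 2L)))
  END_MARGIN + (seq_len(k) - 1L) * w + sample.int(w - gap, k, replace = TRUE)
}

draw_alleles <- function(seq, pos, types, config) {
  n <- length(pos)
  ref <- character(n)
  alt <- character(n)
  for (i in seq_len(n)) {
    base <- substring(seq, pos[i], pos[i])
    if (types[i] == "SNP") {
      ref[i] <- base
      alt[i] <- sample(setdiff(DNA_BASES, base), 1L)
    } else {
      k <- sample(seq(config$indel_size_range[1], config$indel_size_range[2]), 1L)
      if (stats::runif(1) < 0.5) {       # deletion relative to the reference
        ref[i] <- substring(seq, pos[i], pos[i] + k)
        alt[i] <- base
      } else {                           # insertion
        ref[i] <- base
        alt[i] <- paste0(base, random_dna(k))
      }
    }
  }
  list(ref = ref, alt = alt)
}

#' Simulate a reference assembly with planted variant sites
#'
#' Generates `n_scaffolds` random scaffolds and plants the configured
#' sex-linked (on the sex scaffold) and autosomal sites, all at least 500 bp
#' from scaffold ends and pairwise separated by more than the maximum InDel
#' size. InDels use the left-anchored VCF convention (the REF/ALT allele
#' includes the base before the event).
#'
#' @param config a [sim_config()].
#' @return list with `reference` (named character vector, one scaffold per
#'   element) and `truth` (class `sim_truth`: the planted-site table plus
#'   the config).
#' @export
simulate_reference <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  with_seed(stage_seed(config$seed, 1L), {
    ref <- vapply(seq_len(config$n_scaffolds),
                  function(i) random_dna(config$scaffold_length), character(1))
    names(ref) <- paste0("scaffold_", seq_len(config$n_scaffolds))
    gap <- as.integer(config$indel_size_range[2])
    sites <- list()
    # sex-linked sites
    n_sex <- config$n_sex_linked_snps + config$n_sex_linked_indels
    sex_chrom <- names(ref)[config$sex_scaffold_index]
    if (n_sex > 0) {
      pos <- plant_positions(config$scaffold_length, n_sex, gap)
      types <- sample(c(rep("SNP", config$n_sex_linked_snps),
                        rep("InDel", config$n_sex_linked_indels)))
      al <- draw_alleles(ref[[sex_chrom]], pos, types, config)
      sites[[sex_chrom]] <- data.frame(
        chrom = sex_chrom, pos = pos, ref = al$ref, alt = al$alt,
        type = types, is_sex_linked = TRUE, pool_freq = NA_real_,
        stringsAsFactors = FALSE)
    }
    # autosomal sites, spread round-robin over the remaining scaffolds
    if (config$n_autosomal_sites > 0) {
      auto <- setdiff(names(ref), sex_chrom)
      per <- table(rep(auto, length.out = config$n_autosomal_sites))
      for (chrom in names(per)) {
        k <- as.integer(per[[chrom]])
        pos <- plant_positions(config$scaffold_length, k, gap)
        types <- sample(c("SNP", "InDel"), k, replace = TRUE, prob = c(0.8, 0.2))
        al <- draw_alleles(ref[[chrom]], pos, types, config)
        sites[[chrom]] <- data.frame(
          chrom = chrom, pos = pos, ref = al$ref, alt = al$alt,
          type = types, is_sex_linked = FALSE,
          pool_freq = stats::runif(k, 0.05, 0.95),
          stringsAsFactors = FALSE)
      }
    }
    sites <- if (length(sites))
      do.call(rbind, c(unname(sites), list(make.row.names = FALSE))) else NULL
    if (is.null(sites))
      sites <- data.frame(chrom = character(0), pos = integer(0),
                          ref = character(0), alt = character(0),
                          type = character(0), is_sex_linked = logical(0),
                          pool_freq = numeric(0))
    sites <- sites[order(match(sites$chrom, names(ref)), sites$pos), ,
                   drop = FALSE]
    rownames(sites) <- NULL
    truth <- structure(list(sites = sites, config = config),
                       class = "sim_truth")
    list(reference = ref, truth = truth)
  })
}

#' Simulate diploid individuals
#'
#' Each individual is represented by an allele matrix over the planted sites
#' (rows aligned with `truth$sites`; columns `hap_a`, `hap_b`; 0 = REF,
#' 1 = ALT). Under `XX_XY`, every male carries the gametolog (ALT at all
#' sex-linked sites) on `hap_b` and every female is homozygous reference
#' there; under `ZZ_ZW` the roles are mirrored. Autosomal alleles are
#' Bernoulli draws at each site's pool frequency. Full haplotype sequences
#' are materialised on demand by [haplotype_scaffold()].
#'
#' @param reference,truth output of [simulate_reference()].
#' @param config the same [sim_config()].
#' @return list of `diploid_individual` objects (males first).
#' @export
simulate_individuals <- function(reference, truth, config) {
  if (config$n_males + config$n_females == 0)
    stop("simulate_individuals: need at least one individual")
  sites <- truth$sites
  n_sites <- nrow(sites)
  hetero_sex <- if (config$system == "XX_XY") "male" else "female"
  with_seed(stage_seed(config$seed, 2L), {
    make_ind <- function(id, sex) {
      alleles <- matrix(0L, nrow = n_sites, ncol = 2,
                        dimnames = list(NULL, c("hap_a", "hap_b")))
      auto <- !sites$is_sex_linked
      if (any(auto)) {
        f <- sites$pool_freq[auto]
        alleles[auto, 1] <- stats::rbinom(sum(auto), 1L, f)
        alleles[auto, 2] <- stats::rbinom(sum(auto), 1L, f)
      }
      if (sex == hetero_sex) alleles[sites$is_sex_linked, 2] <- 1L
      structure(list(id = id, phenotypic_sex = sex, alleles = alleles),
                class = "diploid_individual")
    }
    c(lapply(seq_len(config$n_males),
             function(i) make_ind(paste0("M", i), "male")),
      lapply(seq_len(config$n_females),
             function(i) make_ind(paste0("F", i), "female")))
  })
}

#' Materialise one haplotype's sequence for one scaffold
#'
#' Applies the ALT allele at every site where the haplotype carries allele 1
#' to the reference scaffold (left-anchored InDel convention).
#'
#' @param reference named character vector of scaffolds.
#' @param truth a `sim_truth`.
#' @param alleles one column of an individual's allele matrix (0/1 per
#'   site, aligned with `truth$sites`).
#' @param chrom scaffold name.
#' @return a single DNA string.
#' @export
haplotype_scaffold <- function(reference, truth, alleles, chrom) {
  seq <- reference[[chrom]]
  sel <- truth$sites$chrom == chrom & alleles == 1L
  if (!any(sel)) return(seq)
  s <- truth$sites[sel, , drop = FALSE]
  o <- order(s$pos)
  s <- s[o, , drop = FALSE]
  n <- nrow(s)
  starts <- c(1L, s$pos + nchar(s$ref))
  ends <- c(s$pos - 1L, nchar(seq))
  pieces <- substring(seq, starts, ends)
  v <- character(2L * n + 1L)
  v[seq(1L, 2L * n + 1L, by = 2L)] <- pieces
  v[seq(2L, 2L * n, by = 2L)] <- s$alt
  paste(v, collapse = "")
}

# metric draws within "passing" ranges; a failing site gets exactly one
# metric pushed past its threshold so filter behaviour is attributable.
passing_metrics <- function(n) {
  data.frame(QD = stats::runif(n, 5, 35), MQ = stats::runif(n, 50, 60),
             FS = stats::runif(n, 0, 10), SOR = stats::runif(n, 0.5, 2.5),
             MQRankSum = stats::runif(n, -2, 2),
             ReadPosRankSum = stats::runif(n, -2, 2))
}

failing_value <- function(metric, vtype) {
  switch(metric,
         QD = stats::runif(1, 0.1, 1.9),
         MQ = stats::runif(1, 20, 39.5),
         FS = if (vtype == "SNP") stats::runif(1, 61, 150) else stats::runif(1, 201, 400),
         SOR = if (vtype == "SNP") stats::runif(1, 3.1, 8) else stats::runif(1, 10.1, 20),
         MQRankSum = stats::runif(1, -20, -12.6),
         ReadPosRankSum = stats::runif(1, -15, -8.1))
}

#' Simulate pooled male/female resequencing calls
#'
#' For each planted site and pool, the total depth is Poisson with mean
#' `depth_mean` and the ALT allele depth is Binomial at the pool's true
#' allele frequency perturbed by the sequencing error rate
#' (`f' = f(1-e) + (1-f)e`). At sex-linked sites the heterogametic pool
#' therefore sits near 1:1 and the homogametic pool near 0. A
#' `frac_filter_fail_sites` fraction of sites is assigned one INFO metric
#' past its hard-filter threshold; all other metrics are drawn from passing
#' ranges. The failing metric (or `NA`) per site is recorded in the
#' `fail_metric` column of the `truth` attribute of the result.
#'
#' @param individuals list from [simulate_individuals()].
#' @param truth a `sim_truth`.
#' @param config the same [sim_config()].
#' @return a `vcf_records` data frame with samples `MALES` and `FEMALES`;
#'   attribute `"truth"` carries the truth table extended with
#'   `fail_metric`.
#' @export
simulate_pools <- function(individuals, truth, config) {
  sites <- truth$sites
  n <- nrow(sites)
  samples <- c("MALES", "FEMALES")
  if (n == 0L) {
    out <- empty_vcf_records(samples)
    attr(out, "truth") <- truth
    return(out)
  }
  sex_of <- vapply(individuals, `[[`, character(1), "phenotypic_sex")
  pool_freq_of <- function(sex) {
    members <- individuals[sex_of == sex]
    if (length(members) == 0L) return(rep(0, n))
    acc <- Reduce(`+`, lapply(members, function(ind) rowSums(ind$alleles)))
    acc / (2L * length(members))
  }
  f_male <- pool_freq_of("male")
  f_female <- pool_freq_of("female")
  e <- config$seq_error_rate
  with_seed(stage_seed(config$seed, 3L), {
    draw_pool <- function(f) {
      dp <- stats::rpois(n, config$depth_mean)
      fe <- f * (1 - e) + (1 - f) * e
      alt <- stats::rbinom(n, dp, fe)
      list(dp = dp, ad = paste0(dp - alt, ",", alt))
    }
    male <- draw_pool(f_male)
    female <- draw_pool(f_female)
    met <- passing_metrics(n)
    fail_metric <- rep(NA_character_, n)
    n_fail <- round(config$frac_filter_fail_sites * n)
    if (n_fail > 0) {
      idx <- sample.int(n, n_fail)
      for (i in idx) {
        pool <- if (sites$type[i] == "SNP") INFO_METRICS
                else setdiff(INFO_METRICS, "MQ")
        m <- sample(pool, 1L)
        met[i, m] <- failing_value(m, sites$type[i])
        fail_metric[i] <- m
      }
    }
    df <- data.frame(chrom = sites$chrom, pos = sites$pos, id = ".",
                     ref = sites$ref, alt = sites$alt,
                     qual = round(stats::runif(n, 100, 2000), 2),
                     filter = ".", stringsAsFactors = FALSE)
    df <- cbind(df, met)
    df$multiallelic <- FALSE
    df$usable <- TRUE
    df$MALES_AD <- male$ad;    df$MALES_DP <- male$dp
    df$FEMALES_AD <- female$ad; df$FEMALES_DP <- female$dp
    df <- df[, vcf_columns(samples)]
    out <- new_vcf_records(df, samples)
    truth$sites$fail_metric <- fail_metric
    attr(out, "truth") <- truth
    out
  })
}

#' Simulate per-individual 2b-RAD tag sets
#'
#' Each individual's tag set is the union of the in-silico digests of both
#' haplotypes ([digest()]), after which each tag is independently dropped
#' with probability `tag_dropout_rate`. Identical haplotype sequences are
#' digested once (memoised on the allele signature), which keeps
#' population-scale runs fast without changing the result.
#'
#' @param individuals list from [simulate_individuals()].
#' @param reference,truth output of [simulate_reference()].
#' @param config the same [sim_config()].
#' @param digest_cfg a [digest_config()].
#' @return list of [tag_set()] objects, in `individuals` order.
#' @export
simulate_tag_sets <- function(individuals, reference, truth, config,
                              digest_cfg = digest_config()) {
  cache <- new.env(parent = emptyenv())
  cache$keys <- character(0)
  cache$vals <- list()
  site_chrom <- truth$sites$chrom
  digest_hap <- function(chrom, alleles) {
    on_chrom <- site_chrom == chrom
    key <- paste0(chrom, ":", paste(which(alleles[on_chrom] == 1L), collapse = "-"))
    idx <- match(key, cache$keys)
    if (is.na(idx)) {
      got <- digest(haplotype_scaffold(reference, truth, alleles, chrom),
                    digest_cfg)
      cache$keys <- c(cache$keys, key)
      cache$vals[[length(cache$keys)]] <- got
      got
    } else cache$vals[[idx]]
  }
  with_seed(stage_seed(config$seed, 4L), {
    lapply(individuals, function(ind) {
      tags <- unlist(lapply(names(reference), function(chrom) {
        c(digest_hap(chrom, ind$alleles[, 1]),
          digest_hap(chrom, ind$alleles[, 2]))
      }), use.names = FALSE)
      tags <- unique(tags)
      if (config$tag_dropout_rate > 0 && length(tags)) {
        keep <- stats::runif(length(tags)) >= config$tag_dropout_rate
        tags <- tags[keep]
      }
      tag_set(tags, individual_id = ind$id, sex_label = ind$phenotypic_sex)
    })
  })
}

#' Write / read the planted-site truth table
#'
#' Tab-separated, one row per planted site; round-trips through
#' [read_truth_table()].
#'
#' @param truth a `sim_truth` (or the records attribute from
#'   [simulate_pools()], whose extended table includes `fail_metric`).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
emit_truth_table <- function(truth, path) {
  utils::write.table(truth$sites, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname emit_truth_table
#' @return for `read_truth_table`, the planted-site data frame.
#' @export
read_truth_table <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE,
                    colClasses = c(chrom = "character", ref = "character",
                                   alt = "character"))
}
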