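small_cfg <- function(...) {
  sim_config(seed = 42, n_scaffolds = 3, scaffold_length = 5e4,
             n_sex_linked_snps = 5, n_sex_linked_indels = 2,
             n_autosomal_sites = 20, ...)
}

test_that("reference simulation is deterministic and plants what was asked", {
  cfg <- small_cfg()
  a <- simulate_reference(cfg)
  b <- simulate_reference(cfg)
  expect_identical(a, b)
  f1 <- withr::local_tempfile(); f2 <- withr::local_tempfile()
  write_fasta(a$reference, f1); write_fasta(b$reference, f2)
  expect_identical(readLines(f1), readLines(f2))
  expect_false(identical(a$reference,
                         simulate_reference(sim_config(seed = 43,
                                                       n_scaffolds = 3,
                                                       scaffold_length = 5e4))$reference))

  sites <- a$truth$sites
  sex <- sites[sites$is_sex_linked, ]
  expect_equal(nrow(sex), 7)   # 5 SNPs + 2 InDels
  expect_equal(sum(sex$type == "SNP"), 5)
  expect_true(all(sex$chrom == "scaffold_1"))
  # planted REF alleles match the reference sequence
  for (i in seq_len(nrow(sites))) {
    expect_equal(substring(a$reference[[sites$chrom[i]]], sites$pos[i],
                           sites$pos[i] + nchar(sites$ref[i]) - 1L),
                 sites$ref[i])
  }
})

test_that("planted positions respect end margins and pairwise spacing", {
  cfg <- sim_config(seed = 8, n_scaffolds = 2, scaffold_length = 1e5,
                    n_sex_linked_snps = 100, n_sex_linked_indels = 20,
                    n_autosomal_sites = 120)
  sim <- simulate_reference(cfg)
  sites <- sim$truth$sites
  expect_true(all(sites$pos > 500))
  expect_true(all(sites$pos < cfg$scaffold_length - 500))
  gap <- cfg$indel_size_range[2]
  for (chrom in unique(sites$chrom)) {
    p <- sort(sites$pos[sites$chrom == chrom])
    expect_true(all(diff(p) > gap))
  }
  expect_error(simulate_reference(sim_config(seed = 1, n_scaffolds = 2,
                                             scaffold_length = 2000,
                                             n_sex_linked_snps = 500)),
               "too short.*bp")
})

test_that("heterogametic individuals are heterozygous at every sex-linked site", {
  cfg <- small_cfg()
  sim <- simulate_reference(cfg)
  inds <- simulate_individuals(sim$reference, sim$truth, cfg)
  sex_rows <- sim$truth$sites$is_sex_linked
  for (ind in inds) {
    g <- ind$alleles[sex_rows, , drop = FALSE]
    if (ind$phenotypic_sex == "male") {
      expect_true(all(g[, 1] == 0L & g[, 2] == 1L))    # every male X,Y
    } else {
      expect_true(all(g == 0L))                        # every female X,X
    }
  }
  # ZZ/ZW mirror: every male homozygous, every female carries the W
  cfgz <- small_cfg(system = "ZZ_ZW")
  simz <- simulate_reference(cfgz)
  for (ind in simulate_individuals(simz$reference, simz$truth, cfgz)) {
    g <- ind$alleles[simz$truth$sites$is_sex_linked, , drop = FALSE]
    if (ind$phenotypic_sex == "male") expect_true(all(g == 0L))
    else expect_true(all(g[, 2] == 1L))
  }
  expect_error(simulate_individuals(sim$reference, sim$truth,
                                    small_cfg(n_males = 0, n_females = 0)),
               "at least one")
})

test_that("haplotype materialisation applies left-anchored variants correctly", {
  ref <- c(sc = "AAACCCGGGTTTAAACCCGGGTTT")
  sites <- data.frame(chrom = "sc", pos = c(4L, 12L),
                      ref = c("C", "TAAA"), alt = c("T", "T"),
                      type = c("SNP", "InDel"), is_sex_linked = TRUE,
                      pool_freq = NA_real_, stringsAsFactors = FALSE)
  truth <- structure(list(sites = sites), class = "sim_truth")
  # both variants applied: SNP at 4 (C->T), left-anchored deletion of AAA
  # after the T at position 12
  expect_equal(haplotype_scaffold(ref, truth, c(1L, 1L), "sc"),
               "AAATCCGGGTTTCCCGGGTTT")
  expect_equal(haplotype_scaffold(ref, truth, c(0L, 0L), "sc"), ref[["sc"]])
  expect_equal(haplotype_scaffold(ref, truth, c(0L, 1L), "sc"),
               "AAACCCGGGTTTCCCGGGTTT")
})

test_that("pooled depths and allele frequencies follow the sampling model", {
  cfg <- sim_config(seed = 12, n_scaffolds = 3, scaffold_length = 3e5,
                    n_sex_linked_snps = 500, n_sex_linked_indels = 20,
                    n_autosomal_sites = 600, depth_mean = 50,
                    seq_error_rate = 0, frac_filter_fail_sites = 0)
  sim <- simulate_reference(cfg)
  inds <- simulate_individuals(sim$reference, sim$truth, cfg)
  rec <- simulate_pools(inds, sim$truth, cfg)
  expect_equal(nrow(rec), nrow(sim$truth$sites))  # conservation

  sex <- sim$truth$sites$is_sex_linked
  f_ad <- do.call(rbind, strsplit(rec$FEMALES_AD[sex], ","))
  m_ad <- do.call(rbind, strsplit(rec$MALES_AD[sex], ","))
  # error-free female pool is homozygous reference: ALT depth exactly 0
  expect_true(all(as.integer(f_ad[, 2]) == 0))
  # male pool sits near 1:1
  m_af <- as.integer(m_ad[, 2]) / pmax(1, rec$MALES_DP[sex])
  expect_equal(mean(m_af), 0.5, tolerance = 0.02)
  # CLT check on the Poisson depth over >= 1000 sites
  dp <- c(rec$MALES_DP, rec$FEMALES_DP)
  expect_gt(length(dp), 1000)
  se <- sqrt(cfg$depth_mean / length(dp))
  expect_lt(abs(mean(dp) - cfg$depth_mean), 3 * se)
})

test_that("injected filter failures are annotated and fail the hard filter", {
  cfg <- sim_config(seed = 19, n_scaffolds = 2, scaffold_length = 2e5,
                    n_sex_linked_snps = 200, n_sex_linked_indels = 50,
                    n_autosomal_sites = 250, frac_filter_fail_sites = 0.2)
  sim <- simulate_reference(cfg)
  inds <- simulate_individuals(sim$reference, sim$truth, cfg)
  rec <- simulate_pools(inds, sim$truth, cfg)
  truth2 <- attr(rec, "truth")
  fail <- !is.na(truth2$sites$fail_metric)
  expect_equal(sum(fail), round(0.2 * nrow(truth2$sites)))
  res <- run_screen(rec, screen_config())
  reason <- res$sites$reason
  expect_true(all(startsWith(reason[fail], "hard_filter:")))
  expect_equal(sub("hard_filter:", "", reason[fail]),
               truth2$sites$fail_metric[fail])
  expect_false(any(startsWith(reason[!fail], "hard_filter:")))
})

test_that("tag sets union both haplotypes, honour dropout, and carry Y tags", {
  cfg <- sim_config(seed = 23, n_scaffolds = 2, scaffold_length = 5e4,
                    n_sex_linked_snps = 600, n_sex_linked_indels = 30,
                    n_autosomal_sites = 0, tag_dropout_rate = 0)
  sim <- simulate_reference(cfg)
  inds <- simulate_individuals(sim$reference, sim$truth, cfg)
  sets <- simulate_tag_sets(inds, sim$reference, sim$truth, cfg)
  sex <- vapply(sets, `[[`, character(1), "sex_label")

  # identical haplotypes (females, no autosomal variation): set == one digest
  ref_tags <- digest(sim$reference)
  for (s in sets[sex == "female"]) expect_setequal(s$tags, ref_tags)

  # Y-specific tags occur in every male set and no female set
  y_hap <- haplotype_scaffold(sim$reference, sim$truth,
                              inds[[1]]$alleles[, 2], "scaffold_1")
  y_tags <- setdiff(digest(y_hap), digest(sim$reference[["scaffold_1"]]))
  expect_gt(length(y_tags), 0)
  for (s in sets[sex == "male"]) expect_true(all(y_tags %in% s$tags))
  for (s in sets[sex == "female"]) expect_false(any(y_tags %in% s$tags))

  # total dropout empties every set
  cfg_drop <- sim_config(seed = 23, n_scaffolds = 2, scaffold_length = 5e4,
                         n_sex_linked_snps = 600, n_sex_linked_indels = 30,
                         n_autosomal_sites = 0, tag_dropout_rate = 1)
  sets_drop <- simulate_tag_sets(inds, sim$reference, sim$truth, cfg_drop)
  expect_true(all(lengths(lapply(sets_drop, `[[`, "tags")) == 0))
})

test_that("truth tables round-trip, including the header-only case", {
  cfg <- small_cfg()
  sim <- simulate_reference(cfg)
  f <- withr::local_tempfile(fileext = ".tsv")
  emit_truth_table(sim$truth, f)
  back <- read_truth_table(f)
  expect_equal(nrow(back), nrow(sim$truth$sites))
  expect_equal(back$pos, sim$truth$sites$pos)
  expect_equal(back$ref, sim$truth$sites$ref)
  expect_equal(back$pool_freq, sim$truth$sites$pool_freq, tolerance = 1e-12)

  empty <- simulate_reference(sim_config(seed = 1, n_scaffolds = 1,
                                         scaffold_length = 5e3,
                                         n_sex_linked_snps = 0,
                                         n_sex_linked_indels = 0,
                                         n_autosomal_sites = 0))
  emit_truth_table(empty$truth, f)
  expect_length(readLines(f), 1)   # header only
  expect_equal(nrow(read_truth_table(f)), 0)
})
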