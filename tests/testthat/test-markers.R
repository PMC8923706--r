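# A handmade marker scene: a reference scaffold with one planted 6 bp
# insertion carried by the gametolog haplotype, built once for the file.
marker_scene <- function(seed = 55, window = 500) {
  set.seed(seed)
  scaffold <- random_dna(3000)
  pos <- 1500L
  ref_allele <- substring(scaffold, pos, pos)
  alt_allele <- paste0(ref_allele, random_dna(6))
  site <- data.frame(chrom = "sc", pos = pos, ref = ref_allele,
                     alt = alt_allele, stringsAsFactors = FALSE)
  cand <- build_candidate(site, c(sc = scaffold), window = window)
  list(scaffold = scaffold, site = site, cand = cand)
}

test_that("candidate selection keeps passed InDels, largest event first", {
  rec <- make_random_vcf(300, seed = 42)
  res <- run_screen(rec, screen_config(het_tol = 0.49, hom_tol = 0.49,
                                       min_depth = 1))
  cands <- select_indel_candidates(res)
  expect_true(all(cands$vtype == "InDel"))
  sz <- abs(nchar(cands$ref) - nchar(cands$alt))
  expect_true(all(diff(sz) <= 0))
  # a screen with no passing InDels yields an empty table
  res_none <- run_screen(rec, screen_config(min_depth = 10000))
  expect_equal(nrow(select_indel_candidates(res_none)), 0)
})

test_that("clearance filtering drops candidates with a variant in the amplicon zone", {
  cands <- data.frame(chrom = c("s1", "s1", "s1"), pos = c(1000L, 5000L, 9000L))
  sites <- data.frame(chrom = c("s1", "s1", "s1", "s1", "s2"),
                      pos = c(1000L, 1300L, 5000L, 8980L, 9100L))
  clear <- filter_clear_candidates(cands, sites)
  # 1300 sits in the downstream product zone of 1000; 8980 is 20 bp
  # upstream of 9000 (inside the primer tail); a site 300 bp upstream
  # would be fine, as is anything on another scaffold
  expect_equal(clear$pos, 5000L)
  sites2 <- data.frame(chrom = "s1", pos = c(1000L, 700L))
  expect_equal(filter_clear_candidates(cands[1, , drop = FALSE],
                                       sites2)$pos, 1000L)
})

test_that("candidate construction produces consistent haplotype pairs", {
  sc <- marker_scene()
  cand <- sc$cand
  # insertion of 6 bp: haplotype lengths differ by exactly 6
  expect_equal(nchar(cand$hap_gametolog) - nchar(cand$hap_hom), 6)
  # without pool counts the reference allele is taken as fixed
  expect_equal(cand$hap_hom, cand$region_ref)
  iv <- cand$indel_interval
  expect_gt(iv[2], iv[1])
  # haplotypes agree outside the divergent interval
  expect_equal(substring(cand$hap_gametolog, 1, iv[1]),
               substring(cand$hap_hom, 1, iv[1]))
  expect_equal(substring(cand$hap_gametolog, iv[2] + 1),
               substring(cand$hap_hom, iv[1] + nchar(cand$ref) + 1))
  # reverting the applied allele restores the reference window
  expect_equal(substring(cand$hap_gametolog, 1, iv[1] + 1),
               substring(cand$region_ref, 1, iv[1] + 1))

  expect_error(build_candidate(data.frame(chrom = "sc", pos = 100,
                                          ref = "A", alt = "AT"),
                               c(sc = sc$scaffold)),
               "truncated")
  # pooled counts flip the fixed allele when the homogametic pool is ALT-fixed
  site2 <- sc$site
  site2$female_ad_ref <- 0; site2$female_ad_alt <- 50
  cand2 <- build_candidate(site2, c(sc = sc$scaffold))
  expect_false(cand2$gametolog_is_alt)
  expect_equal(nchar(cand2$hap_hom) - nchar(cand2$hap_gametolog), 6)
})

test_that("primer overlap detection matches brute-force interval intersection", {
  sc <- marker_scene()
  cand <- sc$cand
  g <- cand$hap_gametolog
  iv <- cand$indel_interval
  # primer entirely upstream of the InDel
  up <- primer_pair("up", substring(g, 101, 124), revcomp(substring(g, 401, 424)))
  expect_false(any(primer_overlaps_indel(up, cand)))
  # forward primer whose 3' end sits inside the divergent interval
  over <- primer_pair("over", substring(g, iv[2] - 23, iv[2]),
                      revcomp(substring(g, 801, 824)))
  expect_true(primer_overlaps_indel(over, cand)[["fwd"]])
  expect_false(primer_overlaps_indel(over, cand)[["rev"]])
  # a primer absent from the haplotype is non-binding, not an error
  alien <- primer_pair("alien", strrep("ACGT", 6), substring(g, 801, 824))
  expect_false(primer_overlaps_indel(alien, cand)[["fwd"]])

  set.seed(71)
  for (i in 1:50) {
    s <- sample(seq_len(nchar(g) - 24), 1)
    p <- primer_pair("r", substring(g, s, s + 23), substring(g, 1, 20))
    want <- max(s - 1, iv[1]) < min(s + 23, iv[2])  # half-open intersection
    expect_equal(unname(primer_overlaps_indel(p, cand)[["fwd"]]), want)
  }
})

test_that("in-silico PCR amplifies constructed templates inside the window", {
  set.seed(61)
  fwd <- random_dna(20)
  rev <- random_dna(20)
  template <- paste0(random_dna(50), fwd, random_dna(315), revcomp(rev),
                     random_dna(50))
  pair <- primer_pair("m", fwd, rev)
  amp <- in_silico_pcr(template, pair)
  expect_equal(nrow(amp), 1)
  expect_equal(amp$length, 20 + 315 + 20)
  expect_equal(amp$start, 50)

  # a 250 bp product is outside the 300-400 bp window
  short <- paste0(random_dna(50), fwd, random_dna(210), revcomp(rev))
  expect_equal(nrow(in_silico_pcr(short, pair)), 0)
  # no forward primer site at all
  expect_equal(nrow(in_silico_pcr(random_dna(600), pair)), 0)
  # reverse-complementing the template preserves amplicon lengths
  amp_rc <- in_silico_pcr(revcomp(template), pair)
  expect_equal(amp_rc$length, amp$length)
})

test_that("the 3' clamp blocks mismatched priming; outer mismatches are tolerated", {
  set.seed(62)
  fwd <- random_dna(22)
  rev <- random_dna(22)
  spacer <- random_dna(306)
  flip <- function(s, i) {
    sub <- substring(s, i, i)
    paste0(substring(s, 1, i - 1),
           setdiff(c("A", "C", "G", "T"), sub)[1],
           substring(s, i + 1, nchar(s)))
  }
  perfect <- paste0(random_dna(40), fwd, spacer, revcomp(rev), random_dna(40))
  pair <- primer_pair("m", fwd, rev)
  # one mismatch in the forward site, far from the 3' end
  t_outer <- paste0(random_dna(40), flip(fwd, 3), spacer, revcomp(rev),
                    random_dna(40))
  expect_equal(nrow(in_silico_pcr(t_outer, pair, max_mismatch = 0)), 0)
  expect_equal(nrow(in_silico_pcr(t_outer, pair, max_mismatch = 1)), 1)
  # the same mismatch inside the 3'-terminal 5 bases is never tolerated
  t_clamp <- paste0(random_dna(40), flip(fwd, 21), spacer, revcomp(rev),
                    random_dna(40))
  expect_equal(nrow(in_silico_pcr(t_clamp, pair, max_mismatch = 1)), 0)
  expect_equal(nrow(in_silico_pcr(perfect, pair, max_mismatch = 1)), 1)
})

test_that("designed overlap primers are allele-specific on the two haplotypes", {
  sc <- marker_scene()
  pair <- design_overlap_primers(sc$cand)
  expect_s3_class(pair, "primer_pair")
  expect_true(any(primer_overlaps_indel(pair, sc$cand)))
  on_g <- in_silico_pcr(sc$cand$hap_gametolog, pair)
  expect_equal(nrow(on_g), 1)
  expect_true(on_g$length >= 300 && on_g$length <= 400)
  expect_equal(nrow(in_silico_pcr(sc$cand$hap_hom, pair)), 0)
  # dominant band logic: gametolog carrier bands, homozygote does not
  expect_true(predict_band(c(sc$cand$hap_hom, sc$cand$hap_gametolog), pair))
  expect_false(predict_band(c(sc$cand$hap_hom, sc$cand$hap_hom), pair))
  expect_error(predict_band(character(0), pair), "no haplotype")
})

test_that("band-to-sex assignment follows the model", {
  expect_equal(assign_sex(TRUE, "XX_XY"), "male")
  expect_equal(assign_sex(FALSE, "XX_XY"), "female")
  expect_equal(assign_sex(TRUE, "ZZ_ZW"), "female")
  expect_equal(assign_sex(c(TRUE, FALSE), "ZZ_ZW"), c("female", "male"))
})

test_that("discrimination rate reproduces the published worked example with exact CI", {
  v <- discrimination_rate(n_correct = 195, n_total = 196)
  expect_equal(v$rate, 100 * 195 / 196)
  expect_equal(round(v$rate, 2), 99.49)
  expect_equal(v$ci95 / 100, brute_cp_ci(195, 196), tolerance = 1e-6)
  out <- paste(capture.output(print(v)), collapse = " ")
  expect_match(out, "99.49% \\(195/196\\)")

  expect_equal(discrimination_rate(n_correct = 10, n_total = 10)$rate, 100)
  v2 <- discrimination_rate(n_correct = 3, n_total = 4)
  expect_equal(v2$rate, 75)
  expect_equal(v2$ci95 / 100, brute_cp_ci(3, 4), tolerance = 1e-6)
  expect_error(discrimination_rate(n_total = 0), "no individuals")

  rec <- data.frame(id = c("a", "b", "c"),
                    phenotypic_sex = c("male", "male", "female"),
                    predicted_sex = c("male", "female", "female"))
  expect_equal(discrimination_rate(rec)$n_correct, 2)
})

test_that("a marker from a planted InDel separates simulated sexes perfectly", {
  cfg <- sim_config(seed = 88, n_scaffolds = 2, scaffold_length = 5e4,
                    n_sex_linked_snps = 10, n_sex_linked_indels = 6,
                    n_autosomal_sites = 30, depth_mean = 100,
                    seq_error_rate = 0, frac_filter_fail_sites = 0,
                    indel_size_range = c(4, 10))
  sim <- simulate_reference(cfg)
  inds <- simulate_individuals(sim$reference, sim$truth, cfg)
  rec <- simulate_pools(inds, sim$truth, cfg)
  res <- run_screen(rec)
  cands <- filter_clear_candidates(select_indel_candidates(res), res$sites)
  expect_gt(nrow(cands), 0)
  cand <- build_candidate(cands[1, ], sim$reference, model = "XX_XY")
  pair <- design_overlap_primers(cand)
  v <- validate_marker(inds, sim$reference, sim$truth, cand, pair)
  expect_equal(v$rate, 100)
  r <- v$records
  expect_true(all(r$band_present[r$phenotypic_sex == "male"]))
  expect_false(any(r$band_present[r$phenotypic_sex == "female"]))
})
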