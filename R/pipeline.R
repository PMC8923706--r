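# End-to-end workflow: simulate -> digest/infer system -> screen ->
# design -> validate. Any prefix is runnable via the `stages` argument, and
# with an output directory every intermediate is written in the formats of
# the io layer so later stages can be resumed from files.

#' Run the full discovery pipeline on simulated data
#'
#' Executes, in order: reference/population simulation, per-individual tag
#' digestion and sex-system inference, pooled variant simulation and the
#' sex-bias screen (with scaffold summary and truth-based scoring), and
#' InDel marker design plus in-silico validation. Every stage draws its
#' randomness from `config$seed`, so a rerun with the same config is
#' bit-identical.
#'
#' @param config a [sim_config()].
#' @param digest_cfg a [digest_config()].
#' @param screen_cfg a [screen_config()]; defaults to the configured
#'   system's model.
#' @param stages subset of `c("simulate", "tags", "screen", "markers")`;
#'   prefixes of the full pipeline are honoured.
#' @param outdir optional directory; when given, the reference FASTA, tag
#'   files, pooled VCF, truth table, and summary TSV are written there.
#' @return an object of class `pipeline_report`.
#' @export
run_pipeline <- function(config = sim_config(),
                         digest_cfg = digest_config(),
                         screen_cfg = screen_config(model = config$system),
                         stages = c("simulate", "tags", "screen", "markers"),
                         outdir = NULL) {
  stages <- match.arg(stages, several.ok = TRUE)
  report <- list(config = config)
  sim <- simulate_reference(config)
  individuals <- simulate_individuals(sim$reference, sim$truth, config)
  report$n_individuals <- length(individuals)
  report$n_planted_sites <- nrow(sim$truth$sites)
  if (!is.null(outdir)) {
    dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
    write_fasta(sim$reference, file.path(outdir, "reference.fa"))
  }
  if ("tags" %in% stages) {
    tag_sets <- simulate_tag_sets(individuals, sim$reference, sim$truth,
                                  config, digest_cfg)
    sex <- vapply(tag_sets, `[[`, character(1), "sex_label")
    report$system_call <- infer_sex_system(tag_sets[sex == "male"],
                                           tag_sets[sex == "female"])
    if (!is.null(outdir)) {
      for (ts in tag_sets)
        write_tag_file(ts, file.path(outdir, sprintf("%s_%s.tags",
                                                     ts$individual_id,
                                                     ts$sex_label)))
    }
  }
  if ("screen" %in% stages) {
    pools <- simulate_pools(individuals, sim$truth, config)
    report$screen <- run_screen(pools, screen_cfg)
    report$scaffold_summary <- scaffold_summary(report$screen)
    report$screen_score <- score_screen(report$screen,
                                        attr(pools, "truth"))
    if (!is.null(outdir)) {
      write_vcf(pools, file.path(outdir, "pools.vcf"))
      keep <- paste(pools$chrom, pools$pos) %in%
        paste(report$screen$passed$chrom, report$screen$passed$pos)
      passed_vcf <- new_vcf_records(pools[keep, , drop = FALSE],
                                    attr(pools, "samples"))
      write_vcf(passed_vcf, file.path(outdir, "passed.vcf"))
      emit_truth_table(attr(pools, "truth"),
                       file.path(outdir, "truth.tsv"))
    }
  }
  if ("markers" %in% stages && !is.null(report$screen)) {
    cands <- select_indel_candidates(report$screen)
    clear <- filter_clear_candidates(cands, report$screen$sites)
    if (nrow(clear) > 0L) {
      candidate <- build_candidate(clear[1L, ], sim$reference,
                                   model = config$system)
      pair <- try(design_overlap_primers(candidate), silent = TRUE)
      if (!inherits(pair, "try-error")) {
        report$marker <- list(candidate = candidate, pair = pair)
        report$validation <- validate_marker(individuals, sim$reference,
                                             sim$truth, candidate, pair)
      }
    }
    report$n_indel_candidates <- nrow(cands)
  }
  structure(report, class = "pipeline_report")
}

#' @export
print.pipeline_report <- function(x, ...) {
  cat("== sexmarker pipeline report ==\n")
  cat(sprintf("simulated system: %s; %d individuals; %d planted sites\n",
              x$config$system, x$n_individuals, x$n_planted_sites))
  if (!is.null(x$system_call)) print(x$system_call)
  if (!is.null(x$screen)) {
    print(x$screen)
    s <- x$scaffold_summary
    if (nrow(s))
      cat(sprintf("  top scaffold: %s (%d passed, %.1f%%)\n",
                  s$chrom[1], s$count[1], 100 * s$fraction[1]))
    sc <- x$screen_score
    cat(sprintf("  recall of planted sex-linked sites: %.3f; autosomal FPR: %.4f\n",
                sc$recall, sc$fpr))
  }
  if (!is.null(x$n_indel_candidates))
    cat(sprintf("InDel marker candidates: %d\n", x$n_indel_candidates))
  if (!is.null(x$validation)) print(x$validation)
  invisible(x)
}

#' Summarise a pipeline report as text plus a TSV table
#'
#' Deterministic flat rendering of the report's headline quantities; the
#' TSV parses back to the same key/value pairs.
#'
#' @param report a `pipeline_report`.
#' @param path optional TSV output path.
#' @return data frame `(key, value)`, invisibly when `path` is given.
#' @export
summarize_report <- function(report, path = NULL) {
  kv <- list(system_configured = report$config$system,
             seed = report$config$seed,
             n_individuals = report$n_individuals,
             n_planted_sites = report$n_planted_sites)
  if (!is.null(report$system_call)) {
    kv$system_called <- report$system_call$system
    kv$male_exclusive_tags <- report$system_call$male_exclusive_count
    kv$female_exclusive_tags <- report$system_call$female_exclusive_count
  }
  if (!is.null(report$screen)) {
    kv$sites_passed <- nrow(report$screen$passed)
    kv$screen_recall <- report$screen_score$recall
    kv$screen_fpr <- report$screen_score$fpr
    if (nrow(report$scaffold_summary))
      kv$top_scaffold <- report$scaffold_summary$chrom[1]
  }
  if (!is.null(report$n_indel_candidates))
    kv$n_indel_candidates <- report$n_indel_candidates
  if (!is.null(report$validation)) {
    kv$discrimination_rate_pct <- round(report$validation$rate, 2)
    kv$discrimination_n <- report$validation$n_total
  }
  df <- data.frame(key = names(kv),
                   value = vapply(kv, function(v) as.character(v), character(1)),
                   stringsAsFactors = FALSE)
  rownames(df) <- NULL
  if (!is.null(path)) {
    utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
    return(invisible(df))
  }
  df
}
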