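# User-facing workflows: call variants on one sample or a cohort, report
# coverage, simulate. These back the `ampcall` command-line script
# (inst/cli/ampcall.R) but are ordinary functions first.

as_panel <- function(x, primer_len_default = 20L) {
  if (inherits(x, "amplicon_panel")) return(x)
  load_panel(x, primer_len_default)
}

as_reference <- function(x) {
  if (inherits(x, "reference_seqs")) return(x)
  load_reference(x)
}

#' Call variants for one sample
#'
#' Full single-sample workflow: read alignments, form read pairs, assign
#' them to amplicons, extract pair-concordant variant observations outside
#' the primer masks, apply the calling thresholds, and write a VCF (plus an
#' optional per-amplicon depth table and a run log).
#'
#' @param alignment Path to a SAM or BAM file (one sample).
#' @param panel An `amplicon_panel` or path to a BED file.
#' @param reference A `reference_seqs` or path to a FASTA file.
#' @param out_vcf Output VCF path, or `NULL` to skip writing.
#' @param sample_id Sample name; defaults to the alignment file stem.
#' @param config A `caller_config`.
#' @param tolerance Pair-to-amplicon coordinate tolerance in bases.
#' @param primer_len_default Primer length when the BED lacks columns 5-6.
#' @param min_base_quality Minimum base quality for SNV evidence (0 = off).
#' @param out_depth Optional depth-table TSV path.
#' @param out_log Optional log file path.
#' @return Invisibly, a list with `calls`, `depths`, `stats` (pairs formed,
#'   orphans, assigned, unassigned, on-target percentage), `sample_id`.
#' @export
run_call <- function(alignment, panel, reference, out_vcf = NULL,
                     sample_id = NULL, config = caller_config(),
                     tolerance = 0L, primer_len_default = 20L,
                     min_base_quality = 0, out_depth = NULL,
                     out_log = NULL) {
  panel <- as_panel(panel, primer_len_default)
  reference <- as_reference(reference)
  check_panel_reference(panel, reference)
  if (is.null(sample_id)) {
    sample_id <- sub("\\.(sam|bam)$", "", basename(alignment),
                     ignore.case = TRUE)
  }
  reads <- read_alignments(alignment)
  pr <- collect_pairs(reads)
  pairs <- assign_to_amplicon(pr$pairs, panel, tolerance)
  evidence <- pair_evidence(reads, pairs, panel, reference,
                            min_base_quality)
  calls <- call_amplicons(evidence, panel, config)
  assigned <- data.frame(
    sample_id = rep(sample_id, sum(!is.na(pairs$amplicon_id))),
    amplicon_id = pairs$amplicon_id[!is.na(pairs$amplicon_id)],
    stringsAsFactors = FALSE)
  depths <- amplicon_depths(assigned, panel, sample_ids = sample_id)
  on_target <- if (any(reads$mapped)) on_target_fraction(reads, panel) else
    NA_real_
  stats <- list(n_records = nrow(reads), n_pairs = nrow(pairs),
                n_orphans = pr$n_orphans, n_nonprimary = pr$n_nonprimary,
                n_assigned = sum(!is.na(pairs$amplicon_id)),
                n_unassigned = sum(is.na(pairs$amplicon_id)),
                on_target_percent = on_target, n_calls = nrow(calls))
  if (!is.null(out_vcf)) write_vcf(calls, sample_id, reference, out_vcf)
  if (!is.null(out_depth)) write_depth_table(depths, out_depth)
  if (!is.null(out_log)) {
    writeLines(c(
      sprintf("ampcall %s", as.character(utils::packageVersion("ampcall"))),
      sprintf("sample: %s", sample_id),
      sprintf("alignment: %s (md5 %s)", alignment,
              unname(tools::md5sum(alignment))),
      sprintf("thresholds: min_pairs=%d min_proportion=%g hom_proportion=%g tolerance=%d",
              config$min_pairs, config$min_proportion,
              config$hom_proportion, as.integer(tolerance)),
      sprintf("records=%d pairs=%d orphans=%d nonprimary=%d assigned=%d unassigned=%d",
              stats$n_records, stats$n_pairs, stats$n_orphans,
              stats$n_nonprimary, stats$n_assigned, stats$n_unassigned),
      sprintf("on_target_percent=%s calls=%d",
              format(on_target), stats$n_calls)
    ), out_log)
  }
  invisible(list(calls = calls, depths = depths, stats = stats,
                 sample_id = sample_id))
}

#' Call variants across a cohort
#'
#' Runs [run_call()] for every sample in a manifest and pools the results.
#'
#' @param manifest Data frame with columns `sample_id` and `sam` (or
#'   `path`) naming one alignment file per sample.
#' @param panel,reference As in [run_call()].
#' @param out_dir Optional directory for per-sample VCFs
#'   (`<sample_id>.vcf`).
#' @param ... Further arguments passed to [run_call()].
#' @return List with `calls` (pooled call data frame with a `sample_id`
#'   column), `depths` (pooled depth records) and `stats` (per-sample data
#'   frame of pairing statistics).
#' @export
call_cohort <- function(manifest, panel, reference, out_dir = NULL, ...) {
  panel <- as_panel(panel)
  reference <- as_reference(reference)
  path_col <- if ("sam" %in% names(manifest)) "sam" else "path"
  fail_if(!path_col %in% names(manifest),
          "manifest needs a 'sam' or 'path' column")
  if (!is.null(out_dir)) dir.create(out_dir, recursive = TRUE,
                                    showWarnings = FALSE)
  calls_l <- vector("list", nrow(manifest))
  depths_l <- vector("list", nrow(manifest))
  stats_l <- vector("list", nrow(manifest))
  for (s in seq_len(nrow(manifest))) {
    sid <- manifest$sample_id[s]
    out_vcf <- if (!is.null(out_dir)) file.path(out_dir,
                                                paste0(sid, ".vcf")) else NULL
    res <- run_call(manifest[[path_col]][s], panel, reference,
                    out_vcf = out_vcf, sample_id = sid, ...)
    if (nrow(res$calls) > 0) res$calls$sample_id <- sid
    calls_l[[s]] <- res$calls
    depths_l[[s]] <- res$depths
    stats_l[[s]] <- data.frame(sample_id = sid,
                               res$stats[names(res$stats) != "n_records"],
                               stringsAsFactors = FALSE)
  }
  keep <- vapply(calls_l, nrow, 0L) > 0
  list(calls = if (any(keep)) do.call(rbind, calls_l[keep]) else NULL,
       depths = do.call(rbind, depths_l),
       stats = do.call(rbind, stats_l))
}

#' Cohort coverage report
#'
#' Computes pooled per-(sample, amplicon) depth records, the per-sample
#' read-level on-target percentage, and the panel uniformity summary;
#' optionally writes the depth table (TSV) and summary (JSON + text).
#'
#' @param manifest Data frame with `sample_id` and `sam`/`path` columns.
#' @param panel,reference As in [run_call()].
#' @param tolerance Pair-to-amplicon tolerance in bases.
#' @param min_depth_threshold,fold_levels Passed to [coverage_summary()].
#' @param out_prefix Optional path prefix; writes `<prefix>_depths.tsv`,
#'   `<prefix>_summary.json`, `<prefix>_summary.txt`.
#' @return List with `records`, `summary`, `on_target` (per-sample data
#'   frame).
#' @export
run_coverage <- function(manifest, panel, reference, tolerance = 0L,
                         min_depth_threshold = 10L,
                         fold_levels = c(5L, 10L, 20L, 30L),
                         out_prefix = NULL) {
  panel <- as_panel(panel)
  reference <- as_reference(reference)
  check_panel_reference(panel, reference)
  path_col <- if ("sam" %in% names(manifest)) "sam" else "path"
  assigned_l <- vector("list", nrow(manifest))
  ot <- numeric(nrow(manifest))
  for (s in seq_len(nrow(manifest))) {
    sid <- manifest$sample_id[s]
    reads <- read_alignments(manifest[[path_col]][s])
    pairs <- assign_to_amplicon(collect_pairs(reads)$pairs, panel,
                                tolerance)
    hit <- !is.na(pairs$amplicon_id)
    assigned_l[[s]] <- data.frame(sample_id = rep(sid, sum(hit)),
                                  amplicon_id = pairs$amplicon_id[hit],
                                  stringsAsFactors = FALSE)
    ot[s] <- if (any(reads$mapped)) on_target_fraction(reads, panel) else
      NA_real_
  }
  records <- amplicon_depths(do.call(rbind, assigned_l), panel,
                             sample_ids = manifest$sample_id)
  summ <- coverage_summary(records, min_depth_threshold, fold_levels,
                           on_target_percent =
                             round_half_up(mean(ot, na.rm = TRUE), 2))
  if (!is.null(out_prefix)) {
    write_depth_table(records, paste0(out_prefix, "_depths.tsv"))
    write_coverage_summary(summ, paste0(out_prefix, "_summary.json"),
                           paste0(out_prefix, "_summary.txt"))
  }
  list(records = records, summary = summ,
       on_target = data.frame(sample_id = manifest$sample_id,
                              on_target_percent = ot,
                              stringsAsFactors = FALSE))
}

#' Simulate a cohort (workflow wrapper)
#'
#' `preset = "table1"` reproduces the packaged 95-sample cohort
#' specification (see [table1_genotype_spec()]); `preset = "none"` plants
#' no variants. Explicit `config` overrides the preset.
#'
#' @param out_dir Output directory.
#' @param preset `"table1"` or `"none"`.
#' @param seed Integer seed.
#' @param config Optional `sim_config` overriding the preset entirely.
#' @param ... Overrides forwarded to [sim_config()] when building from a
#'   preset.
#' @return A `sim_run` (invisibly).
#' @export
run_simulate <- function(out_dir, preset = c("table1", "none"), seed = 1L,
                         config = NULL, ...) {
  if (is.null(config)) {
    preset <- match.arg(preset)
    spec <- if (preset == "table1") table1_genotype_spec() else NULL
    config <- sim_config(seed = seed, genotype_spec = spec, ...)
  }
  simulate_cohort(config, out_dir)
}
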