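# Per-amplicon read-pair depth, on-target rate, and panel uniformity
# statistics. "Coverage" here counts read PAIRS per amplicon: in this
# chemistry one sequenced fragment is one observation, read twice.

#' Per-(sample, amplicon) read-pair depth records
#'
#' Every (sample, amplicon) combination is present, zero-filled where no
#' pairs were assigned, so a 60-amplicon panel over 95 samples always yields
#' exactly 5,700 records.
#'
#' @param assigned Data frame with columns `sample_id` and `amplicon_id`,
#'   one row per assigned read pair (rows with `NA` amplicon are ignored).
#' @param panel An `amplicon_panel`.
#' @param sample_ids Character vector fixing the sample set and order;
#'   defaults to the samples present in `assigned`. Supply explicitly so
#'   samples with zero assigned pairs still get records.
#' @return Data frame `sample_id`, `amplicon_id`, `pair_count`, ordered by
#'   sample then panel order.
#' @export
amplicon_depths <- function(assigned, panel, sample_ids = NULL) {
  if (is.null(sample_ids)) sample_ids <- unique(assigned$sample_id)
  fail_if(length(sample_ids) == 0, "no samples to report depths for")
  ok <- !is.na(assigned$amplicon_id)
  counts <- table(factor(assigned$sample_id[ok], levels = sample_ids),
                  factor(assigned$amplicon_id[ok], levels = panel$id))
  data.frame(
    sample_id = rep(sample_ids, each = nrow(panel)),
    amplicon_id = rep(panel$id, times = length(sample_ids)),
    pair_count = as.integer(t(counts)),
    stringsAsFactors = FALSE
  )
}

#' On-target percentage of mapped reads
#'
#' A mapped read is on target when its alignment span overlaps any panel
#' region by at least one base. This is a read-level statistic (the usual
#' input to genome-interval coverage tools); pair-level amplicon assignment
#' is the separate, stricter notion used for calling.
#'
#' @param reads Data frame from [read_alignments()].
#' @param panel An `amplicon_panel`.
#' @return Percentage in \[0, 100\] rounded to 2 decimals, or `NA` (with a
#'   warning) when there are no mapped reads.
#' @export
on_target_fraction <- function(reads, panel) {
  m <- reads$mapped & !is.na(reads$pos)
  if (!any(m)) {
    warning("no mapped reads; on-target fraction undefined")
    return(NA_real_)
  }
  gr_reads <- GenomicRanges::GRanges(
    reads$chrom[m], IRanges::IRanges(reads$pos[m], reads$end[m]))
  gr_panel <- GenomicRanges::GRanges(
    panel$chrom, IRanges::IRanges(panel$start, panel$end))
  on <- IRanges::overlapsAny(gr_reads, gr_panel)
  round_half_up(100 * sum(on) / sum(m), 2)
}

#' Panel coverage-uniformity summary
#'
#' Reports the fraction of depth records at or above a depth threshold, the
#' median depth, and for each fold level `k` the fraction of records within
#' k-fold of the median (`median/k <= depth <= median*k`). The median is
#' taken over the full pooled (sample x amplicon) record set; an even count
#' uses the mean of the central pair. Percentages are rounded half away
#' from zero to 2 decimals.
#'
#' @param records Depth records from [amplicon_depths()].
#' @param min_depth_threshold Depth threshold (default 10 pairs).
#' @param fold_levels Fold-of-median levels (default 5, 10, 20, 30).
#' @param on_target_percent Optional read-level on-target percentage to
#'   carry in the summary.
#' @return List of class `coverage_summary` with fields `n_records`,
#'   `min_depth_threshold`, `frac_at_threshold`, `median_depth`,
#'   `fold_levels`, `frac_within_fold` (named by level) and
#'   `on_target_percent`.
#' @export
coverage_summary <- function(records, min_depth_threshold = 10L,
                             fold_levels = c(5L, 10L, 20L, 30L),
                             on_target_percent = NA_real_) {
  fail_if(nrow(records) == 0, "no depth records")
  d <- records$pair_count
  n <- length(d)
  med <- stats::median(d)
  fold_levels <- sort(fold_levels)
  within <- vapply(fold_levels, function(k)
    round_half_up(100 * sum(d >= med / k & d <= med * k) / n, 2), 0)
  names(within) <- as.character(fold_levels)
  # bands are nested, so the within-fold fractions must be non-decreasing
  stopifnot(!is.unsorted(within))
  structure(list(
    n_records = n,
    min_depth_threshold = as.integer(min_depth_threshold),
    frac_at_threshold = round_half_up(100 * sum(d >= min_depth_threshold) / n, 2),
    median_depth = med,
    fold_levels = as.integer(fold_levels),
    frac_within_fold = within,
    on_target_percent = on_target_percent
  ), class = "coverage_summary")
}

#' @export
print.coverage_summary <- function(x, ...) {
  cat(sprintf("Coverage summary over %d (sample, amplicon) records\n",
              x$n_records))
  cat(sprintf("  median read-pair depth: %.1f\n", x$median_depth))
  cat(sprintf("  records at >=%dx: %.2f%%\n", x$min_depth_threshold,
              x$frac_at_threshold))
  for (k in names(x$frac_within_fold)) {
    cat(sprintf("  within %s-fold of median: %.2f%%\n", k,
                x$frac_within_fold[[k]]))
  }
  if (!is.na(x$on_target_percent)) {
    cat(sprintf("  on-target reads: %.2f%%\n", x$on_target_percent))
  }
  invisible(x)
}

#' Write a depth table as TSV
#'
#' @param records Depth records from [amplicon_depths()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_depth_table <- function(records, path) {
  utils::write.table(records, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read a depth table written by [write_depth_table()]
#'
#' @param path TSV path.
#' @return Depth record data frame.
#' @export
read_depth_table <- function(path) {
  utils::read.table(path, sep = "\t", header = TRUE,
                    colClasses = c("character", "character", "integer"),
                    stringsAsFactors = FALSE)
}

#' Write a coverage summary as JSON and optional text
#'
#' @param summary A `coverage_summary`.
#' @param json_path Output path for the machine-readable summary.
#' @param txt_path Optional output path for the human-readable rendering.
#' @return `json_path`, invisibly.
#' @export
write_coverage_summary <- function(summary, json_path, txt_path = NULL) {
  x <- unclass(summary)
  x$frac_within_fold <- as.list(x$frac_within_fold)
  jsonlite::write_json(x, json_path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  if (!is.null(txt_path)) {
    con <- file(txt_path, "w")
    sink(con); print(summary); sink()
    close(con)
  }
  invisible(json_path)
}
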