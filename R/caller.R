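# Threshold-based variant calling from pair-concordant evidence.
#
# A variant is called for an amplicon when it (i) appears in both mates of
# its supporting pairs (enforced upstream), (ii) is supported by at least
# `min_pairs` read pairs, and (iii) is present in at least `min_proportion`
# of all read pairs assigned to the amplicon. Genotype is homozygous when
# the variant-allele pair proportion reaches `hom_proportion`, otherwise
# heterozygous. All thresholds are inclusive.

#' Caller configuration
#'
#' @param min_pairs Minimum supporting read pairs (default 2).
#' @param min_proportion Minimum fraction of the amplicon's read pairs that
#'   must carry the variant (default 0.15).
#' @param hom_proportion Fraction at or above which the genotype is called
#'   homozygous (default 0.85).
#' @return List of class `caller_config`.
#' @export
caller_config <- function(min_pairs = 2L, min_proportion = 0.15,
                          hom_proportion = 0.85) {
  fail_if(min_pairs < 1, "min_pairs must be >= 1")
  fail_if(!(min_proportion > 0 && min_proportion <= hom_proportion &&
              hom_proportion <= 1),
          "need 0 < min_proportion <= hom_proportion <= 1")
  structure(list(min_pairs = as.integer(min_pairs),
                 min_proportion = min_proportion,
                 hom_proportion = hom_proportion),
            class = "caller_config")
}

empty_tally <- function() {
  data.frame(chrom = character(0), pos = integer(0), ref = character(0),
             alt = character(0), kind = character(0),
             pair_count = integer(0), total_pairs = integer(0),
             stringsAsFactors = FALSE)
}

#' Tally concordant evidence for one amplicon
#'
#' `total_pairs` is the number of read pairs assigned to the amplicon —
#' including pairs contributing no variant — and is the denominator of the
#' read-pair proportion. `pair_count` is the number of those pairs whose
#' concordant evidence contains the variant.
#'
#' @param evidence A `pair_evidence` object from [pair_evidence()].
#' @param amplicon_id Amplicon to tally.
#' @return Data frame with one row per distinct variant: `chrom`, `pos`,
#'   `ref`, `alt`, `kind`, `pair_count`, `total_pairs`.
#' @export
tally_evidence <- function(evidence, amplicon_id) {
  total <- sum(evidence$pairs$amplicon_id == amplicon_id)
  obs <- evidence$observations
  obs <- obs[obs$amplicon_id == amplicon_id, , drop = FALSE]
  if (nrow(obs) == 0) return(empty_tally())
  key <- paste(obs$chrom, obs$pos, obs$ref, obs$alt, sep = ":")
  first <- !duplicated(key)
  out <- obs[first, c("chrom", "pos", "ref", "alt", "kind"), drop = FALSE]
  out$pair_count <- as.integer(table(key)[key[first]])
  out$total_pairs <- total
  out <- out[order(out$chrom, out$pos, out$ref, out$alt), ]
  rownames(out) <- NULL
  out
}

#' Apply calling thresholds to a tally
#'
#' Emits exactly the variants with `pair_count >= min_pairs` and
#' `pair_count / total_pairs >= min_proportion`; genotype is `hom` when the
#' proportion reaches `hom_proportion`, else `het`. Proportions are also
#' reported as percentages rounded half away from zero to 2 decimals.
#'
#' @param tally Data frame from [tally_evidence()]; an `amplicon_id` column,
#'   if present, is carried through.
#' @param config A `caller_config`.
#' @return Data frame of calls sorted by (`chrom`, `pos`, `ref`, `alt`) with
#'   added `proportion`, `proportion_pct` and `genotype` columns.
#' @export
call_variants <- function(tally, config = caller_config()) {
  eps <- 1e-9   # guards binary representation of decimal thresholds
  prop <- tally$pair_count / tally$total_pairs
  keep <- tally$pair_count >= config$min_pairs &
    prop >= config$min_proportion - eps
  out <- tally[keep, , drop = FALSE]
  out$proportion <- prop[keep]
  out$proportion_pct <- round_half_up(100 * out$proportion, 2)
  out$genotype <- ifelse(out$proportion >= config$hom_proportion - eps,
                         "hom", "het")
  out <- out[order(out$chrom, out$pos, out$ref, out$alt), ]
  rownames(out) <- NULL
  out
}

#' Tally and call every amplicon in an evidence set
#'
#' Convenience wrapper: [tally_evidence()] + [call_variants()] per amplicon
#' (in panel order), then [merge_amplicon_calls()].
#'
#' @param evidence A `pair_evidence` object.
#' @param panel An `amplicon_panel`.
#' @param config A `caller_config`.
#' @return Merged call data frame (see [merge_amplicon_calls()]).
#' @export
call_amplicons <- function(evidence, panel, config = caller_config()) {
  per <- lapply(panel$id, function(a) {
    calls <- call_variants(tally_evidence(evidence, a), config)
    if (nrow(calls) > 0) calls$amplicon_id <- a
    calls
  })
  merge_amplicon_calls(do.call(rbind, per[vapply(per, nrow, 0L) > 0]), panel)
}

#' Merge per-amplicon calls
#'
#' Overlapping amplicon tiles can call the same variant twice. Identical
#' variants collapse to one record keeping the counts from the amplicon with
#' the largest `total_pairs` (ties by panel order); the full provenance list
#' is retained in an `amplicons` column.
#'
#' @param calls Data frame of calls carrying an `amplicon_id` column, or
#'   `NULL`/empty.
#' @param panel An `amplicon_panel` (defines the tie-break order).
#' @return Call data frame with unique (`chrom`, `pos`, `ref`, `alt`) rows,
#'   sorted, with an `amplicons` provenance column.
#' @export
merge_amplicon_calls <- function(calls, panel) {
  if (is.null(calls) || nrow(calls) == 0) {
    out <- cbind(empty_tally(),
                 data.frame(proportion = numeric(0),
                            proportion_pct = numeric(0),
                            genotype = character(0),
                            amplicon_id = character(0),
                            amplicons = character(0)))
    return(out)
  }
  key <- paste(calls$chrom, calls$pos, calls$ref, calls$alt, sep = ":")
  amp_rank <- match(calls$amplicon_id, panel$id)
  # winner per key: largest total_pairs, then earliest panel position
  ord <- order(key, -calls$total_pairs, amp_rank)
  calls <- calls[ord, , drop = FALSE]
  key <- key[ord]
  first <- !duplicated(key)
  out <- calls[first, , drop = FALSE]
  prov <- tapply(seq_along(key), key, function(i) {
    a <- unique(calls$amplicon_id[i])
    paste(a[order(match(a, panel$id))], collapse = ",")  # panel order
  })
  out$amplicons <- as.character(prov[key[first]])
  out <- out[order(out$chrom, out$pos, out$ref, out$alt), ]
  rownames(out) <- NULL
  out
}

#' Write calls as VCF 4.2
#'
#' One sample column; `GT` 0/1 for heterozygous and 1/1 for homozygous
#' calls; `DP` is the total read-pair count of the calling amplicon. INFO
#' carries the amplicon provenance (`AMP`), supporting pair count (`SUP`),
#' total pairs (`TOT`) and the rounded pair percentage (`PCT`). Output is
#' byte-stable for identical input (no timestamps).
#'
#' @param calls Merged call data frame from [call_amplicons()].
#' @param sample_id Sample column name.
#' @param reference A `reference_seqs` object (for contig headers).
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_vcf <- function(calls, sample_id, reference, path) {
  hdr <- c(
    "##fileformat=VCFv4.2",
    "##source=ampcall",
    sprintf("##contig=<ID=%s,length=%d>", names(reference), nchar(reference)),
    "##INFO=<ID=AMP,Number=.,Type=String,Description=\"Amplicon id(s) observing the variant\">",
    "##INFO=<ID=SUP,Number=1,Type=Integer,Description=\"Concordant read pairs supporting the variant\">",
    "##INFO=<ID=TOT,Number=1,Type=Integer,Description=\"Read pairs assigned to the calling amplicon\">",
    "##INFO=<ID=PCT,Number=1,Type=Float,Description=\"Supporting read-pair percentage\">",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Read pairs assigned to the calling amplicon\">",
    paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
          "FORMAT", sample_id, sep = "\t")
  )
  body <- character(0)
  if (!is.null(calls) && nrow(calls) > 0) {
    gt <- ifelse(calls$genotype == "hom", "1/1", "0/1")
    body <- sprintf(
      "%s\t%d\t.\t%s\t%s\t.\tPASS\tAMP=%s;SUP=%d;TOT=%d;PCT=%.2f\tGT:DP\t%s:%d",
      calls$chrom, calls$pos, calls$ref, calls$alt, calls$amplicons,
      calls$pair_count, calls$total_pairs, calls$proportion_pct,
      gt, calls$total_pairs)
  }
  writeLines(c(hdr, body), path)
  invisible(path)
}
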