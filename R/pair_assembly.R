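# Read-pair assembly: ingest alignments, bucket them into pairs, bind each
# pair to the amplicon whose fixed ends it reproduces, and expose the primer
# mask that removes primer-copied bases from evidence.

#' Read alignment records from SAM or BAM
#'
#' Returns one row per record with 1-based positions and flag bits unpacked.
#' SAM input is converted on the fly; coordinate sorting is not required.
#'
#' @param path Path to a SAM (`.sam`) or BAM file.
#' @return Data frame with columns `qname`, `flag`, `chrom`, `pos`, `end`,
#'   `cigar`, `seq`, `qual`, `mapped`, `primary`, `is_reverse`,
#'   `is_first_mate`.
#' @export
read_alignments <- function(path) {
  fail_if(!file.exists(path), "alignment file not found: %s", path)
  bam <- path
  if (tolower(tools::file_ext(path)) == "sam") {
    bam <- Rsamtools::asBam(path, tempfile(), overwrite = TRUE,
                            indexDestination = FALSE)
  }
  param <- Rsamtools::ScanBamParam(
    what = c("qname", "flag", "rname", "pos", "cigar", "seq", "qual"))
  b <- Rsamtools::scanBam(bam, param = param)[[1]]
  n <- length(b$qname)
  flag <- as.integer(b$flag)
  mapped <- bitwAnd(flag, 4L) == 0L
  cigar <- as.character(b$cigar)
  pos <- as.integer(b$pos)
  end <- rep(NA_integer_, n)
  ok <- mapped & !is.na(cigar) & !is.na(pos)
  if (any(ok)) {
    end[ok] <- pos[ok] +
      GenomicAlignments::cigarWidthAlongReferenceSpace(cigar[ok]) - 1L
  }
  data.frame(
    qname = as.character(b$qname),
    flag = flag,
    chrom = as.character(b$rname),
    pos = pos,
    end = end,
    cigar = cigar,
    seq = as.character(b$seq),
    qual = as.character(b$qual),
    mapped = mapped,
    primary = bitwAnd(flag, 0x100L) == 0L & bitwAnd(flag, 0x800L) == 0L,
    is_reverse = bitwAnd(flag, 0x10L) != 0L,
    is_first_mate = bitwAnd(flag, 0x40L) != 0L,
    stringsAsFactors = FALSE
  )
}

#' Group alignment records into read pairs
#'
#' Records are bucketed by query name. A bucket becomes a pair when it holds
#' exactly two primary mapped records on the same chromosome, one per mate;
#' every other primary mapped record (singletons, same-mate duplicates,
#' buckets of three or more) is counted as an orphan. Unmapped and
#' secondary/supplementary records are dropped up front and counted
#' separately. Input order is irrelevant.
#'
#' Fragment bounds are the outer alignment coordinates of the two mates,
#' computed over reference-consuming CIGAR operations.
#'
#' @param reads Data frame from [read_alignments()].
#' @return List with `pairs` (data frame: `qname`, `chrom`,
#'   `fragment_start`, `fragment_end`, `r1`, `r2` row indices into `reads`,
#'   `amplicon_id` all `NA` until assignment), `n_orphans`, and
#'   `n_nonprimary` counts.
#' @export
collect_pairs <- function(reads) {
  keep <- reads$mapped & reads$primary & !is.na(reads$pos)
  n_nonprimary <- sum(!keep)
  idx <- which(keep)
  if (length(idx) == 0) {
    return(list(pairs = empty_pairs(), n_orphans = 0L,
                n_nonprimary = n_nonprimary))
  }
  qn <- reads$qname[idx]
  idx <- idx[order(qn)]                  # bucket records by name
  qn <- reads$qname[idx]
  r <- rle(qn)
  bucket_size <- rep.int(r$lengths, r$lengths)
  orphans <- sum(bucket_size != 2L)
  two <- bucket_size == 2L
  i <- idx[two][c(TRUE, FALSE)]          # adjacent after sorting
  j <- idx[two][c(FALSE, TRUE)]
  ok <- reads$chrom[i] == reads$chrom[j] &
    reads$is_first_mate[i] != reads$is_first_mate[j]
  orphans <- orphans + 2L * sum(!ok)
  i <- i[ok]; j <- j[ok]
  swap <- !reads$is_first_mate[i]        # orient so r1 is the first mate
  tmp <- i[swap]; i[swap] <- j[swap]; j[swap] <- tmp
  pairs <- data.frame(
    qname = reads$qname[i], chrom = reads$chrom[i],
    fragment_start = pmin(reads$pos[i], reads$pos[j]),
    fragment_end = pmax(reads$end[i], reads$end[j]),
    r1 = i, r2 = j, amplicon_id = rep(NA_character_, length(i)),
    stringsAsFactors = FALSE)
  list(pairs = pairs, n_orphans = orphans, n_nonprimary = n_nonprimary)
}

empty_pairs <- function() {
  data.frame(qname = character(0), chrom = character(0),
             fragment_start = integer(0), fragment_end = integer(0),
             r1 = integer(0), r2 = integer(0),
             amplicon_id = character(0), stringsAsFactors = FALSE)
}

#' Assign read pairs to amplicons by fragment coordinates
#'
#' A pair matches an amplicon when both fragment bounds lie within
#' `tolerance` bases of the amplicon's bounds on the same chromosome. Among
#' several qualifiers the smallest total coordinate discrepancy wins, with
#' ties broken by panel order. Multiplexed PCR amplicons have fixed ends, so
#' the default tolerance is 0 (exact matching); a positive tolerance
#' accommodates noisier alignments. Pairs matching nothing keep
#' `amplicon_id = NA`: they are off-target for calling but still count in
#' read-level on-target statistics.
#'
#' @param pairs Pair data frame from [collect_pairs()].
#' @param panel An `amplicon_panel`.
#' @param tolerance Maximum per-end discrepancy in bases (default 0).
#' @return `pairs` with `amplicon_id` filled in where a match exists.
#' @export
assign_to_amplicon <- function(pairs, panel, tolerance = 0L) {
  if (nrow(pairs) == 0) return(pairs)
  if (tolerance == 0) {
    key_p <- paste(pairs$chrom, pairs$fragment_start, pairs$fragment_end)
    key_a <- paste(panel$chrom, panel$start, panel$end)
    hit <- match(key_p, key_a)           # first panel row on exact tie
    pairs$amplicon_id <- panel$id[hit]
    return(pairs)
  }
  for (k in seq_len(nrow(pairs))) {
    ds <- abs(panel$start - pairs$fragment_start[k])
    de <- abs(panel$end - pairs$fragment_end[k])
    cand <- which(panel$chrom == pairs$chrom[k] &
                    ds <= tolerance & de <= tolerance)
    if (length(cand) == 0) next
    pairs$amplicon_id[k] <- panel$id[cand[which.min(ds[cand] + de[cand])]]
  }
  pairs
}

#' Primer masks for a panel
#'
#' For each amplicon, the reference positions covered by its forward primer
#' (first `fwd_primer_len` bases of the fragment) and reverse primer (last
#' `rev_primer_len` bases). Read bases aligned to these positions copy the
#' primer oligonucleotide rather than the template, so they are excluded
#' from variant evidence and concordance decisions; the read records
#' themselves are left intact so coverage accounting still sees full pairs.
#'
#' @param panel An `amplicon_panel`.
#' @return Named list (by amplicon id) of sorted integer position vectors.
#' @export
mask_primers <- function(panel) {
  masks <- lapply(seq_len(nrow(panel)), function(k)
    sort(primer_mask_positions(panel[k, ])))
  names(masks) <- panel$id
  masks
}
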