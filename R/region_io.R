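# Amplicon panel (BED) and reference (FASTA) input.
#
# All coordinates inside the package are 1-based inclusive (the VCF
# convention); BED's 0-based half-open coordinates are converted at this
# boundary and nowhere else.

#' Construct an amplicon panel
#'
#' An amplicon panel is a data frame with one row per targeted region and
#' columns `id`, `chrom`, `start`, `end` (1-based inclusive span of the full
#' amplified fragment, primers included), `fwd_primer_len` and
#' `rev_primer_len`. Row order is the panel order and is the tie-break used
#' when a read pair matches several amplicons equally well.
#'
#' @param id Character vector of unique amplicon labels.
#' @param chrom Character vector of sequence names.
#' @param start,end Integer vectors, 1-based inclusive fragment bounds.
#' @param fwd_primer_len,rev_primer_len Non-negative primer lengths in bases.
#' @return A data frame of class `amplicon_panel`.
#' @export
amplicon_panel <- function(id, chrom, start, end,
                           fwd_primer_len = 20L, rev_primer_len = 20L) {
  p <- data.frame(
    id = as.character(id), chrom = as.character(chrom),
    start = as.integer(start), end = as.integer(end),
    fwd_primer_len = as.integer(rep_len(fwd_primer_len, length(id))),
    rev_primer_len = as.integer(rep_len(rev_primer_len, length(id))),
    stringsAsFactors = FALSE
  )
  validate_panel(p)
  class(p) <- c("amplicon_panel", "data.frame")
  p
}

validate_panel <- function(p) {
  fail_if(nrow(p) < 1, "panel must contain at least one amplicon")
  fail_if(anyDuplicated(p$id) > 0, "duplicate amplicon ids: %s",
          paste(unique(p$id[duplicated(p$id)]), collapse = ", "))
  bad <- which(p$start > p$end)
  fail_if(length(bad) > 0, "amplicon '%s': start > end", p$id[bad[1]])
  fail_if(any(p$fwd_primer_len < 0 | p$rev_primer_len < 0),
          "primer lengths must be non-negative")
  too_long <- which(p$fwd_primer_len + p$rev_primer_len >= p$end - p$start + 1)
  fail_if(length(too_long) > 0,
          "amplicon '%s': primers leave no insert (fwd+rev >= length)",
          p$id[too_long[1]])
  invisible(p)
}

#' Load an amplicon panel from a BED file
#'
#' Accepts BED3 and upward: `chrom`, `start`, `end` (0-based half-open),
#' optional column 4 `name`, and optional numeric columns 5 and 6 which are
#' read as forward and reverse primer lengths. Missing names are
#' auto-assigned `amplicon_<k>` in file order; missing primer columns fall
#' back to `primer_len_default` per side (default 20, the fixed per-end trim
#' used when mapping this library type).
#'
#' @param bed_path Path to a BED file.
#' @param primer_len_default Primer length used when columns 5-6 are absent.
#' @return An `amplicon_panel`.
#' @export
load_panel <- function(bed_path, primer_len_default = 20L) {
  fail_if(!file.exists(bed_path), "BED file not found: %s", bed_path)
  lines <- readLines(bed_path)
  lines <- lines[!grepl("^(#|track|browser)", lines) & nzchar(trimws(lines))]
  fail_if(length(lines) == 0, "BED file is empty: %s", bed_path)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  n <- length(fields)
  id <- chrom <- character(n)
  start <- end <- fwd <- rev <- integer(n)
  for (k in seq_len(n)) {
    f <- fields[[k]]
    fail_if(length(f) < 3, "BED line %d: fewer than 3 columns", k)
    s0 <- suppressWarnings(as.integer(f[2]))
    e0 <- suppressWarnings(as.integer(f[3]))
    fail_if(is.na(s0) || is.na(e0),
            "BED line %d: non-numeric start/end", k)
    fail_if(s0 >= e0, "BED line %d: start >= end", k)
    chrom[k] <- f[1]
    start[k] <- s0 + 1L   # 0-based half-open -> 1-based inclusive
    end[k] <- e0
    id[k] <- if (length(f) >= 4 && nzchar(f[4])) f[4] else
      sprintf("amplicon_%d", k)
    fp <- if (length(f) >= 5) suppressWarnings(as.integer(f[5])) else NA
    rp <- if (length(f) >= 6) suppressWarnings(as.integer(f[6])) else NA
    fwd[k] <- if (!is.na(fp)) fp else as.integer(primer_len_default)
    rev[k] <- if (!is.na(rp)) rp else as.integer(primer_len_default)
  }
  amplicon_panel(id, chrom, start, end, fwd, rev)
}

#' Write an amplicon panel to BED
#'
#' Inverse of [load_panel()]: emits BED6-style lines whose columns 5 and 6
#' hold the forward and reverse primer lengths, converting back to 0-based
#' half-open coordinates.
#'
#' @param panel An `amplicon_panel`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_panel_bed <- function(panel, path) {
  lines <- sprintf("%s\t%d\t%d\t%s\t%d\t%d",
                   panel$chrom, panel$start - 1L, panel$end, panel$id,
                   panel$fwd_primer_len, panel$rev_primer_len)
  writeLines(lines, path)
  invisible(path)
}

#' Load a reference from FASTA
#'
#' Sequences are upper-cased and stored as a named character vector keyed by
#' the first whitespace-delimited token of each header. Only A/C/G/T/N are
#' accepted after upper-casing.
#'
#' @param fasta_path Path to a (possibly multi-sequence) FASTA file.
#' @return Named character vector of class `reference_seqs`.
#' @export
load_reference <- function(fasta_path) {
  fail_if(!file.exists(fasta_path), "FASTA file not found: %s", fasta_path)
  ss <- Biostrings::readDNAStringSet(fasta_path)
  fail_if(length(ss) == 0, "FASTA file contains no sequences: %s", fasta_path)
  seqs <- toupper(as.character(ss))
  names(seqs) <- sub("\\s.*$", "", names(ss))
  bad <- grepl("[^ACGTN]", seqs)
  fail_if(any(bad), "reference sequence '%s' contains non-ACGTN characters",
          names(seqs)[bad][1])
  class(seqs) <- "reference_seqs"
  seqs
}

#' Check that a panel is contained in a reference
#'
#' Every amplicon's chromosome must resolve to a reference sequence long
#' enough to contain its full span.
#'
#' @param panel An `amplicon_panel`.
#' @param reference A `reference_seqs` object (named character vector).
#' @return `TRUE`, invisibly; errors otherwise.
#' @export
check_panel_reference <- function(panel, reference) {
  missing <- setdiff(unique(panel$chrom), names(reference))
  fail_if(length(missing) > 0,
          "panel chromosome(s) absent from reference: %s",
          paste(missing, collapse = ", "))
  len <- nchar(reference)[match(panel$chrom, names(reference))]
  over <- which(panel$end > len)
  fail_if(length(over) > 0,
          "amplicon '%s' extends beyond the end of %s",
          panel$id[over[1]], panel$chrom[over[1]])
  invisible(TRUE)
}

# Reference positions masked as primer-derived for one amplicon (row of a
# panel): the first fwd_primer_len and last rev_primer_len bases of the
# fragment. Bases there copy the primer oligo, not the template, so they
# never contribute variant evidence.
primer_mask_positions <- function(amp) {
  fwd <- if (amp$fwd_primer_len > 0)
    seq.int(amp$start, amp$start + amp$fwd_primer_len - 1L) else integer(0)
  rev <- if (amp$rev_primer_len > 0)
    seq.int(amp$end - amp$rev_primer_len + 1L, amp$end) else integer(0)
  c(fwd, rev)
}

#' Unmasked insert bounds of an amplicon
#'
#' @param amp One-row slice of an `amplicon_panel`.
#' @return Integer vector `c(start, end)` of the primer-free insert.
#' @export
insert_bounds <- function(amp) {
  c(amp$start + amp$fwd_primer_len, amp$end - amp$rev_primer_len)
}
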