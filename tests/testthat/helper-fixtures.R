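# Shared fixture builders and independent oracles. Everything is built in
# code at test time; no binary fixtures.

tiny_reference <- function(...) {
  seqs <- c(...)
  class(seqs) <- "reference_seqs"
  seqs
}

write_tmp_fasta <- function(seqs, path = tempfile(fileext = ".fa")) {
  con <- file(path, "w")
  for (nm in names(seqs)) writeLines(c(paste0(">", nm), seqs[[nm]]), con)
  close(con)
  path
}

write_tmp_bed <- function(lines, path = tempfile(fileext = ".bed")) {
  writeLines(lines, path)
  path
}

# Minimal SAM writer for handcrafted alignment fixtures. `records` is a
# data frame with qname, flag, chrom, pos, cigar, seq (qual defaults to
# all-'I').
write_tmp_sam <- function(records, reference,
                          path = tempfile(fileext = ".sam")) {
  hdr <- c("@HD\tVN:1.6\tSO:unknown",
           sprintf("@SQ\tSN:%s\tLN:%d", names(reference), nchar(reference)))
  body <- character(0)
  if (nrow(records) > 0) {
    qual <- if ("qual" %in% names(records)) records$qual else
      strrep("I", nchar(records$seq))
    body <- sprintf("%s\t%d\t%s\t%d\t60\t%s\t=\t%d\t0\t%s\t%s",
                    records$qname, records$flag, records$chrom,
                    records$pos, records$cigar, records$pos,
                    records$seq, qual)
  }
  writeLines(c(hdr, body), path)
  path
}

# A mate pair fully spanning [pos, pos+width-1]: both records share pos and
# cigar (reference orientation), as fully overlapping amplicon reads do.
sam_pair <- function(qname, chrom, pos, cigar, seq1, seq2 = seq1) {
  data.frame(qname = qname, flag = c(99L, 147L), chrom = chrom, pos = pos,
             cigar = cigar, seq = c(seq1, seq2), stringsAsFactors = FALSE)
}

# One-row read data frame shaped like read_alignments() output, for direct
# extract_read_variants() calls.
make_read <- function(chrom, pos, cigar, seq,
                      qual = strrep("I", nchar(seq))) {
  data.frame(qname = "r", flag = 0L, chrom = chrom, pos = pos,
             end = pos + GenomicAlignments::cigarWidthAlongReferenceSpace(cigar) - 1L,
             cigar = cigar, seq = seq, qual = qual, mapped = TRUE,
             primary = TRUE, is_reverse = FALSE, is_first_mate = TRUE,
             stringsAsFactors = FALSE)
}

# Independent oracle: apply a set of anchored observations to the reference
# and rebuild the haplotype over [start, end]. Used for the reconstruction
# round-trip; deliberately a different algorithm from the CIGAR walk.
apply_observations <- function(refseq, start, end, obs) {
  hap <- substr(refseq, start, end)
  if (nrow(obs) == 0) return(hap)
  obs <- obs[order(-obs$pos), , drop = FALSE]   # right-to-left: offsets stay valid
  for (k in seq_len(nrow(obs))) {
    rel <- obs$pos[k] - start + 1L
    nref <- nchar(obs$ref[k])
    hap <- paste0(substr(hap, 1, rel - 1L), obs$alt[k],
                  substr(hap, rel + nref, nchar(hap)))
  }
  hap
}

# Independent rule evaluator for the calling thresholds, in exact integer
# arithmetic: called iff support >= 2 pairs and >= 15% of pairs; homozygous
# iff >= 85% of pairs.
brute_force_rule <- function(pair_count, total_pairs) {
  if (pair_count < 2 || 100 * pair_count < 15 * total_pairs) return("none")
  if (100 * pair_count >= 85 * total_pairs) "hom" else "het"
}

# Construct a pair_evidence object directly: `amp_of_pair` is a character
# vector (one amplicon id per pair), `obs` a data frame with pair, chrom,
# pos, ref, alt, kind.
make_evidence <- function(amp_of_pair, obs = NULL) {
  pairs <- data.frame(pair = seq_along(amp_of_pair),
                      amplicon_id = amp_of_pair, stringsAsFactors = FALSE)
  if (is.null(obs)) {
    obs <- data.frame(pair = integer(0), amplicon_id = character(0),
                      chrom = character(0), pos = integer(0),
                      ref = character(0), alt = character(0),
                      kind = character(0), stringsAsFactors = FALSE)
  } else {
    obs$amplicon_id <- amp_of_pair[obs$pair]
    if (!"kind" %in% names(obs)) obs$kind <- "SNV"
    obs <- obs[, c("pair", "amplicon_id", "chrom", "pos", "ref", "alt",
                   "kind")]
  }
  structure(list(pairs = pairs, observations = obs),
            class = "pair_evidence")
}

random_dna <- function(n) paste(sample(c("A", "C", "G", "T"), n,
                                       replace = TRUE), collapse = "")
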