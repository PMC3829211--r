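# Variant extraction: walk each mate's alignment against the reference,
# normalize what it sees, and keep only observations the two mates agree on.
#
# Observations use VCF-style anchored alleles: an SNV is (pos, ref, alt)
# with single bases; an insertion is anchored at the reference base before
# the inserted sequence (ref = anchor, alt = anchor + inserted); a deletion
# likewise (ref = anchor + deleted, alt = anchor). Indels are left-aligned
# so that a given physical edit has exactly one representation.

variant_key <- function(v) paste(v$chrom, v$pos, v$ref, v$alt, sep = ":")

empty_observations <- function() {
  data.frame(chrom = character(0), pos = integer(0), ref = character(0),
             alt = character(0), kind = character(0), stringsAsFactors = FALSE)
}

#' Left-normalize an anchored indel
#'
#' Slides an anchored insertion or deletion left along the reference while
#' an equivalent representation with a smaller anchor position exists. SNVs
#' are returned unchanged. The operation is idempotent.
#'
#' @param chrom Sequence name.
#' @param pos 1-based anchor position.
#' @param ref,alt Anchored allele strings.
#' @param reference A `reference_seqs` object.
#' @return List with elements `pos`, `ref`, `alt`.
#' @export
left_normalize <- function(chrom, pos, ref, alt, reference) {
  refseq <- reference[[chrom]]
  nr <- nchar(ref); na <- nchar(alt)
  if (nr == na) return(list(pos = pos, ref = ref, alt = alt))
  if (nr < na) {                                   # insertion: alt = ref + S
    s <- substring(alt, 2)
    n <- nchar(s)
    while (pos > 1 && substr(s, n, n) == substr(refseq, pos, pos)) {
      s <- paste0(substr(refseq, pos, pos), substr(s, 1, n - 1))
      pos <- pos - 1L
    }
    anchor <- substr(refseq, pos, pos)
    return(list(pos = pos, ref = anchor, alt = paste0(anchor, s)))
  }
  n <- nr - 1L                                     # deletion of n bases
  while (pos > 1 &&
         substr(refseq, pos + n, pos + n) == substr(refseq, pos, pos)) {
    pos <- pos - 1L
  }
  list(pos = pos,
       ref = substr(refseq, pos, pos + n),
       alt = substr(refseq, pos, pos))
}

# Core single-read walk. `ops`/`lens` are the exploded CIGAR; scalars
# otherwise. Returns a data frame of observations (possibly empty). Masked
# reference positions produce no SNVs; indels whose (normalized) footprint
# touches a masked position are dropped. Mismatches involving N on either
# side are not variants.
extract_core <- function(chrom, pos, ops, lens, seq, qual, refseq, mask,
                         min_base_quality = 0) {
  rp <- pos                       # next reference position
  qp <- 1L                        # next read position
  n_code <- 78L                   # utf8 'N'
  snv_pos <- integer(0); snv_ref <- integer(0); snv_alt <- integer(0)
  ind <- list()
  for (k in seq_along(ops)) {
    op <- ops[k]; len <- lens[k]
    if (op == "M" || op == "=" || op == "X") {
      rb <- utf8ToInt(substr(refseq, rp, rp + len - 1L))
      qb <- utf8ToInt(substr(seq, qp, qp + len - 1L))
      if (length(rb) != len || length(qb) != len) {
        stop("CIGAR extends beyond reference or read sequence", call. = FALSE)
      }
      mm <- which(rb != qb & rb != n_code & qb != n_code)
      if (length(mm) > 0) {
        gp <- rp + mm - 1L
        keep <- !(gp %in% mask)
        if (min_base_quality > 0 && any(keep)) {
          q <- utf8ToInt(substr(qual, qp, qp + len - 1L)) - 33L
          keep <- keep & q[mm] >= min_base_quality
        }
        snv_pos <- c(snv_pos, gp[keep])
        snv_ref <- c(snv_ref, rb[mm][keep])
        snv_alt <- c(snv_alt, qb[mm][keep])
      }
      rp <- rp + len; qp <- qp + len
    } else if (op == "I") {
      if (rp > pos) {             # needs a preceding aligned base to anchor
        ind[[length(ind) + 1L]] <- list(
          kind = "INS", anchor = rp - 1L,
          seq = substr(seq, qp, qp + len - 1L))
      }
      qp <- qp + len
    } else if (op == "D" || op == "N") {
      if (op == "D" && rp > pos) {
        ind[[length(ind) + 1L]] <- list(kind = "DEL", anchor = rp - 1L,
                                        len = len)
      }
      rp <- rp + len
    } else if (op == "S") {
      qp <- qp + len
    }                             # H, P consume nothing we track
  }
  if (qp - 1L != nchar(seq)) {
    stop("CIGAR and sequence length disagree", call. = FALSE)
  }
  out <- if (length(snv_pos) > 0) {
    data.frame(chrom = chrom, pos = snv_pos,
               ref = vapply(snv_ref, intToUtf8, ""),
               alt = vapply(snv_alt, intToUtf8, ""),
               kind = "SNV", stringsAsFactors = FALSE)
  } else empty_observations()
  for (iv in ind) {
    if (iv$kind == "INS") {
      if (grepl("N", iv$seq, fixed = TRUE)) next
      anchor_base <- substr(refseq, iv$anchor, iv$anchor)
      nv <- left_normalize_chr(iv$anchor, anchor_base,
                               paste0(anchor_base, iv$seq), refseq)
      touched <- c(nv$pos, nv$pos + 1L)
    } else {
      del_end <- iv$anchor + iv$len
      if (del_end > nchar(refseq)) next
      anchor_base <- substr(refseq, iv$anchor, iv$anchor)
      nv <- left_normalize_chr(iv$anchor,
                               substr(refseq, iv$anchor, del_end),
                               anchor_base, refseq)
      touched <- seq.int(nv$pos, nv$pos + nchar(nv$ref) - 1L)
    }
    if (any(touched %in% mask)) next
    out <- rbind(out, data.frame(chrom = chrom, pos = nv$pos, ref = nv$ref,
                                 alt = nv$alt, kind = iv$kind,
                                 stringsAsFactors = FALSE))
  }
  if (nrow(out) > 1) out <- out[order(out$pos, out$ref, out$alt), ]
  rownames(out) <- NULL
  out
}

# left_normalize against a bare character reference sequence
left_normalize_chr <- function(pos, ref, alt, refseq) {
  tmp <- list(x = refseq); names(tmp) <- "x"
  left_normalize("x", pos, ref, alt, tmp)
}

#' Extract variant observations from one read alignment
#'
#' Walks the CIGAR once against the reference. Mismatching aligned bases at
#' unmasked positions become SNVs; `I`/`D` operations become anchored,
#' left-normalized insertions/deletions. Soft-clipped bases never produce
#' evidence; mismatches involving `N` are ignored; indels whose footprint
#' touches a masked (primer) position are dropped.
#'
#' @param read One-row data frame from [read_alignments()].
#' @param reference A `reference_seqs` object.
#' @param mask Integer vector of masked reference positions (typically the
#'   amplicon's primer positions from [mask_primers()]).
#' @param min_base_quality Minimum Phred base quality for SNV evidence;
#'   0 (default) disables the filter — pair concordance is the error filter
#'   in this design.
#' @return Data frame with columns `chrom`, `pos`, `ref`, `alt`, `kind`.
#' @export
extract_read_variants <- function(read, reference, mask = integer(0),
                                  min_base_quality = 0) {
  fail_if(!isTRUE(read$mapped), "cannot extract variants from unmapped read")
  refseq <- reference[[read$chrom]]
  fail_if(is.null(refseq), "read chromosome '%s' absent from reference",
          read$chrom)
  ops <- GenomicAlignments::explodeCigarOps(read$cigar)[[1]]
  lens <- GenomicAlignments::explodeCigarOpLengths(read$cigar)[[1]]
  extract_core(read$chrom, read$pos, ops, lens, read$seq, read$qual,
               refseq, mask, min_base_quality)
}

#' Concordant variants of a read pair
#'
#' The evidence a pair contributes is the intersection of its two mates'
#' observation sets: both reads of the pair must report the identical
#' normalized variant. Since each mate only observes positions it covers,
#' positions covered by one mate alone can never contribute. Single-mate
#' observations — the signature of sequencing chemistry artifacts — are
#' discarded here.
#'
#' @param vars1,vars2 Observation data frames from
#'   [extract_read_variants()] for the two mates.
#' @return Observation data frame (subset of both inputs).
#' @export
concordant_pair_variants <- function(vars1, vars2) {
  if (nrow(vars1) == 0 || nrow(vars2) == 0) return(empty_observations())
  out <- vars1[variant_key(vars1) %in% variant_key(vars2), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Concordant evidence for every assigned pair
#'
#' Runs extraction on both mates of every amplicon-assigned pair (with that
#' amplicon's primer mask) and intersects the mates' observations. Pairs
#' with no concordant variant still appear in the evidence: they carry the
#' denominator of the read-pair proportion.
#'
#' @param reads Data frame from [read_alignments()].
#' @param pairs Assigned pair data frame from [assign_to_amplicon()].
#' @param panel An `amplicon_panel`.
#' @param reference A `reference_seqs` object.
#' @param min_base_quality Passed to the extraction walk.
#' @return Object of class `pair_evidence`: list with `pairs` (data frame
#'   `pair`, `amplicon_id`, one row per assigned pair) and `observations`
#'   (data frame `pair`, `amplicon_id`, `chrom`, `pos`, `ref`, `alt`,
#'   `kind`, one row per concordant observation).
#' @export
pair_evidence <- function(reads, pairs, panel, reference,
                          min_base_quality = 0) {
  masks <- mask_primers(panel)
  assigned <- which(!is.na(pairs$amplicon_id))
  obs_list <- vector("list", length(assigned))
  # hoist columns out of the data frames for the hot loop
  rd_cigar <- reads$cigar; rd_pos <- reads$pos
  rd_seq <- reads$seq; rd_qual <- reads$qual
  p_amp <- pairs$amplicon_id; p_chrom <- pairs$chrom
  p_r1 <- pairs$r1; p_r2 <- pairs$r2
  # cache exploded CIGARs: panels reuse a handful of shapes
  cig_cache <- new.env(parent = emptyenv())
  get_ops <- function(cig) {
    v <- get0(cig, envir = cig_cache)
    if (is.null(v)) {
      v <- list(ops = GenomicAlignments::explodeCigarOps(cig)[[1]],
                lens = GenomicAlignments::explodeCigarOpLengths(cig)[[1]])
      assign(cig, v, envir = cig_cache)
    }
    v
  }
  for (j in seq_along(assigned)) {
    k <- assigned[j]
    amp_id <- p_amp[k]
    mask <- masks[[amp_id]]
    refseq <- reference[[p_chrom[k]]]
    vars <- vector("list", 2)
    for (m in 1:2) {
      i <- if (m == 1) p_r1[k] else p_r2[k]
      cig <- get_ops(rd_cigar[i])
      # fast path: gapless read identical to the reference
      if (length(cig$ops) == 1 && cig$ops == "M" &&
          substr(refseq, rd_pos[i], rd_pos[i] + cig$lens - 1L) == rd_seq[i]) {
        vars[m] <- list(NULL)
        next
      }
      vars[[m]] <- extract_core(p_chrom[k], rd_pos[i], cig$ops,
                                cig$lens, rd_seq[i], rd_qual[i],
                                refseq, mask, min_base_quality)
    }
    if (is.null(vars[[1]]) || is.null(vars[[2]]) ||
        nrow(vars[[1]]) == 0 || nrow(vars[[2]]) == 0) next
    conc <- concordant_pair_variants(vars[[1]], vars[[2]])
    if (nrow(conc) > 0) {
      conc$pair <- k
      conc$amplicon_id <- amp_id
      obs_list[[j]] <- conc
    }
  }
  obs <- do.call(rbind, obs_list[!vapply(obs_list, is.null, TRUE)])
  if (is.null(obs)) {
    obs <- cbind(empty_observations(),
                 data.frame(pair = integer(0), amplicon_id = character(0)))
  }
  structure(list(
    pairs = data.frame(pair = assigned,
                       amplicon_id = pairs$amplicon_id[assigned],
                       stringsAsFactors = FALSE),
    observations = obs[, c("pair", "amplicon_id", "chrom", "pos", "ref",
                           "alt", "kind")]
  ), class = "pair_evidence")
}
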