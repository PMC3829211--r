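# Synthetic amplicon-sequencing cohorts with ground truth.
#
# The simulator emulates a highly multiplexed PCR library sequenced with
# paired-end reads that completely overlap their amplicon: both mates span
# the full fragment (forward read and reverse-complement read), so every
# template base is sequenced twice. Because fragment coordinates are known
# at generation time, the simulator writes its own correct SAM alignments
# (positions and CIGARs derived from the planted haplotype), removing any
# need for an external aligner; FASTQ and a per-sample truth VCF are
# written alongside.

#' Simulation configuration
#'
#' Defaults describe the study conditions this package is tested against: a
#' 60-amplicon panel screened across 95 samples at a mean depth of 50 read
#' pairs per amplicon with a 0.1% per-base substitution error rate, 150 bp
#' amplicons (no longer than one 150 bp read) with 20 bp primers at both
#' ends.
#'
#' @param seed Integer seed driving all randomness.
#' @param ref_length Reference length in bases.
#' @param n_amplicons Number of equal-length amplicons tiled across the
#'   reference.
#' @param amplicon_length Amplicon (= read) length in bases.
#' @param primer_len Primer length per side in bases.
#' @param n_samples Cohort size.
#' @param depth_mean Mean read pairs per amplicon.
#' @param depth_dispersion Negative-binomial dispersion of per-amplicon
#'   depth (variance = mean + dispersion * mean^2); 0 gives constant depth.
#' @param error_rate Per-base substitution error rate per read, in
#'   \[0, 0.5).
#' @param genotype_spec Data frame describing variants to plant (see
#'   [table1_genotype_spec()] for the column layout), or `NULL` for a
#'   variant-free cohort.
#' @return List of class `sim_config`.
#' @export
sim_config <- function(seed = 1L, ref_length = 12000L, n_amplicons = 60L,
                       amplicon_length = 150L, primer_len = 20L,
                       n_samples = 95L, depth_mean = 50,
                       depth_dispersion = 0.1, error_rate = 0.001,
                       genotype_spec = NULL) {
  fail_if(amplicon_length - 2 * primer_len <= 0,
          "primers leave no insert (amplicon_length <= 2 * primer_len)")
  fail_if(!(error_rate >= 0 && error_rate < 0.5),
          "error_rate must be in [0, 0.5)")
  fail_if(depth_mean < 1, "depth_mean must be >= 1")
  fail_if(depth_dispersion < 0, "depth_dispersion must be >= 0")
  fail_if(n_amplicons * amplicon_length > ref_length,
          "reference too short for %d amplicons of %d bases",
          n_amplicons, amplicon_length)
  structure(list(
    seed = as.integer(seed), ref_length = as.integer(ref_length),
    n_amplicons = as.integer(n_amplicons),
    amplicon_length = as.integer(amplicon_length),
    primer_len = as.integer(primer_len), n_samples = as.integer(n_samples),
    depth_mean = depth_mean, depth_dispersion = depth_dispersion,
    error_rate = error_rate, genotype_spec = genotype_spec
  ), class = "sim_config")
}

#' Simulate a reference sequence
#'
#' Uniform random A/C/G/T sequence of `config$ref_length` bases on a single
#' chromosome named `chrS`, reproducible from `config$seed`.
#'
#' @param config A `sim_config`.
#' @return A `reference_seqs` object with one sequence.
#' @export
simulate_reference <- function(config) {
  set.seed(config$seed)
  s <- paste(sample(c("A", "C", "G", "T"), config$ref_length,
                    replace = TRUE), collapse = "")
  ref <- c(chrS = s)
  class(ref) <- "reference_seqs"
  ref
}

#' Tile an amplicon panel across a simulated reference
#'
#' `n_amplicons` equal-length amplicons with fixed ends, evenly spaced with
#' the slack distributed as inter-amplicon gaps. Deterministic given the
#' config (no randomness).
#'
#' @param reference A `reference_seqs` object.
#' @param config A `sim_config`.
#' @return An `amplicon_panel`.
#' @export
design_panel <- function(reference, config) {
  n <- config$n_amplicons
  L <- config$amplicon_length
  chrom <- names(reference)[1]
  gap <- (nchar(reference[[chrom]]) - n * L) %/% (n + 1L)
  start <- gap + (seq_len(n) - 1L) * (L + gap) + 1L
  amplicon_panel(
    id = sprintf("amp%02d", seq_len(n)), chrom = chrom,
    start = start, end = start + L - 1L,
    fwd_primer_len = config$primer_len, rev_primer_len = config$primer_len
  )
}

#' Cohort genotype specification reproducing the reference study's carriers
#'
#' Thirteen variants over a 95-sample cohort: 11 variants carried by
#' previously characterized samples (53 heterozygous plus 3 homozygous
#' carriers, 56 calls in total) and 4 additional heterozygous calls (two of
#' them extra carriers of known variants, two of them variants of their
#' own). Rows give the variant class (SNV or single-base insertion), a host
#' amplicon, an offset into its primer-free insert, and the carrier counts
#' split into previously-known heterozygous/homozygous and additional
#' heterozygous carriers.
#'
#' @return Data frame with columns `id`, `kind`, `amplicon`, `offset`,
#'   `ins_seq`, `del_len`, `n_het`, `n_hom`, `n_het_extra`.
#' @export
table1_genotype_spec <- function() {
  data.frame(
    id = c("v196", "v3113", "v1947insA", "v2982insT", "v1010", "v1676",
           "v2014", "v2590", "v2993", "v1470", "v1572", "v3300", "v3495"),
    kind = c("SNV", "SNV", "INS", "INS", "SNV", "SNV", "SNV", "SNV", "SNV",
             "SNV", "SNV", "SNV", "SNV"),
    amplicon = c(2L, 6L, 10L, 14L, 18L, 22L, 26L, 30L, 34L, 38L, 42L, 46L,
                 50L),
    offset = c(5L, 17L, 29L, 41L, 53L, 65L, 77L, 89L, 11L, 23L, 35L, 47L,
               59L),
    ins_seq = c(NA, NA, "A", "T", NA, NA, NA, NA, NA, NA, NA, NA, NA),
    del_len = NA_integer_,
    n_het = c(2L, 4L, 1L, 1L, 5L, 13L, 8L, 0L, 7L, 0L, 3L, 8L, 1L),
    n_hom = c(0L, 0L, 0L, 0L, 0L, 1L, 1L, 0L, 0L, 0L, 0L, 1L, 0L),
    n_het_extra = c(0L, 0L, 0L, 0L, 0L, 1L, 0L, 1L, 1L, 1L, 0L, 0L, 0L),
    stringsAsFactors = FALSE
  )
}

# Resolve one genotype_spec row against panel + reference into a concrete
# left-normalized variant; errors if its footprint leaves the unmasked
# insert.
resolve_variant <- function(row, panel, reference) {
  amp <- panel[row$amplicon, ]
  ins <- insert_bounds(amp)
  refseq <- reference[[amp$chrom]]
  pos <- ins[1] + row$offset
  if (row$kind == "SNV") {
    rb <- substr(refseq, pos, pos)
    alt <- c(A = "C", C = "G", G = "T", T = "A")[[rb]]
    v <- list(pos = pos, ref = rb, alt = alt)
    touched <- pos
  } else if (row$kind == "INS") {
    anchor <- substr(refseq, pos, pos)
    v <- left_normalize(amp$chrom, pos, anchor,
                        paste0(anchor, row$ins_seq), reference)
    touched <- c(v$pos, v$pos + 1L)
  } else if (row$kind == "DEL") {
    fail_if(is.na(row$del_len) || row$del_len < 1,
            "variant '%s': DEL needs del_len >= 1", row$id)
    v <- left_normalize(amp$chrom, pos,
                        substr(refseq, pos, pos + row$del_len),
                        substr(refseq, pos, pos), reference)
    touched <- seq.int(v$pos, v$pos + nchar(v$ref) - 1L)
  } else {
    stop(sprintf("variant '%s': unknown kind '%s'", row$id, row$kind),
         call. = FALSE)
  }
  fail_if(any(touched < ins[1] | touched > ins[2]),
          "variant '%s' falls inside a primer region of %s",
          row$id, amp$id)
  data.frame(variant_id = row$id, amplicon_id = amp$id, chrom = amp$chrom,
             pos = v$pos, ref = v$ref, alt = v$alt, kind = row$kind,
             stringsAsFactors = FALSE)
}

#' Plant cohort genotypes
#'
#' Resolves each specified variant against the panel and reference, then
#' draws its carriers without replacement from the cohort (heterozygous,
#' homozygous and additional heterozygous carriers of one variant are all
#' distinct samples; carriers of different variants are drawn
#' independently).
#'
#' @param panel An `amplicon_panel`.
#' @param reference A `reference_seqs` object.
#' @param genotype_spec Data frame as in [table1_genotype_spec()], or
#'   `NULL` for no variants.
#' @param n_samples Cohort size.
#' @param seed Integer seed for carrier draws.
#' @return List of class `truth_set` with `truth` (data frame `sample_id`,
#'   `variant_id`, `amplicon_id`, `chrom`, `pos`, `ref`, `alt`, `kind`,
#'   `genotype`, `known`), `variants` (resolved variant table), `panel`,
#'   `reference`, `sample_ids`.
#' @export
plant_cohort <- function(panel, reference, genotype_spec, n_samples, seed) {
  sample_ids <- sprintf("S%03d", seq_len(n_samples))
  set.seed(seed)
  variants <- NULL
  rows <- list()
  if (!is.null(genotype_spec) && nrow(genotype_spec) > 0) {
    variants <- do.call(rbind, lapply(seq_len(nrow(genotype_spec)),
      function(k) resolve_variant(genotype_spec[k, ], panel, reference)))
    for (k in seq_len(nrow(genotype_spec))) {
      g <- genotype_spec[k, ]
      n_tot <- g$n_het + g$n_hom + g$n_het_extra
      if (n_tot == 0) next
      fail_if(n_tot > n_samples,
              "variant '%s': more carriers than samples", g$id)
      carriers <- sample.int(n_samples, n_tot)
      rows[[length(rows) + 1L]] <- data.frame(
        sample_id = sample_ids[carriers],
        variants[rep(k, n_tot), ],
        genotype = rep(c("het", "hom", "het"),
                       c(g$n_het, g$n_hom, g$n_het_extra)),
        known = rep(c(TRUE, FALSE), c(g$n_het + g$n_hom, g$n_het_extra)),
        stringsAsFactors = FALSE
      )
    }
  }
  truth <- if (length(rows) > 0) do.call(rbind, rows) else
    data.frame(sample_id = character(0), variant_id = character(0),
               amplicon_id = character(0), chrom = character(0),
               pos = integer(0), ref = character(0), alt = character(0),
               kind = character(0), genotype = character(0),
               known = logical(0), stringsAsFactors = FALSE)
  rownames(truth) <- NULL
  structure(list(truth = truth, variants = variants, panel = panel,
                 reference = reference, sample_ids = sample_ids),
            class = "truth_set")
}

# Apply a set of variants (global coordinates) to one amplicon's reference
# fragment; returns the haplotype sequence and its CIGAR. SNVs keep the
# all-match CIGAR; indels split it. Variants must not overlap.
build_haplotype <- function(frag, amp_start, vars) {
  L <- nchar(frag)
  if (is.null(vars) || nrow(vars) == 0) {
    return(list(seq = frag, cigar = paste0(L, "M")))
  }
  vars <- vars[order(vars$pos), , drop = FALSE]
  for (k in which(vars$kind == "SNV")) {
    rel <- vars$pos[k] - amp_start + 1L
    substr(frag, rel, rel) <- vars$alt[k]
  }
  ind <- vars[vars$kind != "SNV", , drop = FALSE]
  if (nrow(ind) == 0) return(list(seq = frag, cigar = paste0(L, "M")))
  pieces <- character(0); cig <- character(0); cur <- 1L
  for (k in seq_len(nrow(ind))) {
    rel <- ind$pos[k] - amp_start + 1L       # anchor, relative
    pieces <- c(pieces, substr(frag, cur, rel))
    cig <- c(cig, paste0(rel - cur + 1L, "M"))
    if (ind$kind[k] == "INS") {
      inserted <- substring(ind$alt[k], 2)
      pieces <- c(pieces, inserted)
      cig <- c(cig, paste0(nchar(inserted), "I"))
      cur <- rel + 1L
    } else {
      ndel <- nchar(ind$ref[k]) - 1L
      cig <- c(cig, paste0(ndel, "D"))
      cur <- rel + ndel + 1L
    }
  }
  if (cur <= L) {
    pieces <- c(pieces, substr(frag, cur, L))
    cig <- c(cig, paste0(L - cur + 1L, "M"))
  }
  list(seq = paste(pieces, collapse = ""), cigar = paste(cig, collapse = ""))
}

# Independent substitution errors: each base flips to one of the other
# three with probability `rate`.
add_errors <- function(seqs, rate) {
  if (rate <= 0) return(seqs)
  lens <- nchar(seqs)
  k <- stats::rbinom(length(seqs), lens, rate)
  for (i in which(k > 0)) {
    p <- sample.int(lens[i], k[i])
    for (pp in p) {
      cur <- substr(seqs[i], pp, pp)
      substr(seqs[i], pp, pp) <- sample(setdiff(c("A", "C", "G", "T"), cur),
                                        1)
    }
  }
  seqs
}

truth_vcf_lines <- function(truth_rows, sample_id, reference) {
  hdr <- c(
    "##fileformat=VCFv4.2",
    "##source=ampcall-simulator",
    sprintf("##contig=<ID=%s,length=%d>", names(reference), nchar(reference)),
    "##INFO=<ID=AMP,Number=1,Type=String,Description=\"Host amplicon\">",
    "##INFO=<ID=KNOWN,Number=0,Type=Flag,Description=\"Previously identified carrier\">",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
          "FORMAT", sample_id, sep = "\t")
  )
  if (nrow(truth_rows) == 0) return(hdr)
  truth_rows <- truth_rows[order(truth_rows$chrom, truth_rows$pos), ,
                           drop = FALSE]
  body <- sprintf("%s\t%d\t%s\t%s\t%s\t.\tPASS\tAMP=%s%s\tGT\t%s",
                  truth_rows$chrom, truth_rows$pos, truth_rows$variant_id,
                  truth_rows$ref, truth_rows$alt, truth_rows$amplicon_id,
                  ifelse(truth_rows$known, ";KNOWN", ""),
                  ifelse(truth_rows$genotype == "hom", "1/1", "0/1"))
  c(hdr, body)
}

#' Simulate fully overlapping read pairs for a cohort
#'
#' For every sample and amplicon, draws a read-pair count from a
#' negative-binomial law (constant when `depth_dispersion` is 0), assigns
#' each pair a haplotype (heterozygous carriers: fair coin between
#' reference and variant haplotype; homozygous: variant haplotype only) and
#' writes both mates spanning the full amplicon — the forward read and the
#' reverse-complement read — with independent per-base substitution errors.
#' Outputs per sample: a SAM file with correct positions and CIGARs, paired
#' FASTQ (`/1`, `/2` suffixes) and a truth VCF. The reference FASTA, panel
#' BED, pooled truth table and a sample manifest are written once per run.
#' Identical config and seed reproduce byte-identical files.
#'
#' @param truth A `truth_set` from [plant_cohort()].
#' @param config A `sim_config`.
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, a list of class `sim_run` with `manifest` (data frame
#'   `sample_id`, `sam`, `fastq1`, `fastq2`, `truth_vcf`), `truth`,
#'   `panel_bed`, `reference_fa`, `out_dir`.
#' @export
simulate_read_pairs <- function(truth, config, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  panel <- truth$panel
  reference <- truth$reference
  chrom <- panel$chrom[1]
  refseq <- reference[[chrom]]
  n_amp <- nrow(panel)

  ref_fa <- file.path(out_dir, "reference.fa")
  writeLines(c(paste0(">", names(reference)[1]), refseq), ref_fa)
  panel_bed <- file.path(out_dir, "panel.bed")
  write_panel_bed(panel, panel_bed)
  utils::write.table(truth$truth, file.path(out_dir, "truth.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  # pre-build per-amplicon haplotypes for each carrier (sample, amplicon)
  frag <- substr(rep(refseq, n_amp), panel$start, panel$end)
  sam_header <- c("@HD\tVN:1.6\tSO:unknown",
                  sprintf("@SQ\tSN:%s\tLN:%d", names(reference),
                          nchar(reference)))

  set.seed(config$seed + 1L)
  manifest <- data.frame(sample_id = truth$sample_ids,
                         sam = character(config$n_samples),
                         fastq1 = character(config$n_samples),
                         fastq2 = character(config$n_samples),
                         truth_vcf = character(config$n_samples),
                         stringsAsFactors = FALSE)
  for (s in seq_len(config$n_samples)) {
    sid <- truth$sample_ids[s]
    depth <- if (config$depth_dispersion == 0) {
      rep(as.integer(round(config$depth_mean)), n_amp)
    } else {
      stats::rnbinom(n_amp, mu = config$depth_mean,
                     size = 1 / config$depth_dispersion)
    }
    qn <- list(); ps <- list(); cg1 <- list(); sq1 <- list(); sq2 <- list()
    for (a in seq_len(n_amp)) {
      d <- depth[a]
      if (d == 0) next
      svars <- truth$truth[truth$truth$sample_id == sid &
                             truth$truth$amplicon_id == panel$id[a], ,
                           drop = FALSE]
      ref_hap <- list(seq = frag[a], cigar = paste0(nchar(frag[a]), "M"))
      if (nrow(svars) > 0) {
        alt_hap <- build_haplotype(frag[a], panel$start[a], svars)
        use_alt <- if (all(svars$genotype == "hom")) rep(TRUE, d) else
          stats::runif(d) < 0.5
      } else {
        alt_hap <- ref_hap
        use_alt <- rep(FALSE, d)
      }
      hseq <- ifelse(use_alt, alt_hap$seq, ref_hap$seq)
      hcig <- ifelse(use_alt, alt_hap$cigar, ref_hap$cigar)
      qn[[a]] <- sprintf("%s_%s_%05d", sid, panel$id[a], seq_len(d))
      ps[[a]] <- rep(panel$start[a], d)
      cg1[[a]] <- hcig
      sq1[[a]] <- add_errors(hseq, config$error_rate)
      sq2[[a]] <- add_errors(hseq, config$error_rate)
    }
    qname <- unlist(qn); pos <- unlist(ps); cigar <- unlist(cg1)
    a1 <- unlist(sq1); a2 <- unlist(sq2)
    sam_path <- file.path(out_dir, paste0(sid, ".sam"))
    fq1_path <- file.path(out_dir, paste0(sid, "_R1.fastq"))
    fq2_path <- file.path(out_dir, paste0(sid, "_R2.fastq"))
    vcf_path <- file.path(out_dir, paste0(sid, ".truth.vcf"))
    if (length(qname) > 0) {
      span <- GenomicAlignments::cigarWidthAlongReferenceSpace(cigar)
      q1 <- strrep("I", nchar(a1)); q2 <- strrep("I", nchar(a2))
      l1 <- sprintf("%s\t99\t%s\t%d\t60\t%s\t=\t%d\t%d\t%s\t%s",
                    qname, chrom, pos, cigar, pos, span, a1, q1)
      l2 <- sprintf("%s\t147\t%s\t%d\t60\t%s\t=\t%d\t%d\t%s\t%s",
                    qname, chrom, pos, cigar, pos, -span, a2, q2)
      sam <- character(2 * length(qname))
      sam[c(TRUE, FALSE)] <- l1
      sam[c(FALSE, TRUE)] <- l2
      writeLines(c(sam_header, sam), sam_path)
      writeLines(as.vector(rbind(paste0("@", qname, "/1"), a1, "+", q1)),
                 fq1_path)
      a2rc <- revcomp(a2)
      writeLines(as.vector(rbind(paste0("@", qname, "/2"), a2rc, "+", q2)),
                 fq2_path)
    } else {
      writeLines(sam_header, sam_path)
      file.create(fq1_path, fq2_path)
    }
    writeLines(truth_vcf_lines(
      truth$truth[truth$truth$sample_id == sid, , drop = FALSE],
      sid, reference), vcf_path)
    manifest$sam[s] <- sam_path
    manifest$fastq1[s] <- fq1_path
    manifest$fastq2[s] <- fq2_path
    manifest$truth_vcf[s] <- vcf_path
  }
  utils::write.table(manifest, file.path(out_dir, "manifest.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(structure(list(manifest = manifest, truth = truth,
                           panel_bed = panel_bed, reference_fa = ref_fa,
                           out_dir = out_dir),
                      class = "sim_run"))
}

#' Simulate a full cohort in one call
#'
#' Reference, panel, cohort genotypes and reads from a single config:
#' [simulate_reference()], [design_panel()], [plant_cohort()] (seeded from
#' `config$seed`), then [simulate_read_pairs()].
#'
#' @param config A `sim_config`.
#' @param out_dir Output directory.
#' @return A `sim_run` (invisibly), as from [simulate_read_pairs()].
#' @export
simulate_cohort <- function(config, out_dir) {
  reference <- simulate_reference(config)
  panel <- design_panel(reference, config)
  truth <- plant_cohort(panel, reference, config$genotype_spec,
                        config$n_samples, seed = config$seed + 2L)
  simulate_read_pairs(truth, config, out_dir)
}
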