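test_that("hand-aligned reads produce the expected observations", {
  ref <- tiny_reference(chrT = "ACGTA")
  # identical read: no observations
  expect_equal(nrow(extract_read_variants(
    make_read("chrT", 1L, "5M", "ACGTA"), ref)), 0L)
  # single mismatch at position 3
  v <- extract_read_variants(make_read("chrT", 1L, "5M", "ACTTA"), ref)
  expect_equal(v$pos, 3L)
  expect_equal(v$ref, "G")
  expect_equal(v$alt, "T")
  expect_equal(v$kind, "SNV")
  # adjacent mismatches become independent SNVs, no MNP merging
  v2 <- extract_read_variants(make_read("chrT", 1L, "5M", "ATTTA"), ref)
  expect_equal(v2$pos, c(2L, 3L))
  expect_equal(v2$kind, c("SNV", "SNV"))
})

test_that("insertions and deletions are anchored and left-normalized", {
  ref <- tiny_reference(chrT = "GCAAATG")
  # deletion of one A from the homopolymer, aligned mid-run
  v <- extract_read_variants(make_read("chrT", 1L, "3M1D3M", "GCAATG"), ref)
  expect_equal(v$kind, "DEL")
  expect_equal(v$pos, 2L)       # leftmost representation anchors at the C
  expect_equal(v$ref, "CA")
  expect_equal(v$alt, "C")
  # insertion of an A: every placement inside the run normalizes alike
  # (brute-force oracle: enumerate all placements)
  for (cut in 2:5) {
    read <- paste0(substr("GCAAATG", 1, cut), "A",
                   substr("GCAAATG", cut + 1, 7))
    cig <- sprintf("%dM1I%dM", cut, 7 - cut)
    v <- extract_read_variants(make_read("chrT", 1L, cig, read), ref)
    expect_equal(v$kind, "INS")
    expect_equal(v$pos, 2L)
    expect_equal(v$ref, "C")
    expect_equal(v$alt, "CA")
  }
})

test_that("left-normalization is idempotent on random indels", {
  set.seed(99)
  for (rep in 1:60) {
    ref <- tiny_reference(chrT = random_dna(60))
    pos <- sample(5:40, 1)
    refseq <- ref[["chrT"]]
    anchor <- substr(refseq, pos, pos)
    if (runif(1) < 0.5) {
      v <- list(pos = pos, ref = anchor,
                alt = paste0(anchor, random_dna(sample(1:4, 1))))
    } else {
      len <- sample(1:4, 1)
      v <- list(pos = pos, ref = substr(refseq, pos, pos + len),
                alt = anchor)
    }
    n1 <- left_normalize("chrT", v$pos, v$ref, v$alt, ref)
    n2 <- left_normalize("chrT", n1$pos, n1$ref, n1$alt, ref)
    expect_identical(n1, n2)
    # normalization preserves the edit: applying either representation
    # yields the same haplotype
    expect_identical(
      apply_observations(refseq, 1, 60,
                         data.frame(pos = v$pos, ref = v$ref, alt = v$alt)),
      apply_observations(refseq, 1, 60,
                         data.frame(pos = n1$pos, ref = n1$ref,
                                    alt = n1$alt)))
  }
})

test_that("masked positions and N bases never generate evidence", {
  ref <- tiny_reference(chrT = "ACGTACGTAC")
  rd <- make_read("chrT", 1L, "10M", "AGGTACGTAC")  # SNV at pos 2
  expect_equal(nrow(extract_read_variants(rd, ref, mask = 2L)), 0L)
  expect_equal(nrow(extract_read_variants(rd, ref)), 1L)
  # read N and reference N are silent
  expect_equal(nrow(extract_read_variants(
    make_read("chrT", 1L, "10M", "ANGTACGTAC"), ref)), 0L)
  refn <- tiny_reference(chrT = "ANGTACGTAC")
  expect_equal(nrow(extract_read_variants(
    make_read("chrT", 1L, "10M", "ACGTACGTAC"), refn)), 0L)
  # indel touching a masked position is dropped
  rd2 <- make_read("chrT", 2L, "3M1D5M", "CGTCGTAC")
  expect_equal(extract_read_variants(rd2, ref)$kind, "DEL")
  del_pos <- extract_read_variants(rd2, ref)$pos
  expect_equal(nrow(extract_read_variants(rd2, ref, mask = del_pos)), 0L)
})

test_that("soft clips are silent and malformed CIGARs are rejected", {
  ref <- tiny_reference(chrT = "ACGTACGTAC")
  v <- extract_read_variants(make_read("chrT", 3L, "2S6M", "TTGTACGT"), ref)
  expect_equal(nrow(v), 0L)   # clipped TT never compared to reference
  expect_error(extract_read_variants(
    make_read("chrT", 1L, "9M", "ACGTACGTAC"), ref), "disagree")
})

test_that("minimum base quality filters SNV evidence when enabled", {
  ref <- tiny_reference(chrT = "ACGTA")
  low <- make_read("chrT", 1L, "5M", "ACTTA", qual = "II#II")  # Q2 at SNV
  expect_equal(nrow(extract_read_variants(low, ref)), 1L)      # default off
  expect_equal(nrow(extract_read_variants(low, ref,
                                          min_base_quality = 10)), 0L)
})

test_that("observations reconstruct the simulated haplotype (round trip)", {
  set.seed(123)
  for (rep in 1:30) {
    ref <- tiny_reference(chrT = random_dna(120))
    refseq <- ref[["chrT"]]
    # plant 1-3 well-separated edits in the middle of the fragment
    kinds <- sample(c("SNV", "INS", "DEL"), sample(1:3, 1), replace = TRUE)
    pos <- sort(sample(seq(20, 90, by = 12), length(kinds)))
    obs <- do.call(rbind, lapply(seq_along(kinds), function(k) {
      p <- pos[k]; a <- substr(refseq, p, p)
      switch(kinds[k],
        SNV = data.frame(pos = p, ref = a,
                         alt = setdiff(c("A", "C", "G", "T"), a)[1]),
        INS = data.frame(pos = p, ref = a, alt = paste0(a, random_dna(2))),
        DEL = data.frame(pos = p, ref = substr(refseq, p, p + 2), alt = a))
    }))
    hap <- apply_observations(refseq, 11, 110, obs)
    # align the haplotype back: construct the CIGAR from the known edits
    cig <- character(0); cur <- 11L
    for (k in seq_len(nrow(obs))) {
      dl <- nchar(obs$ref[k]) - 1L; il <- nchar(obs$alt[k]) - 1L
      if (dl == 0 && il == 0) next
      cig <- c(cig, paste0(obs$pos[k] - cur + 1L, "M"),
               if (il > 0) paste0(il, "I") else paste0(dl, "D"))
      cur <- obs$pos[k] + dl + 1L
    }
    cig <- paste(c(cig, paste0(110L - cur + 1L, "M")), collapse = "")
    got <- extract_read_variants(make_read("chrT", 11L, cig, hap), ref)
    # re-applying what was extracted reproduces the haplotype exactly
    expect_identical(apply_observations(refseq, 11, 110, got), hap)
  }
})

test_that("pair concordance keeps only observations present in both mates", {
  ref <- tiny_reference(chrT = "ACGTACGTAC")
  v_both <- extract_read_variants(make_read("chrT", 1L, "10M",
                                            "AGGTACGTAC"), ref)
  v_extra <- extract_read_variants(make_read("chrT", 1L, "10M",
                                             "AGGTACTTAC"), ref)
  conc <- concordant_pair_variants(v_extra, v_both)
  expect_equal(nrow(conc), 1L)
  expect_equal(conc$pos, 2L)
  # subset property both ways
  k <- paste(conc$pos, conc$ref, conc$alt)
  expect_true(all(k %in% paste(v_both$pos, v_both$ref, v_both$alt)))
  expect_true(all(k %in% paste(v_extra$pos, v_extra$ref, v_extra$alt)))
  # single-mate observation excluded entirely
  expect_equal(nrow(concordant_pair_variants(
    v_extra, extract_read_variants(make_read("chrT", 1L, "10M",
                                             "ACGTACGTAC"), ref))), 0L)
})

test_that("pair_evidence intersects mates per pair over assigned amplicons", {
  set.seed(31)
  ref <- tiny_reference(chrT = random_dna(300))
  panel <- amplicon_panel("A1", "chrT", 51L, 200L, 20L, 20L)
  frag <- substr(ref[["chrT"]], 51, 200)
  mut <- frag
  substr(mut, 75, 75) <- setdiff(c("A", "C", "G", "T"),
                                 substr(frag, 75, 75))[1]
  # pair 1 carries the variant in both mates; pair 2 in one mate only
  recs <- rbind(sam_pair("c1", "chrT", 51L, "150M", mut, mut),
                sam_pair("c2", "chrT", 51L, "150M", mut, frag))
  reads <- read_alignments(write_tmp_sam(recs, ref))
  pairs <- assign_to_amplicon(collect_pairs(reads)$pairs, panel)
  ev <- pair_evidence(reads, pairs, panel, ref)
  expect_equal(nrow(ev$pairs), 2L)
  expect_equal(nrow(ev$observations), 1L)
  expect_equal(ev$observations$pos, 51L + 74L)
})
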