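snv_obs <- function(pair_ids, pos = 10L, ref = "A", alt = "G") {
  data.frame(pair = pair_ids, chrom = "chrT", pos = pos, ref = ref,
             alt = alt, stringsAsFactors = FALSE)
}

test_that("tallies count supporting pairs over all assigned pairs", {
  # 94 pairs on one amplicon, 35 carrying the variant
  ev <- make_evidence(rep("A1", 94), snv_obs(1:35))
  t <- tally_evidence(ev, "A1")
  expect_equal(t$pair_count, 35L)
  expect_equal(t$total_pairs, 94L)
  # pairs with empty sets still count in the denominator only
  ev2 <- make_evidence(rep("A1", 10))
  t2 <- tally_evidence(ev2, "A1")
  expect_equal(nrow(t2), 0L)
  expect_equal(sum(ev2$pairs$amplicon_id == "A1"), 10L)
  # empty evidence stream
  t3 <- tally_evidence(make_evidence(character(0)), "A1")
  expect_equal(nrow(t3), 0L)
})

test_that("random planted sets match a brute-force recount", {
  set.seed(55)
  for (rep in 1:20) {
    n_pairs <- sample(5:60, 1)
    amp <- sample(c("A1", "A2"), n_pairs, replace = TRUE)
    n_var <- sample(1:4, 1)
    obs <- do.call(rbind, lapply(seq_len(n_var), function(v) {
      carriers <- sample(n_pairs, sample(0:n_pairs, 1))
      if (length(carriers) == 0) return(NULL)
      snv_obs(carriers, pos = 10L + v)
    }))
    ev <- make_evidence(amp, obs)
    for (a in c("A1", "A2")) {
      t <- tally_evidence(ev, a)
      expect_true(all(t$total_pairs == sum(amp == a)))
      for (k in seq_len(nrow(t))) {
        # brute-force recount of supporting pairs
        sup <- sum(ev$observations$amplicon_id == a &
                     ev$observations$pos == t$pos[k])
        expect_equal(t$pair_count[k], sup)
      }
    }
  }
})

test_that("worked proportions reproduce the printed heterozygous extremes", {
  t <- data.frame(chrom = "chrT", pos = c(10L, 20L), ref = "A", alt = "G",
                  kind = "SNV", pair_count = c(35L, 513L),
                  total_pairs = c(94L, 823L), stringsAsFactors = FALSE)
  calls <- call_variants(t, caller_config())
  expect_equal(nrow(calls), 2L)
  expect_equal(calls$proportion_pct, c(37.23, 62.33))
  expect_equal(calls$genotype, c("het", "het"))
})

test_that("threshold boundaries behave as printed", {
  cfg <- caller_config()
  mk <- function(s, t) data.frame(chrom = "c", pos = 1L, ref = "A",
                                  alt = "G", kind = "SNV", pair_count = s,
                                  total_pairs = t, stringsAsFactors = FALSE)
  expect_equal(nrow(call_variants(mk(1L, 4L), cfg)), 0L)    # < 2 pairs
  expect_equal(nrow(call_variants(mk(2L, 100L), cfg)), 0L)  # 2% < 15%
  expect_equal(call_variants(mk(90L, 100L), cfg)$genotype, "hom")
  expect_equal(call_variants(mk(3L, 20L), cfg)$genotype, "het")   # 15% edge
  expect_equal(call_variants(mk(17L, 20L), cfg)$genotype, "hom")  # 85% edge
})

test_that("exhaustive sweep agrees with the brute-force rule evaluator", {
  cfg <- caller_config()
  for (total in 1:50) {
    t <- data.frame(chrom = "c", pos = seq_len(total), ref = "A", alt = "G",
                    kind = "SNV", pair_count = seq_len(total),
                    total_pairs = total, stringsAsFactors = FALSE)
    calls <- call_variants(t, cfg)
    got <- setNames(rep("none", total), seq_len(total))
    got[as.character(calls$pos)] <- calls$genotype
    want <- vapply(seq_len(total), brute_force_rule, "",
                   total_pairs = total)
    expect_identical(unname(got), want)
  }
})

test_that("raising thresholds never adds a call", {
  set.seed(77)
  for (rep in 1:20) {
    total <- sample(5:80, 1)
    t <- data.frame(chrom = "c", pos = 1:6, ref = "A", alt = "G",
                    kind = "SNV",
                    pair_count = sample.int(total, 6, replace = TRUE),
                    total_pairs = total, stringsAsFactors = FALSE)
    base <- call_variants(t, caller_config(2L, 0.15, 0.85))$pos
    stricter <- list(caller_config(3L, 0.15, 0.85),
                     caller_config(2L, 0.30, 0.85),
                     caller_config(5L, 0.40, 0.90))
    for (cfg in stricter) {
      expect_true(all(call_variants(t, cfg)$pos %in% base))
    }
  }
})

test_that("overlapping-tile calls merge to the deepest amplicon", {
  calls <- rbind(
    data.frame(chrom = "c", pos = 10L, ref = "A", alt = "G", kind = "SNV",
               pair_count = 20L, total_pairs = 40L, proportion = 0.5,
               proportion_pct = 50, genotype = "het", amplicon_id = "A1",
               stringsAsFactors = FALSE),
    data.frame(chrom = "c", pos = 10L, ref = "A", alt = "G", kind = "SNV",
               pair_count = 30L, total_pairs = 60L, proportion = 0.5,
               proportion_pct = 50, genotype = "het", amplicon_id = "A2",
               stringsAsFactors = FALSE),
    data.frame(chrom = "c", pos = 25L, ref = "C", alt = "T", kind = "SNV",
               pair_count = 12L, total_pairs = 40L, proportion = 0.3,
               proportion_pct = 30, genotype = "het", amplicon_id = "A1",
               stringsAsFactors = FALSE))
  panel <- amplicon_panel(c("A1", "A2"), "c", c(1L, 20L), c(60L, 80L),
                          5L, 5L)
  m <- merge_amplicon_calls(calls, panel)
  expect_equal(nrow(m), 2L)
  expect_equal(m$pair_count[m$pos == 10L], 30L)   # larger denominator wins
  expect_equal(m$amplicons[m$pos == 10L], "A1,A2")
  expect_equal(m$amplicons[m$pos == 25L], "A1")
  # no duplicate variant keys under randomized overlapping tiles
  set.seed(13)
  for (rep in 1:10) {
    n <- sample(4:20, 1)
    rnd <- data.frame(chrom = "c", pos = sample(1:6, n, replace = TRUE),
                      ref = "A", alt = "G", kind = "SNV",
                      pair_count = sample(2:30, n, replace = TRUE),
                      total_pairs = sample(30:60, n, replace = TRUE),
                      proportion = 0.5, proportion_pct = 50,
                      genotype = "het",
                      amplicon_id = sample(c("A1", "A2"), n, TRUE),
                      stringsAsFactors = FALSE)
    mm <- merge_amplicon_calls(rnd, panel)
    expect_false(any(duplicated(paste(mm$chrom, mm$pos, mm$ref, mm$alt))))
  }
})

test_that("VCF output round-trips through an independent parser", {
  skip_if_not_installed("vcfR")
  ref <- tiny_reference(chrT = strrep("ACGT", 50))
  calls <- data.frame(
    chrom = "chrT", pos = c(30L, 90L), ref = c("A", "C"),
    alt = c("G", "CT"), kind = c("SNV", "INS"),
    pair_count = c(35L, 90L), total_pairs = c(94L, 100L),
    proportion = c(35 / 94, 0.9), proportion_pct = c(37.23, 90),
    genotype = c("het", "hom"), amplicon_id = c("A1", "A2"),
    amplicons = c("A1", "A2"), stringsAsFactors = FALSE)
  path <- tempfile(fileext = ".vcf")
  write_vcf(calls, "S001", ref, path)
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  expect_equal(as.integer(v@fix[, "POS"]), c(30L, 90L))
  expect_equal(unname(v@fix[, "REF"]), c("A", "C"))
  expect_equal(unname(v@fix[, "ALT"]), c("G", "CT"))
  gt <- vcfR::extract.gt(v, "GT")
  expect_equal(unname(gt[, "S001"]), c("0/1", "1/1"))
  dp <- vcfR::extract.gt(v, "DP")
  expect_equal(as.integer(dp[, "S001"]), c(94L, 100L))
  expect_equal(unname(vcfR::extract.info(v, "SUP")), c("35", "90"))
  expect_equal(unname(vcfR::extract.info(v, "TOT")), c("94", "100"))
  # byte-stable on rewrite; header-only when there are no calls
  path2 <- tempfile(fileext = ".vcf")
  write_vcf(calls, "S001", ref, path2)
  expect_identical(readLines(path), readLines(path2))
  write_vcf(merge_amplicon_calls(NULL, NULL), "S001", ref, path2)
  expect_true(all(grepl("^#", readLines(path2))))
})
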