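meta100 <- sample_meta(purity = 0.8, expected_depth = 50)

test_that("single fragments classify by the split/spanning/normal rules", {
  p <- 10000
  # right-clipped read ending at the breakend, matching "+": split
  split_frag <- data.frame(pos = p - 84, cigar = "85M15S", strand = "+")
  expect_equal(classify_read(split_frag, p, "+", meta100), "SPLIT")
  # same read against a "-" breakend: wrong side, not a split
  expect_false(classify_read(split_frag, p, "-", meta100) == "SPLIT")
  # clip below the threshold: anomalous, not split
  small_clip <- data.frame(pos = p - 91, cigar = "92M8S", strand = "+")
  expect_equal(classify_read(small_clip, p, "+", meta100), "ANOMALOUS")
  # clip boundary away from the breakend: not a split
  off_locus <- data.frame(pos = p - 84 - 50, cigar = "85M15S", strand = "+")
  expect_false(classify_read(off_locus, p, "+", meta100) == "SPLIT")
  # double-clipped read over the locus: anomalous
  dbl <- data.frame(pos = p - 30, cigar = "15S70M15S", strand = "+")
  expect_equal(classify_read(dbl, p, "+", meta100), "ANOMALOUS")
  # clean pair crossing with >= 10 bp on each side: normal
  norm <- data.frame(pos = c(p - 60, p + 40), cigar = c("100M", "100M"),
                     strand = c("+", "-"))
  expect_equal(classify_read(norm, p, "+", meta100), "NORMAL")
  # mates flanking the two breakends, facing them, insert in bound: spanning
  q <- 50000
  span <- data.frame(pos = c(p - 110, q + 10), cigar = c("100M", "100M"),
                     strand = c("+", "-"))
  expect_equal(classify_read(span, p, "+", meta100,
                             partner_pos = q, partner_dir = "-"), "SPANNING")
  # same geometry but the far mate not facing its break: not spanning
  bad <- data.frame(pos = c(p - 110, q + 10), cigar = c("100M", "100M"),
                    strand = c("+", "+"))
  expect_false(classify_read(bad, p, "+", meta100,
                             partner_pos = q, partner_dir = "-") == "SPANNING")
  # fragment far away: irrelevant
  far <- data.frame(pos = p + 5000, cigar = "100M", strand = "+")
  expect_equal(classify_read(far, p, "+", meta100), "IRRELEVANT")
})

test_that("generated alignments are recovered exactly by counting", {
  bp <- breakpoints("1", 10000, "+", "1", 50000, "-")
  bam <- generate_alignments(bp, 10, 8, 5, 30, 32, 4, meta100)
  ct <- count_sv(bp, bam, meta100)
  expect_equal(unlist(ct[c("split1", "split2", "span", "norm1", "norm2",
                           "anom")], use.names = FALSE),
               c(10, 8, 5, 30, 32, 4))
  expect_equal(ct$support, 23)   # s_l + s_u + c
  expect_equal(ct$depth1, 53)
  expect_equal(ct$depth2, 55)
  expect_false(ct$high_depth)
})

test_that("the closed loop holds across classes and random count requests", {
  set.seed(101)
  dirs <- list(DEL = c("+", "-"), DUP = c("-", "+"),
               INV1 = c("+", "+"), INV2 = c("-", "-"))
  for (nm in names(dirs)) {
    req <- c(sample(0:12, 2, replace = TRUE), sample(0:6, 1),
             sample(0:30, 2, replace = TRUE), sample(0:4, 1))
    bp <- breakpoints("1", 20000, dirs[[nm]][1], "1", 70000, dirs[[nm]][2])
    bam <- generate_alignments(bp, req[1], req[2], req[3], req[4], req[5],
                               req[6], meta100)
    ct <- count_sv(bp, bam, meta100)
    expect_equal(unlist(ct[c("split1", "split2", "span", "norm1", "norm2",
                             "anom")], use.names = FALSE), req,
                 info = nm)
  }
  # inter-chromosomal translocation
  bp <- breakpoints("1", 20000, "+", "2", 30000, "-")
  bam <- generate_alignments(bp, 3, 4, 6, 12, 9, 2, meta100)
  ct <- count_sv(bp, bam, meta100)
  expect_equal(unlist(ct[c("split1", "split2", "span", "norm1", "norm2",
                           "anom")], use.names = FALSE), c(3, 4, 6, 12, 9, 2))
})

test_that("zero-read regions give all-zero counts without flags", {
  bp <- breakpoints("1", 10000, "+", "1", 50000, "-")
  bam <- generate_alignments(bp, 0, 0, 0, 0, 0, 0, meta100)
  ct <- count_sv(bp, bam, meta100)
  expect_true(all(unlist(ct[1:9]) == 0))
  expect_false(ct$high_depth)
})

test_that("mean depth above expected_depth * max_cn sets the high-depth flag", {
  bp <- breakpoints("1", 10000, "+", "1", 50000, "-")
  bam <- generate_alignments(bp, 0, 0, 0, 250, 5, 0, meta100)
  ct <- count_sv(bp, bam, meta100)   # 250 > 50 * 4
  expect_true(ct$high_depth)
})

test_that("direction-mismatched supporting reads are never counted", {
  # reads generated for a (+,-) deletion junction must not support the
  # mirrored (-,+) interpretation of the same loci
  bp <- breakpoints("1", 10000, "+", "1", 50000, "-")
  bam <- generate_alignments(bp, 12, 9, 7, 10, 10, 0, meta100)
  flipped <- breakpoints("1", 10000, "-", "1", 50000, "+")
  ct <- count_sv(flipped, bam, meta100)
  expect_equal(ct$split1 + ct$split2 + ct$span, 0)
})

test_that("DNA-gain classes get the purity/ploidy normal-read adjustment", {
  tbl <- make_var_table(b1 = c(20, 20, 25), d1 = c(70, 70, 100),
                        svclass = c("DUP", "DEL", "DUP"))
  tbl$support <- tbl$b1
  meta <- sample_meta(purity = 0.8, ploidy = 2)
  adj <- adjust_normals(tbl, meta)
  expect_equal(adj$norm1[1], 50 * (1 - 0.4))   # 30
  expect_equal(adj$norm1[2], 50)               # non-gain untouched
  expect_true(all(adj$adjusted == c(TRUE, FALSE, TRUE)))
  # purity 1, ploidy 2: b=25, o=75 -> o'=37.5, VAF = 25/62.5 = 0.4
  meta1 <- sample_meta(purity = 1, ploidy = 2)
  adj1 <- compute_vaf(adjust_normals(tbl, meta1))
  expect_equal(adj1$vaf1[3], 0.4)
  # purity 0 limit: factor 1 (approached, never reached; use tiny purity)
  meta0 <- sample_meta(purity = 1e-9, ploidy = 2)
  adj0 <- adjust_normals(tbl, meta0)
  expect_equal(adj0$norm1[1], 50, tolerance = 1e-6)
  # purity above ploidy clamps at 0 with a warning
  metac <- sample_meta(purity = 1, ploidy = 0.5)
  expect_warning(adjc <- adjust_normals(tbl, metac), "clamped")
  expect_equal(adjc$norm1[1], 0)
})

test_that("VAF is support over per-end depth, 0 without support", {
  tbl <- make_var_table(b1 = c(30, 0), d1 = c(60, 40))
  tbl$support <- tbl$b1
  out <- compute_vaf(tbl)
  expect_equal(out$vaf1, c(0.5, 0))
})

test_that("simulated heterozygous non-gain VAFs converge to purity/2", {
  for (t in c(0.2, 0.6, 1.0)) {
    cfg <- sim_config(n_sv = 120, ccf = 1, purity = t, depth = 200,
                      class_probs = c(DEL = 0.5, INV = 0.5), eps = 0)
    sim <- simulate_counts(cfg, seed = round(100 * t))
    mv <- mean(c(sim$variants$vaf1, sim$variants$vaf2))
    expect_lt(abs(mv - t / 2), 0.01)
  }
})

test_that("duplication VAFs are biased low raw and unbiased adjusted", {
  for (t in c(0.2, 0.6, 1.0)) {
    cfg <- sim_config(n_sv = 120, ccf = 1, purity = t, depth = 200,
                      class_probs = c(DUP = 1), eps = 0)
    sim <- simulate_counts(cfg, seed = round(100 * t) + 1)
    raw <- mean(c(sim$variants$vaf1_raw, sim$variants$vaf2_raw))
    adj <- mean(c(sim$variants$vaf1, sim$variants$vaf2))
    expect_lt(raw, t / 2)                       # bias sign
    expect_lt(raw, adj)                         # ordering
    expect_equal(adj, t / 2, tolerance = 0.02)  # unbiasedness
  }
})
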