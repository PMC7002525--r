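meta <- sample_meta(purity = 0.8, insert_mean = 300)

# a counted variant table row with controllable fields
count_row <- function(id = "v1", pos1 = 1e4, pos2 = 6e4, chrom2 = "1",
                      split1 = 2, split2 = 2, span = 2, norm1 = 40,
                      norm2 = 38, svclass = "DEL", dir1 = "+", dir2 = "-",
                      high_depth = FALSE) {
  support <- split1 + split2 + span
  data.frame(id = id, chrom1 = "1", pos1 = pos1, dir1 = dir1,
             chrom2 = chrom2, pos2 = pos2, dir2 = dir2, svclass = svclass,
             split1 = split1, split2 = split2, span = span,
             norm1 = norm1, norm2 = norm2, anom = 0,
             support = support, depth1 = support + norm1,
             depth2 = support + norm2, high_depth = high_depth,
             stringsAsFactors = FALSE)
}

test_that("minimum support and depth defaults keep a bare-minimum SV", {
  ok <- count_row(split1 = 1, split2 = 0, span = 1, norm1 = 38, norm2 = 36)
  res <- apply_filters(ok, NULL, meta)
  expect_equal(nrow(res$kept), 1)
  no_split <- count_row(split1 = 0, split2 = 0, span = 3)
  expect_equal(apply_filters(no_split, NULL, meta)$rejected$reason, "support")
  no_span <- count_row(span = 0)
  expect_equal(apply_filters(no_span, NULL, meta)$rejected$reason, "support")
  thin <- count_row(split1 = 1, split2 = 0, span = 1, norm1 = 0, norm2 = 0)
  expect_equal(apply_filters(thin, NULL, meta)$rejected$reason, "depth")
})

test_that("intra-chromosomal SVs at or below the fragment size are rejected", {
  small <- count_row(pos1 = 1e4, pos2 = 1e4 + 200)   # 200 <= 300
  expect_equal(apply_filters(small, NULL, meta)$rejected$reason, "size")
  edge <- count_row(pos1 = 1e4, pos2 = 1e4 + 300)    # boundary: rejected
  expect_equal(apply_filters(edge, NULL, meta)$rejected$reason, "size")
  inter <- count_row(chrom2 = "2", pos2 = 1e4 + 100, svclass = "INTRX")
  expect_equal(nrow(apply_filters(inter, NULL, meta)$kept), 1)
})

test_that("germline-supported SVs are rejected within the 6 bp window", {
  som <- count_row()
  germ_hit <- count_row(id = "g1", pos1 = 1e4 + 6, pos2 = 6e4 - 6,
                        split1 = 2, split2 = 0, span = 0)
  res <- apply_filters(som, NULL, meta, germline = germ_hit)
  expect_equal(res$rejected$reason, "germline")
  germ_far <- count_row(id = "g2", pos1 = 1e4 + 7, pos2 = 6e4)
  expect_equal(nrow(apply_filters(som, NULL, meta,
                                  germline = germ_far)$kept), 1)
  # matching loci but opposite directions do not reject
  germ_dir <- count_row(id = "g3", dir1 = "-", dir2 = "+")
  expect_equal(nrow(apply_filters(som, NULL, meta,
                                  germline = germ_dir)$kept), 1)
  # zero-support germline records never reject
  germ_zero <- count_row(id = "g4", split1 = 0, split2 = 0, span = 0)
  expect_equal(nrow(apply_filters(som, NULL, meta,
                                  germline = germ_zero)$kept), 1)
})

write_cn <- function(lines, env = parent.frame()) {
  f <- withr::local_tempfile(fileext = ".txt", .local_envir = env)
  writeLines(c(paste("chr", "startpos", "endpos", "nMaj1_A", "nMin1_A",
                     "frac1_A", "nMaj2_A", "nMin2_A", "frac2_A", sep = "\t"),
               lines), f)
  read_cn_input(f, "battenberg")
}

test_that("copy-number validity and the optional CN filters apply", {
  cn0 <- write_cn("1\t1\t900000\t0\t0\t1\tNA\tNA\tNA")
  res <- apply_filters(count_row(), cn0, meta)
  expect_equal(res$rejected$reason, "invalid_cn")
  cn21 <- write_cn("1\t1\t900000\t2\t1\t1\tNA\tNA\tNA")
  expect_equal(apply_filters(count_row(), cn21, meta,
                             filter_params(neutral_only = TRUE)
                             )$rejected$reason, "non_neutral")
  cnsub <- write_cn("1\t1\t900000\t2\t1\t0.6\t1\t1\t0.4")
  expect_equal(apply_filters(count_row(), cnsub, meta,
                             filter_params(exclude_subclonal_cn = TRUE)
                             )$rejected$reason, "subclonal_cn")
  expect_equal(nrow(apply_filters(count_row(), cnsub, meta)$kept), 1)
})

test_that("one invalid end falls back to the default annotation, flagged", {
  cn <- write_cn(c("1\t1\t30000\t0\t0\t1\tNA\tNA\tNA",
                   "1\t30000\t900000\t2\t1\t1\tNA\tNA\tNA"))
  res <- apply_filters(count_row(), cn, meta)
  expect_equal(nrow(res$kept), 1)
  expect_true(res$kept$cn_fallback)
  expect_equal(res$kept$ntot_t_1, 2)   # default, not the invalid 0+0
  expect_equal(res$kept$ntot_t_2, 3)
})

test_that("blacklist overlaps and high-depth flags reject", {
  bl <- data.frame(chrom = "1", start = 9000, end = 11000)
  res <- apply_filters(count_row(), NULL, meta,
                       filter_params(blacklist = bl))
  expect_equal(res$rejected$reason, "blacklist")
  res2 <- apply_filters(count_row(high_depth = TRUE), NULL, meta)
  expect_equal(res2$rejected$reason, "high_depth")
  res3 <- apply_filters(count_row(svclass = "COMPLEX"), NULL, meta)
  expect_equal(res3$rejected$reason, "complex")
})

test_that("kept and rejected partition the input, order-independently", {
  rows <- rbind(count_row("a"), count_row("b", split1 = 0, split2 = 0),
                count_row("c", pos2 = 1e4 + 50),
                count_row("d", high_depth = TRUE), count_row("e"))
  res <- apply_filters(rows, NULL, meta)
  expect_setequal(c(res$kept$id, res$rejected$id), rows$id)
  expect_length(intersect(res$kept$id, res$rejected$id), 0)
  set.seed(5)
  perm <- rows[sample(nrow(rows)), ]
  res2 <- apply_filters(perm, NULL, meta)
  expect_setequal(res2$kept$id, res$kept$id)
  expect_setequal(res2$rejected$reason, res$rejected$reason)
})

test_that("background CN comes from outside the rearranged interval", {
  # DEL with an adversarial segmentation: the deleted interval has its own
  # state that must never be consulted
  cn <- write_cn(c("1\t1\t10000\t2\t1\t1\tNA\tNA\tNA",
                   "1\t10000\t50000\t1\t0\t1\tNA\tNA\tNA",
                   "1\t50000\t900000\t2\t1\t1\tNA\tNA\tNA"))
  bp <- breakpoints("1", 10000, "+", "1", 50000, "-")
  ann <- assign_background_cn(bp, cn, meta)
  expect_equal(ann$lo$states$major, 2)
  expect_equal(ann$hi$states$major, 2)
  expect_equal(ann$lo$total_tumour, 3)
  # shifting the breakends inside the interval switches the annotation
  bp2 <- breakpoints("1", 10001, "+", "1", 49999, "-")
  ann2 <- assign_background_cn(bp2, cn, meta)
  expect_equal(ann2$lo$states$major, 1)
})

test_that("inter-chromosomal background CN is taken opposite the direction", {
  cn <- write_cn(c("1\t1\t20000\t3\t1\t1\tNA\tNA\tNA",
                   "1\t20000\t900000\t2\t1\t1\tNA\tNA\tNA",
                   "2\t1\t30000\t1\t1\t1\tNA\tNA\tNA",
                   "2\t30000\t900000\t4\t1\t1\tNA\tNA\tNA"))
  bp <- breakpoints("1", 20000, "+", "2", 30000, "-")
  ann <- assign_background_cn(bp, cn, meta)
  expect_equal(ann$lo$states$major, 3)   # "+": upstream segment
  expect_equal(ann$hi$states$major, 4)   # "-": downstream segment
  bp2 <- breakpoints("1", 20000, "-", "2", 30000, "+")
  ann2 <- assign_background_cn(bp2, cn, meta)
  expect_equal(ann2$lo$states$major, 2)
  expect_equal(ann2$hi$states$major, 1)
})

test_that("subclonal background states carry the weighted total", {
  cn <- write_cn("1\t1\t900000\t2\t1\t0.6\t1\t1\t0.4")
  bp <- breakpoints("1", 10000, "+", "1", 50000, "-")
  ann <- assign_background_cn(bp, cn, meta)
  expect_equal(ann$lo$total_tumour, 2.6)
})
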