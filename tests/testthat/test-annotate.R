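test_that("soft-clip evidence maps to directions with the 10% mixed rule", {
  expect_equal(infer_direction(0, 12), "+")
  expect_equal(infer_direction(12, 0), "-")
  expect_equal(infer_direction(3, 20), "mixed")   # 3/23 ~ 13% >= 10%
  expect_equal(infer_direction(1, 20), "+")       # 1/21 ~ 4.8% < 10%
  expect_equal(infer_direction(2, 18), "mixed")   # exactly 10%
  expect_equal(infer_direction(0, 0), "unknown")
})

test_that("a lone both-mixed SV is emitted as (-,-) plus a (+,+) duplicate", {
  bp <- breakpoints("1", 10000, "mixed", "1", 50000, "mixed")
  out <- resolve_mixed(bp)
  expect_equal(nrow(out), 2)
  expect_setequal(paste(out$dir1, out$dir2), c("- -", "+ +"))
  expect_true(all(out$pos1 == 10000 & out$pos2 == 50000))
})

test_that("two matching both-mixed SVs split into (-,-) and (+,+) by file order", {
  bp <- breakpoints(c("1", "1"), c(10000, 10003), c("mixed", "mixed"),
                    c("1", "1"), c(50000, 50002), c("mixed", "mixed"))
  out <- resolve_mixed(bp)
  expect_equal(nrow(out), 2)
  first <- out[out$id == bp$id[1], ]
  expect_equal(c(first$dir1, first$dir2), c("-", "-"))
  second <- out[out$id == bp$id[2], ]
  expect_equal(c(second$dir1, second$dir2), c("+", "+"))
})

test_that("the translocation rank pattern gets (+,-),(+,-),(-,+)", {
  # three breakpoints over loci ranked 1 < 2 < 3 with pairs (1,2),(2,3),(1,3)
  bp <- breakpoints(c("1", "1", "1"), c(10000, 50000, 10000), "mixed",
                    c("1", "1", "1"), c(50000, 90000, 90000), "mixed")
  out <- resolve_mixed(bp)
  expect_equal(nrow(out), 3)
  dirs <- setNames(paste(out$dir1, out$dir2), out$id)
  expect_equal(unname(dirs[bp$id]), c("+ -", "+ -", "- +"))
})

test_that("more than two matching partners marks events COMPLEX", {
  bp <- breakpoints(rep("1", 4), c(10000, 10002, 10004, 10001), "mixed",
                    rep("1", 4), c(50000, 50001, 50003, 50002), "mixed")
  out <- resolve_mixed(bp)
  expect_true(any(out$svclass == "COMPLEX"))
})

test_that("resolution conserves or increases count and never moves loci", {
  bp <- breakpoints(c("1", "2", "3"), c(10000, 20000, 5000),
                    c("mixed", "+", "mixed"),
                    c("1", "2", "3"), c(50000, 60000, 45000),
                    c("mixed", "-", "+"))
  out <- resolve_mixed(bp)
  expect_gte(nrow(out), nrow(bp))
  expect_true(all(out$pos1 %in% bp$pos1) && all(out$pos2 %in% bp$pos2))
})

test_that("the classification decision tree covers the six categories", {
  expect_equal(classify_sv(breakpoints("1", 1e4, "+", "1", 5e4, "-")), "DEL")
  expect_equal(classify_sv(breakpoints("1", 1e4, "-", "1", 5e4, "+")), "DUP")
  expect_equal(classify_sv(breakpoints("1", 1e4, "+", "1", 5e4, "+")), "INV")
  expect_equal(classify_sv(breakpoints("1", 1e4, "-", "1", 5e4, "-")), "INV")
  # inter-chromosomal: no direction check at all
  expect_equal(classify_sv(breakpoints("1", 1e4, "+", "2", 5e4, "-")), "INTRX")
  expect_equal(classify_sv(breakpoints("1", 1e4, "-", "2", 5e4, "-")), "INTRX")
  expect_equal(classify_sv(breakpoints("1", 1e4, "unknown", "1", 5e4, "-")),
               "UNKNOWN")
})

test_that("interspersed duplications need the paired signature within 100 bp", {
  pair <- breakpoints(c("1", "1"), c(10000, 10020), c("-", "+"),
                      c("1", "1"), c(50000, 80000), c("+", "-"))
  expect_equal(classify_sv(pair[1, ], pair[2, ]), "INTDUP")
  expect_equal(classify_sv(pair[2, ], pair[1, ]), "INTDUP")
  # lower ends too far apart: plain DUP / DEL
  far <- breakpoints(c("1", "1"), c(10000, 10200), c("-", "+"),
                     c("1", "1"), c(50000, 80000), c("+", "-"))
  expect_equal(classify_sv(far[1, ], far[2, ]), "DUP")
  expect_equal(classify_sv(far[2, ], far[1, ]), "DEL")
})

test_that("a third deletion spanning the mobile element upgrades to TRX", {
  trio <- breakpoints(c("1", "1", "1"), c(10000, 10020, 50002),
                      c("-", "+", "+"),
                      c("1", "1", "1"), c(50000, 80000, 79997),
                      c("+", "-", "-"))
  expect_equal(classify_sv(trio[1, ], trio[-1, ]), "TRX")
  expect_equal(classify_sv(trio[2, ], trio[-2, ]), "TRX")
  # the spanning deletion itself stays a deletion
  expect_equal(classify_sv(trio[3, ], trio[-3, ]), "DEL")
  # ends further than 6 bp from the mobile element: no upgrade
  trio$pos1[3] <- 50010
  expect_equal(classify_sv(trio[1, ], trio[-1, ]), "INTDUP")
})

test_that("classification is invariant to partner order", {
  set.seed(42)
  trio <- breakpoints(c("1", "1", "1"), c(10000, 10020, 50002),
                      c("-", "+", "+"),
                      c("1", "1", "1"), c(50000, 80000, 79997),
                      c("+", "-", "-"))
  base <- classify_sv(trio[1, ], trio[-1, ])
  for (i in 1:5) {
    perm <- trio[-1, ][sample(2), ]
    expect_equal(classify_sv(trio[1, ], perm), base)
  }
})

test_that("caller-provided classes are preserved by classify_all", {
  bp <- breakpoints(c("1", "1"), c(1e4, 2e5), c("+", "+"),
                    c("1", "1"), c(5e4, 3e5), c("-", "+"),
                    svclass = c("INTDUP", "UNKNOWN"))
  out <- classify_all(bp)
  expect_equal(out$svclass, c("INTDUP", "INV"))
})
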