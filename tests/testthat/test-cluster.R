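test_that("the VAF weight follows the purity/copy-number formula", {
  expect_equal(compute_weight(1, 2, 2, purity = 1, eps = 0), 0.5)
  expect_equal(compute_weight(1, 2, 2, purity = 0.8, eps = 0), 0.4)
  expect_equal(compute_weight(1, 2, 2, purity = 1, eps = 0.001), 0.4985)
  # subclonal background enters through the weighted-average total
  expect_equal(compute_weight(1, 2.6, 2, purity = 0.5, eps = 0),
               0.5 / (0.5 * 2 + 0.5 * 2.6))
})

test_that("multiplicity candidate sets distinguish clonal and subclonal", {
  expect_equal(multiplicity_candidates(2), c(1, 2))
  expect_equal(multiplicity_candidates(1), 1)
  expect_equal(multiplicity_candidates(2, 0.7, 1, 0.3),
               c(0, 0.3, 0.7, 1.0, 1.4, 1.7))
  expect_error(multiplicity_candidates(0), "no mutable copies")
})

test_that("variant CCF inverts the linear model with the cap at 2", {
  expect_equal(variant_ccf(0.4, 0.4, eps = 0), 1)
  expect_equal(variant_ccf(5 * 0.4, 0.4, eps = 0), 2)
  expect_equal(variant_ccf(0.24, 0.4, eps = 0), 0.6)
  expect_equal(variant_ccf(0.001, 0.4, eps = 0.01), 0)  # floored
  expect_error(variant_ccf(0.2, 0), "positive")
  # noiseless limit: vaf = w * phi + eps recovers phi exactly
  for (phi in c(0.25, 0.7, 1)) {
    w <- compute_weight(1, 2, 2, 0.8, 1e-3)
    expect_equal(variant_ccf(w * phi + 1e-3, w, 1e-3), phi)
  }
})

test_that("multiplicity estimation matches exhaustive enumeration", {
  set.seed(2024)
  for (i in 1:150) {
    maj <- sample(1:4, 1)
    subclonal <- runif(1) < 0.4
    if (subclonal) {
      rho <- runif(1, 0.2, 0.8)
      majB <- sample(1:3, 1)
      cand <- multiplicity_candidates(maj, rho, majB, 1 - rho)
      ntot_t <- rho * (maj + 1) + (1 - rho) * (majB + 1)
    } else {
      cand <- multiplicity_candidates(maj)
      ntot_t <- maj + 1
    }
    purity <- runif(1, 0.3, 1)
    K <- sample(1:3, 1)
    mu <- sort(runif(K, 0.2, 1.2))
    sigma2 <- runif(K, 1e-4, 0.01)
    resp <- as.vector(stats::rmultinom(1, 20, rep(1, K))) / 20
    d <- sample(30:300, 1)
    b <- rbinom(1, d, runif(1, 0.05, 0.6))
    got <- estimate_multiplicity(b, d, cand, ntot_t, 2, purity, mu,
                                 sigma2, resp)
    want <- brute_multiplicity(b, d, cand, ntot_t, 2, purity, mu,
                               sigma2, resp)
    expect_equal(got$m, want, info = paste("case", i))
  }
})

test_that("a single clone is recovered with calibrated CCF", {
  sim <- simulate_counts(sim_config(n_sv = 60, ccf = 1, purity = 0.75,
                                    depth = 100), seed = 42)
  meta <- sample_meta(0.75, expected_depth = 100)
  fit <- fit_ccf_clusters(sim$variants, meta, quick_config(42))
  expect_equal(fit$K, 1)
  expect_lt(abs(fit$mu - 1), 0.05)
})

test_that("two well-separated clones are recovered", {
  sim <- simulate_counts(sim_config(n_sv = c(40, 40), ccf = c(1, 0.4),
                                    purity = 0.75, depth = 100), seed = 7)
  meta <- sample_meta(0.75, expected_depth = 100)
  fit <- fit_ccf_clusters(sim$variants, meta, quick_config(7))
  expect_equal(fit$K, 2)
  mt <- match_clusters(c(1, 0.4), fit$mu)
  expect_true(all(abs(mt$pairs$inferred - mt$pairs$true) < 0.05))
  # posterior structure invariants
  expect_equal(rowSums(fit$resp), rep(1, 80), tolerance = 1e-9)
  expect_true(all(fit$alpha >= fit$config$dir_conc))
  expect_true(all(diff(fit$elbo_trace) >= -1e-8))
})

test_that("duplicating every variant leaves cluster means unchanged", {
  sim <- simulate_counts(sim_config(n_sv = c(30, 30), ccf = c(1, 0.4),
                                    purity = 0.75, depth = 100), seed = 9)
  meta <- sample_meta(0.75, expected_depth = 100)
  fit1 <- fit_ccf_clusters(sim$variants, meta, quick_config(9))
  doubled <- rbind(sim$variants, transform(sim$variants,
                                           id = paste0(id, "_dup")))
  fit2 <- fit_ccf_clusters(doubled, meta, quick_config(9))
  expect_equal(fit2$K, fit1$K)
  expect_equal(sort(fit2$mu), sort(fit1$mu), tolerance = 0.02)
})

test_that("the dual-end model is symmetric in its ends and degenerates", {
  # identical information moved from end 1 to end 2 gives the same fit
  tbl1 <- make_var_table(b1 = rbinom(40, 100, 0.4), d1 = 100)
  tbl1$depth2 <- 0; tbl1$vaf2 <- NA; tbl1$b2 <- 0
  tbl2 <- tbl1
  tbl2$b2 <- tbl1$b1; tbl2$depth2 <- tbl1$depth1; tbl2$vaf2 <- tbl1$vaf1
  tbl2$b1 <- 0; tbl2$depth1 <- 0; tbl2$vaf1 <- NA
  meta <- sample_meta(0.8, expected_depth = 100)
  f1 <- fit_ccf_clusters(tbl1, meta, quick_config(3, K_range = 1:2))
  f2 <- fit_ccf_clusters(tbl2, meta, quick_config(3, K_range = 1:2))
  expect_equal(f1$elbo, f2$elbo, tolerance = 1e-8)
  expect_equal(f1$mu, f2$mu, tolerance = 1e-8)
  # and a fit with both ends carrying the same data is sharper than one
  expect_lt(fit_ccf_clusters(make_var_table(b1 = rbinom(40, 100, 0.4),
                                            d1 = 100),
                             meta, quick_config(3, K_range = 1))$sigma2[1],
            f1$sigma2[1])
})

test_that("QC leaves distinct, well-populated clusters untouched", {
  sim <- simulate_counts(sim_config(n_sv = c(40, 40), ccf = c(1, 0.4),
                                    purity = 0.75, depth = 100), seed = 11)
  meta <- sample_meta(0.75, expected_depth = 100)
  fit <- fit_ccf_clusters(sim$variants, meta, quick_config(11))
  refit <- qc_fit(fit)
  expect_equal(refit$K, fit$K)
  expect_equal(refit$mu, fit$mu, tolerance = 1e-6)
})

test_that("ELBO traces are non-decreasing across assorted fits", {
  meta <- sample_meta(0.6, expected_depth = 60)
  for (s in 1:3) {
    sim <- simulate_counts(sim_config(n_sv = c(25, 25), ccf = c(1, 0.35),
                                      purity = 0.6, depth = 60,
                                      cn_states = data.frame(
                                        major = c(1, 2), minor = c(1, 1),
                                        prob = c(0.6, 0.4)),
                                      subclonal_cn_frac = 0.3), seed = s)
    fit <- fit_ccf_clusters(sim$variants, meta, quick_config(s))
    expect_true(all(diff(fit$elbo_trace) >= -1e-8), info = paste("seed", s))
  }
})
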