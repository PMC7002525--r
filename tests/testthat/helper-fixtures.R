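# shared fixtures and independent oracles for the test suite

# minimal clustering input table built from raw per-end counts; diploid
# clonal background unless overridden
make_var_table <- function(b1, d1, b2 = b1, d2 = d1, majA = 1, minA = 1,
                           fracA = 1, majB = NA, minB = NA, fracB = NA,
                           svclass = "DEL", ntot_n = 2) {
  n <- length(b1)
  rec <- function(x) rep_len(x, n)
  ntot_t <- ifelse(is.na(rec(fracB)), rec(majA) + rec(minA),
                   rec(fracA) * (rec(majA) + rec(minA)) +
                     rec(fracB) * (rec(majB) + rec(minB)))
  data.frame(id = paste0("v", seq_len(n)),
             chrom1 = "1", pos1 = 1e5 * seq_len(n), dir1 = "+",
             chrom2 = "1", pos2 = 1e5 * seq_len(n) + 5e4, dir2 = "-",
             svclass = rec(svclass),
             b1 = b1, b2 = b2,
             norm1 = d1 - b1, norm2 = d2 - b2,
             depth1 = d1, depth2 = d2,
             vaf1 = ifelse(d1 > 0, b1 / d1, NA),
             vaf2 = ifelse(d2 > 0, b2 / d2, NA),
             support = round((b1 + b2) / 2),
             majA_1 = rec(majA), minA_1 = rec(minA), fracA_1 = rec(fracA),
             majB_1 = rec(majB), minB_1 = rec(minB), fracB_1 = rec(fracB),
             ntot_t_1 = ntot_t, ntot_n_1 = rec(ntot_n),
             majA_2 = rec(majA), minA_2 = rec(minA), fracA_2 = rec(fracA),
             majB_2 = rec(majB), minB_2 = rec(minB), fracB_2 = rec(fracB),
             ntot_t_2 = ntot_t, ntot_n_2 = rec(ntot_n),
             stringsAsFactors = FALSE)
}

# independent multiplicity oracle: exhaustive enumeration over the
# candidate set with the expected binomial log-likelihood computed by
# adaptive quadrature over the Gaussian CCF posterior
brute_multiplicity <- function(b, d, candidates, ntot_t, ntot_n, purity,
                               mu, sigma2, resp, eps = 1e-3) {
  w_of <- function(m)
    purity * (m * (1 - eps) - ntot_t * eps) /
      ((1 - purity) * ntot_n + purity * ntot_t)
  scores <- rep(-Inf, length(candidates))
  for (ci in seq_along(candidates)) {
    w <- w_of(candidates[ci])
    if (w <= 0) next
    s <- 0
    for (k in seq_along(mu)) {
      f <- function(phi) {
        p <- pmin(pmax(w * phi + eps, 1e-12), 1 - 1e-12)
        stats::dnorm(phi, mu[k], sqrt(sigma2[k])) *
          stats::dbinom(b, d, p, log = TRUE)
      }
      lo <- mu[k] - 8 * sqrt(sigma2[k]); hi <- mu[k] + 8 * sqrt(sigma2[k])
      s <- s + resp[k] * stats::integrate(f, lo, hi)$value
    }
    scores[ci] <- s
  }
  if (all(!is.finite(scores))) return(NA_real_)
  best <- which(scores >= max(scores) - 1e-7)
  candidates[best][which.min(candidates[best])]
}

# exact hypergeometric upper tail by pmf enumeration (oracle for the
# balanced-rearrangement enrichment test)
enum_hyper_upper <- function(x, K, N, n) {
  if (x == 0) return(1)
  kk <- x:min(K, n)
  sum(choose(K, kk) * choose(N - K, n - kk)) / choose(N, n)
}

# small helper: quick model config for unit tests (restricted search)
quick_config <- function(seed, K_range = 1:3, repeats = 2)
  model_config(K_range = K_range, repeats = repeats, seed = seed)
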