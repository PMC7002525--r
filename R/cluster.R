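#' Clustering model configuration
#'
#' @param K_range Candidate cluster numbers explored; default `1:6`.
#' @param repeats Random restarts per K; default 5.
#' @param max_iter Maximum coordinate-ascent iterations; default 1000.
#' @param elbo_tol Relative ELBO change declaring convergence; default 1e-6.
#' @param seed Base seed; restart seeds are derived deterministically from
#'   `(seed, K, repeat)`.
#' @param eps Sequencing error constant added to the success probability;
#'   default 1e-3.
#' @param phi_prior_mean,phi_prior_var Gaussian prior on cluster CCFs;
#'   defaults 1 and 1.
#' @param dir_conc Dirichlet concentration per component (sparsity-
#'   inducing so quality control can prune); default 0.01.
#' @param qc_small_frac Clusters holding less than this fraction of the
#'   data are removed; default 0.01.
#' @param qc_merge_gap Clusters with posterior means closer than this (in
#'   CCF units) are merged; default 0.10.
#' @return Object of class `sv_model_config`.
#' @export
model_config <- function(K_range = 1:6, repeats = 5, max_iter = 1000,
                         elbo_tol = 1e-6, seed = 1, eps = 1e-3,
                         phi_prior_mean = 1, phi_prior_var = 1,
                         dir_conc = 0.01, qc_small_frac = 0.01,
                         qc_merge_gap = 0.10) {
  stopifnot(length(K_range) >= 1, repeats >= 1,
            qc_small_frac > 0, qc_small_frac < 1,
            qc_merge_gap > 0, qc_merge_gap < 1)
  structure(list(K_range = K_range, repeats = repeats, max_iter = max_iter,
                 elbo_tol = elbo_tol, seed = seed, eps = eps,
                 phi_prior_mean = phi_prior_mean,
                 phi_prior_var = phi_prior_var, dir_conc = dir_conc,
                 qc_small_frac = qc_small_frac, qc_merge_gap = qc_merge_gap),
            class = "sv_model_config")
}

#' Binomial success-probability weight for a breakend
#'
#' The linear coefficient relating cluster CCF to the expected VAF:
#' `f = w * phi + eps` with
#' `w = t (m (1 - eps) - n_tot_t eps) / ((1 - t) n_tot_n + t n_tot_t)`,
#' where `t` is purity, `m` the multiplicity and `n_tot_t`, `n_tot_n` the
#' total tumour and normal copy number at the locus (the weighted-average
#' total under subclonal background copy number).
#'
#' @param m Multiplicity (number of mutated chromosomal copies).
#' @param ntot_t,ntot_n Total tumour and normal copy number.
#' @param purity Tumour purity t.
#' @param eps Sequencing error constant.
#' @return The weight w (vectorised over any argument).
#' @examples
#' compute_weight(1, 2, 2, purity = 1, eps = 0)    # 0.5
#' compute_weight(1, 2, 2, purity = 0.8, eps = 0)  # 0.4
#' @export
compute_weight <- function(m, ntot_t, ntot_n, purity, eps = 1e-3) {
  den <- (1 - purity) * ntot_n + purity * ntot_t
  if (any(den <= 0)) stop("copy-number denominator must be positive")
  purity * (m * (1 - eps) - ntot_t * eps) / den
}

#' Candidate multiplicities for a breakend
#'
#' Clonal background (single state): `{1, ..., major}`. Subclonal
#' background (two states with fractions rho): every weighted sum
#' `rho_1 x_1 + rho_2 x_2` over integer states `x_r in 0..major_r`
#' (including 0, which downstream estimation treats as infeasible for a
#' variant-carrying locus).
#'
#' @param majA,fracA Major copy number and fraction of the first clone.
#' @param majB,fracB Second clone (NA when the segment is clonal).
#' @return Sorted numeric vector of candidate multiplicities.
#' @examples
#' multiplicity_candidates(2)                       # 1 2
#' multiplicity_candidates(2, 0.7, 1, 0.3)          # 0 0.3 0.7 1.0 1.4 1.7
#' @export
multiplicity_candidates <- function(majA, fracA = 1, majB = NA, fracB = NA) {
  if (is.na(majB) || is.na(fracB)) {
    if (majA < 1) stop("no mutable copies: clonal major copy number is 0")
    return(as.numeric(seq_len(floor(majA))))
  }
  grid <- expand.grid(x1 = 0:floor(majA), x2 = 0:floor(majB))
  cand <- sort(unique(round(fracA * grid$x1 + fracB * grid$x2, 10)))
  if (all(cand == 0)) stop("no mutable copies: all candidate multiplicities are 0")
  cand
}

#' Per-variant CCF from an allele frequency
#'
#' Inverts the linear VAF model at the variant level:
#' `CCF = min(2, (VAF - eps) / w)`, floored at 0. In the noiseless limit
#' (`VAF = w * phi + eps` exactly) this recovers `phi`.
#'
#' @param vaf Observed variant allele frequency.
#' @param w Weight from [compute_weight()]; must be positive.
#' @param eps Sequencing error constant.
#' @return CCF in `[0, 2]` (vectorised).
#' @export
variant_ccf <- function(vaf, w, eps = 1e-3) {
  if (any(w <= 0)) stop("weight must be positive to invert the VAF model")
  pmin(2, pmax(0, (vaf - eps) / w))
}

# ---- numerical helpers --------------------------------------------------

# Gauss-Hermite nodes/weights (Golub-Welsch; physicists' convention)
.gauss_hermite <- function(n) {
  i <- seq_len(n - 1)
  J <- matrix(0, n, n)
  J[cbind(i, i + 1)] <- J[cbind(i + 1, i)] <- sqrt(i / 2)
  e <- eigen(J, symmetric = TRUE)
  list(nodes = e$values, weights = sqrt(pi) * e$vectors[1, ]^2)
}
.GH <- .gauss_hermite(11)

.clamp_p <- function(p) pmin(pmax(p, 1e-12), 1 - 1e-12)

# expected binomial log-likelihood under phi ~ N(mu, s2), one candidate w
.exp_binom_loglik <- function(b, d, w, mu, s2, eps) {
  phi <- mu + sqrt(2 * s2) * .GH$nodes
  sum(.GH$weights / sqrt(pi) *
        stats::dbinom(b, d, .clamp_p(w * phi + eps), log = TRUE))
}

#' Estimate the multiplicity of one breakend
#'
#' Maximises the responsibility-weighted expected binomial log-likelihood
#' over the candidate multiplicity set: for each candidate m, the score is
#' `sum_k r_k E_q(phi_k)[log Binomial(b | d, w(m) phi_k + eps)]`, the
#' expectation taken under the Gaussian posterior of each cluster CCF by
#' Gauss-Hermite quadrature. Candidates whose weight is non-positive
#' (including multiplicity 0) are infeasible; ties break toward the
#' smallest multiplicity.
#'
#' @param b,d Supporting reads and depth at the breakend.
#' @param candidates Candidate multiplicities from
#'   [multiplicity_candidates()].
#' @param ntot_t,ntot_n Total tumour and normal copy number at the locus.
#' @param purity Tumour purity.
#' @param mu,sigma2 Posterior means and variances of the cluster CCFs.
#' @param resp Responsibility vector over clusters (sums to 1).
#' @param eps Sequencing error constant.
#' @return List with `m` (chosen multiplicity) and `w` (its weight).
#' @export
estimate_multiplicity <- function(b, d, candidates, ntot_t, ntot_n, purity,
                                  mu, sigma2, resp, eps = 1e-3) {
  w_all <- compute_weight(candidates, ntot_t, ntot_n, purity, eps)
  ok <- w_all > 0
  if (!any(ok)) {
    # degenerate locus: fall back to the largest-weight candidate
    ok <- w_all == max(w_all)
  }
  cand <- candidates[ok]
  w_ok <- w_all[ok]
  scores <- vapply(seq_along(cand), function(ci)
    sum(resp * vapply(seq_along(mu), function(k)
      .exp_binom_loglik(b, d, w_ok[ci], mu[k], sigma2[k], eps),
      numeric(1))), numeric(1))
  best <- which(scores >= max(scores) - 1e-9)
  pick <- best[which.min(cand[best])]
  list(m = cand[pick], w = w_ok[pick])
}

# ---- variational inference core ----------------------------------------

# Build per-end data arrays from a filtered/simulated variant table.
# Returns J x 2 matrices b, d, y, tau plus per-(j,end) candidate lists.
.vi_data <- function(variants, cfg) {
  J <- nrow(variants)
  b <- cbind(if ("b1" %in% names(variants)) variants$b1 else variants$support,
             if ("b2" %in% names(variants)) variants$b2 else variants$support)
  d <- cbind(variants$depth1, variants$depth2)
  b <- round(b); d_int <- round(d)
  y <- b / d
  fh <- (b + 0.5) / (d + 1)          # variance-stabilised plug-in rate
  tau <- d / (fh * (1 - fh))
  use <- is.finite(y) & d > 0
  cands <- vector("list", J)
  for (j in 1:J) {
    cands[[j]] <- list(
      multiplicity_candidates(variants$majA_1[j], variants$fracA_1[j],
                              variants$majB_1[j], variants$fracB_1[j]),
      multiplicity_candidates(variants$majA_2[j], variants$fracA_2[j],
                              variants$majB_2[j], variants$fracB_2[j]))
  }
  ntot_t <- cbind(variants$ntot_t_1, variants$ntot_t_2)
  ntot_n <- cbind(variants$ntot_n_1, variants$ntot_n_2)
  list(J = J, b = b, d = d_int, y = y, tau = tau, use = use,
       cands = cands, ntot_t = ntot_t, ntot_n = ntot_n)
}

# Gaussian-model score of one candidate weight under current q
.gauss_m_score <- function(y, tau, w, mu, sigma2, resp, eps) {
  sum(resp * (-0.5 * tau * ((y - eps - w * mu)^2 + w^2 * sigma2)))
}

# in-loop multiplicity update: exact coordinate ascent on the ELBO
.update_m_gauss <- function(dat, w, m, mu, sigma2, resp, purity, eps) {
  for (j in seq_len(dat$J)) for (i in 1:2) {
    if (!dat$use[j, i]) next
    cand <- dat$cands[[j]][[i]]
    w_all <- compute_weight(cand, dat$ntot_t[j, i], dat$ntot_n[j, i],
                            purity, eps)
    ok <- w_all > 0
    if (!any(ok)) ok <- w_all == max(w_all)
    cand <- cand[ok]; w_ok <- w_all[ok]
    sc <- vapply(seq_along(cand), function(ci)
      .gauss_m_score(dat$y[j, i], dat$tau[j, i], w_ok[ci], mu, sigma2,
                     resp[j, ], eps), numeric(1))
    best <- which(sc >= max(sc) - 1e-12)
    pick <- best[which.min(cand[best])]
    m[j, i] <- cand[pick]
    w[j, i] <- w_ok[pick]
  }
  list(w = w, m = m)
}

.elbo <- function(dat, w, r, mu, sigma2, alpha, cfg) {
  K <- length(mu)
  a0 <- cfg$dir_conc
  m0 <- cfg$phi_prior_mean; s0 <- cfg$phi_prior_var
  elogpi <- digamma(alpha) - digamma(sum(alpha))
  loglik <- 0
  for (k in 1:K) {
    term <- 0.5 * log(dat$tau / (2 * pi)) -
      0.5 * dat$tau * ((dat$y - cfg$eps - w * mu[k])^2 + w^2 * sigma2[k])
    term[!dat$use] <- 0
    loglik <- loglik + sum(r[, k] * rowSums(term))
  }
  ez <- sum(r %*% elogpi)
  lr <- r * log(pmax(r, 1e-300))
  entz <- -sum(lr)
  ephi <- sum(-0.5 * log(2 * pi * s0) - 0.5 * (sigma2 + (mu - m0)^2) / s0)
  entphi <- sum(0.5 * (log(2 * pi * sigma2) + 1))
  epi <- lgamma(K * a0) - K * lgamma(a0) + sum((a0 - 1) * elogpi)
  eqpi <- lgamma(sum(alpha)) - sum(lgamma(alpha)) +
    sum((alpha - 1) * elogpi)
  loglik + ez + entz + ephi + entphi + epi - eqpi
}

# one full CAVI run from given initial state; returns the fitted state
.cavi <- function(dat, cfg, purity, init) {
  K <- length(init$mu)
  mu <- init$mu; sigma2 <- init$sigma2
  alpha <- init$alpha
  w <- init$w; m <- init$m
  r <- init$r
  m0 <- cfg$phi_prior_mean; s0 <- cfg$phi_prior_var
  trace <- numeric(0)
  converged <- FALSE
  for (it in seq_len(cfg$max_iter)) {
    # multiplicities (coordinate ascent on the same objective)
    upd <- .update_m_gauss(dat, w, m, mu, sigma2, r, purity, cfg$eps)
    w <- upd$w; m <- upd$m
    # q(phi)
    for (k in 1:K) {
      txw2 <- dat$tau * w^2; txw2[!dat$use] <- 0
      txwy <- dat$tau * w * (dat$y - cfg$eps); txwy[!dat$use] <- 0
      prec <- 1 / s0 + sum(r[, k] * rowSums(txw2))
      mu[k] <- (m0 / s0 + sum(r[, k] * rowSums(txwy))) / prec
      sigma2[k] <- 1 / prec
    }
    # q(pi)
    alpha <- cfg$dir_conc + colSums(r)
    # q(Z)
    elogpi <- digamma(alpha) - digamma(sum(alpha))
    logr <- matrix(0, dat$J, K)
    for (k in 1:K) {
      term <- 0.5 * log(dat$tau / (2 * pi)) -
        0.5 * dat$tau * ((dat$y - cfg$eps - w * mu[k])^2 + w^2 * sigma2[k])
      term[!dat$use] <- 0
      logr[, k] <- elogpi[k] + rowSums(term)
    }
    logr <- logr - apply(logr, 1, max)
    r <- exp(logr)
    r <- r / rowSums(r)
    trace <- c(trace, .elbo(dat, w, r, mu, sigma2, alpha, cfg))
    if (it > 1) {
      d_el <- trace[it] - trace[it - 1]
      if (abs(d_el) < cfg$elbo_tol * abs(trace[it])) { converged <- TRUE; break }
    }
  }
  list(K = K, mu = mu, sigma2 = sigma2, alpha = alpha, r = r, w = w, m = m,
       elbo = trace[length(trace)], trace = trace, converged = converged,
       n_iter = length(trace))
}

# empirical per-variant CCFs at multiplicity 1 (initialisation heuristic)
.empirical_ccf <- function(dat, purity, eps) {
  w1 <- compute_weight(1, dat$ntot_t, dat$ntot_n, purity, eps)
  cc <- (dat$y - eps) / pmax(w1, 1e-6)
  cc <- matrix(pmin(2, pmax(0, cc)), nrow = dat$J)
  cc[!dat$use] <- NA
  rowMeans(cc, na.rm = TRUE)
}

.restart_seed <- function(seed, K, rep)
  ((abs(as.integer(seed)) %% 1000003L) * 1009L + K * 101L + rep) %% 2147483647L

# initial state for one restart
.init_state <- function(dat, cfg, purity, K, rep) {
  set.seed(.restart_seed(cfg$seed, K, rep))
  ecc <- .empirical_ccf(dat, purity, cfg$eps)
  qs <- stats::quantile(ecc, probs = (seq_len(K) - 0.5) / K, na.rm = TRUE,
                        names = FALSE)
  mu <- qs + if (rep > 1) stats::rnorm(K, 0, 0.02) else 0
  mu <- pmax(mu, 1e-3)
  sigma2 <- rep(0.01, K)
  alpha <- rep(cfg$dir_conc + dat$J / K, K)
  # start every end at its smallest feasible multiplicity
  m <- w <- matrix(NA_real_, dat$J, 2)
  for (j in seq_len(dat$J)) for (i in 1:2) {
    cand <- dat$cands[[j]][[i]]
    w_all <- compute_weight(cand, dat$ntot_t[j, i], dat$ntot_n[j, i],
                            purity, cfg$eps)
    ok <- which(w_all > 0)
    pick <- if (length(ok)) ok[1] else which.max(w_all)
    m[j, i] <- cand[pick]; w[j, i] <- w_all[pick]
  }
  # soft initial responsibilities from distance to the initial means
  dist <- outer(ecc, mu, function(a, b) -(a - b)^2 / 0.02)
  dist[is.na(dist)] <- 0
  dist <- dist - apply(dist, 1, max)
  r <- exp(dist); r <- r / rowSums(r)
  list(mu = mu, sigma2 = sigma2, alpha = alpha, m = m, w = w, r = r)
}

#' Fit the dual-breakend CCF mixture model
#'
#' Clusters SVs by cancer cell fraction with a Bayesian mixture fitted by
#' coordinate-ascent variational inference. Both breakends of an SV share
#' one cluster assignment and one CCF; each end contributes its own
#' (adjusted) supporting read count, depth and background copy number.
#' The model is fitted over every cluster number in `K_range` with
#' `repeats` restarts each; the solution with the best evidence lower
#' bound is kept and passed through quality control ([qc_fit()]). Final
#' multiplicities are re-estimated per end by
#' [estimate_multiplicity()] and per-variant CCFs by [variant_ccf()],
#' with the representative CCF the mean of the two ends (capped at 2).
#'
#' @param variants Filtered variant table: counts (`support` or `b1`/`b2`,
#'   `depth1`, `depth2`, `vaf1`, `vaf2`) plus per-end background CN columns
#'   as produced by [apply_filters()] or [simulate_counts()].
#' @param meta A [sample_meta()].
#' @param cfg A [model_config()].
#' @return Object of class `sv_cluster_fit`: cluster posterior (`mu`,
#'   `sigma2`, `alpha`), responsibilities (`resp`), ELBO and trace, QC'd
#'   cluster count `K`, and an `assignments` data.frame with per-end CCFs,
#'   representative CCF, cluster and multiplicities.
#' @export
fit_ccf_clusters <- function(variants, meta, cfg = model_config()) {
  if (nrow(variants) == 0) stop("no variants to cluster")
  dat <- .vi_data(variants, cfg)
  best <- NULL
  for (K in cfg$K_range) {
    for (rep in seq_len(cfg$repeats)) {
      init <- .init_state(dat, cfg, meta$purity, K, rep)
      st <- .cavi(dat, cfg, meta$purity, init)
      if (is.null(best) || st$elbo > best$elbo) best <- st
    }
  }
  fit <- .finalise_fit(best, dat, variants, meta, cfg)
  qc_fit(fit, cfg)
}

# attach assignments/CCFs and wrap as sv_cluster_fit
.finalise_fit <- function(st, dat, variants, meta, cfg) {
  K <- st$K
  m <- w <- matrix(NA_real_, dat$J, 2)
  for (j in seq_len(dat$J)) for (i in 1:2) {
    if (!dat$use[j, i]) next
    est <- estimate_multiplicity(dat$b[j, i], dat$d[j, i],
                                 dat$cands[[j]][[i]],
                                 dat$ntot_t[j, i], dat$ntot_n[j, i],
                                 meta$purity, st$mu, st$sigma2, st$r[j, ],
                                 cfg$eps)
    m[j, i] <- est$m; w[j, i] <- est$w
  }
  ccf1 <- ifelse(dat$use[, 1], variant_ccf(pmax(dat$y[, 1], 0),
                                           pmax(w[, 1], 1e-9), cfg$eps), NA)
  ccf2 <- ifelse(dat$use[, 2], variant_ccf(pmax(dat$y[, 2], 0),
                                           pmax(w[, 2], 1e-9), cfg$eps), NA)
  ccf <- pmin(2, rowMeans(cbind(ccf1, ccf2), na.rm = TRUE))
  cluster <- apply(st$r, 1, which.max)
  assignments <- data.frame(id = variants$id, cluster = cluster,
                            ccf1 = ccf1, ccf2 = ccf2, ccf = ccf,
                            m1 = m[, 1], m2 = m[, 2],
                            w1 = w[, 1], w2 = w[, 2],
                            cluster_ccf = st$mu[cluster],
                            stringsAsFactors = FALSE)
  structure(list(K = K, mu = st$mu, sigma2 = st$sigma2, alpha = st$alpha,
                 resp = st$r, elbo = st$elbo, elbo_trace = st$trace,
                 n_iter = st$n_iter, converged = st$converged,
                 m = m, w = w, assignments = assignments,
                 variants = variants, meta = meta, config = cfg,
                 dat = dat),
            class = "sv_cluster_fit")
}

#' @export
print.sv_cluster_fit <- function(x, ...) {
  cat(sprintf("sv_cluster_fit: %d cluster(s), %d variant(s), ELBO %.3f%s\n",
              x$K, nrow(x$assignments), x$elbo,
              if (x$converged) "" else " (not converged)"))
  sizes <- tabulate(x$assignments$cluster, nbins = x$K)
  for (k in seq_len(x$K))
    cat(sprintf("  cluster %d: mean CCF %.3f (sd %.3f), %d variants\n",
                k, x$mu[k], sqrt(x$sigma2[k]), sizes[k]))
  invisible(x)
}

# drop clusters by index, renormalise responsibilities, refine by VI
.drop_and_refine <- function(fit, keep, cfg) {
  dat <- fit$dat
  r <- fit$resp[, keep, drop = FALSE]
  rs <- rowSums(r)
  zero <- rs <= 0
  r[zero, ] <- 1 / length(keep)
  r[!zero, ] <- r[!zero, , drop = FALSE] / rs[!zero]
  init <- list(mu = fit$mu[keep], sigma2 = fit$sigma2[keep],
               alpha = cfg$dir_conc + colSums(r), m = fit$m, w = fit$w,
               r = r)
  st <- .cavi(dat, cfg, fit$meta$purity, init)
  .finalise_fit(st, dat, fit$variants, fit$meta, cfg)
}

#' Quality control of a cluster fit
#'
#' Three steps applied in order, each followed by a refinement run of the
#' same variational inference with the surviving clusters: (1) remove
#' empty clusters (no variant assigned by maximum responsibility), (2)
#' remove clusters holding less than `qc_small_frac` of the data, (3)
#' merge clusters whose posterior mean CCFs are less than `qc_merge_gap`
#' apart (closest pair first, repeated until no pair qualifies). Variants
#' of removed clusters are reassigned through the refreshed
#' responsibilities.
#'
#' @param fit An `sv_cluster_fit`.
#' @param cfg A [model_config()] (thresholds are read from here).
#' @return The fit after QC (class `sv_cluster_fit`).
#' @export
qc_fit <- function(fit, cfg = fit$config) {
  # (1) empty clusters
  repeat {
    sizes <- tabulate(apply(fit$resp, 1, which.max), nbins = fit$K)
    if (fit$K > 1 && any(sizes == 0))
      fit <- .drop_and_refine(fit, which(sizes > 0), cfg)
    else break
  }
  # (2) small clusters
  repeat {
    sizes <- tabulate(apply(fit$resp, 1, which.max), nbins = fit$K)
    small <- which(sizes / nrow(fit$resp) < cfg$qc_small_frac)
    if (fit$K > 1 && length(small) > 0) {
      drop <- small[which.min(sizes[small])]
      fit <- .drop_and_refine(fit, setdiff(seq_len(fit$K), drop), cfg)
    } else break
  }
  # (3) merge close means
  repeat {
    if (fit$K < 2) break
    dm <- abs(outer(fit$mu, fit$mu, "-"))
    diag(dm) <- Inf
    if (min(dm) >= cfg$qc_merge_gap) break
    pair <- which(dm == min(dm), arr.ind = TRUE)[1, ]
    a <- min(pair); bdx <- max(pair)
    # merge responsibilities into a, drop b, refine
    fit$resp[, a] <- fit$resp[, a] + fit$resp[, bdx]
    fit <- .drop_and_refine(fit, setdiff(seq_len(fit$K), bdx), cfg)
  }
  fit
}
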