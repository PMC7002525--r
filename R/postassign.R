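#' Post-assign variants to the clusters of a reference fit
#'
#' Assigns a new set of variants (for example SVs too few to cluster on
#' their own, or variants removed by filtering) to the clusters of an
#' existing fit. The reference cluster CCF posterior `q(phi)` is frozen;
#' only the assignment posterior `q(Z)` and the mixing-weight posterior
#' `q(pi)` are iterated to convergence, so the post-assignment mixing
#' proportions reflect the new data rather than the reference cohort's.
#' Multiplicities are estimated per end against the frozen cluster
#' posterior. The same quality-control steps are applied, except that
#' merging operates on assignment labels only: frozen reference means are
#' never altered, and per-label means are recomputed for reporting
#' (flagged in the returned object).
#'
#' Works in both directions: SVs onto SNV-derived clusters and vice versa
#' (any fit with Gaussian cluster posteriors serves as reference).
#'
#' @param variants New variant table (counts + background CN columns, as
#'   for [fit_ccf_clusters()]).
#' @param reference An `sv_cluster_fit` providing `q(phi)`.
#' @param meta A [sample_meta()] for the new variants' sample.
#' @param cfg A [model_config()].
#' @return An `sv_cluster_fit` for the new variants with the reference
#'   CCF posterior (element `reference_mu` keeps the untouched means;
#'   `merged_labels` records any QC label merges).
#' @export
post_assign <- function(variants, reference, meta, cfg = model_config()) {
  stopifnot(inherits(reference, "sv_cluster_fit"))
  if (reference$K < 1) stop("reference fit has no clusters")
  if (nrow(variants) == 0) stop("no variants to post-assign")
  dat <- .vi_data(variants, cfg)
  K <- reference$K
  mu <- reference$mu
  sigma2 <- reference$sigma2
  # initial state: uniform responsibilities, smallest feasible multiplicity
  init <- .init_state(dat, cfg, meta$purity, K, 1)
  r <- matrix(1 / K, dat$J, K)
  alpha <- cfg$dir_conc + colSums(r)
  w <- init$w; m <- init$m
  trace <- numeric(0)
  converged <- FALSE
  for (it in seq_len(cfg$max_iter)) {
    upd <- .update_m_gauss(dat, w, m, mu, sigma2, r, meta$purity, cfg$eps)
    w <- upd$w; m <- upd$m
    alpha <- cfg$dir_conc + colSums(r)
    elogpi <- digamma(alpha) - digamma(sum(alpha))
    logr <- matrix(0, dat$J, K)
    for (k in 1:K) {
      term <- 0.5 * log(dat$tau / (2 * pi)) -
        0.5 * dat$tau * ((dat$y - cfg$eps - w * mu[k])^2 + w^2 * sigma2[k])
      term[!dat$use] <- 0
      logr[, k] <- elogpi[k] + rowSums(term)
    }
    logr <- logr - apply(logr, 1, max)
    r <- exp(logr); r <- r / rowSums(r)
    trace <- c(trace, .elbo(dat, w, r, mu, sigma2, alpha, cfg))
    if (it > 1 && abs(trace[it] - trace[it - 1]) <
        cfg$elbo_tol * abs(trace[it])) { converged <- TRUE; break }
  }
  st <- list(K = K, mu = mu, sigma2 = sigma2, alpha = alpha, r = r,
             w = w, m = m, elbo = trace[length(trace)], trace = trace,
             converged = converged, n_iter = length(trace))
  fit <- .finalise_fit(st, dat, variants, meta, cfg)
  fit$reference_mu <- reference$mu
  # QC on labels only: empty/small label removal reassigns by next-best
  # responsibility; close means merge labels without touching frozen q(phi)
  lab <- fit$assignments$cluster
  merged <- list()
  rep_of <- seq_len(K)
  repeat {
    active <- sort(unique(rep_of))
    if (length(active) < 2) break
    dm <- abs(outer(mu[active], mu[active], "-")); diag(dm) <- Inf
    if (min(dm) >= cfg$qc_merge_gap) break
    pair <- which(dm == min(dm), arr.ind = TRUE)[1, ]
    from <- active[max(pair)]; to <- active[min(pair)]
    rep_of[rep_of == from] <- to
    merged[[length(merged) + 1]] <- c(from = from, to = to)
  }
  lab <- rep_of[lab]
  fit$assignments$cluster <- lab
  # reported per-label means recomputed from member CCFs (reference means
  # themselves are untouched)
  fit$assignments$cluster_ccf <- vapply(lab, function(k) {
    mem <- fit$assignments$ccf[lab == k]
    if (length(mem)) mean(mem) else mu[k]
  }, numeric(1))
  fit$merged_labels <- merged
  fit
}
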