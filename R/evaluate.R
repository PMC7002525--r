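#' Match true and inferred clusters by alternating extremes
#'
#' Pairs are formed rank-wise, alternating from the extremes inward:
#' highest true mean with highest inferred mean, then lowest with lowest,
#' then second-highest with second-highest, and so on, until either list
#' is exhausted. When the counts are even the highest-first convention
#' claims the middle. Unmatched means are reported.
#'
#' @param true_means,inferred_means Non-empty numeric vectors of cluster
#'   mean CCFs.
#' @return List with `pairs` (data.frame `true`, `inferred`),
#'   `unmatched_true`, `unmatched_inferred`.
#' @examples
#' match_clusters(c(1.0, 0.4, 0.7), c(0.95, 0.45))
#' @export
match_clusters <- function(true_means, inferred_means) {
  stopifnot(length(true_means) >= 1, length(inferred_means) >= 1)
  n <- min(length(true_means), length(inferred_means))
  pick_order <- function(len) {
    hi <- seq_len(ceiling(n / 2))
    lo <- len + 1 - seq_len(floor(n / 2))
    idx <- integer(n)
    idx[seq(1, n, by = 2)] <- hi
    if (n > 1) idx[seq(2, n, by = 2)] <- lo
    idx
  }
  ts <- sort(true_means, decreasing = TRUE)
  is <- sort(inferred_means, decreasing = TRUE)
  ti <- pick_order(length(ts))
  ii <- pick_order(length(is))
  pairs <- data.frame(true = ts[ti], inferred = is[ii])
  list(pairs = pairs,
       unmatched_true = ts[setdiff(seq_along(ts), ti)],
       unmatched_inferred = is[setdiff(seq_along(is), ii)])
}

#' Optimal multiplicity and CCF given the true cluster CCF
#'
#' The benchmarking oracle: with the true cluster CCF known, the best
#' multiplicity is the candidate maximising the binomial log-likelihood of
#' the observed supporting reads with success probability
#' `w(m) * phi_true + eps`, and the optimal CCF follows from
#' [variant_ccf()] with that candidate's weight.
#'
#' @param b,d Supporting reads and depth at the breakend.
#' @param candidates Candidate multiplicities.
#' @param ntot_t,ntot_n Total tumour and normal copy numbers.
#' @param purity Tumour purity.
#' @param phi_true True cluster CCF.
#' @param eps Sequencing error constant.
#' @return List with `m` and `ccf`.
#' @export
optimal_multiplicity_ccf <- function(b, d, candidates, ntot_t, ntot_n,
                                     purity, phi_true, eps = 1e-3) {
  w_all <- compute_weight(candidates, ntot_t, ntot_n, purity, eps)
  ok <- w_all > 0
  if (!any(ok)) ok <- w_all == max(w_all)
  cand <- candidates[ok]; w_ok <- w_all[ok]
  ll <- vapply(seq_along(cand), function(ci)
    stats::dbinom(b, d, .clamp_p(w_ok[ci] * phi_true + eps), log = TRUE),
    numeric(1))
  best <- which(ll >= max(ll) - 1e-9)
  pick <- best[which.min(cand[best])]
  list(m = cand[pick],
       ccf = variant_ccf(b / d, max(w_ok[pick], 1e-9), eps))
}

#' Benchmarking metrics against a truth table
#'
#' Computes the standard performance panel for CCF inference: cluster
#' number error (true K minus inferred K), signed mean cluster CCF error
#' over matched cluster pairs (inferred minus true, matched by
#' [match_clusters()]), signed mean variant CCF error, signed mean
#' multiplicity error (inferred multiplicity minus the multiplicity
#' implied by the true cluster mean via [optimal_multiplicity_ccf()]),
#' and sensitivity/specificity for calling a variant subclonal at the
#' given cutoff (positive class: truly subclonal).
#'
#' @param truth Truth table: data.frame with `id`, `ccf_true`,
#'   `cluster_true`, `clonality_true` (`"clonal"`/`"subclonal"`) and
#'   optionally per-cluster means recoverable from `ccf_true`.
#' @param fit An `sv_cluster_fit` whose assignments align with `truth$id`.
#' @param cutoff Subclonality cutoff; default 0.7.
#' @return List of the six metrics plus the matched cluster pairs.
#' @export
evaluate_fit <- function(truth, fit, cutoff = 0.7) {
  asn <- fit$assignments
  if (!setequal(truth$id, asn$id))
    stop("truth/result id mismatch: ",
         paste(c(setdiff(truth$id, asn$id), setdiff(asn$id, truth$id)),
               collapse = ", "))
  truth <- truth[match(asn$id, truth$id), ]
  true_means <- sort(unique(truth$ccf_true), decreasing = TRUE)
  mt <- match_clusters(true_means, fit$mu)
  cluster_number_error <- length(true_means) - fit$K
  mean_cluster_ccf_error <- mean(mt$pairs$inferred - mt$pairs$true)
  mean_variant_ccf_error <- mean(asn$ccf - truth$ccf_true)

  # multiplicity implied by the true cluster mean, per end
  dat <- fit$dat
  m_opt <- matrix(NA_real_, nrow(asn), 2)
  for (j in seq_len(nrow(asn))) for (i in 1:2) {
    if (!dat$use[j, i]) next
    m_opt[j, i] <- optimal_multiplicity_ccf(
      dat$b[j, i], dat$d[j, i], dat$cands[[j]][[i]],
      dat$ntot_t[j, i], dat$ntot_n[j, i], fit$meta$purity,
      truth$ccf_true[j], fit$config$eps)$m
  }
  merr <- cbind(asn$m1, asn$m2) - m_opt
  mean_multiplicity_error <- mean(merr, na.rm = TRUE)

  truly_sub <- truth$clonality_true == "subclonal"
  called_sub <- asn$ccf < cutoff
  sens <- if (any(truly_sub)) mean(called_sub[truly_sub]) else NA_real_
  spec <- if (any(!truly_sub)) mean(!called_sub[!truly_sub]) else NA_real_
  list(cluster_number_error = cluster_number_error,
       mean_cluster_ccf_error = mean_cluster_ccf_error,
       mean_variant_ccf_error = mean_variant_ccf_error,
       mean_multiplicity_error = mean_multiplicity_error,
       subclonal_sensitivity = sens,
       subclonal_specificity = spec,
       matched = mt)
}
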