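#' Classify a CCF as clonal or subclonal
#'
#' A variant is subclonal when its CCF falls strictly below the cutoff;
#' a CCF exactly at the cutoff is clonal.
#'
#' @param ccf CCF values in `[0, 2]`.
#' @param cutoff Subclonality cutoff; default 0.7.
#' @return Character vector, `"clonal"` or `"subclonal"`.
#' @examples
#' classify_clonality(c(0.6, 0.7, 1.3))
#' @export
classify_clonality <- function(ccf, cutoff = 0.7) {
  stopifnot(all(ccf >= 0), all(ccf <= 2))
  ifelse(ccf < cutoff, "subclonal", "clonal")
}

#' Fraction of subclonal variants
#'
#' @param ccf CCF values (or an `sv_cluster_fit`, in which case the
#'   representative CCFs are used).
#' @param cutoff Subclonality cutoff; default 0.7.
#' @return Fraction of variants with CCF below the cutoff.
#' @export
subclonal_fraction <- function(ccf, cutoff = 0.7) {
  if (inherits(ccf, "sv_cluster_fit")) ccf <- ccf$assignments$ccf
  if (length(ccf) == 0) stop("no variants")
  mean(ccf < cutoff)
}

#' Enrichment test for subclonal balanced rearrangements
#'
#' Tests whether balanced rearrangements (inversions and inter-chromosomal
#' translocations) are enriched among subclonal SVs, using the
#' hypergeometric upper tail P(X >= x): population N = all SVs, successes
#' K = balanced SVs, draws n = subclonal SVs (CCF below the cutoff),
#' observed x = subclonal balanced SVs. A small p-value indicates the
#' subclonal copy-number-neutral rearrangement (SCNR) pattern.
#'
#' @param svclass SV class per variant (see [SV_CLASSES]).
#' @param ccf Representative CCF per variant.
#' @param cutoff Subclonality cutoff; default 0.7.
#' @param balanced_classes Classes counted as balanced; default
#'   `c("INV", "INTRX")`.
#' @return List with `p_value`, `N`, `K`, `n`, `x`.
#' @export
scnr_test <- function(svclass, ccf, cutoff = 0.7,
                      balanced_classes = c("INV", "INTRX")) {
  stopifnot(length(svclass) == length(ccf), length(ccf) >= 1)
  N <- length(ccf)
  bal <- svclass %in% balanced_classes
  sub <- ccf < cutoff
  K <- sum(bal)
  n <- sum(sub)
  x <- sum(bal & sub)
  p <- if (x == 0) 1 else stats::phyper(x - 1, K, N - K, n, lower.tail = FALSE)
  list(p_value = p, N = N, K = K, n = n, x = x)
}

# beta-binomial log pmf
.lbetabinom <- function(b, d, alpha, beta) {
  lchoose(d, b) + lbeta(b + alpha, d - b + beta) - lbeta(alpha, beta)
}

#' Binomial versus beta-binomial dispersion test
#'
#' Tests, per variant, whether the supporting read counts of copy-number
#' neutral heterozygous variants are adequately described by a binomial
#' with success probability `purity / 2`. The alternative beta-binomial's
#' `beta` parameter is a moment-style plug-in estimated from the cohort:
#' with `mu = mean(d) * t / 2` (or per-variant `mu_j = d_j * t / 2` when
#' `per_variant_depth = TRUE`), `n = d_j` and `sigma` the standard
#' deviation of the observed supporting reads,
#' `beta = ((mu - n)(mu^2 - mu n + sigma^2)) / (mu^2 - mu n + n sigma^2)`
#' and `alpha = -mu beta / (mu - d_j)`. A likelihood-ratio statistic
#' `2(l1 - l0)` is referred to chi-square with one degree of freedom.
#'
#' When the implied `alpha` or `beta` is non-positive (the data are not
#' overdispersed relative to the binomial) the alternative collapses to
#' the null and the statistic is 0. Note the plug-in alternative is not a
#' maximum-likelihood fit, which makes the test conservative under the
#' null.
#'
#' @param b,d Supporting read counts and depths (length >= 2).
#' @param meta A [sample_meta()] (purity is used).
#' @param alpha_level Rejection level for the reported fraction; default
#'   0.05.
#' @param per_variant_depth Use each variant's own depth for `mu` instead
#'   of the sample mean; default `FALSE`.
#' @return List with `p_values`, `statistics`, `rejected_fraction`,
#'   `alpha`, `beta`.
#' @export
dispersion_test <- function(b, d, meta, alpha_level = 0.05,
                            per_variant_depth = FALSE) {
  stopifnot(length(b) == length(d))
  if (length(b) < 2) stop("at least 2 variants required (sd undefined)")
  t <- meta$purity
  p0 <- t / 2
  mu <- if (per_variant_depth) d * p0 else mean(d) * p0
  sig <- stats::sd(b)
  n <- d
  beta <- ((mu - n) * (mu^2 - mu * n + sig^2)) / (mu^2 - mu * n + n * sig^2)
  alpha <- -mu * beta / (mu - d)
  l0 <- stats::dbinom(b, d, p0, log = TRUE)
  ok <- is.finite(beta) & is.finite(alpha) & beta > 0 & alpha > 0
  l1 <- l0
  l1[ok] <- .lbetabinom(b[ok], d[ok], alpha[ok], beta[ok])
  stat <- pmax(0, 2 * (l1 - l0))
  pv <- stats::pchisq(stat, df = 1, lower.tail = FALSE)
  list(p_values = pv, statistics = stat,
       rejected_fraction = mean(pv < alpha_level),
       alpha = alpha, beta = beta)
}
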