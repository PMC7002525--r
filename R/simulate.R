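#' Synthetic dataset configuration
#'
#' Defaults emulate the read-simulation design used to validate the VAF
#' estimator: heterozygous SVs (multiplicity drawn from the background
#' state) on a copy-number neutral diploid background, placed at regular
#' 100 kb intervals, sequenced at Poisson-distributed depth around
#' `depth`. Richer backgrounds (amplified or subclonal states) are
#' opt-in via `cn_states` and `subclonal_cn_frac`.
#'
#' @param n_sv Number of SVs per clone (recycled against `ccf`).
#' @param ccf Clone CCFs in (0, 1]; one entry per clone.
#' @param purity,ploidy Sample purity and tumour ploidy.
#' @param depth Expected reads per locus at copy number 2 (lambda).
#' @param eps Sequencing error constant.
#' @param class_probs Named probabilities over SV classes; must sum to 1.
#' @param cn_states Data frame `major`, `minor`, `prob` of clonal
#'   background states; default copy-number neutral (1, 1).
#' @param subclonal_cn_frac Fraction of SVs receiving a subclonal
#'   background (two states); default 0.
#' @param subclonal_rho Range the primary clone fraction is drawn from
#'   for subclonal backgrounds; default `c(0.3, 0.7)`.
#' @param fixed_depth If `TRUE`, depths are fixed at their expectation
#'   instead of Poisson-drawn.
#' @return Object of class `sv_sim_config`.
#' @export
sim_config <- function(n_sv = 100, ccf = 1, purity = 0.75, ploidy = 2,
                       depth = 50, eps = 1e-3,
                       class_probs = c(DEL = 0.4, DUP = 0.2, INV = 0.25,
                                       INTRX = 0.15),
                       cn_states = data.frame(major = 1, minor = 1, prob = 1),
                       subclonal_cn_frac = 0,
                       subclonal_rho = c(0.3, 0.7),
                       fixed_depth = FALSE) {
  stopifnot(all(ccf > 0), all(ccf <= 1),
            abs(sum(class_probs) - 1) < 1e-8,
            abs(sum(cn_states$prob) - 1) < 1e-8,
            subclonal_cn_frac >= 0, subclonal_cn_frac <= 1)
  n_sv <- rep_len(n_sv, length(ccf))
  structure(list(n_sv = n_sv, ccf = ccf, purity = purity, ploidy = ploidy,
                 depth = depth, eps = eps, class_probs = class_probs,
                 cn_states = cn_states,
                 subclonal_cn_frac = subclonal_cn_frac,
                 subclonal_rho = subclonal_rho, fixed_depth = fixed_depth),
            class = "sv_sim_config")
}

# directions implied by each simulated class
.class_dirs <- function(cls) {
  switch(cls,
         DEL = c("+", "-"), DUP = c("-", "+"), INTDUP = c("-", "+"),
         INV = c("+", "+"), TRX = c("+", "-"), INTRX = c("+", "-"),
         c("+", "-"))
}

# draw read counts for one SV at CCF phi; returns per-end raw counts
.draw_counts <- function(cls, m, ntot_t, ntot_n, phi, cfg) {
  t <- cfg$purity
  n_bg <- (1 - t) * ntot_n + t * ntot_t
  gain <- cls %in% SV_GAIN_CLASSES
  draw_d <- function(lam) if (cfg$fixed_depth) round(lam) else stats::rpois(2, lam)
  if (gain) {
    lam <- cfg$depth * (n_bg + t * m * phi) / 2
    d <- draw_d(lam)
    p <- .clamp_p(t * m * phi / (n_bg + t * m * phi) + cfg$eps)
    b <- stats::rbinom(2, d, p)
    o <- d - b
  } else {
    lam <- cfg$depth * n_bg / 2
    d <- draw_d(lam)
    w <- compute_weight(m, ntot_t, ntot_n, t, cfg$eps)
    b <- stats::rbinom(2, d, .clamp_p(w * phi + cfg$eps))
    o <- d - b
  }
  list(b = b, o = o)
}

# draw a background CN annotation; returns list(majA,minA,fracA,majB,minB,
# fracB, ntot_t)
.draw_cn <- function(cfg) {
  if (stats::runif(1) < cfg$subclonal_cn_frac) {
    idx <- sample.int(nrow(cfg$cn_states), 2, replace = TRUE,
                      prob = cfg$cn_states$prob)
    # force distinct states so the segment is genuinely subclonal
    stA <- cfg$cn_states[idx[1], ]
    stB <- cfg$cn_states[idx[2], ]
    if (stA$major == stB$major && stA$minor == stB$minor)
      stB$major <- stB$major + 1
    rho <- stats::runif(1, cfg$subclonal_rho[1], cfg$subclonal_rho[2])
    list(majA = stA$major, minA = stA$minor, fracA = rho,
         majB = stB$major, minB = stB$minor, fracB = 1 - rho,
         ntot_t = rho * (stA$major + stA$minor) +
           (1 - rho) * (stB$major + stB$minor))
  } else {
    idx <- sample.int(nrow(cfg$cn_states), 1, prob = cfg$cn_states$prob)
    st <- cfg$cn_states[idx, ]
    list(majA = st$major, minA = st$minor, fracA = 1,
         majB = NA_real_, minB = NA_real_, fracB = NA_real_,
         ntot_t = st$major + st$minor)
  }
}

#' Simulate a count-level SV dataset with known truth
#'
#' Generates SVs from the forward model of the clustering likelihood: for
#' each SV a background copy-number state and multiplicity are drawn, the
#' per-end success probability is `w * phi + eps`, depths are Poisson
#' around the expected coverage for the locus and supporting reads are
#' binomial at both ends independently (shared CCF). DNA-gain classes are
#' generated with undisplaced reference reads (inflated normal counts)
#' and then passed through the standard adjustment, so the emitted table
#' carries both raw and adjusted values.
#'
#' @param cfg A [sim_config()].
#' @param seed Integer seed; identical seeds give identical datasets.
#' @param id_prefix Prefix for variant ids.
#' @return Object of class `sv_sim`: list with `variants` (filtered-table
#'   dialect: positions, directions, class, `b1`, `b2`, `norm1`, `norm2`,
#'   raw and adjusted depths/VAFs, background CN columns), `truth`
#'   (`id`, `ccf_true`, `cluster_true`, `clonality_true`, `m_true`) and
#'   `config`.
#' @export
simulate_counts <- function(cfg = sim_config(), seed = 1, id_prefix = "sv") {
  set.seed(seed)
  J <- sum(cfg$n_sv)
  clone <- rep(seq_along(cfg$ccf), cfg$n_sv)
  rows <- vector("list", J)
  tn <- 2
  for (j in seq_len(J)) {
    phi <- cfg$ccf[clone[j]]
    cls <- sample(names(cfg$class_probs), 1, prob = cfg$class_probs)
    cn <- .draw_cn(cfg)
    cand <- multiplicity_candidates(cn$majA, cn$fracA, cn$majB, cn$fracB)
    feasible <- cand[cand > 0 &
                       compute_weight(cand, cn$ntot_t, tn, cfg$purity,
                                      cfg$eps) > 0]
    tries <- 0
    while (length(feasible) == 0 && tries < 100) {
      cn <- .draw_cn(cfg)
      cand <- multiplicity_candidates(cn$majA, cn$fracA, cn$majB, cn$fracB)
      feasible <- cand[cand > 0 &
                         compute_weight(cand, cn$ntot_t, tn, cfg$purity,
                                        cfg$eps) > 0]
      tries <- tries + 1
    }
    if (length(feasible) == 0) {
      warning("no feasible multiplicity after 100 draws for SV ", j)
      feasible <- 1
    }
    m <- if (length(feasible) == 1) feasible else sample(feasible, 1)
    cnt <- .draw_counts(cls, m, cn$ntot_t, tn, phi, cfg)
    dirs <- .class_dirs(cls)
    pos1 <- 1e5 * j
    intrx <- cls == "INTRX"
    rows[[j]] <- data.frame(
      id = paste0(id_prefix, j),
      chrom1 = "1", pos1 = pos1, dir1 = dirs[1],
      chrom2 = if (intrx) "2" else "1",
      pos2 = if (intrx) pos1 else pos1 + 5e4, dir2 = dirs[2],
      svclass = cls,
      b1 = cnt$b[1], b2 = cnt$b[2],
      norm1_raw = cnt$o[1], norm2_raw = cnt$o[2],
      m_true = m,
      majA_1 = cn$majA, minA_1 = cn$minA, fracA_1 = cn$fracA,
      majB_1 = cn$majB, minB_1 = cn$minB, fracB_1 = cn$fracB,
      ntot_t_1 = cn$ntot_t, ntot_n_1 = tn,
      majA_2 = cn$majA, minA_2 = cn$minA, fracA_2 = cn$fracA,
      majB_2 = cn$majB, minB_2 = cn$minB, fracB_2 = cn$fracB,
      ntot_t_2 = cn$ntot_t, ntot_n_2 = tn,
      stringsAsFactors = FALSE)
  }
  variants <- do.call(rbind, rows)
  # raw VAFs, then the DNA-gain adjustment
  af <- 1 - cfg$purity / cfg$ploidy
  gain <- variants$svclass %in% SV_GAIN_CLASSES
  variants$vaf1_raw <- variants$b1 / (variants$b1 + variants$norm1_raw)
  variants$vaf2_raw <- variants$b2 / (variants$b2 + variants$norm2_raw)
  variants$norm1 <- variants$norm1_raw * ifelse(gain, af, 1)
  variants$norm2 <- variants$norm2_raw * ifelse(gain, af, 1)
  variants$depth1 <- variants$b1 + variants$norm1
  variants$depth2 <- variants$b2 + variants$norm2
  variants$vaf1 <- ifelse(variants$depth1 > 0,
                          variants$b1 / variants$depth1, NA)
  variants$vaf2 <- ifelse(variants$depth2 > 0,
                          variants$b2 / variants$depth2, NA)
  variants$support <- round((variants$b1 + variants$b2) / 2)
  variants$adjusted <- gain
  truth <- data.frame(id = variants$id,
                      ccf_true = cfg$ccf[clone],
                      cluster_true = clone,
                      clonality_true = ifelse(cfg$ccf[clone] < 0.7,
                                              "subclonal", "clonal"),
                      m_true = variants$m_true,
                      svclass = variants$svclass,
                      stringsAsFactors = FALSE)
  structure(list(variants = variants, truth = truth, config = cfg,
                 seed = seed),
            class = "sv_sim")
}

#' @export
print.sv_sim <- function(x, ...) {
  cat(sprintf("sv_sim: %d SVs, clone CCF(s) %s, purity %.2f, depth %g\n",
              nrow(x$variants), paste(x$config$ccf, collapse = "/"),
              x$config$purity, x$config$depth))
  invisible(x)
}

#' Build an in-silico two-sample mixture at count level
#'
#' Emulates mixing two clonal samples at proportions `pA` and `1 - pA`:
#' shared variants keep a true CCF of 1, variants private to sample A get
#' CCF `pA`, private to B get `1 - pA`. Read counts are re-drawn from the
#' forward model at the new CCFs (each variant keeps its class, background
#' copy number and multiplicity). The expected truth has three clusters
#' `{1, pA, 1 - pA}` (two when `pA = 0.5` or no shared variants exist).
#'
#' @param simA,simB Clonal `sv_sim` datasets (truth CCF 1 throughout).
#' @param shared_ids Variant ids present in both samples.
#' @param pA Mixture proportion of sample A, in (0, 1).
#' @param seed Seed for the re-drawn counts.
#' @return An `sv_sim` for the mixture.
#' @export
make_mixture <- function(simA, simB, shared_ids, pA, seed = 1) {
  if (pA <= 0 || pA >= 1) stop("pA must be in (0, 1)")
  stopifnot(inherits(simA, "sv_sim"), inherits(simB, "sv_sim"))
  if (any(simA$truth$ccf_true != 1) || any(simB$truth$ccf_true != 1))
    stop("mixture inputs must be clonal (true CCF 1)")
  if (!all(shared_ids %in% simA$variants$id) ||
      !all(shared_ids %in% simB$variants$id))
    stop("shared_ids must appear in both datasets")
  set.seed(seed)
  cfg <- simA$config
  b_only <- setdiff(simB$variants$id, shared_ids)
  a_only <- setdiff(simA$variants$id, shared_ids)
  if (length(intersect(a_only, b_only)))
    stop("private variant ids collide between the samples: ",
         paste(utils::head(intersect(a_only, b_only), 5), collapse = ", "))
  vb <- simB$variants[simB$variants$id %in% b_only, , drop = FALSE]
  va <- simA$variants
  pool <- rbind(va, vb)
  from_a <- seq_len(nrow(pool)) <= nrow(va)
  shared <- pool$id %in% shared_ids
  phi <- round(ifelse(shared, 1, ifelse(from_a, pA, 1 - pA)), 10)
  cluster <- ifelse(shared, 1L, ifelse(from_a, 2L, 3L))
  af <- 1 - cfg$purity / cfg$ploidy
  for (j in seq_len(nrow(pool))) {
    cnt <- .draw_counts(pool$svclass[j], pool$m_true[j], pool$ntot_t_1[j],
                        pool$ntot_n_1[j], phi[j], cfg)
    pool$b1[j] <- cnt$b[1]; pool$b2[j] <- cnt$b[2]
    pool$norm1_raw[j] <- cnt$o[1]; pool$norm2_raw[j] <- cnt$o[2]
  }
  gain <- pool$svclass %in% SV_GAIN_CLASSES
  pool$vaf1_raw <- pool$b1 / (pool$b1 + pool$norm1_raw)
  pool$vaf2_raw <- pool$b2 / (pool$b2 + pool$norm2_raw)
  pool$norm1 <- pool$norm1_raw * ifelse(gain, af, 1)
  pool$norm2 <- pool$norm2_raw * ifelse(gain, af, 1)
  pool$depth1 <- pool$b1 + pool$norm1
  pool$depth2 <- pool$b2 + pool$norm2
  pool$vaf1 <- ifelse(pool$depth1 > 0, pool$b1 / pool$depth1, NA)
  pool$vaf2 <- ifelse(pool$depth2 > 0, pool$b2 / pool$depth2, NA)
  pool$support <- round((pool$b1 + pool$b2) / 2)
  truth <- data.frame(id = pool$id, ccf_true = phi, cluster_true = cluster,
                      clonality_true = ifelse(phi < 0.7, "subclonal",
                                              "clonal"),
                      m_true = pool$m_true, svclass = pool$svclass,
                      stringsAsFactors = FALSE)
  rownames(pool) <- NULL
  structure(list(variants = pool, truth = truth, config = cfg, seed = seed),
            class = "sv_sim")
}

#' Perturb background copy-number annotations
#'
#' Systematic perturbations for robustness experiments: `cn_minus_1`
#' subtracts one from the primary clone's major allele (falling back to
#' the minor allele when the major is 1; a 1-0 state is left unchanged);
#' `cn_plus_1` adds one to the primary clone's major allele;
#' `frac_pm_03` adds 0.3 to the primary clone fraction of subclonal
#' segments unless the result would exceed 0.9, in which case 0.3 is
#' subtracted; the second clone's fraction is set to the complement.
#' Weighted total tumour copy numbers are recomputed.
#'
#' @param sim An `sv_sim` dataset.
#' @param mode One of `"cn_minus_1"`, `"cn_plus_1"`, `"frac_pm_03"`.
#' @param sides `"one"` (lower breakend only) or `"both"`.
#' @return The perturbed `sv_sim`.
#' @export
simulate_cn_perturbation <- function(sim, mode = c("cn_minus_1", "cn_plus_1",
                                                   "frac_pm_03"),
                                     sides = c("one", "both")) {
  mode <- match.arg(mode)
  sides <- match.arg(sides)
  v <- sim$variants
  ends <- if (sides == "one") 1 else 1:2
  for (e in ends) {
    majA <- v[[paste0("majA_", e)]]; minA <- v[[paste0("minA_", e)]]
    fracA <- v[[paste0("fracA_", e)]]
    majB <- v[[paste0("majB_", e)]]; minB <- v[[paste0("minB_", e)]]
    fracB <- v[[paste0("fracB_", e)]]
    if (mode == "cn_minus_1") {
      can_major <- majA > 1
      can_minor <- majA == 1 & minA >= 1
      majA[can_major] <- majA[can_major] - 1
      minA[can_minor] <- minA[can_minor] - 1   # 1-0 states untouched
    } else if (mode == "cn_plus_1") {
      majA <- majA + 1
    } else {
      sub <- !is.na(fracB)
      up <- sub & (fracA + 0.3 <= 0.9)
      dn <- sub & !up
      fracA[up] <- fracA[up] + 0.3
      fracA[dn] <- fracA[dn] - 0.3
      fracB[sub] <- 1 - fracA[sub]
    }
    v[[paste0("majA_", e)]] <- majA; v[[paste0("minA_", e)]] <- minA
    v[[paste0("fracA_", e)]] <- fracA
    v[[paste0("majB_", e)]] <- majB; v[[paste0("minB_", e)]] <- minB
    v[[paste0("fracB_", e)]] <- fracB
    tot <- fracA * (majA + minA)
    sub <- !is.na(fracB)
    tot[sub] <- tot[sub] + fracB[sub] * (majB[sub] + minB[sub])
    v[[paste0("ntot_t_", e)]] <- tot
  }
  sim$variants <- v
  sim
}

# ---- alignment-record fixtures -----------------------------------------

.sam_line <- function(qname, flag, chrom, pos, cigar, mchrom, mpos, tlen,
                      read_len) {
  paste(qname, flag, chrom, pos, 60, cigar, mchrom, mpos, tlen,
        paste(rep("A", read_len), collapse = ""), "*", sep = "\t")
}

#' Generate an indexed alignment fixture realising exact category counts
#'
#' Writes a small coordinate-sorted, indexed BAM whose fragments classify
#' into exactly the requested split/spanning/normal/anomalous tallies for
#' the given breakpoint under the standard read-classification rules:
#' split reads carry a soft clip longer than the clip threshold ending at
#' the breakend on the direction-matching side; spanning pairs face their
#' breakends with adjusted insert under the bound; normal pairs cross a
#' locus cleanly with ample overlap; anomalous reads are double-clipped at
#' the locus. Intra-chromosomal breakpoints must be separated by more than
#' twice the insert bound so the two ends' reads cannot interact.
#'
#' @param bp One-row breakpoint table with resolved `+`/`-` directions.
#' @param n_split_lo,n_split_hi Split reads at the lower/upper breakend.
#' @param n_span Spanning pairs.
#' @param n_norm_lo,n_norm_hi Normal fragments per end.
#' @param n_anom Anomalous (double-clipped) fragments at the lower end.
#' @param meta A [sample_meta()].
#' @param path Output path prefix (the `.bam` extension is added).
#' @return Path to the indexed BAM.
#' @export
generate_alignments <- function(bp, n_split_lo, n_split_hi, n_span,
                                n_norm_lo, n_norm_hi, n_anom, meta,
                                path = tempfile()) {
  stopifnot(nrow(bp) == 1, all(c(n_split_lo, n_split_hi, n_span,
                                 n_norm_lo, n_norm_hi, n_anom) >= 0))
  if (!bp$dir1 %in% c("+", "-") || !bp$dir2 %in% c("+", "-"))
    stop("breakpoint directions must be resolved")
  R <- meta$read_len
  max_ins <- meta$insert_mean + 3 * meta$insert_sd
  intra <- bp$chrom1 == bp$chrom2
  if (intra && (bp$pos2 - bp$pos1) <= 2 * max_ins + 2 * R)
    stop("breakends too close for non-interacting fixtures (need span > ",
         2 * max_ins + 2 * R, " bp)")
  if (min(bp$pos1, bp$pos2) <= max_ins + 2 * R)
    stop("breakend too close to the chromosome start for normal fragments")
  clip <- round(0.1 * R) + 5
  lines <- character(0)
  add <- function(...) lines <<- c(lines, .sam_line(...))

  split_reads <- function(p, dir, chrom, n, tag) {
    for (i in seq_len(n)) {
      off <- (i - 1) %% 20
      if (dir == "+") {
        aln <- R - clip
        start <- p - aln + 1
        add(paste0(tag, i), 65, chrom, start,
            paste0(aln, "M", clip, "S"), chrom, start - 150 - off, 0, R)
        add(paste0(tag, i), 129, chrom, start - 150 - off,
            paste0(R, "M"), chrom, start, 0, R)
      } else {
        aln <- R - clip
        add(paste0(tag, i), 81, chrom, p, paste0(clip, "S", aln, "M"),
            chrom, p + aln + 50 + off, 0, R)
        add(paste0(tag, i), 161, chrom, p + aln + 50 + off,
            paste0(R, "M"), chrom, p, 0, R)
      }
    }
  }
  facing_read <- function(p, dir, chrom, qname, flag_base, off) {
    # a read facing breakend (p, dir) with distance ~ (R + 10 + off)
    if (dir == "+") {
      start <- p - R - 10 - off + 1
      add(qname, flag_base, chrom, start, paste0(R, "M"), chrom, start, 0, R)
    } else {
      start <- p + 10 + off
      add(qname, flag_base + 16, chrom, start, paste0(R, "M"), chrom,
          start, 0, R)
    }
  }
  # splits
  split_reads(bp$pos1, bp$dir1, bp$chrom1, n_split_lo, "spl_lo")
  split_reads(bp$pos2, bp$dir2, bp$chrom2, n_split_hi, "spl_hi")
  # spanning pairs: one mate facing each breakend
  for (i in seq_len(n_span)) {
    off <- (i - 1) %% 20
    facing_read(bp$pos1, bp$dir1, bp$chrom1, paste0("span", i), 65, off)
    facing_read(bp$pos2, bp$dir2, bp$chrom2, paste0("span", i), 129, off)
  }
  # normals: clean FR pairs crossing the locus
  normal_pair <- function(p, chrom, n, tag) {
    for (i in seq_len(n)) {
      off <- (i - 1) %% 25
      s1 <- p - 60 - off
      s2 <- p + 40 + off
      add(paste0(tag, i), 97, chrom, s1, paste0(R, "M"), chrom, s2,
          s2 + R - s1, R)
      add(paste0(tag, i), 145, chrom, s2, paste0(R, "M"), chrom, s1,
          -(s2 + R - s1), R)
    }
  }
  normal_pair(bp$pos1, bp$chrom1, n_norm_lo, "norm_lo")
  normal_pair(bp$pos2, bp$chrom2, n_norm_hi, "norm_hi")
  # anomalous: double-clipped reads over the lower breakend
  for (i in seq_len(n_anom)) {
    off <- (i - 1) %% 10
    mid <- R - 2 * clip
    add(paste0("anom", i), 65, bp$chrom1, bp$pos1 - floor(mid / 2) - off,
        paste0(clip, "S", mid, "M", clip, "S"), bp$chrom1,
        bp$pos1 - 400, 0, R)
    add(paste0("anom", i), 129, bp$chrom1, bp$pos1 - 400, paste0(R, "M"),
        bp$chrom1, bp$pos1, 0, R)
  }
  chroms <- unique(c(bp$chrom1, bp$chrom2))
  maxpos <- max(bp$pos1, bp$pos2) + 1e5
  header <- c("@HD\tVN:1.6\tSO:unsorted",
              paste0("@SQ\tSN:", chroms, "\tLN:", maxpos))
  sam <- paste0(path, ".sam")
  writeLines(c(header, lines), sam)
  bam <- suppressMessages(Rsamtools::asBam(sam, path, overwrite = TRUE,
                                           indexDestination = TRUE))
  unlink(sam)
  bam
}
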