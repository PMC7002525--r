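#' Read-counting parameters
#'
#' @param clip_min Minimum soft-clip length (exclusive) for a split read;
#'   default `round(0.1 * read_len)` (10 for 100 bp reads), resolved when a
#'   [sample_meta()] is available.
#' @param window Positional tolerance around a breakend in bp (absorbs
#'   micro-homologies up to this length); default 6.
#' @param norm_overlap Minimum overlap of a normal fragment on each side of
#'   the locus in bp; default 10.
#' @param norm_clip_max Maximum soft-clip length tolerated on a normal
#'   read; default 6.
#' @param support_mode `"total"`: the supporting count b = s_l + s_u + c is
#'   shared by both ends' binomial trials (d_i = b + o_i); `"per-side"`:
#'   each end uses only its own split reads plus spanning (b_i = s_i + c).
#' @return Object of class `sv_count_params`.
#' @export
count_params <- function(clip_min = NULL, window = 6, norm_overlap = 10,
                         norm_clip_max = 6,
                         support_mode = c("total", "per-side")) {
  structure(list(clip_min = clip_min, window = window,
                 norm_overlap = norm_overlap, norm_clip_max = norm_clip_max,
                 support_mode = match.arg(support_mode)),
            class = "sv_count_params")
}

.resolve_clip_min <- function(params, meta) {
  if (!is.null(params$clip_min)) params$clip_min else round(0.1 * meta$read_len)
}

# ---- CIGAR / fragment helpers ------------------------------------------

# parse cigar strings -> data.frame(clip_left, clip_right, ref_width)
.parse_cigar <- function(cigar) {
  n <- length(cigar)
  cl <- cr <- rw <- numeric(n)
  ops <- regmatches(cigar, gregexpr("[0-9]+[MIDNSHP=X]", cigar))
  for (i in seq_len(n)) {
    o <- ops[[i]]
    len <- as.numeric(sub("[A-Z=]$", "", o))
    op <- sub("^[0-9]+", "", o)
    if (length(op) && op[1] == "S") cl[i] <- len[1]
    if (length(op) > 1 && op[length(op)] == "S") cr[i] <- len[length(op)]
    rw[i] <- sum(len[op %in% c("M", "D", "N", "=", "X")])
  }
  data.frame(clip_left = cl, clip_right = cr, ref_width = rw)
}

# normalise a scanBam chunk into a reads data.frame
.reads_df <- function(res) {
  df <- data.frame(qname = res$qname, flag = res$flag,
                   chrom = as.character(res$rname), pos = res$pos,
                   cigar = res$cigar, strand = as.character(res$strand),
                   isize = res$isize, stringsAsFactors = FALSE)
  df <- df[!is.na(df$pos) & !is.na(df$cigar), , drop = FALSE]
  if (nrow(df) == 0) {
    df$clip_left <- df$clip_right <- df$ref_width <- df$aln_end <- numeric(0)
    return(df)
  }
  cig <- .parse_cigar(df$cigar)
  df$clip_left <- cig$clip_left
  df$clip_right <- cig$clip_right
  df$ref_width <- cig$ref_width
  df$aln_end <- df$pos + df$ref_width - 1
  df[!duplicated(paste(df$qname, df$flag, df$pos)), , drop = FALSE]
}

# split-read test for the reads of one fragment at breakend (p, dir)
.frag_split <- function(reads, p, dir, clip_min, window, norm_clip_max) {
  dbl <- reads$clip_left > norm_clip_max & reads$clip_right > norm_clip_max
  if (dir == "+")
    any(!dbl & reads$clip_right > clip_min & abs(reads$aln_end - p) <= window)
  else
    any(!dbl & reads$clip_left > clip_min & abs(reads$pos - p) <= window)
}

# one read facing breakend (p, dir): returns distance to the break or NA
.face_dist <- function(read, p, dir, window, max_ins) {
  if (dir == "+") {
    if (read$strand == "+" && read$aln_end <= p + window &&
        read$aln_end >= p - max_ins)
      return(p - read$pos + 1)
  } else {
    if (read$strand == "-" && read$pos >= p - window &&
        read$pos <= p + max_ins)
      return(read$aln_end - p + 1)
  }
  NA_real_
}

# spanning test: mates flank (p1,d1)-(p2,d2), both facing their break,
# adjusted insert (sum of distances to the breakends) under the bound
.frag_spanning <- function(reads, p1, d1, p2, d2, window, max_ins) {
  if (nrow(reads) < 2) return(FALSE)
  for (a in 1:2) {
    r1 <- reads[a, ]; r2 <- reads[3 - a, ]
    dist1 <- .face_dist(r1, p1, d1, window, max_ins)
    dist2 <- .face_dist(r2, p2, d2, window, max_ins)
    if (!is.na(dist1) && !is.na(dist2) && dist1 > 0 && dist2 > 0 &&
        dist1 + dist2 < max_ins)
      return(TRUE)
  }
  FALSE
}

# normal test at breakend p: read or insert crosses the locus with
# norm_overlap bp on each side, clips under threshold, sane fragment
.frag_normal <- function(reads, p, norm_overlap, norm_clip_max, max_ins) {
  if (any(reads$clip_left > norm_clip_max | reads$clip_right > norm_clip_max))
    return(FALSE)
  os <- min(reads$pos); oe <- max(reads$aln_end)
  if (!(os <= p - norm_overlap && oe >= p + norm_overlap)) return(FALSE)
  if (oe - os + 1 >= max_ins) return(FALSE)
  read_crosses <- any(reads$pos <= p & reads$aln_end >= p)
  if (read_crosses) return(TRUE)
  # insert between the mates must cross, with conventional FR orientation
  if (nrow(reads) < 2) return(FALSE)
  left <- reads[which.min(reads$pos), ]
  right <- reads[which.max(reads$aln_end), ]
  left$strand == "+" && right$strand == "-" &&
    left$aln_end < p && right$pos > p
}

# does the fragment touch the neighbourhood of p at all?
.frag_touches <- function(reads, p, window) {
  os <- min(reads$pos); oe <- max(reads$aln_end)
  os <= p + window && oe >= p - window
}

#' Classify one read fragment at a breakend
#'
#' Applies the split / spanning / normal / anomalous decision rules for a
#' single read pair against one breakend. A fragment is `SPLIT` when a read
#' has a soft-clip boundary within `window` bp of the breakend, clip length
#' above `clip_min`, on the side matching the breakend direction;
#' `SPANNING` when the mates flank the breakpoint facing their respective
#' breakends with adjusted insert (sum of each mate's distance to its
#' breakend) under `insert_mean + 3 * insert_sd`; `NORMAL` when the read or
#' the insert crosses the locus with at least `norm_overlap` bp on each
#' side and soft-clips at most `norm_clip_max`; `ANOMALOUS` when it touches
#' the locus but fits no category (oversized insert, mates not facing the
#' break, double-clipped, sub-threshold clip, opposite-direction support);
#' otherwise `IRRELEVANT`.
#'
#' @param reads Data frame with one row per read of the fragment: columns
#'   `pos`, `cigar`, `strand` (and anything else is ignored).
#' @param be_pos,be_dir Breakend position and direction (`"+"` or `"-"`).
#' @param meta A [sample_meta()].
#' @param params A [count_params()].
#' @param partner_pos,partner_dir The partner breakend (required to detect
#'   `SPANNING`; omitted in single-breakend use).
#' @return One of `"SPLIT"`, `"SPANNING"`, `"NORMAL"`, `"ANOMALOUS"`,
#'   `"IRRELEVANT"`.
#' @export
classify_read <- function(reads, be_pos, be_dir, meta,
                          params = count_params(),
                          partner_pos = NULL, partner_dir = NULL) {
  stopifnot(be_dir %in% c("+", "-"))
  cig <- .parse_cigar(reads$cigar)
  reads$clip_left <- cig$clip_left
  reads$clip_right <- cig$clip_right
  reads$ref_width <- cig$ref_width
  reads$aln_end <- reads$pos + reads$ref_width - 1
  clip_min <- .resolve_clip_min(params, meta)
  max_ins <- meta$insert_mean + 3 * meta$insert_sd
  if (.frag_split(reads, be_pos, be_dir, clip_min, params$window,
                  params$norm_clip_max))
    return("SPLIT")
  if (!is.null(partner_pos) &&
      .frag_spanning(reads, be_pos, be_dir, partner_pos, partner_dir,
                     params$window, max_ins))
    return("SPANNING")
  if (.frag_normal(reads, be_pos, params$norm_overlap, params$norm_clip_max,
                   max_ins))
    return("NORMAL")
  if (.frag_touches(reads, be_pos, params$window)) return("ANOMALOUS")
  "IRRELEVANT"
}

# fetch reads around a position from an open BamFile
.fetch_reads <- function(bam, chrom, p, max_ins, read_len) {
  pad <- max_ins + read_len
  param <- Rsamtools::ScanBamParam(
    which = GenomicRanges::GRanges(chrom, IRanges::IRanges(max(1, p - pad), p + pad)),
    what = c("qname", "flag", "rname", "pos", "cigar", "strand", "isize"),
    flag = Rsamtools::scanBamFlag(isUnmappedQuery = FALSE,
                                  isSecondaryAlignment = FALSE,
                                  isDuplicate = FALSE))
  .reads_df(Rsamtools::scanBam(bam, param = param)[[1]])
}

#' Count supporting and normal reads for one SV
#'
#' Tallies split reads per end, spanning read pairs, normal reads per end
#' and anomalous fragments for one breakpoint from a coordinate-sorted,
#' indexed BAM. Supporting reads are only counted when they match the
#' breakend direction (avoiding double-counting for events with reads on
#' both sides, such as inversions). The high-depth flag is set when the
#' read depth at either breakend exceeds `expected_depth * max_cn`.
#'
#' @param bp One-row breakpoint table with resolved directions (not
#'   `COMPLEX`).
#' @param bam_path Path to an indexed BAM.
#' @param meta A [sample_meta()].
#' @param params A [count_params()].
#' @return A one-row data.frame: `split1`, `split2`, `span`, `norm1`,
#'   `norm2`, `anom`, `support`, `depth1`, `depth2`, `high_depth`.
#' @export
count_sv <- function(bp, bam_path, meta, params = count_params()) {
  stopifnot(nrow(bp) == 1)
  if (bp$svclass == "COMPLEX") stop("COMPLEX SVs are not counted")
  if (!bp$dir1 %in% c("+", "-") || !bp$dir2 %in% c("+", "-"))
    stop("directions must be resolved before counting (SV ", bp$id, ")")
  if (!file.exists(bam_path)) stop("BAM not found: ", bam_path)
  bam <- Rsamtools::BamFile(bam_path)
  max_ins <- meta$insert_mean + 3 * meta$insert_sd
  r1 <- tryCatch(.fetch_reads(bam, bp$chrom1, bp$pos1, max_ins, meta$read_len),
                 error = function(e) stop("alignment fetch failed at ",
                                          bp$chrom1, ":", bp$pos1, ": ",
                                          conditionMessage(e)))
  r2 <- .fetch_reads(bam, bp$chrom2, bp$pos2, max_ins, meta$read_len)
  reads <- rbind(r1, r2)
  reads <- reads[!duplicated(paste(reads$qname, reads$flag, reads$pos)), ,
                 drop = FALSE]
  intra <- bp$chrom1 == bp$chrom2
  tally <- c(split1 = 0, split2 = 0, span = 0, norm1 = 0, norm2 = 0, anom = 0)
  if (nrow(reads) > 0) {
    for (q in unique(reads$qname)) {
      fr <- reads[reads$qname == q, , drop = FALSE]
      fr1 <- fr[fr$chrom == bp$chrom1, , drop = FALSE]
      fr2 <- fr[fr$chrom == bp$chrom2, , drop = FALSE]
      # spanning: one mate facing each breakend, adjusted insert bounded
      span_ok <- FALSE
      if (intra) {
        span_ok <- .frag_spanning(fr1, bp$pos1, bp$dir1, bp$pos2, bp$dir2,
                                  params$window, max_ins)
      } else if (nrow(fr1) >= 1 && nrow(fr2) >= 1) {
        d1 <- .face_dist(fr1[1, ], bp$pos1, bp$dir1, params$window, max_ins)
        d2 <- .face_dist(fr2[1, ], bp$pos2, bp$dir2, params$window, max_ins)
        span_ok <- !is.na(d1) && !is.na(d2) && d1 > 0 && d2 > 0 &&
          d1 + d2 < max_ins
      }
      if (span_ok) {
        tally["span"] <- tally["span"] + 1
        next
      }
      c1 <- if (nrow(fr1)) classify_read(fr1, bp$pos1, bp$dir1, meta, params)
      else "IRRELEVANT"
      c2 <- if (nrow(fr2)) classify_read(fr2, bp$pos2, bp$dir2, meta, params)
      else "IRRELEVANT"
      if (c1 == "SPLIT") tally["split1"] <- tally["split1"] + 1
      if (c2 == "SPLIT" && !(intra && c1 == "SPLIT"))
        tally["split2"] <- tally["split2"] + 1
      if (c1 == "NORMAL") tally["norm1"] <- tally["norm1"] + 1
      if (c2 == "NORMAL" && !(intra && bp$pos1 == bp$pos2))
        tally["norm2"] <- tally["norm2"] + 1
      if (!c1 %in% c("SPLIT", "NORMAL") && !c2 %in% c("SPLIT", "NORMAL") &&
          (c1 == "ANOMALOUS" || c2 == "ANOMALOUS"))
        tally["anom"] <- tally["anom"] + 1
    }
  }
  # depth at the exact loci (reads whose aligned span covers the position)
  dep1 <- if (nrow(reads)) sum(reads$chrom == bp$chrom1 &
                                 reads$pos <= bp$pos1 &
                                 reads$aln_end >= bp$pos1) else 0
  dep2 <- if (nrow(reads)) sum(reads$chrom == bp$chrom2 &
                                 reads$pos <= bp$pos2 &
                                 reads$aln_end >= bp$pos2) else 0
  high <- max(dep1, dep2) > meta$expected_depth * meta$max_cn
  out <- data.frame(t(tally))
  out$support <- out$split1 + out$split2 + out$span
  if (params$support_mode == "per-side") {
    out$depth1 <- out$split1 + out$span + out$norm1
    out$depth2 <- out$split2 + out$span + out$norm2
  } else {
    out$depth1 <- out$support + out$norm1
    out$depth2 <- out$support + out$norm2
  }
  out$high_depth <- high
  out
}

#' Count reads for a whole breakpoint table
#'
#' @param bp Breakpoint table (COMPLEX rows are skipped with NA counts).
#' @inheritParams count_sv
#' @return `bp` with count columns appended (see [count_sv()]).
#' @export
count_svs <- function(bp, bam_path, meta, params = count_params()) {
  res <- lapply(seq_len(nrow(bp)), function(i) {
    if (bp$svclass[i] == "COMPLEX")
      data.frame(split1 = NA_real_, split2 = NA_real_, span = NA_real_,
                 norm1 = NA_real_, norm2 = NA_real_, anom = NA_real_,
                 support = NA_real_, depth1 = NA_real_, depth2 = NA_real_,
                 high_depth = NA)
    else count_sv(bp[i, ], bam_path, meta, params)
  })
  cbind(bp, do.call(rbind, res))
}

#' Adjust normal read counts for DNA-gain events
#'
#' Duplicated sequence does not displace reference-supporting DNA, so
#' normal read counts at DNA-gain breakends (classes `DUP`, `INTDUP`) are
#' inflated relative to other rearrangements. They are rescaled by the
#' factor `1 - purity / ploidy`; other classes are untouched. Adjusted
#' counts are carried as reals; depths are recomputed.
#'
#' @param counts Variant table with count columns (from [count_svs()] or
#'   [simulate_counts()]).
#' @param meta A [sample_meta()].
#' @return The table with `norm1`, `norm2`, `depth1`, `depth2` adjusted and
#'   a logical `adjusted` column.
#' @export
adjust_normals <- function(counts, meta) {
  af <- 1 - meta$purity / meta$ploidy
  if (af < 0) {
    warning("purity exceeds ploidy; adjustment factor clamped at 0")
    af <- 0
  }
  gain <- counts$svclass %in% SV_GAIN_CLASSES
  counts$norm1[gain] <- counts$norm1[gain] * af
  counts$norm2[gain] <- counts$norm2[gain] * af
  counts$depth1 <- counts$support + counts$norm1
  counts$depth2 <- counts$support + counts$norm2
  counts$adjusted <- gain
  counts
}

#' Compute per-end variant allele frequencies
#'
#' VAF at each end is the supporting read count divided by the end's total
#' depth (`support / (support + norm_i)`), 0 when there is no support, and
#' `NA` (flagged for filtering) when the depth is 0.
#'
#' @param counts Variant table with (adjusted) count columns.
#' @return The table with `vaf1` and `vaf2` columns.
#' @export
compute_vaf <- function(counts) {
  v1 <- ifelse(counts$depth1 > 0, counts$support / counts$depth1,
               ifelse(counts$support == 0, NA_real_, NA_real_))
  v2 <- ifelse(counts$depth2 > 0, counts$support / counts$depth2, NA_real_)
  v1[counts$support == 0 & counts$depth1 > 0] <- 0
  v2[counts$support == 0 & counts$depth2 > 0] <- 0
  counts$vaf1 <- v1
  counts$vaf2 <- v2
  counts
}
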