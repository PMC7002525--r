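#' Filtering parameters
#'
#' Defaults follow a conservative baseline: at least one split and one
#' spanning read, per-end depth above `min_depth`, SV span above the
#' fragment size for intra-chromosomal events, and a 6 bp window for
#' germline matching.
#'
#' @param min_split Minimum split-read support (either end); default 1.
#' @param min_span Minimum spanning-read support; default 1.
#' @param min_depth Per-end depth must exceed this (b_min); default 2.
#' @param germline_window Breakend matching window for germline rejection
#'   in bp; default 6.
#' @param size_min Minimum intra-chromosomal SV size in bp; defaults to
#'   the fragment size (`insert_mean`) when `NULL`.
#' @param require_valid_cn Reject SVs with no valid copy-number state
#'   (major + minor >= 1) at either end when a CN map is supplied; default
#'   `TRUE`.
#' @param neutral_only Optionally keep only SVs whose background states are
#'   copy-number neutral (1, 1) at both ends; default `FALSE`.
#' @param exclude_subclonal_cn Optionally reject SVs on subclonal CN
#'   segments; default `FALSE`.
#' @param blacklist Optional data.frame of half-open regions (`chrom`,
#'   `start`, `end`); any overlap of a breakend rejects the SV.
#' @return Object of class `sv_filter_params`.
#' @export
filter_params <- function(min_split = 1, min_span = 1, min_depth = 2,
                          germline_window = 6, size_min = NULL,
                          require_valid_cn = TRUE, neutral_only = FALSE,
                          exclude_subclonal_cn = FALSE, blacklist = NULL) {
  stopifnot(min_split >= 0, min_span >= 0, min_depth >= 0,
            germline_window >= 0)
  structure(list(min_split = min_split, min_span = min_span,
                 min_depth = min_depth, germline_window = germline_window,
                 size_min = size_min, require_valid_cn = require_valid_cn,
                 neutral_only = neutral_only,
                 exclude_subclonal_cn = exclude_subclonal_cn,
                 blacklist = blacklist),
            class = "sv_filter_params")
}

#' Assign background copy-number states to both breakends
#'
#' The background state is the copy number that existed before the SV
#' occurred. For intra-chromosomal SVs this is the segment immediately
#' upstream of the lower breakend and downstream of the upper breakend
#' (never the segment inside the rearranged interval). For
#' inter-chromosomal translocations the state is taken in the direction
#' opposite each breakend's direction. Positions outside all segments fall
#' back to the normal-ploidy default with a warning.
#'
#' @param bp One-row breakpoint table with resolved directions.
#' @param cn_map A `sv_cn_map` from [read_cn_input()], or `NULL`.
#' @param meta A [sample_meta()].
#' @return List of two [cn_annotation()] objects (`lo`, `hi`).
#' @export
assign_background_cn <- function(bp, cn_map, meta) {
  stopifnot(nrow(bp) == 1)
  if (bp$chrom1 == bp$chrom2) {
    q1 <- bp$pos1 - 1L  # upstream of the lower breakend
    q2 <- bp$pos2 + 1L  # downstream of the upper breakend
  } else {
    # opposite the breakend direction: "+" joins rightwards, so background
    # lies left (upstream); "-" the mirror
    q1 <- if (bp$dir1 == "+") bp$pos1 - 1L else bp$pos1 + 1L
    q2 <- if (bp$dir2 == "+") bp$pos2 - 1L else bp$pos2 + 1L
  }
  list(lo = suppressWarnings(cn_at(cn_map, bp$chrom1, max(1L, q1), meta)),
       hi = suppressWarnings(cn_at(cn_map, bp$chrom2, max(1L, q2), meta)))
}

# does an SV match any germline breakpoint (both ends within window bp,
# matching directions) with supporting reads?
.germline_hit <- function(bp, germ, window) {
  if (is.null(germ) || nrow(germ) == 0) return(FALSE)
  any(germ$chrom1 == bp$chrom1 & germ$chrom2 == bp$chrom2 &
        abs(germ$pos1 - bp$pos1) <= window &
        abs(germ$pos2 - bp$pos2) <= window &
        germ$dir1 == bp$dir1 & germ$dir2 == bp$dir2 &
        !is.na(germ$support) & germ$support >= 1)
}

.blacklist_hit <- function(bp, bl) {
  if (is.null(bl) || nrow(bl) == 0) return(FALSE)
  hit <- function(chrom, pos)
    any(bl$chrom == chrom & bl$start <= pos & pos < bl$end)
  hit(bp$chrom1, bp$pos1) || hit(bp$chrom2, bp$pos2)
}

#' Apply variant filters and attach background copy number
#'
#' Order-independent filtering of counted SVs. Rejection reason codes:
#' `complex` (unresolved events), `high_depth`, `germline` (a germline
#' breakpoint with at least one supporting read matches both ends within
#' the window and direction), `size` (intra-chromosomal span at or below
#' the fragment size), `support` (split or spanning reads below minimum),
#' `depth` (either end's depth at or below `min_depth`), `invalid_cn` (no
#' valid state — major + minor >= 1 — at either end), `non_neutral`,
#' `subclonal_cn`, `blacklist`. Kept variants get per-end background CN
#' columns attached (an end with an invalid state individually falls back
#' to the default annotation and is flagged in `cn_fallback`).
#'
#' @param counts Counted variant table (after [adjust_normals()] and
#'   [compute_vaf()], though raw tables are accepted).
#' @param cn_map Optional `sv_cn_map`.
#' @param meta A [sample_meta()].
#' @param params A [filter_params()].
#' @param germline Optional germline count table (same dialect as
#'   `counts`).
#' @return List with `kept` (variant table with CN columns) and `rejected`
#'   (input rows plus a `reason` column); the two partition the input.
#' @export
apply_filters <- function(counts, cn_map = NULL, meta,
                          params = filter_params(), germline = NULL) {
  n <- nrow(counts)
  size_min <- if (is.null(params$size_min)) meta$insert_mean else params$size_min
  reason <- rep(NA_character_, n)
  ann_lo <- vector("list", n)
  ann_hi <- vector("list", n)
  fallback <- logical(n)
  for (i in seq_len(n)) {
    row <- counts[i, ]
    if (row$svclass == "COMPLEX") { reason[i] <- "complex"; next }
    if (isTRUE(row$high_depth)) { reason[i] <- "high_depth"; next }
    if (.germline_hit(row, germline, params$germline_window)) {
      reason[i] <- "germline"; next
    }
    if (row$chrom1 == row$chrom2 && (row$pos2 - row$pos1) <= size_min) {
      reason[i] <- "size"; next
    }
    if ((row$split1 + row$split2) < params$min_split ||
        row$span < params$min_span) {
      reason[i] <- "support"; next
    }
    if (row$depth1 <= params$min_depth || row$depth2 <= params$min_depth) {
      reason[i] <- "depth"; next
    }
    if (.blacklist_hit(row, params$blacklist)) {
      reason[i] <- "blacklist"; next
    }
    ann <- assign_background_cn(row, cn_map, meta)
    valid <- function(a) sum(a$states$major[1], a$states$minor[1]) >= 1
    v_lo <- valid(ann$lo); v_hi <- valid(ann$hi)
    if (!is.null(cn_map)) {
      if (params$require_valid_cn && !v_lo && !v_hi) {
        reason[i] <- "invalid_cn"; next
      }
      neutral <- function(a) nrow(a$states) == 1 &&
        a$states$major[1] == 1 && a$states$minor[1] == 1
      if (params$neutral_only && !(neutral(ann$lo) && neutral(ann$hi))) {
        reason[i] <- "non_neutral"; next
      }
      if (params$exclude_subclonal_cn &&
          (nrow(ann$lo$states) > 1 || nrow(ann$hi$states) > 1)) {
        reason[i] <- "subclonal_cn"; next
      }
      # one invalid end: keep, fall back to default annotation, flag
      if (!v_lo) { ann$lo <- .default_cn_annotation(row$chrom1, meta); fallback[i] <- TRUE }
      if (!v_hi) { ann$hi <- .default_cn_annotation(row$chrom2, meta); fallback[i] <- TRUE }
    }
    ann_lo[[i]] <- ann$lo
    ann_hi[[i]] <- ann$hi
  }
  keep <- is.na(reason)
  kept <- counts[keep, , drop = FALSE]
  if (nrow(kept) > 0) {
    cn_cols <- do.call(rbind, lapply(which(keep), function(i)
      as.data.frame(c(.cn_cols(ann_lo[[i]], 1), .cn_cols(ann_hi[[i]], 2)))))
    kept <- cbind(kept, cn_cols)
    kept$cn_fallback <- fallback[keep]
  }
  rejected <- counts[!keep, , drop = FALSE]
  if (nrow(rejected) > 0) rejected$reason <- reason[!keep]
  else rejected$reason <- character(0)
  rownames(kept) <- rownames(rejected) <- NULL
  list(kept = kept, rejected = rejected)
}
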