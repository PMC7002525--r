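#' @keywords internal
"_PACKAGE"

#' Breakend direction codes
#'
#' A breakend direction records which side of the locus is joined to the
#' distant partner locus: `"+"` means the breakpoint lies on the right side
#' of the locus (the retained sequence extends leftwards from the position,
#' soft-clipped read portions lie to the right), `"-"` is the mirror case.
#' `"mixed"` marks loci with substantial soft-clip evidence on both sides
#' (multiple breakend pairs involved), `"unknown"` means no evidence.
#'
#' @format Character vector of the four valid codes.
#' @export
SV_DIRECTIONS <- c("+", "-", "mixed", "unknown")

#' Structural variant classification codes
#'
#' The recognised rearrangement classes: deletion (`DEL`), tandem
#' duplication (`DUP`), interspersed duplication (`INTDUP`), inversion
#' (`INV`), intra-chromosomal translocation (`TRX`), inter-chromosomal
#' translocation (`INTRX`), plus `UNKNOWN` (no rule fired) and `COMPLEX`
#' (unresolvable multi-breakpoint events, discarded before counting).
#' `DUP` and `INTDUP` are the DNA-gain classes whose normal read counts
#' receive the purity/ploidy adjustment (see [adjust_normals()]).
#'
#' @format Character vector of the valid class codes.
#' @export
SV_CLASSES <- c("DEL", "DUP", "INTDUP", "INV", "TRX", "INTRX",
                "UNKNOWN", "COMPLEX")

#' DNA-gain SV classes
#' @format Character vector; subset of [SV_CLASSES].
#' @export
SV_GAIN_CLASSES <- c("DUP", "INTDUP")

#' Construct a breakpoint table
#'
#' The canonical internal record for paired breakends. One row per SV with
#' the lower breakend first: on a shared chromosome `pos1 <= pos2`; for
#' inter-chromosomal events `chrom1` is the lexicographically (numerically,
#' where possible) lower chromosome. Rows violating the ordering are
#' swapped silently.
#'
#' @param chrom1,pos1,dir1 Chromosome, 1-based position and direction of
#'   the lower breakend. Directions must be in [SV_DIRECTIONS].
#' @param chrom2,pos2,dir2 The upper breakend.
#' @param svclass SV class per row (see [SV_CLASSES]); default `"UNKNOWN"`.
#' @param id Stable identifiers; autogenerated `sv1, sv2, ...` if omitted.
#' @return A `data.frame` with columns `id`, `chrom1`, `pos1`, `dir1`,
#'   `chrom2`, `pos2`, `dir2`, `svclass`.
#' @examples
#' breakpoints("1", 1000, "+", "1", 5000, "-")
#' @export
breakpoints <- function(chrom1, pos1, dir1, chrom2, pos2, dir2,
                        svclass = "UNKNOWN", id = NULL) {
  n <- length(pos1)
  stopifnot(length(pos2) == n)
  chrom1 <- as.character(chrom1); chrom2 <- as.character(chrom2)
  dir1 <- as.character(dir1); dir2 <- as.character(dir2)
  svclass <- rep_len(as.character(svclass), n)
  if (is.null(id)) id <- paste0("sv", seq_len(n))
  if (!all(dir1 %in% SV_DIRECTIONS) || !all(dir2 %in% SV_DIRECTIONS))
    stop("invalid breakend direction; must be one of: ",
         paste(SV_DIRECTIONS, collapse = " "))
  if (!all(svclass %in% SV_CLASSES))
    stop("invalid svclass; must be one of: ", paste(SV_CLASSES, collapse = " "))
  if (any(pos1 < 1) || any(pos2 < 1)) stop("breakend positions must be >= 1")
  bp <- data.frame(id = as.character(id),
                   chrom1 = chrom1, pos1 = as.integer(pos1), dir1 = dir1,
                   chrom2 = chrom2, pos2 = as.integer(pos2), dir2 = dir2,
                   svclass = svclass, stringsAsFactors = FALSE)
  # enforce lo/hi ordering
  swap <- (bp$chrom1 == bp$chrom2 & bp$pos1 > bp$pos2) |
    (bp$chrom1 != bp$chrom2 & .chrom_rank(bp$chrom1) > .chrom_rank(bp$chrom2))
  if (any(swap)) {
    tmp <- bp[swap, c("chrom1", "pos1", "dir1")]
    bp[swap, c("chrom1", "pos1", "dir1")] <- bp[swap, c("chrom2", "pos2", "dir2")]
    bp[swap, c("chrom2", "pos2", "dir2")] <- tmp
  }
  bp
}

# orderable chromosome rank: numeric chromosomes first in numeric order,
# then X, Y, M/MT, then anything else lexicographically
.chrom_rank <- function(chrom) {
  ch <- sub("^chr", "", as.character(chrom))
  num <- suppressWarnings(as.numeric(ch))
  r <- ifelse(!is.na(num), num,
              ifelse(ch == "X", 100, ifelse(ch == "Y", 101,
                     ifelse(ch %in% c("M", "MT"), 102, 103))))
  # distinguish non-standard names deterministically
  r + ifelse(r == 103, match(ch, sort(unique(ch))) / 1e3, 0)
}

#' Sample-level sequencing and model metadata
#'
#' @param purity Tumour purity t in (0, 1]: the fraction of sequenced cells
#'   that are tumour cells.
#' @param ploidy Tumour ploidy n_p > 0: average tumour genome copy number.
#' @param error_rate Sequencing error constant in \[0, 1); default `1e-3`.
#' @param expected_depth Expected reads per locus (lambda); default 50.
#' @param max_cn Maximum expected copy number; loci whose mean depth
#'   exceeds `expected_depth * max_cn` are flagged high-depth. Default 4.
#' @param insert_mean,insert_sd Mean and standard deviation of the insert
#'   (fragment) size; defaults 300 and 20.
#' @param read_len Read length in bp; default 100.
#' @param male Logical; if `TRUE`, X/Y loci have normal total copy number 1.
#' @return Object of class `sv_sample_meta`.
#' @examples
#' sample_meta(purity = 0.75, ploidy = 2)
#' @export
sample_meta <- function(purity, ploidy = 2, error_rate = 1e-3,
                        expected_depth = 50, max_cn = 4,
                        insert_mean = 300, insert_sd = 20, read_len = 100,
                        male = FALSE) {
  stopifnot(purity > 0, purity <= 1, ploidy > 0,
            error_rate >= 0, error_rate < 1,
            expected_depth > 0, max_cn > 0,
            insert_mean > 0, insert_sd >= 0, read_len > 0)
  structure(list(purity = purity, ploidy = ploidy, error_rate = error_rate,
                 expected_depth = expected_depth, max_cn = max_cn,
                 insert_mean = insert_mean, insert_sd = insert_sd,
                 read_len = read_len, male = male),
            class = "sv_sample_meta")
}

#' @export
print.sv_sample_meta <- function(x, ...) {
  cat(sprintf(paste0("sample_meta: purity %.3f, ploidy %.2f, error %.2g, ",
                     "depth %g, max_cn %g, insert %g+/-%g, read_len %g\n"),
              x$purity, x$ploidy, x$error_rate, x$expected_depth, x$max_cn,
              x$insert_mean, x$insert_sd, x$read_len))
  invisible(x)
}

# normal total copy number at a locus
.normal_total_cn <- function(chrom, meta) {
  ifelse(meta$male & sub("^chr", "", chrom) %in% c("X", "Y"), 1, 2)
}

#' Background copy-number annotation for one locus
#'
#' One or two allele-specific copy-number states (two when the segment is
#' subclonal) with clone fractions summing to 1. The weighted total tumour
#' copy number is `sum(frac * (major + minor))` over the states.
#'
#' @param major,minor Non-negative copy numbers per state.
#' @param frac Clone fractions in (0, 1], summing to 1.
#' @param total_normal Total copy number of the normal population (2 for
#'   autosomes).
#' @return Object of class `sv_cn_annotation`: list with `states`
#'   (data.frame `major`, `minor`, `frac`), `total_tumour`, `total_normal`.
#' @examples
#' cn_annotation(major = c(2, 1), minor = c(1, 1), frac = c(0.6, 0.4))
#' @export
cn_annotation <- function(major, minor, frac = 1, total_normal = 2) {
  stopifnot(length(major) == length(minor),
            length(frac) == length(major),
            length(major) %in% c(1L, 2L))
  if (any(major < 0) || any(minor < 0)) stop("copy numbers must be >= 0")
  if (any(frac <= 0) || any(frac > 1)) stop("clone fractions must be in (0,1]")
  if (abs(sum(frac) - 1) > 1e-6) stop("clone fractions must sum to 1")
  states <- data.frame(major = as.numeric(major), minor = as.numeric(minor),
                       frac = as.numeric(frac))
  structure(list(states = states,
                 total_tumour = sum(states$frac * (states$major + states$minor)),
                 total_normal = total_normal),
            class = "sv_cn_annotation")
}

#' @export
print.sv_cn_annotation <- function(x, ...) {
  st <- x$states
  cat("cn_annotation:",
      paste(sprintf("%g+%g (frac %g)", st$major, st$minor, st$frac),
            collapse = "; "),
      sprintf("| total_tumour %.3f, total_normal %g\n",
              x$total_tumour, x$total_normal))
  invisible(x)
}

# default annotation when no CN data covers a locus: tumour total matches
# the normal total, no subclonality
.default_cn_annotation <- function(chrom, meta) {
  tn <- .normal_total_cn(chrom, meta)
  cn_annotation(major = ceiling(tn / 2), minor = floor(tn / 2),
                frac = 1, total_normal = tn)
}

# flatten per-end CN annotations into table columns (used by filter/simulate)
.cn_cols <- function(ann, end) {
  st <- ann$states
  out <- list(st$major[1], st$minor[1], st$frac[1],
              if (nrow(st) > 1) st$major[2] else NA_real_,
              if (nrow(st) > 1) st$minor[2] else NA_real_,
              if (nrow(st) > 1) st$frac[2] else NA_real_,
              ann$total_tumour, ann$total_normal)
  names(out) <- paste0(c("majA", "minA", "fracA", "majB", "minB", "fracB",
                         "ntot_t", "ntot_n"), "_", end)
  out
}
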