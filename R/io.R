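#' Read structural-variant breakpoint input
#'
#' Reads paired single-nucleotide-resolution SV breakends either from a VCF
#' with `BND` records (VCF 4.2 bracket notation; mates resolved via the
#' `MATEID` INFO field or, failing that, by reciprocal ALT coordinates) or
#' from a tab-delimited file with header
#' `chrom1,pos1,dir1,chrom2,pos2,dir2[,classification]`. Caller-provided
#' directions and classes are preserved when present; otherwise breakends
#' get direction `"unknown"` and class `"UNKNOWN"`.
#'
#' For a BND record the ALT bracket encodes the local direction: a bracket
#' *after* the base (`t[p[`, `t]p]`) means the retained local sequence lies
#' left of the locus (direction `"+"`); a bracket *before* the base
#' (`]p]t`, `[p[t`) means direction `"-"`.
#'
#' @param path Path to the input file.
#' @param dialect `"vcf_bnd"` or `"tsv_pairs"`; default guessed from the
#'   file extension (`.vcf` / `.vcf.gz` selects `"vcf_bnd"`).
#' @return A breakpoint table (see [breakpoints()]).
#' @export
read_sv_input <- function(path, dialect = c("auto", "vcf_bnd", "tsv_pairs")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("SV input file not found: ", path)
  if (dialect == "auto")
    dialect <- if (grepl("\\.vcf(\\.gz)?$", path)) "vcf_bnd" else "tsv_pairs"
  switch(dialect,
         vcf_bnd = .read_sv_vcf(path),
         tsv_pairs = .read_sv_tsv(path))
}

.read_sv_tsv <- function(path) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE,
                          colClasses = "character")
  if (nrow(df) == 0) {
    warning("empty SV input: ", path)
    return(breakpoints(character(), integer(), character(),
                       character(), integer(), character(), id = character()))
  }
  need <- c("chrom1", "pos1", "dir1", "chrom2", "pos2", "dir2")
  if (!all(need %in% names(df)))
    stop("tsv_pairs input must have columns ", paste(need, collapse = ","))
  p1 <- suppressWarnings(as.integer(df$pos1))
  p2 <- suppressWarnings(as.integer(df$pos2))
  if (anyNA(p1) || anyNA(p2))
    stop("malformed coordinate in rows: ",
         paste(which(is.na(p1) | is.na(p2)), collapse = ", "))
  dirs1 <- ifelse(df$dir1 %in% SV_DIRECTIONS, df$dir1, "unknown")
  dirs2 <- ifelse(df$dir2 %in% SV_DIRECTIONS, df$dir2, "unknown")
  cls <- if ("classification" %in% names(df))
    ifelse(df$classification %in% SV_CLASSES, df$classification, "UNKNOWN")
  else "UNKNOWN"
  id <- if ("id" %in% names(df)) df$id else NULL
  breakpoints(df$chrom1, p1, dirs1, df$chrom2, p2, dirs2,
              svclass = cls, id = id)
}

# parse a VCF 4.2 BND ALT string -> list(chrom, pos, local_dir, mate_dir)
.parse_bnd_alt <- function(alt) {
  m <- regmatches(alt, regexec("([\\[\\]])([^\\[\\]:]+):([0-9]+)([\\[\\]])",
                               alt, perl = TRUE))[[1]]
  if (length(m) == 0 || m[2] != m[5]) return(NULL)
  bracket <- m[2]
  before <- regexpr("[\\[\\]]", alt, perl = TRUE) == 1L  # bracket first?
  list(chrom = m[3], pos = as.integer(m[4]),
       local_dir = if (before) "-" else "+",
       mate_dir = if (bracket == "]") "+" else "-")
}

.read_sv_vcf <- function(path) {
  vcf <- VariantAnnotation::readVcf(path, genome = "unknown")
  rr <- SummarizedExperiment::rowRanges(vcf)
  alt <- vapply(VariantAnnotation::alt(vcf),
                function(a) as.character(a)[1], character(1))
  is_bnd <- grepl("[\\[\\]]", alt, perl = TRUE)
  if (!any(is_bnd)) {
    warning("no BND records in ", path)
    return(breakpoints(character(), integer(), character(),
                       character(), integer(), character(), id = character()))
  }
  ids <- names(rr)[is_bnd]
  chrom <- as.character(GenomicRanges::seqnames(rr))[is_bnd]
  pos <- GenomicRanges::start(rr)[is_bnd]
  alt <- alt[is_bnd]
  parsed <- lapply(alt, .parse_bnd_alt)
  bad <- vapply(parsed, is.null, logical(1))
  if (any(bad))
    stop("malformed BND ALT for record(s): ", paste(ids[bad], collapse = ", "))
  mate_chrom <- vapply(parsed, `[[`, character(1), "chrom")
  mate_pos <- vapply(parsed, `[[`, integer(1), "pos")
  local_dir <- vapply(parsed, `[[`, character(1), "local_dir")
  inf <- VariantAnnotation::info(vcf)
  mateid <- if ("MATEID" %in% names(inf)) {
    mi <- inf$MATEID
    if (methods::is(mi, "CharacterList") || is.list(mi))
      vapply(mi, function(x) if (length(x)) as.character(x)[1] else NA_character_,
             character(1))[is_bnd]
    else as.character(mi)[is_bnd]
  } else rep(NA_character_, sum(is_bnd))

  # resolve mate index: by MATEID when present, else reciprocal coordinates
  idx <- match(mateid, ids)
  need <- which(is.na(idx))
  for (i in need) {
    j <- which(chrom == mate_chrom[i] & pos == mate_pos[i] &
                 mate_chrom == chrom[i] & mate_pos == pos[i])
    j <- setdiff(j, i)
    if (length(j) >= 1) idx[i] <- j[1]
  }
  if (anyNA(idx))
    stop("unresolvable BND mate for record(s): ",
         paste(ids[is.na(idx)], collapse = ", "))
  # keep each pair once (first occurrence by file order)
  first <- seq_along(idx) < idx
  # self-inconsistent pairings (mate's mate differs) are record-level errors
  recip <- idx[idx[first]] == which(first)
  if (any(!recip))
    stop("non-reciprocal BND mate pairing for record(s): ",
         paste(ids[first][!recip], collapse = ", "))
  i1 <- which(first); i2 <- idx[first]
  breakpoints(chrom[i1], pos[i1], local_dir[i1],
              chrom[i2], pos[i2], local_dir[i2],
              id = sub("_[12ab]$", "", ids[i1]))
}

#' Read allele-specific copy-number segmentation input
#'
#' Supported dialects: Battenberg subclones tables (columns `chr`,
#' `startpos`, `endpos`, `nMaj1_A`, `nMin1_A`, `frac1_A` and optionally
#' `nMaj2_A`, `nMin2_A`, `frac2_A`; only the first segmentation solution
#' is used, and a segment with `frac1_A = 1` is treated as clonal),
#' ASCAT-like tables (`chr`, `start`, `end`, `nMajor`, `nMinor`) and a
#' consensus format (`chromosome`, `start`, `end`, `major_cn`, `minor_cn`,
#' `clonal_frequency`). Segment coordinates are interpreted 1-based
#' half-open `[start, end)` for queries; overlapping segments keep the
#' first by file order with a warning; rows with clone fractions outside
#' (0, 1] are rejected with a warning.
#'
#' @param path Path to the segmentation file (tab-delimited with header).
#' @param dialect `"battenberg"`, `"ascat"` or `"consensus"`.
#' @return Object of class `sv_cn_map`, queryable with [cn_at()].
#' @export
read_cn_input <- function(path, dialect = c("battenberg", "ascat", "consensus")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("CN input file not found: ", path)
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  cols <- switch(dialect,
    battenberg = c(chrom = "chr", start = "startpos", end = "endpos",
                   majA = "nMaj1_A", minA = "nMin1_A", fracA = "frac1_A"),
    ascat = c(chrom = "chr", start = "start", end = "end",
              majA = "nMajor", minA = "nMinor"),
    consensus = c(chrom = "chromosome", start = "start", end = "end",
                  majA = "major_cn", minA = "minor_cn",
                  fracA = "clonal_frequency"))
  if (!all(cols %in% names(df)))
    stop(dialect, " CN input missing column(s): ",
         paste(setdiff(cols, names(df)), collapse = ", "))
  seg <- data.frame(chrom = as.character(df[[cols["chrom"]]]),
                    start = as.numeric(df[[cols["start"]]]),
                    end = as.numeric(df[[cols["end"]]]),
                    majA = as.numeric(df[[cols["majA"]]]),
                    minA = as.numeric(df[[cols["minA"]]]),
                    stringsAsFactors = FALSE)
  seg$fracA <- if (is.na(cols["fracA"])[1] || !"fracA" %in% names(cols)) 1
  else as.numeric(df[[cols["fracA"]]])
  if (dialect == "ascat") seg$fracA <- 1
  seg$majB <- seg$minB <- seg$fracB <- NA_real_
  if (dialect == "battenberg" &&
      all(c("nMaj2_A", "nMin2_A", "frac2_A") %in% names(df))) {
    seg$majB <- as.numeric(df$nMaj2_A)
    seg$minB <- as.numeric(df$nMin2_A)
    seg$fracB <- as.numeric(df$frac2_A)
  }
  # frac1_A == 1 means clonal
  clonal <- !is.na(seg$fracA) & abs(seg$fracA - 1) < 1e-9
  seg$majB[clonal] <- seg$minB[clonal] <- seg$fracB[clonal] <- NA_real_
  seg$fracA[clonal] <- 1

  bad <- is.na(seg$fracA) | seg$fracA <= 0 | seg$fracA > 1 |
    (!is.na(seg$fracB) & (seg$fracB <= 0 | seg$fracB > 1))
  if (any(bad)) {
    warning(sum(bad), " CN segment(s) with clone fraction outside (0,1] rejected")
    seg <- seg[!bad, , drop = FALSE]
  }
  # subclonal rows must have complementary fractions
  sub <- !is.na(seg$fracB)
  seg$fracB[sub] <- 1 - seg$fracA[sub]

  # resolve overlaps: keep the first by file order
  if (nrow(seg) > 1) {
    gr <- GenomicRanges::GRanges(seg$chrom,
                                 IRanges::IRanges(seg$start, seg$end - 1))
    hits <- GenomicRanges::findOverlaps(gr, drop.self = TRUE,
                                        drop.redundant = TRUE)
    drop <- unique(pmax(S4Vectors::queryHits(hits),
                        S4Vectors::subjectHits(hits)))
    if (length(drop)) {
      warning(length(drop), " overlapping CN segment(s) dropped (first by ",
              "file order kept)")
      seg <- seg[-drop, , drop = FALSE]
    }
  }
  structure(list(segments = seg,
                 granges = GenomicRanges::GRanges(
                   seg$chrom, IRanges::IRanges(seg$start, pmax(seg$start, seg$end - 1)))),
            class = "sv_cn_map")
}

#' @export
print.sv_cn_map <- function(x, ...) {
  cat(sprintf("cn_map: %d segments on %d chromosome(s)\n",
              nrow(x$segments), length(unique(x$segments$chrom))))
  invisible(x)
}

#' Query the copy-number state covering a position
#'
#' @param cn_map Object from [read_cn_input()], or `NULL`.
#' @param chrom,pos Locus to query (1-based). Segments are half-open
#'   `[start, end)`.
#' @param meta Optional [sample_meta()]; used for the normal-ploidy default
#'   (sex chromosomes) when the position is uncovered or `cn_map` is `NULL`.
#' @return A [cn_annotation()]; the normal-ploidy default (tumour total =
#'   normal total, no subclonality) when uncovered, with a warning.
#' @export
cn_at <- function(cn_map, chrom, pos, meta = NULL) {
  if (is.null(meta)) meta <- sample_meta(purity = 1)
  if (is.null(cn_map))
    return(.default_cn_annotation(chrom, meta))
  seg <- cn_map$segments
  hit <- which(seg$chrom == as.character(chrom) &
                 seg$start <= pos & pos < seg$end)
  if (length(hit) == 0) {
    warning("position ", chrom, ":", pos, " outside all CN segments; ",
            "using normal-ploidy default")
    return(.default_cn_annotation(chrom, meta))
  }
  s <- seg[hit[1], ]
  tn <- .normal_total_cn(chrom, meta)
  if (is.na(s$fracB))
    cn_annotation(s$majA, s$minA, 1, total_normal = tn)
  else
    cn_annotation(c(s$majA, s$majB), c(s$minA, s$minB),
                  c(s$fracA, s$fracB), total_normal = tn)
}

.fmt_num <- function(x) {
  ifelse(is.na(x), "NA",
         ifelse(x == floor(x) & abs(x) < 1e15 & (x == 0 | abs(x) >= 1e-4),
                formatC(x, format = "d"), formatC(x, format = "f", digits = 6)))
}

.write_tsv <- function(df, path) {
  out <- df
  for (j in seq_along(out))
    if (is.numeric(out[[j]]) && !is.integer(out[[j]]))
      out[[j]] <- formatC(out[[j]], format = "f", digits = 6)
  out[is.na(df)] <- "NA"
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "NA")
  invisible(path)
}

#' Write clustering results to a run directory
#'
#' Emits deterministic UTF-8 tab-delimited files: `filtered_svs.tsv` (the
#' input variant table with counts, adjusted VAFs and background copy
#' number), `cluster_summary.tsv` (cluster id, posterior mean CCF, size),
#' `assignments.tsv` (per-variant end CCFs, representative CCF, cluster,
#' multiplicities, responsibility vector) and `run_meta.txt` (seed,
#' parameters, final ELBO). Floats are written with six decimal places;
#' missing values as `NA`.
#'
#' @param fit An `sv_cluster_fit` from [fit_ccf_clusters()].
#' @param out_dir Output directory (created if absent).
#' @return Invisibly, the paths written.
#' @export
write_results <- function(fit, out_dir) {
  stopifnot(inherits(fit, "sv_cluster_fit"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- file.path(out_dir, c("filtered_svs.tsv", "cluster_summary.tsv",
                                "assignments.tsv", "run_meta.txt"))
  .write_tsv(fit$variants, paths[1])
  sizes <- if (nrow(fit$assignments) > 0)
    tabulate(fit$assignments$cluster, nbins = fit$K) else rep(0L, fit$K)
  .write_tsv(data.frame(cluster = seq_len(fit$K), ccf_mean = fit$mu,
                        ccf_var = fit$sigma2, n_variants = sizes,
                        weight = fit$alpha / sum(fit$alpha)), paths[2])
  asn <- fit$assignments
  resp <- as.data.frame(fit$resp)
  names(resp) <- paste0("resp_", seq_len(ncol(resp)))
  .write_tsv(cbind(asn, resp), paths[3])
  meta_lines <- c(
    sprintf("seed\t%s", fit$config$seed),
    sprintf("K_range\t%s", paste(fit$config$K_range, collapse = ",")),
    sprintf("repeats\t%d", fit$config$repeats),
    sprintf("K_effective\t%d", fit$K),
    sprintf("elbo\t%.6f", fit$elbo),
    sprintf("n_iter\t%d", fit$n_iter),
    sprintf("converged\t%s", fit$converged),
    sprintf("purity\t%.6f", fit$meta$purity),
    sprintf("ploidy\t%.6f", fit$meta$ploidy),
    sprintf("error_rate\t%.6g", fit$meta$error_rate))
  writeLines(meta_lines, paths[4])
  invisible(paths)
}

#' Read back a written assignments table
#'
#' Convenience reader for the `assignments.tsv` written by
#' [write_results()].
#'
#' @param out_dir Run directory.
#' @return Data frame of per-variant assignments.
#' @export
read_assignments <- function(out_dir) {
  utils::read.delim(file.path(out_dir, "assignments.tsv"),
                    stringsAsFactors = FALSE)
}
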