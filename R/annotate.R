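#' Infer breakend direction from soft-clip evidence
#'
#' Reads soft-clipped on the *right* of a locus (aligned sequence arriving
#' from the left) support direction `"+"`; left-side clips support `"-"`.
#' When the minority side still holds at least 10% of all clipped reads the
#' locus is called `"mixed"` (multiple breakend pairs involved); with no
#' clipped reads at all it is `"unknown"`.
#'
#' @param n_clip_left,n_clip_right Counts of reads soft-clipped on the left
#'   and right side of the locus (non-negative).
#' @param mixed_frac Minority fraction at or above which the call is
#'   `"mixed"`; default 0.1.
#' @return One of `"+"`, `"-"`, `"mixed"`, `"unknown"`.
#' @examples
#' infer_direction(0, 12)   # "+"
#' infer_direction(3, 20)   # "mixed" (3/23 >= 10%)
#' infer_direction(1, 20)   # "+"     (1/21 < 10%)
#' @export
infer_direction <- function(n_clip_left, n_clip_right, mixed_frac = 0.1) {
  stopifnot(n_clip_left >= 0, n_clip_right >= 0)
  tot <- n_clip_left + n_clip_right
  if (tot == 0) return("unknown")
  minority <- min(n_clip_left, n_clip_right)
  if (minority / tot >= mixed_frac) return("mixed")
  if (n_clip_right >= n_clip_left) "+" else "-"
}

# do two breakpoints match at both ends within window bp (any direction)?
.ends_match <- function(bp, i, j, window) {
  bp$chrom1[i] == bp$chrom1[j] & bp$chrom2[i] == bp$chrom2[j] &
    abs(bp$pos1[i] - bp$pos1[j]) <= window &
    abs(bp$pos2[i] - bp$pos2[j]) <= window
}

#' Resolve mixed-direction breakpoints
#'
#' Breakends called `"mixed"` indicate that multiple breakend pairs share a
#' locus. Events with exactly one mixed end are split into two SVs, one
#' taking `"-"` and the other `"+"` at that end. Events mixed at both ends
#' are resolved against the rest of the input: (i) no partner matches
#' either locus: the event is emitted as `(-,-)` plus a duplicate `(+,+)`;
#' (ii) exactly one partner matches both loci within the window: the first
#' (by file order) becomes `(-,-)` and the partner `(+,+)`; (iii) three
#' breakpoints on one chromosome whose positional ranks form the pattern
#' `(1,2),(2,3),(1,3)` are treated as a reciprocal translocation and
#' assigned `(+,-),(+,-),(-,+)`; (iv) more than two matching partners: all
#' involved events are marked `COMPLEX` (discarded before counting).
#'
#' Loci are never changed; only directions, ids (a `.1`/`.2` suffix for
#' splits) and classes (`COMPLEX`) are. The SV count is conserved or
#' increased.
#'
#' @param bp Breakpoint table with per-end directions already inferred.
#' @param match_window Breakend matching tolerance in bp; default 6.
#' @return A breakpoint table with directions resolved.
#' @export
resolve_mixed <- function(bp, match_window = 6) {
  if (nrow(bp) == 0) return(bp)
  out <- list()
  mixed1 <- bp$dir1 == "mixed"
  mixed2 <- bp$dir2 == "mixed"
  both <- which(mixed1 & mixed2)
  one <- which(xor(mixed1, mixed2))
  none <- which(!mixed1 & !mixed2)
  complex_ids <- character()
  handled <- rep(FALSE, nrow(bp))

  # scenario (iii): translocation rank pattern among both-mixed triples on
  # one chromosome. Detect triples before pairwise handling.
  if (length(both) >= 3) {
    cand <- both[bp$chrom1[both] == bp$chrom2[both]]
    for (chr in unique(bp$chrom1[cand])) {
      tri <- cand[bp$chrom1[cand] == chr & !handled[cand]]
      if (length(tri) != 3) next
      pos <- sort(unique(c(bp$pos1[tri], bp$pos2[tri])))
      # collapse near-identical loci within the window
      grp <- cumsum(c(TRUE, diff(pos) > match_window))
      anchors <- tapply(pos, grp, min)
      if (length(anchors) != 3) next
      rank_of <- function(p) which.min(abs(anchors - p))
      ranks <- lapply(tri, function(i)
        c(rank_of(bp$pos1[i]), rank_of(bp$pos2[i])))
      key <- vapply(ranks, paste, character(1), collapse = ",")
      want <- c("1,2", "2,3", "1,3")
      if (setequal(key, want) && !anyDuplicated(key)) {
        dirs <- list(`1,2` = c("+", "-"), `2,3` = c("+", "-"),
                     `1,3` = c("-", "+"))
        for (i in seq_along(tri)) {
          row <- bp[tri[i], ]
          row$dir1 <- dirs[[key[i]]][1]
          row$dir2 <- dirs[[key[i]]][2]
          out[[length(out) + 1]] <- row
        }
        handled[tri] <- TRUE
      }
    }
  }

  for (i in both[!handled[both]]) {
    partners <- setdiff(which(vapply(seq_len(nrow(bp)), function(j)
      .ends_match(bp, i, j, match_window), logical(1))), i)
    if (length(partners) == 0) {
      # (i) lone event: emit (-,-) and a duplicated (+,+)
      lo <- hi <- bp[i, ]
      lo$dir1 <- lo$dir2 <- "-"
      hi$dir1 <- hi$dir2 <- "+"
      hi$id <- paste0(hi$id, ".dup")
      out[[length(out) + 1]] <- lo
      out[[length(out) + 1]] <- hi
      handled[i] <- TRUE
    } else if (length(partners) == 1 && !handled[partners]) {
      # (ii) matched pair: file order decides which is (-,-)
      j <- partners
      a <- bp[min(i, j), ]; b <- bp[max(i, j), ]
      a$dir1 <- a$dir2 <- "-"
      b$dir1 <- b$dir2 <- "+"
      out[[length(out) + 1]] <- a
      out[[length(out) + 1]] <- b
      handled[c(i, j)] <- TRUE
    } else if (length(partners) > 2) {
      # (iv) complex
      row <- bp[i, ]
      row$svclass <- "COMPLEX"
      out[[length(out) + 1]] <- row
      complex_ids <- c(complex_ids, bp$id[partners])
      handled[i] <- TRUE
    } else if (!handled[i]) {
      # partners already consumed or ambiguous two-partner case: complex
      row <- bp[i, ]
      row$svclass <- "COMPLEX"
      out[[length(out) + 1]] <- row
      handled[i] <- TRUE
    }
  }

  for (i in one) {
    # one mixed end: split into two events, mixed locus (-) with partner
    # (+), and the reverse
    a <- b <- bp[i, ]
    if (bp$dir1[i] == "mixed") {
      a$dir1 <- "-"; a$dir2 <- "+"
      b$dir1 <- "+"; b$dir2 <- "-"
    } else {
      a$dir2 <- "-"; a$dir1 <- "+"
      b$dir2 <- "+"; b$dir1 <- "-"
    }
    a$id <- paste0(a$id, ".1"); b$id <- paste0(b$id, ".2")
    out[[length(out) + 1]] <- a
    out[[length(out) + 1]] <- b
    handled[i] <- TRUE
  }

  res <- rbind(bp[none, , drop = FALSE], do.call(rbind, out))
  if (length(complex_ids))
    res$svclass[res$id %in% complex_ids] <- "COMPLEX"
  rownames(res) <- NULL
  res
}

#' Classify a structural variant
#'
#' Decision rules applied in order: inter-chromosomal events are `INTRX`
#' (no direction check); matching directions (`(+,+)` or `(-,-)`) give
#' `INV`; `(+,-)` with `pos1 < pos2` gives `DEL` unless the interspersed-
#' duplication / translocation partner patterns fire; `(-,+)` gives `DUP`
#' or `INTDUP`. An `INTDUP` requires a partner breakpoint whose lower ends
#' agree within `pos_tol` while the upper ends differ, with the
#' `(-,+)`/`(+,-)` signature pair; a `TRX` additionally requires a third
#' deletion-signature breakpoint spanning the mobile element with both ends
#' within `del_tol` bp.
#'
#' The function is pure: permuting `partners` never changes the result.
#'
#' @param bp One-row breakpoint table (directions resolved).
#' @param partners Breakpoint table of other events from the same sample
#'   (may be empty).
#' @param pos_tol Lower-end matching tolerance for INTDUP in bp; default 100.
#' @param del_tol Mobile-element end tolerance for TRX in bp; default 6.
#' @return A single class code from [SV_CLASSES].
#' @export
classify_sv <- function(bp, partners = NULL, pos_tol = 100, del_tol = 6) {
  stopifnot(nrow(bp) == 1)
  if (bp$svclass == "COMPLEX") return("COMPLEX")
  if (bp$chrom1 != bp$chrom2) return("INTRX")
  d1 <- bp$dir1; d2 <- bp$dir2
  if (!d1 %in% c("+", "-") || !d2 %in% c("+", "-")) return("UNKNOWN")
  if (d1 == d2) return("INV")
  if (is.null(partners)) partners <- bp[0, ]
  partners <- partners[partners$chrom1 == bp$chrom1 &
                         partners$chrom2 == bp$chrom2 &
                         partners$id != bp$id, , drop = FALSE]

  sig <- paste0(d1, d2)
  if (sig == "+-") {
    # deletion signature unless it spans an interspersed duplication's
    # mobile element together with a duplication-signature partner (TRX
    # companion) -- the deletion itself stays DEL; but this (+,-) event may
    # be the second breakpoint of an INTDUP pair
    j <- which(partners$dir1 == "-" & partners$dir2 == "+" &
                 abs(partners$pos1 - bp$pos1) <= pos_tol &
                 partners$pos2 != bp$pos2)
    if (length(j) > 0) {
      jj <- j[1]
      if (.has_trx_deletion(bp$pos1, bp$pos2, partners$pos1[jj],
                            partners$pos2[jj], partners, del_tol,
                            dup_lo = partners$pos1[jj]))
        return("TRX")
      return("INTDUP")
    }
    return("DEL")
  }
  if (sig == "-+") {
    j <- which(partners$dir1 == "+" & partners$dir2 == "-" &
                 abs(partners$pos1 - bp$pos1) <= pos_tol &
                 partners$pos2 != bp$pos2)
    if (length(j) > 0) {
      jj <- j[1]
      if (.has_trx_deletion(partners$pos1[jj], partners$pos2[jj],
                            bp$pos1, bp$pos2, partners, del_tol,
                            dup_lo = bp$pos1))
        return("TRX")
      return("INTDUP")
    }
    return("DUP")
  }
  "UNKNOWN"
}

# is there a third (+,-) deletion breakpoint spanning the mobile element?
# (l1,u1) = the deletion-signature member, (l2,u2) = the duplication-
# signature member of the pair: requires l3 ~ u2 and u3 ~ u1 within del_tol
.has_trx_deletion <- function(l1, u1, l2, u2, partners, del_tol, dup_lo) {
  any(partners$dir1 == "+" & partners$dir2 == "-" &
        abs(partners$pos1 - u2) <= del_tol &
        abs(partners$pos2 - u1) <= del_tol)
}

#' Classify every SV in a table
#'
#' Applies [classify_sv()] to each row using the rest of the table as
#' partner candidates; caller-provided classes (anything other than
#' `UNKNOWN`) are preserved.
#'
#' @param bp Breakpoint table.
#' @inheritParams classify_sv
#' @return The table with `svclass` filled in.
#' @export
classify_all <- function(bp, pos_tol = 100, del_tol = 6) {
  if (nrow(bp) == 0) return(bp)
  for (i in seq_len(nrow(bp))) {
    if (bp$svclass[i] != "UNKNOWN") next
    bp$svclass[i] <- classify_sv(bp[i, ], bp[-i, , drop = FALSE],
                                 pos_tol = pos_tol, del_tol = del_tol)
  }
  bp
}
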