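# Genomic-context classification of peaks (coding sequence vs intergenic
# and the mixed boundary categories) and replication-fork orientation
# calls: whether the gene(s) under a peak lie on the template for lagging
# or leading strand synthesis given the peak's position relative to
# ori/ter on its circular replicon.

CONTEXT_LEVELS <- c("CDS", "IR", "IR_5CDS", "IR_3CDS", "CDS5_IR_CDS3", "OTHER")
FORK_LEVELS <- c("LEAD", "LAG", "ND")

# genes overlapping an unwrapped peak, with coordinates rotated so the
# peak starts at 0 (genes may get negative starts; they stay contiguous)
genes_near_peak <- function(peak_start, peak_len, genes, L) {
  if (nrow(genes) == 0) return(genes[0, ])
  gs <- (genes$start - peak_start) %% L
  glen <- genes$end - genes$start
  # re-center genes whose rotated interval crosses the new seam so they
  # stay contiguous (negative start, containing 0)
  gs[gs + glen > L] <- gs[gs + glen > L] - L
  out <- genes
  out$start <- gs
  out$end <- gs + glen
  ov <- pmin(out$end, peak_len) - pmax(out$start, 0)
  out[ov > 0, , drop = FALSE]
}

# which strand-relative end of a gene does the peak cover: the gene's
# coordinate-left boundary is its 5' end on "+", its 3' end on "-"
covered_end <- function(side, strand) {
  if (side == "left") { if (strand == "+") "5" else "3" }
  else { if (strand == "+") "3" else "5" }
}

#' Classify the genomic context of one peak
#'
#' Categories: `CDS` (peak within one gene), `IR` (no gene overlap),
#' `IR_5CDS` / `IR_3CDS` (intergenic region plus the 5'- or 3'-terminal
#' part of exactly one adjacent gene, ends taken in the gene's own strand
#' orientation), `CDS5_IR_CDS3` (3' end of one gene, the intergenic
#' region, and the 5' end of the next), and `OTHER` for any remaining
#' configuration (e.g. a peak spanning a full gene, three or more genes,
#' or two same-polarity gene ends). A peak covering only an IR plus one
#' 3' gene end stays `IR_3CDS`; it is never promoted into `CDS5_IR_CDS3`.
#'
#' @param peak one-row data.frame (`replicon, start, end`; end may exceed
#'   L for a seam-wrapped peak).
#' @param genes gene annotation data.frame for the replicon (assumed
#'   non-overlapping).
#' @param replicons a [replicon_set()].
#' @return a single category string.
#' @export
classify_context <- function(peak, genes, replicons) {
  L <- replicon_row(replicons, peak$replicon)$length
  plen <- peak$end - peak$start
  g <- genes_near_peak(peak$start %% L, plen,
                       genes[genes$replicon == peak$replicon, , drop = FALSE],
                       L)
  n <- nrow(g)
  if (n == 0) return("IR")
  if (n == 1) {
    if (g$start <= 0 && g$end >= plen) return("CDS")
    if (g$start >= 0 && g$end <= plen) return("OTHER")  # spans full gene
    side <- if (g$start > 0) "left" else "right"
    # peak overhangs into the IR and covers the gene's boundary part:
    # side == "left" means the gene lies to the right, peak covers its
    # coordinate-left end
    return(if (covered_end(side, g$strand) == "5") "IR_5CDS" else "IR_3CDS")
  }
  if (n == 2) {
    g <- g[order(g$start), , drop = FALSE]
    left_partial <- g$start[1] < 0 && g$end[1] < plen
    right_partial <- g$start[2] > 0 && g$end[2] > plen
    if (!left_partial || !right_partial) return("OTHER")
    e1 <- covered_end("right", g$strand[1])  # covered end of left gene
    e2 <- covered_end("left", g$strand[2])   # covered end of right gene
    if (sort(c(e1, e2))[1] == "3" && sort(c(e1, e2))[2] == "5") {
      return("CDS5_IR_CDS3")
    }
    return("OTHER")
  }
  "OTHER"
}

#' Relative position of a peak within its host gene
#'
#' Peak midpoint position measured 5' to 3' in the gene's own orientation,
#' scaled to `[0, 1]`. Defined only for peaks fully contained in the gene
#' (`CDS` context).
#'
#' @param peak one-row peak data.frame.
#' @param gene one-row gene data.frame containing the peak.
#' @param replicons a [replicon_set()].
#' @return value in `[0, 1]`.
#' @export
relative_position_in_gene <- function(peak, gene, replicons) {
  L <- replicon_row(replicons, peak$replicon)$length
  glen <- gene$end - gene$start
  mid <- circ_midpoint(peak$start, peak$end, L)
  u <- ((mid - gene$start) %% L) / glen
  if (u > 1) stop_format("peak midpoint outside gene %s", gene$gene_id)
  if (gene$strand == "-") u <- 1 - u
  u
}

#' Replication-fork direction at a genomic position
#'
#' With bidirectional replication from `ori`, the fork covering a
#' position moves clockwise (coordinate-increasing, `CW`) on the arc from
#' ori to ter walked in increasing coordinates, and counterclockwise
#' (`CCW`) on the other arc. Positions equal to ori or ter are
#' `AMBIGUOUS`. Vectorized over `position`.
#'
#' @param position 0-based position(s) in `[0, L)`.
#' @param replicon optional single-row [replicon_set()] entry supplying
#'   `L`, `ori`, `ter`.
#' @param L,ori,ter geometry, if not given via `replicon`.
#' @return character vector over `{CW, CCW, AMBIGUOUS}`.
#' @export
fork_direction <- function(position, replicon = NULL,
                           L = replicon$length, ori = replicon$ori,
                           ter = replicon$ter) {
  stopifnot(all(position >= 0 & position < L))
  a <- (position - ori) %% L
  b <- (ter - ori) %% L
  ifelse(a == 0 | a == b, "AMBIGUOUS", ifelse(a < b, "CW", "CCW"))
}

#' Assign a LEAD/LAG/ND fork-orientation call to a peak
#'
#' The call compares the strand of the gene(s) under the peak with the
#' lagging-strand template at the peak midpoint: under a CW
#' (coordinate-increasing) fork the plus strand runs 5'->3' in the fork
#' direction and therefore templates discontinuous (lagging) synthesis;
#' under a CCW fork the minus strand does. Returns `LAG` when the
#' (unique, consistent) overlapping gene strand equals the lagging
#' template, `LEAD` otherwise, and `ND` when no gene overlaps the peak,
#' overlapping genes disagree in strand, the midpoint sits exactly at
#' ori/ter, or the peak spans ori or ter.
#'
#' @param peak one-row peak data.frame.
#' @param genes gene annotation data.frame.
#' @param replicon single-row [replicon_set()] entry.
#' @param use_summit use the `summit` column instead of the midpoint for
#'   the fork-direction position.
#' @return one of `"LEAD"`, `"LAG"`, `"ND"`.
#' @export
assign_fork_orientation <- function(peak, genes, replicon,
                                    use_summit = FALSE) {
  L <- replicon$length
  if (circ_contains(peak$start %% L, peak$end, replicon$ori, L) ||
      circ_contains(peak$start %% L, peak$end, replicon$ter, L)) {
    return("ND")
  }
  g <- genes_near_peak(peak$start %% L, peak$end - peak$start,
                       genes[genes$replicon == peak$replicon, , drop = FALSE],
                       L)
  if (nrow(g) == 0) return("ND")
  s <- unique(g$strand)
  if (length(s) != 1) return("ND")
  pos <- if (use_summit && !is.null(peak$summit)) peak$summit else
    circ_midpoint(peak$start, peak$end, L)
  d <- fork_direction(pos, replicon)
  if (d == "AMBIGUOUS") return("ND")
  lag_strand <- if (d == "CW") "+" else "-"
  if (s == lag_strand) "LAG" else "LEAD"
}

#' Annotate peaks with context, fork orientation, and ori distance
#'
#' @param peaks peak data.frame (as from [call_peaks()]).
#' @param genes gene annotation data.frame.
#' @param replicons a [replicon_set()].
#' @param use_summit pass the summit (when present) to the fork call.
#' @return `peaks` with added columns `category, fork, ori_distance,
#'   relative_gene_position` (the last is `NA` unless category is `CDS`).
#' @export
annotate_peaks <- function(peaks, genes, replicons, use_summit = FALSE) {
  n <- nrow(peaks)
  category <- character(n); fork <- character(n)
  ori_distance <- numeric(n); relpos <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    pk <- peaks[i, , drop = FALSE]
    rr <- replicon_row(replicons, pk$replicon)
    L <- rr$length
    category[i] <- classify_context(pk, genes, replicons)
    fork[i] <- assign_fork_orientation(pk, genes, rr, use_summit = use_summit)
    mid <- circ_midpoint(pk$start, pk$end, L)
    ori_distance[i] <- circular_distance(mid, rr$ori, L)
    if (category[i] == "CDS") {
      g <- genes_near_peak(pk$start %% L, pk$end - pk$start,
                           genes[genes$replicon == pk$replicon, ,
                                 drop = FALSE], L)
      host <- genes[genes$gene_id == g$gene_id[1], , drop = FALSE]
      relpos[i] <- relative_position_in_gene(pk, host, replicons)
    }
  }
  out <- peaks
  out$category <- category
  out$fork <- fork
  out$ori_distance <- ori_distance
  out$relative_gene_position <- relpos
  out
}

#' Summarize annotated peaks per replicon
#'
#' @param annotated data.frame from [annotate_peaks()].
#' @return list with `category` and `fork` count/percentage tables
#'   (percentages per replicon sum to 100).
#' @export
summarize_by_replicon <- function(annotated) {
  if (nrow(annotated) == 0) {
    empty <- data.frame(replicon = character(), level = character(),
                        count = integer(), percent = numeric())
    return(list(category = empty, fork = empty))
  }
  tab <- function(col, levels) {
    t <- table(factor(annotated$replicon),
               factor(annotated[[col]], levels = levels))
    df <- as.data.frame(t, stringsAsFactors = FALSE)
    names(df) <- c("replicon", "level", "count")
    tot <- stats::ave(df$count, df$replicon, FUN = sum)
    df$percent <- ifelse(tot > 0, 100 * df$count / tot, 0)
    df[order(df$replicon, match(df$level, levels)), , drop = FALSE]
  }
  list(category = tab("category", CONTEXT_LEVELS),
       fork = tab("fork", FORK_LEVELS))
}
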