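# Interval subtraction with bedtools `intersect -v` semantics and the
# two-step construct-subtraction filter that isolates peaks unique to the
# tagged active-RNP construct.

# expand unwrapped peaks (end may exceed L) into linear segments with ids
peak_segments <- function(peaks, replicons) {
  if (nrow(peaks) == 0) {
    return(data.frame(replicon = character(), start = numeric(),
                      end = numeric(), id = integer()))
  }
  L <- replicons$length[match(peaks$replicon, replicons$name)]
  if (anyNA(L)) {
    stop_format("unknown replicon '%s'", peaks$replicon[is.na(L)][1])
  }
  stopifnot(peaks$start >= 0, peaks$start < L, peaks$end > peaks$start,
            peaks$end <= peaks$start + L)
  wrap <- peaks$end > L
  data.frame(
    replicon = c(peaks$replicon, peaks$replicon[wrap]),
    start = c(peaks$start, rep(0, sum(wrap))),
    end = c(pmin(peaks$end, L), peaks$end[wrap] - L[wrap]),
    id = c(seq_len(nrow(peaks)), which(wrap)),
    stringsAsFactors = FALSE)
}

#' Remove intervals of `a` overlapping any interval of `b`
#'
#' Reproduces `bedtools intersect -a A -b B -v`: an element of `a` is kept
#' exactly when it shares zero bp with every element of `b` on the same
#' replicon (half-open abutment is not overlap; one shared bp excludes).
#' Seam-wrapped peaks are compared through their split segments, so
#' overlap on either side of the seam counts. Input order is preserved.
#'
#' @param a,b peak data.frames (`replicon, start, end`, end may exceed L
#'   for seam-wrapped peaks).
#' @param replicons a [replicon_set()].
#' @return the retained rows of `a`.
#' @export
subtract_overlapping <- function(a, b, replicons) {
  if (nrow(a) == 0 || nrow(b) == 0) return(a)
  sa <- peak_segments(a, replicons)
  sb <- peak_segments(b, replicons)
  drop_ids <- integer(0)
  for (rn in intersect(unique(sa$replicon), unique(sb$replicon))) {
    xa <- sa[sa$replicon == rn, , drop = FALSE]
    xb <- sb[sb$replicon == rn, , drop = FALSE]
    # half-open [start, end): IRanges is closed, so use end - 1
    ha <- IRanges::IRanges(start = xa$start + 1, end = xa$end)
    hb <- IRanges::IRanges(start = xb$start + 1, end = xb$end)
    ov <- IRanges::findOverlaps(ha, hb, minoverlap = 1)
    drop_ids <- c(drop_ids, xa$id[unique(S4Vectors::queryHits(ov))])
  }
  a[!(seq_len(nrow(a)) %in% drop_ids), , drop = FALSE]
}

#' Two-step unique-peak filter across constructs
#'
#' Removes from the tagged active-RNP peak set every peak overlapping the
#' IEP-only construct's peaks, then every survivor overlapping the
#' untagged construct's peaks (operation order fixed as in the original
#' two-step filter; subtraction is order-commutative, which the test
#' suite verifies as a property).
#'
#' @param tagged_rnp,iep_only,untagged peak data.frames for the three
#'   constructs.
#' @param replicons a [replicon_set()].
#' @return the unique peaks of `tagged_rnp`.
#' @export
unique_peaks <- function(tagged_rnp, iep_only, untagged, replicons) {
  step1 <- subtract_overlapping(tagged_rnp, iep_only, replicons)
  subtract_overlapping(step1, untagged, replicons)
}
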