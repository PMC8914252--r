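# Internal helpers shared across modules. All coordinates are 0-based
# half-open; circular wrap is represented by split segments or by an
# "unwrapped" form where end may exceed L (meaning the interval crosses
# the seam at L).

`%||%` <- function(x, y) if (is.null(x)) y else x

#' Circular distance between positions on a circular replicon
#'
#' Shortest arc distance `min(|p - o|, L - |p - o|)`; vectorized over `p`
#' and `o`.
#'
#' @param p,o integer positions in `[0, L)`.
#' @param L replicon length in bp.
#' @return numeric vector of distances in `[0, floor(L/2)]`.
#' @export
circular_distance <- function(p, o, L) {
  stopifnot(all(p >= 0 & p < L), all(o >= 0 & o < L), L > 0)
  d <- abs(p - o)
  pmin(d, L - d)
}

# Split an unwrapped interval [start, end) with 0 <= start < L and
# start < end <= start + L into 1 or 2 linear segments within [0, L).
split_circular <- function(start, end, L) {
  stopifnot(start >= 0, start < L, end > start, end <= start + L)
  if (end <= L) {
    data.frame(start = start, end = end)
  } else {
    data.frame(start = c(start, 0), end = c(L, end - L))
  }
}

# Vectorized: given segment data.frame columns (start, end) and ids,
# rebuild unwrapped intervals. Two rows sharing an id are joined at the
# seam: the row ending at L supplies the start, the row starting at 0 the
# wrapped end (so the joined interval has end > L). Ids appear at most
# twice.
unwrap_intervals <- function(df, L) {
  stopifnot(all(c("id", "start", "end") %in% names(df)))
  n <- nrow(df)
  if (n == 0) {
    df$len <- numeric(0)
    return(df)
  }
  o <- order(df$id)
  out <- df[o, , drop = FALSE]
  id <- out$id
  first_of_pair <- c(id[-n] == id[-1], FALSE)
  if (any(first_of_pair)) {
    i1 <- which(first_of_pair)
    i2 <- i1 + 1L
    s1 <- out$start[i1]; e1 <- out$end[i1]
    s2 <- out$start[i2]; e2 <- out$end[i2]
    hi_first <- e1 == L  # which piece touches the seam from below
    if (!all(ifelse(hi_first, s2 == 0, s1 == 0 & e2 == L))) {
      stop_format("malformed seam-split pair (id %s)",
                  id[i1[which(!ifelse(hi_first, s2 == 0,
                                      s1 == 0 & e2 == L))[1]]])
    }
    out$start[i1] <- ifelse(hi_first, s1, s2)
    out$end[i1] <- L + ifelse(hi_first, e2, e1)
    out <- out[-i2, , drop = FALSE]
  }
  out$len <- out$end - out$start
  rownames(out) <- NULL
  out
}

# Reverse complement of plain character DNA strings (A/C/G/T/N).
revcomp <- function(x) {
  if (length(x) == 0) return(x)
  if (length(x) == 1) {
    return(as.character(Biostrings::reverseComplement(
      Biostrings::DNAString(x))))
  }
  unname(as.character(Biostrings::reverseComplement(
    Biostrings::DNAStringSet(x))))
}

# Lean vector-level variant of unwrap_intervals for hot paths: returns
# parallel vectors (start, end, strand) with end possibly > L, one entry
# per read id.
unwrap_vectors <- function(start, end, strand, id, L) {
  n <- length(id)
  if (n == 0) return(list(start = start, end = end, strand = strand))
  o <- order(id)
  start <- start[o]; end <- end[o]; strand <- strand[o]; id <- id[o]
  first_of_pair <- c(id[-n] == id[-1], FALSE)
  if (any(first_of_pair)) {
    i1 <- which(first_of_pair)
    i2 <- i1 + 1L
    hi_first <- end[i1] == L
    start[i1] <- ifelse(hi_first, start[i1], start[i2])
    end[i1] <- L + ifelse(hi_first, end[i2], end[i1])
    keep <- rep(TRUE, n); keep[i2] <- FALSE
    start <- start[keep]; end <- end[keep]; strand <- strand[keep]
  }
  list(start = start, end = end, strand = strand)
}

# Fast reverse complement for many equal-width strings: complement and
# reverse the concatenation in one pass, then cut it back up in reverse
# order. Falls back to per-string conversion for ragged widths.
revcomp_many <- function(x) {
  n <- length(x)
  if (n == 0) return(x)
  w <- nchar(x)
  if (length(unique(w)) != 1) return(revcomp(x))
  k <- w[1]
  big <- revcomp(paste(x, collapse = ""))
  at <- seq.int(0, by = k, length.out = n)
  rev(substring(big, at + 1, at + k))
}

# Does the circular interval [start, end) (unwrapped form) contain
# position p on a circle of length L?
circ_contains <- function(start, end, p, L) {
  ((p - start) %% L) < (end - start)
}

# Midpoint of an unwrapped interval, mapped back to [0, L).
circ_midpoint <- function(start, end, L) {
  (start + (end - start) %/% 2) %% L
}

stop_format <- function(...) {
  stop(sprintf(...), call. = FALSE)
}
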