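# Per-base coverage from read placements (fixed fragment extension, as
# with model-free peak calling on sonication fragments of known size
# range) and mean-coverage comparison between library groups.

#' Per-base extended-fragment coverage on a circular replicon
#'
#' Each read is extended to `extension` bp from its 5' end in read
#' orientation (plus reads extend rightward from `start`, minus reads
#' leftward from `end`); coverage wraps across the circular seam.
#' Seam-split placements (two rows sharing an id) are re-joined first.
#'
#' @param reads placement data.frame with columns
#'   `replicon, start, end, strand, id`.
#' @param replicon a single-row [replicon_set()] entry (or the registry
#'   plus `name`).
#' @param extension fragment extension in bp (`>=` read length).
#' @param name replicon name when `replicon` is a multi-row registry.
#' @return object of class `coverage_track`: list with `replicon`,
#'   `values` (integer vector of length L) and `n_fragments`.
#' @export
pileup <- function(reads, replicon, extension = 300, name = NULL) {
  if (nrow(replicon) > 1) replicon <- replicon_row(replicon, name)
  L <- replicon$length
  df <- reads[reads$replicon == replicon$name, , drop = FALSE]
  if (nrow(df) > 0 && (any(df$start < 0) || any(df$end > L))) {
    stop_format("read outside [0, %d) on replicon %s", L, replicon$name)
  }
  uw <- unwrap_vectors(df$start, df$end, df$strand, df$id, L)
  if (length(uw$start) > 0 && extension < max(uw$end - uw$start)) {
    stop_format("extension (%d) shorter than read length (%d)",
                extension, max(uw$end - uw$start))
  }
  # 5' fragment start: read start for +, read end - extension for -
  fs <- ifelse(uw$strand == "+", uw$start, (uw$end %% L) - extension) %% L
  values <- fragment_coverage(fs, extension, L)
  structure(list(replicon = replicon$name, values = values,
                 n_fragments = length(fs)),
            class = "coverage_track")
}

# coverage of n fragments of fixed length starting at positions a (0-based,
# wrapped) on a circle of length L; cumsum-of-deltas, wrap split in two
fragment_coverage <- function(a, len, L) {
  if (length(a) == 0) return(integer(L))
  a <- a %% L
  b <- a + len
  over <- b > L
  starts <- c(a, rep(0, sum(over)))
  ends <- c(pmin(b, L), b[over] - L)
  inc <- tabulate(starts + 1L, nbins = L)
  dec <- tabulate(ends[ends < L] + 1L, nbins = L)
  as.integer(cumsum(inc - dec))
}

#' Mean per-base coverage over a region
#'
#' @param track a `coverage_track` from [pileup()].
#' @param region `NULL` for the whole replicon, or `c(start, end)` in the
#'   unwrapped convention (`end` may exceed L to indicate seam wrap).
#' @return arithmetic mean of the per-base values over the region.
#' @export
mean_coverage <- function(track, region = NULL) {
  v <- track$values
  L <- length(v)
  if (is.null(region)) return(mean(v))
  start <- region[1]; end <- region[2]
  if (end <= start) stop_format("empty region")
  stopifnot(start >= 0, start < L, end <= start + L)
  seg <- split_circular(start, end, L)
  tot <- sum(vapply(seq_len(nrow(seg)), function(i)
    sum(v[(seg$start[i] + 1):seg$end[i]]), numeric(1)))
  tot / (end - start)
}

#' Welch's unequal-variance two-sample t test
#'
#' Thin wrapper over the standard Welch test with explicit conventions
#' for degenerate inputs: if both groups have zero variance, `p = 1` when
#' the means are equal and `p = 0` otherwise.
#'
#' @param group_a,group_b numeric vectors (each of length `>= 2`).
#' @return list with `t`, `df`, `p` (two-sided).
#' @export
welch_t_test <- function(group_a, group_b) {
  stopifnot(length(group_a) >= 2, length(group_b) >= 2)
  va <- stats::var(group_a); vb <- stats::var(group_b)
  if (va == 0 && vb == 0) {
    eq <- isTRUE(all.equal(mean(group_a), mean(group_b)))
    return(list(t = if (eq) 0 else Inf, df = NA_real_,
                p = if (eq) 1 else 0))
  }
  tt <- stats::t.test(group_a, group_b, var.equal = FALSE)
  list(t = unname(tt$statistic), df = unname(tt$parameter),
       p = unname(tt$p.value))
}

#' Compare input and IP mean coverage per replicon
#'
#' For each replicon, tests whether mean coverage differs between the
#' input and IP library groups, both over the whole replicon and over the
#' origin-proximal window (all positions within `ori_window` circular bp
#' of ori on either arm, since replication is bidirectional).
#'
#' @param tracks named list of `coverage_track`s per library key (as from
#'   [pileup()] applied per library), for a single replicon.
#' @param replicon single-row [replicon_set()] entry.
#' @param ori_window half-width of the origin window in bp.
#' @param constructs restrict to these constructs (default: all, i.e. the
#'   pooled 9-vs-9 comparison).
#' @return data.frame with columns `replicon, scope, n_input, n_ip, t, df, p`.
#' @export
compare_input_vs_ip <- function(tracks, replicon, ori_window = 1000,
                                constructs = NULL) {
  keys <- library_keys()
  keys <- keys[keys$key %in% names(tracks), , drop = FALSE]
  if (!is.null(constructs)) {
    keys <- keys[keys$construct %in% constructs, , drop = FALSE]
  }
  in_keys <- keys$key[keys$fraction == "input"]
  ip_keys <- keys$key[keys$fraction == "IP"]
  if (length(in_keys) < 2 || length(ip_keys) < 2) {
    stop_format("need >= 2 input and >= 2 IP libraries")
  }
  L <- replicon$length
  ori <- replicon$ori
  w <- min(ori_window, floor(L / 2))
  ori_region <- c((ori - w) %% L, (ori - w) %% L + 2 * w)
  scope_means <- function(region) {
    list(input = vapply(in_keys, function(k)
           mean_coverage(tracks[[k]], region), numeric(1)),
         ip = vapply(ip_keys, function(k)
           mean_coverage(tracks[[k]], region), numeric(1)))
  }
  rows <- lapply(list(whole = NULL, ori_window = ori_region), function(region) {
    m <- scope_means(region)
    welch_t_test(m$input, m$ip)
  })
  data.frame(
    replicon = replicon$name,
    scope = c("whole", "ori_window"),
    n_input = length(in_keys), n_ip = length(ip_keys),
    t = vapply(rows, `[[`, numeric(1), "t"),
    df = vapply(rows, `[[`, numeric(1), "df"),
    p = vapply(rows, `[[`, numeric(1), "p"),
    stringsAsFactors = FALSE, row.names = NULL)
}

#' Export a coverage track as bedGraph
#'
#' Runs of equal coverage are collapsed to intervals.
#'
#' @param track a `coverage_track`.
#' @param path output path.
#' @param header optional `#` comment lines.
#' @return `path`, invisibly.
#' @export
write_bedgraph <- function(track, path, header = NULL) {
  v <- track$values
  r <- rle(v)
  ends <- cumsum(r$lengths)
  starts <- c(0, ends[-length(ends)])
  writeLines(if (is.null(header)) character(0) else paste0("#", header),
             path)
  data.table::fwrite(
    data.frame(track$replicon, starts, ends, r$values),
    path, sep = "\t", col.names = FALSE, append = TRUE, scipen = 50)
  invisible(path)
}
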