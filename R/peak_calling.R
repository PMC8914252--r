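# Simplified enrichment peak caller in the MACS2 mold: per-bin extended
# fragment counts from the pooled IP libraries are tested against a local
# Poisson background lambda estimated from the pooled input libraries
# (max over a genome-wide rate and several local window rates), p-values
# are corrected by Benjamini-Hochberg across all bins of all replicons in
# one pass, and significant bins are merged into peaks. This is an
# explicit, documented stand-in for MACS2: no fragment-shift model is
# built (fragments are extended to a fixed size, as with --nomodel), no
# deduplication exists at all (--keep-dup all), and no broad-peak mode.

#' Peak caller configuration
#'
#' @param bin_width genomic bin width w in bp.
#' @param extension fragment extension d in bp.
#' @param local_windows spans (bp) of the local background windows.
#' @param genome_size effective genome size g in bp; `NULL` means the sum
#'   of registered replicon lengths.
#' @param q_threshold emit peaks with BH q-value at or below this (FDR).
#' @param merge_gap merge significant bins separated by at most this many
#'   bp.
#' @param min_peak_len drop merged peaks shorter than this.
#' @return list of class `peak_caller_config`.
#' @export
peak_caller_config <- function(bin_width = 50, extension = 300,
                               local_windows = c(1000, 5000, 10000),
                               genome_size = NULL, q_threshold = 0.001,
                               merge_gap = 100, min_peak_len = 200) {
  stopifnot(bin_width > 0, q_threshold > 0, q_threshold < 1,
            min_peak_len >= bin_width, extension > 0,
            all(local_windows > 0))
  cfg <- as.list(environment())
  class(cfg) <- "peak_caller_config"
  cfg
}

#' Upper-tail Poisson p-value
#'
#' `P(X >= count)` for `X ~ Poisson(lambda)`, computed from the stable
#' distribution-function tail; vectorized.
#'
#' @param count non-negative integer observed count(s).
#' @param lambda positive Poisson mean(s).
#' @return p-value(s) in `(0, 1]`.
#' @export
poisson_pvalue <- function(count, lambda) {
  stopifnot(all(count >= 0))
  if (any(lambda <= 0)) stop_format("lambda must be > 0")
  stats::ppois(count - 1, lambda, lower.tail = FALSE)
}

#' Benjamini-Hochberg q-values
#'
#' Step-up adjusted p-values controlling the FDR, returned in input order.
#'
#' @param p vector of p-values in `[0, 1]`.
#' @return vector of q-values.
#' @export
bh_qvalues <- function(p) {
  if (any(p < 0 | p > 1)) stop_format("p-values must lie in [0, 1]")
  stats::p.adjust(p, method = "BH")
}

# two-lap prefix sums for circular window arithmetic
circ_prefix <- function(values) {
  cumsum(c(0, values, values))
}

# circular window mean from a precomputed two-lap prefix
window_mean_prefix <- function(cs, L, centers, span) {
  span <- min(span, L)
  a <- (centers - span %/% 2) %% L
  (cs[a + span + 1] - cs[a + 1]) / span
}

# circular mean of `values` over windows of length `span` centered at
# each of `centers` (0-based positions)
circular_window_mean <- function(values, centers, span) {
  window_mean_prefix(circ_prefix(values), length(values), centers, span)
}

#' Local Poisson background rate at a position
#'
#' The background for a bin of width w is the maximum of the genome-wide
#' rate and the rates implied by the mean input coverage in each
#' configured local window around `center`, all scaled by `depth_ratio`
#' (IP/input fragment count) and converted from per-base coverage to an
#' expected extended-fragment overlap count for a w-bin via the factor
#' `(w + d) / d`.
#'
#' @param input_track input `coverage_track` for the replicon.
#' @param center 0-based position (bin center).
#' @param cfg a [peak_caller_config()].
#' @param depth_ratio IP/input total fragment-count ratio.
#' @param total_fragments total input fragments genome-wide (defaults to
#'   the track's own count, appropriate for single-replicon use).
#' @return the local lambda (expected fragment count per bin).
#' @export
estimate_lambda <- function(input_track, center, cfg, depth_ratio,
                            total_fragments = input_track$n_fragments) {
  g <- cfg$genome_size %||% length(input_track$values)
  if (g <= 0) stop_format("effective genome size must be > 0")
  w <- cfg$bin_width; d <- cfg$extension
  lam_bg <- depth_ratio * total_fragments * (w + d) / g
  lam_local <- vapply(cfg$local_windows, function(span) {
    depth_ratio * circular_window_mean(input_track$values, center, span) *
      (w + d) / d
  }, numeric(1))
  max(lam_bg, lam_local)
}

# number of extended fragments (start positions fs, fixed length len)
# overlapping each bin of width w tiling [0, L); circular
bin_fragment_counts <- function(fs, len, L, w) {
  nbins <- ceiling(L / w)
  if (length(fs) == 0) return(integer(nbins))
  a <- fs %% L
  b <- a + len
  over <- b > L
  starts <- c(a, rep(0, sum(over)))
  ends <- c(pmin(b, L), b[over] - L)
  first <- starts %/% w
  last <- (ends - 1) %/% w
  inc <- tabulate(first + 1L, nbins = nbins)
  dec <- tabulate(last + 2L, nbins = nbins + 1L)
  cumsum(inc - dec[seq_len(nbins)])
}

# extract 5' fragment start positions (wrapped) from a placement df
fragment_starts <- function(reads, L, extension) {
  uw <- unwrap_vectors(reads$start, reads$end, reads$strand, reads$id, L)
  (ifelse(uw$strand == "+", uw$start, (uw$end %% L) - extension)) %% L
}

#' Call enrichment peaks from pooled IP and input placements
#'
#' Replicates are pooled (the default, matching joint calling of all
#' inputs and all IP samples in one run). Per bin, the IP extended
#' fragment count is tested against the local Poisson background from the
#' input; BH correction runs jointly across all bins of all replicons;
#' bins with `q <= q_threshold` are merged (gap at most `merge_gap` bp,
#' circularly across the seam) and short peaks dropped.
#'
#' @param ip_reads,input_reads placement data.frames (possibly pooled over
#'   replicates).
#' @param replicons a [replicon_set()].
#' @param cfg a [peak_caller_config()].
#' @return data.frame of peaks: `replicon, start, end, summit,
#'   fold_enrichment, p_value, q_value` (end may exceed replicon length
#'   for a seam-wrapped peak).
#' @export
call_peaks <- function(ip_reads, input_reads, replicons,
                       cfg = peak_caller_config()) {
  if (nrow(ip_reads) == 0) stop_format("empty IP read set")
  bad <- setdiff(unique(c(ip_reads$replicon, input_reads$replicon)),
                 replicons$name)
  if (length(bad)) stop_format("reads on unregistered replicon '%s'", bad[1])
  if (is.null(cfg$genome_size)) cfg$genome_size <- sum(replicons$length)
  d <- cfg$extension; w <- cfg$bin_width

  per_rep <- lapply(seq_len(nrow(replicons)), function(i) {
    L <- replicons$length[i]; rn <- replicons$name[i]
    fs_ip <- fragment_starts(ip_reads[ip_reads$replicon == rn, , drop = FALSE],
                             L, d)
    fs_in <- fragment_starts(
      input_reads[input_reads$replicon == rn, , drop = FALSE], L, d)
    list(name = rn, L = L, fs_ip = fs_ip, fs_in = fs_in)
  })
  n_ip <- sum(vapply(per_rep, function(x) length(x$fs_ip), numeric(1)))
  n_in <- sum(vapply(per_rep, function(x) length(x$fs_in), numeric(1)))
  if (n_in == 0) stop_format("empty input read set")
  depth_ratio <- n_ip / n_in
  lam_bg <- depth_ratio * n_in * (w + d) / cfg$genome_size

  tested <- lapply(per_rep, function(x) {
    L <- x$L
    nbins <- ceiling(L / w)
    counts <- bin_fragment_counts(x$fs_ip, d, L, w)
    in_cov <- fragment_coverage(x$fs_in, d, L)
    in_cs <- circ_prefix(in_cov)
    centers <- pmin(seq_len(nbins) * w - w %/% 2, L - 1)
    lam <- rep(lam_bg, nbins)
    for (span in cfg$local_windows) {
      lam <- pmax(lam, depth_ratio *
                    window_mean_prefix(in_cs, L, centers, span) * (w + d) / d)
    }
    list(name = x$name, L = L, nbins = nbins, counts = counts, lam = lam,
         p = poisson_pvalue(counts, lam),
         ip_cov = fragment_coverage(x$fs_ip, d, L), in_cs = in_cs)
  })

  # one multiple-testing universe: all bins of all replicons
  all_p <- unlist(lapply(tested, `[[`, "p"))
  all_q <- bh_qvalues(all_p)
  offs <- cumsum(c(0, vapply(tested, `[[`, numeric(1), "nbins")))

  peaks <- list()
  for (i in seq_along(tested)) {
    x <- tested[[i]]
    q <- all_q[(offs[i] + 1):offs[i + 1]]
    sig <- which(q <= cfg$q_threshold)
    if (length(sig) == 0) next
    bin_start <- (sig - 1) * w
    bin_end <- pmin(sig * w, x$L)
    # merge: gap between consecutive significant bins, then circular join
    gap <- bin_start[-1] - bin_end[-length(bin_end)]
    run_id <- cumsum(c(1, as.integer(gap > cfg$merge_gap)))
    runs <- lapply(split(seq_along(sig), run_id), function(ii) {
      list(start = bin_start[ii[1]], end = bin_end[ii[length(ii)]],
           bins = sig[ii])
    })
    if (length(runs) > 1) {
      seam_gap <- (x$L - runs[[length(runs)]]$end) + runs[[1]]$start
      if (seam_gap <= cfg$merge_gap) {
        lastr <- runs[[length(runs)]]
        runs[[1]] <- list(start = lastr$start,
                          end = x$L + runs[[1]]$end,
                          bins = c(lastr$bins, runs[[1]]$bins))
        runs[[length(runs)]] <- NULL
      }
    } else if (length(runs) == 1 &&
               runs[[1]]$start == 0 && runs[[1]]$end == x$L) {
      # fully significant replicon: keep as one linear peak
    }
    for (r in runs) {
      plen <- r$end - r$start
      if (plen < cfg$min_peak_len) next
      pos <- ((r$start:(r$end - 1)) %% x$L) + 1
      summit <- pos[which.max(x$ip_cov[pos])] - 1
      # per-base background at the summit: genome-wide rate vs local means
      bg_base <- depth_ratio * n_in * d / cfg$genome_size
      for (span in cfg$local_windows) {
        bg_base <- max(bg_base, depth_ratio *
                         window_mean_prefix(x$in_cs, x$L, summit, span))
      }
      best <- r$bins[which.min(x$p[r$bins])]
      peaks[[length(peaks) + 1]] <- data.frame(
        replicon = x$name, start = r$start, end = r$end, summit = summit,
        fold_enrichment = x$ip_cov[summit + 1] / bg_base,
        p_value = x$p[best],
        q_value = all_q[offs[i] + best],
        stringsAsFactors = FALSE)
    }
  }
  if (length(peaks) == 0) {
    return(data.frame(replicon = character(), start = numeric(),
                      end = numeric(), summit = numeric(),
                      fold_enrichment = numeric(), p_value = numeric(),
                      q_value = numeric(), stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, peaks)
  rownames(out) <- NULL
  out
}

#' Write peaks as narrowPeak-style BED6+
#'
#' Seam-wrapped peaks are split into two BED rows sharing a name.
#'
#' @param peaks data.frame from [call_peaks()].
#' @param replicons a [replicon_set()] (for seam splitting).
#' @param path output path.
#' @param header optional `#` comment lines.
#' @return `path`, invisibly.
#' @export
write_peaks <- function(peaks, replicons, path, header = NULL) {
  col_or <- function(name, default) {
    if (name %in% names(peaks) && is.numeric(peaks[[name]]))
      peaks[[name]] else rep(default, nrow(peaks))
  }
  fold <- col_or("fold_enrichment", 0)
  pval <- col_or("p_value", NA_real_)
  qval <- col_or("q_value", NA_real_)
  summit <- col_or("summit", NA_real_)
  rows <- list()
  for (i in seq_len(nrow(peaks))) {
    L <- replicon_row(replicons, peaks$replicon[i])$length
    seg <- split_circular(peaks$start[i], peaks$end[i], L)
    rows[[i]] <- data.frame(
      replicon = peaks$replicon[i], start = seg$start, end = seg$end,
      name = sprintf("peak_%d", i),
      score = round(fold[i] * 10),
      strand = ".",
      p_value = signif(pval[i], 6),
      q_value = signif(qval[i], 6),
      summit = summit[i],
      stringsAsFactors = FALSE)
  }
  df <- if (length(rows)) do.call(rbind, rows) else
    data.frame(replicon = character(), start = numeric(), end = numeric())
  writeLines(if (is.null(header)) character(0) else paste0("#", header),
             path)
  if (nrow(df)) {
    data.table::fwrite(df, path, sep = "\t", col.names = FALSE,
                       append = TRUE, scipen = 50)
  }
  invisible(path)
}

#' Read peaks written by [write_peaks()] (or any BED3+) into peak form
#'
#' Rows sharing a name with one row ending at `L` and one starting at 0
#' are re-joined into a single seam-wrapped peak.
#'
#' @param path BED file path.
#' @param replicons a [replicon_set()].
#' @return data.frame with `replicon, start, end` (+ extra columns when
#'   present).
#' @export
read_peaks <- function(path, replicons) {
  df <- read_bed(path)
  # restore the extra narrowPeak-style columns emitted by write_peaks
  extra <- c(V7 = "p_value", V8 = "q_value", V9 = "summit")
  for (v in names(extra)) {
    if (v %in% names(df)) names(df)[names(df) == v] <- extra[[v]]
  }
  if ("score" %in% names(df) && is.numeric(df$score)) {
    df$fold_enrichment <- df$score / 10
  }
  if (nrow(df) == 0 || !"name" %in% names(df)) {
    df$id <- seq_len(nrow(df))
  } else {
    df$id <- match(df$name, unique(df$name))
  }
  out <- lapply(unique(df$replicon), function(rn) {
    L <- replicon_row(replicons, rn)$length
    unwrap_intervals(df[df$replicon == rn, , drop = FALSE], L)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
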