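# Scan sequencing libraries for the three canonical 25-nt site queries
# (insertion site plus its upstream/downstream controls), normalize per
# million reads, and compare insertion-site occupancy across constructs
# (the depletion signal left by intron insertion during retrohoming).

#' Count reads containing a site query
#'
#' A read counts (at most once per query) when it contains the query or
#' its reverse complement as a substring; exact matching by default, with
#' an optional mismatch tolerance.
#'
#' @param reads character vector of read sequences.
#' @param query query DNA string (e.g. one row of [site_queries()]).
#' @param max_mismatch allowed mismatches (0 = exact substring).
#' @return integer count of matching reads.
#' @export
count_kmer_matches <- function(reads, query, max_mismatch = 0) {
  if (length(reads) == 0) return(0L)
  if (nchar(query) > max(nchar(reads))) {
    stop_format("query length (%d) exceeds read length (%d)",
                nchar(query), max(nchar(reads)))
  }
  rc <- revcomp(query)
  if (max_mismatch == 0) {
    return(sum(grepl(query, reads, fixed = TRUE) |
                 grepl(rc, reads, fixed = TRUE)))
  }
  set <- Biostrings::DNAStringSet(reads)
  fwd <- Biostrings::vcountPattern(query, set, max.mismatch = max_mismatch)
  rev <- Biostrings::vcountPattern(rc, set, max.mismatch = max_mismatch)
  sum(fwd + rev > 0)
}

#' Counts per million normalization
#'
#' @param count raw read count.
#' @param total library size (total reads, > 0).
#' @return `count * 1e6 / total`.
#' @export
normalize_cpm <- function(count, total) {
  if (any(total <= 0)) stop_format("library total must be > 0")
  count * 1e6 / total
}

#' Scan all libraries for the site queries
#'
#' @param libs named list of placement data.frames (see
#'   [generate_reads()]), or of character vectors of read sequences.
#' @param replicons a [replicon_set()] with sequences (needed when `libs`
#'   holds placements).
#' @param queries data.frame `name, sequence` (default [site_queries()]).
#' @param max_mismatch mismatch tolerance passed to
#'   [count_kmer_matches()].
#' @return data.frame with one row per library x query: `construct,
#'   fraction, replicate, query, raw, total, cpm`.
#' @export
scan_libraries <- function(libs, replicons = NULL, queries = site_queries(),
                           max_mismatch = 0) {
  keys <- library_keys()
  rows <- list()
  for (key in names(libs)) {
    lib <- libs[[key]]
    seqs <- if (is.character(lib)) lib else read_sequences(lib, replicons)
    total <- length(seqs)
    ki <- match(key, keys$key)
    meta <- if (is.na(ki)) {
      data.frame(construct = key, fraction = NA_character_,
                 replicate = NA_integer_, stringsAsFactors = FALSE)
    } else {
      keys[ki, c("construct", "fraction", "replicate")]
    }
    for (qi in seq_len(nrow(queries))) {
      raw <- count_kmer_matches(seqs, queries$sequence[qi], max_mismatch)
      rows[[length(rows) + 1]] <- data.frame(
        meta, query = queries$name[qi], raw = raw, total = total,
        cpm = normalize_cpm(raw, total), stringsAsFactors = FALSE,
        row.names = NULL)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Count query occurrences in a genome
#'
#' Genome-level mode of the site scan: occurrences of the query on either
#' strand of each sequence (used e.g. to count planted IS copies).
#'
#' @param seqs named character vector of replicon sequences.
#' @param query query DNA string.
#' @param max_mismatch allowed mismatches.
#' @return total occurrence count across sequences and strands.
#' @export
count_genome_occurrences <- function(seqs, query, max_mismatch = 0) {
  sum(vapply(seqs, function(s) {
    subj <- Biostrings::DNAString(s)
    Biostrings::countPattern(query, subj, max.mismatch = max_mismatch) +
      Biostrings::countPattern(revcomp(query), subj,
                               max.mismatch = max_mismatch)
  }, numeric(1)))
}

#' Compare site occupancy across constructs
#'
#' For every construct x query, the IP/input occupancy ratio of mean
#' normalized counts; plus a Welch test of the per-replicate IP/input CPM
#' ratio at the insertion site between the tagged active-RNP construct
#' and the IEP-only construct (the flanking queries serve as controls).
#' With missing replicates the test degrades to descriptive ratios with a
#' warning.
#'
#' @param scan data.frame from [scan_libraries()].
#' @return list with `ratios` (construct, query, cpm_input, cpm_ip,
#'   ratio) and `depletion_test` (query, t, df, p, ratio_active,
#'   ratio_iep_only) or `NULL` when replicates are missing.
#' @export
compare_site_occupancy <- function(scan) {
  agg <- stats::aggregate(cpm ~ construct + query + fraction, data = scan,
                          FUN = mean)
  wide <- stats::reshape(agg, idvar = c("construct", "query"),
                         timevar = "fraction", direction = "wide")
  names(wide) <- sub("^cpm\\.", "cpm_", names(wide))
  wide$ratio <- ifelse(wide$cpm_input > 0, wide$cpm_IP / wide$cpm_input, NA)
  ratios <- wide[order(wide$construct, wide$query), , drop = FALSE]
  rownames(ratios) <- NULL

  rep_ratio <- function(construct, query) {
    x <- scan[scan$construct == construct & scan$query == query, ,
              drop = FALSE]
    ip <- x$cpm[x$fraction == "IP"][order(x$replicate[x$fraction == "IP"])]
    inp <- x$cpm[x$fraction == "input"][order(x$replicate[x$fraction == "input"])]
    if (length(ip) != length(inp) || length(ip) < 2 || any(inp == 0)) {
      return(NULL)
    }
    ip / inp
  }
  test_rows <- list()
  for (q in unique(scan$query)) {
    ra <- rep_ratio("pKG4_FlagIEP", q)
    rb <- rep_ratio("pKG_FlagIEP", q)
    if (is.null(ra) || is.null(rb)) next
    tt <- welch_t_test(ra, rb)
    test_rows[[q]] <- data.frame(
      query = q, t = tt$t, df = tt$df, p = tt$p,
      ratio_active = mean(ra), ratio_iep_only = mean(rb),
      stringsAsFactors = FALSE)
  }
  if (length(test_rows) == 0) {
    warning("missing replicates: reporting descriptive ratios only")
    return(list(ratios = ratios, depletion_test = NULL))
  }
  list(ratios = ratios,
       depletion_test = do.call(rbind, c(test_rows, make.row.names = FALSE)))
}
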