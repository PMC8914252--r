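# Shared fixture builders. Everything is generated in code; nothing is
# read from stored files.

# one small circular replicon registry
toy_registry <- function(L = 1000, ori = 0, ter = L %/% 2, name = "chr",
                         sequence = NULL) {
  replicon_set(name, L, ori, ter, sequence = sequence)
}

# a placement data.frame from explicit read intervals (auto ids);
# wrapped reads can be given with end > L and are split at the seam
make_reads <- function(replicon, start, end, strand, L) {
  rows <- lapply(seq_along(start), function(i) {
    seg <- rnpchip:::split_circular(start[i], end[i], L)
    data.frame(replicon = replicon, start = seg$start, end = seg$end,
               strand = strand[i], id = i, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

# random unwrapped intervals on a circle (end may exceed L)
random_intervals <- function(n, L, min_len = 50, max_len = 500,
                             replicon = "chr") {
  start <- sample.int(L, n, replace = TRUE) - 1
  len <- sample(min_len:max_len, n, replace = TRUE)
  data.frame(replicon = replicon, start = start, end = start + len,
             stringsAsFactors = FALSE)
}

# independent brute-force circular overlap: do unwrapped intervals a and
# b share at least one bp on a circle of length L?
circ_overlaps_oracle <- function(as, ae, bs, be, L) {
  ((bs - as) %% L) < (ae - as) | ((as - bs) %% L) < (be - bs)
}

# a tiny synthetic config that keeps unit tests fast; ... overrides any
# default, including the ones set here
small_config <- function(...) {
  defaults <- list(
    replicons = data.frame(name = c("chrS", "plasS"),
                           length = c(60000, 30000),
                           ori = c(15000, 7000),
                           ter = c(45000, 22000),
                           stringsAsFactors = FALSE),
    n_true_peaks = 12, n_decoy_peaks = 8, n_is_copies = 5,
    depth_input = 12, depth_ip = 12)
  do.call(synthetic_config, utils::modifyList(defaults, list(...)))
}
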