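test_that("the generator plants exactly the configured number of IS copies", {
  cfg <- small_config(seed = 28)
  g <- generate_genome(cfg)
  seqs <- setNames(g$replicons$sequence, g$replicons$name)
  q <- site_queries()
  expect_equal(count_genome_occurrences(seqs, q$sequence[1]), 5)
  expect_equal(count_genome_occurrences(seqs, q$sequence[2]), 5)
  expect_equal(count_genome_occurrences(seqs, q$sequence[3]), 5)
  expect_equal(nrow(g$truth$is_copies), 5)
  # the insertion-site 25-mer sits exactly at its recorded coordinates
  for (i in seq_len(5)) {
    rr <- g$truth$is_copies[i, ]
    s <- seqs[[rr$replicon]]
    expect_equal(substring(s, rr$site_start + 1, rr$site_end),
                 q$sequence[1])
  }
})

test_that("generation is deterministic under a fixed seed", {
  cfg <- small_config(seed = 29)
  g1 <- generate_genome(cfg)
  g2 <- generate_genome(cfg)
  expect_identical(g1, g2)
  keys <- c("pKG4_FlagIEP.IP.1", "pKGEMA4.input.2")
  expect_identical(generate_reads(g1, cfg, keys = keys),
                   generate_reads(g2, cfg, keys = keys))
  g3 <- generate_genome(small_config(seed = 30))
  expect_false(identical(g1$replicons$sequence, g3$replicons$sequence))
})

test_that("planted genes and peaks respect the basic geometry", {
  cfg <- small_config(seed = 31)
  g <- generate_genome(cfg, make_sequence = FALSE)
  genes <- g$genes
  for (rn in g$replicons$name) {
    gg <- genes[genes$replicon == rn, ]
    gg <- gg[order(gg$start), ]
    expect_true(all(gg$start < gg$end))
    expect_true(all(diff(gg$start) > 0))
    expect_true(all(gg$end[-nrow(gg)] <= gg$start[-1]))  # non-overlapping
    L <- g$replicons$length[g$replicons$name == rn]
    expect_true(all(gg$end <= L))
  }
  pkl <- g$truth$peaks
  expect_true(all(pkl$fork_label %in% c("LAG", "LEAD", "ND")))
  expect_true(all(pkl$host_strand %in% c("+", "-")))
  # host strand really realizes the recorded label
  for (i in seq_len(nrow(pkl))) {
    rr <- g$replicons[g$replicons$name == pkl$replicon[i], ]
    mid <- rnpchip:::circ_midpoint(pkl$start[i], pkl$end[i], rr$length)
    d <- fork_direction(mid, rr)
    if (d == "AMBIGUOUS") next
    lag <- if (d == "CW") "+" else "-"
    expect_equal(pkl$fork_label[i],
                 ifelse(pkl$host_strand[i] == lag, "LAG", "LEAD"))
  }
})

test_that("library depth follows the configured Poisson law", {
  cfg <- synthetic_config(
    replicons = data.frame(name = "c", length = 100000, ori = 20000,
                           ter = 70000, stringsAsFactors = FALSE),
    n_true_peaks = 0, n_decoy_peaks = 0, n_is_copies = 0,
    depth_input = 10, deplete_insertion_site = 0, seed = 32)
  g <- generate_genome(cfg, make_sequence = FALSE)
  lib <- generate_reads(g, cfg, keys = "pKG4_FlagIEP.input.1")[[1]]
  n_frag <- length(unique(lib$id))
  lambda <- 10 * 100000 / 300
  expect_lt(abs(n_frag - lambda), 5 * sqrt(lambda))
})

test_that("uniform fragment starts pass a chi-square uniformity screen", {
  pass <- 0
  for (seed in 1:10) {
    cfg <- synthetic_config(
      replicons = data.frame(name = "c", length = 50000, ori = 10000,
                             ter = 35000, stringsAsFactors = FALSE),
      n_true_peaks = 0, n_decoy_peaks = 0, n_is_copies = 0,
      depth_input = 15, deplete_insertion_site = 0, seed = seed)
    g <- generate_genome(cfg, make_sequence = FALSE)
    lib <- generate_reads(g, cfg, keys = "pKG_FlagIEP.input.1")[[1]]
    uw <- rnpchip:::unwrap_vectors(lib$start, lib$end, lib$strand, lib$id,
                                   50000)
    counts <- tabulate(uw$start %/% 2500 + 1, nbins = 20)
    if (chisq.test(counts)$p.value > 0.01) pass <- pass + 1
  }
  expect_gte(pass, 8)
})

test_that("planted LAG fraction converges to p_lag at n = 1000", {
  cfg <- synthetic_config(n_true_peaks = 1000, n_decoy_peaks = 0,
                          n_is_copies = 0, peak_len_range = c(200, 200),
                          ori_decay_scale = Inf, p_lag = 0.70, seed = 33)
  g <- generate_genome(cfg, make_sequence = FALSE)
  lab <- g$truth$peaks$fork_label
  frac <- mean(lab[lab != "ND"] == "LAG")
  expect_lt(abs(frac - 0.70), 0.05)
})

test_that("IP enrichment raises coverage at planted peaks by the configured fold", {
  cfg <- synthetic_config(
    replicons = data.frame(name = "c", length = 80000, ori = 15000,
                           ter = 55000, stringsAsFactors = FALSE),
    n_true_peaks = 6, n_decoy_peaks = 0, n_is_copies = 0,
    peak_enrichment = 8, depth_input = 30, depth_ip = 30,
    deplete_insertion_site = 0, seed = 34)
  g <- generate_genome(cfg, make_sequence = FALSE)
  libs <- generate_reads(g, cfg,
                         keys = c("pKG4_FlagIEP.IP.1", "pKG4_FlagIEP.input.1"))
  tr_ip <- pileup(libs[["pKG4_FlagIEP.IP.1"]], g$replicons, 300, name = "c")
  tr_in <- pileup(libs[["pKG4_FlagIEP.input.1"]], g$replicons, 300, name = "c")
  pkl <- g$truth$peaks
  fold <- vapply(seq_len(nrow(pkl)), function(i)
    mean_coverage(tr_ip, c(pkl$start[i], pkl$end[i])) /
      mean_coverage(tr_in, c(pkl$start[i], pkl$end[i])), numeric(1))
  expect_true(all(fold > 4))
  expect_lt(abs(mean(fold) - 8), 2)
  # and background stays flat: whole-replicon IP/input ratio is modest
  expect_lt(mean_coverage(tr_ip) / mean_coverage(tr_in), 1.5)
})

test_that("insertion-site depletion halves site-covering IP reads in active constructs", {
  cfg <- synthetic_config(deplete_insertion_site = 0.5, depth_input = 30,
                          depth_ip = 30, seed = 35)
  g <- generate_genome(cfg, make_sequence = FALSE)
  libs <- generate_reads(g, cfg, keys = c(
    "pKG4_FlagIEP.IP.1", "pKG4_FlagIEP.input.1",
    "pKG_FlagIEP.IP.1", "pKG_FlagIEP.input.1"))
  count_cover <- function(lib) {
    tot <- 0
    sites <- g$truth$is_copies
    for (i in seq_len(nrow(sites))) {
      df <- lib[lib$replicon == sites$replicon[i], ]
      tot <- tot + sum(df$start <= sites$site_start[i] &
                         df$end >= sites$site_end[i])
    }
    tot
  }
  # IEP-only construct is untouched; the active construct's IP is halved
  r_active <- count_cover(libs[["pKG4_FlagIEP.IP.1"]]) /
    count_cover(libs[["pKG4_FlagIEP.input.1"]])
  r_ctrl <- count_cover(libs[["pKG_FlagIEP.IP.1"]]) /
    count_cover(libs[["pKG_FlagIEP.input.1"]])
  expect_lt(r_active, 0.75)
  expect_gt(r_ctrl, 0.75)
})

test_that("read sequences honor strand and the circular seam", {
  cfg <- small_config(seed = 36)
  g <- generate_genome(cfg)
  L <- g$replicons$length[1]
  s <- g$replicons$sequence[1]
  reads <- make_reads(g$replicons$name[1],
                      start = c(100, 100, L - 30),
                      end = c(175, 175, L + 45),
                      strand = c("+", "-", "+"), L = L)
  got <- read_sequences(reads, g$replicons)
  fwd <- substring(s, 101, 175)
  expect_equal(got[1], fwd)
  expect_equal(got[2], rnpchip:::revcomp(fwd))
  expect_equal(got[3], paste0(substring(s, L - 29, L), substring(s, 1, 45)))
})

test_that("cumulative GC-skew extremum localizes the planted chromosome ori", {
  cfg <- small_config(seed = 37)
  g <- generate_genome(cfg)
  win <- locate_ori_ter_window()
  rr <- g$replicons[1, ]
  est <- locate_ori_ter(gc_skew(rr$sequence, window = min(win, rr$length %/% 8)))
  expect_lte(circular_distance(est$ori, rr$ori, rr$length),
             min(win, rr$length %/% 8))
})
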