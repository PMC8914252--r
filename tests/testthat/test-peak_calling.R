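test_that("poisson_pvalue matches direct series summation and is monotone", {
  expect_equal(poisson_pvalue(0, 3.7), 1)
  # independent oracle: 1 - sum_{k<10} e^-2 2^k / k!
  series <- 1 - sum(exp(-2) * 2^(0:9) / factorial(0:9))
  expect_equal(poisson_pvalue(10, 2), series, tolerance = 1e-12)
  p <- poisson_pvalue(0:30, 5)
  expect_true(all(diff(p) < 0))
  expect_error(poisson_pvalue(3, 0), "lambda")
})

test_that("bh_qvalues implements the step-up rule", {
  # hand evaluation of the step-up formula for m = 4
  expect_equal(bh_qvalues(c(0.001, 0.01, 0.02, 0.04)),
               c(0.004, 0.02, 4 * 0.02 / 3, 0.04), tolerance = 1e-12)
  expect_equal(bh_qvalues(rep(0.03, 5)), rep(0.03, 5))
  expect_equal(bh_qvalues(0.2), 0.2)
  # order-restoring: shuffled input gives shuffled output
  p <- c(0.04, 0.001, 0.02, 0.01)
  expect_equal(bh_qvalues(p), c(0.04, 0.004, 4 * 0.02 / 3, 0.02))
  expect_error(bh_qvalues(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("estimate_lambda reduces to the scaled background on flat input", {
  L <- 20000
  cfg <- peak_caller_config(genome_size = L)
  flat <- structure(list(replicon = "chr", values = rep(6L, L),
                         n_fragments = 6 * L / cfg$extension),
                    class = "coverage_track")
  for (dr in c(0.5, 1, 2)) {
    lam <- estimate_lambda(flat, center = 4321, cfg, depth_ratio = dr)
    lam_bg <- dr * flat$n_fragments * (cfg$bin_width + cfg$extension) / L
    expect_equal(lam, lam_bg, tolerance = 1e-9)
  }
})

test_that("estimate_lambda is dominated by a local input spike", {
  L <- 50000
  cfg <- peak_caller_config(genome_size = L)
  v <- rep(2L, L)
  v[10000:10400] <- 80L  # spike at the tested center
  spiky <- structure(list(replicon = "chr", values = v,
                          n_fragments = sum(v) / cfg$extension),
                     class = "coverage_track")
  lam <- estimate_lambda(spiky, center = 10200, cfg, depth_ratio = 1)
  lam_1k <- rnpchip:::circular_window_mean(v, 10200, 1000) *
    (cfg$bin_width + cfg$extension) / cfg$extension
  expect_equal(lam, lam_1k, tolerance = 1e-9)
  lam_bg <- spiky$n_fragments * (cfg$bin_width + cfg$extension) / L
  expect_gt(lam, lam_bg)
})

test_that("estimate_lambda equals brute-force re-summation on random tracks", {
  set.seed(12)
  L <- 30000
  cfg <- peak_caller_config(genome_size = L)
  v <- as.integer(rpois(L, 4))
  trk <- structure(list(replicon = "chr", values = v,
                        n_fragments = sum(v) / cfg$extension),
                   class = "coverage_track")
  for (center in sample.int(L, 8) - 1) {
    # oracle: explicit circular index arithmetic, one span at a time
    span_means <- vapply(cfg$local_windows, function(span) {
      idx <- ((center - span %/% 2 + 0:(span - 1)) %% L) + 1
      mean(v[idx])
    }, numeric(1))
    lam_oracle <- max(
      0.8 * trk$n_fragments * (cfg$bin_width + cfg$extension) / L,
      0.8 * span_means * (cfg$bin_width + cfg$extension) / cfg$extension)
    expect_equal(estimate_lambda(trk, center, cfg, depth_ratio = 0.8),
                 lam_oracle, tolerance = 1e-9)
  }
})

test_that("self-comparison of identical IP and input yields no peaks", {
  set.seed(13)
  L <- 40000
  reg <- toy_registry(L = L, ori = 10000, ter = 30000)
  start <- sample.int(L, 3000, replace = TRUE) - 1
  reads <- make_reads("chr", start, start + 75,
                      sample(c("+", "-"), 3000, replace = TRUE), L)
  peaks <- call_peaks(reads, reads, reg, peak_caller_config())
  expect_equal(nrow(peaks), 0)
})

test_that("call_peaks recovers strong planted peaks with clean margins", {
  set.seed(14)
  cfg <- small_config(seed = 14, peak_enrichment = 8,
                      depth_input = 25, depth_ip = 25)
  g <- generate_genome(cfg, make_sequence = FALSE)
  libs <- generate_reads(g, cfg,
                         keys = c("pKG4_FlagIEP.IP.1", "pKG4_FlagIEP.input.1"))
  peaks <- call_peaks(libs[["pKG4_FlagIEP.IP.1"]],
                      libs[["pKG4_FlagIEP.input.1"]],
                      g$replicons, peak_caller_config())
  ev <- evaluate_against_truth(peaks, g$truth$peaks, g$replicons)
  expect_gte(ev$recall, 0.9)
  expect_gte(ev$precision, 0.95)

  # emitted-peak invariants
  expect_true(all(peaks$q_value <= 0.001))
  expect_true(all(peaks$end - peaks$start >= 200))
  for (rn in unique(peaks$replicon)) {
    pk <- peaks[peaks$replicon == rn, ]
    if (nrow(pk) < 2) next
    L <- g$replicons$length[g$replicons$name == rn]
    segs <- rnpchip:::peak_segments(pk, g$replicons)
    ov <- circ_overlaps_oracle(
      rep(segs$start, each = nrow(segs)), rep(segs$end, each = nrow(segs)),
      rep(segs$start, nrow(segs)), rep(segs$end, nrow(segs)), L)
    same <- rep(segs$id, each = nrow(segs)) == rep(segs$id, nrow(segs))
    expect_true(all(!ov[!same]))  # merged peaks are pairwise disjoint
  }
})

test_that("peak calling commutes with a joint circular rotation", {
  set.seed(15)
  L <- 30000
  reg <- toy_registry(L = L, ori = 5000, ter = 20000)
  start_in <- sample.int(L, 2500, replace = TRUE) - 1
  # one strong planted region
  start_pk <- 12000 + sample.int(400, 900, replace = TRUE) - 1
  strands_in <- sample(c("+", "-"), 2500, replace = TRUE)
  strands_pk <- sample(c("+", "-"), 900, replace = TRUE)
  input <- make_reads("chr", start_in, start_in + 75, strands_in, L)
  ip <- make_reads("chr", c(start_in, start_pk), c(start_in, start_pk) + 75,
                   c(strands_in, strands_pk), L)
  cfg <- peak_caller_config()
  p0 <- call_peaks(ip, input, reg, cfg)

  k <- 17650
  rot <- function(df) {
    s <- (df$start + k) %% L
    uw <- rnpchip:::unwrap_vectors(df$start, df$end, df$strand, df$id, L)
    make_reads("chr", (uw$start + k) %% L, (uw$start + k) %% L +
                 (uw$end - uw$start), uw$strand, L)
  }
  p1 <- call_peaks(rot(ip), rot(input), reg, cfg)
  expect_equal(nrow(p1), nrow(p0))
  expect_equal(sort((p0$start + k) %% L), sort(p1$start %% L))
})
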